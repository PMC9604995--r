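test_that("Mendelian expected counts follow the 25/50/25 redistribution", {
  e <- expected_selfed_counts(812, 1770, 798)
  expect_equal(unlist(e, use.names = FALSE), c(1254.5, 885, 1240.5))

  # fully homozygous parent is a fixed point
  expect_equal(unlist(expected_selfed_counts(500, 0, 0), use.names = FALSE),
               c(500, 0, 0))

  # totals conserved exactly, for random count vectors
  withr::with_seed(2, {
    for (i in 1:20) {
      n <- sample.int(3000, 3)
      e <- expected_selfed_counts(n[1], n[2], n[3])
      expect_equal(e$e_AA + e$e_AB + e$e_BB, sum(n))
    }
  })

  # iterated expectation halves the heterozygous class geometrically
  cur <- c(0, 4096, 0)
  for (g in 1:5) {
    cur <- as.numeric(expected_selfed_counts(cur[1], cur[2], cur[3]))
    expect_equal(cur[2], 4096 / 2^g)
  }
  expect_error(expected_selfed_counts(0, 0, 0), "zero genotyped")
})

test_that("homozygosity propagation matches published one-step expectations", {
  expect_equal(round(expected_homozygosity(1610 / 3380, 1), 3), 0.738)
  expect_equal(round(expected_homozygosity(1838 / 3380, 1), 3), 0.772)
  expect_equal(round(expected_homozygosity(2506 / 3380, 1), 3), 0.871)
  expect_equal(round(expected_homozygosity(3274 / 3380, 1), 3), 0.984)
  expect_equal(expected_homozygosity(1, 7), 1)
  h <- expected_homozygosity(0.3, 0:10)
  expect_true(all(diff(h) > 0))
  expect_lt(1 - h[11], 0.001)
  expect_error(expected_homozygosity(1.2, 1), "\\[0, 1\\]")

  # count-level and fraction-level formulations agree
  withr::with_seed(3, for (i in 1:10) {
    n <- sample.int(2000, 3)
    e <- expected_selfed_counts(n[1], n[2], n[3])
    h0 <- (n[1] + n[3]) / sum(n)
    expect_equal((e$e_AA + e$e_BB) / sum(n), expected_homozygosity(h0, 1))
  })
})

test_that("deviation chi-square reproduces published statistics", {
  t1 <- selfing_chisq_test(924, 1542, 914, 812, 1770, 798)
  expect_equal(round(t1$chi2, 2), 660.74)
  expect_equal(t1$df, 2L)
  expect_true(t1$significant)
  expect_equal(t1$direction, "below")  # S1 lagged its Mendelian expectation

  t2 <- selfing_chisq_test(1193, 1044, 1141, 924, 1542, 914)
  expect_equal(round(t2$chi2, 2), 126.36)
  # rescaling the expectation to the offspring total shifts it slightly
  t2r <- selfing_chisq_test(1193, 1044, 1141, 924, 1542, 914, rescale = TRUE)
  expect_equal(round(t2r$chi2, 2), 126.44)

  # observation exactly at expectation
  t0 <- selfing_chisq_test(1254.5, 885, 1240.5, 812, 1770, 798)
  expect_equal(t0$chi2, 0)
  expect_false(t0$significant)
  expect_equal(t0$direction, "at")

  # impossible class under a fully homozygous parent
  tinf <- selfing_chisq_test(99, 1, 0, 100, 0, 0)
  expect_equal(tinf$chi2, Inf)
})

test_that("deviation test rejects at the nominal rate under the null", {
  e <- as.numeric(expected_selfed_counts(812, 1770, 798))
  withr::with_seed(17, {
    obs <- rmultinom(2000, 3380, e / sum(e))
  })
  chi2 <- colSums((obs - e)^2 / e)
  rate <- mean(pchisq(chi2, df = 2, lower.tail = FALSE) <= 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("surrogate parental counts average the siblings class-wise", {
  sibs <- tibble::tibble(n_AA = c(924, 909), n_AB = c(1542, 1536),
                         n_BB = c(914, 934))
  expect_equal(unlist(surrogate_parent_counts(sibs), use.names = FALSE),
               c(916.5, 1539.0, 924.0))
  one <- surrogate_parent_counts(sibs[1, ])
  expect_equal(unlist(one, use.names = FALSE), c(924, 1542, 914))
  same <- surrogate_parent_counts(sibs[c(1, 1, 1), ])
  expect_equal(unlist(same, use.names = FALSE), c(924, 1542, 914))
  expect_error(surrogate_parent_counts(sibs[0, ]), "no sibling")
})

test_that("standardized homozygosity has zero mean, unit sd, published values", {
  famA <- c(2334 / 3378, 2552 / 3369, 2634 / 3380, 2638 / 3378,
            2648 / 3377, 2709 / 3379, 2796 / 3376, 2914 / 3379)
  z <- standardize_homozygosity(famA)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(round(max(z), 3), 1.523)
  expect_equal(round(min(z), 3), -1.879)
  expect_warning(zeq <- standardize_homozygosity(c(0.5, 0.5, 0.5)), "equal")
  expect_true(all(is.na(zeq)))
  expect_error(standardize_homozygosity(0.5), ">= 2")
})

test_that("the full offspring table regression reproduces every printed value", {
  cts <- table1_counts()
  fit <- analyze_selfing(cts, table1_pedigree(),
                         surrogate_overrides = family_c_override)
  off <- tidy(fit)
  chk <- dplyr::inner_join(
    off, cts[c("individual", "obs_hom_printed", "exp_hom_printed",
               "z_printed", "chi2_printed", "sig_printed")],
    by = "individual")
  expect_equal(nrow(chk), 49)
  expect_equal(round(chk$obs_hom, 3), chk$obs_hom_printed)
  has_exp <- !is.na(chk$exp_hom_printed)
  expect_equal(round(chk$exp_hom[has_exp], 3), chk$exp_hom_printed[has_exp])
  has_z <- !is.na(chk$z_printed)
  expect_equal(round(chk$z[has_z], 3), chk$z_printed[has_z])
  has_chi <- !is.na(chk$chi2_printed)
  expect_equal(round(chk$chi2[has_chi], 2), chk$chi2_printed[has_chi])
  # significance calls agree with the published stars at alpha = 0.05
  expect_equal(chk$significant[has_chi], chk$sig_printed[has_chi] == "**")

  # footnote sibling-mean surrogate shifts family C's expectation to 0.772
  fit2 <- analyze_selfing(cts, table1_pedigree())
  offC <- dplyr::filter(tidy(fit2), family == "C")
  expect_equal(round(offC$exp_hom[1], 3), 0.772)
})

test_that("family summaries reproduce the published family table", {
  fit <- analyze_selfing(table1_counts(), table1_pedigree(),
                         surrogate_overrides = family_c_override)
  fam <- glance(fit)
  expect_equal(fam$family, LETTERS[1:6])
  expect_equal(fam$n_offspring, c(8L, 6L, 7L, 9L, 10L, 6L))
  expect_equal(round(fam$expected_mean_hom, 3),
               c(0.772, 0.773, 0.773, 0.745, 0.871, 0.984))
  expect_equal(round(fam$observed_mean_hom, 3),
               c(0.786, 0.753, 0.789, 0.715, 0.868, 0.985))
  expect_equal(round(fam$sd_hom, 3), c(0.050, 0.046, 0.030, 0.055, 0.010, 0.003))
  expect_equal(round(fam$min_hom, 3), c(0.691, 0.704, 0.740, 0.625, 0.849, 0.979))
  expect_equal(round(fam$max_hom, 3), c(0.862, 0.814, 0.818, 0.791, 0.879, 0.988))
  expect_equal(round(fam$rmsd, 3), c(0.049, 0.046, 0.032, 0.060, 0.010, 0.003))
  # family means do not deviate significantly from the Mendelian expectation
  expect_true(all(fam$t_p > 0.05))

  # offspring at exactly the expectation: rmsd and t collapse to zero
  ped <- as_pedigree(tibble::tibble(
    individual = c("P", "K1", "K2"), parent = c(NA, "P", "P"),
    generation = c("S0", "S1", "S1"), family = c(NA, "X", "X")))
  cts0 <- tibble::tibble(individual = c("P", "K1", "K2"),
                         n_AA = c(100, 125, 125), n_AB = c(100, 50, 50),
                         n_BB = c(100, 125, 125))
  fit0 <- analyze_selfing(cts0, ped)
  expect_true(all(is.na(tidy(fit0)$z)))  # sd = 0: z undefined, flagged NA
  fam0 <- glance(fit0)
  expect_equal(fam0$rmsd, 0)
  expect_true(is.na(fam0$t_stat))  # zero variance in the differences
})

test_that("candidate selection is deterministic with lexicographic ties", {
  fit <- analyze_selfing(table1_counts(), table1_pedigree(),
                         surrogate_overrides = family_c_override)
  top <- select_candidates(fit, 1)
  expect_equal(top$individual[top$family == "A"], "TSH-1188_S2_2_4")
  expect_equal(round(top$z[top$family == "A"], 3), 1.523)

  all_b <- select_candidates(fit, 6)
  expect_error(select_candidates(fit, 7), "exceeds")
  b <- dplyr::filter(all_b, family == "B")
  expect_equal(nrow(b), 6)
  expect_true(all(diff(b$z) <= 0))

  # identical offspring tie -> id order breaks it
  ped <- as_pedigree(tibble::tibble(
    individual = c("P", "kidB", "kidA", "kidC"), parent = c(NA, "P", "P", "P"),
    generation = c("S0", "S1", "S1", "S1"), family = c(NA, "X", "X", "X")))
  cts <- tibble::tibble(individual = c("P", "kidB", "kidA", "kidC"),
                        n_AA = c(100, 140, 140, 120), n_AB = c(100, 20, 20, 60),
                        n_BB = c(100, 140, 140, 120))
  fit2 <- analyze_selfing(cts, ped)
  expect_equal(select_candidates(fit2, 2)$individual, c("kidA", "kidB"))
})
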