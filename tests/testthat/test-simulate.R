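test_that("a fixed seed makes every generator byte-identical", {
  expect_identical(simulate_founders(5, 40, seed = 1),
                   simulate_founders(5, 40, seed = 1))
  f <- simulate_founders(1, 60, ids = "P", seed = 2)
  expect_identical(simulate_selfing_offspring(f, "P", 3, seed = 3),
                   simulate_selfing_offspring(f, "P", 3, seed = 3))
  expect_identical(apply_genotyping_noise(f, 0.1, 0.1, seed = 4),
                   apply_genotyping_noise(f, 0.1, 0.1, seed = 4))
  s1 <- simulate_selfing_series(n_founders = 1, offspring_per_family = c(3, 5),
                                n_generations = 2, n_markers = 50, seed = 5)
  s2 <- simulate_selfing_series(n_founders = 1, offspring_per_family = c(3, 5),
                                n_generations = 2, n_markers = 50, seed = 5)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(selfing_trajectory_mc(0.5, 100, 5, 2, reps = 20, seed = 6),
                   selfing_trajectory_mc(0.5, 100, 5, 2, reps = 20, seed = 6))
})

test_that("founder genotypes respect the inbreeding-adjusted proportions", {
  full <- simulate_founders(10, 300, founder_f = 1, seed = 7)
  expect_equal(sum(as.matrix(full[-1]) == "AB"), 0)

  # F = 0 at p = 0.5 gives ~50% heterozygotes
  half <- simulate_founders(30, 400, founder_f = 0, maf_model = "uniform",
                            maf_range = c(0.5, 0.5), seed = 8)
  het <- mean(as.matrix(half[-1]) == "AB")
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / (30 * 400)))

  # cohort-level F recovers the simulated founder inbreeding
  g <- simulate_founders(200, 1000, founder_f = 0.3, seed = 9)
  expect_lt(abs(cohort_summary(g)$f_inbreeding - 0.3), 0.04)

  # default MAF spectrum is skewed toward high MAF like an ascertained panel
  sp <- marker_stats(simulate_founders(400, 2000, founder_f = 0, seed = 10))
  expect_lt(abs(mean(sp$maf) - 1 / 3), 0.02)
  expect_gt(median(sp$maf), 0.3)
  expect_error(simulate_founders(5, 10, founder_f = 1.5), "\\[0, 1\\]")
})

test_that("selfed offspring segregate 1:2:1 at heterozygous loci only", {
  hom <- make_geno(rep(c("AA", "BB"), 50), ids = "P")
  kid <- simulate_selfing_offspring(hom, "P", 2, seed = 11)
  expect_equal(unname(as.matrix(kid[-1])[1, ]), rep(c("AA", "BB"), 50))

  het <- make_geno(c(rep("AB", 2000), NA), ids = "P")
  kids <- simulate_selfing_offspring(het, "P", 6, seed = 12)
  km <- as.matrix(kids[-1])
  expect_true(all(is.na(km[, 2001])))          # missing propagates
  counts <- table(factor(km[, 1:2000], levels = c("AA", "AB", "BB")))
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 1e-4)

  # halving law: mean offspring heterozygous count ~ parent's / 2
  f <- simulate_founders(1, 3000, founder_f = 0, ids = "P", seed = 13)
  nhet_p <- sum(geno_calls(f, "P") == "AB", na.rm = TRUE)
  kk <- simulate_selfing_offspring(f, "P", 40, seed = 14)
  nhet_k <- genotype_counts(kk)$n_AB
  se <- sqrt(nhet_p * 0.25 / 40)
  expect_lt(abs(mean(nhet_k) - nhet_p / 2), 3 * se)
  expect_error(simulate_selfing_offspring(f, "P", 0), ">= 1")
})

test_that("noise rates land at their binomial expectations", {
  g <- simulate_founders(10, 1000, seed = 15)
  expect_equal(apply_genotyping_noise(g, 0, 0, seed = 1)[-1], g[-1],
               ignore_attr = TRUE)

  noisy <- apply_genotyping_noise(g, missing_rate = 0.05, error_rate = 0, seed = 16)
  n_missing <- sum(is.na(as.matrix(noisy[-1])))
  expect_lt(abs(n_missing - 500), 4 * sqrt(10000 * 0.05 * 0.95))

  flipped <- apply_genotyping_noise(g, missing_rate = 0, error_rate = 0.02, seed = 17)
  n_diff <- sum(as.matrix(flipped[-1]) != as.matrix(g[-1]), na.rm = TRUE)
  expect_lt(abs(n_diff - 200), 4 * sqrt(10000 * 0.02 * 0.98))
})

test_that("selfing series emit consistent genotypes, pedigree and truth", {
  sim <- simulate_selfing_series(n_founders = 2, offspring_per_family = c(6, 10),
                                 n_generations = 2, n_markers = 300,
                                 founder_f = 0.3, missing_rate = 0.02,
                                 error_rate = 0, seed = 18)
  expect_setequal(sim$pedigree$individual, sim$genotypes$sample_id)
  expect_equal(sum(sim$pedigree$founder), 2)
  fams <- dplyr::count(dplyr::filter(sim$pedigree, !is.na(family)), family)
  expect_equal(nrow(fams), 4)
  expect_true(all(fams$n >= 6 & fams$n <= 10))

  # noiseless truth shows perfect selfing inheritance
  res <- verify_parentage(sim$truth$genotypes, sim$pedigree, min_compared = 100)
  expect_true(all(res$n_incompatible == 0))

  # the emitted dialects round-trip through the io layer
  gp <- withr::local_tempfile(fileext = ".csv")
  pp <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(sim$genotypes, gp)
  readr::write_csv(sim$pedigree[c("individual", "parent", "generation", "family")],
                   pp, na = "")
  expect_equal(read_genotypes(gp), sim$genotypes)
  expect_equal(nrow(read_pedigree(pp)), nrow(sim$pedigree))
})

test_that("trajectories match the closed form and strategies coincide at size 1", {
  mc <- selfing_trajectory_mc(0.48, 3380, 30, 3, reps = 300, seed = 19)
  rnd <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(mc, strategy == "random"), generation),
    m = mean(hom), se = sd(hom) / sqrt(dplyr::n()), .groups = "drop")
  expect_true(all(abs(rnd$m - expected_homozygosity(0.48, rnd$generation))
                  < 4 * rnd$se))

  # marker-assisted selection dominates random at every generation
  comp <- dplyr::summarise(dplyr::group_by(mc, strategy, generation),
                           m = mean(hom), .groups = "drop")
  comp <- tidyr::pivot_wider(comp, names_from = strategy, values_from = m)
  expect_true(all(comp$max_z > comp$random))

  # a family of one leaves nothing to select on
  one <- simulate_program(0.5, n_markers = 200, family_size = 1,
                          n_generations = 2, strategy = "max_z", seed = 20)
  two <- simulate_program(0.5, n_markers = 200, family_size = 1,
                          n_generations = 2, strategy = "random", seed = 20)
  expect_equal(one$selected_hom, two$selected_hom)

  # a fully homozygous founder stays at 1
  flat <- selfing_trajectory_mc(1, 500, 5, 3, reps = 10, seed = 21)
  expect_true(all(flat$hom == 1))
  flatg <- simulate_program(1, n_markers = 500, family_size = 5,
                            n_generations = 2, seed = 22)
  expect_true(all(flatg$selected_hom == 1))
})

test_that("genotype-level and counts-level simulators agree in distribution", {
  # generation-1 selected homozygosity, max_z, family of 10, h0 = 0.5
  reps <- 40
  gl <- vapply(seq_len(reps), function(i) {
    simulate_program(0.5, n_markers = 1000, family_size = 10,
                     n_generations = 1, strategy = "max_z",
                     seed = 3000 + i)$selected_hom
  }, 1.0)
  mc <- selfing_trajectory_mc(0.5, 1000, 10, 1, reps = 400,
                              strategies = "max_z", seed = 23)
  se <- sqrt(sd(gl)^2 / reps + sd(mc$hom)^2 / nrow(mc))
  expect_lt(abs(mean(gl) - mean(mc$hom)), 4 * se)
})

test_that("simulate_program writes per-generation files when asked", {
  out <- withr::local_tempdir()
  tr <- simulate_program(0.5, n_markers = 100, family_size = 4,
                         n_generations = 2, out_dir = out, seed = 24)
  expect_equal(nrow(tr), 2)
  expect_true(file.exists(file.path(out, "generation_1.csv")))
  expect_true(file.exists(file.path(out, "pedigree.csv")))
  g1 <- read_genotypes(file.path(out, "generation_1.csv"))
  expect_equal(nrow(g1), 4)
  ped <- read_pedigree(file.path(out, "pedigree.csv"))
  expect_equal(sum(ped$founder), 1)
})
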