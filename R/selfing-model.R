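#' Mendelian expected genotypic counts after one selfing generation
#'
#' Under selfing, each heterozygous locus segregates 1:2:1, so from a
#' parent's genotypic counts the offspring expectation is
#' `(n_AA + n_AB/4, n_AB/2, n_BB + n_AB/4)`: both homozygous classes gain a
#' quarter of the parent's heterozygous calls and the heterozygous class
#' halves. Totals are conserved exactly; a fully homozygous parent is a
#' fixed point.
#'
#' @param n_AA,n_AB,n_BB Parent genotypic counts (vectorized).
#' @return Tibble with columns `e_AA`, `e_AB`, `e_BB`.
#' @examples
#' expected_selfed_counts(812, 1770, 798) # 1254.5, 885, 1240.5
#' @export
expected_selfed_counts <- function(n_AA, n_AB, n_BB) {
  total <- n_AA + n_AB + n_BB
  if (any(!is.na(total) & total <= 0)) abort("parent has zero genotyped calls")
  tibble::tibble(e_AA = n_AA + n_AB / 4, e_AB = n_AB / 2, e_BB = n_BB + n_AB / 4)
}

#' Expected homozygosity after g generations of selfing
#'
#' The heterozygous fraction halves each generation, so
#' `h_g = 1 - (1 - h0) / 2^g`: homozygosity gains half the previous
#' generation's heterozygosity, is monotone non-decreasing in `g`, and
#' tends to 1.
#'
#' @param h0 Baseline observed homozygosity in `[0, 1]` (vectorized).
#' @param generations Number of selfing generations (>= 0).
#' @return Expected homozygosity fraction(s).
#' @examples
#' expected_homozygosity(1610 / 3380, 1) # 0.738...
#' @export
expected_homozygosity <- function(h0, generations = 1) {
  if (any(!is.na(h0) & (h0 < 0 | h0 > 1))) abort("`h0` must lie in [0, 1]")
  if (any(generations < 0)) abort("`generations` must be >= 0")
  1 - (1 - h0) / 2^generations
}

#' Chi-square test of a selfed offspring against Mendelian expectation
#'
#' Pearson chi-square (df = 2: three genotypic classes, fully specified
#' null) of an offspring's observed counts against the expected counts
#' derived from its parent with [expected_selfed_counts()]. By default the
#' expectation is *not* rescaled to the offspring's genotyped total, so a
#' call-rate difference between parent and offspring contributes to the
#' statistic; set `rescale = TRUE` to scale the expectation to the
#' offspring total. `direction` reports whether the observed homozygous
#' fraction lies above or below the expected fraction.
#'
#' @param obs_AA,obs_AB,obs_BB Offspring genotypic counts (vectorized).
#' @param par_AA,par_AB,par_BB Parent genotypic counts.
#' @param alpha Significance level (default 0.05).
#' @param rescale Rescale expected counts to the offspring total.
#' @return Tibble with columns `chi2`, `df`, `p`, `direction`
#'   (`"above"`/`"below"`/`"at"`), `significant`. A zero expected class with
#'   nonzero observed count yields `chi2 = Inf` (infinite-deviation flag).
#' @examples
#' selfing_chisq_test(924, 1542, 914, 812, 1770, 798) # chi2 = 660.74
#' @export
selfing_chisq_test <- function(obs_AA, obs_AB, obs_BB, par_AA, par_AB, par_BB,
                               alpha = 0.05, rescale = FALSE) {
  e <- expected_selfed_counts(par_AA, par_AB, par_BB)
  obs_total <- obs_AA + obs_AB + obs_BB
  if (any(!is.na(obs_total) & obs_total <= 0)) abort("offspring has zero genotyped calls")
  if (rescale) {
    k <- obs_total / (e$e_AA + e$e_AB + e$e_BB)
    e <- tibble::tibble(e_AA = e$e_AA * k, e_AB = e$e_AB * k, e_BB = e$e_BB * k)
  }
  term <- function(o, ex) dplyr::case_when(
    ex > 0 ~ (o - ex)^2 / ex,
    ex == 0 & o == 0 ~ 0,
    TRUE ~ Inf)
  chi2 <- term(obs_AA, e$e_AA) + term(obs_AB, e$e_AB) + term(obs_BB, e$e_BB)
  exp_hom <- (e$e_AA + e$e_BB) / (e$e_AA + e$e_AB + e$e_BB)
  obs_hom <- (obs_AA + obs_BB) / obs_total
  tibble::tibble(
    chi2 = chi2, df = 2L, p = pchisq(chi2, df = 2, lower.tail = FALSE),
    direction = dplyr::case_when(obs_hom > exp_hom ~ "above",
                                 obs_hom < exp_hom ~ "below",
                                 TRUE ~ "at"),
    significant = .data$p <= alpha)
}

#' Surrogate parental counts from sibling averages
#'
#' When a selfed parent was not genotyped, the class-wise arithmetic mean of
#' its genotyped siblings' counts stands in for it (siblings share the
#' grandparent, so their Mendelian expectation matches the missing
#' parent's).
#'
#' @param counts Data frame of sibling counts with columns `n_AA`, `n_AB`,
#'   `n_BB` (one row per sibling, >= 1 row).
#' @return One-row tibble with real-valued `n_AA`, `n_AB`, `n_BB`.
#' @export
surrogate_parent_counts <- function(counts) {
  need <- c("n_AA", "n_AB", "n_BB")
  if (!all(need %in% names(counts))) abort("`counts` needs columns n_AA, n_AB, n_BB")
  counts <- counts[stats::complete.cases(counts[need]), need]
  if (nrow(counts) < 1) abort("no sibling counts available for surrogate")
  tibble::as_tibble(as.list(colMeans(counts)))
}

#' Standardize homozygosities within a family
#'
#' `z_i = (h_i - mean(h)) / sd(h)` with the sample (n-1) standard
#' deviation; the ranking statistic for choosing which offspring to advance.
#'
#' @param h Numeric vector of per-offspring observed homozygosities
#'   (>= 2 values).
#' @return Vector of z-scores; all `NA` (with a warning) when the
#'   homozygosities are all equal.
#' @export
standardize_homozygosity <- function(h) {
  if (length(h) < 2) abort("standardization needs >= 2 offspring")
  s <- sd(h)
  if (is.na(s) || s == 0) {
    warn("all offspring homozygosities equal: z undefined")
    return(rep(NA_real_, length(h)))
  }
  (h - mean(h)) / s
}

#' Family-level selfing analysis
#'
#' The core analysis: for every pedigree individual with genotypic counts
#' and a selfed parent, derives the Mendelian expectation from the parent,
#' tests the observed counts against it ([selfing_chisq_test()]), and
#' propagates the parent's homozygosity one generation
#' ([expected_homozygosity()]). Within each family (>= 2 offspring sharing
#' a selfed parent), offspring homozygosities are standardized and ranked,
#' and a family summary is computed: mean, sd, min, max of observed
#' homozygosity at full precision, the expected family mean, the
#' root-mean-square deviation (RMSD, n denominator) of observed from
#' predicted homozygosity, and a one-sample t-test of per-offspring
#' (observed - expected) homozygous-call counts against zero.
#'
#' A parent without counts is replaced by a surrogate: by default the
#' class-wise mean of its genotyped siblings ([surrogate_parent_counts()]).
#' `surrogate_overrides` can pin a specific substitution, e.g.
#' `list("P1" = "SIB2")` (use sibling SIB2's counts alone) or a numeric
#' `c(n_AA, n_AB, n_BB)` vector.
#'
#' @param counts Per-individual counts (columns `individual`, `n_AA`,
#'   `n_AB`, `n_BB`), or a genotype tibble, in which case
#'   [genotype_counts()] is applied first.
#' @param pedigree Pedigree table (see [read_pedigree()]/[as_pedigree()]).
#' @param alpha Significance level for the per-offspring chi-square test.
#' @param surrogate_overrides Named list mapping an ungenotyped parent id to
#'   a sibling id or a counts vector.
#' @param rescale Passed to [selfing_chisq_test()].
#' @return A `selfing_analysis` object; [tidy()] returns the per-offspring
#'   table, [glance()] the per-family summary, [select_candidates()] the
#'   top-ranked offspring per family.
#' @examples
#' counts <- cacao_selfing_counts()
#' ped <- cacao_selfing_pedigree()
#' fit <- analyze_selfing(counts, ped)
#' glance(fit)
#' @export
analyze_selfing <- function(counts, pedigree, alpha = 0.05,
                            surrogate_overrides = NULL, rescale = FALSE) {
  if (!all(c("n_AA", "n_AB", "n_BB") %in% names(counts))) {
    counts <- genotype_counts(counts)
  }
  counts <- tibble::as_tibble(counts)
  if (!"individual" %in% names(counts)) abort("`counts` needs an `individual` column")
  if (anyDuplicated(counts$individual)) abort("duplicate individual in counts")
  if (!"gen_index" %in% names(pedigree)) pedigree <- as_pedigree(pedigree)

  counts <- counts[c("individual", "n_AA", "n_AB", "n_BB")]
  counts$total <- counts$n_AA + counts$n_AB + counts$n_BB
  counts$obs_hom <- ifelse(counts$total > 0,
                           (counts$n_AA + counts$n_BB) / counts$total, NA_real_)
  cts <- function(id) {
    r <- counts[match(id, counts$individual), c("n_AA", "n_AB", "n_BB")]
    if (nrow(r) == 0 || anyNA(r)) NULL else as.numeric(r)
  }

  # resolve parental counts, using surrogates where the parent lacks counts
  resolve_parent <- function(pid) {
    direct <- cts(pid)
    if (!is.null(direct)) return(direct)
    ov <- surrogate_overrides[[pid]]
    if (!is.null(ov)) {
      if (is.character(ov)) {
        v <- cts(ov)
        if (is.null(v)) abort(paste0("surrogate sibling ", ov, " has no counts"))
        return(v)
      }
      if (is.numeric(ov) && length(ov) == 3) return(as.numeric(ov))
      abort("surrogate override must be a sibling id or c(n_AA, n_AB, n_BB)")
    }
    # footnote rule: mean of the parent's genotyped siblings
    prow <- pedigree[match(pid, pedigree$individual), ]
    if (nrow(prow) == 0 || is.na(prow$parent)) return(NULL)
    sibs <- pedigree$individual[!is.na(pedigree$parent) &
                                  pedigree$parent == prow$parent &
                                  pedigree$individual != pid]
    sib_counts <- counts[counts$individual %in% sibs, c("n_AA", "n_AB", "n_BB")]
    sib_counts <- sib_counts[stats::complete.cases(sib_counts), ]
    if (nrow(sib_counts) == 0) return(NULL)
    as.numeric(surrogate_parent_counts(sib_counts))
  }

  off <- pedigree %>%
    dplyr::filter(!.data$founder) %>%
    dplyr::inner_join(counts, by = "individual") %>%
    dplyr::filter(!is.na(.data$n_AA))
  if (nrow(off) == 0) abort("no offspring with genotypic counts and a pedigree parent")

  par_tbl <- purrr::map(unique(off$parent), resolve_parent)
  names(par_tbl) <- unique(off$parent)
  pc <- do.call(rbind, lapply(off$parent, function(p) {
    v <- par_tbl[[p]]
    if (is.null(v)) c(NA_real_, NA_real_, NA_real_) else v
  }))
  unresolved <- unique(off$parent[is.na(pc[, 1])])
  if (length(unresolved) > 0) {
    warn(paste0("no counts or surrogate for parent(s): ",
                paste(unresolved, collapse = ", "), "; tests skipped"))
  }

  parent_hom <- ifelse(rowSums(pc) > 0, (pc[, 1] + pc[, 3]) / rowSums(pc), NA_real_)
  test <- selfing_chisq_test(off$n_AA, off$n_AB, off$n_BB,
                             pc[, 1], pc[, 2], pc[, 3],
                             alpha = alpha, rescale = rescale)
  test[is.na(pc[, 1]), ] <- NA

  offspring <- tibble::tibble(
    individual = off$individual, family = off$family, generation = off$generation,
    parent = off$parent,
    n_AA = off$n_AA, n_AB = off$n_AB, n_BB = off$n_BB,
    total = off$total, obs_hom = off$obs_hom,
    exp_hom = expected_homozygosity(parent_hom, 1)) %>%
    dplyr::bind_cols(test) %>%
    dplyr::group_by(.data$family) %>%
    dplyr::mutate(
      z = if (dplyr::n() >= 2 && !is.na(.data$family[1]))
        suppressWarnings(standardize_homozygosity(.data$obs_hom)) else NA_real_) %>%
    dplyr::arrange(dplyr::desc(.data$z), .data$individual, .by_group = TRUE) %>%
    dplyr::mutate(rank = if (all(is.na(.data$z))) NA_integer_ else
      dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$family, .data$individual)

  families <- offspring %>%
    dplyr::filter(!is.na(.data$family)) %>%
    dplyr::group_by(.data$family) %>%
    dplyr::filter(dplyr::n() >= 2) %>%
    dplyr::summarise(
      parent = .data$parent[1],
      generation = .data$generation[1],
      n_offspring = dplyr::n(),
      expected_mean_hom = .data$exp_hom[1],
      observed_mean_hom = mean(.data$obs_hom),
      sd_hom = sd(.data$obs_hom),
      min_hom = min(.data$obs_hom),
      max_hom = max(.data$obs_hom),
      rmsd = sqrt(mean((.data$obs_hom - .data$exp_hom[1])^2)),
      t_stat = hom_count_t(.data$n_AA + .data$n_BB, .data$total, .data$exp_hom[1])$t,
      t_df = hom_count_t(.data$n_AA + .data$n_BB, .data$total, .data$exp_hom[1])$df,
      t_p = hom_count_t(.data$n_AA + .data$n_BB, .data$total, .data$exp_hom[1])$p,
      .groups = "drop")

  structure(list(offspring = offspring, families = families,
                 alpha = alpha, rescale = rescale),
            class = "selfing_analysis")
}

# one-sample t of per-offspring (observed - expected) homozygous counts vs 0
hom_count_t <- function(obs_hom_counts, totals, exp_frac) {
  d <- obs_hom_counts - exp_frac * totals
  if (length(d) < 2 || is.na(exp_frac) || sd(d) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  }
  tt <- t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Top-ranked offspring for advancement
#'
#' Deterministic selection within each family: order by standardized
#' homozygosity `z` descending, ties broken by individual id ascending,
#' and return the top `k` with their deviation tests.
#'
#' @param x A `selfing_analysis` object.
#' @param k Number of offspring to select per family (must not exceed any
#'   family's size).
#' @return Tibble of selected offspring rows (one block of `k` per family).
#' @export
select_candidates <- function(x, k = 1) {
  stopifnot(inherits(x, "selfing_analysis"))
  fam <- x$offspring %>% dplyr::filter(!is.na(.data$family), !is.na(.data$rank))
  sizes <- fam %>% dplyr::count(.data$family)
  too_small <- sizes$family[sizes$n < k]
  if (length(too_small) > 0) {
    abort(paste0("k = ", k, " exceeds the size of family ",
                 paste(too_small, collapse = ", ")))
  }
  fam %>%
    dplyr::group_by(.data$family) %>%
    dplyr::slice_min(.data$rank, n = k, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$family, .data$rank)
}

#' @export
print.selfing_analysis <- function(x, ...) {
  cat("Selfing homozygosity analysis\n")
  cat("  offspring tested: ", nrow(x$offspring),
      "  families: ", nrow(x$families),
      "  alpha: ", x$alpha, "\n", sep = "")
  sig <- sum(x$offspring$significant, na.rm = TRUE)
  cat("  offspring deviating from Mendelian expectation: ", sig, "\n", sep = "")
  invisible(x)
}

#' @rdname analyze_selfing
#' @param x A `selfing_analysis` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.selfing_analysis <- function(x, ...) x$offspring

#' @rdname analyze_selfing
#' @exportS3Method generics::glance
glance.selfing_analysis <- function(x, ...) x$families

#' Plot observed vs expected homozygosity by family
#'
#' Dot plot of per-offspring observed homozygosity by family with the
#' Mendelian expected family mean as a crossbar.
#'
#' @param object A `selfing_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.selfing_analysis <- function(object, ...) {
  off <- object$offspring %>% dplyr::filter(!is.na(.data$family))
  fam <- object$families
  ggplot2::ggplot(off, ggplot2::aes(x = .data$family, y = .data$obs_hom)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8,
                         ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_errorbar(data = fam,
                           ggplot2::aes(x = .data$family, y = NULL,
                                        ymin = .data$expected_mean_hom,
                                        ymax = .data$expected_mean_hom),
                           width = 0.4, linewidth = 0.7) +
    ggplot2::labs(x = "family", y = "observed homozygosity",
                  colour = "deviates from\nMendelian expectation") +
    ggplot2::theme_minimal()
}
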