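#' Per-sample genotypic counts and observed homozygosity
#'
#' Counts `AA`, `AB`, `BB` and missing calls for each sample and computes
#' the observed homozygosity, the fraction of homozygous calls among that
#' sample's own genotyped (non-missing) calls.
#'
#' @param geno Genotype tibble.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples; unknown ids are an error.
#' @return Tibble with columns `individual`, `n_AA`, `n_AB`, `n_BB`,
#'   `n_missing`, `total` (genotyped calls) and `obs_hom`. `obs_hom` is `NA`
#'   for an all-missing sample.
#' @examples
#' g <- tibble::tibble(sample_id = "s1", m1 = "AA", m2 = "AB", m3 = "BB",
#'                     m4 = "AA", m5 = NA)
#' genotype_counts(g)
#' @export
genotype_counts <- function(geno, samples = NULL) {
  m <- as_geno_matrix(geno)
  if (!is.null(samples)) {
    unknown <- setdiff(samples, rownames(m))
    if (length(unknown) > 0) abort(paste0("unknown sample id: ", unknown[1]))
    m <- m[samples, , drop = FALSE]
  }
  out <- tibble::tibble(
    individual = rownames(m),
    n_AA = unname(rowSums(m == "AA", na.rm = TRUE)),
    n_AB = unname(rowSums(m == "AB", na.rm = TRUE)),
    n_BB = unname(rowSums(m == "BB", na.rm = TRUE)),
    n_missing = unname(rowSums(is.na(m))))
  out$total <- out$n_AA + out$n_AB + out$n_BB
  out$obs_hom <- observed_homozygosity(out$n_AA, out$n_AB, out$n_BB)
  out
}

#' Observed homozygosity from genotypic counts
#'
#' `(n_AA + n_BB) / (n_AA + n_AB + n_BB)`. Vectorized; `NA` with a warning
#' when a total is zero.
#'
#' @param n_AA,n_AB,n_BB Genotypic counts.
#' @return Fraction(s) in `[0, 1]`.
#' @examples
#' observed_homozygosity(812, 1770, 798) # 0.476...
#' @export
observed_homozygosity <- function(n_AA, n_AB, n_BB) {
  total <- n_AA + n_AB + n_BB
  if (any(total == 0, na.rm = TRUE)) warn("sample(s) with zero genotyped calls: homozygosity is NA")
  ifelse(total > 0, (n_AA + n_BB) / total, NA_real_)
}

#' Per-marker allele statistics and Hardy-Weinberg tests
#'
#' For each marker: genotypic counts over samples, minor allele frequency
#' from allele counts, and a Hardy-Weinberg equilibrium chi-square comparing
#' observed genotype counts to `(p^2, 2pq, q^2) * n` with 1 degree of
#' freedom (one estimated allele frequency, three classes; no continuity
#' correction). Markers with fewer than two informative samples, and
#' monomorphic markers, are flagged and not scored; markers with any
#' expected class count below 1 are flagged `small_expected` but still
#' scored.
#'
#' @param geno Genotype tibble.
#' @return Tibble with columns `marker_id`, `n_AA`, `n_AB`, `n_BB`,
#'   `n_missing`, `call_freq`, `maf`, `hwe_chi2`, `hwe_p`, `flag`.
#' @export
marker_stats <- function(geno) {
  m <- as_geno_matrix(geno)
  nAA <- unname(colSums(m == "AA", na.rm = TRUE))
  nAB <- unname(colSums(m == "AB", na.rm = TRUE))
  nBB <- unname(colSums(m == "BB", na.rm = TRUE))
  nmis <- unname(colSums(is.na(m)))
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)

  eAA <- n * p^2; eAB <- n * 2 * p * (1 - p); eBB <- n * (1 - p)^2
  chi2 <- (nAA - eAA)^2 / eAA + (nAB - eAB)^2 / eAB + (nBB - eBB)^2 / eBB

  flag <- rep(NA_character_, length(n))
  flag[n < 2] <- "too_few_samples"
  flag[n >= 2 & (maf == 0 | is.na(maf))] <- "monomorphic"
  scored <- is.na(flag)
  small <- scored & pmin(eAA, eAB, eBB) < 1
  flag[small] <- "small_expected"
  chi2[!scored & !small] <- NA_real_
  chi2[!is.na(flag) & flag %in% c("too_few_samples", "monomorphic")] <- NA_real_

  tibble::tibble(
    marker_id = colnames(m), n_AA = nAA, n_AB = nAB, n_BB = nBB,
    n_missing = nmis, call_freq = (n) / (n + nmis), maf = maf,
    hwe_chi2 = chi2, hwe_p = pchisq(chi2, df = 1, lower.tail = FALSE),
    flag = flag)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 3380)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || any(alpha <= 0)) abort("`alpha` must be positive")
  if (!is.numeric(n_tests) || any(n_tests < 1)) abort("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Cohort-level homozygosity, MAF and inbreeding summary
#'
#' Summarizes a set of samples: mean/sd/median of per-sample observed
#' homozygosity; the mean expected homozygosity under Hardy-Weinberg
#' equilibrium (per-marker `1 - 2pq`, averaged over polymorphic markers);
#' and the inbreeding coefficient `F = 1 - Ho/He` from heterozygosities.
#' Monomorphic markers (and markers with no calls) are excluded from `F`
#' and from the expected-homozygosity average.
#'
#' @param geno Genotype tibble.
#' @param samples Optional sample subset (>= 2 samples).
#' @param f_method How marker heterozygosities enter `F`:
#'   `"ratio_of_means"` (default) uses `1 - mean(Ho_m)/mean(He_m)` over
#'   markers; `"mean_of_ratios"` averages per-marker `1 - Ho_m/He_m`.
#' @param maf_thresholds Thresholds for which the count of markers with
#'   `MAF >= t` is reported.
#' @return One-row tibble with columns `n_samples`, `n_markers`,
#'   `mean_obs_hom`, `sd_obs_hom`, `median_obs_hom`, `mean_exp_hom_hwe`,
#'   `f_inbreeding`, `maf_mean`, `maf_sd`, `maf_median`, and one
#'   `n_maf_ge_<t>` column per threshold.
#' @export
cohort_summary <- function(geno, samples = NULL,
                           f_method = c("ratio_of_means", "mean_of_ratios"),
                           maf_thresholds = c(0.05, 0.25)) {
  f_method <- match.arg(f_method)
  m <- as_geno_matrix(geno)
  if (!is.null(samples)) {
    unknown <- setdiff(samples, rownames(m))
    if (length(unknown) > 0) abort(paste0("unknown sample id: ", unknown[1]))
    m <- m[samples, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("cohort_summary() needs >= 2 samples")

  cts <- genotype_counts(new_geno_tbl(m))
  hom <- cts$obs_hom[!is.na(cts$obs_hom)]

  nAA <- colSums(m == "AA", na.rm = TRUE)
  nAB <- colSums(m == "AB", na.rm = TRUE)
  nBB <- colSums(m == "BB", na.rm = TRUE)
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  poly <- !is.na(maf) & maf > 0
  ho <- ifelse(n > 0, nAB / n, NA_real_)       # per-marker observed het
  he <- 2 * p * (1 - p)                        # per-marker expected het

  f <- if (!any(poly)) NA_real_ else if (f_method == "ratio_of_means") {
    1 - mean(ho[poly]) / mean(he[poly])
  } else {
    mean(1 - ho[poly] / he[poly])
  }

  out <- tibble::tibble(
    n_samples = nrow(m), n_markers = ncol(m),
    mean_obs_hom = mean(hom), sd_obs_hom = sd(hom), median_obs_hom = median(hom),
    mean_exp_hom_hwe = if (any(poly)) mean(1 - he[poly]) else NA_real_,
    f_inbreeding = f,
    maf_mean = mean(maf, na.rm = TRUE), maf_sd = sd(maf, na.rm = TRUE),
    maf_median = median(maf, na.rm = TRUE))
  for (t in maf_thresholds) {
    out[[paste0("n_maf_ge_", format(t))]] <- sum(maf >= t, na.rm = TRUE)
  }
  out
}

#' Minor-allele-frequency spectrum of a panel
#'
#' @param geno Genotype tibble.
#' @param thresholds MAF thresholds to tabulate.
#' @return Tibble with columns `threshold`, `n_markers`, `proportion`.
#' @export
maf_spectrum <- function(geno, thresholds = c(0.01, 0.05, 0.25)) {
  maf <- marker_maf(as_geno_matrix(geno))
  total <- sum(!is.na(maf))
  n_ge <- vapply(thresholds, function(t) sum(maf >= t, na.rm = TRUE), 1L)
  tibble::tibble(threshold = thresholds, n_markers = n_ge, proportion = n_ge / total)
}
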