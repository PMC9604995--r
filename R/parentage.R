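#' Genotype configurations impossible under selfing
#'
#' A selfed offspring can only carry alleles present in its single parent:
#' a homozygous parent call (`AA` or `BB`) is compatible only with the same
#' homozygous offspring call; a heterozygous parent is compatible with
#' everything. Vectorized; `NA` where either call is missing.
#'
#' @param parent,offspring Character vectors of calls (`AA`/`AB`/`BB`/`NA`).
#' @return Logical vector: `TRUE` where the pair is incompatible with
#'   selfing.
#' @examples
#' selfing_incompatible(c("AA", "AA", "AB"), c("AA", "BB", "BB"))
#' @export
selfing_incompatible <- function(parent, offspring) {
  ifelse(is.na(parent) | is.na(offspring), NA,
         (parent == "AA" & offspring != "AA") |
           (parent == "BB" & offspring != "BB"))
}

#' Verify selfed parent-offspring relationships
#'
#' For every pedigree individual whose parent is genotyped, counts loci
#' (non-missing in both) whose genotype configuration is impossible under
#' selfing. True selfed offspring show incompatibilities only through
#' genotyping error; a mislabeled or unrelated individual shows hundreds on
#' a polymorphic panel.
#'
#' @param geno Genotype tibble.
#' @param pedigree Pedigree table; individuals or parents absent from the
#'   genotypes are skipped (parent absent entirely is an error only when no
#'   individual can be checked).
#' @param max_rate Incompatibility rate above which an offspring is
#'   `excluded` (default 0.02, allowing ~1% per-call error in either
#'   member).
#' @param min_compared Minimum comparable loci for a verdict (default 500);
#'   below it the result is `inconclusive`.
#' @return Tibble with columns `individual`, `parent`, `n_compared`,
#'   `n_incompatible`, `incompatibility_rate`, `verdict`
#'   (`confirmed`/`excluded`/`inconclusive`).
#' @export
verify_parentage <- function(geno, pedigree, max_rate = 0.02, min_compared = 500) {
  m <- as_geno_matrix(geno)
  if (!"gen_index" %in% names(pedigree)) pedigree <- as_pedigree(pedigree)
  ped <- pedigree %>%
    dplyr::filter(!.data$founder,
                  .data$individual %in% rownames(m),
                  .data$parent %in% rownames(m))
  if (nrow(ped) == 0) abort("no offspring/parent pair is genotyped")
  purrr::map2_dfr(ped$individual, ped$parent, function(ind, par) {
    bad <- selfing_incompatible(m[par, ], m[ind, ])
    n_cmp <- sum(!is.na(bad))
    n_bad <- sum(bad, na.rm = TRUE)
    rate <- if (n_cmp > 0) n_bad / n_cmp else NA_real_
    tibble::tibble(
      individual = ind, parent = par,
      n_compared = n_cmp, n_incompatible = n_bad, incompatibility_rate = rate,
      verdict = dplyr::case_when(
        n_cmp < min_compared ~ "inconclusive",
        rate > max_rate ~ "excluded",
        TRUE ~ "confirmed"))
  })
}
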