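#' Genotypic counts for six selfed cacao families
#'
#' Published SNP genotypic counts (3,380-SNP Infinium panel) for four cacao
#' founder clones (TSH-1188, PS-13.19, CCN-51, SIAL-169), three genotyped S1
#' plants, and 49 S1/S2 offspring across six selfing families A-F. The S1
#' parent of family C was not genotyped (`NA` counts) and is handled by the
#' sibling-surrogate rule in [analyze_selfing()]. The `*_printed` columns
#' carry the values as originally reported (3 d.p. homozygosities, 2 d.p.
#' chi-squares) and are used for regression testing only.
#'
#' @return Tibble with columns `family`, `generation`, `individual`,
#'   `n_AA`, `n_AB`, `n_BB` and the `*_printed` reference columns.
#' @examples
#' head(cacao_selfing_counts())
#' @export
cacao_selfing_counts <- function() {
  readr::read_csv(system.file("extdata", "cacao_selfing_counts.csv",
                              package = "selfpath"),
                  col_types = readr::cols(
                    family = "c", generation = "c", individual = "c",
                    n_AA = "i", n_AB = "i", n_BB = "i",
                    obs_hom_printed = "d", exp_hom_printed = "d",
                    z_printed = "d", chi2_printed = "d", sig_printed = "c"))
}

#' Pedigree of the six selfed cacao families
#'
#' Companion pedigree to [cacao_selfing_counts()]: four founders, their S1
#' offspring, and the S2 families obtained by selfing three S1 plants of
#' TSH-1188 (families A-C) and one of CCN-51 (family E); families D and F
#' are S1 families of PS-13.19 and SIAL-169.
#'
#' @return A validated pedigree tibble (see [as_pedigree()]).
#' @export
cacao_selfing_pedigree <- function() {
  read_pedigree(system.file("extdata", "cacao_selfing_pedigree.csv",
                            package = "selfpath"))
}
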