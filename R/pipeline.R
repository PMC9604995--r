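#' Run the full selfing-analysis pipeline
#'
#' Orchestrates the stages in a fixed order - read, quality control,
#' per-sample and per-marker statistics, parentage verification, family
#' selfing analysis, genetic distances + UPGMA tree - and writes a report
#' bundle under `out_dir`. Rounding in the human-readable offspring/family
#' reports follows the field's print conventions (homozygosities and z to
#' 3 d.p., chi-square to 2 d.p.); full-precision parallels are written
#' alongside, and every number is reproducible by calling the underlying
#' functions directly. Reports are stable: rerunning on identical inputs
#' rewrites byte-identical CSVs (the timestamp goes only to the log).
#'
#' A counts-only mode (`counts` given instead of `genotypes`) accepts
#' per-individual genotypic count rows directly and skips the call-level
#' stages (QC, marker statistics, parentage, distances).
#'
#' @param genotypes Genotype tibble or path to a genotype file.
#' @param pedigree Pedigree tibble or path.
#' @param out_dir Output directory (created if needed).
#' @param counts Optional per-individual counts table (counts-only mode).
#' @param min_marker_call_freq,min_maf,min_sample_call_rate QC thresholds,
#'   see [qc_genotypes()].
#' @param alpha Significance level for deviation tests.
#' @param max_rate,min_compared Parentage thresholds, see
#'   [verify_parentage()].
#' @param normalize_distance Per-locus normalization of distances.
#' @param surrogate_overrides Passed to [analyze_selfing()].
#' @param distance Compute the distance matrix and UPGMA tree.
#' @return Invisibly, a list with the stage results (`qc_report`,
#'   `sample_stats`, `marker_stats`, `parentage`, `analysis`, `distance`,
#'   `tree`, and `files`, the paths written).
#' @export
run_selfing_pipeline <- function(genotypes = NULL, pedigree, out_dir,
                                 counts = NULL,
                                 min_marker_call_freq = 0.95, min_maf = 0.01,
                                 min_sample_call_rate = 0.87,
                                 alpha = 0.05, max_rate = 0.02, min_compared = 500,
                                 normalize_distance = FALSE,
                                 surrogate_overrides = NULL, distance = TRUE) {
  if (is.null(genotypes) && is.null(counts)) abort("supply `genotypes` or `counts`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("# selfpath pipeline run %s\n", format(Sys.time())), file = log_path)
  logline <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  files <- character(0)
  res <- list()

  stage <- function(name, expr) {
    logline("stage ", name, ": start")
    out <- tryCatch(force(expr), error = function(e) {
      logline("stage ", name, ": FAILED - ", conditionMessage(e))
      readr::write_lines(
        c(paste0("stage: ", name), paste0("error: ", conditionMessage(e))),
        file.path(out_dir, "failure.txt"))
      abort(paste0("pipeline failed at stage `", name, "`: ", conditionMessage(e)))
    })
    logline("stage ", name, ": done")
    out
  }

  ped <- stage("read_pedigree", {
    if (is.character(pedigree)) read_pedigree(pedigree) else as_pedigree(pedigree)
  })

  if (!is.null(genotypes)) {
    geno <- stage("read_genotypes", {
      if (is.character(genotypes)) read_genotypes(genotypes) else {
        as_geno_matrix(genotypes); genotypes
      }
    })
    geno <- stage("qc", qc_genotypes(geno, min_marker_call_freq, min_maf,
                                     min_sample_call_rate))
    res$qc_report <- qc_report(geno)
    p <- file.path(out_dir, "qc_report.tsv")
    readr::write_tsv(res$qc_report, p, progress = FALSE); files <- c(files, p)

    res$sample_stats <- stage("sample_stats", genotype_counts(geno))
    p <- file.path(out_dir, "sample_stats.csv")
    readr::write_csv(res$sample_stats, p, progress = FALSE); files <- c(files, p)

    res$marker_stats <- stage("marker_stats", marker_stats(geno))
    p <- file.path(out_dir, "marker_stats.csv")
    readr::write_csv(res$marker_stats, p, progress = FALSE); files <- c(files, p)

    res$parentage <- stage("parentage",
                           verify_parentage(geno, ped, max_rate, min_compared))
    p <- file.path(out_dir, "parentage.csv")
    readr::write_csv(res$parentage, p, progress = FALSE); files <- c(files, p)
    cts <- res$sample_stats
  } else {
    cts <- tibble::as_tibble(counts)
  }

  res$analysis <- stage("family_analysis",
                        analyze_selfing(cts, ped, alpha = alpha,
                                        surrogate_overrides = surrogate_overrides))
  off <- res$analysis$offspring
  p <- file.path(out_dir, "offspring_full.csv")
  readr::write_csv(off, p, progress = FALSE, na = ""); files <- c(files, p)
  off_print <- off %>% dplyr::mutate(
    obs_hom = round(.data$obs_hom, 3), exp_hom = round(.data$exp_hom, 3),
    z = round(.data$z, 3), chi2 = round(.data$chi2, 2),
    p = signif(.data$p, 3))
  p <- file.path(out_dir, "offspring_report.csv")
  readr::write_csv(off_print, p, progress = FALSE, na = ""); files <- c(files, p)

  fam <- res$analysis$families
  p <- file.path(out_dir, "family_full.csv")
  readr::write_csv(fam, p, progress = FALSE, na = ""); files <- c(files, p)
  fam_print <- fam %>% dplyr::mutate(dplyr::across(
    c("expected_mean_hom", "observed_mean_hom", "sd_hom", "min_hom",
      "max_hom", "rmsd", "t_stat"), ~ round(.x, 3)))
  p <- file.path(out_dir, "family_report.csv")
  readr::write_csv(fam_print, p, progress = FALSE, na = ""); files <- c(files, p)

  if (!is.null(genotypes) && distance) {
    res$distance <- stage("distance",
                          genetic_distance(geno, normalize = normalize_distance))
    p <- file.path(out_dir, "distance.csv")
    write_distance(res$distance, p); files <- c(files, p)
    res$tree <- stage("upgma", upgma(res$distance,
                                     newick = file.path(out_dir, "tree.nwk")))
    files <- c(files, file.path(out_dir, "tree.nwk"))
  }

  logline("pipeline complete: ", length(files), " files")
  res$files <- files
  invisible(res)
}
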