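#' Read an AB-coded SNP genotype matrix
#'
#' Reads a delimited text file with samples in rows and markers in columns
#' (Illumina AB-format calls `AA`, `AB`, `BB`). The first row holds marker
#' ids, the first column sample ids. Tokens in `missing_tokens` become
#' missing calls; any other token is an error, never silently treated as
#' missing.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. Default `NULL` guesses from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param missing_tokens Character vector of tokens read as missing calls.
#' @param transpose If `TRUE` the file stores markers in rows and samples in
#'   columns and is transposed on read.
#' @return A genotype tibble: column `sample_id` followed by one character
#'   column per marker with calls in `AA`/`AB`/`BB` and `NA` for missing.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,m1,m2,m3", "s1,AA,AB,BB", "s2,BB,AB,--"), p)
#' read_genotypes(p)
#' @export
read_genotypes <- function(path, delim = NULL,
                           missing_tokens = c("--", "NC", ""),
                           transpose = FALSE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), trim_ws = TRUE, progress = FALSE,
                           name_repair = "minimal")
  pr <- readr::problems(raw)
  if (nrow(pr) > 0) {
    abort(paste0("malformed genotype file (ragged rows?): ", path,
                 " -- first problem at row ", pr$row[1]))
  }
  if (ncol(raw) < 2 || nrow(raw) < 1) abort("genotype file needs >= 1 sample and >= 1 marker")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  if (transpose) m <- t(m)
  m[m %in% missing_tokens] <- NA_character_
  bad <- setdiff(unique(as.vector(m)), c("AA", "AB", "BB", NA))
  if (length(bad) > 0) {
    abort(paste0("unknown genotype token(s): ", paste(utils::head(bad, 5), collapse = ", "),
                 " -- declare missing tokens explicitly via `missing_tokens`"))
  }
  new_geno_tbl(as_geno_matrix(m))  # validates id uniqueness
}

#' Write a genotype tibble to delimited text
#'
#' Missing calls are always written as `--`; `read_genotypes()` on the
#' output reproduces the input exactly.
#'
#' @param geno Genotype tibble (see [read_genotypes()]).
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, delim = ",") {
  m <- as_geno_matrix(geno)
  m[is.na(m)] <- "--"
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read and validate a selfing pedigree
#'
#' Expects delimited text with columns `individual`, `parent`, `generation`
#' (labels `S0`, `S1`, ...) and `family`. An empty `parent` marks a founder.
#'
#' @param path Path to a CSV/TSV pedigree file.
#' @param genotypes Optional genotype tibble; non-founder parents absent
#'   from both the pedigree and the genotype samples are an error.
#' @return A validated pedigree tibble in topological order (parents before
#'   offspring) with columns `individual`, `parent`, `generation`, `family`,
#'   `gen_index` and `founder`.
#' @export
read_pedigree <- function(path, genotypes = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  ped <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), trim_ws = TRUE, progress = FALSE)
  as_pedigree(ped, genotypes = genotypes)
}

#' Validate an in-memory pedigree table
#'
#' @param ped Data frame with columns `individual`, `parent`, `generation`,
#'   `family` (`parent` `NA` for founders).
#' @param genotypes Optional genotype tibble used to resolve parents that are
#'   genotyped but not listed as pedigree rows.
#' @return A validated pedigree tibble (see [read_pedigree()]).
#' @export
as_pedigree <- function(ped, genotypes = NULL) {
  need <- c("individual", "parent", "generation", "family")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0) abort(paste0("pedigree lacks column(s): ", paste(miss, collapse = ", ")))
  ped <- tibble::as_tibble(ped)[need]
  ped$parent[!is.na(ped$parent) & ped$parent == ""] <- NA_character_
  ped$family[!is.na(ped$family) & ped$family == ""] <- NA_character_
  if (anyDuplicated(ped$individual)) {
    abort(paste0("duplicate pedigree individual: ",
                 ped$individual[duplicated(ped$individual)][1]))
  }
  gi <- suppressWarnings(as.integer(sub("^[Ss]", "", ped$generation)))
  if (anyNA(gi)) abort("generation labels must look like S0, S1, S2, ...")
  ped$gen_index <- gi
  ped$founder <- is.na(ped$parent)

  known <- ped$individual
  if (!is.null(genotypes)) known <- union(known, genotypes$sample_id)
  orphan <- setdiff(ped$parent[!ped$founder], known)
  if (length(orphan) > 0) {
    abort(paste0("parent absent from pedigree and genotypes: ", orphan[1]))
  }

  # topological order (Kahn); failure to place everyone means a cycle
  placed <- character(0)
  remaining <- ped
  out <- ped[0, ]
  while (nrow(remaining) > 0) {
    ready <- remaining$founder | remaining$parent %in% placed |
      !(remaining$parent %in% ped$individual)
    if (!any(ready)) {
      abort(paste0("pedigree cycle involving: ",
                   paste(utils::head(remaining$individual, 3), collapse = ", ")))
    }
    out <- dplyr::bind_rows(out, remaining[ready, ])
    placed <- c(placed, remaining$individual[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }

  # generation consistency for parents listed in the pedigree
  pg <- out$gen_index[match(out$parent, out$individual)]
  bad <- which(!out$founder & !is.na(pg) & out$gen_index != pg + 1L)
  if (length(bad) > 0) {
    abort(paste0("generation of ", out$individual[bad[1]],
                 " is not its parent's generation + 1"))
  }
  out
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the three standard panel filters in a fixed, documented order:
#' (1) drop samples whose call rate (non-missing fraction across all markers
#' present before marker filtering) falls below `min_sample_call_rate`;
#' (2) drop markers whose call frequency among retained samples falls below
#' `min_marker_call_freq`; (3) drop markers whose minor allele frequency,
#' computed on retained samples, falls below `min_maf`. Defaults follow
#' common Infinium-panel practice (call frequency >= 95%, MAF >= 0.01,
#' sample call rate >= 87%). The operation is idempotent.
#'
#' @param geno Genotype tibble.
#' @param min_marker_call_freq Minimum per-marker call frequency.
#' @param min_maf Minimum minor allele frequency.
#' @param min_sample_call_rate Minimum per-sample call rate.
#' @return The filtered genotype tibble with the dropped ids recorded in a
#'   report tibble (columns `id`, `type`, `reason`, `value`) retrievable
#'   with [qc_report()].
#' @export
qc_genotypes <- function(geno, min_marker_call_freq = 0.95, min_maf = 0.01,
                         min_sample_call_rate = 0.87) {
  thr <- c(min_marker_call_freq, min_maf, min_sample_call_rate)
  if (any(!is.finite(thr) | thr < 0 | thr > 1)) abort("QC thresholds must lie in [0, 1]")
  m <- as_geno_matrix(geno)
  rep0 <- tibble::tibble(id = character(), type = character(),
                         reason = character(), value = double())

  call_rate <- rowMeans(!is.na(m))
  drop_s <- call_rate < min_sample_call_rate
  if (any(drop_s)) {
    rep0 <- dplyr::bind_rows(rep0, tibble::tibble(
      id = rownames(m)[drop_s], type = "sample", reason = "low_call_rate",
      value = call_rate[drop_s]))
    m <- m[!drop_s, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("QC removed all samples")

  call_freq <- colMeans(!is.na(m))
  drop_cf <- call_freq < min_marker_call_freq
  if (any(drop_cf)) {
    rep0 <- dplyr::bind_rows(rep0, tibble::tibble(
      id = colnames(m)[drop_cf], type = "marker", reason = "low_call_freq",
      value = call_freq[drop_cf]))
    m <- m[, !drop_cf, drop = FALSE]
  }
  if (ncol(m) == 0) abort("QC removed all markers")

  maf <- marker_maf(m)
  drop_maf <- !is.na(maf) & maf < min_maf
  drop_maf[is.na(maf)] <- TRUE  # markers with no informative calls
  if (any(drop_maf)) {
    rep0 <- dplyr::bind_rows(rep0, tibble::tibble(
      id = colnames(m)[drop_maf], type = "marker", reason = "low_maf",
      value = maf[drop_maf]))
    m <- m[, !drop_maf, drop = FALSE]
  }
  if (ncol(m) == 0) abort("QC removed all markers")

  out <- new_geno_tbl(m)
  attr(out, "qc_report") <- rep0
  out
}

#' Retrieve the QC report attached by [qc_genotypes()]
#'
#' @param geno A genotype tibble returned by [qc_genotypes()].
#' @return Tibble with columns `id`, `type`, `reason`, `value`.
#' @export
qc_report <- function(geno) {
  rep <- attr(geno, "qc_report")
  if (is.null(rep)) abort("no QC report attached; run qc_genotypes() first")
  rep
}

#' Concordance between replicated samples
#'
#' Fraction of matching calls at loci non-missing in both members of each
#' pair; used to confirm genotyping reproducibility (replicated control
#' samples are expected above 99%).
#'
#' @param geno Genotype tibble.
#' @param pairs Two-column data frame (or matrix) of sample-id pairs.
#' @return Tibble with columns `sample_1`, `sample_2`, `n_compared`,
#'   `n_match`, `concordance`.
#' @export
replicate_concordance <- function(geno, pairs) {
  m <- as_geno_matrix(geno)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) abort("`pairs` needs two columns of sample ids")
  purrr::pmap_dfr(list(as.character(pairs[[1]]), as.character(pairs[[2]])),
    function(a, b) {
      for (id in c(a, b)) {
        if (!id %in% rownames(m)) abort(paste0("unknown sample id: ", id))
      }
      ga <- m[a, ]; gb <- m[b, ]
      ok <- !is.na(ga) & !is.na(gb)
      if (!any(ok)) abort(paste0("no comparable loci for pair ", a, " / ", b))
      tibble::tibble(sample_1 = a, sample_2 = b,
                     n_compared = sum(ok), n_match = sum(ga[ok] == gb[ok]),
                     concordance = sum(ga[ok] == gb[ok]) / sum(ok))
    })
}

## ---- internal representation helpers ----

# validate a genotype tibble and return the character call matrix
# (rownames = sample ids, colnames = marker ids)
as_geno_matrix <- function(geno) {
  if (is.matrix(geno)) {
    m <- geno
  } else {
    if (!is.data.frame(geno) || !"sample_id" %in% names(geno)) {
      abort("genotypes must be a tibble with a `sample_id` column (see read_genotypes())")
    }
    m <- as.matrix(geno[setdiff(names(geno), "sample_id")])
    rownames(m) <- as.character(geno$sample_id)
  }
  if (nrow(m) < 1 || ncol(m) < 1) abort("genotype matrix needs >= 1 sample and >= 1 marker")
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate sample id: ", rownames(m)[duplicated(rownames(m))][1]))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate marker id: ", colnames(m)[duplicated(colnames(m))][1]))
  }
  bad <- setdiff(unique(as.vector(m)), c("AA", "AB", "BB", NA))
  if (length(bad) > 0) {
    abort(paste0("invalid genotype call(s): ", paste(utils::head(bad, 5), collapse = ", ")))
  }
  m
}

new_geno_tbl <- function(m) {
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

# B-allele dosage (0 = AA, 1 = AB, 2 = BB), NA for missing
geno_dosage <- function(m) {
  d <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  d[m == "AA"] <- 0; d[m == "AB"] <- 1; d[m == "BB"] <- 2
  d
}

# per-marker minor allele frequency from a call matrix; NA when no calls
marker_maf <- function(m) {
  nAA <- unname(colSums(m == "AA", na.rm = TRUE))
  nAB <- unname(colSums(m == "AB", na.rm = TRUE))
  nBB <- unname(colSums(m == "BB", na.rm = TRUE))
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)  # A-allele frequency
  pmin(p, 1 - p)
}
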