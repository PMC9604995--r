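#' Smouse-Peakall codominant distance between two genotype rows
#'
#' Per-locus squared genotypic distance: 0 for identical genotypes, 1
#' between a homozygote and a heterozygote sharing an allele, 4 between
#' opposite homozygotes (so an `AA x BB` configuration, which guarantees a
#' heterozygous F1, weighs four times an `AA x AB` one). Loci missing in
#' either sample are dropped from numerator and denominator (per-pair
#' deletion). Equivalent to the squared difference in B-allele dosage.
#'
#' @param g1,g2 Character vectors of calls (equal length) or sample ids
#'   when `geno` is given.
#' @param geno Optional genotype tibble from which `g1`/`g2` rows are taken.
#' @param normalize Divide by the number of comparable loci (per-locus
#'   average instead of a sum).
#' @return One-row tibble with `distance` and `n_loci`.
#' @examples
#' pair_distance(c("AA", "AA"), c("BB", "AB")) # 4 + 1 = 5 over 2 loci
#' @export
pair_distance <- function(g1, g2, geno = NULL, normalize = FALSE) {
  if (!is.null(geno)) {
    m <- as_geno_matrix(geno)
    for (id in c(g1, g2)) if (!id %in% rownames(m)) abort(paste0("unknown sample id: ", id))
    g1 <- m[g1, ]; g2 <- m[g2, ]
  }
  if (length(g1) != length(g2)) abort("genotype rows differ in length")
  d1 <- call_dosage(g1); d2 <- call_dosage(g2)
  ok <- !is.na(d1) & !is.na(d2)
  if (!any(ok)) abort("no comparable loci for the pair")
  d <- sum((d1[ok] - d2[ok])^2)
  tibble::tibble(distance = if (normalize) d / sum(ok) else d, n_loci = sum(ok))
}

call_dosage <- function(g) {
  d <- rep(NA_real_, length(g))
  d[g == "AA"] <- 0; d[g == "AB"] <- 1; d[g == "BB"] <- 2
  bad <- !is.na(g) & is.na(d)
  if (any(bad)) abort(paste0("invalid genotype call: ", g[bad][1]))
  d
}

#' Pairwise Smouse-Peakall distance matrix
#'
#' All-pairs codominant genotypic distances with per-pair deletion of
#' missing loci. Symmetric with a zero diagonal; the per-pair comparable
#' locus count is kept alongside. Pairs with zero comparable loci get `NA`
#' and a warning.
#'
#' @param geno Genotype tibble.
#' @param samples Optional subset of sample ids (>= 2).
#' @param normalize Per-locus average instead of a sum over loci.
#' @return A `genetic_dist` object; use `as.matrix()`, `as.dist()`,
#'   [tidy()] (long pair table) or [upgma()].
#' @export
genetic_distance <- function(geno, samples = NULL, normalize = FALSE) {
  m <- as_geno_matrix(geno)
  if (!is.null(samples)) {
    unknown <- setdiff(samples, rownames(m))
    if (length(unknown) > 0) abort(paste0("unknown sample id: ", unknown[1]))
    m <- m[samples, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("distance matrix needs >= 2 samples")
  x <- geno_dosage(m)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  s <- x0^2
  mm <- obs * 1
  # sum over loci present in both: x_i^2 + x_j^2 - 2 x_i x_j
  d <- s %*% t(mm) + mm %*% t(s) - 2 * (x0 %*% t(x0))
  n_loci <- mm %*% t(mm)
  if (any(n_loci[upper.tri(n_loci)] == 0)) {
    warn("pair(s) with zero comparable loci: distance set to NA")
    d[n_loci == 0] <- NA_real_
  }
  if (normalize) d <- d / n_loci
  diag(d) <- 0
  d <- (d + t(d)) / 2  # exact symmetry against floating-point drift
  structure(list(d = d, n_loci = n_loci, normalized = normalize),
            class = "genetic_dist")
}

#' @export
as.matrix.genetic_dist <- function(x, ...) x$d

#' @export
as.dist.genetic_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' @export
print.genetic_dist <- function(x, ...) {
  cat("Smouse-Peakall genotypic distance matrix: ", nrow(x$d), " samples",
      if (x$normalized) " (per-locus normalized)", "\n", sep = "")
  print(utils::head(round(x$d, 3), 6))
  invisible(x)
}

#' @rdname genetic_distance
#' @param x A `genetic_dist` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.genetic_dist <- function(x, ...) {
  ids <- rownames(x$d)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(sample_1 = ids[idx[, 1]], sample_2 = ids[idx[, 2]],
                 distance = x$d[idx], n_loci = x$n_loci[idx]) %>%
    dplyr::arrange(.data$sample_1, .data$sample_2)
}

#' Write a distance matrix to CSV or PHYLIP format
#'
#' @param x A `genetic_dist` object (or square matrix).
#' @param path Output path.
#' @param format `"csv"` (square, with ids) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance <- function(x, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  d <- as.matrix(x)
  if (format == "csv") {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(d)),
                            tibble::as_tibble(d))
    readr::write_csv(out, path, progress = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    writeLines(paste0(formatC(rownames(d), width = -10),
                      apply(d, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))),
               con)
  }
  invisible(path)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering producing an ultrametric tree
#' (node height = half the merge distance, so cophenetic distances
#' reproduce average-linkage merge distances). Input rows are sorted by id
#' first so the output, including its Newick text, is reproducible
#' regardless of input order.
#'
#' @param dist A `genetic_dist` object, `dist`, or square symmetric matrix.
#' @param newick Optional path; when given, the tree is also written as
#'   Newick text.
#' @return An [ape::phylo] ultrametric tree.
#' @export
upgma <- function(dist, newick = NULL) {
  d <- if (inherits(dist, "genetic_dist")) dist$d
       else if (inherits(dist, "dist")) as.matrix(dist)
       else as.matrix(dist)
  if (any(!is.finite(d))) abort("non-finite distances: cannot build UPGMA tree")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  # as.phylo halves cophenetic heights already (edge lengths from $height/2)
  if (!is.null(newick)) ape::write.tree(tree, file = newick)
  tree
}

#' Expected F1 heterozygosity between candidate parents
#'
#' Per-locus probability that the F1 of a cross is heterozygous: 1 for
#' opposite homozygotes (`AA x BB`), 0 for identical homozygotes, 0.5
#' whenever either parent is heterozygous; averaged over loci comparable in
#' both parents. A proxy for the heterosis potential of a cross: for fully
#' homozygous parents it equals the per-locus Smouse-Peakall distance
#' divided by 4.
#'
#' @param geno Genotype tibble.
#' @param pairs Optional two-column data frame of sample-id pairs; default
#'   all pairs.
#' @return Tibble with columns `sample_1`, `sample_2`, `n_loci`, `f1_het`.
#' @export
expected_f1_heterozygosity <- function(geno, pairs = NULL) {
  m <- as_geno_matrix(geno)
  if (is.null(pairs)) {
    ids <- rownames(m)
    if (length(ids) < 2) abort("need >= 2 samples")
    idx <- utils::combn(ids, 2)
    pairs <- data.frame(sample_1 = idx[1, ], sample_2 = idx[2, ])
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  purrr::map2_dfr(as.character(pairs[[1]]), as.character(pairs[[2]]),
    function(a, b) {
      for (id in c(a, b)) if (!id %in% rownames(m)) abort(paste0("unknown sample id: ", id))
      g1 <- m[a, ]; g2 <- m[b, ]
      ok <- !is.na(g1) & !is.na(g2)
      if (!any(ok)) abort(paste0("no comparable loci for pair ", a, " / ", b))
      het <- ifelse(g1[ok] == "AB" | g2[ok] == "AB", 0.5,
                    ifelse(g1[ok] == g2[ok], 0, 1))
      tibble::tibble(sample_1 = a, sample_2 = b, n_loci = sum(ok),
                     f1_het = mean(het))
    })
}
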