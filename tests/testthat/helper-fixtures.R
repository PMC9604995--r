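# Shared fixtures and independent oracles, built in code.

# genotype tibble from a character matrix given as row vectors
make_geno <- function(..., ids = NULL, markers = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- ids %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- markers %||% paste0("m", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_geno <- function(n_samples, n_markers, missing_rate = 0.05, seed = 1) {
  withr::with_seed(seed, {
    calls <- sample(c("AA", "AB", "BB"), n_samples * n_markers, replace = TRUE)
    calls[runif(length(calls)) < missing_rate] <- NA
    m <- matrix(calls, n_samples, n_markers,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("m%03d", seq_len(n_markers))))
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), tibble::as_tibble(m))
  })
}

geno_calls <- function(geno, id) {
  m <- as.matrix(geno[setdiff(names(geno), "sample_id")])
  rownames(m) <- geno$sample_id
  m[id, ]
}

# brute-force Smouse-Peakall distance: explicit per-locus lookup table
sp_oracle <- function(g1, g2) {
  tab <- c("AA.AA" = 0, "AB.AB" = 0, "BB.BB" = 0,
           "AA.AB" = 1, "AB.AA" = 1, "BB.AB" = 1, "AB.BB" = 1,
           "AA.BB" = 4, "BB.AA" = 4)
  ok <- !is.na(g1) & !is.na(g2)
  sum(tab[paste(g1[ok], g2[ok], sep = ".")])
}

# naive UPGMA: average over original distances between cluster members,
# always merging the current closest pair; returns the cophenetic matrix
upgma_oracle_cophenetic <- function(d) {
  ids <- rownames(d)
  clusters <- as.list(ids)
  coph <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
  diag(coph) <- 0
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best_d) { best_d <- avg; best <- c(j, i) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

table1_counts <- function() cacao_selfing_counts()
table1_pedigree <- function() cacao_selfing_pedigree()

# the single-sibling surrogate that reproduces the printed family-C values
family_c_override <- list("TSH-1188_S1_1" = "TSH-1188_S1_3")
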