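#' Simulate founder genotypes with a tunable inbreeding level
#'
#' Draws per-marker allele frequencies from a MAF model and genotypes from
#' inbreeding-adjusted proportions `(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)`. The
#' default `"beta"` model draws the MAF as `0.5 * Beta(4, 2)` (mean ~0.33,
#' median ~0.34) and assigns the minor allele to A or B at random, giving a
#' site-frequency spectrum skewed toward high MAF, the shape typical of
#' Infinium panels ascertained for informativeness. The `"uniform"` model
#' draws the MAF uniformly over `maf_range` (useful for null calibration).
#'
#' @param n_samples,n_markers Dimensions of the simulated cohort.
#' @param founder_f Inbreeding coefficient in `[0, 1]` of the founders.
#' @param maf_model `"beta"` or `"uniform"`.
#' @param maf_range MAF bounds for the uniform model.
#' @param ids,marker_ids Optional identifier vectors.
#' @param seed Optional integer seed; with a fixed seed the output is
#'   reproducible byte for byte.
#' @return Genotype tibble with the true A-allele frequencies attached as
#'   attribute `"allele_freq"`.
#' @export
simulate_founders <- function(n_samples, n_markers, founder_f = 0,
                              maf_model = c("beta", "uniform"),
                              maf_range = c(0.05, 0.5),
                              ids = NULL, marker_ids = NULL, seed = NULL) {
  maf_model <- match.arg(maf_model)
  if (founder_f < 0 || founder_f > 1) abort("`founder_f` must lie in [0, 1]")
  run <- function() {
    maf <- if (maf_model == "beta") {
      0.5 * rbeta(n_markers, 4, 2)
    } else {
      runif(n_markers, maf_range[1], maf_range[2])
    }
    p <- ifelse(runif(n_markers) < 0.5, maf, 1 - maf)
    q <- 1 - p
    pAA <- p^2 + founder_f * p * q
    pAB <- 2 * p * q * (1 - founder_f)
    u <- matrix(runif(n_samples * n_markers), n_samples, n_markers)
    thr1 <- matrix(pAA, n_samples, n_markers, byrow = TRUE)
    thr2 <- matrix(pAA + pAB, n_samples, n_markers, byrow = TRUE)
    g <- matrix("BB", n_samples, n_markers)
    g[u < thr2] <- "AB"
    g[u < thr1] <- "AA"
    rownames(g) <- ids %||% sprintf("F%03d", seq_len(n_samples))
    colnames(g) <- marker_ids %||% sprintf("M%05d", seq_len(n_markers))
    out <- new_geno_tbl(g)
    attr(out, "allele_freq") <- p
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate selfed offspring of a genotyped parent
#'
#' Per locus: a homozygous parent call is copied; a heterozygous call
#' segregates 1:2:1 (`AA`:`AB`:`BB`) independently across loci (free
#' recombination); a missing call stays missing.
#'
#' @param geno Genotype tibble containing the parent.
#' @param parent Parent sample id.
#' @param n Number of offspring (>= 1).
#' @param ids Optional offspring ids (default `<parent>_S_1 ...`).
#' @param seed Optional integer seed.
#' @return Genotype tibble of the `n` offspring.
#' @export
simulate_selfing_offspring <- function(geno, parent, n, ids = NULL, seed = NULL) {
  if (n < 1) abort("`n` must be >= 1")
  m <- as_geno_matrix(geno)
  if (!parent %in% rownames(m)) abort(paste0("unknown sample id: ", parent))
  pg <- m[parent, ]
  run <- function() {
    off <- matrix(rep(pg, each = n), n, length(pg))
    het <- which(pg == "AB")
    if (length(het) > 0) {
      u <- matrix(runif(n * length(het)), n, length(het))
      seg <- matrix("AB", n, length(het))
      seg[u < 0.25] <- "AA"
      seg[u >= 0.75] <- "BB"
      off[, het] <- seg
    }
    rownames(off) <- ids %||% sprintf("%s_S_%d", parent, seq_len(n))
    colnames(off) <- colnames(m)
    new_geno_tbl(off)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Add genotyping noise to a genotype matrix
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving call is replaced by one of the two other genotype classes
#' (uniformly) with probability `error_rate`.
#'
#' @param geno Genotype tibble.
#' @param missing_rate,error_rate Per-call probabilities in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Genotype tibble of the same shape.
#' @export
apply_genotyping_noise <- function(geno, missing_rate = 0, error_rate = 0, seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1) {
    abort("rates must lie in [0, 1]")
  }
  m <- as_geno_matrix(geno)
  run <- function() {
    classes <- c("AA", "AB", "BB")
    drop <- matrix(runif(length(m)) < missing_rate, nrow(m))
    err <- matrix(runif(length(m)) < error_rate, nrow(m))
    pick <- matrix(runif(length(m)), nrow(m))
    flip <- !is.na(m) & !drop & err
    if (any(flip)) {
      cur <- m[flip]
      alt1 <- ifelse(cur == "AA", "AB", "AA")
      alt2 <- ifelse(cur == "BB", "AB", "BB")
      m[flip] <- ifelse(pick[flip] < 0.5, alt1, alt2)
    }
    m[drop] <- NA_character_
    new_geno_tbl(m)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a multi-generation selfing series with bookkeeping
#'
#' Generates founders, then for each founder a chain of selfing families
#' (one family per generation, the advanced parent chosen per `advance`),
#' applies genotyping noise last, and returns the genotype matrix, the
#' pedigree, and the noiseless truth so every downstream module can be
#' tested against known ground truth.
#'
#' @param n_founders Number of independent founder clones.
#' @param offspring_per_family Family size, a single number or a
#'   `c(lo, hi)` range sampled per family (the study's families had 6-10).
#' @param n_generations Selfing generations (1-3 in the emulated design).
#' @param n_markers,founder_f,maf_model Passed to [simulate_founders()].
#' @param missing_rate,error_rate Passed to [apply_genotyping_noise()].
#' @param advance `"first"` (deterministic), `"random"`, or `"max_hom"` -
#'   how the individual selfed to produce the next generation is chosen.
#' @param seed Optional integer seed; fixes every draw in the series.
#' @return List with elements `genotypes` (noisy calls, all individuals),
#'   `pedigree` (validated tibble), and `truth` (list: `genotypes` before
#'   noise, `allele_freq`).
#' @export
simulate_selfing_series <- function(n_founders = 2, offspring_per_family = c(6, 10),
                                    n_generations = 2, n_markers = 500,
                                    founder_f = 0.3, maf_model = "beta",
                                    missing_rate = 0.02, error_rate = 0.005,
                                    advance = c("first", "random", "max_hom"),
                                    seed = NULL) {
  advance <- match.arg(advance)
  if (n_generations < 1) abort("`n_generations` must be >= 1")
  run <- function() {
    founders <- simulate_founders(n_founders, n_markers, founder_f = founder_f,
                                  maf_model = maf_model,
                                  ids = sprintf("C%02d", seq_len(n_founders)))
    geno <- founders
    ped <- tibble::tibble(individual = founders$sample_id,
                          parent = NA_character_, generation = "S0",
                          family = NA_character_)
    fam_i <- 0
    for (f in founders$sample_id) {
      parent <- f
      for (g in seq_len(n_generations)) {
        fam_i <- fam_i + 1
        fam_id <- sprintf("FAM%02d", fam_i)
        k <- if (length(offspring_per_family) > 1) {
          sample(seq(offspring_per_family[1], offspring_per_family[2]), 1)
        } else offspring_per_family
        kids <- simulate_selfing_offspring(
          geno, parent, k, ids = sprintf("%s_S%d_%d", f, g, seq_len(k)))
        geno <- dplyr::bind_rows(geno, kids)
        ped <- dplyr::bind_rows(ped, tibble::tibble(
          individual = kids$sample_id, parent = parent,
          generation = paste0("S", g), family = fam_id))
        hom <- genotype_counts(kids)$obs_hom
        parent <- switch(advance,
                         first = kids$sample_id[1],
                         random = sample(kids$sample_id, 1),
                         max_hom = kids$sample_id[order(-hom, kids$sample_id)][1])
      }
    }
    truth <- geno
    noisy <- apply_genotyping_noise(geno, missing_rate, error_rate)
    list(genotypes = noisy, pedigree = as_pedigree(ped),
         truth = list(genotypes = truth,
                      allele_freq = attr(founders, "allele_freq")))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one marker-assisted (or random) advancement program
#'
#' Genotype-level forward simulation of the proposed breeding scheme: each
#' generation the current parent is selfed into a family, the advancing
#' individual is the family's most homozygous offspring (`"max_z"`) or a
#' random one (`"random"`), and the trajectory of family mean/max and
#' selected homozygosity is recorded. Optionally writes each generation's
#' genotype matrix and the pedigree in the package's standard file
#' dialects.
#'
#' @param founder_hom Founder observed homozygosity; the founder is built
#'   deterministically with this exact homozygous fraction. Ignored when
#'   `founder` is given.
#' @param founder Optional one-sample genotype tibble to start from.
#' @param n_markers Number of markers for the constructed founder.
#' @param family_size Offspring genotyped per generation.
#' @param n_generations Number of selfing generations (>= 1).
#' @param strategy `"max_z"` or `"random"` advancement.
#' @param out_dir Optional directory for per-generation genotype files and
#'   the pedigree.
#' @param seed Optional integer seed.
#' @return Trajectory tibble: `generation`, `family_size`, `mean_hom`,
#'   `max_hom`, `selected`, `selected_hom`.
#' @export
simulate_program <- function(founder_hom = 0.48, founder = NULL, n_markers = 3380,
                             family_size = 30, n_generations = 3,
                             strategy = c("max_z", "random"),
                             out_dir = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  if (n_generations < 1) abort("`n_generations` must be >= 1")
  run <- function() {
    if (is.null(founder)) {
      n_het <- round((1 - founder_hom) * n_markers)
      n_hom <- n_markers - n_het
      calls <- c(rep("AA", ceiling(n_hom / 2)), rep("AB", n_het),
                 rep("BB", floor(n_hom / 2)))
      g <- matrix(calls, 1, n_markers,
                  dimnames = list("P0", sprintf("M%05d", seq_len(n_markers))))
      founder <- new_geno_tbl(g)
    }
    geno <- founder
    parent <- founder$sample_id[1]
    ped <- tibble::tibble(individual = parent, parent = NA_character_,
                          generation = "S0", family = NA_character_)
    traj <- list()
    for (g in seq_len(n_generations)) {
      kids <- simulate_selfing_offspring(
        geno, parent, family_size,
        ids = sprintf("G%d_%02d", g, seq_len(family_size)))
      hom <- genotype_counts(kids)$obs_hom
      sel <- switch(strategy,
                    max_z = kids$sample_id[order(-hom, kids$sample_id)][1],
                    random = if (family_size == 1) kids$sample_id[1]
                             else sample(kids$sample_id, 1))
      traj[[g]] <- tibble::tibble(
        generation = g, family_size = family_size,
        mean_hom = mean(hom), max_hom = max(hom),
        selected = sel, selected_hom = hom[match(sel, kids$sample_id)])
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        individual = kids$sample_id, parent = parent,
        generation = paste0("S", g), family = sprintf("FAM%d", g)))
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_genotypes(kids, file.path(out_dir, sprintf("generation_%d.csv", g)))
      }
      geno <- dplyr::bind_rows(geno, kids)
      parent <- sel
    }
    if (!is.null(out_dir)) {
      readr::write_csv(ped, file.path(out_dir, "pedigree.csv"), na = "",
                       progress = FALSE)
    }
    dplyr::bind_rows(traj)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Monte-Carlo homozygosity trajectories under selfing with selection
#'
#' Counts-level replicate simulator for comparing advancement strategies.
#' Because loci are unlinked, an offspring's heterozygous-call count is
#' Binomial(parent heterozygous count, 1/2) and ranking offspring by
#' homozygosity is ranking by that count alone, so the full genotype matrix
#' is not needed; the trajectory distribution matches [simulate_program()]
#' exactly (asserted in the test suite). Both strategies are run within
#' each replicate so replicates pair across strategies.
#'
#' @param h0 Founder observed homozygosity.
#' @param n_markers Panel size.
#' @param family_size Offspring per generation.
#' @param n_generations Selfing generations.
#' @param reps Number of replicates.
#' @param strategies Subset of `c("max_z", "random")`.
#' @param seed Optional integer seed.
#' @return Tibble with columns `rep`, `strategy`, `generation`, `hom`
#'   (homozygosity of the selected individual).
#' @export
selfing_trajectory_mc <- function(h0, n_markers = 3380, family_size = 30,
                                  n_generations = 3, reps = 500,
                                  strategies = c("max_z", "random"),
                                  seed = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  run <- function() {
    out <- list()
    for (s in strategies) {
      n_het <- rep(round((1 - h0) * n_markers), reps)
      for (g in seq_len(n_generations)) {
        draws <- matrix(rbinom(reps * family_size,
                               size = rep(n_het, each = family_size), prob = 0.5),
                        nrow = family_size)
        n_het <- if (s == "max_z") {
          apply(draws, 2, min)
        } else {
          draws[cbind(sample.int(family_size, reps, replace = TRUE), seq_len(reps))]
        }
        out[[length(out) + 1]] <- tibble::tibble(
          rep = seq_len(reps), strategy = s, generation = g,
          hom = 1 - n_het / n_markers)
      }
    }
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plot Monte-Carlo homozygosity trajectories
#'
#' Mean selected homozygosity per generation and strategy with the
#' no-selection Mendelian expectation `1 - (1 - h0)/2^g` as a dashed
#' reference.
#'
#' @param traj Output of [selfing_trajectory_mc()].
#' @param h0 Founder homozygosity used for the reference curve.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, h0 = NULL) {
  summ <- traj %>%
    dplyr::group_by(.data$strategy, .data$generation) %>%
    dplyr::summarise(hom = mean(.data$hom), .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$generation, .data$hom,
                                          colour = .data$strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "selfing generation", y = "selected homozygosity") +
    ggplot2::theme_minimal()
  if (!is.null(h0)) {
    ref <- tibble::tibble(generation = sort(unique(summ$generation)))
    ref$hom <- expected_homozygosity(h0, ref$generation)
    p <- p + ggplot2::geom_line(data = ref, linetype = "dashed",
                                colour = "grey40",
                                ggplot2::aes(.data$generation, .data$hom))
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
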