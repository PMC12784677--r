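#' Default inheritance-mode proportions for the count simulator
#'
#' One fifth conserved, one fifth additive, and the remaining three fifths
#' non-additive, split evenly between expression-level dominance toward
#' either parent and over-/under-dominant (transgressive) expression.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_mode_proportions <- function() {
  c(conserved = 0.2, additive = 0.2,
    dominant_p1 = 0.15, dominant_p2 = 0.15,
    overdominant = 0.15, underdominant = 0.15)
}

# proportions -> exact per-mode counts summing to n (largest remainder)
.mode_counts <- function(proportions, n) {
  raw <- proportions * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  cnt
}

#' Simulate hybrid-vs-parent RNA-seq counts with planted inheritance modes
#'
#' Generates a negative-binomial count matrix for three groups — two
#' parental lines and their hybrid, `reps_per_group` replicates each —
#' with every gene assigned one inheritance mode. Baseline parent-1 means
#' are log-normal; for non-conserved genes parent 2 sits `parent_lfc`
#' log2 units above or below parent 1 (random sign); the hybrid mean is
#' the mid-parent value for additive genes, the matching parent for
#' dominant genes, and one log2 unit beyond the extreme parent for over-
#' and under-dominant genes. Means are scaled so the expected parent-1
#' library size equals `depth`, then counts are drawn NB with the given
#' dispersion (Poisson when `dispersion = 0`). The generator is a pure
#' function of its arguments: the same seed always yields the same output
#' and the global RNG state is left untouched.
#'
#' @param n_genes Number of genes.
#' @param reps_per_group Biological replicates per group.
#' @param depth Expected parent-1 library size (total counts per sample).
#' @param dispersion NB dispersion `alpha` (variance `m + alpha m^2`).
#' @param mode_proportions Named proportions over the six modes
#'   `conserved`, `additive`, `dominant_p1`, `dominant_p2`,
#'   `overdominant`, `underdominant`; must sum to 1.
#' @param parent_lfc Magnitude of the planted parental log2 fold change.
#' @param seed Integer seed (required).
#' @return List with `counts` (integer matrix), `design` (data.frame with
#'   groups `P1`, `P2`, `HYB` in roles parent1/parent2/hybrid) and `truth`
#'   (data.frame `gene_id`, `mode`, `parent_lfc` signed,
#'   `hybrid_lfc_vs_mpv`).
#' @export
simulate_hybrid_counts <- function(n_genes, reps_per_group = 4, depth = 1e6,
                                   dispersion = 0.05,
                                   mode_proportions = default_mode_proportions(),
                                   parent_lfc = 2.0, seed) {
  if (missing(seed)) stop("seed is required")
  modes <- names(default_mode_proportions())
  if (!setequal(names(mode_proportions), modes))
    stop("mode_proportions must be named: ", paste(modes, collapse = ", "))
  mode_proportions <- mode_proportions[modes]
  if (abs(sum(mode_proportions) - 1) > 1e-9)
    stop("mode proportions must sum to 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  withr::with_seed(seed, {
    cnt <- .mode_counts(mode_proportions, n_genes)
    mode <- sample(rep(names(cnt), times = cnt))
    base <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1.3)
    s <- sample(c(-1, 1), n_genes, replace = TRUE)
    s[mode == "conserved"] <- 0
    p1 <- base
    p2 <- base * 2^(s * parent_lfc)
    mpv <- (p1 + p2) / 2
    hyb <- ifelse(mode == "additive", mpv,
           ifelse(mode == "dominant_p1", p1,
           ifelse(mode == "dominant_p2", p2,
           ifelse(mode == "overdominant", 2 * pmax(p1, p2),
           ifelse(mode == "underdominant", pmin(p1, p2) / 2, base)))))
    scale <- depth / sum(p1)
    draw <- function(mu) {
      mu_rep <- rep(mu * scale, times = reps_per_group)
      x <- if (dispersion > 0)
        stats::rnbinom(length(mu_rep), size = 1 / dispersion, mu = mu_rep)
      else stats::rpois(length(mu_rep), lambda = mu_rep)
      matrix(x, nrow = length(mu), ncol = reps_per_group)
    }
    counts <- cbind(draw(p1), draw(p2), draw(hyb))
    groups <- c("P1", "P2", "HYB")
    samples <- as.vector(vapply(groups, function(g)
      paste0(g, "_", seq_len(reps_per_group)), character(reps_per_group)))
    dimnames(counts) <- list(paste0("g", seq_len(n_genes)), samples)
    storage.mode(counts) <- "integer"
    design <- data.frame(
      sample = samples,
      group = rep(groups, each = reps_per_group),
      role = rep(c("parent1", "parent2", "hybrid"), each = reps_per_group),
      stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = rownames(counts),
                        mode = mode,
                        parent_lfc = s * parent_lfc,
                        hybrid_lfc_vs_mpv = log2(hyb / mpv),
                        stringsAsFactors = FALSE)
    list(counts = counts, design = design, truth = truth)
  })
}

#' Default growth trajectories for the growth-cohort simulator
#'
#' Mean body length (mm) and weight (g) at 30, 60 and 90 days for two
#' purebred and two reciprocal hybrid groups, with the hybrids growing
#' faster than either parent — the hybrid-vigor structure the growth
#' statistics are meant to detect.
#'
#' @return Named list: per group, a list with `length_mm` and `weight_g`
#'   vectors over the timepoints.
#' @export
default_growth_means <- function() {
  list(
    TJ = list(length_mm = c(55, 75, 95),  weight_g = c(1.6, 3.6, 6.5)),
    LC = list(length_mm = c(58, 80, 102), weight_g = c(1.8, 4.2, 7.8)),
    LT = list(length_mm = c(62, 92, 120), weight_g = c(2.1, 5.8, 11.5)),
    TL = list(length_mm = c(60, 88, 115), weight_g = c(2.0, 5.3, 10.4)))
}

#' Simulate a growth cohort
#'
#' Draws individual fish measurements around group mean trajectories with
#' mean-preserving log-normal noise of the given coefficient of variation.
#' `cv = 0` returns the group means exactly. Reproducible per seed, global
#' RNG untouched.
#'
#' @param group_means Named list as returned by [default_growth_means()].
#' @param n_fish Fish sampled per group and timepoint.
#' @param cv Coefficient of variation of the individual noise (>= 0).
#' @param timepoints Ages in days, aligned with the trajectory vectors.
#' @param seed Integer seed (required).
#' @return Data.frame with columns `fish_id`, `group`, `timepoint_days`,
#'   `length_mm`, `weight_g`.
#' @export
simulate_growth_cohort <- function(group_means = default_growth_means(),
                                   n_fish = 30, cv = 0.1,
                                   timepoints = c(30, 60, 90), seed) {
  if (missing(seed)) stop("seed is required")
  if (cv < 0) stop("cv must be >= 0")
  for (g in names(group_means)) {
    gm <- group_means[[g]]
    if (length(gm$length_mm) != length(timepoints) ||
        length(gm$weight_g) != length(timepoints))
      stop("trajectory for group '", g, "' does not match timepoints")
    if (any(gm$length_mm <= 0) || any(gm$weight_g <= 0))
      stop("trajectory means must be positive")
  }
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    rows <- lapply(names(group_means), function(g) {
      gm <- group_means[[g]]
      per_tp <- lapply(seq_along(timepoints), function(ti) {
        noise <- function(mu) {
          if (cv == 0) return(rep(mu, n_fish))
          stats::rlnorm(n_fish, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
        }
        data.frame(fish_id = sprintf("%s_d%d_%02d", g, timepoints[ti],
                                     seq_len(n_fish)),
                   group = g,
                   timepoint_days = timepoints[ti],
                   length_mm = noise(gm$length_mm[ti]),
                   weight_g = noise(gm$weight_g[ti]),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_tp)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' Random terms drawn from the universe, plus one engineered term that
#' overlaps a designated query list at exactly the requested count — a
#' positive control for [enrich()].
#'
#' @param universe Character vector of background genes.
#' @param n_terms Number of random (non-planted) terms.
#' @param term_size_range Length-2 integer range of random term sizes.
#' @param planted_term_overlap Overlap between the planted term and
#'   `query`.
#' @param query Character vector the planted term is engineered against
#'   (subset of `universe`).
#' @param planted_term_size Size of the planted term (default: top of
#'   `term_size_range`).
#' @param seed Integer seed (required).
#' @return List with `sets` (GMT-style named list, `term_names`
#'   attribute) and `planted_term` (its id, `"T_planted"`).
#' @export
simulate_gene_sets <- function(universe, n_terms = 50,
                               term_size_range = c(10, 100),
                               planted_term_overlap, query,
                               planted_term_size = max(term_size_range),
                               seed) {
  if (missing(seed)) stop("seed is required")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of universe")
  if (max(term_size_range) > length(universe) ||
      planted_term_size > length(universe))
    stop("term sizes exceed universe size")
  if (planted_term_overlap > planted_term_size)
    stop("planted overlap exceeds planted term size")
  if (planted_term_overlap > length(query))
    stop("planted overlap exceeds query size")
  if (planted_term_size - planted_term_overlap > length(universe) - length(query))
    stop("not enough non-query genes for the planted term")
  withr::with_seed(seed, {
    sizes <- sample(seq(term_size_range[1L], term_size_range[2L]),
                    n_terms, replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(universe, sz))
    names(sets) <- sprintf("T%03d", seq_len(n_terms))
    inside <- sample(query, planted_term_overlap)
    outside <- sample(setdiff(universe, query),
                      planted_term_size - planted_term_overlap)
    sets[["T_planted"]] <- c(inside, outside)
    attr(sets, "term_names") <- stats::setNames(
      c(sprintf("random term %d", seq_len(n_terms)), "planted enriched term"),
      names(sets))
    list(sets = sets, planted_term = "T_planted")
  })
}

#' Write a sample design sheet to CSV
#'
#' @param design Data.frame with columns `sample`, `group`, `role`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation truth labels to TSV
#'
#' @param truth Data.frame from [simulate_hybrid_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
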