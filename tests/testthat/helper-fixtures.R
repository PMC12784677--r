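# shared fixture builders; everything is generated in code, no data files

make_counts <- function(values, genes = NULL, samples = NULL) {
  n <- if (is.matrix(values)) nrow(values) else length(values) / 2L
  m <- if (is.matrix(values)) values else matrix(values, nrow = n, byrow = TRUE)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

# three-group design around a count matrix whose columns are grouped in
# consecutive blocks of `reps`
make_design <- function(reps = 4L, groups = c("P1", "P2", "HYB"),
                        roles = c("parent1", "parent2", "hybrid")) {
  data.frame(
    sample = as.vector(vapply(groups, function(g)
      paste0(g, "_", seq_len(reps)), character(reps))),
    group = rep(groups, each = reps),
    role = rep(roles, each = reps),
    stringsAsFactors = FALSE)
}

# deterministic counts for planted-pattern construction: per-group means,
# tiny fixed jitter so variances are nonzero but negligible
planted_counts <- function(mean_p1, mean_p2, mean_hyb, reps = 4L) {
  jit <- c(-2L, -1L, 1L, 2L)[seq_len(reps)]
  build <- function(mu) t(vapply(mu, function(m)
    as.integer(pmax(m + jit, 0)), integer(reps)))
  m <- cbind(build(mean_p1), build(mean_p2), build(mean_hyb))
  dimnames(m) <- list(paste0("g", seq_along(mean_p1)),
                      make_design(reps)$sample)
  storage.mode(m) <- "integer"
  m
}

# hand-rolled BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force hypergeometric upper tail by enumerating pmf terms
hyper_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# run the three pairwise comparisons the classifier expects
run_three_de <- function(counts, design, sf = size_factors(counts)) {
  roles <- role_groups(design)
  list(
    h_p1 = de_test(counts, design, roles[["parent1"]], roles[["hybrid"]], sf = sf),
    h_p2 = de_test(counts, design, roles[["parent2"]], roles[["hybrid"]], sf = sf),
    p1_p2 = de_test(counts, design, roles[["parent1"]], roles[["parent2"]], sf = sf))
}
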