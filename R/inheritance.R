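#' Mid-parent expression value
#'
#' The arithmetic mean of the two parental group means: the expected
#' hybrid expression under pure additivity.
#'
#' @param mean_p1,mean_p2 Non-negative normalized expression means
#'   (vectorized).
#' @return `(mean_p1 + mean_p2) / 2`.
#' @export
mid_parent_value <- function(mean_p1, mean_p2) {
  if (any(mean_p1 < 0) || any(mean_p2 < 0))
    stop("parental means must be non-negative")
  (mean_p1 + mean_p2) / 2
}

#' Test hybrid deviation from the mid-parent value
#'
#' Two-sided one-sample t-test of the hybrid replicates' `log2(x + 1)`
#' values against `log2(mpv + 1)`. With zero replicate variance the
#' t-statistic is undefined; by convention the gene deviates (p = 0) when
#' the constant replicate value differs from the MPV beyond 1e-9 relative
#' tolerance, and does not (p = 1) otherwise.
#'
#' @param hybrid_reps Numeric vector of normalized hybrid expression, one
#'   value per replicate (>= 2 required).
#' @param mpv Mid-parent value, `>= 0`.
#' @param alpha Significance level for the deviation call.
#' @return List with `p` and `deviates` (`p < alpha`).
#' @export
mpv_deviation_test <- function(hybrid_reps, mpv, alpha = 0.05) {
  if (length(hybrid_reps) < 2L) stop("need >= 2 hybrid replicates")
  if (mpv < 0) stop("mpv must be non-negative")
  x <- log2(hybrid_reps + 1)
  mu0 <- log2(mpv + 1)
  s <- stats::sd(x)
  if (s == 0) {
    differs <- abs(mean(x) - mu0) > 1e-9 * max(1, abs(mu0))
    p <- if (differs) 0 else 1
  } else {
    tt <- (mean(x) - mu0) / (s / sqrt(length(x)))
    p <- 2 * stats::pt(-abs(tt), df = length(x) - 1L)
  }
  list(p = p, deviates = p < alpha)
}

# Vectorized version over genes: xlog is a G x n matrix of log2(x+1) hybrid
# replicates, mu0 the per-gene log2(mpv+1). Same conventions as above.
.mpv_test_rows <- function(xlog, mu0) {
  n <- ncol(xlog)
  m <- rowMeans(xlog)
  s <- sqrt(rowSums((xlog - m)^2) / (n - 1L))
  p <- numeric(nrow(xlog))
  zero_var <- s == 0
  tt <- (m - mu0) / (s / sqrt(n))
  p[!zero_var] <- 2 * stats::pt(-abs(tt[!zero_var]), df = n - 1L)
  p[zero_var] <- ifelse(abs(m[zero_var] - mu0[zero_var]) >
                          1e-9 * pmax(1, abs(mu0[zero_var])), 0, 1)
  p
}

#' Conserved-expression call
#'
#' A gene is conserved when the hybrid differs from neither parent beyond
#' the fold-change band: both `|log2FC| < threshold`, strict.
#'
#' @param lfc_h_vs_p1,lfc_h_vs_p2 Finite log2 fold changes of hybrid over
#'   each parent (vectorized).
#' @param threshold Band half-width in log2 units.
#' @return Logical.
#' @export
conserved_call <- function(lfc_h_vs_p1, lfc_h_vs_p2, threshold = 1.25) {
  abs(lfc_h_vs_p1) < threshold & abs(lfc_h_vs_p2) < threshold
}

.class_levels <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                   "IX", "X", "XI", "XII", "conserved", "ambiguous")

# Decision table keyed by "c a b" where
#   a = sign of the hybrid-vs-parent1 DEG call,
#   b = sign of the hybrid-vs-parent2 DEG call,
#   c = sign of the parent2-vs-parent1 DEG call,
# and a sign is 0 when the comparison is not a DEG.
.pattern_table <- c(
  "1 1 -1"   = "I",    # F1 between parents, P2 high (additive if on MPV)
  "-1 -1 1"  = "II",   # mirror of I, P1 high
  "1 0 -1"   = "III",  # F1 matches the low parent P1
  "-1 0 1"   = "IV",   # F1 matches the high parent P1
  "1 1 0"    = "V",    # F1 matches the high parent P2
  "-1 -1 0"  = "VI",   # F1 matches the low parent P2
  "1 -1 -1"  = "VII",  # transgressive down, P2 high
  "-1 -1 -1" = "VIII", # transgressive down, P1 high
  "0 1 1"    = "IX",   # transgressive up, parents equal
  "0 -1 -1"  = "X",    # transgressive down, parents equal
  "1 1 1"    = "XI",   # transgressive up, P2 high
  "-1 1 1"   = "XII"   # transgressive up, P1 high
)

#' Classify one gene's inheritance pattern
#'
#' Deterministic lookup from the three pairwise comparison signs plus the
#' MPV-deviation and conserved flags. Conserved wins outright; classes I
#' and II (hybrid significantly between the diverged parents) are additive
#' only when the hybrid does not deviate from the MPV, otherwise the gene
#' is ambiguous; any sign combination outside the twelve patterns is
#' ambiguous, so the function is total.
#'
#' @param a Sign of the hybrid-vs-parent1 call: -1, 0 or +1 (0 = not a DEG).
#' @param b Sign of the hybrid-vs-parent2 call.
#' @param c_sign Sign of the parent2-vs-parent1 call.
#' @param mpv_deviates Logical: hybrid significantly off the MPV.
#' @param conserved Logical: both hybrid-parent fold changes inside the
#'   conserved band.
#' @return One of `"I"`..`"XII"`, `"conserved"`, `"ambiguous"`.
#' @export
classify_gene <- function(a, b, c_sign, mpv_deviates, conserved) {
  stopifnot(a %in% c(-1, 0, 1), b %in% c(-1, 0, 1), c_sign %in% c(-1, 0, 1))
  if (conserved) return("conserved")
  cls <- .pattern_table[paste(c_sign, a, b)]
  if (is.na(cls)) return("ambiguous")
  if (cls %in% c("I", "II") && mpv_deviates) return("ambiguous")
  unname(cls)
}

#' Additivity category of a class label
#'
#' @param class_label Vector of labels from [classify_gene()].
#' @return `"additive"` for I/II, `"non-additive"` for III-XII, otherwise
#'   the label itself (`"conserved"`, `"ambiguous"`).
#' @export
additivity_category <- function(class_label) {
  ifelse(class_label %in% c("I", "II"), "additive",
         ifelse(class_label %in% .class_levels[3:12], "non-additive",
                class_label))
}

#' Classify all DEGs into inheritance patterns
#'
#' Combines three DE tables — hybrid vs parent1, hybrid vs parent2 and
#' parent2 vs parent1, all produced by [de_test()] with the stated
#' orientation (`log2fc` of the second-named group over the first) — into
#' per-gene inheritance calls. The classification universe is the union of
#' DEGs across the three comparisons; other genes are omitted. Parental
#' means, the MPV and the hybrid replicate values are taken from one
#' whole-matrix size-factor normalization so all groups share a scale.
#'
#' @param counts Count matrix covering all three groups.
#' @param design Sample design with exactly one group per role.
#' @param de_h_p1 DE table, hybrid over parent1.
#' @param de_h_p2 DE table, hybrid over parent2.
#' @param de_p1_p2 DE table, parent2 over parent1.
#' @param alpha Significance level of the MPV deviation test.
#' @param conserved_threshold Band for [conserved_call()].
#' @return Data.frame with columns `gene_id`, `class_label`, `additivity`,
#'   `mpv`, `mpv_p`, `lfc_h_p1`, `lfc_h_p2`, `lfc_p2_p1`.
#' @export
classify_all <- function(counts, design, de_h_p1, de_h_p2, de_p1_p2,
                         alpha = 0.05, conserved_threshold = 1.25) {
  validate_counts(counts)
  validate_design(design, counts)
  tabs <- list(de_h_p1 = de_h_p1, de_h_p2 = de_h_p2, de_p1_p2 = de_p1_p2)
  ref <- tabs[[1L]]$gene_id
  for (nm in names(tabs)[-1L]) {
    dif <- c(setdiff(ref, tabs[[nm]]$gene_id), setdiff(tabs[[nm]]$gene_id, ref))
    if (length(dif))
      stop("DE tables cover different gene universes; symmetric difference: ",
           paste(utils::head(dif, 20L), collapse = ", "))
  }
  # align every table to the first table's gene order
  tabs <- lapply(tabs, function(t) t[match(ref, t$gene_id), ])
  sign_of <- function(t) ifelse(t$is_deg, sign(t$log2fc), 0)
  a <- sign_of(tabs$de_h_p1)
  b <- sign_of(tabs$de_h_p2)
  c_sign <- sign_of(tabs$de_p1_p2)
  universe <- a != 0 | b != 0 | c_sign != 0

  roles <- role_groups(design)
  normmat <- normalized_counts(counts)
  cols_for <- function(g) intersect(colnames(counts),
                                    design$sample[design$group == g])
  m1 <- rowMeans(normmat[, cols_for(roles["parent1"]), drop = FALSE])
  m2 <- rowMeans(normmat[, cols_for(roles["parent2"]), drop = FALSE])
  hyb <- normmat[, cols_for(roles["hybrid"]), drop = FALSE]
  if (ncol(hyb) < 2L) stop("hybrid group needs >= 2 replicates")
  mpv <- mid_parent_value(m1, m2)
  mpv_p <- .mpv_test_rows(log2(hyb + 1), log2(mpv + 1))

  idx <- which(universe)
  lfc1 <- tabs$de_h_p1$log2fc
  lfc2 <- tabs$de_h_p2$log2fc
  cons <- conserved_call(lfc1, lfc2, conserved_threshold)
  label <- vapply(idx, function(i) {
    classify_gene(a[i], b[i], c_sign[i],
                  mpv_deviates = mpv_p[i] < alpha, conserved = cons[i])
  }, character(1L))
  data.frame(gene_id = ref[idx],
             class_label = label,
             additivity = additivity_category(label),
             mpv = mpv[idx], mpv_p = mpv_p[idx],
             lfc_h_p1 = lfc1[idx], lfc_h_p2 = lfc2[idx],
             lfc_p2_p1 = tabs$de_p1_p2$log2fc[idx],
             row.names = NULL, stringsAsFactors = FALSE)
}

# round half away from zero, as printed tables usually do
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Summarize inheritance-pattern calls
#'
#' Counts per class and the additive / non-additive split. Percentages use
#' the classified total (classes I-XII) as denominator — conserved and
#' ambiguous genes are reported separately — and are rounded half-up to
#' one decimal.
#'
#' @param calls Data.frame from [classify_all()] (needs `class_label`).
#' @return List with `classified`, `per_class` (named counts over all 14
#'   bins), `additive_count`, `nonadditive_count`, `additive_pct`,
#'   `nonadditive_pct`, `conserved`, `ambiguous`.
#' @export
summarize_patterns <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L)
    stop("no inheritance calls to summarize")
  lab <- factor(calls$class_label, levels = .class_levels)
  if (anyNA(lab))
    stop("unknown class label(s): ",
         paste(unique(calls$class_label[is.na(lab)]), collapse = ", "))
  per_class <- table(lab)
  additive <- sum(per_class[c("I", "II")])
  nonadd <- sum(per_class[.class_levels[3:12]])
  classified <- additive + nonadd
  if (classified == 0L)
    warning("no gene classified into patterns I-XII; percentages are NA")
  pct <- function(k) if (classified > 0) round_half_up(100 * k / classified, 1L) else NA_real_
  list(classified = classified,
       per_class = as.list(per_class),
       additive_count = additive,
       nonadditive_count = nonadd,
       additive_pct = pct(additive),
       nonadditive_pct = pct(nonadd),
       conserved = unname(per_class["conserved"]),
       ambiguous = unname(per_class["ambiguous"]))
}

#' Write inheritance calls to TSV
#'
#' @param calls Data.frame from [classify_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inheritance_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
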