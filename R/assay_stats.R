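#' Specific growth rate
#'
#' `SGR = (ln x2 - ln x1) / T * 100`, in percent per day, for body length
#' or body weight.
#'
#' @param x1,x2 Initial and final measurement, strictly positive
#'   (vectorized).
#' @param days Culture period in days, strictly positive.
#' @return Percent per day.
#' @export
specific_growth_rate <- function(x1, x2, days) {
  if (any(x1 <= 0) || any(x2 <= 0)) stop("measurements must be positive")
  if (any(days <= 0)) stop("culture period must be positive")
  (log(x2) - log(x1)) / days * 100
}

#' Survival rate
#'
#' `SR = final / initial * 100`, in percent.
#'
#' @param final_n,initial_n Fish counts; `0 <= final_n <= initial_n`,
#'   `initial_n > 0`.
#' @return Percent.
#' @export
survival_rate <- function(final_n, initial_n) {
  if (any(initial_n <= 0)) stop("initial count must be positive")
  if (any(final_n < 0) || any(final_n > initial_n))
    stop("final count must lie in [0, initial count]")
  100 * final_n / initial_n
}

#' Enzyme specific activity
#'
#' Activity per milligram of protein, U/mg.
#'
#' @param total_units Enzyme activity in U (>= 0).
#' @param protein_mg Protein mass in mg, strictly positive.
#' @return U/mg protein.
#' @export
specific_activity <- function(total_units, protein_mg) {
  if (any(protein_mg <= 0)) stop("protein mass must be positive")
  total_units / protein_mg
}

#' Villus density
#'
#' Number of villi per millimetre of mucosal contour.
#'
#' @param n_villi Villus count (>= 0).
#' @param mucosal_length_mm Mucosal length in mm, strictly positive.
#' @return Villi per mm.
#' @export
villus_density <- function(n_villi, mucosal_length_mm) {
  if (any(mucosal_length_mm <= 0)) stop("mucosal length must be positive")
  n_villi / mucosal_length_mm
}

#' Fold-length / crypt-depth ratio
#'
#' Dimensionless histomorphometry index of absorptive capacity.
#'
#' @param fold_height_um Fold (villus) height in micrometres, > 0.
#' @param crypt_depth_um Crypt depth in micrometres, > 0.
#' @return Ratio.
#' @export
fold_crypt_ratio <- function(fold_height_um, crypt_depth_um) {
  if (any(fold_height_um <= 0) || any(crypt_depth_um <= 0))
    stop("heights and depths must be positive")
  fold_height_um / crypt_depth_um
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#'         (Ct_target,calibrator - Ct_ref,calibrator)`;
#' fold change is `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_cal,ct_ref_cal Ct of target and reference gene in the
#'   calibrator sample.
#' @return Fold change relative to the calibrator.
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_cal, ct_ref_cal) {
  if (any(!is.finite(c(ct_target_sample, ct_ref_sample,
                       ct_target_cal, ct_ref_cal))))
    stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

.as_group_samples <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of numeric vectors")
  if (length(groups) < 2L) stop("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2L))
    stop("every group needs n >= 2 (variance undefined otherwise): ",
         paste(names(groups)[n < 2L], collapse = ", "))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), n), levels = names(groups)))
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via a fixed-effects fit; the
#' p-value is the upper tail of `F(df1, df2)`. Degenerate inputs follow
#' the conventions `F = 0, p = 1` when there is no between-group variation
#' and `F = Inf, p = 0` when groups differ but the within-group variance
#' is exactly zero.
#'
#' @param groups Named list of numeric vectors, one per group; >= 2 groups,
#'   each with n >= 2.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  df <- .as_group_samples(groups)
  fit <- stats::aov(value ~ group, data = df)
  # perfect fits are handled by the conventions below, not by aov warnings
  tab <- suppressWarnings(stats::anova(fit))
  Fv <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  ss_b <- tab$`Sum Sq`[1L]
  ms_w <- tab$`Mean Sq`[2L]
  tol <- 1e-12 * max(1, sum(df$value^2))
  if (!is.finite(Fv)) {
    if (ss_b <= tol) { Fv <- 0; p <- 1 } else { Fv <- Inf; p <- 0 }
  } else if (ms_w <= tol && ss_b <= tol) {
    Fv <- 0; p <- 1
  }
  list(F = Fv, df1 = tab$Df[1L], df2 = tab$Df[2L], p = p)
}

# Insert-and-absorb compact letter display.
# ord: group names in display (descending mean) order.
# sig: function(g1, g2) -> TRUE when the pair is significantly different.
.compact_letters <- function(ord, sig_mat) {
  cols <- list(ord)  # each column = set of groups allowed to share a letter
  for (i in seq_along(ord)) {
    for (j in seq_len(i - 1L)) {
      if (!sig_mat[ord[i], ord[j]]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (all(c(ord[i], ord[j]) %in% col)) {
          cols[[ci]] <- setdiff(col, ord[i])
          cols[[length(cols) + 1L]] <- setdiff(col, ord[j])
        }
      }
      # absorb: drop duplicates and any column strictly contained in another
      cols <- unique(cols)
      strict_subset <- vapply(seq_along(cols), function(ci) {
        any(vapply(seq_along(cols), function(cj) {
          cj != ci && length(cols[[cj]]) > length(cols[[ci]]) &&
            all(cols[[ci]] %in% cols[[cj]])
        }, logical(1L)))
      }, logical(1L))
      cols <- cols[!strict_subset]
    }
  }
  # letter order follows the highest-mean member of each column
  first_pos <- vapply(cols, function(col) min(match(col, ord)), numeric(1L))
  cols <- cols[order(first_pos)]
  letters_out <- stats::setNames(rep("", length(ord)), ord)
  for (ci in seq_along(cols))
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  letters_out
}

#' Tukey HSD post hoc test with compact letter display
#'
#' All pairwise comparisons after a one-way ANOVA, with family-wise
#' adjusted p-values from the studentized range distribution
#' (Tukey-Kramer harmonic means under unbalance) and lowercase letters
#' assigned by the insert-and-absorb compact-letter-display algorithm,
#' groups ordered by descending mean: groups sharing no letter differ
#' significantly.
#'
#' @param groups Named list of numeric vectors (same contract as
#'   [anova_oneway()]).
#' @param alpha Family-wise significance level for the letters.
#' @return List with `table` (data.frame: `group_a`, `group_b`, `diff`
#'   (b - a), `q_stat`, `p_adj`, `significant`), `letters` (named by
#'   group, descending mean order) and `means`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  df <- .as_group_samples(groups)
  fit <- stats::aov(value ~ group, data = df)
  ms_w <- stats::anova(fit)$`Mean Sq`[2L]
  tk <- stats::TukeyHSD(fit)$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  g_b <- vapply(pair, `[[`, character(1L), 1L)
  g_a <- vapply(pair, `[[`, character(1L), 2L)
  n <- lengths(groups)
  se <- sqrt(ms_w / 2 * (1 / n[g_a] + 1 / n[g_b]))
  q_stat <- abs(tk[, "diff"]) / se
  p_adj <- tk[, "p adj"]
  # zero within-group variance: identical means tie at p = 1, distinct at 0
  degen <- !is.finite(q_stat) | is.na(p_adj)
  if (any(degen)) {
    same <- abs(tk[, "diff"]) <= 1e-12 * max(1, max(abs(df$value)))
    p_adj[degen] <- ifelse(same[degen], 1, 0)
    q_stat[degen] <- ifelse(same[degen], 0, Inf)
  }
  means <- vapply(groups, mean, numeric(1L))
  ord <- names(sort(means, decreasing = TRUE))
  sig_mat <- matrix(FALSE, length(groups), length(groups),
                    dimnames = list(names(groups), names(groups)))
  sig <- p_adj < alpha
  for (i in seq_along(g_a)) {
    sig_mat[g_a[i], g_b[i]] <- sig[i]
    sig_mat[g_b[i], g_a[i]] <- sig[i]
  }
  list(table = data.frame(group_a = g_a, group_b = g_b,
                          diff = unname(tk[, "diff"]),
                          q_stat = unname(q_stat),
                          p_adj = unname(p_adj),
                          significant = unname(sig),
                          row.names = NULL, stringsAsFactors = FALSE),
       letters = .compact_letters(ord, sig_mat),
       means = means)
}

#' Descriptive growth-curve summary
#'
#' Group mean and standard deviation of length and weight per timepoint —
#' the descriptive counterpart of a growth curve, no parametric fit.
#'
#' @param records Data.frame with columns `fish_id`, `group`,
#'   `timepoint_days`, `length_mm`, `weight_g` (as produced by
#'   [simulate_growth_cohort()] or read from CSV).
#' @return Data.frame: `group`, `timepoint_days`, `n`, `length_mean`,
#'   `length_sd`, `weight_mean`, `weight_sd`.
#' @export
growth_summary <- function(records) {
  need <- c("group", "timepoint_days", "length_mm", "weight_g")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  agg <- function(v, f) stats::aggregate(
    records[[v]], records[c("group", "timepoint_days")], f)$x
  out <- stats::aggregate(records$length_mm,
                          records[c("group", "timepoint_days")], length)
  names(out)[3L] <- "n"
  out$length_mean <- agg("length_mm", mean)
  out$length_sd <- agg("length_mm", stats::sd)
  out$weight_mean <- agg("weight_g", mean)
  out$weight_sd <- agg("weight_g", stats::sd)
  out[order(out$group, out$timepoint_days), , drop = FALSE]
}
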