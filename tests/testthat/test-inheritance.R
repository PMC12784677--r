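test_that("mid-parent value is the parental mean", {
  expect_equal(mid_parent_value(10, 20), 15)
  expect_equal(mid_parent_value(7, 7), 7)
  expect_equal(mid_parent_value(0, 0), 0)
  expect_error(mid_parent_value(-1, 5), "non-negative")
})

test_that("MPV deviation test follows the t-test and its conventions", {
  # replicates exactly at the MPV
  r <- mpv_deviation_test(rep(10, 4), 10)
  expect_equal(r$p, 1)
  expect_false(r$deviates)
  # zero-variance, off-MPV convention
  r2 <- mpv_deviation_test(rep(100, 4), 10)
  expect_equal(r2$p, 0)
  expect_true(r2$deviates)
  expect_error(mpv_deviation_test(5, 10), ">= 2")

  # agrees with stats::t.test on noisy replicates
  set.seed(41)
  for (i in 1:10) {
    reps <- rlnorm(4, log(50), 0.3)
    mpv <- runif(1, 20, 80)
    got <- mpv_deviation_test(reps, mpv)
    ref <- t.test(log2(reps + 1), mu = log2(mpv + 1))$p.value
    expect_equal(got$p, ref, tolerance = 1e-12)
  }
})

test_that("a two-fold shift off the MPV is detected almost always", {
  set.seed(42)
  sdlog <- sqrt(log(1 + 0.1^2))  # CV 10%
  hits <- vapply(1:200, function(i) {
    mpv <- 50
    reps <- rlnorm(4, meanlog = log(2 * mpv) - sdlog^2 / 2, sdlog = sdlog)
    mpv_deviation_test(reps, mpv)$deviates
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("conserved band is strict on both sides", {
  expect_true(conserved_call(0, 0))
  expect_false(conserved_call(1.25, 0))
  expect_true(conserved_call(-1.24, 1.24))
})

test_that("the pattern lookup is total and matches its definition", {
  # additive: F1 between diverged parents, on the MPV
  expect_identical(classify_gene(a = 1, b = -1, c_sign = 1,
                                 mpv_deviates = FALSE, conserved = FALSE), "I")
  expect_identical(classify_gene(-1, 1, -1, FALSE, FALSE), "II")
  # off-MPV yet between parents: ambiguous, not additive
  expect_identical(classify_gene(1, -1, 1, TRUE, FALSE), "ambiguous")
  # dominance toward the high parent P2
  expect_identical(classify_gene(1, 0, 1, FALSE, FALSE), "V")
  # transgressive up with equal parents
  expect_identical(classify_gene(1, 1, 0, FALSE, FALSE), "IX")
  # conserved short-circuits everything
  expect_identical(classify_gene(1, 1, 0, FALSE, TRUE), "conserved")
  # unlisted combination
  expect_identical(classify_gene(0, 0, 1, FALSE, FALSE), "ambiguous")

  # total function over every sign combination and flag setting
  for (a in -1:1) for (b in -1:1) for (cc in -1:1)
    for (dev in c(TRUE, FALSE)) {
      lab <- classify_gene(a, b, cc, dev, FALSE)
      expect_true(lab %in% c(as.character(utils::as.roman(1:12)), "ambiguous"))
    }
})

test_that("swapping parent roles permutes classes as the table dictates", {
  # role swap: a' = b, b' = a, c' = -c
  mirror <- c(I = "II", II = "I", III = "VI", VI = "III", IV = "V", V = "IV",
              VII = "VIII", VIII = "VII", IX = "IX", X = "X",
              XI = "XII", XII = "XI",
              conserved = "conserved", ambiguous = "ambiguous")
  set.seed(43)
  for (i in 1:500) {
    a <- sample(-1:1, 1); b <- sample(-1:1, 1); cc <- sample(-1:1, 1)
    dev <- sample(c(TRUE, FALSE), 1)
    orig <- classify_gene(a, b, cc, dev, FALSE)
    swapped <- classify_gene(b, a, -cc, dev, FALSE)
    expect_identical(swapped, unname(mirror[orig]))
  }
})

test_that("classify_all recovers clean planted patterns", {
  # parents 4-fold apart (or equal), hybrid placed by mode; tight
  # replicates; a block of flat anchor genes keeps the size factors honest
  anchor <- 150 + 7 * seq_len(30)
  m <- planted_counts(
    mean_p1 = c(100, 100, 100, 100, 400, anchor),
    mean_p2 = c(400, 400, 100, 400, 100, anchor),
    mean_hyb = c(400, 100, 400, 1600, 25, anchor))
  d <- make_design()
  de <- run_three_de(m, d)
  calls <- classify_all(m, d, de$h_p1, de$h_p2, de$p1_p2)
  got <- setNames(calls$class_label, calls$gene_id)
  expect_identical(got[["g1"]], "V")     # dominant toward high parent P2
  expect_identical(got[["g2"]], "III")   # dominant toward low parent P1
  expect_identical(got[["g3"]], "IX")    # transgressive up, parents equal
  expect_identical(got[["g4"]], "XI")    # transgressive up, P2 high
  expect_identical(got[["g5"]], "VIII")  # transgressive down, P1 high
  expect_identical(unique(calls$additivity[calls$gene_id %in%
                                             paste0("g", 1:5)]),
                   "non-additive")
})

test_that("classify_all enforces a shared gene universe and the DEG rule", {
  m <- planted_counts(c(100, 100), c(400, 100), c(400, 100))
  d <- make_design()
  de <- run_three_de(m, d)
  # g2 is a DEG nowhere -> absent from the calls
  calls <- classify_all(m, d, de$h_p1, de$h_p2, de$p1_p2)
  expect_false("g2" %in% calls$gene_id)
  # mismatched universes are rejected with the offending ids
  de_bad <- de$h_p2[1, , drop = FALSE]
  expect_error(classify_all(m, d, de$h_p1, de_bad, de$p1_p2), "g2")
})

test_that("noise-free planted modes map to their deterministic classes", {
  # zero dispersion, strong parental divergence: the rule set expresses
  # dominant and transgressive truth exactly; genes planted additive sit on
  # the arithmetic MPV, which at these thresholds presents as dominance
  # toward the high parent (the MPV is always within one doubling of it)
  sim <- simulate_hybrid_counts(400, seed = 44, dispersion = 0,
                                parent_lfc = 2)
  de <- run_three_de(sim$counts, sim$design)
  calls <- classify_all(sim$counts, sim$design, de$h_p1, de$h_p2, de$p1_p2)
  truth <- setNames(sim$truth$mode, sim$truth$gene_id)[calls$gene_id]
  dominant <- truth %in% c("dominant_p1", "dominant_p2")
  trans <- truth %in% c("overdominant", "underdominant")
  expect_gte(mean(calls$class_label[dominant] %in%
                    c("III", "IV", "V", "VI")), 0.99)
  expect_gte(mean(calls$additivity[trans] == "non-additive"), 0.99)
  additive <- truth == "additive"
  expect_gte(mean(calls$class_label[additive] %in%
                    c("IV", "V", "conserved")), 0.95)
})

test_that("pattern summaries count and round correctly", {
  calls <- data.frame(
    gene_id = paste0("g", 1:6),
    class_label = c("I", "II", "V", "conserved", "ambiguous", "IX"))
  s <- summarize_patterns(calls)
  expect_equal(s$classified, 4)
  expect_equal(s$additive_count, 2)
  expect_equal(s$nonadditive_count, 2)
  expect_equal(s$additive_pct, 50.0)
  expect_equal(s$conserved, 1)
  expect_equal(s$ambiguous, 1)
  expect_equal(s$additive_count + s$nonadditive_count, s$classified)

  # rounding is half-up at one decimal: 1/3 and 2/3 split
  calls2 <- data.frame(gene_id = paste0("g", 1:3),
                       class_label = c("I", "V", "IX"))
  s2 <- summarize_patterns(calls2)
  expect_equal(s2$additive_pct, 33.3)
  expect_equal(s2$nonadditive_pct, 66.7)

  calls3 <- data.frame(gene_id = "g1", class_label = "II")
  s3 <- summarize_patterns(calls3)
  expect_equal(s3$additive_pct, 100.0)
  expect_equal(s3$nonadditive_pct, 0.0)

  expect_error(summarize_patterns(calls[0, ]), "no inheritance calls")
})
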