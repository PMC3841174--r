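test_that("planted genes at large effect are exactly the ones selected", {
  sim <- simulate_paired_cell_lines(
    cell_line_sim_config(n_probesets = 500, n_de_per_direction = 5,
                         delta = 4, seed = 6))
  de <- paired_diffexp(sim$matrix, sim$design)
  sig <- select_signature(de, k_per_direction = 5)
  expect_setequal(sig$probeset_id, sim$truth$probeset_id)
  expect_equal(sum(sig$weight == 1), 5)
  expect_equal(sum(sig$weight == -1), 5)
  planted_up <- sim$truth$probeset_id[sim$truth$direction == "FNE-up"]
  expect_setequal(sig$probeset_id[sig$weight == 1], planted_up)
})

test_that("duplicate symbols: only the best-ranked probeset per gene enters", {
  de <- fake_de(
    probeset_id = c("A1", "A2", "B1", "C1", "D1", "E1", "F1",
                    "G1", "H1", "I1", "J1", "K1", "L1"),
    symbol = c("GA", "GA", "GB", "GC", "GD", "GE", "GF",
               "GG", "GH", "GI", "GJ", "GK", "GL"),
    p = c(1e-9, 2e-9, 3e-9, 4e-9, 5e-9, 6e-9, 7e-9,
          1e-8, 2e-8, 3e-8, 4e-8, 5e-8, 6e-8),
    t = c(30, 29, 28, 27, 26, 25, 24, -30, -29, -28, -27, -26, -25),
    direction = c(rep("FNE-up", 7), rep("OCE-up", 6)),
    q = rep(1e-6, 13))
  sig <- select_signature(de, k_per_direction = 5)
  up <- sig$probeset_id[sig$weight == 1]
  # A2 shares GA with the better-ranked A1: skipped, F1 fills the slot
  expect_equal(up, c("A1", "B1", "C1", "D1", "E1"))
  expect_false("A2" %in% sig$probeset_id)

  # shortfall is a clear error naming the direction and deficit
  # (7 FNE-up probesets but only 6 distinct symbols)
  expect_error(select_signature(de, k_per_direction = 7),
               "FNE-up.*need 7, found 6")
})

test_that("scores: symmetry, construction, partial signature", {
  sig <- balanced_signature()
  # all ten values equal -> +1/-1 weights cancel exactly
  v_eq <- matrix(3.7, 10, 2,
                 dimnames = list(sig$probeset_id, c("s1", "s2")))
  sc <- score_samples(expression_matrix(v_eq, scale = "normalized"), sig)
  expect_equal(sc$score, c(0, 0))
  expect_equal(sc$n_used, c(10L, 10L))

  # FNE probesets at 1, OCE probesets at 0 -> score 5
  v_01 <- matrix(rep(c(1, 0), each = 5), 10, 1,
                 dimnames = list(sig$probeset_id, "s1"))
  expect_equal(
    score_samples(expression_matrix(v_01, scale = "normalized"), sig)$score,
    5)

  # 8/10 probesets present: n_used = 8 and the sum runs over those 8
  keep <- sig$probeset_id[-c(1, 6)]
  v_8 <- matrix(rnorm(8), 8, 1, dimnames = list(keep, "s1"))
  x8 <- expression_matrix(v_8, scale = "normalized")
  sc8 <- score_samples(x8, sig)
  expect_equal(sc8$n_used, 8L)
  expect_setequal(attr(sc8, "dropped"), sig$probeset_id[c(1, 6)])
  expect_equal(sc8$score,
               sum(v_8[sig$probeset_id[2:5], 1]) -
                 sum(v_8[sig$probeset_id[7:10], 1]))

  # no probesets present at all is an error
  v_none <- matrix(1, 2, 1, dimnames = list(c("X1", "X2"), "s1"))
  expect_error(
    score_samples(expression_matrix(v_none, scale = "normalized"), sig),
    "no signature probeset")
  # missing values among used probesets are an error, not an imputation
  v_na <- v_eq; v_na[2, 1] <- NA
  expect_error(
    score_samples(expression_matrix(v_na, scale = "normalized"), sig),
    "missing")
})

test_that("score invariances: weight negation, row order, balanced shift", {
  sig <- balanced_signature()
  set.seed(7)
  v <- matrix(rnorm(10 * 6, 8), 10, 6,
              dimnames = list(sig$probeset_id, sprintf("s%d", 1:6)))
  x <- expression_matrix(v, scale = "normalized")
  sc <- score_samples(x, sig)

  neg <- sig; neg$weight <- -neg$weight
  expect_equal(score_samples(x, neg)$score, -sc$score)

  shuffle <- sig[sample(nrow(sig)), ]
  expect_equal(score_samples(x, shuffle)$score, sc$score)
  x_shuf <- expression_matrix(v[sample(nrow(v)), , drop = FALSE],
                              scale = "normalized")
  expect_equal(score_samples(x_shuf, sig)$score, sc$score)

  # adding a constant to one sample's values leaves its score unchanged
  v2 <- v; v2[, 3] <- v2[, 3] + 11.5
  expect_equal(
    score_samples(expression_matrix(v2, scale = "normalized"), sig)$score,
    sc$score)
})

test_that("random signatures: determinism, symbol uniqueness, overlap", {
  set.seed(8)
  universe <- data.frame(
    probeset_id = sprintf("u%05d_at", 1:4000),
    symbol = sprintf("USYM%04d", rep(1:2000, each = 2)))
  s1 <- random_signature(universe, seed = 42)
  s2 <- random_signature(universe, seed = 42)
  expect_identical(s1, s2)
  expect_error(random_signature(universe[1:2, ], k_per_direction = 5),
               "too small")

  draws <- lapply(1:200, function(s) random_signature(universe, seed = s))
  expect_true(all(vapply(draws, function(s) !anyDuplicated(s$symbol),
                         logical(1))))
  # overlap with a fixed 10-symbol set follows the hypergeometric mean
  fixed <- sprintf("USYM%04d", 1:10)
  overlap <- vapply(draws, function(s) sum(s$symbol %in% fixed),
                    numeric(1))
  expected <- 10 * 10 / 2000
  se <- sqrt(expected / length(draws))    # Poisson-scale Monte-Carlo error
  expect_lt(abs(mean(overlap) - expected), 4 * se + 1e-9)
})
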