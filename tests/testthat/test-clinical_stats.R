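test_that("Mann-Whitney: symmetry, ties, and oracle agreement", {
  a <- c(1, 2, 3, 4)
  r <- mann_whitney_tiecorrected(a, a)
  expect_equal(r$statistic, length(a)^2 / 2)
  expect_equal(r$p, 1)
  expect_warning(r0 <- mann_whitney_tiecorrected(rep(1, 5), rep(1, 3)),
                 "tied")
  expect_equal(r0$p, 1)
  expect_error(mann_whitney_tiecorrected(numeric(0), 1), "non-empty")

  # label swap leaves the two-sided p unchanged
  set.seed(20)
  for (i in 1:5) {
    x <- sample(0:3, 12, replace = TRUE)
    y <- sample(0:3, 9, replace = TRUE)
    p1 <- mann_whitney_tiecorrected(x, y)$p
    expect_equal(mann_whitney_tiecorrected(y, x)$p, p1)
    # oracle: the tie-corrected normal approximation without continuity
    # correction as implemented independently in stats::wilcox.test
    p_oracle <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
    expect_equal(p1, p_oracle, tolerance = 1e-12)
  }
})

test_that("Fisher exact 2x2: enumeration anchors and oracle agreement", {
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)))$p, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)))$p, 1)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 1))), "margin")
  expect_error(fisher_exact(rbind(c(1.5, 1), c(1, 1))), "integer")

  set.seed(21)
  for (i in 1:8) {
    tab <- matrix(rpois(4, 5), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher 2xK: Monte-Carlo agrees with full enumeration", {
  tab <- rbind(c(4, 1, 3), c(2, 5, 1))
  exact <- fisher_exact(tab)
  expect_match(exact$test, "enumeration")
  expect_equal(exact$p, fisher.test(tab)$p.value, tolerance = 1e-9)
  mc <- fisher_exact(tab, mc_iterations = 20000L, seed = 9,
                     max_enumeration = 0)
  expect_match(mc$test, "Monte-Carlo")
  expect_lt(abs(mc$p - exact$p), 2 * mc$mc_se + 1e-4)
  # determinism of the seeded branch
  mc2 <- fisher_exact(tab, mc_iterations = 20000L, seed = 9,
                      max_enumeration = 0)
  expect_identical(mc$p, mc2$p)
})

test_that("proportional odds: null construction, grid oracle, null calibration", {
  # class carries no information: log-odds ~ 0
  outcome <- rep(c(1, 2, 3), times = 40)
  class <- rep(c("a", "b"), each = 60)
  r <- proportional_odds_assoc(outcome, class)
  expect_equal(r$log_odds, 0, tolerance = 1e-6)
  expect_equal(r$p, 1, tolerance = 1e-6)

  # small 3-level table: ML fit must match a dense-grid + polish oracle
  set.seed(22)
  y <- c(rep(1, 8), rep(2, 6), rep(3, 4), rep(1, 3), rep(2, 5), rep(3, 9))
  g <- rep(c(0, 1), c(18, 17))
  fit <- proportional_odds_assoc(y, g)
  negll <- function(par) {
    a1 <- par[1]; a2 <- par[1] + exp(par[2]); b <- par[3]
    eta <- b * g
    p1 <- plogis(a1 - eta)
    p2 <- plogis(a2 - eta) - p1
    p3 <- 1 - plogis(a2 - eta)
    -sum(log(ifelse(y == 1, p1, ifelse(y == 2, p2, p3))))
  }
  grid <- expand.grid(a1 = seq(-2, 2, 0.5), la = seq(-1, 1, 0.5),
                      b = seq(-2, 2, 0.5))
  vals <- apply(grid, 1, negll)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_lt(abs(-opt$value - fit$loglik), 1e-4)

  # null simulation: LRT p approximately uniform
  ps <- vapply(1:100, function(s) {
    set.seed(400 + s)
    yy <- sample(1:3, 200, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    gg <- rbinom(200, 1, 0.5)
    proportional_odds_assoc(yy, gg)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Welch t: anchors, df limit, oracle", {
  a <- c(1, 2, 3, 4)
  r <- welch_t(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  set.seed(23)
  x <- rnorm(30); y <- rnorm(30)
  r2 <- welch_t(x, y)
  o <- t.test(x, y)
  expect_equal(r2$statistic, unname(o$statistic), tolerance = 1e-12)
  expect_equal(r2$df, unname(o$parameter), tolerance = 1e-9)
  expect_equal(r2$p, o$p.value, tolerance = 1e-12)
  # equal-variance equal-n: Welch df close to pooled n1 + n2 - 2
  expect_equal(r2$df, 58, tolerance = 0.15)
})

test_that("log-rank: anchors, hand-computed toy, survdiff oracle, power", {
  tt <- rep(c(1, 2, 3), 2); ee <- rep(1, 6)
  gg <- rep(c("x", "y"), each = 3)
  r <- logrank_test(tt, ee, gg)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # 6-subject toy, A: 1,2,3 events, B: 4,5,6 events; O/E/V table by hand:
  # O = 3, E = 0.5 + 0.4 + 0.25 = 1.15, V = 0.25 + 0.24 + 0.1875 = 0.6775
  r2 <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6),
                     rep(c("A", "B"), each = 3))
  expect_equal(r2$observed, 3)
  expect_equal(r2$expected, 1.15)
  expect_equal(r2$variance, 0.6775)
  expect_equal(r2$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)

  set.seed(24)
  for (i in 1:3) {
    time <- rexp(80, ifelse(rep(c(TRUE, FALSE), each = 40), 1, 2))
    event <- rbinom(80, 1, 0.8)
    grp <- rep(c("a", "b"), each = 40)
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(logrank_test(time, event, grp)$statistic,
                 unname(sd_fit$chisq), tolerance = 1e-9)
  }

  # strong hazard contrast: essentially always detected
  hits <- vapply(1:20, function(s) {
    set.seed(500 + s)
    t1 <- rexp(150, 3); t0 <- rexp(150, 1)
    logrank_test(c(t1, t0), rep(1, 300),
                 rep(c("hi", "lo"), each = 150))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_warning(r3 <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(r3$p, 1)
})

test_that("Cox: anchors and null behavior", {
  set.seed(25)
  hrs <- vapply(1:10, function(s) {
    set.seed(600 + s)
    z <- rbinom(200, 1, 0.5)
    time <- rexp(200, 0.05)          # covariate independent of survival
    cox_ph(time, rep(1, 200), data.frame(z = z))$table$hr
  }, numeric(1))
  expect_lt(abs(mean(log(hrs))), 0.15)

  # km_curves: survival starts at 1 and is non-increasing per group
  time <- rexp(60, 0.1); event <- rbinom(60, 1, 0.7)
  grp <- rep(c("a", "b"), 30)
  km <- km_curves(time, event, grp)
  for (g in c("a", "b")) {
    s <- km$survival[km$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("permutation null: edge cases and determinism", {
  sig <- balanced_signature()
  co <- simulate_tumor_cohort(
    cohort_sim_config(n_tumors = 80, n_probesets = 300, seed = 30), sig)
  empty <- permutation_signature_null(co$matrix, co$clinical,
                                      n_permutations = 0, seed = 1)
  expect_equal(nrow(empty$p_values), 0L)
  expect_true(all(is.na(empty$fraction_significant)))

  p1 <- permutation_signature_null(co$matrix, co$clinical,
                                   n_permutations = 5, seed = 7,
                                   mc_iterations = 2000)
  p2 <- permutation_signature_null(co$matrix, co$clinical,
                                   n_permutations = 5, seed = 7,
                                   mc_iterations = 2000)
  expect_identical(p1$p_values, p2$p_values)
  expect_true(all(unlist(p1$p_values) >= 0 & unlist(p1$p_values) <= 1))
})
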