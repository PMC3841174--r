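make_design <- function(P = 2) {
  data.frame(
    sample_id = as.vector(outer(c("FNE", "OCE"), 1:P,
                                \(ct, p) sprintf("P%d_%s", p, ct))),
    patient_block = rep(sprintf("P%d", 1:P), each = 2),
    cell_type = rep(c("FNE", "OCE"), P))
}

test_that("consensus correlation: perfect duplicates clamp at 0.99", {
  d <- make_design()
  set.seed(1)
  fne <- matrix(rnorm(60 * 2), 60, 2)
  v <- cbind(fne[, 1], fne[, 1], fne[, 2], fne[, 2])  # OCE == FNE per block
  dimnames(v) <- list(sprintf("p%02d", 1:60), d$sample_id)
  est <- estimate_consensus_correlation(
    expression_matrix(v, scale = "normalized"), d)
  expect_gte(est$rho, 0.989)
})

test_that("consensus correlation: independent noise stays near zero", {
  d <- make_design()
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    v <- matrix(rnorm(2000 * 4), 2000, 4,
                dimnames = list(sprintf("p%04d", 1:2000), d$sample_id))
    estimate_consensus_correlation(
      expression_matrix(v, scale = "normalized"), d)$rho
  }, numeric(1))
  expect_true(all(abs(rhos) < 0.1))
})

test_that("GLS: rho = 0 is OLS; positive rho shrinks the contrast variance", {
  d <- make_design()
  set.seed(2)
  v <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(sprintf("p%02d", 1:40), d$sample_id))
  x <- expression_matrix(v, scale = "normalized")
  f0 <- fit_paired_gls(x, d, rho = 0)
  is_fne <- d$cell_type == "FNE"
  expect_equal(f0$beta,
               unname(rowMeans(v[, is_fne]) - rowMeans(v[, !is_fne])),
               tolerance = 1e-12)
  f5 <- fit_paired_gls(x, d, rho = 0.5)
  # balanced blocks: the contrast estimate is unchanged, its variance drops
  expect_equal(f5$beta, f0$beta, tolerance = 1e-10)
  expect_lt(f5$v[[1]], f0$v[[1]])
  expect_error(fit_paired_gls(x, d, rho = 1), "rho")
})

test_that("GLS solution matches a numerical optimizer on a toy gene", {
  d <- make_design()
  y <- c(3.1, 1.2, 2.8, 0.7)
  v <- matrix(y, 1, 4, dimnames = list("p1", d$sample_id))
  rho <- 0.4
  f <- fit_paired_gls(expression_matrix(v, scale = "normalized"), d, rho)
  V <- diag(4)
  V[1, 2] <- V[2, 1] <- V[3, 4] <- V[4, 3] <- rho
  Vi <- solve(V)
  X <- cbind(1, as.numeric(d$cell_type == "FNE"))
  obj <- function(b) {
    r <- y - X %*% b
    as.numeric(t(r) %*% Vi %*% r)
  }
  opt <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(f$beta, opt$par[[2]], tolerance = 1e-6)
})

test_that("moderation matches limma's empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  sim <- simulate_paired_cell_lines(
    cell_line_sim_config(n_probesets = 3000, n_de_per_direction = 100,
                         seed = 8))
  fits <- fit_paired_gls(sim$matrix, sim$design, rho = 0)
  mod <- moderate_statistics(fits)
  sq <- limma::squeezeVar(fits$s2, df = fits$df)
  expect_equal(attr(mod, "d0"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s0sq"), sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("variance prior (d0, s0^2) is recovered within 25%", {
  sim <- simulate_paired_cell_lines(
    cell_line_sim_config(n_probesets = 5000, n_de_per_direction = 0,
                         d0_true = 4, s0sq_true = 0.05, seed = 21))
  de <- paired_diffexp(sim$matrix, sim$design)
  expect_equal(attr(de, "d0"), 4, tolerance = 0.25)
  expect_equal(attr(de, "s0sq"), 0.05, tolerance = 0.25)
})

test_that("huge variance spread brings the moderated t back to ordinary t", {
  set.seed(3)
  n <- 2000
  fits <- data.frame(probeset_id = sprintf("p%04d", 1:n),
                     beta = rnorm(n), v = 0.5,
                     s2 = exp(runif(n, -12, 12)), df = 20)
  mod <- moderate_statistics(fits)
  expect_lt(attr(mod, "d0"), 0.5)
  # in the d0 -> 0 limit shrinkage vanishes; with the tiny estimated d0 the
  # typical gene's moderated t is already indistinguishable from ordinary t
  t_raw <- fits$beta / sqrt(fits$s2 * fits$v)
  rel <- abs(mod$t - t_raw) / pmax(abs(t_raw), 1e-12)
  expect_lt(median(rel), 0.02)
  expect_gt(cor(mod$t, t_raw, method = "spearman"), 0.999)
})

test_that("equal variances trigger the d0 = Inf complete-shrinkage branch", {
  fits <- data.frame(probeset_id = sprintf("p%02d", 1:20),
                     beta = rnorm(20), v = 0.5, s2 = 0.3, df = 4)
  expect_message(mod <- moderate_statistics(fits), "Inf")
  expect_true(is.infinite(attr(mod, "d0")))
  expect_true(all(mod$s2_post == attr(mod, "s0sq")))
})

test_that("with rho = 0 and one sample per block/condition the pipeline is a two-sample t", {
  d <- make_design()
  set.seed(4)
  v <- matrix(rnorm(30 * 4, 7, 1), 30, 4,
              dimnames = list(sprintf("p%02d", 1:30), d$sample_id))
  fits <- fit_paired_gls(expression_matrix(v, scale = "normalized"), d, 0)
  t_mine <- fits$beta / sqrt(fits$s2 * fits$v)
  is_fne <- d$cell_type == "FNE"
  t_oracle <- apply(v, 1, function(row) {
    t.test(row[is_fne], row[!is_fne], var.equal = TRUE)$statistic
  })
  expect_equal(t_mine, unname(t_oracle), tolerance = 1e-8)
})

test_that("BH adjustment: hand cases, oracle, order invariance", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:5) {
    p <- runif(200)^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    expect_true(all(bh_adjust(p) >= p))
    perm <- sample(200)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
})

test_that("moderation gains power over the raw t under overdispersed variances", {
  hits <- vapply(1:3, function(s) {
    sim <- simulate_paired_cell_lines(
      cell_line_sim_config(n_probesets = 2000, n_de_per_direction = 50,
                           delta = 1.5, d0_true = 2, seed = 30 + s))
    de <- paired_diffexp(sim$matrix, sim$design)
    truth <- de$probeset_id %in% sim$truth$probeset_id
    t_raw <- de$beta / sqrt(de$s2 * de$v)
    p_raw <- 2 * pt(-abs(t_raw), df = de$df)
    c(mod = mean(de$p[truth] < 0.05), raw = mean(p_raw[truth] < 0.05))
  }, numeric(2))
  expect_gt(mean(hits["mod", ]), mean(hits["raw", ]))
})
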