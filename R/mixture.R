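#' Fit a two-component Gaussian mixture to signature scores
#'
#' Expectation-maximization on a 1-D score vector, with 10 restarts
#' (quantile-based splits plus seeded random partitions), convergence when
#' the absolute log-likelihood change drops below `tol`, and a monotone
#' log-likelihood asserted at every iteration. Two variance families are
#' available: `shared` (one sigma) and `separate` (per-component sigmas);
#' under `auto` both are fit and the lower BIC
#' (`-2 logL + n_params * log(n)`) wins, mirroring the equal/unequal
#' variance 1-D model families of standard model-based clustering. The
#' component with the larger mean is labeled FT-like.
#'
#' @param scores Numeric vector with at least 10 distinct values.
#' @param variance_mode `"auto"` (default), `"shared"` or `"separate"`.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of initializations (default 10).
#' @param max_iter,tol EM iteration cap (1000) and absolute log-likelihood
#'   convergence tolerance (1e-8).
#' @return An object of class `MixtureModel`: list with `pi` (FT-like
#'   mixing weight), `mu` (named, `OV-like < FT-like`), `sigma` (named),
#'   `variance_mode` actually used, `loglik`, `bic`, `posterior_FT`
#'   (per-sample), `labels` (factor) and `n`.
#' @export
fit_two_component_mixture <- function(scores,
                                      variance_mode = c("auto", "shared",
                                                        "separate"),
                                      seed = 1L, n_restarts = 10L,
                                      max_iter = 1000L, tol = 1e-8) {
  variance_mode <- match.arg(variance_mode)
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(scores)) < 10L) {
    stop("need at least 10 distinct score values")
  }
  if (variance_mode == "auto") {
    fits <- list(shared = em_best(scores, TRUE, seed, n_restarts,
                                  max_iter, tol),
                 separate = em_best(scores, FALSE, seed, n_restarts,
                                    max_iter, tol))
    best <- if (fits$shared$bic <= fits$separate$bic) fits$shared else
      fits$separate
  } else {
    best <- em_best(scores, variance_mode == "shared", seed, n_restarts,
                    max_iter, tol)
  }
  best
}

em_best <- function(x, shared, seed, n_restarts, max_iter, tol) {
  n <- length(x)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  inits <- list(
    list(mu = c(qs[1L], qs[3L])),
    list(mu = c(min(x), max(x))),
    list(mu = c(qs[2L] - stats::sd(x), qs[2L] + stats::sd(x))))
  set.seed(seed)
  while (length(inits) < n_restarts) {
    mu <- sort(sample(x, 2L))
    if (mu[1L] == mu[2L]) mu <- mu + c(-1, 1) * stats::sd(x) / 4
    inits[[length(inits) + 1L]] <- list(mu = mu)
  }
  best <- NULL
  for (init in inits[seq_len(n_restarts)]) {
    fit <- tryCatch(
      em_run(x, init$mu, shared, max_iter, tol),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("EM collapsed (sigma -> 0) from every initialization")
  }
  best
}

em_run <- function(x, mu0, shared, max_iter, tol) {
  n <- length(x)
  sd0 <- stats::sd(x) / 2
  pi1 <- 0.5                       # weight of component 2 (larger mean)
  mu <- sort(mu0)
  sg <- c(sd0, sd0)
  min_sigma <- max(1e-8 * stats::sd(x), 1e-12)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    ld1 <- stats::dnorm(x, mu[1L], sg[1L], log = TRUE) + log1p(-pi1)
    ld2 <- stats::dnorm(x, mu[2L], sg[2L], log = TRUE) + log(pi1)
    m <- pmax(ld1, ld2)
    ll <- sum(m + log(exp(ld1 - m) + exp(ld2 - m)))
    if (ll < ll_old - 1e-8) {
      stop("EM log-likelihood decreased; numerical failure")
    }
    conv <- is.finite(ll_old) && abs(ll - ll_old) < tol
    ll_old <- ll
    g2 <- 1 / (1 + exp(ld1 - ld2))   # responsibility of component 2
    if (conv) break
    n2 <- sum(g2); n1 <- n - n2
    if (n1 < 1e-10 || n2 < 1e-10) stop("EM component emptied")
    pi1 <- n2 / n
    mu <- c(sum((1 - g2) * x) / n1, sum(g2 * x) / n2)
    if (shared) {
      s2 <- (sum((1 - g2) * (x - mu[1L])^2) +
               sum(g2 * (x - mu[2L])^2)) / n
      sg <- rep(sqrt(s2), 2L)
    } else {
      sg <- sqrt(c(sum((1 - g2) * (x - mu[1L])^2) / n1,
                   sum(g2 * (x - mu[2L])^2) / n2))
    }
    if (any(sg < min_sigma)) stop("EM collapsed: sigma -> 0")
  }
  # orient: component with larger mean is FT-like
  if (mu[2L] >= mu[1L]) {
    mu_ft <- mu[2L]; mu_ov <- mu[1L]
    sg_ft <- sg[2L]; sg_ov <- sg[1L]
    pi_ft <- pi1; post_ft <- g2
  } else {
    mu_ft <- mu[1L]; mu_ov <- mu[2L]
    sg_ft <- sg[1L]; sg_ov <- sg[2L]
    pi_ft <- 1 - pi1; post_ft <- 1 - g2
  }
  n_par <- if (shared) 4L else 5L
  labels <- factor(ifelse(post_ft >= 0.5, "FT-like", "OV-like"),
                   levels = c("OV-like", "FT-like"))
  structure(list(
    pi = pi_ft,
    mu = c("OV-like" = mu_ov, "FT-like" = mu_ft),
    sigma = c("OV-like" = sg_ov, "FT-like" = sg_ft),
    variance_mode = if (shared) "shared" else "separate",
    loglik = ll_old, bic = -2 * ll_old + n_par * log(n),
    posterior_FT = post_ft, labels = labels, n = n),
    class = "MixtureModel")
}

#' @export
print.MixtureModel <- function(x, ...) {
  cat(sprintf(
    "Two-component Gaussian mixture (%s variance)\n  pi(FT-like) = %.3f\n  mu: OV-like %.3f, FT-like %.3f\n  sigma: OV-like %.3f, FT-like %.3f\n  logL = %.3f, BIC = %.3f, n = %d\n",
    x$variance_mode, x$pi, x$mu[["OV-like"]], x$mu[["FT-like"]],
    x$sigma[["OV-like"]], x$sigma[["FT-like"]], x$loglik, x$bic, x$n))
  invisible(x)
}

#' Hard FT-like/OV-like classification from a fitted mixture
#'
#' Applies the Bayes rule at posterior 0.5 and summarizes the subgroups.
#'
#' @param model A `MixtureModel`.
#' @param scores Optional score vector to classify; defaults to the
#'   per-sample posteriors stored in the model.
#' @return List with `labels` (factor), `posterior_FT`, and `summary`
#'   (data.frame of subgroup size and mean posterior).
#' @export
classify_samples <- function(model, scores = NULL) {
  if (!inherits(model, "MixtureModel")) stop("`model` must be a MixtureModel")
  if (is.null(scores)) {
    post <- model$posterior_FT
  } else {
    post <- posterior_ft(model, scores)
  }
  labels <- factor(ifelse(post >= 0.5, "FT-like", "OV-like"),
                   levels = c("OV-like", "FT-like"))
  summ <- data.frame(
    label = levels(labels),
    n = as.integer(table(labels)),
    mean_posterior_FT = as.numeric(tapply(post, labels, mean)),
    stringsAsFactors = FALSE)
  list(labels = labels, posterior_FT = post, summary = summ)
}

#' Posterior probability of the FT-like component at arbitrary scores
#'
#' @param model A `MixtureModel`.
#' @param scores Numeric vector.
#' @return Posterior probability of FT-like membership for each score.
#' @export
posterior_ft <- function(model, scores) {
  ld_ov <- stats::dnorm(scores, model$mu[["OV-like"]],
                        model$sigma[["OV-like"]], log = TRUE) +
    log1p(-model$pi)
  ld_ft <- stats::dnorm(scores, model$mu[["FT-like"]],
                        model$sigma[["FT-like"]], log = TRUE) +
    log(model$pi)
  1 / (1 + exp(ld_ov - ld_ft))
}
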