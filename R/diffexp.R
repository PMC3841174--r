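#' Consensus intra-patient correlation
#'
#' Estimates a single correlation shared by all probesets between arrays
#' from the same patient block, after removing cell-type means. Per
#' probeset a moment (intraclass-type) correlation is formed from the
#' within-block cross-products of residuals,
#' `r_g = sum(e_F * e_O) / ((sum(e_F^2) + sum(e_O^2)) / 2)`,
#' the per-probeset values are mapped by `atanh` (clamped at +/-0.99), a
#' 15%-trimmed mean is taken, and the result mapped back by `tanh`. This
#' trimmed-mean-of-atanh consensus is deterministic and plays the role of
#' a consensus duplicate correlation in the paired generalized least
#' squares fits.
#'
#' @param x Normalized `ExpressionMatrix`.
#' @param design Data.frame with `sample_id`, `patient_block`, `cell_type`
#'   covering the matrix columns; blocks need at least one sample of each
#'   cell type (blocks with fewer than 2 samples contribute nothing).
#' @param trim Trim fraction for the consensus mean (default 0.15).
#' @return An object of class `CorrelationEstimate`: list with `rho`
#'   (consensus, clamped to (-0.99, 0.99)) and `atanh_correlations`
#'   (per-probeset values on the atanh scale).
#' @export
estimate_consensus_correlation <- function(x, design, trim = 0.15) {
  stopifnot_normalized(x, "estimate_consensus_correlation")
  design <- validate_design(design, colnames(x$values))
  v <- x$values[, design$sample_id, drop = FALSE]

  # residuals after removing cell-type means
  res <- v
  for (ct in unique(design$cell_type)) {
    idx <- design$cell_type == ct
    res[, idx] <- v[, idx, drop = FALSE] -
      rowMeans(v[, idx, drop = FALSE])
  }

  blocks <- split(seq_len(nrow(design)), design$patient_block)
  blocks <- blocks[vapply(blocks, length, 1L) >= 2L]
  if (length(blocks) == 0L) stop("all blocks degenerate (< 2 samples)")

  num <- 0; den <- 0
  for (idx in blocks) {
    fne <- idx[design$cell_type[idx] == "FNE"]
    oce <- idx[design$cell_type[idx] == "OCE"]
    if (length(fne) == 0L || length(oce) == 0L) next
    eF <- rowMeans(res[, fne, drop = FALSE])
    eO <- rowMeans(res[, oce, drop = FALSE])
    num <- num + eF * eO
    den <- den + (eF^2 + eO^2) / 2
  }
  if (all(den == 0)) stop("all blocks degenerate: no residual variation")
  r <- ifelse(den > 0, num / den, 0)
  r <- pmin(pmax(r, -0.99), 0.99)
  z <- atanh(r)
  rho <- tanh(mean(z, trim = trim))
  rho <- min(max(rho, -0.99), 0.99)
  structure(list(rho = rho, atanh_correlations = z),
            class = "CorrelationEstimate")
}

#' @export
print.CorrelationEstimate <- function(x, ...) {
  cat(sprintf("Consensus intra-block correlation: %.4f (%d probesets)\n",
              x$rho, length(x$atanh_correlations)))
  invisible(x)
}

validate_design <- function(design, sample_ids) {
  req <- c("sample_id", "patient_block", "cell_type")
  if (!all(req %in% names(design))) {
    stop("design needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(design$cell_type %in% c("FNE", "OCE"))) {
    stop("cell_type must be FNE or OCE")
  }
  if (!all(design$sample_id %in% sample_ids)) {
    stop("design samples missing from matrix: ",
         setdiff(design$sample_id, sample_ids)[[1L]])
  }
  ok_blocks <- tapply(design$cell_type, design$patient_block,
                      function(ct) all(c("FNE", "OCE") %in% ct))
  if (!any(ok_blocks)) {
    stop("no block contains both cell types; paired contrast undefined")
  }
  design
}

#' Per-probeset paired generalized least squares fit
#'
#' Fits, for every probeset, the two-cell-type model by generalized least
#' squares with an equicorrelated working covariance: unit diagonal and
#' `rho` between arrays from the same patient block. The contrast is
#' FNE minus OCE. With `rho = 0` this reduces to ordinary least squares
#' (the plain difference of cell-type means in a balanced design).
#'
#' @param x Normalized `ExpressionMatrix`.
#' @param design Sample design (see [estimate_consensus_correlation()]).
#' @param rho Working intra-block correlation, `|rho| < 1`.
#' @return Data.frame with one row per probeset: `probeset_id`, `symbol`,
#'   `beta` (log2 fold change FNE - OCE), `v` (unscaled contrast variance),
#'   `s2` (residual variance), `df` (residual degrees of freedom).
#' @export
fit_paired_gls <- function(x, design, rho) {
  stopifnot_normalized(x, "fit_paired_gls")
  design <- validate_design(design, colnames(x$values))
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  v <- x$values[, design$sample_id, drop = FALSE]
  n <- nrow(design)

  X <- cbind(intercept = 1, fne = as.numeric(design$cell_type == "FNE"))
  if (qr(X)$rank < ncol(X)) stop("singular design")

  V <- diag(n)
  same_block <- outer(design$patient_block, design$patient_block, "==")
  V[same_block & !diag(n)] <- rho
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("rho = ", rho, " makes the working covariance non positive-definite")
  }
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  XtViX_inv <- solve(XtVi %*% X)
  A <- XtViX_inv %*% XtVi                  # coefficients = A %*% y
  coefs <- v %*% t(A)                      # genes x 2
  beta <- coefs[, 2L]
  vg <- XtViX_inv[2L, 2L]

  fitted <- coefs %*% t(X)
  r <- v - fitted
  df <- n - ncol(X)
  s2 <- rowSums((r %*% Vi) * r) / df

  data.frame(probeset_id = rownames(v),
             symbol = unname(x$annotation[rownames(v)]),
             beta = unname(beta), v = vg, s2 = unname(s2), df = df,
             stringsAsFactors = FALSE)
}

# Solve trigamma(x) = y for x > 0 by bisection (y > 0), tolerance 1e-10.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < y) return(lo)
  if (trigamma(hi) > y) return(hi)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)       # bisect in log space
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo - 1 < 1e-12) break
  }
  sqrt(lo * hi)
}

#' Empirical-Bayes moderation of per-probeset variances
#'
#' Estimates a variance prior (d0 degrees of freedom, s0^2 scale) by
#' moment-matching the log residual variances against the scaled-F model:
#' with `e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)`, the model gives
#' `E[e] = log(s0^2) - digamma(d0/2) + log(d0/2)` and
#' `Var[e] = trigamma(df_g/2) + trigamma(d0/2)`, so `d0` comes from a
#' trigamma inversion (bisection, tolerance 1e-10) and `s0^2` from the
#' mean. Posterior variances are `(d0*s0^2 + df*s2) / (d0 + df)`, the
#' moderated t is `beta / (s_tilde * sqrt(v))` with `d0 + df` degrees of
#' freedom. When the observed spread of log variances is no larger than
#' the chi-square sampling noise, `d0 = Inf` and all variances shrink
#' completely to `s0^2` (a message is emitted).
#'
#' @param fits Data.frame from [fit_paired_gls()] (>= 10 probesets).
#' @return A data.frame of class `DEResult`: the input columns plus
#'   `s2_post`, `t` (moderated), `df_total`, `p`, `q` (Benjamini-Hochberg)
#'   and `direction` (`FNE-up`/`OCE-up`); attributes `d0` and `s0sq` carry
#'   the prior.
#' @export
moderate_statistics <- function(fits) {
  req <- c("probeset_id", "beta", "v", "s2", "df")
  if (!all(req %in% names(fits))) {
    stop("fits needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(fits) < 10L) stop("need >= 10 probesets to estimate the prior")
  s2 <- pmax(fits$s2, 1e-300)
  dg <- fits$df
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  ev <- stats::var(e)
  excess <- ev - mean(trigamma(dg / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    message("log-variance spread at or below sampling noise; d0 = Inf ",
            "(complete shrinkage)")
    d0 <- Inf
    s0sq <- exp(ebar)
  }
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else {
    (d0 * s0sq + dg * s2) / (d0 + dg)
  }
  tmod <- fits$beta / sqrt(s2_post * fits$v)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  out <- fits
  out$s2_post <- s2_post
  out$t <- tmod
  out$df_total <- df_total
  out$p <- p
  out$q <- bh_adjust(p)
  out$direction <- ifelse(out$beta >= 0, "FNE-up", "OCE-up")
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values: `q[i] >= p[i]`, capped at 1, monotone along
#'   the p-value ordering, invariant to input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Paired FNE-versus-OCE differential expression
#'
#' Convenience wrapper chaining [estimate_consensus_correlation()],
#' [fit_paired_gls()] and [moderate_statistics()].
#'
#' @param x Normalized `ExpressionMatrix`.
#' @param design Sample design data.frame.
#' @param rho Optional fixed intra-block correlation; estimated from the
#'   data when `NULL` (default).
#' @return A `DEResult` data.frame (attribute `rho` records the
#'   correlation used).
#' @export
paired_diffexp <- function(x, design, rho = NULL) {
  if (is.null(rho)) rho <- estimate_consensus_correlation(x, design)$rho
  fits <- fit_paired_gls(x, design, rho)
  out <- moderate_statistics(fits)
  attr(out, "rho") <- rho
  out
}
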