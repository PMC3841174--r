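#' Generalized-log (glog2) transform
#'
#' The variance-stabilizing core of vsn-style calibration:
#' `log2((y + sqrt(y^2 + c)) / 2)`. The transform is defined for all real
#' `y` (including zero and negative background-corrected intensities), is
#' strictly increasing, behaves linearly near zero and converges to plain
#' `log2(y)` for `y >> sqrt(c)`.
#'
#' @param y Numeric vector of intensities (any real values).
#' @param c Positive glog offset controlling where the transform switches
#'   from linear-like to log-like behavior.
#' @return Numeric vector of glog2-transformed values.
#' @export
glog_transform <- function(y, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("glog offset `c` must be a positive scalar")
  }
  log2((y + sqrt(y^2 + c)) / 2)
}

#' Inverse of the glog2 transform
#'
#' Exact inverse of [glog_transform()]: if `t = glog2(y, c)` then
#' `y = 2^t - c / (4 * 2^t)`.
#'
#' @inheritParams glog_transform
#' @param t Numeric vector of glog2-scale values.
#' @return Numeric vector on the original intensity scale.
#' @export
glog_inverse <- function(t, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("glog offset `c` must be a positive scalar")
  }
  u <- 2^t
  u - c / (4 * u)
}

#' Fit an array-affine variance-stabilizing calibration
#'
#' A simplified, deterministic stand-in for vsn's probe-level maximum
#' likelihood fit, operating on probeset summaries: every array `s` gets an
#' affine calibration `(y - a_s) / b_s`, followed by a shared glog2
#' transform with offset `c`. The per-array parameters are estimated by a
#' robust (least-trimmed) regression of each array's order statistics on the
#' across-array mean order statistic, which minimizes the trimmed
#' between-array spread of rank-matched values. The glog offset is then
#' chosen on a deterministic log-spaced grid to flatten the
#' intensity-dependence of the row-wise spread (SD-versus-rank slope).
#'
#' @param x An `ExpressionMatrix` with `scale == "raw"` and at least two
#'   arrays.
#' @param trim Trimming fraction for the robust affine fit (default 0.1:
#'   10% of rank-matched points with the largest residuals are discarded at
#'   each iteration).
#' @param c Optional fixed glog offset; if `NULL` (default) it is chosen by
#'   the grid search described above.
#' @return An object of class `NormalizationModel`: list with per-array
#'   offsets `a`, per-array scales `b` (all positive), and glog offset `c`.
#' @export
fit_vsn_calibration <- function(x, trim = 0.1, c = NULL) {
  if (!is_expression_matrix(x)) stop("`x` must be an ExpressionMatrix")
  if (x$scale != "raw") stop("calibration expects a raw-scale matrix")
  v <- x$values
  if (ncol(v) < 2L) stop("calibration needs at least two arrays")
  if (any(is.na(v))) stop("calibration input must not contain missing values")
  if (any(apply(v, 2L, stats::sd) == 0)) stop("constant array in input")

  sorted <- apply(v, 2L, sort)
  ref <- rowMeans(sorted)
  n <- nrow(sorted)
  keep_n <- max(3L, floor((1 - trim) * n))

  fit_one <- function(ys) {
    keep <- rep(TRUE, n)
    ab <- c(0, 1)
    for (iter in 1:20) {
      fit <- stats::lm.fit(cbind(1, ref[keep]), ys[keep])
      ab_new <- fit$coefficients
      resid <- ys - (ab_new[[1L]] + ab_new[[2L]] * ref)
      ord <- order(abs(resid))
      keep_new <- rep(FALSE, n)
      keep_new[ord[seq_len(keep_n)]] <- TRUE
      if (max(abs(ab_new - ab)) < 1e-12 && identical(keep_new, keep)) break
      ab <- ab_new
      keep <- keep_new
    }
    ab
  }
  ab <- apply(sorted, 2L, fit_one)
  a <- ab[1L, ]
  b <- ab[2L, ]
  if (any(b <= 0)) stop("calibration produced a non-positive array scale")
  names(a) <- names(b) <- colnames(v)

  calibrated <- sweep(sweep(v, 2L, a, "-"), 2L, b, "/")
  if (is.null(c)) {
    c <- choose_glog_offset(calibrated)
  } else if (!is.numeric(c) || length(c) != 1L || c <= 0) {
    stop("glog offset `c` must be a positive scalar")
  }
  structure(list(a = a, b = b, c = c), class = "NormalizationModel")
}

# Grid-search the glog offset that flattens the dependence of the row-wise
# SD on mean intensity rank (the variance-stabilization criterion), using
# a running-quantile-free summary: absolute slope of lm(rowSD ~ rank).
choose_glog_offset <- function(calibrated) {
  spread <- stats::median(abs(calibrated - stats::median(calibrated)))
  if (spread <= 0) spread <- 1
  grid <- spread^2 * 2^seq(-10, 14, by = 0.5)
  crit <- vapply(grid, function(cc) {
    g <- glog_transform(calibrated, cc)
    dim(g) <- dim(calibrated)
    rsd <- apply(g, 1L, stats::sd)
    rmn <- rank(rowMeans(g)) / nrow(g)
    fit <- stats::lm.fit(cbind(1, rmn), rsd)
    abs(fit$coefficients[[2L]])
  }, numeric(1L))
  grid[[which.min(crit)]]
}

#' @export
print.NormalizationModel <- function(x, ...) {
  cat(sprintf("NormalizationModel: %d arrays, glog offset c = %.4g\n",
              length(x$a), x$c))
  invisible(x)
}

#' Apply a fitted calibration and glog2 transform
#'
#' @param x Raw-scale `ExpressionMatrix`.
#' @param model A `NormalizationModel` from [fit_vsn_calibration()]; if
#'   `NULL`, one is fitted on `x`.
#' @return A normalized `ExpressionMatrix` (glog2 scale).
#' @export
normalize_vsn <- function(x, model = NULL) {
  if (is.null(model)) model <- fit_vsn_calibration(x)
  if (!inherits(model, "NormalizationModel")) {
    stop("`model` must be a NormalizationModel")
  }
  v <- x$values
  if (!all(colnames(v) %in% names(model$a))) {
    stop("model does not cover all arrays in the matrix")
  }
  cal <- sweep(sweep(v, 2L, model$a[colnames(v)], "-"),
               2L, model$b[colnames(v)], "/")
  g <- glog_transform(cal, model$c)
  dim(g) <- dim(v)
  dimnames(g) <- dimnames(v)
  out <- x
  out$values <- g
  out$scale <- "normalized"
  out
}

#' Quantile normalization
#'
#' Forces every column to share the same distribution: each value is
#' replaced by the mean of the order statistics at its rank, with tied
#' values receiving the average of the target values they span.
#'
#' @param x An `ExpressionMatrix` (raw or normalized) with at least two
#'   columns and no missing values.
#' @return An `ExpressionMatrix` with identical sorted values per column;
#'   the scale flag is preserved.
#' @export
quantile_normalize <- function(x) {
  if (!is_expression_matrix(x)) stop("`x` must be an ExpressionMatrix")
  v <- x$values
  if (ncol(v) < 2L) stop("quantile normalization needs at least two arrays")
  if (any(is.na(v))) stop("quantile normalization input must be complete")
  target <- rowMeans(apply(v, 2L, sort))
  out_v <- apply(v, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    # fractional ranks from ties -> average the two flanking target values
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out_v) <- dimnames(v)
  out <- x
  out$values <- out_v
  out
}
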