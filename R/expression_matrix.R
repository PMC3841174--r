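#' Expression matrix container
#'
#' A light S3 container for a probeset-by-sample intensity matrix together
#' with an optional probeset-to-gene-symbol annotation and a scale flag
#' distinguishing raw linear intensities from log-like normalized values.
#'
#' @param values Numeric matrix, probesets in rows (rownames required,
#'   unique) and samples in columns (colnames required, unique).
#' @param scale Either `"raw"` (linear intensities) or `"normalized"`
#'   (log2/glog2 scale values ready for scoring and differential expression).
#' @param annotation Optional named character vector mapping probeset id to
#'   gene symbol. Probesets without an entry keep a missing symbol. Symbols
#'   are upper-cased on construction so joins are case-insensitive.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale` and `annotation`.
#' @export
expression_matrix <- function(values, scale = c("normalized", "raw"),
                              annotation = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probeset rownames and sample colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stop("duplicate probeset id: ", dup[[1L]])
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0) {
    stop("duplicate sample id: ", dup[[1L]])
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("expression values must be finite or NA")
  }
  ann <- rep(NA_character_, nrow(values))
  names(ann) <- rownames(values)
  if (!is.null(annotation)) {
    if (is.null(names(annotation))) {
      stop("`annotation` must be a named character vector")
    }
    hit <- intersect(names(annotation), rownames(values))
    ann[hit] <- toupper(as.character(annotation[hit]))
  }
  structure(list(values = values, scale = scale, annotation = ann),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d probesets x %d samples (%s scale), %d annotated\n",
    nrow(x$values), ncol(x$values), x$scale, sum(!is.na(x$annotation))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

stopifnot_normalized <- function(x, what) {
  if (!is_expression_matrix(x)) stop(what, " requires an ExpressionMatrix")
  if (x$scale != "normalized") {
    stop(what, " requires a normalized (log-scale) matrix; got scale = '",
         x$scale, "'")
  }
  invisible(x)
}
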