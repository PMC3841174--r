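#' Read an expression matrix from TSV or GEO Series Matrix format
#'
#' The TSV dialect is a header row of sample ids, first column probeset ids.
#' The Series Matrix dialect is the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` block of a GEO Series Matrix file: all
#' `!`-prefixed metadata lines are skipped, the table is read with quoted
#' fields honored, and the `"ID_REF"` column supplies probeset ids.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param annotation_path Optional path to a two-column (probeset id, gene
#'   symbol) TSV/CSV annotation table joined onto the matrix; probesets
#'   without a row keep a missing symbol.
#' @param scale Scale flag to record, `"normalized"` (default) or `"raw"`.
#' @return An `ExpressionMatrix`. Duplicate probeset ids are a hard error
#'   naming the first duplicate. Row/column/missing-symbol counts are
#'   reported via `message()`.
#' @export
read_expression_matrix <- function(path,
                                   format = c("tsv", "series_matrix"),
                                   annotation_path = NULL,
                                   scale = c("normalized", "raw")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "series_matrix") {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
      stop("malformed series matrix: table begin/end markers not found")
    }
    body <- lines[(beg + 1L):(end - 1L)]
    tab <- utils::read.delim(text = body, header = TRUE, quote = "\"",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!identical(toupper(names(tab)[[1L]]), "ID_REF")) {
      stop("malformed series matrix: first column must be ID_REF")
    }
  } else {
    tab <- utils::read.delim(path, header = TRUE, quote = "\"",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("malformed header: need id column plus samples")
  }

  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate probeset id: ", dup[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  rownames(values) <- ids

  ann <- NULL
  if (!is.null(annotation_path)) ann <- read_annotation(annotation_path)
  out <- expression_matrix(values, scale = scale, annotation = ann)
  message(sprintf("read %d probesets x %d samples (%d without gene symbol)",
                  nrow(values), ncol(values), sum(is.na(out$annotation))))
  out
}

#' Read a probeset-to-symbol annotation table
#'
#' Two columns (probeset id, gene symbol), TSV or CSV, with or without a
#' header (a header is assumed when the first field is not unique-looking
#' data; pass `header` explicitly to override).
#'
#' @param path File path.
#' @param header Logical; default `TRUE`.
#' @return Named character vector, probeset id to upper-cased symbol.
#' @export
read_annotation <- function(path, header = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = header, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation must have two columns")
  stats::setNames(toupper(as.character(tab[[2L]])), as.character(tab[[1L]]))
}

#' Write an expression matrix as TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path. First column `probeset_id`, then one column per
#'   sample; full precision is preserved.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is_expression_matrix(x))
  df <- data.frame(probeset_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-tumor clinical table
#'
#' Accepts TSV or CSV with a header; `sample_id` is required. Ordinal grade
#' and stage fields are mapped to 1-based integer codes through explicit,
#' configurable level orderings; unknown tokens become missing with a
#' warning. Survival times must be strictly positive: rows with a
#' non-positive time are rejected with a warning naming the sample.
#'
#' @param path File path.
#' @param grade_levels Ordered character vector of grade tokens
#'   (default `c("1","2","3")`).
#' @param stage_levels Ordered character vector of stage tokens
#'   (default `c("I","II","III","IV")`).
#' @param subtype_levels Recognized histologic subtypes; unknown tokens
#'   become `"other"`.
#' @return A data.frame of class `ClinicalTable` with integer `grade` and
#'   `stage` codes, character `subtype`, numeric `age`, binary
#'   `residual_disease`, and `dfs_time`/`dfs_event`/`os_time`/`os_event`
#'   where the columns are present in the file.
#' @export
read_clinical_table <- function(path,
                                grade_levels = c("1", "2", "3"),
                                stage_levels = c("I", "II", "III", "IV"),
                                subtype_levels = c("serous", "endometrioid",
                                                   "clear cell", "mucinous",
                                                   "other")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = TRUE)
  if (!"sample_id" %in% names(tab)) stop("missing sample_id column")
  tab$sample_id <- as.character(tab$sample_id)

  map_ordinal <- function(x, levels, what) {
    x <- trimws(as.character(x))
    code <- match(x, levels)
    bad <- !is.na(x) & x != "" & is.na(code)
    if (any(bad)) {
      warning(sprintf("%d unknown %s level(s) (e.g. '%s') set to missing",
                      sum(bad), what, x[bad][[1L]]), call. = FALSE)
    }
    code
  }
  if ("grade" %in% names(tab)) {
    tab$grade <- map_ordinal(tab$grade, grade_levels, "grade")
  }
  if ("stage" %in% names(tab)) {
    tab$stage <- map_ordinal(tab$stage, stage_levels, "stage")
  }
  if ("subtype" %in% names(tab)) {
    st <- tolower(trimws(as.character(tab$subtype)))
    unknown <- !is.na(st) & !(st %in% subtype_levels)
    if (any(unknown)) {
      warning(sprintf("%d unrecognized subtype token(s) mapped to 'other'",
                      sum(unknown)), call. = FALSE)
      st[unknown] <- "other"
    }
    tab$subtype <- st
  }
  for (ev in c("dfs_event", "os_event")) {
    if (ev %in% names(tab) && !all(tab[[ev]] %in% c(0L, 1L, NA))) {
      stop(ev, " must be 0/1")
    }
  }
  for (tm in c("dfs_time", "os_time")) {
    if (tm %in% names(tab)) {
      bad <- !is.na(tab[[tm]]) & tab[[tm]] <= 0
      if (any(bad)) {
        warning(sprintf("rejected %d row(s) with non-positive %s (e.g. %s)",
                        sum(bad), tm, tab$sample_id[bad][[1L]]),
                call. = FALSE)
        tab <- tab[!bad, , drop = FALSE]
      }
    }
  }
  class(tab) <- c("ClinicalTable", "data.frame")
  tab
}

#' Align a clinical table with an expression matrix
#'
#' Never silently reindexes: reports the intersection explicitly and
#' returns both objects restricted to the shared samples, in the
#' expression matrix order.
#'
#' @param x An `ExpressionMatrix`.
#' @param clinical A clinical data.frame with `sample_id`.
#' @return List with `matrix`, `clinical`, and `dropped` (list of the
#'   sample ids present on only one side).
#' @export
align_samples <- function(x, clinical) {
  stopifnot(is_expression_matrix(x), "sample_id" %in% names(clinical))
  shared <- intersect(colnames(x$values), clinical$sample_id)
  only_expr <- setdiff(colnames(x$values), shared)
  only_clin <- setdiff(clinical$sample_id, shared)
  if (length(only_expr) || length(only_clin)) {
    message(sprintf(
      "sample intersection: %d shared, %d expression-only, %d clinical-only",
      length(shared), length(only_expr), length(only_clin)))
  }
  if (length(shared) == 0L) stop("no shared samples")
  out <- x
  out$values <- x$values[, shared, drop = FALSE]
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  list(matrix = out, clinical = clin,
       dropped = list(expression_only = only_expr,
                      clinical_only = only_clin))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
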