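#' Signature construction and scoring
#'
#' A cell-of-origin signature is an ordered set of probesets with unique
#' gene symbols and weights +1 (FNE-up, fallopian-tube pole) or -1
#' (OCE-up, ovarian pole). A sample's score is the weighted sum of its
#' normalized expression values over the signature probesets present in
#' the matrix; higher scores are more FT-like.
#'
#' @param probeset_id,symbol Character vectors.
#' @param weight Integer vector of +1/-1 weights.
#' @return A data.frame of class `Signature`.
#' @export
signature_set <- function(probeset_id, symbol, weight) {
  sig <- data.frame(probeset_id = as.character(probeset_id),
                    symbol = toupper(as.character(symbol)),
                    weight = as.integer(weight),
                    stringsAsFactors = FALSE)
  validate_signature(sig)
}

validate_signature <- function(sig) {
  req <- c("probeset_id", "symbol", "weight")
  if (!is.data.frame(sig) || !all(req %in% names(sig))) {
    stop("signature needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(sig$weight %in% c(-1L, 1L))) stop("weights must be +1 or -1")
  if (anyDuplicated(sig$symbol)) {
    stop("duplicate gene symbol in signature: ",
         sig$symbol[duplicated(sig$symbol)][[1L]])
  }
  if (anyDuplicated(sig$probeset_id)) {
    stop("duplicate probeset in signature: ",
         sig$probeset_id[duplicated(sig$probeset_id)][[1L]])
  }
  class(sig) <- c("Signature", "data.frame")
  sig
}

# total significance order: ascending p, then descending |t|, then id
de_order <- function(de) {
  order(de$p, -abs(de$t), de$probeset_id)
}

#' Select the top discriminating probesets per direction
#'
#' Ranks probesets by ascending p, then descending absolute moderated t,
#' then probeset id (a total order), separately for each direction, and
#' takes the top `k_per_direction` with unique, non-missing gene symbols:
#' among probesets sharing a symbol only the best-ranked is eligible.
#' FNE-up entries get weight +1, OCE-up entries weight -1.
#'
#' @param de A `DEResult` data.frame.
#' @param k_per_direction Entries per direction (default 5, giving the
#'   standard 10-probeset signature; 10 gives the 20-probeset variant).
#' @param fdr Significance gate: only probesets with `q < fdr` are
#'   eligible (default 0.05). Use `Inf` to disable the gate.
#' @return A `Signature` with `2 * k_per_direction` rows, FNE-up first.
#' @export
select_signature <- function(de, k_per_direction = 5L, fdr = 0.05) {
  if (!inherits(de, "DEResult")) stop("`de` must be a DEResult")
  k <- as.integer(k_per_direction)
  if (k < 1L) stop("k_per_direction must be >= 1")
  de <- de[de_order(de), , drop = FALSE]
  pick <- function(direction) {
    cand <- de[de$direction == direction & de$q < fdr &
                 !is.na(de$symbol), , drop = FALSE]
    cand <- cand[!duplicated(cand$symbol), , drop = FALSE]
    if (nrow(cand) < k) {
      stop(sprintf(
        "insufficient eligible %s probesets: need %d, found %d",
        direction, k, nrow(cand)))
    }
    cand[seq_len(k), c("probeset_id", "symbol")]
  }
  up <- pick("FNE-up")
  dn <- pick("OCE-up")
  signature_set(c(up$probeset_id, dn$probeset_id),
                c(up$symbol, dn$symbol),
                rep(c(1L, -1L), each = k))
}

#' Score samples with a +1/-1 weighted signature
#'
#' `S_j = sum_i w_i * x_ij` over the signature probesets present in the
#' matrix. Probesets absent from the matrix are dropped from the sum and
#' `n_used` records how many remain (their ids are attached as attribute
#' `dropped`). Missing expression values among the used probesets are an
#' error: the score is a plain sum, never an imputation.
#'
#' @param x Normalized `ExpressionMatrix`.
#' @param signature A `Signature`.
#' @param standardize If `TRUE`, each signature probeset row is z-scored
#'   across samples before summing (cross-platform option; default
#'   `FALSE`, scoring plain normalized values).
#' @return Data.frame of class `ScoreSet`: `sample_id`, `score`, `n_used`.
#' @export
score_samples <- function(x, signature, standardize = FALSE) {
  stopifnot_normalized(x, "score_samples")
  signature <- validate_signature(signature)
  present <- signature$probeset_id %in% rownames(x$values)
  if (!any(present)) stop("no signature probeset present in the matrix")
  dropped <- signature$probeset_id[!present]
  sig <- signature[present, , drop = FALSE]
  sub <- x$values[sig$probeset_id, , drop = FALSE]
  if (any(is.na(sub))) {
    stop("missing expression values among signature probesets; ",
         "scores are plain sums and do not impute")
  }
  if (standardize) {
    sub <- t(scale(t(sub)))
    if (any(!is.finite(sub))) {
      stop("constant probeset row cannot be z-scored")
    }
  }
  # plus- and minus-sums kept separate so a sample with all signature
  # values equal scores exactly zero (no dot-product roundoff)
  up <- sig$weight == 1L
  s_up <- if (any(up)) colSums(sub[up, , drop = FALSE]) else 0
  s_dn <- if (any(!up)) colSums(sub[!up, , drop = FALSE]) else 0
  s <- as.numeric(s_up - s_dn)
  out <- data.frame(sample_id = colnames(x$values), score = s,
                    n_used = nrow(sig), stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("ScoreSet", "data.frame")
  out
}

#' Draw a random +1/-1 signature from a probeset universe
#'
#' Samples `2 * k_per_direction` probesets without replacement, honoring
#' gene-symbol uniqueness (at most one probeset per symbol), and assigns
#' the first half weight +1 and the second half weight -1. Used to build
#' the permuted-signature null ensemble.
#'
#' @param universe Data.frame with `probeset_id` and `symbol` (probesets
#'   with missing symbols are excluded).
#' @param k_per_direction Entries per direction (default 5).
#' @param seed Integer seed; same seed, same signature.
#' @return A `Signature`.
#' @export
random_signature <- function(universe, k_per_direction = 5L, seed = 1L) {
  k <- as.integer(k_per_direction)
  if (!all(c("probeset_id", "symbol") %in% names(universe))) {
    stop("universe needs probeset_id and symbol columns")
  }
  u <- universe[!is.na(universe$symbol), c("probeset_id", "symbol")]
  u$symbol <- toupper(u$symbol)
  if (length(unique(u$symbol)) < 2L * k) {
    stop("universe too small: need ", 2L * k, " distinct symbols")
  }
  set.seed(seed)
  # pick one probeset per symbol uniformly, then sample symbols
  perm <- u[sample.int(nrow(u)), , drop = FALSE]
  perm <- perm[!duplicated(perm$symbol), , drop = FALSE]
  take <- perm[sample.int(nrow(perm), 2L * k), , drop = FALSE]
  signature_set(take$probeset_id, take$symbol,
                rep(c(1L, -1L), each = k))
}
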