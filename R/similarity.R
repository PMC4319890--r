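#' @title Similarity scoring and top-N ranking
#' @name similarity
#' @description
#' Two descriptor vectors are compared with an inverse weighted Manhattan
#' score scaled to (0, 1]:
#'
#' \deqn{S_{qc} = \frac{1}{1 + \sum_k w_k \cdot \frac{1}{12}
#'   \sum_{i \in k} |q_i - c_i|}}
#'
#' where k runs over the four channels and the inner sum over that
#' channel's twelve entries. With a single all-atom channel and unit
#' weight this reduces to the published USR score
#' \eqn{1 / (1 + \frac{1}{12}\sum |q_i - c_i|)}. The score is 1 exactly
#' when the vectors are identical, symmetric, and strictly decreasing in
#' every per-entry difference whose channel has positive weight.
NULL

#' Per-channel weights
#'
#' @param w_all,w_hydrophobic,w_acceptor,w_donor non-negative weights;
#'   normalised to sum 1.
#' @return a `ChannelWeights` numeric vector of length 4.
#' @export
channel_weights <- function(w_all = 0.25, w_hydrophobic = 0.25,
                            w_acceptor = 0.25, w_donor = 0.25) {
  w <- c(all = w_all, hydrophobic = w_hydrophobic,
         acceptor = w_acceptor, donor = w_donor)
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be non-negative")
  if (sum(w) <= 0) stop("at least one weight must be positive")
  structure(w / sum(w), class = "ChannelWeights")
}

.check_conventions <- function(q, c) {
  for (a in c("mode", "skew", "per_channel_refpoints")) {
    qa <- attr(q, a); ca <- attr(c, a)
    if (!is.null(qa) && !is.null(ca) && !identical(qa, ca))
      stop("descriptor convention mismatch: ", a, " '", qa, "' vs '", ca, "'")
  }
  if (length(q) != length(c))
    stop("descriptor length mismatch: ", length(q), " vs ", length(c))
}

#' Similarity score between two descriptor vectors
#'
#' @param q,c descriptor vectors of the same mode and build conventions
#'   (length 48 typed, or length 12 all-atom).
#' @param w a [channel_weights()] object; ignored for 12-value vectors,
#'   which use the single all-atom channel with weight 1.
#' @return similarity in (0, 1]; 1 exactly iff the vectors are equal.
#' @export
score <- function(q, c, w = channel_weights()) {
  .check_conventions(q, c)
  ad <- abs(as.numeric(q) - as.numeric(c))
  if (length(ad) == 12) return(1 / (1 + sum(ad) / 12))
  if (length(ad) != 48) stop("descriptor vectors must have length 12 or 48")
  d <- c(sum(ad[1:12]), sum(ad[13:24]), sum(ad[25:36]), sum(ad[37:48])) / 12
  1 / (1 + sum(as.numeric(w) * d))
}

# scores for a 48 x m (or 12 x m) matrix of candidate columns, vectorised
.score_matrix <- function(qv, mat, w) {
  ad <- abs(mat - qv)
  if (nrow(mat) == 12) return(1 / (1 + colSums(ad) / 12))
  d <- rbind(colSums(ad[1:12, , drop = FALSE]),
             colSums(ad[13:24, , drop = FALSE]),
             colSums(ad[25:36, , drop = FALSE]),
             colSums(ad[37:48, , drop = FALSE])) / 12
  1 / (1 + colSums(as.numeric(w) * d))
}

# order ids ascending: numerically when all coerce cleanly, else lexically
.id_order_key <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) num else as.character(ids)
}

# merge a batch of (id, score) into a running top-n buffer
.topn_merge <- function(buf, ids, scores, n) {
  ids <- c(buf$id, ids)
  scores <- c(buf$score, scores)
  ord <- order(-scores, .id_order_key(ids))
  keep <- ord[seq_len(min(n, length(ord)))]
  list(id = ids[keep], score = scores[keep])
}

#' Rank candidates against a query, keeping the top N
#'
#' A single pass over the candidate stream with a bounded top-N buffer
#' (memory O(N + batch)), so the stream may be arbitrarily large. Ties in
#' score are broken by ascending candidate id for reproducible lists.
#'
#' @param q the query `DescriptorVector`.
#' @param candidates a named list of descriptor vectors, or a function
#'   `function()` returning the next batch as a named list (`NULL` when
#'   exhausted), for streaming sources.
#' @param n number of hits to keep (>= 1).
#' @param w a [channel_weights()] object.
#' @return a `RankedHits` data frame with columns `id` and `score`,
#'   descending score.
#' @export
rank_hits <- function(q, candidates, n = 500L, w = channel_weights()) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  buf <- list(id = character(0), score = numeric(0))
  next_batch <- if (is.function(candidates)) candidates else {
    served <- FALSE
    function() {
      if (served) return(NULL)
      served <<- TRUE
      candidates
    }
  }
  repeat {
    batch <- next_batch()
    if (is.null(batch) || length(batch) == 0) {
      if (is.null(batch)) break
      next
    }
    for (v in batch) .check_conventions(q, v)
    mat <- vapply(batch, as.numeric, numeric(length(q)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(q))
    sc <- .score_matrix(as.numeric(q), mat, w)
    buf <- .topn_merge(buf, names(batch), sc, n)
  }
  structure(data.frame(id = buf$id, score = buf$score,
                       stringsAsFactors = FALSE),
            class = c("RankedHits", "data.frame"))
}

#' @export
print.RankedHits <- function(x, ...) {
  cat(sprintf("Top %d hits by similarity:\n", nrow(x)))
  print.data.frame(utils::head(x, 20), row.names = FALSE, ...)
  if (nrow(x) > 20) cat("...", nrow(x) - 20, "more\n")
  invisible(x)
}
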