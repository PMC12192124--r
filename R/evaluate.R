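#' Signed edge predictions of one window network
#'
#' Flattens a window's signed adjacency matrix into a prediction table:
#' one row per ordered non-self gene pair with nonzero adjacency, scored
#' by the absolute adjacency value and carrying the predicted sign.
#'
#' @param window one element of an `fdygrn` fit's `windows` list, or any
#'   list with an `adjacency` matrix with gene dimnames
#' @return data.frame with columns `regulator`, `target`, `score`, `sign`
#' @export
window_predictions <- function(window) {
  adj <- window$adjacency
  genes <- rownames(adj)
  idx <- which(adj != 0, arr.ind = TRUE)
  data.frame(regulator = genes[idx[, 1L]], target = genes[idx[, 2L]],
             score = abs(adj[idx]), sign = sign(adj[idx]),
             stringsAsFactors = FALSE)
}

#' Sign-aware AUROC against a gold-standard network
#'
#' Area under the ROC curve where a predicted edge counts as a true
#' positive only if both its presence and its sign match the gold
#' standard. The instance construction mirrors that definition exactly:
#' every gold edge is one positive instance, scored by its prediction's
#' |adjacency| when the predicted sign matches the gold sign and 0
#' otherwise (a wrong-signed or absent prediction never detects it);
#' every non-gold ordered non-self pair is a negative instance scored by
#' its prediction (0 when absent); and a gold pair predicted with the
#' wrong sign additionally contributes a negative instance carrying its
#' score — a false positive at any threshold admitting it. The AUROC is
#' the Mann-Whitney probability that a positive outranks a negative,
#' ties counted one half, so an uninformative (all-tied) prediction
#' scores 0.5.
#'
#' @param predictions data.frame with columns `regulator`, `target`,
#'   `score` (non-negative), `sign` (-1/+1), e.g. from
#'   [window_predictions()]
#' @param gold a `grn` object
#' @param gene_filter optional character vector restricting the instance
#'   universe to pairs among these genes (e.g. the gold-standard TF
#'   subset of a larger inferred network)
#' @return AUROC in `[0, 1]`
#' @export
signed_auroc <- function(predictions, gold, gene_filter = NULL) {
  stopifnot(inherits(gold, "grn"))
  genes <- gold$genes
  if (!is.null(gene_filter)) genes <- intersect(genes, gene_filter)
  if (length(genes) < 2L) stop("fewer than 2 genes in the instance universe")
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  key <- function(r, t) paste(r, t, sep = "\r")
  allk <- key(pairs$regulator, pairs$target)
  score <- stats::setNames(rep(0, nrow(pairs)), allk)
  psign <- stats::setNames(rep(0, nrow(pairs)), allk)
  if (nrow(predictions) > 0L) {
    pk <- key(predictions$regulator, predictions$target)
    keep <- pk %in% allk
    score[pk[keep]] <- predictions$score[keep]
    psign[pk[keep]] <- predictions$sign[keep]
  }
  gk <- key(gold$edges$regulator, gold$edges$target)
  gsign <- stats::setNames(gold$edges$sign, gk)
  ing <- gk %in% allk
  gk <- gk[ing]
  gsign <- gsign[ing]
  if (length(gk) == 0L)
    stop("gold standard has no edges in the universe: AUROC undefined")
  # positives: one per gold edge, detected only by a correctly signed
  # prediction
  pos_scores <- ifelse(psign[gk] == gsign, score[gk], 0)
  # negatives: all non-gold pairs, plus wrong-signed predictions on gold
  # pairs (false positives carrying their score)
  neg_scores <- score[setdiff(allk, gk)]
  wrong <- psign[gk] != 0 & psign[gk] != gsign
  neg_scores <- c(neg_scores, score[gk][wrong])
  if (length(neg_scores) == 0L)
    stop("gold standard covers every pair with matching signs: AUROC undefined")
  r <- rank(c(pos_scores, neg_scores))
  npos <- length(pos_scores)
  nneg <- length(neg_scores)
  (sum(r[seq_len(npos)]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Signed similarity of two consecutive window networks
#'
#' Ratio of edges matching in presence, direction and sign to the total
#' number of unique directed edges across the two networks (a signed
#' Jaccard index). Two empty networks count as identical (1).
#'
#' @param net1,net2 window networks over the same gene set (elements of
#'   an `fdygrn` fit's `windows`)
#' @return similarity in `[0, 1]`
#' @export
consecutive_similarity <- function(net1, net2) {
  a1 <- net1$adjacency
  a2 <- net2$adjacency
  if (!identical(dim(a1), dim(a2)) ||
      !identical(rownames(a1), rownames(a2)))
    stop("the two networks must share one gene set")
  e1 <- a1 != 0
  e2 <- a2 != 0
  union_n <- sum(e1 | e2)
  if (union_n == 0L) return(1)
  match_n <- sum(e1 & e2 & (sign(a1) == sign(a2)))
  match_n / union_n
}

#' Score a dynamic-network fit against a gold standard
#'
#' Computes the sign-aware AUROC of every window network, their mean, and
#' the signed similarity of each consecutive window pair.
#'
#' @param result an `fdygrn` fit
#' @param gold a `grn` object
#' @param gene_filter optional gene subset for the AUROC universe, see
#'   [signed_auroc()]
#' @return object of class `fdygrn_eval`: list with `per_window_auroc`,
#'   `mean_auroc` and `similarity`
#' @export
evaluate_run <- function(result, gold, gene_filter = NULL) {
  stopifnot(inherits(result, "fdygrn"), inherits(gold, "grn"))
  auc <- vapply(result$windows, function(w)
    signed_auroc(window_predictions(w), gold, gene_filter), numeric(1))
  nw <- length(result$windows)
  sim <- if (nw > 1L)
    vapply(seq_len(nw - 1L), function(i)
      consecutive_similarity(result$windows[[i]], result$windows[[i + 1L]]),
      numeric(1)) else numeric(0)
  structure(list(per_window_auroc = auc, mean_auroc = mean(auc),
                 similarity = sim), class = "fdygrn_eval")
}

#' @export
print.fdygrn_eval <- function(x, ...) {
  cat(sprintf("Signed AUROC per window: %s\n",
              paste(round(x$per_window_auroc, 3), collapse = ", ")))
  cat(sprintf("Mean signed AUROC: %.3f\n", x$mean_auroc))
  if (length(x$similarity))
    cat(sprintf("Consecutive-window similarity: %s\n",
                paste(round(x$similarity, 3), collapse = ", ")))
  invisible(x)
}
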