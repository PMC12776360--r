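#' AUROC and AUPRC
#'
#' AUROC is computed from the rank statistic (Mann-Whitney form, ties
#' averaged); AUPRC by step integration of the precision-recall curve
#' (average precision), with ranking ties broken by a stable sort on
#' decreasing score then original position.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels; both classes must be present.
#' @return list with `auroc` and `auprc`.
#' @export
auroc_auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stop_if(length(scores) != length(labels), "length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  stop_if(np == 0L || nn == 0L, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  auprc <- sum(prec[y == 1L]) / np
  list(auroc = auroc, auprc = auprc)
}

#' Enrichment factor at a top-ranked cutoff
#'
#' Fold enrichment of actives among the top `cutoff_pct` percent of the
#' ranking relative to random selection:
#' `EF = (actives in top k / k) / (actives / N)` with
#' `k = ceiling(cutoff_pct/100 * N)`. Ranking ties are broken by a stable
#' sort on (-score, position).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (>= 1 active).
#' @param cutoff_pct percentage cutoff (e.g. 0.5, 1, 2).
#' @return EF value >= 0.
#' @export
enrichment_factor <- function(scores, labels, cutoff_pct) {
  labels <- as.integer(labels)
  n <- length(labels)
  na <- sum(labels == 1L)
  stop_if(na == 0L, "no actives in labels")
  k <- max(1L, as.integer(ceiling(cutoff_pct / 100 * n)))
  ord <- order(-scores, seq_along(scores))
  hits <- sum(labels[ord][seq_len(k)] == 1L)
  (hits / k) / (na / n)
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon-Bayly): the
#' exponentially weighted Robust Initial Enhancement normalised to [0, 1],
#' emphasising actives ranked at the very top. With active ranks r_i among N
#' compounds, Ra = n_actives/N and weighting parameter alpha,
#' `RIE = (sum_i exp(-alpha r_i / N)) / (Ra * (1 - exp(-alpha)) / (exp(alpha/N) - 1))`
#' and
#' `BEDROC = RIE * Ra * sinh(alpha/2) / (cosh(alpha/2) - cosh(alpha/2 - alpha*Ra)) + 1 / (1 - exp(alpha*(1 - Ra)))`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (>= 1 active and >= 1 inactive).
#' @param alpha early-recognition weighting parameter (default 80.5).
#' @return BEDROC value in [0, 1].
#' @export
bedroc <- function(scores, labels, alpha = 80.5) {
  labels <- as.integer(labels)
  n <- length(labels)
  na <- sum(labels == 1L)
  stop_if(na == 0L || na == n, "need at least one active and one inactive")
  ord <- order(-scores, seq_along(scores))
  ranks <- which(labels[ord] == 1L)
  ra <- na / n
  rie <- sum(exp(-alpha * ranks / n)) /
    (ra * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}
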