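# Residual fusion, MLP interaction head, and the dual
# BCE + supervised-contrastive objective.

#' Fuse one drug-protein pair into a joint embedding
#'
#' The fused pair embedding is the concatenation of the protein and drug
#' DCGAT outputs, each with a scaled residual connection to its
#' (dimension-matched) initial encoding:
#' `Z = [(p_i + delta * x_i) || (d_j + gamma * y_j)]`.
#'
#' @param p_i protein output row (length d).
#' @param x_i dimension-matched initial protein encoding (length d).
#' @param d_j drug output row (length d).
#' @param y_j dimension-matched initial drug encoding (length d).
#' @param delta,gamma residual scales (>= 0).
#' @return numeric vector of length 2d.
#' @export
fuse_pair <- function(p_i, x_i, d_j, y_j, delta = 1, gamma = 1) {
  stop_if(length(p_i) != length(x_i),
          "protein residual dimension mismatch: ", length(p_i), " vs ",
          length(x_i))
  stop_if(length(d_j) != length(y_j),
          "drug residual dimension mismatch: ", length(d_j), " vs ",
          length(y_j))
  c(p_i + delta * x_i, d_j + gamma * y_j)
}

# tape-aware fused embeddings for a batch of pairs.
# fw: output of dcgat_forward_core; XR, YR: residual-projected initial
# encodings (nodes or matrices); ip, id: pair index vectors.
fuse_batch_core <- function(tape, fw, XR, YR, ip, id, cfg) {
  Zp <- ad_add(tape, ad_rows(tape, fw$P, ip),
               ad_smul(tape, ad_rows(tape, XR, ip), cfg$delta))
  Zd <- ad_add(tape, ad_rows(tape, fw$D, id),
               ad_smul(tape, ad_rows(tape, YR, id), cfg$gamma))
  ad_cbind(tape, Zp, Zd)
}

# tape-aware MLP head on fused embeddings; returns the sigmoid scores
mlp_head_core <- function(tape, pl, Z, n_hidden) {
  h <- Z
  for (i in seq_len(n_hidden)) {
    h <- ad_relu(tape, ad_bias(tape, ad_mm(tape, h, pl[[sprintf("head_W%d", i)]]),
                               pl[[sprintf("head_b%d", i)]]))
  }
  logit <- ad_bias(tape, ad_mm(tape, h, pl$head_Wout), pl$head_bout)
  ad_sigmoid(tape, logit)
}

#' Predict interaction scores from fused pair embeddings
#'
#' Runs the MLP interaction head (ReLU hidden layers, sigmoid output) on a
#' matrix of fused embeddings.
#'
#' @param Z matrix of fused pair embeddings (one row per pair).
#' @param params parameter list containing the `head_*` tensors (from
#'   [dcgat_init]).
#' @param config a [dcgat_config] (supplies the number of hidden layers).
#' @return numeric vector of scores in (0, 1).
#' @export
predict_scores <- function(Z, params, config = dcgat_config()) {
  Z <- as.matrix(Z)
  stop_if(any(!is.finite(Z)), "non-finite input to prediction head")
  as.vector(mlp_head_core(NULL, params, Z, length(config$head_hidden)))
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy of predicted interaction scores against binary
#' labels, with logs clamped at `eps`.
#'
#' @param scores numeric vector in (0, 1).
#' @param labels binary vector of the same length.
#' @param eps clamp applied inside the logs.
#' @return scalar >= 0.
#' @export
bce_loss <- function(scores, labels, eps = 1e-12) {
  stop_if(length(scores) != length(labels),
          "scores and labels differ in length")
  -mean(labels * log(pmax(scores, eps)) +
          (1 - labels) * log(pmax(1 - scores, eps)))
}

#' Supervised contrastive loss over a batch of fused pair embeddings
#'
#' Temperature-scaled softmax (NT-Xent style) loss that pulls together the
#' fused embeddings of drug-protein pairs sharing the same interaction label
#' and pushes apart the rest. For each anchor k, the positive set P(k) holds
#' the other batch samples with the same label and A(k) all other samples;
#' the per-anchor loss is
#' `-(1/|P(k)|) sum_{r in P(k)} log( exp(s_kr/tau) / sum_{l in A(k)} exp(s_kl/tau) )`
#' and anchors with empty P(k) are excluded from the mean. The similarity s
#' is cosine by default (`similarity = "dot"` uses the raw dot product).
#'
#' @param Z matrix of fused embeddings (>= 2 rows).
#' @param labels binary labels, one per row.
#' @param tau_c contrastive temperature > 0.
#' @param similarity `"cosine"` or `"dot"`.
#' @return scalar >= 0 (0 with a warning if every anchor is skipped).
#' @export
contrastive_loss <- function(Z, labels, tau_c = 0.5,
                             similarity = c("cosine", "dot")) {
  similarity <- match.arg(similarity)
  Z <- as.matrix(Z)
  stop_if(nrow(Z) < 2L, "contrastive loss needs a batch of >= 2 samples")
  stop_if(nrow(Z) != length(labels), "labels must match rows of Z")
  stop_if(tau_c <= 0, "tau_c must be > 0")
  val <- contrastive_core(NULL, Z, labels, tau_c, similarity)
  if (is.null(val)) {
    warning("all anchors skipped (no same-label partner); returning 0")
    return(0)
  }
  as.numeric(val)
}

# tape-aware contrastive loss; returns NULL when no anchor has a positive
contrastive_core <- function(tape, Z, labels, tau_c, similarity) {
  nb <- nrow(ad_val(Z))
  same <- outer(labels, labels, "==") * 1
  diag(same) <- 0
  npos <- rowSums(same)
  valid <- npos > 0
  if (!any(valid)) return(NULL)
  if (similarity == "cosine") {
    ss <- ad_rowsums(tape, ad_emul(tape, Z, Z))
    inv <- ad_rsqrt(tape, ad_sadd(tape, ss, 1e-12))
    Zs <- ad_rowmul(tape, Z, inv)
  } else {
    Zs <- Z
  }
  S <- ad_smul(tape, ad_mm(tape, Zs, ad_t(tape, Zs)), 1 / tau_c)
  off <- matrix(1, nb, nb); diag(off) <- 0
  sv <- ad_val(S)
  mx <- apply(sv + log(off), 1L, max)  # detached row max over A(k)
  e <- ad_cmul(tape, ad_exp(tape, ad_shift_rows(tape, S, mx)), off)
  logden <- ad_add(tape, ad_log(tape, ad_rowsums(tape, e)),
                   matrix(mx, ncol = 1L))
  term <- ad_sub_colvec(tape, S, logden)   # log softmax over A(k)
  wt <- same / pmax(npos, 1) / sum(valid)
  wt[!valid, ] <- 0
  ad_smul(tape, ad_sum(tape, ad_cmul(tape, term, wt)), -1)
}

#' Total training loss
#'
#' Weighted combination of the BCE and contrastive components:
#' `L_total = L_BCE + lambda * L_contrastive`.
#'
#' @param bce BCE loss value.
#' @param contrastive contrastive loss value.
#' @param lambda contrastive weight >= 0.
#' @return scalar.
#' @export
total_loss <- function(bce, contrastive, lambda = 0.1) {
  stop_if(lambda < 0, "lambda must be >= 0")
  bce + lambda * contrastive
}

# tape-aware BCE on score node
bce_core <- function(tape, scores, labels, eps = 1e-12) {
  y <- matrix(labels, ncol = 1L)
  lp <- ad_log(tape, ad_sadd(tape, scores, eps))
  ln <- ad_log(tape, ad_sadd(tape, ad_smul(tape, scores, -1), 1 + eps))
  ad_smul(tape, ad_mean(tape, ad_add(tape, ad_cmul(tape, lp, y),
                                     ad_cmul(tape, ln, 1 - y))), -1)
}
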