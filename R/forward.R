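# The DCGAT forward stack.
#
# All functions here are tape-aware: with a live tape and leaf-wrapped
# parameters they build the computation graph for training; with tape = NULL
# and plain parameter matrices they compute the same values with ordinary
# matrix arithmetic (deterministic inference).

# Cross-neighborhood selection policy for one side.
#   Q: query-side node embeddings at this layer (nq x d)
#   C: cross-side node embeddings (nc x d)
#   A_hat_cross: normalised adjacency of the cross side's similarity graph
# A 2-layer GCN over the cross graph yields structural context per cross
# candidate; a pairwise scorer MLP on [query || context] emits two logits
# (select / not-select) per (query, candidate) pair. Returns the
# select-probability matrix as an (nq*nc) x 1 column, row-major in the query
# index.
cns_policy_core <- function(tape, pl, l, side, Q, C, A_hat_cross) {
  nm <- function(x) pl[[sprintf("L%d_cns_%s_%s", l, side, x)]]
  nq <- nrow(ad_val(Q)); nc <- nrow(ad_val(C))
  stop_if(nc == 0L, "empty cross side: no candidate nodes to select from")
  g1 <- ad_relu(tape, ad_mm(tape, ad_mm_amat(tape, A_hat_cross, C), nm("gcn1")))
  ctx <- ad_mm(tape, ad_mm_amat(tape, A_hat_cross, g1), nm("gcn2"))
  qh <- ad_mm(tape, Q, nm("q"))       # nq x hs
  ch <- ad_mm(tape, ctx, nm("c"))     # nc x hs
  idx_q <- rep(seq_len(nq), each = nc)
  idx_c <- rep(seq_len(nc), times = nq)
  hid <- ad_relu(tape, ad_bias(tape, ad_add(tape,
                                            ad_rows(tape, qh, idx_q),
                                            ad_rows(tape, ch, idx_c)),
                               nm("b")))
  logits <- ad_bias(tape, ad_mm(tape, hid, nm("o")), nm("bo"))  # (nq*nc) x 2
  lv <- ad_val(logits)
  d10 <- ad_node(tape, lv[, 1L, drop = FALSE] - lv[, 2L, drop = FALSE],
                 list(logits), function(g) list(cbind(g, -g)))
  ad_sigmoid(tape, d10)  # two-way softmax select probability
}

# one multi-head dual-attention layer update for one side.
#   Q: this side's embeddings (n x d); Xn: cross side's embeddings (nc x d)
#   Mintra: constant {0,1} intra-neighborhood mask (n x n)
#   Asel: selection mask node/matrix (n x nc)
#   Qnb, Xnb: neighbor-path versions of Q and Xn (equal to Q / Xn except in
#   the noise-injection probe)
layer_update_side <- function(tape, pl, l, side, Q, Qnb, Xn, Xnb, Mintra,
                              Asel, cfg) {
  acc <- NULL
  for (h in seq_len(cfg$n_heads)) {
    nm <- function(x) pl[[sprintf("L%d_H%d_%s_%s", l, h, side, x)]]
    da <- cfg$att_dim
    # intra-graph attention (scores: LeakyReLU(phi' [W q_i || W q_r]))
    Wq <- ad_mm(tape, Q, nm("intra_W"))
    Wn <- ad_mm(tape, Qnb, nm("intra_W"))
    phi <- nm("intra_phi")
    phv <- ad_val(phi)
    s1 <- ad_mm(tape, Wq, ad_rows(tape, phi, seq_len(da)))
    s2 <- ad_mm(tape, Wn, ad_rows(tape, phi, da + seq_len(da)))
    Ei <- ad_leakyrelu(tape, ad_outer_sum(tape, s1, s2), cfg$leaky_slope)
    alpha <- ad_masked_softmax(tape, Ei, Mintra)
    intra <- ad_mm(tape, alpha, ad_mm(tape, Qnb, nm("W1")))
    # cross-graph attention over dynamically selected cross neighbors
    Wc <- ad_mm(tape, Q, nm("cross_W"))
    Wx <- ad_mm(tape, Xnb, nm("cross_W"))
    phc <- nm("cross_phi")
    c1 <- ad_mm(tape, Wc, ad_rows(tape, phc, seq_len(da)))
    c2 <- ad_mm(tape, Wx, ad_rows(tape, phc, da + seq_len(da)))
    Ec <- ad_leakyrelu(tape, ad_outer_sum(tape, c1, c2), cfg$leaky_slope)
    beta <- ad_masked_softmax(tape, Ec, Asel)
    cross <- ad_mm(tape, beta, ad_mm(tape, Xnb, nm("W2")))
    head_out <- ad_elu(tape, ad_add(tape, intra, cross))
    acc <- if (is.null(acc)) head_out else ad_add(tape, acc, head_out)
  }
  ad_smul(tape, acc, 1 / cfg$n_heads)
}

# full stack. pl: list of parameter nodes (training) or matrices (inference).
# Returns P, D (nodes or matrices), per-layer selection info.
dcgat_forward_core <- function(tape, pl, X, Y, gP, gD, cfg,
                               stochastic = TRUE, noise_sd = 0) {
  m <- nrow(X); n <- nrow(Y)
  stop_if(m == 0L || n == 0L, "empty modality")
  P <- ad_bias(tape, ad_mm_amat(tape, X, pl$proj_P), pl$b_proj_P)
  D <- ad_bias(tape, ad_mm_amat(tape, Y, pl$proj_D), pl$b_proj_D)
  sel_log <- list()
  if (cfg$variant == "no_dcgat" || cfg$n_layers == 0L) {
    return(list(P = P, D = D, selection_log = data.frame()))
  }
  MP <- graph_adjacency(gP); MD <- graph_adjacency(gD)
  if (cfg$self_inclusion) { diag(MP) <- 1; diag(MD) <- 1 }
  AhP <- gcn_adjacency(gP); AhD <- gcn_adjacency(gD)
  for (l in seq_len(cfg$n_layers)) {
    if (cfg$variant == "no_dynamic_neighborhood") {
      AselP <- matrix(1, m, n)
      AselD <- matrix(1, n, m)
      fr_p <- rep(1, m); fr_d <- rep(1, n)
    } else {
      rho_p <- cns_policy_core(tape, pl, l, "p", P, D, AhD)  # (m*n) x 1
      rho_d <- cns_policy_core(tape, pl, l, "d", D, P, AhP)  # (n*m) x 1
      if (stochastic) {
        ap <- st_select(tape, rho_p, cfg$temperature, eps = cfg$gs_eps)
        ad_ <- st_select(tape, rho_d, cfg$temperature, eps = cfg$gs_eps)
      } else {
        ap <- matrix(as.numeric(ad_val(rho_p) > 0.5), ncol = 1L)
        ad_ <- matrix(as.numeric(ad_val(rho_d) > 0.5), ncol = 1L)
      }
      AselP <- ad_reshape_rowmajor(tape, ap, m, n)
      AselD <- ad_reshape_rowmajor(tape, ad_, n, m)
      fr_p <- rowMeans(ad_val(AselP)); fr_d <- rowMeans(ad_val(AselD))
    }
    sel_log[[l]] <- rbind(
      data.frame(layer = l, side = "protein", node = seq_len(m),
                 selected_fraction = fr_p),
      data.frame(layer = l, side = "drug", node = seq_len(n),
                 selected_fraction = fr_d))
    Pnb <- P; Dnb <- D
    if (noise_sd > 0) {
      Pnb <- ad_add(tape, P, matrix(stats::rnorm(m * cfg$d, 0, noise_sd), m))
      Dnb <- ad_add(tape, D, matrix(stats::rnorm(n * cfg$d, 0, noise_sd), n))
    }
    Pn <- layer_update_side(tape, pl, l, "p", P, Pnb, D, Dnb, MP, AselP, cfg)
    Dn <- layer_update_side(tape, pl, l, "d", D, Dnb, P, Pnb, MD, AselD, cfg)
    P <- Pn; D <- Dn
    chk <- ad_val(P)
    stop_if(any(!is.finite(chk)) || any(!is.finite(ad_val(D))),
            "non-finite embedding at layer ", l)
  }
  list(P = P, D = D, selection_log = do.call(rbind, sel_log))
}

#' Run the DCGAT encoder stack
#'
#' Applies the learnable input projections to the raw protein and drug
#' embeddings, then `n_layers` rounds of (cross-neighborhood selection ->
#' straight-through Gumbel-softmax sampling -> dual intra/cross multi-head
#' attention update), returning the final node embeddings of both modalities
#' and a log of the per-node cross-neighbor selection fractions per layer.
#'
#' @param params parameter list from [dcgat_init].
#' @param protein_emb,drug_emb [dti_embeddings] objects (or plain matrices).
#' @param gP,gD `similarity_graph`s over the same row orderings.
#' @param config a [dcgat_config].
#' @param stochastic sample selections with Gumbel noise (training
#'   behaviour); `FALSE` uses the deterministic argmax of the policy
#'   (inference behaviour).
#' @param seed RNG seed for the Gumbel draws (ignored when
#'   `stochastic = FALSE`).
#' @return list with `P` (m x d), `D` (n x d), `selection_log` (data.frame
#'   with columns layer, side, node, selected_fraction).
#' @export
dcgat_forward <- function(params, protein_emb, drug_emb, gP, gD,
                          config = dcgat_config(), stochastic = TRUE,
                          seed = 1) {
  X <- if (inherits(protein_emb, "dti_embeddings")) protein_emb$values else protein_emb
  Y <- if (inherits(drug_emb, "dti_embeddings")) drug_emb$values else drug_emb
  out <- with_seed(derive_seed(seed, 2),
                   dcgat_forward_core(NULL, params, X, Y, gP, gD, config,
                                      stochastic = stochastic))
  out$P <- ad_val(out$P); out$D <- ad_val(out$D)
  out
}

#' Cross-neighborhood selection policy distribution
#'
#' Evaluates one side's CNS policy: for every query node of one modality, a
#' strictly positive two-way probability (select / not-select) for each node
#' of the other modality, conditioned on the query embedding and the
#' cross-side embeddings contextualised by a GCN over the cross similarity
#' graph.
#'
#' @param params parameter list from [dcgat_init].
#' @param layer layer index.
#' @param side `"p"` (proteins selecting drug neighbors) or `"d"`.
#' @param Q query-side embeddings at this layer (nq x d).
#' @param C cross-side embeddings (nc x d).
#' @param g_cross `similarity_graph` over the cross side.
#' @param config a [dcgat_config].
#' @return nq x nc matrix of select probabilities (each entry pairs with its
#'   complement to form the two-way distribution).
#' @export
cns_forward <- function(params, layer, side, Q, C, g_cross,
                        config = dcgat_config()) {
  rho <- cns_policy_core(NULL, params, layer, side, Q, C,
                         gcn_adjacency(g_cross))
  matrix(as.vector(rho), nrow(Q), nrow(C), byrow = TRUE)
}

#' Intra-graph attention coefficients (single node, single head)
#'
#' Direct evaluation of the graph-attention coefficients over a node's
#' intra-graph neighbors: softmax over
#' `LeakyReLU(phi' [W q || W n_r])`.
#'
#' @param query query node embedding (length-d vector).
#' @param neighbors matrix of neighbor embeddings (r x d).
#' @param W d x da weight matrix.
#' @param phi length 2*da score vector.
#' @param slope LeakyReLU negative slope.
#' @return coefficient per neighbor (positive, sums to 1).
#' @export
intra_attention_coeffs <- function(query, neighbors, W, phi, slope = 0.2) {
  stop_if(nrow(neighbors) == 0L, "empty neighbor set")
  da <- ncol(W)
  wq <- as.vector(query %*% W)
  wn <- neighbors %*% W
  e <- as.vector(wn %*% phi[da + seq_len(da)]) + sum(wq * phi[seq_len(da)])
  e <- ifelse(e > 0, e, slope * e)
  e <- exp(e - max(e))
  e / sum(e)
}

#' Cross-graph attention coefficients (single node, single head)
#'
#' Same functional form as [intra_attention_coeffs] with the cross-graph
#' weights, evaluated over a node's dynamically selected cross-modal
#' neighbors.
#'
#' @inheritParams intra_attention_coeffs
#' @param selected matrix of selected cross-neighbor embeddings.
#' @param W_cr,phi_cr cross-graph attention weights.
#' @return coefficient per selected neighbor (positive, sums to 1).
#' @export
cross_attention_coeffs <- function(query, selected, W_cr, phi_cr,
                                   slope = 0.2) {
  intra_attention_coeffs(query, selected, W_cr, phi_cr, slope)
}

#' Single dual-attention layer update
#'
#' Applies one layer of intra-graph plus cross-graph multi-head attention to
#' both modalities, given an explicit cross-neighbor selection. The per-head
#' update for a protein node i is
#' `sigma(sum_r alpha_ir W1 p_r + sum_r beta_ir W2 d_r)` with `sigma = ELU`;
#' the drug side is symmetric; head outputs are averaged.
#'
#' @param params parameter list from [dcgat_init].
#' @param layer layer index.
#' @param P,D current protein / drug embeddings (m x d, n x d).
#' @param gP,gD similarity graphs.
#' @param sel_P m x n binary matrix of selected drug neighbors per protein.
#' @param sel_D n x m binary matrix of selected protein neighbors per drug.
#' @param config a [dcgat_config].
#' @return list with updated `P` and `D`.
#' @export
layer_update <- function(params, layer, P, D, gP, gD, sel_P, sel_D,
                         config = dcgat_config()) {
  MP <- graph_adjacency(gP); MD <- graph_adjacency(gD)
  if (config$self_inclusion) { diag(MP) <- 1; diag(MD) <- 1 }
  list(P = layer_update_side(NULL, params, layer, "p", P, P, D, D, MP,
                             sel_P, config),
       D = layer_update_side(NULL, params, layer, "d", D, D, P, P, MD,
                             sel_D, config))
}
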