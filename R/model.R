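#' Model and training configuration
#'
#' Assembles all tunable hyperparameters of the DCGAT model with their
#' defaults. Any subset can be overridden; unknown names are an error.
#'
#' @param ... name = value overrides of the defaults listed below.
#' @return named list of class `dcgat_config`.
#'
#' @details Main fields:
#' \describe{
#'   \item{d}{shared hidden width after the input projections (default 16).}
#'   \item{n_layers}{number of DCGAT layers (default 2).}
#'   \item{n_heads}{attention heads H per layer (default 2); head outputs are
#'     averaged.}
#'   \item{att_dim}{width of the attention score space (default = d).}
#'   \item{temperature}{Gumbel-softmax temperature T > 0 (default 1).}
#'   \item{gs_eps}{probability floor before logs in the GS estimator.}
#'   \item{leaky_slope}{LeakyReLU negative slope for attention scores (0.2).}
#'   \item{self_inclusion}{include a node's own embedding in its intra-graph
#'     neighborhood (default TRUE; FALSE reproduces the bare neighbor sum,
#'     under which isolated nodes receive a zero intra term).}
#'   \item{cns_gcn_dim, cns_hidden}{widths of the 2-layer GCN context encoder
#'     and the pairwise scorer MLP inside the cross-neighborhood selection
#'     policy.}
#'   \item{delta, gamma}{residual scales on the initial protein/drug
#'     encodings in the fused pair embedding (default 1, 1).}
#'   \item{lambda}{weight of the supervised contrastive loss (default 0.1).}
#'   \item{tau_contrastive}{contrastive temperature (default 0.5).}
#'   \item{similarity}{pair similarity in the contrastive loss: "cosine"
#'     (default) or "dot".}
#'   \item{head_hidden}{hidden widths of the MLP interaction head.}
#'   \item{threshold_protein, threshold_drug}{threshold specs for
#'     [build_graph] per modality (default percentile 10).}
#'   \item{l2_normalize}{L2-normalise embedding rows before graph
#'     construction (default FALSE).}
#'   \item{lr, batch_size, epochs, patience}{Adam learning rate, minibatch
#'     size, epoch cap and early-stopping patience on validation AUROC.}
#'   \item{variant}{"full", "no_dcgat" (skip the attention stack),
#'     "no_contrastive" (lambda = 0), or "no_dynamic_neighborhood" (all
#'     cross-modal nodes selected).}
#' }
#' @export
dcgat_config <- function(...) {
  cfg <- list(
    d = 16L, n_layers = 2L, n_heads = 2L, att_dim = NULL,
    temperature = 1, gs_eps = 1e-10, leaky_slope = 0.2,
    self_inclusion = TRUE,
    cns_gcn_dim = 16L, cns_hidden = 32L,
    delta = 1, gamma = 1, lambda = 0.1, tau_contrastive = 0.5,
    similarity = "cosine",
    head_hidden = c(32L, 16L), dropout = 0,
    threshold_protein = list(percentile = 10),
    threshold_drug = list(percentile = 10),
    l2_normalize = FALSE,
    lr = 1e-3, batch_size = 128L, epochs = 200L, patience = 20L,
    negative_ratio = 1L, split_ratios = c(0.79, 0.01, 0.20),
    variant = "full"
  )
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1L]]) && is.null(names(ov))) ov <- ov[[1L]]
  bad <- setdiff(names(ov), names(cfg))
  stop_if(length(bad) > 0, "unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (is.null(cfg$att_dim)) cfg$att_dim <- cfg$d
  stop_if(cfg$temperature <= 0, "temperature must be > 0")
  stop_if(cfg$lambda < 0, "lambda must be >= 0")
  stop_if(cfg$tau_contrastive <= 0, "tau_contrastive must be > 0")
  stop_if(cfg$delta < 0 || cfg$gamma < 0, "delta and gamma must be >= 0")
  stop_if(!cfg$variant %in% c("full", "no_dcgat", "no_contrastive",
                              "no_dynamic_neighborhood"),
          "unknown variant: ", cfg$variant)
  if (cfg$variant == "no_contrastive") cfg$lambda <- 0
  structure(cfg, class = c("dcgat_config", "list"))
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Initialise DCGAT parameters
#'
#' Draws all learnable tensors (input projections, residual maps, per-layer
#' cross-neighborhood selection networks, per-layer per-head attention
#' weights, and the MLP head) with Glorot-uniform initialisation.
#'
#' @param p,q raw protein / drug embedding widths.
#' @param config a [dcgat_config].
#' @param seed RNG seed.
#' @return flat named list of parameter matrices.
#' @export
dcgat_init <- function(p, q, config = dcgat_config(), seed = 1) {
  d <- config$d; da <- config$att_dim
  gd <- config$cns_gcn_dim; hs <- config$cns_hidden
  with_seed(derive_seed(seed, 1), {
    pr <- list(
      proj_P = glorot(p, d), b_proj_P = matrix(0, 1, d),
      proj_D = glorot(q, d), b_proj_D = matrix(0, 1, d),
      res_P = glorot(p, d), res_D = glorot(q, d)
    )
    for (l in seq_len(config$n_layers)) {
      for (side in c("p", "d")) {
        nm <- function(x) sprintf("L%d_cns_%s_%s", l, side, x)
        pr[[nm("gcn1")]] <- glorot(d, gd)
        pr[[nm("gcn2")]] <- glorot(gd, gd)
        pr[[nm("q")]] <- glorot(d, hs)
        pr[[nm("c")]] <- glorot(gd, hs)
        pr[[nm("b")]] <- matrix(0, 1, hs)
        pr[[nm("o")]] <- glorot(hs, 2)
        pr[[nm("bo")]] <- matrix(0, 1, 2)
      }
      for (h in seq_len(config$n_heads)) {
        for (side in c("p", "d")) {
          nm <- function(x) sprintf("L%d_H%d_%s_%s", l, h, side, x)
          pr[[nm("intra_W")]] <- glorot(d, da)
          pr[[nm("intra_phi")]] <- glorot(2 * da, 1)
          pr[[nm("cross_W")]] <- glorot(d, da)
          pr[[nm("cross_phi")]] <- glorot(2 * da, 1)
          pr[[nm("W1")]] <- glorot(d, d)
          pr[[nm("W2")]] <- glorot(d, d)
        }
      }
    }
    widths <- c(2 * d, config$head_hidden)
    for (i in seq_along(config$head_hidden)) {
      pr[[sprintf("head_W%d", i)]] <- glorot(widths[i], widths[i + 1])
      pr[[sprintf("head_b%d", i)]] <- matrix(0, 1, widths[i + 1])
    }
    pr$head_Wout <- glorot(utils::tail(widths, 1), 1)
    pr$head_bout <- matrix(0, 1, 1)
    pr
  })
}

# left-multiply a node by a constant matrix
ad_mm_amat <- function(tape, A, b) {
  vb <- ad_val(b)
  ad_node(tape, A %*% vb, list(b), function(g) list(crossprod(A, g)))
}
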