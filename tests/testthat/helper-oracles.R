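# Independent oracles and shared fixtures for the test suite.
# Oracles are written as direct loop/formula evaluations, independent of the
# package's vectorised implementation paths.

# brute-force pairwise Euclidean distances (double loop)
oracle_distances <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    S[i, k] <- sqrt(sum((X[i, ] - X[k, ])^2))
  }
  S
}

# brute-force thresholded graph edge set
oracle_edges <- function(X, tau) {
  S <- oracle_distances(X)
  out <- NULL
  for (i in seq_len(nrow(X) - 1)) for (k in (i + 1):nrow(X)) {
    if (S[i, k] <= tau) out <- rbind(out, c(i, k))
  }
  out
}

# direct evaluation of the intra/cross attention coefficient formula:
# softmax over LeakyReLU(phi' [W q || W n_r]) computed term by term
oracle_att_coeffs <- function(query, neighbors, W, phi, slope = 0.2) {
  da <- ncol(W)
  e <- numeric(nrow(neighbors))
  for (r in seq_len(nrow(neighbors))) {
    concat <- c(as.vector(query %*% W), as.vector(neighbors[r, , drop = FALSE] %*% W))
    s <- sum(phi * concat)
    e[r] <- if (s > 0) s else slope * s
  }
  exp(e) / sum(exp(e))
}

# single-head dual-attention update for one node, by direct summation
# (Eq-style: sigma(sum_r alpha W1 n_r + sum_r beta W2 c_r), sigma = ELU)
oracle_node_update <- function(query, intra_nb, cross_nb, W, phi, Wcr, phicr,
                               W1, W2, slope = 0.2) {
  acc <- numeric(ncol(W1))
  if (!is.null(intra_nb) && nrow(intra_nb) > 0) {
    al <- oracle_att_coeffs(query, intra_nb, W, phi, slope)
    for (r in seq_len(nrow(intra_nb))) {
      acc <- acc + al[r] * as.vector(intra_nb[r, , drop = FALSE] %*% W1)
    }
  }
  if (!is.null(cross_nb) && nrow(cross_nb) > 0) {
    be <- oracle_att_coeffs(query, cross_nb, Wcr, phicr, slope)
    for (r in seq_len(nrow(cross_nb))) {
      acc <- acc + be[r] * as.vector(cross_nb[r, , drop = FALSE] %*% W2)
    }
  }
  ifelse(acc > 0, acc, exp(acc) - 1)  # ELU
}

# brute-force supervised contrastive loss (anchor/term loops)
oracle_contrastive <- function(Z, labels, tau, cosine = TRUE) {
  n <- nrow(Z)
  if (cosine) Z <- Z / sqrt(rowSums(Z^2))
  sims <- Z %*% t(Z)
  total <- 0; n_valid <- 0
  for (k in seq_len(n)) {
    A <- setdiff(seq_len(n), k)
    P <- A[labels[A] == labels[k]]
    if (length(P) == 0) next
    n_valid <- n_valid + 1
    lk <- 0
    for (r in P) {
      lk <- lk + log(exp(sims[k, r] / tau) /
                       sum(exp(sims[k, A] / tau)))
    }
    total <- total - lk / length(P)
  }
  if (n_valid == 0) return(NULL)
  total / n_valid
}

# brute-force AUROC over all positive-negative pairs (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# MLP head forward by explicit layer-by-layer loops
oracle_mlp <- function(Z, params, n_hidden) {
  out <- numeric(nrow(Z))
  for (r in seq_len(nrow(Z))) {
    h <- Z[r, ]
    for (i in seq_len(n_hidden)) {
      h <- pmax(as.vector(h %*% params[[sprintf("head_W%d", i)]]) +
                  as.vector(params[[sprintf("head_b%d", i)]]), 0)
    }
    z <- sum(h * params$head_Wout) + as.numeric(params$head_bout)
    out[r] <- 1 / (1 + exp(-z))
  }
  out
}

# a tiny deterministic model configuration for fast structural tests
tiny_config <- function(...) {
  base <- list(d = 4L, n_layers = 1L, n_heads = 1L, att_dim = 3L,
               cns_gcn_dim = 4L, cns_hidden = 6L, head_hidden = c(8L),
               epochs = 3L, batch_size = 64L)
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(dcgat_config, base)
}

# cached frozen fixture and one trained model, shared across test files
.test_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.test_cache$fx)) .test_cache$fx <- fixture_small()
  .test_cache$fx
}

get_trained_fixture <- function() {
  if (is.null(.test_cache$fit)) {
    fx <- get_fixture()
    sp <- make_split(fx$interactions, fx$drugs$ids, fx$proteins$ids,
                     "warm", negative_ratio = 1, seed = 1)
    fit <- dti_train(fx$proteins, fx$drugs, sp$train, NULL,
                     dcgat_config(epochs = 30), seed = 1)
    ev <- evaluate_model(fit, fx$proteins, fx$drugs, sp$test)
    .test_cache$fit <- list(fx = fx, sp = sp, fit = fit, ev = ev)
  }
  .test_cache$fit
}
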