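# Core attention stack: formula-oracle equivalence, selection policy
# behaviour, permutation equivariance, determinism.

test_that("attention coefficient helpers normalise and handle symmetry", {
  set.seed(5)
  W <- matrix(rnorm(12, 0, 0.3), 4, 3)
  phi <- rnorm(6, 0, 0.3)
  q <- rnorm(4)

  # single neighbor -> coefficient 1
  expect_equal(intra_attention_coeffs(q, matrix(rnorm(4), 1), W, phi), 1)

  # two identical neighbors -> 0.5 each
  nb <- matrix(rep(rnorm(4), 2), 2, byrow = TRUE)
  expect_equal(intra_attention_coeffs(q, nb, W, phi), c(0.5, 0.5))

  # cross side: one selected -> 1; identical selected -> uniform
  expect_equal(cross_attention_coeffs(q, matrix(rnorm(4), 1), W, phi), 1)
  nb4 <- matrix(rep(rnorm(4), 4), 4, byrow = TRUE)
  expect_equal(cross_attention_coeffs(q, nb4, W, phi), rep(0.25, 4))
})

test_that("attention coefficients match the direct-formula oracle", {
  set.seed(6)
  for (rep in 1:5) {
    W <- matrix(rnorm(12, 0, 0.4), 4, 3)
    phi <- rnorm(6, 0, 0.4)
    q <- rnorm(4)
    nb <- matrix(rnorm(12), 3, 4)
    expect_equal(intra_attention_coeffs(q, nb, W, phi),
                 oracle_att_coeffs(q, nb, W, phi), tolerance = 1e-6)
    sel <- matrix(rnorm(16), 4, 4)
    expect_equal(cross_attention_coeffs(q, sel, W, phi),
                 oracle_att_coeffs(q, sel, W, phi), tolerance = 1e-6)
  }
})

test_that("layer update matches per-node direct summation on a small graph", {
  set.seed(7)
  cfg <- tiny_config()
  m <- 5; n <- 4; d <- cfg$d
  params <- dcgat_init(d, d, cfg, seed = 2)
  P <- matrix(rnorm(m * d, 0, 0.5), m)
  D <- matrix(rnorm(n * d, 0, 0.5), n)
  gP <- build_graph(matrix(c(0, 1, 1.9, 5, 5.5), ncol = 1),
                    list(absolute = 1.2))
  gD <- build_graph(matrix(c(0, 0.5, 4, 9), ncol = 1), list(absolute = 1))
  selP <- matrix(rbinom(m * n, 1, 0.5), m, n)
  selD <- matrix(rbinom(n * m, 1, 0.5), n, m)
  up <- layer_update(params, 1, P, D, gP, gD, selP, selD, cfg)

  MP <- dcgat:::graph_adjacency(gP); diag(MP) <- 1   # self-inclusion default
  nmp <- function(x) params[[sprintf("L1_H1_p_%s", x)]]
  for (i in seq_len(m)) {
    intra_nb <- P[which(MP[i, ] == 1), , drop = FALSE]
    cross_nb <- D[which(selP[i, ] == 1), , drop = FALSE]
    want <- oracle_node_update(P[i, ], intra_nb, cross_nb,
                               nmp("intra_W"), as.vector(nmp("intra_phi")),
                               nmp("cross_W"), as.vector(nmp("cross_phi")),
                               nmp("W1"), nmp("W2"))
    expect_equal(unname(up$P[i, ]), want, tolerance = 1e-6)
  }
  # drug side symmetric (with its own weights, attending selected proteins)
  MD <- dcgat:::graph_adjacency(gD); diag(MD) <- 1
  nmd <- function(x) params[[sprintf("L1_H1_d_%s", x)]]
  for (j in seq_len(n)) {
    intra_nb <- D[which(MD[j, ] == 1), , drop = FALSE]
    cross_nb <- P[which(selD[j, ] == 1), , drop = FALSE]
    want <- oracle_node_update(D[j, ], intra_nb, cross_nb,
                               nmd("intra_W"), as.vector(nmd("intra_phi")),
                               nmd("cross_W"), as.vector(nmd("cross_phi")),
                               nmd("W1"), nmd("W2"))
    expect_equal(unname(up$D[j, ]), want, tolerance = 1e-6)
  }
})

test_that("empty cross selection reduces to intra-only attention", {
  set.seed(8)
  cfg <- tiny_config()
  m <- 4; d <- cfg$d
  params <- dcgat_init(d, d, cfg, seed = 3)
  P <- matrix(rnorm(m * d, 0, 0.5), m)
  D <- matrix(rnorm(3 * d, 0, 0.5), 3)
  gP <- build_graph(matrix(c(0, 1, 2, 10), ncol = 1), list(absolute = 1.5))
  gD <- build_graph(matrix(c(0, 1, 2), ncol = 1), list(absolute = 1.5))
  up <- layer_update(params, 1, P, D, gP, gD,
                     matrix(0, m, 3), matrix(0, 3, m), cfg)
  MP <- dcgat:::graph_adjacency(gP); diag(MP) <- 1
  nmp <- function(x) params[[sprintf("L1_H1_p_%s", x)]]
  for (i in seq_len(m)) {
    want <- oracle_node_update(P[i, ], P[which(MP[i, ] == 1), , drop = FALSE],
                               NULL,
                               nmp("intra_W"), as.vector(nmp("intra_phi")),
                               nmp("cross_W"), as.vector(nmp("cross_phi")),
                               nmp("W1"), nmp("W2"))
    expect_equal(unname(up$P[i, ]), want, tolerance = 1e-6)
  }

  # all-zero state: zero pre-activation, ELU(0) = 0
  up0 <- layer_update(params, 1, P * 0, D * 0, gP, gD,
                      matrix(1, m, 3), matrix(1, 3, m), cfg)
  expect_true(all(up0$P == 0) && all(up0$D == 0))
})

test_that("identical heads average to the single-head output", {
  set.seed(9)
  cfg1 <- tiny_config()
  cfg3 <- tiny_config(); cfg3$n_heads <- 3L
  d <- cfg1$d
  params <- dcgat_init(d, d, cfg3, seed = 4)
  for (h in 2:3) for (side in c("p", "d")) {
    for (w in c("intra_W", "intra_phi", "cross_W", "cross_phi", "W1", "W2")) {
      params[[sprintf("L1_H%d_%s_%s", h, side, w)]] <-
        params[[sprintf("L1_H1_%s_%s", side, w)]]
    }
  }
  P <- matrix(rnorm(4 * d, 0, 0.5), 4)
  D <- matrix(rnorm(3 * d, 0, 0.5), 3)
  gP <- build_graph(matrix(1:4, ncol = 1), list(absolute = 1))
  gD <- build_graph(matrix(1:3, ncol = 1), list(absolute = 1))
  selP <- matrix(1, 4, 3); selD <- matrix(1, 3, 4)
  u1 <- layer_update(params, 1, P, D, gP, gD, selP, selD, cfg1)
  u3 <- layer_update(params, 1, P, D, gP, gD, selP, selD, cfg3)
  expect_equal(u3$P, u1$P, tolerance = 1e-12)
  expect_equal(u3$D, u1$D, tolerance = 1e-12)
})

test_that("CNS policy rows are valid distributions, equivariant, differentiable", {
  set.seed(10)
  cfg <- tiny_config()
  d <- cfg$d
  params <- dcgat_init(d, d, cfg, seed = 5)
  Q <- matrix(rnorm(3 * d), 3)
  C <- matrix(rnorm(4 * d), 4)
  C[2, ] <- C[1, ]  # identical candidates
  gC <- build_graph(matrix(c(0, 0, 5, 9), ncol = 1), list(absolute = 0.5))
  # candidates 1,2 identical in embedding and graph context (mutual edge)
  rho <- cns_forward(params, 1, "p", Q, C, gC, cfg)
  expect_true(all(rho > 0 & rho < 1))          # strictly positive 2-way rows
  expect_equal(rho[, 1], rho[, 2], tolerance = 1e-10)  # equivariance

  expect_error(cns_forward(params, 1, "p", Q, C[0, , drop = FALSE],
                           gC, cfg), "empty cross side|row")

  # autodiff gradient w.r.t. a query embedding entry vs finite differences
  f <- function(Qv, grad = FALSE) {
    tape <- dcgat:::ad_tape()
    pl <- lapply(params, function(v) dcgat:::ad_leaf(tape, v))
    Qn <- dcgat:::ad_leaf(tape, Qv)
    rho <- dcgat:::cns_policy_core(tape, pl, 1, "p", Qn, C,
                                   dcgat:::gcn_adjacency(gC))
    loss <- dcgat:::ad_mean(tape, dcgat:::ad_emul(tape, rho, rho))
    if (grad) {
      dcgat:::ad_backward(tape, loss)
      Qn$grad
    } else as.numeric(dcgat:::ad_val(loss))
  }
  g <- f(Q, grad = TRUE)
  eps <- 1e-5
  for (idx in c(1L, 5L, 9L)) {
    Qp <- Q; Qp[idx] <- Qp[idx] + eps
    Qm <- Q; Qm[idx] <- Qm[idx] - eps
    fd <- (f(Qp) - f(Qm)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})

test_that("forward stack: empty stack, determinism, selection log", {
  fx <- get_fixture()
  cfg0 <- tiny_config(); cfg0$n_layers <- 0L
  params <- dcgat_init(16, 16, cfg0, seed = 6)
  gP <- build_graph(fx$proteins, cfg0$threshold_protein)
  gD <- build_graph(fx$drugs, cfg0$threshold_drug)
  out0 <- dcgat_forward(params, fx$proteins, fx$drugs, gP, gD, cfg0)
  proj <- sweep(fx$proteins$values %*% params$proj_P, 2,
                as.vector(params$b_proj_P), "+")
  expect_equal(out0$P, proj, tolerance = 1e-12)

  cfg <- tiny_config(); cfg$n_layers <- 2L
  params <- dcgat_init(16, 16, cfg, seed = 6)
  o1 <- dcgat_forward(params, fx$proteins, fx$drugs, gP, gD, cfg, seed = 42)
  o2 <- dcgat_forward(params, fx$proteins, fx$drugs, gP, gD, cfg, seed = 42)
  expect_identical(o1$P, o2$P)
  expect_identical(o1$selection_log, o2$selection_log)

  fr <- o1$selection_log$selected_fraction
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(nrow(o1$selection_log), 2L * (40L + 60L))
})

test_that("deterministic inference is equivariant to drug permutation", {
  fx <- get_fixture()
  cfg <- tiny_config(); cfg$n_layers <- 2L
  params <- dcgat_init(16, 16, cfg, seed = 7)
  gP <- build_graph(fx$proteins, cfg$threshold_protein)
  gD <- build_graph(fx$drugs, cfg$threshold_drug)
  base <- dcgat_forward(params, fx$proteins, fx$drugs, gP, gD, cfg,
                        stochastic = FALSE)
  set.seed(11)
  perm <- sample(length(fx$drugs$ids))
  drugs_p <- dti_embeddings(fx$drugs$ids[perm], fx$drugs$values[perm, ],
                            "drug")
  gD_p <- build_graph(drugs_p, cfg$threshold_drug)
  out_p <- dcgat_forward(params, fx$proteins, drugs_p, gP, gD_p, cfg,
                         stochastic = FALSE)
  expect_equal(out_p$D, base$D[perm, ], tolerance = 1e-9)
  expect_equal(out_p$P, base$P, tolerance = 1e-9)
})
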