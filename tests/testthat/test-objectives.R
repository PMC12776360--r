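test_that("pair fusion applies scaled residuals and concatenates", {
  set.seed(12)
  p <- rnorm(4); x <- rnorm(4); d <- rnorm(4); y <- rnorm(4)
  expect_equal(fuse_pair(p, x, d, y, delta = 0, gamma = 0), c(p, d))
  # cancellation
  expect_equal(fuse_pair(-0.5 * x, x, -2 * y, y, delta = 0.5, gamma = 2),
               rep(0, 8))
  # elementwise hand computation
  expect_equal(fuse_pair(p, x, d, y, delta = 0.5, gamma = 2),
               c(p + 0.5 * x, d + 2 * y))
  expect_error(fuse_pair(p, x[1:3], d, y), "mismatch")
})

test_that("MLP head scores match layer-by-layer evaluation", {
  set.seed(13)
  cfg <- tiny_config()
  params <- dcgat_init(cfg$d, cfg$d, cfg, seed = 8)
  Z <- matrix(rnorm(6 * 2 * cfg$d), 6)
  s <- predict_scores(Z, params, cfg)
  expect_true(all(s > 0 & s < 1))
  expect_equal(s, oracle_mlp(Z, params, length(cfg$head_hidden)),
               tolerance = 1e-6)

  # zero final layer -> sigmoid(0) = 0.5 for every pair
  p0 <- params
  p0$head_Wout <- p0$head_Wout * 0
  p0$head_bout <- p0$head_bout * 0
  expect_equal(predict_scores(Z, p0, cfg), rep(0.5, 6))

  # identical inputs -> identical scores
  Z2 <- Z[c(1, 1, 2), ]
  s2 <- predict_scores(Z2, params, cfg)
  expect_identical(s2[1], s2[2])
  expect_error(predict_scores(matrix(c(1, NA), 1), params, cfg),
               "non-finite")
})

test_that("BCE loss has its analytic values", {
  expect_equal(bce_loss(rep(0.5, 8), rep(c(0, 1), 4)), log(2),
               tolerance = 1e-12)
  y <- c(1, 0, 1, 1, 0)
  eps <- 1e-9
  expect_lte(bce_loss(abs(y - eps), y), 1e-6)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)), tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("contrastive loss matches the brute-force oracle", {
  # two samples, same label: the sole A(k) element is the sole positive
  set.seed(14)
  Z2 <- matrix(rnorm(8), 2)
  expect_equal(contrastive_loss(Z2, c(1, 1)), 0, tolerance = 1e-12)

  # 3-sample worked case: e1 = e2 (label 1), e3 orthogonal (label 0)
  Z3 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  got <- contrastive_loss(Z3, c(1, 1, 0), tau_c = 1)
  want <- oracle_contrastive(Z3, c(1, 1, 0), tau = 1)
  expect_equal(got, want, tolerance = 1e-10)
  # closed form for this geometry: both valid anchors see
  # exp(1)/(exp(1)+exp(0)) under cosine similarity
  expect_equal(got, -log(exp(1) / (exp(1) + 1)), tolerance = 1e-10)

  # random batches against the oracle, both similarities
  for (rep in 1:4) {
    Z <- matrix(rnorm(5 * 3), 5)
    lab <- c(1, 1, 0, 0, 1)
    expect_equal(contrastive_loss(Z, lab, tau_c = 0.5),
                 oracle_contrastive(Z, lab, 0.5), tolerance = 1e-8)
    expect_equal(contrastive_loss(Z, lab, tau_c = 0.7, similarity = "dot"),
                 oracle_contrastive(Z, lab, 0.7, cosine = FALSE),
                 tolerance = 1e-8)
  }

  # cosine similarity is scale invariant
  Z <- matrix(rnorm(12), 4)
  lab <- c(1, 0, 1, 0)
  expect_equal(contrastive_loss(Z, lab), contrastive_loss(Z * 7.3, lab),
               tolerance = 1e-10)

  expect_error(contrastive_loss(Z[1, , drop = FALSE], 1), ">= 2")
  expect_warning(v <- contrastive_loss(Z[1:2, ], c(0, 1)), "skipped")
  expect_equal(v, 0)
})

test_that("total loss is the lambda-weighted sum and affine in lambda", {
  expect_equal(total_loss(0.37, 9.9, lambda = 0), 0.37)
  expect_equal(total_loss(0.5, 0.2, lambda = 2), 0.9)
  l <- seq(0, 3, by = 0.5)
  v <- vapply(l, function(x) total_loss(1.1, 0.4, x), numeric(1))
  expect_equal(diff(v), rep(0.4 * 0.5, length(l) - 1))
  expect_error(total_loss(1, 1, -0.1), "lambda")
})

test_that("total-loss gradients decompose into component gradients", {
  set.seed(15)
  cfg <- tiny_config()
  params <- dcgat_init(cfg$d, cfg$d, cfg, seed = 9)
  Z <- matrix(rnorm(6 * 2 * cfg$d, 0, 0.5), 6)
  lab <- c(1, 0, 1, 1, 0, 0)
  lambda <- 0.3
  grad_of <- function(mode) {
    tape <- dcgat:::ad_tape()
    pl <- lapply(params, function(v) dcgat:::ad_leaf(tape, v))
    Zn <- dcgat:::ad_leaf(tape, Z)
    s <- dcgat:::mlp_head_core(tape, pl, Zn, 1L)
    lb <- dcgat:::bce_core(tape, s, lab)
    lc <- dcgat:::contrastive_core(tape, Zn, lab, 0.5, "cosine")
    loss <- switch(mode,
                   bce = lb,
                   con = lc,
                   total = dcgat:::ad_add(tape, lb,
                                          dcgat:::ad_smul(tape, lc, lambda)))
    dcgat:::ad_backward(tape, loss)
    list(W = pl$head_W1$grad, Z = Zn$grad)
  }
  gb <- grad_of("bce"); gc <- grad_of("con"); gt <- grad_of("total")
  # the contrastive term never touches the head weights
  expect_null(gc$W)
  expect_equal(gt$W, gb$W, tolerance = 1e-10)
  expect_equal(gt$Z, gb$Z + lambda * gc$Z, tolerance = 1e-10)
})
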