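make_toy_interactions <- function(n_pos = 20, n_drugs = 10, n_prot = 8,
                                  seed = 1) {
  dcgat:::with_seed(seed, {
    all_pairs <- expand.grid(d = sprintf("D%d", 1:n_drugs),
                             p = sprintf("P%d", 1:n_prot),
                             stringsAsFactors = FALSE)
    take <- sample(nrow(all_pairs), n_pos)
    dti_interactions(all_pairs$d[take], all_pairs$p[take], rep(1L, n_pos))
  })
}

test_that("warm split follows the floor/remainder rounding policy", {
  tbl <- make_toy_interactions(20)
  sp <- make_split(tbl, sprintf("D%d", 1:10), sprintf("P%d", 1:8), "warm",
                   ratios = c(0.79, 0.01, 0.20), negative_ratio = 1, seed = 3)
  expect_equal(sum(sp$val$label), 0L)    # floor(0.01 * 20)
  expect_equal(sum(sp$test$label), 4L)   # floor(0.20 * 20)
  expect_equal(sum(sp$train$label), 16L) # remainder
})

test_that("cold splits give disjoint entity sets and balanced negatives", {
  tbl <- make_toy_interactions(40, n_drugs = 15, n_prot = 12, seed = 2)
  spd <- make_split(tbl, sprintf("D%d", 1:15), sprintf("P%d", 1:12),
                    "cold_drug", negative_ratio = 1, seed = 4)
  expect_length(intersect(unique(spd$train$drug_id),
                          unique(spd$test$drug_id)), 0)
  spp <- make_split(tbl, sprintf("D%d", 1:15), sprintf("P%d", 1:12),
                    "cold_protein", negative_ratio = 1, seed = 4)
  expect_length(intersect(unique(spp$train$protein_id),
                          unique(spp$test$protein_id)), 0)

  # balanced sampling: equal positives and negatives per partition
  for (pt in spd) {
    expect_equal(sum(pt$label == 0L), sum(pt$label == 1L))
  }

  expect_error(make_split(tbl, c("D1", "D2"), sprintf("P%d", 1:12),
                          "cold_drug"), "infeasible")
})

test_that("splits are leakage-free, deterministic, and never reuse positives", {
  tbl <- make_toy_interactions(30, n_drugs = 12, n_prot = 10, seed = 3)
  pos_keys <- paste(tbl$drug_id, tbl$protein_id)
  for (strat in c("warm", "cold_drug", "cold_protein")) {
    for (nr in c(1L, 3L)) {
      sp <- make_split(tbl, sprintf("D%d", 1:12), sprintf("P%d", 1:10),
                       strat, negative_ratio = nr, seed = 7)
      all_rows <- do.call(rbind, lapply(sp, function(x) x[, 1:3]))
      keys <- paste(all_rows$drug_id, all_rows$protein_id)
      expect_false(any(duplicated(keys)))                 # no pair reused
      expect_false(any(keys[all_rows$label == 0] %in% pos_keys))
      # positives partition the input positives
      expect_setequal(keys[all_rows$label == 1], pos_keys)
    }
    sp2 <- make_split(tbl, sprintf("D%d", 1:12), sprintf("P%d", 1:10),
                      strat, negative_ratio = 1, seed = 7)
    expect_identical(
      make_split(tbl, sprintf("D%d", 1:12), sprintf("P%d", 1:10), strat,
                 negative_ratio = 1, seed = 7), sp2)
  }
})

test_that("unbalanced sampling hits the requested or maximum achievable ratio", {
  # plenty of negatives: exact 1:10 per partition
  tbl <- make_toy_interactions(8, n_drugs = 20, n_prot = 20, seed = 6)
  sp <- make_split(tbl, sprintf("D%d", 1:20), sprintf("P%d", 1:20), "warm",
                   negative_ratio = 10L, seed = 5)
  expect_equal(sum(sp$test$label == 0L), 10L * sum(sp$test$label == 1L))
  expect_equal(sum(sp$train$label == 0L), 10L * sum(sp$train$label == 1L))

  # scarce negatives: the achievable ratio is applied uniformly, so the
  # shared pool is not exhausted by the training partition
  fx <- get_fixture()
  spx <- make_split(fx$interactions, fx$drugs$ids, fx$proteins$ids, "warm",
                    negative_ratio = 10L, seed = 5)
  avail <- 40 * 60 - nrow(fx$interactions)
  eff <- avail / nrow(fx$interactions)
  for (pt in spx[c("train", "test")]) {
    got <- sum(pt$label == 0L) / sum(pt$label == 1L)
    expect_lt(abs(got - eff), 0.2)
  }
})

test_that("training reduces the loss and is reproducible", {
  fx <- get_fixture()
  sp <- make_split(fx$interactions, fx$drugs$ids, fx$proteins$ids, "warm",
                   negative_ratio = 1, seed = 1)
  cfg <- dcgat_config(epochs = 4L)
  fit1 <- dti_train(fx$proteins, fx$drugs, sp$train, NULL, cfg, seed = 2)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])

  fit2 <- dti_train(fx$proteins, fx$drugs, sp$train, NULL, cfg, seed = 2)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
})

test_that("lambda = 0 removes the contrastive term from the gradient", {
  fx <- get_fixture()
  sp <- make_split(fx$interactions, fx$drugs$ids, fx$proteins$ids, "warm",
                   negative_ratio = 1, seed = 1)
  cfg_a <- dcgat_config(epochs = 2L, lambda = 0, similarity = "cosine")
  cfg_b <- dcgat_config(epochs = 2L, lambda = 0, similarity = "dot")
  fit_a <- dti_train(fx$proteins, fx$drugs, sp$train, NULL, cfg_a, seed = 3)
  fit_b <- dti_train(fx$proteins, fx$drugs, sp$train, NULL, cfg_b, seed = 3)
  # recorded contrastive values differ (different similarity) ...
  expect_false(isTRUE(all.equal(fit_a$history$contrastive,
                                fit_b$history$contrastive)))
  expect_true(all(fit_a$history$contrastive > 0))
  # ... but the parameter trajectory is identical: the term is detached
  expect_identical(fit_a$params, fit_b$params)
  expect_identical(fit_a$history$bce, fit_b$history$bce)
})

test_that("evaluation reports per-pair predictions and ranking metrics", {
  tf <- get_trained_fixture()
  ev <- tf$ev
  expect_identical(nrow(ev$predictions), nrow(tf$sp$test))
  expect_true(all(ev$predictions$score > 0 & ev$predictions$score < 1))
  expect_named(ev$metrics, c("auroc", "auprc", "ef0.5", "ef1", "ef2",
                             "bedroc"))
  expect_gt(ev$metrics$auroc, 0.8)
  # missing IDs are reported
  bad <- dti_interactions("NOPE", tf$fx$proteins$ids[1], 1L)
  expect_error(evaluate_model(tf$fit, tf$fx$proteins, tf$fx$drugs, bad),
               "no overlap|missing")
})
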