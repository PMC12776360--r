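# Robustness diagnostics: neighborhood-noise injection, batch-context
# stability, temperature/selection sweep, and the component ablation suite.

#' Noise-robustness probe
#'
#' At inference, Gaussian noise of each given standard deviation is injected
#' into the neighbor-path node embeddings (intra-graph and cross-graph)
#' prior to aggregation — the query/self path is unperturbed — and the test
#' AUROC is recorded per noise level. `sigma = 0` reproduces the clean
#' evaluation exactly.
#'
#' @param fit a `dcgat_fit`.
#' @param proteins,drugs [dti_embeddings] objects.
#' @param tbl evaluation [dti_interactions] table.
#' @param sigmas noise standard deviations.
#' @param seed seed for the injected noise.
#' @return data.frame with columns `sigma`, `auroc`, `auprc`.
#' @export
noise_robustness_probe <- function(fit, proteins, drugs, tbl,
                                   sigmas = c(0, 0.01, 0.05, 0.1, 0.5),
                                   seed = 1) {
  sigmas <- sort(sigmas)
  rows <- lapply(seq_along(sigmas), function(i) {
    ev <- evaluate_model(fit, proteins, drugs, tbl, noise_sd = sigmas[i],
                         noise_seed = seed + i)
    data.frame(sigma = sigmas[i], auroc = ev$metrics$auroc,
               auprc = ev$metrics$auprc)
  })
  do.call(rbind, rows)
}

#' Batch-context stability probe
#'
#' For each anchor drug-protein pair, the similarity graphs are rebuilt over
#' `n_contexts` random co-sampled entity sets (always containing the anchor
#' entities), the anchor is scored under deterministic inference in each
#' context, and the per-anchor score distribution is summarised.
#'
#' @param fit a `dcgat_fit`.
#' @param proteins,drugs [dti_embeddings] objects.
#' @param anchors data.frame with columns `drug_id`, `protein_id` (and
#'   optionally `label`).
#' @param n_contexts number of random batch contexts (default 30).
#' @param context_size number of co-sampled proteins and drugs per context,
#'   as `c(n_proteins, n_drugs)`.
#' @param seed RNG seed for context sampling.
#' @return list with `summary` (per-anchor mean/sd/quantiles) and `scores`
#'   (anchors x contexts matrix).
#' @export
batch_stability_probe <- function(fit, proteins, drugs, anchors,
                                  n_contexts = 30, context_size = c(20, 30),
                                  seed = 1) {
  stop_if(!all(anchors$protein_id %in% proteins$ids),
          "anchor protein(s) missing from embeddings")
  stop_if(!all(anchors$drug_id %in% drugs$ids),
          "anchor drug(s) missing from embeddings")
  na <- nrow(anchors)
  scores <- matrix(NA_real_, na, n_contexts)
  with_seed(derive_seed(seed, 7), {
    for (cx in seq_len(n_contexts)) {
      ps <- unique(c(anchors$protein_id,
                     sample(proteins$ids, min(context_size[1],
                                              length(proteins$ids)))))
      ds <- unique(c(anchors$drug_id,
                     sample(drugs$ids, min(context_size[2],
                                           length(drugs$ids)))))
      ctx_tbl <- dti_interactions(anchors$drug_id, anchors$protein_id,
                                  anchors$label %||% rep(0L, na))
      ctx <- split_context(
        dti_embeddings(ps, proteins$values[ps, , drop = FALSE], "protein"),
        dti_embeddings(ds, drugs$values[ds, , drop = FALSE], "drug"),
        list(data.frame(drug_id = ds[1], protein_id = ps[1], label = 0L),
             data.frame(drug_id = rep(ds, each = length(ps)),
                        protein_id = rep(ps, length(ds)), label = 0L)),
        fit$config)
      pri <- pair_indices(ctx_tbl, ctx$pid, ctx$did)
      sc <- score_pairs_core(NULL, fit$params, ctx, pri$ip, pri$id,
                             fit$config, stochastic = FALSE)
      scores[, cx] <- as.vector(sc$scores)
    }
  })
  qs <- t(apply(scores, 1L, stats::quantile, c(0.025, 0.5, 0.975)))
  summary <- data.frame(drug_id = anchors$drug_id,
                        protein_id = anchors$protein_id,
                        mean = rowMeans(scores),
                        sd = apply(scores, 1L, stats::sd),
                        q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L],
                        stringsAsFactors = FALSE)
  list(summary = summary, scores = scores)
}

#' Temperature / selection sweep
#'
#' For each Gumbel-softmax temperature, runs stochastic forward passes of a
#' fitted model and records the mean selected fraction of cross-modal
#' neighbors — both the hard sampled bits and the soft relaxation weights —
#' together with the test AUROC of the stochastic pass. The hard sampling
#' law of a two-way Gumbel argmax is temperature-invariant; the soft
#' fraction reflects the temperature-controlled softness of the relaxation
#' that shapes training.
#'
#' @param fit a `dcgat_fit`.
#' @param proteins,drugs [dti_embeddings] objects.
#' @param tbl evaluation table.
#' @param temperatures temperatures to sweep.
#' @param n_repeats stochastic passes per temperature.
#' @param seed RNG seed.
#' @return data.frame with one row per (temperature, repeat):
#'   `hard_fraction`, `soft_fraction`, `auroc`.
#' @export
temperature_probe <- function(fit, proteins, drugs, tbl,
                              temperatures = c(0.1, 0.5, 1, 2, 5),
                              n_repeats = 5, seed = 1) {
  cfg <- fit$config
  ctx <- split_context(proteins, drugs, list(tbl), cfg)
  pri <- pair_indices(tbl, ctx$pid, ctx$did)
  rows <- list()
  for (tt in temperatures) {
    cfg_t <- cfg; cfg_t$temperature <- tt
    for (r in seq_len(n_repeats)) {
      res <- with_seed(derive_seed(seed, 1000 * tt + r), {
        sc <- score_pairs_core(NULL, fit$params, ctx, pri$ip, pri$id, cfg_t,
                               stochastic = TRUE)
        soft <- soft_selection_fraction(fit$params, ctx, cfg_t)
        list(sc = sc, soft = soft)
      })
      au <- if (length(unique(tbl$label)) == 2L)
        auroc_auprc(as.vector(res$sc$scores), tbl$label)$auroc else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = tt, repeat_ = r,
        hard_fraction = mean(res$sc$fw$selection_log$selected_fraction),
        soft_fraction = res$soft, auroc = au)
    }
  }
  do.call(rbind, rows)
}

# mean soft (relaxed) selection weight over both sides at layer 1,
# one stochastic Gumbel draw
soft_selection_fraction <- function(params, ctx, cfg) {
  AhP <- gcn_adjacency(ctx$gP); AhD <- gcn_adjacency(ctx$gD)
  P <- sweep(ctx$X %*% params$proj_P, 2, as.vector(params$b_proj_P), "+")
  D <- sweep(ctx$Y %*% params$proj_D, 2, as.vector(params$b_proj_D), "+")
  fr <- vapply(list(list("p", P, D, AhD), list("d", D, P, AhP)),
               function(a) {
                 rho <- cns_policy_core(NULL, params, 1L, a[[1]], a[[2]],
                                        a[[3]], a[[4]])
                 gs <- gumbel_softmax_st(cbind(as.vector(rho),
                                               1 - as.vector(rho)),
                                         cfg$temperature)
                 mean(gs$soft)
               }, numeric(1))
  mean(fr)
}

#' Component ablation suite
#'
#' Trains and evaluates the model variants `full`, `no_dcgat` (attention
#' stack skipped; projected embeddings go straight to fusion and the head),
#' `no_contrastive` (lambda = 0) and `no_dynamic_neighborhood` (every
#' cross-modal node selected) under a shared seed protocol, and compares
#' each ablated variant against the full model with a one-sided Wilcoxon
#' rank-sum test on the per-repeat AUROC.
#'
#' @param proteins,drugs [dti_embeddings] objects.
#' @param interactions positive interaction table.
#' @param config base [dcgat_config].
#' @param variants variants to run.
#' @param strategy split strategy.
#' @param n_repeats repeats per variant.
#' @param seed base seed (repeat r uses seed + r - 1 in every variant).
#' @return list with `report` (per-variant mean/sd metrics), `per_repeat`,
#'   and `tests` (one-sided rank-sum p-values vs the full model).
#' @export
ablation_suite <- function(proteins, drugs, interactions,
                           config = dcgat_config(),
                           variants = c("full", "no_dcgat", "no_contrastive",
                                        "no_dynamic_neighborhood"),
                           strategy = "warm", n_repeats = 10, seed = 1) {
  runs <- list()
  for (v in variants) {
    cfg_v <- config
    cfg_v$variant <- v
    if (v == "no_contrastive") cfg_v$lambda <- 0
    runs[[v]] <- run_experiment(proteins, drugs, interactions, cfg_v,
                                strategy = strategy, n_repeats = n_repeats,
                                seed = seed)
  }
  report <- do.call(rbind, lapply(variants, function(v) {
    data.frame(variant = v, lambda = if (v == "no_contrastive") 0
               else config$lambda,
               mean_auroc = runs[[v]]$mean$auroc,
               sd_auroc = runs[[v]]$sd$auroc,
               mean_auprc = runs[[v]]$mean$auprc,
               sd_auprc = runs[[v]]$sd$auprc)
  }))
  tests <- NULL
  if ("full" %in% variants && length(variants) > 1L) {
    full_au <- runs[["full"]]$per_repeat$auroc
    tests <- do.call(rbind, lapply(setdiff(variants, "full"), function(v) {
      p <- stats::wilcox.test(full_au, runs[[v]]$per_repeat$auroc,
                              alternative = "greater", exact = FALSE)$p.value
      data.frame(comparison = paste0("full>", v), p_value = p)
    }))
  }
  per <- do.call(rbind, lapply(variants, function(v)
    cbind(variant = v, runs[[v]]$per_repeat)))
  list(report = report, per_repeat = per, tests = tests)
}
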