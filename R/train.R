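# Data splitting, negative sampling, the training loop, and evaluation.

#' Split interactions into train/validation/test with sampled negatives
#'
#' Positive pairs (label 1) are partitioned according to the strategy:
#' `"warm"` partitions pairs directly; `"cold_drug"` / `"cold_protein"`
#' partition the cold-side entity IDs at the given ratios (by entity count)
#' and pairs inherit their entity's partition, so train and test entity sets
#' are disjoint. Rounding policy: validation and test sizes are floored,
#' the remainder goes to train. Negatives are then sampled uniformly from
#' unobserved pairs within each partition's allowed entities at
#' `negative_ratio` per positive (or the maximum achievable number),
#' never overlapping across partitions. Deterministic given `seed`.
#'
#' @param interactions a [dti_interactions] table (rows with label 1 are the
#'   positives; any label-0 rows are excluded from the sampling universe).
#' @param all_drugs,all_proteins character vectors of all entity IDs.
#' @param strategy `"warm"`, `"cold_drug"` or `"cold_protein"`.
#' @param ratios train/val/test proportions summing to 1.
#' @param negative_ratio negatives sampled per positive (1 = balanced,
#'   10 = unbalanced).
#' @param seed RNG seed.
#' @return list of [dti_interactions]: `train`, `val`, `test`.
#' @export
make_split <- function(interactions, all_drugs, all_proteins,
                       strategy = c("warm", "cold_drug", "cold_protein"),
                       ratios = c(0.79, 0.01, 0.20), negative_ratio = 1L,
                       seed = 1) {
  strategy <- match.arg(strategy)
  stop_if(abs(sum(ratios) - 1) > 1e-8, "ratios must sum to 1")
  stop_if(negative_ratio < 1, "negative_ratio must be >= 1")
  pos <- interactions[interactions$label == 1L, , drop = FALSE]
  stop_if(nrow(pos) == 0L, "no positive interactions")
  observed <- paste(interactions$drug_id, interactions$protein_id, sep = "\r")

  with_seed(derive_seed(seed, 5), {
    part <- list()
    if (strategy == "warm") {
      n <- nrow(pos)
      idx <- sample(n)
      nv <- floor(ratios[2] * n); nt <- floor(ratios[3] * n)
      part$val <- pos[idx[seq_len(nv)], , drop = FALSE]
      part$test <- pos[idx[nv + seq_len(nt)], , drop = FALSE]
      part$train <- pos[idx[-seq_len(nv + nt)], , drop = FALSE]
      allowed <- list(train = list(d = all_drugs, p = all_proteins),
                      val = list(d = all_drugs, p = all_proteins),
                      test = list(d = all_drugs, p = all_proteins))
    } else {
      cold_col <- if (strategy == "cold_drug") "drug_id" else "protein_id"
      ents <- if (strategy == "cold_drug") all_drugs else all_proteins
      other <- if (strategy == "cold_drug") all_proteins else all_drugs
      ne <- length(ents)
      stop_if(ne < 3L, "cold split infeasible: fewer than 3 distinct ",
              if (strategy == "cold_drug") "drugs" else "proteins")
      idx <- sample(ne)
      nv <- floor(ratios[2] * ne); nt <- max(1L, floor(ratios[3] * ne))
      ev <- ents[idx[seq_len(nv)]]
      et <- ents[idx[nv + seq_len(nt)]]
      er <- ents[idx[-seq_len(nv + nt)]]
      stop_if(length(er) < 1L, "cold split infeasible: empty training entity set")
      part$val <- pos[pos[[cold_col]] %in% ev, , drop = FALSE]
      part$test <- pos[pos[[cold_col]] %in% et, , drop = FALSE]
      part$train <- pos[pos[[cold_col]] %in% er, , drop = FALSE]
      mk <- function(cold_set) {
        if (strategy == "cold_drug") list(d = cold_set, p = other)
        else list(d = other, p = cold_set)
      }
      allowed <- list(train = mk(er), val = mk(ev), test = mk(et))
    }
    # when partitions share a sampling universe (warm start) the achievable
    # negative:positive ratio is capped globally, so early partitions cannot
    # exhaust the pool ("maximum achievable ratio")
    eff_ratio <- negative_ratio
    if (strategy == "warm") {
      avail <- length(all_drugs) * length(all_proteins) - length(observed)
      eff_ratio <- min(negative_ratio, avail / nrow(pos))
    }
    used <- observed
    out <- list()
    for (nm in c("train", "val", "test")) {
      pp <- part[[nm]]
      negs <- sample_negatives(allowed[[nm]]$d, allowed[[nm]]$p, used,
                               floor(eff_ratio * nrow(pp)))
      used <- c(used, paste(negs$drug_id, negs$protein_id, sep = "\r"))
      out[[nm]] <- dti_interactions(
        c(pp$drug_id, negs$drug_id), c(pp$protein_id, negs$protein_id),
        c(rep(1L, nrow(pp)), rep(0L, nrow(negs))),
        provenance = paste0(strategy, ":", nm))
    }
    out
  })
}

# uniform sample of n_wanted unobserved pairs among drugs x proteins
sample_negatives <- function(drugs, proteins, used_keys, n_wanted) {
  if (n_wanted == 0L || length(drugs) == 0L || length(proteins) == 0L) {
    return(data.frame(drug_id = character(), protein_id = character()))
  }
  cand_d <- rep(drugs, times = length(proteins))
  cand_p <- rep(proteins, each = length(drugs))
  free <- !(paste(cand_d, cand_p, sep = "\r") %in% used_keys)
  pool <- which(free)
  take <- pool[sample.int(length(pool), min(n_wanted, length(pool)))]
  data.frame(drug_id = cand_d[take], protein_id = cand_p[take],
             stringsAsFactors = FALSE)
}

# Adam optimiser state and update
adam_new <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(st, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = st, params = params)
}

# map an interaction table to row indices of the embedding matrices
pair_indices <- function(tbl, pid, did) {
  ip <- match(tbl$protein_id, pid)
  id <- match(tbl$drug_id, did)
  miss <- unique(c(tbl$protein_id[is.na(ip)], tbl$drug_id[is.na(id)]))
  stop_if(length(miss) > 0, "ID(s) missing from embeddings: ",
          paste(utils::head(miss, 10), collapse = ", "))
  list(ip = ip, id = id)
}

# restrict embeddings to the entities appearing in the given tables and
# build the split-context similarity graphs
split_context <- function(proteins, drugs, tables, cfg) {
  tbl <- do.call(rbind, lapply(tables, function(t) t[, 1:3]))
  pid <- intersect(proteins$ids, unique(tbl$protein_id))
  did <- intersect(drugs$ids, unique(tbl$drug_id))
  stop_if(length(pid) == 0L || length(did) == 0L,
          "no overlap between tables and embeddings")
  X <- proteins$values[pid, , drop = FALSE]
  Y <- drugs$values[did, , drop = FALSE]
  norm_rows <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)
  Xg <- if (cfg$l2_normalize) norm_rows(X) else X
  Yg <- if (cfg$l2_normalize) norm_rows(Y) else Y
  list(pid = pid, did = did, X = X, Y = Y,
       gP = build_graph(dti_embeddings(pid, Xg, "protein"),
                        cfg$threshold_protein),
       gD = build_graph(dti_embeddings(did, Yg, "drug"), cfg$threshold_drug))
}

# forward + heads for a set of pair indices; returns scores (and Z, loss
# nodes when training)
score_pairs_core <- function(tape, pl, ctx, ip, id, cfg, stochastic,
                             noise_sd = 0) {
  fw <- dcgat_forward_core(tape, pl, ctx$X, ctx$Y, ctx$gP, ctx$gD, cfg,
                           stochastic = stochastic, noise_sd = noise_sd)
  XR <- ad_mm_amat(tape, ctx$X, pl$res_P)
  YR <- ad_mm_amat(tape, ctx$Y, pl$res_D)
  Z <- fuse_batch_core(tape, fw, XR, YR, ip, id, cfg)
  scores <- mlp_head_core(tape, pl, Z, length(cfg$head_hidden))
  list(Z = Z, scores = scores, fw = fw)
}

#' Train a DCGAT model
#'
#' Joint minibatch gradient training (Adam) of the input projections,
#' cross-neighborhood selection policies, attention weights, residual maps
#' and MLP head under the combined BCE + contrastive objective. Similarity
#' graphs are built once over the entities appearing in the training (and
#' validation) tables. Early stopping monitors validation AUROC computed
#' with deterministic inference. Fully reproducible given `seed`.
#'
#' @param proteins,drugs [dti_embeddings] objects.
#' @param train_tbl,val_tbl [dti_interactions] tables (`val_tbl` may be
#'   `NULL` or too small to score; then no early stopping is applied).
#' @param config a [dcgat_config].
#' @param seed RNG seed governing initialisation, batching and sampling.
#' @param verbose print per-epoch progress.
#' @return object of class `dcgat_fit`: list with `params`, `config`,
#'   `history` (per-epoch losses and validation AUROC), `seed`.
#' @export
dti_train <- function(proteins, drugs, train_tbl, val_tbl = NULL,
                      config = dcgat_config(), seed = 1, verbose = FALSE) {
  cfg <- config
  tables <- list(train_tbl)
  if (!is.null(val_tbl) && nrow(val_tbl)) tables <- c(tables, list(val_tbl))
  ctx <- split_context(proteins, drugs, tables, cfg)
  tri <- pair_indices(train_tbl, ctx$pid, ctx$did)
  y_tr <- train_tbl$label
  # AUROC-based early stopping is only engaged when the validation set is
  # large enough to rank reliably; tiny validation sets would snapshot
  # near-initial parameters on a saturated AUROC estimate
  has_val <- !is.null(val_tbl) && nrow(val_tbl) >= 10L &&
    length(unique(val_tbl$label)) == 2L
  if (has_val) vri <- pair_indices(val_tbl, ctx$pid, ctx$did)

  params <- dcgat_init(ncol(ctx$X), ncol(ctx$Y), cfg, seed)
  with_seed(derive_seed(seed, 3),
            train_loop(params, cfg, ctx, tri, y_tr, has_val,
                       if (has_val) vri else NULL, val_tbl, hist_seed = seed,
                       verbose = verbose))
}

train_loop <- function(params, cfg, ctx, tri, y_tr, has_val, vri, val_tbl,
                       hist_seed, verbose) {
  opt <- adam_new(params)
  n_tr <- length(tri$ip)
  hist <- list()
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_bce <- ep_con <- 0
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        tape <- ad_tape()
        pl <- lapply(params, function(v) ad_leaf(tape, v))
        sc <- score_pairs_core(tape, pl, ctx, tri$ip[b], tri$id[b], cfg,
                               stochastic = TRUE)
        lb <- bce_core(tape, sc$scores, y_tr[b])
        use_con <- cfg$lambda > 0 && length(b) >= 2L
        if (use_con) {
          lc <- contrastive_core(tape, sc$Z, y_tr[b], cfg$tau_contrastive,
                                 cfg$similarity)
          use_con <- !is.null(lc)
        }
        loss <- if (use_con) ad_add(tape, lb, ad_smul(tape, lc, cfg$lambda))
                else lb
        lv <- as.numeric(ad_val(loss))
        if (!is.finite(lv)) {
          warning("non-finite loss at epoch ", ep,
                  "; stopping with last finite parameters")
          hist[[length(hist) + 1L]] <-
            data.frame(epoch = ep, loss = NA_real_, bce = NA_real_,
                       contrastive = NA_real_, val_auroc = NA_real_)
          return(finish_fit(params, best, cfg, ctx, hist, hist_seed, has_val))
        }
        ep_bce <- ep_bce + as.numeric(ad_val(lb)) * length(b)
        con_val <- if (cfg$lambda > 0 && length(b) >= 2L && use_con)
          as.numeric(ad_val(lc))
        else if (length(b) >= 2L)
          contrastive_core(NULL, ad_val(sc$Z), y_tr[b],
                           cfg$tau_contrastive, cfg$similarity) %||% 0
        else 0
        ep_con <- ep_con + as.numeric(con_val) * length(b)
        ad_backward(tape, loss)
        grads <- lapply(pl, function(nd) nd$grad)
        up <- adam_step(opt, params, grads, cfg$lr)
        opt <- up$state; params <- up$params
      }
      ep_bce <- ep_bce / n_tr; ep_con <- ep_con / n_tr
      va <- NA_real_
      if (has_val) {
        vs <- score_pairs_core(NULL, params, ctx, vri$ip, vri$id, cfg,
                               stochastic = FALSE)
        va <- auroc_auprc(as.vector(vs$scores), val_tbl$label)$auroc
        if (va > best$auroc + 1e-9) {
          best <- list(auroc = va, params = params, epoch = ep)
          wait <- 0L
        } else wait <- wait + 1L
      }
      hist[[length(hist) + 1L]] <-
        data.frame(epoch = ep, loss = ep_bce + cfg$lambda * ep_con,
                   bce = ep_bce, contrastive = ep_con, val_auroc = va)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  bce %.4f  con %.4f  val %.3f",
                        ep, ep_bce + cfg$lambda * ep_con, ep_bce, ep_con, va))
      }
      if (has_val && wait >= cfg$patience) break
    }
    finish_fit(params, best, cfg, ctx, hist, hist_seed, has_val)
  }
}

finish_fit <- function(params, best, cfg, ctx, hist, seed, has_val) {
  final <- if (has_val && best$auroc > -Inf) best$params else params
  structure(list(params = final, config = cfg,
                 history = do.call(rbind, hist),
                 thresholds = list(protein = ctx$gP$threshold,
                                   drug = ctx$gD$threshold),
                 best_epoch = if (has_val) best$epoch else NA_integer_,
                 seed = seed),
            class = "dcgat_fit")
}

#' @export
print.dcgat_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<dcgat_fit> variant=%s, %d epochs trained, final loss %.4f\n",
              x$config$variant, nrow(h), utils::tail(stats::na.omit(h$loss), 1)))
  if (!all(is.na(h$val_auroc)))
    cat(sprintf("  best val AUROC %.4f at epoch %d\n",
                max(h$val_auroc, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' Score and evaluate a fitted model on an interaction table
#'
#' Rebuilds the similarity graphs over the entities appearing in `tbl`
#' (the evaluation batch context), runs deterministic inference, and
#' computes classification and virtual-screening metrics.
#'
#' @param fit a `dcgat_fit`.
#' @param proteins,drugs [dti_embeddings] objects.
#' @param tbl a [dti_interactions] table.
#' @param ef_cutoffs enrichment-factor cutoff percentages.
#' @param bedroc_alpha BEDROC weighting parameter.
#' @param noise_sd optional Gaussian noise injected into neighbor embeddings
#'   prior to aggregation (robustness probe); 0 disables.
#' @param noise_seed seed for the injected noise.
#' @return list with `predictions` (data.frame drug_id, protein_id, label,
#'   score) and `metrics` (auroc, auprc, ef per cutoff, bedroc).
#' @export
evaluate_model <- function(fit, proteins, drugs, tbl,
                           ef_cutoffs = c(0.5, 1, 2), bedroc_alpha = 80.5,
                           noise_sd = 0, noise_seed = 1) {
  cfg <- fit$config
  ctx <- split_context(proteins, drugs, list(tbl), cfg)
  pri <- pair_indices(tbl, ctx$pid, ctx$did)
  sc <- with_seed(derive_seed(noise_seed, 23),
                  score_pairs_core(NULL, fit$params, ctx, pri$ip, pri$id,
                                   cfg, stochastic = FALSE,
                                   noise_sd = noise_sd))
  s <- as.vector(sc$scores)
  metrics <- list(auroc = NA_real_, auprc = NA_real_)
  if (length(unique(tbl$label)) == 2L) {
    aa <- auroc_auprc(s, tbl$label)
    ef <- vapply(ef_cutoffs, function(cp) enrichment_factor(s, tbl$label, cp),
                 numeric(1))
    names(ef) <- paste0("ef", ef_cutoffs)
    metrics <- c(aa, as.list(ef),
                 list(bedroc = bedroc(s, tbl$label, bedroc_alpha)))
  }
  list(predictions = data.frame(drug_id = tbl$drug_id,
                                protein_id = tbl$protein_id,
                                label = tbl$label, score = s,
                                stringsAsFactors = FALSE),
       metrics = metrics)
}

#' Run a full split/train/evaluate experiment, with repeats
#'
#' For each repeat r (seeds `seed + r - 1`): draw a split, train on it, and
#' evaluate on the test partition. Mirrors the repeated-split protocol used
#' to report mean metrics.
#'
#' @param proteins,drugs [dti_embeddings] objects.
#' @param interactions positive interaction table.
#' @param config a [dcgat_config].
#' @param strategy split strategy.
#' @param n_repeats number of repeated splits.
#' @param seed base seed.
#' @return list with `per_repeat` (data.frame of metrics per repeat),
#'   `mean` and `sd` (named lists), and `fits` (list of `dcgat_fit`).
#' @export
run_experiment <- function(proteins, drugs, interactions,
                           config = dcgat_config(),
                           strategy = "warm", n_repeats = 10, seed = 1) {
  cfg <- config
  rows <- list(); fits <- list()
  for (r in seq_len(n_repeats)) {
    sr <- seed + r - 1
    sp <- make_split(interactions, drugs$ids, proteins$ids, strategy,
                     ratios = cfg$split_ratios,
                     negative_ratio = cfg$negative_ratio, seed = sr)
    fit <- dti_train(proteins, drugs, sp$train, sp$val, cfg, seed = sr)
    ev <- evaluate_model(fit, proteins, drugs, sp$test)
    rows[[r]] <- data.frame(repeat_ = r, seed = sr,
                            as.data.frame(ev$metrics))
    fits[[r]] <- fit
  }
  per <- do.call(rbind, rows)
  mcols <- setdiff(names(per), c("repeat_", "seed"))
  list(per_repeat = per,
       mean = as.list(colMeans(per[mcols], na.rm = TRUE)),
       sd = as.list(apply(per[mcols], 2, stats::sd)),
       fits = fits)
}
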