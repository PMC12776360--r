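# Latent-factor synthetic data with the statistical structure the model
# assumes: modality-internal similarity clusters and a cross-modal bilinear
# interaction signal, so that similar drugs bind similar proteins.

#' Synthetic data configuration
#'
#' @param m,n protein / drug counts.
#' @param p,q observed embedding widths.
#' @param K shared latent cluster count (K <= min(m, n)).
#' @param latent_dim latent factor dimension.
#' @param noise_sd Gaussian observation noise on the embeddings.
#' @param interaction_scale slope of the bilinear interaction logit.
#' @param positive_rate target interaction prevalence in (0, 1).
#' @param seed RNG seed.
#' @param regime `"separable"` (default), `"noisy_cross_modality"` (drug
#'   embeddings observed at 5x the noise), or `"null"` (labels permuted,
#'   destroying the embedding-label association).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(m = 40, n = 60, p = 16, q = 16, K = 4,
                         latent_dim = 8, noise_sd = 0.2,
                         interaction_scale = 4, positive_rate = 0.15,
                         seed = 1,
                         regime = c("separable", "noisy_cross_modality",
                                    "null")) {
  regime <- match.arg(regime)
  stop_if(K > min(m, n), "K must be <= min(m, n)")
  stop_if(positive_rate <= 0 || positive_rate >= 1,
          "positive_rate must be in (0, 1)")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(m = m, n = n, p = p, q = q, K = K, latent_dim = latent_dim,
                 noise_sd = noise_sd, interaction_scale = interaction_scale,
                 positive_rate = positive_rate, seed = seed, regime = regime),
            class = "synth_config")
}

#' Generate a synthetic drug-target interaction dataset
#'
#' Latent protein vectors u_i and drug vectors v_j are drawn around K shared
#' cluster centers; observed embeddings are modality-specific fixed random
#' linear maps of the latents plus Gaussian noise (this creates the
#' homophily that thresholded similarity graphs exploit). Interaction labels
#' are Bernoulli(sigmoid(interaction_scale * <u_i, v_j> + b)) with the bias
#' b solved numerically so the expected prevalence matches `positive_rate`.
#' The `"null"` regime randomly permutes the label matrix over pairs;
#' `"noisy_cross_modality"` observes the drug embeddings at 5x the noise.
#'
#' @param config a [synth_config].
#' @return list with `proteins`, `drugs` ([dti_embeddings]), `interactions`
#'   (a [dti_interactions] table of the positive pairs), and `truth`
#'   (clusters, latents, bias, full label and probability matrices).
#' @export
synth_generate <- function(config = synth_config()) {
  cf <- config
  with_seed(derive_seed(cf$seed, 11), {
    centers <- matrix(stats::rnorm(cf$K * cf$latent_dim), cf$K)
    cl_p <- rep_len(seq_len(cf$K), cf$m)
    cl_d <- rep_len(seq_len(cf$K), cf$n)
    U <- centers[cl_p, ] + matrix(stats::rnorm(cf$m * cf$latent_dim, 0, 0.2), cf$m)
    V <- centers[cl_d, ] + matrix(stats::rnorm(cf$n * cf$latent_dim, 0, 0.2), cf$n)
    Ap <- matrix(stats::rnorm(cf$latent_dim * cf$p), cf$latent_dim) /
      sqrt(cf$latent_dim)
    Ad <- matrix(stats::rnorm(cf$latent_dim * cf$q), cf$latent_dim) /
      sqrt(cf$latent_dim)
    sd_p <- cf$noise_sd
    sd_d <- if (cf$regime == "noisy_cross_modality") 5 * cf$noise_sd else cf$noise_sd
    X <- U %*% Ap + matrix(stats::rnorm(cf$m * cf$p, 0, sd_p), cf$m)
    Y <- V %*% Ad + matrix(stats::rnorm(cf$n * cf$q, 0, sd_d), cf$n)
    logits0 <- cf$interaction_scale * (U %*% t(V))
    f <- function(b) mean(stats::plogis(logits0 + b)) - cf$positive_rate
    lo <- -50; hi <- 50
    stop_if(f(lo) > 0 || f(hi) < 0,
            "positive_rate unreachable for this latent configuration")
    b <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    prob <- stats::plogis(logits0 + b)
    lab <- matrix(stats::rbinom(length(prob), 1L, prob), cf$m, cf$n)
    if (cf$regime == "null") {
      lab <- matrix(sample(as.vector(lab)), cf$m, cf$n)
    }
    pid <- sprintf("P%03d", seq_len(cf$m))
    did <- sprintf("D%03d", seq_len(cf$n))
    pos <- which(lab == 1L, arr.ind = TRUE)
    interactions <- dti_interactions(did[pos[, 2L]], pid[pos[, 1L]],
                                     rep(1L, nrow(pos)),
                                     provenance = paste0("synthetic:", cf$regime))
    list(
      proteins = dti_embeddings(pid, X, "protein"),
      drugs = dti_embeddings(did, Y, "drug"),
      interactions = interactions,
      truth = list(clusters_protein = cl_p, clusters_drug = cl_d,
                   U = U, V = V, bias = b, prob = prob, labels = lab,
                   config = cf)
    )
  })
}

#' The frozen small test fixture
#'
#' Deterministic tiny instance (40 proteins, 60 drugs, 16-dimensional
#' embeddings, 4 latent clusters, separable regime, fixed seed) used across
#' the test suite and diagnostics.
#'
#' @return the [synth_generate] output for the frozen configuration.
#' @export
fixture_small <- function() {
  synth_generate(synth_config(m = 40, n = 60, p = 16, q = 16, K = 4,
                              latent_dim = 8, noise_sd = 0.2,
                              interaction_scale = 4, positive_rate = 0.15,
                              seed = 20240817, regime = "separable"))
}

# stable content checksum of a generated dataset (embeddings rounded to 10
# significant digits to absorb float formatting differences)
synth_checksum <- function(data) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(format(signif(data$proteins$values, 10), trim = TRUE),
               format(signif(data$drugs$values, 10), trim = TRUE),
               paste(data$interactions$drug_id, data$interactions$protein_id)),
             tmp)
  unname(tools::md5sum(tmp))
}
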