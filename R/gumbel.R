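#' Straight-through Gumbel-softmax sampling for binary neighbor selection
#'
#' Given per-candidate two-way probability rows (select / not-select), draws
#' a hard binary action per row while retaining a differentiable relaxation.
#' The relaxed score for action a is
#' `exp((log rho_a + g_a)/T) / sum_b exp((log rho_b + g_b)/T)` with
#' `g ~ Gumbel(0,1)`; the forward value is the one-hot argmax of the relaxed
#' scores (equivalently of the perturbed log-probabilities), and in the
#' straight-through scheme the backward gradient is that of the relaxation.
#' Probabilities are floored at `eps` before taking logs.
#'
#' For two actions the hard "select" frequency equals `rho_select` exactly,
#' independent of `T`; the temperature controls the softness of the
#' relaxation (and hence the gradient signal and the expected soft selection
#' weight), not the hard sampling law.
#'
#' @param rho numeric matrix with 2 columns `(select, not_select)`, rows
#'   strictly positive and summing to 1 (a vector of select-probabilities is
#'   also accepted).
#' @param temperature T > 0.
#' @param noise if `FALSE`, Gumbel noise is disabled (then with `T = 1` the
#'   soft scores equal `rho` exactly, and the hard action is the argmax of
#'   `rho`).
#' @param eps numerical floor applied to probabilities before `log`.
#' @return list with `hard` (0/1 select bit per row), `soft` (relaxed select
#'   score per row, in (0,1)).
#' @export
gumbel_softmax_st <- function(rho, temperature = 1, noise = TRUE,
                              eps = 1e-10) {
  stop_if(!is.finite(temperature) || temperature <= 0,
          "temperature must be > 0")
  if (is.null(dim(rho))) rho <- cbind(rho, 1 - rho)
  stop_if(ncol(rho) != 2L, "rho must have two columns (select, not-select)")
  if (any(rho < eps)) {
    warning("probabilities below eps floor were clamped")
    rho <- pmax(rho, eps)
  }
  lp <- log(rho)
  g <- if (noise) matrix(rgumbel(length(lp)), nrow(lp), 2L) else 0
  z <- (lp + g) / temperature
  soft <- 1 / (1 + exp(z[, 2L] - z[, 1L]))
  hard <- as.numeric(z[, 1L] > z[, 2L])
  list(hard = hard, soft = soft)
}

# tape-aware straight-through sampler used inside the DCGAT stack.
# rho_sel: (n x 1) node/matrix of select-probabilities. Returns an (n x 1)
# node whose forward value is hard {0,1} and whose backward pass follows the
# soft relaxation.
st_select <- function(tape, rho_sel, temperature, noise = TRUE, eps = 1e-10) {
  v <- ad_val(rho_sel)
  n <- nrow(v)
  rho_c <- ad_sadd(tape, ad_smul(tape, rho_sel, -1), 1)  # not-select prob
  lp1 <- ad_log(tape, ad_sadd(tape, rho_sel, eps))
  lp0 <- ad_log(tape, ad_sadd(tape, rho_c, eps))
  if (noise) {
    g1 <- matrix(rgumbel(n), ncol = 1L)
    g0 <- matrix(rgumbel(n), ncol = 1L)
  } else {
    g1 <- g0 <- matrix(0, n, 1L)
  }
  z1 <- ad_smul(tape, ad_add(tape, lp1, g1), 1 / temperature)
  z0 <- ad_smul(tape, ad_add(tape, lp0, g0), 1 / temperature)
  soft <- ad_sigmoid(tape, ad_sub(tape, z1, z0))
  hard <- matrix(as.numeric(ad_val(z1) > ad_val(z0)), ncol = 1L)
  ad_straight_through(tape, soft, hard)
}
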