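# Reverse-mode automatic differentiation over dense matrices.
#
# A tape records operation nodes in execution order; nodes are environments
# holding the forward value, parent references and a pullback closure.
# Backward sweeps the tape in reverse, accumulating gradients into every node
# that requires them. Ops accept either ad nodes or plain matrices; when the
# tape is NULL (inference) or no input requires a gradient, ops degrade to
# plain matrix arithmetic with no recording overhead, so the same forward
# code serves training and deterministic evaluation.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_is_node <- function(x) is.environment(x)

ad_val <- function(x) if (is.environment(x)) x$value else x

ad_requires <- function(x) is.environment(x) && isTRUE(x$requires)

# Leaf node for a learnable parameter; gradient is read from $grad after
# ad_backward().
ad_leaf <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$requires <- TRUE
  nd$parents <- NULL
  nd$backfn <- NULL
  nd$grad <- NULL
  nd
}

ad_node <- function(tape, value, parents, backfn) {
  if (is.null(tape) || !any(vapply(parents, ad_requires, logical(1)))) {
    return(value)
  }
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$requires <- TRUE
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# Backpropagate from a scalar (1x1) loss node through the tape.
ad_backward <- function(tape, loss) {
  stopifnot(ad_is_node(loss))
  loss$grad <- matrix(1, 1L, 1L)
  for (k in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (ad_requires(p) && !is.null(gs[[j]])) {
        p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
      }
    }
  }
  invisible(NULL)
}

## ---- primitive operations ----

ad_mm <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va %*% vb, list(a, b), function(g) {
    list(g %*% t(vb), crossprod(va, g))
  })
}

ad_t <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, t(va), list(a), function(g) list(t(g)))
}

ad_add <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va + vb, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va - vb, list(a, b), function(g) list(g, -g))
}

ad_emul <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va * vb, list(a, b), function(g) list(g * vb, g * va))
}

# scalar constant multiply / add
ad_smul <- function(tape, a, s) {
  va <- ad_val(a)
  ad_node(tape, va * s, list(a), function(g) list(g * s))
}

ad_sadd <- function(tape, a, s) {
  va <- ad_val(a)
  ad_node(tape, va + s, list(a), function(g) list(g))
}

# elementwise multiply by a constant matrix (masks)
ad_cmul <- function(tape, a, m) {
  va <- ad_val(a)
  ad_node(tape, va * m, list(a), function(g) list(g * m))
}

# add a row-vector bias to every row
ad_bias <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  val <- sweep(va, 2L, as.vector(vb), "+")
  ad_node(tape, val, list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

# subtract a constant column vector from every column (detached max shift)
ad_shift_rows <- function(tape, a, cv) {
  va <- ad_val(a)
  val <- va - as.vector(cv)
  ad_node(tape, val, list(a), function(g) list(g))
}

# subtract a column-vector node from every column of a
ad_sub_colvec <- function(tape, a, cv) {
  va <- ad_val(a); vc <- ad_val(cv)
  val <- va - as.vector(vc)
  ad_node(tape, val, list(a, cv), function(g) {
    list(g, matrix(rowSums(g), ncol = 1L))
  })
}

# divide rows of a (m x k) by column vector d (m x 1), with additive floor
ad_rowdiv <- function(tape, a, d, floor = 0) {
  va <- ad_val(a); vd <- as.vector(ad_val(d)) + floor
  val <- va / vd
  ad_node(tape, val, list(a, d), function(g) {
    list(g / vd, matrix(-rowSums(g * va / vd^2), ncol = 1L))
  })
}

# multiply rows of a (m x k) by column vector d (m x 1)
ad_rowmul <- function(tape, a, d) {
  va <- ad_val(a); vd <- as.vector(ad_val(d))
  val <- va * vd
  ad_node(tape, val, list(a, d), function(g) {
    list(g * vd, matrix(rowSums(g * va), ncol = 1L))
  })
}

ad_rowsums <- function(tape, a) {
  va <- ad_val(a)
  k <- ncol(va)
  ad_node(tape, matrix(rowSums(va), ncol = 1L), list(a), function(g) {
    list(matrix(g, nrow(va), k))
  })
}

ad_sum <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, matrix(sum(va), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(va), ncol(va)))
  })
}

ad_mean <- function(tape, a) {
  va <- ad_val(a)
  nel <- length(va)
  ad_node(tape, matrix(mean(va), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / nel, nrow(va), ncol(va)))
  })
}

ad_exp <- function(tape, a) {
  v <- exp(ad_val(a))
  ad_node(tape, v, list(a), function(g) list(g * v))
}

ad_log <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, log(va), list(a), function(g) list(g / va))
}

ad_sqrt <- function(tape, a) {
  v <- sqrt(ad_val(a))
  ad_node(tape, v, list(a), function(g) list(g / (2 * v)))
}

ad_rsqrt <- function(tape, a) {
  va <- ad_val(a)
  v <- 1 / sqrt(va)
  ad_node(tape, v, list(a), function(g) list(-0.5 * g * va^(-1.5)))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-ad_val(a)))
  ad_node(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

ad_relu <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, pmax(va, 0), list(a), function(g) list(g * (va > 0)))
}

ad_leakyrelu <- function(tape, a, slope = 0.2) {
  va <- ad_val(a)
  v <- ifelse(va > 0, va, slope * va)
  ad_node(tape, v, list(a), function(g) {
    list(g * ifelse(va > 0, 1, slope))
  })
}

ad_elu <- function(tape, a, alpha = 1) {
  va <- ad_val(a)
  v <- ifelse(va > 0, va, alpha * (exp(va) - 1))
  ad_node(tape, v, list(a), function(g) {
    list(g * ifelse(va > 0, 1, alpha * exp(pmin(va, 0))))
  })
}

# gather rows by (possibly repeated) index vector
ad_rows <- function(tape, a, idx) {
  va <- ad_val(a)
  val <- va[idx, , drop = FALSE]
  ad_node(tape, val, list(a), function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    acc <- rowsum(g, idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ad_cbind <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ka <- ncol(va)
  ad_node(tape, cbind(va, vb), list(a, b), function(g) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

# outer sum: a (m x 1) + b (n x 1) -> m x n with value a_i + b_j
ad_outer_sum <- function(tape, a, b) {
  va <- as.vector(ad_val(a)); vb <- as.vector(ad_val(b))
  val <- outer(va, vb, "+")
  ad_node(tape, val, list(a, b), function(g) {
    list(matrix(rowSums(g), ncol = 1L), matrix(colSums(g), ncol = 1L))
  })
}

# reshape an (m*n) x 1 column into an m x n matrix, row-major
ad_reshape_rowmajor <- function(tape, a, m, n) {
  va <- ad_val(a)
  val <- matrix(as.vector(va), m, n, byrow = TRUE)
  ad_node(tape, val, list(a), function(g) {
    list(matrix(as.vector(t(g)), ncol = 1L))
  })
}

# straight-through: forward takes the (pre-computed) hard value, backward
# passes the incoming gradient to the soft relaxation unchanged
ad_straight_through <- function(tape, soft, hard) {
  ad_node(tape, hard, list(soft), function(g) list(g))
}

# softmax over rows with a multiplicative {0,1} mask; mask may itself be a
# node (gradients flow through selection). Fully masked rows yield zero rows.
ad_masked_softmax <- function(tape, scores, mask, floor = 1e-12) {
  vs <- ad_val(scores)
  mx <- apply(vs, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- ad_exp(tape, ad_shift_rows(tape, scores, mx))
  num <- if (ad_is_node(mask)) ad_emul(tape, e, mask) else ad_cmul(tape, e, mask)
  den <- ad_rowsums(tape, num)
  ad_rowdiv(tape, num, den, floor = floor)
}
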