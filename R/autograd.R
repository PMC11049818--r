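# Minimal tape-based reverse-mode automatic differentiation over numeric
# matrices. Internal: powers the deep classifiers (MLP, capsule network,
# BiLSTM, decoder transformer). Nodes are environments holding `value`,
# `grad` and a `backward` closure that scatters the incoming gradient to the
# node's inputs; the tape replays in reverse creation order.

ag_env <- new.env(parent = emptyenv())

ag_begin <- function() {
  ag_env$tape <- vector("list", 512L)
  ag_env$n <- 0L
}

ag_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- ag_env$n + 1L
  if (n > length(ag_env$tape)) {
    ag_env$tape <- c(ag_env$tape, vector("list", length(ag_env$tape)))
  }
  ag_env$tape[[n]] <- nd
  ag_env$n <- n
  nd
}

ag_leaf <- function(value) ag_node(as.matrix(value))

ag_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ag_backward <- function(loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq.int(ag_env$n, 1L)) {
    nd <- ag_env$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ag_matmul <- function(a, b) {
  ag_node(a$value %*% b$value, function(g) {
    ag_acc(a, g %*% t(b$value))
    ag_acc(b, t(a$value) %*% g)
  })
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

# b is a 1 x D bias row broadcast over the rows of a
ag_add_bias <- function(a, b) {
  ag_node(sweep(a$value, 2, as.vector(b$value), "+"), function(g) {
    ag_acc(a, g)
    ag_acc(b, matrix(colSums(g), 1))
  })
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, function(g) {
    ag_acc(a, g)
    ag_acc(b, -g)
  })
}

ag_mul <- function(a, b) {
  ag_node(a$value * b$value, function(g) {
    ag_acc(a, g * b$value)
    ag_acc(b, g * a$value)
  })
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, function(g) ag_acc(a, g * s))
}

# multiply each row of a by the matching entry of column-vector node v (N x 1)
ag_mul_colvec <- function(a, v) {
  ag_node(a$value * as.vector(v$value), function(g) {
    ag_acc(a, g * as.vector(v$value))
    ag_acc(v, matrix(rowSums(g * a$value), ncol = 1))
  })
}

ag_relu <- function(a) {
  keep <- a$value > 0
  ag_node(a$value * keep, function(g) ag_acc(a, g * keep))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, function(g) ag_acc(a, g * s * (1 - s)))
}

ag_tanh <- function(a) {
  t <- tanh(a$value)
  ag_node(t, function(g) ag_acc(a, g * (1 - t^2)))
}

# exact Gaussian-error linear unit: x * pnorm(x)
ag_gelu <- function(a) {
  x <- a$value
  Phi <- stats::pnorm(x)
  ag_node(x * Phi, function(g) ag_acc(a, g * (Phi + x * stats::dnorm(x))))
}

ag_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ag_node(s, function(g) ag_acc(a, (g - rowSums(g * s)) * s))
}

# gather rows (embedding lookup); backward scatter-adds into the table
ag_rows <- function(a, idx) {
  idx <- as.integer(idx)
  ag_node(a$value[idx, , drop = FALSE], function(g) {
    z <- matrix(0, nrow(a$value), ncol(a$value))
    rs <- rowsum(g, group = idx)
    z[as.integer(rownames(rs)), ] <- rs
    ag_acc(a, z)
  })
}

ag_mean_rows <- function(a) {
  n <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), 1), function(g) {
    ag_acc(a, matrix(as.vector(g), n, ncol(a$value), byrow = TRUE) / n)
  })
}

ag_concat_cols <- function(a, b) {
  na <- ncol(a$value)
  ag_node(cbind(a$value, b$value), function(g) {
    ag_acc(a, g[, seq_len(na), drop = FALSE])
    ag_acc(b, g[, -seq_len(na), drop = FALSE])
  })
}

ag_cols <- function(a, j) {
  ag_node(a$value[, j, drop = FALSE], function(g) {
    z <- matrix(0, nrow(a$value), ncol(a$value))
    z[, j] <- g
    ag_acc(a, z)
  })
}

ag_transpose <- function(a) {
  ag_node(t(a$value), function(g) ag_acc(a, t(g)))
}

ag_dropout <- function(a, rate, train = TRUE) {
  if (!train || rate <= 0) return(a)
  keep <- matrix(runif(length(a$value)) >= rate, nrow(a$value)) / (1 - rate)
  ag_node(a$value * keep, function(g) ag_acc(a, g * keep))
}

# per-row layer normalization with learnable 1 x D gain and bias
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  D <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * rep(1, nrow(x)) %o% as.vector(gamma$value), 2,
    as.vector(beta$value), "+"
  )
  ag_node(y, function(g) {
    gam <- as.vector(gamma$value)
    dxhat <- g * rep(1, nrow(x)) %o% gam
    ag_acc(gamma, matrix(colSums(g * xhat), 1))
    ag_acc(beta, matrix(colSums(g), 1))
    rs1 <- rowSums(dxhat)
    rs2 <- rowSums(dxhat * xhat)
    ag_acc(a, inv * (dxhat - rs1 / D - xhat * rs2 / D))
  })
}

# capsule nonlinearity applied per row: v = s * ||s|| / (1 + ||s||^2)
ag_squash_rows <- function(a, eps = 1e-9) {
  s <- a$value
  n <- sqrt(rowSums(s^2) + eps)
  cfac <- n / (1 + n^2)
  ag_node(s * cfac, function(g) {
    cprime <- (1 - n^2) / (1 + n^2)^2
    dot <- rowSums(g * s)
    ag_acc(a, g * cfac + s * (cprime / n) * dot)
  })
}

# per-row L2 norms as an N x 1 column
ag_row_norms <- function(a, eps = 1e-12) {
  n <- sqrt(rowSums(a$value^2) + eps)
  ag_node(matrix(n, ncol = 1), function(g) {
    ag_acc(a, a$value * as.vector(g) / n)
  })
}

# mean binary cross-entropy on probabilities already in (0, 1)
ag_bce_probs <- function(p, y, eps = 1e-7) {
  pv <- pmin(pmax(p$value, eps), 1 - eps)
  yv <- as.vector(y)
  n <- length(pv)
  val <- -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
  ag_node(matrix(val, 1, 1), function(g) {
    ag_acc(p, matrix((pv - yv) / (pv * (1 - pv)) / n, nrow(p$value)) * as.vector(g))
  })
}

# mean binary cross-entropy on a single-logit column (numerically stable)
ag_bce_logits <- function(z, y) {
  zv <- z$value
  yv <- as.vector(y)
  n <- length(zv)
  val <- mean(pmax(zv, 0) - zv * yv + log1p(exp(-abs(zv))))
  ag_node(matrix(val, 1, 1), function(g) {
    sig <- 1 / (1 + exp(-zv))
    ag_acc(z, matrix((sig - yv) / n, nrow(zv)) * as.vector(g))
  })
}

# mean 2-class (or K-class) cross-entropy on an N x K logit matrix
ag_ce_logits <- function(z, y_idx) {
  zv <- z$value - apply(z$value, 1, max)
  e <- exp(zv)
  sm <- e / rowSums(e)
  n <- nrow(zv)
  picked <- sm[cbind(seq_len(n), y_idx)]
  val <- -mean(log(pmax(picked, 1e-12)))
  ag_node(matrix(val, 1, 1), function(g) {
    onehot <- matrix(0, n, ncol(zv))
    onehot[cbind(seq_len(n), y_idx)] <- 1
    ag_acc(z, (sm - onehot) / n * as.vector(g))
  })
}

# --- parameter plumbing -----------------------------------------------------

ag_wrap_params <- function(params) lapply(params, ag_leaf)

ag_collect_grads <- function(param_nodes) {
  lapply(param_nodes, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
  })
}

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

param_count <- function(params) sum(vapply(params, length, numeric(1)))
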