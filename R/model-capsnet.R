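#' Capsule squashing nonlinearity
#'
#' Maps a vector to the same direction with norm
#' `||s||^2 / (1 + ||s||^2) < 1`, so a capsule's length can be read as the
#' probability that its entity is present. The zero vector maps to itself.
#'
#' @param s Numeric vector (one capsule pre-activation).
#' @return Numeric vector of the same length.
#' @examples
#' sqrt(sum(squash(c(1, 0))^2)) # 0.5
#' @export
squash <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s)
  (n2 / (1 + n2)) * s / sqrt(n2)
}

#' Dynamic routing by agreement
#'
#' Iteratively sets the coupling of each primary capsule to each class
#' capsule: coupling logits start at zero, couplings are their softmax over
#' classes, class capsules are the squashed coupling-weighted vote sums, and
#' logits grow by the scalar agreement between each vote and the class
#' capsule.
#'
#' @param votes 3-D array `n_primary x n_class x dim` (vote of primary
#'   capsule i for class j), or a list of per-class vote matrices
#'   (`n_primary x dim`).
#' @param iters Routing iterations (>= 1).
#' @return List with `capsules` (`n_class x dim` matrix of output capsule
#'   vectors) and `couplings` (`n_primary x n_class`, rows summing to 1).
#' @export
dynamic_routing <- function(votes, iters = 3) {
  if (iters < 1) abort("routing needs at least one iteration")
  if (is.list(votes)) {
    votes <- array(
      unlist(lapply(votes, as.matrix)),
      dim = c(nrow(votes[[1]]), ncol(votes[[1]]), length(votes))
    )
    votes <- aperm(votes, c(1, 3, 2))
  }
  np <- dim(votes)[1]
  nc <- dim(votes)[2]
  d <- dim(votes)[3]
  b <- matrix(0, np, nc)
  v <- matrix(0, nc, d)
  for (it in seq_len(iters)) {
    e <- exp(b - apply(b, 1, max))
    cpl <- e / rowSums(e)
    for (j in seq_len(nc)) {
      vmat <- matrix(votes[, j, ], np, d)
      v[j, ] <- squash(colSums(vmat * cpl[, j]))
    }
    if (it < iters) {
      for (j in seq_len(nc)) {
        b[, j] <- b[, j] + matrix(votes[, j, ], np, d) %*% v[j, ]
      }
    }
  }
  list(capsules = v, couplings = cpl)
}

#' Configuration for the capsule-network classifier
#'
#' A 1-D convolution (kernel 3, stride 1, no pooling anywhere) over the
#' feature vector produces one 8-D primary capsule per position; per-capsule
#' linear votes feed two 16-D class capsules through dynamic routing
#' (3 iterations), and class-capsule norms are the class probabilities.
#' Trained with binary cross-entropy on both capsule norms and Adam at
#' learning rate 0.001.
#'
#' @param kernel Convolution kernel size.
#' @param stride Convolution stride (1; the architecture has no pooling).
#' @param primary_dim Primary capsule dimensionality (= convolution channels).
#' @param class_dim Class capsule dimensionality.
#' @param n_class Number of class capsules.
#' @param routing_iters Routing iterations.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return A `capsnet_config` list.
#' @export
capsnet_config <- function(kernel = 3, stride = 1, primary_dim = 8,
                           class_dim = 16, n_class = 2, routing_iters = 3,
                           lr = 0.001, batch_size = 10) {
  stopifnot(kernel >= 1, stride == 1, routing_iters >= 1)
  structure(
    list(
      kernel = kernel, stride = stride, primary_dim = primary_dim,
      class_dim = class_dim, n_class = n_class, routing_iters = routing_iters,
      lr = lr, batch_size = batch_size, pooling = "none"
    ),
    class = "capsnet_config"
  )
}

capsnet_init_params <- function(n_features, cfg) {
  np <- n_features - cfg$kernel + 1 # primary capsules (stride 1, valid conv)
  p <- list(
    W_conv = glorot_init(cfg$kernel, cfg$primary_dim),
    b_conv = matrix(0, 1, cfg$primary_dim)
  )
  for (j in seq_len(cfg$n_class)) {
    for (k in seq_len(cfg$primary_dim)) {
      p[[paste0("W_vote_", j, "_", k)]] <- glorot_init(np, cfg$class_dim) / sqrt(np)
      # per-capsule vote weights: row i transforms dim k of primary capsule i
    }
  }
  p
}

# sliding windows of one sample's feature vector: (n_positions x kernel)
conv_windows <- function(x_row, kernel) {
  np <- length(x_row) - kernel + 1
  mat <- matrix(0, np, kernel)
  for (k in seq_len(kernel)) mat[, k] <- x_row[k:(k + np - 1)]
  mat
}

# forward for ONE sample; returns list of class-capsule nodes (1 x class_dim)
capsnet_forward_one <- function(pn, x_row, cfg) {
  win <- ag_leaf(conv_windows(x_row, cfg$kernel))
  primary <- ag_squash_rows(ag_relu(ag_add_bias(ag_matmul(win, pn$W_conv), pn$b_conv)))
  np <- nrow(primary$value)
  votes <- lapply(seq_len(cfg$n_class), function(j) {
    u <- NULL
    for (k in seq_len(cfg$primary_dim)) {
      contrib <- ag_mul_colvec(pn[[paste0("W_vote_", j, "_", k)]], ag_cols(primary, k))
      u <- if (is.null(u)) contrib else ag_add(u, contrib)
    }
    u # np x class_dim
  })
  b <- ag_leaf(matrix(0, np, cfg$n_class))
  v <- NULL
  for (it in seq_len(cfg$routing_iters)) {
    cpl <- ag_softmax_rows(b)
    v <- lapply(seq_len(cfg$n_class), function(j) {
      s <- ag_matmul(ag_transpose(ag_cols(cpl, j)), votes[[j]]) # 1 x class_dim
      ag_squash_rows(s)
    })
    if (it < cfg$routing_iters) {
      agree <- NULL
      for (j in seq_len(cfg$n_class)) {
        a_j <- ag_matmul(votes[[j]], ag_transpose(v[[j]])) # np x 1
        agree <- if (is.null(agree)) a_j else ag_concat_cols(agree, a_j)
      }
      b <- ag_add(b, agree)
    }
  }
  v
}

#' Fit the capsule-network classifier
#'
#' @inheritParams fit_dnn
#' @param config A [capsnet_config()].
#' @return Object of class `capsnet_fit`.
#' @export
fit_capsnet <- function(x, y, config = capsnet_config(), epochs = 100, seed = 0,
                        validation = NULL, patience = 10) {
  x <- as.matrix(x)
  y <- as.integer(y)
  check_training_data(x, y)
  if (ncol(x) < config$kernel) abort("fewer features than the convolution kernel")
  with_private_seed(derive_seed(seed, "capsnet"), {
    params <- capsnet_init_params(ncol(x), config)
    state <- adam_init(params)
    log <- train_minibatch(
      params, state, x, y,
      epochs = epochs, batch_size = config$batch_size, lr = config$lr,
      forward_loss = function(pn, xb, yb, train) {
        loss <- NULL
        for (s in seq_len(nrow(xb))) {
          v <- capsnet_forward_one(pn, xb[s, ], config)
          # BCE against the one-hot target on both class-capsule norms
          l0 <- ag_bce_probs(ag_row_norms(v[[1]]), 1 - yb[s])
          l1 <- ag_bce_probs(ag_row_norms(v[[2]]), yb[s])
          l <- ag_add(l0, l1)
          loss <- if (is.null(loss)) l else ag_add(loss, l)
        }
        ag_scale(loss, 1 / nrow(xb))
      },
      validation = validation, patience = patience,
      env = environment()
    )
  })
  structure(
    list(params = params, config = config, log = log, seed = seed, n_features = ncol(x)),
    class = c("capsnet_fit", "drugseqr_fit")
  )
}

# class-capsule norms for one sample (values only)
capsnet_norms_one <- function(object, x_row) {
  ag_begin()
  pn <- ag_wrap_params(object$params)
  v <- capsnet_forward_one(pn, x_row, object$config)
  vapply(v, function(nd) sqrt(sum(nd$value^2)), numeric(1))
}

#' @export
predict_proba.capsnet_fit <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) abort("feature width differs from training")
  apply(x, 1, function(row) {
    n <- capsnet_norms_one(object, row)
    n[2] / sum(n) # normalized class-capsule norms
  })
}

#' Class-capsule norms for new samples
#' @param object A `capsnet_fit`.
#' @param x Feature matrix.
#' @return Matrix (samples x classes) of capsule norms, each in `[0, 1)`.
#' @export
capsule_norms <- function(object, x) {
  stopifnot(inherits(object, "capsnet_fit"))
  t(apply(as.matrix(x), 1, function(row) capsnet_norms_one(object, row)))
}
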