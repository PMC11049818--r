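#' Configuration for the bidirectional LSTM classifier
#'
#' A single bidirectional LSTM layer with input dimension 320, hidden
#' dimension 64 per direction (128 after concatenation) and a 2-unit output,
#' trained in batches of 16 with Adam at learning rate 0.001 and binary
#' cross-entropy on the softmax probability of the positive class. A flat
#' feature vector is framed as a length-`n_steps` sequence of
#' `input_dim / n_steps`-wide steps; the default is a single step carrying
#' the whole vector.
#'
#' @param input_dim Total feature width.
#' @param hidden_dim LSTM hidden size per direction.
#' @param output_dim Number of output units (2).
#' @param n_steps How many time steps the feature vector is folded into
#'   (must divide `input_dim`).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return A `bilstm_config` list.
#' @export
bilstm_config <- function(input_dim = 320, hidden_dim = 64, output_dim = 2,
                          n_steps = 1, lr = 0.001, batch_size = 16) {
  stopifnot(input_dim > 0, hidden_dim > 0, output_dim == 2, n_steps >= 1)
  if (input_dim %% n_steps != 0) abort("n_steps must divide input_dim")
  structure(
    list(
      input_dim = input_dim, hidden_dim = hidden_dim, output_dim = output_dim,
      n_steps = n_steps, step_dim = input_dim %/% n_steps,
      lr = lr, batch_size = batch_size
    ),
    class = "bilstm_config"
  )
}

bilstm_init_params <- function(cfg) {
  H <- cfg$hidden_dim
  sd_ <- cfg$step_dim
  p <- list()
  for (dir in c("f", "b")) {
    p[[paste0("Wx_", dir)]] <- glorot_init(sd_, 4 * H)
    p[[paste0("Wh_", dir)]] <- glorot_init(H, 4 * H)
    bias <- matrix(0, 1, 4 * H)
    bias[1, (H + 1):(2 * H)] <- 1 # forget-gate bias
    p[[paste0("b_", dir)]] <- bias
  }
  p$W_out <- glorot_init(2 * H, cfg$output_dim)
  p$b_out <- matrix(0, 1, cfg$output_dim)
  p
}

lstm_run <- function(pn, steps, dir, H, n_batch) {
  h <- ag_leaf(matrix(0, n_batch, H))
  cc <- ag_leaf(matrix(0, n_batch, H))
  Wx <- pn[[paste0("Wx_", dir)]]
  Wh <- pn[[paste0("Wh_", dir)]]
  b <- pn[[paste0("b_", dir)]]
  for (xt in steps) {
    gates <- ag_add_bias(ag_add(ag_matmul(xt, Wx), ag_matmul(h, Wh)), b)
    i <- ag_sigmoid(ag_cols(gates, 1:H))
    f <- ag_sigmoid(ag_cols(gates, (H + 1):(2 * H)))
    o <- ag_sigmoid(ag_cols(gates, (2 * H + 1):(3 * H)))
    g <- ag_tanh(ag_cols(gates, (3 * H + 1):(4 * H)))
    cc <- ag_add(ag_mul(f, cc), ag_mul(i, g))
    h <- ag_mul(o, ag_tanh(cc))
  }
  h
}

bilstm_forward <- function(pn, x, cfg) {
  n_batch <- nrow(x)
  steps <- lapply(seq_len(cfg$n_steps), function(t) {
    ag_leaf(x[, ((t - 1) * cfg$step_dim + 1):(t * cfg$step_dim), drop = FALSE])
  })
  h_f <- lstm_run(pn, steps, "f", cfg$hidden_dim, n_batch)
  h_b <- lstm_run(pn, rev(steps), "b", cfg$hidden_dim, n_batch)
  ag_add_bias(ag_matmul(ag_concat_cols(h_f, h_b), pn$W_out), pn$b_out) # N x 2 logits
}

#' Fit the bidirectional LSTM classifier
#'
#' @inheritParams fit_dnn
#' @param config A [bilstm_config()]; its `input_dim` must match `ncol(x)`.
#' @return Object of class `bilstm_fit`.
#' @export
fit_bilstm <- function(x, y, config = NULL, epochs = 100, seed = 0,
                       validation = NULL, patience = 10) {
  x <- as.matrix(x)
  y <- as.integer(y)
  check_training_data(x, y)
  config <- config %||% bilstm_config(input_dim = ncol(x))
  if (config$input_dim != ncol(x)) abort("config input_dim differs from feature width")
  with_private_seed(derive_seed(seed, "bilstm"), {
    params <- bilstm_init_params(config)
    state <- adam_init(params)
    log <- train_minibatch(
      params, state, x, y,
      epochs = epochs, batch_size = config$batch_size, lr = config$lr,
      forward_loss = function(pn, xb, yb, train) {
        logits <- bilstm_forward(pn, xb, config)
        probs <- ag_softmax_rows(logits)
        ag_bce_probs(ag_cols(probs, 2), yb) # BCE on the class-1 softmax component
      },
      validation = validation, patience = patience,
      env = environment()
    )
  })
  structure(
    list(params = params, config = config, log = log, seed = seed, n_features = ncol(x)),
    class = c("bilstm_fit", "drugseqr_fit")
  )
}

#' @export
predict_proba.bilstm_fit <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) abort("feature width differs from training")
  ag_begin()
  pn <- ag_wrap_params(object$params)
  z <- bilstm_forward(pn, x, object$config)$value
  e <- exp(z - apply(z, 1, max))
  (e / rowSums(e))[, 2]
}
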