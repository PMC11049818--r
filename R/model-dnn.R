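#' Configuration for the feed-forward classifier
#'
#' A multilayer perceptron with three ReLU hidden layers of 180, 60 and 30
#' units, dropout 0.5 after each, and a single sigmoid output unit, trained
#' with binary cross-entropy and Adam at learning rate 0.001 in batches of 10.
#'
#' @param hidden_sizes Hidden-layer widths.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(hidden_sizes = c(180, 60, 30), dropout = 0.5,
                       lr = 0.001, batch_size = 10) {
  stopifnot(all(hidden_sizes > 0), dropout >= 0, dropout < 1)
  structure(
    list(
      hidden_sizes = hidden_sizes, dropout = dropout,
      lr = lr, batch_size = batch_size
    ),
    class = "dnn_config"
  )
}

dnn_init_params <- function(n_features, cfg) {
  dims <- c(n_features, cfg$hidden_sizes, 1)
  params <- list()
  for (l in seq_len(length(dims) - 1)) {
    params[[paste0("W", l)]] <- glorot_init(dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- matrix(0, 1, dims[l + 1])
  }
  params
}

dnn_forward <- function(pn, x_node, cfg, train) {
  h <- x_node
  n_hidden <- length(cfg$hidden_sizes)
  for (l in seq_len(n_hidden)) {
    h <- ag_relu(ag_add_bias(ag_matmul(h, pn[[paste0("W", l)]]), pn[[paste0("b", l)]]))
    h <- ag_dropout(h, cfg$dropout, train)
  }
  ag_add_bias(
    ag_matmul(h, pn[[paste0("W", n_hidden + 1)]]),
    pn[[paste0("b", n_hidden + 1)]]
  ) # single logit column
}

#' Fit the feed-forward classifier
#'
#' @param x Feature matrix (samples x features).
#' @param y Binary 0/1 labels, both classes present.
#' @param config A [dnn_config()].
#' @param epochs Training epochs.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @param validation Optional `list(x = , y = )`; when given, training stops
#'   early once validation loss has not improved for `patience` epochs.
#' @param patience Early-stopping patience in epochs.
#' @return Object of class `dnn_fit` with the trained parameters and a
#'   per-epoch `log` tibble (`epoch`, `loss`, `val_loss`).
#' @export
fit_dnn <- function(x, y, config = dnn_config(), epochs = 100, seed = 0,
                    validation = NULL, patience = 10) {
  x <- as.matrix(x)
  y <- as.integer(y)
  check_training_data(x, y)
  with_private_seed(derive_seed(seed, "dnn"), {
    params <- dnn_init_params(ncol(x), config)
    state <- adam_init(params)
    log <- train_minibatch(
      params, state, x, y,
      epochs = epochs, batch_size = config$batch_size, lr = config$lr,
      forward_loss = function(pn, xb, yb, train) {
        ag_bce_logits(dnn_forward(pn, ag_leaf(xb), config, train), yb)
      },
      validation = validation, patience = patience,
      env = environment()
    )
  })
  structure(
    list(params = params, config = config, log = log, seed = seed, n_features = ncol(x)),
    class = c("dnn_fit", "drugseqr_fit")
  )
}

#' @export
predict_proba.dnn_fit <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) abort("feature width differs from training")
  ag_begin()
  pn <- ag_wrap_params(object$params)
  z <- dnn_forward(pn, ag_leaf(x), object$config, train = FALSE)
  as.vector(1 / (1 + exp(-z$value)))
}

# shared mini-batch Adam loop; mutates `params`/`state` in `env`
train_minibatch <- function(params, state, x, y, epochs, batch_size, lr,
                            forward_loss, validation, patience, env) {
  n <- nrow(x)
  best_val <- Inf
  best_params <- params
  stall <- 0
  rows <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      b <- ord[start:min(start + batch_size - 1, n)]
      ag_begin()
      pn <- ag_wrap_params(params)
      loss <- forward_loss(pn, x[b, , drop = FALSE], y[b], TRUE)
      ag_backward(loss)
      upd <- adam_step(params, ag_collect_grads(pn), state, lr = lr)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, loss$value[1, 1])
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      ag_begin()
      pn <- ag_wrap_params(params)
      vl <- forward_loss(pn, as.matrix(validation$x), as.integer(validation$y), FALSE)
      val_loss <- vl$value[1, 1]
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss
        best_params <- params
        stall <- 0
      } else {
        stall <- stall + 1
      }
    }
    rows[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses), val_loss = val_loss)
    if (!is.null(validation) && stall >= patience) break
  }
  if (!is.null(validation)) params <- best_params
  assign("params", params, envir = env)
  assign("state", state, envir = env)
  dplyr::bind_rows(rows)
}

check_training_data <- function(x, y) {
  if (length(y) != nrow(x)) abort("labels and feature rows differ in length")
  if (!all(y %in% c(0L, 1L))) abort("labels must be binary 0/1")
  if (length(unique(y)) < 2) abort("both classes must be present for fitting")
  invisible(NULL)
}

#' @export
print.drugseqr_fit <- function(x, ...) {
  cat("<", class(x)[1], "> ", param_count(x$params), " parameters, ",
    nrow(x$log), " epochs trained, final loss ",
    format(utils::tail(x$log$loss, 1), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}
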