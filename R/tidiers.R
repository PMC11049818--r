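#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted deep classifier's training history
#'
#' @param x A `dnn_fit`, `capsnet_fit`, `bilstm_fit` or `gpt_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch (`epoch`, `loss`, and `val_loss` or
#'   `train_acc` where tracked).
#' @method tidy drugseqr_fit
#' @export
tidy.drugseqr_fit <- function(x, ...) x$log

#' One-row summary of a fitted deep classifier
#'
#' @param x A fitted model object.
#' @param ... Unused.
#' @return Tibble: `model`, `n_parameters`, `epochs`, `final_loss`, `seed`.
#' @method glance drugseqr_fit
#' @export
glance.drugseqr_fit <- function(x, ...) {
  tibble::tibble(
    model = sub("_fit$", "", class(x)[1]),
    n_parameters = param_count(x$params),
    epochs = nrow(x$log),
    final_loss = utils::tail(x$log$loss, 1),
    seed = x$seed
  )
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$roc

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) tibble::tibble(auc = x$auc)

#' @method tidy three_way_split
#' @export
tidy.three_way_split <- function(x, ...) {
  tidyr::pivot_longer(x$counts, -"label",
    names_to = "partition", values_to = "n"
  )
}

#' @method tidy finetuned_embedder
#' @export
tidy.finetuned_embedder <- function(x, ...) x$log

#' @method glance finetuned_embedder
#' @export
glance.finetuned_embedder <- function(x, ...) {
  tibble::tibble(
    backend = x$embedder_cfg$backend,
    output_dim = x$embedder_cfg$output_dim,
    epochs = nrow(x$log),
    final_loss = utils::tail(x$log$loss, 1)
  )
}
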