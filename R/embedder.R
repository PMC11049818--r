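#' Configuration for the protein-language-model embedder
#'
#' The embedder contract is backend-pluggable: every backend yields
#' per-residue representations (L x `output_dim`), a mean-pooled per-protein
#' vector (cls/eos excluded from the mean) and an L x L contact map. The
#' `stub` backend is a deterministic random-feature encoder — token and
#' bigram lookup tables drawn once from `seed` — used for offline testing;
#' `esm2_t6_8M` names the 6-layer, 320-dimensional pretrained transformer
#' whose weights must be supplied externally and is not bundled.
#'
#' @param backend `"stub"` or `"esm2_t6_8M"`.
#' @param repr_layer Representation layer to read (6 = final layer of the
#'   small pretrained model).
#' @param output_dim Embedding width (320 matches the pretrained family).
#' @param contact_head_width Feature width of the (reduced) contact head.
#' @param seed Seed for the stub backend's tables.
#' @return An `embedder_config` list.
#' @export
embedder_config <- function(backend = c("stub", "esm2_t6_8M"), repr_layer = 6,
                            output_dim = 320, contact_head_width = 24, seed = 1) {
  backend <- tryCatch(match.arg(backend), error = function(e) {
    abort(paste0("unknown embedder backend: ", backend[1]))
  })
  stopifnot(output_dim > 0, repr_layer >= 1)
  structure(
    list(
      backend = backend, repr_layer = repr_layer, output_dim = output_dim,
      contact_head_width = contact_head_width, seed = seed
    ),
    class = "embedder_config"
  )
}

# stub lookup tables, memoised per (output_dim, seed)
stub_cache <- new.env(parent = emptyenv())

stub_tables <- function(cfg) {
  key <- paste0("d", cfg$output_dim, "_s", cfg$seed)
  if (is.null(stub_cache[[key]])) {
    nv <- length(protein_alphabet())
    stub_cache[[key]] <- with_private_seed(derive_seed(cfg$seed, "stub"), list(
      tok = matrix(rnorm(nv * cfg$output_dim), nv, cfg$output_dim),
      bigram = matrix(rnorm(nv * nv * cfg$output_dim, sd = 0.5), nv * nv, cfg$output_dim)
    ))
  }
  stub_cache[[key]]
}

stub_residue_reps <- function(sequence, cfg) {
  ab <- protein_alphabet()
  ids <- tokenize(sequence, ab)
  res_ids <- ids[-c(1, length(ids))] # residues only
  prev <- c(attr(ab, "cls"), head(res_ids, -1))
  tabs <- stub_tables(cfg)
  tabs$tok[res_ids + 1L, , drop = FALSE] +
    tabs$bigram[prev * length(ab) + res_ids + 1L, , drop = FALSE]
}

#' Embed one protein
#'
#' @param sequence Amino-acid string (or a one-row record tibble).
#' @param cfg An [embedder_config()] or a fine-tuned embedder from
#'   [finetune_plm()].
#' @return List with `residues` (L x D matrix of per-residue representations,
#'   special tokens excluded) and `pooled` (length-D mean over residues).
#' @export
embed_protein <- function(sequence, cfg = embedder_config()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  if (inherits(cfg, "finetuned_embedder")) {
    return(finetuned_embed_one(sequence, cfg))
  }
  if (cfg$backend != "stub") {
    abort(paste0(
      "backend '", cfg$backend, "' needs externally supplied pretrained ",
      "weights; only the deterministic 'stub' backend is bundled"
    ))
  }
  R <- stub_residue_reps(sequence, cfg)
  list(residues = R, pooled = colMeans(R))
}

#' Pooled embeddings for a dataset of records
#'
#' @param records Record tibble (`id`, `sequence`, optional `label`).
#' @param cfg An [embedder_config()] or fine-tuned embedder.
#' @return Tibble: `id`, optional `label`, then `e1 ... eD` columns.
#' @export
plm_embedding_matrix <- function(records, cfg = embedder_config()) {
  assert_records(records)
  rows <- purrr::map(records$sequence, function(s) embed_protein(s, cfg)$pooled)
  feat <- do.call(rbind, rows)
  colnames(feat) <- paste0("e", seq_len(ncol(feat)))
  out <- tibble::tibble(id = records$id)
  if ("label" %in% names(records)) out$label <- records$label
  dplyr::bind_cols(out, tibble::as_tibble(feat))
}

#' Predicted residue-residue contact map
#'
#' Backends score every residue pair, the matrix is symmetrized as
#' `(M + t(M)) / 2` and clipped to `[0, 1]`. The stub backend derives a
#' deterministic pseudo-map from its residue representations (first
#' `contact_head_width` dimensions) with a short-range distance decay.
#'
#' @param sequence Amino-acid string (or one-row record tibble).
#' @param cfg An [embedder_config()] or fine-tuned embedder.
#' @return L x L symmetric numeric matrix with entries in `[0, 1]`.
#' @export
predict_contacts <- function(sequence, cfg = embedder_config()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  base_cfg <- if (inherits(cfg, "finetuned_embedder")) cfg$embedder_cfg else cfg
  R <- if (inherits(cfg, "finetuned_embedder")) {
    finetuned_embed_one(sequence, cfg, residues = TRUE)$residues
  } else {
    embed_protein(sequence, cfg)$residues
  }
  w <- min(base_cfg$contact_head_width, ncol(R))
  Rw <- R[, seq_len(w), drop = FALSE]
  L <- nrow(Rw)
  M <- 1 / (1 + exp(-(Rw %*% t(Rw)) / sqrt(w)))
  decay <- 1 / (1 + abs(outer(seq_len(L), seq_len(L), "-")) / 8)
  M <- M * decay
  M <- (M + t(M)) / 2
  pmin(pmax(M, 0), 1)
}

#' Sort records into length-homogeneous padded batches
#'
#' Records are sorted by ascending sequence length (ties by id) and grouped
#' into consecutive batches, so padding within a batch only fills up to the
#' batch's own maximum — with batch size two this keeps padding minimal
#' among all groupings of the same size.
#'
#' @param records Record tibble.
#' @param batch_size Records per batch.
#' @return List of batches: each has `records` (the tibble slice), `tokens`
#'   and `mask` (from [pad_batch()]).
#' @export
make_length_batches <- function(records, batch_size = 2) {
  assert_records(records)
  if (nrow(records) == 0) abort("no records to batch")
  ord <- order(nchar(records$sequence), records$id)
  records <- records[ord, ]
  ab <- protein_alphabet()
  starts <- seq(1, nrow(records), by = batch_size)
  lapply(starts, function(s) {
    chunk <- records[s:min(s + batch_size - 1, nrow(records)), ]
    pb <- pad_batch(lapply(chunk$sequence, tokenize, alphabet = ab), ab)
    list(records = chunk, tokens = pb$tokens, mask = pb$mask)
  })
}

#' Fine-tuning configuration
#'
#' @param batch_size Length-sorted batch size (2 keeps padding minimal).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param hidden Width of the appended fully connected layer.
#' @param seed Integer seed.
#' @return A `finetune_config` list; the loss is binary cross-entropy.
#' @export
finetune_config <- function(batch_size = 2, epochs = 20, lr = 0.01,
                            hidden = 32, seed = 0) {
  stopifnot(batch_size >= 1, epochs >= 1)
  structure(
    list(
      batch_size = batch_size, epochs = epochs, lr = lr,
      hidden = hidden, seed = seed, loss = "bce"
    ),
    class = "finetune_config"
  )
}

#' Fine-tune the embedder on labeled records
#'
#' Appends a fully connected layer and a single-unit sigmoid classification
#' layer on top of the pooled backbone representation and minimizes binary
#' cross-entropy over length-sorted batches. All backbone weights train
#' (for the stub backend the backbone is a linear transform initialized at
#' the identity, so with learning rate 0 fine-tuning is an exact no-op on
#' extracted embeddings). Downstream embeddings are read immediately before
#' the fully connected layer.
#'
#' @param records Labeled record tibble, both classes present.
#' @param ft_cfg A [finetune_config()].
#' @param embedder_cfg The backbone [embedder_config()].
#' @return Object of class `finetuned_embedder` with `params`, `log`
#'   (per-epoch loss) and `batch_sizes` (as trained).
#' @export
finetune_plm <- function(records, ft_cfg = finetune_config(),
                         embedder_cfg = embedder_config()) {
  assert_records(records, need_label = TRUE)
  y_all <- as.integer(records$label)
  check_training_data(matrix(0, nrow(records), 1), y_all)
  batches <- make_length_batches(records, ft_cfg$batch_size)
  # pooled backbone inputs are fixed per record; the trainable backbone
  # transform and the appended head sit on top
  pooled <- plm_embedding_matrix(records, embedder_cfg)
  fm <- feature_matrix(pooled)
  D <- ncol(fm$x)
  log <- NULL
  with_private_seed(derive_seed(ft_cfg$seed, "finetune"), {
    params <- list(
      W_bb = diag(D), b_bb = matrix(0, 1, D),
      W_fc = glorot_init(D, ft_cfg$hidden), b_fc = matrix(0, 1, ft_cfg$hidden),
      w_cls = glorot_init(ft_cfg$hidden, 1), b_cls = matrix(0, 1, 1)
    )
    state <- adam_init(params)
    rows <- list()
    for (ep in seq_len(ft_cfg$epochs)) {
      losses <- c()
      for (b in batches) {
        xb <- fm$x[match(b$records$id, records$id), , drop = FALSE]
        yb <- y_all[match(b$records$id, records$id)]
        ag_begin()
        pn <- ag_wrap_params(params)
        z <- ag_add_bias(ag_matmul(ag_leaf(xb), pn$W_bb), pn$b_bb)
        h <- ag_relu(ag_add_bias(ag_matmul(z, pn$W_fc), pn$b_fc))
        logit <- ag_add_bias(ag_matmul(h, pn$w_cls), pn$b_cls)
        loss <- ag_bce_logits(logit, yb)
        ag_backward(loss)
        upd <- adam_step(params, ag_collect_grads(pn), state, lr = ft_cfg$lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, loss$value[1, 1])
      }
      rows[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses))
    }
    log <- dplyr::bind_rows(rows)
  })
  structure(
    list(
      params = params, ft_cfg = ft_cfg, embedder_cfg = embedder_cfg,
      log = log, batch_sizes = vapply(batches, function(b) nrow(b$records), numeric(1))
    ),
    class = "finetuned_embedder"
  )
}

finetuned_embed_one <- function(sequence, ft, residues = FALSE) {
  base <- embed_protein(sequence, ft$embedder_cfg)
  z <- as.vector(base$pooled %*% ft$params$W_bb + ft$params$b_bb)
  out <- list(residues = base$residues, pooled = z)
  if (residues) {
    # push the backbone transform through to residue level for contact maps
    out$residues <- base$residues %*% ft$params$W_bb
  }
  out
}

#' @export
predict_proba.finetuned_embedder <- function(object, x, ...) {
  records <- if (is.data.frame(x) && "sequence" %in% names(x)) x else abort("records expected")
  emb <- plm_embedding_matrix(records, object)
  z <- feature_matrix(emb)$x
  h <- pmax(sweep(z %*% object$params$W_fc, 2, as.vector(object$params$b_fc), "+"), 0)
  as.vector(1 / (1 + exp(-(h %*% object$params$w_cls + object$params$b_cls[1, 1]))))
}

#' @export
print.finetuned_embedder <- function(x, ...) {
  cat("<finetuned_embedder> backbone=", x$embedder_cfg$backend,
    " dim=", x$embedder_cfg$output_dim,
    " final loss=", format(utils::tail(x$log$loss, 1), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}
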