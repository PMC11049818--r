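#' Configuration for the decoder-transformer sequence classifier
#'
#' A compact GPT-style decoder trained from random initialization that maps a
#' tokenized protein sequence straight to two class probabilities: summed
#' token and position embeddings, `n_layer` pre-norm transformer blocks with
#' causal self-attention and a GELU feed-forward expansion, and a 2-logit
#' softmax head read from the last non-pad position. The vocabulary is the
#' 33-token protein alphabet; block size, heads, layers and width are reduced
#' from the original language-model scale for speed.
#'
#' @param vocab_size Vocabulary size (33, the protein alphabet).
#' @param block_size Maximum encoded length, cls and eos included.
#' @param n_layer Transformer blocks.
#' @param n_head Attention heads (`embed_dim` must be divisible by it).
#' @param embed_dim Embedding width.
#' @param dropout Dropout rate (0 keeps training fully deterministic).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return A `gpt_config` list.
#' @export
gpt_config <- function(vocab_size = 33, block_size = 512, n_layer = 4,
                       n_head = 4, embed_dim = 128, dropout = 0,
                       lr = 0.001, batch_size = 8) {
  stopifnot(block_size >= 3, embed_dim %% n_head == 0, vocab_size >= 5)
  structure(
    list(
      vocab_size = vocab_size, block_size = block_size, n_layer = n_layer,
      n_head = n_head, embed_dim = embed_dim, head_dim = embed_dim %/% n_head,
      dropout = dropout, lr = lr, batch_size = batch_size
    ),
    class = "gpt_config"
  )
}

gpt_init_params <- function(cfg) {
  E <- cfg$embed_dim
  p <- list(
    tok_emb = matrix(rnorm(cfg$vocab_size * E, sd = 0.02), cfg$vocab_size, E),
    pos_emb = matrix(rnorm(cfg$block_size * E, sd = 0.02), cfg$block_size, E)
  )
  for (l in seq_len(cfg$n_layer)) {
    p[[paste0("ln1_g_", l)]] <- matrix(1, 1, E)
    p[[paste0("ln1_b_", l)]] <- matrix(0, 1, E)
    p[[paste0("W_qkv_", l)]] <- glorot_init(E, 3 * E)
    p[[paste0("b_qkv_", l)]] <- matrix(0, 1, 3 * E)
    p[[paste0("W_o_", l)]] <- glorot_init(E, E)
    p[[paste0("b_o_", l)]] <- matrix(0, 1, E)
    p[[paste0("ln2_g_", l)]] <- matrix(1, 1, E)
    p[[paste0("ln2_b_", l)]] <- matrix(0, 1, E)
    p[[paste0("W_fc_", l)]] <- glorot_init(E, 4 * E)
    p[[paste0("b_fc_", l)]] <- matrix(0, 1, 4 * E)
    p[[paste0("W_pr_", l)]] <- glorot_init(4 * E, E)
    p[[paste0("b_pr_", l)]] <- matrix(0, 1, E)
  }
  p$lnf_g <- matrix(1, 1, E)
  p$lnf_b <- matrix(0, 1, E)
  p$W_head <- glorot_init(E, 2)
  p$b_head <- matrix(0, 1, 2)
  p
}

# truncate ids to the block size, keeping cls and replacing the final kept
# residue with eos so the encoding contract survives truncation
gpt_clip_ids <- function(ids, cfg, alphabet, warn_on_truncate = TRUE) {
  if (any(ids >= cfg$vocab_size)) abort("token id outside the model vocabulary")
  if (length(ids) > cfg$block_size) {
    if (warn_on_truncate) {
      warn(paste0("sequence of ", length(ids), " tokens truncated to block size ", cfg$block_size))
    }
    ids <- c(ids[seq_len(cfg$block_size - 1)], attr(alphabet, "eos"))
  }
  ids
}

#' Position-aware token embeddings
#'
#' Row `t` of the result is `token_embedding[id_t] + position_embedding[t]`.
#'
#' @param ids Integer token ids (as from [tokenize()]).
#' @param params Parameter list from a `gpt_fit` (or `gpt_init_params`).
#' @param cfg The matching [gpt_config()].
#' @return `length(ids) x embed_dim` numeric matrix.
#' @export
gpt_embed_tokens <- function(ids, params, cfg) {
  ids <- gpt_clip_ids(ids, cfg, protein_alphabet())
  params$tok_emb[ids + 1L, , drop = FALSE] +
    params$pos_emb[seq_along(ids), , drop = FALSE]
}

# forward for one id vector (may contain pad tokens); returns 1 x 2 logit node
gpt_forward_one <- function(pn, ids, cfg, alphabet, train = FALSE) {
  pad <- attr(alphabet, "pad")
  real <- which(ids != pad)
  if (length(real) == 0) abort("sequence is all padding")
  T_ <- length(ids)
  x <- ag_add(ag_rows(pn$tok_emb, ids + 1L), ag_rows(pn$pos_emb, seq_len(T_)))
  # attention bias: disallow future positions and pad keys
  bias <- matrix(0, T_, T_)
  bias[upper.tri(bias)] <- -1e9
  bias[, ids == pad] <- -1e9
  for (l in seq_len(cfg$n_layer)) {
    h <- ag_layernorm(x, pn[[paste0("ln1_g_", l)]], pn[[paste0("ln1_b_", l)]])
    qkv <- ag_add_bias(ag_matmul(h, pn[[paste0("W_qkv_", l)]]), pn[[paste0("b_qkv_", l)]])
    E <- cfg$embed_dim
    heads <- NULL
    for (hh in seq_len(cfg$n_head)) {
      cols <- ((hh - 1) * cfg$head_dim + 1):(hh * cfg$head_dim)
      q <- ag_cols(qkv, cols)
      k <- ag_cols(qkv, E + cols)
      v <- ag_cols(qkv, 2 * E + cols)
      att <- ag_scale(ag_matmul(q, ag_transpose(k)), 1 / sqrt(cfg$head_dim))
      att <- ag_softmax_rows(ag_add(att, ag_leaf(bias)))
      att <- ag_dropout(att, cfg$dropout, train)
      out <- ag_matmul(att, v)
      heads <- if (is.null(heads)) out else ag_concat_cols(heads, out)
    }
    proj <- ag_add_bias(ag_matmul(heads, pn[[paste0("W_o_", l)]]), pn[[paste0("b_o_", l)]])
    x <- ag_add(x, ag_dropout(proj, cfg$dropout, train))
    h2 <- ag_layernorm(x, pn[[paste0("ln2_g_", l)]], pn[[paste0("ln2_b_", l)]])
    mlp <- ag_gelu(ag_add_bias(ag_matmul(h2, pn[[paste0("W_fc_", l)]]), pn[[paste0("b_fc_", l)]]))
    mlp <- ag_add_bias(ag_matmul(mlp, pn[[paste0("W_pr_", l)]]), pn[[paste0("b_pr_", l)]])
    x <- ag_add(x, ag_dropout(mlp, cfg$dropout, train))
  }
  x <- ag_layernorm(x, pn$lnf_g, pn$lnf_b)
  read <- ag_rows(x, max(real)) # representation of the last non-pad token
  ag_add_bias(ag_matmul(read, pn$W_head), pn$b_head)
}

#' Forward pass of the decoder-transformer classifier
#'
#' @param ids Integer token ids (pad tokens allowed; they are masked out of
#'   attention and the read-out position is the last non-pad token).
#' @param params Parameter list.
#' @param cfg The matching [gpt_config()].
#' @return List with `logits` and `probs` (each a 2-vector).
#' @export
gpt_forward <- function(ids, params, cfg) {
  alphabet <- protein_alphabet()
  ids <- gpt_clip_ids(ids, cfg, alphabet, warn_on_truncate = FALSE)
  ag_begin()
  pn <- ag_wrap_params(params)
  z <- gpt_forward_one(pn, ids, cfg, alphabet, train = FALSE)$value
  e <- exp(z - max(z))
  list(logits = as.vector(z), probs = as.vector(e / sum(e)))
}

#' Train the decoder-transformer classifier end to end
#'
#' Tokenizes the records, truncates anything longer than the block size
#' (C-terminal residues dropped, with a warning) and minimizes the two-class
#' cross-entropy with Adam. No pretrained weights are involved.
#'
#' @param records Labeled record tibble (`id`, `sequence`, `label`).
#' @param config A [gpt_config()].
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return Object of class `gpt_fit` with `params`, `config` and a per-epoch
#'   `log` tibble (`epoch`, `loss`, `train_acc`).
#' @export
fit_gpt <- function(records, config = gpt_config(), epochs = 50, seed = 0) {
  assert_records(records, need_label = TRUE)
  y <- as.integer(records$label)
  check_training_data(matrix(0, nrow(records), 1), y)
  alphabet <- protein_alphabet()
  ids_list <- lapply(records$sequence, function(s) {
    gpt_clip_ids(tokenize(s, alphabet), config, alphabet)
  })
  n <- length(ids_list)
  log <- NULL
  with_private_seed(derive_seed(seed, "gpt"), {
    params <- gpt_init_params(config)
    state <- adam_init(params)
    rows <- list()
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        b <- ord[start:min(start + config$batch_size - 1, n)]
        ag_begin()
        pn <- ag_wrap_params(params)
        logits <- NULL
        for (s in b) {
          z <- gpt_forward_one(pn, ids_list[[s]], config, alphabet, train = TRUE)
          logits <- if (is.null(logits)) z else rbind_nodes(logits, z)
        }
        loss <- ag_ce_logits(logits, y[b] + 1L)
        ag_backward(loss)
        upd <- adam_step(params, ag_collect_grads(pn), state, lr = config$lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, loss$value[1, 1])
        correct <- correct + sum(apply(logits$value, 1, which.max) - 1L == y[b])
      }
      rows[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses), train_acc = correct / n)
    }
    log <- dplyr::bind_rows(rows)
  })
  structure(
    list(params = params, config = config, log = log, seed = seed),
    class = c("gpt_fit", "drugseqr_fit")
  )
}

# stack two nodes row-wise (for building a batch logit matrix)
rbind_nodes <- function(a, b) {
  na <- nrow(a$value)
  ag_node(rbind(a$value, b$value), function(g) {
    ag_acc(a, g[seq_len(na), , drop = FALSE])
    ag_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

#' @export
predict_proba.gpt_fit <- function(object, x, ...) {
  records <- x
  assert_records(records)
  vapply(records$sequence, function(s) {
    ids <- tokenize(s)
    gpt_forward(ids, object$params, object$config)$probs[2]
  }, numeric(1), USE.NAMES = FALSE)
}
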