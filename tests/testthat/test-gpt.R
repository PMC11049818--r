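toy_gpt_cfg <- function() gpt_config(block_size = 16, n_layer = 1, n_head = 1, embed_dim = 4)

test_that("token embeddings are additive in token and position tables", {
  cfg <- toy_gpt_cfg()
  params <- withr::with_seed(1, drugseqr:::gpt_init_params(cfg))
  expect_equal(nrow(params$tok_emb), 33)
  zero <- params
  zero$tok_emb[] <- 0
  zero$pos_emb[] <- 0
  expect_true(all(gpt_embed_tokens(c(0L, 4L, 2L), zero, cfg) == 0))
  # same token at two positions differs exactly by the position rows
  ids <- c(5L, 5L)
  E <- gpt_embed_tokens(ids, params, cfg)
  expect_equal(E[2, ] - E[1, ], params$pos_emb[2, ] - params$pos_emb[1, ])
  expect_error(gpt_embed_tokens(c(0L, 40L), params, cfg), "vocabulary")
})

# independent straight-line transcription of the 1-layer, 1-head forward pass
gpt_oracle_logits <- function(ids, params, cfg) {
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * as.vector(g) + as.vector(b)
    }))
  }
  softmax_rows <- function(z) {
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  }
  E <- cfg$embed_dim
  x <- params$tok_emb[ids + 1, , drop = FALSE] +
    params$pos_emb[seq_along(ids), , drop = FALSE]
  h <- ln(x, params$ln1_g_1, params$ln1_b_1)
  qkv <- sweep(h %*% params$W_qkv_1, 2, as.vector(params$b_qkv_1), "+")
  q <- qkv[, 1:E, drop = FALSE]
  k <- qkv[, (E + 1):(2 * E), drop = FALSE]
  v <- qkv[, (2 * E + 1):(3 * E), drop = FALSE]
  att <- q %*% t(k) / sqrt(E)
  att[upper.tri(att)] <- att[upper.tri(att)] - 1e9
  out <- softmax_rows(att) %*% v
  proj <- sweep(out %*% params$W_o_1, 2, as.vector(params$b_o_1), "+")
  x <- x + proj
  h2 <- ln(x, params$ln2_g_1, params$ln2_b_1)
  mlp <- sweep(h2 %*% params$W_fc_1, 2, as.vector(params$b_fc_1), "+")
  mlp <- mlp * pnorm(mlp)
  mlp <- sweep(mlp %*% params$W_pr_1, 2, as.vector(params$b_pr_1), "+")
  x <- ln(x + mlp, params$lnf_g, params$lnf_b)
  as.vector(x[length(ids), , drop = FALSE] %*% params$W_head + params$b_head)
}

test_that("the toy forward pass matches the straight-line oracle", {
  cfg <- toy_gpt_cfg()
  params <- withr::with_seed(3, drugseqr:::gpt_init_params(cfg))
  ids <- tokenize("ACD")[1:3] # cls + 2 residues, no pads
  got <- gpt_forward(ids, params, cfg)
  expect_equal(got$logits, gpt_oracle_logits(ids, params, cfg), tolerance = 1e-10)
  expect_equal(sum(got$probs), 1, tolerance = 1e-6)
  expect_true(all(got$probs >= 0))
})

test_that("padding and post-read positions never change the output", {
  cfg <- toy_gpt_cfg()
  params <- withr::with_seed(4, drugseqr:::gpt_init_params(cfg))
  ids <- tokenize("ACDKW")
  base <- gpt_forward(ids, params, cfg)
  padded <- gpt_forward(c(ids, rep(1L, 5)), params, cfg)
  expect_identical(base$logits, padded$logits)
  # perturbing embeddings at positions after the read position is invisible
  bumped <- params
  bumped$pos_emb[(length(ids) + 1):nrow(bumped$pos_emb), ] <- 99
  expect_identical(
    gpt_forward(c(ids, rep(1L, 5)), bumped, cfg)$logits,
    base$logits
  )
})

test_that("the parameter count matches the closed-form architecture count", {
  for (cfg in list(toy_gpt_cfg(), gpt_config(block_size = 32, n_layer = 2, n_head = 2, embed_dim = 8))) {
    params <- withr::with_seed(5, drugseqr:::gpt_init_params(cfg))
    E <- cfg$embed_dim
    expected <- 33 * E + cfg$block_size * E +
      cfg$n_layer * (12 * E^2 + 13 * E) +
      2 * E + (2 * E + 2)
    expect_equal(drugseqr:::param_count(params), expected)
  }
})

test_that("end-to-end training separates motif from background sequences", {
  spec <- fixture_spec(n_pos = 10, n_neg = 10, length_range = c(20, 30), seed = 11)
  recs <- generate_records(spec)
  cfg <- gpt_config(block_size = 40, n_layer = 1, n_head = 2, embed_dim = 16, batch_size = 4)
  fit <- fit_gpt(recs, cfg, epochs = 50, seed = 2)
  expect_equal(utils::tail(fit$log$train_acc, 1), 1)
  # chance-level cross-entropy at the start of training on balanced labels
  expect_lt(abs(fit$log$loss[1] - log(2)), 0.2)
  prob <- predict_proba(fit, recs)
  expect_equal(mean((prob >= 0.5) == recs$label), 1)
  # determinism replay
  fit2 <- fit_gpt(recs, cfg, epochs = 50, seed = 2)
  expect_identical(fit$params, fit2$params)
  # over-length sequences truncate with a warning rather than failing
  long <- tibble::tibble(id = c("l1", "s1"), sequence = c(strrep("ACDK", 30), "MKVL"), label = c(1L, 0L))
  expect_warning(fit3 <- fit_gpt(long, cfg, epochs = 1, seed = 1), "truncated")
})
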