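test_that("squash keeps direction and bounds the norm below one", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- squash(c(1, 0))
  expect_equal(sqrt(sum(v^2)), 0.5) # ||s|| = 1 -> 1/(1+1)
  withr::with_seed(2, {
    for (i in 1:20) {
      s <- rnorm(8) * 10^runif(1, -2, 2)
      out <- squash(s)
      expect_lt(sqrt(sum(out^2)), 1)
      expect_equal(out / sqrt(sum(out^2)), s / sqrt(sum(s^2))) # same direction
    }
  })
})

# literal step-by-step transcription of routing-by-agreement for the
# 2-primary, 2-class, 3-iteration toy case; no loops over iterations
routing_oracle_2x2 <- function(u11, u12, u21, u22) {
  # iteration 1: all logits 0 -> couplings 1/2
  s1 <- 0.5 * u11 + 0.5 * u21
  s2 <- 0.5 * u12 + 0.5 * u22
  v1 <- squash(s1)
  v2 <- squash(s2)
  b11 <- sum(u11 * v1); b12 <- sum(u12 * v2)
  b21 <- sum(u21 * v1); b22 <- sum(u22 * v2)
  # iteration 2
  c11 <- exp(b11) / (exp(b11) + exp(b12)); c12 <- 1 - c11
  c21 <- exp(b21) / (exp(b21) + exp(b22)); c22 <- 1 - c21
  v1 <- squash(c11 * u11 + c21 * u21)
  v2 <- squash(c12 * u12 + c22 * u22)
  b11 <- b11 + sum(u11 * v1); b12 <- b12 + sum(u12 * v2)
  b21 <- b21 + sum(u21 * v1); b22 <- b22 + sum(u22 * v2)
  # iteration 3
  c11 <- exp(b11) / (exp(b11) + exp(b12)); c12 <- 1 - c11
  c21 <- exp(b21) / (exp(b21) + exp(b22)); c22 <- 1 - c21
  v1 <- squash(c11 * u11 + c21 * u21)
  v2 <- squash(c12 * u12 + c22 * u22)
  rbind(v1, v2)
}

test_that("dynamic routing matches a straight-line oracle and its symmetries", {
  withr::with_seed(5, {
    u11 <- rnorm(4); u12 <- rnorm(4); u21 <- rnorm(4); u22 <- rnorm(4)
    votes <- array(0, c(2, 2, 4))
    votes[1, 1, ] <- u11; votes[1, 2, ] <- u12
    votes[2, 1, ] <- u21; votes[2, 2, ] <- u22
    r <- dynamic_routing(votes, iters = 3)
    expect_equal(unname(r$capsules), unname(routing_oracle_2x2(u11, u12, u21, u22)))
    expect_equal(rowSums(r$couplings), c(1, 1))
    # one primary capsule, one class: coupling forced to 1
    single <- array(rnorm(4), c(1, 1, 4))
    expect_equal(as.vector(dynamic_routing(single, 3)$capsules), squash(as.vector(single)))
    # identical votes to both classes stay symmetric
    same <- array(rep(rnorm(4), each = 2), c(1, 2, 4))
    same[1, 2, ] <- same[1, 1, ]
    expect_equal(dynamic_routing(same, 5)$couplings[1, 1], 0.5)
  })
  expect_error(dynamic_routing(array(0, c(1, 1, 2)), iters = 0), "iteration")
})

test_that("the feed-forward net has the documented parameter count on 320-D input", {
  cfg <- dnn_config()
  params <- drugseqr:::dnn_init_params(320, cfg)
  expect_equal(
    drugseqr:::param_count(params),
    (320 * 180 + 180) + (180 * 60 + 60) + (60 * 30 + 30) + (30 * 1 + 1)
  )
  expect_equal(drugseqr:::param_count(params), 70501)
})

test_that("each architecture overfits separable data and replays deterministically", {
  d <- separable_features(n = 40, d = 24)
  fits <- list(
    dnn = fit_dnn(d$x, d$y, dnn_config(hidden_sizes = c(32, 16, 8), dropout = 0.2),
      epochs = 100, seed = 1
    ),
    bilstm = fit_bilstm(d$x, d$y, bilstm_config(input_dim = 24, hidden_dim = 16, n_steps = 4),
      epochs = 150, seed = 1
    ),
    capsnet = fit_capsnet(d$x, d$y, capsnet_config(), epochs = 30, seed = 1)
  )
  for (nm in names(fits)) {
    prob <- predict_proba(fits[[nm]], d$x)
    expect_true(all(prob >= 0 & prob <= 1), info = nm)
    expect_equal(mean((prob >= 0.5) == d$y), 1, info = nm)
    # inference is deterministic (dropout off outside training)
    expect_identical(prob, predict_proba(fits[[nm]], d$x), info = nm)
  }
  # bit-for-bit replay with the same seed
  again <- fit_dnn(d$x, d$y, dnn_config(hidden_sizes = c(32, 16, 8), dropout = 0.2),
    epochs = 100, seed = 1
  )
  expect_identical(fits$dnn$params, again$params)
  expect_identical(fits$dnn$log, again$log)
})

test_that("the BiLSTM concatenates a 128-wide state and outputs softmax pairs", {
  cfg <- bilstm_config(input_dim = 320)
  params <- drugseqr:::bilstm_init_params(cfg)
  expect_equal(dim(params$W_out), c(128, 2)) # 2 x 64 hidden -> 2 logits
  d <- separable_features(n = 12, d = 16)
  fit <- fit_bilstm(d$x, d$y, bilstm_config(input_dim = 16, hidden_dim = 8), epochs = 3, seed = 2)
  ag <- drugseqr:::ag_begin()
  pn <- drugseqr:::ag_wrap_params(fit$params)
  z <- drugseqr:::bilstm_forward(pn, d$x, fit$config)$value
  p <- exp(z) / rowSums(exp(z))
  expect_equal(rowSums(p), rep(1, 12))
})

test_that("the capsule network exposes capsule norms and contains no pooling", {
  cfg <- capsnet_config()
  expect_equal(cfg$pooling, "none")
  expect_false(any(grepl("pool", deparse(drugseqr:::capsnet_forward_one), ignore.case = TRUE)))
  d <- separable_features(n = 8, d = 12)
  fit <- fit_capsnet(d$x, d$y, cfg, epochs = 2, seed = 3)
  norms <- capsule_norms(fit, d$x)
  expect_equal(dim(norms), c(8, 2))
  expect_true(all(norms >= 0 & norms < 1)) # squash bound
  expect_error(fit_capsnet(d$x[, 1:2], d$y, capsnet_config(kernel = 3)), "kernel")
})

test_that("training rejects degenerate inputs before starting", {
  d <- separable_features(n = 10, d = 8)
  expect_error(fit_dnn(d$x, rep(1, 10)), "both classes")
  expect_error(fit_dnn(d$x, d$y[1:5]), "differ in length")
  fit <- fit_dnn(d$x, d$y, dnn_config(hidden_sizes = c(4, 4, 4)), epochs = 2, seed = 1)
  expect_error(predict_proba(fit, d$x[, 1:3]), "width")
})

test_that("early stopping tracks validation loss", {
  d <- separable_features(n = 30, d = 10)
  # unlearnable validation set: noise features, random labels
  val <- withr::with_seed(10, list(x = matrix(rnorm(100), 10, 10), y = rep(0:1, 5)))
  fit <- fit_dnn(d$x, d$y, dnn_config(hidden_sizes = c(8, 4, 4), dropout = 0),
    epochs = 400, seed = 1,
    validation = val, patience = 5
  )
  expect_lt(nrow(fit$log), 400) # stopped early
  expect_false(anyNA(fit$log$val_loss))
})
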