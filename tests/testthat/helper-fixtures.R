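# shared builders for the test suite; everything is generated in code

aa20 <- drugseqr:::PSSM_AA_ORDER

# profile with unit-indicator rows: row k is e_{cols[k]}
indicator_pssm <- function(cols, residues = strrep("A", length(cols))) {
  m <- matrix(0, length(cols), 20)
  m[cbind(seq_along(cols), cols)] <- 1
  pssm(residues, m)
}

random_pssm <- function(L, score_range = -10:10) {
  m <- matrix(sample(score_range, L * 20, replace = TRUE), L, 20)
  res <- sample(c(aa20, "X"), L, replace = TRUE)
  pssm(paste(res, collapse = ""), m)
}

# naive triple-loop encoder oracles, independent of the vectorized path
oracle_dpc <- function(P) {
  L <- nrow(P)
  Y <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (j in 1:20) {
      s <- 0
      for (k in 1:(L - 1)) s <- s + P[k, i] * P[k + 1, j]
      Y[i, j] <- s / (L - 1)
    }
  }
  as.vector(t(Y))
}

oracle_ksb <- function(P, k) {
  L <- nrow(P)
  Y <- matrix(0, 20, 20)
  if (L > k) {
    for (i in 1:20) {
      for (j in 1:20) {
        s <- 0
        for (t in 1:(L - k)) s <- s + P[t, i] * P[t + k, j]
        Y[i, j] <- s
      }
    }
  }
  as.vector(t(Y))
}

oracle_sfp <- function(P, res, aa_order) {
  fp <- pmax(P, 0)
  Y <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (j in 1:20) {
      s <- 0
      for (k in seq_len(nrow(P))) if (res[k] == aa_order[i]) s <- s + fp[k, j]
      Y[i, j] <- s
    }
  }
  as.vector(t(Y))
}

# linearly separable two-class feature data
separable_features <- function(n = 40, d = 24, shift = 2, seed = 9) {
  withr::with_seed(seed, {
    y <- rep(c(1L, 0L), each = n / 2)
    x <- matrix(rnorm(n * d), n, d)
    x[y == 1, 1:4] <- x[y == 1, 1:4] + shift
    list(x = x, y = y)
  })
}

# all ways to group 1..n into unordered pairs plus at most one leftover
combinat_pairings <- function(items) {
  if (length(items) <= 2) return(list(list(items)))
  out <- list()
  first <- items[1]
  rest <- items[-1]
  for (j in seq_along(rest)) {
    pair <- c(first, rest[j])
    for (sub in combinat_pairings(rest[-j])) {
      out[[length(out) + 1]] <- c(list(pair), sub)
    }
  }
  if (length(items) %% 2 == 1) {
    for (sub in combinat_pairings(rest)) {
      out[[length(out) + 1]] <- c(list(first), sub)
    }
  }
  out
}
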