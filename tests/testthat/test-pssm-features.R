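test_that("ASCII profile writer and parser round-trip exactly", {
  withr::with_seed(2, {
    p <- random_pssm(12)
    f <- withr::local_tempfile(fileext = ".pssm")
    write_pssm(p, f)
    back <- read_pssm(f)
    expect_identical(back$residues, p$residues)
    expect_true(all(back$scores == p$scores))
    expect_identical(back$aa_order, p$aa_order)
  })
})

test_that("malformed profiles fail with the offending line named", {
  p <- indicator_pssm(c(1, 2, 1), "ACD")
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(p, f)
  expect_identical(read_pssm(f)$residues, "ACD")
  lines <- readLines(f)
  truncated <- sub("^(\\s*2\\s+C.{30}).*$", "\\1", lines) # chop row 2 mid-way
  writeLines(truncated, f)
  expect_error(read_pssm(f), "line 5")
  # non-consecutive positions
  write_pssm(p, f)
  lines <- readLines(f)
  lines <- lines[-4] # drop data row 1
  writeLines(lines, f)
  expect_error(read_pssm(f), "consecutive")
})

test_that("dipeptide-composition features match hand-derived cases", {
  z <- pssm(strrep("A", 5), matrix(0, 5, 20))
  expect_true(all(dpc_pssm(z) == 0))
  p <- indicator_pssm(c(1, 2, 1), "ACD") # rows e1, e2, e1
  v <- dpc_pssm(p)
  expect_equal(unname(v[(1 - 1) * 20 + 2]), 0.5) # y_{1,2}
  expect_equal(unname(v[(2 - 1) * 20 + 1]), 0.5) # y_{2,1}
  expect_equal(sum(v != 0), 2)
  expect_length(v, 400)
  expect_error(dpc_pssm(indicator_pssm(1, "A")), "L-1")
})

test_that("k-separated bigram features match hand-derived cases", {
  p <- indicator_pssm(c(1, 2, 3, 4, 1), "ACDEF")
  v <- ksb_pssm(p, k = 3)
  expect_equal(unname(v[(1 - 1) * 20 + 4]), 1) # y_{1,4}: t=1 pairs e1 with e4
  expect_equal(unname(v[(2 - 1) * 20 + 1]), 1) # y_{2,1}: t=2 pairs e2 with e1
  expect_equal(sum(v != 0), 2)
  short <- indicator_pssm(c(1, 2, 3), "ACD")
  expect_warning(vs <- ksb_pssm(short, k = 3), "all zeros")
  expect_true(all(vs == 0))
  expect_error(ksb_pssm(p, k = 0), "k")
  # bilinearity: doubling every score quadruples every value
  withr::with_seed(3, {
    r <- random_pssm(15)
    r2 <- pssm(r$residues, 2 * r$scores)
    expect_equal(unname(ksb_pssm(r2, 3)), 4 * unname(ksb_pssm(r, 3)))
  })
})

test_that("filtered row-sum features match direct evaluation", {
  neg <- pssm("ACD", matrix(-abs(rnorm(60)), 3, 20))
  expect_true(all(s_fpssm(neg) == 0))
  m <- matrix(0, 2, 20)
  m[1, 1] <- 2
  m[1, 2] <- -1
  m[2, 1] <- -3
  m[2, 2] <- 5
  p <- pssm("AC", m)
  v <- s_fpssm(p)
  expect_equal(unname(v[(1 - 1) * 20 + 1]), 2) # Y_1(A): filtered row 1
  crow <- which(p$aa_order == "C") # C is the 5th column in profile order
  expect_equal(unname(v[(crow - 1) * 20 + 2]), 5) # Y_2(C): filtered row 2
  expect_equal(sum(v != 0), 2)
  withr::with_seed(5, expect_true(all(s_fpssm(random_pssm(20)) >= 0)))
  # a single residue type concentrates all mass in one 20-value row
  withr::with_seed(6, {
    mono <- pssm(strrep("K", 8), matrix(sample(-5:9, 160, TRUE), 8, 20))
    v <- s_fpssm(mono)
    krow <- which(mono$aa_order == "K")
    expect_true(all(v[-((krow - 1) * 20 + 1:20)] == 0))
  })
})

test_that("each encoder equals the naive triple-loop oracle on random profiles", {
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- random_pssm(sample(2:60, 1))
      res <- strsplit(p$residues, "")[[1]]
      expect_equal(unname(dpc_pssm(p)), oracle_dpc(p$scores))
      expect_equal(unname(suppressWarnings(ksb_pssm(p, 3))), oracle_ksb(p$scores, 3))
      expect_equal(unname(s_fpssm(p)), oracle_sfp(p$scores, res, p$aa_order))
    }
  })
})

test_that("appending an all-zero row rescales normalized dipeptide features by (L-1)/L", {
  withr::with_seed(12, {
    p <- random_pssm(10)
    L <- 10
    p2 <- pssm(paste0(p$residues, "A"), rbind(p$scores, 0))
    expect_equal(unname(dpc_pssm(p2)), unname(dpc_pssm(p)) * (L - 1) / L)
  })
})

test_that("the concatenated vector keeps block order and group tags", {
  withr::with_seed(13, {
    p <- random_pssm(9)
    v <- pssm_features(p)
    expect_length(v, 1200)
    expect_equal(attr(v, "groups"), rep(c("dpc", "ksb", "sfp"), each = 400))
    expect_equal(unname(v[1:400]), unname(dpc_pssm(p)))
    expect_equal(unname(v[401:800]), unname(ksb_pssm(p, 3)))
    expect_equal(unname(v[801:1200]), unname(s_fpssm(p)))
  })
})

test_that("batch featurization tolerates a missing profile with a zero fallback", {
  spec <- fixture_spec(n_pos = 2, n_neg = 2, length_range = c(10, 15), seed = 4)
  recs <- generate_records(spec)
  pssms <- setNames(
    lapply(seq_len(3), function(i) generate_synthetic_pssm(recs[i, ], spec)),
    recs$id[1:3]
  ) # record 4 has no profile
  expect_warning(feats <- pssm_feature_matrix(recs, pssms), "all-zero")
  expect_equal(dim(feats), c(4, 1202))
  expect_true(all(feature_matrix(feats)$x[4, ] == 0))
})
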