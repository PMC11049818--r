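PSSM_AA_ORDER <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, a column-label line with
#' 40 amino-acid labels, then one row per position holding the position index,
#' the query residue, 20 integer log-odds scores, 20 weighted percentages and
#' (optionally) two trailing information-content floats. Only the first 20
#' numeric columns — the log-odds scores — are retained.
#'
#' @param path File path.
#' @return An object of class `pssm`: a list with `residues` (string),
#'   `scores` (L x 20 integer matrix, columns named by `aa_order`) and
#'   `aa_order` (the 20-letter column order from the file header).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 40 && all(f[1:40] %in% PSSM_AA_ORDER)) {
      header_at <- i
      aa_order <- f[1:20]
      break
    }
  }
  if (is.na(header_at)) abort(paste0("not an ASCII PSSM (no 40-label column header): ", path))
  if (anyDuplicated(aa_order) || !setequal(aa_order, PSSM_AA_ORDER)) {
    abort("PSSM column labels are not a permutation of the 20 standard amino acids")
  }
  residues <- character()
  scores <- list()
  positions <- integer()
  for (i in seq((header_at + 1), length(lines))) {
    ln <- trimws(lines[i])
    if (!grepl("^[0-9]+\\s", ln)) break # footer (lambda/K block) or blank
    f <- strsplit(ln, "\\s+")[[1]]
    if (!length(f) %in% c(42L, 44L)) {
      abort(paste0("PSSM parse error at line ", i, ": expected 42 or 44 fields, got ", length(f)))
    }
    vals <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(vals)) abort(paste0("PSSM parse error at line ", i, ": non-numeric score"))
    positions <- c(positions, as.integer(f[1]))
    residues <- c(residues, toupper(f[2]))
    scores[[length(scores) + 1]] <- vals
  }
  if (length(scores) == 0) abort(paste0("ASCII PSSM has no data rows: ", path))
  if (!all(positions == seq_along(positions))) {
    abort("PSSM position numbers are not consecutive from 1")
  }
  m <- do.call(rbind, scores)
  colnames(m) <- aa_order
  new_pssm(paste(residues, collapse = ""), m, aa_order)
}

new_pssm <- function(residues, scores, aa_order = colnames(scores)) {
  stopifnot(nchar(residues) == nrow(scores), ncol(scores) == 20)
  colnames(scores) <- aa_order
  structure(list(residues = residues, scores = scores, aa_order = aa_order),
    class = "pssm"
  )
}

#' Construct a PSSM object from a residue string and score matrix
#' @param residues Residue string of length L.
#' @param scores L x 20 numeric matrix of log-odds scores.
#' @param aa_order Column order; defaults to the PSI-BLAST standard order.
#' @return A `pssm` object.
#' @export
pssm <- function(residues, scores, aa_order = PSSM_AA_ORDER) {
  if (anyDuplicated(aa_order) || !setequal(aa_order, PSSM_AA_ORDER)) {
    abort("aa_order must be a permutation of the 20 standard amino acids")
  }
  new_pssm(unname(toupper(residues)), as.matrix(scores), aa_order)
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> L=", nrow(x$scores), " residues=",
    substr(x$residues, 1, 30), if (nchar(x$residues) > 30) "..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the same layout [read_pssm()] consumes (the percentage block is
#' filled with zeros); used by the synthetic fixture generator.
#'
#' @param x A `pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts", con)
  writeLines(paste0("           ", paste(sprintf("%3s", c(x$aa_order, x$aa_order)), collapse = " ")), con)
  res <- strsplit(x$residues, "")[[1]]
  for (k in seq_len(nrow(x$scores))) {
    writeLines(paste0(
      sprintf("%5d %s  ", k, res[k]),
      paste(sprintf("%3d", as.integer(x$scores[k, ])), collapse = " "), "  ",
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
      sprintf("  %4.2f %4.2f", 0, 0)
    ), con)
  }
  writeLines("", con)
  invisible(path)
}

block_names <- function(prefix, aa_order) {
  as.vector(t(outer(aa_order, aa_order, function(i, j) paste(prefix, i, j, sep = "."))))
}

flatten_rowmajor <- function(Y, prefix, aa_order) {
  v <- as.vector(t(Y)) # position 20(i-1)+j holds Y[i, j]
  names(v) <- block_names(prefix, aa_order)
  v
}

#' Dipeptide-composition profile features (400-D)
#'
#' Length-normalized products of adjacent profile rows:
#' `y[i, j] = (1/(L-1)) * sum_k p[k, i] * p[k+1, j]`.
#'
#' @param x A `pssm` object with L >= 2.
#' @param normalize Squash scores through `1/(1+exp(-p))` first (off by
#'   default; the encoders operate on raw log-odds).
#' @return Named numeric vector of length 400 (`dpc.<i>.<j>`), row-major
#'   over the profile's amino-acid column order.
#' @export
dpc_pssm <- function(x, normalize = FALSE) {
  stopifnot(inherits(x, "pssm"))
  P <- score_matrix(x, normalize)
  L <- nrow(P)
  if (L < 2) abort("DPC features need a profile of length >= 2 (divisor L-1)")
  Y <- crossprod(P[-L, , drop = FALSE], P[-1, , drop = FALSE]) / (L - 1)
  flatten_rowmajor(Y, "dpc", x$aa_order)
}

#' K-separated-bigram profile features (400-D)
#'
#' Unnormalized products of profile rows k positions apart:
#' `y[i, j] = sum_t p[t, i] * p[t+k, j]`, as the descriptor is printed;
#' `normalize = TRUE` divides by the number of summed pairs `L - k`.
#'
#' @param x A `pssm` object.
#' @param k Gap parameter (>= 1); 3 pairs residues separated by two others.
#' @param normalize Divide by `L - k` (off by default).
#' @param sigmoid Squash scores through `1/(1+exp(-p))` first.
#' @return Named numeric vector of length 400 (`ksb.<i>.<j>`). When `L <= k`
#'   the summation range is empty: an all-zero vector is returned with a
#'   warning.
#' @export
ksb_pssm <- function(x, k = 3, normalize = FALSE, sigmoid = FALSE) {
  stopifnot(inherits(x, "pssm"))
  if (k < 1) abort("gap parameter k must be >= 1")
  P <- score_matrix(x, sigmoid)
  L <- nrow(P)
  if (L <= k) {
    warn(paste0("profile length ", L, " <= k = ", k, "; k-separated bigram block is all zeros"))
    Y <- matrix(0, 20, 20)
  } else {
    Y <- crossprod(P[seq_len(L - k), , drop = FALSE], P[(k + 1):L, , drop = FALSE])
    if (normalize) Y <- Y / (L - k)
  }
  flatten_rowmajor(Y, "ksb", x$aa_order)
}

#' Filtered row-sum profile features (400-D)
#'
#' Negative scores are clipped to zero (the filtered profile), then column
#' sums are accumulated per residue type: `Y_j(i) = sum_k fp[k, j] * [r_k == a_i]`.
#' Rows whose residue is not one of the 20 standard amino acids (for example
#' `X`) match no type and contribute nothing.
#'
#' @param x A `pssm` object.
#' @param normalize Squash scores through `1/(1+exp(-p))` first.
#' @return Named numeric vector of length 400 (`sfp.<i>.<j>`), all values
#'   non-negative.
#' @export
s_fpssm <- function(x, normalize = FALSE) {
  stopifnot(inherits(x, "pssm"))
  fp <- pmax(score_matrix(x, normalize), 0)
  res <- strsplit(x$residues, "")[[1]]
  Y <- matrix(0, 20, 20)
  for (i in seq_len(20)) {
    hit <- res == x$aa_order[i]
    if (any(hit)) Y[i, ] <- colSums(fp[hit, , drop = FALSE])
  }
  flatten_rowmajor(Y, "sfp", x$aa_order)
}

score_matrix <- function(x, normalize) {
  P <- x$scores
  if (normalize) P <- 1 / (1 + exp(-P))
  P
}

#' Concatenated 1200-D profile feature vector
#'
#' Binds the three 400-D blocks in the fixed order dipeptide composition,
#' k-separated bigrams, filtered row sums.
#'
#' @param x A `pssm` object.
#' @param k Gap parameter for the bigram block.
#' @param normalize Sigmoid-normalize scores in every block.
#' @return Named numeric vector of length 1200 with attribute `groups`
#'   (per-position block tag: `"dpc"`, `"ksb"`, `"sfp"`).
#' @export
pssm_features <- function(x, k = 3, normalize = FALSE) {
  v <- c(
    dpc_pssm(x, normalize = normalize),
    ksb_pssm(x, k = k, sigmoid = normalize),
    s_fpssm(x, normalize = normalize)
  )
  stopifnot(length(v) == 1200)
  attr(v, "groups") <- rep(c("dpc", "ksb", "sfp"), each = 400)
  v
}

#' Profile features for a dataset of records
#'
#' Looks up one ASCII PSSM per record id (`<id>.pssm` under `pssm_dir`) and
#' returns the 1200-D encoding per protein. A record with no profile on disk
#' gets an all-zero profile (with a warning), keeping batch featurization
#' total.
#'
#' @param records Record tibble (`id`, `sequence`, optional `label`).
#' @param pssm_dir Directory of `<id>.pssm` files, or a named list of `pssm`
#'   objects keyed by id.
#' @param k,normalize Passed to [pssm_features()].
#' @return Tibble: `id`, optional `label`, then 1200 feature columns.
#' @export
pssm_feature_matrix <- function(records, pssm_dir, k = 3, normalize = FALSE) {
  assert_records(records)
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    p <- if (is.list(pssm_dir) && !is.character(pssm_dir)) {
      pssm_dir[[id]]
    } else {
      f <- file.path(pssm_dir, paste0(id, ".pssm"))
      if (file.exists(f)) read_pssm(f) else NULL
    }
    if (is.null(p)) {
      warn(paste0("no PSSM for record '", id, "'; using an all-zero profile"))
      zeros <- matrix(0L, nchar(records$sequence[i]), 20)
      seqres <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", records$sequence[i])
      p <- pssm(seqres, zeros)
    }
    suppressWarnings(pssm_features(p, k = k, normalize = normalize))
  })
  feat <- tibble::as_tibble(do.call(rbind, rows))
  out <- tibble::tibble(id = records$id)
  if ("label" %in% names(records)) out$label <- records$label
  dplyr::bind_cols(out, feat)
}

#' Split a feature tibble into a numeric matrix and labels
#' @param features Tibble from [pssm_feature_matrix()] or [plm_embedding_matrix()].
#' @return List with `x` (numeric matrix, rownames = id) and `y`
#'   (integer labels or NULL).
#' @export
feature_matrix <- function(features) {
  meta <- intersect(c("id", "label"), names(features))
  x <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  rownames(x) <- features$id
  list(x = x, y = if ("label" %in% meta) as.integer(features$label) else NULL)
}
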