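# background amino-acid composition (approximate vertebrate proteome
# frequencies), used when a fixture spec does not override it
DEFAULT_AA_FREQ <- c(
  A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, Q = 0.037,
  E = 0.058, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
  M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
  Y = 0.033, V = 0.067
)

#' Specification for a synthetic two-class benchmark
#'
#' Positives carry a planted sequence motif at a random position; negatives
#' are pure background composition. Each record also gets a synthetic
#' evolutionary profile whose row scores peak (at `pssm_signal`) in the
#' column of the true residue with uniform integer noise elsewhere, so both
#' the sequence channel (motif) and the profile channel carry class signal
#' and each feature family is separable by construction. Everything derives
#' deterministically from `seed` via per-record substreams, so record-level
#' outputs do not depend on generation order.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Residue-length range (min, max).
#' @param motif Amino-acid string planted in positives (`""` disables the
#'   motif, removing the class signal).
#' @param background Named length-20 composition weights for negatives.
#' @param positive_background Composition for positives (defaults to
#'   `background`).
#' @param pssm_signal Log-odds score of a residue's own profile column.
#' @param pssm_noise Half-width of the uniform integer noise on other columns.
#' @param seed Master seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_pos = 100, n_neg = 100, length_range = c(50, 120),
                         motif = "WWWWW", background = DEFAULT_AA_FREQ,
                         positive_background = NULL,
                         pssm_signal = 7, pssm_noise = 2, seed = 7) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2)
  if (nchar(motif) >= length_range[1]) abort("motif must be shorter than the minimum length")
  stopifnot(length(background) == 20)
  structure(
    list(
      n_pos = n_pos, n_neg = n_neg, length_range = length_range,
      motif = toupper(motif), background = background,
      positive_background = positive_background %||% background,
      pssm_signal = pssm_signal, pssm_noise = pssm_noise, seed = seed
    ),
    class = "fixture_spec"
  )
}

random_sequence <- function(len, freq) {
  paste(sample(names(freq), len, replace = TRUE, prob = freq), collapse = "")
}

#' Generate a labeled synthetic record set
#'
#' @param spec A [fixture_spec()].
#' @return Record tibble (`id`, `sequence`, `label`) with positives first.
#' @export
generate_records <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  gen_one <- function(id, positive) {
    with_private_seed(derive_seed(spec$seed, id), {
      len <- sample(spec$length_range[1]:spec$length_range[2], 1)
      freq <- if (positive) spec$positive_background else spec$background
      s <- random_sequence(len, freq)
      if (positive && nchar(spec$motif) > 0) {
        at <- sample.int(len - nchar(spec$motif) + 1, 1)
        substr(s, at, at + nchar(spec$motif) - 1) <- spec$motif
      }
      s
    })
  }
  pos_ids <- sprintf("pos_%04d", seq_len(spec$n_pos))
  neg_ids <- sprintf("neg_%04d", seq_len(spec$n_neg))
  tibble::tibble(
    id = c(pos_ids, neg_ids),
    sequence = unname(c(
      vapply(pos_ids, gen_one, character(1), positive = TRUE),
      vapply(neg_ids, gen_one, character(1), positive = FALSE)
    )),
    label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  )
}

#' Generate a synthetic evolutionary profile for one record
#'
#' @param record One-row record tibble (or a list with `id` and `sequence`).
#' @param spec A [fixture_spec()].
#' @param path Optional path; when given the profile is also written in the
#'   ASCII dialect [read_pssm()] consumes.
#' @return A `pssm` object.
#' @export
generate_synthetic_pssm <- function(record, spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  seqres <- strsplit(record$sequence[1], "")[[1]]
  L <- length(seqres)
  scores <- with_private_seed(derive_seed(spec$seed, paste0("pssm:", record$id[1])), {
    noise_vals <- seq(-spec$pssm_noise, spec$pssm_noise)
    m <- matrix(
      noise_vals[sample.int(length(noise_vals), L * 20, replace = TRUE)],
      L, 20
    )
    hit <- match(seqres, PSSM_AA_ORDER)
    ok <- which(!is.na(hit))
    m[cbind(ok, hit[ok])] <- spec$pssm_signal
    m
  })
  p <- pssm(record$sequence[1], scores)
  if (!is.null(path)) write_pssm(p, path)
  p
}

#' Materialize a self-contained synthetic benchmark directory
#'
#' Writes `data.fasta`, one ASCII profile per record under `pssm/`,
#' `labels.tsv` and a `split.json` with the stratified train/validation/test
#' row indices, all derived from the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return The record tibble, invisibly; paths as attributes.
#' @export
make_benchmark <- function(spec = fixture_spec(), dir = tempfile("bench")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  records <- generate_records(spec)
  write_fasta(records, file.path(dir, "data.fasta"))
  write_labels(records, file.path(dir, "labels.tsv"))
  for (i in seq_len(nrow(records))) {
    generate_synthetic_pssm(
      records[i, ], spec,
      path = file.path(dir, "pssm", paste0(records$id[i], ".pssm"))
    )
  }
  split <- stratified_three_way_split(records, seed = spec$seed)
  jsonlite::write_json(
    list(counts = split$counts, indices = split$indices, seed = split$seed),
    file.path(dir, "split.json"),
    auto_unbox = TRUE
  )
  attr(records, "dir") <- dir
  invisible(records)
}

#' Read back a benchmark split file
#' @param path `split.json` path written by [make_benchmark()].
#' @return A `three_way_split` object.
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      counts = tibble::as_tibble(s$counts),
      indices = lapply(s$indices, as.integer), seed = s$seed
    ),
    class = "three_way_split"
  )
}
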