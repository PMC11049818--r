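#' The 33-token protein alphabet
#'
#' Tokenization vocabulary shared by the embedder and the decoder-transformer
#' classifier: the 20 standard amino acids, the extended residue codes
#' (X, B, U, Z, O, gap symbols) and the special tokens `<cls>`, `<pad>`,
#' `<eos>`, `<unk>`, `<null_1>`, `<mask>`. Ordering follows the convention of
#' the small ESM-2 protein language models (specials first, then residues by
#' background frequency), so token ids are interchangeable with that family.
#'
#' @return An object of class `aa_alphabet`: a named integer vector mapping
#'   each of the 33 symbols to its id in `0:32`, with attributes `cls`, `pad`,
#'   `eos`, `unk`, `mask` giving the special-token ids.
#' @examples
#' ab <- protein_alphabet()
#' length(ab)     # 33
#' ab[["<cls>"]]  # 0
#' @export
protein_alphabet <- function() {
  tokens <- c(
    "<cls>", "<pad>", "<eos>", "<unk>",
    "L", "A", "G", "V", "S", "E", "R", "T", "I", "D", "P", "K",
    "Q", "N", "F", "Y", "M", "H", "W", "C", "X", "B", "U", "Z", "O",
    ".", "-", "<null_1>", "<mask>"
  )
  ab <- setNames(seq_along(tokens) - 1L, tokens)
  structure(
    ab,
    cls = ab[["<cls>"]], pad = ab[["<pad>"]], eos = ab[["<eos>"]],
    unk = ab[["<unk>"]], mask = ab[["<mask>"]],
    class = "aa_alphabet"
  )
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet> ", length(x), " tokens; specials: cls=",
    attr(x, "cls"), " pad=", attr(x, "pad"), " eos=", attr(x, "eos"),
    " unk=", attr(x, "unk"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tokenize a protein sequence
#'
#' Encodes a sequence as `[cls] residue-ids [eos]`. Residues missing from the
#' alphabet map to the unknown token; when `max_len` is given the encoding is
#' truncated to that many ids by dropping C-terminal residues (the terminal
#' `<eos>` is kept).
#'
#' @param sequence A single amino-acid string.
#' @param alphabet An [protein_alphabet()] object.
#' @param max_len Optional maximum total length (>= 3, counting cls and eos).
#' @return Integer vector of token ids with attribute `n_residues`.
#' @examples
#' tokenize("ACD")
#' @export
tokenize <- function(sequence, alphabet = protein_alphabet(), max_len = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) abort("cannot tokenize an empty sequence")
  if (!is.null(max_len)) {
    stopifnot(max_len >= 3)
    sequence <- substr(sequence, 1, max_len - 2L)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ids <- unname(alphabet[chars])
  ids[is.na(ids)] <- attr(alphabet, "unk")
  out <- c(attr(alphabet, "cls"), ids, attr(alphabet, "eos"))
  attr(out, "n_residues") <- length(ids)
  out
}

#' Invert tokenization back to a residue string
#'
#' Drops cls/eos/pad. Residue tokens render as their alphabet symbol; the
#' unknown token renders as the placeholder residue `"X"`.
#'
#' @param ids Integer token ids.
#' @param alphabet An [protein_alphabet()] object.
#' @return A single string.
#' @export
detokenize <- function(ids, alphabet = protein_alphabet()) {
  specials <- c(attr(alphabet, "cls"), attr(alphabet, "pad"), attr(alphabet, "eos"))
  keep <- ids[!ids %in% specials]
  syms <- names(alphabet)[match(keep, alphabet)]
  syms[keep == attr(alphabet, "unk")] <- "X"
  paste(syms, collapse = "")
}

#' Pad a list of tokenized sequences into a rectangular batch
#'
#' @param seqs Non-empty list of integer id vectors (as from [tokenize()]).
#' @param alphabet An [protein_alphabet()] object (for the pad id).
#' @return A list with `tokens` (n x width integer matrix, pad-filled) and
#'   `mask` (same shape, 1 for real tokens, 0 for padding).
#' @export
pad_batch <- function(seqs, alphabet = protein_alphabet()) {
  stopifnot(is.list(seqs), length(seqs) > 0)
  lens <- lengths(seqs)
  width <- max(lens)
  pad <- attr(alphabet, "pad")
  tokens <- matrix(pad, nrow = length(seqs), ncol = width)
  mask <- matrix(0L, nrow = length(seqs), ncol = width)
  for (i in seq_along(seqs)) {
    tokens[i, seq_len(lens[i])] <- seqs[[i]]
    mask[i, seq_len(lens[i])] <- 1L
  }
  list(tokens = tokens, mask = mask)
}

#' Length statistics for a protein dataset
#'
#' Extremes are exact; mean, median and population standard deviation are
#' rounded half-away-from-zero to whole residues, the convention used for
#' dataset summary tables.
#'
#' @param records Tibble with a `sequence` column.
#' @return One-row tibble: `longest`, `shortest`, `mean`, `median`, `std`.
#' @examples
#' summarize_lengths(tibble::tibble(id = c("a", "b"), sequence = c("ACD", "ACDEF")))
#' @export
summarize_lengths <- function(records) {
  assert_records(records)
  if (nrow(records) == 0) abort("cannot summarize an empty dataset")
  len <- nchar(records$sequence)
  pop_sd <- sqrt(mean((len - mean(len))^2))
  tibble::tibble(
    longest = max(len),
    shortest = min(len),
    mean = as.integer(round_half_away(mean(len))),
    median = as.integer(round_half_away(median(len))),
    std = as.integer(round_half_away(pop_sd))
  )
}
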