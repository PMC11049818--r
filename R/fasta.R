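#' Read a FASTA file into a record tibble
#'
#' Wrapped sequence lines are concatenated and sequences are uppercased.
#' An optional two-column label TSV (id, 0/1) can be joined on the fly.
#'
#' @param path FASTA file path.
#' @param labels Optional path to a label TSV (see [read_labels()]) or a
#'   data frame with columns `id` and `label`.
#' @return Tibble with columns `id`, `sequence` and, when labels are supplied,
#'   `label` (integer 0/1, NA for ids absent from the label file).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "MKV"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    out <- tibble::tibble(id = character(), sequence = character())
    if (!is.null(labels)) out$label <- integer()
    return(out)
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(trimws(first), ">")) {
    abort(paste0("malformed FASTA (line 1 does not start with '>'): ", path))
  }
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("FASTA parse error in ", path, ": ", conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort(paste0("record '", ids[empty[1]], "' has an empty sequence"))
  }
  out <- tibble::tibble(id = unname(ids), sequence = unname(seqs))
  assert_records(out)
  if (!is.null(labels)) {
    lab <- if (is.data.frame(labels)) labels else read_labels(labels)
    out <- dplyr::left_join(out, lab[, c("id", "label")], by = "id")
  }
  out
}

#' Write records to FASTA
#'
#' @param records Tibble with `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  assert_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a two-column label TSV (id, 0/1); a header line is optional
#'
#' @param path TSV path.
#' @return Tibble with columns `id` (character) and `label` (integer).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble::tibble(id = character(), label = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) abort(paste0("label file line ", bad[1], " has fewer than 2 columns"))
  # a header line is one whose second field is not numeric
  if (is.na(suppressWarnings(as.numeric(trimws(fields[[1]][2]))))) fields <- fields[-1]
  ids <- vapply(fields, `[`, character(1), 1)
  lab <- trimws(vapply(fields, `[`, character(1), 2))
  if (!all(lab %in% c("0", "1"))) {
    abort(paste0("non-binary label for id '", ids[which(!lab %in% c("0", "1"))[1]], "'"))
  }
  tibble::tibble(id = ids, label = as.integer(lab))
}

#' Write labels as a two-column TSV
#' @param records Tibble with `id` and `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  assert_records(records, need_label = TRUE)
  utils::write.table(records[, c("id", "label")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
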