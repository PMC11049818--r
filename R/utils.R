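#' @importFrom rlang abort warn %||%
#' @importFrom stats median predict rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# run code under a private RNG stream without disturbing the caller's stream
with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit substream seed from a master seed and a string tag
derive_seed <- function(seed, tag) {
  h <- 0
  for (b in utf8ToInt(paste0(tag, ":", seed))) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1)
}

assert_records <- function(records, need_label = FALSE) {
  stopifnot(is.data.frame(records))
  if (!all(c("id", "sequence") %in% names(records))) {
    abort("`records` must have columns `id` and `sequence`")
  }
  if (nrow(records) > 0 && anyDuplicated(records$id)) {
    abort(paste0("duplicate record id: ", records$id[duplicated(records$id)][1]))
  }
  if (need_label) {
    if (!"label" %in% names(records) || anyNA(records$label)) {
      abort("`records` must carry a complete binary `label` column")
    }
    if (!all(records$label %in% c(0, 1))) abort("labels must be 0/1")
  }
  invisible(records)
}
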