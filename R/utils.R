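#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible sub-seed for a named random stream.  Keeps every
# derived seed inside the 32-bit integer range R's RNG accepts.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 1234567) %% .Machine$integer.max)
}

# Collect validation failures, then raise them all at once.
fail_all <- function(failures, what) {
  if (length(failures) > 0L) {
    abort(paste0(
      "invalid ", what, ":\n",
      paste0("  - ", failures, collapse = "\n")
    ))
  }
  invisible(TRUE)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
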