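# shared plumbing: tolerant line reading and seed handling

# Read a text file into lines, stripping a UTF-8 BOM and CR line endings.
read_clean_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) > 0) {
    lines[1] <- sub("^﻿", "", lines[1])
  }
  sub("\r$", "", lines)
}

# All user-facing randomness flows through here so that identical seeds give
# bit-identical results without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- rlang::`%||%`
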