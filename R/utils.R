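# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this so that
# every generator is a pure function of its spec.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Format numbers with 9 significant digits for reproducible CSV checksums.
fmt9 <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  out <- trimws(formatC(x, digits = 9L, format = "g"))
  out[is.na(x)] <- NA_character_
  out
}

write_csv9 <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) fmt9(col) else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
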