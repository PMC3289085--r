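# Shared internal helpers.

# Accepts a file path, a single string with embedded newlines, or a character
# vector of lines; returns a character vector of lines.
as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  as.character(x)
}

# Evaluates `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's global RNG state afterwards. All fixture generation goes
# through this so no generator leaks global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic, locale-independent ordering used for every tie-break.
radix_order <- function(...) order(..., method = "radix")

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("oiip_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("oiip_usage_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
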