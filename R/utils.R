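# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf
  m + log(sum(exp(x - m)))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# split a string into Unicode code points
chars_of <- function(text) {
  if (!length(text) || !nzchar(text)) return(character(0))
  strsplit(text, "", fixed = FALSE)[[1L]]
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
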