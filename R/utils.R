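# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG with `seed`, evaluates `expr`, then restores the
#' caller's RNG state, so every generator in the package is a pure function
#' of its arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Stable string/argument hash into a 31-bit seed, so each (seed, subject,
# trial) tuple has its own stream and adding subjects never perturbs the
# streams of existing ones.
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "\r")
  h <- 17
  for (cp in utf8ToInt(parts)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

stop_named <- function(name, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(name, "physioemo_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
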