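# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code can be
#' deterministic without clobbering the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
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
  set.seed(seed)
  expr
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= 1", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

stopifnot_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Benjamini-Hochberg step-up, written out explicitly (monotonized from the
# largest p downward, capped at 1, order-preserving). NA p-values propagate.
bh_step_up <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  q <- rep(NA_real_, m)
  ok <- which(!is.na(p))
  k <- length(ok)
  if (k == 0L) return(q)
  ord <- ok[order(p[ok])]
  adj <- p[ord] * k / seq_len(k)
  adj <- rev(cummin(rev(adj)))
  q[ord] <- pmin(adj, 1)
  q
}
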