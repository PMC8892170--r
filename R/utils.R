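#' @keywords internal
#' @noRd
norm_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' @keywords internal
#' @noRd
msg_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @keywords internal
#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
#' @noRd
is_binary_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x == 0L | x == 1L)
}
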