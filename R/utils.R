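# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; chromosome counts derived from
#' allele frequencies use the conventional half-up rule so that e.g.
#' 0.5 * 3 = 1.5 rounds to 2.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  # guard against representation error just below .5 (e.g. 0.701*67)
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Polynomial rolling hash of a character scalar, returned as 8 hex digits.
# Used to stamp output tables with a config fingerprint without external
# dependencies; not cryptographic.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
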