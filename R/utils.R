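#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream seeded at `seed`, then
#' restores the previous stream so callers' randomness is unaffected. With
#' `seed = NULL` the expression runs against the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (5 rounds up in
#' magnitude), the convention used for the package's report tables; base
#' [round()] rounds ties to even. A guard of 1e-9 absorbs binary
#' floating-point representations of decimal midpoints (e.g. 2.685 stored
#' fractionally below the midpoint) so that values entered as decimals round
#' the way they read.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) is 2
#' round_half_up(1.905, 1)   # 1.9
#' round_half_up(-59.99, 0)  # -60
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# stop() with sprintf formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an R object via its serialization, used to stamp output files
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
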