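## internal helpers: argument checks and seed plumbing

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("rlmsim_invalid_argument", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && (is.null(x) || length(x) == 1L && is.na(x))) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(name, " must be a single number")
  }
  if (x < lower || x > upper) {
    stop_invalid(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

#' Derive a stream seed from a master seed
#'
#' All stochastic stages draw their randomness from one master seed; each
#' stage (and each acquisition within a stage) uses a deterministically
#' derived sub-seed so that stages are reproducible in isolation. The
#' derivation is a multiplicative hash kept strictly below 2^31.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0); distinct streams give
#'   effectively independent sub-seeds.
#' @return a single integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(master, stream = 0L) {
  check_number(master, "master")
  check_number(stream, "stream", lower = 0)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + 1 + as.numeric(stream) * 2654435) %% m
  x <- (x * 48271 + 11) %% m
  as.integer(x)
}

## set.seed only when a seed is supplied; NULL leaves the RNG stream alone
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
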