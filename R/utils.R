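# Internal helpers: seeding, logging, argument checks.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed
#'
#' Each simulated study (and the SNP-parameter draw) gets its own
#' pseudo-random stream so that adding or removing a study does not perturb
#' the others. The derivation is a fixed affine map reduced modulo
#' 2^31 - 1, keeping every derived seed a valid 32-bit integer.
#'
#' @param master integer master seed.
#' @param index non-negative stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647
  s <- (abs(as.double(master)) %% m)
  as.integer((s * 48271 + 7919 * (index + 1)) %% m)
}

# Evaluate `expr` under a private RNG stream, restoring global RNG state.
with_stream <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Structured one-line log messages, silenced via options(heightmr.verbose = FALSE).
hm_log <- function(fmt, ...) {
  if (isTRUE(getOption("heightmr.verbose", TRUE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

is_fraction <- function(x, open = FALSE) {
  ok <- is.numeric(x) & is.finite(x)
  if (open) ok & x > 0 & x < 1 else ok & x >= 0 & x <= 1
}

stop_bad_arg <- function(name, why) {
  stop(sprintf("invalid `%s`: %s", name, why), call. = FALSE)
}

# 95% Wald z, pinned for bit-reproducibility across platforms.
Z95 <- 1.959964
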