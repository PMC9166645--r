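#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' One root seed drives a whole run; each stage or stochastic decision
#' category gets its own derived seed so stages can be re-run in isolation
#' and adding a draw category never perturbs existing ones. The scheme is a
#' small multiplicative hash of the label folded into the root seed, kept
#' within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer root seed.
#' @param label character label of the sub-stream (e.g. "arrivals").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147480009
  as.integer((abs(seed) + h * 97) %% 2147480009)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = FALSE) {
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (!is.numeric(x) || any(is.na(x)) || bad) {
    stop(sprintf("'%s' must be %s", name,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

assert_freq <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    stop(sprintf("'%s' must be non-negative frequencies", name), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

#' Canonicalize triangular-distribution parameters
#'
#' Service-time triangular distributions are specified by three points whose
#' ordering is not guaranteed by the source tables; the three values are
#' sorted and interpreted as (min, mode, max).
#'
#' @param a,b,c the three parameters, any order.
#' @return numeric vector `c(min, mode, max)`.
#' @examples
#' canonicalize_triangular(16.9, 29.1, 20)  # c(16.9, 20, 29.1)
#' @export
canonicalize_triangular <- function(a, b, c) {
  v <- c(a, b, c)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < 0)) {
    stop("triangular parameters must be three finite non-negative numbers",
         call. = FALSE)
  }
  v <- sort(v)
  names(v) <- c("min", "mode", "max")
  v
}

#' Sample from a triangular distribution
#'
#' Inverse-CDF sampling from Triangular(min, mode, max). Degenerate
#' (min == max) specifications return the constant.
#'
#' @param n number of draws.
#' @param tri canonicalized parameter vector from [canonicalize_triangular()].
#' @return numeric vector of `n` draws.
#' @export
rtriangular <- function(n, tri) {
  a <- tri[[1L]]; m <- tri[[2L]]; b <- tri[[3L]]
  if (b <= a) return(rep(a, n))
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Sample from a location-shifted lognormal distribution
#'
#' Three-parameter lognormal in the common simulation-package
#' parameterization: `shift + exp(rnorm(meanlog, sdlog))`.
#'
#' @param n number of draws.
#' @param meanlog,sdlog log-scale mean and standard deviation.
#' @param shift location shift (minutes).
#' @return numeric vector of `n` draws, all `>= shift`.
#' @export
rlnorm3 <- function(n, meanlog, sdlog, shift = 0) {
  if (sdlog <= 0) stop("sdlog must be > 0", call. = FALSE)
  shift + stats::rlnorm(n, meanlog, sdlog)
}

#' Theoretical mean of the shifted lognormal
#' @inheritParams rlnorm3
#' @return `shift + exp(meanlog + sdlog^2 / 2)`.
#' @export
lnorm3_mean <- function(meanlog, sdlog, shift = 0) {
  shift + exp(meanlog + sdlog^2 / 2)
}

# Split "a;b;c" encoded integer lists (used by the population table format).
split_ints <- function(s) {
  lapply(strsplit(as.character(s), ";", fixed = TRUE),
         function(x) if (length(x) == 1L && x == "") integer(0) else as.integer(x))
}

join_ints <- function(lst) {
  vapply(lst, function(x) paste(x, collapse = ";"), character(1))
}
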