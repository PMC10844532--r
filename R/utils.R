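#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median optimize rlnorm rnorm runif sd setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic derivation of child seeds from a study-level seed, kept
# below 2^31 so they remain valid R integers.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in seq_along(idx)) {
    x <- (x * 48271 + as.double(idx[i]) * 16807 + 1) %% 2147483647
  }
  as.integer(x)
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_times <- function(times, what = "times") {
  if (length(times) < 1L || !is.numeric(times) || anyNA(times)) {
    stop_arg(what, " must be a non-empty numeric vector without NA")
  }
  if (any(times <= 0)) {
    stop_arg(what, " must be strictly positive (extravascular sampling ",
             "starts after dosing); got minimum ", min(times))
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_arg(what, " must be strictly increasing")
  }
  invisible(times)
}

# Adjusted r-squared of a simple linear regression with n points.
adj_r2 <- function(r2, n) 1 - (1 - r2) * (n - 1) / (n - 2)
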