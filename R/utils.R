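# Internal numerical helpers shared across the package.

GENO_CLASSES <- c("AA", "AB", "BA", "BB", "NP")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log density of a bivariate normal with mean mu and 2x2 covariance S,
# evaluated at u (length-2). Plain algebra on purpose: used by the
# independent reference implementations in the tests as well.
#' @noRd
ldmvnorm2 <- function(u, mu, S) {
  d1 <- u[1] - mu[1]
  d2 <- u[2] - mu[2]
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (det <= 0) stop("covariance matrix is not positive definite")
  q <- (d1 * d1 * S[2, 2] - 2 * d1 * d2 * S[1, 2] + d2 * d2 * S[1, 1]) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed below 2^31 from a base seed and a tag.
#' @noRd
child_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 1e5) * 17783 + 7919 * (as.numeric(i) %% 1e5)
  as.integer(s %% 2147483647)
}

#' @noRd
stopifnot_scalar_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (open) {
    if (x <= 0 || x >= 1) stop(sprintf("'%s' must be in (0, 1)", name))
  } else if (x < 0 || x > 1) {
    stop(sprintf("'%s' must be in [0, 1]", name))
  }
  invisible(x)
}
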