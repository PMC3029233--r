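# The two-chromosome continuous-state HMM: hyperparameters, the three-state
# jump process driving changes of the parent-specific copy numbers
# theta = (theta1, theta2), and the genotype-dependent emission model.

#' Hyperparameters of the two-chromosome model
#'
#' @param mu0 length-2 baseline parent-specific copy numbers (normal state);
#'   default (1, 1), one copy from each parent.
#' @param z length-2 prior mean of the copy numbers in a variant state.
#' @param V 2x2 symmetric positive-definite prior covariance of a variant
#'   state; each new variant segment draws its value from N(z, V).
#' @param sigma named list of 2x2 positive-definite error covariances, one
#'   per genotype class \code{AA, AB, BA, BB, NP}. \code{BA} must be the
#'   coordinate swap of \code{AB}.
#' @param p probability of leaving the normal state per SNP step (split
#'   equally between the two variant states).
#' @param r probability of returning from a variant state to normal.
#' @param s probability of jumping from a variant state to the other variant
#'   state (a fresh copy-number value); requires 1 - r - s > 0.
#' @return a validated list of class \code{pscn_hyperparams}.
#' @details The three-state chain (normal, variant1, variant2) with these
#'   moves has stationary distribution
#'   \eqn{(r/(r+p),\ p/(2(r+p)),\ p/(2(r+p)))} and is reversible when started
#'   there, so smoothing from the right gives the same answer as from the
#'   left.
#' @export
pscn_hyperparams <- function(mu0 = c(1, 1), z = c(1, 1),
                             V = diag(0.25, 2),
                             sigma = default_sigma(),
                             p = 1e-3, r = 5e-3, s = 1e-4) {
  stopifnot_scalar_prob(p, "p", open = TRUE)
  stopifnot_scalar_prob(r, "r", open = TRUE)
  stopifnot_scalar_prob(s, "s")
  if (1 - r - s <= 0) stop("need 1 - r - s > 0")
  if (length(mu0) != 2L || length(z) != 2L) stop("mu0 and z must have length 2")
  V <- as.matrix(V)
  check_pd2 <- function(S, nm) {
    if (!all(dim(S) == c(2L, 2L)) || abs(S[1, 2] - S[2, 1]) > 1e-12 ||
        S[1, 1] <= 0 || S[1, 1] * S[2, 2] - S[1, 2]^2 <= 0)
      stop(sprintf("'%s' must be 2x2 symmetric positive-definite", nm))
  }
  check_pd2(V, "V")
  if (!all(GENO_CLASSES %in% names(sigma)))
    stop("sigma needs entries for AA, AB, BA, BB, NP")
  for (g in GENO_CLASSES) check_pd2(as.matrix(sigma[[g]]), paste0("sigma$", g))
  sw <- matrix(c(0, 1, 1, 0), 2)
  if (max(abs(sigma[["BA"]] - sw %*% sigma[["AB"]] %*% sw)) > 1e-8)
    stop("sigma$BA must be the coordinate swap of sigma$AB")
  structure(list(mu0 = as.numeric(mu0), z = as.numeric(z), V = V,
                 sigma = lapply(sigma[GENO_CLASSES], as.matrix),
                 p = p, r = r, s = s),
            class = "pscn_hyperparams")
}

# Default per-class noise; NP markers share the heterozygote noise.
#' @noRd
default_sigma <- function(sd_het = 0.15, sd_hom = 0.18) {
  het <- diag(sd_het^2, 2)
  hom <- diag(sd_hom^2, 2)
  list(AA = hom, AB = het, BA = het, BB = hom, NP = het)
}

#' Transition matrix of the three-state jump process
#'
#' Rows and columns are ordered (normal, variant1, variant2). From normal
#' the chain stays with probability 1 - p and moves to each variant state
#' with probability p/2; from a variant state it returns to normal with
#' probability r, stays put with probability 1 - r - s, and jumps to the
#' other variant state with probability s.
#'
#' @inheritParams pscn_hyperparams
#' @return 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(p, r, s) {
  stopifnot_scalar_prob(p, "p")
  stopifnot_scalar_prob(r, "r", open = TRUE)
  stopifnot_scalar_prob(s, "s")
  if (1 - r - s <= 0) stop("need 1 - r - s > 0")
  m <- rbind(c(1 - p, p / 2, p / 2),
             c(r, 1 - r - s, s),
             c(r, s, 1 - r - s))
  dimnames(m) <- list(c("normal", "variant1", "variant2"),
                      c("normal", "variant1", "variant2"))
  m
}

#' Stationary distribution of the jump process
#' @inheritParams pscn_hyperparams
#' @return length-3 probability vector over (normal, variant1, variant2).
#' @export
stationary_distribution <- function(p, r, s) {
  pi_n <- r / (r + p)
  c(normal = pi_n, variant1 = (1 - pi_n) / 2, variant2 = (1 - pi_n) / 2)
}

#' Allele assignment matrix for a genotype configuration
#'
#' The 2x2 matrix A(g) mapping parent-specific copy numbers
#' theta = (theta1, theta2) to expected allele intensities (E x, E y).
#' A heterozygote AB passes theta through unchanged, BA swaps the
#' coordinates, homozygotes put the total on one allele, and the
#' non-polymorphic class NP spreads the total over both coordinates so that
#' only total copy number informs the likelihood.
#'
#' @param g one of \code{"AA", "AB", "BA", "BB", "NP"}.
#' @return a 2x2 numeric matrix.
#' @export
assignment_matrix <- function(g) {
  switch(match.arg(g, GENO_CLASSES),
         AA = matrix(c(1, 0, 1, 0), 2),
         AB = diag(2),
         BA = matrix(c(0, 1, 1, 0), 2),
         BB = matrix(c(0, 1, 0, 1), 2),
         NP = matrix(0.5, 2, 2))
}

#' Expected allele intensities under a genotype configuration
#'
#' @param g genotype class (see [assignment_matrix()]).
#' @param theta length-2 parent-specific copy numbers.
#' @return length-2 vector A(g) theta = (E x, E y).
#' @examples
#' emission_mean("AA", c(1, 1))  # both parental copies carry A -> (2, 0)
#' @export
emission_mean <- function(g, theta) {
  if (length(theta) != 2L) stop("theta must have length 2")
  as.numeric(assignment_matrix(g) %*% theta)
}
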