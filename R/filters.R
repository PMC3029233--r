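# R surface over the compiled filter/smoother kernels.

# genotype labels -> integer codes used by the C++ kernels
#' @noRd
geno_code <- function(g) {
  code <- match(g, GENO_CLASSES)
  if (anyNA(code)) stop("unknown genotype class label")
  code
}

#' @noRd
hp_as_list <- function(hp) {
  stopifnot(inherits(hp, "pscn_hyperparams"))
  unclass(hp)
}

#' Forward filter of the two-chromosome model
#'
#' Computes, for every SNP t, the filtered distribution of the
#' parent-specific copy numbers theta_t given the observations up to t and
#' the genotype track: a point mass at the baseline mu0 plus one Gaussian
#' component per retained candidate change time, updated conjugately and
#' pruned to at most M components (always keeping the K most recent change
#' times).
#'
#' @param track an [allele_signal_track()].
#' @param genotypes character vector of per-SNP classes in
#'   \code{AA, AB, BA, BB, NP}.
#' @param hp a [pscn_hyperparams()] object.
#' @param M maximum number of mixture components kept per step.
#' @param K number of most recent change times always retained.
#' @return a list with \code{$states} (one mixture-filter state per SNP:
#'   baseline_weight, component weights, means, covariances and 1-based
#'   change-time origins) and the marginal \code{$loglik}.
#' @export
forward_filter <- function(track, genotypes, hp, M = 20L, K = 10L) {
  u <- track_xy(track)
  if (length(genotypes) != nrow(u))
    stop("genotypes and track must have equal length")
  pscn_filter_cpp(u, geno_code(genotypes) - 1L, hp_as_list(hp),
                  as.integer(M), as.integer(K), FALSE)
}

#' Backward filter of the two-chromosome model
#'
#' Identical to [forward_filter()] applied to the index-reversed sequence
#' and re-reversed, which is valid because the three-state jump process is
#' reversible at stationarity. The state at position t conditions on
#' observations t..n.
#'
#' @inheritParams forward_filter
#' @return as [forward_filter()], states reported in genomic order.
#' @export
backward_filter <- function(track, genotypes, hp, M = 20L, K = 10L) {
  u <- track_xy(track)
  if (length(genotypes) != nrow(u))
    stop("genotypes and track must have equal length")
  pscn_filter_cpp(u, geno_code(genotypes) - 1L, hp_as_list(hp),
                  as.integer(M), as.integer(K), TRUE)
}

#' Posterior-mean parent-specific copy numbers (smoother)
#'
#' Combines the forward filter at t and the backward filter at t+1 by Bayes'
#' rule (a combined component has precision
#' \eqn{V_f^{-1} + V_b^{-1} - V^{-1}}) into the full-data posterior of
#' theta_t, and returns its mean together with the posterior mass on the
#' normal baseline.
#'
#' @inheritParams forward_filter
#' @return list with \code{$theta_hat} (n x 2 matrix), \code{$baseline_prob}
#'   (posterior probability that theta_t = mu0) and the forward-pass
#'   marginal \code{$loglik}.
#' @export
pscn_smooth <- function(track, genotypes, hp, M = 20L, K = 10L) {
  u <- track_xy(track)
  if (length(genotypes) != nrow(u))
    stop("genotypes and track must have equal length")
  out <- pscn_smooth_cpp(u, geno_code(genotypes) - 1L, hp_as_list(hp),
                         as.integer(M), as.integer(K))
  colnames(out$theta_hat) <- c("theta1", "theta2")
  out
}
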