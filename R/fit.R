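# The outer iterative algorithm: alternate posterior-mean copy numbers
# (E-step, smoothing) with MAP genotypes (M-step), re-estimating the
# hyperparameters from the current fit each round.

#' Re-estimate model hyperparameters from the current fit
#'
#' Per-class error covariances are re-estimated from the residuals
#' u - A(g) theta_hat pooled by genotype class; a class with fewer than 50
#' SNPs is shrunk toward the pooled covariance (weight 0.9 on the pooled
#' estimate). The variant prior (z, V) is taken from the mean and covariance
#' of theta_hat over SNPs whose posterior baseline mass is below 0.5, with
#' an eigenvalue floor of 0.01 on V so the prior for a new segment never
#' collapses. The jump rates p and r come from the entry/exit counts of runs
#' with \eqn{\lVert\hat\theta - \mu_0\rVert > 0.2} divided by the
#' corresponding run lengths, clipped to [1e-6, 0.2]; s is kept fixed.
#' With no variant SNPs, z, V, p and r are retained from \code{previous}.
#'
#' @param track an [allele_signal_track()].
#' @param theta_hat n x 2 posterior-mean copy numbers.
#' @param genotypes per-SNP classes.
#' @param previous the current [pscn_hyperparams()].
#' @param baseline_prob per-SNP posterior mass on the baseline (from
#'   [pscn_smooth()]).
#' @return an updated [pscn_hyperparams()].
#' @export
estimate_hyperparams <- function(track, theta_hat, genotypes, previous,
                                 baseline_prob = NULL) {
  u <- track_xy(track)
  n <- nrow(u)
  mu0 <- previous$mu0

  # residuals per genotype class
  resid <- u
  for (cls in GENO_CLASSES) {
    i <- which(genotypes == cls)
    if (!length(i)) next
    A <- assignment_matrix(cls)
    resid[i, ] <- u[i, , drop = FALSE] - theta_hat[i, , drop = FALSE] %*% t(A)
  }
  # Robust covariance: residuals outside 4 MADs in either coordinate are
  # excluded before taking the product-moment covariance. Complete-LOH
  # regions at very low contamination produce blocks of badly modeled
  # residuals within a class; an unguarded covariance would inflate,
  # turning that class into a catch-all and destabilizing the whole
  # alternating fit.
  robust_cov <- function(R) {
    m1 <- stats::median(R[, 1]); m2 <- stats::median(R[, 2])
    s1 <- stats::mad(R[, 1]); s2 <- stats::mad(R[, 2])
    if (s1 <= 0 || s2 <= 0) return(stats::cov(R))
    keep <- abs(R[, 1] - m1) <= 4 * s1 & abs(R[, 2] - m2) <= 4 * s2
    if (sum(keep) < 3L) return(stats::cov(R))
    stats::cov(R[keep, , drop = FALSE])
  }
  pooled <- robust_cov(resid)
  covs <- list()
  for (cls in c("AA", "AB", "BA", "BB")) {
    i <- which(genotypes == cls)
    if (length(i) >= 3L) {
      S <- robust_cov(resid[i, , drop = FALSE])
      if (length(i) < 50L) S <- 0.9 * pooled + 0.1 * S
    } else {
      S <- pooled
    }
    covs[[cls]] <- S
  }
  # AB and BA describe the same heterozygote with coordinates exchanged
  sw <- matrix(c(0, 1, 1, 0), 2)
  nab <- sum(genotypes == "AB")
  nba <- sum(genotypes == "BA")
  wab <- if (nab + nba > 0) nab / (nab + nba) else 0.5
  Shet <- wab * covs[["AB"]] + (1 - wab) * (sw %*% covs[["BA"]] %*% sw)
  covs[["AB"]] <- Shet
  covs[["BA"]] <- sw %*% Shet %*% sw
  covs[["NP"]] <- Shet
  covs <- lapply(covs, regularize_cov2)

  variant <- if (is.null(baseline_prob)) {
    sqrt(rowSums((theta_hat - matrix(mu0, n, 2, byrow = TRUE))^2)) > 0.2
  } else baseline_prob < 0.5

  z <- previous$z
  V <- previous$V
  p <- previous$p
  r <- previous$r
  if (any(variant)) {
    th_v <- theta_hat[variant, , drop = FALSE]
    z <- colMeans(th_v)
    V <- if (nrow(th_v) >= 3L) stats::cov(th_v) else previous$V
    V <- floor_eigen2(V, 0.01)
    # Jump rates from the run structure of the deviation indicator. The raw
    # per-SNP indicator is denoised with a running median first: isolated
    # flickers come from genotype-assignment noise, not from segment
    # boundaries, and counting them as jumps would push p and r far above
    # the scale of real copy-number events.
    dev_raw <- sqrt(rowSums((theta_hat - matrix(mu0, n, 2, byrow = TRUE))^2)) > 0.2
    dev <- stats::runmed(as.numeric(dev_raw), k = min(21L, n - (1 - n %% 2))) > 0.5
    if (any(dev) && !all(dev)) {
      entries <- sum(diff(dev) == 1L)
      exits <- sum(diff(dev) == -1L)
      p <- min(max(entries / sum(!dev), 1e-6), 0.2)
      r <- min(max(exits / sum(dev), 1e-6), 0.2)
    }
  }
  pscn_hyperparams(mu0 = mu0, z = z, V = V, sigma = covs[GENO_CLASSES],
                   p = p, r = r, s = previous$s)
}

#' @noRd
regularize_cov2 <- function(S, min_var = 1e-6) {
  S <- (S + t(S)) / 2
  S[1, 1] <- max(S[1, 1], min_var)
  S[2, 2] <- max(S[2, 2], min_var)
  lim <- 0.99 * sqrt(S[1, 1] * S[2, 2])
  S[1, 2] <- S[2, 1] <- sign(S[1, 2]) * min(abs(S[1, 2]), lim)
  S
}

#' @noRd
floor_eigen2 <- function(S, floor) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
}

# Initial per-class noise covariances from first differences of (x, y)
# between consecutive SNPs of the same class: differencing removes the
# slowly varying copy-number level, so aberrant regions do not inflate the
# estimate. 2 percent of the most extreme differences are trimmed to guard
# the few pairs straddling a true breakpoint.
#' @noRd
estimate_sigma_init <- function(u, genotypes) {
  sig <- default_sigma()
  for (cls in c("AA", "AB", "BA", "BB")) {
    i <- which(genotypes == cls)
    if (length(i) < 30L) next
    d <- diff(u[i, , drop = FALSE])
    nrm <- sqrt(rowSums(d^2))
    keep <- nrm <= stats::quantile(nrm, 0.98)
    S <- stats::cov(d[keep, , drop = FALSE]) / 2
    sig[[cls]] <- regularize_cov2(S)
  }
  sw <- matrix(c(0, 1, 1, 0), 2)
  Shet <- (sig[["AB"]] + sw %*% sig[["BA"]] %*% sw) / 2
  sig[["AB"]] <- Shet
  sig[["BA"]] <- sw %*% Shet %*% sw
  sig[["NP"]] <- Shet
  sig
}

#' Fit the two-chromosome model by allele-specific iterative smoothing
#'
#' Alternates the expectation step (posterior-mean parent-specific copy
#' numbers given the genotype configurations, via [pscn_smooth()]) with the
#' maximization step (per-SNP MAP genotypes given the copy numbers, via
#' [genotype_mstep()]), re-estimating hyperparameters each round, until the
#' mean per-SNP change of theta_hat drops below \code{tol} or
#' \code{max_iter} rounds.
#'
#' When genotypes from a matched normal sample are supplied the
#' configuration track is held fixed and only E-steps (plus hyperparameter
#' updates) are run.
#'
#' @param track an [allele_signal_track()].
#' @param priors prior matrix from [load_genotype_priors()]; NULL for the
#'   uniform prior.
#' @param hp0 optional starting [pscn_hyperparams()]; by default the noise
#'   covariances are estimated robustly from within-class first differences.
#' @param config a [pscn_config()] list (tol, max_iter, bcmix_M, bcmix_K,
#'   seed).
#' @param genotypes optional fixed genotype classes (matched-normal mode).
#' @return an object of class \code{pscn_fit}: list with \code{theta_hat},
#'   \code{baseline_prob}, \code{genotypes}, \code{hp}, \code{trace}
#'   (iteration count, per-iteration change norms, converged flag) and
#'   \code{loglik}.
#' @export
pscn_fit <- function(track, priors = NULL, hp0 = NULL, config = pscn_config(),
                     genotypes = NULL) {
  u <- track_xy(track)
  n <- nrow(u)
  if (n < 2L * config$min_sep)
    stop("track too short for the configured min_sep")
  if (is.null(priors)) priors <- load_genotype_priors(NULL, track)

  fixed_g <- !is.null(genotypes)
  g <- if (fixed_g) genotypes else
    initialize_genotypes(track, priors, seed = config$seed)

  hp <- hp0 %||% pscn_hyperparams(sigma = estimate_sigma_init(u, g))

  theta_prev <- matrix(hp$mu0, n, 2, byrow = TRUE)
  changes <- numeric(0)
  converged <- FALSE
  stopped_on <- "max_iter"
  sm <- NULL
  for (it in seq_len(config$max_iter)) {
    sm <- pscn_smooth(track, g, hp, M = config$bcmix_M, K = config$bcmix_K)
    theta <- sm$theta_hat
    if (!fixed_g) g <- genotype_mstep(track, theta, priors, hp)
    hp <- estimate_hyperparams(track, theta, g, hp,
                               baseline_prob = sm$baseline_prob)
    ch <- mean(sqrt(rowSums((theta - theta_prev)^2)))
    changes <- c(changes, ch)
    theta_prev <- theta
    if (ch < config$tol) {
      converged <- TRUE
      stopped_on <- "tol"
      break
    }
    # cycle detection: hard genotype assignments can oscillate in regions
    # where configurations are near-tied (complete LOH at very low
    # contamination); when the change norm has stopped shrinking the
    # iteration has reached its limit cycle and further rounds change
    # nothing material
    if (it >= 4L && ch > 0.7 * changes[it - 3L]) {
      converged <- TRUE
      stopped_on <- "cycle"
      break
    }
  }
  if (!converged) {
    stopped_on <- "max_iter"
    warning(sprintf("did not converge in %d iterations (last change %.3g)",
                    config$max_iter, utils::tail(changes, 1)))
  }
  structure(list(theta_hat = theta_prev, baseline_prob = sm$baseline_prob,
                 genotypes = g, hp = hp, loglik = sm$loglik,
                 trace = list(iterations = length(changes),
                              change_norm = changes, converged = converged,
                              stopped_on = stopped_on)),
            class = "pscn_fit")
}

#' @export
print.pscn_fit <- function(x, ...) {
  cat(sprintf("<pscn_fit> %d SNPs, %d iterations (%s), loglik %.1f\n",
              nrow(x$theta_hat), x$trace$iterations,
              if (x$trace$converged) "converged" else "not converged",
              x$loglik))
  invisible(x)
}
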