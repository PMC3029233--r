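# Segment-level four-component mixture: the workhorse behind region
# characterization. Every SNP of a segment is modeled as one of the four
# genotype configurations whose means are tied through the segment's
# (major, minor) copy numbers - AA at (major + minor, 0), AB at
# (major, minor), BA at (minor, major), BB at (0, major + minor) - with a
# heterozygote and a homozygote noise scale. Because the component means
# are shared functions of two parameters, the fit is invariant to per-SNP
# AB/BA orientation errors made upstream, and homozygous SNPs contribute
# their full information about the segment total.

#' Fit the four-configuration mixture of one segment
#'
#' EM over (mu_major, mu_minor, sigma_het, sigma_hom, class weights) for
#' all SNPs of one segment. The copy-number update is a responsibility-
#' weighted least-squares solve; two deterministic starts are used (the
#' near-diploid start 1.1/0.9 and a moment start from the per-SNP max/min
#' coordinates) and the higher-likelihood solution is kept, which matters
#' for segments with complete loss of heterozygosity where the heterozygote
#' and homozygote components coincide. Swap-normalized so
#' mu_major >= mu_minor.
#'
#' @param xy two-column matrix of (x, y) for all SNPs of the segment.
#' @param eps convergence tolerance on the largest parameter change.
#' @param max_iter EM iteration cap.
#' @return list of class \code{pscn_segment_fit}: mu_major, mu_minor,
#'   sigma_het, sigma_hom, weights (AA, AB, BA, BB), n_het_eff (summed
#'   heterozygote responsibility), mix_p (AB share among heterozygotes),
#'   loglik, iterations.
#' @export
fit_segment_mixture <- function(xy, eps = 1e-6, max_iter = 500L) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  x <- xy[, 1]
  y <- xy[, 2]
  n <- length(x)
  if (n < 4L) stop("segment too small to fit")
  starts <- list(c(M = 1.1, m = 0.9),
                 c(M = mean(pmax(x, y)), m = mean(pmin(x, y))))
  # heterozygote-moment start: points whose smaller coordinate is well off
  # zero are heterozygous-like, and their max/min means sit at (M, m); for
  # high-copy segments this is the only start near the truth
  hi <- pmin(x, y) > 0.125 * mean(x + y)
  if (mean(hi) > 0.1) {
    starts <- c(starts, list(c(M = mean(pmax(x[hi], y[hi])),
                               m = mean(pmin(x[hi], y[hi])))))
  }
  best <- NULL
  for (st in starts) {
    # a start that is already at a found solution would only re-converge
    # to it; skip it
    if (!is.null(best) &&
        abs(st[["M"]] - best$mu_major) < 0.05 &&
        abs(st[["m"]] - best$mu_minor) < 0.05) next
    fit <- segment_mixture_em(x, y, st[["M"]], st[["m"]], eps, max_iter)
    # ties (within 1e-6) go to the later, moment start: under complete LOH
    # the heterozygote components coincide with the homozygote ones and
    # the diploid start reaches a same-likelihood solution that parks the
    # het components at the (unsupported) near-diploid split
    if (is.null(best) || fit$loglik > best$loglik - 1e-6) best <- fit
  }
  structure(best, class = "pscn_segment_fit")
}

#' @noRd
segment_mixture_em <- function(x, y, M, m, eps, max_iter) {
  n <- length(x)
  sh <- 0.2
  so <- 0.2
  w <- c(rep(0.245, 4), 0.02)
  w <- w / sum(w)
  # uniform background over the data's bounding box: absorbs the few SNPs
  # that bleed across an imperfectly placed boundary, which would otherwise
  # hijack an unused mixture component as a tight outlier-catcher
  lbg <- -log((diff(range(x)) + 1) * (diff(range(y)) + 1))
  prev <- c(M, m, sh, so, w)
  ll <- -Inf
  it <- 0L
  resp <- NULL
  l2pi <- log(2 * pi)
  repeat {
    it <- it + 1L
    tot <- M + m
    qh <- 0.5 / sh^2
    qo <- 0.5 / so^2
    ch <- -l2pi - 2 * log(sh)
    co <- -l2pi - 2 * log(so)
    lw <- log(pmax(w, 1e-12))
    ld <- cbind(
      AA = co - qo * ((x - tot)^2 + y^2) + lw[1],
      AB = ch - qh * ((x - M)^2 + (y - m)^2) + lw[2],
      BA = ch - qh * ((x - m)^2 + (y - M)^2) + lw[3],
      BB = co - qo * (x^2 + (y - tot)^2) + lw[4],
      BG = lbg + lw[5])
    mx <- pmax(ld[, 1], ld[, 2], ld[, 3], ld[, 4], ld[, 5])
    se <- exp(ld - mx)
    rs <- rowSums(se)
    ll <- sum(mx + log(rs))
    resp <- se / rs
    # M-step: weights (background capped so it never absorbs real classes)
    w <- pmax(colMeans(resp), 1e-8)
    w <- w / sum(w)
    if (w[5] > 0.2) {
      w[1:4] <- w[1:4] * (1 - 0.2) / sum(w[1:4])
      w[5] <- 0.2
    }
    # copy numbers by weighted least squares (means linear in (M, m))
    R <- colSums(resp[, 1:4, drop = FALSE])
    sxc <- colSums(resp[, 1:4, drop = FALSE] * x)
    syc <- colSums(resp[, 1:4, drop = FALSE] * y)
    whom <- (R[1] + R[4]) / so^2
    whet <- (R[2] + R[3]) / sh^2
    a11 <- whom + whet
    a12 <- whom
    a22 <- whom + whet
    b1 <- (sxc[1] + syc[4]) / so^2 + (sxc[2] + syc[3]) / sh^2
    b2 <- (sxc[1] + syc[4]) / so^2 + (syc[2] + sxc[3]) / sh^2
    det <- a11 * a22 - a12^2
    if (is.finite(det) && abs(det) > 1e-10 * (a11 + a22)^2) {
      Mn <- (a22 * b1 - a12 * b2) / det
      mn <- (a11 * b2 - a12 * b1) / det
    } else {
      # heterozygote mass vanished: only the total is identified; keep the
      # current major - minor split
      tot_hat <- (sxc[1] + syc[4]) / max(R[1] + R[4], 1e-12)
      d <- M - m
      Mn <- (tot_hat + d) / 2
      mn <- (tot_hat - d) / 2
    }
    # noise scales
    het_ss <- sum(resp[, 2] * ((x - Mn)^2 + (y - mn)^2) +
                  resp[, 3] * ((x - mn)^2 + (y - Mn)^2))
    hom_ss <- sum(resp[, 1] * ((x - Mn - mn)^2 + y^2) +
                  resp[, 4] * (x^2 + (y - Mn - mn)^2))
    shn <- sqrt(het_ss / max(2 * (R[2] + R[3]), 1e-9))
    son <- sqrt(hom_ss / max(2 * (R[1] + R[4]), 1e-9))
    shn <- min(max(shn, 0.02), 2)
    son <- min(max(son, 0.02), 2)
    # convergence is judged on the location/scale parameters; the class
    # weights move on a near-flat likelihood direction when components
    # coincide and would stall the stop rule without affecting (M, m)
    cur <- c(Mn, mn, shn, son)
    delta <- max(abs(cur - prev[1:4]))
    M <- Mn; m <- mn; sh <- shn; so <- son
    prev <- c(cur, w)
    if (delta < eps || it >= max_iter) break
  }
  if (M < m) { # swap-normalize: exchange the parent labels
    tmp <- M; M <- m; m <- tmp
    w <- w[c(1, 3, 2, 4, 5)]
    resp <- resp[, c(1, 3, 2, 4, 5), drop = FALSE]
  }
  n_het_eff <- sum(resp[, 2] + resp[, 3])
  list(mu_major = M, mu_minor = m, sigma_het = sh, sigma_hom = so,
       weights = c(AA = w[1], AB = w[2], BA = w[3], BB = w[4]) / sum(w[1:4]),
       background_weight = w[5],
       n_het_eff = n_het_eff,
       mix_p = if (w[2] + w[3] > 0) w[2] / (w[2] + w[3]) else 0.5,
       resp = resp, loglik = ll, iterations = it)
}

# Per-SNP genotype re-call inside one segment from its fitted mixture:
# argmax over classes of per-SNP prior times the component density. This
# replaces upstream per-SNP calls, which can carry AB/BA orientation noise,
# with segment-coherent ones.
#' @noRd
segment_genotype_recall <- function(xy, sfit, priors) {
  x <- xy[, 1]
  y <- xy[, 2]
  M <- sfit$mu_major
  m <- sfit$mu_minor
  sh <- sfit$sigma_het
  so <- sfit$sigma_hom
  ld <- cbind(
    AA = stats::dnorm(x, M + m, so, log = TRUE) + stats::dnorm(y, 0, so, log = TRUE),
    AB = stats::dnorm(x, M, sh, log = TRUE) + stats::dnorm(y, m, sh, log = TRUE),
    BA = stats::dnorm(x, m, sh, log = TRUE) + stats::dnorm(y, M, sh, log = TRUE),
    BB = stats::dnorm(x, 0, so, log = TRUE) + stats::dnorm(y, M + m, so, log = TRUE))
  ld <- ld + log(pmax(priors[, 1:4, drop = FALSE], 1e-300))
  g <- GENO_CLASSES[max.col(ld, ties.method = "first")]
  g[priors[, "NP"] >= 0.5] <- "NP"
  g
}
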