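# Post-segmentation region characterization: major/minor copy numbers via a
# two-component EM on heterozygous SNPs, Welch t-tests against the normal
# baseline with Bonferroni correction, six-way aberration typing, and an
# inherited-LOH plausibility flag.

SEGMENT_LABELS <- c("normal", "gain/gain", "gain/normal", "balanced gain/loss",
                    "unbalanced gain/loss", "normal/loss", "loss/loss")

#' Major/minor copy numbers of one segment by a two-component EM
#'
#' Each heterozygous SNP's (x, y) pair reads (major, minor) with probability
#' \code{mix_p} and (minor, major) with probability 1 - mix_p (the AB versus
#' BA orientation), with Gaussian noise per coordinate. The five parameters
#' (mu_major, mu_minor, sigma_major, sigma_minor, mix_p) are fitted by EM
#' from the fixed starting point (1.1, 0.9, 1, 1, 0.5) until the largest
#' parameter change drops below \code{eps}. The fit is swap-normalized so
#' mu_major >= mu_minor on return.
#'
#' Segments with fewer than \code{min_het} identified heterozygotes fall
#' back to a pooled estimate with confidence \code{"low"}: mu_major and
#' mu_minor are the means of max(x, y) and min(x, y) over all segment SNPs.
#' A segment with essentially no heterozygotes is either homozygous by
#' chance or has lost heterozygosity; in both readings each SNP carries the
#' segment total on one axis, which is what the pooled estimate measures.
#'
#' @param het_xy two-column matrix of (x, y) for the segment's heterozygous
#'   SNPs.
#' @param eps convergence tolerance on the maximum absolute parameter
#'   change.
#' @param all_xy optional two-column matrix of all segment SNPs, used by the
#'   low-heterozygosity fallback.
#' @param min_het minimum number of heterozygous SNPs for the EM path.
#' @param max_iter EM iteration cap.
#' @param mu_major_init,mu_minor_init,mix_p_init,sigma_init fixed EM
#'   starting values. The near-diploid start (1.1 and 0.9) reflects that a
#'   changed segment is expected to have major at least 1 and minor at most
#'   1; equal orientation odds start at 0.5; the noise start of 1 is
#'   deliberately diffuse.
#' @return list of class \code{pscn_region_fit} with mu_major, mu_minor,
#'   sigma_major, sigma_minor, mix_p, n_het, loglik, confidence.
#' @export
fit_region_mixture <- function(het_xy, eps = 1e-6, all_xy = NULL,
                               min_het = 10L, max_iter = 1000L,
                               mu_major_init = 1.1, mu_minor_init = 0.9,
                               mix_p_init = 0.5, sigma_init = 1) {
  het_xy <- matrix(as.numeric(het_xy), ncol = 2)
  n <- nrow(het_xy)
  if (n < min_het) {
    if (is.null(all_xy) || nrow(all_xy) < 2L)
      stop("too few heterozygous SNPs and no segment-wide fallback data")
    hi <- pmax(all_xy[, 1], all_xy[, 2])
    lo <- pmin(all_xy[, 1], all_xy[, 2])
    return(structure(list(mu_major = mean(hi), mu_minor = mean(lo),
                          sigma_major = max(stats::sd(hi), 1e-3),
                          sigma_minor = max(stats::sd(lo), 1e-3),
                          mix_p = 0.5, n_het = nrow(all_xy), loglik = NA_real_,
                          iterations = 0L, confidence = "low"),
                     class = "pscn_region_fit"))
  }
  x <- het_xy[, 1]
  y <- het_xy[, 2]
  mu_maj <- mu_major_init; mu_min <- mu_minor_init
  s_maj <- sigma_init; s_min <- sigma_init; mix_p <- mix_p_init
  ll <- NA_real_
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step: responsibility that the SNP is in (major, minor) orientation
    l1 <- stats::dnorm(x, mu_maj, s_maj, log = TRUE) +
      stats::dnorm(y, mu_min, s_min, log = TRUE) + log(mix_p)
    l2 <- stats::dnorm(x, mu_min, s_min, log = TRUE) +
      stats::dnorm(y, mu_maj, s_maj, log = TRUE) + log(1 - mix_p)
    m <- pmax(l1, l2)
    ll_new <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    gam <- 1 / (1 + exp(l2 - l1))
    # M-step
    new_maj <- sum(gam * x + (1 - gam) * y) / n
    new_min <- sum(gam * y + (1 - gam) * x) / n
    new_smaj <- sqrt(sum(gam * (x - new_maj)^2 + (1 - gam) * (y - new_maj)^2) / n)
    new_smin <- sqrt(sum(gam * (y - new_min)^2 + (1 - gam) * (x - new_min)^2) / n)
    new_smaj <- max(new_smaj, 1e-4)
    new_smin <- max(new_smin, 1e-4)
    new_p <- min(max(mean(gam), 1e-6), 1 - 1e-6)
    delta <- max(abs(c(new_maj - mu_maj, new_min - mu_min, new_smaj - s_maj,
                       new_smin - s_min, new_p - mix_p)))
    mu_maj <- new_maj; mu_min <- new_min
    s_maj <- new_smaj; s_min <- new_smin; mix_p <- new_p
    ll <- ll_new
    if (!is.finite(ll)) stop("region mixture EM diverged (non-finite loglik)")
    if (delta < eps || it >= max_iter) break
  }
  if (mu_maj < mu_min) { # swap-normalize
    tmp <- mu_maj; mu_maj <- mu_min; mu_min <- tmp
    tmp <- s_maj; s_maj <- s_min; s_min <- tmp
    mix_p <- 1 - mix_p
  }
  structure(list(mu_major = mu_maj, mu_minor = mu_min, sigma_major = s_maj,
                 sigma_minor = s_min, mix_p = mix_p, n_het = n, loglik = ll,
                 iterations = it, confidence = "high"),
            class = "pscn_region_fit")
}

#' Baseline per-allele level from the normal segments
#'
#' Pools the x and y coordinates of heterozygous SNPs across all segments at
#' the normal state; each heterozygote contributes both coordinates, whose
#' common mean is the per-parent baseline level.
#'
#' @param het_xy two-column matrix of heterozygous (x, y) from normal
#'   segments.
#' @return list with \code{mean}, \code{var}, \code{n}.
#' @export
normal_baseline <- function(het_xy) {
  v <- c(het_xy[, 1], het_xy[, 2])
  if (length(v) < 4L)
    stop(paste("no usable normal segments: supply a baseline",
               "(see the 'baseline' argument of characterize_segments)"))
  list(mean = mean(v), var = stats::var(v), n = length(v))
}

#' Test a segment's major/minor copy numbers against the baseline
#'
#' Welch two-sample t-statistics comparing mu_major and mu_minor with the
#' baseline per-allele level, plus a third test of the segment total
#' (mu_major + mu_minor) against twice the baseline level; degrees of
#' freedom by Welch-Satterthwaite from the fitted variances. The per-test
#' significance level is Bonferroni corrected as
#' alpha / (3 * n_segments_tested).
#'
#' @param fit a \code{pscn_region_fit}.
#' @param baseline output of [normal_baseline()] (or a compatible list).
#' @param n_segments_tested number of segments entering the correction.
#' @param alpha family-wise significance level.
#' @return list with t and two-sided p for major, minor and total, and the
#'   corrected \code{alpha_bonf}.
#' @export
test_region <- function(fit, baseline, n_segments_tested, alpha = 0.05) {
  if (is.null(baseline) || !is.finite(baseline$mean))
    stop("empty baseline: supply a user baseline level")
  n <- fit$n_het
  welch <- function(est, se2_parts, df_parts) {
    se <- sqrt(sum(se2_parts))
    df <- sum(se2_parts)^2 / sum(se2_parts^2 / df_parts)
    t <- est / se
    list(t = t, p = 2 * stats::pt(-abs(t), df))
  }
  b_se2 <- baseline$var / baseline$n
  maj <- welch(fit$mu_major - baseline$mean,
               c(fit$sigma_major^2 / n, b_se2), c(n - 1, baseline$n - 1))
  mnr <- welch(fit$mu_minor - baseline$mean,
               c(fit$sigma_minor^2 / n, b_se2), c(n - 1, baseline$n - 1))
  tot <- welch(fit$mu_major + fit$mu_minor - 2 * baseline$mean,
               c((fit$sigma_major^2 + fit$sigma_minor^2) / n, 4 * b_se2),
               c(n - 1, baseline$n - 1))
  list(t_major = maj$t, t_minor = mnr$t, t_total = tot$t,
       p_major = maj$p, p_minor = mnr$p, p_total = tot$p,
       alpha_bonf = alpha / (3 * n_segments_tested))
}

#' Classify a segment into one of six aberration types (or normal)
#'
#' Decision table on the signs of the significant deviations (up = estimate
#' significantly above baseline, down = significantly below):
#' major up & minor up -> gain/gain; major up only -> gain/normal;
#' major up & minor down -> balanced gain/loss when the total is not
#' significantly changed, unbalanced gain/loss when it is;
#' minor down only -> normal/loss; both down -> loss/loss; nothing
#' significant -> normal. After swap normalization major < baseline with
#' minor significantly above cannot occur; a significant minor-only gain
#' means the changed chromosome was relabeled, hence gain/normal.
#'
#' @param tests output of [test_region()].
#' @param fit the corresponding \code{pscn_region_fit} (for deviation
#'   signs).
#' @param baseline output of [normal_baseline()].
#' @param min_effect smallest deviation (copy-number units) treated as a
#'   real change. With thousands of SNPs per segment the t-tests resolve
#'   deviations far below any biologically meaningful copy-number change
#'   (and below the small biases of data-driven segment boundaries), so a
#'   call requires both statistical significance and a material effect.
#' @return one of the labels in \code{SEGMENT_LABELS}.
#' @export
classify_segment <- function(tests, fit, baseline, min_effect = 0.05) {
  a <- tests$alpha_bonf
  d_maj <- fit$mu_major - baseline$mean
  d_min <- fit$mu_minor - baseline$mean
  d_tot <- fit$mu_major + fit$mu_minor - 2 * baseline$mean
  maj_up <- tests$p_major < a & d_maj > min_effect
  maj_dn <- tests$p_major < a & d_maj < -min_effect
  min_up <- tests$p_minor < a & d_min > min_effect
  min_dn <- tests$p_minor < a & d_min < -min_effect
  tot_sig <- tests$p_total < a & abs(d_tot) > min_effect
  if (maj_up && min_up) return("gain/gain")
  if (maj_up && min_dn) {
    return(if (tot_sig) "unbalanced gain/loss" else "balanced gain/loss")
  }
  if (maj_up || min_up) return("gain/normal")
  if (maj_dn && min_dn) return("loss/loss")
  if (min_dn || maj_dn) return("normal/loss")
  "normal"
}

#' Chance probability of an inherited (germline) LOH segment
#'
#' Independence approximation for the probability that the inherited
#' genotypes are homozygous at every SNP of the segment:
#' \eqn{\prod_i (1 - h_i)} with h_i the per-SNP heterozygosity. Segments
#' with probability above the flag threshold are plausible inherited LOH
#' rather than somatic events; the flag is recorded but never deletes a
#' call. Linkage disequilibrium between SNPs is ignored.
#'
#' @param het_rates per-SNP heterozygosity rates of the segment's SNPs.
#' @return a probability in [0, 1].
#' @export
inherited_loh_probability <- function(het_rates) {
  if (is.null(het_rates) || !length(het_rates)) return(NA_real_)
  if (any(het_rates < 0 | het_rates > 1)) stop("het rates must be in [0, 1]")
  prod(1 - het_rates)
}

#' Characterize all segments of a fitted chromosome
#'
#' For every segment, fits the four-configuration mixture
#' ([fit_segment_mixture()]) over all its SNPs - which estimates
#' (major, minor) in a way that is robust to AB/BA orientation errors in
#' the per-SNP genotype track and remains identified in complete-LOH
#' segments, where the heterozygote and homozygote components coincide -
#' then runs [test_region()] and [classify_segment()]. The baseline is
#' pooled from heterozygous SNPs of segments preliminarily at the normal
#' state (mean theta_hat within 0.1 of mu0 in both coordinates); if no
#' segment qualifies, a user-supplied \code{baseline} list(mean, var, n)
#' is required. Heterozygous SNPs entering the baseline are re-called
#' segment-coherently from each normal segment's fitted mixture.
#'
#' @param track an [allele_signal_track()].
#' @param fit a [pscn_fit()] result.
#' @param changepoints a \code{pscn_changepoints}.
#' @param priors genotype prior matrix (for the inherited-LOH rates);
#'   optional.
#' @param alpha family-wise significance level for the t-tests.
#' @param baseline optional user baseline (list with mean, var, n).
#' @param loh_flag_threshold chance probability above which a complete-LOH
#'   segment is flagged possibly inherited.
#' @param loh_minor_max largest minor copy number still treated as
#'   complete LOH for the inherited-LOH flag.
#' @return data.frame with one row per segment: coordinates, n_snps, n_het,
#'   major, minor, total, mix_p, t/p statistics, label,
#'   inherited_loh_prob, loh_flag, confidence.
#' @export
characterize_segments <- function(track, fit, changepoints, priors = NULL,
                                  alpha = 0.05, baseline = NULL,
                                  loh_flag_threshold = 1e-3,
                                  loh_minor_max = 0.2) {
  u <- track_xy(track)
  n <- nrow(u)
  segs <- segments_from_breakpoints(changepoints$breakpoints, n)
  nseg <- nrow(segs)
  mu0 <- fit$hp$mu0
  if (is.null(priors)) priors <- load_genotype_priors(NULL, track)

  sfits <- vector("list", nseg)
  geno <- character(n)
  for (k in seq_len(nseg)) {
    i <- seq.int(segs$start_index[k], segs$end_index[k])
    # estimate on the segment interior: breakpoint placement is uncertain
    # at the scale of the separation constraint, and a handful of SNPs
    # bleeding across a boundary can hijack a mixture component
    trim <- min(25L, (length(i) - 20L) %/% 8L)
    i_fit <- if (trim > 0L) i[seq.int(trim + 1L, length(i) - trim)] else i
    sfits[[k]] <- fit_segment_mixture(u[i_fit, , drop = FALSE])
    geno[i] <- segment_genotype_recall(u[i, , drop = FALSE], sfits[[k]],
                                       priors[i, , drop = FALSE])
  }
  het <- geno %in% c("AB", "BA")

  prelim_normal <- vapply(seq_len(nseg), function(k) {
    i <- seq.int(segs$start_index[k], segs$end_index[k])
    all(abs(colMeans(fit$theta_hat[i, , drop = FALSE]) - mu0) < 0.1)
  }, logical(1))

  if (any(prelim_normal)) {
    idx_norm <- unlist(lapply(which(prelim_normal), function(k)
      seq.int(segs$start_index[k], segs$end_index[k])))
    base <- normal_baseline(u[idx_norm[het[idx_norm]], , drop = FALSE])
  } else if (!is.null(baseline)) {
    base <- baseline
  } else {
    stop(paste("no segment is at the normal state:",
               "supply 'baseline' (list with mean, var, n) to classify",
               "a whole-chromosome aberration"))
  }

  rows <- lapply(seq_len(nseg), function(k) {
    i <- seq.int(segs$start_index[k], segs$end_index[k])
    sf <- sfits[[k]]
    rf <- structure(list(mu_major = sf$mu_major, mu_minor = sf$mu_minor,
                         sigma_major = sf$sigma_het,
                         sigma_minor = sf$sigma_het,
                         mix_p = sf$mix_p,
                         n_het = max(2L, round(sf$n_het_eff)),
                         loglik = sf$loglik,
                         confidence = if (sf$n_het_eff >= 10) "high" else "low"),
                    class = "pscn_region_fit")
    ts <- test_region(rf, base, n_segments_tested = nseg, alpha = alpha)
    label <- classify_segment(ts, rf, base)
    loh_p <- NA_real_
    loh_flag <- FALSE
    if (rf$mu_minor < loh_minor_max) {
      hrates <- priors[i, "AB"] + priors[i, "BA"]
      loh_p <- inherited_loh_probability(hrates)
      loh_flag <- is.finite(loh_p) && loh_p > loh_flag_threshold
    }
    data.frame(chrom = track$records$chrom[1],
               start_pos = track$records$pos[segs$start_index[k]],
               end_pos = track$records$pos[segs$end_index[k]],
               start_index = segs$start_index[k],
               end_index = segs$end_index[k],
               n_snps = length(i), n_het = sum(het[i]),
               major = rf$mu_major, minor = rf$mu_minor,
               total = rf$mu_major + rf$mu_minor, mix_p = rf$mix_p,
               sigma_het = sf$sigma_het, sigma_hom = sf$sigma_hom,
               t_major = ts$t_major, t_minor = ts$t_minor,
               t_total = ts$t_total, p_major = ts$p_major,
               p_minor = ts$p_minor, p_total = ts$p_total,
               label = label, inherited_loh_prob = loh_p,
               loh_flag = loh_flag, confidence = rf$confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "genotypes") <- geno
  out
}
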