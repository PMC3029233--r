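# Hard segmentation of the posterior-mean copy-number track and rank-sum
# based merging of adjacent segments.

#' Hard segmentation by one-step Euclidean distances
#'
#' Computes \eqn{d_t = \lVert\hat\theta_{t+1} - \hat\theta_t\rVert_2} and,
#' starting from the sequence end points, greedily adds the change point
#' with the largest d exceeding the threshold among positions at least
#' \code{min_sep} SNPs from every current change point, until no further
#' candidate qualifies. A deliberately permissive threshold is intended
#' here: false positives are cleaned up afterwards by [merge_segments()].
#' Ties go to the smallest index, so the procedure is deterministic.
#'
#' @param theta_hat n x 2 matrix of posterior-mean copy numbers.
#' @param threshold minimum one-step distance (copy-number units).
#' @param min_sep minimum number of SNPs between change points (and between
#'   a change point and either end).
#' @return a list of class \code{pscn_changepoints}: sorted vector
#'   \code{$breakpoints} (index t means a segment boundary between SNP t
#'   and t+1) and the distances \code{$d} at those indices.
#' @export
hard_segment <- function(theta_hat, threshold = 0.1, min_sep = 20L) {
  n <- nrow(theta_hat)
  d <- sqrt(rowSums(diff(theta_hat)^2)) # d[t] between SNP t and t+1
  cand <- which(d > threshold)
  bounds <- c(0L, n)
  bp <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-d[cand], cand)]
    for (t in ord) {
      if (all(abs(t - c(bounds, bp)) >= min_sep)) bp <- c(bp, t)
    }
    bp <- sort(bp)
  }
  structure(list(breakpoints = bp, d = d[bp], n = n, min_sep = min_sep),
            class = "pscn_changepoints")
}

#' @export
print.pscn_changepoints <- function(x, ...) {
  cat(sprintf("<pscn_changepoints> %d breakpoint(s) over %d SNPs\n",
              length(x$breakpoints), x$n))
  invisible(x)
}

#' Merge adjacent segments with indistinguishable signal
#'
#' For each adjacent pair of segments two two-sided Wilcoxon rank-sum tests
#' are run: one on total intensity x + y and one on the allelic-imbalance
#' magnitude |x - y|. A breakpoint is removable when both p-values exceed
#' \code{alpha}; removable breakpoints are eliminated least-significant
#' first (largest min p-value), re-testing the affected neighbours, until
#' the segmentation is stable. The imbalance test is what defends
#' copy-neutral LOH boundaries, where totals on both sides agree.
#'
#' @param track an [allele_signal_track()].
#' @param changepoints a \code{pscn_changepoints} from [hard_segment()].
#' @param alpha p-value threshold below which a difference counts as real.
#' @param genotypes optional per-SNP genotype classes. When supplied, a
#'   third rank-sum test compares |x - y| over heterozygous-called SNPs
#'   only (both sides needing at least 20): the all-SNP imbalance test is
#'   diluted by homozygotes, whose |x - y| equals the total on both sides
#'   of a copy-neutral LOH boundary.
#' @return a pruned \code{pscn_changepoints}.
#' @export
merge_segments <- function(track, changepoints, alpha = 1e-4,
                           genotypes = NULL) {
  u <- track_xy(track)
  n <- nrow(u)
  stopifnot(changepoints$n == n)
  tot <- u[, 1] + u[, 2]
  imb <- abs(u[, 1] - u[, 2])
  het <- if (is.null(genotypes)) rep(FALSE, n) else
    genotypes %in% c("AB", "BA")
  bp <- changepoints$breakpoints

  # degenerate segments (< 2 SNPs) merge into their neighbour outright
  repeat {
    len <- diff(c(0L, bp, n))
    short <- which(len < 2L)
    if (!length(short)) break
    drop <- min(short, length(bp))
    bp <- bp[-drop]
  }

  pair_p <- function(bp, k) {
    # breakpoint k separates segments (left, right) under the current set
    lo <- if (k == 1L) 1L else bp[k - 1L] + 1L
    hi <- if (k == length(bp)) n else bp[k + 1L]
    il <- seq.int(lo, bp[k])
    ir <- seq.int(bp[k] + 1L, hi)
    p1 <- stats::wilcox.test(tot[il], tot[ir], exact = FALSE)$p.value
    p2 <- stats::wilcox.test(imb[il], imb[ir], exact = FALSE)$p.value
    p <- min(p1, p2)
    hl <- il[het[il]]
    hr <- ir[het[ir]]
    if (length(hl) >= 20L && length(hr) >= 20L) {
      p <- min(p, stats::wilcox.test(imb[hl], imb[hr],
                                     exact = FALSE)$p.value)
    }
    p
  }
  # p-values are cached; removing a breakpoint only invalidates its two
  # neighbours
  pm <- vapply(seq_along(bp), function(k) pair_p(bp, k), numeric(1))
  while (length(bp)) {
    removable <- which(pm > alpha)
    if (!length(removable)) break
    k <- removable[which.max(pm[removable])]
    bp <- bp[-k]
    pm <- pm[-k]
    for (k2 in c(k - 1L, k)) {
      if (k2 >= 1L && k2 <= length(bp)) pm[k2] <- pair_p(bp, k2)
    }
  }
  structure(list(breakpoints = bp,
                 d = changepoints$d[match(bp, changepoints$breakpoints)],
                 n = n, min_sep = changepoints$min_sep),
            class = "pscn_changepoints")
}

# segment index ranges (start, end inclusive) implied by breakpoints
#' @noRd
segments_from_breakpoints <- function(bp, n) {
  data.frame(start_index = c(1L, bp + 1L), end_index = c(bp, n))
}

#' Heterozygosity-deficit refinement of a segmentation
#'
#' Copy-neutral LOH with no normal-cell admixture leaves the posterior-mean
#' copy-number track flat: heterozygous SNPs sit exactly on the homozygote
#' clusters and the one-step distances carry no signal. What such a region
#' cannot hide is its run of homozygous genotype calls. This pass runs a
#' recursive binary split on the per-SNP heterozygote indicator within each
#' existing segment and adds a boundary wherever the heterozygote fraction
#' changes with overwhelming evidence (two-proportion z above
#' \code{z_threshold}, both sides at least \code{min_run} SNPs). The guard
#' is deliberately extreme: at the default settings a pure-diploid
#' chromosome essentially never produces a spurious split, so specificity
#' is unaffected. Added boundaries face the same rank-sum merging as all
#' others.
#'
#' @param changepoints a \code{pscn_changepoints}.
#' @param genotypes per-SNP genotype classes (heterozygous = AB or BA).
#' @param min_run smallest segment piece considered (SNPs).
#' @param z_threshold two-proportion z-statistic needed to split.
#' @return an augmented \code{pscn_changepoints}.
#' @export
roh_refine <- function(changepoints, genotypes, min_run = 200L,
                       z_threshold = 6) {
  n <- changepoints$n
  het <- as.numeric(genotypes %in% c("AB", "BA"))
  split_seg <- function(a, b) {
    len <- b - a + 1L
    if (len < 2L * min_run) return(integer(0))
    cs <- cumsum(het[a:b])
    ks <- seq.int(min_run, len - min_run)
    n1 <- ks
    n2 <- len - ks
    p1 <- cs[ks] / n1
    p2 <- (cs[len] - cs[ks]) / n2
    p <- cs[len] / len
    se <- sqrt(pmax(p * (1 - p), 1e-12) * (1 / n1 + 1 / n2))
    z <- abs(p1 - p2) / se
    k <- which.max(z)
    if (z[k] <= z_threshold) return(integer(0))
    cut <- a + ks[k] - 1L # boundary between cut and cut + 1
    c(split_seg(a, cut), cut, split_seg(cut + 1L, b))
  }
  segs <- segments_from_breakpoints(changepoints$breakpoints, n)
  extra <- unlist(lapply(seq_len(nrow(segs)), function(k)
    split_seg(segs$start_index[k], segs$end_index[k])))
  keep <- extra[vapply(extra, function(t)
    all(abs(t - c(0L, changepoints$breakpoints, n)) >=
          changepoints$min_sep), logical(1))]
  bp <- sort(unique(c(changepoints$breakpoints, keep)))
  structure(list(breakpoints = bp,
                 d = rep(NA_real_, length(bp)), n = n,
                 min_sep = changepoints$min_sep),
            class = "pscn_changepoints")
}
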