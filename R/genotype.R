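# Genotype-configuration estimation: initial clustering and the per-SNP
# maximum a posteriori update used in the M-step.

#' Initial genotype configurations by 4-group clustering
#'
#' Clusters the (x, y) intensities into four groups with k-means and maps
#' the clusters to genotype classes by centroid geometry: the cluster with
#' the largest x - y becomes AA, the largest y - x becomes BB, and the two
#' central clusters are heterozygous. Because AB and BA cannot be told apart
#' before any copy-number asymmetry is estimated, heterozygous SNPs are
#' assigned AB or BA uniformly at random under the given seed.
#' Non-polymorphic markers (prior mass on NP) keep the label NP, and a SNP
#' never receives a label its prior excludes.
#'
#' @param track an [allele_signal_track()].
#' @param priors prior matrix from [load_genotype_priors()].
#' @param seed integer seed for the clustering and the AB/BA coin flips.
#' @return character vector of per-SNP classes.
#' @export
initialize_genotypes <- function(track, priors, seed = 1L) {
  u <- track_xy(track)
  n <- nrow(u)
  if (nrow(priors) != n) stop("priors and track must have equal length")
  np <- priors[, "NP"] >= 0.5
  free <- which(!np)
  pts <- u[free, , drop = FALSE]
  # cheap degeneracy screen first; the exhaustive distinct-point count is
  # only needed when the data are nearly constant
  rng <- max(apply(pts, 2, function(v) diff(range(v))))
  if (rng <= 0 || nrow(unique(pts[seq_len(min(nrow(pts), 2000L)), ])) < 4L)
    if (nrow(unique(pts)) < 4L)
      stop("degenerate clustering: fewer than 4 distinct (x, y) points")
  g <- character(n)
  g[np] <- "NP"
  with_seed(seed, {
    km <- stats::kmeans(pts, centers = 4L, nstart = 5L, iter.max = 200L,
                        algorithm = "Lloyd")
    ctr <- km$centers
    # label each center by its allelic angle; k-means may split one
    # homozygote cloud into two centers, and both must stay homozygous
    ang <- atan2(pmax(ctr[, 2], 0), pmax(ctr[, 1], 0)) / (pi / 2)
    lab <- ifelse(ang < 0.25, "AA", ifelse(ang > 0.75, "BB", "HET"))
    if (!any(lab == "HET")) lab[which.min(abs(ang - 0.5))] <- "HET"
    gi <- lab[km$cluster]
    is_het <- gi == "HET"
    gi[is_het] <- sample(c("AB", "BA"), sum(is_het), replace = TRUE)
    g[free] <- gi
  })
  # respect zero-prior exclusions
  for (cls in c("AA", "AB", "BA", "BB")) {
    bad <- which(g == cls & priors[, cls] <= 0)
    if (length(bad)) {
      for (i in bad) {
        allowed <- GENO_CLASSES[priors[i, ] > 0]
        g[i] <- allowed[1]
      }
    }
  }
  g
}

#' MAP genotype configurations given copy-number estimates
#'
#' For each SNP independently, picks the class g maximizing
#' prior_g x N(u; A(g) theta_hat, Sigma_g): given theta, the observation is
#' a four-component (plus NP) mixture of Gaussians and the configuration is
#' the identifier of the component. Ties are broken by the fixed class
#' order AA, AB, BA, BB.
#'
#' @param track an [allele_signal_track()].
#' @param theta_hat n x 2 matrix of posterior-mean copy numbers.
#' @param priors prior matrix from [load_genotype_priors()].
#' @param hp a [pscn_hyperparams()] (supplies the per-class covariances).
#' @return character vector of per-SNP classes.
#' @export
genotype_mstep <- function(track, theta_hat, priors, hp) {
  u <- track_xy(track)
  if (nrow(theta_hat) != nrow(u) || nrow(priors) != nrow(u))
    stop("theta_hat, priors and track must have equal length")
  lp <- log(priors)
  code <- genotype_map_cpp(u, as.matrix(theta_hat), lp, hp_as_list(hp))
  GENO_CLASSES[code]
}
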