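# Synthetic tumor-dilution generator: a diploid chromosome with genotype
# configurations drawn from population priors, imposed (major, minor)
# copy-number segments, tumor/normal mixing at a stated contamination
# fraction, and per-class bivariate Gaussian noise.

#' The six-region aberration layout used by the benchmark chromosome
#'
#' Six non-overlapping regions, one per aberration type, on a 42,000-SNP
#' chromosome: SNP index ranges (inclusive) with the imposed (major, minor)
#' copy numbers of the two parental chromosomes.
#'
#' @return data.frame with columns start_index, end_index, major, minor,
#'   label.
#' @export
table2_specs <- function() {
  data.frame(
    start_index = c(2000L, 9000L, 16000L, 23000L, 30000L, 37000L),
    end_index = c(5000L, 12000L, 19000L, 26000L, 33000L, 40000L),
    major = c(3, 2, 2, 3, 1, 0),
    minor = c(2, 1, 0, 0, 0, 0),
    label = c("gain/gain", "gain/normal", "balanced gain/loss",
              "unbalanced gain/loss", "normal/loss", "loss/loss"),
    stringsAsFactors = FALSE
  )
}

#' @noRd
validate_specs <- function(specs, n_snps) {
  if (!nrow(specs)) return(invisible(specs))
  o <- order(specs$start_index)
  specs <- specs[o, , drop = FALSE]
  if (any(specs$end_index > n_snps) || any(specs$start_index < 1L))
    stop("aberration specs must fit inside n_snps")
  if (any(specs$minor > specs$major) || any(specs$minor < 0))
    stop("need 0 <= minor <= major in every spec")
  if (nrow(specs) > 1L &&
      any(specs$start_index[-1L] <= specs$end_index[-nrow(specs)]))
    stop("aberration specs must be non-overlapping")
  invisible(specs)
}

#' Simulate one chromosome of allele-specific signals
#'
#' Genotype configurations are drawn per SNP from the heterozygosity prior
#' ((1-h)/2, h/2, h/2, (1-h)/2). The tumor carries parent-specific copy
#' numbers (1, 1) outside the aberration specs and (major, minor) inside,
#' with the parent orientation of each region randomized (exercising the
#' AB/BA bookkeeping). Mixing c parts normal cells with 1 - c parts tumor
#' cells gives the observed theta = c (1,1) + (1-c) theta_tumor, assuming a
#' linear signal response over the 0-3 fold-change range. Observations are
#' u = A(g) theta + e with per-class Gaussian noise; they are not clamped
#' at zero, so the per-class error distribution is exactly the requested
#' Gaussian.
#'
#' @param n_snps number of SNPs.
#' @param specs aberration regions (see [table2_specs()]); may have zero
#'   rows for a pure-normal chromosome.
#' @param contamination normal-cell fraction c in [0, 1].
#' @param sd_het,sd_hom per-coordinate noise standard deviations for
#'   heterozygous and homozygous SNPs (diagonal covariances, on the scale
#'   of a 550k-style Illumina array).
#' @param het_rate population heterozygosity h.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param chrom chromosome name for the track.
#' @return list with \code{$track} (an [allele_signal_track()]),
#'   \code{$truth} (data.frame: per-SNP theta1, theta2 after dilution, the
#'   genotype configuration and region label) and \code{$specs}.
#' @export
simulate_chromosome <- function(n_snps = 42000L, specs = table2_specs(),
                                contamination = 0, sd_het = 0.15,
                                sd_hom = 0.18, het_rate = 0.3, seed = 1L,
                                chrom = "chr1") {
  stopifnot_scalar_prob(contamination, "contamination")
  stopifnot_scalar_prob(het_rate, "het_rate")
  specs <- validate_specs(specs, n_snps)
  parts <- with_seed(seed, simulate_draws(n_snps, specs, het_rate,
                                          sd_het, sd_hom))
  assemble_chromosome(parts, specs, contamination, n_snps, chrom)
}

# All random draws for one chromosome; kept separate so a dilution series
# can reuse identical draws across contamination levels.
#' @noRd
simulate_draws <- function(n_snps, specs, het_rate, sd_het, sd_hom) {
  h <- het_rate
  g <- sample(c("AA", "AB", "BA", "BB"), n_snps, replace = TRUE,
              prob = c((1 - h) / 2, h / 2, h / 2, (1 - h) / 2))
  flip <- if (nrow(specs)) stats::runif(nrow(specs)) < 0.5 else logical(0)
  sd_vec <- ifelse(g %in% c("AB", "BA"), sd_het, sd_hom)
  noise <- cbind(stats::rnorm(n_snps, 0, sd_vec), stats::rnorm(n_snps, 0, sd_vec))
  list(g = g, flip = flip, noise = noise)
}

#' @noRd
assemble_chromosome <- function(parts, specs, contamination, n_snps, chrom) {
  g <- parts$g
  theta_tumor <- matrix(1, n_snps, 2)
  region <- rep("normal", n_snps)
  if (nrow(specs)) {
    for (k in seq_len(nrow(specs))) {
      i <- seq.int(specs$start_index[k], specs$end_index[k])
      pair <- c(specs$major[k], specs$minor[k])
      if (parts$flip[k]) pair <- rev(pair)
      theta_tumor[i, 1] <- pair[1]
      theta_tumor[i, 2] <- pair[2]
      region[i] <- if ("label" %in% names(specs)) specs$label[k] else
        sprintf("region_%d", k)
    }
  }
  theta <- contamination * 1 + (1 - contamination) * theta_tumor
  # expected allele intensities per inherited configuration: homozygotes
  # put the total on one allele, heterozygotes read the parental copies
  mean_x <- numeric(n_snps)
  mean_y <- numeric(n_snps)
  i <- g == "AA"; mean_x[i] <- theta[i, 1] + theta[i, 2]; mean_y[i] <- 0
  i <- g == "AB"; mean_x[i] <- theta[i, 1]; mean_y[i] <- theta[i, 2]
  i <- g == "BA"; mean_x[i] <- theta[i, 2]; mean_y[i] <- theta[i, 1]
  i <- g == "BB"; mean_x[i] <- 0; mean_y[i] <- theta[i, 1] + theta[i, 2]
  x <- mean_x + parts$noise[, 1]
  y <- mean_y + parts$noise[, 2]
  track <- allele_signal_track(sprintf("snp%06d", seq_len(n_snps)), chrom,
                               seq_len(n_snps), x, y, platform = "raw_xy",
                               clamp = FALSE)
  truth <- data.frame(index = seq_len(n_snps), theta1 = theta[, 1],
                      theta2 = theta[, 2], genotype = g, region = region,
                      stringsAsFactors = FALSE)
  list(track = track, truth = truth, specs = specs,
       contamination = contamination)
}

#' Paired dilution series over contamination levels
#'
#' Simulates one chromosome per (contamination level, seed) pair. For a
#' given seed the genotype draws, region orientations and noise are
#' identical across levels - only the dilution varies - so sensitivity
#' curves across contamination are paired.
#'
#' @inheritParams simulate_chromosome
#' @param levels contamination fractions in [0, 1].
#' @param seeds integer vector of seeds.
#' @return list of simulation results (as [simulate_chromosome()]), ordered
#'   level-major, each carrying \code{$contamination} and \code{$seed}.
#' @export
dilution_series <- function(levels, seeds, n_snps = 42000L,
                            specs = table2_specs(), sd_het = 0.15,
                            sd_hom = 0.18, het_rate = 0.3, chrom = "chr1") {
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  specs <- validate_specs(specs, n_snps)
  out <- list()
  draws <- lapply(seeds, function(sd)
    with_seed(sd, simulate_draws(n_snps, specs, het_rate, sd_het, sd_hom)))
  for (lev in levels) {
    for (j in seq_along(seeds)) {
      sim <- assemble_chromosome(draws[[j]], specs, lev, n_snps, chrom)
      sim$seed <- seeds[j]
      out[[length(out) + 1L]] <- sim
    }
  }
  out
}

#' Write a simulated chromosome's truth table
#' @param sim result of [simulate_chromosome()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_truth_table <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
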