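# Scoring of segment calls against a simulation truth: region-level
# sensitivity (plain and type-correct) and SNP-level specificity.

#' Score segment calls against a simulation truth
#'
#' A true aberrant region counts as detected when at least half of its SNPs
#' are covered by non-normal calls, and as type-correct when at least half
#' are covered by calls carrying exactly the generating label. Specificity
#' is the fraction of SNPs outside all true regions that are not called
#' aberrant; type-correct specificity additionally counts truly aberrant
#' SNPs called with a wrong type as wrong calls.
#'
#' @param calls segment data.frame from [characterize_segments()] (needs
#'   start_index, end_index, label).
#' @param truth truth data.frame from [simulate_chromosome()] (per-SNP
#'   \code{region} label, "normal" outside aberrations).
#' @param min_overlap fraction of a true region that must be covered.
#' @return list with \code{$regions} (per-region detected / type_correct),
#'   \code{$sensitivity}, \code{$type_sensitivity}, \code{$specificity},
#'   \code{$type_specificity}.
#' @export
evaluate_calls <- function(calls, truth, min_overlap = 0.5) {
  n <- nrow(truth)
  if (any(calls$end_index > n)) stop("calls extend beyond the truth track")
  called <- rep("normal", n)
  for (k in seq_len(nrow(calls))) {
    i <- seq.int(calls$start_index[k], calls$end_index[k])
    called[i] <- calls$label[k]
  }
  labs <- rle(truth$region)
  ends <- cumsum(labs$lengths)
  starts <- ends - labs$lengths + 1L
  aberrant <- which(labs$values != "normal")
  regions <- data.frame(
    label = labs$values[aberrant],
    start_index = starts[aberrant], end_index = ends[aberrant],
    detected = NA, type_correct = NA, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(regions))) {
    i <- seq.int(regions$start_index[k], regions$end_index[k])
    regions$detected[k] <- mean(called[i] != "normal") >= min_overlap
    regions$type_correct[k] <- mean(called[i] == regions$label[k]) >= min_overlap
  }
  outside <- truth$region == "normal"
  inside <- !outside
  list(regions = regions,
       sensitivity = if (nrow(regions)) mean(regions$detected) else NA_real_,
       type_sensitivity = if (nrow(regions)) mean(regions$type_correct) else NA_real_,
       specificity = if (any(outside)) mean(called[outside] == "normal") else NA_real_,
       type_specificity = mean(c(called[outside] == "normal",
                                 called[inside] == truth$region[inside])))
}

#' Dilution tolerance scan: largest contamination with a correct type call
#'
#' Runs the full segmentation + classification pipeline over a grid of
#' contamination levels with several seeded replicates per level, scores
#' each aberrant region's type call, and reports for every region the
#' largest contamination level at which the correct type is called in a
#' majority of replicates.
#'
#' @param levels contamination fractions to scan.
#' @param seeds integer seeds (one replicate per seed per level).
#' @param n_snps chromosome size.
#' @param specs aberration layout (see [table2_specs()]).
#' @param config a [pscn_config()].
#' @param verbose print one line per run.
#' @param ... further arguments to [dilution_series()].
#' @return list with \code{$correct} (region x level majority-correct
#'   matrix), \code{$max_level} (named vector, per region label, of the
#'   largest correct level in percent; -Inf when never correct) and
#'   \code{$runs} (per-run region scores).
#' @export
dilution_type_scan <- function(levels = seq(0, 0.95, by = 0.05),
                               seeds = 1:3, n_snps = 42000L,
                               specs = table2_specs(),
                               config = pscn_config(), verbose = FALSE,
                               ...) {
  sims <- dilution_series(levels, seeds, n_snps = n_snps, specs = specs, ...)
  nreg <- nrow(specs)
  runs <- list()
  correct <- matrix(0L, nreg, length(levels),
                    dimnames = list(specs$label, sprintf("%g", 100 * levels)))
  for (sim in sims) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, sim$seed)
    res <- try(pscn_segment(sim$track, config = cfg), silent = TRUE)
    lev_i <- match(sim$contamination, levels)
    if (inherits(res, "try-error")) {
      ok <- rep(FALSE, nreg)
    } else {
      ev <- evaluate_calls(res$segments, sim$truth)
      m <- match(specs$label, ev$regions$label)
      ok <- ev$regions$type_correct[m]
      ok[is.na(ok)] <- FALSE
    }
    correct[, lev_i] <- correct[, lev_i] + as.integer(ok)
    runs[[length(runs) + 1L]] <- data.frame(
      contamination = sim$contamination, seed = sim$seed,
      label = specs$label, type_correct = ok, stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("c=%.2f seed=%d: %s", sim$contamination, sim$seed,
                      paste(as.integer(ok), collapse = "")))
  }
  need <- ceiling(length(seeds) / 2 + 0.1) # strict majority
  maj <- correct >= need
  max_level <- apply(maj, 1, function(row) {
    hit <- which(row)
    if (!length(hit)) -Inf else 100 * levels[max(hit)]
  })
  list(correct = maj, counts = correct, max_level = max_level,
       runs = do.call(rbind, runs))
}
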