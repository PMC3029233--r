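# End-to-end pipeline on one chromosome track, and the standard-format
# writers for its results.

#' Segment and classify one chromosome
#'
#' The full analysis on a single track: fit the two-chromosome model
#' ([pscn_fit()]), hard-segment the posterior-mean copy numbers
#' ([hard_segment()]), merge indistinguishable neighbours
#' ([merge_segments()]) and characterize every segment
#' ([characterize_segments()]).
#'
#' @param track an [allele_signal_track()].
#' @param priors optional genotype prior matrix ([load_genotype_priors()]).
#' @param config a [pscn_config()].
#' @param genotypes optional matched-normal genotype classes (held fixed).
#' @param baseline optional user baseline for whole-chromosome aberrations.
#' @return object of class \code{pscn_result}: list with \code{$fit},
#'   \code{$changepoints}, \code{$segments} (the calls data.frame) and
#'   \code{$config}.
#' @export
pscn_segment <- function(track, priors = NULL, config = pscn_config(),
                         genotypes = NULL, baseline = NULL) {
  if (is.null(priors)) priors <- load_genotype_priors(NULL, track)
  fit <- pscn_fit(track, priors = priors, config = config,
                  genotypes = genotypes)
  cps <- hard_segment(fit$theta_hat, threshold = config$d_threshold,
                      min_sep = config$min_sep)
  cps <- roh_refine(cps, fit$genotypes)
  cps <- merge_segments(track, cps, alpha = config$wilcoxon_alpha,
                        genotypes = fit$genotypes)
  segs <- characterize_segments(track, fit, cps, priors = priors,
                                alpha = config$alpha, baseline = baseline,
                                loh_flag_threshold = config$loh_flag_threshold)
  # final per-SNP genotypes: segment-coherent re-calls from the fitted
  # segment mixtures (robust to AB/BA orientation noise in the E/M track)
  geno <- attr(segs, "genotypes")
  attr(segs, "genotypes") <- NULL
  structure(list(fit = fit, changepoints = cps, segments = segs,
                 genotypes = geno, config = config),
            class = "pscn_result")
}

#' @export
print.pscn_result <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<pscn_result> %d segment(s), %d non-normal\n",
              nrow(s), sum(s$label != "normal")))
  print(s[, c("start_index", "end_index", "n_snps", "major", "minor", "label")])
  invisible(x)
}

#' Write segment calls as TSV
#'
#' Columns: chrom, start, end (closed 1-based positions), n_snps, n_het,
#' major, minor, total, label, p_major, p_minor, p_total,
#' inherited_loh_prob.
#'
#' @param segments calls data.frame from [characterize_segments()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom, start = segments$start_pos,
                    end = segments$end_pos, n_snps = segments$n_snps,
                    n_het = segments$n_het, major = segments$major,
                    minor = segments$minor, total = segments$total,
                    label = segments$label, p_major = segments$p_major,
                    p_minor = segments$p_minor, p_total = segments$p_total,
                    inherited_loh_prob = segments$inherited_loh_prob)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-label RGB: reds for gains, blues for losses, purple for gain/loss
#' @noRd
label_rgb <- function(label) {
  map <- c("normal" = "0,170,0", "gain/gain" = "180,0,0",
           "gain/normal" = "255,80,80", "balanced gain/loss" = "160,32,240",
           "unbalanced gain/loss" = "120,0,180",
           "normal/loss" = "80,80,255", "loss/loss" = "0,0,180")
  unname(map[label])
}

#' Write segment calls as a colour-coded BED file
#'
#' 0-based half-open intervals, the label in the name field, and an
#' itemRgb colour per aberration type (reds for gains, blues for losses,
#' purples for simultaneous gain/loss).
#'
#' @inheritParams write_segments_tsv
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_pos - 1L,
                    end = segments$end_pos,
                    name = gsub("[ /]", "_", segments$label),
                    score = 0L, strand = ".",
                    thickStart = segments$start_pos - 1L,
                    thickEnd = segments$end_pos,
                    itemRgb = label_rgb(segments$label))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the per-SNP copy-number and genotype estimates as TSV
#'
#' Columns: snp_id, chrom, pos, theta1, theta2, genotype, baseline_prob.
#'
#' @param track the analyzed [allele_signal_track()].
#' @param fit its [pscn_fit()] result.
#' @param path output path.
#' @export
write_pscn_tsv <- function(track, fit, path) {
  r <- track$records
  out <- data.frame(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
                    theta1 = fit$theta_hat[, 1], theta2 = fit$theta_hat[, 2],
                    genotype = fit$genotypes,
                    baseline_prob = fit$baseline_prob)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
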