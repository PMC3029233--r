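#' Ordered per-SNP allele-intensity track for one chromosome
#'
#' The basic data container of the package: one row per SNP with a genome
#' coordinate and the bivariate allele intensities (x, y). Tracks are always
#' single-chromosome and sorted by position.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param chrom single chromosome name (recycled).
#' @param pos 1-based physical positions, strictly increasing after sorting.
#' @param x,y non-negative allele intensities; values slightly below zero
#'   (possible for raw platform input) are clamped to 0 with a warning.
#' @param platform provenance of the signal columns: \code{"raw_xy"} or
#'   \code{"illumina_logr_baf"}.
#' @param clamp clamp negative intensities to zero (the platform-input
#'   convention). The synthetic generator sets this to FALSE so its noise
#'   distribution stays exactly Gaussian.
#' @return an object of class \code{allele_signal_track}: a list with a
#'   data.frame \code{$records} (snp_id, chrom, pos, x, y) and the
#'   \code{$platform} string.
#' @export
allele_signal_track <- function(snp_id, chrom, pos, x, y,
                                platform = c("raw_xy", "illumina_logr_baf"),
                                clamp = TRUE) {
  platform <- match.arg(platform)
  n <- length(pos)
  if (n < 2L) stop("a track needs at least 2 SNPs")
  chrom <- rep_len(as.character(chrom), n)
  if (length(unique(chrom)) != 1L)
    stop("a track holds exactly one chromosome")
  if (length(snp_id) != n || length(x) != n || length(y) != n)
    stop("snp_id, pos, x and y must have equal length")
  if (any(!is.finite(pos)) || any(pos < 0)) stop("positions must be non-negative")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (clamp) {
    n_clamp <- sum(x < 0) + sum(y < 0)
    if (n_clamp > 0) {
      warning(sprintf("clamped %d negative intensity value(s) to 0", n_clamp))
      x <- pmax(x, 0)
      y <- pmax(y, 0)
    }
  }
  o <- order(pos)
  rec <- data.frame(snp_id = as.character(snp_id)[o], chrom = chrom[o],
                    pos = as.integer(pos)[o], x = as.numeric(x)[o],
                    y = as.numeric(y)[o], stringsAsFactors = FALSE)
  if (anyDuplicated(rec$pos))
    stop("duplicated (chrom, pos) in track")
  structure(list(records = rec, platform = platform),
            class = "allele_signal_track")
}

#' @export
print.allele_signal_track <- function(x, ...) {
  r <- x$records
  cat(sprintf("<allele_signal_track> %s: %d SNPs, pos %d..%d, platform %s\n",
              r$chrom[1], nrow(r), r$pos[1], r$pos[nrow(r)], x$platform))
  invisible(x)
}

#' @export
length.allele_signal_track <- function(x) nrow(x$records)

# (x, y) matrix of a track
#' @noRd
track_xy <- function(track) {
  as.matrix(track$records[, c("x", "y")])
}
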