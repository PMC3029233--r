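#' Read a per-SNP table of allele-specific signals
#'
#' Reads a tab-separated file with header columns \code{snp_id}, \code{chrom},
#' \code{pos} plus either raw intensities \code{x}, \code{y} or platform
#' summaries \code{logR}, \code{BAF}. logR/BAF input is converted to the
#' (x, y) scale via [logr_baf_to_xy()]. Rows with non-finite signal values
#' are dropped with a message stating how many; rows may arrive unsorted.
#' Gzip-compressed files are read transparently.
#'
#' @param path path to a TSV file (optionally gzipped).
#' @param format \code{"auto"} detects from the header; \code{"raw_xy"} or
#'   \code{"illumina_logr_baf"} force an interpretation.
#' @inheritParams logr_baf_to_xy
#' @return a named list of [allele_signal_track()] objects, one per
#'   chromosome, each sorted by position.
#' @export
read_snp_table <- function(path, format = c("auto", "raw_xy", "illumina_logr_baf"),
                           baf_dialect = c("arctan", "ratio")) {
  format <- match.arg(format)
  baf_dialect <- match.arg(baf_dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  has_xy <- all(c("x", "y") %in% names(df))
  has_lb <- all(c("logR", "BAF") %in% names(df))
  if (format == "auto") {
    if (has_xy) format <- "raw_xy"
    else if (has_lb) format <- "illumina_logr_baf"
    else stop("need either {x, y} or {logR, BAF} signal columns")
  }
  if (format == "raw_xy" && !has_xy) stop("format 'raw_xy' needs columns x, y")
  if (format == "illumina_logr_baf" && !has_lb)
    stop("format 'illumina_logr_baf' needs columns logR, BAF")

  sig <- if (format == "raw_xy") df[, c("x", "y")] else df[, c("logR", "BAF")]
  ok <- is.finite(sig[[1]]) & is.finite(sig[[2]])
  if (format == "illumina_logr_baf")
    ok <- ok & sig[[2]] >= 0 & sig[[2]] <= 1
  if (any(!ok)) {
    message(sprintf("read_snp_table: dropped %d row(s) with non-finite or out-of-range signal (lines %s)",
                    sum(!ok),
                    paste(utils::head(which(!ok) + 1L, 5L), collapse = ", ")))
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) < 2L) stop("fewer than 2 usable rows after filtering")
  if (anyDuplicated(df[, c("chrom", "pos")]))
    stop("duplicated (chrom, pos) entries in input")

  if (format == "illumina_logr_baf") {
    xy <- logr_baf_to_xy(df$logR, df$BAF, baf_dialect = baf_dialect)
    df$x <- xy[, "x"]
    df$y <- xy[, "y"]
  }
  out <- lapply(split(df, df$chrom), function(d)
    allele_signal_track(d$snp_id, d$chrom, d$pos, d$x, d$y, platform = format))
  out[order(names(out))]
}

#' Write a track to the TSV dialect read by [read_snp_table()]
#'
#' Writes snp_id, chrom, pos, x, y plus the logR/BAF representation
#' (arctan dialect) so the file round-trips through either format.
#'
#' @param track an [allele_signal_track()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_snp_table <- function(track, path) {
  r <- track$records
  # the logR/BAF columns require non-negative intensities with positive total
  xc <- pmax(r$x, 0)
  yc <- pmax(r$y, 0)
  zero <- xc + yc <= 0
  xc[zero] <- 1e-6
  lb <- xy_to_logr_baf(xc, yc)
  out <- cbind(r, logR = lb[, "logR"], BAF = lb[, "BAF"])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-SNP genotype-configuration priors
#'
#' Builds the n x 5 prior matrix over inherited allele configurations
#' (AA, AB, BA, BB, NP) for every SNP of a track. With a heterozygosity file
#' (TSV columns \code{snp_id}, \code{het_rate}, typically estimated from
#' normal control samples), a SNP with heterozygosity h gets
#' ((1-h)/2, h/2, h/2, (1-h)/2, 0): AB and BA are indistinguishable in
#' normal samples, so each receives half the heterozygote proportion.
#' SNPs absent from the file (or all SNPs when \code{path} is NULL) get the
#' uniform prior (1/4, 1/4, 1/4, 1/4, 0), which works reasonably well in
#' practice because the copy-number posterior is insensitive to this prior.
#' Non-polymorphic intensity-only markers get all mass on the NP class, so
#' their genotype never moves and only total intensity informs segmentation.
#'
#' @param path optional TSV of per-SNP heterozygosity rates; NULL for the
#'   uniform prior everywhere.
#' @param track the [allele_signal_track()] the priors are for.
#' @param non_polymorphic character vector of snp_ids (or logical vector
#'   along the track) marking non-polymorphic copy number markers.
#' @return matrix with rows matching the track and columns
#'   \code{AA, AB, BA, BB, NP}; every row sums to 1.
#' @export
load_genotype_priors <- function(path = NULL, track, non_polymorphic = NULL) {
  n <- length(track)
  ids <- track$records$snp_id
  pri <- matrix(rep(c(0.25, 0.25, 0.25, 0.25, 0), each = n), nrow = n,
                dimnames = list(NULL, GENO_CLASSES))
  if (!is.null(path)) {
    het <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("snp_id", "het_rate") %in% names(het)))
      stop("prior file needs columns snp_id, het_rate")
    if (any(!is.finite(het$het_rate)) || any(het$het_rate < 0 | het$het_rate > 1))
      stop("het_rate values must lie in [0, 1]")
    m <- match(ids, het$snp_id)
    hit <- !is.na(m)
    h <- het$het_rate[m[hit]]
    pri[hit, ] <- cbind((1 - h) / 2, h / 2, h / 2, (1 - h) / 2, 0)
  }
  if (!is.null(non_polymorphic)) {
    np <- if (is.logical(non_polymorphic)) non_polymorphic else ids %in% non_polymorphic
    pri[np, ] <- rep(c(0, 0, 0, 0, 1), each = sum(np))
  }
  pri
}
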