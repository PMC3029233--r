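#' Convert logR/BAF values to allele intensities (x, y)
#'
#' Transforms per-SNP summaries as emitted by Illumina-style genotyping
#' platforms into the bivariate allele-intensity scale on which the
#' two-chromosome model operates. The total intensity is taken to be
#' \eqn{R = 2 \cdot 2^{logR}}, so a normal diploid SNP (logR = 0) has
#' total 2 and a per-parent baseline of 1, making copy numbers directly
#' readable from the transformed scale.
#'
#' Under the default \code{"arctan"} dialect the BAF column is interpreted
#' the way the Illumina platform defines it: the arc-tangent of the ratio of
#' B versus A raw copy number scaled to [0, 1], i.e.
#' \eqn{y/x = \tan(\mathrm{BAF}\cdot\pi/2)}. The \code{"ratio"} dialect
#' instead reads BAF as the naive proportion \eqn{y/(x+y)}.
#'
#' @param logr numeric vector of log2 relative total intensities.
#' @param baf numeric vector of B-allele frequencies in [0, 1].
#' @param baf_dialect either \code{"arctan"} (Illumina definition, default)
#'   or \code{"ratio"}.
#' @return a two-column matrix with columns \code{x} and \code{y};
#'   \code{x + y} equals the total intensity exactly.
#' @examples
#' logr_baf_to_xy(0, 0.5)   # balanced heterozygote -> (1, 1)
#' logr_baf_to_xy(0, 0)     # homozygous A -> (2, 0)
#' @seealso [xy_to_logr_baf()] for the inverse.
#' @export
logr_baf_to_xy <- function(logr, baf, baf_dialect = c("arctan", "ratio")) {
  baf_dialect <- match.arg(baf_dialect)
  if (length(logr) != length(baf))
    stop("'logr' and 'baf' must have the same length")
  if (any(!is.finite(logr))) stop("'logr' must be finite")
  if (any(!is.finite(baf)) || any(baf < 0) || any(baf > 1))
    stop("'baf' must lie in [0, 1]")
  r <- 2 * 2^logr
  if (baf_dialect == "arctan") {
    tb <- rep(0, length(baf))
    ok <- baf < 1 # tan of pi/2 is undefined; baf = 1 maps to x = 0 below
    tb[ok] <- tanpi(baf[ok] / 2)
    x <- ifelse(baf >= 1, 0, r / (1 + tb))
  } else {
    x <- r * (1 - baf)
  }
  y <- r - x
  cbind(x = x, y = y)
}

#' Convert allele intensities (x, y) to logR/BAF
#'
#' Exact inverse of [logr_baf_to_xy()] up to floating tolerance:
#' \eqn{\mathrm{logR} = \log_2((x+y)/2)} and, under the arctan dialect,
#' \eqn{\mathrm{BAF} = (2/\pi)\arctan(y/x)}.
#'
#' @param x,y non-negative numeric vectors of A- and B-allele intensities;
#'   \code{x + y} must be strictly positive.
#' @inheritParams logr_baf_to_xy
#' @return a two-column matrix with columns \code{logR} and \code{BAF}.
#' @export
xy_to_logr_baf <- function(x, y, baf_dialect = c("arctan", "ratio")) {
  baf_dialect <- match.arg(baf_dialect)
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0))
    stop("'x' and 'y' must be finite and non-negative")
  if (any(x + y <= 0))
    stop("x + y must be positive: logR is undefined at zero total intensity")
  logr <- log2((x + y) / 2)
  baf <- if (baf_dialect == "arctan") (2 / pi) * atan2(y, x) else y / (x + y)
  cbind(logR = logr, BAF = baf)
}
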