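# Run configuration: every tunable of the pipeline with its default, plus
# serialization to/from a flat key = value text file.

#' Pipeline configuration
#'
#' @param tol E/M stopping threshold on the mean per-SNP change of
#'   theta_hat (copy-number units).
#' @param max_iter maximum E/M rounds.
#' @param d_threshold one-step distance threshold of [hard_segment()].
#' @param min_sep minimum SNPs between change points.
#' @param wilcoxon_alpha p-value threshold of [merge_segments()].
#' @param bcmix_M,bcmix_K mixture pruning sizes of the smoother.
#' @param seed seed for the initial clustering / AB-BA assignment.
#' @param baf_dialect BAF convention of logR/BAF input files.
#' @param alpha family-wise level of the region t-tests.
#' @param loh_flag_threshold inherited-LOH flag threshold.
#' @return named list of class \code{pscn_config}.
#' @export
pscn_config <- function(tol = 1e-4, max_iter = 20L, d_threshold = 0.1,
                        min_sep = 20L, wilcoxon_alpha = 1e-4,
                        bcmix_M = 20L, bcmix_K = 10L, seed = 1L,
                        baf_dialect = c("arctan", "ratio"), alpha = 0.05,
                        loh_flag_threshold = 1e-3) {
  cfg <- list(tol = tol, max_iter = as.integer(max_iter),
              d_threshold = d_threshold, min_sep = as.integer(min_sep),
              wilcoxon_alpha = wilcoxon_alpha, bcmix_M = as.integer(bcmix_M),
              bcmix_K = as.integer(bcmix_K), seed = as.integer(seed),
              baf_dialect = match.arg(baf_dialect), alpha = alpha,
              loh_flag_threshold = loh_flag_threshold)
  class(cfg) <- "pscn_config"
  cfg
}

#' Write a configuration as a flat key = value file
#' @param config a [pscn_config()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pscn_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_pscn_config()]
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path input path.
#' @return a [pscn_config()].
#' @export
read_pscn_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  defaults <- pscn_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  args <- as.list(vals)
  names(args) <- keys
  for (k in keys) {
    if (k != "baf_dialect") args[[k]] <- as.numeric(args[[k]])
  }
  do.call(pscn_config, args)
}
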