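# Signal transforms, table reading and genotype priors.

test_that("logR/BAF to (x, y) hits the boundary and symmetry points", {
  expect_equal(logr_baf_to_xy(0, 0), cbind(x = 2, y = 0))
  expect_equal(logr_baf_to_xy(0, 0.5), cbind(x = 1, y = 1))
  expect_equal(logr_baf_to_xy(1, 1), cbind(x = 0, y = 4))
  # x + y reproduces the total exactly
  xy <- logr_baf_to_xy(c(-1, 0.3, 2), c(0.2, 0.7, 0.99))
  expect_equal(rowSums(xy), 2 * 2^c(-1, 0.3, 2))
  expect_error(logr_baf_to_xy(0, 1.2), "baf")
})

test_that("transform round-trips and swaps correctly", {
  set.seed(11)
  lr <- stats::runif(1000, -3, 3)
  bf <- stats::runif(1000, 0, 1)
  xy <- logr_baf_to_xy(lr, bf)
  back <- xy_to_logr_baf(xy[, "x"], xy[, "y"])
  expect_lt(max(abs(back[, "logR"] - lr)), 1e-9)
  expect_lt(max(abs(back[, "BAF"] - bf)), 1e-9)
  # the naive ratio dialect round-trips too
  xy2 <- logr_baf_to_xy(lr, bf, baf_dialect = "ratio")
  back2 <- xy_to_logr_baf(xy2[, "x"], xy2[, "y"], baf_dialect = "ratio")
  expect_lt(max(abs(back2[, "BAF"] - bf)), 1e-9)
  # label swap: x <-> y maps BAF -> 1 - BAF and leaves logR unchanged
  sw <- xy_to_logr_baf(xy[, "y"], xy[, "x"])
  expect_equal(unname(sw[, "logR"]), unname(back[, "logR"]))
  expect_lt(max(abs(sw[, "BAF"] - (1 - bf))), 1e-9)
  expect_error(xy_to_logr_baf(0, 0), "total")
})

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

test_that("read_snp_table sorts, filters and validates", {
  f <- withr_local_tempfile()
  write_tsv(data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                       pos = c(30, 10, 20), x = 1:3, y = 3:1), f)
  tr <- read_snp_table(f)
  expect_length(tr, 1)
  expect_equal(length(tr[[1]]), 3L)
  expect_equal(tr[[1]]$records$snp_id, c("b", "c", "a"))
  expect_equal(tr[[1]]$records$pos, c(10L, 20L, 30L))

  # one NaN BAF among 100 rows: 99 survive, drop is reported
  f2 <- withr_local_tempfile()
  baf <- rep(0.5, 100)
  baf[37] <- NaN
  write_tsv(data.frame(snp_id = sprintf("s%03d", 1:100), chrom = "chr2",
                       pos = 1:100, logR = 0, BAF = baf), f2)
  expect_message(tr2 <- read_snp_table(f2), "dropped 1 row")
  expect_equal(length(tr2[[1]]), 99L)
  expect_equal(tr2[[1]]$platform, "illumina_logr_baf")
  expect_equal(unname(pscnseg:::track_xy(tr2[[1]])[1, ]), c(1, 1))

  f3 <- withr_local_tempfile()
  write_tsv(data.frame(snp_id = "a", chrom = "chr1", pos = 1), f3)
  expect_error(read_snp_table(f3), "signal columns")
  f4 <- withr_local_tempfile()
  write_tsv(data.frame(snp_id = c("a", "b"), chrom = "chr1",
                       pos = c(5, 5), x = 1, y = 1), f4)
  expect_error(read_snp_table(f4), "duplicated")
})

test_that("genotype priors follow heterozygosity, default and NP rules", {
  u <- matrix(1, 10, 2)
  tr <- make_track(u)
  pri <- load_genotype_priors(NULL, tr)
  expect_equal(dim(pri), c(10L, 5L))
  expect_true(all(abs(rowSums(pri) - 1) < 1e-12))
  expect_true(all(pri[, "AA"] == 0.25))

  f <- withr_local_tempfile()
  utils::write.table(data.frame(snp_id = c("s0001", "s0003"),
                                het_rate = c(0.5, 0.2)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  pri2 <- load_genotype_priors(f, tr)
  expect_equal(unname(pri2[1, ]), c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(unname(pri2[3, ]), c(0.4, 0.1, 0.1, 0.4, 0))
  expect_equal(unname(pri2[2, ]), c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(pri2[, "AB"], pri2[, "BA"])

  pri3 <- load_genotype_priors(NULL, tr, non_polymorphic = "s0005")
  expect_equal(unname(pri3[5, ]), c(0, 0, 0, 0, 1))

  f2 <- withr_local_tempfile()
  utils::write.table(data.frame(snp_id = "s0001", het_rate = 1.4),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_genotype_priors(f2, tr), "\\[0, 1\\]")
})

test_that("tracks clamp negative input intensities when asked", {
  expect_warning(
    tr <- allele_signal_track(c("a", "b"), "chr1", 1:2, c(-0.1, 1), c(1, 1)),
    "clamped")
  expect_equal(tr$records$x, c(0, 1))
  tr2 <- allele_signal_track(c("a", "b"), "chr1", 1:2, c(-0.1, 1), c(1, 1),
                             clamp = FALSE)
  expect_equal(tr2$records$x, c(-0.1, 1))
})
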