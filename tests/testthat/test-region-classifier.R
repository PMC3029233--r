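# Region characterization: mixture fits, t-tests, six-way typing and the
# inherited-LOH flag.

gen_het <- function(n, major, minor, sd = 0.15, seed = 1) {
  set.seed(seed)
  orient <- stats::runif(n) < 0.5
  x <- ifelse(orient, major, minor) + stats::rnorm(n, 0, sd)
  y <- ifelse(orient, minor, major) + stats::rnorm(n, 0, sd)
  cbind(x, y)
}

test_that("het-only mixture EM recovers (major, minor) and starts as
          documented", {
  f <- fit_region_mixture(gen_het(500, 2, 0, seed = 2))
  expect_lt(abs(f$mu_major - 2), 0.05)
  expect_lt(abs(f$mu_minor - 0), 0.05)
  expect_gte(f$mu_major, f$mu_minor)

  # symmetric normal data: both means near 1, mix_p stays interior
  f2 <- fit_region_mixture(gen_het(500, 1, 1, seed = 3))
  expect_lt(abs(f2$mu_major - 1), 0.05)
  expect_lt(abs(f2$mu_minor - 1), 0.05)
  expect_gt(f2$mix_p, 0)
  expect_lt(f2$mix_p, 1)

  # the fixed EM starting point
  fm <- formals(fit_region_mixture)
  expect_equal(fm$mu_major_init, 1.1)
  expect_equal(fm$mu_minor_init, 0.9)
  expect_equal(fm$mix_p_init, 0.5)
  expect_equal(fm$sigma_init, 1)

  # unbiased recovery across seeds
  errs <- vapply(1:20, function(s) {
    f <- fit_region_mixture(gen_het(500, 2, 0, seed = 100 + s))
    abs(f$mu_major - 2) + abs(f$mu_minor)
  }, numeric(1))
  expect_lt(mean(errs) / 2, 0.05)

  # too few heterozygotes: pooled fallback with low confidence
  all_xy <- rbind(gen_het(5, 2, 0), cbind(stats::rnorm(200, 2, 0.18),
                                          stats::rnorm(200, 0, 0.18)))
  f3 <- fit_region_mixture(all_xy[1:5, ], all_xy = all_xy)
  expect_equal(f3$confidence, "low")
  expect_lt(abs(f3$mu_major - 2), 0.1)
})

test_that("segment-level four-configuration mixture is orientation robust
          and identified under complete LOH", {
  set.seed(7)
  sim_seg <- function(n, major, minor, h = 0.3) {
    g <- sample(c("AA", "AB", "BA", "BB"), n, TRUE,
                c((1 - h) / 2, h / 2, h / 2, (1 - h) / 2))
    sd <- ifelse(g %in% c("AB", "BA"), 0.15, 0.18)
    u <- t(vapply(seq_len(n), function(t)
      emission_mean(g[t], c(major, minor)), numeric(2))) +
      cbind(stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd))
    list(u = u, g = g)
  }
  for (mm in list(c(2, 1.5), c(1.2, 1), c(1, 1))) {
    s <- sim_seg(2000, mm[1], mm[2])
    f <- fit_segment_mixture(s$u)
    expect_lt(abs(f$mu_major - mm[1]), 0.05)
    expect_lt(abs(f$mu_minor - mm[2]), 0.05)
  }
  # complete LOH at zero contamination: het and hom components coincide,
  # yet (major, minor) stays identified through the cluster structure
  s <- sim_seg(2000, 2, 0)
  f <- fit_segment_mixture(s$u)
  expect_lt(abs(f$mu_major - 2), 0.05)
  expect_lt(abs(f$mu_minor - 0), 0.05)

  # genotype re-calls from the fitted segment recover het/hom status
  s2 <- sim_seg(2000, 1.5, 1)
  f2 <- fit_segment_mixture(s2$u)
  pri <- matrix(rep(c(0.25, 0.25, 0.25, 0.25, 0), each = 2000), 2000,
                dimnames = list(NULL, c("AA", "AB", "BA", "BB", "NP")))
  g2 <- pscnseg:::segment_genotype_recall(s2$u, f2, pri)
  expect_gt(mean((g2 %in% c("AB", "BA")) == (s2$g %in% c("AB", "BA"))), 0.99)
})

test_that("region t-tests behave at the null, at strong signal, and use the
          stated Bonferroni count", {
  base <- list(mean = 1, var = 0.15^2, n = 4000)
  null_fit <- structure(list(mu_major = 1, mu_minor = 1, sigma_major = 0.15,
                             sigma_minor = 0.15, n_het = 500),
                        class = "pscn_region_fit")
  ts <- test_region(null_fit, base, n_segments_tested = 10)
  expect_lt(abs(ts$t_major), 1e-9)
  expect_lt(abs(ts$t_total), 1e-9)
  expect_equal(ts$alpha_bonf, 0.05 / 30)

  gain_fit <- null_fit
  gain_fit$mu_major <- 2
  ts2 <- test_region(gain_fit, base, n_segments_tested = 10)
  expect_lt(ts2$p_major, 1e-20)
  expect_error(test_region(gain_fit, list(mean = NA, var = 1, n = 2), 1),
               "baseline")
})

test_that("the six-way decision table matches its definition", {
  base <- list(mean = 1, var = 0.15^2, n = 4000)
  mk <- function(maj, mnr, n = 500) {
    f <- structure(list(mu_major = maj, mu_minor = mnr, sigma_major = 0.15,
                        sigma_minor = 0.15, n_het = n),
                   class = "pscn_region_fit")
    list(fit = f, tests = test_region(f, base, n_segments_tested = 5))
  }
  cell <- function(maj, mnr) {
    z <- mk(maj, mnr)
    classify_segment(z$tests, z$fit, base)
  }
  expect_equal(cell(2, 1.5), "gain/gain")
  expect_equal(cell(2, 1), "gain/normal")
  expect_equal(cell(2, 0), "balanced gain/loss")    # total 2: not changed
  expect_equal(cell(3, 0), "unbalanced gain/loss")  # total 3: changed
  expect_equal(cell(1, 0.5), "normal/loss")
  expect_equal(cell(0.5, 0.2), "loss/loss")
  expect_equal(cell(1, 1), "normal")
  # sub-threshold deviations are not material changes
  expect_equal(cell(1.01, 0.99), "normal")
})

test_that("inherited-LOH chance probability follows the independence
          product", {
  expect_equal(inherited_loh_probability(rep(0.3, 10)), 0.7^10)
  expect_lt(inherited_loh_probability(rep(0.3, 3000)), 1e-100)
  expect_equal(inherited_loh_probability(c(0.3, 1, 0.3)), 0)
  expect_true(is.na(inherited_loh_probability(numeric(0))))
  expect_error(inherited_loh_probability(c(0.5, 1.2)))
})

test_that("allele relabeling leaves segment calls invariant", {
  sim <- simulate_chromosome(n_snps = 4000,
                             specs = data.frame(start_index = 1200L,
                                                end_index = 2400L,
                                                major = 2, minor = 0.5),
                             contamination = 0, seed = 23)
  res <- pscn_segment(sim$track, config = pscn_config(seed = 2))
  u <- pscnseg:::track_xy(sim$track)
  swapped <- make_track(u[, 2:1])
  res2 <- pscn_segment(swapped, config = pscn_config(seed = 2))
  expect_equal(res2$segments$label, res$segments$label)
  expect_equal(res2$segments$major, res$segments$major, tolerance = 0.02)
  expect_equal(res2$segments$minor, res$segments$minor, tolerance = 0.02)
})
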