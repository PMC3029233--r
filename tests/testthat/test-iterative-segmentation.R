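# Outer algorithm: initial clustering, MAP genotyping, hyperparameter
# estimation, the E/M fit, hard segmentation and rank-sum merging.

sim_normal_track <- function(n, seed, sd_het = 0.15, sd_hom = 0.18,
                             h = 0.3) {
  set.seed(seed)
  g <- sample(c("AA", "AB", "BA", "BB"), n, TRUE,
              c((1 - h) / 2, h / 2, h / 2, (1 - h) / 2))
  sd <- ifelse(g %in% c("AB", "BA"), sd_het, sd_hom)
  u <- t(vapply(seq_len(n), function(t)
    emission_mean(g[t], c(1, 1)), numeric(2))) +
    cbind(stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd))
  list(track = make_track(u), g = g)
}

test_that("initial clustering separates heterozygotes from homozygotes", {
  sim <- sim_normal_track(1000, seed = 21)
  pri <- load_genotype_priors(NULL, sim$track)
  g0 <- initialize_genotypes(sim$track, pri, seed = 1)
  het_true <- sim$g %in% c("AB", "BA")
  het_call <- g0 %in% c("AB", "BA")
  expect_gt(mean(het_true == het_call), 0.99)

  # NP markers keep their label regardless of clustering
  pri2 <- pri
  pri2[5, ] <- c(0, 0, 0, 0, 1)
  g2 <- initialize_genotypes(sim$track, pri2, seed = 1)
  expect_equal(g2[5], "NP")

  # degenerate input: all points identical
  u <- matrix(1, 50, 2)
  expect_error(initialize_genotypes(make_track(u),
                                    load_genotype_priors(NULL, make_track(u)),
                                    seed = 1),
               "degenerate")
})

test_that("MAP genotyping picks the density-maximizing configuration", {
  hp <- pscn_hyperparams(sigma = default_sigma_for_tests(0.2))
  u <- rbind(c(2, 0), c(1.5, 0.5), c(0.5, 1.5), c(0, 2), c(1, 1))
  th <- rbind(c(1, 1), c(1.5, 0.5), c(1.5, 0.5), c(1, 1), c(1, 1))
  tr <- make_track(u)
  pri <- load_genotype_priors(NULL, tr)
  g <- genotype_mstep(tr, th, pri, hp)
  expect_equal(g, c("AA", "AB", "BA", "BB", "AB"))
  # the (1, 1) point ties AB/BA exactly: fixed class order picks AB

  pri[2, ] <- c(0, 0, 0, 0, 1)
  g2 <- genotype_mstep(tr, th, pri, hp)
  expect_equal(g2[2], "NP")
})

test_that("hyperparameter re-estimation recovers the error covariance", {
  set.seed(31)
  n <- 5000
  S_true <- matrix(c(0.04, 0.01, 0.01, 0.03), 2)
  g <- sample(c("AA", "AB", "BA", "BB"), n, TRUE)
  th <- matrix(1, n, 2)
  L <- chol(S_true)
  u <- t(vapply(seq_len(n), function(t) emission_mean(g[t], th[t, ]),
                numeric(2))) + matrix(stats::rnorm(2 * n), n) %*% L
  hp0 <- test_hp()
  hp1 <- estimate_hyperparams(make_track(u), th, g, hp0,
                              baseline_prob = rep(1, n))
  # class AA covariance within 10% (Frobenius) of truth; AB symmetrized
  # with the swapped BA residuals, which halves the off-diagonal here
  rel <- norm(hp1$sigma$AA - S_true, "F") / norm(S_true, "F")
  expect_lt(rel, 0.10)
  # no variant SNPs: z, V, p, r retained
  expect_equal(hp1$z, hp0$z)
  expect_equal(hp1$p, hp0$p)
  expect_equal(hp1$r, hp0$r)
})

test_that("jump-rate estimates come from runs and are clipped", {
  n <- 2000
  th <- matrix(1, n, 2)
  th[501:1500, 1] <- 1.8 # one long variant run
  tr <- make_track(th + 0) # noise-free observations, AB everywhere
  hp0 <- test_hp()
  hp1 <- estimate_hyperparams(tr, th, rep("AB", n), hp0,
                              baseline_prob = as.numeric(rowSums(abs(th - 1)) == 0))
  expect_equal(hp1$p, 1 / 1000, tolerance = 1e-6) # 1 entry / 1000 normal SNPs
  expect_equal(hp1$r, 1 / 1000, tolerance = 1e-6) # 1 exit / 1000 variant SNPs
  expect_gte(hp1$p, 1e-6)
  expect_lte(hp1$p, 0.2)

  # variant block at the start: zero entries -> lower clip
  th2 <- matrix(1, n, 2)
  th2[1:400, 1] <- 1.8
  hp2 <- estimate_hyperparams(make_track(th2 + 0), th2, rep("AB", n), hp0,
                              baseline_prob = as.numeric(th2[, 1] == 1))
  expect_equal(hp2$p, 1e-6)
})

test_that("the E/M fit recovers a pure-normal chromosome", {
  sim <- sim_normal_track(1000, seed = 41)
  f <- pscn_fit(sim$track, config = pscn_config(seed = 5))
  expect_true(f$trace$converged)
  expect_lt(max(abs(f$theta_hat - 1)), 0.1)
  het_true <- sim$g %in% c("AB", "BA")
  het_call <- f$genotypes %in% c("AB", "BA")
  expect_gt(mean(het_true == het_call), 0.99)
  expect_true(all(diff(c(0, f$trace$iterations)) <= pscn_config()$max_iter))
})

test_that("matched-normal mode is at least as accurate as unmatched", {
  sim <- simulate_chromosome(n_snps = 4000,
                             specs = data.frame(start_index = 1500L,
                                                end_index = 2500L,
                                                major = 2, minor = 0.5),
                             contamination = 0, seed = 13)
  err <- function(f) mean(sqrt(rowSums((f$theta_hat -
    as.matrix(sim$truth[, c("theta1", "theta2")]))^2)))
  # true theta is defined up to parent exchange within each segment; align
  # by the better of the two orientations per SNP
  err_aligned <- function(f) {
    tt <- as.matrix(sim$truth[, c("theta1", "theta2")])
    d1 <- sqrt(rowSums((f$theta_hat - tt)^2))
    d2 <- sqrt(rowSums((f$theta_hat - tt[, 2:1])^2))
    mean(pmin(d1, d2))
  }
  f_un <- pscn_fit(sim$track, config = pscn_config(seed = 3))
  f_ma <- pscn_fit(sim$track, config = pscn_config(seed = 3),
                   genotypes = sim$truth$genotype)
  expect_lte(err_aligned(f_ma), err_aligned(f_un) + 1e-8)
})

test_that("hard segmentation is greedy with a separation constraint", {
  th <- matrix(1, 200, 2)
  th[101:200, 1] <- 2
  cp <- hard_segment(th, threshold = 0.1, min_sep = 20)
  expect_equal(cp$breakpoints, 100L)

  # two candidate jumps 5 SNPs apart: only the larger-d one survives
  th2 <- matrix(1, 200, 2)
  th2[101:200, 1] <- 2    # jump of 1.0 at t = 100
  th2[106:200, 2] <- 1.5  # jump of 0.5 at t = 105
  cp2 <- hard_segment(th2, threshold = 0.1, min_sep = 20)
  expect_equal(cp2$breakpoints, 100L)

  expect_equal(hard_segment(matrix(1, 100, 2))$breakpoints, integer(0))
})

test_that("rank-sum merging removes null breakpoints, keeps real ones", {
  set.seed(51)
  # identical distributions on both sides: breakpoint removed
  u <- cbind(stats::rnorm(400, 1, 0.15), stats::rnorm(400, 1, 0.15))
  cp <- structure(list(breakpoints = 200L, d = 0.2, n = 400L, min_sep = 20L),
                  class = "pscn_changepoints")
  m <- merge_segments(make_track(u), cp, alpha = 1e-4)
  expect_equal(m$breakpoints, integer(0))

  # total shift of 0.5: retained
  u2 <- u
  u2[201:400, 1] <- u2[201:400, 1] + 0.5
  m2 <- merge_segments(make_track(u2), cp, alpha = 1e-4)
  expect_equal(m2$breakpoints, 200L)

  # copy-neutral LOH boundary: totals equal, imbalance differs - this is
  # what the |x - y| test exists for
  u3 <- rbind(cbind(stats::rnorm(200, 1, 0.15), stats::rnorm(200, 1, 0.15)),
              cbind(stats::rnorm(200, 2, 0.15), stats::rnorm(200, 0, 0.15)))
  m3 <- merge_segments(make_track(u3), cp, alpha = 1e-4)
  expect_equal(m3$breakpoints, 200L)
})

test_that("identical seeds give identical pipeline output", {
  sim <- simulate_chromosome(n_snps = 3000,
                             specs = data.frame(start_index = 1000L,
                                                end_index = 1800L,
                                                major = 2, minor = 1),
                             contamination = 0.3, seed = 17)
  r1 <- pscn_segment(sim$track, config = pscn_config(seed = 9))
  r2 <- pscn_segment(sim$track, config = pscn_config(seed = 9))
  expect_identical(r1$segments, r2$segments)
  expect_identical(r1$fit$theta_hat, r2$fit$theta_hat)
  expect_identical(r1$genotypes, r2$genotypes)
})
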