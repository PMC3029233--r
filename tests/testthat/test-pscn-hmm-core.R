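# The two-chromosome HMM: transition structure, emission model, filters and
# smoother, certified against independent reference implementations.

test_that("transition matrix is stochastic, stationary and reversible", {
  P <- transition_matrix(0.001, 0.005, 1e-4)
  expect_equal(unname(rowSums(P)), c(1, 1, 1))
  # p = r gives the closed-form stationary distribution (1/2, 1/4, 1/4)
  pi0 <- stationary_distribution(0.01, 0.01, 1e-3)
  expect_equal(unname(pi0), c(0.5, 0.25, 0.25))
  # detailed balance at stationarity, elementwise
  for (pars in list(c(0.001, 0.005, 1e-4), c(0.05, 0.02, 0.01))) {
    P <- transition_matrix(pars[1], pars[2], pars[3])
    pi0 <- stationary_distribution(pars[1], pars[2], pars[3])
    F <- diag(pi0) %*% P
    expect_equal(F, t(F), tolerance = 1e-12, ignore_attr = TRUE)
  }
  # p = 0: the normal state is absorbing
  expect_equal(unname(transition_matrix(0, 0.01, 0)[1, ]), c(1, 0, 0))
  expect_error(transition_matrix(0.1, 0.7, 0.4), "1 - r - s")
})

test_that("emission means follow the allele assignment matrices", {
  expect_equal(emission_mean("AA", c(1, 1)), c(2, 0))
  expect_equal(emission_mean("BB", c(1, 1)), c(0, 2))
  expect_equal(emission_mean("AB", c(1.5, 0.5)), c(1.5, 0.5))
  expect_equal(emission_mean("BA", c(1.5, 0.5)), c(0.5, 1.5))
  expect_equal(emission_mean("NP", c(1.5, 0.5)), c(1, 1))
  expect_error(emission_mean("XX", c(1, 1)))
  expect_equal(assignment_matrix("AB"), diag(2))
  expect_equal(assignment_matrix("AA"), matrix(c(1, 0, 1, 0), 2))
  expect_equal(assignment_matrix("BB"), matrix(c(0, 1, 0, 1), 2))
  expect_equal(assignment_matrix("BA"), matrix(c(0, 1, 1, 0), 2))
})

test_that("filter states are normalized and favour baseline on baseline data", {
  hp <- test_hp(sd = 0.05)
  prob <- sim_problem(30, seed = 2)
  ff <- forward_filter(make_track(prob$u), prob$g, hp, M = 40, K = 10)
  for (st in ff$states) {
    expect_equal(st$baseline_weight + sum(st$weight), 1, tolerance = 1e-9)
  }
  # single exact-baseline observation with small noise: the point mass wins
  u1 <- rbind(emission_mean("AB", hp$mu0), emission_mean("AA", hp$mu0))
  f1 <- forward_filter(make_track(u1), c("AB", "AA"), hp, M = 5, K = 5)
  st1 <- f1$states[[1]]
  expect_gt(st1$baseline_weight, max(st1$weight))
})

test_that("backward filter is the reversed forward filter", {
  hp <- test_hp()
  prob <- sim_problem(25, seed = 3)
  n <- nrow(prob$u)
  bf <- backward_filter(make_track(prob$u), prob$g, hp, M = 30, K = 10)
  ff_rev <- forward_filter(make_track(prob$u[n:1, ]), rev(prob$g), hp,
                           M = 30, K = 10)
  for (t in seq_len(n)) {
    a <- bf$states[[t]]
    b <- ff_rev$states[[n + 1 - t]]
    expect_equal(a$baseline_weight, b$baseline_weight, tolerance = 1e-12)
    expect_equal(a$weight, b$weight, tolerance = 1e-12)
    expect_equal(a$mean1, b$mean1, tolerance = 1e-12)
  }
})

test_that("unpruned filter matches the from-scratch O(n^2) reference", {
  hp <- test_hp()
  for (seed in 1:2) {
    prob <- sim_problem(40, seed = seed)
    n <- nrow(prob$u)
    ff <- forward_filter(make_track(prob$u), prob$g, hp, M = n + 1, K = n + 1)
    ref <- ref_filter(prob$u, prob$g, hp)
    for (t in seq_len(n)) {
      a <- ff$states[[t]]
      b <- ref[[t]]
      expect_equal(a$baseline_weight, exp(b$lw0), tolerance = 1e-8)
      expect_equal(a$origin, b$comps$j)
      expect_equal(a$weight, exp(b$comps$lw), tolerance = 1e-8)
      keep <- a$weight > 1e-10
      post <- lapply(b$comps$j[keep], function(j)
        conj_post(prob$u, prob$g, j:t, hp)$mean)
      expect_equal(a$mean1[keep], vapply(post, `[`, 0, 1), tolerance = 1e-8)
      expect_equal(a$mean2[keep], vapply(post, `[`, 0, 2), tolerance = 1e-8)
    }
  }
})

test_that("smoother matches the O(n^2) reference and the exact enumeration", {
  hp <- test_hp()
  prob <- sim_problem(40, seed = 5)
  sm <- pscn_smooth(make_track(prob$u), prob$g, hp, M = 50, K = 50)
  ref <- ref_smooth(prob$u, prob$g, hp)
  expect_lt(max(abs(sm$theta_hat - ref)), 1e-8)

  # tiny problems: compare against full 3^n enumeration
  hp2 <- test_hp(p = 0.05, r = 0.1, s = 0.02)
  for (seed in 1:2) {
    prob <- sim_problem(7, seed = seed, span = 4:7)
    sm <- pscn_smooth(make_track(prob$u), prob$g, hp2, M = 10, K = 10)
    en <- enum_smoother(prob$u, prob$g, hp2)
    expect_lt(max(abs(sm$theta_hat - en$theta_hat)), 1e-8)
    expect_equal(sm$loglik, en$loglik, tolerance = 1e-8)
    ref <- ref_smooth(prob$u, prob$g, hp2)
    expect_lt(max(abs(ref - en$theta_hat)), 1e-8)
  }
})

test_that("BCMIX pruning changes the smoother only negligibly", {
  hp <- test_hp(p = 0.005, r = 0.01, s = 1e-3)
  prob <- sim_problem(500, seed = 8, span = 180:320)
  tr <- make_track(prob$u)
  full <- pscn_smooth(tr, prob$g, hp, M = 501, K = 501)
  pruned <- pscn_smooth(tr, prob$g, hp, M = 20, K = 10)
  expect_lt(max(abs(full$theta_hat - pruned$theta_hat)), 0.01)
})

test_that("smoothing is reversal invariant and label-swap equivariant", {
  # an exchangeable prior (z1 = z2, V symmetric under coordinate swap) is
  # required for exact swap equivariance; unpruned smoothing keeps the two
  # directions algebraically identical
  hp <- pscn_hyperparams(z = c(1.05, 1.05),
                         V = matrix(c(0.3, 0.05, 0.05, 0.3), 2),
                         sigma = default_sigma_for_tests(0.2),
                         p = 0.02, r = 0.05, s = 0.01)
  prob <- sim_problem(120, seed = 9, span = 40:80)
  n <- nrow(prob$u)
  tr <- make_track(prob$u)
  sm <- pscn_smooth(tr, prob$g, hp, M = n, K = n)
  # reversal: same answer right-to-left
  smr <- pscn_smooth(make_track(prob$u[n:1, ]), rev(prob$g), hp, M = n, K = n)
  expect_lt(max(abs(smr$theta_hat[n:1, ] - sm$theta_hat)), 1e-6)
  # with default BCMIX pruning the two directions may prune differently;
  # the discrepancy stays at the pruning error scale
  smp <- pscn_smooth(tr, prob$g, hp)
  smrp <- pscn_smooth(make_track(prob$u[n:1, ]), rev(prob$g), hp)
  expect_lt(max(abs(smrp$theta_hat[n:1, ] - smp$theta_hat)), 0.01)
  # allele-label swap: exchange x/y and AA<->BB, AB<->BA. Each parent keeps
  # its copy number (it merely carries the other allele), so theta_hat is
  # unchanged and the total is trivially invariant
  swap_map <- c(AA = "BB", AB = "BA", BA = "AB", BB = "AA", NP = "NP")
  sms <- pscn_smooth(make_track(prob$u[, 2:1]), unname(swap_map[prob$g]), hp,
                     M = n, K = n)
  expect_lt(max(abs(sms$theta_hat - sm$theta_hat)), 1e-6)
  expect_lt(max(abs(rowSums(sms$theta_hat) - rowSums(sm$theta_hat))), 1e-6)
  # parent-label exchange: AB<->BA everywhere swaps theta exactly
  flip_map <- c(AA = "AA", AB = "BA", BA = "AB", BB = "BB", NP = "NP")
  smf <- pscn_smooth(tr, unname(flip_map[prob$g]), hp, M = n, K = n)
  expect_lt(max(abs(smf$theta_hat[, 2:1] - sm$theta_hat)), 1e-6)
})

test_that("limiting cases: rare jumps pin the posterior to baseline, and a
          noiseless variant segment is recovered", {
  hp0 <- pscn_hyperparams(p = 1e-6, r = 5e-3, s = 1e-4,
                          sigma = default_sigma_for_tests(0.15))
  set.seed(10)
  n <- 200
  g <- sample(c("AA", "AB", "BA", "BB"), n, TRUE)
  u <- t(vapply(seq_len(n), function(t)
    emission_mean(g[t], c(1, 1)) + stats::rnorm(2, 0, 0.15), numeric(2)))
  sm <- pscn_smooth(make_track(u), g, hp0)
  expect_lt(max(sqrt(rowSums((sm$theta_hat - 1)^2))), 0.05)

  # near-noiseless data from one variant value
  hp1 <- test_hp(sd = 1e-3)
  th <- c(1.6, 0.4)
  g2 <- rep(c("AB", "BA", "AA", "BB"), length.out = 60)
  u2 <- t(vapply(1:60, function(t) emission_mean(g2[t], th), numeric(2)))
  u2[, 1] <- u2[, 1] + stats::rnorm(60, 0, 1e-3)
  u2[, 2] <- u2[, 2] + stats::rnorm(60, 0, 1e-3)
  sm2 <- pscn_smooth(make_track(u2), g2, hp1, M = 61, K = 61)
  expect_lt(max(abs(sm2$theta_hat[10:50, 1] - th[1])), 1e-2)
  expect_lt(max(abs(sm2$theta_hat[10:50, 2] - th[2])), 1e-2)
})
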