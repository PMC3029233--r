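# Independent reference implementations used as oracles.
#
# Two layers: (1) an exact smoother that enumerates every hidden state
# sequence (feasible for ~8 SNPs) - fully independent of the package's
# recursions; (2) a plain-R O(n^2) filter/smoother that recomputes every
# conjugate posterior from scratch per change-time hypothesis, with no
# pruning - an independent coding of the mixture recursion usable up to a
# few hundred SNPs.

ldn2 <- function(u, mu, S) {
  d <- as.numeric(u) - as.numeric(mu)
  dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
  q <- (d[1]^2 * S[2, 2] - 2 * d[1] * d[2] * S[1, 2] + d[2]^2 * S[1, 1]) / dt
  -log(2 * pi) - 0.5 * log(dt) - 0.5 * q
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

amat <- function(g) assignment_matrix(g)

withr_local_tempfile <- function() tempfile(fileext = ".tsv")

make_track <- function(u, clamp = FALSE) {
  allele_signal_track(sprintf("s%04d", seq_len(nrow(u))), "chrT",
                      seq_len(nrow(u)), u[, 1], u[, 2], clamp = clamp)
}

# conjugate posterior of a variant value given observations at `idx`
conj_post <- function(u, g, idx, hp) {
  Lam <- solve(hp$V)
  h <- Lam %*% hp$z
  for (t in idx) {
    A <- amat(g[t])
    Si <- solve(hp$sigma[[g[t]]])
    Lam <- Lam + t(A) %*% Si %*% A
    h <- h + t(A) %*% Si %*% u[t, ]
  }
  C <- solve(Lam)
  list(Lam = Lam, h = h, mean = as.numeric(C %*% h), cov = C)
}

# exact smoother by enumeration of all 3^n hidden state sequences
enum_smoother <- function(u, g, hp) {
  n <- nrow(u)
  P <- transition_matrix(hp$p, hp$r, hp$s)
  pi0 <- stationary_distribution(hp$p, hp$r, hp$s)
  run_ll <- function(idx) {
    Lam <- solve(hp$V)
    h <- Lam %*% hp$z
    ll <- 0
    for (t in idx) {
      A <- amat(g[t])
      C <- solve(Lam)
      m <- C %*% h
      ll <- ll + ldn2(u[t, ], A %*% m, A %*% C %*% t(A) + hp$sigma[[g[t]]])
      Si <- solve(hp$sigma[[g[t]]])
      Lam <- Lam + t(A) %*% Si %*% A
      h <- h + t(A) %*% Si %*% u[t, ]
    }
    ll
  }
  seqs <- as.matrix(expand.grid(rep(list(1:3), n)))
  lws <- numeric(nrow(seqs))
  means <- vector("list", nrow(seqs))
  for (si in seq_len(nrow(seqs))) {
    s <- seqs[si, ]
    lw <- log(pi0[s[1]])
    if (n > 1) for (t in 2:n) lw <- lw + log(P[s[t - 1], s[t]])
    mt <- matrix(NA_real_, n, 2)
    t <- 1
    while (t <= n) {
      if (s[t] == 1) {
        A <- amat(g[t])
        lw <- lw + ldn2(u[t, ], A %*% hp$mu0, hp$sigma[[g[t]]])
        mt[t, ] <- hp$mu0
        t <- t + 1
      } else {
        e <- t
        while (e < n && s[e + 1] == s[t]) e <- e + 1
        lw <- lw + run_ll(t:e)
        pm <- conj_post(u, g, t:e, hp)$mean
        for (tt in t:e) mt[tt, ] <- pm
        t <- e + 1
      }
    }
    lws[si] <- lw
    means[[si]] <- mt
  }
  m <- max(lws)
  w <- exp(lws - m)
  theta <- Reduce(`+`, Map(`*`, w, means)) / sum(w)
  list(theta_hat = theta, loglik = m + log(sum(w)))
}

# O(n^2) unpruned forward filter; returns per t the baseline log weight and
# a data.frame of components (origin j, log weight, mean, cov)
ref_filter <- function(u, g, hp) {
  n <- nrow(u)
  pi_n <- hp$r / (hp$r + hp$p)
  states <- vector("list", n)
  prev <- NULL
  for (t in seq_len(n)) {
    A <- amat(g[t])
    Sg <- hp$sigma[[g[t]]]
    if (t == 1) {
      prior0 <- log(pi_n)
      prior_new <- log(1 - pi_n)
      cont <- NULL
    } else {
      lsev <- lse(prev$comps$lw)
      prior0 <- lse(c(prev$lw0 + log(1 - hp$p), lsev + log(hp$r)))
      prior_new <- lse(c(prev$lw0 + log(hp$p), lsev + log(hp$s)))
      cont <- prev$comps$lw + log(1 - hp$r - hp$s)
    }
    lw0 <- prior0 + ldn2(u[t, ], A %*% hp$mu0, Sg)
    js <- c(if (t > 1) prev$comps$j, t)
    lws <- numeric(length(js))
    for (k in seq_along(js)) {
      j <- js[k]
      if (j == t) {
        pri <- list(mean = hp$z, cov = hp$V)
        lp <- prior_new
      } else {
        pri <- conj_post(u, g, j:(t - 1), hp)
        lp <- cont[k]
      }
      lws[k] <- lp + ldn2(u[t, ], A %*% pri$mean,
                          A %*% pri$cov %*% t(A) + Sg)
    }
    tot <- lse(c(lw0, lws))
    comps <- data.frame(j = js, lw = lws - tot)
    states[[t]] <- list(lw0 = lw0 - tot, comps = comps)
    prev <- states[[t]]
  }
  states
}

# O(n^2) unpruned smoother combining ref_filter passes in both directions
ref_smooth <- function(u, g, hp) {
  n <- nrow(u)
  pi_n <- hp$r / (hp$r + hp$p)
  lpin <- log(pi_n)
  lpiv <- log(1 - pi_n)
  fwd <- ref_filter(u, g, hp)
  bwd <- ref_filter(u[n:1, , drop = FALSE], rev(g), hp)
  Vinv <- solve(hp$V)
  hz <- Vinv %*% hp$z
  gfun <- function(Lam, h) {
    0.5 * as.numeric(t(h) %*% solve(Lam) %*% h) - 0.5 * log(det(Lam))
  }
  g0 <- gfun(Vinv, hz)
  theta <- matrix(NA_real_, n, 2)
  for (t in seq_len(n)) {
    f <- fwd[[t]]
    lws <- f$lw0
    ms <- list(hp$mu0)
    fposts <- lapply(f$comps$j, function(j) conj_post(u, g, j:t, hp))
    if (t == n) {
      for (k in seq_along(fposts)) {
        lws <- c(lws, f$comps$lw[k])
        ms <- c(ms, list(fposts[[k]]$mean))
      }
    } else {
      b <- bwd[[n - t]] # covers original indices (t+1)..n
      lseb <- lse(b$comps$lw)
      lqb0s <- lse(c(b$lw0 + log(1 - hp$p), lseb + log(hp$r)))
      lqbnews <- lse(c(b$lw0 + log(hp$p), lseb + log(hp$s)))
      bposts <- lapply(b$comps$j, function(jr)
        conj_post(u, g, (t + 1):(n - jr + 1), hp))
      lws[1] <- f$lw0 + lqb0s - lpin
      for (k in seq_along(fposts)) {
        lws <- c(lws, f$comps$lw[k] + lqbnews - lpiv)
        ms <- c(ms, list(fposts[[k]]$mean))
        for (kk in seq_along(bposts)) {
          Lam <- fposts[[k]]$Lam + bposts[[kk]]$Lam - Vinv
          h <- fposts[[k]]$h + bposts[[kk]]$h - hz
          logc <- gfun(Lam, h) - gfun(fposts[[k]]$Lam, fposts[[k]]$h) -
            gfun(bposts[[kk]]$Lam, bposts[[kk]]$h) + g0
          lws <- c(lws, f$comps$lw[k] + b$comps$lw[kk] +
                     log(1 - hp$r - hp$s) - lpiv + logc)
          ms <- c(ms, list(as.numeric(solve(Lam) %*% h)))
        }
      }
    }
    w <- exp(lws - max(lws))
    w <- w / sum(w)
    theta[t, ] <- Reduce(`+`, Map(`*`, w, ms))
  }
  theta
}

# small simulated test problem with one variant stretch
sim_problem <- function(n, seed = 1, theta_var = c(1.7, 0.5),
                        span = NULL, sd = 0.2) {
  set.seed(seed)
  g <- sample(c("AA", "AB", "BA", "BB"), n, replace = TRUE)
  th <- matrix(1, n, 2)
  if (is.null(span)) span <- seq.int(max(1, floor(n / 3)), floor(2 * n / 3))
  th[span, 1] <- theta_var[1]
  th[span, 2] <- theta_var[2]
  u <- t(vapply(seq_len(n), function(t)
    emission_mean(g[t], th[t, ]) + stats::rnorm(2, 0, sd), numeric(2)))
  list(u = u, g = g, theta = th, span = span)
}

default_sigma_for_tests <- function(sd) {
  S <- diag(sd^2, 2)
  list(AA = S, AB = S, BA = S, BB = S, NP = S)
}

test_hp <- function(p = 0.02, r = 0.05, s = 0.01, sd = 0.2) {
  pscn_hyperparams(z = c(1.2, 0.9), V = matrix(c(0.3, 0.05, 0.05, 0.25), 2),
                   sigma = list(AA = diag(sd^2, 2), AB = diag(sd^2, 2),
                                BA = diag(sd^2, 2), BB = diag(sd^2, 2),
                                NP = diag(sd^2, 2)),
                   p = p, r = r, s = s)
}
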