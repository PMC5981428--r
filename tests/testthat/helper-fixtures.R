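# Small hand-built communities and an independent fixed-step oracle used
# across the test files.

# a fully specified tiny community: explicit network, constant parameters
# (no jitter so expected values are exact), manual state
toy_community <- function(edges, n_plants, n_animals,
                          mortality = 0.05, base = default_base_params(0)) {
  net <- bipartite_network(n_plants, n_animals, edges)
  params <- init_parameters(net, mortality, base)
  list(net = net, params = params)
}

uniform_alpha <- function(net) {
  deg <- tabulate(net$edges$animal, net$n_animals)
  1 / deg[net$edges$animal]
}

# Independent transcription of the model equations on dense matrices,
# written against the printed equations rather than the package's
# link-list kernel. Used as the oracle for integration tests.
dense_rhs <- function(p, a, R, alpha_m, pl, an, lk, threshold = 1e-3) {
  nP <- length(p)
  nA <- length(a)
  V <- matrix(0, nP, nA)
  for (i in seq_len(nP)) {
    for (j in seq_len(nA)) {
      V[i, j] <- alpha_m[i, j] * lk$tau[i, j] * a[j] * p[i]
    }
  }
  sigma <- matrix(0, nP, nA)
  for (j in seq_len(nA)) {
    den <- sum(pl$eps * V[, j])
    if (den > 0) sigma[, j] <- pl$eps * V[, j] / den
  }
  f <- ifelse(p > threshold, R / p, 0)
  dp <- numeric(nP)
  dR <- numeric(nP)
  for (i in seq_len(nP)) {
    gamma <- pl$g[i] * (1 - sum(pl$u[-i] * p[-i]) - pl$w[i] * p[i])
    dp[i] <- gamma * sum(lk$e[i, ] * sigma[i, ] * V[i, ]) - pl$mu_p[i] * p[i]
    dR[i] <- pl$beta[i] * p[i] - pl$phi[i] * R[i] -
      sum(V[i, ] * lk$b[i, ]) * f[i]
  }
  da <- numeric(nA)
  dalpha <- matrix(0, nP, nA)
  for (j in seq_len(nA)) {
    da[j] <- sum(lk$c[, j] * V[, j] * lk$b[, j] * f) - an$mu_a[j] * a[j]
    if (an$adaptive[j]) {
      rwd <- lk$c[, j] * lk$tau[, j] * lk$b[, j] * R
      mean_rwd <- sum(alpha_m[, j] * rwd)
      dalpha[, j] <- an$G[j] * alpha_m[, j] * (rwd - mean_rwd)
    }
  }
  list(dp = dp, da = da, dR = dR, dalpha = dalpha)
}

# package params -> the dense matrices the oracle wants
dense_inputs <- function(net, params) {
  nP <- net$n_plants
  nA <- net$n_animals
  mk <- function(v) {
    m <- matrix(0, nP, nA)
    m[cbind(net$edges$plant, net$edges$animal)] <- v
    m
  }
  list(
    pl = as.list(params$plants),
    an = list(mu_a = params$animals$mu_a,
              G = params$animals$G,
              adaptive = params$animals$adaptive),
    lk = list(tau = mk(params$links$tau), c = mk(params$links$c),
              b = mk(params$links$b), e = mk(params$links$e))
  )
}

# fixed-step RK4 on the dense oracle equations
rk4_oracle <- function(net, params, state, t_end, dt, threshold = 1e-3) {
  di <- dense_inputs(net, params)
  nP <- net$n_plants
  nA <- net$n_animals
  amat <- function(alpha) {
    m <- matrix(0, nP, nA)
    m[cbind(net$edges$plant, net$edges$animal)] <- alpha
    m
  }
  y <- list(p = state$p, a = state$a, R = state$R,
            alpha_m = amat(state$alpha))
  deriv <- function(y) {
    dense_rhs(pmax(y$p, 0), pmax(y$a, 0), pmax(y$R, 0),
              pmax(y$alpha_m, 0), di$pl, di$an, di$lk, threshold)
  }
  step <- function(y, dt) {
    k1 <- deriv(y)
    add <- function(y, k, h) list(
      p = y$p + h * k$dp, a = y$a + h * k$da, R = y$R + h * k$dR,
      alpha_m = y$alpha_m + h * k$dalpha
    )
    k2 <- deriv(add(y, k1, dt / 2))
    k3 <- deriv(add(y, k2, dt / 2))
    k4 <- deriv(add(y, k3, dt))
    list(
      p = y$p + dt / 6 * (k1$dp + 2 * k2$dp + 2 * k3$dp + k4$dp),
      a = y$a + dt / 6 * (k1$da + 2 * k2$da + 2 * k3$da + k4$da),
      R = y$R + dt / 6 * (k1$dR + 2 * k2$dR + 2 * k3$dR + k4$dR),
      alpha_m = y$alpha_m +
        dt / 6 * (k1$dalpha + 2 * k2$dalpha + 2 * k3$dalpha + k4$dalpha)
    )
  }
  n <- round((t_end - state$time) / dt)
  for (k in seq_len(n)) y <- step(y, dt)
  y
}

# brute-force literal NODF over all pairs, straight from the definition
nodf_brute <- function(m) {
  pair_sum <- function(mm) {
    n <- nrow(mm)
    tot <- 0
    npair <- 0
    if (n >= 2) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          npair <- npair + 1
          di <- sum(mm[i, ]); dj <- sum(mm[j, ])
          if (di == dj || min(di, dj) == 0) next
          lo <- if (di < dj) i else j
          hi <- if (di < dj) j else i
          shared <- sum(mm[lo, ] == 1 & mm[hi, ] == 1)
          tot <- tot + 100 * shared / sum(mm[lo, ])
        }
      }
    }
    c(tot, npair)
  }
  r <- pair_sum(m)
  cl <- pair_sum(t(m))
  if (r[2] + cl[2] == 0) return(0)
  (r[1] + cl[1]) / (r[2] + cl[2])
}
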