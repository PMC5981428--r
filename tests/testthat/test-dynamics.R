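test_that("plant parameters jitter within 10% and natives are identical", {
  set.seed(31)
  net <- generate_network(6, 12, 0.3, 0.5)
  base <- default_base_params()
  params <- init_parameters(net, mortality = 0.05, base)
  for (nm in c("g", "u", "w", "e", "eps", "mu_p", "beta", "phi")) {
    expect_true(all(params$plants[[nm]] >= 0.9 * base[[nm]] - 1e-12))
    expect_true(all(params$plants[[nm]] <= 1.1 * base[[nm]] + 1e-12))
  }
  expect_true(all(params$animals$mu_a == 0.05))
  expect_true(all(params$animals$G == base$G))
  expect_true(all(params$links$tau == 1))
  # degenerate jitter: all plants identical
  p0 <- init_parameters(net, 0.05, default_base_params(0))
  expect_equal(length(unique(p0$plants$g)), 1)
  # invariant u < w enforced
  bad <- default_base_params()
  bad$u <- 2
  expect_error(init_parameters(net, 0.05, bad), "competition")
})

test_that("native pollinators adaptively forage iff they have >1 link", {
  edges <- data.frame(plant = c(1, 2, 1), animal = c(1, 1, 2))
  net <- bipartite_network(2, 2, edges)
  params <- init_parameters(net, 0.05, default_base_params(0))
  expect_equal(params$animals$adaptive, c(TRUE, FALSE))
})

test_that("all-zero densities are a fixed point of the equations", {
  toy <- toy_community(data.frame(plant = c(1, 2), animal = c(1, 1)), 2, 1)
  st <- community_state(0, c(0, 0), 0, c(0, 0), c(0.5, 0.5))
  out <- community_rhs(st, toy$params, toy$net)
  expect_equal(out$dp, c(0, 0))
  expect_equal(out$da, 0)
  expect_equal(out$dR, c(0, 0))
})

test_that("pollination success fractions follow pollen-weighted visits", {
  toy <- toy_community(data.frame(plant = c(1, 2), animal = c(1, 1)), 2, 1)
  # equal pollen, equal visits -> equal split
  st <- community_state(0, c(1, 1), 2, c(0.5, 0.5), c(0.5, 0.5))
  out <- community_rhs(st, toy$params, toy$net)
  expect_equal(out$rates$sigma, c(0.5, 0.5))
  # pollen 2:1 at equal visits -> 2/3 vs 1/3
  toy$params$plants$eps <- c(2, 1)
  out2 <- community_rhs(st, toy$params, toy$net)
  expect_equal(out2$rates$V, c(1, 1))
  expect_equal(out2$rates$sigma, c(2 / 3, 1 / 3))
})

test_that("compiled kernel matches the R transcription of the equations", {
  set.seed(37)
  for (k in 1:10) {
    net <- generate_network(5, 9, 0.3, runif(1))
    params <- init_parameters(net, 0.05)
    st <- init_state(net, params)
    ctx <- pollinvade:::build_ctx(net, params)
    y <- pollinvade:::pack_state(st)
    r_dy <- pollinvade:::rhs_core(y, ctx)
    cpp_dy <- pollinvade:::rhs_kernel(
      y, ctx$lp, ctx$la, ctx$nP, ctx$nA, ctx$g, ctx$u, ctx$w, ctx$eps,
      ctx$mu_p, ctx$beta, ctx$phi, ctx$mu_a, ctx$G_l, ctx$tau, ctx$cc,
      ctx$bb, ctx$ee, ctx$threshold
    )
    expect_equal(r_dy, cpp_dy, tolerance = 1e-12)
  }
})

test_that("adaptive integration matches a fixed-step RK4 oracle (1x1)", {
  toy <- toy_community(data.frame(plant = 1, animal = 1), 1, 1)
  st <- community_state(0, 0.2, 0.2, 0.5, 1)
  traj <- integrate_community(st, toy$params, toy$net, t_end = 50,
                              prune_dt = 10)
  oracle <- rk4_oracle(toy$net, toy$params, st, t_end = 50, dt = 1e-3)
  expect_equal(traj$state$p, oracle$p, tolerance = 1e-4)
  expect_equal(traj$state$a, oracle$a, tolerance = 1e-4)
  expect_equal(traj$state$R, oracle$R, tolerance = 1e-4)
})

test_that("adaptive integration matches the RK4 oracle on 3x3 systems", {
  set.seed(41)
  for (k in 1:3) {
    net <- generate_network(3, 3, runif(1, 0.5, 0.9), runif(1))
    params <- init_parameters(net, 0.05)
    st <- init_state(net, params)
    # oracle step chosen small enough that halving it moves nothing at
    # the asserted tolerance (RK4 global error ~ dt^4)
    oracle <- rk4_oracle(net, params, st, t_end = 100, dt = 5e-3)
    traj <- integrate_community(st, params, net, t_end = 100,
                                prune_dt = 25)
    dead <- oracle$p < 1e-3
    expect_lt(max(abs(traj$state$p - ifelse(dead, 0, oracle$p))), 1e-3)
    expect_lt(max(abs(traj$state$a - oracle$a) /
                    pmax(abs(oracle$a), 1e-3)), 1e-3)
  }
})

test_that("a pollinator with huge mortality dies; its lone plant follows", {
  toy <- toy_community(data.frame(plant = 1, animal = 1), 1, 1,
                       mortality = 5)
  st <- community_state(0, 0.2, 0.2, 0.5, 1)
  traj <- integrate_community(st, toy$params, toy$net, t_end = 3000,
                              prune_dt = 50)
  expect_equal(traj$state$a, 0)
  # without pollination dp = -mu_p * p < 0, so the plant starves too
  expect_equal(traj$state$p, 0)
})

test_that("preferences stay on the simplex and states stay non-negative", {
  set.seed(43)
  net <- generate_network(8, 20, 0.28, 1)
  params <- init_parameters(net, 0.05)
  st <- init_state(net, params)
  traj <- integrate_community(st, params, net, t_end = 3000)
  expect_gte(min(traj$y), 0)
  ctx <- pollinvade:::build_ctx(net, params)
  for (r in seq_along(traj$times)) {
    y <- traj$y[r, ]
    a <- y[ctx$ia]
    asum <- as.numeric(ctx$A_inc %*% y[ctx$ial])
    # living animals sit on the simplex; those whose whole diet died have
    # all-zero preferences while they starve
    expect_true(all(abs(asum[a > 0] - 1) < 1e-6 | asum[a > 0] == 0))
    expect_lt(max(abs(asum[a > 0 & asum > 0.5] - 1)), 1e-6)
    # sigma sums to 1 (or 0 without visits) for every pollinator
    st_r <- pollinvade:::unpack_state(y, ctx, traj$times[r])
    rates <- community_rhs(st_r, params, net)$rates
    ssum <- tapply(rates$sigma, rates$animal, sum)
    expect_true(all(abs(ssum) < 1e-9 | abs(ssum - 1) < 1e-9))
  }
})

test_that("without pollinators rewards relax to beta*p/phi", {
  base <- default_base_params(0)
  base$mu_p <- 0   # isolate the rewards equation from plant decay
  toy <- toy_community(
    data.frame(plant = c(1, 2, 1, 2), animal = c(1, 1, 2, 2)), 2, 2,
    base = base
  )
  st <- community_state(0, c(0.4, 0.8), c(0, 0), c(0.1, 0.1),
                        rep(0.5, 4))
  traj <- integrate_community(st, toy$params, toy$net, t_end = 400,
                              prune_dt = 50)
  expect_equal(traj$state$p, c(0.4, 0.8), tolerance = 1e-8)
  expect_equal(traj$state$R,
               toy$params$plants$beta * c(0.4, 0.8) / toy$params$plants$phi,
               tolerance = 1e-4)
})

test_that("equilibrium detection flags constant but not drifting series", {
  fake <- function(vals) {
    ns <- length(vals[[1]])
    y <- do.call(rbind, vals)
    structure(
      list(times = seq(0, by = 100, length.out = length(vals)),
           y = cbind(y, y),  # reuse as both p and a blocks
           ctx_dims = list(nP = ns, nA = ns, ip = seq_len(ns),
                           ia = ns + seq_len(ns))),
      class = "community_trajectory"
    )
  }
  const <- fake(replicate(11, c(1, 2), simplify = FALSE))
  expect_true(equilibrium_reached(const, window = 500))
  grow <- fake(lapply(seq(1, 2, length.out = 11), function(s) c(s, 2 * s)))
  expect_false(equilibrium_reached(grow, window = 500))
})
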