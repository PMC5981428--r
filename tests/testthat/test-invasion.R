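# a settled-looking state built by hand: everything alive, uniform alpha
manual_state <- function(net, p = NULL, a = NULL) {
  p <- p %||% rep(1, net$n_plants)
  a <- a %||% rep(0.1, net$n_animals)
  community_state(10000, p, a, rep(0.6, net$n_plants), uniform_alpha(net))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# network whose animal degrees are exactly `degs`
net_with_animal_degrees <- function(degs) {
  nP <- max(degs)
  edges <- do.call(rbind, lapply(seq_along(degs), function(j) {
    data.frame(plant = seq_len(degs[j]), animal = j)
  }))
  bipartite_network(nP, length(degs), edges)
}

test_that("alien degree follows the 30% generality rule", {
  net <- net_with_animal_degrees(c(1, 1, 2, 4, 6, 8, 10, 10, 12, 14))
  st <- manual_state(net)
  expect_equal(alien_degree(net, st, generalist = TRUE), 12)
  expect_equal(alien_degree(net, st, generalist = FALSE), 1)
  all1 <- net_with_animal_degrees(rep(1, 5))
  expect_equal(alien_degree(all1, manual_state(all1), TRUE), 1)
  dead <- manual_state(net)
  dead$alive_a[] <- FALSE
  expect_error(alien_degree(net, dead, TRUE), "no living pollinators")
})

test_that("attachment picks partners by connectivity rule", {
  # plant degrees 5, 3, 1
  edges <- data.frame(
    plant = c(rep(1, 5), rep(2, 3), 3),
    animal = c(1:5, 1:3, 1)
  )
  net <- bipartite_network(3, 5, edges)
  st <- manual_state(net)
  set.seed(47)
  expect_equal(attach_alien(net, st, 1, "most_connected"), 1L)
  expect_equal(attach_alien(net, st, 1, "least_connected"), 3L)
  expect_equal(attach_alien(net, st, 3, "random"), c(1L, 2L, 3L))
  expect_error(attach_alien(net, st, 4, "random"), "exceeds")
})

test_that("random attachment is uniform over equal-degree plants", {
  edges <- data.frame(plant = c(1, 2, 3), animal = c(1, 1, 1))
  net <- bipartite_network(3, 1, edges)
  st <- manual_state(net)
  set.seed(53)
  picks <- replicate(6000, attach_alien(net, st, 1, "random"))
  freq <- table(factor(picks, levels = 1:3)) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.025))
})

test_that("introduction wires the alien with native-average parameters", {
  set.seed(59)
  net <- generate_network(6, 10, 0.3, 0.5)
  params <- init_parameters(net, 0.05)
  st <- manual_state(net)
  set.seed(60)
  alien <- alien_spec(6, net, st, attachment = "random")
  expect_true(alien$efficient && alien$adaptive && alien$generalist)
  intro <- introduce_alien(net, st, params, alien)
  j <- intro$alien_index
  newl <- (nrow(net$edges) + 1):nrow(intro$net$edges)
  expect_equal(intro$net$n_animals, net$n_animals + 1)
  expect_equal(unique(intro$params$links$tau[newl]), 2)   # efficient: 2x
  expect_equal(unique(intro$params$links$c[newl]), mean(params$links$c))
  expect_equal(unique(intro$params$links$b[newl]), mean(params$links$b))
  expect_equal(unique(intro$params$links$e[newl]), mean(params$links$e))
  expect_equal(intro$state$a[j], 1.5e-3)
  expect_equal(intro$state$alpha[newl], rep(1 / alien$degree, alien$degree))
  expect_equal(intro$params$animals$mu_a[j], 0.05)
  # average forager keeps tau at the native mean
  set.seed(60)
  avg <- introduce_alien(net, st, params, alien_spec(5, net, st))
  newl2 <- (nrow(net$edges) + 1):nrow(avg$net$edges)
  expect_equal(unique(avg$params$links$tau[newl2]), 1)
})

test_that("specialist aliens have one partner and never adapt", {
  types <- alien_types()
  expect_false(any(types$adaptive[!types$generalist]))
  set.seed(61)
  net <- generate_network(6, 10, 0.3, 0.5)
  st <- manual_state(net)
  for (ty in 1:2) {
    al <- alien_spec(ty, net, st)
    expect_equal(al$degree, 1L)
    expect_false(al$adaptive)
  }
})

test_that("a zero-density alien leaves native derivatives bit-identical", {
  set.seed(67)
  net <- generate_network(5, 8, 0.35, 0.5)
  params <- init_parameters(net, 0.05)
  st <- manual_state(net)
  base <- community_rhs(st, params, net)
  set.seed(68)
  alien <- alien_spec(4, net, st)
  alien$initial_density <- 0
  intro <- introduce_alien(net, st, params, alien)
  ext <- community_rhs(intro$state, intro$params, intro$net)
  nat <- seq_len(net$n_animals)
  expect_identical(ext$dp, base$dp)
  expect_identical(ext$dR, base$dR)
  expect_identical(ext$da[nat], base$da)
  expect_identical(ext$da[intro$alien_index], 0)
  # and trajectories agree through the integrator at its own accuracy
  t1 <- integrate_community(st, params, net, 10500, prune_dt = 100)
  t2 <- integrate_community(intro$state, intro$params, intro$net, 10500,
                            prune_dt = 100)
  expect_equal(t2$state$p, t1$state$p, tolerance = 1e-8)
  expect_equal(t2$state$a[nat], t1$state$a, tolerance = 1e-8)
})

test_that("outcome classification follows the density thresholds", {
  expect_equal(classify_outcome(9e-4), "unsuccessful")
  expect_equal(classify_outcome(1.2e-3), "naturalized")
  expect_equal(classify_outcome(0.7), "invader")
  # ever dipping below the threshold is fatal even if the end is high
  expect_equal(classify_outcome(0.7, min_density = 5e-4), "unsuccessful")
  # the band edge tolerates integrator-level drift above the initial value
  expect_equal(classify_outcome(1.5005e-3), "naturalized")
  err <- tryCatch(classify_outcome(0.1), condition = identity)
  expect_s3_class(err, "pollinvade_gap_outcome")
})
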