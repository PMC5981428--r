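test_that("jaccard similarity handles the canonical cases", {
  expect_equal(jaccard_similarity(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(jaccard_similarity(1:4, 1:4), 1)
  expect_equal(jaccard_similarity(1:2, 3:4), 0)
  expect_error(jaccard_similarity(integer(0), integer(0)), "undefined")
})

test_that("horn overlap matches the 1966 entropy formula", {
  expect_equal(horn_overlap(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(horn_overlap(c(1, 0), c(0, 1)), 0)
  # hand evaluation for (.5,.5,0) vs (0,.5,.5):
  # numerator  = sum((x+y)log(x+y)) - sum(x log x) - sum(y log y)
  #            = (.5 log .5 + 1 log 1 + .5 log .5) - log .5 - log .5 = log 2
  # denominator = 2 log 2  ->  0.5
  expect_equal(horn_overlap(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  expect_error(horn_overlap(c(0, 0), c(1, 0)), "undefined")
})

test_that("similarity indices are symmetric", {
  set.seed(71)
  for (k in 1:20) {
    a <- sample(10, sample(1:6, 1))
    b <- sample(10, sample(1:6, 1))
    expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
    x <- runif(5)
    y <- runif(5)
    expect_equal(horn_overlap(x, y), horn_overlap(y, x))
  }
})

test_that("the normalized effect measure behaves as specified", {
  expect_equal(effect_size(1, 1), 0)
  expect_equal(effect_size(1, 0), 1)
  expect_equal(effect_size(2, 1), 1 / 3)
  expect_equal(effect_size(0, 0), 0)
  expect_error(effect_size(-1, 1), "non-negative")
  set.seed(73)
  a <- runif(50, 0, 10)
  b <- runif(50, 0, 10)
  expect_equal(effect_size(a, b), -effect_size(b, a))
  expect_true(all(abs(effect_size(a, b)) <= 1))
})

test_that("persistence is the surviving fraction of the initial set", {
  expect_equal(persistence(rep(TRUE, 4), rep(TRUE, 4)), 1)
  expect_equal(persistence(rep(TRUE, 4), rep(FALSE, 4)), 0)
  expect_equal(persistence(rep(TRUE, 4), c(TRUE, TRUE, TRUE, FALSE)), 0.75)
})

test_that("network properties are right on a complete 2x2 community", {
  net <- bipartite_network(2, 2, data.frame(plant = c(1, 1, 2, 2),
                                            animal = c(1, 2, 1, 2)))
  st <- community_state(1e4, c(1, 1), c(0.1, 0.1), c(0.5, 0.5),
                        rep(0.5, 4))
  set.seed(79)
  pr <- network_properties(net, st)
  expect_equal(ncol(pr), 23)
  expect_equal(pr$net_connectance, 1)
  expect_equal(pr$net_plant_frac_single, 0)
  expect_equal(pr$net_plant_gen_link_frac, 0.5)
  expect_equal(pr$net_jacc_an_mean, 1)
  expect_equal(pr$net_horn_an_mean, 1)
  # a saturated network has no null variation; its score is undefined
  expect_true(is.na(pr$net_nodfst))
})

test_that("the most-generalist plant of a star holds its link share", {
  # plant 1 linked to all 4 animals, plant 2 to one: share 4/5
  edges <- data.frame(plant = c(1, 1, 1, 1, 2), animal = c(1, 2, 3, 4, 1))
  net <- bipartite_network(2, 4, edges)
  st <- community_state(1e4, c(1, 1), rep(0.1, 4), c(0.5, 0.5),
                        uniform_alpha(net))
  set.seed(83)
  pr <- network_properties(net, st)
  expect_equal(pr$net_plant_gen_link_frac, 4 / 5)
  expect_equal(pr$net_animal_frac_single, 3 / 4)
})

test_that("degree-heterogeneity stats match brute-force recomputation", {
  set.seed(89)
  for (k in 1:10) {
    net <- generate_network(5, 5, 0.5, runif(1))
    st <- community_state(1e4, rep(1, 5), rep(0.1, 5), rep(0.5, 5),
                          uniform_alpha(net))
    set.seed(100 + k)
    pr <- network_properties(net, st)
    deg_a <- tabulate(net$edges$animal, 5)
    L <- nrow(net$edges)
    expect_equal(pr$net_animal_degree_sd_norm, sd(deg_a) / (L / 5))
    deg_p <- tabulate(net$edges$plant, 5)
    expect_equal(pr$net_plant_degree_sd_norm, sd(deg_p) / (L / 5))
    expect_equal(pr$net_plant_frac_single, mean(deg_p == 1))
  }
})

test_that("network properties are invariant to species relabelling", {
  set.seed(97)
  net <- generate_network(6, 9, 0.3, 0.8)
  st <- community_state(1e4, runif(6, 0.5, 1), runif(9, 0.05, 0.3),
                        rep(0.6, 6), uniform_alpha(net))
  perm_p <- sample(6)
  perm_a <- sample(9)
  net2 <- bipartite_network(6, 9,
    data.frame(plant = perm_p[net$edges$plant],
               animal = perm_a[net$edges$animal]))
  # permute the state consistently; alpha rows follow the new edge order
  map <- match(
    paste(perm_p[net$edges$plant], perm_a[net$edges$animal]),
    paste(net2$edges$plant, net2$edges$animal)
  )
  alpha2 <- numeric(nrow(net2$edges))
  alpha2[map] <- st$alpha
  p2 <- numeric(6); p2[perm_p] <- st$p
  r2 <- numeric(6); r2[perm_p] <- st$R
  a2 <- numeric(9); a2[perm_a] <- st$a
  st2 <- community_state(1e4, p2, a2, r2, alpha2)
  set.seed(1); pr1 <- network_properties(net, st)
  set.seed(1); pr2 <- network_properties(net2, st2)
  expect_equal(pr1, pr2, tolerance = 1e-12)
})

test_that("response variables: totals, hand value, and sigma bound", {
  # single-link system: visitation = alpha * tau * a * p
  toy <- toy_community(data.frame(plant = 1, animal = 1), 1, 1)
  st <- community_state(0, 0.8, 0.3, 0.6, 1)
  rv <- response_variables(st, toy$params, toy$net)
  expect_equal(rv$visitation, 1 * 1 * 0.3 * 0.8)
  expect_equal(rv$pollination, rv$visitation)  # sigma = 1 with one plant
  expect_equal(rv$plant_density, 0.8)
  expect_equal(rv$rewards, 0.6)
  # empty community
  st0 <- community_state(0, 0, 0, 0, 0)
  rv0 <- response_variables(st0, toy$params, toy$net)
  expect_true(all(unlist(rv0) == 0))
  # pollination never exceeds visitation
  set.seed(101)
  net <- generate_network(5, 8, 0.4, 0.5)
  params <- init_parameters(net, 0.05)
  stl <- init_state(net, params)
  rvl <- response_variables(stl, params, net)
  expect_lte(rvl$pollination, rvl$visitation)
})

test_that("alien properties report the eight recorded traits", {
  set.seed(103)
  net <- generate_network(6, 9, 0.3, 0.5)
  st <- community_state(1e4, rep(1, 6), rep(0.1, 9), rep(0.6, 6),
                        uniform_alpha(net))
  al <- alien_spec(6, net, st)
  pr <- alien_properties(net, st, al, final_density = 0.8)
  expect_equal(ncol(pr), 8)
  expect_equal(pr$alien_efficiency, 2)
  expect_equal(pr$alien_degree, al$degree)
  expect_equal(pr$alien_adaptive, 1)
  expect_equal(pr$alien_final_density, 0.8)
  expect_true(pr$alien_jacc_max >= pr$alien_jacc_mean)
  expect_true(all(c(pr$alien_jacc_max, pr$alien_horn_max) <= 1))
})
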