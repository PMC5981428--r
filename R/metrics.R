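#' Jaccard similarity of two partner sets
#'
#' `|A intersect B| / |A union B|`. Used for qualitative diet overlap
#' between two pollinators (shared plant partners) or two plants (shared
#' pollinators).
#'
#' @param a,b Vectors of partner indices; at least one must be non-empty.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  un <- length(union(a, b))
  if (un == 0) stop("similarity of two empty sets is undefined",
                    call. = FALSE)
  length(intersect(a, b)) / un
}

#' Horn's information-theoretic overlap of two preference distributions
#'
#' Horn's (1966) index of community overlap applied to two foraging
#' preference vectors over the same plant axis. For distributions `x`, `y`
#' normalised to sum 1 it equals
#' `(H(x) + H(y) - ... )` in its entropy form:
#' `[sum((x+y) log(x+y)) - sum(x log x) - sum(y log y)] / (2 log 2)`,
#' with `0 log 0 = 0`. Identical distributions give 1, distributions with
#' disjoint support give 0.
#'
#' @param x,y Non-negative numeric vectors of equal length, each with a
#'   positive sum (normalised internally).
#' @return Overlap in `[0, 1]`.
#' @export
horn_overlap <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sum(x) <= 0 || sum(y) <= 0) {
    stop("overlap of a zero preference vector is undefined", call. = FALSE)
  }
  x <- x / sum(x)
  y <- y / sum(y)
  xlogx <- function(v) sum(v[v > 0] * log(v[v > 0]))
  (xlogx(x + y) - xlogx(x) - xlogx(y)) / (2 * log(2))
}

#' Normalized before-after effect measure
#'
#' `E = (A - B) / (A + B)` for non-negative response values after (`A`) and
#' before (`B`) an introduction; defined as 0 when both are 0. The
#' denominator damps the inflation that ratios suffer when the baseline is
#' close to zero. Antisymmetric in its arguments and bounded in `[-1, 1]`.
#'
#' @param after,before Non-negative response values.
#' @return Effect in `[-1, 1]`.
#' @export
effect_size <- function(after, before) {
  if (any(after < 0) || any(before < 0)) {
    stop("effect measure requires non-negative inputs", call. = FALSE)
  }
  s <- after + before
  ifelse(s == 0, 0, (after - before) / s)
}

#' Fraction of species persisting between two states
#'
#' @param alive_before,alive_after Logical persistence masks over the same
#'   species set.
#' @return `|alive after & alive before| / |alive before|` (1 if nothing
#'   was alive before).
#' @export
persistence <- function(alive_before, alive_after) {
  stopifnot(length(alive_before) == length(alive_after))
  n0 <- sum(alive_before)
  if (n0 == 0) return(1)
  sum(alive_before & alive_after) / n0
}

# least-squares slope of the log-log complementary cumulative degree
# distribution; a deterministic summary of degree-distribution shape
degree_ccdf_exponent <- function(deg) {
  deg <- deg[deg > 0]
  ks <- sort(unique(deg))
  ccdf <- vapply(ks, function(k) mean(deg >= k), numeric(1))
  if (length(ks) < 2) return(NA_real_)
  stats::coef(stats::lm(log(ccdf) ~ log(ks)))[[2]]
}

pairwise_stats <- function(items, fun) {
  n <- length(items)
  if (n < 2) return(c(max = NA_real_, mean = NA_real_))
  vals <- unlist(lapply(seq_len(n - 1), function(i) {
    vapply((i + 1):n, function(j) fun(items[[i]], items[[j]]), numeric(1))
  }))
  c(max = max(vals), mean = mean(vals))
}

guild_degree_stats <- function(deg, L, prefix) {
  n <- length(deg)
  k30 <- ceiling(0.3 * n)
  top <- sort(deg, decreasing = TRUE)[seq_len(k30)]
  out <- tibble::tibble(
    exponent = degree_ccdf_exponent(deg),
    frac_single = mean(deg == 1),
    gen_link_frac = max(deg) / L,
    gen30_mean_degree = mean(top),
    degree_sd_norm = stats::sd(deg) / (L / n)
  )
  names(out) <- paste0(prefix, "_", names(out))
  out
}

# the living sub-network of a settled community, as plain structures
living_network <- function(net, state) {
  live <- living_degrees(net, state)
  e <- net$edges[live$live_links, ]
  plants <- which(state$alive_p)
  animals <- which(state$alive_a)
  list(
    edges = e, plants = plants, animals = animals,
    plant_partners = lapply(plants, function(i) e$animal[e$plant == i]),
    animal_partners = lapply(animals, function(j) e$plant[e$animal == j])
  )
}

#' The 23 structural properties of a settled network
#'
#' Computes, on the living species only, the predictor set used to explain
#' invasion outcomes: richness `s`; animal/plant richness ratio; four
#' linkage densities (connectance, links per species, per plant, per
#' animal); five degree-heterogeneity measures for each guild (power-law
#' exponent of the complementary cumulative degree distribution, fraction
#' of single-link species, link fraction of the most-generalist species,
#' mean degree of the 30% most generalised species, and the standard
#' deviation of degrees normalised by the guild's mean degree); maxima and
#' means of pairwise Jaccard similarity within each guild; maximum and mean
#' of pairwise Horn overlap of the pollinators' foraging preferences; and
#' standardised nestedness ([nodfst()]) of the living network.
#'
#' @param net A [bipartite_network()].
#' @param state The settled `community_state` (typically at t = 10,000).
#' @param nodfst_reps Null-ensemble size for [nodfst()].
#' @return A one-row tibble with 23 columns prefixed `net_`.
#' @export
network_properties <- function(net, state, nodfst_reps = 100) {
  lv <- living_network(net, state)
  nP <- length(lv$plants)
  nA <- length(lv$animals)
  if (nP < 2 || nA < 2) {
    stop("degenerate community: fewer than 2 living species in a guild",
         call. = FALSE)
  }
  L <- nrow(lv$edges)
  deg_p <- lengths(lv$plant_partners)
  deg_a <- lengths(lv$animal_partners)

  jac_a <- pairwise_stats(lv$animal_partners, jaccard_similarity)
  jac_p <- pairwise_stats(lv$plant_partners, jaccard_similarity)
  prefs <- lapply(lv$animals, function(j) {
    sel <- net$edges$animal == j & state$alive_p[net$edges$plant]
    v <- numeric(net$n_plants)
    v[net$edges$plant[sel]] <- state$alpha[sel]
    v
  })
  prefs <- prefs[vapply(prefs, sum, numeric(1)) > 0]
  horn_a <- pairwise_stats(prefs, horn_overlap)

  live_net <- bipartite_network(
    nP, nA,
    data.frame(plant = match(lv$edges$plant, lv$plants),
               animal = match(lv$edges$animal, lv$animals))
  )

  out <- dplyr::bind_cols(
    tibble::tibble(
      s = nP + nA,
      ratio_an_pl = nA / nP,
      connectance = L / (nP * nA),
      links_per_s = L / (nP + nA),
      links_per_plant = L / nP,
      links_per_animal = L / nA
    ),
    guild_degree_stats(deg_p, L, "plant"),
    guild_degree_stats(deg_a, L, "animal"),
    tibble::tibble(
      jacc_pl_max = jac_p[["max"]], jacc_pl_mean = jac_p[["mean"]],
      jacc_an_max = jac_a[["max"]], jacc_an_mean = jac_a[["mean"]],
      horn_an_max = horn_a[["max"]], horn_an_mean = horn_a[["mean"]],
      # undefined for saturated/degenerate shapes whose null mean is 0
      nodfst = tryCatch(nodfst(live_net, nodfst_reps),
                        error = function(e) NA_real_)
    )
  )
  names(out) <- paste0("net_", names(out))
  out
}

#' The 8 recorded properties of an introduced alien
#'
#' Foraging efficiency (the alien's visitation efficiency relative to the
#' native mean: 1 for average, 2 for efficient foragers), number of
#' interactions, maxima and means of Jaccard similarity (partner sets) and
#' Horn overlap (initial uniform preferences vs the natives' settled
#' preferences) against all living native pollinators, final density, and
#' the adaptive-forager flag.
#'
#' @param net,state The settled native community (before introduction).
#' @param alien An [alien_spec()].
#' @param final_density Alien density at the end of the run.
#' @return A one-row tibble with 8 columns prefixed `alien_`.
#' @export
alien_properties <- function(net, state, alien, final_density = NA_real_) {
  lv <- living_network(net, state)
  jac <- vapply(lv$animal_partners, function(pp) {
    jaccard_similarity(alien$partners, pp)
  }, numeric(1))
  apref <- numeric(net$n_plants)
  apref[alien$partners] <- 1 / alien$degree
  prefs <- lapply(lv$animals, function(j) {
    sel <- net$edges$animal == j & state$alive_p[net$edges$plant]
    v <- numeric(net$n_plants)
    v[net$edges$plant[sel]] <- state$alpha[sel]
    v
  })
  keep <- vapply(prefs, sum, numeric(1)) > 0
  horn <- vapply(prefs[keep], function(v) horn_overlap(apref, v), numeric(1))
  tibble::tibble(
    alien_efficiency = 1 + as.numeric(alien$efficient),
    alien_degree = alien$degree,
    alien_jacc_max = max(jac), alien_jacc_mean = mean(jac),
    alien_horn_max = max(horn), alien_horn_mean = mean(horn),
    alien_final_density = final_density,
    alien_adaptive = as.numeric(alien$adaptive)
  )
}

#' Community-level response variables at a state
#'
#' Totals over living native species: plant density, pollinator density,
#' floral rewards, visitation (`sum V`), and pollination events
#' (`sum sigma * V`). Pass the alien's index in `exclude_animals` to
#' restrict the totals to natives after an introduction.
#'
#' @param state A `community_state`.
#' @param params,net The matching parameters and network.
#' @param exclude_animals Animal indices excluded from all totals.
#' @return A one-row tibble with columns `plant_density`, `animal_density`,
#'   `rewards`, `visitation`, `pollination`.
#' @export
response_variables <- function(state, params, net,
                               exclude_animals = integer(0)) {
  rhs <- community_rhs(state, params, net)
  keep_l <- !(rhs$rates$animal %in% exclude_animals)
  keep_a <- setdiff(seq_along(state$a), exclude_animals)
  tibble::tibble(
    plant_density = sum(state$p),
    animal_density = sum(state$a[keep_a]),
    rewards = sum(state$R),
    visitation = sum(rhs$rates$V[keep_l]),
    pollination = sum(rhs$rates$sigma[keep_l] * rhs$rates$V[keep_l])
  )
}
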