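#' Bipartite plant-pollinator network objects
#'
#' A `bipartite_network` is a binary interaction structure between `n_plants`
#' plant species and `n_animals` pollinator (animal) species. Links are stored
#' as an edge table with 1-based, dense species indices. Every species has at
#' least one link and connectance is `C = L / (n_plants * n_animals)`.
#'
#' @param n_plants,n_animals Number of plant and animal species.
#' @param edges A data frame with integer columns `plant` and `animal`.
#' @param pnest Optional generation parameter recorded as metadata.
#'
#' @return An object of class `bipartite_network`: a list with elements
#'   `n_plants`, `n_animals`, `edges` (a tibble) and `pnest`.
#' @export
bipartite_network <- function(n_plants, n_animals, edges, pnest = NA_real_) {
  edges <- tibble::tibble(
    plant = as.integer(edges$plant),
    animal = as.integer(edges$animal)
  )
  net <- structure(
    list(
      n_plants = as.integer(n_plants),
      n_animals = as.integer(n_animals),
      edges = edges,
      pnest = pnest
    ),
    class = "bipartite_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  e <- net$edges
  if (nrow(e) == 0L) stop("network has no links", call. = FALSE)
  if (any(e$plant < 1L | e$plant > net$n_plants) ||
      any(e$animal < 1L | e$animal > net$n_animals)) {
    stop("edge indices out of range", call. = FALSE)
  }
  if (anyDuplicated(paste(e$plant, e$animal))) {
    stop("duplicate links in network", call. = FALSE)
  }
  if (length(unique(e$plant)) < net$n_plants ||
      length(unique(e$animal)) < net$n_animals) {
    stop("network contains isolated species", call. = FALSE)
  }
  invisible(net)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %d plants x %d animals, %d links (C = %.3f)\n",
    x$n_plants, x$n_animals, nrow(x$edges), connectance(x)
  ))
  invisible(x)
}

#' @rdname bipartite_network
#' @param x,net A `bipartite_network`.
#' @export
connectance <- function(net) {
  nrow(net$edges) / (net$n_plants * net$n_animals)
}

#' Incidence matrix of a bipartite network
#'
#' @param net A `bipartite_network`.
#' @return A binary `n_plants` x `n_animals` matrix.
#' @export
as_incidence <- function(net) {
  m <- matrix(0L, net$n_plants, net$n_animals)
  m[cbind(net$edges$plant, net$edges$animal)] <- 1L
  m
}

#' @importFrom generics tidy
#' @export
tidy.bipartite_network <- function(x, ...) {
  e <- x$edges
  e$plant_degree <- tabulate(e$plant, x$n_plants)[e$plant]
  e$animal_degree <- tabulate(e$animal, x$n_animals)[e$animal]
  e
}

#' @importFrom generics glance
#' @export
glance.bipartite_network <- function(x, ...) {
  dp <- tabulate(x$edges$plant, x$n_plants)
  da <- tabulate(x$edges$animal, x$n_animals)
  tibble::tibble(
    n_plants = x$n_plants,
    n_animals = x$n_animals,
    n_links = nrow(x$edges),
    connectance = connectance(x),
    mean_plant_degree = mean(dp),
    mean_animal_degree = mean(da),
    nodf = nodf(x)
  )
}

#' Sample species interaction weights from a truncated power law
#'
#' Draws i.i.d. weights from a continuous power-law density proportional to
#' `x^exponent`, truncated to `[xmin, xmax]`, by inversion of the CDF. These
#' weights play the role of per-species interaction probabilities: a few
#' species receive large weights (generalists) while most receive small ones
#' (specialists). Weights are not normalised; normalisation happens at
#' partner choice.
#'
#' @param n Number of species.
#' @param exponent Power-law exponent, must be `< -1`. Default -2.
#' @param xmin,xmax Truncation bounds of the support.
#' @return A numeric vector of `n` positive weights.
#' @export
rpowerlaw_weights <- function(n, exponent = -2, xmin = 0.01, xmax = 1) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (exponent >= -1) stop("exponent must be < -1", call. = FALSE)
  a1 <- exponent + 1
  u <- stats::runif(n)
  (u * (xmax^a1 - xmin^a1) + xmin^a1)^(1 / a1)
}

# Integer quotas proportional to weights: max(1, round(w * L / sum(w))),
# capped at `cap`, then adjusted to sum exactly to L by adding links to the
# highest-weight species with spare capacity and removing from the
# lowest-weight species with more than one link.
degree_quotas <- function(weights, L, cap) {
  n <- length(weights)
  if (L < n) stop("infeasible: fewer links than species", call. = FALSE)
  if (L > n * cap) stop("infeasible: more links than cells", call. = FALSE)
  q <- pmin(cap, pmax(1L, round(weights * L / sum(weights))))
  ord <- order(weights, decreasing = TRUE)
  while (sum(q) < L) {
    i <- ord[which(q[ord] < cap)[1L]]
    q[i] <- q[i] + 1L
  }
  ord_inc <- order(weights)
  while (sum(q) > L) {
    i <- ord_inc[which(q[ord_inc] > 1L)[1L]]
    q[i] <- q[i] - 1L
  }
  as.integer(q)
}

#' Generate a bipartite network with power-law degrees and tunable nestedness
#'
#' Implements a stochastic generation scheme in which every species first
#' receives an interaction weight drawn from a truncated power law with
#' exponent -2 ([rpowerlaw_weights()]), producing few generalists and many
#' specialists. Animal species receive integer link quotas proportional to
#' their weights (minimum one link, adjusted to hit the target link count
#' exactly). Each link's plant partner is then chosen sequentially: with
#' probability `pnest` proportionally to the plants' weights, otherwise
#' uniformly. High `pnest` concentrates links on high-weight plants and
#' therefore yields more-nested networks. Isolated plants are repaired by
#' reassigning a link from a plant with two or more links, preserving both
#' the link count and all animal degrees.
#'
#' @param n_plants,n_animals Species richness of each guild.
#' @param connectance Target connectance; the realised value equals
#'   `round(connectance * n_plants * n_animals)` links.
#' @param pnest Probability in `[0, 1]` that a partner is chosen
#'   preferentially by weight rather than uniformly.
#' @param max_attempts Redraw cap per link before generation fails.
#' @return A [bipartite_network()].
#' @export
generate_network <- function(n_plants, n_animals, connectance, pnest,
                             max_attempts = 1e4) {
  stopifnot(n_plants >= 1, n_animals >= 1, pnest >= 0, pnest <= 1)
  L <- round(connectance * n_plants * n_animals)
  if (L < max(n_plants, n_animals)) {
    stop("infeasible spec: target links fewer than species in a guild",
         call. = FALSE)
  }
  w_p <- rpowerlaw_weights(n_plants)
  w_a <- rpowerlaw_weights(n_animals)
  quota <- degree_quotas(w_a, L, cap = n_plants)

  prob_p <- w_p / sum(w_p)
  plant_of <- integer(L)
  animal_of <- integer(L)
  pos <- 0L
  for (j in seq_len(n_animals)) {
    chosen <- integer(0)
    for (s in seq_len(quota[j])) {
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > max_attempts) {
          stop("network generation failed: too many duplicate redraws",
               call. = FALSE)
        }
        cand <- if (stats::runif(1) < pnest) {
          sample.int(n_plants, 1L, prob = prob_p)
        } else {
          sample.int(n_plants, 1L)
        }
        if (!(cand %in% chosen)) break
      }
      chosen <- c(chosen, cand)
    }
    idx <- pos + seq_len(quota[j])
    plant_of[idx] <- chosen
    animal_of[idx] <- j
    pos <- pos + quota[j]
  }

  # repair isolated plants without touching animal degrees or L
  deg_p <- tabulate(plant_of, n_plants)
  for (orphan in which(deg_p == 0L)) {
    donors <- which(deg_p[plant_of] >= 2L)
    take <- donors[sample.int(length(donors), 1L)]
    deg_p[plant_of[take]] <- deg_p[plant_of[take]] - 1L
    plant_of[take] <- orphan
    deg_p[orphan] <- 1L
  }

  bipartite_network(
    n_plants, n_animals,
    data.frame(plant = plant_of, animal = animal_of),
    pnest = pnest
  )
}

#' Nestedness based on overlap and decreasing fill (NODF)
#'
#' Computes the standard NODF score of a binary incidence matrix: for every
#' ordered pair of rows (and of columns) in which the first member has
#' strictly larger degree, the pair contributes the percentage of the
#' smaller-degree member's partners that are shared; pairs with equal degree
#' contribute zero. The score averages the contributions over all row pairs
#' and column pairs and lies in `[0, 100]`.
#'
#' @param net A [bipartite_network()] or a binary incidence matrix.
#' @return NODF score in `[0, 100]`; 0 for matrices with a single row and
#'   column.
#' @export
nodf <- function(net) {
  m <- if (inherits(net, "bipartite_network")) as_incidence(net) else net
  nodf_axis <- function(m) {
    n <- nrow(m)
    if (n < 2L) return(c(0, 0))
    d <- rowSums(m)
    ov <- tcrossprod(m)              # shared partners per row pair
    contrib <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        hi <- max(d[i], d[j]); lo <- min(d[i], d[j])
        if (hi > lo && lo > 0) {
          contrib <- contrib + 100 * ov[i, j] / lo
        }
      }
    }
    c(contrib, n * (n - 1) / 2)
  }
  rows <- nodf_axis(m)
  cols <- nodf_axis(t(m))
  denom <- rows[2] + cols[2]
  if (denom == 0) return(0)
  (rows[1] + cols[1]) / denom
}

# Null-ensemble NODF means are cached per (n_plants, n_animals, L) so that
# repeated standardisation over an ensemble of same-shape networks is cheap.
.nodf_null_cache <- new.env(parent = emptyenv())

null_nodf_mean <- function(n_plants, n_animals, L, null_reps) {
  key <- paste(n_plants, n_animals, L, null_reps, sep = "_")
  if (!is.null(.nodf_null_cache[[key]])) return(.nodf_null_cache[[key]])
  conn <- L / (n_plants * n_animals)
  vals <- vapply(seq_len(null_reps), function(k) {
    nodf(generate_network(n_plants, n_animals, conn, pnest = 0))
  }, numeric(1))
  m <- mean(vals)
  .nodf_null_cache[[key]] <- m
  m
}

#' Standardised nestedness against a degree-heterogeneous null ensemble
#'
#' Standardises the NODF score of a network as the proportional deviation
#' from the mean NODF of a null ensemble of networks with the same richness
#' and connectance, generated by the same stochastic algorithm with
#' `pnest = 0` (power-law degree quotas but uniform partner choice):
#' `(NODF_obs - mean(NODF_null)) / mean(NODF_null)`. Values near 0 indicate
#' nestedness no greater than expected from degree heterogeneity alone;
#' generated ensembles typically span roughly -0.33 to 2.3.
#'
#' @param net A [bipartite_network()].
#' @param null_reps Size of the null ensemble (at least 100).
#' @return The standardised nestedness score.
#' @export
nodfst <- function(net, null_reps = 100) {
  stopifnot(null_reps >= 100)
  m0 <- null_nodf_mean(net$n_plants, net$n_animals, nrow(net$edges), null_reps)
  if (m0 == 0) stop("null ensemble mean NODF is zero; score undefined",
                    call. = FALSE)
  (nodf(net) - m0) / m0
}

#' Split total richness into plant and animal guilds
#'
#' Chooses the integer split of `s` species that brings the animal-to-plant
#' ratio closest to `ratio` (the empirically observed mean of about 2.5).
#'
#' @param s Total species richness.
#' @param ratio Target animal/plant richness ratio.
#' @return A named integer vector with elements `n_plants` and `n_animals`.
#' @export
split_richness <- function(s, ratio = 2.5) {
  stopifnot(s >= 2)
  np <- seq_len(s - 1L)
  best <- np[which.min(abs((s - np) / np - ratio))]
  c(n_plants = best, n_animals = s - best)
}

#' Default richness/connectance classes
#'
#' Three combinations of species richness and connectance mirroring the
#' empirically observed inverse richness-connectance relationship.
#'
#' @return A tibble with columns `s` and `c`.
#' @export
network_classes <- function() {
  tibble::tibble(s = c(40L, 90L, 200L), c = c(0.25, 0.15, 0.06))
}

#' Generate an ensemble of networks across richness/connectance classes
#'
#' For each class, generates `n_per_class` networks with richness and
#' connectance jittered uniformly within +/- `jitter` of the class targets
#' and total richness split between guilds at an animal/plant ratio of about
#' `ratio`. Half of the networks in each class are generated with
#' `pnest = pnest_nested` (nested), the other half with `pnest = pnest_random`.
#'
#' @param classes A data frame with columns `s` and `c`; defaults to
#'   [network_classes()].
#' @param n_per_class Networks per class.
#' @param pnest_nested,pnest_random `pnest` used for the nested and
#'   non-nested halves.
#' @param jitter Relative half-width of the uniform jitter on `s` and `c`.
#' @param ratio Target animal/plant richness ratio.
#' @param seed Optional RNG seed.
#' @return A tibble with one row per network: class targets, realised
#'   `n_plants`, `n_animals`, `connectance`, `pnest`, logical `nested`, and a
#'   list-column `network` of [bipartite_network()] objects.
#' @export
generate_ensemble <- function(classes = network_classes(), n_per_class,
                              pnest_nested = 1, pnest_random = 0,
                              jitter = 0.1, ratio = 2.5, seed = NULL) {
  stopifnot(n_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::pmap(classes, function(s, c) {
    purrr::map(seq_len(n_per_class), function(k) {
      nested <- k <= n_per_class / 2
      s_k <- round(s * stats::runif(1, 1 - jitter, 1 + jitter))
      c_k <- c * stats::runif(1, 1 - jitter, 1 + jitter)
      guilds <- split_richness(s_k, ratio)
      pn <- if (nested) pnest_nested else pnest_random
      net <- generate_network(guilds[["n_plants"]], guilds[["n_animals"]],
                              c_k, pn)
      tibble::tibble(
        class_s = s, class_c = c,
        n_plants = net$n_plants, n_animals = net$n_animals,
        n_links = nrow(net$edges),
        connectance = connectance(net),
        pnest = pn, nested = nested,
        network = list(net)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$network_id <- seq_len(nrow(out))
  dplyr::relocate(out, "network_id")
}

#' Write / read a network as a CSV edge list with a JSON sidecar
#'
#' The edge list has header `plant_id,animal_id`; the sidecar records
#' `n_plants`, `n_animals` and `pnest`.
#'
#' @param net A [bipartite_network()].
#' @param path Path of the CSV file; the sidecar is `<path>.json`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [bipartite_network()].
#' @export
write_network <- function(net, path) {
  utils::write.csv(
    data.frame(plant_id = net$edges$plant, animal_id = net$edges$animal),
    path, row.names = FALSE, quote = FALSE
  )
  meta <- list(n_plants = net$n_plants, n_animals = net$n_animals,
               pnest = net$pnest)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  e <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bipartite_network(meta$n_plants, meta$n_animals,
                    data.frame(plant = e$plant_id, animal = e$animal_id),
                    pnest = meta$pnest %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
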