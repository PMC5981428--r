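#' The six alien pollinator types
#'
#' Aliens differ in three binary traits: foraging breadth (specialist vs
#' generalist), visitation efficiency (average vs efficient, i.e. visiting
#' twice as many flowers per unit time as the native average), and adaptive
#' foraging. Specialists visit a single plant species and therefore cannot
#' forage adaptively, so only six of the eight combinations exist:
#' 1 specialist, 2 efficient specialist, 3 generalist, 4 efficient
#' generalist, 5 adaptive generalist, 6 adaptive efficient generalist.
#'
#' @return A tibble with columns `type_id`, `generalist`, `efficient`,
#'   `adaptive`.
#' @export
alien_types <- function() {
  tibble::tibble(
    type_id = 1:6,
    generalist = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    efficient = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    adaptive = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

# degrees of living species in the living network
living_degrees <- function(net, state) {
  live <- state$alive_p[net$edges$plant] & state$alive_a[net$edges$animal]
  list(
    plant = tabulate(net$edges$plant[live], net$n_plants),
    animal = tabulate(net$edges$animal[live], net$n_animals),
    live_links = live
  )
}

#' Number of plant partners assigned to an alien
#'
#' Generalist aliens receive the rounded mean degree of the 30% most
#' generalised living native pollinators; specialist aliens always receive
#' one link (and the 30% most specialised natives define that same rule's
#' lower tail). The 30% subset is `ceiling(0.3 * n)` pollinators so it is
#' never empty.
#'
#' @param net A [bipartite_network()].
#' @param state Settled `community_state`.
#' @param generalist Logical; alien foraging breadth.
#' @return Integer degree, at least 1.
#' @export
alien_degree <- function(net, state, generalist) {
  deg <- living_degrees(net, state)$animal[state$alive_a]
  if (length(deg) == 0) stop("no living pollinators in community",
                             call. = FALSE)
  if (!generalist) return(1L)
  k <- ceiling(0.3 * length(deg))
  top <- sort(deg, decreasing = TRUE)[seq_len(k)]
  max(1L, as.integer(round(mean(top))))
}

#' Choose the plant partners of an alien pollinator
#'
#' @param net A [bipartite_network()].
#' @param state Settled `community_state`.
#' @param degree Number of partners to choose among living plants.
#' @param attachment One of `"most_connected"` (top-degree living plants,
#'   ties broken uniformly at random), `"least_connected"` (bottom-degree),
#'   or `"random"` (uniform without replacement, independent of degree).
#' @return Integer vector of plant indices.
#' @export
attach_alien <- function(net, state, degree,
                         attachment = c("random", "most_connected",
                                        "least_connected")) {
  attachment <- match.arg(attachment)
  live <- which(state$alive_p)
  if (degree > length(live)) {
    stop("alien degree exceeds number of living plants", call. = FALSE)
  }
  deg <- living_degrees(net, state)$plant[live]
  tie <- stats::runif(length(live))
  idx <- switch(attachment,
    most_connected = live[order(-deg, tie)][seq_len(degree)],
    least_connected = live[order(deg, tie)][seq_len(degree)],
    random = live[sample.int(length(live), degree)]
  )
  sort(as.integer(idx))
}

#' Build the specification of one alien introduction
#'
#' Combines the type's trait flags with the degree rule ([alien_degree()])
#' and an attachment algorithm ([attach_alien()]).
#'
#' @param type_id Alien type, 1-6 (see [alien_types()]).
#' @param net,state Settled community.
#' @param attachment Attachment algorithm passed to [attach_alien()].
#' @param initial_density Alien starting density (default `1.5e-3`, just
#'   above the `1e-3` extinction threshold).
#' @return An `alien_spec` list: `type_id`, trait flags, `degree`,
#'   `partners`, `attachment`, `initial_density`.
#' @export
alien_spec <- function(type_id, net, state, attachment = "random",
                       initial_density = 1.5e-3) {
  traits <- alien_types()[alien_types()$type_id == type_id, ]
  if (nrow(traits) != 1) stop("unknown alien type", call. = FALSE)
  degree <- alien_degree(net, state, traits$generalist)
  partners <- attach_alien(net, state, degree, attachment)
  structure(
    list(
      type_id = as.integer(type_id),
      generalist = traits$generalist, efficient = traits$efficient,
      adaptive = traits$adaptive,
      degree = degree, partners = partners,
      attachment = attachment, initial_density = initial_density
    ),
    class = "alien_spec"
  )
}

#' @export
print.alien_spec <- function(x, ...) {
  cat(sprintf(
    "<alien_spec> type %d (%s%s%s), %d partner(s) via %s\n",
    x$type_id,
    if (x$generalist) "generalist" else "specialist",
    if (x$efficient) ", efficient" else "",
    if (x$adaptive) ", adaptive" else "",
    x$degree, x$attachment
  ))
  invisible(x)
}

#' Add an alien pollinator to a settled community
#'
#' Extends the network, parameter set and state with one pollinator node.
#' The alien's per-link parameters (`c`, `b`, `e`) and its mortality and
#' adaptation rate equal the averages over native links/pollinators; its
#' visitation efficiency `tau` equals the native mean, doubled for
#' efficient aliens. Its foraging preferences start uniform over its
#' partners and stay frozen unless the alien is adaptive. The alien starts
#' at `alien$initial_density`.
#'
#' @param net,state,params The settled community.
#' @param alien An [alien_spec()].
#' @return A list with the extended `net`, `params`, `state`, the
#'   `alien_index` of the new pollinator, and `alien`.
#' @export
introduce_alien <- function(net, state, params, alien) {
  j <- net$n_animals + 1L
  new_edges <- rbind(
    as.data.frame(net$edges),
    data.frame(plant = alien$partners, animal = j)
  )
  net2 <- bipartite_network(net$n_plants, j, new_edges, pnest = net$pnest)
  k <- alien$degree
  links2 <- dplyr::bind_rows(
    params$links,
    tibble::tibble(
      tau = mean(params$links$tau) * (1 + alien$efficient),
      c = mean(params$links$c),
      b = mean(params$links$b),
      e = mean(params$links$e),
      .rows = k
    )
  )
  animals2 <- dplyr::bind_rows(
    params$animals,
    tibble::tibble(
      mu_a = mean(params$animals$mu_a),
      G = mean(params$animals$G),
      adaptive = alien$adaptive
    )
  )
  params2 <- structure(
    list(plants = params$plants, animals = animals2, links = links2),
    class = "community_params"
  )
  state2 <- community_state(
    state$time,
    state$p, c(state$a, alien$initial_density),
    state$R, c(state$alpha, rep(1 / k, k)),
    alive_p = state$alive_p, alive_a = c(state$alive_a, TRUE)
  )
  list(net = net2, params = params2, state = state2,
       alien_index = j, alien = alien)
}

#' Classify the outcome of an introduction
#'
#' An alien whose density ever fell below the extinction threshold is
#' `unsuccessful` (it is pruned and removed from the network). A surviving
#' alien whose final density stays between the threshold (`1e-3`) and its
#' initial density (`1.5e-3`) is `naturalized`; one whose final density
#' exceeds 0.5 (over 333 times its initial density) is an `invader`. Final
#' densities in the open gap `(1.5e-3, 0.5]` are not observed in the
#' simulation design; they raise a classed error
#' (`pollinvade_gap_outcome`) so callers can log them rather than silently
#' bin them.
#'
#' @param final_density Alien density at the end of the run.
#' @param min_density Minimum alien density observed along the run
#'   (defaults to `final_density`).
#' @param threshold,initial_density,invader_density The three cut-offs.
#' @param band_tol Relative tolerance on the naturalized band's upper edge.
#'   A neutral alien sits exactly at its initial density, so finite
#'   integrator accuracy can leave it a hair's breadth above it; densities
#'   within `initial_density * (1 + band_tol)` still count as naturalized.
#' @return One of `"unsuccessful"`, `"naturalized"`, `"invader"`.
#' @export
classify_outcome <- function(final_density, min_density = final_density,
                             threshold = 1e-3, initial_density = 1.5e-3,
                             invader_density = 0.5, band_tol = 0.01) {
  if (min_density < threshold || final_density < threshold) {
    return("unsuccessful")
  }
  if (final_density <= initial_density * (1 + band_tol)) {
    return("naturalized")
  }
  if (final_density > invader_density) return("invader")
  stop(structure(
    class = c("pollinvade_gap_outcome", "error", "condition"),
    list(
      message = sprintf(
        "alien final density %.3g lies in the unclassifiable gap (%.3g, %.3g]",
        final_density, initial_density, invader_density
      ),
      call = NULL
    )
  ))
}
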