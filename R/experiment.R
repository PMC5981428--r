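derive_seed <- function(master, a, b = 0, d = 0) {
  x <- (master %% 2147483647) * 48271 + a * 1299709 + b * 15485863 +
    d * 32452843
  as.integer(x %% 2147483647)
}

#' Settle a native community to its pre-introduction state
#'
#' Draws the parameter set and initial state under `seed`, integrates the
#' native dynamics to `settle_t` (default 10,000 time steps, long past the
#' ~3,000 steps most networks need to equilibrate), and records everything
#' an introduction trial needs: the settled state, the before-introduction
#' response totals, per-guild persistence since t = 0, and the 23 network
#' properties of the living community.
#'
#' @param net A [bipartite_network()].
#' @param mortality Pollinator mortality rate (0.05 or 0.001 in the study
#'   design).
#' @param seed RNG seed for parameter and initial-state draws.
#' @param base Base constants, see [default_base_params()].
#' @param settle_t Settling horizon.
#' @param threshold,prune_dt,nodfst_reps Passed to [integrate_community()]
#'   and [network_properties()].
#' @return A `settled_community` list.
#' @export
settle_community <- function(net, mortality, seed,
                             base = default_base_params(),
                             settle_t = 10000, threshold = 1e-3,
                             prune_dt = 250, nodfst_reps = 100) {
  set.seed(seed)
  params <- init_parameters(net, mortality, base)
  state0 <- init_state(net, params)
  traj <- integrate_community(state0, params, net, settle_t,
                              threshold = threshold, prune_dt = prune_dt)
  state <- traj$state
  set.seed(derive_seed(seed, 999))
  props <- network_properties(net, state, nodfst_reps = nodfst_reps)
  structure(
    list(
      net = net, params = params, mortality = mortality, state = state,
      equilibrium = equilibrium_reached(traj, window = settle_t / 2),
      before = response_variables(state, params, net),
      pol_persist = persistence(rep(TRUE, net$n_animals), state$alive_a),
      pl_persist = persistence(rep(TRUE, net$n_plants), state$alive_p),
      props = props,
      threshold = threshold, prune_dt = prune_dt, settle_t = settle_t
    ),
    class = "settled_community"
  )
}

#' @export
print.settled_community <- function(x, ...) {
  cat(sprintf(
    "<settled_community> t = %g, mortality %g: %d/%d plants, %d/%d animals\n",
    x$state$time, x$mortality, sum(x$state$alive_p), x$net$n_plants,
    sum(x$state$alive_a), x$net$n_animals
  ))
  invisible(x)
}

#' Run one alien-introduction trial
#'
#' Settles the native community (or reuses a precomputed
#' [settle_community()] result), introduces one alien pollinator of the
#' requested type at t = 10,000 with density `1.5e-3`, integrates for
#' another 10,000 time steps, and records the full trial row: the 23
#' network predictors, the 8 alien predictors, the outcome class, and the
#' normalized effects `E = (A - B)/(A + B)` of the introduction on native
#' pollinator persistence, pollinator density, plant density, floral
#' rewards, visitation, and pollination events. Trials whose final alien
#' density falls in the unclassifiable gap `(1.5e-3, 0.5]` are recorded
#' with outcome `"gap"`.
#'
#' @param net A [bipartite_network()], or `NULL` if `settle` is given.
#' @param mortality Pollinator mortality rate.
#' @param type_id Alien type 1-6, see [alien_types()].
#' @param attachment `"random"`, `"most_connected"` or `"least_connected"`.
#' @param seed Trial RNG seed (alien construction).
#' @param settle Optional precomputed [settle_community()] result.
#' @param settle_seed Seed for the settling phase when `settle` is NULL
#'   (defaults to `seed`).
#' @param end_t Final time (default 20,000).
#' @param ... Passed to [settle_community()] when it is run here.
#' @return A one-row tibble.
#' @export
run_trial <- function(net = NULL, mortality = 0.05, type_id, attachment,
                      seed, settle = NULL, settle_seed = seed,
                      end_t = 20000, ...) {
  if (is.null(settle)) {
    settle <- settle_community(net, mortality, settle_seed, ...)
  }
  net <- settle$net
  set.seed(seed)
  alien <- alien_spec(type_id, net, settle$state, attachment)
  intro <- introduce_alien(net, settle$state, settle$params, alien)
  traj <- integrate_community(
    intro$state, intro$params, intro$net, end_t,
    threshold = settle$threshold, prune_dt = settle$prune_dt
  )
  j <- intro$alien_index
  final <- traj$state
  alien_final <- final$a[j]
  alien_min <- traj$min_a[j]
  outcome <- tryCatch(
    classify_outcome(alien_final, alien_min, threshold = settle$threshold,
                     initial_density = alien$initial_density),
    pollinvade_gap_outcome = function(e) "gap"
  )
  after <- response_variables(final, intro$params, intro$net,
                              exclude_animals = j)
  natives_a <- seq_len(net$n_animals)
  pol_persist_after <- persistence(rep(TRUE, net$n_animals),
                                   final$alive_a[natives_a])
  pl_persist_after <- persistence(rep(TRUE, net$n_plants), final$alive_p)

  dplyr::bind_cols(
    tibble::tibble(
      mortality = mortality, type_id = as.integer(type_id),
      attachment = attachment, seed = as.integer(seed),
      outcome = outcome,
      eff_pol_persistence = effect_size(pol_persist_after,
                                        settle$pol_persist),
      eff_pol_density = effect_size(after$animal_density,
                                    settle$before$animal_density),
      eff_pl_density = effect_size(after$plant_density,
                                   settle$before$plant_density),
      eff_rewards = effect_size(after$rewards, settle$before$rewards),
      eff_visitation = effect_size(after$visitation,
                                   settle$before$visitation),
      eff_pollination = effect_size(after$pollination,
                                    settle$before$pollination),
      pol_persist_before = settle$pol_persist,
      pol_persist_after = pol_persist_after,
      pl_persist_before = settle$pl_persist,
      pl_persist_after = pl_persist_after,
      alien_frac_plants = alien$degree / sum(settle$state$alive_p)
    ),
    settle$props,
    alien_properties(net, settle$state, alien, final_density = alien_final)
  )
}

#' The factorial introduction design
#'
#' Expands the full cross of alien types, mortality scenarios and
#' attachment algorithms over a set of networks: with all levels, 6 x 2 x 3
#' = 36 trials per network (43,200 for the full 1,200-network ensemble).
#' With `glm_subset = TRUE` the design instead assigns one trial per
#' network - alternating adaptive average (type 5) and adaptive efficient
#' (type 6) foragers, high mortality, random attachment - mirroring the
#' subset used for the linear models.
#'
#' @param network_ids Integer vector of network identifiers.
#' @param types,mortalities,attachments Design levels.
#' @param glm_subset Logical; build the linear-model subset design.
#' @return A tibble with one row per trial (`trial_id`, `network_id`,
#'   `type_id`, `mortality`, `attachment`).
#' @export
design_grid <- function(network_ids, types = 1:6,
                        mortalities = c(0.05, 0.001),
                        attachments = c("most_connected", "least_connected",
                                        "random"),
                        glm_subset = FALSE) {
  if (glm_subset) {
    g <- tibble::tibble(
      network_id = network_ids,
      type_id = rep_len(c(5L, 6L), length(network_ids)),
      mortality = 0.05,
      attachment = "random"
    )
  } else {
    g <- tidyr::expand_grid(
      network_id = network_ids,
      type_id = as.integer(types),
      mortality = mortalities,
      attachment = attachments
    )
  }
  if (anyDuplicated(g) > 0) stop("duplicate trials in design", call. = FALSE)
  g$trial_id <- seq_len(nrow(g))
  dplyr::relocate(g, "trial_id")
}

#' Run the factorial introduction experiment
#'
#' Settles each (network, mortality) combination once and runs every trial
#' of the design on the settled state. Per-trial seeds are derived from the
#' master `seed` by a counter scheme, so any subset of trials reproduces
#' the same rows as the full run. With `out_csv` set, rows are appended to
#' the CSV as they complete and trials already present in the file are
#' skipped, making long runs resumable.
#'
#' @param networks A tibble with columns `network_id` and list-column
#'   `network` (as returned by [generate_ensemble()]), or a plain list of
#'   [bipartite_network()] objects.
#' @param design Optional design tibble from [design_grid()]; defaults to
#'   the full factorial over all networks.
#' @param seed Master seed.
#' @param out_csv Optional path for streaming, resumable CSV output.
#' @param progress Print one line per settled community.
#' @param end_t Final time of each trial (default 20,000).
#' @param ... Passed to [settle_community()].
#' @return A tibble with one row per trial, ordered by `trial_id`.
#' @export
run_design <- function(networks, design = NULL, seed = 1, out_csv = NULL,
                       progress = FALSE, end_t = 20000, ...) {
  if (!is.data.frame(networks)) {
    networks <- tibble::tibble(
      network_id = seq_along(networks),
      network = networks
    )
  }
  if (is.null(design)) design <- design_grid(networks$network_id)
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv)
    design <- design[!(design$trial_id %in% done$trial_id), ]
  }
  rows <- vector("list", nrow(design))
  groups <- split(seq_len(nrow(design)),
                  paste(design$network_id, design$mortality))
  for (grp in groups) {
    nid <- design$network_id[grp[1]]
    mort <- design$mortality[grp[1]]
    net <- networks$network[[match(nid, networks$network_id)]]
    mort_idx <- as.integer(round(mort * 1000))
    settle <- settle_community(
      net, mort, seed = derive_seed(seed, nid, mort_idx), ...
    )
    if (progress) {
      cat(sprintf("settled network %d at mortality %g (%d trials)\n",
                  nid, mort, length(grp)))
    }
    for (k in grp) {
      row <- run_trial(
        mortality = mort, type_id = design$type_id[k],
        attachment = design$attachment[k],
        seed = derive_seed(seed, design$trial_id[k], 7),
        settle = settle, end_t = end_t
      )
      row <- dplyr::bind_cols(
        tibble::tibble(trial_id = design$trial_id[k], network_id = nid),
        row
      )
      rows[[k]] <- row
      if (!is.null(out_csv)) {
        utils::write.table(
          row, out_csv, sep = ",", row.names = FALSE,
          col.names = !file.exists(out_csv), append = file.exists(out_csv)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows, done)
  dplyr::arrange(out, .data$trial_id)
}
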