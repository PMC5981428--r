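#' Base parameter values of the consumer-resource model
#'
#' Returns the constants around which per-species parameters are drawn.
#' Plant-side parameters vary stochastically among plant species within a
#' relative `jitter` of these constants; pollinator-side parameters do not
#' vary among native pollinators. Units follow the model's convention of
#' densities per unit area and rates per time step.
#'
#' * `g` maximum fraction of seeds recruiting to adulthood (dimensionless)
#' * `u` interspecific plant competition coefficient (per density), `u < w`
#' * `w` intraspecific plant competition coefficient (per density)
#' * `e` expected seeds per successful pollination event (per visit)
#' * `eps` pollen production, weighting pollination success (per plant)
#' * `mu_p` plant mortality rate (per time)
#' * `beta` floral rewards production rate (per time)
#' * `phi` rewards self-limitation rate (per time)
#' * `c` conversion efficiency of rewards into pollinator births (per link)
#' * `b` rewards extraction efficiency (per link)
#' * `tau` visitation efficiency (per link; 1 for natives in this design)
#' * `G` basal adaptation rate of foraging preferences (per time)
#'
#' @param jitter Relative half-width of the uniform jitter applied to
#'   plant-side parameters (default 0.1, i.e. within 10%).
#' @return A named list of base values.
#' @export
default_base_params <- function(jitter = 0.1) {
  list(
    g = 0.4, u = 0.002, w = 1.0, e = 0.8, eps = 1,
    mu_p = 0.002, beta = 0.2, phi = 0.04,
    c = 0.2, b = 0.4, tau = 1, G = 2,
    jitter = jitter
  )
}

#' Draw the full parameter set for a network
#'
#' Plant parameters (`g`, `u`, `w`, `e`, `eps`, `mu_p`, `beta`, `phi`) are
#' drawn independently per plant species, uniformly within `base$jitter` of
#' the base constants. Pollinator parameters (`mu_a`, `G`, `tau`, `c`, `b`)
#' are identical across native pollinators; `tau` is fixed at 1. Link-level
#' parameters (`tau`, `c`, `b`, `e`) are stored per link, with `e` inherited
#' from the link's plant. All native pollinators with more than one plant
#' partner forage adaptively.
#'
#' @param net A [bipartite_network()].
#' @param mortality Pollinator mortality rate, applied to every pollinator
#'   (the study design uses 0.05 or 0.001).
#' @param base Base constants from [default_base_params()].
#' @return A `community_params` object: list of tibbles `plants`, `animals`
#'   and `links` (rows of `links` aligned with `net$edges`).
#' @export
init_parameters <- function(net, mortality = 0.05,
                            base = default_base_params()) {
  if (base$u >= base$w) {
    stop("interspecific competition u must be below intraspecific w",
         call. = FALSE)
  }
  nP <- net$n_plants
  nA <- net$n_animals
  jit <- function(x, n) x * stats::runif(n, 1 - base$jitter, 1 + base$jitter)
  plants <- tibble::tibble(
    g = jit(base$g, nP), u = jit(base$u, nP), w = jit(base$w, nP),
    e = jit(base$e, nP), eps = jit(base$eps, nP),
    mu_p = jit(base$mu_p, nP), beta = jit(base$beta, nP),
    phi = jit(base$phi, nP)
  )
  deg_a <- tabulate(net$edges$animal, nA)
  animals <- tibble::tibble(
    mu_a = rep(mortality, nA),
    G = rep(base$G, nA),
    adaptive = deg_a > 1L
  )
  links <- tibble::tibble(
    tau = rep(base$tau, nrow(net$edges)),
    c = rep(base$c, nrow(net$edges)),
    b = rep(base$b, nrow(net$edges)),
    e = plants$e[net$edges$plant]
  )
  structure(list(plants = plants, animals = animals, links = links),
            class = "community_params")
}

#' Initial community state
#'
#' Plant and pollinator densities start uniformly between `dens_min` and
#' `dens_max`; floral rewards start at half their per-plant equilibrium
#' `beta * p / phi`; every pollinator's foraging preferences are uniform
#' over its plant partners.
#'
#' @param net A [bipartite_network()].
#' @param params A `community_params` object from [init_parameters()].
#' @param dens_min,dens_max Bounds of the uniform initial densities.
#' @return A `community_state` object: list with `time`, plant densities
#'   `p`, animal densities `a`, rewards `R`, per-link preferences `alpha`,
#'   and persistence masks `alive_p`, `alive_a`.
#' @export
init_state <- function(net, params, dens_min = 0.05, dens_max = 0.3) {
  nP <- net$n_plants
  nA <- net$n_animals
  p <- stats::runif(nP, dens_min, dens_max)
  a <- stats::runif(nA, dens_min, dens_max)
  R <- params$plants$beta * p / params$plants$phi / 2
  deg_a <- tabulate(net$edges$animal, nA)
  alpha <- 1 / deg_a[net$edges$animal]
  community_state(0, p, a, R, alpha)
}

community_state <- function(time, p, a, R, alpha,
                            alive_p = p > 0, alive_a = a > 0) {
  structure(
    list(time = time, p = p, a = a, R = R, alpha = alpha,
         alive_p = alive_p, alive_a = alive_a),
    class = "community_state"
  )
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf(
    "<community_state> t = %g: %d/%d plants, %d/%d animals alive\n",
    x$time, sum(x$alive_p), length(x$p), sum(x$alive_a), length(x$a)
  ))
  invisible(x)
}

# Precomputed integration context: index vectors, sparse link-incidence
# operators and flat parameter vectors. Kept separate from the user-facing
# params object so the right-hand side touches only flat numerics.
build_ctx <- function(net, params, threshold = 1e-3) {
  L <- nrow(net$edges)
  nP <- net$n_plants
  nA <- net$n_animals
  lp <- net$edges$plant
  la <- net$edges$animal
  # contiguous-group orderings for O(L) dispatch-free group sums
  ord_a <- order(la)
  ord_p <- order(lp)
  list(
    nP = nP, nA = nA, L = L, lp = lp, la = la,
    ip = seq_len(nP), ia = nP + seq_len(nA), iR = nP + nA + seq_len(nP),
    ial = nP + nA + nP + seq_len(L),
    ord_a = ord_a, ends_a = cumsum(tabulate(la, nA)),
    ord_p = ord_p, ends_p = cumsum(tabulate(lp, nP)),
    P_inc = Matrix::sparseMatrix(i = lp, j = seq_len(L), x = 1,
                                 dims = c(nP, L)),
    A_inc = Matrix::sparseMatrix(i = la, j = seq_len(L), x = 1,
                                 dims = c(nA, L)),
    g = params$plants$g, u = params$plants$u, w = params$plants$w,
    eps = params$plants$eps, mu_p = params$plants$mu_p,
    beta = params$plants$beta, phi = params$plants$phi,
    mu_a = params$animals$mu_a,
    G_l = params$animals$G[la] * as.numeric(params$animals$adaptive[la]),
    tau = params$links$tau, cc = params$links$c, bb = params$links$b,
    ee = params$links$e,
    threshold = threshold
  )
}

pack_state <- function(state) {
  c(state$p, state$a, state$R, state$alpha)
}

unpack_state <- function(y, ctx, time) {
  community_state(time, y[ctx$ip], y[ctx$ia], y[ctx$iR], y[ctx$ial])
}

sum_by_animal <- function(x, ctx) {
  cs <- cumsum(x[ctx$ord_a])
  c(cs[ctx$ends_a[1L]], diff(cs[ctx$ends_a]))
}

sum_by_plant <- function(x, ctx) {
  cs <- cumsum(x[ctx$ord_p])
  c(cs[ctx$ends_p[1L]], diff(cs[ctx$ends_p]))
}

# Core model equations. Returns the derivative vector; with derived = TRUE
# also the per-link visit frequencies V, pollination success fractions
# sigma, and per-plant realised recruitment gamma.
rhs_core <- function(y, ctx, derived = FALSE) {
  p <- pmax(y[ctx$ip], 0)
  a <- pmax(y[ctx$ia], 0)
  R <- pmax(y[ctx$iR], 0)
  alpha <- pmax(y[ctx$ial], 0)

  V <- alpha * ctx$tau * a[ctx$la] * p[ctx$lp]
  # per-flower rewards; dead or near-extinct plants offer none
  f <- (p > ctx$threshold) * R / pmax(p, ctx$threshold)
  epsV <- ctx$eps[ctx$lp] * V
  denom <- sum_by_animal(epsV, ctx)[ctx$la]
  sigma <- (denom > 0) * epsV / (denom + (denom == 0))
  pol <- sum_by_plant(ctx$ee * sigma * V, ctx)
  gamma <- ctx$g * (1 - (sum(ctx$u * p) - ctx$u * p) - ctx$w * p)
  dp <- gamma * pol - ctx$mu_p * p

  Vb <- V * ctx$bb
  da <- sum_by_animal(ctx$cc * Vb * f[ctx$lp], ctx) - ctx$mu_a * a

  dR <- ctx$beta * p - ctx$phi * R - sum_by_plant(Vb, ctx) * f

  rwd <- ctx$cc * ctx$tau * ctx$bb * R[ctx$lp]
  mean_rwd <- sum_by_animal(alpha * rwd, ctx)
  dalpha <- ctx$G_l * alpha * (rwd - mean_rwd[ctx$la])

  dy <- c(dp, da, dR, dalpha)
  if (!derived) return(dy)
  list(dy = dy, V = V, sigma = sigma, gamma = gamma, f = f)
}

#' Evaluate the model's right-hand side at a state
#'
#' Computes all derivatives of the consumer-resource model with adaptive
#' foraging at a given state, together with the derived rates: per-link
#' visit frequencies `V = alpha * tau * a * p`, successful-pollination
#' fractions `sigma` (pollen-production-weighted shares of each pollinator's
#' visits, zero when the pollinator makes no visits), and per-plant realised
#' recruitment `gamma`.
#'
#' @param state A `community_state`.
#' @param params A `community_params`.
#' @param net The matching [bipartite_network()].
#' @param threshold Extinction threshold used to zero per-flower rewards of
#'   effectively extinct plants.
#' @return A list with numeric vectors `dp`, `da`, `dR`, `dalpha` and a
#'   tibble `rates` (columns `plant`, `animal`, `V`, `sigma`).
#' @export
community_rhs <- function(state, params, net, threshold = 1e-3) {
  if (any(!is.finite(c(state$p, state$a, state$R, state$alpha)))) {
    stop("state contains non-finite values", call. = FALSE)
  }
  ctx <- build_ctx(net, params, threshold)
  out <- rhs_core(pack_state(state), ctx, derived = TRUE)
  list(
    dp = out$dy[ctx$ip], da = out$dy[ctx$ia], dR = out$dy[ctx$iR],
    dalpha = out$dy[ctx$ial],
    gamma = out$gamma,
    rates = tibble::tibble(plant = ctx$lp, animal = ctx$la,
                           V = out$V, sigma = out$sigma)
  )
}

# Extinction pruning applied to a raw state vector: clamp negatives, kill
# species below the threshold, zero dead plants' rewards and dead links'
# preferences, and renormalise every surviving pollinator's preferences
# proportionally over its surviving partners.
prune_state <- function(y, ctx) {
  y[y < 0] <- 0
  p <- y[ctx$ip]
  a <- y[ctx$ia]
  p[p < ctx$threshold] <- 0
  a[a < ctx$threshold] <- 0
  R <- y[ctx$iR]
  R[p == 0] <- 0
  alpha <- y[ctx$ial]
  alpha[p[ctx$lp] == 0 | a[ctx$la] == 0] <- 0
  tot <- as.numeric(ctx$A_inc %*% alpha)
  scale <- ifelse(tot > 0, 1 / tot, 0)
  alpha <- alpha * scale[ctx$la]
  c(p, a, R, alpha)
}

#' Integrate the community dynamics with extinction pruning
#'
#' Advances the model from `state$time` to `t_end` with the stiff-capable
#' adaptive integrator `lsoda`. At regular pruning checkpoints (every
#' `prune_dt` time units) any species whose density has fallen below the
#' extinction `threshold` is removed: its density is set to zero, a dead
#' plant's rewards are zeroed, all preferences on its links are zeroed, and
#' surviving pollinators' preferences are renormalised proportionally over
#' their surviving partners. Zero density is absorbing, so pruned species
#' never return.
#'
#' @param state Initial `community_state`.
#' @param params A `community_params`.
#' @param net The matching [bipartite_network()].
#' @param t_end Final time.
#' @param threshold Extinction threshold (default `1e-3`).
#' @param prune_dt Spacing of pruning checkpoints, which are also the
#'   recorded output times.
#' @param rtol,atol Integrator tolerances.
#' @return A `community_trajectory`: list with `times`, the state matrix
#'   `y` (one row per output time, post-pruning), the final
#'   `community_state` in `state`, the context dimensions, and `min_a`, the
#'   per-animal minimum density observed at checkpoints (0 once pruned).
#' @export
integrate_community <- function(state, params, net, t_end,
                                threshold = 1e-3, prune_dt = 250,
                                rtol = 1e-6, atol = 1e-9) {
  stopifnot(t_end > state$time)
  ctx <- build_ctx(net, params, threshold)
  times <- unique(c(seq(state$time, t_end, by = prune_dt), t_end))
  y0 <- prune_state(pack_state(state), ctx)
  func <- function(t, y, parms) {
    list(rhs_kernel(
      y, parms$lp, parms$la, parms$nP, parms$nA,
      parms$g, parms$u, parms$w, parms$eps, parms$mu_p, parms$beta,
      parms$phi, parms$mu_a, parms$G_l, parms$tau, parms$cc, parms$bb,
      parms$ee, parms$threshold
    ))
  }
  event <- function(t, y, parms) prune_state(y, parms)
  sol <- deSolve::lsoda(
    y = y0, times = times, func = func, parms = ctx,
    rtol = rtol, atol = atol,
    events = list(func = event, time = times[-1])
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed before t_end; last good time ",
         max(sol[, 1]), call. = FALSE)
  }
  ymat <- unname(sol[, -1, drop = FALSE])
  # rows are post-event states except possibly the first
  ymat[1, ] <- y0
  # clip rounding-level negatives (within the integrator's atol)
  ymat[ymat < 0 & ymat > -atol] <- 0
  final <- unpack_state(ymat[nrow(ymat), ], ctx, t_end)
  structure(
    list(
      times = sol[, 1], y = ymat, state = final, ctx_dims = ctx[c(
        "nP", "nA", "L", "ip", "ia", "iR", "ial", "lp", "la"
      )],
      min_a = apply(ymat[, ctx$ia, drop = FALSE], 2, min)
    ),
    class = "community_trajectory"
  )
}

#' @export
print.community_trajectory <- function(x, ...) {
  cat(sprintf(
    "<community_trajectory> %d output times over [%g, %g]\n",
    length(x$times), min(x$times), max(x$times)
  ))
  print(x$state)
  invisible(x)
}

#' @export
tidy.community_trajectory <- function(x, ...) {
  d <- x$ctx_dims
  dplyr::bind_rows(
    tibble::tibble(
      time = rep(x$times, d$nP),
      guild = "plant",
      species = rep(seq_len(d$nP), each = length(x$times)),
      density = as.vector(x$y[, d$ip])
    ),
    tibble::tibble(
      time = rep(x$times, d$nA),
      guild = "animal",
      species = rep(seq_len(d$nA), each = length(x$times)),
      density = as.vector(x$y[, d$ia])
    )
  )
}

#' Has the trajectory reached a (numerical) equilibrium?
#'
#' Checks that the relative fluctuation of every living species' density
#' over the trailing `window` of the trajectory is below `tol`. The
#' fluctuation of a species is `(max - min) / max` of its density over the
#' window; species extinct by the end of the window are ignored.
#'
#' @param traj A `community_trajectory`.
#' @param window Length of the trailing time window.
#' @param tol Relative-change tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
equilibrium_reached <- function(traj, window, tol = 1e-3) {
  t1 <- max(traj$times) - window
  stopifnot(t1 >= min(traj$times))
  sel <- traj$times >= t1
  d <- traj$ctx_dims
  dens <- traj$y[sel, c(d$ip, d$ia), drop = FALSE]
  alive <- dens[nrow(dens), ] > 0
  if (!any(alive)) return(TRUE)
  dens <- dens[, alive, drop = FALSE]
  hi <- apply(dens, 2, max)
  lo <- apply(dens, 2, min)
  all((hi - lo) / hi < tol)
}
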