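#' Culture state vector
#'
#' Builds and validates a culture state in the canonical component order
#' `X, Xd, G, Gn, L, MAb` (see [state_components()]).
#'
#' @param X Viable biomass (10^6 cells/mL).
#' @param Xd Dead biomass (10^6 cells/mL).
#' @param G Glucose (g/L).
#' @param Gn Glutamine (g/L).
#' @param L Lactate (g/L).
#' @param MAb Monoclonal antibody (ug/mL).
#' @return Named numeric vector of length 6.
#' @export
culture_state <- function(X = 0, Xd = 0, G = 0, Gn = 0, L = 0, MAb = 0) {
  s <- c(X = X, Xd = Xd, G = G, Gn = Gn, L = L, MAb = MAb)
  validate_state(s)
  s
}

validate_state <- function(state) {
  if (length(state) != 6 || any(!is.finite(state)) || any(state < 0))
    stop("invalid culture state: all six components must be finite and >= 0",
         call. = FALSE)
  invisible(state)
}

#' Volumetric reaction rates of the overflow model
#'
#' Evaluates the three reaction rates at one state. The substrate uptake rate
#' `phi_G` follows Monod kinetics in glutamine (and, for the full variant,
#' glucose); the oxidative pathway carries `phi1 = min(phi_G, mu_max2 * X)`
#' and the excess `phi2 = max(0, phi_G - mu_max2 * X)` overflows to lactate
#' (bottleneck assumption). The death rate `phi3` uses inverse Monod factors
#' that accelerate death as substrates deplete. All three rates are
#' volumetric, i.e. they already contain the factor `X`.
#'
#' @param state A [culture_state()] (named or positional, canonical order).
#' @param params A [model_parameters()] object.
#' @return Named vector `c(phi1, phi2, phi3)` (per day, volumetric).
#' @examples
#' reaction_rates(culture_state(X = 1, G = 2, Gn = 0.4), hb1_parameters())
#' @export
reaction_rates <- function(state, params) {
  validate_state(state)
  p <- param_vector(params)
  X <- state[[1]]; G <- state[[3]]; Gn <- state[[4]]
  phiG <- p[["mu_max1"]] * Gn / (p[["K_Gn"]] + Gn) * X
  if (!is_reduced(params)) phiG <- phiG * G / (p[["K_G"]] + G)
  phimax <- p[["mu_max2"]] * X
  phi3 <- p[["mu_dmax"]] * p[["K_Gd"]] / (p[["K_Gd"]] + G) *
    p[["K_Gnd"]] / (p[["K_Gnd"]] + Gn) * X
  c(phi1 = min(phiG, phimax), phi2 = max(0, phiG - phimax), phi3 = phi3)
}

#' Mass-balance right-hand side
#'
#' Time derivative of the six-component state under the three-reaction scheme:
#' `dX = phi1 + phi2 - phi3`, `dXd = phi3`,
#' `dG = -k31 phi1 - k32 phi2`, `dGn = -k41 phi1 - k42 phi2`,
#' `dL = k52 phi2`, `dMAb = k61 phi1 + k63 phi3`
#' with the volumetric rates of [reaction_rates()].
#'
#' @inheritParams reaction_rates
#' @return Named numeric derivative vector (per day).
#' @export
ode_rhs <- function(state, params) {
  validate_state(state)
  d <- rhs_cpp(as.numeric(state)[1:6], param_vector(params), is_reduced(params))
  stats::setNames(d, state_components())
}

#' Medium-renewal events
#'
#' A renewal withdraws the metabolites (lactate and antibody), sets the
#' substrates to prescribed concentrations and keeps both viable and dead
#' biomass in the reactor.
#'
#' @param time Renewal times (days), strictly increasing.
#' @param G_renewal Glucose set-point at each renewal (g/L), recycled.
#' @param Gn_renewal Glutamine set-point at each renewal (g/L), recycled.
#' @return A tibble with columns `time`, `G_renewal`, `Gn_renewal`.
#' @export
renewal_events <- function(time = numeric(), G_renewal = 6, Gn_renewal = 0.4) {
  if (length(time) && any(diff(time) <= 0))
    stop("renewal times must be strictly increasing", call. = FALSE)
  tibble::tibble(time = as.numeric(time),
                 G_renewal = rep_len(as.numeric(G_renewal), length(time)),
                 Gn_renewal = rep_len(as.numeric(Gn_renewal), length(time)))
}

validate_events <- function(events, horizon) {
  if (is.null(events) || nrow(events) == 0) return(renewal_events())
  stopifnot(all(c("time", "G_renewal", "Gn_renewal") %in% names(events)))
  if (any(diff(events$time) <= 0))
    stop("renewal times must be strictly increasing", call. = FALSE)
  if (any(events$time <= 0) || any(events$time >= horizon))
    stop("renewal times must lie strictly inside the simulation horizon",
         call. = FALSE)
  events
}

#' Simulate a sequential-batch culture
#'
#' Integrates the overflow model through a schedule of medium renewals. The
#' integration restarts exactly at each event time; the value reported *at* an
#' event time is the post-renewal state, while the pre-renewal (harvest) state
#' is kept in the `events` element of the result.
#'
#' @param initial Initial [culture_state()].
#' @param params A [model_parameters()] object.
#' @param events A [renewal_events()] tibble (may be empty).
#' @param horizon Simulation end time (days).
#' @param times Output time grid; defaults to a dense grid of step 0.05 day
#'   starting at 0.
#' @param engine `"rk45"` (compiled adaptive Dormand-Prince, default),
#'   `"lsoda"` (deSolve, stiff-capable) or `"rk4"` (fixed-step reference,
#'   step `rk4_dt`).
#' @param rtol,atol Integration tolerances.
#' @param rk4_dt Step size of the `"rk4"` engine (days).
#' @return An `sbr_simulation` object: list with `trajectory` (tibble
#'   `time, X, Xd, G, Gn, L, MAb`), `events` (schedule plus pre/post states),
#'   `harvests` (MAb concentration harvested at each renewal and at the final
#'   time), `params`, `horizon`.
#' @examples
#' sim <- simulate_sbr(culture_state(X = 0.1, G = 6, Gn = 0.4),
#'                     hb1_parameters(), renewal_events(7), horizon = 14)
#' sim$harvests
#' @export
simulate_sbr <- function(initial, params, events = renewal_events(),
                         horizon, times = NULL,
                         engine = c("rk45", "lsoda", "rk4"),
                         rtol = 1e-8, atol = 1e-10, rk4_dt = 1e-3) {
  engine <- match.arg(engine)
  stopifnot(is.numeric(horizon), horizon > 0)
  validate_state(initial)
  events <- validate_events(events, horizon)
  if (is.null(times)) times <- seq(0, horizon, by = 0.05)
  times <- sort(unique(as.numeric(times)))
  if (max(times) > horizon) stop("output times exceed the horizon", call. = FALSE)

  p <- param_vector(params)
  red <- is_reduced(params)
  ev <- as.matrix(events[c("time", "G_renewal", "Gn_renewal")])
  storage.mode(ev) <- "double"

  if (engine == "rk45") {
    res <- sim_sbr_cpp(as.numeric(initial)[1:6], p, red, ev, times, rtol, atol)
    if (!isTRUE(res$ok))
      stop(sprintf("integration failed in segment %d near t = %.4f",
                   res$segment, res$t_fail), call. = FALSE)
    if (res$undershoot < -1e-6)
      warning(sprintf("solver undershoot below zero (min %.3g); clipped at 0",
                      res$undershoot))
    traj <- res$trajectory
    pre <- res$event_pre; post <- res$event_post
  } else {
    res <- sim_sbr_r(as.numeric(initial)[1:6], p, red, ev, times,
                     engine, rtol, atol, rk4_dt)
    traj <- res$trajectory; pre <- res$event_pre; post <- res$event_post
  }

  colnames(traj) <- state_components()
  trajectory <- dplyr::bind_cols(tibble::tibble(time = times),
                                 tibble::as_tibble(traj))
  ev_tbl <- events
  if (nrow(ev_tbl)) {
    colnames(pre) <- paste0(state_components(), "_pre")
    colnames(post) <- paste0(state_components(), "_post")
    ev_tbl <- dplyr::bind_cols(ev_tbl, tibble::as_tibble(pre),
                               tibble::as_tibble(post))
  }
  harvests <- tibble::tibble(
    batch = seq_len(nrow(ev_tbl) + 1L),
    end_time = c(ev_tbl$time, horizon),
    MAb = c(if (nrow(ev_tbl)) ev_tbl$MAb_pre else numeric(),
            utils::tail(trajectory$MAb, 1))
  )
  structure(list(trajectory = trajectory, events = ev_tbl, harvests = harvests,
                 params = params, horizon = horizon),
            class = "sbr_simulation")
}

# deSolve / fixed-step fallback engines, segment-by-segment across events
sim_sbr_r <- function(y0, p, reduced, ev, times, engine, rtol, atol, rk4_dt) {
  nseg <- nrow(ev) + 1L
  bounds <- c(times[1], ev[, 1], max(times, if (nrow(ev)) ev[, 1]))
  pre <- matrix(NA_real_, nrow(ev), 6)
  post <- matrix(NA_real_, nrow(ev), 6)
  out <- matrix(NA_real_, length(times), 6)
  y <- y0
  derivs <- function(t, y, parms) list(rhs_cpp(y, p, reduced))
  for (s in seq_len(nseg)) {
    a <- bounds[s]; b <- bounds[s + 1]
    if (s == 1) { out[times == a, ] <- rep(y, each = sum(times == a)) }
    idx <- which(times > a + 1e-12 & times <= b + 1e-12)
    # always integrate to the segment end to apply the event
    tt <- sort(unique(c(a, times[idx], b)))
    if (length(tt) > 1) {
      if (engine == "lsoda") {
        sol <- deSolve::lsoda(y, tt, derivs, NULL, rtol = rtol, atol = atol)
        m <- unname(sol[, -1, drop = FALSE])
      } else {
        m <- rk4_segment(y, tt, p, reduced, rk4_dt)
      }
      m[m < 0] <- 0
      if (length(idx)) out[idx, ] <- m[match(times[idx], tt), , drop = FALSE]
      y <- m[nrow(m), ]
    }
    if (s <= nrow(ev)) {
      pre[s, ] <- y
      y[3] <- ev[s, 2]; y[4] <- ev[s, 3]; y[5] <- 0; y[6] <- 0
      post[s, ] <- y
      if (length(idx) && any(times[idx] == b)) out[times == b, ] <- rep(y, each = sum(times == b))
    }
  }
  list(trajectory = out, event_pre = pre, event_post = post)
}

# classical fixed-step RK4 reference, recording states at the times in tt
rk4_segment <- function(y, tt, p, reduced, dt) {
  out <- matrix(NA_real_, length(tt), 6)
  out[1, ] <- y
  f <- function(y) rhs_cpp(y, p, reduced)
  for (i in seq_along(tt)[-1]) {
    a <- tt[i - 1]; b <- tt[i]
    n <- max(1L, ceiling((b - a) / dt - 1e-9))
    h <- (b - a) / n
    for (k in seq_len(n)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y[y < 0] <- 0
    }
    out[i, ] <- y
  }
  out
}

#' @export
print.sbr_simulation <- function(x, ...) {
  cat("<sbr_simulation>", nrow(x$trajectory), "time points over",
      x$horizon, "days;", nrow(x$events), "renewal(s)\n")
  cat("batch-end MAb (ug/mL):", paste(round(x$harvests$MAb, 2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a simulation trajectory
#'
#' @param x An `sbr_simulation`.
#' @param ... Unused.
#' @return Long tibble with columns `time`, `component`, `concentration`.
#' @export
tidy.sbr_simulation <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, -"time", names_to = "component",
                      values_to = "concentration") |>
    dplyr::mutate(component = factor(.data$component, state_components()))
}

#' Plot a simulated sequential-batch culture
#'
#' @param object An `sbr_simulation`.
#' @param ... Unused.
#' @return A ggplot with one facet per component; renewal times are marked.
#' @export
autoplot.sbr_simulation <- function(object, ...) {
  df <- tidy.sbr_simulation(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL)
  if (nrow(object$events))
    gg <- gg + ggplot2::geom_vline(xintercept = object$events$time,
                                   linetype = "dashed", colour = "grey50")
  gg
}
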