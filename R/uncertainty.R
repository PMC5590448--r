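#' Forward parametric sensitivities
#'
#' Integrates the forward sensitivity system `dS/dt = (df/dx) S + df/dtheta`
#' jointly with the state through the renewal schedule. At an event the
#' sensitivity rows of the reset components are reset to zero (post-event
#' lactate/antibody are 0 and the substrates are fixed constants, so their
#' sensitivities vanish) while the biomass rows are carried over. The RHS
#' Jacobians are evaluated numerically; the min/max kink of the overflow
#' switch contributes one-sided derivatives on a measure-zero set, which is
#' harmless to the quadrature.
#'
#' For kinetic/stoichiometric parameters the sensitivities start at zero; for
#' initial-state parameters (named `init_X`, ..., `init_MAb`) they start at
#' the corresponding identity block.
#'
#' @param params A [model_parameters()].
#' @param initial Initial [culture_state()].
#' @param events A [renewal_events()] tibble.
#' @param horizon End time (days).
#' @param free Names of the parameters to differentiate with respect to:
#'   kinetic/stoichiometric names and/or `init_<component>`.
#' @param times Output grid (defaults to step 0.1 day).
#' @param rtol,atol Integration tolerances.
#' @return A `sensitivity_trajectory`: list with `times`, `state` (matrix),
#'   and `S` (array time x state x parameter).
#' @export
sensitivities <- function(params, initial, events = renewal_events(), horizon,
                          free = NULL, times = NULL, rtol = 1e-10, atol = 1e-12) {
  validate_state(initial)
  events <- validate_events(events, horizon)
  v <- param_vector(params)
  red <- is_reduced(params)
  avail <- if (red) setdiff(.param_names, "K_G") else .param_names
  if (is.null(free)) free <- avail
  init_par <- grep("^init_", free, value = TRUE)
  dyn_par <- setdiff(free, init_par)
  bad <- setdiff(dyn_par, avail)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  np <- length(free)
  if (is.null(times)) times <- seq(0, horizon, by = 0.1)
  times <- sort(unique(c(0, times)))

  aug_rhs <- function(t, y, parms) {
    x <- pmax(y[1:6], 0)
    S <- matrix(y[-(1:6)], 6, np)
    jac <- rhs_jacobians(x, v, red)
    dS <- jac$Jx %*% S
    if (length(dyn_par))
      dS[, seq_along(dyn_par)] <- dS[, seq_along(dyn_par)] +
        jac$Jth[, dyn_par, drop = FALSE]
    list(c(jac$f, as.numeric(dS)))
  }

  S0 <- matrix(0, 6, np)
  for (k in seq_along(init_par))
    S0[match(sub("^init_", "", init_par[k]), state_components()),
       length(dyn_par) + k] <- 1

  bounds <- c(0, events$time, horizon)
  y <- c(as.numeric(initial), as.numeric(S0))
  out_state <- matrix(NA_real_, length(times), 6)
  out_S <- array(NA_real_, c(length(times), 6, np))
  record <- function(idx, y) {
    out_state[idx, ] <<- rep(y[1:6], each = length(idx))
    for (i in idx) out_S[i, , ] <<- matrix(y[-(1:6)], 6, np)
  }
  if (times[1] == 0) record(1L, y)

  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    idx <- which(times > a + 1e-12 & times <= b + 1e-12)
    tt <- sort(unique(c(a, times[idx], b)))
    if (length(tt) > 1) {
      sol <- deSolve::lsoda(y, tt, aug_rhs, NULL, rtol = rtol, atol = atol)
      m <- unname(sol[, -1, drop = FALSE])
      for (i in idx) {
        row <- m[match(times[i], tt), ]
        out_state[i, ] <- row[1:6]
        out_S[i, , ] <- matrix(row[-(1:6)], 6, np)
      }
      y <- m[nrow(m), ]
    }
    if (s <= nrow(events)) {
      y[3] <- events$G_renewal[s]; y[4] <- events$Gn_renewal[s]
      y[5] <- 0; y[6] <- 0
      S <- matrix(y[-(1:6)], 6, np)
      S[3:6, ] <- 0  # substrates fixed, metabolites withdrawn
      y[-(1:6)] <- as.numeric(S)
      if (length(idx) && any(times[idx] == b)) record(which(times == b), y)
    }
  }
  colnames(out_state) <- state_components()
  dimnames(out_S) <- list(NULL, state_components(), free)
  structure(list(times = times, state = out_state, S = out_S, free = free),
            class = "sensitivity_trajectory")
}

#' @export
print.sensitivity_trajectory <- function(x, ...) {
  cat("<sensitivity_trajectory>", length(x$times), "time points,",
      dim(x$S)[3], "parameter(s)\n")
  invisible(x)
}

# analytic RHS value and Jacobians with respect to state and parameters.
# At the overflow switch (phi_G = phi_Gmax) the oxidative branch is taken
# (one-sided derivative; the crossing set has measure zero in time).
rhs_jacobians <- function(x, v, reduced) {
  X <- x[1]; G <- x[3]; Gn <- x[4]
  mgn <- Gn / (v[["K_Gn"]] + Gn)
  dmgn_dGn <- v[["K_Gn"]] / (v[["K_Gn"]] + Gn)^2
  if (reduced) {
    g <- mgn; dg_dG <- 0; dg_dGn <- dmgn_dGn
  } else {
    mg <- G / (v[["K_G"]] + G)
    g <- mgn * mg
    dg_dG <- mgn * v[["K_G"]] / (v[["K_G"]] + G)^2
    dg_dGn <- dmgn_dGn * mg
  }
  a <- v[["mu_max1"]] * g           # specific uptake rate
  over <- a > v[["mu_max2"]]        # overflow regime
  m1 <- min(a, v[["mu_max2"]]); m2 <- max(0, a - v[["mu_max2"]])
  cg <- v[["K_Gd"]] / (v[["K_Gd"]] + G)
  cgn <- v[["K_Gnd"]] / (v[["K_Gnd"]] + Gn)
  cd <- v[["mu_dmax"]] * cg * cgn   # specific death rate

  phi1 <- m1 * X; phi2 <- m2 * X; phi3 <- cd * X

  # volumetric rate partials wrt (X, G, Gn)
  da_dG <- v[["mu_max1"]] * dg_dG; da_dGn <- v[["mu_max1"]] * dg_dGn
  dphi1 <- c(m1, if (over) 0 else da_dG * X, if (over) 0 else da_dGn * X)
  dphi2 <- c(m2, if (over) da_dG * X else 0, if (over) da_dGn * X else 0)
  dphi3 <- c(cd, -phi3 / (v[["K_Gd"]] + G), -phi3 / (v[["K_Gnd"]] + Gn))

  # rate partials wrt parameters (canonical 14-name order)
  Z <- stats::setNames(numeric(length(.param_names)), .param_names)
  p1 <- Z; p2 <- Z; p3 <- Z
  p1[["mu_max1"]] <- if (over) 0 else g * X
  p2[["mu_max1"]] <- if (over) g * X else 0
  p1[["mu_max2"]] <- if (over) X else 0
  p2[["mu_max2"]] <- if (over) -X else 0
  if (!reduced) {
    daKG <- -a / (v[["K_G"]] + G) * X
    p1[["K_G"]] <- if (over) 0 else daKG
    p2[["K_G"]] <- if (over) daKG else 0
  }
  daKGn <- -v[["mu_max1"]] * (if (reduced) 1 else G / (v[["K_G"]] + G)) *
    Gn / (v[["K_Gn"]] + Gn)^2
  p1[["K_Gn"]] <- if (over) 0 else daKGn * X
  p2[["K_Gn"]] <- if (over) daKGn * X else 0
  p3[["K_Gd"]] <- phi3 * G / (v[["K_Gd"]] * (v[["K_Gd"]] + G))
  p3[["K_Gnd"]] <- phi3 * Gn / (v[["K_Gnd"]] * (v[["K_Gnd"]] + Gn))
  p3[["mu_dmax"]] <- cg * cgn * X

  f <- c(phi1 + phi2 - phi3, phi3,
         -v[["k31"]] * phi1 - v[["k32"]] * phi2,
         -v[["k41"]] * phi1 - v[["k42"]] * phi2,
         v[["k52"]] * phi2,
         v[["k61"]] * phi1 + v[["k63"]] * phi3)

  # assemble state Jacobian (columns X, Xd, G, Gn, L, MAb)
  Jx <- matrix(0, 6, 6)
  cols <- c(1, 3, 4)
  Jx[1, cols] <- dphi1 + dphi2 - dphi3
  Jx[2, cols] <- dphi3
  Jx[3, cols] <- -v[["k31"]] * dphi1 - v[["k32"]] * dphi2
  Jx[4, cols] <- -v[["k41"]] * dphi1 - v[["k42"]] * dphi2
  Jx[5, cols] <- v[["k52"]] * dphi2
  Jx[6, cols] <- v[["k61"]] * dphi1 + v[["k63"]] * dphi3

  Jth <- matrix(0, 6, length(.param_names),
                dimnames = list(NULL, .param_names))
  Jth[1, ] <- p1 + p2 - p3
  Jth[2, ] <- p3
  Jth[3, ] <- -v[["k31"]] * p1 - v[["k32"]] * p2
  Jth[4, ] <- -v[["k41"]] * p1 - v[["k42"]] * p2
  Jth[5, ] <- v[["k52"]] * p2
  Jth[6, ] <- v[["k61"]] * p1 + v[["k63"]] * p3
  Jth[3, "k31"] <- Jth[3, "k31"] - phi1
  Jth[3, "k32"] <- Jth[3, "k32"] - phi2
  Jth[4, "k41"] <- Jth[4, "k41"] - phi1
  Jth[4, "k42"] <- Jth[4, "k42"] - phi2
  Jth[5, "k52"] <- Jth[5, "k52"] + phi2
  Jth[6, "k61"] <- Jth[6, "k61"] + phi1
  Jth[6, "k63"] <- Jth[6, "k63"] + phi3

  # nonnegativity projection of the RHS: an exhausted pool stops reacting
  frozen <- which(x <= 0 & f < 0)
  if (length(frozen)) {
    f[frozen] <- 0
    Jx[frozen, ] <- 0
    Jth[frozen, ] <- 0
  }

  list(f = f, Jx = Jx, Jth = Jth)
}

#' Fisher information matrix from sensitivities
#'
#' `FIM = sum_k S_k' Q^{-1} S_k` over the sample times, `S_k` being the
#' state-by-parameter sensitivity slice at sample `k`.
#'
#' @param sens A [sensitivities()] result.
#' @param Q Named vector of diagonal normalization entries (per component).
#' @param sample_times Times at which measurements are taken (must lie on the
#'   sensitivity grid).
#' @return An `uncertainty_report` with the `fim` element filled, plus
#'   condition diagnostics (`condition`, `singular` flag and any
#'   zero-sensitivity parameters).
#' @export
fisher_information <- function(sens, Q, sample_times) {
  stopifnot(inherits(sens, "sensitivity_trajectory"))
  Q <- param_state_vector(Q)
  idx <- match(sample_times, sens$times)
  if (any(is.na(idx)))
    stop("sample times must lie on the sensitivity grid", call. = FALSE)
  np <- dim(sens$S)[3]
  fim <- matrix(0, np, np, dimnames = list(sens$free, sens$free))
  for (k in idx) {
    Sk <- matrix(sens$S[k, , ], 6, np)
    fim <- fim + crossprod(Sk, Sk / Q)
  }
  fim <- (fim + t(fim)) / 2
  zero <- sens$free[diag(fim) == 0]
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  structure(list(fim = fim, condition = cond,
                 singular = cond > 1e12, zero_parameters = zero),
            class = "uncertainty_report")
}

#' Parameter covariance lower bound and relative standard deviations
#'
#' Completes an uncertainty report with the optimistic covariance bound
#' `P = sigma^2 FIM^{-1}` where `sigma^2 = J*/(N_meas - n_theta)` is the
#' posterior residual-variance estimate, and with per-parameter relative
#' standard deviations `100 sqrt(P_kk) / |theta_k|` (percent). A
#' near-singular FIM (condition number above 1e12) falls back to the
#' pseudo-inverse and is flagged; an outsized relative standard deviation is
#' the over-parametrization signature that motivates model reduction.
#'
#' @param report An `uncertainty_report` from [fisher_information()].
#' @param J_star Residual cost at the optimum.
#' @param n_meas_total Total number of scalar measurements.
#' @param estimate Named vector of the parameter estimates (same order as the
#'   FIM).
#' @return The completed `uncertainty_report` (elements `sigma2`, `P`,
#'   `relative_sd`, `table`).
#' @export
parameter_covariance <- function(report, J_star, n_meas_total, estimate) {
  stopifnot(inherits(report, "uncertainty_report"))
  np <- nrow(report$fim)
  if (n_meas_total <= np)
    stop("need more measurements than parameters", call. = FALSE)
  sigma2 <- J_star / (n_meas_total - np)
  P <- if (!report$singular) solve(report$fim) else pracma::pinv(report$fim)
  P <- sigma2 * (P + t(P)) / 2
  rel <- 100 * sqrt(pmax(diag(P), 0)) / abs(estimate)
  report$sigma2 <- sigma2
  report$P <- P
  report$relative_sd <- rel
  report$table <- tibble::tibble(parameter = names(estimate),
                                 estimate = unname(estimate),
                                 relative_sd_pct = unname(rel))
  report
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("<uncertainty_report> condition =", format(x$condition, digits = 3),
      if (x$singular) "(singular)", "\n")
  if (!is.null(x$table)) print(x$table, n = 20)
  invisible(x)
}

#' @rdname tidy.sbr_fit
#' @export
tidy.uncertainty_report <- function(x, ...) {
  if (is.null(x$table)) stop("run parameter_covariance() first", call. = FALSE)
  x$table
}

#' Monte-Carlo robustness analysis
#'
#' Draws each free parameter from `Normal(theta_k, (rel_sd_k |theta_k| /
#' 100)^2)`, truncated at a positive floor, simulates each draw and evaluates
#' the residual cost against the problem's datasets. Simulation failures are
#' excluded from the statistics and reported; more than `max_failure_rate`
#' failures is an error.
#'
#' @param params Central [model_parameters()].
#' @param relative_sds Named vector of relative standard deviations (%) for
#'   the perturbed parameters.
#' @param problem An [identification_problem()] providing datasets and `Q`.
#' @param n_runs Number of draws (default 100).
#' @param seed Integer seed.
#' @param floor_frac Truncation floor as a fraction of `|theta_k|`
#'   (default 1e-6); with `resample = TRUE` out-of-floor draws are redrawn
#'   instead of clamped.
#' @param resample Redraw instead of clamping at the floor.
#' @param max_failure_rate Error threshold on the failed-run fraction.
#' @param envelope_times Optional time grid on which to record the trajectory
#'   envelope of the first experiment.
#' @return A `monte_carlo_result`: list with `summary` (tibble `runs, min_J,
#'   max_J, mean_J, sd_J`), `J` (per-run costs), `failures`, and optionally
#'   `envelope` (tibble of per-time min/max per component).
#' @export
monte_carlo <- function(params, relative_sds, problem, n_runs = 100, seed = 1L,
                        floor_frac = 1e-6, resample = FALSE,
                        max_failure_rate = 0.05, envelope_times = NULL) {
  stopifnot(n_runs >= 1, all(relative_sds >= 0))
  withr::local_seed(seed)
  v <- param_vector(params)
  nm <- names(relative_sds)
  stopifnot(!is.null(nm), all(nm %in% .param_names))

  prob0 <- problem
  prob0$free <- character(0)
  prob0$free_initial_states <- FALSE
  prob0$kinetic_start <- v[.kinetic_names]
  prob0$stoich_start <- v[.stoich_names]

  draw_one <- function() {
    th <- v
    for (k in nm) {
      s <- relative_sds[[k]] * abs(v[[k]]) / 100
      floor_k <- floor_frac * abs(v[[k]])
      x <- stats::rnorm(1, v[[k]], s)
      if (resample) while (x < floor_k) x <- stats::rnorm(1, v[[k]], s)
      th[[k]] <- max(x, floor_k)
    }
    th
  }

  J <- rep(NA_real_, n_runs)
  env_min <- env_max <- NULL
  if (!is.null(envelope_times)) {
    env_min <- matrix(Inf, length(envelope_times), 6)
    env_max <- matrix(-Inf, length(envelope_times), 6)
  }
  failures <- 0L
  for (r in seq_len(n_runs)) {
    th <- draw_one()
    p0 <- prob0; p0$kinetic_start <- th[.kinetic_names]
    p0$stoich_start <- th[.stoich_names]
    Jr <- withCallingHandlers(
      wls_cost(numeric(0), p0),
      warning = function(w) invokeRestart("muffleWarning"))
    if (Jr >= 1e6) { failures <- failures + 1L; next }
    J[r] <- Jr
    if (!is.null(envelope_times)) {
      d1 <- problem$datasets[[1]]
      sim <- simulate_sbr(pmax(as.numeric(d1$measurements[1, state_components()]), 0),
                          vals_to_parameters(th, problem$variant),
                          d1$events, max(envelope_times), times = envelope_times)
      m <- as.matrix(sim$trajectory[state_components()])
      env_min <- pmin(env_min, m); env_max <- pmax(env_max, m)
    }
  }
  if (failures / n_runs > max_failure_rate)
    stop(sprintf("%d of %d Monte-Carlo runs failed", failures, n_runs),
         call. = FALSE)
  Jok <- J[!is.na(J)]
  out <- list(
    summary = tibble::tibble(runs = length(Jok), min_J = min(Jok),
                             max_J = max(Jok), mean_J = mean(Jok),
                             sd_J = stats::sd(Jok)),
    J = Jok, failures = failures
  )
  if (!is.null(envelope_times)) {
    colnames(env_min) <- colnames(env_max) <- state_components()
    out$envelope <- dplyr::bind_cols(
      tibble::tibble(time = envelope_times),
      tibble::as_tibble(env_min) |> dplyr::rename_with(~paste0(.x, "_min")),
      tibble::as_tibble(env_max) |> dplyr::rename_with(~paste0(.x, "_max"))
    )
  }
  structure(out, class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat("<monte_carlo_result>", x$failures, "failure(s)\n")
  print(x$summary)
  invisible(x)
}
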