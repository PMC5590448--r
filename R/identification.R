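#' Define a weighted least-squares identification problem
#'
#' Bundles datasets, the model variant, the free-parameter selection, box
#' bounds, the normalization matrix and optimizer settings for
#' [multistart_identify()].
#'
#' The cost is `J(theta) = sum (model - measurement)^2 / Q_cc` over all
#' experiments, retained (non-masked) cells and components, with `Q` diagonal
#' and `Q_cc` the square of the component's maximum over the identification
#' datasets, so that states of different magnitudes weigh equally. Initial
#' states default to the first measurement of each experiment; they can be
#' co-estimated by listing them as free.
#'
#' @param datasets List of `sbr_dataset` objects.
#' @param variant Model variant, `"reduced"` or `"full"`.
#' @param free Character vector naming the free parameters (subset of the
#'   kinetic/stoichiometric names; `"K_G"` only for the full variant).
#' @param free_initial_states If `TRUE`, the six initial states of every
#'   experiment are appended to the free parameters.
#' @param stoich_start Named vector of starting magnitudes for the free
#'   stoichiometric parameters (typically the MLPCA estimate).
#' @param kinetic_start Optional named vector of starting values for the free
#'   kinetic parameters (used by [wls_cost()] checks and as multistart
#'   fallback; multistart draws kinetics in `polytope`).
#' @param polytope Start region for the kinetic parameters
#'   (default [kinetic_polytope()]).
#' @param Q Optional named vector of diagonal normalization entries; defaults
#'   to the per-component squared maxima over the datasets.
#' @param bounds Optional tibble `parameter, lower, upper` overriding the
#'   default bounds (kinetics: polytope widened to `[lower/10, 10 upper]`;
#'   stoichiometry: `[0, 10 x start]`; initial states: first measurement
#'   +/- 3 noise standard deviations, floored at 0).
#' @param maxit Iteration cap of each of the three chained local
#'   minimizations (default 150).
#' @return An `identification_problem` object.
#' @export
identification_problem <- function(datasets, variant = c("reduced", "full"),
                                   free = NULL, free_initial_states = FALSE,
                                   stoich_start = NULL, kinetic_start = NULL,
                                   polytope = kinetic_polytope(), Q = NULL,
                                   bounds = NULL, maxit = 150) {
  variant <- match.arg(variant)
  if (inherits(datasets, "sbr_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  kin <- if (variant == "reduced") setdiff(.kinetic_names, "K_G") else .kinetic_names
  if (is.null(free)) free <- c(kin, .stoich_names)
  bad <- setdiff(free, c(kin, .stoich_names))
  if (length(bad)) stop("unknown or unavailable free parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  if (is.null(Q)) {
    mx <- purrr::map(datasets, function(d) {
      m <- as.matrix(d$measurements[state_components()])
      m[d$mask] <- 0  # outlier-masked cells must not drive the weighting
      apply(m, 2, max)
    }) |> purrr::reduce(pmax)
    Q <- mx^2
  } else Q <- param_state_vector(Q)
  if (any(Q <= 0)) stop("Q must be positive definite", call. = FALSE)

  # initial states: first measurement row of each experiment
  init_states <- purrr::map(datasets, ~as.numeric(.x$measurements[1, state_components()]))

  theta_names <- free
  if (free_initial_states)
    theta_names <- c(theta_names,
                     unlist(purrr::imap(datasets, ~paste0("exp", .y, "_",
                                                          state_components()))))

  prob <- structure(list(datasets = datasets, variant = variant, free = free,
                         free_initial_states = free_initial_states,
                         theta_names = theta_names,
                         stoich_start = stoich_start,
                         kinetic_start = kinetic_start,
                         polytope = polytope, Q = Q,
                         init_states = init_states, maxit = maxit),
                    class = "identification_problem")
  prob$bounds <- if (is.null(bounds)) default_bounds(prob) else bounds
  stopifnot(all(prob$bounds$lower < prob$bounds$upper))
  prob
}

default_bounds <- function(prob) {
  rows <- list()
  poly <- prob$polytope
  for (nm in prob$free) {
    if (nm %in% .kinetic_names) {
      i <- match(nm, poly$parameter)
      rows[[nm]] <- tibble::tibble(parameter = nm, lower = poly$lower[i] / 10,
                                   upper = poly$upper[i] * 10)
    } else {
      st <- if (!is.null(prob$stoich_start) && nm %in% names(prob$stoich_start))
        prob$stoich_start[[nm]] else 1
      rows[[nm]] <- tibble::tibble(parameter = nm, lower = 0,
                                   upper = 10 * max(st, 1))
    }
  }
  if (prob$free_initial_states) {
    for (e in seq_along(prob$datasets)) {
      first <- prob$init_states[[e]]
      sd3 <- 3 * prob$datasets[[e]]$sd
      halfwidth <- pmax(sd3, 0.05 * pmax(first, 1e-3))
      rows[[paste0("init", e)]] <- tibble::tibble(
        parameter = paste0("exp", e, "_", state_components()),
        lower = pmax(first - halfwidth, 0),
        upper = first + halfwidth + 1e-9
      )
    }
  }
  dplyr::bind_rows(rows)
}

# assemble the full parameter vector + per-experiment initial states from theta
unpack_theta <- function(theta, prob) {
  vals <- stats::setNames(numeric(length(.param_names)), .param_names)
  if (!is.null(prob$kinetic_start)) vals[names(prob$kinetic_start)] <- prob$kinetic_start
  if (!is.null(prob$stoich_start)) vals[names(prob$stoich_start)] <- prob$stoich_start
  nfree <- length(prob$free)
  vals[prob$free] <- theta[seq_len(nfree)]
  inits <- prob$init_states
  if (prob$free_initial_states) {
    rest <- if (nfree > 0) theta[-seq_len(nfree)] else theta
    for (e in seq_along(inits)) inits[[e]] <- rest[(e - 1) * 6 + 1:6]
  }
  list(values = vals, inits = inits)
}

#' Weighted least-squares cost
#'
#' Evaluates the normalized residual cost of a parameter vector against the
#' problem's datasets: the model is simulated through each experiment's
#' renewal schedule, sampled at the measurement times, and squared residuals
#' are summed with weights `1/Q_cc`, skipping outlier-masked cells. A failed
#' simulation yields a large penalty (with a warning) instead of an error so
#' optimizers can continue.
#'
#' @param theta Numeric vector of the free parameters, in
#'   `problem$theta_names` order.
#' @param problem An [identification_problem()].
#' @return The scalar cost `J >= 0`.
#' @export
wls_cost <- function(theta, problem) {
  up <- unpack_theta(theta, problem)
  red <- problem$variant == "reduced"
  J <- 0
  for (e in seq_along(problem$datasets)) {
    d <- problem$datasets[[e]]
    times <- d$measurements$time
    ev <- as.matrix(d$events[c("time", "G_renewal", "Gn_renewal")])
    storage.mode(ev) <- "double"
    res <- sim_sbr_cpp(pmax(up$inits[[e]], 0), up$values, red, ev, times,
                       1e-8, 1e-10)
    if (!isTRUE(res$ok)) {
      warning("simulation failure during cost evaluation; penalty applied")
      return(1e6 * (J + 1))
    }
    R <- res$trajectory - as.matrix(d$measurements[state_components()])
    R[d$mask] <- 0
    J <- J + sum(sweep(R^2, 2, problem$Q, "/"))
  }
  J
}

# three chained bounded local minimizations from one start
chained_local_fit <- function(start, problem, n_calls = 3, factr = 1e4) {
  lower <- problem$bounds$lower; upper <- problem$bounds$upper
  x <- pmin(pmax(start, lower), upper)
  best_val <- Inf; conv <- FALSE
  for (k in seq_len(n_calls)) {
    fit <- try(stats::optim(x, wls_cost, problem = problem, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = problem$maxit,
                                           factr = factr,
                                           parscale = pmax(abs(x), 1e-3))),
               silent = TRUE)
    if (inherits(fit, "try-error")) break
    x <- fit$par; best_val <- fit$value; conv <- fit$convergence == 0
  }
  list(par = x, value = best_val, converged = conv)
}

#' Multistart parameter identification
#'
#' Repeats three chained bounded local minimizations of [wls_cost()] from
#' randomly drawn starting points: the kinetic parameters are drawn uniformly
#' in the start polytope, the stoichiometric magnitudes start at the supplied
#' estimate (optionally jittered), and initial states (when free) start at
#' the first measurements. The best run and the full start table are
#' returned.
#'
#' @param problem An [identification_problem()] with `stoich_start` set for
#'   the free stoichiometric parameters.
#' @param n_starts Number of starts (default 25).
#' @param stoich_jitter Relative half-width of the uniform jitter applied to
#'   the stoichiometric starting magnitudes (default 0: all starts share the
#'   supplied estimate).
#' @param seed Integer seed making the start draws reproducible.
#' @param starts Optional list of explicit start vectors (in
#'   `problem$theta_names` order) overriding the random draws.
#' @return An `sbr_fit`: list with `estimate` (named vector of the free
#'   parameters at the optimum), `parameters` (a [model_parameters()] object
#'   completed with the estimate), `initial_states`, `J` (best residual
#'   cost), `starts` (per-start tibble), `problem`.
#' @export
multistart_identify <- function(problem, n_starts = 25, stoich_jitter = 0,
                                seed = 1L, starts = NULL) {
  stopifnot(inherits(problem, "identification_problem"), n_starts >= 1)
  withr::local_seed(seed)
  kin <- intersect(problem$free, .kinetic_names)
  sto <- intersect(problem$free, .stoich_names)
  if (length(sto) && (is.null(problem$stoich_start) ||
                      !all(sto %in% names(problem$stoich_start))))
    stop("stoich_start must cover the free stoichiometric parameters",
         call. = FALSE)
  poly <- problem$polytope

  if (!is.null(starts)) {
    starts <- purrr::map(starts, function(s) {
      stopifnot(length(s) == length(problem$theta_names))
      as.numeric(s)
    })
  } else starts <- purrr::map(seq_len(n_starts), function(s) {
    th <- stats::setNames(numeric(length(problem$theta_names)),
                          problem$theta_names)
    for (nm in kin) {
      i <- match(nm, poly$parameter)
      th[nm] <- stats::runif(1, poly$lower[i], poly$upper[i])
    }
    if (length(sto)) {
      jit <- if (stoich_jitter > 0)
        stats::runif(length(sto), 1 - stoich_jitter, 1 + stoich_jitter) else 1
      th[sto] <- problem$stoich_start[sto] * jit
    }
    if (problem$free_initial_states) {
      ii <- length(problem$free) + seq_len(6 * length(problem$datasets))
      th[ii] <- unlist(problem$init_states)
    }
    th
  })

  runs <- purrr::map(starts, chained_local_fit, problem = problem)
  ok <- purrr::map_lgl(runs, ~is.finite(.x$value))
  if (!any(ok)) stop("all identification starts failed", call. = FALSE)
  vals <- purrr::map_dbl(runs, "value")
  best_i <- which.min(vals)
  best <- runs[[best_i]]
  # polish the incumbent with a tighter tolerance
  polish <- chained_local_fit(best$par, problem, n_calls = 2, factr = 10)
  if (is.finite(polish$value) && polish$value <= best$value) best <- polish

  start_tbl <- tibble::tibble(
    start = seq_along(starts),
    J_start = purrr::map_dbl(starts, wls_cost, problem = problem),
    J_final = vals,
    converged = purrr::map_lgl(runs, "converged")
  )

  est <- stats::setNames(best$par, problem$theta_names)
  up <- unpack_theta(best$par, problem)
  pars <- vals_to_parameters(up$values, problem$variant)
  structure(list(estimate = est, parameters = pars,
                 initial_states = up$inits, J = best$value,
                 starts = start_tbl, problem = problem),
            class = "sbr_fit")
}

vals_to_parameters <- function(vals, variant) {
  model_parameters(mu_max1 = vals[["mu_max1"]], mu_max2 = vals[["mu_max2"]],
                   K_G = if (variant == "full") vals[["K_G"]] else NA_real_,
                   K_Gn = vals[["K_Gn"]], K_Gd = vals[["K_Gd"]],
                   K_Gnd = vals[["K_Gnd"]], mu_dmax = vals[["mu_dmax"]],
                   k31 = vals[["k31"]], k32 = vals[["k32"]],
                   k41 = vals[["k41"]], k42 = vals[["k42"]],
                   k52 = vals[["k52"]], k61 = vals[["k61"]],
                   k63 = vals[["k63"]], variant = variant)
}

#' @export
print.sbr_fit <- function(x, ...) {
  cat("<sbr_fit> J =", format(x$J, digits = 6), "| best of",
      nrow(x$starts), "start(s)\n")
  print(round(x$estimate, 4))
  invisible(x)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns per-term estimates; `glance()` returns one-row model
#' summaries.
#'
#' @param x A fitted object (`sbr_fit`, `subspace_fit`, `model_parameters`,
#'   `uncertainty_report`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sbr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname tidy.sbr_fit
#' @export
glance.sbr_fit <- function(x, ...) {
  tibble::tibble(J = x$J, n_starts = nrow(x$starts),
                 n_near_optimum = sum(x$starts$J_final <= 1.05 * x$J),
                 converged = any(x$starts$converged))
}

#' Plot measured data against the best-fit trajectories
#'
#' @param object An `sbr_fit`.
#' @param ... Unused.
#' @return A ggplot faceted by component, one linetype per experiment.
#' @export
autoplot.sbr_fit <- function(object, ...) {
  prob <- object$problem
  sims <- purrr::imap(prob$datasets, function(d, e) {
    sim <- simulate_sbr(pmax(object$initial_states[[e]], 0), object$parameters,
                        d$events, max(d$measurements$time))
    dplyr::mutate(tidy.sbr_simulation(sim), experiment = factor(e))
  }) |> dplyr::bind_rows()
  meas <- purrr::imap(prob$datasets, function(d, e) {
    tidyr::pivot_longer(d$measurements, -"time", names_to = "component",
                        values_to = "concentration") |>
      dplyr::mutate(experiment = factor(e),
                    component = factor(.data$component, state_components()))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(sims, ggplot2::aes(.data$time, .data$concentration,
                                     colour = .data$experiment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = meas, size = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL)
}

#' Cross-validate fixed parameters on a held-out dataset
#'
#' Keeps the kinetic and stoichiometric parameters fixed and re-estimates only
#' the initial states of the held-out experiment (initial measurement noise
#' being a critical source of degradation), then reports the residual cost.
#'
#' @param params Fixed [model_parameters()].
#' @param dataset A held-out `sbr_dataset` (disjoint from the identification
#'   data; the caller is responsible).
#' @param Q Normalization vector; defaults to the held-out dataset's maxima
#'   squared.
#' @param maxit Iteration cap per local call.
#' @return An `sbr_fit` whose free parameters are the six initial states.
#' @export
cross_validate <- function(params, dataset, Q = NULL, maxit = 150) {
  v <- param_vector(params)
  prob <- identification_problem(list(dataset),
                                 variant = if (is_reduced(params)) "reduced"
                                           else "full",
                                 free = character(0),
                                 free_initial_states = TRUE,
                                 stoich_start = v[.stoich_names],
                                 kinetic_start = v[.kinetic_names],
                                 Q = Q, maxit = maxit)
  start <- unlist(prob$init_states)
  run <- chained_local_fit(start, prob)
  up <- unpack_theta(run$par, prob)
  J0 <- wls_cost(start, prob)
  structure(list(estimate = stats::setNames(run$par, prob$theta_names),
                 parameters = params, initial_states = up$inits,
                 J = run$value,
                 starts = tibble::tibble(start = 1L,
                                         J_start = J0,
                                         J_final = run$value,
                                         converged = run$converged),
                 problem = prob),
            class = "sbr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
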