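#' Medium-renewal policy
#'
#' A renewal time together with the renewal medium composition and the
#' substrate-saving weight `alpha` of the production objective
#' `J_obj = MAb(t_renewal)^2 + MAb(t_f)^2 - alpha (G_renewal^2 +
#' Gn_renewal^2)`, where `MAb(t_renewal)` is the concentration harvested just
#' before the reset. Units are used as printed (MAb in ug/mL, substrates in
#' g/L, `alpha` dimensionless).
#'
#' @param t_renewal Renewal time (days).
#' @param G_renewal,Gn_renewal Renewal composition (g/L).
#' @param alpha Substrate-saving weight (>= 0).
#' @param bounds Named list of length-2 ranges for `t`, `G`, `Gn`
#'   (defaults: t in 3-14 d, G in 1-15 g/L, Gn in 0.1-1 g/L).
#' @return A `renewal_policy` object.
#' @export
renewal_policy <- function(t_renewal, G_renewal = 6, Gn_renewal = 0.4,
                           alpha = 0, bounds = policy_bounds()) {
  stopifnot(alpha >= 0)
  pol <- structure(list(t_renewal = t_renewal, G_renewal = G_renewal,
                        Gn_renewal = Gn_renewal, alpha = alpha,
                        bounds = bounds),
                   class = "renewal_policy")
  check_policy_bounds(pol)
  pol
}

#' @rdname renewal_policy
#' @param t,G,Gn Length-2 numeric ranges.
#' @export
policy_bounds <- function(t = c(3, 14), G = c(1, 15), Gn = c(0.1, 1)) {
  list(t = t, G = G, Gn = Gn)
}

check_policy_bounds <- function(pol) {
  b <- pol$bounds
  inb <- function(x, r) x >= r[1] - 1e-9 && x <= r[2] + 1e-9
  if (!inb(pol$t_renewal, b$t) || !inb(pol$G_renewal, b$G) ||
      !inb(pol$Gn_renewal, b$Gn))
    stop("policy outside its bounds", call. = FALSE)
  invisible(pol)
}

#' @export
print.renewal_policy <- function(x, ...) {
  cat(sprintf("<renewal_policy> t = %.3f d, G = %.3f g/L, Gn = %.3f g/L, alpha = %g\n",
              x$t_renewal, x$G_renewal, x$Gn_renewal, x$alpha))
  invisible(x)
}

#' Evaluate a renewal policy
#'
#' Simulates the two batches induced by the policy (one renewal event) and
#' evaluates the production objective. The harvested antibody concentration
#' is read immediately before the renewal reset; total production is the sum
#' of the two batch-end concentrations.
#'
#' @param policy A [renewal_policy()].
#' @param params [model_parameters()].
#' @param initial Initial [culture_state()]; default
#'   `(0.1, 0, 6, 0.4, 0, 0)`.
#' @param horizon Final time `t_f` (days, default 14).
#' @return A `policy_evaluation`: list with `J_obj`, `MAb_renewal`,
#'   `MAb_final`, `production` (ug/mL) and the `simulation`.
#' @examples
#' evaluate_policy(renewal_policy(7), hb1_parameters())
#' @export
evaluate_policy <- function(policy, params,
                            initial = culture_state(X = 0.1, G = 6, Gn = 0.4),
                            horizon = 14) {
  stopifnot(inherits(policy, "renewal_policy"), policy$t_renewal < horizon)
  sim <- simulate_sbr(initial, params,
                      renewal_events(policy$t_renewal, policy$G_renewal,
                                     policy$Gn_renewal),
                      horizon, times = c(0, policy$t_renewal, horizon))
  mab_r <- sim$events$MAb_pre[1]
  mab_f <- utils::tail(sim$trajectory$MAb, 1)
  jobj <- mab_r^2 + mab_f^2 -
    policy$alpha * (policy$G_renewal^2 + policy$Gn_renewal^2)
  structure(list(J_obj = jobj, MAb_renewal = mab_r, MAb_final = mab_f,
                 production = mab_r + mab_f, policy = policy,
                 simulation = sim),
            class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat(sprintf("<policy_evaluation> J_obj = %.4f | harvest %.2f + final %.2f = %.2f ug/mL\n",
              x$J_obj, x$MAb_renewal, x$MAb_final, x$production))
  invisible(x)
}

#' Optimize the renewal policy
#'
#' Maximizes the production objective over any subset of the policy
#' components (renewal time, glucose, glutamine) within their bounds, by
#' seeded multistart bounded local search. Components not listed in `free`
#' are held at the values supplied through `policy`.
#'
#' @param params [model_parameters()].
#' @param alpha Substrate-saving weight.
#' @param free Components to optimize, subset of `c("t", "G", "Gn")`.
#' @param policy Starting [renewal_policy()] supplying the fixed components.
#' @param initial,horizon As in [evaluate_policy()].
#' @param n_starts Multistart count (default 10, uniform in the bounds).
#' @param seed Integer seed.
#' @param extra_starts Optional matrix/list of additional start points (rows
#'   in the order of `free`), e.g. a warm start from a previous solution.
#' @return A `policy_optimum`: list with `policy` (best), `evaluation`,
#'   `starts` (per-start table).
#' @export
optimize_policy <- function(params, alpha = 0, free = c("t", "G", "Gn"),
                            policy = renewal_policy(7, alpha = alpha),
                            initial = culture_state(X = 0.1, G = 6, Gn = 0.4),
                            horizon = 14, n_starts = 10, seed = 1L,
                            extra_starts = NULL) {
  free <- match.arg(free, c("t", "G", "Gn"), several.ok = TRUE)
  stopifnot(length(free) >= 1, n_starts >= 1)
  policy$alpha <- alpha
  b <- policy$bounds
  lower <- c(t = b$t[1], G = b$G[1], Gn = b$Gn[1])[free]
  upper <- c(t = b$t[2], G = b$G[2], Gn = b$Gn[2])[free]

  make_policy <- function(x) {
    v <- c(t = policy$t_renewal, G = policy$G_renewal, Gn = policy$Gn_renewal)
    v[free] <- x
    renewal_policy(v[["t"]], v[["G"]], v[["Gn"]], alpha = alpha, bounds = b)
  }
  negobj <- function(x) {
    ev <- try(evaluate_policy(make_policy(x), params, initial, horizon),
              silent = TRUE)
    if (inherits(ev, "try-error")) return(1e12)
    -ev$J_obj
  }

  withr::local_seed(seed)
  starts <- purrr::map(seq_len(n_starts),
                       ~stats::runif(length(free), lower, upper))
  if (!is.null(extra_starts)) {
    if (is.matrix(extra_starts))
      extra_starts <- asplit(extra_starts, 1)
    starts <- c(purrr::map(extra_starts, ~pmin(pmax(as.numeric(.x), lower), upper)),
                starts)
  }

  runs <- purrr::map(starts, function(s) {
    fit <- try(stats::optim(s, negobj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(parscale = pmax(abs(s), 0.1))),
               silent = TRUE)
    if (inherits(fit, "try-error")) list(par = s, value = Inf, ok = FALSE)
    else list(par = fit$par, value = fit$value, ok = TRUE)
  })
  if (!any(purrr::map_lgl(runs, "ok")))
    stop("all policy-optimization starts failed", call. = FALSE)
  vals <- purrr::map_dbl(runs, "value")
  best <- runs[[which.min(vals)]]
  pol <- make_policy(best$par)
  structure(list(policy = pol,
                 evaluation = evaluate_policy(pol, params, initial, horizon),
                 starts = tibble::tibble(
                   start = seq_along(runs),
                   J_obj = -vals,
                   t = purrr::map_dbl(runs, ~make_policy(.x$par)$t_renewal),
                   G = purrr::map_dbl(runs, ~make_policy(.x$par)$G_renewal),
                   Gn = purrr::map_dbl(runs, ~make_policy(.x$par)$Gn_renewal))),
            class = "policy_optimum")
}

#' @export
print.policy_optimum <- function(x, ...) {
  print(x$policy); print(x$evaluation)
  invisible(x)
}

#' Sweep the substrate-saving weight
#'
#' Re-optimizes the policy over a grid of `alpha` values, warm-starting each
#' optimization from the previous optimum in addition to fresh random starts.
#' Failures at single grid points are recorded and the sweep continues.
#'
#' @param params [model_parameters()].
#' @param alpha_grid Nonnegative weights (e.g. `seq(0, 500, by = 50)`).
#' @param free,policy,initial,horizon,n_starts,seed As in [optimize_policy()].
#' @return An `alpha_sweep` object: tibble with columns `alpha, t, G, Gn,
#'   production, J_obj, ok`.
#' @export
alpha_sweep <- function(params, alpha_grid, free = c("t", "G", "Gn"),
                        policy = renewal_policy(7),
                        initial = culture_state(X = 0.1, G = 6, Gn = 0.4),
                        horizon = 14, n_starts = 10, seed = 1L) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0))
  warm <- NULL
  rows <- purrr::map(seq_along(alpha_grid), function(i) {
    a <- alpha_grid[i]
    res <- try(optimize_policy(params, alpha = a, free = free, policy = policy,
                               initial = initial, horizon = horizon,
                               n_starts = n_starts, seed = seed + i - 1L,
                               extra_starts = warm),
               silent = TRUE)
    if (inherits(res, "try-error"))
      return(tibble::tibble(alpha = a, t = NA_real_, G = NA_real_,
                            Gn = NA_real_, production = NA_real_,
                            J_obj = NA_real_, ok = FALSE))
    warm <<- matrix(c(res$policy$t_renewal, res$policy$G_renewal,
                      res$policy$Gn_renewal)[match(free, c("t", "G", "Gn"))],
                    nrow = 1)
    tibble::tibble(alpha = a, t = res$policy$t_renewal,
                   G = res$policy$G_renewal, Gn = res$policy$Gn_renewal,
                   production = res$evaluation$production,
                   J_obj = res$evaluation$J_obj, ok = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("alpha_sweep", class(out))
  out
}

#' Plot an alpha sweep
#'
#' @param object An [alpha_sweep()] result.
#' @param ... Unused.
#' @return A ggplot of the optimal policy components and production vs alpha.
#' @export
autoplot.alpha_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("t", "G", "Gn", "production"),
                            names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(alpha), y = NULL)
}
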