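test_that("forward sensitivities agree with central finite differences", {
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  ev <- renewal_events(7, 6, 0.4)
  free <- c("mu_max1", "mu_max2", "K_Gn", "k41", "k61", "mu_dmax")
  sens <- sensitivities(ref_params, init, ev, 14, free = free, times = 0:14)
  for (par in free) {
    v0 <- as.double(ref_params)[[par]]
    h <- 1e-5 * max(abs(v0), 0.1)
    # the difference quotient inherits the solver error amplified by 1/h, so
    # the oracle runs at much tighter tolerances than the sensitivity system
    sp <- simulate_sbr(init, update_parameters(ref_params,
                                               stats::setNames(v0 + h, par)),
                       ev, 14, times = 0:14, rtol = 1e-12, atol = 1e-14)
    sm <- simulate_sbr(init, update_parameters(ref_params,
                                               stats::setNames(v0 - h, par)),
                       ev, 14, times = 0:14, rtol = 1e-12, atol = 1e-14)
    for (comp in state_components()) {
      fd <- (sp$trajectory[[comp]] - sm$trajectory[[comp]]) / (2 * h)
      scale <- max(abs(fd))
      comp_scale <- max(abs(sp$trajectory[[comp]]), 1)
      if (scale < 1e-5 * comp_scale) {
        # structurally insensitive pair: the quotient is pure solver noise,
        # so only require that the forward system agrees it is negligible
        expect_lt(max(abs(sens$S[, comp, par])), 1e-5 * comp_scale)
      } else {
        expect_lt(max(abs(sens$S[, comp, par] - fd)) / scale, 1e-4)
      }
    }
  }
})

test_that("initial-state sensitivities start at the identity block", {
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  sens <- sensitivities(ref_params, init, renewal_events(), 3,
                        free = c("mu_max1", "init_X", "init_G"), times = 0:3)
  expect_equal(sens$S[1, , "mu_max1"], stats::setNames(rep(0, 6),
                                                       state_components()))
  expect_equal(unname(sens$S[1, , "init_X"]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(sens$S[1, , "init_G"]), c(0, 0, 1, 0, 0, 0))
  # and the X sensitivity to X0 grows with the culture
  expect_gt(sens$S[4, "X", "init_X"], 1)
})

test_that("parameters of an inactive death pathway have zero sensitivity", {
  p0 <- update_parameters(ref_params, mu_dmax = 0)
  sens <- sensitivities(p0, culture_state(X = 0.1, G = 6, Gn = 0.4),
                        renewal_events(), 5, free = c("K_Gd", "K_Gnd"),
                        times = 0:5)
  expect_equal(max(abs(sens$S)), 0)
})

test_that("glutamine can only fall with a larger oxidative glutamine yield", {
  sens <- sensitivities(ref_params, culture_state(X = 0.1, G = 6, Gn = 0.4),
                        renewal_events(), 6, free = "k41", times = 0:6)
  expect_true(all(sens$S[, "Gn", "k41"] <= 1e-10))
})

test_that("the FIM is additive over samples and flags dead parameters", {
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  sens <- sensitivities(ref_params, init, renewal_events(), 6,
                        free = c("mu_max1", "mu_max2"), times = 0:6)
  Q <- stats::setNames(rep(2, 6), state_components())
  f1 <- fisher_information(sens, Q, 0:6)
  f2 <- fisher_information(sens, Q, rep(0:6, each = 2))
  expect_equal(f2$fim, 2 * f1$fim, tolerance = 1e-12)
  expect_true(all(eigen(f1$fim, symmetric = TRUE)$values >= 0))

  p0 <- update_parameters(ref_params, mu_dmax = 0)
  sens0 <- sensitivities(p0, init, renewal_events(), 6,
                         free = c("mu_max1", "K_Gd"), times = 0:6)
  f0 <- fisher_information(sens0, Q, 0:6)
  expect_equal(f0$zero_parameters, "K_Gd")
  expect_true(f0$singular)
})

test_that("the linear toy model reproduces textbook least-squares uncertainty", {
  # y = theta1 + theta2 * t observed at t = 0..9 in one channel, Q_cc = q
  tgrid <- 0:9
  np <- 2
  S <- array(0, c(length(tgrid), 6, np),
             dimnames = list(NULL, state_components(), c("a", "b")))
  S[, "X", "a"] <- 1
  S[, "X", "b"] <- tgrid
  sens <- structure(list(times = tgrid, state = NULL, S = S,
                         free = c("a", "b")),
                    class = "sensitivity_trajectory")
  q <- 0.49
  Q <- stats::setNames(c(q, rep(1e6, 5)), state_components())
  # the five dead channels contribute ~nothing through their huge variance
  rep1 <- fisher_information(sens, Q, tgrid)
  Xd <- cbind(1, tgrid)
  expect_equal(unname(rep1$fim), unname(crossprod(Xd) / q), tolerance = 1e-9)

  J_star <- 3.1
  rep2 <- parameter_covariance(rep1, J_star, n_meas_total = 10,
                               estimate = c(a = 2, b = 0.5))
  sigma2 <- J_star / (10 - 2)
  expect_equal(unname(rep2$P), unname(sigma2 * solve(crossprod(Xd) / q)),
               tolerance = 1e-6)
  expect_equal(unname(rep2$relative_sd["a"]),
               100 * sqrt(sigma2 * solve(crossprod(Xd) / q)[1, 1]) / 2,
               tolerance = 1e-6)
})

test_that("covariance scales linearly with the normalization", {
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  sens <- sensitivities(ref_params, init, renewal_events(), 6,
                        free = c("mu_max1", "mu_max2"), times = 0:6)
  Q1 <- stats::setNames(rep(1, 6), state_components())
  c2 <- 9
  r1 <- parameter_covariance(fisher_information(sens, Q1, 0:6), 2, 42,
                             c(mu_max1 = 0.4849, mu_max2 = 0.3198))
  r2 <- parameter_covariance(fisher_information(sens, c2 * Q1, 0:6), 2, 42,
                             c(mu_max1 = 0.4849, mu_max2 = 0.3198))
  expect_equal(r2$P, c2 * r1$P, tolerance = 1e-9)
  expect_equal(r2$relative_sd, sqrt(c2) * r1$relative_sd, tolerance = 1e-9)
})

test_that("a full-model fit at low glucose shows the overparametrization signature", {
  # glucose stays far above K_G, so G/(K_G+G) is ~1 and K_G is barely
  # identifiable: its relative standard deviation dwarfs the others
  v <- as.double(ref_params)
  full <- model_parameters(mu_max1 = v["mu_max1"], mu_max2 = v["mu_max2"],
                           K_G = 0.05, K_Gn = v["K_Gn"], K_Gd = v["K_Gd"],
                           K_Gnd = v["K_Gnd"], mu_dmax = v["mu_dmax"],
                           k31 = v["k31"], k32 = v["k32"], k41 = v["k41"],
                           k42 = v["k42"], k52 = v["k52"], k61 = v["k61"],
                           k63 = v["k63"], variant = "full")
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  free <- c("mu_max1", "mu_max2", "K_G", "K_Gn", "mu_dmax")
  sens <- sensitivities(full, init, renewal_events(7), 15, free = free,
                        times = 0:15)
  sim <- simulate_sbr(init, full, renewal_events(7), 15, times = 0:15)
  Q <- apply(sim$trajectory[state_components()], 2, max)^2
  rep <- parameter_covariance(fisher_information(sens, Q, 0:15),
                              J_star = 1.2, n_meas_total = 96,
                              estimate = as.double(full)[free])
  rel <- rep$relative_sd
  expect_gt(rel[["K_G"]], 10 * max(rel[setdiff(free, "K_G")]))
})

test_that("Monte-Carlo propagation is degenerate at zero spread and seeded", {
  sets <- generate_experiments(ref_params, seed = 13)
  prob <- identification_problem(sets, stoich_start = ref_stoich_start())
  zero <- stats::setNames(rep(0, 4), c("mu_max1", "mu_max2", "k41", "k61"))
  mc0 <- monte_carlo(ref_params, zero, prob, n_runs = 5, seed = 1)
  expect_equal(mc0$summary$min_J, mc0$summary$max_J)
  expect_equal(mc0$summary$mean_J, mc0$summary$min_J)
  expect_equal(mc0$summary$sd_J, 0)

  rel <- hb1_relative_sd()
  a <- monte_carlo(ref_params, rel, prob, n_runs = 30, seed = 4)
  b <- monte_carlo(ref_params, rel, prob, n_runs = 30, seed = 4)
  expect_identical(a$summary, b$summary)
  expect_equal(a$summary$runs, 30)
})

test_that("widening the parameter spread inflates the mean residual cost", {
  sets <- generate_experiments(ref_params, seed = 13)
  prob <- identification_problem(sets, stoich_start = ref_stoich_start())
  rel <- hb1_relative_sd()
  means <- purrr::map_dbl(c(0.5, 1, 2), function(s)
    monte_carlo(ref_params, s * rel, prob, n_runs = 400, seed = 2)$summary$mean_J)
  expect_true(all(diff(means) > 0))
})

test_that("Monte-Carlo envelopes bracket the central trajectory", {
  sets <- generate_experiments(ref_params, seed = 13)
  prob <- identification_problem(sets, stoich_start = ref_stoich_start())
  mc <- monte_carlo(ref_params, hb1_relative_sd(), prob, n_runs = 20, seed = 6,
                    envelope_times = 0:15)
  env <- mc$envelope
  expect_true(all(env$X_min <= env$X_max))
  central <- simulate_sbr(pmax(as.numeric(
    sets[[1]]$measurements[1, state_components()]), 0), ref_params,
    sets[[1]]$events, 15, times = 0:15)
  expect_true(all(env$MAb_min <= central$trajectory$MAb + 1e-9))
})
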