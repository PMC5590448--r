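test_that("reaction rates reproduce hand-evaluated values", {
  s <- culture_state(X = 1, G = 2, Gn = 0.4)
  r <- reaction_rates(s, ref_params)

  phiG <- 0.4849 * 0.4 / (0.0089 + 0.4)
  expect_equal(unname(r["phi1"]), 0.3198, tolerance = 1e-10)
  expect_equal(unname(r["phi2"]), phiG - 0.3198, tolerance = 1e-10)
  expect_equal(unname(r["phi1"] + r["phi2"]), phiG, tolerance = 1e-12)
  # death rate with inverse Monod factors
  expect_equal(unname(r["phi3"]),
               0.8667 * (1.5899 / 3.5899) * (1.3359 / 1.7359),
               tolerance = 1e-10)
  expect_equal(unname(r["phi3"]), 0.2954, tolerance = 1e-3)
})

test_that("rates vanish with biomass or substrate and reject bad states", {
  expect_equal(unname(reaction_rates(culture_state(X = 0, G = 5, Gn = 0.4),
                                     ref_params)),
               c(0, 0, 0))
  r <- reaction_rates(culture_state(X = 2, G = 3, Gn = 0), ref_params)
  expect_equal(unname(r[c("phi1", "phi2")]), c(0, 0))
  expect_equal(unname(r["phi3"]),
               0.8667 * 1.5899 / (1.5899 + 3) * 2, tolerance = 1e-12)

  expect_error(reaction_rates(c(1, -0.1, 2, 0.3, 0, 0), ref_params),
               "invalid culture state")
  expect_error(reaction_rates(c(1, NaN, 2, 0.3, 0, 0), ref_params),
               "invalid culture state")
})

test_that("bottleneck switching holds across random states and parameters", {
  withr::local_seed(99)
  for (i in 1:50) {
    p <- model_parameters(mu_max1 = runif(1, 0.1, 1), mu_max2 = runif(1, 0.1, 1),
                          K_G = runif(1, 0.01, 1), K_Gn = runif(1, 0.01, 1),
                          K_Gd = runif(1, 0.1, 10), K_Gnd = runif(1, 0.1, 10),
                          mu_dmax = runif(1, 0.1, 1),
                          k31 = runif(1, 0, 20), k32 = runif(1, 0, 20),
                          k41 = runif(1, 0, 2), k42 = runif(1, 0, 2),
                          k52 = runif(1, 0, 30), k61 = runif(1, 0, 50),
                          k63 = runif(1, 0, 20),
                          variant = sample(c("full", "reduced"), 1))
    s <- culture_state(X = runif(1, 0, 2), Xd = runif(1, 0, 1),
                       G = runif(1, 0, 7), Gn = runif(1, 0, 0.5))
    r <- reaction_rates(s, p)
    v <- as.double(p)
    phiG <- v["mu_max1"] * s["Gn"] / (v["K_Gn"] + s["Gn"]) * s["X"]
    if (p$variant == "full") phiG <- phiG * s["G"] / (v["K_G"] + s["G"])
    phimax <- v["mu_max2"] * s["X"]
    expect_true(all(r >= 0))
    expect_equal(unname(r["phi1"] + r["phi2"]), unname(phiG), tolerance = 1e-12)
    expect_lte(r["phi1"], phimax + 1e-12)
    expect_equal(unname(r["phi2"]) > 1e-14, unname(phiG > phimax + 1e-14))
  }
})

test_that("mass balances compose the rates with the stoichiometric signs", {
  expect_equal(unname(ode_rhs(culture_state(), ref_params)), rep(0, 6))

  s <- culture_state(X = 1, G = 2, Gn = 0.4)
  d <- ode_rhs(s, ref_params)
  r <- reaction_rates(s, ref_params)
  expect_equal(unname(d["G"]),
               unname(-3.1207 * r["phi1"] - 15.2090 * r["phi2"]),
               tolerance = 1e-12)
  expect_equal(unname(d["G"]), -3.3486, tolerance = 1e-4)
  expect_lte(d["G"], 0); expect_lte(d["Gn"], 0)
  expect_gte(d["Xd"], 0); expect_gte(d["L"], 0); expect_gte(d["MAb"], 0)

  # below the oxidative bottleneck no lactate is formed
  p_slow <- update_parameters(ref_params, mu_max2 = 10)
  d2 <- ode_rhs(s, p_slow)
  expect_equal(unname(d2["L"]), 0)
})

test_that("renewal events implement the medium-replacement semantics", {
  p0 <- model_parameters(mu_max1 = 0, mu_max2 = 0, K_Gn = 0.1, K_Gd = 1,
                         K_Gnd = 1, mu_dmax = 0,
                         k31 = 1, k32 = 1, k41 = 1, k42 = 1, k52 = 1,
                         k61 = 1, k63 = 1)
  init <- culture_state(X = 0.3, Xd = 0.2, G = 2, Gn = 0.1, L = 1.5, MAb = 9)
  sim <- simulate_sbr(init, p0, renewal_events(7, 6, 0.4), horizon = 10,
                      times = c(0, 3, 6.999, 7, 10))
  tr <- sim$trajectory
  # constant before the event
  expect_equal(as.numeric(tr[tr$time == 6.999, -1]), unname(init),
               tolerance = 1e-12)
  # post-event: substrates set, metabolites withdrawn, biomass kept
  post <- as.numeric(tr[tr$time == 7, -1])
  expect_equal(post, c(0.3, 0.2, 6, 0.4, 0, 0), tolerance = 1e-12)
  expect_equal(sim$events$MAb_pre[1], 9, tolerance = 1e-12)
  expect_equal(as.numeric(tr[tr$time == 10, -1]), c(0.3, 0.2, 6, 0.4, 0, 0),
               tolerance = 1e-12)

  expect_error(simulate_sbr(init, p0, renewal_events(12), horizon = 10),
               "inside the simulation horizon")
  expect_error(renewal_events(c(5, 3)), "strictly increasing")
})

test_that("glutamine never increases within a batch", {
  sim <- simulate_sbr(culture_state(X = 0.1, G = 6, Gn = 0.4), ref_params,
                      horizon = 15)
  expect_true(all(diff(sim$trajectory$Gn) <= 1e-10))
})

test_that("adaptive integrator matches the fine-step RK4 reference", {
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  ev <- renewal_events(7, 6, 0.4)
  times <- seq(0, 14, by = 0.5)
  s45 <- simulate_sbr(init, ref_params, ev, 14, times = times)
  sr4 <- simulate_sbr(init, ref_params, ev, 14, times = times, engine = "rk4",
                      rk4_dt = 1e-3)
  a <- as.matrix(s45$trajectory[-1]); b <- as.matrix(sr4$trajectory[-1])
  scale <- matrix(apply(abs(b), 2, max), nrow(b), 6, byrow = TRUE)
  expect_lt(max(abs(a - b) / scale), 1e-5)

  slsoda <- simulate_sbr(init, ref_params, ev, 14, times = times,
                         engine = "lsoda")
  c2 <- as.matrix(slsoda$trajectory[-1])
  expect_lt(max(abs(a - c2) / scale), 1e-5)
})

test_that("substrate losses satisfy the linear conservation relations", {
  # eliminate the rate integrals: I2 = L/k52, and both substrate balances
  # must then agree on I1
  v <- as.double(ref_params)
  sim <- simulate_sbr(culture_state(X = 0.1, G = 6.5, Gn = 0.35), ref_params,
                      horizon = 10, times = seq(0, 10, 0.5))
  tr <- sim$trajectory
  I2 <- tr$L / v["k52"]
  I1_from_G <- (6.5 - tr$G - v["k32"] * I2) / v["k31"]
  I1_from_Gn <- (0.35 - tr$Gn - v["k42"] * I2) / v["k41"]
  expect_equal(I1_from_G, I1_from_Gn, tolerance = 1e-6)
  # and the biomass balance closes: X - X0 + Xd = I1 + I2
  expect_equal(tr$X - 0.1 + tr$Xd, I1_from_G + I2, tolerance = 1e-6)
})

test_that("the full model approaches the reduced one as K_G vanishes", {
  init <- culture_state(X = 0.1, G = 6, Gn = 0.4)
  times <- seq(0, 10, 0.5)
  red <- simulate_sbr(init, ref_params, horizon = 10, times = times)
  prev <- Inf
  for (kg in c(1e-2, 1e-4, 1e-6)) {
    v <- as.double(ref_params)
    full <- model_parameters(mu_max1 = v["mu_max1"], mu_max2 = v["mu_max2"],
                             K_G = kg, K_Gn = v["K_Gn"], K_Gd = v["K_Gd"],
                             K_Gnd = v["K_Gnd"], mu_dmax = v["mu_dmax"],
                             k31 = v["k31"], k32 = v["k32"], k41 = v["k41"],
                             k42 = v["k42"], k52 = v["k52"], k61 = v["k61"],
                             k63 = v["k63"], variant = "full")
    sf <- simulate_sbr(init, full, horizon = 10, times = times)
    dif <- max(abs(as.matrix(sf$trajectory[-1]) - as.matrix(red$trajectory[-1])))
    expect_lt(dif, prev)
    prev <- dif
  }
  expect_lt(prev, 1e-4)
})

test_that("trajectory tidier and plot builders work", {
  sim <- simulate_sbr(culture_state(X = 0.1, G = 6, Gn = 0.4), ref_params,
                      renewal_events(7), 14, times = 0:14)
  td <- tidy(sim)
  expect_named(td, c("time", "component", "concentration"))
  expect_equal(nrow(td), 15 * 6)
  expect_s3_class(autoplot(sim), "ggplot")
})
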