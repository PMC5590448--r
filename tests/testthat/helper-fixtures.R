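# shared fixtures built in code

ref_params <- hb1_parameters()

stoich_names <- c("k31", "k32", "k41", "k42", "k52", "k61", "k63")
kin_reduced <- c("mu_max1", "mu_max2", "K_Gn", "K_Gd", "K_Gnd", "mu_dmax")

ref_stoich_start <- function() as.double(ref_params)[stoich_names]

# true stoichiometric matrix implied by a parameter set (signs per the
# oxidation / overflow / death scheme, biomass yields normalized to 1)
true_K <- function(params = ref_params) {
  v <- as.double(params)
  matrix(c( 1,        1,        -1,
            0,        0,         1,
           -v["k31"], -v["k32"],  0,
           -v["k41"], -v["k42"],  0,
            0,        v["k52"],   0,
            v["k61"], 0,          v["k63"]),
         nrow = 6, byrow = TRUE,
         dimnames = list(state_components(), NULL))
}

# noiseless campaign sampled on a tight-tolerance simulation, wrapped as
# sbr_dataset objects with a stated (not injected) noise level
precise_campaign <- function(stated_sd_frac = 0.05, n_experiments = 2,
                             horizon = 15, renewal_day = 7) {
  times <- 0:horizon
  events <- renewal_events(renewal_day, 6, 0.4)
  X0 <- 0.1; Xd0 <- 0
  sets <- list()
  for (e in seq_len(n_experiments)) {
    init <- culture_state(X = X0, Xd = Xd0, G = 6, Gn = 0.4)
    sim <- simulate_sbr(init, ref_params, events, horizon, times = times,
                        rtol = 1e-11, atol = 1e-13)
    m <- sim$trajectory
    last <- as.numeric(m[nrow(m), state_components()])
    X0 <- last[1]; Xd0 <- last[2]
    sets[[e]] <- sbrmab:::new_sbr_dataset(
      measurements = m,
      mask = matrix(FALSE, nrow(m), 6,
                    dimnames = list(NULL, state_components())),
      events = events,
      sd = stats::setNames(
        stated_sd_frac * apply(m[state_components()], 2, max),
        state_components()),
      truth = list(params = ref_params, initial = init,
                   clean = as.matrix(m[state_components()]))
    )
  }
  sets
}

# largest principal angle (radians) between the column spaces of two bases,
# via the sine formulation, which stays accurate for tiny angles
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  res <- qa - qb %*% crossprod(qb, qa)
  asin(min(1, max(svd(res)$d)))
}
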