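test_that("differential transform counts within-batch pairs and drops masked rows", {
  sets <- generate_experiments(ref_params, seed = 2)
  # 16 daily samples, renewal at day 7: segments of 7 and 9 samples
  d <- differential_transform(sets[[1]])
  expect_equal(nrow(d$D), 6 + 8)
  expect_equal(nrow(differential_transform(sets)$D), 28)
  # per-row variance is the sum of the two samples' variances
  expect_equal(d$var[1, ], unname(2 * sets[[1]]$sd^2))

  masked <- inject_outliers(sets[[1]], "Gn", samples = 14:16, offset = 0.1)
  # 3 trailing samples flagged: second segment keeps 6 samples -> 5 rows
  expect_equal(nrow(differential_transform(masked)$D), 6 + 5)

  allmasked <- sets[[1]]
  allmasked$mask[] <- TRUE
  expect_error(differential_transform(allmasked), "no usable")
})

test_that("constant measurements difference to zero rows", {
  sets <- generate_experiments(ref_params, seed = 2)
  d <- sets[[1]]
  d$measurements[state_components()] <-
    tibble::as_tibble(matrix(1, 16, 6, dimnames = list(NULL, state_components())))
  expect_equal(max(abs(differential_transform(d)$D)), 0)
})

test_that("noiseless difference vectors lie in the column space of K", {
  sets <- precise_campaign()
  D <- differential_transform(sets)$D
  K <- true_K()
  Qk <- qr.Q(qr(K))
  resid <- D - D %*% Qk %*% t(Qk)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("the full space has zero cost and J_p never increases in p", {
  sets <- generate_experiments(ref_params, seed = 4)
  diffs <- differential_transform(sets)
  expect_equal(mlpca_fit(diffs, 6)$J, 0)
  for (seed in 1:3) {
    sets <- generate_experiments(ref_params, seed = seed)
    J <- purrr::map_dbl(1:6, ~mlpca_fit(differential_transform(sets), .x)$J)
    expect_true(all(diff(J) <= 1e-8))
  }
})

test_that("MLPCA reduces to ordinary PCA under a uniform covariance", {
  withr::local_seed(8)
  D <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(5, 3, 2, 1, 0.5, 0.2))
  colnames(D) <- state_components()
  diffs <- structure(list(D = D, var = matrix(1, 40, 6),
                          info = tibble::tibble()),
                     class = "sbr_differences")
  for (p in c(1, 2, 3)) {
    fit <- mlpca_fit(diffs, p)
    Vpca <- svd(D, nu = 0, nv = p)$v
    expect_lt(principal_angle(fit$basis, Vpca), 1e-8)
    # and the cost equals the sum of discarded squared singular values
    expect_equal(fit$J, sum(svd(D)$d[-(1:p)]^2), tolerance = 1e-8)
  }
})

test_that("heteroscedastic MLPCA matches a brute-force subspace search", {
  withr::local_seed(12)
  n <- 6
  D <- matrix(rnorm(n * 6), n, 6)
  colnames(D) <- state_components()
  vars <- matrix(runif(n * 6, 0.05, 2), n, 6)
  diffs <- structure(list(D = D, var = vars, info = tibble::tibble()),
                     class = "sbr_differences")
  p <- 2
  fit <- mlpca_fit(diffs, p, n_restarts = 8)

  # oracle: generic optimizer over an unconstrained 6 x p parametrization
  Jof <- function(vpar) {
    V <- qr.Q(qr(matrix(vpar, 6, p)))
    J <- 0
    for (i in 1:n) {
      w <- 1 / vars[i, ]
      A <- crossprod(V, w * V)
      b <- solve(A, crossprod(V, w * D[i, ]))
      r <- D[i, ] - V %*% b
      J <- J + sum(w * r^2)
    }
    J
  }
  best <- Inf
  for (k in 1:20) {
    o <- stats::optim(rnorm(6 * p), Jof, control = list(maxit = 2000,
                                                        reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$J, best, tolerance = 1e-6)
})

test_that("exact low-rank data give zero cost and the right dimension", {
  withr::local_seed(21)
  # two-reaction generator: random coefficients on two K columns
  K2 <- true_K()[, 1:2]
  D <- matrix(runif(30 * 2, -1, 1), 30, 2) %*% t(K2)
  colnames(D) <- state_components()
  diffs <- structure(list(D = D, var = matrix(1e-4, 30, 6),
                          info = tibble::tibble()),
                     class = "sbr_differences")
  sel <- select_reaction_count(diffs)
  expect_equal(sel$p, 2)
  expect_lt(sel$table$J[2], 1e-12)
  expect_lt(principal_angle(sel$fits[[2]]$basis, K2), 1e-6)
  expect_true(all(sel$table$below_lower[2:6]))
})

test_that("the campaign supports three reactions at high assay precision", {
  # at 0.5% of max the weak death direction is resolvable and the chi-square
  # criterion settles on the generating three-reaction scheme
  for (seed in 1:3) {
    sets <- generate_experiments(ref_params,
                                 noise = error_model(relative_sd = 0.005),
                                 seed = seed)
    sel <- select_reaction_count(differential_transform(sets))
    expect_equal(sel$p, 3)
  }
})

test_that("noiseless synthetic differences recover the generating subspace", {
  sets <- precise_campaign(stated_sd_frac = 0.01)
  diffs <- differential_transform(sets)
  fit <- mlpca_fit(diffs, 3)
  expect_lt(fit$J / nrow(diffs$D), 1e-6)
  expect_lt(principal_angle(fit$basis, true_K()), 1e-4)
})

test_that("constrained recovery reproduces the reference stoichiometry", {
  K <- constrained_stoichiometry(hb1_subspace_basis(), hb1_constraints())
  # cited entries at 0.5%
  expect_equal(K["G", 1], -3.2892, tolerance = 0.005)
  expect_equal(K["L", 2], 25.4828, tolerance = 0.005)
  # every constraint reproduced essentially exactly
  expect_equal(unname(K["X", ]), c(1, 1, -1), tolerance = 1e-10)
  expect_equal(unname(K["Xd", ]), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(unname(K[c("L", "MAb"), c(1, 2)][c(1, 4)]), c(0, 0),
               tolerance = 1e-10)
})

test_that("constrained recovery on an elementary basis is the identity geometry", {
  rho <- diag(6)[, c(1, 2, 5)]
  cons <- tibble::tribble(
    ~reaction, ~component, ~value,
    1L, "X", 1, 1L, "Xd", 0, 1L, "L", 0,
    2L, "X", 0, 2L, "Xd", 1, 2L, "L", 0,
    3L, "X", 0, 3L, "Xd", 0, 3L, "L", 1)
  K <- constrained_stoichiometry(rho, cons)
  expect_equal(unname(K[c("X", "Xd", "L"), ]), diag(3))
  expect_equal(unname(K[c("G", "Gn", "MAb"), ]), matrix(0, 3, 3))
})

test_that("infeasible constraint systems are reported by column", {
  rho <- diag(6)[, c(1, 2, 5)]  # basis touching only X, Xd, L
  cons <- hb1_constraints()
  # constraining Gn, L, MAb pins two components the basis cannot reach
  cons$component[cons$reaction == 2] <- c("Gn", "L", "MAb")
  expect_error(constrained_stoichiometry(rho, cons), "reaction 2")
})

test_that("simplification zeroes only the negligible third-reaction substrates", {
  K <- constrained_stoichiometry(hb1_subspace_basis(), hb1_constraints())
  expect_equal(simplify_stoichiometry(K, 0)$K, K)
  s <- simplify_stoichiometry(K, 0.1)
  expect_equal(s$K["G", 3], 0)
  expect_equal(s$K["Gn", 3], 0)
  expect_equal(sort(paste0(s$changes$component, s$changes$reaction)),
               c("G3", "Gn3"))
  keep <- !(row(K) %in% c(3, 4) & col(K) == 3)
  expect_equal(s$K[keep], K[keep])

  Z <- matrix(0, 6, 3, dimnames = list(state_components(), NULL))
  expect_equal(simplify_stoichiometry(Z, 0.5)$K, Z)
})

test_that("stoichiometry is recovered end to end from a noiseless campaign", {
  sets <- precise_campaign(stated_sd_frac = 0.01)
  fit <- mlpca_fit(differential_transform(sets), 3)
  K <- constrained_stoichiometry(fit, hb1_constraints())
  expect_equal(unname(K), unname(true_K()), tolerance = 1e-4)
})
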