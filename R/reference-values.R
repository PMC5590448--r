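#' Reference parameter set identified for the HB1 hybridoma strain
#'
#' Best-run estimates of the reduced (glutamine-driven) overflow model,
#' identified from a sequential-batch campaign of the HB1 hybridoma strain,
#' together with their relative estimation-error standard deviations (percent).
#' Rates are interpreted in 1/day on a time axis in days.
#'
#' These values serve as the package's worked-example fixture: the
#' synthetic-data generator uses them as the default ground truth, and the
#' renewal-optimization examples evaluate them.
#'
#' @return [hb1_parameters()]: a [model_parameters()] object (reduced variant).
#' @export
hb1_parameters <- function() {
  model_parameters(
    mu_max1 = 0.4849, mu_max2 = 0.3198,
    K_Gn = 0.0089, K_Gd = 1.5899, K_Gnd = 1.3359, mu_dmax = 0.8667,
    k31 = 3.1207, k32 = 15.2090,
    k41 = 0.6245, k42 = 1.2221,
    k52 = 23.9586,
    k61 = 43.5907, k63 = 14.2221,
    variant = "reduced"
  )
}

#' @rdname hb1_parameters
#' @return [hb1_relative_sd()]: named vector of relative standard
#'   deviations (%) of the same estimates.
#' @export
hb1_relative_sd <- function() {
  c(mu_max1 = 1.7652, mu_max2 = 8.1283, K_Gn = 23.2540, K_Gd = 15.4666,
    K_Gnd = 49.2893, mu_dmax = 66.5216, k31 = 34.1265, k32 = 26.3604,
    k41 = 9.5667, k42 = 19.2377, k52 = 20.3273, k61 = 8.3527, k63 = 10.9999)
}

#' Multistart polytope for the kinetic parameters
#'
#' Vertices of the 7-dimensional box in which multistart identification draws
#' its kinetic starting points. Rates in 1/day, half-saturation constants in
#' g/L.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
kinetic_polytope <- function() {
  tibble::tibble(
    parameter = .kinetic_names,
    lower = c(0.1, 0.1, 0.01, 0.01, 0.1, 0.1, 0.1),
    upper = c(1,   1,   1,    1,    10,  10,  1)
  )
}

#' Reference maximum-likelihood subspace basis for the HB1 campaign
#'
#' The 6 x 3 basis of the three-dimensional subspace fitted by MLPCA to the
#' within-batch difference vectors of the HB1 identification data sets
#' (components in canonical order). Only its column space matters; the
#' stoichiometric matrix is recovered from it by [constrained_stoichiometry()].
#'
#' @return A 6 x 3 numeric matrix with component row names.
#' @export
hb1_subspace_basis <- function() {
  m <- matrix(c(-0.0074,  0.0317,  0.4314,
                -0.0173, -0.0045, -0.3108,
                 0.1366, -0.5955, -0.6581,
                 0.0169, -0.0404, -0.0561,
                -0.1389,  0.7778, -0.5300,
                -0.9805, -0.1940, -0.0153),
              nrow = 6, byrow = TRUE)
  dimnames(m) <- list(state_components(), paste0("pc", 1:3))
  m
}

#' Biological constraints identifying the three-reaction stoichiometry
#'
#' Three constraints per reaction (the maximum the 3 x 3 combination matrix
#' supports) pinning the stoichiometric matrix inside the fitted subspace:
#'
#' * Reaction 1 (oxidative growth): biomass yield normalized to 1, no death,
#'   no lactate.
#' * Reaction 2 (glucose overflow): biomass yield 1, no death, no antibody.
#' * Reaction 3 (death): one unit of viable biomass converts to one unit of
#'   dead biomass; lactate uninvolved.
#'
#' @return A tibble with columns `reaction`, `component`, `value`
#'   (values in -1, 0, 1), suitable for [constrained_stoichiometry()].
#' @export
hb1_constraints <- function() {
  tibble::tribble(
    ~reaction, ~component, ~value,
    1L, "X",   1,
    1L, "Xd",  0,
    1L, "L",   0,
    2L, "X",   1,
    2L, "Xd",  0,
    2L, "MAb", 0,
    3L, "X",  -1,
    3L, "Xd",  1,
    3L, "L",   0
  )
}
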