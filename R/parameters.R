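#' Canonical state component order
#'
#' All matrices, CSV files and state vectors in the package use the fixed
#' component ordering `X, Xd, G, Gn, L, MAb`: viable biomass
#' (10^6 cells/mL), dead biomass (10^6 cells/mL), glucose (g/L), glutamine
#' (g/L), lactate (g/L) and monoclonal antibody (ug/mL).
#'
#' @return Character vector of the six component names.
#' @export
state_components <- function() c("X", "Xd", "G", "Gn", "L", "MAb")

# canonical kinetic + stoichiometric parameter order used by the compiled core
.param_names <- c("mu_max1", "mu_max2", "K_G", "K_Gn", "K_Gd", "K_Gnd",
                  "mu_dmax", "k31", "k32", "k41", "k42", "k52", "k61", "k63")

.kinetic_names <- c("mu_max1", "mu_max2", "K_G", "K_Gn", "K_Gd", "K_Gnd", "mu_dmax")
.stoich_names  <- c("k31", "k32", "k41", "k42", "k52", "k61", "k63")

#' Kinetic and stoichiometric model parameters
#'
#' Container for the parameters of the three-reaction overflow model.
#' Rates are per day; yields are expressed per unit of viable biomass
#' (10^6 cells/mL): `k31`, `k32` in g glucose, `k41`, `k42` in g glutamine,
#' `k52` in g lactate and `k61`, `k63` in ug MAb. All values are magnitudes
#' (nonnegative); signs live in the stoichiometric matrix, not here.
#'
#' The `reduced` variant drops the glucose Monod factor from the uptake rate
#' (growth driven by glutamine alone), so `K_G` is ignored.
#'
#' @param mu_max1 Maximum specific uptake rate of the oxidative pathway (1/day).
#' @param mu_max2 Maximum oxidative capacity (1/day); uptake beyond
#'   `mu_max2 * X` overflows to lactate.
#' @param K_G Glucose half-saturation constant (g/L); full variant only.
#' @param K_Gn Glutamine half-saturation constant (g/L).
#' @param K_Gd,K_Gnd Inverse-Monod constants of the death rate (g/L): death
#'   accelerates as glucose/glutamine become depleted.
#' @param mu_dmax Maximum specific death rate (1/day).
#' @param k31,k32 Glucose yields of the oxidative and overflow reactions.
#' @param k41,k42 Glutamine yields of the oxidative and overflow reactions.
#' @param k52 Lactate yield of the overflow reaction.
#' @param k61,k63 MAb yields of the oxidative and death reactions.
#' @param variant `"reduced"` (default) or `"full"`.
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters(mu_max1 = 0.5, mu_max2 = 0.3, K_Gn = 0.01,
#'                       K_Gd = 1.5, K_Gnd = 1.3, mu_dmax = 0.9,
#'                       k31 = 3, k32 = 15, k41 = 0.6, k42 = 1.2,
#'                       k52 = 24, k61 = 44, k63 = 14)
#' @export
model_parameters <- function(mu_max1, mu_max2, K_G = NA_real_, K_Gn, K_Gd, K_Gnd,
                             mu_dmax, k31, k32, k41, k42, k52, k61, k63,
                             variant = c("reduced", "full")) {
  variant <- match.arg(variant)
  vals <- c(mu_max1 = mu_max1, mu_max2 = mu_max2, K_G = K_G, K_Gn = K_Gn,
            K_Gd = K_Gd, K_Gnd = K_Gnd, mu_dmax = mu_dmax,
            k31 = k31, k32 = k32, k41 = k41, k42 = k42, k52 = k52,
            k61 = k61, k63 = k63)
  # named scalars would otherwise produce compound names
  vals <- stats::setNames(as.numeric(vals), .param_names)
  if (variant == "full" && is.na(vals[["K_G"]]))
    stop("the full variant requires K_G", call. = FALSE)
  if (variant == "reduced") vals[["K_G"]] <- 0
  check <- vals[.param_names != "K_G" | variant == "full"]
  if (any(!is.finite(check)) || any(check < 0))
    stop("all parameters must be finite and nonnegative", call. = FALSE)
  structure(list(values = vals, variant = variant), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> variant:", x$variant, "\n")
  v <- x$values
  if (x$variant == "reduced") v <- v[names(v) != "K_G"]
  print(round(v, 4))
  invisible(x)
}

#' @export
as.double.model_parameters <- function(x, ...) x$values

# coerce user input (model_parameters or named vector) to the canonical
# 14-vector consumed by the compiled core
param_vector <- function(params) {
  if (inherits(params, "model_parameters")) return(params$values)
  if (is.numeric(params) && !is.null(names(params))) {
    out <- stats::setNames(numeric(length(.param_names)), .param_names)
    out[names(params)] <- params
    return(out)
  }
  stop("`params` must be a model_parameters object or a named numeric vector",
       call. = FALSE)
}

is_reduced <- function(params) {
  if (inherits(params, "model_parameters")) params$variant == "reduced" else TRUE
}

#' Modify a subset of model parameters
#'
#' @param params A [model_parameters()] object.
#' @param ... Named parameter values to replace.
#' @return The modified `model_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "model_parameters"))
  new <- c(...)
  bad <- setdiff(names(new), .param_names)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  params$values[names(new)] <- new
  params
}

#' @rdname tidy.sbr_fit
#' @export
tidy.model_parameters <- function(x, ...) {
  v <- x$values
  if (x$variant == "reduced") v <- v[names(v) != "K_G"]
  tibble::tibble(term = names(v), estimate = unname(v))
}
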