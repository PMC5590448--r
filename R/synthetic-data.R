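#' Measurement error model
#'
#' Per-component Gaussian measurement noise, specified either as absolute
#' standard deviations or as a fraction of each component's maximum level over
#' the campaign (the latter is resolved to absolute values when a dataset is
#' generated). The induced diagonal covariance must be positive definite, so
#' all resolved standard deviations must be strictly positive unless the
#' model is the degenerate noise-free one (`relative_sd = 0`).
#'
#' @param sd Optional named numeric vector of absolute standard deviations for
#'   the six components (canonical order / names).
#' @param relative_sd Fraction of each component's trajectory maximum used
#'   when `sd` is absent (default 0.05, i.e. 5% of max).
#' @return An `error_model` object.
#' @export
error_model <- function(sd = NULL, relative_sd = 0.05) {
  if (!is.null(sd)) {
    sd <- param_state_vector(sd)
    if (any(sd < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  } else if (relative_sd < 0) {
    stop("relative_sd must be >= 0", call. = FALSE)
  }
  structure(list(sd = sd, relative_sd = relative_sd), class = "error_model")
}

param_state_vector <- function(x) {
  out <- stats::setNames(numeric(6), state_components())
  if (is.null(names(x))) {
    stopifnot(length(x) == 6)
    out[] <- x
  } else out[names(x)] <- x
  out
}

# resolve an error model against the noiseless truth of a campaign
resolve_error_model <- function(em, truth_max) {
  sd <- if (!is.null(em$sd)) em$sd else em$relative_sd * truth_max
  stats::setNames(sd, state_components())
}

#' Generate a synthetic sequential-batch campaign
#'
#' Simulates `n_experiments` successive 15-day cultures of the overflow model
#' and samples them at regular intervals with per-component Gaussian noise.
#' The campaign emulates standard hybridoma SBR practice: the first experiment
#' starts from 0.1 x 10^6 cells/mL of viable biomass; each later experiment
#' starts from the end-of-culture viable and dead biomass of the previous one;
#' at each (re)start and at the mid-culture medium renewal, glucose and
#' glutamine are set to prescribed levels and metabolites are withdrawn.
#'
#' Noise is zero-mean Gaussian per component (standard deviations from the
#' [error_model()], resolved against the campaign-wide trajectory maxima) and
#' measurements are truncated at zero.
#'
#' @param params True [model_parameters()].
#' @param n_experiments Number of successive cultures (default 2, the
#'   identification campaign).
#' @param horizon Culture duration (days, default 15).
#' @param sampling_interval Sampling interval (days, default 1).
#' @param renewal_day Day of the mid-culture medium renewal (default 7).
#' @param renewal_G,renewal_Gn Renewal composition (g/L; defaults 6 and 0.4).
#' @param initial_G,initial_Gn Substrate levels at the start of each
#'   experiment. Scalars, or ranges of length 2 from which each experiment
#'   draws uniformly (defaults: ranges 6-7 and 0.3-0.4 g/L).
#' @param initial_X Viable biomass at the start of the first experiment
#'   (10^6 cells/mL, default 0.1).
#' @param noise An [error_model()].
#' @param seed Integer seed; the dataset is bit-reproducible given the seed.
#' @return A list of `sbr_dataset` objects, one per experiment. Each carries
#'   `measurements` (tibble `time, X, Xd, G, Gn, L, MAb`), `mask` (logical
#'   matrix of excluded cells, all `FALSE` initially), `events`, `sd`
#'   (resolved noise standard deviations), and the generating `truth`
#'   (`params`, `initial`, noiseless sample values).
#' @examples
#' sets <- generate_experiments(hb1_parameters(), seed = 1)
#' sets[[1]]
#' @export
generate_experiments <- function(params,
                                 n_experiments = 2,
                                 horizon = 15,
                                 sampling_interval = 1,
                                 renewal_day = 7,
                                 renewal_G = 6, renewal_Gn = 0.4,
                                 initial_G = c(6, 7), initial_Gn = c(0.3, 0.4),
                                 initial_X = 0.1,
                                 noise = error_model(),
                                 seed = 1L) {
  if (sampling_interval > horizon)
    stop("sampling interval exceeds the horizon", call. = FALSE)
  stopifnot(n_experiments >= 1, horizon > 0, sampling_interval > 0)
  withr::local_seed(seed)

  draw <- function(rng) if (length(rng) == 2) stats::runif(1, rng[1], rng[2]) else rng[1]
  times <- seq(0, horizon, by = sampling_interval)
  events <- renewal_events(renewal_day, renewal_G, renewal_Gn)

  sims <- vector("list", n_experiments)
  inits <- vector("list", n_experiments)
  X0 <- initial_X; Xd0 <- 0
  for (i in seq_len(n_experiments)) {
    init <- culture_state(X = X0, Xd = Xd0, G = draw(initial_G),
                          Gn = draw(initial_Gn), L = 0, MAb = 0)
    sims[[i]] <- simulate_sbr(init, params, events, horizon, times = times)
    inits[[i]] <- init
    last <- as.numeric(sims[[i]]$trajectory[nrow(sims[[i]]$trajectory),
                                            state_components()])
    X0 <- last[1]; Xd0 <- last[2]
  }

  truth_max <- purrr::map(sims, ~apply(.x$trajectory[state_components()], 2, max)) |>
    purrr::reduce(pmax)
  sd <- resolve_error_model(noise, truth_max)

  purrr::map2(sims, inits, function(sim, init) {
    clean <- as.matrix(sim$trajectory[state_components()])
    eps <- matrix(stats::rnorm(length(clean)), nrow(clean), 6)
    noisy <- pmax(clean + eps %*% diag(sd), 0)
    colnames(noisy) <- state_components()
    new_sbr_dataset(
      measurements = dplyr::bind_cols(tibble::tibble(time = times),
                                      tibble::as_tibble(noisy)),
      mask = matrix(FALSE, length(times), 6,
                    dimnames = list(NULL, state_components())),
      events = events,
      sd = sd,
      truth = list(params = params, initial = init, clean = clean)
    )
  })
}

new_sbr_dataset <- function(measurements, mask, events, sd, truth = NULL) {
  stopifnot(all(diff(measurements$time) > 0),
            all(is.finite(as.matrix(measurements))),
            nrow(mask) == nrow(measurements))
  structure(list(measurements = measurements, mask = mask, events = events,
                 sd = sd, truth = truth), class = "sbr_dataset")
}

#' @export
print.sbr_dataset <- function(x, ...) {
  cat("<sbr_dataset>", nrow(x$measurements), "samples,",
      nrow(x$events), "renewal(s),", sum(x$mask), "masked cell(s)\n")
  print(x$measurements, n = 4)
  invisible(x)
}

#' Inject outliers into a dataset
#'
#' Perturbs selected cells and flags them in the outlier mask, emulating
#' assay artifacts such as a spuriously rising glutamine tail. All other
#' entries are untouched.
#'
#' @param dataset An `sbr_dataset`.
#' @param component Component name (one of [state_components()]).
#' @param samples Integer sample indices to perturb.
#' @param offset Additive offsets (recycled; applied cumulatively when
#'   `cumulative = TRUE`, producing a monotone drift).
#' @param multiplier Optional multiplicative factor applied instead of
#'   `offset`.
#' @param cumulative If `TRUE`, offsets accumulate across the listed samples.
#' @return The modified `sbr_dataset` with updated measurements and mask.
#' @examples
#' sets <- generate_experiments(hb1_parameters(), seed = 1)
#' d <- inject_outliers(sets[[1]], "Gn", samples = 14:16, offset = 0.1)
#' sum(d$mask)
#' @export
inject_outliers <- function(dataset, component, samples, offset = 0,
                            multiplier = NULL, cumulative = TRUE) {
  stopifnot(inherits(dataset, "sbr_dataset"))
  if (length(samples) == 0) return(dataset)
  comp <- match.arg(component, state_components())
  n <- nrow(dataset$measurements)
  if (any(samples < 1 | samples > n))
    stop("sample indices out of range", call. = FALSE)
  vals <- dataset$measurements[[comp]]
  if (!is.null(multiplier)) {
    vals[samples] <- vals[samples] * multiplier
  } else {
    off <- rep_len(offset, length(samples))
    if (cumulative) off <- cumsum(off)
    vals[samples] <- vals[samples] + off
  }
  dataset$measurements[[comp]] <- pmax(vals, 0)
  dataset$mask[samples, comp] <- TRUE
  dataset
}

#' Write / read a dataset as plain CSV
#'
#' The measurement table uses the canonical column layout
#' `time_days, X, Xd, G, Gn, L, MAb`; the outlier mask travels in an optional
#' sidecar CSV of the same shape with logical cells. On reading, negative
#' measurement cells are masked with a warning rather than rejected.
#'
#' @param dataset An `sbr_dataset`.
#' @param path CSV path for the measurements.
#' @param mask_path Optional sidecar path (default `<path>` with `_mask.csv`).
#' @return `write_dataset()` the input, invisibly; `read_dataset()` an
#'   `sbr_dataset` (without truth; events must be supplied by the caller).
#' @export
write_dataset <- function(dataset, path, mask_path = default_mask_path(path)) {
  m <- dataset$measurements
  names(m)[names(m) == "time"] <- "time_days"
  utils::write.csv(m, path, row.names = FALSE)
  if (any(dataset$mask))
    utils::write.csv(as.data.frame(dataset$mask), mask_path, row.names = FALSE)
  invisible(dataset)
}

default_mask_path <- function(path) sub("\\.csv$", "_mask.csv", path)

#' @rdname write_dataset
#' @param events A [renewal_events()] tibble describing the schedule under
#'   which the data were collected.
#' @param sd Per-component noise standard deviations (for downstream
#'   weighting); defaults to zero.
#' @export
read_dataset <- function(path, events = renewal_events(), sd = NULL,
                         mask_path = default_mask_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_days", state_components())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  bad <- !vapply(df[need], is.numeric, logical(1))
  if (any(bad))
    stop("unparseable column(s): ", paste(need[bad], collapse = ", "),
         call. = FALSE)
  m <- tibble::as_tibble(df[need])
  names(m)[1] <- "time"
  if (any(diff(m$time) <= 0))
    stop("sampling times must be strictly increasing", call. = FALSE)
  mask <- matrix(FALSE, nrow(m), 6, dimnames = list(NULL, state_components()))
  if (file.exists(mask_path)) {
    mk <- utils::read.csv(mask_path)
    mask[] <- as.matrix(mk[state_components()]) |> apply(2, as.logical)
  }
  mm <- as.matrix(m[state_components()])
  neg <- mm < 0
  if (any(neg)) {
    warning(sum(neg), " negative cell(s) masked")
    mask <- mask | neg
    mm[neg] <- 0
    m[state_components()] <- tibble::as_tibble(mm)
  }
  new_sbr_dataset(m, mask, events,
                  if (is.null(sd)) stats::setNames(numeric(6), state_components())
                  else param_state_vector(sd))
}
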