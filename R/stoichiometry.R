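#' Within-batch differential transform
#'
#' Differences of consecutive retained samples within each batch segment.
#' Because the cultures are batch between renewals (no transport term), each
#' difference vector lies in the column space of the stoichiometric matrix,
#' which is what the subspace analysis exploits. No difference spans a
#' renewal event; a difference touching any sample with a masked cell is
#' dropped. Each row's error covariance is the sum of the two samples'
#' diagonal covariances (independent measurement errors).
#'
#' @param datasets An `sbr_dataset` or list of them.
#' @return An `sbr_differences` object: list with `D` (n_S x 6 matrix of
#'   difference vectors), `var` (n_S x 6 matrix of per-row error variances)
#'   and `info` (tibble mapping rows to experiment/segment/samples).
#' @examples
#' sets <- generate_experiments(hb1_parameters(), seed = 1)
#' diffs <- differential_transform(sets)
#' nrow(diffs$D)
#' @export
differential_transform <- function(datasets) {
  if (inherits(datasets, "sbr_dataset")) datasets <- list(datasets)
  rows <- list(); vars <- list(); info <- list()
  for (e in seq_along(datasets)) {
    d <- datasets[[e]]
    t <- d$measurements$time
    m <- as.matrix(d$measurements[state_components()])
    keep <- !apply(d$mask, 1, any)
    # segment index: samples at/after an event time belong to the next batch
    seg <- if (nrow(d$events)) rowSums(outer(t, d$events$time, ">=")) + 1L
           else rep(1L, length(t))
    for (s in unique(seg)) {
      idx <- which(seg == s & keep)
      if (length(idx) < 2) next
      i1 <- idx[-length(idx)]; i2 <- idx[-1]
      rows[[length(rows) + 1L]] <- m[i2, , drop = FALSE] - m[i1, , drop = FALSE]
      vars[[length(vars) + 1L]] <- matrix(2 * d$sd^2, length(i1), 6, byrow = TRUE)
      info[[length(info) + 1L]] <- tibble::tibble(experiment = e, segment = s,
                                                  from = i1, to = i2)
    }
  }
  if (!length(rows)) stop("no usable within-batch sample pairs", call. = FALSE)
  D <- do.call(rbind, rows)
  colnames(D) <- state_components()
  structure(list(D = D, var = do.call(rbind, vars),
                 info = dplyr::bind_rows(info)),
            class = "sbr_differences")
}

#' @export
print.sbr_differences <- function(x, ...) {
  cat("<sbr_differences>", nrow(x$D), "difference vectors x 6 components\n")
  invisible(x)
}

#' Maximum-likelihood principal component analysis
#'
#' Fits the best `p`-dimensional linear subspace through the origin to the
#' difference vectors in the Mahalanobis sense: it minimizes the
#' log-likelihood cost
#' `J_p = sum_i (d_i - d_hat_i)' Q_i^{-1} (d_i - d_hat_i)`
#' over subspaces and maximum-likelihood projections `d_hat_i`, with known
#' per-row diagonal error covariances `Q_i`. With a common covariance the
#' problem reduces to ordinary PCA in whitened coordinates (used for
#' initialization); heteroscedastic rows are handled by alternating
#' minimization: row-wise generalized least-squares projection given the
#' basis, then component-wise weighted least-squares basis update.
#'
#' @param diffs An `sbr_differences` object.
#' @param p Subspace dimension (1-6).
#' @param max_iter,tol Convergence control: stop when the relative change of
#'   `J_p` falls below `tol` (default 1e-10) or after `max_iter` iterations.
#' @param n_restarts Number of alternating-minimization restarts (the first
#'   from the whitened-PCA solution, the rest from random rotations of it);
#'   the best local minimum is returned.
#' @param seed Seed for the random restarts.
#' @return A `subspace_fit`: list with `p`, `basis` (6 x p orthonormal),
#'   `scores` (n_S x p ML coordinates), `projections` (n_S x 6), `J`,
#'   `converged`, `iterations`.
#' @export
mlpca_fit <- function(diffs, p, max_iter = 10000, tol = 1e-10,
                      n_restarts = 5, seed = 1L) {
  stopifnot(inherits(diffs, "sbr_differences"), p >= 1, p <= 6)
  D <- diffs$D
  W <- 1 / diffs$var
  if (any(!is.finite(W)))
    stop("error variances must be strictly positive", call. = FALSE)
  n <- nrow(D)

  if (p == 6) {
    return(structure(list(p = 6, basis = diag(6), scores = D, projections = D,
                          J = 0, converged = TRUE, iterations = 0L),
                     class = "subspace_fit"))
  }

  # whitened-PCA initialization under the pooled covariance
  qbar <- colMeans(diffs$var)
  Z <- sweep(D, 2, sqrt(qbar), "/")
  V0 <- sweep(svd(Z, nu = 0, nv = p)$v, 1, sqrt(qbar), "*")
  V0 <- qr.Q(qr(V0))

  homoscedastic <- max(abs(sweep(diffs$var, 2, diffs$var[1, ]))) <
    1e-12 * max(diffs$var)
  if (homoscedastic) {
    # common row covariance: the ML subspace is exactly the whitened PCA
    sv <- svd(Z)
    V <- qr.Q(qr(sweep(sv$v[, seq_len(p), drop = FALSE], 1, sqrt(qbar), "*")))
    B <- matrix(0, n, p)
    W1 <- 1 / diffs$var[1, ]
    A <- crossprod(V, W1 * V)
    for (i in seq_len(n)) B[i, ] <- solve(A, crossprod(V, W1 * D[i, ]))
    return(structure(list(p = p, basis = V, scores = B,
                          projections = B %*% t(V),
                          J = sum(sv$d[-seq_len(p)]^2),
                          converged = TRUE, iterations = 0L),
                     class = "subspace_fit"))
  }

  cost_fit <- function(V) {
    # ML projection row by row (diagonal weights), then per-component basis WLS
    J_prev <- Inf; it <- 0L; conv <- FALSE
    B <- matrix(0, n, p)
    repeat {
      it <- it + 1L
      for (i in seq_len(n)) {
        wv <- t(W[i, ] * V)          # p x 6: V' Wi
        A <- wv %*% V                # p x p
        B[i, ] <- safe_solve(A, wv %*% D[i, ])
      }
      R <- D - B %*% t(V)
      J <- sum(W * R^2)
      # exact fits bottom out at round-off; treat them as converged
      if (J <= 1e-10 * n ||
          (is.finite(J_prev) && abs(J_prev - J) <= tol * max(J, 1e-300))) {
        conv <- TRUE; break
      }
      if (it >= max_iter) break
      J_prev <- J
      for (r in 1:6) {
        A <- crossprod(B, W[, r] * B)
        V[r, ] <- safe_solve(A, crossprod(B, W[, r] * D[, r]))
      }
      V <- qr.Q(qr(V))
    }
    list(V = V, J = J, converged = conv, iterations = it)
  }

  withr::local_seed(seed)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    Vk <- if (k == 1) V0 else qr.Q(qr(V0 + matrix(stats::rnorm(6 * p, sd = 0.3), 6, p)))
    fit <- cost_fit(Vk)
    if (is.null(best) || fit$J < best$J) best <- fit
  }
  if (!best$converged)
    warning("MLPCA did not reach the relative tolerance; best iterate returned")

  V <- best$V
  B <- matrix(0, n, p)
  for (i in seq_len(n)) {
    wv <- t(W[i, ] * V)
    B[i, ] <- safe_solve(wv %*% V, wv %*% D[i, ])
  }
  structure(list(p = p, basis = V, scores = B, projections = B %*% t(V),
                 J = best$J, converged = best$converged,
                 iterations = best$iterations),
            class = "subspace_fit")
}

#' @export
print.subspace_fit <- function(x, ...) {
  cat("<subspace_fit> p =", x$p, " J =", format(x$J, digits = 6),
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}

#' @rdname tidy.sbr_fit
#' @export
glance.subspace_fit <- function(x, ...) {
  tibble::tibble(p = x$p, J = x$J, converged = x$converged,
                 iterations = x$iterations)
}

# linear solve with a pseudo-inverse fallback for rank-deficient systems
# (exactly low-rank data make the basis-update normal equations singular)
safe_solve <- function(A, b) {
  out <- try(solve(A, b), silent = TRUE)
  if (!inherits(out, "try-error")) return(out)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
}

#' Select the number of reactions by the chi-square criterion
#'
#' Fits subspaces of dimension 1 to 6 and returns the smallest `p` whose cost
#' `J_p` falls at or below the upper chi-square quantile (default 99.9%) with
#' `n_S * N` degrees of freedom, `n_S` being the number of difference vectors
#' and `N = 6` the number of components. A `J_p` below the complementary
#' lower quantile is flagged as possible noise overestimation.
#'
#' @param diffs An `sbr_differences` object.
#' @param confidence Upper-quantile confidence level (default 0.999).
#' @param ... Passed to [mlpca_fit()].
#' @return A `reaction_count` object: list with `p` (selected dimension),
#'   `table` (tibble `p, J, lower, upper, below_lower`), `df`, and the per-p
#'   `fits`.
#' @export
select_reaction_count <- function(diffs, confidence = 0.999, ...) {
  stopifnot(inherits(diffs, "sbr_differences"))
  df <- nrow(diffs$D) * 6
  upper <- stats::qchisq(confidence, df)
  lower <- stats::qchisq(1 - confidence, df)
  fits <- purrr::map(1:6, ~mlpca_fit(diffs, .x, ...))
  tab <- tibble::tibble(
    p = 1:6,
    J = purrr::map_dbl(fits, "J"),
    lower = lower, upper = upper,
    below_lower = purrr::map_dbl(fits, "J") < lower
  )
  ok <- which(tab$J <= upper)
  if (!length(ok)) {
    stop(paste0("no subspace dimension satisfies the chi-square bound\n",
                paste(utils::capture.output(print(tab)), collapse = "\n")),
         call. = FALSE)
  }
  structure(list(p = min(ok), table = tab, df = df, fits = fits),
            class = "reaction_count")
}

#' @export
print.reaction_count <- function(x, ...) {
  cat("<reaction_count> selected p =", x$p, " (chi-square df =", x$df, ")\n")
  print(x$table)
  invisible(x)
}

#' Plot the rank-selection cost profile
#'
#' @param object A `reaction_count`.
#' @param ... Unused.
#' @return A ggplot of `J_p` against `p` with the chi-square band.
#' @export
autoplot.reaction_count <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$p, .data$J)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper),
                        linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower),
                        linetype = "dotted") +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "subspace dimension p", y = "log-likelihood cost J_p")
}

#' Recover the stoichiometric matrix from a fitted subspace
#'
#' The stoichiometric matrix is a linear combination `K = rho G` of the
#' fitted basis `rho`; each column of the `p x p` matrix `G` is pinned by
#' exactly `p` linear constraints of the form "component r has stoichiometric
#' value v" with `v` in -1, 0, 1 (biological normalizations such as "biomass
#' yield 1" or "no lactate in this reaction").
#'
#' @param fit A `subspace_fit`, or a 6 x p basis matrix.
#' @param constraints A tibble with columns `reaction`, `component`, `value`
#'   (see [hb1_constraints()]), exactly `p` rows per reaction with distinct
#'   components.
#' @return A 6 x p stoichiometric matrix with component row names; constraint
#'   cells are reproduced exactly (to numerical precision).
#' @examples
#' K <- constrained_stoichiometry(hb1_subspace_basis(), hb1_constraints())
#' round(K, 4)
#' @export
constrained_stoichiometry <- function(fit, constraints) {
  basis <- if (inherits(fit, "subspace_fit")) fit$basis else as.matrix(fit)
  p <- ncol(basis)
  stopifnot(nrow(basis) == 6,
            all(c("reaction", "component", "value") %in% names(constraints)))
  comp_idx <- match(constraints$component, state_components())
  if (any(is.na(comp_idx))) stop("unknown component in constraints", call. = FALSE)
  K <- matrix(NA_real_, 6, p,
              dimnames = list(state_components(), paste0("reaction", seq_len(p))))
  for (j in seq_len(p)) {
    cj <- constraints[constraints$reaction == j, ]
    rows <- comp_idx[constraints$reaction == j]
    if (nrow(cj) != p || anyDuplicated(rows))
      stop(sprintf("reaction %d needs exactly %d constraints on distinct components",
                   j, p), call. = FALSE)
    A <- basis[rows, , drop = FALSE]
    if (abs(det(A)) < 1e-12)
      stop(sprintf("infeasible constraints: singular system for reaction %d", j),
           call. = FALSE)
    K[, j] <- basis %*% solve(A, cj$value)
  }
  K
}

#' Zero out negligible stoichiometric entries
#'
#' Entries that are small relative to the same component's involvement in the
#' other reactions (the sum of the magnitudes of that row's other entries)
#' are set to zero, simplifying the reaction scheme. Entries whose reference
#' is zero are kept.
#'
#' @param K Stoichiometric matrix (6 x p).
#' @param zero_threshold Relative threshold (default 0.1).
#' @return List with `K` (simplified matrix) and `changes` (tibble of zeroed
#'   entries with their reference magnitudes).
#' @examples
#' K <- constrained_stoichiometry(hb1_subspace_basis(), hb1_constraints())
#' simplify_stoichiometry(K)$changes
#' @export
simplify_stoichiometry <- function(K, zero_threshold = 0.1) {
  stopifnot(zero_threshold >= 0)
  changes <- list()
  K2 <- K
  for (i in seq_len(nrow(K))) for (j in seq_len(ncol(K))) {
    ref <- sum(abs(K[i, -j]))
    if (ref > 0 && abs(K[i, j]) < zero_threshold * ref) {
      K2[i, j] <- 0
      # entries that were numerically zero already are snapped silently
      if (abs(K[i, j]) > 1e-9 * ref)
        changes[[length(changes) + 1L]] <-
          tibble::tibble(component = rownames(K)[i], reaction = j,
                         value = K[i, j], reference = ref)
    }
  }
  list(K = K2,
       changes = if (length(changes)) dplyr::bind_rows(changes)
                 else tibble::tibble(component = character(), reaction = integer(),
                                     value = numeric(), reference = numeric()))
}
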