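#' Observed plasmid-stability curves
#'
#' A stability curve records the fraction of plasmid-bearing cells (scored
#' by colony replica plating or an equivalent retention assay) at a series
#' of generations of antibiotic-free growth.
#'
#' @param generation Non-negative, strictly increasing generation numbers.
#' @param fraction Fractions of plasmid-bearing cells, in `[0, 1]`.
#' @param label Free-text label (strain/plasmid), stored as an attribute.
#' @return A `stability_curve` tibble with columns `generation`, `fraction`.
#' @examples
#' stability_curve(c(0, 50, 100), c(1, 0.8, 0.55), label = "pRB2/MG1655")
#' @export
stability_curve <- function(generation, fraction, label = "") {
  if (length(generation) != length(fraction) || length(generation) == 0L) {
    stop("`generation` and `fraction` must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(generation < 0) || any(diff(generation) <= 0)) {
    stop("`generation` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("`fraction` values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    tibble::tibble(generation = as.numeric(generation),
                   fraction = as.numeric(fraction)),
    label = label,
    class = c("stability_curve", class(tibble::tibble()))
  )
}

#' Sum-of-squared-errors between a simulated and an observed stability curve
#'
#' The simulated series is linearly interpolated at each observed
#' generation; the objective is the sum of squared differences. Observed
#' generations beyond the simulated horizon are an error — extendable only
#' by simulating further.
#'
#' @param sim A data frame with columns `generation` and `S` (a
#'   `plasmid_trajectory` or `plasmid_ensemble` works directly).
#' @param curve A [stability_curve()].
#' @return A single non-negative number.
#' @export
sse_objective <- function(sim, curve) {
  if (!all(c("generation", "S") %in% names(sim))) {
    stop("`sim` needs columns `generation` and `S`", call. = FALSE)
  }
  if (max(curve$generation) > max(sim$generation)) {
    stop("observed generations extend beyond the simulated horizon",
         call. = FALSE)
  }
  s_hat <- stats::approx(sim$generation, sim$S, xout = curve$generation)$y
  sum((s_hat - curve$fraction)^2)
}

# ensemble-mean S(g) over g = 0..generations for one parameter combination
sim_S_series <- function(alpha, delta, beta, n0, generations, replicates, seed) {
  params <- sim_params(alpha = alpha, delta = delta, beta = beta,
                       generations = generations, replicates = replicates,
                       seed = seed)
  simulate_ensemble(init_poisson(n0), params)
}

grid_fit <- function(curve, parameter, grid, beta_grid, fixed_beta, n0,
                     replicates, seed, refine, tie = c("low", "high")) {
  tie <- match.arg(tie)
  horizon <- max(curve$generation)
  betas <- if (is.null(beta_grid)) fixed_beta else beta_grid
  eval_point <- function(value, beta) {
    ens <- switch(parameter,
      alpha = sim_S_series(value, 0.5, beta, n0, horizon, replicates, seed),
      delta = sim_S_series(0, value, beta, n0, horizon, replicates, seed)
    )
    sse_objective(ens, curve)
  }
  evaluate <- function(values) {
    combos <- tidyr::expand_grid(value = values, beta = betas)
    combos$objective <- purrr::map2_dbl(combos$value, combos$beta, eval_point)
    combos
  }
  # sort so which.min's first-hit rule implements the tie-break direction
  grid <- sort(unique(grid), decreasing = (tie == "high"))
  evals <- evaluate(grid)
  step <- if (length(grid) > 1L) min(abs(diff(sort(grid)))) else 0
  for (i in seq_len(refine)) {
    if (step <= 0) break
    step <- step / 2
    best <- evals$value[which.min(evals$objective)]
    cand <- setdiff(c(best - step, best + step), evals$value)
    cand <- cand[cand >= min(grid) & cand <= max(grid)]
    if (parameter == "delta") cand <- cand[cand > 0 & cand <= 0.5]
    if (parameter == "alpha") cand <- cand[cand >= 0]
    if (length(cand) == 0L) next
    cand <- sort(cand, decreasing = (tie == "high"))
    evals <- dplyr::bind_rows(evals, evaluate(cand))
  }
  # re-apply the tie-break direction over the full evaluation set
  evals <- dplyr::arrange(evals,
                          if (tie == "high") dplyr::desc(.data$value) else .data$value)
  ibest <- which.min(evals$objective)
  structure(
    list(
      parameter = parameter,
      estimate = evals$value[ibest],
      beta = evals$beta[ibest],
      objective = evals$objective[ibest],
      grid = tibble::as_tibble(evals[c("value", "beta", "objective")]),
      fixed = list(n0 = n0,
                   beta = if (is.null(beta_grid)) fixed_beta else NULL,
                   delta = if (parameter == "alpha") 0.5 else NULL,
                   alpha = if (parameter == "delta") 0 else NULL),
      replicates = replicates,
      seed = seed,
      curve = curve
    ),
    class = "stability_fit"
  )
}

#' Fit the replication-failure parameter to a stability curve
#'
#' Grid search for the failure scale `alpha` under the replication-failure
#' scenario: partition is even (`delta = 0.5`) and plasmid loss is driven
#' by replication-defective units alone. Each candidate value is scored by
#' simulating an ensemble (zero-truncated Poisson start at `n0`) and
#' computing the [sse_objective()] against the observed curve. All grid
#' points share the same master seed, so simulation noise is common across
#' candidates and the objective surface is comparable point to point.
#'
#' Grid search is used rather than a gradient method because the floor
#' operations in replication and partition make the objective a noisy,
#' step-like function of the parameter. Ties are broken towards the
#' smaller `alpha` (the more stable interpretation).
#'
#' @param curve A [stability_curve()].
#' @param n0 Mean initial copy number (from a PCR measurement of the
#'   starter culture).
#' @param beta Survival fraction of plasmid-free cells, fixed during the
#'   fit (default 1, no post-segregational killing).
#' @param grid Candidate `alpha` values (default `seq(0, 2, by = 0.05)`).
#' @param replicates Ensemble size per grid point (default 50).
#' @param seed Master seed shared by every grid point.
#' @param refine Number of local refinement rounds, each halving the grid
#'   step around the current minimizer (default 0).
#' @param beta_grid Optional vector of `beta` values for a joint 2-D
#'   search; overrides `beta`.
#' @return A `stability_fit` object; see [tidy.stability_fit()].
#' @export
fit_alpha <- function(curve, n0, beta = 1, grid = seq(0, 2, by = 0.05),
                      replicates = 50L, seed = 0L, refine = 0L,
                      beta_grid = NULL) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (any(grid < 0)) stop("`alpha` grid values must be >= 0", call. = FALSE)
  grid_fit(curve, "alpha", grid, beta_grid, beta, n0, replicates, seed,
           refine, tie = "low")
}

#' Fit the partition parameter to a stability curve
#'
#' Grid search for the partition fraction `delta` under the uneven-partition
#' scenario: replication is error-free (`alpha = 0`) and plasmid loss is
#' driven by biased segregation alone — for high-copy plasmids, the
#' signature of unresolved multimers segregating as single units. With
#' `alpha = 0` the class dynamics are deterministic, so each grid point is
#' a single exact run. Ties are broken towards `delta = 0.5` (even
#' segregation).
#'
#' @inheritParams fit_alpha
#' @param grid Candidate `delta` values in `(0, 0.5]`
#'   (default `seq(0.30, 0.50, by = 0.01)`).
#' @return A `stability_fit` object.
#' @export
fit_delta <- function(curve, n0, beta = 1, grid = seq(0.30, 0.50, by = 0.01),
                      replicates = 50L, seed = 0L, refine = 0L,
                      beta_grid = NULL) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (any(grid <= 0) || any(grid > 0.5)) {
    stop("`delta` grid values must lie in (0, 0.5]", call. = FALSE)
  }
  grid_fit(curve, "delta", grid, beta_grid, beta, n0, replicates, seed,
           refine, tie = "high")
}

#' Express a partition fraction as a segregation ratio
#'
#' @param delta Partition fraction in `(0, 0.5]`.
#' @return A string such as `"40:60"`.
#' @examples
#' split_ratio(0.40)
#' @export
split_ratio <- function(delta) {
  if (any(delta <= 0) || any(delta > 0.5)) {
    stop("`delta` must lie in (0, 0.5]", call. = FALSE)
  }
  sprintf("%d:%d", round(100 * delta), round(100 * (1 - delta)))
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("<stability_fit: %s = %g (SSE = %.4g, %d grid points)>\n",
              x$parameter, x$estimate, x$objective, nrow(x$grid)))
  if (x$parameter == "delta") {
    cat(sprintf("  segregation ratio %s\n", split_ratio(x$estimate)))
  }
  if (is.null(x$fixed$beta)) cat(sprintf("  joint beta estimate: %g\n", x$beta))
  invisible(x)
}

#' Tidy a stability fit
#'
#' `tidy()` returns the full grid of evaluated parameter values with their
#' objective; `glance()` returns a one-row summary.
#'
#' @param x A `stability_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stability_fit <- function(x, ...) {
  out <- x$grid
  out$term <- x$parameter
  dplyr::relocate(out, "term")
}

#' @rdname tidy.stability_fit
#' @export
glance.stability_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    estimate = x$estimate,
    beta = x$beta,
    sse = x$objective,
    n_grid = nrow(x$grid),
    n_obs = nrow(x$curve),
    replicates = x$replicates,
    seed = x$seed
  )
}

#' Write a stability fit to CSV
#'
#' The evaluated grid goes to `path`; a one-line summary (parameter,
#' estimate, SSE, seed) is prepended as comment lines.
#'
#' @param fit A `stability_fit`.
#' @param path Output file.
#' @export
write_fit_csv <- function(fit, path) {
  hdr <- sprintf("# %s = %g, sse = %g, replicates = %d, seed = %d",
                 fit$parameter, fit$estimate, fit$objective,
                 fit$replicates, fit$seed)
  writeLines(c(hdr, readr::format_csv(tidy(fit))), path)
  invisible(path)
}
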