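#' Densitometry peak model for plasmid multimer ladders
#'
#' Plasmid multimers (monomer, dimer, trimer, ...) separated on an agarose
#' gel produce a ladder of bands at integer multiples of the monomer size.
#' A calibrated lane profile (intensity versus DNA size) is modeled as a
#' sigmoidal background step plus one asymmetric peak per multimer rank:
#'
#' \deqn{I(x) = \frac{T}{1 + e^{-(x - x_T)/c}} + \sum_{k=1}^{k_{max}}
#'   \frac{N_k}{1 + \left(\frac{x - k x_0}{\sigma_k / 2}\right)^2} \cdot
#'   \frac{1}{1 + e^{-(x - k x_0)/b}}}
#'
#' i.e. a Lorentzian of half-width `sigma_k / 2` centred at `k * x0`,
#' multiplied by a logistic factor of scale `b_asym` that skews each peak
#' towards larger sizes, on top of a logistic background of height `T`,
#' midpoint `xT` and width `c`.
#'
#' @param x0 Monomer size (same units as the profile positions, e.g. kb;
#'   4.6 for a 4.6-kb plasmid).
#' @param N Peak amplitudes, one per rank `k = 1..k_max` (non-negative).
#' @param sigma Peak widths, one per rank (positive), or a scalar recycled.
#' @param b_asym Asymmetry scale shared by all peaks (positive).
#' @param T_bg,xT,c_bg Background step height, midpoint and width.
#' @return A `multimer_peak_model` object.
#' @examples
#' m <- multimer_peak_model(x0 = 4.6, N = c(100, 60, 30), sigma = 1)
#' peak_model_intensity(4.6, m)
#' @export
multimer_peak_model <- function(x0, N, sigma, b_asym = x0 / 20,
                                T_bg = 0, xT = 0, c_bg = 1) {
  stopifnot(x0 > 0, length(N) >= 1, all(N >= 0), b_asym > 0, c_bg > 0,
            T_bg >= 0)
  sigma <- rep_len(sigma, length(N))
  if (any(sigma <= 0)) stop("peak widths must be positive", call. = FALSE)
  structure(
    list(x0 = x0, k_max = length(N), N = as.numeric(N),
         sigma = as.numeric(sigma), b_asym = b_asym,
         T_bg = T_bg, xT = xT, c_bg = c_bg),
    class = "multimer_peak_model"
  )
}

#' @export
print.multimer_peak_model <- function(x, ...) {
  cat(sprintf("<multimer_peak_model: x0 = %g, %d ranks, background T = %g>\n",
              x$x0, x$k_max, x$T_bg))
  print(tibble::tibble(k = seq_len(x$k_max), N = x$N, sigma = x$sigma))
  invisible(x)
}

# single peak term (Lorentzian x logistic asymmetry), vectorized over x
peak_term <- function(x, k, model) {
  ctr <- k * model$x0
  lor <- model$N[k] / (1 + ((x - ctr) / (model$sigma[k] / 2))^2)
  lor / (1 + exp(-(x - ctr) / model$b_asym))
}

#' Evaluate the peak model
#'
#' @param x Positions (calibrated size units), vectorized.
#' @param model A [multimer_peak_model()].
#' @return Model intensity at each `x`.
#' @export
peak_model_intensity <- function(x, model) {
  out <- model$T_bg / (1 + exp(-(x - model$xT) / model$c_bg))
  for (k in seq_len(model$k_max)) out <- out + peak_term(x, k, model)
  out
}

#' Fit the multimer peak model to a densitometry lane profile
#'
#' Least-squares fit (Levenberg–Marquardt, via \pkg{minpack.lm}) of all
#' model parameters to an observed profile. Peak centres are *fixed* at
#' integer multiples of the monomer size `x0`; only amplitudes, widths,
#' the shared asymmetry scale and the three background parameters are
#' free. Amplitudes are bounded below by zero and widths kept positive.
#'
#' @param profile A data frame with columns `position` and `intensity`
#'   (at least 50 samples, positions increasing).
#' @param x0 Monomer size in the profile's position units.
#' @param k_max Highest multimer rank to model.
#' @param init Optional starting [multimer_peak_model()]; by default
#'   amplitudes start at the local intensity near each `k * x0` and the
#'   background at the high-size plateau.
#' @return A `multimer_fit` object: the fitted model plus the data,
#'   fitted values and residual norm. Supports [tidy.multimer_fit()],
#'   `glance()` and `autoplot()`.
#' @export
fit_multimer_profile <- function(profile, x0, k_max, init = NULL) {
  if (!all(c("position", "intensity") %in% names(profile))) {
    stop("`profile` needs columns `position` and `intensity`", call. = FALSE)
  }
  x <- as.numeric(profile$position)
  y <- as.numeric(profile$intensity)
  if (length(x) < 50L) stop("profile must have at least 50 samples", call. = FALSE)
  if (is.unsorted(x, strictly = FALSE)) {
    stop("profile positions must be increasing", call. = FALSE)
  }
  if (x0 <= 0 || k_max < 1) stop("invalid `x0` or `k_max`", call. = FALSE)

  if (is.null(init)) {
    t0 <- max(stats::median(y[x > max(x) - 0.5 * x0]), 1e-6 * max(y))
    n0 <- vapply(seq_len(k_max), function(k) {
      near <- abs(x - k * x0) < 0.25 * x0
      if (!any(near)) return(0.1 * max(y))
      max(max(y[near]) - t0, 0.05 * max(y))
    }, numeric(1))
    init <- multimer_peak_model(
      x0 = x0, N = n0, sigma = x0 / 4, b_asym = x0 / 20,
      T_bg = t0, xT = x0 / 2, c_bg = x0 / 10
    )
  }

  # parameter vector: log-widths and log-scales keep positivity without
  # active box constraints biting mid-search
  pack <- function(m) {
    c(m$N, log(m$sigma), log(m$b_asym), m$T_bg, m$xT, log(m$c_bg))
  }
  unpack <- function(p) {
    multimer_peak_model(
      x0 = x0,
      N = pmax(p[seq_len(k_max)], 0),
      sigma = exp(p[k_max + seq_len(k_max)]),
      b_asym = exp(p[2 * k_max + 1]),
      T_bg = max(p[2 * k_max + 2], 0),
      xT = p[2 * k_max + 3],
      c_bg = exp(p[2 * k_max + 4])
    )
  }
  resid_fn <- function(p) peak_model_intensity(x, unpack(p)) - y
  fit <- minpack.lm::nls.lm(
    par = pack(init), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  if (fit$info == 0 || fit$info > 4) {
    stop(sprintf("peak fit did not converge (residual norm %.4g)",
                 sqrt(sum(fit$fvec^2))), call. = FALSE)
  }
  model <- unpack(fit$par)
  structure(
    list(model = model,
         profile = tibble::tibble(position = x, intensity = y),
         fitted = peak_model_intensity(x, model),
         rss = sum(fit$fvec^2),
         convergence = fit$info),
    class = "multimer_fit"
  )
}

#' @export
print.multimer_fit <- function(x, ...) {
  cat(sprintf("<multimer_fit: %d ranks, RSS = %.4g>\n", x$model$k_max, x$rss))
  print(x$model)
  invisible(x)
}

#' Tidy a multimer fit
#'
#' `tidy()` gives one row per rank (amplitude, width, integrated area,
#' and the two weighting variants of the multimer fraction); `glance()`
#' a one-row fit summary.
#'
#' @param x A `multimer_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.multimer_fit <- function(x, ...) {
  areas <- peak_areas(x$model)
  tibble::tibble(
    k = seq_len(x$model$k_max),
    N = x$model$N,
    sigma = x$model$sigma,
    area = areas,
    rho_intensity = areas / sum(areas),
    rho_molecule = (areas / seq_along(areas)) / sum(areas / seq_along(areas))
  )
}

#' @rdname tidy.multimer_fit
#' @export
glance.multimer_fit <- function(x, ...) {
  tibble::tibble(
    k_max = x$model$k_max,
    x0 = x$model$x0,
    rss = x$rss,
    T_bg = x$model$T_bg,
    b_asym = x$model$b_asym,
    n_obs = nrow(x$profile),
    convergence = x$convergence
  )
}

# integrated area of each rank's peak term over the whole axis
peak_areas <- function(model) {
  vapply(seq_len(model$k_max), function(k) {
    if (model$N[k] == 0) return(0)
    ctr <- k * model$x0
    span <- 200 * model$sigma[k]
    stats::integrate(function(x) peak_term(x, k, model),
                     lower = ctr - span, upper = ctr + span,
                     rel.tol = 1e-9, subdivisions = 2000L)$value
  }, numeric(1))
}

#' Normalized multimer distribution from a fitted peak model
#'
#' Converts the fitted per-rank peaks into a normalized distribution over
#' multimer rank. With `weighting = "intensity"` each rank's share is its
#' integrated peak area. Band intensity is proportional to DNA mass, so a
#' k-mer contributes k times the signal per molecule; `weighting =
#' "molecule"` divides each area by its rank before normalizing, yielding
#' fractions of independently segregating molecules.
#'
#' @param model A `multimer_peak_model` or `multimer_fit`.
#' @param weighting `"intensity"` (as scanned) or `"molecule"`
#'   (mass-corrected).
#' @return A `multimer_distribution` tibble with columns `k`, `rho`
#'   summing to 1.
#' @export
multimer_fractions <- function(model, weighting = c("intensity", "molecule")) {
  weighting <- match.arg(weighting)
  if (inherits(model, "multimer_fit")) model <- model$model
  areas <- peak_areas(model)
  if (sum(areas) <= 0) stop("all peak areas are zero", call. = FALSE)
  w <- if (weighting == "molecule") areas / seq_along(areas) else areas
  multimer_distribution(seq_along(w), w)
}

#' Construct a normalized multimer distribution
#'
#' @param k Multimer ranks (positive integers).
#' @param rho Non-negative weights; normalized to sum to 1.
#' @return A `multimer_distribution` tibble.
#' @export
multimer_distribution <- function(k, rho) {
  if (length(k) != length(rho) || length(k) == 0L) {
    stop("`k` and `rho` must be non-empty and equal length", call. = FALSE)
  }
  if (any(k < 1) || any(k != floor(k))) {
    stop("ranks `k` must be positive integers", call. = FALSE)
  }
  if (any(rho < 0) || sum(rho) <= 0) {
    stop("`rho` must be non-negative with positive total", call. = FALSE)
  }
  ord <- order(k)
  structure(
    tibble::tibble(k = as.numeric(k[ord]), rho = rho[ord] / sum(rho)),
    class = c("multimer_distribution", class(tibble::tibble()))
  )
}

#' Mean multimer rank
#'
#' @param rho A `multimer_distribution` (or data frame with columns `k`,
#'   `rho`).
#' @return The expectation of the rank under `rho`.
#' @export
mean_rank <- function(rho) {
  sum(rho$k * rho$rho) / sum(rho$rho)
}

#' Correct a PCR-derived copy number for multimerization
#'
#' Droplet-digital PCR counts plasmid *units* and cannot distinguish a
#' monomer from one unit inside a multimer. Dividing the unit count by the
#' mean multimer rank converts it into the number of independently
#' segregating molecules — the quantity that matters for segregation.
#'
#' @param ddpcr_units Copy number in plasmid units per cell (> 0).
#' @param rho A `multimer_distribution`.
#' @return Molecules per cell.
#' @examples
#' rho <- multimer_distribution(c(1, 2), c(0.5, 0.5))
#' correct_pcn(30, rho)  # 20: mean rank 1.5
#' @export
correct_pcn <- function(ddpcr_units, rho) {
  if (any(ddpcr_units <= 0)) stop("`ddpcr_units` must be positive", call. = FALSE)
  ddpcr_units / mean_rank(rho)
}

#' Assign ladder band positions to multimer ranks
#'
#' Each observed band position is matched to the nearest integer multiple
#' of the monomer size; positions farther than `tol * x0` from any
#' multiple are left unassigned (`NA`).
#'
#' @param positions Sorted band positions (calibrated size units).
#' @param x0 Monomer size.
#' @param tol Relative tolerance (default 0.1, i.e. 10% of the monomer
#'   size).
#' @return A tibble with columns `position`, `rank` (`NA` when
#'   unassigned).
#' @examples
#' assign_ladder(c(4.6, 9.2, 13.8), x0 = 4.6)
#' @export
assign_ladder <- function(positions, x0, tol = 0.1) {
  if (x0 <= 0) stop("`x0` must be positive", call. = FALSE)
  if (length(positions) == 0L) {
    return(tibble::tibble(position = numeric(0), rank = numeric(0)))
  }
  k <- pmax(round(positions / x0), 1)
  ok <- abs(positions - k * x0) <= tol * x0
  tibble::tibble(position = as.numeric(positions),
                 rank = ifelse(ok, k, NA_real_))
}

#' Read / write multimer distributions as CSV
#'
#' Two-column CSV with header `k,rho`.
#'
#' @param path File path.
#' @return `read_rho_csv()` returns a `multimer_distribution`.
#' @export
read_rho_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    k = readr::col_double(), rho = readr::col_double()
  ))
  multimer_distribution(tbl$k, tbl$rho)
}

#' @param rho A `multimer_distribution` to write.
#' @rdname read_rho_csv
#' @export
write_rho_csv <- function(rho, path) {
  readr::write_csv(tibble::tibble(k = rho$k, rho = rho$rho), path)
  invisible(path)
}
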