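#' Copy-number distributions
#'
#' A copy-number distribution describes a bacterial population as the
#' abundance of cells carrying each possible number of plasmid units.
#' It is stored as a tibble with two columns:
#'
#' * `n` — plasmid units per cell (non-negative integer, one row per
#'   occupied class, sorted ascending);
#' * `abundance` — cell count (census mode, whole numbers) or normalized
#'   class weight (weights mode, summing to 1).
#'
#' The sparse row-per-class representation is deliberate: under uneven
#' partition the support drifts upward over generations and a dense vector
#' over `0:n_max` would mostly hold zeros.
#'
#' @param n Integer vector of plasmid counts per cell.
#' @param abundance Numeric vector of abundances, same length as `n`.
#' @param mode Either `"weights"` (normalized class weights summing to 1)
#'   or `"census"` (whole-number cell counts).
#' @return A `cn_dist` tibble with columns `n` and `abundance`.
#' @examples
#' cn_distribution(c(0, 1, 2), c(1, 1, 1), mode = "census")
#' @export
cn_distribution <- function(n, abundance, mode = c("weights", "census")) {
  mode <- match.arg(mode)
  if (length(n) != length(abundance)) {
    stop("`n` and `abundance` must have the same length", call. = FALSE)
  }
  if (length(n) == 0L) stop("a distribution needs at least one class", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n))) {
    stop("plasmid counts `n` must be non-negative integers", call. = FALSE)
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  if (anyDuplicated(n)) {
    abundance <- as.numeric(rowsum(abundance, n))
    n <- sort(unique(n))
  }
  if (mode == "census" && any(abs(abundance - round(abundance)) > 1e-8)) {
    stop("census-mode abundances must be whole numbers", call. = FALSE)
  }
  ord <- order(n)
  out <- tibble::tibble(n = as.numeric(n[ord]), abundance = abundance[ord])
  if (mode == "weights") {
    tot <- sum(out$abundance)
    if (tot <= 0) stop("total abundance must be positive", call. = FALSE)
    out$abundance <- out$abundance / tot
  }
  new_cn_dist(out, mode)
}

new_cn_dist <- function(tbl, mode) {
  structure(tbl, mode = mode, class = c("cn_dist", class(tibble::tibble())))
}

#' @export
print.cn_dist <- function(x, ...) {
  cat(sprintf(
    "<cn_dist: %d classes, mode = %s, mean = %.4g, stability = %.4g>\n",
    nrow(x), dist_mode(x), mean_pcn(x), stability(x)
  ))
  NextMethod()
}

#' Storage mode of a copy-number distribution
#'
#' @param dist A `cn_dist` object.
#' @return `"weights"` or `"census"`.
#' @export
dist_mode <- function(dist) {
  m <- attr(dist, "mode")
  if (is.null(m)) "weights" else m
}

validate_cn_dist <- function(dist) {
  if (!inherits(dist, "cn_dist")) {
    stop("expected a `cn_dist` object (see `cn_distribution()`)", call. = FALSE)
  }
  invisible(dist)
}

# Upper support bound n* where the untruncated upper-tail mass beyond n*
# drops below eps; used by both parametric initializers.
poisson_upper <- function(lambda, eps) {
  max(stats::qpois(eps, lambda, lower.tail = FALSE) + 2L, ceiling(lambda) + 2L)
}

#' Initial population from a zero-truncated Poisson distribution
#'
#' Builds the starter-culture copy-number distribution: cells are Poisson
#' distributed around the measured mean copy number `n0`, and the zero class
#' is removed because the starter culture grows under antibiotic selection —
#' a cell without at least one plasmid unit does not survive. The truncated
#' distribution is renormalized; all downstream observables are ratios, so
#' only relative class frequencies matter.
#'
#' @param n0 Mean plasmid copy number of the untruncated distribution
#'   (real, > 0). Measured copy numbers such as 1.8 are accepted.
#' @param support_eps Upper-tail mass cutoff for the finite support
#'   (default `1e-12`). The support ends at the smallest `n` whose
#'   untruncated upper-tail mass falls below this cutoff.
#' @param mode Storage mode; census mode additionally requires `m0`.
#' @param m0 Total initial cell count (census mode only). Class counts are
#'   obtained by rounding `m0` times the class weight.
#' @return A `cn_dist` with `abundance(0) = 0` (the zero row is absent).
#' @examples
#' d <- init_poisson(20)
#' mean_pcn(d)  # 20 / (1 - exp(-20)), the zero-truncated Poisson mean
#' @export
init_poisson <- function(n0, support_eps = 1e-12, mode = c("weights", "census"),
                         m0 = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 <= 0) {
    stop("`n0` must be a single positive number", call. = FALSE)
  }
  n <- seq_len(poisson_upper(n0, support_eps))
  w <- stats::dpois(n, n0)
  finish_init(n, w, mode, m0)
}

#' Initial population from a zero-truncated discretized Gaussian
#'
#' Alternative starter-culture model: class weights proportional to
#' `exp(-((n - n0) / sigma)^2 / 2)` on integer `n >= 1`. For mean copy
#' numbers above ~10 with `sigma^2 = n0` it is nearly indistinguishable
#' from [init_poisson()].
#'
#' @inheritParams init_poisson
#' @param sigma Standard deviation of the Gaussian (real, > 0).
#' @return A `cn_dist` with the zero class removed.
#' @export
init_gaussian <- function(n0, sigma, support_eps = 1e-12,
                          mode = c("weights", "census"), m0 = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 <= 0) {
    stop("`n0` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  # support ends where the Gaussian upper tail beyond n falls below eps
  upper <- max(ceiling(n0 + sigma * abs(stats::qnorm(support_eps))) + 2L,
               ceiling(n0) + 2L)
  n <- seq_len(upper)
  w <- exp(-0.5 * ((n - n0) / sigma)^2)
  finish_init(n, w, mode, m0)
}

#' Initial population with every cell at the same copy number
#'
#' All cells start with exactly `n0` plasmid units (antibiotic selection
#' still forbids `n0 = 0`). Random fluctuations spread the distribution
#' within a few generations, so the long-run behaviour is insensitive to
#' this idealized start.
#'
#' @param n0 Plasmid units per cell (positive integer).
#' @param m0 Total cell count (census mode) — ignored in weights mode.
#' @param mode Storage mode.
#' @return A single-class `cn_dist`.
#' @export
init_delta <- function(n0, m0 = 1L, mode = c("census", "weights")) {
  mode <- match.arg(mode)
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) ||
      n0 < 1 || n0 != floor(n0)) {
    stop("`n0` must be a positive integer (selection forbids plasmid-free cells)",
         call. = FALSE)
  }
  if (!is.numeric(m0) || length(m0) != 1L || m0 < 1 || m0 != floor(m0)) {
    stop("`m0` must be a positive integer", call. = FALSE)
  }
  abundance <- if (mode == "census") m0 else 1
  cn_distribution(n0, abundance, mode = mode)
}

finish_init <- function(n, w, mode, m0) {
  # zero-truncate (n starts at 1 already), drop numerically empty tail rows
  keep <- w > 0
  n <- n[keep]
  w <- w[keep]
  w <- w / sum(w)
  if (mode == "census") {
    if (is.null(m0)) stop("census mode requires `m0`", call. = FALSE)
    counts <- round(m0 * w)
    keep <- counts > 0
    cn_distribution(n[keep], counts[keep], mode = "census")
  } else {
    cn_distribution(n, w, mode = "weights")
  }
}

#' Read / write copy-number distributions as CSV
#'
#' Two-column CSV with header `n,abundance`, one row per occupied class,
#' strictly non-negative integer `n`.
#'
#' @param path File path.
#' @param mode Storage mode to assign on reading.
#' @return `read_cn_csv()` returns a `cn_dist`; `write_cn_csv()` returns
#'   `path` invisibly.
#' @export
read_cn_csv <- function(path, mode = c("weights", "census")) {
  mode <- match.arg(mode)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    n = readr::col_double(), abundance = readr::col_double()
  ))
  cn_distribution(tbl$n, tbl$abundance, mode = mode)
}

#' @param dist A `cn_dist` to write.
#' @rdname read_cn_csv
#' @export
write_cn_csv <- function(dist, path) {
  validate_cn_dist(dist)
  readr::write_csv(tibble::tibble(n = dist$n, abundance = dist$abundance), path)
  invisible(path)
}
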