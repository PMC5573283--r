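#' Population observables
#'
#' Three quantities summarize a copy-number distribution and are the link
#' between simulation and experiment: the fraction of cells in a given
#' copy-number class, the plasmid stability (fraction of cells carrying at
#' least one plasmid unit — what a colony-scoring retention assay measures),
#' and the mean plasmid copy number (what droplet-digital PCR measures).
#' All three are ratios, so they are invariant under uniform rescaling of
#' the abundances and identical between census and weights modes.
#'
#' @param dist A `cn_dist` object.
#' @param n Plasmid count class to query.
#' @return A single number.
#' @examples
#' d <- cn_distribution(c(0, 1, 2), c(2, 3, 1), mode = "census")
#' count_fraction(d, 1)  # 0.5
#' stability(d)          # 4/6
#' mean_pcn(d)           # 5/6
#' @name observables
NULL

total_abundance <- function(dist) {
  tot <- sum(dist$abundance)
  if (tot <= 0) stop("distribution has zero total abundance", call. = FALSE)
  tot
}

#' @rdname observables
#' @export
count_fraction <- function(dist, n) {
  validate_cn_dist(dist)
  tot <- total_abundance(dist)
  hit <- match(n, dist$n)
  out <- ifelse(is.na(hit), 0, dist$abundance[hit] / tot)
  as.numeric(out)
}

#' @rdname observables
#' @export
stability <- function(dist) {
  validate_cn_dist(dist)
  tot <- total_abundance(dist)
  sum(dist$abundance[dist$n >= 1]) / tot
}

#' @param bearing_only If `TRUE`, average only over plasmid-bearing cells
#'   (`n >= 1`). The default `FALSE` includes plasmid-free cells, matching
#'   the population-wide mean; PCR-based measurements of surviving cultures
#'   may implicitly condition on plasmid bearers, hence the option.
#' @rdname observables
#' @export
mean_pcn <- function(dist, bearing_only = FALSE) {
  validate_cn_dist(dist)
  if (bearing_only) {
    keep <- dist$n >= 1
    tot <- sum(dist$abundance[keep])
    if (tot <= 0) stop("no plasmid-bearing cells in the population", call. = FALSE)
    return(sum(dist$n[keep] * dist$abundance[keep]) / tot)
  }
  sum(dist$n * dist$abundance) / total_abundance(dist)
}
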