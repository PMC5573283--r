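#' Simulation parameters
#'
#' Bundles the three model parameters and the run-control settings for the
#' generation-based simulation.
#'
#' The model tracks, generation by generation, how many cells carry each
#' number of plasmid units. Each cell cycle has three stages:
#'
#' 1. **Replication** — the plasmid complement of a cell with `n` units
#'    grows to `floor(R(n) * n) - n_fail`, where `R(n) = 2` under the
#'    default fixed-doubling policy and `n_fail` is a random number of
#'    replication-defective units drawn from the exponential-tail law with
#'    scale `alpha` (see [fail_pmf()]).
#' 2. **Division** — the post-replication complement is split between two
#'    daughters as `floor(delta * n_post)` and the remainder. `delta = 0.5`
#'    is an even split; smaller values bias one daughter, the reading for
#'    high-copy plasmids being unresolved multimers that segregate as
#'    single units.
#' 3. **Post-segregational killing** — only a fraction `beta` of
#'    plasmid-free cells survives each generation (`beta = 1`: no killing).
#'
#' @param alpha Replication-failure scale (>= 0). `alpha = 0` disables
#'   replication errors.
#' @param delta Partition fraction given to the first daughter, in
#'   `(0, 0.5]`.
#' @param beta Per-generation survival fraction of plasmid-free cells,
#'   in `[0, 1]`.
#' @param generations Number of generations to simulate (positive integer).
#' @param replicates Number of independent runs averaged by
#'   [simulate_ensemble()] (default 50).
#' @param seed Master RNG seed (default 0). Ensemble replicates use
#'   sub-seeds derived deterministically from it.
#' @param replication_policy Either [fixed_doubling()] (the default; every
#'   plasmid unit replicates once per cell cycle) or [saturating_policy()].
#' @param prune_eps Classes whose relative weight falls below this
#'   threshold are dropped (weights mode only; default `1e-12`).
#' @param n_cap Copy numbers above this value are merged into a single
#'   boundary class (default 10000); under `delta < 0.5` the support grows
#'   without bound otherwise.
#' @return A `sim_params` list.
#' @examples
#' sim_params(alpha = 0.25, delta = 0.5, beta = 1, generations = 100)
#' @export
sim_params <- function(alpha = 0, delta = 0.5, beta = 1,
                       generations = 100L, replicates = 50L, seed = 0L,
                       replication_policy = fixed_doubling(),
                       prune_eps = 1e-12, n_cap = 10000L) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
    is.numeric(delta), length(delta) == 1L,
    is.numeric(beta), length(beta) == 1L,
    is.numeric(generations), generations >= 1, generations == floor(generations),
    is.numeric(replicates), replicates >= 1, replicates == floor(replicates)
  )
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (delta <= 0 || delta > 0.5) stop("`delta` must lie in (0, 0.5]", call. = FALSE)
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  structure(
    list(
      alpha = alpha, delta = delta, beta = beta,
      generations = as.integer(generations),
      replicates = as.integer(replicates), seed = as.integer(seed),
      replication_policy = replication_policy,
      prune_eps = prune_eps, n_cap = as.integer(n_cap)
    ),
    class = "sim_params"
  )
}

#' Replication policies
#'
#' `fixed_doubling()` doubles the plasmid complement every cell cycle
#' (`R(n) = 2`), the standard assumption for copy-number-controlled
#' replicons. `saturating_policy()` lets the multiplier fall towards 1 as
#' the complement approaches the cell's carrying capacity:
#' `R(n) = 1 + a / (1 + b * (n - n_max))`, clamped to `[1, 1 + a]` because
#' the raw form has a pole where the denominator vanishes.
#'
#' @param a,b Empirical shape parameters (`a > 0`, `b >= 0`).
#' @param n_max Copy number at which the multiplier equals `1 + a / 1`.
#' @return A replication-policy object.
#' @export
fixed_doubling <- function() {
  structure(list(type = "fixed"), class = "replication_policy")
}

#' @rdname fixed_doubling
#' @export
saturating_policy <- function(a, b, n_max) {
  stopifnot(a > 0, b >= 0, n_max > 0)
  structure(list(type = "saturating", a = a, b = b, n_max = n_max),
            class = "replication_policy")
}

#' Replication multiplier for a given copy number
#'
#' @param n Copy number(s), non-negative.
#' @param policy A replication policy (default [fixed_doubling()]).
#' @return Numeric vector of multipliers.
#' @examples
#' replication_multiplier(5)                                # 2
#' replication_multiplier(40, saturating_policy(1, 0.1, 40))  # 2 at n_max
#' @export
replication_multiplier <- function(n, policy = fixed_doubling()) {
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  if (policy$type == "fixed") return(rep(2, length(n)))
  denom <- 1 + policy$b * (n - policy$n_max)
  r <- ifelse(denom > 0, 1 + policy$a / denom, 1 + policy$a)
  pmin(pmax(r, 1), 1 + policy$a)
}

#' Distribution of the number of replication-defective plasmid units
#'
#' Replication failures per generation follow the law of
#' `n_fail = floor(-alpha * log(U))` with `U` uniform on (0, 1): the
#' fractional part of an exponential waiting time is discarded, giving the
#' exact probability mass `P(k) = exp(-k/alpha) - exp(-(k+1)/alpha)` — a
#' geometric distribution with success probability `1 - exp(-1/alpha)`.
#' `alpha = 0` means failure-free replication (all mass at `k = 0`).
#'
#' @param k Number of failed units (non-negative integer, vectorized).
#' @param alpha Failure scale (>= 0).
#' @return `fail_pmf()` returns probabilities; `sample_fail_count()` returns
#'   random draws using the session RNG.
#' @examples
#' fail_pmf(1, 1.20)   # ~0.246: one failure per generation is a 25% event
#' fail_pmf(0, 0.51)   # ~0.86: usually all units replicate correctly
#' @export
fail_pmf <- function(k, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a single number >= 0", call. = FALSE)
  }
  if (any(k < 0) || any(k != floor(k))) {
    stop("`k` must be non-negative integers", call. = FALSE)
  }
  if (alpha == 0) return(as.numeric(k == 0))
  exp(-k / alpha) - exp(-(k + 1) / alpha)
}

#' @param m Number of draws.
#' @rdname fail_pmf
#' @export
sample_fail_count <- function(alpha, m = 1L) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (alpha == 0) return(rep(0, m))
  # runif() never returns the endpoints, so log() is always finite
  floor(-alpha * log(stats::runif(m)))
}

#' Post-replication copy number
#'
#' The number of plasmid units available for segregation: the replicated
#' complement minus the replication failures, floored at zero. Plasmid-free
#' cells stay plasmid-free regardless of the draw.
#'
#' @param n Pre-replication copy number(s).
#' @param n_fail Replication-defective units (same length or scalar).
#' @param policy Replication policy.
#' @return Non-negative integer vector.
#' @examples
#' replicate_count(2, 1)  # 3: one of the two new units failed
#' @export
replicate_count <- function(n, n_fail, policy = fixed_doubling()) {
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  r <- replication_multiplier(n, policy)
  out <- pmax(0, floor(r * n) - n_fail)
  out[n == 0] <- 0
  out
}

#' Partition of plasmid units between the two daughter cells
#'
#' The first daughter receives `floor(delta * n_post)` units, the second
#' the remainder; the two always sum to `n_post` exactly.
#'
#' @param n_post Post-replication copy number(s).
#' @param delta Partition fraction, in `(0, 0.5]`.
#' @return A two-column tibble `daughter1`, `daughter2`.
#' @examples
#' partition(3, 0.5)    # 1 and 2: odd complements split unevenly
#' partition(10, 0.40)  # 4 and 6: a 40:60 split
#' @export
partition <- function(n_post, delta) {
  if (delta <= 0 || delta > 0.5) stop("`delta` must lie in (0, 0.5]", call. = FALSE)
  if (any(n_post < 0)) stop("`n_post` must be non-negative", call. = FALSE)
  d1 <- floor(delta * n_post)
  tibble::tibble(daughter1 = d1, daughter2 = n_post - d1)
}

#' Post-segregational killing
#'
#' Multiplies the plasmid-free class by the survival fraction `beta`
#' (floored to a whole cell count in census mode); plasmid-bearing classes
#' are untouched. In weights mode the distribution is renormalized.
#'
#' @param dist A `cn_dist`.
#' @param beta Survival fraction of plasmid-free cells, in `[0, 1]`.
#' @return The updated `cn_dist`.
#' @export
apply_psk <- function(dist, beta) {
  validate_cn_dist(dist)
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  mode <- dist_mode(dist)
  st <- psk_state(dist$n, dist$abundance, mode, beta)
  cn_distribution(st$n, st$w, mode = mode)
}

# ---- internal vectorized state machinery -----------------------------------
# The simulation loop works on bare (n, w) vectors, sorted by n; cn_dist
# tibbles only appear at the public boundary.

psk_state <- function(n, w, mode, beta) {
  iz <- which(n == 0)
  if (length(iz)) {
    w[iz] <- if (mode == "census") floor(beta * w[iz]) else beta * w[iz]
    if (w[iz] <= 0) {
      n <- n[-iz]
      w <- w[-iz]
    }
  }
  list(n = n, w = w)
}

step_state <- function(n, w, mode, alpha, delta, beta, policy,
                       prune_eps, n_cap, fail_draws = NULL) {
  if (length(n) == 0L) stop("cannot advance an empty population", call. = FALSE)
  pos <- n > 0
  zero_w <- 2 * sum(w[!pos]) # a plasmid-free cell yields two plasmid-free cells
  nn <- numeric(0)
  ww <- numeric(0)
  if (any(pos)) {
    np <- n[pos]                       # ascending order fixes the draw order
    wp <- w[pos]
    if (!is.null(fail_draws)) {
      nf <- fail_draws[as.character(np)]
      nf[is.na(nf)] <- 0
    } else if (alpha > 0) {
      nf <- floor(-alpha * log(stats::runif(length(np))))
    } else {
      nf <- 0
    }
    post <- replicate_count(np, nf, policy)
    d1 <- floor(delta * post)
    # each mother contributes her whole class abundance to both daughters
    nn <- c(d1, post - d1)
    ww <- c(wp, wp)
  }
  if (zero_w > 0) {
    nn <- c(nn, 0)
    ww <- c(ww, zero_w)
  }
  nn <- pmin(nn, n_cap)
  agg <- rowsum(ww, nn)
  nn <- as.numeric(rownames(agg))
  ww <- as.numeric(agg)
  st <- psk_state(nn, ww, mode, beta)
  nn <- st$n
  ww <- st$w
  if (mode == "weights") {
    ww <- ww / sum(ww)
    keep <- ww >= prune_eps
    if (!all(keep)) {
      nn <- nn[keep]
      ww <- ww[keep]
    }
    ww <- ww / sum(ww)
  }
  list(n = nn, w = ww)
}

#' Advance a population by one generation
#'
#' Applies one full cell cycle to every occupied class: replication with a
#' per-class failure draw, partition into two daughters each inheriting the
#' mother class's abundance (the population doubles), doubling of the
#' plasmid-free class, post-segregational killing, and finally support
#' pruning/capping (weights mode renormalizes).
#'
#' One failure count is drawn per occupied class per generation — all cells
#' of a class behave identically within a generation — with draws taken in
#' ascending class order so runs are reproducible.
#'
#' @param dist A `cn_dist`.
#' @param params A [sim_params()] object.
#' @param fail_draws Optional named numeric vector overriding the random
#'   failure draws: names are parent copy numbers, values the failure count
#'   for that class (classes not named get 0). Useful for worked examples
#'   and tests.
#' @return The next-generation `cn_dist`.
#' @examples
#' d <- cn_distribution(c(0, 1, 2), c(1, 1, 1), mode = "census")
#' # the class of two-unit cells suffers one replication failure:
#' step_generation(d, sim_params(generations = 1), fail_draws = c("2" = 1))
#' @export
step_generation <- function(dist, params, fail_draws = NULL) {
  validate_cn_dist(dist)
  mode <- dist_mode(dist)
  st <- step_state(dist$n, dist$abundance, mode,
                   params$alpha, params$delta, params$beta,
                   params$replication_policy, params$prune_eps, params$n_cap,
                   fail_draws = fail_draws)
  cn_distribution(st$n, st$w, mode = mode)
}

run_trajectory_state <- function(n, w, mode, params, keep_distributions = FALSE) {
  gmax <- params$generations
  S <- numeric(gmax + 1L)
  PCN <- numeric(gmax + 1L)
  dists <- if (keep_distributions) vector("list", gmax + 1L) else NULL
  tot <- sum(w)
  S[1L] <- sum(w[n >= 1]) / tot
  PCN[1L] <- sum(n * w) / tot
  if (keep_distributions) dists[[1L]] <- cn_distribution(n, w, mode = mode)
  for (g in seq_len(gmax)) {
    st <- step_state(n, w, mode, params$alpha, params$delta, params$beta,
                     params$replication_policy, params$prune_eps, params$n_cap)
    n <- st$n
    w <- st$w
    tot <- sum(w)
    S[g + 1L] <- sum(w[n >= 1]) / tot
    PCN[g + 1L] <- sum(n * w) / tot
    if (keep_distributions) dists[[g + 1L]] <- cn_distribution(n, w, mode = mode)
  }
  list(S = S, PCN = PCN, dists = dists)
}

#' Simulate a single population trajectory
#'
#' Runs [step_generation()] for `params$generations` generations from the
#' given initial distribution, recording the stability `S(g)` and mean copy
#' number `PCN(g)` at every generation, including the initial state at
#' `g = 0`. The RNG is seeded from `params$seed`.
#'
#' @param init Initial `cn_dist` (see [init_poisson()] and friends).
#' @param params A [sim_params()] object.
#' @param keep_distributions If `TRUE`, attach the full copy-number
#'   distribution of every generation as a list-column `dist`.
#' @return A `plasmid_trajectory` tibble with columns `generation`, `S`,
#'   `PCN` (and optionally `dist`).
#' @examples
#' traj <- simulate_trajectory(init_poisson(20),
#'                             sim_params(alpha = 1, generations = 50))
#' tail(traj)
#' @export
simulate_trajectory <- function(init, params, keep_distributions = FALSE) {
  validate_cn_dist(init)
  set.seed(params$seed)
  mode <- dist_mode(init)
  res <- run_trajectory_state(init$n, init$abundance, mode, params,
                              keep_distributions = keep_distributions)
  out <- tibble::tibble(
    generation = 0:params$generations,
    S = res$S,
    PCN = res$PCN
  )
  if (keep_distributions) out$dist <- res$dists
  structure(out, params = params,
            class = c("plasmid_trajectory", class(tibble::tibble())))
}

#' Simulate an averaged ensemble of trajectories
#'
#' Runs `params$replicates` independent trajectories and returns the
#' per-generation mean and standard deviation of `S(g)` and `PCN(g)`.
#' Replicate `r` is seeded with a sub-seed drawn deterministically from the
#' master seed, so results are exactly reproducible and replicates are
#' mutually independent. When `alpha = 0` the dynamics contain no random
#' element (partition and killing act deterministically on class weights),
#' so a single run is performed and the spread is exactly zero.
#'
#' @inheritParams simulate_trajectory
#' @return A `plasmid_ensemble` tibble with columns `generation`, `S`,
#'   `S_sd`, `PCN`, `PCN_sd`.
#' @export
simulate_ensemble <- function(init, params) {
  validate_cn_dist(init)
  mode <- dist_mode(init)
  reps <- params$replicates
  set.seed(params$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, reps)
  deterministic <- params$alpha == 0
  nrun <- if (deterministic) 1L else reps
  Smat <- matrix(0, nrow = params$generations + 1L, ncol = nrun)
  Pmat <- matrix(0, nrow = params$generations + 1L, ncol = nrun)
  for (r in seq_len(nrun)) {
    set.seed(subseeds[r])
    res <- run_trajectory_state(init$n, init$abundance, mode, params)
    Smat[, r] <- res$S
    Pmat[, r] <- res$PCN
  }
  if (deterministic) {
    S_mean <- Smat[, 1L]
    P_mean <- Pmat[, 1L]
    S_sd <- rep(0, length(S_mean))
    P_sd <- S_sd
  } else {
    S_mean <- rowMeans(Smat)
    P_mean <- rowMeans(Pmat)
    S_sd <- apply(Smat, 1L, stats::sd)
    P_sd <- apply(Pmat, 1L, stats::sd)
  }
  out <- tibble::tibble(
    generation = 0:params$generations,
    S = S_mean, S_sd = S_sd,
    PCN = P_mean, PCN_sd = P_sd
  )
  structure(out, params = params, replicates = reps, seed = params$seed,
            class = c("plasmid_ensemble", class(tibble::tibble())))
}

#' Write a trajectory or ensemble to CSV
#'
#' Columns `generation,S,PCN` plus the spread columns when present.
#'
#' @param traj A `plasmid_trajectory` or `plasmid_ensemble` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- intersect(c("generation", "S", "S_sd", "PCN", "PCN_sd"), names(traj))
  readr::write_csv(as.data.frame(traj)[cols], path)
  invisible(path)
}

#' Write the full per-generation distributions to long-form CSV
#'
#' Requires a trajectory simulated with `keep_distributions = TRUE`;
#' columns `generation,n,weight`.
#'
#' @inheritParams write_trajectory_csv
#' @export
write_distributions_csv <- function(traj, path) {
  if (is.null(traj$dist)) {
    stop("trajectory was simulated without `keep_distributions = TRUE`",
         call. = FALSE)
  }
  long <- purrr::map2_dfr(traj$generation, traj$dist, function(g, d) {
    tibble::tibble(generation = g, n = d$n, weight = d$abundance)
  })
  readr::write_csv(long, path)
  invisible(path)
}
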