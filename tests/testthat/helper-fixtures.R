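# Small shared fixtures built in code.

# the three-cell census used throughout the docs: one plasmid-free cell,
# one with a single unit, one with two
census3 <- function() {
  cn_distribution(c(0, 1, 2), c(1, 1, 1), mode = "census")
}

# a modest multimer ladder model (monomer 4.6 kb, three ranks)
ladder_model <- function(N = c(100, 60, 30), sigma = c(1, 1.2, 1.4)) {
  multimer_peak_model(x0 = 4.6, N = N, sigma = sigma, b_asym = 0.3,
                      T_bg = 20, xT = 2, c_bg = 0.5)
}

# total-variation distance between two weight-mode distributions
tv_distance <- function(a, b) {
  ns <- sort(union(a$n, b$n))
  wa <- a$abundance[match(ns, a$n)]
  wb <- b$abundance[match(ns, b$n)]
  wa[is.na(wa)] <- 0
  wb[is.na(wb)] <- 0
  0.5 * sum(abs(wa - wb))
}
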