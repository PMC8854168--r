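# Independent oracles used across the suite. Each is a direct, brute-force
# restatement of a definition, kept free of the package code paths it checks.

# Two-tailed Fisher p by exhaustive enumeration over tables with the
# observed margins: sum of hypergeometric probabilities <= the observed
# table's (1 + 1e-7 relative slack for floating-point ties).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + c        # first-column margin
  n <- b + d
  k <- a + b        # first-row margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by its O(m^2) definition: adj_i = min over j with
# p_j >= p_i of m * p_j / rank(p_j).
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i] | seq_len(m) == i] /
                 r[p >= p[i] | seq_len(m) == i]))
  }, numeric(1))
}

# Gamma-Poisson Bayes factor by numerical quadrature of the integrand
# exp(x*log(g) - lambda0*(g-1)) against the Gamma(gamma_bar*beta, beta)
# prior (the Poisson ratio written so nothing underflows).
bf_quadrature_oracle <- function(x, lambda0, gamma_bar, beta) {
  shape <- gamma_bar * beta
  # integration window covering prior and posterior mass (posterior shape
  # x + shape, rate beta + lambda0), so sharp priors are not missed
  lo <- min(stats::qgamma(1e-14, shape, beta),
            stats::qgamma(1e-14, shape + x, beta + lambda0))
  hi <- max(stats::qgamma(1e-14, shape, beta, lower.tail = FALSE),
            stats::qgamma(1e-14, shape + x, beta + lambda0,
                          lower.tail = FALSE))
  f <- function(g) {
    exp(x * log(g) - lambda0 * (g - 1)) *
      stats::dgamma(g, shape = shape, rate = beta)
  }
  stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0)$value
}

# Exact expected distinct-gene overlap when h1 and h2 hits are assigned to
# a small universe by weighted multinomial sampling: full enumeration over
# all G^h1 x G^h2 outcomes.
overlap_enum_oracle <- function(h1, h2, weights) {
  G <- length(weights)
  p <- weights / sum(weights)
  grids <- function(h) {
    as.matrix(expand.grid(rep(list(seq_len(G)), h)))
  }
  g1 <- grids(h1)
  g2 <- grids(h2)
  pr1 <- apply(g1, 1, function(r) prod(p[r]))
  pr2 <- apply(g2, 1, function(r) prod(p[r]))
  total <- 0
  for (i in seq_len(nrow(g1))) {
    s1 <- unique(g1[i, ])
    for (j in seq_len(nrow(g2))) {
      total <- total + pr1[i] * pr2[j] * length(intersect(s1, g2[j, ]))
    }
  }
  total
}

# Small classified DNM record table used by io/count tests.
make_records <- function(disorder, gene, consequence, score = NA_real_,
                         study = "s1") {
  n <- max(length(disorder), length(gene), length(consequence))
  data.frame(study_id = rep_len(study, n),
             disorder = rep_len(disorder, n),
             sample_id = paste0("t", seq_len(n)),
             gene = rep_len(gene, n),
             consequence = rep_len(consequence, n),
             score = rep_len(score, n),
             stringsAsFactors = FALSE)
}
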