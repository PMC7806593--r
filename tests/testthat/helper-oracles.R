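# Independent oracles used to freeze expected values. These deliberately
# avoid the package's code paths.

# Exact two-sided binomial p at p = 1/2 by brute-force PMF enumeration:
# sum of the probabilities of all outcomes no more likely than k.
enum_binom_p <- function(k, n) {
  pmf <- dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Exhaustive additive-null enumeration: all combinations of one replicate
# AI per constituent, equally likely. Returns the exact two-sided p for an
# observed blend mean (no add-one correction).
enum_additive_p <- function(constituent_ais, observed) {
  grid <- expand.grid(constituent_ais, KEEP.OUT.ATTRS = FALSE)
  draws <- rowMeans(as.matrix(grid))
  p_le <- mean(draws <= observed)
  p_ge <- mean(draws >= observed)
  min(1, 2 * min(p_le, p_ge))
}

# Build a minimal T-maze table from parallel count vectors.
make_reps <- function(n_t, n_c, n_centre = 0, treatment = "trtA",
                      species = "D_suzukii") {
  m <- length(n_t)
  data.frame(
    replicate_id = sprintf("%s_%s_r%02d", species, treatment, seq_len(m)),
    fly_species = rep_len(species, m),
    treatment_id = rep_len(treatment, m),
    n_treatment_arm = n_t,
    n_control_arm = n_c,
    n_centre = rep_len(n_centre, m),
    stringsAsFactors = FALSE)
}

# Binomial log-likelihood of replicate-level arm counts at given per-group
# success probabilities (used as the deviance-test oracle).
binom_loglik <- function(k, n, p) {
  sum(dbinom(k, n, p, log = TRUE))
}
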