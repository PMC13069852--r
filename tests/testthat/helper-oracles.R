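# Independent oracles, kept deliberately naive.

# Brute-force pairwise AUC: wins + half ties over all pos x neg pairs.
auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Exhaustive two-sided Mann-Whitney p: enumerate every assignment of
# the pooled tie-free values to group A, build the exact U null
# distribution, apply the 2 * min(tail) rule.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n_a <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">"))
  u_obs <- u_of(a, b)
  idx <- combn(length(pooled), n_a)
  u_null <- apply(idx, 2L, function(i) u_of(pooled[i], pooled[-i]))
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Small labeled dataset with one perfect marker per type.
tiny_sim <- function(seed = 42L, ...) {
  simulate_dataset(simulation_config(n_types = 3L, cells_per_type = 30L,
                                     n_marker = 6L, n_de = 4L,
                                     n_ubiquitous = 10L, seed = seed, ...))
}
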