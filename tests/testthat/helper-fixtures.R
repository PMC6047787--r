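# Shared fixtures and independent oracles for the test suite.

# Small fixed 5-class toy table used by the arithmetic and grid-search
# oracles (counts <= 50 so the oracle stays cheap).
toy_haul <- function(qt = 0.2, qc = 0.1) {
  paired_haul(
    haul_id = "toy",
    class_lower = c(30, 35, 40, 45, 50),
    test_count = c(2, 8, 15, 22, 24),
    control_count = c(20, 24, 18, 10, 6),
    qt = qt, qc = qc,
    mesh_type = "T0", mesh_size = 22, catch_weight = 10,
    sea_state = 1, side = 0)
}

# Direct simulator for one haul at known truth, written independently of the
# package's experiment generator: fixed entries per class, binomial split,
# binomial retention, binomial subsampling.
sim_haul <- function(L50 = 40, SR = 8, SP = 0.5, qt = 0.25, qc = 0.25,
                     n_per_class = 60, grid = seq(20, 70, by = 0.5),
                     id = "sim") {
  enter_t <- rbinom(length(grid), n_per_class, SP)
  enter_c <- n_per_class - enter_t
  x <- exp(log(9) * (grid - L50) / SR)
  r <- x / (1 + x)
  kept_t <- rbinom(length(grid), enter_t, r)
  paired_haul(id, grid,
              test_count = rbinom(length(grid), kept_t, qt),
              control_count = rbinom(length(grid), enter_c, qc),
              qt = qt, qc = qc, mesh_type = "T0", mesh_size = 22,
              catch_weight = 10, sea_state = 1, side = 0)
}

# Coarse-to-fine grid-search oracle over (L50, SR, logit SP), maximising the
# haul log-likelihood by brute force; independent of the optimiser path.
grid_oracle <- function(haul, L50_range = c(25, 55), SR_range = c(1, 20)) {
  best <- c(NA, NA, NA); best_ll <- -Inf
  scan <- function(L50s, SRs, SPs) {
    for (L50 in L50s) for (SR in SRs) for (SP in SPs) {
      ll <- haul_log_likelihood(haul, L50, SR, SP)
      if (ll > best_ll) { best_ll <<- ll; best <<- c(L50, SR, SP) }
    }
  }
  scan(seq(L50_range[1], L50_range[2], by = 0.5),
       seq(SR_range[1], SR_range[2], by = 0.5),
       plogis(seq(-5, 5, by = 0.25)))
  scan(seq(best[1] - 1, best[1] + 1, by = 0.02),
       seq(max(best[2] - 1, 0.1), best[2] + 1, by = 0.02),
       plogis(seq(qlogis(best[3]) - 0.5, qlogis(best[3]) + 0.5, by = 0.02)))
  scan(seq(best[1] - 0.12, best[1] + 0.12, by = 0.005),
       seq(max(best[2] - 0.12, 0.05), best[2] + 0.12, by = 0.005),
       plogis(seq(qlogis(best[3]) - 0.12, qlogis(best[3]) + 0.12, by = 0.005)))
  list(par = c(L50 = best[1], SR = best[2], SP = best[3]), logLik = best_ll)
}

# Haul table rows built directly from given estimates and diagonal
# covariances (bypasses haul fitting; for meta-analysis unit tests).
fake_haul_table <- function(L50, SR, SP, var_L50, var_SR, var_SP,
                            m = 22, w = 10, s = 1, p = 0, mesh_type = "T0") {
  n <- length(L50)
  rec <- function(x) rep_len(x, n)
  data.frame(
    haul_id = sprintf("F%02d", seq_len(n)), mesh_type = rec(mesh_type),
    mesh_size_mm = rec(m), catch_weight_kg = rec(w), sea_state = rec(s),
    side = rec(p), qt = 0.2, qc = 0.2,
    L50 = L50, SR = SR, SP = SP,
    sd_L50 = sqrt(rec(var_L50)), sd_SR = sqrt(rec(var_SR)),
    sd_SP = sqrt(rec(var_SP)),
    CO11 = rec(var_L50), CO12 = 0, CO13 = 0,
    CO22 = rec(var_SR), CO23 = 0, CO33 = rec(var_SP),
    deviance = 1, dof = 10, p_value = 0.5, converged = TRUE, valid = TRUE,
    stringsAsFactors = FALSE)
}
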