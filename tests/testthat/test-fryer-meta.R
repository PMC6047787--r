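test_that("design matrix blocks follow the structure", {
  tab <- fake_haul_table(L50 = c(40, 42), SR = c(8, 9), SP = c(0.5, 0.5),
                         var_L50 = 1, var_SR = 0.5, var_SP = 1e-3,
                         m = c(21.7, 25))
  d0 <- build_design_matrix(tab, fe_structure("intercept", "intercept",
                                              "intercept"))
  expect_equal(d0$X[[1]], diag(3), ignore_attr = TRUE)
  # selected diamond-type structure at m = 21.7: row values m, m^2 | m | 1
  ds <- build_design_matrix(tab, fe_structure(L50 = c("m", "m2"), SR = "m",
                                              SP = "intercept"))
  expect_equal(unname(ds$X[[1]]),
               rbind(c(21.7, 470.89, 0, 0), c(0, 0, 21.7, 0), c(0, 0, 0, 1)))
  expect_equal(ds$labels, c("L50:m", "L50:m2", "SR:m", "SP:intercept"))
})

test_that("design matrix rejects mixed mesh types and collinear terms", {
  tab <- fake_haul_table(L50 = c(40, 42), SR = c(8, 9), SP = c(0.5, 0.5),
                         var_L50 = 1, var_SR = 0.5, var_SP = 1e-3)
  tab$mesh_type <- c("T0", "T90")
  expect_error(build_design_matrix(tab, full_structure()), "mixed mesh types")
  # a term constant across hauls together with the intercept is collinear
  tab2 <- fake_haul_table(L50 = c(40, 42, 41), SR = c(8, 9, 8),
                          SP = c(0.5, 0.5, 0.5), var_L50 = 1, var_SR = 0.5,
                          var_SP = 1e-3, m = 22)
  expect_error(
    build_design_matrix(tab2, fe_structure(L50 = c("intercept", "m"),
                                           SR = "intercept", SP = "intercept")),
    "collinear.*L50")
})

test_that("with D = 0 the intercept-only fit is the closed-form weighted mean", {
  v_L50 <- c(1, 4, 2, 8); v_SR <- c(0.5, 1, 2, 0.25); v_SP <- c(1, 2, 3, 4) * 1e-3
  tab <- fake_haul_table(L50 = c(39, 41, 44, 40), SR = c(7, 9, 8, 10),
                         SP = c(0.45, 0.52, 0.50, 0.48),
                         var_L50 = v_L50, var_SR = v_SR, var_SP = v_SP)
  fit <- fit_fryer_model(tab, fe_structure("intercept", "intercept",
                                           "intercept"), D_type = "zero")
  # independent closed-form inverse-variance weighted means
  ivw <- function(x, v) sum(x / v) / sum(1 / v)
  expect_equal(unname(fit$coefficients["L50:intercept"]),
               ivw(tab$L50, v_L50), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["SR:intercept"]),
               ivw(tab$SR, v_SR), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["SP:intercept"]),
               ivw(tab$SP, v_SP), tolerance = 1e-8)
  expect_equal(unname(fit$se["L50:intercept"]), sqrt(1 / sum(1 / v_L50)),
               tolerance = 1e-8)
  # equal variances reduce to the arithmetic mean
  tab_eq <- fake_haul_table(L50 = c(39, 41), SR = c(7, 9), SP = c(0.45, 0.55),
                            var_L50 = 1, var_SR = 1, var_SP = 1)
  fit_eq <- fit_fryer_model(tab_eq, fe_structure("intercept", "intercept",
                                                 "intercept"), D_type = "zero")
  expect_equal(unname(fit_eq$coefficients),
               c(mean(tab_eq$L50), mean(tab_eq$SR), mean(tab_eq$SP)),
               tolerance = 1e-8)
})

test_that("AICc follows the small-sample formula with its sentinels", {
  expect_equal(compute_aicc(-5, k = 2, n = 10),
               -2 * (-5) + 2 * 2 + 2 * 2 * 3 / (10 - 2 - 1), tolerance = 1e-12)
  expect_equal(compute_aicc(-5, k = 2, n = 10), 15.714, tolerance = 1e-3)
  # correction vanishes for large n
  expect_equal(compute_aicc(-5, k = 2, n = 1e7), -2 * (-5) + 4,
               tolerance = 1e-4)
  expect_identical(compute_aicc(-5, k = 9, n = 10), Inf)
})

test_that("structure enumeration is complete, duplicate-free and deterministic", {
  full3 <- fe_structure(L50 = "m", SR = "m", SP = "intercept")
  enum <- enumerate_structures(full3)
  expect_equal(enum$n, 8)
  labs <- vapply(seq_len(enum$n), function(i) format(structure_at(enum, i)), "")
  expect_equal(anyDuplicated(labs), 0L)
  # 2^t scaling and uniqueness on a larger toggled set
  full6 <- fe_structure(L50 = c("m", "m2"), SR = c("m", "w"),
                        SP = c("intercept", "s"))
  e6 <- enumerate_structures(full6)
  expect_equal(e6$n, 64)
  labs6 <- vapply(seq_len(64), function(i) format(structure_at(e6, i)), "")
  expect_equal(length(unique(labs6)), 64)
  # empty full model enumerates the single empty structure
  expect_equal(enumerate_structures(fe_structure())$n, 1)
  # forced terms are present in every candidate
  ef <- enumerate_structures(full3, forced = "SP:intercept")
  expect_equal(ef$n, 4)
  expect_true(all(vapply(1:4, function(i)
    "intercept" %in% structure_at(ef, i)$SP, logical(1))))
})

test_that("the full 21-term model yields 2,097,152 candidates", {
  expect_identical(enumerate_structures(full_structure())$n, 2^21)
  expect_identical(2^21, 2097152)
})

test_that("model selection ranks by AICc deterministically and finds truth", {
  set.seed(55)
  m <- runif(30, 19, 36); w <- runif(30, 5, 80)
  true_str <- fe_structure(L50 = "m", SR = "m", SP = "intercept")
  n_win <- 0
  for (rep in 1:15) {
    L50 <- 2.05 * m + rnorm(30, 0, 2) + rnorm(30, 0, sqrt(1))
    SR <- 0.37 * m + rnorm(30, 0, 0.7)
    SP <- 0.49 + rnorm(30, 0, 0.03)
    tab <- fake_haul_table(L50 = L50, SR = SR, SP = SP, var_L50 = 4,
                           var_SR = 0.5, var_SP = 9e-4, m = m, w = w)
    cands <- list(true_str,
                  fe_structure(L50 = c("m", "w"), SR = c("m", "w"),
                               SP = "intercept"))
    sel <- select_best_model(tab, cands, D_type = "diagonal")
    if (sel$ranking$candidate[1] == 1) n_win <- n_win + 1
  }
  expect_gt(n_win, 7)  # true structure preferred in the majority of replicates
})

test_that("ranking is invariant to candidate input order", {
  tab <- fake_haul_table(L50 = 2.05 * seq(20, 34, 2), SR = 0.37 * seq(20, 34, 2),
                         SP = 0.5, var_L50 = 2, var_SR = 0.3, var_SP = 1e-3,
                         m = seq(20, 34, 2))
  cands <- list(fe_structure(L50 = "m", SR = "m", SP = "intercept"),
                fe_structure(L50 = c("m", "m2"), SR = "m", SP = "intercept"),
                fe_structure(L50 = "intercept", SR = "intercept",
                             SP = "intercept"))
  s1 <- select_best_model(tab, cands, D_type = "zero")
  s2 <- select_best_model(tab, rev(cands), D_type = "zero")
  expect_equal(s1$ranking$structure, s2$ranking$structure)
  expect_equal(s1$ranking$AICc, s2$ranking$AICc, tolerance = 1e-8)
  expect_equal(format(s1$best$structure), format(s2$best$structure))
  # single candidate is trivially rank 1
  s3 <- select_best_model(tab, cands[1], D_type = "zero")
  expect_equal(nrow(s3$ranking), 1)
})

test_that("coefficient recovery from simulated meta-data is within 3 SE", {
  set.seed(77)
  n <- 60
  m <- runif(n, 19, 36)
  D <- diag(c(26.14, 6.38, 0.01))
  R <- diag(c(1.5, 0.8, 4e-4))
  theta <- cbind(2.05 * m - 0.01 * m^2, 0.37 * m, 0.49) +
    matrix(rnorm(3 * n), n) %*% chol(D + R)
  tab <- fake_haul_table(L50 = theta[, 1], SR = theta[, 2], SP = theta[, 3],
                         var_L50 = R[1, 1], var_SR = R[2, 2],
                         var_SP = R[3, 3], m = m)
  fit <- fit_fryer_model(tab, fe_structure(L50 = c("m", "m2"), SR = "m",
                                           SP = "intercept"),
                         D_type = "diagonal")
  truth <- c("L50:m" = 2.05, "L50:m2" = -0.01, "SR:m" = 0.37,
             "SP:intercept" = 0.49)
  expect_true(all(abs(fit$coefficients - truth) < 3 * fit$se))
  # between-haul variances recovered to the right order of magnitude
  expect_gt(fit$D["L50", "L50"], 26.14 / 3)
  expect_lt(fit$D["L50", "L50"], 26.14 * 3)
})

test_that("prediction intervals: total tier always encloses estimation tier", {
  mod <- reference_codend_models("T0")
  pred <- predict(mod, data.frame(m = seq(19.5, 36, by = 0.5)))
  expect_true(all(pred$L50_total_lower <= pred$L50_est_lower))
  expect_true(all(pred$L50_total_upper >= pred$L50_est_upper))
  expect_true(all(pred$SR_total_lower <= pred$SR_est_lower))
  expect_true(all(pred$SR_total_upper >= pred$SR_est_upper))
  # with D = 0 the two tiers coincide
  mod0 <- codend_model(mod$structure, mod$coefficients, mod$se,
                       D_diag = c(0, 0, 0), mesh_type = "T0",
                       m_range = mod$m_range)
  p0 <- predict(mod0, data.frame(m = 25))
  expect_equal(p0$L50_total_lower, p0$L50_est_lower, tolerance = 1e-12)
  expect_equal(p0$SR_total_upper, p0$SR_est_upper, tolerance = 1e-12)
  expect_warning(predict(mod, data.frame(m = 50)), "extrapolating")
})
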