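test_that("reference diamond model reproduces the published benchmark", {
  mod <- reference_codend_models("T0")
  pred <- predict(mod, data.frame(m = 21.7))
  expect_equal(pred$L50_mean, 39.8, tolerance = 0.05)
  expect_equal(pred$SR_mean, 8.0, tolerance = 0.05)
  expect_equal(pred$SP_mean, 0.49, tolerance = 1e-8)
})

test_that("isoline grid is ordered, flagged, and pins the 50% level at L50", {
  mod <- reference_codend_models("T0")
  iso <- retention_isolines(mod, mesh_sizes = seq(20, 30, 2))
  expect_s3_class(iso, "isoline_grid")
  for (ms in unique(iso$mesh_size)) {
    sub <- iso[iso$mesh_size == ms, ]
    # higher retention requires larger shrimp: L_r increasing in r
    expect_true(all(diff(sub$L_r) > 0))
    expect_equal(sub$L_r[sub$r_percent == 50], sub$L50_mean[1],
                 tolerance = 1e-10)
  }
  # a degenerate model with negative SR is flagged, not dropped
  bad <- codend_model(fe_structure(L50 = "m", SR = "intercept",
                                   SP = "intercept"),
                      coefficients = c("L50:m" = 2, "SR:intercept" = -1,
                                       "SP:intercept" = 0.5),
                      se = c("L50:m" = 0.1, "SR:intercept" = 0.1,
                             "SP:intercept" = 0.01),
                      D_diag = c(1, 1, 0.001), mesh_type = "T0",
                      m_range = c(19, 36))
  iso_bad <- suppressWarnings(retention_isolines(bad, 21))
  expect_true(all(!iso_bad$ok))
  expect_true(all(is.na(iso_bad$L_r)))
})

test_that("diamond codends of 20-21 mm retain mls-sized shrimp nearly fully", {
  mod <- reference_codend_models("T0")
  pred <- predict(mod, data.frame(m = c(20, 21)))
  r50 <- retention_probability(50, pred$L50_mean, pred$SR_mean)
  r45 <- retention_probability(45, pred$L50_mean, pred$SR_mean)
  expect_true(all(r50 >= 0.95))  # 50 mm shrimp fully retained
  expect_true(all(r45 >= 0.80))
  # equivalently via the isolines: the 95% isoline sits at or below 50 mm
  iso <- retention_isolines(mod, c(20, 21))
  expect_true(all(iso$L_r[iso$r_percent == 95] <= 50))
})

test_that("selection applied to a population matches per-class arithmetic", {
  nPop <- data.frame(class_lower = c(30, 30.5, 31), count = c(100, 50, 20))
  nc <- apply_selection_to_population(nPop, L50 = 30.5, SR = 2)
  r_mid <- retention_probability(c(30.25, 30.75, 31.25), 30.5, 2)
  expect_equal(nc$count, c(100, 50, 20) * r_mid, tolerance = 1e-12)
  nc_low <- apply_selection_to_population(nPop, 30.5, 2, at = "lower")
  r_low <- retention_probability(c(30, 30.5, 31), 30.5, 2)
  expect_equal(nc_low$count, c(100, 50, 20) * r_low, tolerance = 1e-12)
  # retention ~ 1 and ~ 0 limits
  expect_equal(apply_selection_to_population(nPop, -500, 2)$count,
               nPop$count, tolerance = 1e-9)
  expect_equal(apply_selection_to_population(nPop, 500, 2)$count,
               rep(0, 3), tolerance = 1e-9)
})

test_that("usability indicators: limits, conservation, summation oracle", {
  nPop <- generate_population(population_spec(N = 5e4), seed = 9)
  # nCatch = nPop: full retention of everything
  full <- usability_indicators(nPop, nPop, mls = 50)
  expect_equal(full$nP, 100, tolerance = 1e-10)
  expect_equal(full$nPa, 100, tolerance = 1e-10)
  expect_equal(full$nPb, 100, tolerance = 1e-10)
  expect_equal(full$nR,
               100 * sum(nPop$count[nPop$class_lower < 50]) / sum(nPop$count),
               tolerance = 1e-10)
  # knife-edge retention at mls
  knife <- nPop
  knife$count[knife$class_lower < 50] <- 0
  ke <- usability_indicators(nPop, knife, mls = 50)
  expect_equal(ke$nR, 0, tolerance = 1e-12)
  expect_equal(ke$nPb, 0, tolerance = 1e-12)
  expect_equal(ke$nPa, 100, tolerance = 1e-12)
  # spreadsheet-style summation oracle for a predicted diamond curve
  mod <- reference_codend_models("T0")
  pred <- predict(mod, data.frame(m = 21))
  nCatch <- apply_selection_to_population(nPop, pred$L50_mean, pred$SR_mean)
  ind <- usability_indicators(nPop, nCatch, mls = 50)
  under <- nPop$class_lower < 50
  expect_equal(ind$nR, 100 * sum(nCatch$count[under]) / sum(nCatch$count),
               tolerance = 1e-12)
  expect_equal(ind$nPa,
               100 * sum(nCatch$count[!under]) / sum(nPop$count[!under]),
               tolerance = 1e-12)
  # conservation identity: nP * sum(nPop) = nPa * sum(above) + nPb * sum(below)
  lhs <- ind$nP * sum(nPop$count)
  rhs <- ind$nPa * sum(nPop$count[!under]) + ind$nPb * sum(nPop$count[under])
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_true(all(unlist(ind[c("nR", "nP", "nPa", "nPb")]) >= 0))
  expect_true(all(unlist(ind[c("nR", "nP", "nPa", "nPb")]) <= 100))
})

test_that("indicators are monotone in L50 for a fixed population", {
  nPop <- generate_population(population_spec(N = 2e4), seed = 4)
  l50s <- seq(30, 60, by = 1)
  vals <- t(vapply(l50s, function(L50) {
    nc <- apply_selection_to_population(nPop, L50, 8)
    ind <- usability_indicators(nPop, nc)
    c(ind$nR, ind$nP, ind$nPa, ind$nPb)
  }, numeric(4)))
  # shifting the curve right releases more of everything
  expect_true(all(diff(vals[, 2]) < 0))
  expect_true(all(diff(vals[, 3]) < 0))
  expect_true(all(diff(vals[, 4]) < 0))
})

test_that("indicator table spans types x mesh sizes with expected ordering", {
  nPop <- generate_population(population_spec(N = 5e4), seed = 9)
  tab <- indicator_table(reference_codend_models(),
                         mesh_sizes = c(21, 23, 25, 27, 29), nPop = nPop)
  expect_equal(nrow(tab), 15)
  expect_true(all(c("nR", "nP", "nPa", "nPb") %in% names(tab)))
  for (mt in unique(tab$mesh_type)) {
    sub <- tab[tab$mesh_type == mt, ]
    sub <- sub[order(sub$mesh_size), ]
    # larger mesh releases more shrimp at every length
    expect_true(all(diff(sub$nP) < 0))
    expect_true(all(diff(sub$nPa) < 0))
    expect_true(all(diff(sub$nPb) < 0))
    # retention above mls always exceeds retention below it
    expect_true(all(sub$nPa >= sub$nPb))
  }
})
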