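#' Population length-structure specification
#'
#' Describes a unimodal brown-shrimp population over the 0.5 mm length-class
#' grid. The default is gamma-shaped with its mode near 48 mm over 10-100 mm,
#' the size structure typical of the Wadden Sea fishing grounds where the
#' paired-gear trials this package emulates took place.
#'
#' @param N total number of shrimp.
#' @param range length range (mm), lower/upper bounds of the class grid.
#' @param shape gamma shape parameter of the length distribution.
#' @param mode modal length (mm); fixes the gamma rate at
#'   \code{(shape - 1)/mode}.
#' @param binwidth class width (mm), a multiple of 0.5.
#' @return list of class \code{"population_spec"}.
#' @export
population_spec <- function(N = 1e5, range = c(10, 100), shape = 12,
                            mode = 48, binwidth = 0.5) {
  stopifnot(N > 0, length(range) == 2, range[2] > range[1], shape > 1,
            mode > 0, binwidth > 0, abs(binwidth * 2 - round(binwidth * 2)) < 1e-9)
  structure(list(N = N, range = range, shape = shape, mode = mode,
                 binwidth = binwidth, rate = (shape - 1) / mode),
            class = "population_spec")
}

.population_grid <- function(spec) {
  seq(spec$range[1], spec$range[2] - spec$binwidth, by = spec$binwidth)
}

.population_probs <- function(spec) {
  lower <- .population_grid(spec)
  p <- stats::pgamma(lower + spec$binwidth, spec$shape, spec$rate) -
    stats::pgamma(lower, spec$shape, spec$rate)
  if (sum(p) <= 0) stop("empty length range for the population", call. = FALSE)
  p / sum(p)
}

#' Generate a population length-frequency vector
#'
#' Draws \code{spec$N} shrimp lengths from the discretised population
#' distribution and bins them on the 0.5 mm class grid. Identical seeds give
#' identical vectors.
#'
#' @param spec a \code{\link{population_spec}}.
#' @param seed integer seed.
#' @return data frame with \code{class_lower} (mm) and \code{count}; counts
#'   sum to \code{spec$N}.
#' @export
generate_population <- function(spec = population_spec(), seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, spec$N, .population_probs(spec)))
  data.frame(class_lower = .population_grid(spec), count = counts)
}

#' Ground truth for a synthetic paired-gear experiment
#'
#' Defines the generating process of a synthetic selectivity experiment: the
#' true mean-equation coefficients, the between-haul covariance D, the
#' population, the per-codend design (mesh sizes and hauls per codend), the
#' covariate distributions and the subsampling factor ranges. Defaults mirror
#' the diamond-mesh arm of the sea-trial design this package emulates:
#' 13 codends of 19-36.4 mm mesh with 5-12 hauls each, true coefficients and
#' between-haul variances equal to the packaged diamond reference model,
#' catch weights around 35 kg, and subsampling factors in the observed
#' ranges.
#'
#' @param mesh_type codend type label.
#' @param coefficients named list with elements \code{L50}, \code{SR},
#'   \code{SP}, each a named numeric vector over terms in
#'   \{intercept, m, m2, w, mw, s, p\}.
#' @param D 3x3 positive semi-definite between-haul covariance of
#'   (L50, SR, SP) (a length-3 vector is taken as the diagonal).
#' @param population a \code{\link{population_spec}}.
#' @param design data frame with columns \code{mesh_size} (mm) and
#'   \code{n_hauls}.
#' @param n_enter expected number of shrimp entering the gear pair per haul.
#' @param w_mean,w_sd catch-weight distribution (kg), normal truncated at 0.
#' @param qt_range,qc_range subsampling factor ranges (uniform draws).
#' @param sr_floor lower bound applied to realised haul SR (mm); floor events
#'   are logged in the truth record.
#' @return list of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(
    mesh_type = "T0",
    coefficients = list(L50 = c(m = 2.05, m2 = -0.01),
                        SR = c(m = 0.37),
                        SP = c(intercept = 0.49)),
    D = c(26.14, 6.38, 0.01),
    population = population_spec(),
    design = data.frame(
      mesh_size = c(19.05, 20.19, 21.45, 22.95, 24.65, 25.10, 27.15,
                    27.83, 29.35, 31.58, 32.25, 32.28, 36.38),
      n_hauls = c(6, 9, 9, 6, 6, 5, 6, 8, 5, 6, 6, 12, 5)),
    n_enter = 20000,
    w_mean = 35, w_sd = 25,
    qt_range = c(0.03, 0.47), qc_range = c(0.02, 0.26),
    sr_floor = 0.5) {
  if (is.vector(D) && length(D) == 3) D <- diag(as.numeric(D), 3)
  stopifnot(is.matrix(D), all(dim(D) == 3))
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("'D' must be positive semi-definite", call. = FALSE)
  for (eq in c("L50", "SR", "SP")) {
    bad <- setdiff(names(coefficients[[eq]]), .fe_terms)
    if (length(bad)) stop("unknown term(s) in true ", eq, " equation: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  truth <- structure(list(
    mesh_type = mesh_type, coefficients = coefficients, D = (D + t(D)) / 2,
    population = population, design = design, n_enter = n_enter,
    w_mean = w_mean, w_sd = w_sd, qt_range = qt_range, qc_range = qc_range,
    sr_floor = sr_floor
  ), class = "synthetic_truth")
  ## the design must imply a positive selection range throughout
  sr_chk <- vapply(design$mesh_size, function(m)
    .linear_predictor(coefficients$SR, m, w_mean, 0, 0), numeric(1))
  if (all(sr_chk <= 0)) {
    stop("truth implies non-positive SR over the whole design", call. = FALSE)
  }
  truth
}

.linear_predictor <- function(coefs, m, w, s, p) {
  if (length(coefs) == 0) return(0)
  sum(vapply(names(coefs), function(tm)
    coefs[[tm]] * .term_value(tm, m, w, s, p), numeric(1)))
}

## PSD-safe multivariate normal draw (D may be rank-deficient)
.rmvnorm_psd <- function(n, Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(A)
}

#' Generate a synthetic paired-gear experiment
#'
#' Simulates an experiment haul by haul under known ground truth. For each
#' haul: covariates are drawn (catch weight from a truncated normal, sea
#' state uniform on 0-4, side Bernoulli(0.5), qt/qc uniform in their ranges);
#' the haul's true \code{(L50, SR, SP)} is the mean-equation linear predictor
#' plus a N(0, D) between-haul deviation (SR floored, SP clamped to (0, 1),
#' both events logged); shrimp lengths are drawn from the population; each
#' shrimp enters the test codend with probability SP (otherwise control); a
#' test-side shrimp is retained with the logistic retention probability at
#' its length class, the control codend retains everything; finally each
#' codend's catch is independently binomially subsampled at qt/qc to give the
#' measured counts.
#'
#' All randomness descends from \code{seed} through per-haul substreams, so
#' identical seeds give identical experiments regardless of haul order of
#' consumption.
#'
#' @param truth a \code{\link{synthetic_truth}}.
#' @param seed integer master seed.
#' @return list of class \code{"synthetic_experiment"} with \code{hauls}
#'   (list of \code{\link{paired_haul}}), \code{truth_record} (data frame of
#'   realised per-haul parameters and covariates), \code{detail} (per-haul
#'   class-level entered/retained counts before subsampling), and
#'   \code{population} (the expected population structure).
#' @export
generate_experiment <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  design <- truth$design
  n_hauls <- sum(design$n_hauls)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, n_hauls)
  grid <- .population_grid(truth$population)
  probs <- .population_probs(truth$population)

  hauls <- vector("list", n_hauls)
  detail <- vector("list", n_hauls)
  rec <- vector("list", n_hauls)
  h <- 0L
  for (d in seq_len(nrow(design))) {
    for (j in seq_len(design$n_hauls[d])) {
      h <- h + 1L
      set.seed(substreams[h])
      m <- design$mesh_size[d]
      w <- max(stats::rnorm(1, truth$w_mean, truth$w_sd), 0)
      s <- sample(0:4, 1)
      p <- stats::rbinom(1, 1, 0.5)
      qt <- stats::runif(1, truth$qt_range[1], truth$qt_range[2])
      qc <- stats::runif(1, truth$qc_range[1], truth$qc_range[2])

      mu <- c(.linear_predictor(truth$coefficients$L50, m, w, s, p),
              .linear_predictor(truth$coefficients$SR, m, w, s, p),
              .linear_predictor(truth$coefficients$SP, m, w, s, p))
      dev <- drop(.rmvnorm_psd(1, truth$D))
      L50 <- mu[1] + dev[1]
      SR <- mu[2] + dev[2]
      SP <- mu[3] + dev[3]
      sr_floored <- SR < truth$sr_floor
      sp_clamped <- SP < 0.02 || SP > 0.98
      SR <- max(SR, truth$sr_floor)
      SP <- min(max(SP, 0.02), 0.98)

      n_l <- as.vector(stats::rmultinom(1, truth$n_enter, probs))
      enter_t <- stats::rbinom(length(n_l), n_l, SP)
      enter_c <- n_l - enter_t
      retained_t <- stats::rbinom(length(n_l), enter_t,
                                  retention_probability(grid, L50, SR))
      measured_t <- stats::rbinom(length(n_l), retained_t, qt)
      measured_c <- stats::rbinom(length(n_l), enter_c, qc)

      hauls[[h]] <- paired_haul(
        haul_id = sprintf("H%03d", h),
        class_lower = grid, test_count = measured_t,
        control_count = measured_c, qt = qt, qc = qc,
        mesh_type = truth$mesh_type, mesh_size = m, catch_weight = w,
        sea_state = s, side = p)
      detail[[h]] <- data.frame(class_lower = grid, entered = n_l,
                                entered_test = enter_t,
                                entered_control = enter_c,
                                retained_test = retained_t)
      rec[[h]] <- data.frame(
        haul_id = sprintf("H%03d", h), mesh_type = truth$mesh_type,
        mesh_size_mm = m, catch_weight_kg = w, sea_state = s, side = p,
        qt = qt, qc = qc, L50 = L50, SR = SR, SP = SP,
        sr_floored = sr_floored, sp_clamped = sp_clamped,
        stringsAsFactors = FALSE)
    }
  }
  population <- data.frame(class_lower = grid,
                           count = truth$population$N * probs)
  structure(list(hauls = hauls,
                 truth_record = do.call(rbind, rec),
                 detail = detail,
                 population = population,
                 seed = seed),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic paired-gear experiment:", length(x$hauls), "hauls,",
      x$truth_record$mesh_type[1], "codends, seed", x$seed, "\n")
  cat("mesh sizes:", paste(sort(unique(x$truth_record$mesh_size_mm)),
                           collapse = ", "), "mm\n")
  invisible(x)
}
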