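#' Paired-gear haul counts
#'
#' Container for one experimental haul of a paired-gear selectivity trial:
#' length-frequency counts measured in the test and control codends on a
#' shared 0.5 mm length-class grid, the subsampling factors that scale the
#' measured counts to the full catch, and haul-level covariates used by the
#' meta-analysis.
#'
#' Lengths are recorded rounded down to the half millimetre, so the class
#' label \code{class_lower} is the recorded length of every shrimp in the
#' class and is used directly as \code{l} in the likelihood.
#'
#' @param haul_id identifier (scalar).
#' @param class_lower numeric vector of class lower bounds (mm), strictly
#'   increasing, spacing an integer multiple of 0.5 mm.
#' @param test_count,control_count non-negative counts of measured shrimp per
#'   class in the test and control codends.
#' @param qt,qc subsampling factors in (0, 1]: fraction of each codend's
#'   catch that was length-measured.
#' @param mesh_type one of \code{"T0"} (diamond), \code{"T45"} (square),
#'   \code{"T90"}.
#' @param mesh_size mesh size m (mm), > 0.
#' @param catch_weight test-codend catch weight w (kg), >= 0.
#' @param sea_state mean sea state s on the 0-9 scale.
#' @param side trawl side p carrying the test codend: 0 = port, 1 = starboard.
#' @return an object of class \code{"paired_haul"}.
#' @export
paired_haul <- function(haul_id, class_lower, test_count, control_count,
                        qt, qc, mesh_type = c("T0", "T45", "T90"),
                        mesh_size = NA_real_, catch_weight = NA_real_,
                        sea_state = NA_real_, side = NA_integer_) {
  mesh_type <- match.arg(mesh_type)
  n <- length(class_lower)
  if (length(test_count) != n || length(control_count) != n) {
    stop("test and control counts must share the length-class grid",
         call. = FALSE)
  }
  if (n > 1 && any(diff(class_lower) <= 0)) {
    stop("length-class lower bounds must be strictly increasing",
         call. = FALSE)
  }
  if (any(abs(class_lower * 2 - round(class_lower * 2)) > 1e-8)) {
    stop("length classes must sit on a 0.5 mm grid", call. = FALSE)
  }
  if (any(test_count < 0) || any(control_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  for (q in list(qt = qt, qc = qc)) {
    if (!is.finite(q) || q <= 0 || q > 1) {
      stop("subsampling factors qt/qc must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!is.na(mesh_size) && mesh_size <= 0) {
    stop("'mesh_size' must be positive", call. = FALSE)
  }
  if (!is.na(sea_state) && (sea_state < 0 || sea_state > 9)) {
    stop("'sea_state' must be on the 0-9 scale", call. = FALSE)
  }
  if (!is.na(side) && !side %in% c(0, 1)) {
    stop("'side' must be 0 (port) or 1 (starboard)", call. = FALSE)
  }
  structure(list(
    haul_id = haul_id,
    class_lower = as.numeric(class_lower),
    test_count = as.numeric(test_count),
    control_count = as.numeric(control_count),
    qt = qt, qc = qc,
    covariates = list(mesh_type = mesh_type, m = mesh_size,
                      w = catch_weight, s = sea_state, p = side)
  ), class = "paired_haul")
}

#' @export
print.paired_haul <- function(x, ...) {
  cat("Paired-gear haul", format(x$haul_id), "-", x$covariates$mesh_type,
      "codend,", format(x$covariates$m), "mm mesh\n")
  cat(sprintf("  %d length classes [%g, %g] mm; measured test/control = %g/%g; qt = %g, qc = %g\n",
              length(x$class_lower), min(x$class_lower), max(x$class_lower),
              sum(x$test_count), sum(x$control_count), x$qt, x$qc))
  invisible(x)
}

#' Paired-gear log-likelihood for one haul
#'
#' Log-likelihood of the test/control counts given logistic selectivity
#' \code{(L50, SR)} and split parameter \code{SP}, accounting for the
#' subsampling factors:
#' \deqn{\sum_l \Big\{ nt_l \ln\frac{q_t \phi_l}{q_t \phi_l + q_c (1-\phi_l)}
#'   + nc_l \ln\frac{q_c (1-\phi_l)}{q_t \phi_l + q_c (1-\phi_l)} \Big\}}
#' with \eqn{\phi_l} the expected test-codend catch share
#' (\code{\link{catch_share}}). Classes with no measured shrimp contribute
#' zero. Only the ratio \code{qt/qc} affects the value.
#'
#' @param haul a \code{\link{paired_haul}}.
#' @param L50,SR,SP selectivity and split parameters.
#' @return the log-likelihood (scalar).
#' @export
haul_log_likelihood <- function(haul, L50, SR, SP) {
  nt <- haul$test_count
  nc <- haul$control_count
  if (sum(nt) + sum(nc) == 0) {
    stop("degenerate data: all counts are zero", call. = FALSE)
  }
  phi <- catch_share(haul$class_lower, L50, SR, SP)
  pt <- haul$qt * phi / (haul$qt * phi + haul$qc * (1 - phi))
  keep <- (nt + nc) > 0
  sum(nt[keep] * log(pt[keep]) + nc[keep] * log1p(-pt[keep]))
}

## negative log-likelihood in working coordinates (L50, log SR, logit SP);
## the transform keeps SR > 0 and SP in (0,1) without box constraints
.haul_nll_work <- function(par, haul) {
  L50 <- par[1]
  SR <- exp(par[2])
  SP <- stats::plogis(par[3])
  if (!is.finite(SR) || SR <= 0 || SP <= 0 || SP >= 1) return(1e10)
  ll <- haul_log_likelihood(haul, L50, SR, SP)
  if (!is.finite(ll)) return(1e10)
  -ll
}

.haul_nll_natural <- function(par, haul) {
  if (par[2] <= 0 || par[3] <= 0 || par[3] >= 1) return(1e10)
  ll <- haul_log_likelihood(haul, par[1], par[2], par[3])
  if (!is.finite(ll)) return(1e10)
  -ll
}

## starting values from the raised test share: SP from the large-length
## plateau, L50 grid at empirical share quantiles
.haul_starts <- function(haul) {
  l <- haul$class_lower
  tot <- haul$test_count + haul$control_count
  keep <- tot > 0
  l <- l[keep]
  nt <- haul$test_count[keep] / haul$qt
  nc <- haul$control_count[keep] / haul$qc
  upper <- l >= stats::quantile(rep(l, times = round(nt + nc) + 1L), 0.8)
  sp0 <- sum(nt[upper]) / (sum(nt[upper]) + sum(nc[upper]))
  sp0 <- min(max(sp0, 0.05), 0.95)
  qs <- stats::quantile(rep(l, times = round(nt + nc) + 1L), c(0.25, 0.5, 0.75))
  sr0 <- max(diff(range(l)) / 6, 2)
  starts <- lapply(unique(qs), function(l50) c(l50, log(sr0), stats::qlogis(sp0)))
  starts
}

#' Fit logistic selectivity to one haul by maximum likelihood
#'
#' Maximises \code{\link{haul_log_likelihood}} over \code{(L50, SR, SP)} for a
#' single paired-gear haul. Optimisation runs in transformed coordinates
#' (\code{L50} free, \code{log SR}, \code{logit SP}) from a small multi-start
#' grid to avoid boundary failures and local optima. The covariance of the
#' estimates on the natural scale is the inverse of the numerically
#' differenced observed information at the optimum; hauls where that matrix is
#' not positive definite are flagged \code{valid = FALSE} (no error) and are
#' excluded from downstream meta-analysis. Goodness-of-fit diagnostics are
#' attached via \code{\link{assess_haul_fit}}.
#'
#' @param haul a \code{\link{paired_haul}}.
#' @param reltol convergence tolerance on the objective.
#' @return an object of class \code{"haul_fit"} with elements
#'   \code{estimate} (named L50/SR/SP), \code{cov} (3x3), \code{se},
#'   \code{logLik}, \code{deviance}, \code{dof}, \code{p_value},
#'   \code{residuals}, \code{converged}, \code{valid}, \code{covariates},
#'   \code{qt}, \code{qc}.
#' @export
fit_haul <- function(haul, reltol = 1e-8) {
  stopifnot(inherits(haul, "paired_haul"))
  tot <- haul$test_count + haul$control_count
  if (sum(tot) == 0) stop("degenerate data: all counts are zero", call. = FALSE)
  if (sum(haul$test_count) == 0 || sum(haul$control_count) == 0) {
    stop("degenerate data: one codend has no measured shrimp; retention and split are unidentified",
         call. = FALSE)
  }
  if (sum(tot > 0) < 4) {
    stop("need at least 4 length classes with counts to fit 3 parameters",
         call. = FALSE)
  }

  best <- NULL
  for (st in .haul_starts(haul)) {
    fit <- stats::optim(st, .haul_nll_work, haul = haul, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = reltol))
    ## polish with BFGS from the simplex optimum
    fit2 <- tryCatch(
      stats::optim(fit$par, .haul_nll_work, haul = haul, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) fit)
    if (fit2$value <= fit$value) fit <- fit2
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- is.finite(best$value) && best$value < 1e9
  est <- c(L50 = best$par[1], SR = exp(best$par[2]),
           SP = stats::plogis(best$par[3]))

  ## observed information on the natural (L50, SR, SP) scale
  cov <- NULL
  valid <- FALSE
  H <- tryCatch(stats::optimHess(unname(est), .haul_nll_natural, haul = haul),
                error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) {
      cov <- solve(H)
      cov <- (cov + t(cov)) / 2
      dimnames(cov) <- list(names(est), names(est))
      valid <- TRUE
    }
  }

  res <- structure(list(
    haul_id = haul$haul_id,
    estimate = est,
    cov = cov,
    se = if (valid) sqrt(diag(cov)) else rep(NA_real_, 3),
    logLik = -best$value,
    converged = converged,
    valid = valid && converged,
    covariates = haul$covariates,
    qt = haul$qt, qc = haul$qc
  ), class = "haul_fit")
  diag <- assess_haul_fit(haul, res)
  res$deviance <- diag$deviance
  res$dof <- diag$dof
  res$p_value <- diag$p_value
  res$residuals <- diag$residuals
  res
}

#' Goodness-of-fit diagnostics for a haul fit
#'
#' Model deviance against its degrees of freedom, the corresponding chi-square
#' p-value, and per-class deviance residuals for the visual overdispersion
#' check. The deviance is twice the gap between the saturated log-likelihood
#' (each class at its observed test share) and the fitted log-likelihood, over
#' classes with at least one measured shrimp; \code{dof} is the number of such
#' classes minus the three fitted parameters.
#'
#' A fit with p-value < 0.05 but no systematic pattern in the residuals is
#' conventionally attributed to overdispersion and retained; the judgement is
#' left to the analyst via the returned residuals.
#'
#' @param haul a \code{\link{paired_haul}}.
#' @param fit a \code{"haul_fit"} (or any list with an \code{estimate} element
#'   holding L50/SR/SP).
#' @return list with \code{deviance}, \code{dof}, \code{p_value} (NA with a
#'   warning attribute when \code{dof <= 0}), and a data frame
#'   \code{residuals} (class_lower, observed share, fitted share, deviance
#'   residual).
#' @export
assess_haul_fit <- function(haul, fit) {
  est <- fit$estimate
  l <- haul$class_lower
  nt <- haul$test_count
  nc <- haul$control_count
  keep <- (nt + nc) > 0
  phi <- catch_share(l, est[["L50"]], est[["SR"]], est[["SP"]])
  pt <- haul$qt * phi / (haul$qt * phi + haul$qc * (1 - phi))
  obs <- nt / (nt + nc)

  term <- function(p) {
    out <- numeric(length(p))
    pos_t <- keep & nt > 0
    pos_c <- keep & nc > 0
    out[pos_t] <- out[pos_t] + nt[pos_t] * log(p[pos_t])
    out[pos_c] <- out[pos_c] + nc[pos_c] * log1p(-p[pos_c])
    out
  }
  ll_fit <- term(pt)
  ll_sat <- term(obs)
  dev_l <- 2 * (ll_sat - ll_fit)
  dev_l[!keep] <- NA_real_
  dev_l <- pmax(dev_l, 0)  # guard tiny negative rounding
  deviance <- sum(dev_l[keep])
  dof <- sum(keep) - 3L
  p_value <- if (dof > 0) stats::pchisq(deviance, dof, lower.tail = FALSE) else NA_real_
  residuals <- data.frame(
    class_lower = l,
    observed_share = obs,
    fitted_share = pt,
    deviance_residual = sign(obs - pt) * sqrt(dev_l)
  )
  out <- list(deviance = deviance, dof = dof, p_value = p_value,
              residuals = residuals)
  if (dof <= 0) attr(out, "flag") <- "dof <= 0: p-value undefined"
  out
}

#' @export
print.haul_fit <- function(x, ...) {
  cat("Haul", format(x$haul_id), "selectivity fit",
      if (!x$valid) "(INVALID: covariance not estimable)" else "", "\n")
  est <- cbind(estimate = x$estimate, se = x$se)
  print(round(est, 3))
  cat(sprintf("deviance = %.2f on %d DOF (p = %s); logLik = %.2f\n",
              x$deviance, x$dof,
              ifelse(is.na(x$p_value), "NA", sprintf("%.3f", x$p_value)),
              x$logLik))
  invisible(x)
}

#' Tabulate haul fits
#'
#' Collects a list of \code{\link{fit_haul}} results into one data frame, one
#' row per haul, in the layout used for per-haul selectivity reports: point
#' estimates, standard deviations, the six unique covariance entries
#' (CO11..CO33), fit statistics and validity flags, alongside the haul
#' covariates.
#'
#' @param fits list of \code{"haul_fit"} objects.
#' @return data frame with one row per haul.
#' @export
haul_fit_table <- function(fits) {
  stopifnot(length(fits) > 0)
  rows <- lapply(fits, function(f) {
    cv <- f$cov
    if (is.null(cv)) cv <- matrix(NA_real_, 3, 3)
    data.frame(
      haul_id = f$haul_id,
      mesh_type = f$covariates$mesh_type,
      mesh_size_mm = f$covariates$m,
      catch_weight_kg = f$covariates$w,
      sea_state = f$covariates$s,
      side = f$covariates$p,
      qt = f$qt, qc = f$qc,
      L50 = f$estimate[["L50"]], SR = f$estimate[["SR"]], SP = f$estimate[["SP"]],
      sd_L50 = f$se[[1]], sd_SR = f$se[[2]], sd_SP = f$se[[3]],
      CO11 = cv[1, 1], CO12 = cv[1, 2], CO13 = cv[1, 3],
      CO22 = cv[2, 2], CO23 = cv[2, 3], CO33 = cv[3, 3],
      deviance = f$deviance, dof = f$dof, p_value = f$p_value,
      converged = f$converged, valid = f$valid,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
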