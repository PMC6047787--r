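#' Construct a codend selectivity model from published coefficients
#'
#' Builds a prediction-ready model object from a fixed-effect structure,
#' coefficient values, their standard errors, and the diagonal of the
#' between-haul covariance D. The object supports
#' \code{\link{predict.fryer_fit}}, \code{\link{retention_isolines}} and the
#' usability indicators exactly like a model fitted from haul data.
#'
#' Because published coefficient tables report standard errors but not the
#' coefficient covariances, the coefficient covariance is taken as diagonal;
#' estimation-tier confidence limits from such a model are therefore
#' approximate (they ignore coefficient correlations), while the mean
#' predictions are exact.
#'
#' @param structure an \code{\link{fe_structure}}.
#' @param coefficients named numeric vector, names \code{"eq:term"} matching
#'   the structure.
#' @param se standard errors, same names/order.
#' @param D_diag length-3 between-haul variances for (L50, SR, SP).
#' @param mesh_type codend mesh configuration label.
#' @param m_range mesh-size range (mm) over which the model is supported.
#' @return object of class \code{c("codend_model", "fryer_fit")}.
#' @export
codend_model <- function(structure, coefficients, se, D_diag, mesh_type,
                         m_range) {
  labels <- .structure_labels(structure)
  stopifnot(identical(sort(names(coefficients)), sort(labels)),
            length(D_diag) == 3)
  coefficients <- coefficients[labels]
  se <- se[labels]
  vcov <- diag(se^2, length(se))
  dimnames(vcov) <- list(labels, labels)
  D <- diag(as.numeric(D_diag), 3)
  dimnames(D) <- list(c("L50", "SR", "SP"), c("L50", "SR", "SP"))
  structure(list(
    structure = structure,
    coefficients = coefficients,
    se = se,
    ci_lower = coefficients - 1.96 * se,
    ci_upper = coefficients + 1.96 * se,
    vcov = vcov,
    D = D,
    D_type = "diagonal",
    mesh_type = mesh_type,
    m_range = m_range
  ), class = c("codend_model", "fryer_fit"))
}

#' Reference codend selectivity models for North Sea brown shrimp
#'
#' The selected meta-analysis models for diamond-mesh (T0), square-mesh (T45)
#' and T90 codends estimated from paired-gear sea trials in the German Wadden
#' Sea brown shrimp fishery, packaged exactly as published (coefficient
#' values, standard errors, between-haul variances). These are the default
#' models of the prediction framework.
#'
#' Selected structures:
#' \itemize{
#'   \item T0: \code{L50 = a1 m + a2 m^2}, \code{SR = b1 m}, \code{SP = g0}
#'   \item T45: \code{L50 = a1 m}, \code{SR = b2 m^2 + b3 w}, \code{SP = g0}
#'   \item T90: \code{L50 = a1 m + a3 w + a4 m w}, \code{SR = b1 m},
#'     \code{SP = g0}
#' }
#' Standard errors published only as a bound ("> 0.01") are reconstructed
#' from the published 95\% CI half-width. The square-mesh \code{SR} mesh-size
#' coefficient is published as 0.02 with CI 0.014-0.017 (a rounding
#' inconsistency); the printed value is used, and the CI midpoint is kept
#' alongside as attribute \code{"ci_midpoint"} of that model without
#' asserting which drove the published predictions.
#'
#' @param mesh_type optionally one of \code{"T0"}, \code{"T45"}, \code{"T90"}
#'   to return a single model; default returns the named list of all three.
#' @return a \code{\link{codend_model}} or a named list of the three.
#' @examples
#' mod <- reference_codend_models("T0")
#' predict(mod, data.frame(m = 21.7))[, c("L50_mean", "SR_mean")]
#' @export
reference_codend_models <- function(mesh_type = NULL) {
  se_from_ci <- function(lo, hi) (hi - lo) / (2 * 1.96)
  t0 <- codend_model(
    structure = fe_structure(L50 = c("m", "m2"), SR = "m", SP = "intercept"),
    coefficients = c("L50:m" = 2.05, "L50:m2" = -0.01,
                     "SR:m" = 0.37, "SP:intercept" = 0.49),
    se = c("L50:m" = 0.12, "L50:m2" = se_from_ci(-0.018, -0.002),
           "SR:m" = 0.01, "SP:intercept" = 0.01),
    D_diag = c(26.14, 6.38, 0.01),
    mesh_type = "T0", m_range = c(19.05, 36.38))
  t45 <- codend_model(
    structure = fe_structure(L50 = "m", SR = c("m2", "w"), SP = "intercept"),
    coefficients = c("L50:m" = 2.02, "SR:m2" = 0.02, "SR:w" = 0.04,
                     "SP:intercept" = 0.51),
    se = c("L50:m" = 0.03, "SR:m2" = se_from_ci(0.014, 0.017),
           "SR:w" = se_from_ci(0.023, 0.053), "SP:intercept" = 0.01),
    D_diag = c(22.11, 7.93, 0.01),
    mesh_type = "T45", m_range = c(17.25, 29.28))
  attr(t45, "ci_midpoint") <- c("SR:m2" = (0.014 + 0.017) / 2)
  t90 <- codend_model(
    structure = fe_structure(L50 = c("m", "w", "mw"), SR = "m",
                             SP = "intercept"),
    coefficients = c("L50:m" = 1.93, "L50:w" = 0.31, "L50:mw" = -0.01,
                     "SR:m" = 0.40, "SP:intercept" = 0.51),
    se = c("L50:m" = 0.03, "L50:w" = 0.06,
           "L50:mw" = se_from_ci(-0.017, -0.009), "SR:m" = 0.02,
           "SP:intercept" = 0.01),
    D_diag = c(26.44, 7.43, 0.01),
    mesh_type = "T90", m_range = c(18.88, 36.50))
  models <- list(T0 = t0, T45 = t45, T90 = t90)
  if (is.null(mesh_type)) return(models)
  models[[match.arg(mesh_type, names(models))]]
}
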