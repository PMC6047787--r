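#' Retention-probability isolines over mesh size
#'
#' For each mesh size in \code{mesh_sizes}, predicts \code{(L50_mean,
#' SR_mean)} from the model and tabulates the shrimp length \eqn{L_r} at each
#' retention level \code{r} (percent). Lengths below the lowest level are
#' conventionally read as fully released, and lengths above the highest level
#' as fully retained. Grid points where the predicted \code{SR_mean} is not
#' positive are flagged (\code{ok = FALSE}, \code{L_r = NA}) rather than
#' dropped.
#'
#' @param model a \code{"fryer_fit"} or \code{\link{codend_model}}.
#' @param mesh_sizes numeric grid of mesh sizes (mm).
#' @param r_levels retention levels in percent (default 5, 10, ..., 95).
#' @param w,s,p fixed covariates used for every grid point (catch weight kg,
#'   sea state, trawl side).
#' @return data frame of class \code{"isoline_grid"} with columns
#'   \code{mesh_size}, \code{r_percent}, \code{L_r}, \code{L50_mean},
#'   \code{SR_mean}, \code{ok}; fixed covariates kept as attributes.
#' @export
retention_isolines <- function(model, mesh_sizes,
                               r_levels = seq(5, 95, by = 5),
                               w = 35, s = 0, p = 0) {
  stopifnot(length(mesh_sizes) >= 1, all(r_levels > 0), all(r_levels < 100))
  pred <- predict(model, data.frame(m = mesh_sizes, w = w, s = s, p = p))
  rows <- lapply(seq_along(mesh_sizes), function(i) {
    L50 <- pred$L50_mean[i]; SR <- pred$SR_mean[i]
    ok <- is.finite(SR) && SR > 0
    if (!ok) {
      warning("non-positive SR_mean at mesh size ", mesh_sizes[i],
              " mm: flagged", call. = FALSE)
    }
    data.frame(mesh_size = mesh_sizes[i], r_percent = r_levels,
               L_r = if (ok) length_at_retention(L50, SR, r_levels) else NA_real_,
               L50_mean = L50, SR_mean = SR, ok = ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fixed") <- c(w = w, s = s, p = p)
  attr(out, "mesh_type") <- model$mesh_type
  class(out) <- c("isoline_grid", "data.frame")
  out
}

#' Plot retention isolines
#'
#' Shrimp length against mesh size, one line per retention level; the 50\%
#' isoline (the \code{L50_mean} curve) is drawn heavier.
#'
#' @param x an \code{\link{retention_isolines}} grid.
#' @param mls optional horizontal reference at the minimum landing size (mm).
#' @param ... passed to \code{matplot}.
#' @export
plot.isoline_grid <- function(x, mls = 50, ...) {
  wide <- stats::reshape(x[, c("mesh_size", "r_percent", "L_r")],
                         idvar = "mesh_size", timevar = "r_percent",
                         direction = "wide")
  m <- wide$mesh_size
  Y <- as.matrix(wide[, -1])
  lv <- as.numeric(sub("L_r.", "", colnames(Y)))
  graphics::matplot(m, Y, type = "l", lty = 1,
                    col = grDevices::grey(0.75 - 0.5 * lv / 100),
                    lwd = ifelse(lv == 50, 2.5, 1),
                    xlab = "Mesh size (mm)", ylab = "Shrimp length (mm)", ...)
  if (!is.null(mls)) graphics::abline(h = mls, lty = 2, col = "red")
  invisible(x)
}

#' Apply a selection curve to a population length structure
#'
#' Deterministic expected catch: each length class of the population is
#' thinned by the retention probability of the curve, evaluated by default at
#' the class midpoint (lower bound + 0.25 mm on the 0.5 mm grid), or at the
#' lower bound.
#'
#' @param nPop data frame with columns \code{class_lower} (mm) and
#'   \code{count}.
#' @param L50,SR selection-curve parameters (mm).
#' @param at where retention is evaluated within each class:
#'   \code{"midpoint"} (default) or \code{"lower"}.
#' @return data frame \code{nCatch} on the same grid.
#' @export
apply_selection_to_population <- function(nPop, L50, SR,
                                          at = c("midpoint", "lower")) {
  at <- match.arg(at)
  stopifnot(is.data.frame(nPop), nrow(nPop) > 0,
            all(c("class_lower", "count") %in% names(nPop)))
  spacing <- if (nrow(nPop) > 1) min(diff(sort(nPop$class_lower))) else 0.5
  l <- nPop$class_lower + if (at == "midpoint") spacing / 2 else 0
  data.frame(class_lower = nPop$class_lower,
             count = nPop$count * retention_probability(l, L50, SR))
}

#' Codend usability indicators
#'
#' Exploitation-pattern indicators comparing a simulated catch with the
#' population it was drawn from, relative to the minimum landing size
#' \code{mls}:
#' \itemize{
#'   \item \code{nR}: undersized share of the catch (percent of catch below
#'     \code{mls}) — the expected bycatch rate;
#'   \item \code{nP}: overall retention rate (catch as percent of
#'     population);
#'   \item \code{nPa}: retention rate of shrimp at or above \code{mls};
#'   \item \code{nPb}: retention rate of shrimp below \code{mls}.
#' }
#' A well-performing codend has \code{nR} and \code{nPb} near 0 and
#' \code{nPa} near 100.
#'
#' @param nPop,nCatch data frames with \code{class_lower}, \code{count} on an
#'   identical grid (see \code{\link{apply_selection_to_population}}).
#' @param mls minimum landing size (mm), default 50.
#' @return list of class \code{"usability_indicators"} with \code{nR},
#'   \code{nP}, \code{nPa}, \code{nPb} (percent) and \code{mls}; indicators
#'   with an empty denominator stratum are \code{NA} with a flag.
#' @export
usability_indicators <- function(nPop, nCatch, mls = 50) {
  stopifnot(identical(nPop$class_lower, nCatch$class_lower))
  under <- nPop$class_lower < mls
  sPop <- sum(nPop$count); sCatch <- sum(nCatch$count)
  sPop_a <- sum(nPop$count[!under]); sPop_b <- sum(nPop$count[under])
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    mls = mls,
    nR = ratio(sum(nCatch$count[under]), sCatch),
    nP = ratio(sCatch, sPop),
    nPa = ratio(sum(nCatch$count[!under]), sPop_a),
    nPb = ratio(sum(nCatch$count[under]), sPop_b)
  )
  if (anyNA(out[c("nR", "nP", "nPa", "nPb")])) {
    attr(out, "flag") <- "empty denominator stratum: indicator undefined"
  }
  class(out) <- "usability_indicators"
  out
}

#' @export
print.usability_indicators <- function(x, ...) {
  cat(sprintf("Usability indicators (mls = %g mm):\n", x$mls))
  cat(sprintf("  nR  = %6.2f %% (undersized share of catch)\n", x$nR))
  cat(sprintf("  nP  = %6.2f %% (overall retention)\n", x$nP))
  cat(sprintf("  nPa = %6.2f %% (retention at/above mls)\n", x$nPa))
  cat(sprintf("  nPb = %6.2f %% (retention below mls)\n", x$nPb))
  invisible(x)
}

#' Indicator table across mesh types and mesh sizes
#'
#' Applies each mesh type's predicted selection curve at each mesh size to a
#' population length structure and tabulates the usability indicators: one
#' row per (mesh size, mesh configuration).
#'
#' @param models named list of models (e.g.
#'   \code{\link{reference_codend_models}()}); names are the mesh
#'   configuration labels.
#' @param mesh_sizes mesh sizes to evaluate (mm); default the 21-29 mm span
#'   relevant to the fishery.
#' @param nPop population length structure (data frame \code{class_lower},
#'   \code{count}).
#' @param w fixed catch weight (kg) used in the predictions, default 35.
#' @param mls minimum landing size (mm).
#' @param at retention evaluation point within classes, see
#'   \code{\link{apply_selection_to_population}}.
#' @return data frame with columns \code{mesh_size}, \code{mesh_type},
#'   \code{L50_mean}, \code{SR_mean}, \code{nR}, \code{nP}, \code{nPa},
#'   \code{nPb}.
#' @export
indicator_table <- function(models, mesh_sizes = c(21, 23, 25, 27, 29),
                            nPop, w = 35, mls = 50,
                            at = c("midpoint", "lower")) {
  at <- match.arg(at)
  stopifnot(length(models) >= 1, !is.null(names(models)))
  rows <- list()
  for (ms in mesh_sizes) {
    for (nm in names(models)) {
      pred <- suppressWarnings(
        predict(models[[nm]], data.frame(m = ms, w = w)))
      if (!is.finite(pred$SR_mean) || pred$SR_mean <= 0) {
        warning("non-positive SR_mean for ", nm, " at mesh size ", ms,
                " mm: indicators flagged NA", call. = FALSE)
        ind <- list(nR = NA_real_, nP = NA_real_, nPa = NA_real_,
                    nPb = NA_real_)
      } else {
        nCatch <- apply_selection_to_population(nPop, pred$L50_mean,
                                                pred$SR_mean, at = at)
        ind <- usability_indicators(nPop, nCatch, mls = mls)
      }
      rows[[length(rows) + 1]] <- data.frame(
        mesh_size = ms, mesh_type = nm,
        L50_mean = pred$L50_mean, SR_mean = pred$SR_mean,
        nR = ind$nR, nP = ind$nP, nPa = ind$nPa, nPb = ind$nPb,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
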