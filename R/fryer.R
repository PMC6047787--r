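## Candidate fixed-effect terms for each of the three mean equations.
## Values are computed from the haul covariates m (mesh size, mm),
## w (catch weight, kg), s (sea state), p (trawl side).
.fe_terms <- c("intercept", "m", "m2", "w", "mw", "s", "p")

.term_value <- function(term, m, w, s, p) {
  switch(term,
    intercept = rep(1, length(m)),
    m = m,
    m2 = m^2,
    w = w,
    mw = m * w,
    s = s,
    p = p,
    stop("unknown fixed-effect term: ", term, call. = FALSE))
}

#' Fixed-effect structure for the selectivity meta-analysis
#'
#' Describes which candidate terms enter each of the three mean equations
#' (\code{L50_mean}, \code{SR_mean}, \code{SP_mean}). The candidate universe
#' per equation is \{intercept, m, m2, w, mw, s, p\}: intercept, mesh size,
#' squared mesh size, catch weight, mesh-size-by-weight interaction, sea
#' state, trawl side.
#'
#' @param L50,SR,SP character vectors of term names for each equation (may be
#'   empty).
#' @return an object of class \code{"fe_structure"}.
#' @examples
#' fe_structure(L50 = c("m", "m2"), SR = "m", SP = "intercept")
#' @export
fe_structure <- function(L50 = character(), SR = character(),
                         SP = character()) {
  eqs <- list(L50 = unique(L50), SR = unique(SR), SP = unique(SP))
  for (eq in names(eqs)) {
    bad <- setdiff(eqs[[eq]], .fe_terms)
    if (length(bad)) {
      stop("unknown term(s) in ", eq, " equation: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    eqs[[eq]] <- .fe_terms[.fe_terms %in% eqs[[eq]]]  # canonical order
  }
  structure(eqs, class = "fe_structure")
}

#' Full 21-term structure
#'
#' The complete fixed-effect structure with all 7 candidate terms in each of
#' the three equations (21 terms in total).
#' @return an \code{"fe_structure"}.
#' @export
full_structure <- function() {
  fe_structure(L50 = .fe_terms, SR = .fe_terms, SP = .fe_terms)
}

.structure_labels <- function(structure) {
  unlist(lapply(c("L50", "SR", "SP"), function(eq) {
    if (length(structure[[eq]])) paste(eq, structure[[eq]], sep = ":")
    else character()
  }))
}

#' @export
print.fe_structure <- function(x, ...) {
  for (eq in c("L50", "SR", "SP")) {
    cat(sprintf("%s_mean ~ %s\n", eq,
                if (length(x[[eq]])) paste(x[[eq]], collapse = " + ") else "(empty)"))
  }
  invisible(x)
}

#' @export
format.fe_structure <- function(x, ...) {
  paste(vapply(c("L50", "SR", "SP"), function(eq)
    paste0(eq, "{", paste(x[[eq]], collapse = "+"), "}"), ""), collapse = " ")
}

#' Build the stacked design matrices for a Fryer meta-analysis
#'
#' Each valid haul contributes a 3-row block mapping the stacked coefficient
#' vector onto its mean parameter vector \code{(L50, SR, SP)}; the block is
#' block-diagonal across the three equations. All hauls must share one mesh
#' type, since mesh configurations are analysed separately.
#'
#' @param hauls data frame of haul-level estimates (as returned by
#'   \code{\link{haul_fit_table}}), with columns \code{mesh_type},
#'   \code{mesh_size_mm}, \code{catch_weight_kg}, \code{sea_state},
#'   \code{side}.
#' @param structure an \code{\link{fe_structure}}.
#' @return list with \code{X} (list of 3 x p matrices, one per haul) and
#'   \code{labels} (coefficient names, \code{"eq:term"}).
#' @export
build_design_matrix <- function(hauls, structure) {
  stopifnot(inherits(structure, "fe_structure"))
  if (length(unique(hauls$mesh_type)) > 1) {
    stop("mixed mesh types: the meta-analysis is run separately per mesh configuration",
         call. = FALSE)
  }
  labels <- .structure_labels(structure)
  p <- length(labels)
  if (p == 0) stop("empty structure: no coefficients to estimate", call. = FALSE)
  m <- hauls$mesh_size_mm; w <- hauls$catch_weight_kg
  s <- hauls$sea_state; pp <- hauls$side
  n <- nrow(hauls)
  cols <- lapply(seq_along(labels), function(j) {
    parts <- strsplit(labels[j], ":", fixed = TRUE)[[1]]
    list(eq = match(parts[1], c("L50", "SR", "SP")),
         val = .term_value(parts[2], m, w, s, pp))
  })
  X <- lapply(seq_len(n), function(i) {
    Xi <- matrix(0, 3, p, dimnames = list(c("L50", "SR", "SP"), labels))
    for (j in seq_len(p)) Xi[cols[[j]]$eq, j] <- cols[[j]]$val[i]
    Xi
  })
  ## rank check on the stacked design
  stacked <- do.call(rbind, X)
  qr_ <- qr(stacked)
  if (qr_$rank < p) {
    drop <- labels[qr_$pivot[(qr_$rank + 1):p]]
    stop("rank-deficient design: collinear term(s) ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  list(X = X, labels = labels)
}

## Assemble theta_i and within-haul covariance R_i from a haul table
.haul_theta_R <- function(hauls) {
  need <- c("L50", "SR", "SP", "CO11", "CO12", "CO13", "CO22", "CO23", "CO33")
  miss <- setdiff(need, names(hauls))
  if (length(miss)) stop("haul table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  theta <- lapply(seq_len(nrow(hauls)), function(i)
    c(hauls$L50[i], hauls$SR[i], hauls$SP[i]))
  R <- lapply(seq_len(nrow(hauls)), function(i) {
    matrix(c(hauls$CO11[i], hauls$CO12[i], hauls$CO13[i],
             hauls$CO12[i], hauls$CO22[i], hauls$CO23[i],
             hauls$CO13[i], hauls$CO23[i], hauls$CO33[i]), 3, 3)
  })
  list(theta = theta, R = R)
}

## profile negative log-likelihood at fixed D: coefficients solved by GLS
.fryer_profile <- function(D, X, theta, R) {
  p <- ncol(X[[1]])
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  Vinv <- vector("list", length(X))
  logdet <- 0
  for (i in seq_along(X)) {
    V <- R[[i]] + D
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    Vinv[[i]] <- Vi
    XtVX <- XtVX + t(X[[i]]) %*% Vi %*% X[[i]]
    XtVy <- XtVy + t(X[[i]]) %*% Vi %*% theta[[i]]
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- 0
  for (i in seq_along(X)) {
    e <- theta[[i]] - X[[i]] %*% beta
    rss <- rss + drop(t(e) %*% Vinv[[i]] %*% e)
  }
  n3 <- 3 * length(X)
  nll <- 0.5 * (n3 * log(2 * pi) + logdet + rss)
  list(nll = nll, beta = drop(beta), XtVX = XtVX)
}

.D_from_par <- function(par, type) {
  if (type == "zero") return(matrix(0, 3, 3))
  if (type == "diagonal") return(diag(exp(2 * par[1:3]), 3))
  ## full: log-Cholesky, par = (log l11, log l22, log l33, l21, l31, l32)
  L <- matrix(0, 3, 3)
  diag(L) <- exp(par[1:3])
  L[2, 1] <- par[4]; L[3, 1] <- par[5]; L[3, 2] <- par[6]
  L %*% t(L)
}

#' Fit a Fryer random-effects meta-analysis model
#'
#' Models the haul-level estimate vectors \eqn{\theta_i = (L50_i, SR_i, SP_i)}
#' as \eqn{\theta_i \sim N(X_i \beta, R_i + D)}, where \eqn{R_i} is the known
#' within-haul covariance from the haul fit and \eqn{D} the between-haul
#' covariance. Estimation is direct maximum likelihood over \eqn{D}
#' (log-Cholesky parameterised, so always positive semi-definite) with the
#' coefficients profiled out by generalised least squares at each \eqn{D}.
#' Coefficient standard errors come from the inverse GLS information at the
#' optimum.
#'
#' @param hauls data frame of per-haul estimates and covariances
#'   (\code{\link{haul_fit_table}} layout). Rows with \code{valid == FALSE}
#'   are dropped with a message.
#' @param structure an \code{\link{fe_structure}}.
#' @param D_type \code{"full"} (6 free covariance parameters),
#'   \code{"diagonal"} (3), or \code{"zero"} (no between-haul variation).
#' @return an object of class \code{"fryer_fit"}: coefficient table
#'   (\code{coefficients}, \code{se}, \code{ci_lower}, \code{ci_upper}),
#'   \code{vcov}, \code{D}, \code{logLik}, \code{k}, \code{n_hauls},
#'   \code{aicc}, \code{structure}, \code{converged}, \code{m_range},
#'   \code{mesh_type}.
#' @export
fit_fryer_model <- function(hauls, structure,
                            D_type = c("full", "diagonal", "zero")) {
  D_type <- match.arg(D_type)
  if ("valid" %in% names(hauls)) {
    n_bad <- sum(!hauls$valid)
    if (n_bad > 0) {
      message("dropping ", n_bad, " haul(s) with inestimable covariance")
      hauls <- hauls[hauls$valid, , drop = FALSE]
    }
  }
  n <- nrow(hauls)
  des <- build_design_matrix(hauls, structure)
  tr <- .haul_theta_R(hauls)
  p <- length(des$labels)
  nD <- switch(D_type, zero = 0L, diagonal = 3L, full = 6L)
  if (3 * n <= p + nD) {
    stop("too few valid hauls (", n, "; ", 3 * n, " observations) for ",
         p + nD, " parameters", call. = FALSE)
  }

  obj <- function(par) {
    D <- .D_from_par(par, D_type)
    pr <- .fryer_profile(D, des$X, tr$theta, tr$R)
    if (is.null(pr) || !is.finite(pr$nll)) return(1e10)
    pr$nll
  }

  converged <- TRUE
  boundary <- FALSE
  if (D_type == "zero") {
    par_hat <- numeric(0)
  } else {
    ## moment start: residual covariance at D = 0 minus mean within-haul cov;
    ## fall back to a unit start if the D = 0 profile is not computable
    pr0 <- .fryer_profile(diag(1e-8, 3), des$X, tr$theta, tr$R)
    if (is.null(pr0)) {
      start <- 0.5 * log(c(1, 1, 0.01))
    } else {
      resid <- t(vapply(seq_len(n), function(i)
        drop(tr$theta[[i]] - des$X[[i]] %*% pr0$beta), numeric(3)))
      D0 <- diag(pmax(diag(stats::cov(resid)) -
                        diag(Reduce(`+`, tr$R) / n), 1e-4))
      start <- 0.5 * log(diag(D0))
    }
    if (D_type == "full") start <- c(start, 0, 0, 0)
    lower <- c(rep(-8, 3), if (D_type == "full") rep(-50, 3))
    upper <- c(rep(8, 3), if (D_type == "full") rep(50, 3))
    opt <- stats::nlminb(start, obj, lower = lower, upper = upper,
                         control = list(rel.tol = 1e-10, iter.max = 500))
    converged <- opt$convergence == 0 || opt$objective < 1e9
    par_hat <- opt$par
    if (any(abs(par_hat[1:3] - lower[1:3]) < 1e-6)) {
      boundary <- TRUE
      warning("a between-haul variance component collapsed to the boundary",
              call. = FALSE)
    }
  }

  D_hat <- .D_from_par(par_hat, D_type)
  dimnames(D_hat) <- list(c("L50", "SR", "SP"), c("L50", "SR", "SP"))
  pr <- .fryer_profile(D_hat, des$X, tr$theta, tr$R)
  if (is.null(pr)) {
    stop("meta-analysis likelihood not computable at the fitted D (singular total covariance)",
         call. = FALSE)
  }
  vcov_beta <- solve(pr$XtVX)
  dimnames(vcov_beta) <- list(des$labels, des$labels)
  se <- sqrt(diag(vcov_beta))
  beta <- stats::setNames(pr$beta, des$labels)
  k <- p + nD

  fit <- structure(list(
    structure = structure,
    coefficients = beta,
    se = se,
    ci_lower = beta - 1.96 * se,
    ci_upper = beta + 1.96 * se,
    vcov = vcov_beta,
    D = D_hat,
    D_type = D_type,
    logLik = -pr$nll,
    k = k,
    n_hauls = n,
    converged = converged,
    boundary = boundary,
    mesh_type = unique(hauls$mesh_type),
    m_range = range(hauls$mesh_size_mm)
  ), class = "fryer_fit")
  fit$aicc <- compute_aicc(fit)
  fit
}

#' Small-sample corrected AIC
#'
#' \deqn{AICc = -2\log L + 2k + \frac{2k(k+1)}{n - k - 1}}
#' with \eqn{k} the number of estimated parameters (fixed-effect coefficients
#' plus free between-haul covariance parameters) and \eqn{n} the number of
#' hauls. Returns \code{Inf} when \eqn{n - k - 1 \le 0} (correction
#' undefined), so such models can never be selected.
#'
#' @param logLik a fitted \code{"fryer_fit"}, or the log-likelihood value.
#' @param k,n parameter count and number of hauls (ignored when a fit is
#'   supplied).
#' @return the AICc value.
#' @export
compute_aicc <- function(logLik, k = NULL, n = NULL) {
  if (inherits(logLik, "fryer_fit")) {
    k <- logLik$k; n <- logLik$n_hauls; logLik <- logLik$logLik
  }
  if (n - k - 1 <= 0) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.fryer_fit <- function(x, ...) {
  cat("Fryer meta-analysis fit (", x$mesh_type, " codends, n = ", x$n_hauls,
      " hauls, D: ", x$D_type, ")\n", sep = "")
  print(x$structure)
  tab <- data.frame(value = x$coefficients, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(tab, 4))
  cat("D diagonal:", paste(round(diag(x$D), 3), collapse = ", "), "\n")
  cat(sprintf("logLik = %.3f, k = %d, AICc = %.3f\n", x$logLik, x$k, x$aicc))
  invisible(x)
}

#' Enumerate candidate fixed-effect structures
#'
#' Generates every structure obtainable by independently including or
#' excluding each term of the full structure: \eqn{2^t} candidates for
#' \eqn{t} toggled terms (2,097,152 for the full 21-term structure). The
#' enumeration is deterministic: candidate \code{i} corresponds to the bit
#' pattern of \code{i - 1} over the term labels in canonical order, so the
#' stream is reproducible and duplicate-free by construction. Structures are
#' decoded lazily via \code{\link{structure_at}} to keep the full enumeration
#' cheap.
#'
#' @param full the full \code{\link{fe_structure}} whose terms are toggled.
#' @param forced optional character vector of \code{"eq:term"} labels always
#'   kept in every candidate (not toggled).
#' @return an object of class \code{"structure_enumeration"} with elements
#'   \code{n} (number of candidates), \code{toggled}, \code{forced}.
#' @examples
#' enumerate_structures(full_structure())$n  # 2^21
#' @export
enumerate_structures <- function(full, forced = NULL) {
  stopifnot(inherits(full, "fe_structure"))
  labels <- .structure_labels(full)
  forced <- as.character(forced %||% character())
  bad <- setdiff(forced, labels)
  if (length(bad)) stop("forced label(s) not in full structure: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  toggled <- setdiff(labels, forced)
  t <- length(toggled)
  if (t > 21) stop("at most 21 toggled terms supported", call. = FALSE)
  structure(list(n = 2^t, toggled = toggled, forced = forced),
            class = "structure_enumeration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode one candidate from a structure enumeration
#'
#' @param enum a \code{\link{enumerate_structures}} result.
#' @param i candidate index in \code{1..enum$n}.
#' @return the \code{\link{fe_structure}} for candidate \code{i}.
#' @export
structure_at <- function(enum, i) {
  stopifnot(inherits(enum, "structure_enumeration"),
            i >= 1, i <= enum$n)
  mask <- i - 1
  on <- enum$forced
  for (j in seq_along(enum$toggled)) {
    if (bitwAnd(mask, bitwShiftL(1, j - 1)) != 0) on <- c(on, enum$toggled[j])
  }
  parts <- strsplit(on, ":", fixed = TRUE)
  L50 <- SR <- SP <- character()
  for (pt in parts) {
    if (pt[1] == "L50") L50 <- c(L50, pt[2])
    else if (pt[1] == "SR") SR <- c(SR, pt[2])
    else SP <- c(SP, pt[2])
  }
  fe_structure(L50 = L50, SR = SR, SP = SP)
}

#' @export
print.structure_enumeration <- function(x, ...) {
  cat("Structure enumeration:", format(x$n, big.mark = ","),
      "candidates over", length(x$toggled), "toggled terms\n")
  if (length(x$forced)) cat("forced:", paste(x$forced, collapse = ", "), "\n")
  invisible(x)
}

#' Fit and rank candidate structures by AICc
#'
#' Fits every candidate structure to the haul table and ranks the fits by
#' ascending AICc; ties are broken by fewer parameters, then by enumeration
#' order, so the ranking is deterministic regardless of input order.
#' Candidates that cannot be estimated (rank deficiency, too few hauls,
#' optimisation failure) are recorded and skipped.
#'
#' @param hauls haul table (\code{\link{haul_fit_table}} layout).
#' @param structures a list of \code{\link{fe_structure}} objects or a
#'   \code{\link{enumerate_structures}} result.
#' @param D_type between-haul covariance structure, see
#'   \code{\link{fit_fryer_model}}.
#' @return list of class \code{"model_ranking"}: \code{ranking} (data frame
#'   with candidate index, structure label, k, logLik, AICc, delta_AICc),
#'   \code{best} (the rank-1 \code{"fryer_fit"}), \code{fits} (all successful
#'   fits in ranked order), \code{failed} (indices and reasons).
#' @export
select_best_model <- function(hauls, structures,
                              D_type = c("full", "diagonal", "zero"),
                              keep_fits = 20L) {
  D_type <- match.arg(D_type)
  if (inherits(structures, "structure_enumeration")) {
    enum <- structures
    n_cand <- enum$n
    get_structure <- function(i) structure_at(enum, i)
  } else {
    stopifnot(length(structures) >= 1)
    n_cand <- length(structures)
    get_structure <- function(i) structures[[i]]
  }
  rows <- vector("list", n_cand)
  fits <- vector("list", n_cand)
  failed <- list()
  for (i in seq_len(n_cand)) {
    fit <- tryCatch(
      suppressWarnings(fit_fryer_model(hauls, get_structure(i), D_type = D_type)),
      error = function(e) {
        failed[[length(failed) + 1]] <<- list(index = i,
                                              reason = conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      rows[[i]] <- data.frame(candidate = i, structure = format(fit$structure),
                              k = fit$k, logLik = fit$logLik, AICc = fit$aicc,
                              stringsAsFactors = FALSE)
      fits[[i]] <- fit
    }
  }
  ok <- which(!vapply(rows, is.null, logical(1)))
  if (!length(ok)) stop("no candidate structure could be fitted", call. = FALSE)
  ranking <- do.call(rbind, rows[ok])
  ord <- order(ranking$AICc, ranking$k, ranking$candidate)
  ranking <- ranking[ord, , drop = FALSE]
  ranking <- cbind(rank = seq_len(nrow(ranking)), ranking)
  ranking$delta_AICc <- ranking$AICc - ranking$AICc[1]
  rownames(ranking) <- NULL
  top <- utils::head(ranking$candidate, keep_fits)
  structure(list(ranking = ranking, best = fits[[top[1]]],
                 fits = fits[top], failed = failed),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Candidate model ranking (", nrow(x$ranking), " fitted, ",
      length(x$failed), " failed)\n", sep = "")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  cat("\nSelected model:\n")
  print(x$best)
  invisible(x)
}

#' Predict mean selectivity at a covariate point
#'
#' Evaluates the fitted mean equations at new covariate values and reports
#' two tiers of 95\% limits: estimation-only limits from the coefficient
#' covariance, and total limits additionally inflated by the between-haul
#' variation, \eqn{mean \pm 1.96\sqrt{var + D_{jj}}}. The total interval
#' always encloses the estimation interval.
#'
#' @param object a \code{"fryer_fit"} or \code{\link{codend_model}}.
#' @param newdata data frame with columns \code{m} (mesh size, mm) and, as
#'   required by the structure, \code{w}, \code{s}, \code{p}. Missing unused
#'   columns default to 0.
#' @param ... unused.
#' @return data frame, one row per row of \code{newdata}, with means,
#'   estimation variances and the two CI tiers for L50, SR and SP.
#' @export
predict.fryer_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), "m" %in% names(newdata))
  for (col in c("w", "s", "p")) {
    if (is.null(newdata[[col]])) newdata[[col]] <- 0
  }
  if (!is.null(object$m_range) && all(is.finite(object$m_range))) {
    if (any(newdata$m < object$m_range[1] - 1e-9 |
            newdata$m > object$m_range[2] + 1e-9)) {
      warning("mesh size outside the fitted range [",
              paste(round(object$m_range, 2), collapse = ", "),
              "] mm: extrapolating", call. = FALSE)
    }
  }
  labels <- names(object$coefficients)
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    m <- newdata$m[i]; w <- newdata$w[i]; s <- newdata$s[i]; p <- newdata$p[i]
    row <- numeric(length(labels))
    eqs <- vapply(strsplit(labels, ":", fixed = TRUE), `[`, "", 1)
    trm <- vapply(strsplit(labels, ":", fixed = TRUE), `[`, "", 2)
    res <- list()
    for (eq in c("L50", "SR", "SP")) {
      x <- numeric(length(labels))
      sel <- eqs == eq
      x[sel] <- vapply(trm[sel], .term_value, numeric(1), m = m, w = w,
                       s = s, p = p)
      mean_ <- sum(x * object$coefficients)
      var_ <- drop(t(x) %*% object$vcov %*% x)
      Djj <- object$D[eq, eq]
      res[[eq]] <- c(mean = mean_, var = var_,
                     est_lo = mean_ - 1.96 * sqrt(var_),
                     est_hi = mean_ + 1.96 * sqrt(var_),
                     tot_lo = mean_ - 1.96 * sqrt(var_ + Djj),
                     tot_hi = mean_ + 1.96 * sqrt(var_ + Djj))
    }
    data.frame(
      m = m, w = w, s = s, p = p,
      L50_mean = res$L50[["mean"]], SR_mean = res$SR[["mean"]],
      SP_mean = res$SP[["mean"]],
      var_L50 = res$L50[["var"]], var_SR = res$SR[["var"]],
      L50_est_lower = res$L50[["est_lo"]], L50_est_upper = res$L50[["est_hi"]],
      L50_total_lower = res$L50[["tot_lo"]], L50_total_upper = res$L50[["tot_hi"]],
      SR_est_lower = res$SR[["est_lo"]], SR_est_upper = res$SR[["est_hi"]],
      SR_total_lower = res$SR[["tot_lo"]], SR_total_upper = res$SR[["tot_hi"]]
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname predict.fryer_fit
#' @param fit a \code{"fryer_fit"} or \code{\link{codend_model}}.
#' @param at covariate point(s), data frame as \code{newdata}.
#' @export
predict_selectivity_mean <- function(fit, at) predict.fryer_fit(fit, at)
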