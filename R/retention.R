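#' Logistic codend retention probability
#'
#' Probability that a shrimp of length \code{l} is retained by a codend whose
#' size selection follows a logistic curve parameterised by \code{L50} (length
#' at 50\% retention) and \code{SR} (selection range, the length difference
#' between 75\% and 25\% retention).
#'
#' The curve is
#' \deqn{r(l) = \frac{\exp(\ln 9 \, (l - L50)/SR)}{1 + \exp(\ln 9 \, (l - L50)/SR)}}
#' so that \eqn{r(L50) = 0.5} and \eqn{r(L50 + SR/2) = 0.75} exactly.
#'
#' @param l numeric vector of lengths (mm).
#' @param L50 length at 50\% retention probability (mm).
#' @param SR selection range (mm), must be > 0.
#' @return numeric vector of retention probabilities in (0, 1).
#' @examples
#' retention_probability(c(40, 44), L50 = 40, SR = 8)
#' @export
retention_probability <- function(l, L50, SR) {
  if (!is.numeric(SR) || any(!is.finite(SR)) || any(SR <= 0)) {
    stop("'SR' must be a finite positive selection range (mm)", call. = FALSE)
  }
  stats::plogis(log(9) * (l - L50) / SR)
}

#' Expected catch share of the test codend
#'
#' In a paired-gear experiment the proportion of shrimp of length \code{l}
#' ending up in the test codend (relative to test + control) is determined by
#' the length-independent split parameter \code{SP} (probability of entering
#' the test side) and the test codend's retention curve:
#' \deqn{\phi(l) = \frac{SP \, r(l)}{(1 - SP) + SP \, r(l)}}
#' The control codend is assumed non-selective.
#'
#' @inheritParams retention_probability
#' @param SP split parameter in (0, 1): probability that a shrimp enters the
#'   test rather than the control codend.
#' @return numeric vector of expected test-codend catch shares in (0, 1).
#' @export
catch_share <- function(l, L50, SR, SP) {
  if (!is.numeric(SP) || any(!is.finite(SP)) || any(SP <= 0) || any(SP >= 1)) {
    stop("'SP' must lie strictly inside (0, 1)", call. = FALSE)
  }
  r <- retention_probability(l, L50, SR)
  SP * r / ((1 - SP) + SP * r)
}

#' Length at a given retention probability
#'
#' Inverts the logistic selection curve: the length \eqn{L_r} at which the
#' retention probability equals \code{r} percent,
#' \deqn{L_r = L50 + \frac{SR}{\ln 9}\,\ln\!\Big(\frac{0.01 r}{1 - 0.01 r}\Big).}
#' By construction \code{retention_probability(length_at_retention(r)) == r/100}.
#'
#' @param L50 mean length at 50\% retention (mm).
#' @param SR mean selection range (mm), > 0.
#' @param r retention level(s) in percent, strictly between 0 and 100.
#' @return lengths (mm), one per element of \code{r}.
#' @examples
#' length_at_retention(39.78, 8.03, r = 95)
#' @export
length_at_retention <- function(L50, SR, r) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 100)) {
    stop("retention level 'r' must be in percent, strictly between 0 and 100",
         call. = FALSE)
  }
  if (any(SR <= 0)) stop("'SR' must be positive", call. = FALSE)
  p <- 0.01 * r
  L50 + (SR / log(9)) * log(p / (1 - p))
}
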