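# The frequentist disproportionality statistics and the combined signal gate.
# Internal *_stats() helpers are vectorized over cell vectors; the exported
# single-table operations wrap them.

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = ad / bc`; the interval is `exp(log ROR +/- 1.96 * sqrt(1/a + 1/b +
#' 1/c + 1/d))`. With a zero cell the odds ratio is undefined; the
#' Haldane--Anscombe correction (add 0.5 to all four cells, applied only when
#' a zero occurs) keeps it finite.
#'
#' @param t a [contingency_table()] (or numeric vector `c(a, b, c, d)`).
#' @param correction `"haldane"` (default; +0.5 on all cells when any cell is
#'   zero, with a message) or `"none"` (zero cell -> error).
#' @return named numeric `c(ror, lo95, hi95)`.
#' @export
ror <- function(t, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  cl <- as_cells(t)
  res <- ror_stats(cl$a, cl$b, cl$c, cl$d, correction = correction == "haldane")
  c(ror = res$ror, lo95 = res$lo95, hi95 = res$hi95)
}

ror_stats <- function(a, b, c, d, correction = TRUE) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (any(zero)) {
    if (!correction) {
      stop("undefined statistic: zero cell in 2x2 table and correction disabled",
        call. = FALSE
      )
    }
    message(sum(zero), " table(s) with a zero cell: Haldane-Anscombe +0.5 applied for ROR")
    a <- a + 0.5 * zero
    b <- b + 0.5 * zero
    c <- c + 0.5 * zero
    d <- d + 0.5 * zero
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    ror = est,
    lo95 = exp(log(est) - 1.96 * se),
    hi95 = exp(log(est) + 1.96 * se)
  )
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a / (a+b)] / [c / (c+d)]`; the accompanying chi-square is the
#' Pearson statistic of independence on the 2x2 table, by default without
#' Yates continuity correction.
#'
#' @param t a [contingency_table()] (or numeric `c(a, b, c, d)`).
#' @param yates apply the continuity correction.
#' @return named numeric `c(prr, chi2)`.
#' @export
prr <- function(t, yates = FALSE) {
  cl <- as_cells(t)
  if (cl$a + cl$b == 0 || cl$c + cl$d == 0 || cl$a + cl$c == 0) {
    stop("undefined statistic: zero margin in 2x2 table", call. = FALSE)
  }
  res <- prr_stats(cl$a, cl$b, cl$c, cl$d, yates = yates)
  c(prr = res$prr, chi2 = res$chi2)
}

prr_stats <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  est <- (a / (a + b)) / (c / (c + d))
  exp_a <- (a + b) * (a + c) / n
  exp_b <- (a + b) * (b + d) / n
  exp_c <- (c + d) * (a + c) / n
  exp_d <- (c + d) * (b + d) / n
  dev <- abs(a - exp_a) # identical |O - E| for all four cells of a 2x2
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- dev^2 * (1 / exp_a + 1 / exp_b + 1 / exp_c + 1 / exp_d)
  list(prr = est, chi2 = chi2)
}

#' Bayesian information component with lower credibility bound
#'
#' Default closed form: with `E = (a+b)(a+c)/N`, `IC = log2((a + 0.5) /
#' (E + 0.5))` and `IC025 = IC - 3.3 (a + 0.5)^{-1/2} - 2 (a + 0.5)^{-3/2}`
#' (the standard credibility-interval approximation; the 0.5 shrinkage makes
#' every cell legal, including a = 0). `method = "bate"` instead uses the
#' original Bayesian confidence propagation neural network posterior moments
#' (Dirichlet/Beta priors, delta-method variance, 1.96-sigma bound).
#'
#' @param t a [contingency_table()] (or numeric `c(a, b, c, d)`).
#' @param method `"closed"` (default) or `"bate"`.
#' @return named numeric `c(ic, ic025)` in bits (base-2 log).
#' @export
bcpnn_ic <- function(t, method = c("closed", "bate")) {
  method <- match.arg(method)
  cl <- as_cells(t)
  res <- ic_stats(cl$a, cl$b, cl$c, cl$d, method = method)
  c(ic = res$ic, ic025 = res$ic025)
}

ic_stats <- function(a, b, c, d, method = "closed") {
  n <- a + b + c + d
  if (any(n <= 0)) stop("undefined statistic: empty table", call. = FALSE)
  if (method == "closed") {
    e <- (a + b) * (a + c) / n
    ic <- log2((a + 0.5) / (e + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    list(ic = ic, ic025 = ic025)
  } else {
    # posterior-moment form with the customary hyperparameters: margins get
    # Beta(1, 1)-style priors, the joint cell a prior expectation matching
    # independence
    n1. <- a + b
    n.1 <- a + c
    alpha1 <- 1
    beta1 <- 1
    alpha <- 2
    beta <- 2
    gamma11 <- 1
    gam <- gamma11 * (n + alpha) * (n + beta) / ((n1. + alpha1) * (n.1 + beta1))
    ic <- log2(
      (a + gamma11) * (n + alpha) * (n + beta) /
        ((n + gam) * (n1. + alpha1) * (n.1 + beta1))
    )
    v <- (1 / log(2))^2 * (
      (n - a + gam - gamma11) / ((a + gamma11) * (1 + n + gam)) +
        (n - n1. + alpha - alpha1) / ((n1. + alpha1) * (1 + n + alpha)) +
        (n - n.1 + beta - beta1) / ((n.1 + beta1) * (1 + n + beta))
    )
    list(ic = ic, ic025 = ic - 1.96 * sqrt(v))
  }
}

#' Signal thresholds for the four-method gate
#'
#' Defaults are the standard published criteria for the four methods in the
#' spontaneous-report disproportionality literature: at least 3 cases, ROR
#' lower 95% CI above 1, PRR at least 2 with chi-square at least 4, IC025
#' above 0, EBGM05 above 2. All configurable.
#'
#' @param min_a minimum case count `a`.
#' @param ror_lo_gt ROR lower CI must exceed this.
#' @param prr_ge,chi2_ge PRR and chi-square must reach these.
#' @param ic025_gt IC025 must exceed this.
#' @param ebgm05_gt EBGM05 must exceed this.
#' @return object of class `da_thresholds`.
#' @export
da_thresholds <- function(min_a = 3, ror_lo_gt = 1, prr_ge = 2, chi2_ge = 4,
                          ic025_gt = 0, ebgm05_gt = 2) {
  if (min_a < 0) stop("min_a must be >= 0", call. = FALSE)
  structure(
    list(
      min_a = min_a, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
      chi2_ge = chi2_ge, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt
    ),
    class = "da_thresholds"
  )
}

#' Combined four-method signal gate
#'
#' An event label is a potential signal only when it meets all four method
#' thresholds simultaneously (and the minimum case count).
#'
#' @param r a data frame / tibble of results with columns `a`, `ror_lo95`,
#'   `prr`, `chi2`, `ic025`, `ebgm05` (one row per label), or a single-row
#'   list with those fields.
#' @param th a [da_thresholds()].
#' @return logical vector, one element per row of `r`.
#' @export
evaluate_signal <- function(r, th = da_thresholds()) {
  r$a >= th$min_a &
    r$ror_lo95 > th$ror_lo_gt &
    r$prr >= th$prr_ge & r$chi2 >= th$chi2_ge &
    r$ic025 > th$ic025_gt &
    r$ebgm05 > th$ebgm05_gt
}
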