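# Survival estimation and the hypothesis tests used throughout the
# signature workflows. All heavy lifting delegates to the survival
# package; this layer fixes the conventions (median = smallest t with
# S(t) <= 0.5, Breslow ties for Cox, two-sided p-values) and returns
# the package's container classes.

#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects leave the risk set after their time; at tied times
#' events are processed before censorings. The median is the smallest
#' time with S(t) <= 0.5 and is NA if the curve never reaches 0.5.
#'
#' @param time non-negative times in days.
#' @param event 1 = event observed, 0 = right-censored.
#' @return A \linkS4class{KMCurve}.
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("need >= 1 subject")
  if (any(time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  medIdx <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(medIdx)) fit$time[medIdx[1L]] else NA_real_
  new("KMCurve", time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
      nEvent = fit$n.event, median = med)
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected event split follows the
#' hypergeometric margins; the chi-square statistic compares observed
#' and expected events with its variance, on 1 degree of freedom.
#'
#' @param time,event as in \code{\link{kmEstimate}}.
#' @param group two-level group labels.
#' @return A \linkS4class{TestResult} (\code{logrank_chi2}).
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 groups")
  if (sum(event) < 1L) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  TestResult("logrank_chi2", sd$chisq, df = 1, p = p)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood Newton-Raphson with Breslow tie handling; reports
#' the coefficient, its standard error from the observed information,
#' the Wald statistic/p, and the hazard ratio. Monotone-likelihood
#' (perfect separation) fits are flagged non-converged in
#' \code{extra$converged}.
#'
#' @param time,event as in \code{\link{kmEstimate}}.
#' @param covariate per-sample numeric covariate (e.g. the logCPM of one
#'   gene); must not be constant. At least 5 events are required.
#' @return A \linkS4class{TestResult} (\code{cox_wald}) with
#'   \code{extra$beta}, \code{extra$se}, \code{extra$converged};
#'   \code{estimate} is the hazard ratio.
#' @export
coxUnivariate <- function(time, event, covariate) {
  if (sd(covariate) == 0) stop("covariate is constant")
  if (sum(event) < 5L) stop("need >= 5 events")
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  # guard against the numerically singular information of a monotone
  # likelihood (variance can underflow to 0 or tiny negatives)
  se <- sqrt(max(unname(fit$var[1L, 1L]), .Machine$double.eps))
  z <- beta / se
  TestResult("cox_wald", z^2, df = 1,
             p = pchisq(z^2, df = 1, lower.tail = FALSE),
             estimate = exp(beta),
             extra = list(beta = beta, se = se, converged = !warned))
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic sum((O - E)^2 / E) on k - 1 degrees of freedom.
#' Expected values are given as positive counts (they need not sum to
#' the observed total). The canonical worked example of the
#' cross-cohort cluster-composition check: observed (5, 15) vs expected
#' (6.3, 13.7) gives chi-square 0.391, p = 0.531.
#'
#' @param observed non-negative observed counts (length >= 2).
#' @param expected positive expected counts of the same length.
#' @return A \linkS4class{TestResult} (\code{pearson_chi2}).
#' @examples
#' chisqGof(c(5, 15), c(6.3, 13.7))
#' @export
chisqGof <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 2L)
    stop("observed and expected must share a length >= 2")
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  TestResult("pearson_chi2", stat, df = df,
             p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with mid-rank tie handling: exact enumeration for
#' small samples without ties, normal approximation with tie correction
#' otherwise. Reports U (for the first sample) and the rank-biserial
#' correlation as effect estimate.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return A \linkS4class{TestResult} (\code{mannwhitney_U}).
#' @export
mannWhitneyU <- function(x, y, alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- max(length(x), length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = exact, correct = TRUE))
  U <- unname(wt$statistic)
  rb <- 1 - 2 * U / (length(x) * length(y))  # rank-biserial
  TestResult("mannwhitney_U", U, df = NA_real_, p = wt$p.value,
             estimate = rb)
}
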