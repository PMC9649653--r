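# Profile-stratified time-to-event comparison: Kaplan-Meier estimation,
# median survival and the log-rank (Mantel-Cox) test.

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function from right-censored
#' time-to-event records (e.g. progression-free survival in months).
#' Ties between events and censorings at the same time are handled with the
#' standard convention that events precede censorings.
#'
#' @param time Positive event/censoring times.
#' @param event Event indicator: 1 = event (progression/death), 0 =
#'   censored at last follow-up.
#' @return Object of class `km_curve`: list with `time` (distinct ordered
#'   times), `n_risk`, `n_event`, `n_censor`, `surv` (S(t) step values),
#'   `n` (records). S(0) = 1 and S is non-increasing.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  structure(list(time = sf$time,
                 n_risk = sf$n.risk,
                 n_event = sf$n.event,
                 n_censor = sf$n.censor,
                 surv = sf$surv,
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d records, %d events\n",
              x$n, sum(x$n_event)))
  med <- median_survival(x)
  cat("  median survival:", if (is.na(med)) "not reached" else format(med), "\n")
  invisible(x)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' Smallest observed time at which the estimated survival function drops to
#' 0.5 or below; `NA` when the curve never reaches 0.5 (median not
#' reached).
#'
#' @param curve A [km_estimate()] object.
#' @return Median survival time, or `NA`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  curve$time[min(hit)]
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Two-sided log-rank test comparing the survival experience of two groups
#' on pooled event times; the statistic is chi-square distributed with one
#' degree of freedom under the null.
#'
#' @param time_a,event_a Times and 0/1 event indicators of group A.
#' @param time_b,event_b Times and 0/1 event indicators of group B.
#' @return List with `chisq`, `df` (1), `p`, `n_events`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) {
    stop("log-rank test undefined with zero events")
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chisq <- sd$chisq
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_events = as.integer(sum(event)))
}

#' Profile-stratified survival comparison of a variant cohort
#'
#' Classifies each record's variant descriptor, stratifies by profile and
#' compares the two profile groups: per-group Kaplan-Meier curves, medians
#' and the log-rank test.
#'
#' @param cohort Data frame with columns `variant_descriptor` (or
#'   `profile`), `time_months`, `event`.
#' @param context Reference context for descriptor classification.
#' @return List with `curves` (named list of `km_curve` per profile),
#'   `medians` (named numeric), `logrank` (see [logrank_test()]), `n` per
#'   profile.
#' @export
compare_profiles <- function(cohort, context = egfr_reference()) {
  stopifnot(all(c("time_months", "event") %in% names(cohort)))
  if (!"profile" %in% names(cohort)) {
    if (!"variant_descriptor" %in% names(cohort)) {
      stop("cohort needs a `profile` or `variant_descriptor` column")
    }
    cohort$profile <- vapply(cohort$variant_descriptor, function(d) {
      classify_profile(parse_variant(d, context))$profile
    }, integer(1))
  }
  if (!all(cohort$profile %in% c(1L, 2L))) stop("profiles must be 1 or 2")
  g1 <- cohort[cohort$profile == 1L, ]
  g2 <- cohort[cohort$profile == 2L, ]
  if (!nrow(g1) || !nrow(g2)) stop("both profiles must be represented in the cohort")
  curves <- list(profile1 = km_estimate(g1$time_months, g1$event),
                 profile2 = km_estimate(g2$time_months, g2$event))
  list(curves = curves,
       medians = c(profile1 = median_survival(curves$profile1),
                   profile2 = median_survival(curves$profile2)),
       logrank = logrank_test(g1$time_months, g1$event,
                              g2$time_months, g2$event),
       n = c(profile1 = nrow(g1), profile2 = nrow(g2)))
}
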