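#' Split samples at the median of a feature
#'
#' Samples with a value greater than or equal to the feature median go
#' to the "high" group, those below it to "low" — the rule used to
#' stratify patients on Std_Ar_Bin2. Missing values yield NA group
#' labels.
#'
#' @param features samples x features data.frame/matrix, or a numeric
#'   vector.
#' @param feature_name column to split on (ignored for a vector input).
#' @return character vector ("high"/"low"/NA) named by sample.
#' @export
median_split <- function(features, feature_name = NULL) {
  v <- if (is.null(dim(features))) features
       else {
         if (!feature_name %in% colnames(features))
           stop("feature '", feature_name, "' not found")
         setNames(as.matrix(features)[, feature_name],
                  rownames(features))
       }
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  med <- median(v[ok])
  if (all(v[ok] == v[ok][1]))
    stop("all values identical: median split yields a single group")
  out <- rep(NA_character_, length(v))
  out[ok] <- ifelse(v[ok] >= med, "high", "low")
  names(out) <- names(v)
  out
}

#' Kaplan-Meier estimate and median survival
#'
#' Product-limit estimator of the survival function (via
#' \code{survival::survfit}) with the median defined as the earliest
#' event time at which the estimate drops to 0.5 or below; NA when the
#' curve never reaches 0.5.
#'
#' @param time event/censoring times, months.
#' @param event 1 = event observed, 0 = censored.
#' @return list(time, surv, n_risk, median): the step function
#'   evaluated at each event/censoring time, and the median.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) > 0,
            all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       median = med)
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times (hypergeometric variance, handling ties), referred to
#' chi-square with 1 degree of freedom. Delegates to
#' \code{survival::survdiff}.
#'
#' @param time,event survival data for all samples.
#' @param group two-level grouping vector.
#' @return list(statistic, p_value).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test needs exactly 2 non-empty groups")
  if (sum(event) == 0) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = sd$chisq,
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards comparison with covariate adjustment
#'
#' Fits a Cox model of the group effect, optionally adjusted for age,
#' stage and grade, with Efron handling of tied event times. Constant
#' covariates are dropped with a warning; convergence problems are
#' surfaced, not swallowed.
#'
#' @param time,event survival data.
#' @param group two-level grouping vector; the hazard ratio reported is
#'   for the second factor level versus the first.
#' @param covariates optional data.frame of per-sample covariates
#'   (numeric or categorical).
#' @return data.frame with one row per model term: term, hr, lower,
#'   upper (95\% CI), p.
#' @export
cox_ph <- function(time, event, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (sum(event) == 0) stop("no events observed")
  df <- data.frame(time = time, event = event, group = group)
  if (!is.null(covariates)) {
    keep <- vapply(covariates, function(v)
      length(unique(v[!is.na(v)])) > 1L, logical(1))
    if (any(!keep))
      warning("dropping constant covariate(s): ",
              paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
    df <- cbind(df, covariates)
  }
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(setdiff(names(df), c("time", "event")), collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron")
  s <- summary(fit)
  data.frame(term = rownames(s$conf.int),
             hr = s$conf.int[, "exp(coef)"],
             lower = s$conf.int[, "lower .95"],
             upper = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
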