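#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of overall survival (wraps
#' [survival::survfit()]; at tied times events precede censorings, the
#' standard convention).
#'
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator (1 = death, 0 = censored).
#' @return Data frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` at each observed time.
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) .stopf("empty input")
  if (length(time) != length(event)) .stopf("'time' and 'event' must be aligned")
  if (any(time < 0, na.rm = TRUE)) .stopf("negative survival time")
  if (!all(event %in% c(0, 1))) .stopf("'event' must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time,
             n_risk = fit$n.risk,
             n_event = fit$n.event,
             n_censor = fit$n.censor,
             survival = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square comparing survival across groups (wraps
#' [survival::survdiff()]).
#'
#' @inheritParams kaplan_meier
#' @param group Group labels (>= 2 groups, each non-empty).
#' @return List with `statistic`, `df`, `p_value` and the per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) .stopf("need at least 2 groups")
  if (any(table(group) == 0L)) .stopf("empty group")
  if (any(time < 0, na.rm = TRUE)) .stopf("negative survival time")
  if (sum(event) == 0)
    return(list(statistic = 0, df = nlevels(group) - 1L, p_value = 1,
                observed = setNames(rep(0, nlevels(group)), levels(group)),
                expected = setNames(rep(0, nlevels(group)), levels(group))))
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sdf$chisq),
       df = df,
       p_value = pchisq(sdf$chisq, df = df, lower.tail = FALSE),
       observed = setNames(as.numeric(sdf$obs), levels(group)),
       expected = setNames(as.numeric(sdf$exp), levels(group)))
}

#' Cox proportional-hazards model for CIMP
#'
#' Fits a Cox model (Efron tie handling) for CIMP status, optionally
#' adjusted for covariates such as age, and reports the CIMP hazard ratio
#' with its Wald confidence interval.
#'
#' @inheritParams kaplan_meier
#' @param cimp CIMP labels, coercible to a factor whose second level is the
#'   positive class (e.g. the `label` field of a [`cimp_call`][call_cimp]).
#' @param covariates Optional data frame of adjustment covariates, rows
#'   aligned with `time`.
#' @param conf_level Confidence level of the Wald interval. Default 0.95.
#' @return List with `log_hr`, `hr`, `se`, `ci` (length 2), `p_value`,
#'   `n`, `n_events` and the underlying [survival::coxph()] `fit`.
#' @export
cox_cimp <- function(time, event, cimp, covariates = NULL, conf_level = 0.95) {
  if (any(time < 0, na.rm = TRUE)) .stopf("negative survival time")
  cimp <- factor(cimp)
  if (nlevels(cimp) < 2L) .stopf("both CIMP classes must be present")
  df <- data.frame(time = time, event = event, cimp = cimp)
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(time))
      .stopf("'covariates' must be aligned with 'time'")
    df <- cbind(df, covariates)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron")
  co <- summary(fit)$coefficients
  row <- grep("^cimp", rownames(co))[1L]
  log_hr <- co[row, "coef"]; se <- co[row, "se(coef)"]
  if (!is.finite(log_hr) || !is.finite(se) || abs(log_hr) > 15)
    .stopf("Cox fit is degenerate (monotone likelihood?): log HR = %.3g, se = %.3g",
           log_hr, se)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(log_hr = log_hr,
       hr = exp(log_hr),
       se = se,
       ci = exp(log_hr + c(-1, 1) * z * se),
       p_value = co[row, "Pr(>|z|)"],
       n = fit$n, n_events = fit$nevent,
       fit = fit)
}

#' Association of CIMP with clinical covariates
#'
#' Tests each clinical covariate against the binary CIMP label: numeric
#' covariates (age) with a two-sample Student t test (Welch by default),
#' categorical covariates (MSI, ER/PR/HER2 status, tumor size, nodal and
#' metastatic stage) with a chi-squared test on the contingency table
#' without continuity correction. Missing values are dropped per covariate;
#' covariates that are entirely missing, constant, or yield expected counts
#' below 1 are flagged.
#'
#' @param call A binary [`cimp_call`][call_cimp].
#' @param clinical Data frame with a `sample_id` column plus covariate
#'   columns.
#' @param covariates Covariate columns to test; defaults to every column
#'   except `sample_id`, `time`, `event` and `tissue`.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Data frame: `covariate`, `type`, `test`, `statistic`, `p_value`,
#'   `n_used`, `note`.
#' @export
clinical_associations <- function(call, clinical, covariates = NULL,
                                  var_equal = FALSE) {
  if (call$k != 2L) .stopf("clinical association requires a binary CIMP call")
  if (!"sample_id" %in% names(clinical)) .stopf("'clinical' needs a sample_id column")
  common <- intersect(clinical$sample_id, call$sample_ids)
  if (length(common) < 4L) .stopf("too few samples shared with the CIMP call")
  clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  lab <- factor(call$label[common], levels = c("negative", "positive"))
  if (is.null(covariates))
    covariates <- setdiff(names(clin), c("sample_id", "time", "event", "tissue"))
  rows <- lapply(covariates, function(cv) {
    x <- clin[[cv]]
    ok <- !is.na(x) & !is.na(lab)
    base <- data.frame(covariate = cv, type = NA_character_,
                       test = NA_character_, statistic = NA_real_,
                       p_value = NA_real_, n_used = sum(ok), note = "")
    if (!any(ok)) { base$note <- "untestable: entirely missing"; return(base) }
    xl <- x[ok]; ll <- droplevels(lab[ok])
    if (nlevels(ll) < 2L || min(table(ll)) < 2L) {
      base$note <- "untestable: fewer than 2 samples per class"
      return(base)
    }
    if (is.numeric(xl)) {
      base$type <- "numeric"; base$test <- if (var_equal) "t" else "welch_t"
      if (sd(xl) == 0) { base$note <- "untestable: constant"; return(base) }
      tt <- t.test(xl ~ ll, var.equal = var_equal)
      base$statistic <- unname(tt$statistic); base$p_value <- tt$p.value
    } else {
      base$type <- "categorical"; base$test <- "chisq"
      tab <- table(droplevels(factor(xl)), ll)
      if (nrow(tab) < 2L) { base$note <- "untestable: constant"; return(base) }
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      base$statistic <- unname(ct$statistic); base$p_value <- ct$p.value
      if (min(ct$expected) < 1) base$note <- "min expected count < 1"
    }
    base
  })
  do.call(rbind, rows)
}
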