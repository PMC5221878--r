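# Statistical stage: slice-thickness agreement (ICC), univariate and
# forward-conditional multivariable logistic regression for recurrence,
# ROC/C-index, group comparisons and the Cox cross-check.

#' Model result container
#'
#' A tidy summary of a fitted quantity: one row per term with the point
#' estimate (OR/HR/ICC/AUC scale), 95% confidence limits and p-value, plus a
#' type tag, optional selection `trace` and free-form `notes`.
#'
#' @param table Data frame with columns `term`, `estimate`, `lo`, `hi`, `p`.
#' @param type Character tag (e.g. `"icc"`, `"logistic"`, `"auc"`, `"cox"`).
#' @param trace Optional data frame recording a stepwise selection path.
#' @param notes Optional character notes.
#' @param fit Optional underlying fit object.
#' @return An object of class `model_result`.
#' @export
model_result <- function(table, type, trace = NULL, notes = character(),
                         fit = NULL) {
  stopifnot(is.data.frame(table),
            all(c("term", "estimate", "lo", "hi", "p") %in% names(table)))
  structure(list(table = table, type = type, trace = trace, notes = notes,
                 fit = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: %s>\n", x$type))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$lo <- signif(tab$lo, 4)
  tab$hi <- signif(tab$hi, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("selection trace:\n")
    print(x$trace, row.names = FALSE)
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Intraclass correlation for slice-thickness agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC — ICC(A,1)
#' in the McGraw & Wong taxonomy — for paired measurements of the same tumors
#' on two reconstructions. Absolute agreement (not consistency) is the
#' appropriate definition when comparing measurement systems, since a constant
#' offset between reconstructions is a disagreement. The confidence interval
#' uses the Satterthwaite-approximate F method; the p-value tests ICC = 0 with
#' `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param x_1mm,x_5mm Paired numeric vectors (same tumors, two thicknesses),
#'   length >= 3.
#' @param conf Confidence level (default 0.95).
#' @return A `model_result` with the ICC, CI and p-value.
#' @export
icc_agreement <- function(x_1mm, x_5mm, conf = 0.95) {
  x <- as.numeric(x_1mm); y <- as.numeric(x_5mm)
  if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  if (sum((dat - grand)^2) == 0) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # Satterthwaite CI (McGraw & Wong 1996, case A,1)
  alpha <- 1 - conf
  fj <- msc / mse
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  fstat <- msr / mse
  p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  model_result(
    data.frame(term = "ICC(A,1)", estimate = icc, lo = lo, hi = hi, p = p),
    type = "icc",
    notes = sprintf("F = %.4g on (%d, %d) df", fstat, n - 1, (n - 1) * (k - 1))
  )
}

#' Agreement band of an ICC value
#'
#' Interprets an ICC with the kappa-style bands: < 0.20 poor, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 excellent. Boundaries
#' follow the printed two-decimal convention (0.80 is substantial, 0.81
#' excellent); negative values map to poor.
#'
#' @param icc ICC value (<= 1).
#' @return Band label, one of `"poor"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"excellent"`.
#' @export
classify_agreement <- function(icc) {
  stop_if_not_scalar(icc, "icc")
  if (icc > 1 + 1e-9) stop("ICC cannot exceed 1", call. = FALSE)
  v <- round_half_up(icc, 2)
  if (v <= 0.20) "poor"
  else if (v <= 0.40) "fair"
  else if (v <= 0.60) "moderate"
  else if (v <= 0.80) "substantial"
  else "excellent"
}

check_outcome <- function(y) {
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  invisible(y)
}

#' Univariate logistic regression for recurrence
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single predictor.
#' The odds ratio is reported per `scale` units of the predictor
#' (`OR = exp(coef * scale)`), with a Wald confidence interval and p-value.
#' Complete or quasi-complete separation is flagged in the notes.
#'
#' @param cohort Data frame.
#' @param predictor Name of the (numeric) predictor column.
#' @param outcome Name of the 0/1 outcome column (default `"recurrence"`).
#' @param scale Unit multiplier for OR reporting (e.g. 10 for per-10-HU).
#' @param conf Confidence level.
#' @return A `model_result` (type `"logistic"`) with the OR row; the `scale`
#'   is recorded in the table.
#' @export
univariate_logistic <- function(cohort, predictor, outcome = "recurrence",
                                scale = 1, conf = 0.95) {
  x <- cohort[[predictor]]
  if (is.null(x)) stop("no column '", predictor, "'", call. = FALSE)
  if (!is.numeric(x)) stop("predictor must be numeric", call. = FALSE)
  y <- check_outcome(cohort[[outcome]])
  fit <- stats::glm(y ~ x, family = stats::binomial())
  notes <- character()
  if (!fit$converged || abs(stats::coef(fit)[2]) > 15) {
    notes <- "possible complete separation: estimates unreliable"
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  b <- stats::coef(fit)[2]
  se <- sqrt(diag(stats::vcov(fit)))[2]
  tab <- data.frame(term = predictor,
                    estimate = exp(b * scale),
                    lo = exp((b - z * se) * scale),
                    hi = exp((b + z * se) * scale),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    scale = scale)
  model_result(tab, type = "logistic", notes = notes, fit = fit)
}

#' Forward-conditional multivariable logistic regression
#'
#' Stepwise model building in the forward-conditional style: at each step the
#' candidate with the smallest score-test p-value enters if it is below
#' `p_enter`; entered terms are then re-checked and removed by a
#' likelihood-ratio test when their removal p-value exceeds `p_remove`. The
#' full selection trace (step, action, term, p) is returned alongside the
#' final model's odds ratios, Wald confidence intervals and p-values. If no
#' candidate qualifies, the intercept-only model is returned with a note.
#'
#' @param cohort Data frame.
#' @param candidates Character vector of candidate predictor columns.
#' @param outcome Name of the 0/1 outcome column.
#' @param p_enter Score-test entry threshold (default 0.05).
#' @param p_remove Likelihood-ratio removal threshold (default 0.10).
#' @param conf Confidence level for the Wald intervals.
#' @return A `model_result` (type `"stepwise_logistic"`) with one OR row per
#'   selected term and the selection `trace`.
#' @export
forward_conditional_logistic <- function(cohort, candidates,
                                         outcome = "recurrence",
                                         p_enter = 0.05, p_remove = 0.10,
                                         conf = 0.95) {
  y <- check_outcome(cohort[[outcome]])
  dat <- cohort[, candidates, drop = FALSE]
  dat$.y <- y
  selected <- character()
  trace <- data.frame(step = integer(), action = character(),
                      term = character(), p = numeric())
  fit_formula <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    stats::glm(stats::as.formula(paste(".y ~", rhs)), data = dat,
               family = stats::binomial())
  }
  step_no <- 0L
  max_iter <- 2L * length(candidates) + 5L
  for (iter in seq_len(max_iter)) {
    # entry: smallest score (Rao) test p among remaining candidates
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    base_fit <- fit_formula(selected)
    entry_p <- vapply(remaining, function(term) {
      cand_fit <- fit_formula(c(selected, term))
      stats::anova(base_fit, cand_fit, test = "Rao")[2, "Pr(>Chi)"]
    }, numeric(1))
    best <- names(which.min(entry_p))
    if (!length(best) || entry_p[best] >= p_enter) break
    selected <- c(selected, best)
    step_no <- step_no + 1L
    trace <- rbind(trace, data.frame(step = step_no, action = "enter",
                                     term = best, p = unname(entry_p[best])))
    # removal: likelihood-ratio test of each entered term, worst first
    repeat {
      if (length(selected) < 2) break
      full_fit <- fit_formula(selected)
      removal_p <- vapply(selected, function(term) {
        red_fit <- fit_formula(setdiff(selected, term))
        stats::anova(red_fit, full_fit, test = "LRT")[2, "Pr(>Chi)"]
      }, numeric(1))
      worst <- names(which.max(removal_p))
      if (removal_p[worst] <= p_remove) break
      if (worst == best) {
        # the just-entered term would leave again: stable model reached
        selected <- setdiff(selected, worst)
        trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                         term = worst,
                                         p = unname(removal_p[worst])))
        return(finalize_stepwise(fit_formula, selected, trace, conf))
      }
      selected <- setdiff(selected, worst)
      trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                       term = worst,
                                       p = unname(removal_p[worst])))
    }
  }
  finalize_stepwise(fit_formula, selected, trace, conf)
}

finalize_stepwise <- function(fit_formula, selected, trace, conf) {
  fit <- fit_formula(selected)
  notes <- if (!length(selected)) "no candidate met the entry criterion; intercept-only model" else character()
  if (!length(selected)) {
    tab <- data.frame(term = "(Intercept)",
                      estimate = exp(stats::coef(fit)[1]),
                      lo = NA_real_, hi = NA_real_, p = NA_real_)
    return(model_result(tab, "stepwise_logistic", trace = trace,
                        notes = notes, fit = fit))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  b <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  tab <- data.frame(term = selected,
                    estimate = exp(b),
                    lo = exp(b - z * se),
                    hi = exp(b + z * se),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    row.names = NULL)
  model_result(tab, "stepwise_logistic", trace = trace, notes = notes,
               fit = fit)
}

#' ROC C-index of a risk score
#'
#' Area under the ROC curve (equivalently the C-index: the probability that a
#' randomly chosen case outranks a randomly chosen control, ties counted half)
#' with a DeLong confidence interval. For a fitted logistic model, pass the
#' linear predictor as the score. The C-index is apparent (in-sample): no
#' cross-validation is applied.
#'
#' @param scores Numeric risk score per patient.
#' @param outcome 0/1 outcome vector.
#' @param conf Confidence level.
#' @return A `model_result` (type `"auc"`).
#' @export
roc_cindex <- function(scores, outcome, conf = 0.95) {
  outcome <- check_outcome(outcome)
  r <- pROC::roc(response = outcome, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf, method = "delong"))
  model_result(
    data.frame(term = "AUC", estimate = as.numeric(pROC::auc(r)),
               lo = ci[1], hi = ci[3], p = NA_real_),
    type = "auc",
    notes = "apparent (in-sample) C-index, no cross-validation"
  )
}

#' Compare a variable between recurrence groups
#'
#' Numeric variables are compared with the two-sample Student t-test (equal
#' variances); categorical variables with the Pearson chi-square test (no
#' continuity correction), switching to Fisher's exact test when any expected
#' cell count falls below 5 (`method = "auto"`). The method can be forced.
#'
#' @param cohort Data frame.
#' @param variable Column to compare.
#' @param by Name of the 0/1 grouping column (default `"recurrence"`).
#' @param method `"auto"`, `"t"`, `"chisq"` or `"fisher"`.
#' @return List with `method`, `statistic` (NA for Fisher) and `p`.
#' @export
group_compare <- function(cohort, variable, by = "recurrence",
                          method = c("auto", "t", "chisq", "fisher")) {
  method <- match.arg(method)
  x <- cohort[[variable]]
  g <- cohort[[by]]
  if (is.null(x) || is.null(g)) stop("missing column", call. = FALSE)
  if (any(table(g) == 0) || length(unique(g)) < 2) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (is.numeric(x) && length(unique(x)) > 5) "t" else "categorical"
  }
  if (method == "t") {
    ht <- stats::t.test(x ~ g, var.equal = TRUE)
    return(list(method = "t", statistic = unname(ht$statistic), p = ht$p.value))
  }
  tab <- table(x, g)
  if (method == "categorical") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 5)) "fisher" else "chisq"
  }
  if (method == "chisq") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chisq", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- stats::fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p = ht$p.value)
  }
}

#' Univariate Cox regression cross-check
#'
#' Cox proportional-hazards fit (Efron tie handling) of time-to-recurrence on
#' a single predictor, used to cross-check the logistic results. Reports the
#' hazard ratio with a Wald confidence interval.
#'
#' @param cohort Data frame with time and event columns.
#' @param predictor Numeric predictor column name.
#' @param time,event Column names for follow-up time (years, > 0) and the
#'   event indicator (0/1).
#' @param conf Confidence level.
#' @return A `model_result` (type `"cox"`).
#' @export
cox_univariate <- function(cohort, predictor, time = "time_years",
                           event = "event_observed", conf = 0.95) {
  tt <- cohort[[time]]; ev <- cohort[[event]]; x <- cohort[[predictor]]
  if (is.null(tt) || is.null(ev) || is.null(x)) stop("missing column", call. = FALSE)
  if (sum(ev) == 0) stop("no observed events", call. = FALSE)
  fit <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "efron")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  b <- stats::coef(fit)[1]
  se <- sqrt(stats::vcov(fit)[1, 1])
  model_result(
    data.frame(term = predictor, estimate = exp(b),
               lo = exp(b - z * se), hi = exp(b + z * se),
               p = 2 * stats::pnorm(-abs(b / se))),
    type = "cox", fit = fit
  )
}

#' Per-feature thickness-agreement table
#'
#' Runs [icc_agreement()] for every canonical feature present as paired
#' `<feature>_1mm` / `<feature>_5mm` columns and attaches the agreement band.
#'
#' @param cohort Data frame with paired feature columns.
#' @param conf Confidence level.
#' @return Data frame: `feature`, `icc`, `lo`, `hi`, `p`, `band`.
#' @export
icc_table <- function(cohort, conf = 0.95) {
  rows <- lapply(feature_names(), function(f) {
    c1 <- paste0(f, "_1mm"); c5 <- paste0(f, "_5mm")
    if (!all(c(c1, c5) %in% names(cohort))) return(NULL)
    r <- icc_agreement(cohort[[c1]], cohort[[c5]], conf = conf)$table
    data.frame(feature = f, icc = r$estimate, lo = r$lo, hi = r$hi, p = r$p,
               band = classify_agreement(min(1, r$estimate)))
  })
  do.call(rbind, rows)
}
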