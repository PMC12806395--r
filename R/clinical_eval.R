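# Clinical stratification of a subtype labelling: Kaplan-Meier / log-rank
# comparison and multivariate Cox proportional-hazards modelling with
# subtype, dichotomised age and sex as covariates.

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param groups group label per sample (empty groups dropped with a
#'   warning).
#' @param time,event overall-survival time (> 0) and 0/1 event flag.
#' @return list with \code{curves} (data.frame group/time/surv/n_risk),
#'   \code{chisq}, \code{df}, \code{p}.
#' @export
km_logrank <- function(groups, time, event) {
  groups <- as.character(groups)
  keep <- !is.na(groups) & !is.na(time) & !is.na(event)
  if (any(!keep)) warning(sum(!keep), " sample(s) with missing data dropped")
  groups <- groups[keep]; time <- time[keep]; event <- event[keep]
  if (length(unique(groups)) < 2) stop("need >= 2 non-empty groups")
  if (sum(event) < 1) stop("need at least one event")
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata_grp <- sub("^groups=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_grp, time = sf$time, surv = sf$surv,
                       n_risk = sf$n.risk, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), df = df, p = p)
}

#' Multivariate Cox proportional-hazards stratification report
#'
#' Fits \code{Surv(time, event) ~ subtype + age65 + sex} with indicator
#' coding: subtype vs the reference subtype (CIN), age dichotomised at 65
#' years (>= 65 vs < 65) and sex vs the reference sex (female by default).
#' Hazard ratios are exponentiated coefficients with Wald 95\% intervals
#' and per-term p-values; the overall stratification p-value is the
#' likelihood-ratio test of the full model against the null. Subtype levels
#' with no events (or inestimable coefficients) are reported as
#' inestimable rather than aborting. Term p-values additionally carry a
#' multiplicity adjustment (Benjamini-Hochberg by default).
#'
#' @param subtype subtype label per sample.
#' @param age age in years.
#' @param sex \code{"female"} / \code{"male"}.
#' @param time,event survival time (> 0) and 0/1 event indicator.
#' @param reference_subtype reference subtype (default \code{"CIN"}).
#' @param reference_sex reference sex (default \code{"female"}).
#' @param age_cut age dichotomisation cut in years (default 65).
#' @param adjust multiplicity adjustment method for the reported term
#'   p-values (\code{"BH"} default, \code{"holm"} available).
#' @return an object of class \code{survival_report}: \code{terms}
#'   data.frame (term, level, n, percent, hr, ci_lower, ci_upper, p,
#'   p_adjusted), \code{overall_p} (likelihood-ratio), \code{reference}.
#' @export
fit_multivariate_cox <- function(subtype, age, sex, time, event,
                                 reference_subtype = "CIN",
                                 reference_sex = "female",
                                 age_cut = 65, adjust = c("BH", "holm")) {
  adjust <- match.arg(adjust)
  keep <- complete.cases(subtype, age, sex, time, event)
  subtype <- as.character(subtype)[keep]; age <- age[keep]
  sex <- as.character(sex)[keep]; time <- time[keep]; event <- event[keep]
  if (any(time <= 0)) stop("survival times must be > 0")
  if (sum(event) < 1) stop("need at least one event")
  sub_f <- relevel(factor(subtype), ref = reference_subtype)
  age_f <- factor(ifelse(age >= age_cut, paste0("age>=", age_cut),
                         paste0("age<", age_cut)),
                  levels = c(paste0("age<", age_cut), paste0("age>=", age_cut)))
  sex_f <- relevel(factor(sex, levels = c("female", "male")),
                   ref = reference_sex)
  dat <- data.frame(time = time, event = event, subtype = sub_f,
                    age_group = age_f, sex = sex_f)
  fit <- survival::coxph(survival::Surv(time, event) ~ subtype + age_group + sex,
                         data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  term_of <- function(nm) {
    if (startsWith(nm, "subtype")) c("subtype", sub("^subtype", "", nm))
    else if (startsWith(nm, "age_group")) c("age", sub("^age_group", "", nm))
    else c("sex", sub("^sex", "", nm))
  }
  n_total <- length(subtype)
  rows <- list()
  # reference subtype row: HR fixed at 1, no p-value
  rows[[1]] <- data.frame(term = "subtype",
                          level = paste0(reference_subtype, " (reference)"),
                          n = sum(subtype == reference_subtype),
                          percent = 100 * mean(subtype == reference_subtype),
                          hr = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE)
  ev_by_sub <- tapply(event, subtype, sum)
  for (i in seq_len(nrow(co))) {
    nm <- rownames(co)[i]
    tl <- term_of(nm)
    lvl <- tl[2]
    n_lvl <- if (tl[1] == "subtype") sum(subtype == lvl)
             else if (tl[1] == "age") sum(as.character(age_f) == lvl)
             else sum(sex == lvl)
    bad <- is.na(co[i, "coef"]) ||
      (tl[1] == "subtype" && (is.na(ev_by_sub[lvl]) || ev_by_sub[lvl] == 0)) ||
      co[i, "se(coef)"] > 100
    rows[[length(rows) + 1]] <- data.frame(
      term = tl[1], level = lvl, n = n_lvl, percent = 100 * n_lvl / n_total,
      hr = if (bad) NA_real_ else unname(ci[i, "exp(coef)"]),
      ci_lower = if (bad) NA_real_ else unname(ci[i, "lower .95"]),
      ci_upper = if (bad) NA_real_ else unname(ci[i, "upper .95"]),
      p = if (bad) NA_real_ else unname(co[i, "Pr(>|z|)"]),
      stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, rows)
  terms$p_adjusted <- NA_real_
  est <- !is.na(terms$p)
  terms$p_adjusted[est] <- p.adjust(terms$p[est], method = adjust)
  structure(list(terms = terms,
                 overall_p = unname(sm$logtest["pvalue"]),
                 loglik = fit$loglik,
                 reference = list(subtype = reference_subtype,
                                  age = paste0("age<", age_cut),
                                  sex = reference_sex),
                 n = n_total, n_events = sum(event)),
            class = "survival_report")
}

#' @export
#' @method print survival_report
print.survival_report <- function(x, digits = 3, ...) {
  cat(sprintf("<survival_report> n=%d (%d events); reference: subtype=%s, %s, sex=%s\n",
              x$n, x$n_events, x$reference$subtype, x$reference$age,
              x$reference$sex))
  df <- x$terms
  df$percent <- round(df$percent, 1)
  for (cc in c("hr", "ci_lower", "ci_upper", "p", "p_adjusted"))
    df[[cc]] <- signif(df[[cc]], digits)
  print(df, row.names = FALSE)
  cat(sprintf("overall stratification p-value (likelihood ratio): %.4g\n",
              x$overall_p))
  invisible(x)
}

#' Rank competing classifiers by metrics and clinical stratification
#'
#' Builds a comparison table of overall classification scores and the
#' overall stratification p-value per classifier, then flags as selected
#' the classifier with the best (smallest) stratification p-value among
#' those whose overall auROC is within \code{metric_tol} of the best
#' performer.
#'
#' @param metric_reports named list of \code{metrics_report} objects.
#' @param survival_reports named list of \code{survival_report} objects
#'   (same names).
#' @param metric_tol absolute auROC tolerance (default 0.02).
#' @return data.frame, one row per classifier, with a logical
#'   \code{selected} column.
#' @export
rank_strategies <- function(metric_reports, survival_reports,
                            metric_tol = 0.02) {
  nms <- names(metric_reports)
  if (is.null(nms) || !setequal(nms, names(survival_reports)))
    stop("metric_reports and survival_reports must share classifier names")
  nms <- sort(nms)
  tab <- do.call(rbind, lapply(nms, function(nm) {
    ov <- metric_reports[[nm]]$overall
    data.frame(classifier = nm, auROC = ov[["auROC"]],
               accuracy = ov[["accuracy"]], F1 = ov[["F1"]],
               auPRC = ov[["auPRC"]],
               overall_p = survival_reports[[nm]]$overall_p,
               stringsAsFactors = FALSE)
  }))
  eligible <- tab$auROC >= max(tab$auROC) - metric_tol
  p_rank <- ifelse(is.na(tab$overall_p), Inf, tab$overall_p)
  best <- which(eligible)[order(p_rank[eligible],
                                tab$classifier[eligible])][1]
  tab$selected <- seq_len(nrow(tab)) == best
  rownames(tab) <- NULL
  tab
}
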