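#' @importFrom survival Surv survdiff coxph survfit
#' @importFrom stats pchisq wilcox.test ave
NULL

#' Stratify samples at the cohort median of a CIN score
#'
#' Splits samples into high/low groups at the median score of all samples
#' from the same cohort; samples exactly at the median go to the low group
#' by default (the split is then `score > median`), or to the high group
#' with `ties = "high"` (`score >= median`).
#'
#' @param score numeric score per sample.
#' @param cohort optional cohort label per sample; medians are computed
#'   within cohort when given.
#' @param ties `"low"` (default) or `"high"`: group receiving median-tied
#'   samples.
#' @return factor with levels `low`, `high`, one per sample.
#' @examples
#' stratify_by_median(c(1, 2, 3, 4, 5))
#' @export
stratify_by_median <- function(score, cohort = NULL, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (is.null(cohort)) cohort <- rep("all", length(score))
  n_distinct <- tapply(score, cohort, function(x) length(unique(x)))
  if (any(n_distinct < 2))
    stop("constant scores in cohort(s): ",
         paste(names(n_distinct)[n_distinct < 2], collapse = ", "))
  med <- ave(score, cohort, FUN = median)
  hi <- if (ties == "low") score > med else score >= med
  factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
}

# Five-year survival read from the KM curve at `at` days (default 1826).
.km_at <- function(fit, group_levels, at = 1826) {
  s <- summary(fit, times = at, extend = TRUE)
  if (is.null(s$strata)) return(setNames(s$surv[1], group_levels[1]))
  nm <- sub("^group=", "", as.character(s$strata))
  setNames(s$surv, nm)[group_levels]
}

#' Compare survival between high- and low-CIN groups
#'
#' Two-group log-rank test, univariate Cox proportional-hazards model for
#' the high-group indicator (hazard ratio with 95\% CI) and Kaplan-Meier
#' five-year survival per group. Results are flagged unreliable when either
#' group has no events.
#'
#' @param time follow-up time in days.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group factor with levels `low`, `high` (see
#'   [stratify_by_median()]).
#' @param cohort optional label copied into the output row.
#' @param endpoint optional endpoint label copied into the output row.
#' @return one-row `data.frame`: `cohort`, `endpoint`, `n_low`, `n_high`,
#'   `events_low`, `events_high`, `logrank_p`, `hr`, `hr_lower`,
#'   `hr_upper`, `cox_p`, `surv5y_low`, `surv5y_high`, `reliable`.
#' @export
survival_compare <- function(time, event, group, cohort = NA_character_,
                             endpoint = NA_character_) {
  ok <- is.finite(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- droplevels(factor(group[ok]))
  out <- data.frame(cohort = cohort, endpoint = endpoint,
                    n_low = sum(group == "low"), n_high = sum(group == "high"),
                    events_low = sum(event[group == "low"]),
                    events_high = sum(event[group == "high"]),
                    logrank_p = NA_real_, hr = NA_real_,
                    hr_lower = NA_real_, hr_upper = NA_real_,
                    cox_p = NA_real_, surv5y_low = NA_real_,
                    surv5y_high = NA_real_, reliable = FALSE,
                    stringsAsFactors = FALSE)
  if (nlevels(group) < 2 || sum(event) == 0) return(out)

  sv <- survival::Surv(time, event)
  sd <- survival::survdiff(sv ~ group)
  out$logrank_p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)

  # Breslow tie handling keeps the HR invariant under sample duplication
  cx <- suppressWarnings(survival::coxph(sv ~ I(group == "high"),
                                         ties = "breslow"))
  out$hr <- unname(exp(stats::coef(cx)))
  ci <- exp(stats::confint(cx))
  out$hr_lower <- ci[1]; out$hr_upper <- ci[2]
  out$cox_p <- summary(cx)$coefficients[1, "Pr(>|z|)"]

  km <- survival::survfit(sv ~ group)
  s5 <- .km_at(km, levels(group))
  out$surv5y_low <- unname(s5["low"])
  out$surv5y_high <- unname(s5["high"])
  out$reliable <- out$events_low > 0 && out$events_high > 0
  out
}

#' Survival analysis across cohorts with median stratification
#'
#' Convenience driver: stratifies each cohort at its median score, subsets
#' to endpoint-complete samples and runs [survival_compare()] per cohort.
#'
#' @param scores score table from [score_cohort()] (needs `sample_id` and
#'   the chosen score column).
#' @param annotations annotation table with `sample_id`, `cohort` and
#'   `<endpoint>_time` / `<endpoint>_event` columns.
#' @param score score column to stratify on: `"ncs"`, `"scs"` or `"wgii"`.
#' @param endpoint `"os"`, `"dfs"` or `"pfs"`.
#' @param ties median tie rule, see [stratify_by_median()].
#' @return `data.frame` with one [survival_compare()] row per cohort.
#' @export
survival_by_cohort <- function(scores, annotations,
                               score = c("ncs", "scs", "wgii"),
                               endpoint = c("os", "dfs", "pfs"),
                               ties = "low") {
  score <- match.arg(score)
  endpoint <- match.arg(endpoint)
  d <- merge(scores[, c("sample_id", score)], annotations, by = "sample_id")
  d <- d[!is.na(d[[score]]), , drop = FALSE]
  d$group <- stratify_by_median(d[[score]], d$cohort, ties = ties)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  rows <- lapply(split(d, d$cohort), function(dc) {
    keep <- !is.na(dc[[tcol]]) & !is.na(dc[[ecol]])
    survival_compare(dc[[tcol]][keep], dc[[ecol]][keep], dc$group[keep],
                     cohort = dc$cohort[1], endpoint = endpoint)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Wilcoxon rank-sum test of a CIN score between therapy responders and
#' non-responders
#'
#' Responders are samples with complete/partial response; the test is the
#' two-sided rank-sum test of the score between the responder and
#' non-responder groups.
#'
#' @param score numeric score per sample.
#' @param response response labels (`"responder"` / `"non-responder"`,
#'   or a logical vector where `TRUE` means responder); `NA` dropped.
#' @return list: `statistic` (rank-sum W), `p_value`, `median_responder`,
#'   `median_non_responder`, `n_responder`, `n_non_responder`.
#' @export
response_test <- function(score, response) {
  if (is.logical(response))
    response <- ifelse(response, "responder", "non-responder")
  ok <- !is.na(score) & !is.na(response)
  score <- score[ok]; response <- response[ok]
  r <- score[response == "responder"]
  nr <- score[response == "non-responder"]
  if (!length(r) || !length(nr))
    stop("both responder and non-responder groups must be non-empty")
  if (length(unique(c(r, nr))) == 1) {
    # fully tied scores carry no evidence either way
    return(list(statistic = length(r) * length(nr) / 2, p_value = 1,
                median_responder = median(r), median_non_responder = median(nr),
                n_responder = length(r), n_non_responder = length(nr)))
  }
  wt <- suppressWarnings(wilcox.test(r, nr, alternative = "two.sided",
                                     exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_responder = median(r), median_non_responder = median(nr),
       n_responder = length(r), n_non_responder = length(nr))
}
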