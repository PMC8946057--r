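#' @importFrom stats cor.test p.adjust pt qt median
NULL

# Spearman correlation of one feature against the score on pairwise-complete
# observations; returns NA estimate for constant input (logged upstream).
.spearman_one <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n)
    return(list(estimate = NA_real_, p = NA_real_, n = n, tested = FALSE))
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(estimate = NA_real_, p = NA_real_, n = n, tested = FALSE))
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                  exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = n, tested = TRUE)
}

#' Spearman screen of a feature matrix against a CIN score
#'
#' Computes the Spearman correlation and p-value of every feature against
#' the score, either pan-cancer or within each cohort, with
#' Benjamini-Hochberg FDR adjusted within each cohort's screen.
#' Missing values are handled pairwise-complete; features constant on the
#' compared samples are reported with a missing estimate and excluded from
#' the FDR family.
#'
#' @param score numeric score vector, one value per row of `features`.
#' @param features numeric matrix, samples in rows, features in columns.
#' @param cohort optional cohort label per sample; when given the screen is
#'   run per cohort.
#' @param min_n minimum paired non-missing observations per correlation
#'   (default 3).
#' @return `data.frame` of association records: `feature`, `cohort`
#'   (`"pan-cancer"` when no cohorts given), `statistic` (`"spearman_rho"`),
#'   `estimate`, `p_value`, `fdr`, `n`, `tested`.
#' @export
spearman_screen <- function(score, features, cohort = NULL, min_n = 3) {
  stopifnot(length(score) == nrow(features))
  groups <- if (is.null(cohort)) list("pan-cancer" = seq_along(score))
    else split(seq_along(score), cohort)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    rows <- lapply(colnames(features), function(f) {
      r <- .spearman_one(features[idx, f], score[idx], min_n)
      data.frame(feature = f, cohort = g, statistic = "spearman_rho",
                 estimate = r$estimate, p_value = r$p, n = r$n,
                 tested = r$tested, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    n_skip <- sum(!res$tested)
    if (n_skip)
      message("spearman_screen [", g, "]: ", n_skip,
              " constant/undersized feature(s) not tested")
    res$fdr <- NA_real_
    res$fdr[res$tested] <- p.adjust(res$p_value[res$tested], method = "BH")
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-cohort recurrence filter on per-cohort association records
#'
#' A feature's cohort counts as passing when its correlation estimate is at
#' least `rho_min` (positive associations only) with FDR below `fdr_max` in
#' that cohort; the feature passes the filter when it passes in at least
#' `min_cohorts` cohorts.
#'
#' @param records per-cohort records from [spearman_screen()].
#' @param rho_min minimum correlation (default 0.3).
#' @param min_cohorts minimum number of passing cohorts (default 7).
#' @param fdr_max FDR cutoff within each cohort (default 0.05).
#' @return `data.frame` of recurrence calls: `feature`, `n_cohorts_passing`,
#'   `passing_cohorts` (comma-joined), `passes_filter`.
#' @export
recurrence_filter <- function(records, rho_min = 0.3, min_cohorts = 7,
                              fdr_max = 0.05) {
  pass <- records$tested & !is.na(records$estimate) &
    records$estimate >= rho_min & records$estimate > 0 &
    !is.na(records$fdr) & records$fdr < fdr_max
  sp <- split(seq_len(nrow(records)), records$feature)
  out <- lapply(names(sp), function(f) {
    i <- sp[[f]]
    ok <- i[pass[i]]
    data.frame(feature = f, n_cohorts_passing = length(ok),
               passing_cohorts = paste(sort(records$cohort[ok]),
                                       collapse = ","),
               passes_filter = length(ok) >= min_cohorts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[match(unique(records$feature), res$feature), , drop = FALSE]
}

# OLS of y on (alteration indicator + cohort fixed effects); classical
# two-sided t test on the alteration coefficient. Returns NULL when the
# alteration is aliased with the cohort design.
.ols_alteration <- function(y, g, D) {
  X <- cbind(alt = g, D)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NULL)
  cf <- qr.coef(qx, y)
  res <- y - as.vector(X %*% cf)
  df <- length(y) - qx$rank
  s2 <- sum(res^2) / df
  R <- qr.R(qx)
  V <- chol2inv(R)
  piv <- qx$pivot
  vc <- numeric(ncol(X))
  vc[piv] <- diag(V)
  se <- sqrt(s2 * vc[1])
  est <- cf[["alt"]]
  tval <- est / se
  tq <- qt(0.975, df)
  list(estimate = est, se = se,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       ci_lower = est - tq * se, ci_upper = est + tq * se, df = df)
}

#' Cohort-adjusted linear association of binary alterations with a score
#'
#' For every eligible alteration, fits ordinary least squares of the score
#' on the alteration indicator plus cohort fixed effects; the alteration
#' coefficient is the cohort-adjusted mean score difference between altered
#' and wild-type samples. Eligibility requires at least `min_group` samples
#' in both the altered and wild-type groups. P-values are classical
#' two-sided t tests with Benjamini-Hochberg FDR across tested alterations;
#' alterations perfectly confounded with cohort are flagged and excluded
#' from the FDR family.
#'
#' @param score numeric score vector, one per sample.
#' @param alterations binary matrix (samples x alterations, values in
#'   \{0,1\}; NA allowed and dropped casewise per alteration).
#' @param cohort cohort label per sample.
#' @param min_group minimum size of the smaller group (default 20).
#' @return `data.frame`: `feature`, `statistic` (`"linear_coefficient"`),
#'   `estimate`, `se`, `ci_lower`, `ci_upper`, `p_value`, `fdr`, `n`,
#'   `n_altered`, `tested`, `collinear`.
#' @export
regress_alterations <- function(score, alterations, cohort, min_group = 20) {
  stopifnot(length(score) == nrow(alterations),
            length(cohort) == nrow(alterations))
  vals <- alterations[!is.na(alterations)]
  if (!all(vals %in% c(0, 1)))
    stop("alteration matrix must be binary")
  cohort <- factor(cohort)
  D_full <- if (nlevels(cohort) > 1) stats::model.matrix(~cohort)
    else matrix(1, length(cohort), 1, dimnames = list(NULL, "(Intercept)"))

  rows <- lapply(colnames(alterations), function(f) {
    g <- alterations[, f]
    ok <- !is.na(g) & is.finite(score)
    n_alt <- sum(g[ok] == 1)
    n_wt <- sum(g[ok] == 0)
    base <- data.frame(feature = f, statistic = "linear_coefficient",
                       estimate = NA_real_, se = NA_real_,
                       ci_lower = NA_real_, ci_upper = NA_real_,
                       p_value = NA_real_, fdr = NA_real_,
                       n = sum(ok), n_altered = n_alt,
                       tested = FALSE, collinear = FALSE,
                       stringsAsFactors = FALSE)
    if (min(n_alt, n_wt) < min_group) return(base)
    D <- if (all(ok)) D_full else {
      ch <- droplevels(cohort[ok])
      if (nlevels(ch) > 1) stats::model.matrix(~ch)
      else matrix(1, sum(ok), 1, dimnames = list(NULL, "(Intercept)"))
    }
    fit <- .ols_alteration(score[ok], g[ok], D)
    if (is.null(fit)) {
      base$collinear <- TRUE
      return(base)
    }
    base$estimate <- fit$estimate
    base$se <- fit$se
    base$ci_lower <- fit$ci_lower
    base$ci_upper <- fit$ci_upper
    base$p_value <- fit$p
    base$tested <- TRUE
    base
  })
  res <- do.call(rbind, rows)
  res$fdr[res$tested] <- p.adjust(res$p_value[res$tested], method = "BH")
  n_coll <- sum(res$collinear)
  if (n_coll)
    message("regress_alterations: ", n_coll,
            " alteration(s) collinear with cohort, excluded from FDR")
  rownames(res) <- NULL
  res
}

#' Exclude hypermutated (MIN) samples
#'
#' Removes samples flagged as microsatellite-unstable hypermutated, either
#' by a boolean annotation column or by a user-supplied cutoff on a MIN
#' score column. The cutoff is a required user input when only a score is
#' available; no default is imposed.
#'
#' @param annotations annotation `data.frame` with a `sample_id` column.
#' @param flag_col name of a logical MIN-status column (default
#'   `"min_flag"`).
#' @param score_col name of a numeric MIN-score column, used with `cutoff`.
#' @param cutoff numeric cutoff; samples with `score_col > cutoff` are
#'   removed.
#' @return the annotation subset with flagged samples removed; the number
#'   removed is reported via `message()`.
#' @export
exclude_hypermutated <- function(annotations, flag_col = "min_flag",
                                 score_col = "MIN", cutoff = NULL) {
  if (flag_col %in% names(annotations) && is.null(cutoff)) {
    drop <- annotations[[flag_col]] %in% TRUE
  } else if (!is.null(cutoff) && score_col %in% names(annotations)) {
    drop <- !is.na(annotations[[score_col]]) &
      annotations[[score_col]] > cutoff
  } else {
    stop("no MIN flag column found and no score cutoff supplied")
  }
  message("exclude_hypermutated: removed ", sum(drop), " of ",
          nrow(annotations), " sample(s)")
  out <- annotations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
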