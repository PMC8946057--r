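#' Drug-sensitivity index from dose-response AUC
#'
#' Min-max normalises the AUC and returns the sensitivity index
#' `1 - normalised AUC`, in [0, 1]: zero is the highest resistance, one the
#' highest possible sensitivity. Normalisation is global over the screen by
#' default (one minimum and one range, so compound medians live on a common
#' scale); a per-compound alternative is available.
#'
#' @param auc numeric matrix of non-negative AUC values, compounds in rows,
#'   cell lines in columns; `NA` allowed and preserved.
#' @param method `"global"` (default) or `"per_compound"` min-max
#'   normalisation.
#' @return list of class `sensitivity_table`: `sensitivity` (matrix, same
#'   shape as `auc`), `median_sensitivity` (per compound, `NA` removed),
#'   `method`.
#' @export
sensitivity_index <- function(auc, method = c("global", "per_compound")) {
  method <- match.arg(method)
  if (method == "global") {
    rng <- range(auc, na.rm = TRUE)
    if (!all(is.finite(rng)) || rng[1] == rng[2])
      stop("AUC range is zero or undefined; cannot normalise")
    sens <- 1 - (auc - rng[1]) / (rng[2] - rng[1])
  } else {
    sens <- t(apply(auc, 1, function(x) {
      rng <- suppressWarnings(range(x, na.rm = TRUE))
      if (!all(is.finite(rng)) || rng[1] == rng[2])
        stop("constant or empty AUC row; cannot normalise per compound")
      1 - (x - rng[1]) / (rng[2] - rng[1])
    }))
    dimnames(sens) <- dimnames(auc)
  }
  structure(list(sensitivity = sens,
                 median_sensitivity = apply(sens, 1, stats::median,
                                            na.rm = TRUE),
                 method = method),
            class = "sensitivity_table")
}

#' Select candidate compounds targeting high- or low-CIN cells
#'
#' Correlates each compound's sensitivity index with a CIN score across
#' cell lines (Spearman), adjusts p-values by Benjamini-Hochberg across
#' tested compounds, and flags candidates: FDR at most `fdr_max` and median
#' sensitivity above `median_min`. Positive correlations mark compounds
#' selectively targeting high-CIN cells, negative ones low-CIN cells.
#' Compounds with fewer than `min_lines` cell lines carrying both a score
#' and a sensitivity value are reported untested.
#'
#' @param sensitivity a `sensitivity_table` from [sensitivity_index()], or
#'   a sensitivity matrix (compounds x cell lines).
#' @param score named numeric score vector; names must match cell-line
#'   columns.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param median_min median-sensitivity cutoff (default 0.5).
#' @param min_lines minimum overlapping cell lines per compound (default 3).
#' @return `data.frame` of compound calls: `compound`, `estimate` (rho),
#'   `p_value`, `fdr`, `median_sensitivity`, `n`, `direction`, `tested`,
#'   `candidate`.
#' @export
select_candidates <- function(sensitivity, score, fdr_max = 0.05,
                              median_min = 0.5, min_lines = 3) {
  sens <- if (inherits(sensitivity, "sensitivity_table"))
    sensitivity$sensitivity else sensitivity
  shared <- intersect(colnames(sens), names(score))
  if (!length(shared))
    stop("no cell lines shared between sensitivity matrix and scores")
  sens <- sens[, shared, drop = FALSE]
  sc <- score[shared]

  rows <- lapply(rownames(sens), function(cp) {
    r <- .spearman_one(sens[cp, ], sc, min_n = min_lines)
    med <- stats::median(sens[cp, ], na.rm = TRUE)
    data.frame(compound = cp, estimate = r$estimate, p_value = r$p,
               fdr = NA_real_, median_sensitivity = med, n = r$n,
               direction = if (is.na(r$estimate)) NA_character_
                 else if (r$estimate > 0) "targets-high-CIN"
                 else "targets-low-CIN",
               tested = r$tested, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr[res$tested] <- stats::p.adjust(res$p_value[res$tested],
                                         method = "BH")
  res$candidate <- res$tested & !is.na(res$fdr) & res$fdr <= fdr_max &
    res$median_sensitivity > median_min
  rownames(res) <- NULL
  res
}
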