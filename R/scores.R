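#' @import data.table
NULL

.datatable.aware <- TRUE

#' Round half away from zero
#'
#' Nearest-integer rounding with ties at .5 rounded away from zero, so that
#' copy number 2.5 becomes 3. Used for both segment copy numbers and sample
#' ploidy; a fixed tie rule keeps scores bit-reproducible.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Round a copy-number profile to integers and merge equal neighbours
#'
#' Replaces every segment copy number and the sample ploidy by the nearest
#' integer (ties away from zero) and merges contiguous segments on the same
#' chromosome that end up with equal integer copy number, so downstream
#' counting is independent of segmentation granularity.
#'
#' @param segments segment `data.frame` for one or more samples
#'   (`sample_id`, `chromosome`, `start`, `end`, `copy_number`).
#' @param ploidy numeric ploidy, a single value or a vector named by
#'   sample id; may be `NULL` when only the rounded segments are needed.
#' @return list with `segments` (rounded, merged; `copy_number` integral)
#'   and `ploidy` (rounded, same shape as the input `ploidy`).
#' @export
round_profile <- function(segments, ploidy = NULL) {
  dt <- as.data.table(segments)
  dt[, copy_number := round_half_away(copy_number)]
  setorder(dt, sample_id, chromosome, start)
  # new run whenever sample/chromosome changes, CN changes, or a gap opens
  dt[, run := cumsum(
    c(1L, (sample_id[-1] != sample_id[-.N]) |
          (chromosome[-1] != chromosome[-.N]) |
          (copy_number[-1] != copy_number[-.N]) |
          (start[-1] != end[-.N])))]
  merged <- dt[, list(sample_id = sample_id[1], chromosome = chromosome[1],
                      start = start[1], end = end[.N],
                      copy_number = copy_number[1]), by = run]
  merged[, run := NULL]
  out <- as.data.frame(merged)
  if (!is.null(ploidy)) ploidy <- round_half_away(ploidy)
  list(segments = out, ploidy = ploidy)
}

# Per-(sample, chromosome) summary used by all three scores. Expects a
# rounded, merged segment table plus a per-sample integer ploidy lookup
# (NA allowed). Returns one row per sample x covered chromosome.
.chromosome_summary <- function(segments, iploidy, build,
                                scs_min_length = 1e6) {
  dt <- as.data.table(segments)
  dt <- dt[chromosome %in% build$chromosome]
  dt[, len := end - start]
  dt[, ipl := iploidy[sample_id]]

  chrom <- dt[, {
    # length-weighted modal copy number; ties toward integer ploidy when
    # available, else toward the smaller copy number
    w <- tapply(len, copy_number, sum)
    cand <- as.numeric(names(w)[w == max(w)])
    modal <- if (!is.na(ipl[1]) && ipl[1] %in% cand) ipl[1] else min(cand)
    list(
      covered_length = sum(len),
      changed_length = if (is.na(ipl[1])) NA_real_
                       else sum(len[copy_number != ipl[1]]),
      modal_cn = modal,
      n_structural = sum(len >= scs_min_length & copy_number != modal)
    )
  }, by = list(sample_id, chromosome)]
  chrom[, changed_fraction := changed_length / covered_length]
  chrom[]
}

#' Per-chromosome change calls for one sample
#'
#' Computes, for each covered autosome of a single sample, the covered
#' length, the length whose integer copy number deviates from the integer
#' ploidy, the changed fraction, the length-weighted modal copy number and
#' the whole-chromosome-change call (changed fraction at or above the
#' threshold).
#'
#' @param segments segment `data.frame` of a single sample.
#' @param ploidy sample ploidy (positive real, pre-rounding).
#' @param build a [genome_build].
#' @param threshold changed-fraction threshold for a whole-chromosome call
#'   (default 0.75, i.e. at least 75\% of the covered chromosome).
#' @param scs_min_length minimum merged-segment length (bp) for a structural
#'   count (default 1 Mb).
#' @return `data.frame` with one row per covered chromosome: `chromosome`,
#'   `covered_length`, `changed_length`, `changed_fraction`, `modal_cn`,
#'   `is_whole_change`, `n_structural`.
#' @export
chromosome_calls <- function(segments, ploidy, build = default_build(),
                             threshold = 0.75, scs_min_length = 1e6) {
  ids <- unique(segments$sample_id)
  if (length(ids) != 1)
    stop("chromosome_calls expects a single sample")
  rp <- round_profile(segments, ploidy)
  ipl <- setNames(if (is.null(ploidy)) NA_real_ else rp$ploidy, ids)
  ch <- .chromosome_summary(rp$segments, ipl, build, scs_min_length)
  ch[, is_whole_change := !is.na(changed_fraction) &
       changed_fraction >= threshold]
  out <- as.data.frame(ch[, list(chromosome, covered_length, changed_length,
                                 changed_fraction, modal_cn, is_whole_change,
                                 n_structural)])
  out[order(match(out$chromosome, build$chromosome)), , drop = FALSE]
}

#' Numerical complexity score (NCS) of one sample
#'
#' Counts whole-chromosome changes: autosomes whose integer copy number
#' deviates from the sample integer ploidy over at least `threshold` of the
#' covered length. Chromosomes with zero coverage are not counted.
#'
#' @inheritParams chromosome_calls
#' @return list with `ncs` (integer) and `calls` (the per-chromosome table).
#' @export
compute_ncs <- function(segments, ploidy, build = default_build(),
                        threshold = 0.75) {
  if (is.null(ploidy) || is.na(ploidy))
    stop("NCS requires sample ploidy")
  calls <- chromosome_calls(segments, ploidy, build, threshold)
  list(ncs = sum(calls$is_whole_change), calls = calls)
}

#' Structural complexity score (SCS) of one sample
#'
#' Counts, per autosome, rounded-and-merged segments of length at least
#' `min_length` whose integer copy number deviates from the chromosome's
#' length-weighted modal copy number, and sums over autosomes. Ploidy is not
#' used (only as a modal tie-break when available).
#'
#' @inheritParams chromosome_calls
#' @param min_length minimum segment length in bp (default 1 Mb).
#' @return list with `scs` (integer) and `calls` (per-chromosome table).
#' @export
compute_scs <- function(segments, ploidy = NULL, build = default_build(),
                        min_length = 1e6) {
  calls <- chromosome_calls(segments, ploidy, build,
                            scs_min_length = min_length)
  list(scs = sum(calls$n_structural), calls = calls)
}

#' Weighted genome instability index (WGII) of one sample
#'
#' For each covered autosome, the fraction of covered length whose integer
#' copy number deviates from the integer ploidy; the WGII is the unweighted
#' mean of these fractions over covered autosomes, a value in [0, 1].
#'
#' @inheritParams chromosome_calls
#' @return numeric WGII in [0, 1].
#' @export
compute_wgii <- function(segments, ploidy, build = default_build()) {
  if (is.null(ploidy) || is.na(ploidy))
    stop("WGII requires sample ploidy")
  calls <- chromosome_calls(segments, ploidy, build)
  mean(calls$changed_fraction)
}

#' Score a cohort: NCS, SCS and WGII for every sample
#'
#' Vectorised driver over a multi-sample segment table. Samples without
#' ploidy get `NA` NCS and WGII but a valid SCS (the structural score does
#' not require ploidy).
#'
#' @param segments multi-sample segment `data.frame`.
#' @param samples per-sample `data.frame` with `sample_id`, `ploidy` and
#'   optional `wgd`, `cohort` columns; samples present in `segments` but not
#'   here are scored with missing ploidy.
#' @param build a [genome_build].
#' @param ncs_threshold whole-chromosome changed-fraction threshold
#'   (default 0.75).
#' @param scs_min_length minimum structural-segment length in bp
#'   (default 1 Mb).
#' @return `data.frame` with one row per sample: `sample_id`, `ncs`, `scs`,
#'   `wgii`, `ploidy`, and `wgd`/`cohort` when available.
#' @examples
#' seg <- data.frame(sample_id = "S1", chromosome = "chr1",
#'                   start = 0, end = 2e6, copy_number = 3.1)
#' score_cohort(seg, data.frame(sample_id = "S1", ploidy = 2.05),
#'              build = genome_build("chr1", 2e6))
#' @export
score_cohort <- function(segments, samples, build = default_build(),
                         ncs_threshold = 0.75, scs_min_length = 1e6) {
  ids <- unique(segments$sample_id)
  if (!length(ids)) {
    return(data.frame(sample_id = character(), ncs = numeric(),
                      scs = numeric(), wgii = numeric(), ploidy = numeric()))
  }
  pl <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(samples) && nrow(samples)) {
    m <- match(ids, samples$sample_id)
    pl[!is.na(m)] <- samples$ploidy[m[!is.na(m)]]
  }
  rp <- round_profile(segments, pl)
  ch <- .chromosome_summary(rp$segments, rp$ploidy, build, scs_min_length)
  ch[, whole := !is.na(changed_fraction) & changed_fraction >= ncs_threshold]

  per_sample <- ch[, list(
    ncs = if (anyNA(changed_fraction)) NA_real_ else as.numeric(sum(whole)),
    scs = sum(n_structural),
    wgii = mean(changed_fraction)
  ), by = sample_id]

  out <- as.data.frame(per_sample)
  out <- out[match(ids, out$sample_id), , drop = FALSE]
  out$ploidy <- unname(pl[out$sample_id])
  if (!is.null(samples)) {
    for (col in intersect(c("wgd", "cohort"), names(samples)))
      out[[col]] <- samples[[col]][match(out$sample_id, samples$sample_id)]
  }
  rownames(out) <- NULL
  out
}
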