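#' @importFrom stats rpois rnbinom rbinom rnorm runif rexp plogis qlogis sd
NULL

#' Configuration for the synthetic pan-cancer cohort generator
#'
#' Collects every tunable of the simulator in one validated list. The
#' defaults describe a pan-cancer cohort of 22 cancer types with 30 samples
#' each, a whole-genome-doubling (WGD) mixture driving a bimodal
#' whole-chromosome burden, a right-skewed (negative-binomial) structural
#' burden with log-uniform focal lengths, survival whose hazard depends on
#' the CIN group, planted expression/pathway correlations, planted
#' alteration effects (a TP53-like gene shifting NCS by ~4 and SCS by ~11),
#' and a dose-response AUC screen with planted per-compound slopes.
#'
#' All breakpoints are placed on a `unit`-bp lattice (default 10 kb,
#' emulating array-probe segment resolution). Copy-number noise is Gaussian
#' truncated at `noise_clamp` (< 0.5) so integer rounding recovers the
#' planted karyotype exactly; ploidy jitter is uniform within
#' `ploidy_jitter`.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_cohorts = 2, samples_per_cohort = 5)
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_cohorts = 22,
    samples_per_cohort = 30,
    p_wgd = c(0.2, 0.35, 0.5),     # recycled across cohorts
    lambda_whole = 1.5,            # mean whole-chromosome changes, diploid
    lambda_whole_wgd = 8,          # mean given WGD
    struct_mean = 4,               # NB mean structural events per sample
    struct_size = 1.5,             # NB size (right skew)
    focal_length_range = c(1e5, 2e7),  # bp, log-uniform (includes < 1 Mb)
    fixed_whole = NULL,            # force exact whole-change count
    fixed_struct = NULL,           # force exact count of >= 1 Mb events
    cn_noise_sd = 0.2,
    noise_clamp = 0.45,
    ploidy_jitter = 0.25,
    max_backbone_cuts = 3,
    unit = 1e4,                    # breakpoint lattice, bp
    max_event_fraction = 0.4,      # per-chromosome structural budget
    build = default_build(),
    survival = list(h0 = 1 / 1500, beta = log(2), censor_max = 3650,
                    score = "ncs"),
    response = list(rate = 0.35, slope = -0.8, missing = 0.2,
                    score = "ncs"),
    indices = list(hrd_slope = 1, hrd_sd = 3, as_slope = 1, as_sd = 1.5,
                   min_rate = 0.1),
    features = list(n_features = 60, rho = 0.5, n_recurrent = 2,
                    recurrent_cohorts = 10, n_sporadic = 1,
                    sporadic_cohorts = 3, score = "ncs"),
    alterations = list(genes = data.frame(
      gene = c("GENE_CINDRIVER", "GENE_RARE", paste0("GENE_NULL", 1:8)),
      freq = c(0.20, 0.015, rep(0.15, 8)),
      d_ncs = c(4, 0, rep(0, 8)),
      d_scs = c(11, 0, rep(0, 8)),
      stringsAsFactors = FALSE)),
    drugs = list(n_compounds = 40, potent_baseline = 2, weak_baseline = 12,
                 slope = 1.2, null_baseline_range = c(4, 12), noise_sd = 0.5,
                 score = "ncs")
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown generator_config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(override)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(override[[nm]]) &&
                     !is.data.frame(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], override[[nm]]) else override[[nm]]
  }
  stopifnot(all(cfg$p_wgd >= 0 & cfg$p_wgd <= 1),
            cfg$lambda_whole >= 0, cfg$lambda_whole_wgd >= 0,
            cfg$struct_mean >= 0, cfg$cn_noise_sd >= 0,
            cfg$noise_clamp < 0.5, cfg$ploidy_jitter < 0.5,
            cfg$max_event_fraction > 0, cfg$max_event_fraction < 0.5,
            diff(cfg$focal_length_range) >= 0)
  class(cfg) <- "generator_config"
  cfg
}

# Draw per-sample metadata: cohort labels and WGD status.
.draw_meta <- function(cfg) {
  cohorts <- sprintf("C%02d", seq_len(cfg$n_cohorts))
  p_wgd <- rep_len(cfg$p_wgd, cfg$n_cohorts)
  n <- cfg$n_cohorts * cfg$samples_per_cohort
  cohort <- rep(cohorts, each = cfg$samples_per_cohort)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    cohort = cohort,
    wgd = rbinom(n, 1, p_wgd[match(cohort, cohorts)]) == 1,
    extra_ncs = 0, extra_scs = 0,
    stringsAsFactors = FALSE
  )
}

# Non-overlapping placement of structural events on eligible chromosomes,
# with a 1-unit gap between events (so distinct events never merge) and a
# per-chromosome coverage budget that keeps the backbone modal. Events that
# cannot be placed within the bounded retries (possible on near-fully
# aneuploid genomes, where few chromosomes remain eligible) are dropped;
# only placed events enter the returned table, and hence the truth.
.place_events <- function(len_units, chr_units, max_frac, max_tries = 200) {
  n <- length(len_units)
  placed <- vector("list", length(chr_units))
  names(placed) <- names(chr_units)
  used <- setNames(numeric(length(chr_units)), names(chr_units))
  chr_out <- rep(NA_character_, n)
  start_out <- integer(n)
  for (i in order(len_units, decreasing = TRUE)) {
    L <- len_units[i]
    for (try in seq_len(max_tries)) {
      elig <- names(chr_units)[chr_units * max_frac - used >= L]
      if (!length(elig)) break
      ch <- if (length(elig) == 1) elig else
        sample(elig, 1, prob = chr_units[elig])
      s <- sample.int(chr_units[[ch]] - L + 1L, 1L) - 1L
      ints <- placed[[ch]]
      clash <- !is.null(ints) &&
        any(s < ints[, 2] + 1L & s + L > ints[, 1] - 1L)
      if (!clash) {
        placed[[ch]] <- rbind(ints, c(s, s + L))
        used[[ch]] <- used[[ch]] + L
        chr_out[i] <- ch
        start_out[i] <- s
        break
      }
    }
  }
  keep <- !is.na(chr_out)
  data.frame(chromosome = chr_out[keep], start_u = start_out[keep],
             len_u = len_units[keep], stringsAsFactors = FALSE)
}

# Piecewise-constant copy-number intervals for one chromosome (unit coords).
.chrom_intervals <- function(L, base_cn, events = NULL, n_cuts = 0) {
  bp <- c(0L, L)
  if (!is.null(events) && nrow(events))
    bp <- c(bp, events$start_u, events$start_u + events$len_u)
  if (n_cuts > 0 && L > 1)
    bp <- c(bp, sample.int(L - 1L, min(n_cuts, L - 1L)))
  bp <- sort(unique(bp))
  st <- bp[-length(bp)]
  en <- bp[-1]
  cn <- rep(base_cn, length(st))
  if (!is.null(events) && nrow(events))
    for (j in seq_len(nrow(events))) {
      sel <- st >= events$start_u[j] & en <= events$start_u[j] + events$len_u[j]
      cn[sel] <- events$cn[j]
    }
  list(start_u = st, end_u = en, cn = cn)
}

#' Generate synthetic copy-number profiles with ground truth
#'
#' Realises one segmented absolute copy-number profile per sample: baseline
#' copy number 2 (4 after WGD) with uniform ploidy jitter; a Poisson number
#' of whole-chromosome changes at ploidy +/- 1 (rate higher given WGD);
#' a negative-binomial number of structural events with log-uniform lengths
#' at modal +/- \{1, 2\}, placed without overlap on chromosomes not selected
#' for whole-chromosome change; truncated Gaussian noise on every segment.
#' The emitted truth records the planted whole-chromosome count and the
#' count of structural events of length >= 1 Mb, which the scoring module
#' recovers exactly under default noise.
#'
#' @param config a [generator_config].
#' @param meta optional per-sample metadata `data.frame` (`sample_id`,
#'   `cohort`, `wgd`, `extra_ncs`, `extra_scs`); drawn from `config` when
#'   `NULL`. The `extra_*` columns add planted Poisson event counts (used to
#'   condition profiles on alteration-carrier status).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_cohort()]).
#' @param scores_only if `TRUE`, skip segment realisation and return the
#'   truth table only (event counts and lengths are still drawn from the
#'   same model; used for large replicate studies of downstream statistics).
#' @return list with `segments` (internal convention; `NULL` when
#'   `scores_only`), `samples` (`sample_id`, `ploidy`, `wgd`, `cohort`) and
#'   `truth` (`sample_id`, `cohort`, `wgd`, `ncs_true`, `scs_true`).
#' @export
generate_profiles <- function(config = generator_config(), meta = NULL,
                              seed = NULL, scores_only = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (is.null(meta)) meta <- .draw_meta(cfg)
  build <- cfg$build
  n_chr <- nrow(build)
  chr_units_all <- setNames(as.integer(floor(build$length / cfg$unit)),
                            build$chromosome)
  lo <- cfg$focal_length_range[1]
  hi <- cfg$focal_length_range[2]

  seg_list <- vector("list", nrow(meta))
  ploidy <- numeric(nrow(meta))
  ncs_true <- integer(nrow(meta))
  scs_true <- integer(nrow(meta))

  for (i in seq_len(nrow(meta))) {
    wgd <- meta$wgd[i]
    base <- if (wgd) 4 else 2
    ploidy[i] <- base + runif(1, -cfg$ploidy_jitter, cfg$ploidy_jitter)

    k <- if (!is.null(cfg$fixed_whole)) cfg$fixed_whole else
      rpois(1, if (wgd) cfg$lambda_whole_wgd else cfg$lambda_whole) +
        (if (meta$extra_ncs[i] > 0) rpois(1, meta$extra_ncs[i]) else 0L)
    k <- min(k, n_chr)

    if (!is.null(cfg$fixed_struct)) {
      m <- cfg$fixed_struct
      len_bp <- exp(runif(m, log(max(lo, 1e6)), log(max(hi, 1e6))))
    } else {
      m <- rnbinom(1, size = cfg$struct_size, mu = cfg$struct_mean)
      len_bp <- exp(runif(m, log(lo), log(hi)))
      m_extra <- if (meta$extra_scs[i] > 0) rpois(1, meta$extra_scs[i]) else 0L
      if (m_extra > 0) {
        len_bp <- c(len_bp, exp(runif(m_extra, log(max(lo, 1e6)), log(hi))))
        m <- m + m_extra
      }
    }
    len_units <- pmax(1L, as.integer(round(len_bp / cfg$unit)))

    whole_idx <- if (k > 0) sample.int(n_chr, k) else integer(0)
    whole_sign <- if (k > 0) sample(c(-1L, 1L), k, replace = TRUE) else integer(0)
    chr_units <- chr_units_all[setdiff(seq_len(n_chr), whole_idx)]

    events <- if (m > 0) {
      ev <- .place_events(len_units, chr_units, cfg$max_event_fraction)
      delta <- sample(c(-2L, -1L, 1L, 2L), nrow(ev), replace = TRUE,
                      prob = c(0.15, 0.35, 0.35, 0.15))
      ev$cn <- pmax(base + delta, 0L)
      ev
    } else NULL

    ncs_true[i] <- k
    scs_true[i] <- if (!is.null(events))
      sum(events$len_u * cfg$unit >= 1e6) else 0L

    if (!scores_only) {
      chrom_rows <- vector("list", n_chr)
      for (c_idx in seq_len(n_chr)) {
        ch <- build$chromosome[c_idx]
        L <- chr_units_all[[ch]]
        w <- match(c_idx, whole_idx)
        base_cn <- if (!is.na(w)) base + whole_sign[w] else base
        ev_c <- if (!is.null(events)) events[events$chromosome == ch, ,
                                             drop = FALSE] else NULL
        iv <- .chrom_intervals(L, base_cn, ev_c,
                               sample.int(cfg$max_backbone_cuts + 1L, 1L) - 1L)
        noise <- pmin(pmax(rnorm(length(iv$cn), 0, cfg$cn_noise_sd),
                           -cfg$noise_clamp), cfg$noise_clamp)
        chrom_rows[[c_idx]] <- data.frame(
          sample_id = meta$sample_id[i], chromosome = ch,
          start = iv$start_u * cfg$unit, end = iv$end_u * cfg$unit,
          copy_number = pmax(iv$cn + noise, 0),
          stringsAsFactors = FALSE)
      }
      seg_list[[i]] <- data.table::rbindlist(chrom_rows)
    }
  }

  samples <- data.frame(sample_id = meta$sample_id, ploidy = ploidy,
                        wgd = meta$wgd, cohort = meta$cohort,
                        stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = meta$sample_id, cohort = meta$cohort,
                      wgd = meta$wgd, ncs_true = ncs_true,
                      scs_true = scs_true, stringsAsFactors = FALSE)
  segments <- if (scores_only) NULL else
    as.data.frame(data.table::rbindlist(seg_list))
  list(segments = segments, samples = samples, truth = truth)
}

.truth_score <- function(truth, which) {
  col <- paste0(match.arg(which, c("ncs", "scs")), "_true")
  truth[[col]]
}

#' Generate synthetic clinical annotations from cohort truth
#'
#' Survival times are exponential with hazard `h0 * exp(beta)` for samples
#' above the median of the chosen score (independent uniform censoring);
#' responder labels are Bernoulli with log-odds linear in the standardised
#' score (negative default slope: responders tend to have lower NCS);
#' instability indices are linear in the true event counts (HRD tracks the
#' structural count, the aneuploidy score tracks the whole-chromosome
#' count), with SMR/NSMR/ITH/proliferation as independent noise and a
#' Bernoulli hypermutated-MIN flag.
#'
#' @param config a [generator_config].
#' @param truth truth table from [generate_profiles()].
#' @param seed optional seed.
#' @return annotation `data.frame`: `sample_id`, `cohort`, `os_time`/
#'   `os_event`, `dfs_time`/`dfs_event`, `pfs_time`/`pfs_event`, `response`,
#'   `AS`, `HRD`, `SMR`, `NSMR`, `ITH`, `proliferation`, `min_flag`.
#' @export
generate_clinical <- function(config = generator_config(), truth,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- nrow(truth)
  sc <- .truth_score(truth, cfg$survival$score)
  grp <- sc > median(sc)
  endpoint <- function() {
    rate <- cfg$survival$h0 * exp(cfg$survival$beta * grp)
    t <- rexp(n, rate)
    cens <- runif(n, 0, cfg$survival$censor_max)
    list(time = round(pmin(t, cens), 2), event = as.integer(t <= cens))
  }
  os <- endpoint(); dfs <- endpoint(); pfs <- endpoint()

  rsc <- .truth_score(truth, cfg$response$score)
  z <- if (sd(rsc) > 0) (rsc - mean(rsc)) / sd(rsc) else rep(0, n)
  p_resp <- plogis(qlogis(cfg$response$rate) + cfg$response$slope * z)
  response <- ifelse(runif(n) < p_resp, "responder", "non-responder")
  response[runif(n) < cfg$response$missing] <- NA

  idx <- cfg$indices
  data.frame(
    sample_id = truth$sample_id, cohort = truth$cohort,
    os_time = os$time, os_event = os$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    response = response,
    AS = idx$as_slope * truth$ncs_true + rnorm(n, 0, idx$as_sd),
    HRD = idx$hrd_slope * truth$scs_true + rnorm(n, 0, idx$hrd_sd),
    SMR = rnorm(n), NSMR = rnorm(n), ITH = rnorm(n),
    proliferation = rnorm(n),
    min_flag = runif(n) < idx$min_rate,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic expression/pathway feature matrix
#'
#' Planted features equal `rho * z + sqrt(1 - rho^2) * noise` (z the
#' within-cohort standardised score) in their planted cohorts and pure noise
#' elsewhere; null features are independent standard normal. Recurrent
#' features are planted in enough cohorts to pass the recurrence filter,
#' sporadic ones in too few.
#'
#' @inheritParams generate_clinical
#' @return list with `matrix` (samples x features) and `truth`
#'   (`feature`, `rho`, `planted_cohorts` as a comma-joined string).
#' @export
generate_features <- function(config = generator_config(), truth,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fc <- config$features
  n <- nrow(truth)
  sc <- .truth_score(truth, fc$score)
  cohorts <- unique(truth$cohort)
  z <- stats::ave(sc, truth$cohort, FUN = function(x)
    if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x)))

  p <- fc$n_features
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(truth$sample_id, sprintf("F%03d", seq_len(p))))
  planted <- data.frame(feature = character(), rho = numeric(),
                        planted_cohorts = character(),
                        stringsAsFactors = FALSE)
  plant <- function(j, n_coh) {
    chosen <- sample(cohorts, min(n_coh, length(cohorts)))
    in_coh <- truth$cohort %in% chosen
    m[in_coh, j] <<- fc$rho * z[in_coh] +
      sqrt(1 - fc$rho^2) * rnorm(sum(in_coh))
    data.frame(feature = colnames(m)[j], rho = fc$rho,
               planted_cohorts = paste(sort(chosen), collapse = ","),
               stringsAsFactors = FALSE)
  }
  j <- 0
  for (r in seq_len(fc$n_recurrent)) {
    j <- j + 1
    planted <- rbind(planted, plant(j, fc$recurrent_cohorts))
  }
  for (r in seq_len(fc$n_sporadic)) {
    j <- j + 1
    planted <- rbind(planted, plant(j, fc$sporadic_cohorts))
  }
  list(matrix = m, truth = planted)
}

#' Generate a binary alteration matrix with planted score effects
#'
#' Carrier status is Bernoulli per gene; planted genes shift the carrier's
#' expected whole-chromosome and structural event counts by `d_ncs` and
#' `d_scs` (realised by [generate_profiles()] through the `extra_*` meta
#' columns, so the shift acts before profile realisation). Extra structural
#' events planted this way are always >= 1 Mb, so the mean SCS difference
#' equals the planted `d_scs`.
#'
#' @param config a [generator_config].
#' @param sample_ids character vector of sample ids (rows of the matrix).
#' @param seed optional seed.
#' @return list with `matrix` (samples x genes, in \{0,1\}) and `truth`
#'   (the gene table: `gene`, `freq`, `d_ncs`, `d_scs`).
#' @export
generate_alterations <- function(config = generator_config(), sample_ids,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- config$alterations$genes
  n <- length(sample_ids)
  m <- vapply(seq_len(nrow(genes)),
              function(j) rbinom(n, 1, genes$freq[j]),
              integer(n))
  dimnames(m) <- list(sample_ids, genes$gene)
  list(matrix = m, truth = genes)
}

#' Generate a synthetic compound x cell-line AUC screen
#'
#' AUC is `baseline - slope * z + noise` (z the standardised score),
#' clipped at zero. The default screen plants one potent compound (low
#' baseline AUC, hence high sensitivity index after normalisation) and one
#' weak compound (high baseline) with equal positive sensitivity-score
#' slopes, plus null compounds with zero slope.
#'
#' @inheritParams generate_clinical
#' @return list with `auc` (compounds x cell lines) and `truth`
#'   (`compound`, `baseline`, `slope`).
#' @export
generate_drug_screen <- function(config = generator_config(), truth,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dc <- config$drugs
  n <- nrow(truth)
  sc <- .truth_score(truth, dc$score)
  z <- if (sd(sc) > 0) (sc - mean(sc)) / sd(sc) else rep(0, n)

  n_null <- max(dc$n_compounds - 2L, 0L)
  compounds <- data.frame(
    compound = c("CPD_POTENT", "CPD_WEAK",
                 if (n_null) sprintf("CPD_N%03d", seq_len(n_null))),
    baseline = c(dc$potent_baseline, dc$weak_baseline,
                 runif(n_null, dc$null_baseline_range[1],
                       dc$null_baseline_range[2])),
    slope = c(dc$slope, dc$slope, rep(0, n_null)),
    stringsAsFactors = FALSE
  )
  auc <- t(vapply(seq_len(nrow(compounds)), function(j) {
    pmax(compounds$baseline[j] - compounds$slope[j] * z +
           rnorm(n, 0, dc$noise_sd), 0)
  }, numeric(n)))
  dimnames(auc) <- list(compounds$compound, truth$sample_id)
  list(auc = auc, truth = compounds)
}

#' Simulate a complete multi-cohort synthetic dataset
#'
#' Orchestrates the generator: draws cohorts and WGD status, alteration
#' carriers (whose planted effects condition the profile model), realises
#' segmented copy-number profiles, then clinical annotations, feature
#' matrix and drug screen from the resulting truth. A fixed seed makes the
#' whole object bit-reproducible.
#'
#' @param config a [generator_config].
#' @param seed integer seed for all randomness.
#' @return list with elements `segments`, `samples`, `truth`,
#'   `annotations`, `features`, `feature_truth`, `alterations`,
#'   `alteration_truth`, `drug_auc`, `drug_truth`, `config`, `seed`.
#' @examples
#' sim <- simulate_cohort(generator_config(n_cohorts = 2,
#'                                         samples_per_cohort = 4), seed = 1)
#' head(sim$truth)
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1L) {
  set.seed(seed)
  meta <- .draw_meta(config)
  alt <- generate_alterations(config, meta$sample_id)
  genes <- alt$truth
  meta$extra_ncs <- as.numeric(alt$matrix %*% genes$d_ncs)
  meta$extra_scs <- as.numeric(alt$matrix %*% genes$d_scs)
  prof <- generate_profiles(config, meta)
  ann <- generate_clinical(config, prof$truth)
  feat <- generate_features(config, prof$truth)
  drug <- generate_drug_screen(config, prof$truth)
  list(segments = prof$segments, samples = prof$samples, truth = prof$truth,
       annotations = ann, features = feat$matrix,
       feature_truth = feat$truth, alterations = alt$matrix,
       alteration_truth = alt$truth, drug_auc = drug$auc,
       drug_truth = drug$truth, config = config, seed = seed)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the SEG file (TCGA dialect), ploidy table, annotations, feature
#' matrix, alteration matrix, drug AUC matrix and a truth JSON into a
#' directory, in the formats the readers in this package ingest.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    seg = file.path(dir, "segments.seg"),
    ploidy = file.path(dir, "ploidy.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    features = file.path(dir, "features.tsv"),
    alterations = file.path(dir, "alterations.tsv"),
    drug_auc = file.path(dir, "drug_auc.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_seg(sim$segments, paths[["seg"]])
  write.table(sim$samples, paths[["ploidy"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$annotations, paths[["annotations"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix <- function(m, path) {
    out <- data.frame(id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_matrix(sim$features, paths[["features"]])
  write_matrix(sim$alterations, paths[["alterations"]])
  write_matrix(sim$drug_auc, paths[["drug_auc"]])
  jsonlite::write_json(
    list(truth = sim$truth, feature_truth = sim$feature_truth,
         alteration_truth = sim$alteration_truth,
         drug_truth = sim$drug_truth, seed = sim$seed),
    paths[["truth"]], dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
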