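#' @importFrom tools md5sum
#' @importFrom utils packageVersion modifyList
NULL

#' Default pipeline run configuration
#'
#' One place for every stage toggle and threshold of the pipeline: the NCS
#' whole-chromosome fraction (0.75), the SCS minimum segment length (1 Mb),
#' the recurrence filter (rho >= 0.3 in >= 7 cohorts at FDR < 0.05), the
#' regression group-size minimum (20), and the candidate-compound rule
#' (FDR <= 0.05, median sensitivity > 0.5).
#'
#' @param ... named overrides, nested lists merged field-wise (e.g.
#'   `thresholds = list(min_cohorts = 10)`).
#' @return nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(),  # generator_config() overrides; NULL to use inputs
    inputs = NULL,      # list(seg=, ploidy=, annotations=, features=,
                        #      alterations=, drug_auc=) when not simulating
    stages = list(simulate = TRUE, score = TRUE, assoc = TRUE,
                  altreg = TRUE, survival = TRUE, drugs = TRUE),
    thresholds = list(ncs_threshold = 0.75, scs_min_length = 1e6,
                      rho_min = 0.3, min_cohorts = 7, fdr_max = 0.05,
                      min_group = 20, drug_fdr_max = 0.05,
                      drug_median_min = 0.5, score = "ncs", endpoint = "os")
  )
  override <- list(...)
  for (nm in names(override)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(override[[nm]]))
      modifyList(cfg[[nm]], override[[nm]]) else override[[nm]]
  }
  cfg
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(md5sum(tmp))
}

.write_stage <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(file = basename(path), rows = nrow(df))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes ingest (or simulation), scoring and the downstream stages in
#' dependency order, writing one TSV per stage plus a manifest recording the
#' configuration hash, seed, package version and per-stage row counts.
#' Re-running with the same configuration and seed reproduces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()] list or the path to a YAML file with
#'   the same structure.
#' @param out_dir output directory (created if missing).
#' @return the manifest list, invisibly; on-disk outputs under `out_dir`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulate = list(n_cohorts = 3,
#'                                        samples_per_cohort = 10))
#' run_pipeline(cfg, tempfile("run"))
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- do.call(pipeline_config, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  th <- config$thresholds
  stages <- config$stages
  manifest <- list(package = "cinscores",
                   version = as.character(packageVersion("cinscores")),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   stages = list())
  set.seed(config$seed)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  segments <- samples <- annotations <- features <- alterations <- NULL
  drug_auc <- NULL
  if (is.list(config$simulate) && isTRUE(stages$simulate)) {
    sim <- run_stage("simulate", {
      s <- simulate_cohort(do.call(generator_config, config$simulate),
                           seed = config$seed)
      write_cohort(s, file.path(out_dir, "data"))
      s
    })
    manifest$stages$simulate <- list(file = "data", rows = nrow(sim$samples))
    segments <- sim$segments; samples <- sim$samples
    annotations <- sim$annotations; features <- sim$features
    alterations <- sim$alterations; drug_auc <- sim$drug_auc
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    segments <- read_seg(inp$seg)
    ploidy <- read_ploidy_table(inp$ploidy)
    annotations <- if (!is.null(inp$annotations))
      read_annotations(inp$annotations)
    joined <- join_cohort(segments, ploidy, annotations)
    segments <- joined$segments; samples <- joined$samples
    if (!is.null(inp$features))
      features <- read_feature_matrix(inp$features)
    if (!is.null(inp$alterations))
      alterations <- read_feature_matrix(inp$alterations, binary = TRUE)
    if (!is.null(inp$drug_auc))
      drug_auc <- read_drug_screen(inp$drug_auc)
    manifest$stages$ingest <- list(file = NA, rows = nrow(samples))
  }

  scores <- NULL
  if (isTRUE(stages$score) && !is.null(segments)) {
    scores <- score_cohort(segments, samples,
                           ncs_threshold = th$ncs_threshold,
                           scs_min_length = th$scs_min_length)
    manifest$stages$score <- run_stage("score",
      .write_stage(scores, file.path(out_dir, "scores.tsv")))
  }

  score_vec <- function(ids) {
    v <- scores[[th$score]][match(ids, scores$sample_id)]
    names(v) <- ids
    v
  }

  if (isTRUE(stages$assoc) && !is.null(features) && !is.null(scores)) {
    manifest$stages$assoc <- run_stage("assoc", {
      ids <- rownames(features)
      rec <- spearman_screen(score_vec(ids), features,
                             cohort = samples$cohort[match(ids,
                                                    samples$sample_id)])
      calls <- recurrence_filter(rec, rho_min = th$rho_min,
                                 min_cohorts = th$min_cohorts,
                                 fdr_max = th$fdr_max)
      a <- .write_stage(rec, file.path(out_dir, "assoc_records.tsv"))
      b <- .write_stage(calls, file.path(out_dir, "recurrence_calls.tsv"))
      list(file = c(a$file, b$file), rows = c(a$rows, b$rows))
    })
  }

  if (isTRUE(stages$altreg) && !is.null(alterations) && !is.null(scores)) {
    manifest$stages$altreg <- run_stage("altreg", {
      ids <- rownames(alterations)
      coh <- samples$cohort[match(ids, samples$sample_id)]
      res <- do.call(rbind, lapply(c("ncs", "scs"), function(sc) {
        v <- scores[[sc]][match(ids, scores$sample_id)]
        out <- regress_alterations(v, alterations, coh,
                                   min_group = th$min_group)
        out$score <- sc
        out$neg_log10_fdr <- -log10(out$fdr)
        out
      }))
      .write_stage(res, file.path(out_dir, "alteration_regression.tsv"))
    })
  }

  if (isTRUE(stages$survival) && !is.null(annotations) && !is.null(scores)) {
    manifest$stages$survival <- run_stage("survival", {
      res <- survival_by_cohort(scores, annotations, score = th$score,
                                endpoint = th$endpoint)
      .write_stage(res, file.path(out_dir, "survival.tsv"))
    })
  }

  if (isTRUE(stages$drugs) && !is.null(drug_auc) && !is.null(scores)) {
    manifest$stages$drugs <- run_stage("drugs", {
      sens <- sensitivity_index(drug_auc)
      calls <- select_candidates(sens, score_vec(colnames(drug_auc)),
                                 fdr_max = th$drug_fdr_max,
                                 median_min = th$drug_median_min)
      .write_stage(calls, file.path(out_dir, "drug_candidates.tsv"))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
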