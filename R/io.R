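#' @importFrom utils read.delim write.table head
#' @importFrom stats median complete.cases setNames
NULL

# Locate a column by a set of candidate regexes (case-insensitive); returns
# the first matching column name or NA.
.find_col <- function(nms, patterns) {
  for (p in patterns) {
    hit <- grep(p, nms, ignore.case = TRUE, value = TRUE)
    if (length(hit)) return(hit[1])
  }
  NA_character_
}

#' Read a segmented copy-number (SEG) file
#'
#' Reads a tab-delimited SEG table (sample, chromosome, start, end and a
#' copy-number column) and normalises it to the internal coordinate
#' convention: 0-based, half-open. The TCGA SEG dialect (1-based, inclusive)
#' is the default input dialect. Chromosomes absent from the build (e.g.
#' chrX/chrY against the default autosome build) are dropped with a message.
#'
#' @param path path to a tab-delimited SEG file with a header.
#' @param build a [genome_build]; segments on chromosomes outside the build
#'   are dropped.
#' @param dialect coordinate dialect of the input: `"tcga"` (1-based,
#'   inclusive; the TCGA SEG default) or `"bed"` (0-based, half-open).
#' @param value how to interpret the value column: `"absolute"` (absolute
#'   copy number, the default) or `"log2ratio"`, in which case copy number is
#'   derived as `ploidy * 2^log2ratio` and a `ploidy` lookup must be given.
#' @param ploidy named numeric vector of sample ploidies, only used with
#'   `value = "log2ratio"`.
#' @return A `data.frame` of segments with columns `sample_id`,
#'   `chromosome`, `start`, `end` (0-based half-open) and `copy_number`,
#'   sorted by sample, chromosome and start.
#' @seealso [write_seg()] for the inverse operation.
#' @export
read_seg <- function(path, build = default_build(),
                     dialect = c("tcga", "bed"),
                     value = c("absolute", "log2ratio"),
                     ploidy = NULL) {
  dialect <- match.arg(dialect)
  value <- match.arg(value)
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  nms <- names(raw)
  col_sample <- .find_col(nms, c("^sample", "^id$", "^array"))
  col_chrom <- .find_col(nms, c("^chrom", "^chr$"))
  col_start <- .find_col(nms, c("start"))
  col_end <- .find_col(nms, c("end", "stop"))
  col_value <- .find_col(nms, c("copy_?number", "modal", "segment_?mean",
                                "^cn$", "mean", "value"))
  missing_cols <- c(sample = col_sample, chromosome = col_chrom,
                    start = col_start, end = col_end, value = col_value)
  if (anyNA(missing_cols))
    stop("SEG header must name sample, chromosome, start, end and a ",
         "copy-number column; could not locate: ",
         paste(names(missing_cols)[is.na(missing_cols)], collapse = ", "))

  seg <- data.frame(
    sample_id = as.character(raw[[col_sample]]),
    chromosome = as.character(raw[[col_chrom]]),
    start = suppressWarnings(as.numeric(raw[[col_start]])),
    end = suppressWarnings(as.numeric(raw[[col_end]])),
    copy_number = suppressWarnings(as.numeric(raw[[col_value]])),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(seg$start) | is.na(seg$end))
  if (length(bad))
    stop("malformed SEG row(s): non-numeric coordinates at data line(s) ",
         paste(head(bad, 5), collapse = ", "))

  n_na_cn <- sum(is.na(seg$copy_number))
  if (n_na_cn) {
    message("read_seg: dropped ", n_na_cn, " segment(s) with missing copy number")
    seg <- seg[!is.na(seg$copy_number), , drop = FALSE]
  }
  if (any(seg$copy_number < 0))
    stop("absolute copy numbers must be non-negative")

  if (dialect == "tcga") seg$start <- seg$start - 1
  bad <- which(seg$start >= seg$end | seg$start < 0)
  if (length(bad))
    stop("malformed SEG row(s): start >= end after coordinate normalisation ",
         "at data line(s) ", paste(head(bad, 5), collapse = ", "))

  seg$chromosome <- normalize_chromosome(seg$chromosome, build)
  n_off <- sum(is.na(seg$chromosome))
  if (n_off) {
    message("read_seg: dropped ", n_off,
            " segment(s) on chromosomes outside the build")
    seg <- seg[!is.na(seg$chromosome), , drop = FALSE]
  }

  if (value == "log2ratio") {
    if (is.null(ploidy))
      stop("value = \"log2ratio\" requires a named ploidy vector")
    pl <- ploidy[seg$sample_id]
    if (anyNA(pl))
      stop("log2ratio conversion: missing ploidy for sample(s) ",
           paste(unique(seg$sample_id[is.na(pl)]), collapse = ", "))
    seg$copy_number <- as.numeric(pl) * 2^seg$copy_number
  }

  seg <- seg[order(seg$sample_id, match(seg$chromosome, build$chromosome),
                   seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  validate_segments(seg)
  seg
}

#' Validate a segment table
#'
#' Checks the internal segment invariants: positive length in the 0-based
#' half-open convention and no overlap between segments of the same sample
#' and chromosome.
#'
#' @param segments segment `data.frame` as returned by [read_seg()].
#' @return `segments`, invisibly; errors name the offending sample and
#'   chromosome.
#' @export
validate_segments <- function(segments) {
  stopifnot(all(c("sample_id", "chromosome", "start", "end",
                  "copy_number") %in% names(segments)))
  if (!nrow(segments)) return(invisible(segments))
  if (any(segments$end <= segments$start))
    stop("segments with non-positive length present")
  dt <- data.table::as.data.table(segments)
  data.table::setorder(dt, sample_id, chromosome, start)
  ov <- dt[, any(start[-1] < end[-.N]), by = .(sample_id, chromosome)]
  ov <- ov[ov$V1 == TRUE]
  if (nrow(ov))
    stop("overlapping segments in sample ", ov$sample_id[1],
         ", chromosome ", ov$chromosome[1])
  invisible(segments)
}

#' Write a segment table as a TCGA-dialect SEG file
#'
#' @param segments internal segment `data.frame` (0-based half-open).
#' @param path output path.
#' @param dialect output dialect, as in [read_seg()].
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, dialect = c("tcga", "bed")) {
  dialect <- match.arg(dialect)
  out <- data.frame(
    Sample = segments$sample_id,
    Chromosome = segments$chromosome,
    Start = if (dialect == "tcga") segments$start + 1 else segments$start,
    End = segments$end,
    Copy_Number = segments$copy_number,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ABSOLUTE-style ploidy table
#'
#' Reads a TSV/CSV with a sample column, a ploidy column and (optionally) a
#' genome-doubling column; the latter is parsed into a logical whole-genome
#' doubling (WGD) flag (numeric doubling counts > 0 count as doubled).
#'
#' @param path path to the table (tab- or comma-delimited, autodetected).
#' @return `data.frame` with columns `sample_id`, `ploidy` and, when the
#'   input carries doubling status, `wgd` (logical).
#' @export
read_ploidy_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  nms <- names(raw)
  col_sample <- .find_col(nms, c("^sample", "^array", "^cell_?line", "^id$"))
  col_ploidy <- .find_col(nms, c("ploidy"))
  if (is.na(col_sample) || is.na(col_ploidy))
    stop("ploidy table must name a sample column and a ploidy column")
  col_wgd <- .find_col(nms, c("doubl", "^wgd"))

  ids <- as.character(raw[[col_sample]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in ploidy table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ploidy <- suppressWarnings(as.numeric(raw[[col_ploidy]]))
  if (any(is.na(ploidy) & !is.na(raw[[col_ploidy]]) & raw[[col_ploidy]] != ""))
    stop("non-numeric ploidy value(s) in ploidy table")
  if (any(ploidy <= 0, na.rm = TRUE))
    stop("ploidy must be positive")

  out <- data.frame(sample_id = ids, ploidy = ploidy, stringsAsFactors = FALSE)
  if (!is.na(col_wgd)) {
    w <- raw[[col_wgd]]
    out$wgd <- if (is.logical(w)) w
      else if (is.numeric(w)) w > 0
      else suppressWarnings(as.numeric(w)) > 0 |
        tolower(trimws(as.character(w))) %in% c("true", "yes", "wgd")
  }
  out
}

#' Read a per-sample annotation table
#'
#' Thin TSV/CSV reader for clinical and instability-index annotations
#' (cohort, survival endpoints, therapy response, AS/HRD/SMR/NSMR/ITH/MIN,
#' proliferation). The only requirement is a sample-id column; remaining
#' columns are carried through unchanged.
#'
#' @param path path to the table.
#' @return `data.frame` with a `sample_id` column first.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  col_sample <- .find_col(names(raw), c("^sample", "^id$", "patient"))
  if (is.na(col_sample)) stop("annotation table must name a sample column")
  names(raw)[names(raw) == col_sample] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample id(s) in annotation table")
  raw[, c("sample_id", setdiff(names(raw), "sample_id")), drop = FALSE]
}

#' Read a feature matrix (expression, pathway activity or binary alterations)
#'
#' @param path tab-delimited file; first column holds ids.
#' @param samples_in how the matrix is laid out on disk: `"rows"` (samples in
#'   rows, features in columns; the default) or `"cols"` (transposed).
#' @param binary if `TRUE`, values are validated to be in \{0, 1\}.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_feature_matrix <- function(path, samples_in = c("rows", "cols"),
                                binary = FALSE) {
  samples_in <- match.arg(samples_in)
  raw <- read.delim(path, header = TRUE, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "numeric"
  if (samples_in == "cols") m <- t(m)
  if (binary && !all(m %in% c(0, 1) | is.na(m)))
    stop("binary feature matrix contains values outside {0, 1}")
  m
}

#' Read a drug screen (compound x cell-line AUC matrix)
#'
#' @param path tab-delimited file, compounds in rows, cell lines in columns;
#'   missing AUC allowed.
#' @return numeric matrix of non-negative AUC values (compounds x lines).
#' @export
read_drug_screen <- function(path) {
  m <- read_feature_matrix(path, samples_in = "rows")
  if (any(m < 0, na.rm = TRUE) || any(!is.finite(m) & !is.na(m)))
    stop("AUC values must be finite and non-negative where present")
  m
}

#' Join segments, ploidy and annotations into a scored-cohort dataset
#'
#' Inner-joins the three per-sample sources on `sample_id` and reports how
#' many samples each source loses. Samples lacking ploidy cannot enter
#' NCS/WGII computation and are excluded here.
#'
#' @param segments segment `data.frame` ([read_seg()]).
#' @param ploidy ploidy `data.frame` ([read_ploidy_table()]).
#' @param annotations optional annotation `data.frame` ([read_annotations()]);
#'   when given, its `cohort` column (if any) is carried into `samples`.
#' @return list with elements `segments` (restricted to joint samples) and
#'   `samples` (one row per sample: `sample_id`, `ploidy`, `wgd`, `cohort`,
#'   plus remaining annotation columns).
#' @export
join_cohort <- function(segments, ploidy, annotations = NULL) {
  ids_seg <- unique(segments$sample_id)
  samples <- ploidy
  if (!is.null(annotations))
    samples <- merge(samples, annotations, by = "sample_id", sort = FALSE)
  keep <- intersect(ids_seg, samples$sample_id)
  if (!length(keep))
    stop("join_cohort: no samples shared between segments and sample tables")
  drop_seg <- length(ids_seg) - length(keep)
  drop_tab <- nrow(samples) - length(keep)
  if (drop_seg || drop_tab)
    message("join_cohort: dropped ", drop_seg, " segment-only and ",
            drop_tab, " table-only sample(s)")
  samples <- samples[match(keep, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  list(
    segments = segments[segments$sample_id %in% keep, , drop = FALSE],
    samples = samples
  )
}
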