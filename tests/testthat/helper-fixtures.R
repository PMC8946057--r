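# Small fixtures shared across test files. All coordinates are in bp on a
# 10-kb lattice so the brute-force oracle can expand them exactly.

mini_build <- function() {
  genome_build(paste0("chr", 1:4), c(50e6, 40e6, 30e6, 20e6))
}

# A single-sample segment table from (chromosome, start, end, cn) rows.
seg_df <- function(..., sample_id = "S1") {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = sample_id, chromosome = r[[1]],
               start = as.numeric(r[[2]]), end = as.numeric(r[[3]]),
               copy_number = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# Random lattice-aligned profile on the mini build, independent of the
# package's cohort generator: random breakpoints, continuous copy numbers.
random_profile <- function(sample_id = "S1", build = mini_build(),
                           unit = 1e4, max_cn = 6) {
  segs <- lapply(seq_len(nrow(build)), function(i) {
    L <- build$length[i] / unit
    n_bp <- sample(0:5, 1)
    bp <- sort(unique(c(0, L, if (n_bp) sample.int(L - 1, n_bp))))
    st <- bp[-length(bp)]; en <- bp[-1]
    # leave an occasional uncovered gap
    keep <- runif(length(st)) > 0.1
    if (!any(keep)) keep[1] <- TRUE
    data.frame(sample_id = sample_id, chromosome = build$chromosome[i],
               start = st[keep] * unit, end = en[keep] * unit,
               copy_number = runif(sum(keep), 0, max_cn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

small_config <- function(...) {
  generator_config(n_cohorts = 2, samples_per_cohort = 10, ...)
}
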