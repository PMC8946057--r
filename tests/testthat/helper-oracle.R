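# Independent brute-force oracle for the three CIN scores: expands each
# chromosome to a per-base copy-number vector (at `unit` bp resolution; all
# fixture/generator coordinates are lattice-aligned, so the per-unit tally
# equals the per-base tally exactly) and counts bases / runs directly.
# Deliberately shares no interval arithmetic with the package.
oracle_scores <- function(segments, ploidy, build, unit = 1,
                          threshold = 0.75, min_length = 1e6) {
  stopifnot(all(segments$start %% unit == 0), all(segments$end %% unit == 0))
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  ipl <- if (is.null(ploidy) || is.na(ploidy)) NA else half_away(ploidy)

  fracs <- c()
  whole <- c()
  scs <- 0L
  for (ch in build$chromosome) {
    seg <- segments[segments$chromosome == ch, , drop = FALSE]
    if (!nrow(seg)) next
    L <- ceiling(build$length[build$chromosome == ch] / unit)
    v <- rep(NA_integer_, L)
    for (r in seq_len(nrow(seg)))
      v[(seg$start[r] / unit + 1):(seg$end[r] / unit)] <-
        half_away(seg$copy_number[r])
    covered <- sum(!is.na(v))
    if (!covered) next
    if (!is.na(ipl)) {
      frac <- sum(v != ipl, na.rm = TRUE) / covered
      fracs <- c(fracs, frac)
      whole <- c(whole, frac >= threshold)
    }
    # per-base modal copy number (count-weighted == length-weighted)
    tab <- table(v[!is.na(v)])
    cand <- as.integer(names(tab)[tab == max(tab)])
    modal <- if (!is.na(ipl) && ipl %in% cand) ipl else min(cand)
    # runs of equal copy number; uncovered bases break runs
    w <- ifelse(is.na(v), -1L, v)
    r <- rle(w)
    scs <- scs + sum(r$values != -1L & r$values != modal &
                       r$lengths * unit >= min_length)
  }
  list(ncs = if (is.na(ipl)) NA else sum(whole),
       scs = scs,
       wgii = if (is.na(ipl)) NA else mean(fracs))
}
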