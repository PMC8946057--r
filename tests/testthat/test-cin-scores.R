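test_that("rounding is nearest-integer with ties away from zero", {
  expect_equal(round_half_away(c(2.7, 2.49, 2.5, 3.5, 0.2, -2.5)),
               c(3, 2, 3, 4, 0, -3))
})

test_that("round_profile merges contiguous equal-CN segments only", {
  seg <- seg_df(list("chr1", 0, 1e6, 3.2), list("chr1", 1e6, 2e6, 2.8))
  rp <- round_profile(seg, ploidy = 2.1)
  expect_equal(nrow(rp$segments), 1)
  expect_equal(rp$segments$start, 0)
  expect_equal(rp$segments$end, 2e6)
  expect_equal(rp$segments$copy_number, 3)
  expect_equal(rp$ploidy, 2)

  # a gap between equal-CN segments blocks the merge
  gap <- seg_df(list("chr1", 0, 1e6, 3), list("chr1", 2e6, 3e6, 3))
  expect_equal(nrow(round_profile(gap)$segments), 2)
})

test_that("NCS counts whole-chromosome changes at the >= 75% rule", {
  b <- mini_build()
  # everything at ploidy: zero
  flat <- seg_df(list("chr1", 0, 50e6, 2), list("chr2", 0, 40e6, 2.2))
  expect_equal(compute_ncs(flat, 2.1, b)$ncs, 0)

  # exactly 75% of covered length deviating counts ("at least 75%")
  at75 <- seg_df(list("chr1", 0, 37.5e6, 3), list("chr1", 37.5e6, 50e6, 2),
                 list("chr2", 0, 40e6, 2))
  expect_equal(compute_ncs(at75, 2, b)$ncs, 1)

  # just below threshold does not
  below <- seg_df(list("chr1", 0, 37.49e6, 3), list("chr1", 37.49e6, 50e6, 2))
  expect_equal(compute_ncs(below, 2, b)$ncs, 0)

  expect_error(compute_ncs(flat, NA, b), "ploidy")
})

test_that("NCS on a 22-autosome profile with planted trisomies matches a
           brute-force tally", {
  b <- default_build()
  segs <- lapply(seq_len(22), function(i) {
    ch <- b$chromosome[i]
    L <- floor(b$length[i] / 1e4) * 1e4
    if (i <= 5) {                      # fully trisomic
      seg_df(list(ch, 0, L, 3))
    } else if (i == 6) {               # 60% trisomic: not a whole change
      cut <- floor(0.6 * L / 1e4) * 1e4
      seg_df(list(ch, 0, cut, 3), list(ch, cut, L, 2))
    } else {
      seg_df(list(ch, 0, L, 2))
    }
  })
  seg <- do.call(rbind, segs)
  res <- compute_ncs(seg, 2, b)
  expect_equal(res$ncs, 5)
  orc <- oracle_scores(seg, 2, b, unit = 1e4)
  expect_equal(res$ncs, orc$ncs)
})

test_that("SCS counts >= 1 Mb deviations from the modal copy number", {
  b <- mini_build()
  # uniform chromosome contributes nothing
  expect_equal(compute_scs(seg_df(list("chr1", 0, 50e6, 3)))$scs, 0)

  # 1.0 Mb segment counts, 0.9 Mb segment fails the length rule
  seg <- seg_df(list("chr1", 0, 20e6, 2),
                list("chr1", 20e6, 21e6, 3),      # 1.0 Mb at CN 3
                list("chr1", 21e6, 40e6, 2),
                list("chr1", 40e6, 40.9e6, 1),    # 0.9 Mb at CN 1
                list("chr1", 40.9e6, 50e6, 2))
  expect_equal(compute_scs(seg, build = b)$scs, 1)

  # ploidy plays no role in SCS
  expect_equal(compute_scs(seg, ploidy = 4, build = b)$scs, 1)
})

test_that("modal ties break toward integer ploidy, else the smaller CN", {
  b <- mini_build()
  tie <- seg_df(list("chr1", 0, 25e6, 2), list("chr1", 25e6, 50e6, 3))
  # with ploidy 3 the mode is 3, the CN-2 half is one >=1 Mb deviation
  expect_equal(compute_scs(tie, ploidy = 3, build = b)$scs, 1)
  calls3 <- chromosome_calls(tie, 3, b)
  expect_equal(calls3$modal_cn, 3)
  # without ploidy the tie goes to the smaller CN
  expect_equal(compute_scs(tie, build = b)$calls$modal_cn, 2)
})

test_that("WGII is the mean per-autosome changed fraction", {
  b <- mini_build()
  flat <- do.call(rbind, lapply(b$chromosome, function(ch)
    seg_df(list(ch, 0, 20e6, 2))))
  expect_equal(compute_wgii(flat, 2, b), 0)

  full <- do.call(rbind, lapply(b$chromosome, function(ch)
    seg_df(list(ch, 0, 20e6, 3))))
  expect_equal(compute_wgii(full, 2, b), 1)

  # 40% of covered length deviating on every chromosome -> exactly 0.40
  part <- do.call(rbind, lapply(b$chromosome, function(ch)
    seg_df(list(ch, 0, 8e6, 3), list(ch, 8e6, 20e6, 2))))
  expect_equal(compute_wgii(part, 2, b), 0.40)
})

test_that("score_cohort handles empty cohorts and missing ploidy", {
  empty <- score_cohort(data.frame(sample_id = character(),
                                   chromosome = character(),
                                   start = numeric(), end = numeric(),
                                   copy_number = numeric()),
                        NULL, mini_build())
  expect_equal(nrow(empty), 0)

  set.seed(7)
  seg <- rbind(random_profile("A"), random_profile("B"))
  samples <- data.frame(sample_id = "A", ploidy = 2.2)
  sc <- score_cohort(seg, samples, mini_build())
  expect_false(is.na(sc$ncs[sc$sample_id == "A"]))
  expect_true(is.na(sc$ncs[sc$sample_id == "B"]))
  expect_true(is.na(sc$wgii[sc$sample_id == "B"]))
  expect_false(is.na(sc$scs[sc$sample_id == "B"]))
})

test_that("random profiles match the brute-force per-base oracle", {
  set.seed(11)
  b <- mini_build()
  for (i in 1:50) {
    seg <- random_profile(build = b)
    pl <- runif(1, 1.5, 4.5)
    sc <- score_cohort(seg, data.frame(sample_id = "S1", ploidy = pl), b)
    orc <- oracle_scores(seg, pl, b, unit = 1e4)
    expect_identical(as.integer(sc$ncs), as.integer(orc$ncs))
    expect_identical(as.integer(sc$scs), as.integer(orc$scs))
    expect_lt(abs(sc$wgii - orc$wgii), 1e-12)
  }
})

test_that("NCS and WGII are invariant under whole-genome doubling of an
           integer profile", {
  set.seed(13)
  b <- mini_build()
  for (i in 1:10) {
    seg <- random_profile(build = b)
    seg$copy_number <- round_half_away(seg$copy_number)
    pl <- sample(2:3, 1)
    sc1 <- score_cohort(seg, data.frame(sample_id = "S1", ploidy = pl), b)
    seg2 <- seg; seg2$copy_number <- 2 * seg$copy_number
    sc2 <- score_cohort(seg2, data.frame(sample_id = "S1", ploidy = 2 * pl), b)
    expect_equal(sc1$ncs, sc2$ncs)
    expect_equal(sc1$wgii, sc2$wgii)
  }
})

test_that("SCS is invariant to splitting counted segments", {
  b <- mini_build()
  seg <- seg_df(list("chr1", 0, 20e6, 2), list("chr1", 20e6, 25e6, 3),
                list("chr1", 25e6, 50e6, 2))
  split_seg <- seg_df(list("chr1", 0, 20e6, 2),
                      list("chr1", 20e6, 22e6, 3),
                      list("chr1", 22e6, 25e6, 3),
                      list("chr1", 25e6, 50e6, 2))
  expect_equal(compute_scs(seg, build = b)$scs,
               compute_scs(split_seg, build = b)$scs)
})

test_that("adding a deviating whole chromosome raises NCS by one and never
           lowers WGII", {
  set.seed(17)
  b <- mini_build()
  for (i in 1:10) {
    seg <- random_profile(build = b)
    seg <- seg[seg$chromosome != "chr4", , drop = FALSE]
    pl <- 2
    sc1 <- score_cohort(seg, data.frame(sample_id = "S1", ploidy = pl), b)
    seg2 <- rbind(seg, seg_df(list("chr4", 0, 20e6, 3)))
    sc2 <- score_cohort(seg2, data.frame(sample_id = "S1", ploidy = pl), b)
    expect_equal(sc2$ncs, sc1$ncs + 1)
    expect_gte(sc2$wgii, sc1$wgii)
  }
})
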