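test_that("region_density is the mean count over a half-open interval", {
  tm <- toy_model()
  tr <- make_track(tm, c(1:3, rep(0, 33)))
  expect_equal(region_density(tr, c(0L, 3L)), 2)
  expect_equal(region_density(tr, c(5L, 5L)), 0)   # empty interval convention
  expect_error(region_density(tr, c(30L, 40L)), "outside")

  uni <- uniform_track(tm)
  expect_equal(region_density(uni, c(3L, 27L)), 1)
})

test_that("score_transcript reproduces hand-computed pause scores and RRTS", {
  # 350-nt transcript, CDS [10, 310): body density 2/nt, stop counts 6,6,6
  seq310 <- paste0(strrep("A", 10), "ATG", strrep("GGC", 98), "TAA",
                   paste0(strrep("GGG", 10), "TAA"), strrep("C", 7))
  tm <- transcript_model("t", 10L, 310L, seq310)
  counts <- rep(0L, tm$length)
  counts[(10 + 1):310] <- 2L            # whole CDS at 2/nt
  counts[(307 + 1):310] <- 6L           # NTC at 6/nt
  tr <- make_track(tm, counts)
  row <- score_transcript(tr, tm, min_cds_reads = 0L)
  expect_equal(row$pause_score, 3)      # 6 / 2
  expect_equal(row$stop_density, 6)
  expect_equal(row$cds_body_density, 2)

  # extension [310, 340), 30 nt: 6 reads -> density 0.2; CDS density 2.04
  counts2 <- counts
  counts2[c(311, 316, 321, 326, 331, 336)] <- 1L
  tr2 <- make_track(tm, counts2)
  row2 <- score_transcript(tr2, tm, min_cds_reads = 0L)
  cds_density <- (2 * 297 + 3 * 6) / 300
  expect_equal(row2$rrts, (6 / 30) / cds_density)

  # CDS 300 nt at exactly 1/nt, 30-nt extension with 6 reads: RRTS 0.1 * 1
  counts3 <- rep(0L, tm$length)
  counts3[(10 + 1):310] <- 1L
  counts3[310 + c(1, 6, 11, 16, 21, 26)] <- 1L
  row3 <- score_transcript(make_track(tm, counts3), tm, min_cds_reads = 0L)
  expect_equal(row3$rrts, (6 / 30) / 1)

  # uniform track: both ratios are exactly 1
  uni <- score_transcript(uniform_track(tm), tm, min_cds_reads = 0L)
  expect_equal(uni$pause_score, 1)
  expect_equal(uni$rrts, 1)
})

test_that("eligibility guards replace division by zero", {
  tm <- toy_model()   # CDS [3, 27) is 24 nt: too short for a body
  row <- score_transcript(uniform_track(tm), tm, min_cds_reads = 0L)
  expect_false(row$eligible_pause)
  expect_equal(row$reason_pause, "short_cds")

  # zero body density with reads at the stop
  seq310 <- paste0(strrep("A", 10), "ATG", strrep("GGC", 98), "TAA",
                   strrep("C", 40))
  tm2 <- transcript_model("t2", 10L, 310L, seq310)
  counts <- rep(0L, tm2$length)
  counts[(307 + 1):310] <- 5L
  row2 <- score_transcript(make_track(tm2, counts), tm2, min_cds_reads = 0L)
  expect_false(row2$eligible_pause)
  expect_equal(row2$reason_pause, "zero_body_density")
  expect_true(is.na(row2$pause_score))
  expect_equal(row2$stop_density, 5)    # densities still reported

  # low CDS reads trips both scores
  row3 <- score_transcript(make_track(tm2, counts), tm2, min_cds_reads = 32L)
  expect_equal(row3$reason_pause, "low_cds_reads")

  # no in-frame downstream stop: RRTS-ineligible, pause score kept
  tm4 <- transcript_model("t4", 0L, 300L,
                          paste0("ATG", strrep("GGC", 98), "TAA",
                                 strrep("C", 31)))
  row4 <- score_transcript(uniform_track(tm4), tm4, min_cds_reads = 0L)
  expect_false(row4$eligible_rrts)
  expect_equal(row4$reason_rrts, "no_inframe_stop")
  expect_true(row4$eligible_pause)
})

test_that("pipeline scores equal the brute-force per-nucleotide oracle", {
  sim <- small_sim(n = 60)
  tab <- score_table(sim$tracks, sim$models, min_cds_reads = 0L)
  expect_gte(nrow(tab), 50)
  for (tm in sim$models) {
    row <- tab[transcript_id == tm$transcript_id]
    oracle <- naive_scores(sim$tracks[[tm$transcript_id]], tm)
    if (row$eligible_pause) expect_identical(row$pause_score, oracle$pause_score)
    if (row$eligible_rrts) expect_identical(row$rrts, oracle$rrts)
  }
})

test_that("scores are invariant to count scaling and monotone in signal", {
  seq310 <- paste0(strrep("A", 10), "ATG", strrep("GGC", 98), "TAA",
                   paste0(strrep("GGG", 10), "TAA"), strrep("C", 7))
  tm <- transcript_model("t", 10L, 310L, seq310)
  set.seed(5)
  counts <- rpois(tm$length, 2) + 1L
  base <- score_transcript(make_track(tm, counts), tm, min_cds_reads = 0L)
  for (k in c(2L, 7L)) {
    scaled <- score_transcript(make_track(tm, counts * k), tm,
                               min_cds_reads = 0L)
    expect_equal(scaled$pause_score, base$pause_score)
    expect_equal(scaled$rrts, base$rrts)
  }

  # reads added only at the stop codon strictly increase the pause score
  more_stop <- counts; more_stop[(307 + 1):310] <- more_stop[(307 + 1):310] + 5L
  bumped <- score_transcript(make_track(tm, more_stop), tm, min_cds_reads = 0L)
  expect_gt(bumped$pause_score, base$pause_score)

  # reads added only in the extension strictly increase the RRTS
  more_ext <- counts; more_ext[(310 + 1):340] <- more_ext[(310 + 1):340] + 2L
  bumped2 <- score_transcript(make_track(tm, more_ext), tm, min_cds_reads = 0L)
  expect_gt(bumped2$rrts, base$rrts)
})

test_that("score_table is deterministic, sorted, and summarizes reasons", {
  sim <- small_sim(n = 20)
  a <- score_table(sim$tracks, sim$models)
  b <- score_table(sim$tracks, sim$models)
  expect_identical(a, b)
  expect_identical(a$transcript_id, sort(a$transcript_id))
  expect_true(is.list(attr(a, "ineligible")))

  # a raised threshold makes low-coverage transcripts ineligible
  strict <- score_table(sim$tracks, sim$models, min_cds_reads = 10000L)
  expect_true(all(!strict$eligible_pause))
  expect_true(all(strict$reason_pause == "low_cds_reads"))
})

test_that("metagene of uniform tracks is the constant 1 profile", {
  p <- simulation_params(n_transcripts = 5, cds_length_range = c(300L, 450L),
                         utr3_length_range = c(120L, 150L))
  models <- simulate_transcriptome(p, seed = 2)
  tracks <- lapply(models, uniform_track, level = 3L)
  prof <- metagene(tracks, models, min_cds_reads = 0L)
  covered <- prof[n_transcripts > 0]
  expect_true(all(abs(covered$mean_density - 1) < 1e-12))
  expect_equal(prof[position == 0, n_transcripts], 5L)
})

test_that("metagene reflects terminal pausing and tracks coverage", {
  # density 1/nt across the CDS, 3/nt on the NTC
  seq310 <- paste0(strrep("A", 10), "ATG", strrep("GGC", 98), "TAA",
                   strrep("C", 140))
  tm <- transcript_model("t", 10L, 310L, seq310)
  counts <- rep(0L, tm$length)
  counts[(10 + 1):310] <- 1L
  counts[(307 + 1):310] <- 3L
  tracks <- list(t = make_track(tm, counts))
  prof <- metagene(tracks, list(t = tm), min_cds_reads = 0L)
  cds_density <- (297 + 9) / 300
  expect_equal(prof[position %in% 0:2, mean_density],
               rep(3 / cds_density, 3))
  expect_equal(prof[position == -1, mean_density], 1 / cds_density)

  # zero-coverage transcript excluded entirely
  tm2 <- transcript_model("z", 10L, 310L, seq310)
  tracks2 <- c(tracks, list(z = make_track(tm2, rep(0L, tm2$length))))
  prof2 <- metagene(tracks2, list(t = tm, z = tm2), min_cds_reads = 0L)
  expect_equal(prof2[position == 0, n_transcripts], 1L)
  expect_error(metagene(list(z = tracks2$z), list(z = tm2), min_cds_reads = 0L),
               "empty metagene")
})

test_that("score tables round-trip through TSV with provenance", {
  sim <- small_sim(n = 10)
  tab <- score_table(sim$tracks, sim$models)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, path, provenance = list(condition = "demo", k = 2))
  back <- read_tsv_with_header(path)
  expect_equal(attr(back, "provenance")[["condition"]], "demo")
  expect_equal(back$transcript_id, tab$transcript_id)
  expect_equal(back$pause_score, tab$pause_score, tolerance = 1e-12)
})
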