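test_that("simulated transcriptomes are deterministic and valid", {
  p <- simulation_params(n_transcripts = 10)
  a <- simulate_transcriptome(p, seed = 1)
  b <- simulate_transcriptome(p, seed = 1)
  expect_identical(a, b)
  c <- simulate_transcriptome(p, seed = 2)
  expect_false(identical(a, c))

  for (tm in a) expect_length(validate_transcript_model(tm), 0)

  # designated second stops honor the declared extension fraction
  p_all <- simulation_params(n_transcripts = 40, extension_fraction = 1)
  with_ext <- simulate_transcriptome(p_all, seed = 3)
  expect_true(all(!is.na(vapply(with_ext, find_next_inframe_stop, 0L))))

  p_none <- simulation_params(n_transcripts = 40, extension_fraction = 0)
  no_ext <- simulate_transcriptome(p_none, seed = 3)
  expect_true(all(is.na(vapply(no_ext, find_next_inframe_stop, 0L))))
})

test_that("extension fraction 0 makes every transcript RRTS-ineligible", {
  p <- simulation_params(n_transcripts = 15, extension_fraction = 0)
  models <- simulate_transcriptome(p, seed = 4)
  rec <- simulate_footprints(models, p, seed = 5)
  tab <- score_table(build_density(rec, models, p$offsets), models,
                     min_cds_reads = 0L)
  expect_true(all(!tab$eligible_rrts))
  expect_true(all(tab$reason_rrts == "no_inframe_stop"))
})

test_that("footprints back-compute 5' ends consistently with the offsets", {
  sim <- small_sim(n = 15)
  rec <- sim$records
  expect_true(all(rec$read_length %in% as.integer(names(sim$params$offsets))))
  expect_true(all(rec$five_prime_pos >= 0))
  tx_len <- vapply(sim$models, `[[`, 0L, "length")
  expect_true(all(rec$five_prime_pos + rec$read_length <=
                    tx_len[rec$transcript_id]))

  # P-site assignment recovers positions inside the modeled regions only
  asg <- assign_psite(rec, sim$params$offsets, sim$models)
  expect_equal(asg$n_no_offset + asg$n_out_of_bounds, 0L)
  for (id in names(sim$models)[1:3]) {
    tm <- sim$models[[id]]
    ps <- asg$records[transcript_id == id, psite]
    expect_true(all(ps >= tm$cds_start))
    nss <- find_next_inframe_stop(tm)
    upper <- if (is.na(nss)) tm$cds_end else nss + 3L
    expect_true(all(ps < upper))
  }
})

test_that("pure pausing without readthrough leaves the 3'UTR empty", {
  p <- simulation_params(n_transcripts = 500, pause_multiplier = 1,
                         readthrough_fraction = 0,
                         cds_length_range = c(150L, 300L),
                         utr3_length_range = c(90L, 150L))
  models <- simulate_transcriptome(p, seed = 21)
  rec <- simulate_footprints(models, p, seed = 22)
  tab <- score_table(build_density(rec, models, p$offsets), models,
                     min_cds_reads = 32L)
  expect_true(all(tab[eligible_rrts == TRUE, rrts] == 0))
  # with pi = 1 the mean pause score is 1 up to Poisson noise
  expect_gt(mean(tab$pause_score, na.rm = TRUE), 0.9)
  expect_lt(mean(tab$pause_score, na.rm = TRUE), 1.1)
})

test_that("injected PCR duplicates are removed exactly by UMI dedup", {
  p <- simulation_params(n_transcripts = 30, duplication_rate = 0.5)
  models <- simulate_transcriptome(p, seed = 6)
  rec <- simulate_footprints(models, p, seed = 7)
  injected <- attr(rec, "n_duplicates_injected")
  expect_gt(injected, 0)
  out <- deduplicate_by_umi(rec)
  expect_equal(out$n_removed, injected)
  expect_equal(nrow(out$records), nrow(rec) - injected)
})

test_that("depth scaling leaves score distributions unchanged in location", {
  base <- simulation_params(n_transcripts = 300, pause_multiplier = 2,
                            readthrough_fraction = 0.05,
                            cds_length_range = c(150L, 300L),
                            utr3_length_range = c(90L, 150L))
  deep <- simulation_params(n_transcripts = 300, pause_multiplier = 2,
                            readthrough_fraction = 0.05,
                            cds_length_range = c(150L, 300L),
                            utr3_length_range = c(90L, 150L),
                            expression_scale = 10)
  models <- simulate_transcriptome(base, seed = 8)
  tab1 <- score_table(build_density(simulate_footprints(models, base, seed = 9),
                                    models, base$offsets), models)
  tab2 <- score_table(build_density(simulate_footprints(models, deep, seed = 10),
                                    models, deep$offsets), models)
  m1 <- median(tab1$pause_score, na.rm = TRUE)
  m2 <- median(tab2$pause_score, na.rm = TRUE)
  expect_lt(abs(m1 - m2), 0.25)
  r1 <- median(tab1$rrts, na.rm = TRUE)
  r2 <- median(tab2$rrts, na.rm = TRUE)
  expect_lt(abs(r1 - r2), 0.02)
})

test_that("paired null comparisons yield uniform signed-rank p-values", {
  # two arms with identical parameters: the paired pause-score test
  # should be calibrated, i.e. its p-values close to U(0, 1)
  p <- simulation_params(n_transcripts = 200, cds_length_range = c(90L, 180L),
                         utr3_length_range = c(60L, 90L),
                         expression_shape = 1, expression_scale = 1)
  models <- simulate_transcriptome(p, seed = 1)
  pvals <- vapply(1:200, function(i) {
    ta <- score_table(build_density(
      simulate_footprints(models, p, seed = 1000 + 2 * i), models, p$offsets),
      models)
    tb <- score_table(build_density(
      simulate_footprints(models, p, seed = 1001 + 2 * i), models, p$offsets),
      models)
    m <- merge(ta[eligible_pause == TRUE, .(transcript_id, a = pause_score)],
               tb[eligible_pause == TRUE, .(transcript_id, b = pause_score)],
               by = "transcript_id")
    wilcoxon_signed_rank(m$a, m$b)$p_value
  }, 0)
  ks <- max(abs(sort(pvals) - seq_along(pvals) / length(pvals)),
            abs(sort(pvals) - (seq_along(pvals) - 1) / length(pvals)))
  expect_lt(ks, 0.1)
})

test_that("simulate_experiment writes a paired, reproducible experiment", {
  p <- simulation_params(n_transcripts = 12, cds_length_range = c(150L, 240L),
                         utr3_length_range = c(90L, 120L))
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  res_a <- simulate_experiment(p, seed = 5, out_dir = dir_a)
  res_b <- simulate_experiment(p, seed = 5, out_dir = dir_b)

  expect_setequal(names(res_a$footprints), c("DMSO", "G418", "SRI"))
  for (f in c("transcripts.tsv", names(res_a$footprints))) {
    fa <- if (f == "transcripts.tsv") res_a$transcript_table else res_a$footprints[[f]]
    fb <- if (f == "transcripts.tsv") res_b$transcript_table else res_b$footprints[[f]]
    expect_identical(readLines(fa), readLines(fb))
  }

  # conditions share one transcriptome; arms differ only in counts
  models <- read_transcript_table(res_a$transcript_table)
  expect_length(models, 12)
  rec_dmso <- read_footprints(res_a$footprints[["DMSO"]])
  rec_g418 <- read_footprints(res_a$footprints[["G418"]])
  expect_true(all(rec_dmso$transcript_id %in% names(models)))
  expect_false(identical(rec_dmso, rec_g418))
})

test_that("the manifest round-trips into equal simulation parameters", {
  p <- simulation_params(n_transcripts = 8, readthrough_fraction = 0.02,
                         cds_length_range = c(150L, 240L),
                         utr3_length_range = c(90L, 120L))
  dir <- withr::local_tempdir()
  res <- simulate_experiment(p, seed = 9, out_dir = dir)
  man <- read_manifest(res$manifest)
  expect_equal(man$params, p, tolerance = 1e-12)
  expect_equal(man$seed, 9)
  expect_equal(vapply(man$conditions, `[[`, "", "name"),
               c("DMSO", "G418", "SRI"))
  expect_equal(man$conditions[[2]]$readthrough_fraction, 0.08)
})
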