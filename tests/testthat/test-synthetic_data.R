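test_that("sim_spec validates its parameters", {
  expect_error(sim_spec(cds_len = 7L))                 # not a codon multiple
  expect_error(sim_spec(isr_len = 2L))
  expect_error(sim_spec(frame_probs = c(0.5, 0.5, 0.5)))
  expect_error(sim_spec(fragment_lengths = 20:22))     # outside 24-36
  expect_s3_class(sim_spec(), "sim_spec")
})

test_that("transcripts are reproducible and carry the designed ISR", {
  spec <- sim_spec(utr5_len = 40L, cds_len = 150L, isr_len = 99L,
                   utr3_rest_len = 120L, seed = 101L)
  t1 <- make_transcript(spec)
  t2 <- make_transcript(spec)
  expect_identical(t1$sequence, t2$sequence)
  expect_equal(t1$annotation$isr_codons, 33)

  t0 <- make_transcript(sim_spec(utr5_len = 40L, cds_len = 150L,
                                 isr_len = 0L, utr3_rest_len = 120L,
                                 seed = 101L))
  expect_equal(t0$annotation$isr_codons, 0)

  # designed codons: ATG start, TGA canonical stop, TAA downstream stop
  a <- t1$annotation
  expect_equal(substr(t1$sequence, a$cds_start, a$cds_start + 2), "ATG")
  expect_equal(substr(t1$sequence, a$cds_end - 2, a$cds_end), "TGA")
  expect_equal(substr(t1$sequence, a$stop2_start, a$stop2_end), "TAA")

  # all 24-mers unique, so exact mapping is unambiguous
  L <- nchar(t1$sequence)
  expect_equal(anyDuplicated(substring(t1$sequence, 1:(L - 23), 24:L)), 0)
})

test_that("simulated footprints honour the designed region structure", {
  spec <- sim_spec(utr5_len = 60L, cds_len = 300L, isr_len = 99L,
                   utr3_rest_len = 300L,
                   region_densities = c(utr5 = 0, cds = 1, isr = 0.2,
                                        utr3_rest = 0),
                   n_reads = 2000L, seed = 23L)
  tx <- make_transcript(spec)
  sim <- simulate_footprints(tx, spec)
  expect_equal(nrow(sim$truth), 2000)
  expect_false(any(sim$truth$region %in% c("utr5", "utr3_rest")))

  # determinism and read fidelity
  sim2 <- simulate_footprints(tx, spec)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$reads,
                   setNames(substring(tx$sequence, sim$truth$start,
                                      sim$truth$end), sim$truth$read_id))

  # fragment lengths come from the configured support
  expect_true(all(sim$truth$length %in% 27:29))
})

test_that("pure frame-0 CDS signal closes the loop through the mapper", {
  spec <- sim_spec(utr5_len = 60L, cds_len = 300L, isr_len = 30L,
                   utr3_rest_len = 120L,
                   region_densities = c(utr5 = 0, cds = 1, isr = 0,
                                        utr3_rest = 0),
                   frame_probs = c(1, 0, 0), n_reads = 400L, seed = 29L)
  tx <- make_transcript(spec)
  sim <- simulate_footprints(tx, spec)
  fp <- map_reads(sim$reads,
                  setNames(tx$sequence, tx$annotation$transcript_id))
  expect_equal(nrow(fp), 400)
  pr <- frame_proportions(fp, "cds",
                          partition_regions(tx$annotation, 0L),
                          tx$annotation$cds_start)
  expect_equal(c(pr$f0, pr$f1, pr$f2), c(1, 0, 0))
})

test_that("end-to-end: readthrough signal is called, its absence is not", {
  spec_pos <- sim_spec(utr5_len = 100L, cds_len = 600L, isr_len = 99L,
                       utr3_rest_len = 600L,
                       region_densities = c(utr5 = 0.05, cds = 1, isr = 0.25,
                                            utr3_rest = 0.05),
                       n_reads = 5000L, seed = 31L)
  tx <- make_transcript(spec_pos)
  sim <- simulate_footprints(tx, spec_pos)
  fp <- map_reads(sim$reads,
                  setNames(tx$sequence, tx$annotation$transcript_id))
  call <- call_readthrough(region_stats(fp, tx$annotation))
  expect_true(call$verdict)
  expect_gt(call$density_ratio, 3)

  # no ISR enrichment: density ratio near 1 fails the threefold criterion
  spec_null <- sim_spec(utr5_len = 100L, cds_len = 600L, isr_len = 99L,
                        utr3_rest_len = 600L,
                        region_densities = c(utr5 = 0.05, cds = 1,
                                             isr = 0.05, utr3_rest = 0.05),
                        n_reads = 5000L, seed = 31L)
  tx_null <- make_transcript(spec_null)
  sim_null <- simulate_footprints(tx_null, spec_null)
  call_null <- call_readthrough(region_stats(sim_null$truth,
                                             tx_null$annotation))
  expect_false(call_null$verdict)
})

test_that("reporter simulation recovers the designed readthrough fraction", {
  noiseless <- simulate_reporter(0.2, noise_cv = 0, n_replicates = 3,
                                 seed = 41)
  expect_equal(percent_readthrough(noiseless$test,
                                   noiseless$control)$percent, 20)

  same <- simulate_reporter(0.2, noise_cv = 0.1, n_replicates = 6, seed = 42)
  again <- simulate_reporter(0.2, noise_cv = 0.1, n_replicates = 6, seed = 42)
  expect_identical(same$test$fluc, again$test$fluc)

  # across many seeds the mean estimate is close to the truth
  ests <- vapply(1:300, function(s) {
    r <- simulate_reporter(0.2, noise_cv = 0.1, n_replicates = 6, seed = s)
    percent_readthrough(r$test, r$control)$percent
  }, numeric(1))
  expect_lt(abs(mean(ests) - 20), 0.4)  # within 2% of 20%
})

test_that("FASTQ round-trip preserves simulated reads", {
  spec <- sim_spec(utr5_len = 30L, cds_len = 120L, isr_len = 30L,
                   utr3_rest_len = 60L, n_reads = 50L, seed = 43L)
  tx <- make_transcript(spec)
  sim <- simulate_footprints(tx, spec)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_equal(unname(back), unname(sim$reads))
})
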