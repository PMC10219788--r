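test_that("zero mutation rate plants identical copies at recorded coordinates", {
  d <- generate_dataset(n_records = 5, record_length = 400, mutation_rate = 0,
                        seed = 4)
  expect_equal(length(d$records), 5)
  for (r in 1:5) {
    s <- d$records$sequence[r]
    st <- d$truth$coords$start[r]; en <- d$truth$coords$end[r]
    expect_equal(substr(s, st + 1, en), d$truth$planted_nt)
  }
})

test_that("generation is reproducible from the seed", {
  d1 <- generate_dataset(n_records = 4, record_length = 300, seed = 99)
  d2 <- generate_dataset(n_records = 4, record_length = 300, seed = 99)
  expect_identical(d1$records$sequence, d2$records$sequence)
  expect_identical(d1$truth$coords, d2$truth$coords)
  d3 <- generate_dataset(n_records = 4, record_length = 300, seed = 100)
  expect_false(identical(d1$records$sequence, d3$records$sequence))
})

test_that("per-copy divergence matches the binomial expectation", {
  # 45-nt planted ORF has 39 mutable sites; at rate 0.05 a copy carries
  # Binomial(39, 0.05 * 3/4-corrected) >= observed hamming distance, since a
  # 'substitution' may redraw the same codon during stop-resampling but never
  # restores the original at independent sites. Check the mean over many
  # replicates against 39 * 0.05 within 4 standard errors.
  rate <- 0.05
  n_sites <- 39
  reps <- 60
  diffs <- numeric(0)
  for (s in seq_len(reps)) {
    d <- generate_dataset(n_records = 2, record_length = 200,
                          mutation_rate = rate, n_decoys = 0, seed = 1000 + s)
    for (r in 1:2) {
      copy <- substr(d$records$sequence[r], d$truth$coords$start[r] + 1,
                     d$truth$coords$end[r])
      diffs <- c(diffs, sum(strsplit(copy, "")[[1]] !=
                              strsplit(d$truth$planted_nt, "")[[1]]))
    }
  }
  expected <- n_sites * rate
  se <- sqrt(n_sites * rate * (1 - rate) / length(diffs))
  expect_lt(abs(mean(diffs) - expected), 4 * se + 0.15)
  # start and stop codons are never touched
  expect_true(all(diffs <= n_sites))
})

test_that("planted ORFs are always recoverable candidates and records validate", {
  for (s in c(2, 12, 77)) {
    d <- generate_dataset(n_records = 4, record_length = 350,
                          mutation_rate = 0.2, seed = s)
    expect_s3_class(upstream_set(d$records$id, d$records$sequence),
                    "upstream_set")   # re-validation passes
    cand <- find_orfs(d$records)
    for (r in 1:4) {
      co <- orf_coord_df(cand[[r]])
      expect_true(any(co$start == d$truth$coords$start[r] &
                        co$end == d$truth$coords$end[r]))
    }
  }
})

test_that("invalid planted sequences and rates are rejected", {
  expect_error(generate_dataset(planted_nt = "ATGAAA", seed = 1), "valid ORF")
  expect_error(generate_dataset(planted_nt = "ATGTAGAAATAA", seed = 1),
               "valid ORF")   # internal stop
  expect_error(generate_dataset(mutation_rate = 0.6, seed = 1), "mutation_rate")
})

test_that("recovery scoring arithmetic follows the report contract", {
  d <- generate_dataset(n_records = 5, record_length = 400, mutation_rate = 0,
                        seed = 8)
  fit <- uorf_scan(d$records)
  rep1 <- score_recovery(fit$paths, d$truth)
  expect_equal(rep1$recall, 1.0)
  expect_equal(score_recovery(list(), d$truth)$recall, 0)
  # drop one member from the top path: 4/5 recovered
  p <- fit$paths[[1]]
  p$members <- p$members[-1]
  expect_equal(score_recovery(list(p), d$truth)$recall, 0.8)
  # tolerance widens matching
  p2 <- fit$paths[[1]]
  p2$members[[1]]$start <- p2$members[[1]]$start + 2L
  expect_equal(score_recovery(list(p2), d$truth)$recall, 0.8)
  expect_equal(score_recovery(list(p2), d$truth, tolerance_nt = 2)$recall, 1)
})

test_that("truth tables round-trip through the tab-separated writer", {
  d <- generate_dataset(n_records = 3, record_length = 300, seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(d$truth, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$record_id, d$truth$coords$record_id)
  expect_equal(back$start, d$truth$coords$start)
  expect_equal(unique(back$peptide), d$truth$planted_peptide)
})
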