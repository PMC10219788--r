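test_that("energy model loads with negative Watson-Crick stacks", {
  m <- energy_model()
  wc <- c("AU", "UA", "GC", "CG")
  is_wc <- vapply(names(m$stacks), function(k) {
    p <- strsplit(k, "/")[[1]]
    all(paste0(c(substr(p[1], 1, 1), substr(p[1], 2, 2)),
               c(substr(p[2], 1, 1), substr(p[2], 2, 2))) %in% wc)
  }, logical(1))
  expect_true(all(m$stacks[is_wc] < 0))
  expect_true(m$initiation > 0)
})

test_that("duplex energy of a perfect duplex is hand-summable from the table", {
  # independent oracle: read the shipped TSV and sum stacks directly
  for (probe in c("CCUCCU", "UCCUCC", "ACCUCC")) {
    target <- chartr("T", "U", perfect_target_dna(probe))
    expect_equal(duplex_energy(probe, target), indep_perfect_duplex(probe),
                 tolerance = 1e-12)
  }
  expect_equal(duplex_energy("CCUCCU", "AGGAGG"), -8.1)
})

test_that("weak or absent pairing yields no stable duplex", {
  # only isolated (non-adjacent) U:A pairs can form -> no stable duplex
  expect_equal(duplex_energy("CCUCCU", "AAAAAA"), 0)
  # exactly one isolated pair is below the 2-pair minimum
  expect_equal(duplex_energy("CCUCCU", "CCCCCG"), 0)
  expect_equal(duplex_energy("CCUCCU", "CCCCCC"), 0)
  expect_error(duplex_energy("CCUCCU", "AAAA"), "equal length")
})

test_that("duplex energy uses the longest contiguous run and allows wobble", {
  # probe CCUCCU vs target with a 2-pair island and a 3-pair island:
  # the longer (3-pair) run must be scored
  m <- energy_model()
  e3 <- duplex_energy("CCUCCU", "AGGAAA", m)  # pairs at probe pos 4-6
  expect_true(e3 != 0)
  # G:U wobble pairs count as pairs
  expect_true(duplex_energy("CCUCCU", "AGGGGG", m) != 0)
})

test_that("SD scan equals exhaustive per-offset minimization", {
  set.seed(11)
  params <- orf_params(sd_threshold = 0)  # annotate any stable duplex
  m <- energy_model()
  for (i in 1:25) {
    win <- random_seq(20)
    seq <- paste0(win, "ATGAAATAA")
    orfs <- find_orfs(seq)
    orf <- orfs[[which(vapply(orfs, `[[`, integer(1), "start") == 20L)]]
    ann <- scan_sd(seq, orf, params, m)
    # oracle: direct enumeration of all offsets
    rna <- chartr("T", "U", win)
    e <- vapply(0:(20 - 6), function(o) {
      duplex_energy("CCUCCU", substr(rna, o + 1, o + 6), m)
    }, numeric(1))
    if (min(e) <= params$sd_threshold) {
      expect_equal(ann$delta_g, min(e))
      expect_equal(ann$match_offset, max(which(e == min(e))) - 1L)
    } else {
      expect_null(ann)
    }
  }
})

test_that("an exact anti-SD complement in the window is annotated at full energy", {
  seq <- paste0(strrep("C", 4), "AGGAGG", strrep("A", 10), "ATGAAATAA")
  orf <- find_orfs(seq)[[1]]
  expect_equal(orf$start, 20L)
  ann <- scan_sd(seq, orf)
  expect_equal(ann$delta_g, duplex_energy("CCUCCU", "AGGAGG"))
  expect_equal(ann$window_start, 0L)
  expect_equal(ann$match_offset, 4L)
  expect_lte(ann$delta_g, 0)
})

test_that("windows truncate at the sequence start and poor windows stay silent", {
  # ORF starting at position 3: only a 3-nt window, shorter than the probe
  expect_null(scan_sd(paste0("AGG", "ATGAAATAA"), find_orfs("AGGATGAAATAA")[[1]]))
  # all-A window can never pair
  seqA <- paste0(strrep("A", 20), "ATGAAATAA")
  expect_null(scan_sd(seqA, find_orfs(seqA)[[1]]))
  # truncated but probe-sized window works without error
  seq7 <- paste0("CAGGAGG", "ATGAAATAA")
  ann <- scan_sd(seq7, find_orfs(seq7)[[1]])
  expect_equal(ann$window_start, 0L)
})

test_that("eukaryote mode never produces SD annotations", {
  d <- generate_dataset(n_records = 3, record_length = 200, seed = 5,
                        mode = "eukaryote")
  cand <- annotate_sd(d$records, find_orfs(d$records))
  sds <- unlist(lapply(cand, function(cs) lapply(cs, `[[`, "sd")))
  expect_null(sds)
  expect_null(scan_sd(paste0("CAGGAGG", "ATGAAATAA"),
                      find_orfs("CAGGAGGATGAAATAA")[[1]],
                      mode = "eukaryote"))
})
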