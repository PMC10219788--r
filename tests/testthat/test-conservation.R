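test_that("pairwise scores reproduce hand-computed alignment scores", {
  # BLOSUM62 diagonal: M=5, K=5, L=4, F=6
  expect_equal(pairwise_score("MKLF", "MKLF"), 20)
  expect_equal(pairwise_score("MKLF", "MKLF"), pairwise_score("MKLF", "MKLF"))
  # identical 9-nt sequences at +2/match: 9 x 2
  nt <- scoring_scheme("nucleotide")
  expect_equal(pairwise_score("ATGAAATAA", "ATGAAATAA", nt), 18)
  # symmetry on unequal sequences
  expect_equal(pairwise_score("MKLF", "MKF"), pairwise_score("MKF", "MKLF"))
  expect_error(pairwise_score("", "MK"), "empty")
})

test_that("identical ORFs across records form the top path at 3x self-score", {
  planted <- "MKLFAGSTV"
  cand <- list(
    r1 = list(make_orf("r1", planted, 10), make_orf("r1", "MWWWH", 100)),
    r2 = list(make_orf("r2", "MEDED", 5), make_orf("r2", planted, 60)),
    r3 = list(make_orf("r3", planted, 200)))
  paths <- greedy_search(cand)
  expect_gte(length(paths), 1)
  top <- paths[[1]]
  expect_equal(length(top$members), 3)
  expect_equal(top$coverage, 1)
  s <- pairwise_score(planted, planted)
  expect_equal(top$total_score, 3 * s)
  expect_equal(vapply(top$members, `[[`, character(1), "peptide"),
               c(r1 = planted, r2 = planted, r3 = planted))
})

test_that("two single-candidate records force a single full-coverage path", {
  cand <- list(a = list(make_orf("a", "MKLF")), b = list(make_orf("b", "MKLF")))
  paths <- greedy_search(cand)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$coverage, 1)
  expect_equal(paths[[1]]$total_score, 20)
})

test_that("a record whose only candidate fails the accept gate is skipped", {
  planted <- "MKLFAGSTVWYH"
  cand <- list(
    r1 = list(make_orf("r1", planted)),
    r2 = list(make_orf("r2", planted)),
    r3 = list(make_orf("r3", "MPPPP")),   # unrelated, low-scoring
    r4 = list(make_orf("r4", planted)))
  self <- pairwise_score(planted, planted)
  expect_lt(pairwise_score(planted, "MPPPP"), 0.5 * self)  # gate premise
  paths <- greedy_search(cand, params = conservation_params(min_coverage = 0.5))
  top <- paths[[1]]
  expect_equal(length(top$members), 3)
  expect_equal(top$coverage, 0.75)
  expect_false("r3" %in% names(top$members))
})

test_that("fewer than 2 records with candidates is an error", {
  expect_error(greedy_search(list(a = list(make_orf("a", "MK")), b = list())),
               "nothing to compare")
})

test_that("greedy search matches the exhaustive optimum on dominated instances", {
  set.seed(21)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:12) {
    n_rec <- sample(3:5, 1)
    planted <- paste0("M", paste(sample(aas, 8, replace = TRUE), collapse = ""))
    cand <- list()
    for (r in seq_len(n_rec)) {
      rid <- paste0("r", r)
      orfs <- list(make_orf(rid, planted, start = 3 * r))
      for (d in seq_len(sample(1:3, 1))) {
        decoy <- paste0("M", paste(sample(aas, sample(3:6, 1), replace = TRUE),
                                   collapse = ""))
        orfs[[length(orfs) + 1]] <- make_orf(rid, decoy, start = 100 + 10 * d)
      }
      cand[[rid]] <- orfs
    }
    top <- greedy_search(cand)[[1]]
    best <- exhaustive_best_path(cand)
    expect_equal(path_member_keys(top), best$keys)
    expect_equal(top$total_score, best$total, tolerance = 1e-9)
  }
})

test_that("recompute_score reproduces stored totals", {
  planted <- "MKLFAG"
  cand <- list(r1 = list(make_orf("r1", planted)),
               r2 = list(make_orf("r2", "MKLFAC")),
               r3 = list(make_orf("r3", "MKLFAG")),
               r4 = list(make_orf("r4", "MKIFAG")))
  for (p in greedy_search(cand)) {
    if (length(p$members) >= 2) {
      expect_equal(recompute_score(p), p$total_score, tolerance = 1e-9)
    }
  }
  one <- structure(list(members = list(make_orf("a", "MK"))),
                   class = "conserved_path")
  expect_error(recompute_score(one), "at least 2")
})

test_that("removing a decoy never decreases the top path score", {
  planted <- "MKLFAGSTV"
  cand <- list(
    r1 = list(make_orf("r1", planted), make_orf("r1", "MWYWY", 50)),
    r2 = list(make_orf("r2", planted)),
    r3 = list(make_orf("r3", planted), make_orf("r3", "MHHHH", 70)))
  with_decoys <- greedy_search(cand)[[1]]$total_score
  cand$r1 <- cand$r1[1]; cand$r3 <- cand$r3[1]
  without <- greedy_search(cand)[[1]]$total_score
  expect_gte(without, with_decoys - 1e-9)
})

test_that("results depend on record order, not record labels", {
  planted <- "MKLFAGSTV"
  mk <- function(ids) {
    out <- list()
    for (i in seq_along(ids)) {
      out[[ids[i]]] <- list(make_orf(ids[i], planted, 3 * i),
                            make_orf(ids[i], "MWWH", 90 + i))
    }
    out
  }
  p1 <- greedy_search(mk(c("x", "y", "z")))[[1]]
  p2 <- greedy_search(mk(c("n3", "n1", "n2")))[[1]]
  expect_equal(p1$total_score, p2$total_score)
  expect_equal(unname(vapply(p1$members, `[[`, integer(1), "start")),
               unname(vapply(p2$members, `[[`, integer(1), "start")))
})

test_that("nested same-stop variants collapse to one path", {
  # two near-duplicate candidates per record (long and nested short form)
  cand <- list()
  for (r in 1:3) {
    rid <- paste0("r", r)
    cand[[rid]] <- list(make_orf(rid, "MMKLFAGST", 0),
                        make_orf(rid, "MKLFAGST", 3))
  }
  paths <- greedy_search(cand)
  keys <- lapply(paths, path_member_keys)
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (a < b) {
        shared <- length(intersect(keys[[a]], keys[[b]])) /
          min(length(keys[[a]]), length(keys[[b]]))
        expect_lte(shared, 0.5)
      }
    }
  }
})
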