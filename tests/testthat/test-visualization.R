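skip_if_not_installed("xml2")

count_class <- function(path, class) {
  doc <- xml2::read_xml(path)
  length(xml2::xml_find_all(doc, sprintf("//*[@class='%s']", class)))
}

scan_fixture <- function(n = 3, seed = 9) {
  d <- generate_dataset(n_records = n, record_length = 300, mutation_rate = 0,
                        seed = seed)
  list(fit = uorf_scan(d$records), truth = d$truth)
}

test_that("annotation plot glyph counts match the input objects", {
  fx <- scan_fixture()
  fit <- fx$fit
  f <- withr::local_tempfile(fileext = ".svg")
  render_annotation_plot(fit$records, fit$paths, fit$candidates, f)
  expect_true(file.exists(f))
  doc <- xml2::read_xml(f)          # valid XML
  expect_equal(xml2::xml_name(doc), "svg")

  n_conserved <- sum(vapply(fit$paths, function(p) length(p$members),
                            integer(1)))
  expect_equal(count_class(f, "orf-conserved"), n_conserved)
  n_cand <- sum(lengths(fit$candidates))
  expect_equal(count_class(f, "orf-candidate"), n_cand - n_conserved)
  expect_equal(count_class(f, "track-ruler"), length(fit$records))
  expect_equal(count_class(f, "morf-start"), length(fit$records))
  # a path covering 2 of 3 records paints exactly 2 filled glyphs
  p2 <- fit$paths[[1]]
  p2$members <- p2$members[1:2]
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_annotation_plot(fit$records, list(p2), fit$candidates, f2)
  expect_equal(count_class(f2, "orf-conserved"), 2)
})

test_that("annotation plot requires something to draw", {
  rs <- upstream_set("a", "ACGTACGT")
  expect_error(render_annotation_plot(rs[integer(0)], list(), list(),
                                      tempfile()), "no records")
  expect_error(render_annotation_plot(rs, list(), list(a = list()),
                                      tempfile()), "nothing to plot")
})

test_that("logo rendering stacks letters per column in matrix order", {
  a <- center_star_msa(c(a = "MK", b = "MK", c = "MA"))
  lg <- logo_stats(a)
  f <- withr::local_tempfile(fileext = ".svg")
  render_logo(lg, f)
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "svg")
  # column 1 pure M -> 1 letter; column 2 is K/A split -> 2 letters
  expect_equal(count_class(f, "logo-letter"), 3)
  idx <- xml2::xml_text(xml2::xml_find_all(doc, "//*[@class='logo-col-index']"))
  expect_equal(idx, c("1", "2"))
  # zero-information column renders an empty stack
  lg0 <- logo_stats(center_star_msa(
    setNames(paste0("M", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
             paste0("s", 1:20))))
  f0 <- withr::local_tempfile(fileext = ".svg")
  render_logo(lg0, f0)
  letters0 <- xml2::xml_find_all(xml2::read_xml(f0),
                                 "//*[@class='logo-letter']")
  expect_equal(length(letters0), 1)   # only the pure M column draws
})

test_that("MSA panel renders one labeled row per sequence with distinct gaps", {
  a <- center_star_msa(c(r1 = "MKF", r2 = "MKF", r3 = "MK"))
  f <- withr::local_tempfile(fileext = ".svg")
  render_msa(a, f)
  doc <- xml2::read_xml(f)
  labels <- xml2::xml_text(xml2::xml_find_all(doc, "//*[@class='msa-label']"))
  expect_equal(labels, c("r1", "r2", "r3"))
  expect_equal(count_class(f, "msa-cell"), 8)   # 9 positions, 1 gap
  expect_equal(count_class(f, "msa-gap"), 1)
  # identical rows produce identical glyph sequences
  txt <- xml2::xml_find_all(doc, "//*[@class='msa-letter']")
  chars <- xml2::xml_text(txt)
  expect_equal(chars[1:3], chars[4:6])
})

test_that("all renders are byte-identical across repeated runs", {
  fx <- scan_fixture(seed = 13)
  fit <- fx$fit
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_annotation_plot(fit$records, fit$paths, fit$candidates, f1)
  render_annotation_plot(fit$records, fit$paths, fit$candidates, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  render_logo(fit$logos[[1]], f1)
  render_logo(fit$logos[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  render_msa(fit$alignments[[1]], f1)
  render_msa(fit$alignments[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})
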