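ref100 <- reference_index("toy", 100L)

test_that("a single aligned read produces unit start/end/coverage counts", {
  al <- data.frame(start = 10L, end = 20L, strand = "+")
  p <- count_read_ends(al, ref100, "plus", toy_meta())
  expect_equal(p$starts5[10], 1)
  expect_equal(p$ends3[20], 1)
  expect_equal(p$coverage, as.numeric(seq_len(100) %in% 10:20))
  expect_equal(sum(p$starts5), sum(p$ends3))
})

test_that("an empty alignment stream yields an all-zero, valid profile", {
  al <- data.frame(start = integer(0), end = integer(0),
                   strand = character(0))
  p <- count_read_ends(al, ref100, "plus", toy_meta())
  expect_true(all(p$coverage == 0))
  expect_true(validate_profile(p))
})

test_that("counting matches a brute-force per-position tally", {
  L <- 1000L
  al <- random_profile(L, 500L, seed = 42)
  p <- count_read_ends(al, reference_index("r", L), "plus", toy_meta())
  bf <- brute_force_profile(al$start, al$end, L)
  expect_equal(p$coverage, as.numeric(bf$coverage))
  expect_equal(p$starts5, as.numeric(bf$starts5))
  expect_equal(p$ends3, as.numeric(bf$ends3))
})

test_that("counting is permutation-invariant and conserves read length", {
  L <- 500L
  al <- random_profile(L, 200L, seed = 7, max_len = 55L)
  p1 <- count_read_ends(al, reference_index("r", L), "plus", toy_meta())
  p2 <- count_read_ends(al[sample.int(nrow(al)), ], reference_index("r", L),
                        "plus", toy_meta())
  expect_identical(p1$coverage, p2$coverage)
  expect_equal(sum(p1$coverage), sum(al$end - al$start + 1L))
})

test_that("antisense records are dropped with a count; minus-strand profiles use transcript-sense coordinates", {
  al <- data.frame(start = c(10L, 30L), end = c(20L, 40L),
                   strand = c("+", "-"))
  p <- count_read_ends(al, ref100, "plus", toy_meta())
  expect_equal(attr(p, "dropped_antisense"), 1L)
  expect_equal(sum(p$starts5), 1)
  # minus strand: read [30, 40] on '-' has transcript-sense 5' end at
  # reference 40, i.e. transcript position 100 - 40 + 1 = 61
  m <- count_read_ends(al, ref100, "minus", toy_meta())
  expect_equal(m$starts5[61], 1)
  expect_equal(m$ends3[71], 1)
  expect_true(validate_profile(m))
})

test_that("out-of-bounds records error on linear references and are skipped with a warning on circular ones", {
  al <- data.frame(start = c(10L, 95L), end = c(20L, 105L),
                   strand = c("+", "+"))
  expect_error(count_read_ends(al, ref100, "plus", toy_meta()),
               "outside reference bounds")
  circ <- reference_index("mt", 100L, circular = TRUE)
  expect_warning(p <- count_read_ends(al, circ, "plus", toy_meta()),
                 "origin-spanning")
  expect_equal(sum(p$starts5), 1)
  expect_equal(attr(p, "skipped_spanning"), 1L)
})

test_that("profile tables round-trip bit-exactly and reject malformed input", {
  al <- random_profile(300L, 100L, seed = 3)
  p <- count_read_ends(al, reference_index("r", 300L), "plus", toy_meta())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(p, path)
  q <- read_profile_table(path, reference_index("r", 300L), "plus",
                          toy_meta())
  expect_identical(q$coverage, p$coverage)
  expect_identical(q$starts5, p$starts5)
  expect_identical(q$ends3, p$ends3)

  # 1-based bound: a table starting at position 0 is a format error
  tab <- utils::read.delim(path, comment.char = "#")
  tab$position <- tab$position - 1L
  bad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profile_table(bad, meta = toy_meta()), "contiguous")

  # duplicate positions
  tab2 <- utils::read.delim(path, comment.char = "#")
  tab2$position[2] <- 1L
  utils::write.table(tab2, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profile_table(bad, meta = toy_meta()), "duplicate")
})

test_that("a perturbed coverage column is caught naming the first offending position", {
  df <- data.frame(position = 1:3, coverage = c(1, 1, 0),
                   starts5 = c(1, 0, 0), ends3 = c(0, 1, 0))
  df$coverage[2] <- 5   # violates C_2 = C_1 + S_2 - E_1
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profile_table(path, meta = toy_meta()),
               "position 2")
  # strict = FALSE recomputes coverage and succeeds
  p <- read_profile_table(path, meta = toy_meta(), strict = FALSE)
  expect_equal(p$coverage, c(1, 1, 0))
})

test_that("merging profiles is element-wise summation with identity and linearity", {
  L <- 200L
  al <- random_profile(L, 80L, seed = 5)
  p <- count_read_ends(al, reference_index("r", L), "plus", toy_meta("a"))
  zero <- count_read_ends(al[0, ], reference_index("r", L), "plus",
                          toy_meta("z"))
  m0 <- merge_profiles(list(p, zero))
  expect_equal(m0$coverage, p$coverage)
  m2 <- merge_profiles(list(p, p))
  expect_equal(m2$starts5, 2 * p$starts5)
  expect_equal(m2$coverage, 2 * p$coverage)
  expect_true(validate_profile(m2))
})

test_that("merging replicate profiles equals recounting the pooled read set", {
  L <- 400L
  als <- lapply(1:3, function(i) random_profile(L, 60L, seed = 100 + i))
  profs <- lapply(seq_along(als), function(i)
    count_read_ends(als[[i]], reference_index("r", L), "plus",
                    toy_meta(paste0("lane", i))))
  merged <- merge_profiles(profs)
  pooled <- count_read_ends(do.call(rbind, als), reference_index("r", L),
                            "plus", toy_meta("pooled"))
  expect_equal(merged$coverage, pooled$coverage)
  expect_equal(merged$starts5, pooled$starts5)
  expect_equal(merged$ends3, pooled$ends3)
  expect_error(
    merge_profiles(list(profs[[1]],
                        count_read_ends(als[[1]],
                                        reference_index("r", 500L), "plus",
                                        toy_meta()))),
    "different references")
})

test_that("profiles can be built from a SAM file with soft clips excluded", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:toy\tLN:100",
    # 5S soft clip: aligned reference span is [10, 19]
    "r1\t0\ttoy\t10\t60\t5S10M\t*\t0\t0\tACGTACGTACGTACG\t*",
    "r2\t0\ttoy\t30\t60\t11M\t*\t0\t0\tACGTACGTACG\t*",
    "r3\t16\ttoy\t50\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"), sam)
  p <- profile_from_bam(sam, ref100, "plus", toy_meta())
  expect_equal(p$starts5[10], 1)
  expect_equal(p$ends3[19], 1)
  expect_equal(p$starts5[30], 1)
  expect_equal(sum(p$starts5), 2)   # r3 is antisense
  expect_true(validate_profile(p))
})

test_that("library metadata enforces the dNTP/assay pairing", {
  expect_error(library_meta("x", assay = "cleavage", dntp = "low"),
               "iff assay")
  expect_error(library_meta("x", assay = "rtstop"), "iff assay")
  m <- library_meta("x", assay = "rtstop", dntp = "high")
  expect_equal(m$dntp, "high")
})
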