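# Worked clone examples built from the fixture exon sequences in the
# comma/slash notation of the cloning experiment.

fixture_clone <- function(...) {
  paste(vapply(c(...), fixture_exon, ""), collapse = "")
}

test_that("annotated clone paths classify as expected", {
  loc <- fixture_locus()
  div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)

  lin <- classify(decompose(fixture_clone(4, 5, 6), loc), div, loc)
  expect_equal(lin$category, "linear")
  expect_equal(lin$path_string, "4,5,6")

  c57 <- classify(decompose(paste0(fixture_clone(4, 5, 6),
                                   fixture_clone(2, 3, 4)), loc), div, loc)
  expect_equal(c57$category, "circ_consistent")
  expect_equal(c57$matched_circ, "circTRAM1-57")
  expect_equal(c57$path_string, "4,5,6/2,3,4")

  # reverse-complement clone: mirror notation 4,3/6,5,4
  read56 <- rc_chr(paste0(fixture_clone(4, 5, 6), fixture_clone(3, 4)))
  p56 <- decompose(read56, loc)
  c56 <- classify(p56, div, loc)
  expect_equal(c56$category, "circ_consistent")
  expect_equal(c56$matched_circ, "circTRAM1-56")
  expect_equal(c56$path_string, "4,5,6/3,4")
  expect_equal(path_string(p56, "as_read"), "4,3/6,5,4")
  expect_equal(p56$orientation, "reverse-complemented")

  # missing internal exon 5: not an authentic transcript
  skip5 <- classify(decompose(rc_chr(paste0(fixture_exon(4), fixture_exon(6),
                                            fixture_clone(3, 4))), loc),
                    div, loc)
  expect_equal(skip5$category, "artifact")
  expect_equal(skip5$reasons, "missing_internal_exon")

  # 4,3/5,4: back-splice 5 -> 3 matches no predicted circle
  r54 <- rc_chr(paste0(fixture_clone(4, 5), fixture_clone(3, 4)))
  plain <- classify(decompose(r54, loc), div, loc)
  expect_equal(plain$category, "artifact")
  expect_equal(plain$reasons, "inconsistent_bsj")

  # same path with a tandem primer duplication injected
  s <- rc_chr(r54)
  at <- regexpr(div$fwd$seq, s, fixed = TRUE)
  dup <- rc_chr(paste0(substr(s, 1, at + nchar(div$fwd$seq) - 1),
                       div$fwd$seq, substr(s, at + nchar(div$fwd$seq),
                                           nchar(s))))
  dupc <- classify(decompose(dup, loc), div, loc)
  expect_equal(dupc$category, "artifact")
  expect_equal(dupc$reasons, "primer_duplication")
})

test_that("classification is invariant under read orientation", {
  loc <- fixture_locus()
  div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)
  reads <- c(fixture_clone(4, 5, 6),
             paste0(fixture_clone(4, 5, 6), fixture_clone(2, 3, 4)),
             paste0(fixture_exon(4), fixture_exon(6), fixture_clone(3, 4)))
  for (r in reads) {
    a <- classify(decompose(r, loc), div, loc)
    b <- classify(decompose(rc_chr(r), loc), div, loc)
    expect_equal(a$category, b$category)
    expect_equal(a$matched_circ, b$matched_circ)
    expect_equal(a$path_string, b$path_string)
  }
})

test_that("junctions shifted off the exon boundary become non-splice", {
  loc <- fixture_locus()
  r <- paste0(fixture_clone(4, 5, 6), fixture_clone(3, 4))
  # delete the first base of the acceptor exon at the back-splice
  cut <- nchar(fixture_clone(4, 5, 6))
  shifted <- paste0(substr(r, 1, cut), substr(r, cut + 2, nchar(r)))
  p <- decompose(shifted, loc)
  bs <- p$junctions[p$junctions$from_exon == 6, ]
  expect_equal(bs$type, "non_splice")
  expect_equal(nrow(detect_bsj(p, loc)), 0)
})

test_that("decompose matches the exhaustive fragment-placement oracle", {
  loc <- fixture_locus()
  ex_seqs <- vapply(1:11, fixture_exon, "")
  set.seed(13)
  for (rep in 1:40) {
    nfrag <- sample(1:5, 1)
    frags <- vapply(seq_len(nfrag), function(i) {
      e <- sample(1:8, 1)
      len <- nchar(ex_seqs[e])
      a <- sample(1:max(1, len - 30), 1)
      b <- min(len, a + sample(20:150, 1))
      substr(ex_seqs[e], a, b)
    }, "")
    read <- paste(frags, collapse = "")
    if (nchar(read) < 40) next
    got <- decompose(read, loc)
    segs <- oracle_chain(oracle_segments(read, ex_seqs, seed = 15L))
    mb <- if (is.null(segs)) 0L else sum(segs$read_end - segs$read_start + 1L)
    # optimal chains can tie; total optimal coverage is the invariant
    expect_equal(got$matched_bases, mb, label = paste("rep", rep))
    # and every reported segment must be a genuine exact match
    for (si in seq_len(nrow(got$segments))) {
      sg <- got$segments[si, ]
      expect_identical(substr(read, sg$read_start, sg$read_end),
                       substr(ex_seqs[sg$exon], sg$exon_start, sg$exon_end))
    }
  }
})

test_that("reads with no exon hit are foreign; partial foreign gaps are artifacts", {
  loc <- fixture_locus()
  set.seed(14)
  noise <- rand_dna(200)
  f <- classify(decompose(noise, loc), NULL, loc)
  expect_equal(f$category, "foreign")
  half <- paste0(fixture_clone(4, 5), rand_dna(80))
  h <- classify(decompose(half, loc), NULL, loc)
  expect_equal(h$category, "artifact")
  expect_equal(h$reasons, "sequence_deviation")
})

test_that("zero-artifact libraries classify with full agreement", {
  cfg <- synthesis_config(seed = 21,
                          clone_mix = c(linear = 0.4, circB = 0.35,
                                        circC = 0.25))
  loc <- make_locus(cfg)
  div <- design_divergent_pair("circB", loc, exon = 4L)
  lib <- make_clone_library(cfg, loc, div, n = 80)
  expect_equal(nrow(lib$truth), 80)
  expect_true(all(!is.na(lib$truth$category)))
  calls <- lapply(lib$reads, function(r) classify(decompose(r, loc), div, loc))
  pred <- vapply(calls, `[[`, "", "category")
  expect_equal(unname(pred), lib$truth$category)
  circ_pred <- vapply(calls, function(x) x$matched_circ %||% NA_character_, "")
  idx <- lib$truth$category == "circ_consistent"
  expect_equal(unname(circ_pred[idx]), lib$truth$circ[idx])
})

test_that("summaries are permutation invariant and percentages sum to 100", {
  cfg <- synthesis_config(seed = 22)
  loc <- make_locus(cfg)
  div <- design_divergent_pair("circB", loc, exon = 4L)
  lib <- make_clone_library(cfg, loc, div, n = 50)
  calls <- lapply(lib$reads, function(r) classify(decompose(r, loc), div, loc))
  s1 <- summarize_calls(calls)
  s2 <- summarize_calls(calls[sample(length(calls))])
  expect_equal(sum(s1$by_category$percent), 100)
  expect_equal(sum(s1$by_path$percent), 100)
  o1 <- s1$by_category[order(s1$by_category$category), ]
  o2 <- s2$by_category[order(s2$by_category$category), ]
  expect_equal(o1, o2)
  # all-one-category degenerate case
  s3 <- summarize_calls(rep(list(structure(list(category = "linear",
                                                matched_circ = NA,
                                                reasons = character(0),
                                                path_string = "4,5"),
                                           class = "clone_call")), 10))
  expect_equal(nrow(s3$by_category), 1)
  expect_equal(s3$by_category$percent, 100)
  expect_equal(nrow(summarize_calls(list())$by_category), 0)
})
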