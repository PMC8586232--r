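test_that("rolling-circle cDNA tiles a rotation of the circle", {
  loc <- fixture_locus()
  cs <- circ_sequence("circTRAM1-56", loc)
  expect_identical(rolling_circle_cdna(cs, 1, 0)$seq, cs)
  expect_equal(nchar(rolling_circle_cdna(cs, 3, 0)$seq), 3 * 383)
  expect_error(rolling_circle_cdna(cs, 0), "repeats")
  expect_error(rolling_circle_cdna(cs, 2, nchar(cs)), "offset")
})

test_that("BSJ k-mer counts on concatemers match exhaustive substring counts", {
  set.seed(5)
  loc <- make_locus(synthesis_config(seed = 205))
  cs <- circ_sequence("circB", loc)
  km <- bsj_kmer("circB", loc, 12)
  count <- function(hay) {
    m <- gregexpr(km, hay, fixed = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  L <- nchar(cs)
  for (repeats in 1:4) for (offset in c(0L, 5L, 11L, 12L, 200L, L - 12L,
                                        L - 7L)) {
    conc <- rolling_circle_cdna(cs, repeats, offset)
    counted <- count(conc$seq)  # the exhaustive substring-count oracle
    # the junction context sits inside each tile; the terminal tiles carry
    # it completely only when the rotation leaves k = 12 bases on each side
    predicted <- (repeats - 1L) + as.integer(offset >= 12L &&
                                               offset <= L - 12L)
    expect_equal(counted, predicted,
                 label = paste("repeats", repeats, "offset", offset))
  }
})

test_that("binding sites honor the 3'-seed rule", {
  set.seed(6)
  tpl <- new_template("t", rand_dna(400))
  probe <- substr(tpl$seq, 101, 120)
  p <- new_primer("p", probe)
  sites <- find_binding_sites(p, tpl)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$start, 101)
  expect_equal(sites$strand, "+")
  # a mismatch inside the 3' seed kills binding even with budget left
  chars <- strsplit(probe, "")[[1]]
  chars[18] <- setdiff(c("A", "C", "G", "T"), chars[18])[1]
  p_bad <- new_primer("pb", paste(chars, collapse = ""))
  expect_equal(nrow(find_binding_sites(p_bad, tpl, max_mismatch_5prime = 3)), 0)
  # reverse-strand binding of the reverse complement
  p_rc <- new_primer("prc", rc_chr(probe))
  sites_rc <- find_binding_sites(p_rc, tpl)
  expect_equal(sites_rc$strand, "-")
  expect_equal(sites_rc$start, 101)
})

test_that("binding-site lists equal the naive all-positions scan", {
  set.seed(7)
  for (rep in 1:10) {
    tpl <- new_template("t", rand_dna(300))
    # primers related to the template so that near-matches exist
    base <- substr(tpl$seq, sample(1:280, 1), 1000)
    primer_seq <- substr(base, 1, 18)
    if (rep %% 2 == 0) {
      chars <- strsplit(primer_seq, "")[[1]]
      i <- sample(1:8, 1)  # mutate a 5' position
      chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
      primer_seq <- paste(chars, collapse = "")
    }
    p <- new_primer("p", primer_seq)
    got <- find_binding_sites(p, tpl)
    want <- brute_sites(primer_seq, tpl$seq)
    got <- got[order(got$start, got$strand), ]
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("pair orientation is a geometric dichotomy", {
  set.seed(8)
  ref <- rand_dna(500)
  fwd <- new_primer("f", substr(ref, 100, 119))
  rev <- new_primer("r", rc_chr(substr(ref, 181, 200)))
  pair <- new_primer_pair(fwd, rev)
  expect_equal(classify_pair_orientation(pair, ref), "convergent")
  # mirrored placement: forward downstream of the reverse site
  fwd2 <- new_primer("f2", substr(ref, 300, 319))
  rev2 <- new_primer("r2", rc_chr(substr(ref, 100, 119)))
  expect_equal(classify_pair_orientation(new_primer_pair(fwd2, rev2), ref),
               "divergent")
  # no binding at all
  expect_equal(classify_pair_orientation(
    new_primer_pair(new_primer("x", strrep("ACGT", 5)), fwd), ref),
    "invalid")
})

test_that("swapping binding positions maps convergent to divergent on random loci", {
  set.seed(9)
  for (rep in 1:20) {
    ref <- rand_dna(400)
    a <- sample(50:150, 1)
    b <- sample(250:350, 1)
    fwd <- new_primer("f", substr(ref, a, a + 19))
    rev <- new_primer("r", rc_chr(substr(ref, b, b + 19)))
    expect_equal(classify_pair_orientation(new_primer_pair(fwd, rev), ref),
                 "convergent")
    fwd_sw <- new_primer("f", substr(ref, b, b + 19))
    rev_sw <- new_primer("r", rc_chr(substr(ref, a, a + 19)))
    expect_equal(classify_pair_orientation(new_primer_pair(fwd_sw, rev_sw),
                                           ref), "divergent")
  }
})

test_that("divergent pairs amplify circles but not linear or genomic templates", {
  loc <- fixture_locus()
  div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)
  lin <- new_template("parent", spliced_sequence("TRAM1-201", loc), "linear")
  expect_equal(nrow(predict_amplicons(div, lin)), 0)
  g <- new_template("gDNA", loc$sequence, "genomic")
  expect_equal(nrow(predict_amplicons(div, g)), 0)
  for (id in names(loc$circRNAs)) {
    ct <- new_template(id, circ_sequence(id, loc, warn_declared = FALSE),
                       "circular")
    amps <- predict_amplicons(div, ct)
    expect_equal(nrow(amps), 1)
    expect_true(amplicon_contains_bsj(amps$seq, bsj_kmer(id, loc, 10)))
  }
})

test_that("concatemer products equal brute-force site-pair enumeration", {
  loc <- fixture_locus()
  div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)
  cs <- circ_sequence("circTRAM1-56", loc)
  for (repeats in 2:4) {
    conc <- rolling_circle_cdna(cs, repeats, 0)
    got <- sort(predict_amplicons(div, conc, max_len = 3000)$length)
    want <- brute_amplicons(div, conc$seq, max_len = 3000)
    expect_equal(got, want, label = paste("repeats", repeats))
    # ladder structure: lengths are L + m * circle_len
    expect_true(all((got - min(got)) %% nchar(cs) == 0))
  }
})

test_that("engineered genomic exon duplication flips the tandem-repeat verdict", {
  loc <- fixture_locus()
  div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)
  g <- new_template("gDNA", loc$sequence, "genomic")
  rep1 <- tandem_repeat_check(list(div), g)
  expect_equal(rep1$verdict, "no genomic origin")
  # duplicate the exon-4 genomic block in tandem
  t <- loc$transcripts[["TRAM1-201"]]
  e4 <- t$exons[t$exons$index == 4, ]
  block <- substr(loc$sequence, e4$start, e4$end)
  dup <- paste0(substr(loc$sequence, 1, e4$end), block,
                substr(loc$sequence, e4$end + 1, nchar(loc$sequence)))
  g2 <- new_template("gDNA_dup", dup, "genomic")
  rep2 <- tandem_repeat_check(list(div), g2)
  expect_equal(rep2$verdict, "possible tandem repeat")
  got <- sort(attr(rep2, "amplicons")[[1]]$length)
  want <- brute_amplicons(div, dup)
  expect_equal(got, want)
})

test_that("convergent genomic products include the intron", {
  loc <- fixture_locus()
  conv <- design_convergent_pair("TRAM1-201", loc,
                                 placement = "cross_intron",
                                 anchor_exon = 4L)
  lin <- new_template("parent", spliced_sequence("TRAM1-201", loc), "linear")
  g <- new_template("gDNA", loc$sequence, "genomic")
  spliced_len <- predict_amplicons(conv, lin)$length
  genomic_len <- predict_amplicons(conv, g)$length
  intr <- transcript_introns("TRAM1-201", loc)
  i4 <- intr[intr$index == 4, ]
  expect_equal(genomic_len, spliced_len + (i4$end - i4$start + 1))
})

test_that("divergent pairs never amplify non-repetitive linear templates (seeded loci)", {
  for (seed in 1:15) {
    loc <- make_locus(synthesis_config(seed = 400 + seed))
    div <- design_divergent_pair("circB", loc, exon = 4L)
    if (is.null(div)) next
    lin <- new_template("parent", spliced_sequence("TX1", loc), "linear")
    expect_equal(nrow(predict_amplicons(div, lin)), 0,
                 label = paste("seed", 400 + seed))
    conv <- design_convergent_pair("TX1", loc, placement = "same_exon",
                                   anchor_exon = 4L)
    if (!is.null(conv)) {
      amps <- predict_amplicons(conv, lin)
      for (id in names(loc$circRNAs)) {
        km <- bsj_kmer(id, loc, 10)
        expect_false(any(vapply(amps$seq, amplicon_contains_bsj, TRUE,
                                bsj = km)))
      }
    }
  }
})

test_that("primer tables round trip through the TSV interchange format", {
  loc <- fixture_locus()
  div <- design_divergent_pair("circTRAM1-58", loc, exon = 4L)
  conv <- design_convergent_pair("TRAM1-201", loc,
                                 placement = "cross_intron",
                                 anchor_exon = 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_primer_tsv(list(div, conv), path)
  back <- read_primer_tsv(path)
  expect_setequal(names(back), c(div$pair_id, conv$pair_id))
  expect_identical(back[[div$pair_id]]$fwd$seq, div$fwd$seq)
  expect_identical(back[[conv$pair_id]]$rev$seq, conv$rev$seq)
  # malformed table: two forward primers in one pair
  bad <- data.frame(name = c("a", "b"), sequence = c("ACGTACGTACGTACGTAC",
                                                     "ACGTACGTACGTACGTAC"),
                    role = c("fwd", "fwd"), pair_id = "p")
  bp <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, bp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_primer_tsv(bp), "exactly one")
})
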