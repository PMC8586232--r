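test_that("GFF3 loading assigns transcript-order exon indices per strand", {
  dir <- withr::local_tempdir()
  seqn <- "AAACCCGGGTTTAAACCCGGGTTTAAACCCGGGTTTAAAC"
  fa <- file.path(dir, "locus.fa")
  writeLines(c(">toy", seqn), fa)
  gff_lines <- function(strand) c(
    "##gff-version 3",
    paste("toy", "src", "mRNA", 1, 40, ".", strand, ".", "ID=t1", sep = "\t"),
    paste("toy", "src", "exon", 3, 8, ".", strand, ".", "Parent=t1", sep = "\t"),
    paste("toy", "src", "exon", 15, 20, ".", strand, ".", "Parent=t1", sep = "\t"),
    paste("toy", "src", "exon", 30, 36, ".", strand, ".", "Parent=t1", sep = "\t"))
  gp <- file.path(dir, "plus.gff3")
  writeLines(gff_lines("+"), gp)
  lp <- load_locus(fa, gp)
  expect_equal(lp$transcripts[["t1"]]$exons$start, c(3, 15, 30))
  expect_equal(lp$transcripts[["t1"]]$exons$index, 1:3)

  gm <- file.path(dir, "minus.gff3")
  writeLines(gff_lines("-"), gm)
  lm <- load_locus(fa, gm)
  expect_equal(lm$transcripts[["t1"]]$exons$start, c(30, 15, 3))
  expect_equal(lm$transcripts[["t1"]]$exons$index, 1:3)

  # spliced sequences are reverse complements of each other
  expect_identical(spliced_sequence("t1", lm),
                   rc_chr(spliced_sequence("t1", lp)))
})

test_that("invalid annotations are rejected with diagnostics", {
  expect_error(new_transcript("t", data.frame(start = c(1, 5),
                                              end = c(6, 9)), "+"),
               "overlapping exons")
  expect_error(new_transcript("t", data.frame(start = 1, end = 5), "x"),
               "unknown strand")
  expect_error(new_transcript("t", data.frame(start = integer(0),
                                              end = integer(0)), "+"),
               "zero exons")
  tx <- new_transcript("t", data.frame(start = 5, end = 50), "+")
  expect_error(new_gene_locus("g", "ACGTACGT", "+", list(tx)),
               "outside locus")
})

test_that("fixture spliced and circular lengths equal exon-length sums", {
  loc <- fixture_locus()
  t201 <- loc$transcripts[["TRAM1-201"]]
  lens <- t201$exons$end - t201$exons$start + 1
  expect_equal(nchar(spliced_sequence("TRAM1-201", loc)), sum(lens))
  expect_equal(nchar(spliced_sequence("TRAM1-201", loc)), 3056)
  # all circles: computed length equals declared annotation length
  for (cc in loc$circRNAs) {
    span <- seq(cc$acceptor_exon, cc$donor_exon)
    expect_equal(nchar(circ_sequence(cc, loc)),
                 sum(lens[t201$exons$index %in% span]))
    expect_equal(nchar(circ_sequence(cc, loc)), cc$declared_length)
  }
})

test_that("spliced sequence equals brute-force per-base extraction", {
  set.seed(11)
  for (strand in c("+", "-")) {
    cfg <- synthesis_config(seed = 101, strand = strand)
    loc <- make_locus(cfg)
    t <- loc$transcripts[["TX1"]]
    oracle <- vapply(t$exons$index, function(i) {
      e <- t$exons[t$exons$index == i, ]
      raw <- substr(loc$sequence, e$start, e$end)
      if (strand == "-") rc_chr(raw) else raw
    }, "")
    expect_identical(spliced_sequence(t, loc), paste(oracle, collapse = ""))
  }
})

test_that("circle rotation starts at the acceptor exon; declared-length mismatch warns", {
  loc <- fixture_locus()
  cs <- circ_sequence("circTRAM1-56", loc)
  expect_identical(substr(cs, 1, 87), fixture_exon(3))
  expect_identical(substr(cs, 384 - 120, 383), fixture_exon(6))
  # single-exon circle equals that exon
  one <- new_circ_rna("one", "TRAM1-201", 4, 4)
  loc2 <- new_gene_locus(loc$name, loc$sequence, loc$strand,
                         loc$transcripts, list(one))
  expect_identical(circ_sequence("one", loc2), fixture_exon(4))
  bad <- new_circ_rna("bad", "TRAM1-201", 4, 4, declared_length = 999)
  loc3 <- new_gene_locus(loc$name, loc$sequence, loc$strand,
                         loc$transcripts, list(bad))
  expect_warning(circ_sequence("bad", loc3), "declared length")
})

test_that("BSJ 2k-mer joins donor end to acceptor start and is circle specific", {
  loc <- fixture_locus()
  e6 <- fixture_exon(6)
  e3 <- fixture_exon(3)
  expect_identical(bsj_kmer("circTRAM1-56", loc, 1),
                   paste0(substr(e6, 120, 120), substr(e3, 1, 1)))
  k15 <- bsj_kmer("circTRAM1-56", loc, 15)
  cs <- circ_sequence("circTRAM1-56", loc)
  expect_gte(length(gregexpr(k15, strrep(cs, 2), fixed = TRUE)[[1]]), 1)
  expect_false(grepl(k15, spliced_sequence("TRAM1-201", loc), fixed = TRUE))
  expect_error(bsj_kmer("circTRAM1-56", loc, 500), "exceeds")
})

test_that("BSJ k-mer uniqueness holds across random repeat-free loci", {
  for (seed in 1:20) {
    loc <- make_locus(synthesis_config(seed = 3000 + seed))
    for (id in names(loc$circRNAs)) {
      km <- bsj_kmer(id, loc, 15)
      expect_false(grepl(km, spliced_sequence("TX1", loc), fixed = TRUE),
                   label = paste("seed", seed, id))
      expect_true(grepl(km, strrep(circ_sequence(id, loc), 2), fixed = TRUE))
    }
  }
})

test_that("strand round-trip: flipping genome and strand preserves spliced sequences", {
  loc <- make_locus(synthesis_config(seed = 77, strand = "+"))
  t <- loc$transcripts[["TX1"]]
  n <- nchar(loc$sequence)
  flipped_exons <- data.frame(start = n - t$exons$end + 1,
                              end = n - t$exons$start + 1)
  t2 <- new_transcript("TX1", flipped_exons, "-")
  loc2 <- new_gene_locus("flipped", rc_chr(loc$sequence), "-", list(t2))
  expect_identical(spliced_sequence("TX1", loc2), spliced_sequence("TX1", loc))
})

test_that("JSON round trip preserves the full locus model", {
  loc <- fixture_locus()
  path <- withr::local_tempfile(fileext = ".json")
  write_locus_json(loc, path)
  loc2 <- read_locus_json(path)
  expect_identical(loc2$sequence, loc$sequence)
  expect_identical(names(loc2$transcripts), names(loc$transcripts))
  expect_identical(spliced_sequence("TRAM1-205", loc2),
                   spliced_sequence("TRAM1-205", loc))
  expect_identical(circ_sequence("circTRAM1-57", loc2),
                   circ_sequence("circTRAM1-57", loc))
  expect_equal(loc2$circRNAs[["circTRAM1-57"]]$declared_length, 447)
})

test_that("locus FASTA/GFF files round trip through load_locus", {
  loc <- fixture_locus()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "locus.fa")
  gff <- file.path(dir, "locus.gff3")
  write_locus_files(loc, fa, gff)
  loc2 <- load_locus(fa, gff)
  expect_identical(spliced_sequence("TRAM1-201", loc2),
                   spliced_sequence("TRAM1-201", loc))
  expect_identical(spliced_sequence("TRAM1-204", loc2),
                   spliced_sequence("TRAM1-204", loc))
})
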