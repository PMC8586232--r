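#' The bundled TRAM1-like fixture locus
#'
#' A fully synthetic stand-in for the TRAM1 gene locus used throughout the
#' examples and tests: 11 exons on the reverse strand, five linear splice
#' variants and four predicted circRNAs whose exon architectures and mature
#' lengths reproduce the annotated ones (circTRAM1-58 = exons 4-5 / 176 nt,
#' circTRAM1-56 = exons 3-6 / 383 nt, circTRAM1-57 = exons 2-6 / 447 nt,
#' circTRAM1-59 = exons 1-5 / 422 nt; linear lengths 542 / 3394 / 3056 /
#' 872 / 535). The exon memberships of circTRAM1-58 and circTRAM1-59 are an
#' inference from their annotated flanking introns (introns 3/5 and -/5),
#' not an annotated fact. Sequences are random (fixed internal seed), so
#' coordinate- and sequence-level results are synthetic; exon-arithmetic
#' results (lengths, junction indices, flanking-intron indices) mirror the
#' real locus. Inverse-complementary segments are planted into the flanking
#' intron pairs of circTRAM1-56 (introns 2/6) and circTRAM1-57 (introns
#' 1/6), emulating the repeats reported for the real introns; the flanks of
#' circTRAM1-58 and circTRAM1-59 are left plain.
#'
#' @return A `gene_locus`.
#' @export
tram1_fixture_locus <- function() {
  set.seed(20210756L)
  ex_len <- c(95L, 64L, 87L, 90L, 86L, 120L, 150L, 200L, 180L, 184L, 1800L)
  in_len <- c(1300L, 1300L, 250L, 300L, 400L, 2600L, 250L, 250L, 300L, 350L)
  gc <- 0.45
  ex_seq <- vapply(ex_len, random_dna, "", gc = gc)
  in_seq <- vapply(in_len, random_dna, "", gc = gc)

  plant <- function(intr_up, intr_dn, len, identity, at_up, at_dn) {
    core <- random_dna(len, gc)
    splice_in <- function(s, seg, at)
      paste0(substr(s, 1, at - 1L), seg, substr(s, at + nchar(seg), nchar(s)))
    in_seq[intr_up] <<- splice_in(in_seq[intr_up], core, at_up)
    in_seq[intr_dn] <<- splice_in(in_seq[intr_dn],
                                  mutate_seq(revcomp(core), 1 - identity),
                                  at_dn)
  }
  # circTRAM1-56 flanks (introns 2/6): three inverse-complementary segments
  plant(2L, 6L, 334L, 0.674, 20L, 20L)
  plant(2L, 6L, 351L, 0.652, 400L, 400L)
  plant(2L, 6L, 465L, 0.619, 800L, 800L)
  # circTRAM1-57 flanks (introns 1/6)
  plant(1L, 6L, 389L, 0.702, 20L, 1300L)
  plant(1L, 6L, 346L, 0.688, 450L, 1750L)
  plant(1L, 6L, 375L, 0.683, 850L, 2150L)

  pre <- paste(c(rbind(ex_seq, c(in_seq, ""))), collapse = "")
  L <- nchar(pre)
  flank5 <- random_dna(300L, gc)
  flank3 <- random_dna(300L, gc)
  # reverse-strand gene: transcript-sense pre-mRNA reverse-complemented onto
  # the chromosome forward strand, exon 1 at the highest coordinates
  genome <- paste0(flank3, revcomp(pre), flank5)
  starts <- cumsum(c(1L, utils::head(ex_len + c(in_len, 0L), -1L)))
  ends <- starts + ex_len - 1L
  g_start <- 300L + (L - ends + 1L)
  g_end <- 300L + (L - starts + 1L)
  exon_iv <- function(idx) data.frame(start = g_start[idx], end = g_end[idx])

  tx <- list(
    new_transcript("TRAM1-201", exon_iv(1:11), "-", name = "TRAM1-201",
                   biotype = "protein-coding", tsl = 1L),
    new_transcript("TRAM1-203", exon_iv(1:6), "-", name = "TRAM1-203",
                   biotype = "processed-transcript", tsl = 5L),
    local({
      iv <- exon_iv(1:11)
      iv$end[1] <- iv$end[1] + 138L    # 5' extension (higher coordinate)
      iv$start[11] <- iv$start[11] - 200L  # 3' extension
      new_transcript("TRAM1-205", iv, "-", name = "TRAM1-205",
                     biotype = "protein-coding", tsl = 2L)
    }),
    local({
      iv <- exon_iv(4:10)
      iv$start[7] <- iv$end[7] - 46L + 1L  # 3'-truncated last exon
      new_transcript("TRAM1-204", iv, "-", name = "TRAM1-204",
                     biotype = "processed-transcript", tsl = 5L)
    }),
    local({
      iv <- exon_iv(1:5)
      iv$start[5] <- iv$start[5] - 113L    # last exon read into intron 5
      new_transcript("TRAM1-202", iv, "-", name = "TRAM1-202",
                     biotype = "protein-coding", tsl = 4L)
    }))

  circs <- list(
    new_circ_rna("circTRAM1-58", "TRAM1-201", 4L, 5L, 176L),
    new_circ_rna("circTRAM1-56", "TRAM1-201", 3L, 6L, 383L),
    new_circ_rna("circTRAM1-57", "TRAM1-201", 2L, 6L, 447L),
    new_circ_rna("circTRAM1-59", "TRAM1-201", 1L, 5L, 422L))

  new_gene_locus("TRAM1_fixture", genome, "-", tx, circs)
}

#' Packaged TRAM1 expression and nuclease tables
#'
#' Three plain-text tables shipped with the package: pooled urine TPM per
#' transcript and donor group (`urine_tpm`), qPCR copies with and without
#' RNase R (`rnase_r`), and 18S-normalized cell-line expression
#' (`cell_lines`).
#'
#' @param which One of `"urine_tpm"`, `"rnase_r"`, `"cell_lines"`.
#' @return A data frame.
#' @export
tram1_tables <- function(which = c("urine_tpm", "rnase_r", "cell_lines")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("tram1_", which, ".tsv"),
                   package = "circvalid", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Candidate pools of the TRAM1 marker analysis
#'
#' The linear pool holds the three transcripts targeted by the convergent
#' primer pair (those with negative lg10 fold change); the circular pool
#' holds all four predicted circRNAs, jointly targeted by the divergent
#' pair.
#'
#' @return Named list of character vectors.
#' @export
tram1_pools <- function() {
  list(linear = c("TRAM1-203", "TRAM1-205", "TRAM1-201"),
       circular = c("circTRAM1-58", "circTRAM1-56", "circTRAM1-57",
                    "circTRAM1-59"))
}
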