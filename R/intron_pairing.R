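#' Inverse-complementarity of introns flanking a circRNA
#'
#' Base pairing between the introns flanking a back-spliced exon block can
#' bring the splice sites into spatial proximity and thereby favour circRNA
#' biogenesis. This module scores that signal: the upstream flanking intron
#' is locally aligned against the reverse complement of the downstream one
#' (Smith-Waterman with affine gaps; non-intersecting top-k alignments by
#' Waterman-Eggert masking). Scoring defaults: match +5, mismatch -4, first
#' gap base -12, each further gap base -4. Percent identity is computed over
#' all alignment columns, gap columns included.
#'
#' @name intron_pairing
NULL

#' Flanking introns of a circRNA
#'
#' Upstream = the intron preceding the acceptor exon in transcript order
#' (`NULL` when the acceptor is exon 1); downstream = the intron following
#' the donor exon (`NULL` when the donor is the last exon).
#'
#' @param circ A `circ_rna` or its id.
#' @param locus The `gene_locus`.
#' @return List with elements `upstream` and `downstream`, each `NULL` or a
#'   list `(index, start, end, seq)` with `seq` in transcript sense.
#' @export
flanking_introns <- function(circ, locus) {
  cc <- resolve_circ(locus, circ)
  t <- resolve_transcript(locus, cc$parent)
  iv <- transcript_introns(t, locus)
  n_ex <- nrow(t$exons)
  grab <- function(i) {
    row <- iv[iv$index == i, ]
    if (nrow(row) != 1L) return(NULL)
    list(index = i, start = row$start, end = row$end,
         seq = intron_sequence(locus, t, i))
  }
  list(upstream = if (cc$acceptor_exon > 1L) grab(cc$acceptor_exon - 1L),
       downstream = if (cc$donor_exon < n_ex) grab(cc$donor_exon))
}

#' Top-k local alignments of one sequence against the reverse complement of
#' another
#'
#' @param a,b Nonempty DNA sequences; `b` is reverse-complemented before
#'   alignment, so high-scoring alignments are inverse-complementary
#'   stretches of the two inputs.
#' @param k Number of non-intersecting alignments to report.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters; `gap_open` is
#'   the cost of the first base of a gap, `gap_ext` of each additional base
#'   (both given as positive penalties). The defaults (+5/-4, gap -12/-4)
#'   keep local alignment of unrelated DNA in the logarithmic regime; a
#'   cheaper gap extension makes random alignments grow without bound.
#' @return Data frame with columns `score`, `length` (alignment columns),
#'   `matches`, `identity` (percent over all columns), `a_start`, `a_end`
#'   (positions on `a`), `b_start`, `b_end` (positions on the original
#'   orientation of `b`) and the aligned strings `a_aln`, `b_aln` (the
#'   latter in reverse-complement orientation); zero rows when no
#'   positive-scoring alignment exists.
#' @export
rc_local_align <- function(a, b, k = 3L, match = 5L, mismatch = 4L,
                           gap_open = 12L, gap_ext = 4L) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
  brc <- revcomp(b)
  res <- sw_topk_cpp(toupper(a), brc, as.integer(match), -abs(as.integer(mismatch)),
                     abs(as.integer(gap_open)), abs(as.integer(gap_ext)),
                     as.integer(k))
  if (length(res) == 0L)
    return(data.frame(score = integer(0), length = integer(0),
                      matches = integer(0), identity = numeric(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      a_aln = character(0), b_aln = character(0)))
  nb <- nchar(b)
  out <- do.call(rbind, lapply(res, function(x) {
    data.frame(score = x$score, length = x$length, matches = x$matches,
               identity = x$identity, a_start = x$a_start, a_end = x$a_end,
               b_start = nb - x$b_end + 1L, b_end = nb - x$b_start + 1L,
               a_aln = x$a_aln, b_aln = x$b_aln)
  }))
  out[order(-out$score), , drop = FALSE]
}

#' Flanking-intron complementarity report for a circRNA
#'
#' Aligns the upstream flanking intron against the reverse complement of the
#' downstream one and reports the `top` best non-intersecting alignments,
#' plus a count of further alignments passing the listing floor
#' (`min_len` nt and `min_identity` percent). Because Smith-Waterman always
#' returns some positive-scoring stretch even between unrelated sequences,
#' alignments are additionally screened against a seeded permutation null:
#' an alignment is reportable only if its score exceeds every top score
#' obtained after shuffling the downstream intron (`n_perm` shuffles, giving
#' a ~1/(n_perm+1) false-positive rate for the best hit). circRNAs lacking
#' a flanking intron on either side get status `"no flanking pair"`.
#'
#' @param circ A `circ_rna` or its id.
#' @param locus The `gene_locus`.
#' @param top Number of alignments listed in full (default 3).
#' @param min_len,min_identity Listing floor for the "further alignments"
#'   count (defaults 50 nt, 55 percent).
#' @param k_scan How many non-intersecting alignments to compute in total.
#' @param n_perm Permutation-null size (0 disables the significance
#'   screen).
#' @param null_seed Seed for the permutation null (the caller's RNG state
#'   is untouched).
#' @inheritParams rc_local_align
#' @return A `flanking_intron_report`: list with `circ_id`, `status`,
#'   `upstream`, `downstream` (intron descriptors), `alignments` (top data
#'   frame), `n_further`, `further_range` (length and identity ranges),
#'   `null_score` (the permutation threshold).
#' @export
pairing_report <- function(circ, locus, top = 3L, min_len = 50L,
                           min_identity = 55, k_scan = 25L, n_perm = 20L,
                           null_seed = 1L, match = 5L,
                           mismatch = 4L, gap_open = 12L, gap_ext = 4L) {
  cc <- resolve_circ(locus, circ)
  fl <- flanking_introns(cc, locus)
  rep0 <- list(circ_id = cc$id, upstream = fl$upstream,
               downstream = fl$downstream)
  if (is.null(fl$upstream) || is.null(fl$downstream)) {
    rep0$status <- "no flanking pair"
    rep0$alignments <- rc_local_align("A", "T", k = 0L)[0, ]
    rep0$n_further <- 0L
    class(rep0) <- "flanking_intron_report"
    return(rep0)
  }
  aln <- rc_local_align(fl$upstream$seq, fl$downstream$seq, k = k_scan,
                        match = match, mismatch = mismatch,
                        gap_open = gap_open, gap_ext = gap_ext)
  null_score <- 0
  if (n_perm > 0L) {
    dn <- strsplit(fl$downstream$seq, "")[[1]]
    null_score <- with_seed(null_seed, {
      max(vapply(seq_len(n_perm), function(i) {
        shuf <- paste(sample(dn), collapse = "")
        a1 <- rc_local_align(fl$upstream$seq, shuf, k = 1L, match = match,
                             mismatch = mismatch, gap_open = gap_open,
                             gap_ext = gap_ext)
        if (nrow(a1)) a1$score[1] else 0
      }, 0))
    })
  }
  pass <- aln[aln$length >= min_len & aln$identity >= min_identity &
                aln$score > null_score, , drop = FALSE]
  shown <- utils::head(pass, top)
  further <- if (nrow(pass) > top) pass[-seq_len(top), , drop = FALSE] else pass[0, ]
  rep0$status <- if (nrow(pass) == 0L) "no inverse complementary sequences"
                 else "inverse complementary sequences found"
  rep0$alignments <- shown
  rep0$n_further <- nrow(further)
  rep0$further_range <- if (nrow(further))
    list(length = range(further$length), identity = range(further$identity))
  rep0$null_score <- null_score
  class(rep0) <- "flanking_intron_report"
  rep0
}

#' @export
print.flanking_intron_report <- function(x, ...) {
  cat("<flanking_intron_report>", x$circ_id, "\n")
  up <- if (is.null(x$upstream)) "-" else paste0("intron ", x$upstream$index)
  dn <- if (is.null(x$downstream)) "-" else paste0("intron ", x$downstream$index)
  cat("  flanks:", up, ",", dn, "\n  status:", x$status, "\n")
  if (nrow(x$alignments)) {
    for (i in seq_len(nrow(x$alignments)))
      cat(sprintf("  %d nts with %.1f%% sequence match\n",
                  x$alignments$length[i], x$alignments$identity[i]))
    if (x$n_further > 0L)
      cat(sprintf("  %d further alignments of %d-%d nts with %.1f-%.1f%% match\n",
                  x$n_further, x$further_range$length[1],
                  x$further_range$length[2], x$further_range$identity[1],
                  x$further_range$identity[2]))
  }
  invisible(x)
}
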