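#' Gene locus models: linear splice variants and circular RNAs
#'
#' A `gene_locus` bundles a genomic segment (given on the chromosome forward
#' strand), the gene strand, a set of linear transcripts (ordered exon
#' intervals) and a set of predicted circular RNAs defined by exon ranges on a
#' parent transcript. All coordinates are 1-based inclusive and relative to
#' the locus sequence. Exons are numbered in transcript order (5'->3' of the
#' mature transcript): on the minus strand exon 1 has the highest genomic
#' coordinates.
#'
#' @name gene_model
NULL

#' Construct a linear transcript model
#'
#' @param id Stable identifier.
#' @param name Display name (defaults to `id`).
#' @param exons Data frame with columns `start`, `end` (1-based inclusive,
#'   locus coordinates). Transcript-order indices are assigned from the
#'   strand: ascending coordinates on `+`, descending on `-`.
#' @param strand `"+"` or `"-"`.
#' @param biotype One of `"protein-coding"`, `"processed-transcript"`,
#'   `"other"`.
#' @param tsl Transcript support level (1-5) or `NA`.
#' @return A `linear_transcript` object.
#' @export
new_transcript <- function(id, exons, strand, name = id,
                           biotype = "other", tsl = NA_integer_) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) stop("transcript '", id, "' has zero exons")
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  if (any(exons$start > exons$end)) stop("exon with start > end in '", id, "'")
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, c("start", "end"), drop = FALSE]
  # non-overlap check in genomic order
  gs <- sort(exons$start)
  ge <- exons$end[order(exons$start)]
  if (nrow(exons) > 1L && any(gs[-1] <= ge[-length(ge)]))
    stop("overlapping exons within transcript '", id, "'")
  exons$index <- seq_len(nrow(exons))
  rownames(exons) <- NULL
  structure(list(id = id, name = name, strand = strand,
                 exons = exons[, c("index", "start", "end")],
                 biotype = biotype, tsl = tsl),
            class = "linear_transcript")
}

#' Construct a circular RNA model
#'
#' A circRNA is defined by the inclusive exon index range `[acceptor_exon,
#' donor_exon]` on a parent transcript. The back-splice junction (BSJ) joins
#' the 3' end of the donor exon to the 5' start of the acceptor exon.
#'
#' @param id Identifier.
#' @param parent Parent transcript id.
#' @param acceptor_exon,donor_exon Transcript-order exon indices, acceptor <=
#'   donor.
#' @param declared_length Optional annotated mature length in bases; checked
#'   against the computed length at sequence time (warning on mismatch).
#' @param name Display name.
#' @return A `circ_rna` object.
#' @export
new_circ_rna <- function(id, parent, acceptor_exon, donor_exon,
                         declared_length = NA_integer_, name = id) {
  stopifnot(acceptor_exon >= 1L, acceptor_exon <= donor_exon)
  structure(list(id = id, name = name, parent = parent,
                 acceptor_exon = as.integer(acceptor_exon),
                 donor_exon = as.integer(donor_exon),
                 declared_length = as.integer(declared_length)),
            class = "circ_rna")
}

#' Construct and validate a gene locus model
#'
#' @param name Gene symbol.
#' @param sequence Locus sequence (character, chromosome forward strand).
#' @param strand Gene strand, `"+"` or `"-"`.
#' @param transcripts List of [new_transcript()] objects.
#' @param circRNAs List of [new_circ_rna()] objects.
#' @return A `gene_locus` object.
#' @export
new_gene_locus <- function(name, sequence, strand, transcripts,
                           circRNAs = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  names(circRNAs) <- vapply(circRNAs, `[[`, "", "id")
  for (t in transcripts) {
    if (any(t$exons$start < 1L) || any(t$exons$end > n))
      stop("exon outside locus in transcript '", t$id, "'")
    if (t$strand != strand)
      stop("transcript '", t$id, "' strand differs from locus strand")
  }
  for (cc in circRNAs) {
    if (!cc$parent %in% names(transcripts))
      stop("circRNA '", cc$id, "' references unknown parent '", cc$parent, "'")
    if (cc$donor_exon > nrow(transcripts[[cc$parent]]$exons))
      stop("circRNA '", cc$id, "' donor exon beyond parent transcript")
  }
  structure(list(name = name, sequence = sequence, strand = strand,
                 transcripts = transcripts, circRNAs = circRNAs),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat("<gene_locus> ", x$name, " (", nchar(x$sequence), " bp, strand ",
      x$strand, ")\n", sep = "")
  cat("  transcripts: ", paste(names(x$transcripts), collapse = ", "), "\n")
  cat("  circRNAs:    ", paste(names(x$circRNAs), collapse = ", "), "\n")
  invisible(x)
}

#' Load a gene locus from FASTA plus GFF3 or BED12 annotation
#'
#' The FASTA must contain one record: the locus sequence on the chromosome
#' forward strand. Annotation coordinates must be expressed in (or be
#' rebased to, via `offset`) locus coordinates `1..len`. GFF3 exon features
#' are grouped into transcripts by their `Parent` attribute; BED12 lines are
#' one transcript each with exons taken from the block structure.
#'
#' @param fasta_path Path to single-record FASTA.
#' @param annotation_path Path to GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`).
#' @param name Gene symbol; default the FASTA record name.
#' @param offset Number subtracted from annotation coordinates before
#'   validation (use when the annotation is in absolute chromosome
#'   coordinates; locus base 1 corresponds to chromosome `offset + 1`).
#' @param circRNAs Optional list of [new_circ_rna()] definitions to attach.
#' @return A validated [new_gene_locus()] object.
#' @export
load_locus <- function(fasta_path, annotation_path, name = NULL, offset = 0L,
                       circRNAs = list()) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  if (length(fa) != 1L) stop("expected a single-record locus FASTA")
  seqn <- as.character(fa[[1]])
  if (is.null(name)) name <- sub("\\s.*$", "", names(fa)[1])

  is_bed <- grepl("\\.bed$", annotation_path, ignore.case = TRUE)
  gr <- rtracklayer::import(annotation_path,
                            format = if (is_bed) "bed" else "gff3")
  tx <- list()
  strand_seen <- character(0)
  if (is_bed) {
    for (i in seq_along(gr)) {
      blocks <- gr$blocks[[i]]  # exon blocks relative to chromStart
      ab <- IRanges::shift(blocks, GenomicRanges::start(gr[i]) - 1L)
      st <- as.character(GenomicRanges::strand(gr[i]))
      if (!st %in% c("+", "-")) stop("unknown strand in BED record ", i)
      strand_seen <- union(strand_seen, st)
      tx[[length(tx) + 1L]] <- new_transcript(
        id = gr$name[i] %||% paste0("tx", i),
        exons = data.frame(start = IRanges::start(ab) - offset,
                           end = IRanges::end(ab) - offset),
        strand = st)
    }
  } else {
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(ex) == 0L) stop("no exon features in GFF3")
    parent <- as.character(S4Vectors::mcols(ex)$Parent)
    if (all(is.na(parent)) || is.null(parent))
      parent <- as.character(S4Vectors::mcols(ex)$transcript_id)
    for (p in unique(parent)) {
      sel <- ex[parent == p]
      st <- unique(as.character(GenomicRanges::strand(sel)))
      if (length(st) != 1L || !st %in% c("+", "-"))
        stop("unknown or mixed strand for transcript '", p, "'")
      strand_seen <- union(strand_seen, st)
      tx[[length(tx) + 1L]] <- new_transcript(
        id = sub("^transcript:", "", p),
        exons = data.frame(start = GenomicRanges::start(sel) - offset,
                           end = GenomicRanges::end(sel) - offset),
        strand = st)
    }
  }
  if (length(strand_seen) != 1L)
    stop("transcripts on mixed strands are not supported for one locus")
  new_gene_locus(name = name, sequence = seqn, strand = strand_seen,
                 transcripts = tx, circRNAs = circRNAs)
}

# Strand-corrected sequence of one exon (transcript-order index).
exon_sequence <- function(locus, transcript, index) {
  t <- resolve_transcript(locus, transcript)
  e <- t$exons[t$exons$index == index, ]
  if (nrow(e) != 1L) stop("no exon with index ", index)
  s <- substr(locus$sequence, e$start, e$end)
  if (t$strand == "-") revcomp(s) else s
}

resolve_transcript <- function(locus, transcript) {
  if (inherits(transcript, "linear_transcript")) return(transcript)
  t <- locus$transcripts[[transcript]]
  if (is.null(t)) stop("unknown transcript: ", transcript)
  t
}

resolve_circ <- function(locus, circ) {
  if (inherits(circ, "circ_rna")) return(circ)
  cc <- locus$circRNAs[[circ]]
  if (is.null(cc)) stop("unknown circRNA: ", circ)
  cc
}

#' Spliced (mature) sequence of a linear transcript
#'
#' Exon sequences are concatenated in transcript order; on the minus strand
#' each exon is reverse-complemented, so the result reads 5'->3' of the
#' mature RNA.
#'
#' @param transcript A `linear_transcript` or its id.
#' @param locus The `gene_locus`.
#' @return Character sequence.
#' @export
spliced_sequence <- function(transcript, locus) {
  t <- resolve_transcript(locus, transcript)
  paste(vapply(t$exons$index, function(i) exon_sequence(locus, t, i), ""),
        collapse = "")
}

#' Linearized sequence of a circular RNA
#'
#' Rotation convention: the returned string starts at the first base of the
#' acceptor exon and ends at the last base of the donor exon, so the BSJ sits
#' between the last and first character. Occurrence counts on circles are
#' defined on the doubled sequence.
#'
#' @param circ A `circ_rna` or its id.
#' @param locus The `gene_locus`.
#' @param warn_declared Warn if `declared_length` disagrees with the computed
#'   length (default `TRUE`).
#' @return Character sequence of length = sum of exon lengths acceptor..donor.
#' @export
circ_sequence <- function(circ, locus, warn_declared = TRUE) {
  cc <- resolve_circ(locus, circ)
  t <- resolve_transcript(locus, cc$parent)
  s <- paste(vapply(seq(cc$acceptor_exon, cc$donor_exon),
                    function(i) exon_sequence(locus, t, i), ""),
             collapse = "")
  if (warn_declared && !is.na(cc$declared_length) &&
      cc$declared_length != nchar(s))
    warning("circRNA '", cc$id, "': declared length ", cc$declared_length,
            " != computed length ", nchar(s), call. = FALSE)
  s
}

#' Back-splice junction 2k-mer of a circular RNA
#'
#' The last `k` bases of the donor exon joined to the first `k` bases of the
#' acceptor exon: the only sequence unique to the circle relative to its
#' linear parent.
#'
#' @param circ A `circ_rna` or its id.
#' @param locus The `gene_locus`.
#' @param k Flank length in nt on each side of the junction.
#' @return Character sequence of length `2k`.
#' @export
bsj_kmer <- function(circ, locus, k) {
  cc <- resolve_circ(locus, circ)
  t <- resolve_transcript(locus, cc$parent)
  don <- exon_sequence(locus, t, cc$donor_exon)
  acc <- exon_sequence(locus, t, cc$acceptor_exon)
  if (k > nchar(don) || k > nchar(acc))
    stop("k = ", k, " exceeds a BSJ flanking exon length")
  paste0(substr(don, nchar(don) - k + 1L, nchar(don)), substr(acc, 1L, k))
}

#' Transcript-order intron intervals of a transcript
#'
#' Intron `i` is the genomic gap between exon `i` and exon `i + 1` in
#' transcript order.
#'
#' @inheritParams spliced_sequence
#' @return Data frame with columns `index`, `start`, `end` (locus
#'   coordinates); zero rows for single-exon transcripts.
#' @export
transcript_introns <- function(transcript, locus) {
  t <- resolve_transcript(locus, transcript)
  n <- nrow(t$exons)
  if (n < 2L) return(data.frame(index = integer(0), start = integer(0),
                                end = integer(0)))
  out <- lapply(seq_len(n - 1L), function(i) {
    a <- t$exons[t$exons$index == i, ]
    b <- t$exons[t$exons$index == i + 1L, ]
    if (t$strand == "+") data.frame(index = i, start = a$end + 1L, end = b$start - 1L)
    else data.frame(index = i, start = b$end + 1L, end = a$start - 1L)
  })
  do.call(rbind, out)
}

# Strand-corrected (transcript-sense, 5'->3') sequence of one intron.
intron_sequence <- function(locus, transcript, index) {
  t <- resolve_transcript(locus, transcript)
  iv <- transcript_introns(t, locus)
  e <- iv[iv$index == index, ]
  if (nrow(e) != 1L) stop("no intron with index ", index)
  s <- substr(locus$sequence, e$start, e$end)
  if (t$strand == "-") revcomp(s) else s
}

#' Serialize / restore a gene locus as JSON
#'
#' @param locus A `gene_locus`.
#' @param path Output (input) file path.
#' @return `write_locus_json` returns `path` invisibly; `read_locus_json`
#'   returns the restored `gene_locus`.
#' @export
write_locus_json <- function(locus, path) {
  obj <- list(
    name = locus$name, strand = locus$strand, sequence = locus$sequence,
    transcripts = lapply(locus$transcripts, function(t)
      list(id = t$id, name = t$name, biotype = t$biotype, tsl = t$tsl,
           exons = t$exons)),
    circRNAs = lapply(locus$circRNAs, function(cc)
      list(id = cc$id, name = cc$name, parent = cc$parent,
           acceptor_exon = cc$acceptor_exon, donor_exon = cc$donor_exon,
           declared_length = cc$declared_length)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_locus_json
#' @export
read_locus_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  tx <- lapply(obj$transcripts, function(t)
    new_transcript(id = t$id, name = t$name,
                   exons = as.data.frame(t$exons)[, c("start", "end")],
                   strand = obj$strand, biotype = t$biotype,
                   tsl = t$tsl %||% NA_integer_))
  circs <- lapply(obj$circRNAs, function(cc)
    new_circ_rna(id = cc$id, name = cc$name, parent = cc$parent,
                 acceptor_exon = cc$acceptor_exon, donor_exon = cc$donor_exon,
                 declared_length = cc$declared_length %||% NA_integer_))
  new_gene_locus(obj$name, obj$sequence, obj$strand, tx, circs)
}

#' Write locus FASTA and GFF3 files
#'
#' @param locus A `gene_locus`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_locus_files <- function(locus, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(locus$sequence)
  names(seqs) <- locus$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  lines <- c("##gff-version 3")
  for (t in locus$transcripts) {
    lines <- c(lines, paste(locus$name, "circvalid", "mRNA",
                            min(t$exons$start), max(t$exons$end), ".",
                            t$strand, ".", paste0("ID=", t$id), sep = "\t"))
    for (i in seq_len(nrow(t$exons))) {
      e <- t$exons[i, ]
      lines <- c(lines, paste(locus$name, "circvalid", "exon",
                              e$start, e$end, ".", t$strand, ".",
                              paste0("ID=", t$id, ".e", e$index,
                                     ";Parent=", t$id), sep = "\t"))
    }
  }
  writeLines(lines, gff_path)
  invisible(list(fasta = fasta_path, gff = gff_path))
}
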