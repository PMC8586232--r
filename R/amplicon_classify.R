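#' Exon-path decomposition and classification of cloned amplicons
#'
#' Sequenced clones from divergent-primer PCR products are decomposed into
#' ordered exon segments ("exon paths", written in comma/slash notation:
#' commas join canonical splice junctions, a slash marks any non-canonical
#' one, in particular a potential back-splice). Each clone is then called
#' linear, circRNA-consistent, artifact or foreign based on exon order,
#' indication of artifacts (primer duplications, missing internal exons,
#' sequence deviations) and exact agreement of its back-splice junction with
#' a predicted circRNA.
#'
#' Because TA cloning is non-directional, reads arrive in either
#' orientation; paths are normalized to the orientation in which exon
#' indices ascend across canonical junctions (the orientation matching the
#' sense exon sequences) and the raw orientation is retained as metadata.
#'
#' @name amplicon_classify
NULL

# Maximal exact match segments (>= seed nt) between `read` and one exon
# sequence, found by seed k-mer hashing and diagonal run merging.
exact_segments <- function(read, exon_seq, exon_index, seed) {
  nr <- nchar(read)
  ne <- nchar(exon_seq)
  if (nr < seed || ne < seed) return(NULL)
  read_kmers <- substring(read, 1:(nr - seed + 1L), seed:nr)
  exon_kmers <- substring(exon_seq, 1:(ne - seed + 1L), seed:ne)
  # all (read position, exon position) k-mer matches
  hits <- lapply(seq_along(exon_kmers), function(q) {
    p <- which(read_kmers == exon_kmers[q])
    if (length(p)) cbind(p = p, q = q) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(NULL)
  d <- hits[, "p"] - hits[, "q"]
  out <- list()
  for (diag in unique(d)) {
    qs <- sort(hits[d == diag, "q"])
    # merge consecutive q into maximal runs
    brk <- c(0L, which(diff(qs) != 1L), length(qs))
    for (i in seq_len(length(brk) - 1L)) {
      q1 <- qs[brk[i] + 1L]
      q2 <- qs[brk[i + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        exon = exon_index,
        exon_start = q1, exon_end = q2 + seed - 1L,
        read_start = q1 + diag, read_end = q2 + seed - 1L + diag)
    }
  }
  do.call(rbind, out)
}

# Optimal chain of segments: non-overlapping, ordered read intervals
# maximizing total matched bases (weighted interval scheduling DP).
chain_segments <- function(segs) {
  if (is.null(segs) || nrow(segs) == 0L) return(segs)
  segs <- segs[order(segs$read_end, segs$read_start), , drop = FALSE]
  n <- nrow(segs)
  w <- segs$read_end - segs$read_start + 1L
  # p[i]: last segment ending before segs i starts
  p <- vapply(seq_len(n), function(i)
    max(0L, which(segs$read_end < segs$read_start[i])), 0L)
  opt <- numeric(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) {
    with_i <- w[i] + opt[p[i] + 1L]
    opt[i + 1L] <- max(opt[i], with_i)
    take[i] <- with_i >= opt[i]
  }
  sel <- integer(0)
  i <- n
  while (i > 0L) {
    if (take[i] && (w[i] + opt[p[i] + 1L]) == opt[i + 1L]) {
      sel <- c(i, sel)
      i <- p[i]
    } else i <- i - 1L
  }
  segs[sel, , drop = FALSE]
}

# Merge chained neighbors from the same exon and diagonal separated by a
# short mismatch gap (point substitutions split exact segments).
merge_collinear <- function(chain, max_gap = 3L) {
  if (is.null(chain) || nrow(chain) < 2L) return(chain)
  keep <- chain[1, , drop = FALSE]
  for (i in 2:nrow(chain)) {
    last <- keep[nrow(keep), ]
    cur <- chain[i, ]
    gap_read <- cur$read_start - last$read_end - 1L
    gap_exon <- cur$exon_start - last$exon_end - 1L
    if (cur$exon == last$exon && gap_read == gap_exon &&
        gap_read >= 1L && gap_read <= max_gap) {
      keep$read_end[nrow(keep)] <- cur$read_end
      keep$exon_end[nrow(keep)] <- cur$exon_end
    } else {
      keep <- rbind(keep, cur)
    }
  }
  keep
}

decompose_one <- function(read, ex_seqs, seed) {
  segs <- do.call(rbind, lapply(seq_along(ex_seqs), function(i)
    exact_segments(read, ex_seqs[i], i, seed)))
  chain <- chain_segments(segs)
  merge_collinear(chain)
}

#' Decompose a clone read into an exon path
#'
#' Finds the maximal-coverage chain of exon matches (seeded exact matching,
#' point substitutions bridged when the flanks are collinear), chooses the
#' read orientation with more matched bases, and types every junction
#' between consecutive segments: `canonical` (next exon index, exact exon
#' boundaries), `back_splice` (equal or lower index, exact boundaries),
#' `skip` (index jump > 1, exact boundaries), `non_splice` otherwise.
#' Unmatched read stretches of at least `seed` nt are recorded as foreign
#' gaps.
#'
#' @param read Character read sequence (or a list with `$seq`).
#' @param locus The `gene_locus`.
#' @param transcript Reference transcript (default: the one with most
#'   exons).
#' @param seed Exact seed length (default 15 nt).
#' @param min_identity Minimal identity of a merged segment (default 0.95).
#' @return An `exon_path`: list with `segments` (data frame `exon`,
#'   `exon_start`, `exon_end`, `read_start`, `read_end`), `junctions` (data
#'   frame `from_exon`, `to_exon`, `type`), `orientation` (`"as-is"` or
#'   `"reverse-complemented"`), `foreign_gaps`, `read`, `matched_bases`.
#' @export
decompose <- function(read, locus, transcript = NULL, seed = 15L,
                      min_identity = 0.95) {
  if (is.list(read)) read <- read$seq
  read <- toupper(read)
  if (is.null(transcript)) {
    nex <- vapply(locus$transcripts, function(t) nrow(t$exons), 0L)
    transcript <- names(locus$transcripts)[which.max(nex)]
  }
  t <- resolve_transcript(locus, transcript)
  ex_seqs <- vapply(t$exons$index, function(i) exon_sequence(locus, t, i), "")

  fw <- decompose_one(read, ex_seqs, seed)
  rcread <- revcomp(read)
  rv <- decompose_one(rcread, ex_seqs, seed)
  mb <- function(x) if (is.null(x) || nrow(x) == 0L) 0L else
    sum(x$read_end - x$read_start + 1L)
  use_rc <- mb(rv) > mb(fw)
  segs <- if (use_rc) rv else fw
  oriented_read <- if (use_rc) rcread else read

  path <- list(segments = segs, orientation = if (use_rc)
    "reverse-complemented" else "as-is", read = oriented_read,
    matched_bases = mb(segs))
  ex_len <- nchar(ex_seqs)

  if (is.null(segs) || nrow(segs) == 0L) {
    path$segments <- data.frame(exon = integer(0), exon_start = integer(0),
                                exon_end = integer(0), read_start = integer(0),
                                read_end = integer(0))
    path$junctions <- data.frame(from_exon = integer(0), to_exon = integer(0),
                                 type = character(0))
    path$foreign_gaps <- data.frame(start = 1L, end = nchar(read))
    class(path) <- "exon_path"
    return(path)
  }

  jn <- list()
  if (nrow(segs) > 1L) {
    for (i in seq_len(nrow(segs) - 1L)) {
      u <- segs[i, ]
      v <- segs[i + 1L, ]
      exact <- u$exon_end == ex_len[u$exon] && v$exon_start == 1L &&
        v$read_start == u$read_end + 1L
      type <- if (!exact) "non_splice"
        else if (v$exon == u$exon + 1L) "canonical"
        else if (v$exon <= u$exon) "back_splice"
        else "skip"
      jn[[i]] <- data.frame(from_exon = u$exon, to_exon = v$exon, type = type)
    }
  }
  path$junctions <- if (length(jn)) do.call(rbind, jn) else
    data.frame(from_exon = integer(0), to_exon = integer(0),
               type = character(0))

  # foreign gaps: unmatched read stretches >= seed
  covered <- rep(FALSE, nchar(oriented_read))
  for (i in seq_len(nrow(segs)))
    covered[segs$read_start[i]:segs$read_end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap <- !r$values & r$lengths >= seed
  path$foreign_gaps <- data.frame(start = starts[gap], end = ends[gap])
  class(path) <- "exon_path"
  path
}

#' Exon-path string in comma/slash notation
#'
#' @param path An `exon_path`.
#' @param orientation `"normalized"` (ascending across canonical junctions,
#'   the default) or `"as_read"` (mirrored when the read arrived
#'   reverse-complemented, reproducing notations like `4,3/6,5,4`).
#' @return Character such as `"4,5,6/3,4"`.
#' @export
path_string <- function(path, orientation = c("normalized", "as_read")) {
  orientation <- match.arg(orientation)
  segs <- path$segments
  if (nrow(segs) == 0L) return("")
  seps <- ifelse(path$junctions$type == "canonical", ",", "/")
  ex <- segs$exon
  if (orientation == "as_read" && path$orientation == "reverse-complemented") {
    ex <- rev(ex)
    seps <- rev(seps)
  }
  paste0(ex, c(seps, ""), collapse = "")
}

#' Match back-splice junctions of a path against predicted circRNAs
#'
#' A back-splice junction (donor exon `i` joined at its exact 3' boundary to
#' acceptor exon `j` at its exact 5' boundary) matches a predicted circRNA
#' only when donor and acceptor indices agree exactly.
#'
#' @param path An `exon_path` from [decompose()].
#' @param circs List of `circ_rna` objects (or a `gene_locus`, whose
#'   circRNAs are used).
#' @return Data frame with one row per back-splice junction: `from_exon`,
#'   `to_exon`, `matched_circ` (id or `NA`).
#' @export
detect_bsj <- function(path, circs) {
  if (inherits(circs, "gene_locus")) circs <- circs$circRNAs
  bs <- path$junctions[path$junctions$type == "back_splice", , drop = FALSE]
  if (nrow(bs) == 0L)
    return(data.frame(from_exon = integer(0), to_exon = integer(0),
                      matched_circ = character(0)))
  bs$matched_circ <- NA_character_
  for (i in seq_len(nrow(bs))) {
    for (cc in circs) {
      if (cc$donor_exon == bs$from_exon[i] &&
          cc$acceptor_exon == bs$to_exon[i]) {
        bs$matched_circ[i] <- cc$id
        break
      }
    }
  }
  rownames(bs) <- NULL
  bs[, c("from_exon", "to_exon", "matched_circ")]
}

# Occurrence positions of a primer (either orientation) in a read.
primer_occurrences <- function(primer_seq, read) {
  sort(unique(c(str_find_all(primer_seq, read),
                str_find_all(revcomp(primer_seq), read))))
}

#' Classify a decomposed clone read
#'
#' Rules applied in order: (1) `foreign` when no exon segment matched;
#' (2) `artifact`/`primer_duplication` when a primer occurs more often than
#' the amplification geometry predicts: repeated occurrences at tandem-range
#' spacing (below twice the primer length) are duplication artifacts,
#' whereas repeats spaced by the implied circle length are the legitimate
#' signature of circularly wrapped or concatemer-derived reads;
#' (3) `artifact`/`missing_internal_exon` when a back-splice implies a
#' circle whose internal exon complement is incomplete in the path;
#' (4) `artifact`/`inconsistent_bsj` when a back-splice matches no predicted
#' circRNA; (5) `circ_consistent` (with `matched_circ`) when the back-splice
#' junction(s) match one predicted circRNA exactly and the exon complement
#' is complete; (6) `linear` when all junctions are canonical. Anything else
#' (non-splice junctions, foreign gaps inside an otherwise matching read) is
#' an `artifact` with reason `sequence_deviation`.
#'
#' @param path An `exon_path` from [decompose()].
#' @param pair The amplifying [new_primer_pair()] (or `NULL` to skip the
#'   duplication check).
#' @param circs List of `circ_rna` objects or a `gene_locus`.
#' @param locus Optional `gene_locus` used to derive implied circle lengths
#'   for the concatemer exception.
#' @return A `clone_call`: list with `category`, `matched_circ`, `reasons`,
#'   `path_string`.
#' @export
classify <- function(path, pair = NULL, circs = list(), locus = NULL) {
  if (inherits(circs, "gene_locus")) {
    locus <- locus %||% circs
    circs <- circs$circRNAs
  }
  call <- function(category, matched = NA_character_, reasons = character(0))
    structure(list(category = category, matched_circ = matched,
                   reasons = reasons,
                   path_string = path_string(path)), class = "clone_call")

  if (nrow(path$segments) == 0L) return(call("foreign"))
  bsj <- detect_bsj(path, circs)

  if (!is.null(pair)) {
    for (p in list(pair$fwd, pair$rev)) {
      occ <- primer_occurrences(p$seq, path$read)
      if (length(occ) > 1L) {
        spacing <- diff(occ)
        # a circularly wrapped read (monomer amplicon, concatemer) repeats
        # each primer at the implied circle length; only tandem-range
        # repeats indicate a duplication artifact
        if (any(spacing < 2L * nchar(p$seq)))
          return(call("artifact", reasons = "primer_duplication"))
      }
    }
  }

  if (nrow(bsj) > 0L) {
    for (i in seq_len(nrow(bsj))) {
      implied <- seq(bsj$to_exon[i], bsj$from_exon[i])
      if (!all(implied %in% path$segments$exon))
        return(call("artifact", reasons = "missing_internal_exon"))
    }
    if (anyNA(bsj$matched_circ))
      return(call("artifact", reasons = "inconsistent_bsj"))
    ids <- unique(bsj$matched_circ)
    if (length(ids) == 1L &&
        all(path$junctions$type %in% c("canonical", "back_splice")) &&
        nrow(path$foreign_gaps) == 0L)
      return(call("circ_consistent", matched = ids))
    return(call("artifact", reasons = "sequence_deviation"))
  }

  if (nrow(path$foreign_gaps) > 0L)
    return(call("artifact", reasons = "sequence_deviation"))
  if (nrow(path$junctions) == 0L ||
      all(path$junctions$type == "canonical"))
    return(call("linear"))
  call("artifact", reasons = "sequence_deviation")
}

#' Summarize a set of clone calls
#'
#' @param calls List of `clone_call` objects.
#' @return List of two data frames: `by_category` and `by_path`, each with
#'   `count` and `percent` columns (percentages sum to 100 up to rounding).
#' @export
summarize_calls <- function(calls) {
  if (length(calls) == 0L)
    return(list(by_category = data.frame(category = character(0),
                                         count = integer(0),
                                         percent = numeric(0)),
                by_path = data.frame(path = character(0),
                                     category = character(0),
                                     count = integer(0),
                                     percent = numeric(0))))
  df <- data.frame(
    category = vapply(calls, `[[`, "", "category"),
    path = vapply(calls, `[[`, "", "path_string"),
    matched = vapply(calls, function(x)
      as.character(x$matched_circ %||% NA), ""))
  n <- nrow(df)
  bc <- as.data.frame(table(category = df$category),
                      responseName = "count", stringsAsFactors = FALSE)
  bc$percent <- 100 * bc$count / n
  bp <- stats::aggregate(list(count = rep(1L, n)),
                         by = list(path = df$path, category = df$category),
                         FUN = sum)
  bp$percent <- 100 * bp$count / n
  bp <- bp[order(-bp$count), ]
  rownames(bp) <- NULL
  list(by_category = bc, by_path = bp)
}
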