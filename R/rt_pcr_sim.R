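#' In silico PCR with convergent/divergent primer semantics
#'
#' Priming is abstracted by a seed model: a primer binds wherever its
#' 3'-terminal seed (default 10 nt) matches the template exactly and the
#' remaining 5' bases carry at most `max_mismatch_5prime` mismatches (default
#' 2). This operationalises the fact that the 3' end defines the specificity
#' of Taq polymerases. Circular templates are scanned on the doubled sequence
#' with positions reduced modulo the circle length. cDNA strandedness is
#' abstracted away: random-hexamer reverse transcription makes both strands
#' reachable, so all simulation runs in sense space.
#'
#' @name rt_pcr_sim
NULL

#' Construct a primer
#'
#' @param name Label.
#' @param seq Oligo sequence 5'->3' (ACGT).
#' @param check_length Enforce the 15-35 nt convention (default `TRUE`).
#' @return A `primer` object.
#' @export
new_primer <- function(name, seq, check_length = TRUE) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty primer sequence")
  if (grepl("[^ACGT]", seq)) stop("primer '", name, "' has non-ACGT characters")
  if (check_length && (nchar(seq) < 15L || nchar(seq) > 35L))
    stop("primer '", name, "' length ", nchar(seq), " outside 15-35 nt")
  structure(list(name = name, seq = seq, length = nchar(seq)),
            class = "primer")
}

#' Construct a primer pair
#'
#' @param fwd,rev [new_primer()] objects (or character sequences).
#' @param pair_id Label for the pair.
#' @return A `primer_pair` object; the orientation class is derived lazily
#'   against a reference with [classify_pair_orientation()].
#' @export
new_primer_pair <- function(fwd, rev, pair_id = paste0(fwd$name, "/", rev$name)) {
  if (is.character(fwd)) fwd <- new_primer("fwd", fwd, check_length = FALSE)
  if (is.character(rev)) rev <- new_primer("rev", rev, check_length = FALSE)
  structure(list(pair_id = pair_id, fwd = fwd, rev = rev),
            class = "primer_pair")
}

#' Construct a template molecule
#'
#' @param id Label.
#' @param seq Sequence (sense space).
#' @param topology One of `"linear"`, `"circular"`, `"concatemer"`,
#'   `"genomic"`.
#' @param copies Abundance weight (default 1).
#' @param circle_len Monomer length for circular/concatemer topologies.
#' @param repeat_count Number of tiled monomers (concatemers).
#' @return A `template_molecule` object.
#' @export
new_template <- function(id, seq, topology = c("linear", "circular",
                                               "concatemer", "genomic"),
                         copies = 1, circle_len = NULL, repeat_count = NULL) {
  topology <- match.arg(topology)
  if (copies < 0) stop("negative copies")
  if (topology == "circular" && is.null(circle_len)) circle_len <- nchar(seq)
  structure(list(id = id, seq = toupper(seq), topology = topology,
                 copies = copies, circle_len = circle_len,
                 repeat_count = repeat_count),
            class = "template_molecule")
}

#' Rolling-circle reverse transcription of a circular template
#'
#' Reverse transcriptase traversing a circle several times yields a
#' concatemeric cDNA: a rotation of the circle tiled `repeats` times. Such
#' concatemers explain ladders of divergent-primer PCR products spaced by
#' one circle length.
#'
#' @param circ_seq Linearized circle sequence.
#' @param repeats Number of full traversals (>= 1).
#' @param offset 0-based phase at which the polymerase starts (0 = the
#'   linearization origin, i.e. the acceptor exon's first base).
#' @param id Template label.
#' @return A `template_molecule` with topology `"concatemer"`.
#' @export
rolling_circle_cdna <- function(circ_seq, repeats, offset = 0L,
                                id = "concatemer") {
  n <- nchar(circ_seq)
  if (repeats < 1L) stop("repeats must be >= 1")
  if (offset < 0L || offset >= n) stop("offset must be in [0, circle length)")
  rot <- paste0(substr(circ_seq, offset + 1L, n), substr(circ_seq, 1L, offset))
  new_template(id, strrep(rot, repeats), topology = "concatemer",
               circle_len = n, repeat_count = as.integer(repeats))
}

# matchPattern hits of `pat` in `subject` with <= mm total mismatches,
# returned as a (start, end) data.frame.
pattern_hits <- function(pat, subject, mm) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                Biostrings::DNAString(subject),
                                max.mismatch = mm, with.indels = FALSE)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

#' Find primer binding sites on a template
#'
#' A site on strand `"+"` means the primer equals (up to the mismatch model)
#' the template window and extends rightward, 3' end at `end`; strand `"-"`
#' means the primer anneals to the given strand (its reverse complement
#' matches the window) and extends leftward, 3' end at `start`.
#'
#' @param primer A [new_primer()] object.
#' @param template A [new_template()] object (or character sequence, treated
#'   as linear).
#' @param seed_3prime Length of the required exact 3'-terminal match.
#' @param max_mismatch_5prime Maximum mismatches 5' of the seed.
#' @return Data frame with columns `start`, `end`, `strand`; for circular
#'   templates, window starts are reduced into `1..circle_len` (scan on the
#'   doubled sequence, deduplicated modulo circle length).
#' @export
find_binding_sites <- function(primer, template, seed_3prime = 10L,
                               max_mismatch_5prime = 2L) {
  if (is.character(template)) template <- new_template("ref", template)
  pseq <- primer$seq
  L <- nchar(pseq)
  if (L == 0L) stop("empty primer")
  if (seed_3prime > L) stop("seed_3prime exceeds primer length")
  subject <- template$seq
  circular <- template$topology == "circular"
  if (circular) subject <- strrep(subject, 2L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0))
  if (nchar(subject) < L) return(empty)

  seed_plus <- substr(pseq, L - seed_3prime + 1L, L)       # template 3' side
  rc <- revcomp(pseq)
  seed_minus <- substr(rc, 1L, seed_3prime)                # window 5' side

  keep_seed <- function(hits, seed, at_start) {
    if (nrow(hits) == 0L) return(hits)
    ws <- if (at_start) hits$start else hits$end - seed_3prime + 1L
    ok <- substring(subject, ws, ws + seed_3prime - 1L) == seed
    hits[ok, , drop = FALSE]
  }
  plus <- keep_seed(pattern_hits(pseq, subject, max_mismatch_5prime),
                    seed_plus, at_start = FALSE)
  minus <- keep_seed(pattern_hits(rc, subject, max_mismatch_5prime),
                     seed_minus, at_start = TRUE)
  out <- rbind(if (nrow(plus)) cbind(plus, strand = "+"),
               if (nrow(minus)) cbind(minus, strand = "-"))
  if (is.null(out)) return(empty)
  if (circular) {
    n <- template$circle_len
    red <- ((out$start - 1L) %% n) + 1L
    keep <- !duplicated(data.frame(red, out$strand))
    out <- out[keep & out$start <= n, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# All facing (plus site upstream of minus site, pointing at each other)
# site pairs for an unordered primer pair on a template sequence; both
# role assignments are examined. Returns start/end of the would-be amplicon.
facing_site_pairs <- function(pair, template, seed_3prime, max_mismatch_5prime) {
  sf <- find_binding_sites_raw(pair$fwd, template, seed_3prime, max_mismatch_5prime)
  sr <- find_binding_sites_raw(pair$rev, template, seed_3prime, max_mismatch_5prime)
  combos <- rbind(site_cross(sf, sr, pair$fwd$name, pair$rev$name),
                  site_cross(sr, sf, pair$rev$name, pair$fwd$name))
  combos
}

# Binding sites without the circular modular reduction (scan the doubled
# sequence directly); used internally by amplicon enumeration.
find_binding_sites_raw <- function(primer, template, seed_3prime,
                                   max_mismatch_5prime) {
  t2 <- template
  if (template$topology == "circular") {
    t2 <- new_template(template$id, strrep(template$seq, 2L), "linear")
  }
  find_binding_sites(primer, t2, seed_3prime, max_mismatch_5prime)
}

site_cross <- function(a, b, a_name, b_name) {
  ap <- a[a$strand == "+", , drop = FALSE]
  bm <- b[b$strand == "-", , drop = FALSE]
  if (nrow(ap) == 0L || nrow(bm) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      plus_name = character(0), minus_name = character(0)))
  g <- expand.grid(i = seq_len(nrow(ap)), j = seq_len(nrow(bm)))
  res <- data.frame(start = ap$start[g$i], end = bm$end[g$j],
                    plus_end = ap$end[g$i], minus_start = bm$start[g$j],
                    plus_name = a_name, minus_name = b_name)
  # facing: plus site entirely upstream of (or abutting) the minus site
  res <- res[res$start <= res$minus_start & res$plus_end <= res$end, ,
             drop = FALSE]
  res[, c("start", "end", "plus_name", "minus_name")]
}

#' Classify a primer pair as convergent or divergent on a reference
#'
#' Convergent: a sense-strand site lies 5' of an antisense site and the two
#' primers face each other (the geometry that amplifies). Divergent: both
#' primers bind but every site configuration points away. Pairs with no
#' binding, or only overlapping sites, are `"invalid"`.
#'
#' @param pair A [new_primer_pair()].
#' @param reference Reference spliced sequence (character) or a linear
#'   [new_template()].
#' @inheritParams find_binding_sites
#' @return `"convergent"`, `"divergent"` or `"invalid"`.
#' @export
classify_pair_orientation <- function(pair, reference, seed_3prime = 10L,
                                      max_mismatch_5prime = 2L) {
  if (is.character(reference)) reference <- new_template("ref", reference)
  sf <- find_binding_sites(pair$fwd, reference, seed_3prime, max_mismatch_5prime)
  sr <- find_binding_sites(pair$rev, reference, seed_3prime, max_mismatch_5prime)
  if (nrow(sf) == 0L || nrow(sr) == 0L) return("invalid")
  facing <- facing_site_pairs(pair, reference, seed_3prime, max_mismatch_5prime)
  if (nrow(facing) > 0L) return("convergent")
  # any strictly diverging configuration (plus site downstream of minus site)?
  diverging <- function(a, b) {
    ap <- a[a$strand == "+", , drop = FALSE]
    bm <- b[b$strand == "-", , drop = FALSE]
    nrow(ap) > 0L && nrow(bm) > 0L &&
      any(outer(ap$start, bm$end, ">"))
  }
  if (diverging(sf, sr) || diverging(sr, sf)) return("divergent")
  "invalid"
}

#' Predict PCR amplicons of a primer pair on a template
#'
#' One amplicon per facing (sense site, antisense site) configuration within
#' `max_len`. On circular templates the doubled sequence is scanned and only
#' monomer-length products are reported, each once (positions reduced modulo
#' the circle length). On concatemers the enumeration naturally yields a
#' ladder of products spaced by the circle length. Products above `max_len`
#' are dropped (counted in the `dropped` attribute).
#'
#' @param pair A [new_primer_pair()].
#' @param template A [new_template()].
#' @param max_len Longest product considered amplifiable (default 3000 nt).
#' @inheritParams find_binding_sites
#' @return Data frame with columns `template_id`, `start`, `end`, `length`,
#'   `seq` (possibly zero rows).
#' @export
predict_amplicons <- function(pair, template, max_len = 3000L,
                              seed_3prime = 10L, max_mismatch_5prime = 2L) {
  combos <- facing_site_pairs(pair, template, seed_3prime, max_mismatch_5prime)
  subject <- if (template$topology == "circular") strrep(template$seq, 2L)
             else template$seq
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0), seq = character(0))
  if (nrow(combos) == 0L) return(empty)
  combos$length <- combos$end - combos$start + 1L
  if (template$topology == "circular") {
    n <- template$circle_len
    combos <- combos[combos$start <= n & combos$length <= n, , drop = FALSE]
    combos$start_mod <- ((combos$start - 1L) %% n) + 1L
    combos <- combos[!duplicated(combos[, c("start_mod", "length")]), ,
                     drop = FALSE]
  }
  dropped <- sum(combos$length > max_len)
  combos <- combos[combos$length <= max_len, , drop = FALSE]
  if (nrow(combos) == 0L) {
    attr(empty, "dropped") <- dropped
    return(empty)
  }
  out <- data.frame(template_id = template$id, start = combos$start,
                    end = combos$end, length = combos$length,
                    seq = substring(subject, combos$start, combos$end))
  out <- out[order(out$length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Test the tandem-repeat hypothesis against genomic DNA
#'
#' A divergent-primer product could in principle arise from a genomic exon
#' duplication rather than a circRNA. Running the amplicon prediction on the
#' genomic template settles it: no product means no genomic origin for the
#' seeming BSJ.
#'
#' @param pairs List of [new_primer_pair()] objects.
#' @param genomic A [new_template()] with topology `"genomic"`.
#' @inheritParams predict_amplicons
#' @return Data frame with columns `pair_id`, `n_amplicons`, `verdict`
#'   (`"no genomic origin"` or `"possible tandem repeat"`); per-pair amplicon
#'   tables in the `amplicons` attribute.
#' @export
tandem_repeat_check <- function(pairs, genomic, max_len = 3000L,
                                seed_3prime = 10L, max_mismatch_5prime = 2L) {
  amps <- lapply(pairs, predict_amplicons, template = genomic,
                 max_len = max_len, seed_3prime = seed_3prime,
                 max_mismatch_5prime = max_mismatch_5prime)
  out <- data.frame(
    pair_id = vapply(pairs, `[[`, "", "pair_id"),
    n_amplicons = vapply(amps, nrow, 0L),
    verdict = ifelse(vapply(amps, nrow, 0L) == 0L,
                     "no genomic origin", "possible tandem repeat"))
  rownames(out) <- NULL
  attr(out, "amplicons") <- amps
  out
}

#' Does an amplicon sequence contain a back-splice junction?
#'
#' @param amplicon_seq Amplicon sequence.
#' @param bsj BSJ 2k-mer from [bsj_kmer()].
#' @return Logical.
#' @export
amplicon_contains_bsj <- function(amplicon_seq, bsj) {
  length(str_find_all(bsj, amplicon_seq)) > 0L
}

#' Read / write primer-pair tables
#'
#' The interchange format is a TSV with columns `name`, `sequence`, `role`
#' (`fwd` or `rev`) and `pair_id`; each `pair_id` must have exactly one
#' primer per role.
#'
#' @param path File path.
#' @return `read_primer_tsv` returns a named list of [new_primer_pair()]
#'   objects; `write_primer_tsv` returns `path` invisibly.
#' @export
read_primer_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence", "role", "pair_id") %in% names(tab)))
  pairs <- lapply(split(tab, tab$pair_id), function(g) {
    f <- g[g$role == "fwd", ]
    r <- g[g$role == "rev", ]
    if (nrow(f) != 1L || nrow(r) != 1L)
      stop("pair '", g$pair_id[1], "' needs exactly one fwd and one rev row")
    new_primer_pair(new_primer(f$name, f$sequence, check_length = FALSE),
                    new_primer(r$name, r$sequence, check_length = FALSE),
                    pair_id = g$pair_id[1])
  })
  pairs[unique(tab$pair_id)]
}

#' @rdname read_primer_tsv
#' @param pairs List of [new_primer_pair()] objects.
#' @export
write_primer_tsv <- function(pairs, path) {
  rows <- lapply(pairs, function(p)
    data.frame(name = c(p$fwd$name, p$rev$name),
               sequence = c(p$fwd$seq, p$rev$seq),
               role = c("fwd", "rev"), pair_id = p$pair_id))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
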