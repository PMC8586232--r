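#' Primer and antisense-oligonucleotide design
#'
#' Implements the placement and specificity rules used to validate circRNAs:
#' convergent pairs for linear transcript fragments (70-150 nt products,
#' Tm 57-63 degC, optimum 60, pair difference <= 3), divergent pairs placed
#' inside one exon of the circle, BSJ-spanning forward primers whose 3' end
#' reaches a configurable number of bases into the acceptor exon (default 4,
#' exploiting the 3'-end specificity of Taq polymerases), and BSJ-directed
#' antisense oligonucleotides for RNase H work.
#'
#' @name primer_design
NULL

#' Design constraints for primer construction
#'
#' @param tm_min,tm_max,tm_opt Melting-temperature window and optimum (degC).
#' @param tm_pair_diff_max Maximal Tm difference within a pair (degC).
#' @param product_min,product_max Spliced product length range (nt).
#' @param primer_len_range Allowed primer lengths (nt).
#' @param overhang_min Minimal number of 3' bases inside the acceptor exon
#'   for BSJ-spanning primers.
#' @param product_max_circ Cap for circular (divergent) products, which may
#'   legitimately exceed the linear design range.
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(tm_min = 57, tm_max = 63, tm_opt = 60,
                               tm_pair_diff_max = 3, product_min = 70,
                               product_max = 150,
                               primer_len_range = c(18L, 25L),
                               overhang_min = 4L, product_max_circ = 3000L) {
  stopifnot(tm_min <= tm_opt, tm_opt <= tm_max, product_min < product_max,
            overhang_min >= 1L)
  list(tm_min = tm_min, tm_max = tm_max, tm_opt = tm_opt,
       tm_pair_diff_max = tm_pair_diff_max, product_min = product_min,
       product_max = product_max, primer_len_range = primer_len_range,
       overhang_min = overhang_min, product_max_circ = product_max_circ)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); the 6 missing dinucleotides follow by
# complementary symmetry.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor thermodynamics (SantaLucia 1998) with terminal
#' initiation terms, a sodium entropy correction of
#' `0.368 (N - 1) ln[Na+]` cal/(mol K), and
#' `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15` for a non-self-complementary
#' oligo at total strand concentration `C`.
#'
#' @param p A [new_primer()] or character sequence (ACGT).
#' @param na_mM Monovalent cation concentration, mM (default 50).
#' @param oligo_nM Total oligo concentration, nM (default 500).
#' @return Melting temperature in degC.
#' @export
melting_temperature <- function(p, na_mM = 50, oligo_nM = 500) {
  seq <- if (inherits(p, "primer")) p$seq else toupper(p)
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in primer sequence")
  n <- nchar(seq)
  if (n < 2L) stop("primer too short for nearest-neighbor Tm")
  dimers <- substring(seq, 1:(n - 1), 2:n)
  dh <- sum(.nn_dh[dimers])
  ds <- sum(.nn_ds[dimers])
  for (term in c(substr(seq, 1, 1), substr(seq, n, n))) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
  r <- 1.9872
  ct <- oligo_nM * 1e-9
  1000 * dh / (ds + r * log(ct / 4)) - 273.15
}

# Hairpin screen: a stem of >= `stem` perfectly complementary bases closing
# a loop of <= `max_loop` bases.
has_hairpin <- function(seq, stem = 4L, max_loop = 3L) {
  n <- nchar(seq)
  for (i in seq_len(max(0L, n - 2L * stem))) {
    s1 <- substr(seq, i, i + stem - 1L)
    for (loop in 0:max_loop) {
      j <- i + stem + loop
      if (j + stem - 1L > n) break
      if (substr(seq, j, j + stem - 1L) == revcomp(s1)) return(TRUE)
    }
  }
  FALSE
}

# Self-dimer screen: any >= min_len-mer whose reverse complement also occurs
# in the oligo.
has_self_dimer <- function(seq, min_len = 8L) {
  n <- nchar(seq)
  if (n < min_len) return(FALSE)
  kmers <- substring(seq, 1:(n - min_len + 1L), min_len:n)
  any(vapply(kmers, function(k) grepl(revcomp(k), seq, fixed = TRUE), TRUE))
}

# Sequences (as template_molecule) of a set of transcripts/circRNAs used as
# cross-reactivity screen targets.
other_templates <- function(locus, ids) {
  lapply(ids, function(id) {
    if (id %in% names(locus$transcripts))
      new_template(id, spliced_sequence(id, locus), "linear")
    else
      new_template(id, circ_sequence(id, locus, warn_declared = FALSE),
                   "circular")
  })
}

#' Design BSJ-spanning forward primers for a circRNA
#'
#' Every candidate covers the back-splice junction with at least
#' `overhang_min` 3'-terminal bases inside the acceptor exon; the 5' part
#' lies in the donor exon. Candidates must have zero binding sites (under
#' the [find_binding_sites()] seed model) on every member of `others`, which
#' by default is every other transcript and circRNA of the locus. Ranked by
#' `|Tm - tm_opt|`, then decreasing overhang, then sequence.
#'
#' @param circ A `circ_rna` or its id.
#' @param locus The `gene_locus`.
#' @param others Character vector of transcript/circRNA ids to screen
#'   against; default all others in the locus.
#' @param k [design_constraints()].
#' @param seed_3prime,max_mismatch_5prime Binding-model parameters for the
#'   specificity screen.
#' @return Data frame of accepted candidates (`seq`, `length`, `overhang`,
#'   `tm`), best first; when empty, the `reasons` attribute holds a named
#'   rejection histogram.
#' @export
design_bsj_primer <- function(circ, locus, others = NULL,
                              k = design_constraints(), seed_3prime = 10L,
                              max_mismatch_5prime = 2L) {
  cc <- resolve_circ(locus, circ)
  if (is.null(others))
    others <- setdiff(c(names(locus$transcripts), names(locus$circRNAs)),
                      cc$id)
  templates <- other_templates(locus, others)
  t <- resolve_transcript(locus, cc$parent)
  don <- exon_sequence(locus, t, cc$donor_exon)
  acc <- exon_sequence(locus, t, cc$acceptor_exon)

  reasons <- c(tm_out_of_range = 0L, hairpin = 0L, self_dimer = 0L,
               cross_reactive = 0L, flank_too_short = 0L)
  rows <- list()
  for (len in seq(k$primer_len_range[1], k$primer_len_range[2])) {
    for (ov in seq(k$overhang_min, len - 1L)) {
      up <- len - ov
      if (up > nchar(don) || ov > nchar(acc)) {
        reasons["flank_too_short"] <- reasons["flank_too_short"] + 1L
        next
      }
      pseq <- paste0(substr(don, nchar(don) - up + 1L, nchar(don)),
                     substr(acc, 1L, ov))
      tm <- melting_temperature(pseq)
      if (tm < k$tm_min || tm > k$tm_max) {
        reasons["tm_out_of_range"] <- reasons["tm_out_of_range"] + 1L
        next
      }
      if (has_hairpin(pseq)) { reasons["hairpin"] <- reasons["hairpin"] + 1L; next }
      if (has_self_dimer(pseq)) { reasons["self_dimer"] <- reasons["self_dimer"] + 1L; next }
      pr <- new_primer(paste0("bsj_", cc$id, "_", len, "_", ov), pseq)
      hits <- vapply(templates, function(tp)
        nrow(find_binding_sites(pr, tp, seed_3prime, max_mismatch_5prime)), 0L)
      if (any(hits > 0L)) {
        reasons["cross_reactive"] <- reasons["cross_reactive"] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(seq = pseq, length = len,
                                              overhang = ov, tm = tm)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(seq = character(0), length = integer(0),
                      overhang = integer(0), tm = numeric(0))
    attr(out, "reasons") <- reasons
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$tm - k$tm_opt), -out$overhang, out$seq), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reasons") <- reasons
  out
}

# All windows of an exon's spliced sequence passing the Tm window and the
# structure screens; returns start (1-based within the exon), length, seq, tm.
tm_windows <- function(exon_seq, k) {
  rows <- list()
  for (len in seq(k$primer_len_range[1], k$primer_len_range[2])) {
    n <- nchar(exon_seq) - len + 1L
    if (n < 1L) next
    starts <- seq_len(n)
    seqs <- substring(exon_seq, starts, starts + len - 1L)
    tms <- vapply(seqs, melting_temperature, 0)
    ok <- tms >= k$tm_min & tms <= k$tm_max
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <-
      data.frame(start = starts[ok], length = len, seq = seqs[ok],
                 tm = tms[ok])
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), length = integer(0),
                      seq = character(0), tm = numeric(0)))
  out <- do.call(rbind, rows)
  keep <- !vapply(out$seq, has_hairpin, TRUE) &
    !vapply(out$seq, has_self_dimer, TRUE)
  out[keep, , drop = FALSE]
}

#' Design a divergent primer pair inside one exon of a circRNA
#'
#' Both primers sit in the same exon, pointing away from each other on the
#' linear parent (reverse primer upstream of the forward primer). On the
#' circle the pair becomes convergent across the BSJ and yields one monomer
#' product of length `circle_len - gap`, where `gap` is the stretch between
#' the two binding sites.
#'
#' @param circ A `circ_rna` or its id.
#' @param locus The `gene_locus`.
#' @param exon Transcript-order index of the exon carrying the pair;
#'   defaults to the acceptor exon. Must lie within the circle's exon range.
#' @param k [design_constraints()].
#' @return A [new_primer_pair()], or `NULL` with a `reason` attribute when
#'   no placement satisfies the constraints.
#' @export
design_divergent_pair <- function(circ, locus, exon = NULL,
                                  k = design_constraints()) {
  cc <- resolve_circ(locus, circ)
  if (is.null(exon)) exon <- cc$acceptor_exon
  if (exon < cc$acceptor_exon || exon > cc$donor_exon)
    stop("exon ", exon, " is not part of circRNA '", cc$id, "'")
  eseq <- exon_sequence(locus, resolve_transcript(locus, cc$parent), exon)
  circ_len <- nchar(circ_sequence(cc, locus, warn_declared = FALSE))
  w <- tm_windows(eseq, k)
  if (nrow(w) == 0L)
    return(structure(NULL, reason = "exon too short for Tm window"))
  best <- NULL
  best_score <- Inf
  for (i in seq_len(nrow(w))) {      # reverse primer window (upstream)
    rev_end <- w$start[i] + w$length[i] - 1L
    cand <- w[w$start > rev_end, , drop = FALSE]  # forward strictly downstream
    if (nrow(cand) == 0L) next
    gap <- cand$start - rev_end - 1L
    prod <- circ_len - gap
    ok <- prod >= 1L & prod <= k$product_max_circ &
      abs(cand$tm - w$tm[i]) <= k$tm_pair_diff_max
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    score <- abs(cand$tm - k$tm_opt) + abs(w$tm[i] - k$tm_opt)
    j <- order(score, cand$seq)[1]
    if (score[j] < best_score) {
      best_score <- score[j]
      best <- list(rev = w[i, ], fwd = cand[j, ])
    }
  }
  if (is.null(best))
    return(structure(NULL, reason = "no facing window pair within constraints"))
  new_primer_pair(
    new_primer(paste0("div_", cc$id, "_fwd"), best$fwd$seq),
    new_primer(paste0("div_", cc$id, "_rev"), revcomp(best$rev$seq)),
    pair_id = paste0("div_", cc$id))
}

#' Design a convergent primer pair on a linear transcript
#'
#' Three placements: both primers in one exon (`same_exon`), primers in
#' consecutive exons separated by one intron (`cross_intron`), or the
#' forward primer spanning an exon-exon junction (`junction_spanning`).
#' The spliced product must fall in `[product_min, product_max]`.
#'
#' @param transcript A `linear_transcript` or its id.
#' @param locus The `gene_locus`.
#' @param placement Placement rule.
#' @param k [design_constraints()].
#' @param anchor_exon Transcript-order index of the exon holding the forward
#'   primer (for `same_exon`, both primers). Default 1.
#' @return A [new_primer_pair()], or `NULL` with a `reason` attribute.
#' @export
design_convergent_pair <- function(transcript, locus,
                                   placement = c("same_exon", "cross_intron",
                                                 "junction_spanning"),
                                   k = design_constraints(),
                                   anchor_exon = 1L) {
  placement <- match.arg(placement)
  t <- resolve_transcript(locus, transcript)
  n_ex <- nrow(t$exons)
  ex_seqs <- vapply(seq_len(n_ex), function(i) exon_sequence(locus, t, i), "")
  ex_len <- nchar(ex_seqs)
  offs <- cumsum(c(0L, ex_len))[seq_len(n_ex)]  # spliced offset of each exon
  spliced <- paste(ex_seqs, collapse = "")

  fw <- NULL
  if (placement == "same_exon" || placement == "cross_intron") {
    fw <- tm_windows(ex_seqs[anchor_exon], k)
    fw$start <- fw$start + offs[anchor_exon]
  } else {
    if (anchor_exon >= n_ex)
      return(structure(NULL, reason = "no junction downstream of anchor exon"))
    # windows crossing the junction with >= 4 bases each side
    b <- offs[anchor_exon + 1L]  # spliced position of junction (end of exon)
    rows <- list()
    for (len in seq(k$primer_len_range[1], k$primer_len_range[2])) {
      starts <- seq(max(1L, b - len + 5L), b - 3L)
      starts <- starts[starts + len - 1L <= nchar(spliced)]
      if (length(starts) == 0L) next
      seqs <- substring(spliced, starts, starts + len - 1L)
      tms <- vapply(seqs, melting_temperature, 0)
      ok <- tms >= k$tm_min & tms <= k$tm_max
      if (any(ok)) rows[[length(rows) + 1L]] <-
          data.frame(start = starts[ok], length = len, seq = seqs[ok],
                     tm = tms[ok])
    }
    fw <- if (length(rows)) do.call(rbind, rows) else
      data.frame(start = integer(0), length = integer(0), seq = character(0),
                 tm = numeric(0))
    if (nrow(fw)) {
      keep <- !vapply(fw$seq, has_hairpin, TRUE) &
        !vapply(fw$seq, has_self_dimer, TRUE)
      fw <- fw[keep, , drop = FALSE]
    }
  }
  if (nrow(fw) == 0L)
    return(structure(NULL, reason = "no forward window within constraints"))

  rev_exon <- switch(placement, same_exon = anchor_exon,
                     cross_intron = anchor_exon + 1L,
                     junction_spanning = anchor_exon + 1L)
  if (rev_exon > n_ex)
    return(structure(NULL, reason = "no downstream exon for reverse primer"))
  rv <- tm_windows(ex_seqs[rev_exon], k)
  if (nrow(rv) == 0L)
    return(structure(NULL, reason = "no reverse window within constraints"))
  rv$start <- rv$start + offs[rev_exon]

  best <- NULL
  best_score <- Inf
  for (i in seq_len(nrow(fw))) {
    prod <- rv$start + rv$length - fw$start[i]
    ok <- rv$start > fw$start[i] + fw$length[i] - 1L &
      prod >= k$product_min & prod <= k$product_max &
      abs(rv$tm - fw$tm[i]) <= k$tm_pair_diff_max
    cand <- rv[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    score <- abs(cand$tm - k$tm_opt) + abs(fw$tm[i] - k$tm_opt)
    j <- order(score, cand$seq)[1]
    if (score[j] < best_score) {
      best_score <- score[j]
      best <- list(fwd = fw[i, ], rev = cand[j, ])
    }
  }
  if (is.null(best))
    return(structure(NULL, reason = "no product within range"))
  new_primer_pair(
    new_primer(paste0("conv_", t$id, "_fwd"), best$fwd$seq),
    new_primer(paste0("conv_", t$id, "_rev"), revcomp(best$rev$seq)),
    pair_id = paste0("conv_", t$id, "_", placement))
}

#' Select antisense oligonucleotides for a target
#'
#' Linear targets: candidate asONs are reverse complements of target windows
#' lying entirely inside unpaired stretches of at least 10 nt (from an input
#' per-base pairing map; secondary-structure prediction itself is out of
#' scope). Circular targets: only the BSJ distinguishes the circle from its
#' parent, so every candidate spans the junction. Candidates with a >= 8 bp
#' self-dimer, or whose target window occurs in a member of `others`, are
#' rejected.
#'
#' @param target A `circ_rna` (or its id) for junction-spanning design, or a
#'   character target sequence for linear design.
#' @param locus The `gene_locus` (required for circular targets).
#' @param pairing_map Logical vector, one element per target base, `TRUE`
#'   where the base is predicted unpaired (linear targets only).
#' @param n Maximum number of candidates (default 5).
#' @param ason_len Oligo length (default 20 nt; shrunk to the unpaired
#'   window when that is shorter, floor 10 nt).
#' @param min_unpaired Minimal unpaired stretch (default 10 nt).
#' @param others Optional list of cross-screen sequences (character).
#' @return Data frame with columns `name`, `seq`, `target`,
#'   `junction_spanning`, `region_start`, `region_end` (target coordinates);
#'   empty with a `reason` attribute when nothing qualifies.
#' @export
select_ason <- function(target, locus = NULL, pairing_map = NULL, n = 5L,
                        ason_len = 20L, min_unpaired = 10L, others = list()) {
  empty <- data.frame(name = character(0), seq = character(0),
                      target = character(0), junction_spanning = logical(0),
                      region_start = integer(0), region_end = integer(0))
  screen <- function(window_seq) {
    ok <- !has_self_dimer(revcomp(window_seq))
    if (ok && length(others))
      ok <- !any(vapply(others, function(o)
        length(str_find_all(window_seq, o)) > 0L, TRUE))
    ok
  }
  if (is.character(target) && is.null(locus)) {
    seqn <- toupper(target)
    if (is.null(pairing_map)) pairing_map <- rep(TRUE, nchar(seqn))
    stopifnot(length(pairing_map) == nchar(seqn))
    r <- rle(pairing_map)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts, end = ends)[r$values & r$lengths >= min_unpaired, ,
                                                   drop = FALSE]
    if (nrow(runs) == 0L)
      return(structure(empty, reason = "no unpaired stretch >= min_unpaired"))
    rows <- list()
    for (ri in seq_len(nrow(runs))) {
      wlen <- min(ason_len, runs$end[ri] - runs$start[ri] + 1L)
      for (s in seq(runs$start[ri], runs$end[ri] - wlen + 1L)) {
        wseq <- substr(seqn, s, s + wlen - 1L)
        if (!screen(wseq)) next
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0("ason_lin_", length(rows) + 1L), seq = revcomp(wseq),
          target = "linear", junction_spanning = FALSE,
          region_start = s, region_end = s + wlen - 1L)
        if (length(rows) >= n) break
      }
      if (length(rows) >= n) break
    }
    if (length(rows) == 0L)
      return(structure(empty, reason = "all windows failed screens"))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  # circular target: candidates span the BSJ. Ordered center-out, so the
  # most junction-balanced windows (no long single-exon stretch that could
  # form an off-target heteroduplex) come first; every `cross_min`-long
  # subwindow is screened against the other locus members.
  cc <- resolve_circ(locus, target)
  cs <- circ_sequence(cc, locus, warn_declared = FALSE)
  if (length(others) == 0L) {
    other_ids <- setdiff(c(names(locus$transcripts), names(locus$circRNAs)),
                         cc$id)
    others <- lapply(other_ids, function(id)
      if (id %in% names(locus$transcripts)) spliced_sequence(id, locus)
      else strrep(circ_sequence(id, locus, warn_declared = FALSE), 2L))
  }
  cross_min <- 12L
  cross_ok <- function(wseq) {
    nw <- nchar(wseq)
    if (nw < cross_min || length(others) == 0L) return(TRUE)
    subs <- substring(wseq, 1:(nw - cross_min + 1L), cross_min:nw)
    !any(vapply(others, function(o)
      any(vapply(subs, function(k) length(str_find_all(k, o)) > 0L, TRUE)),
      TRUE))
  }
  L <- nchar(cs)
  doubled <- strrep(cs, 2L)
  junction <- L  # BSJ sits between positions L and L + 1 of the doubled view
  rows <- list()
  min_side <- 4L
  offs <- seq(min_side, ason_len - min_side)
  offs <- offs[order(abs(offs - ason_len / 2))]  # balanced splits first
  for (off in offs) {
    s <- junction - (ason_len - off) + 1L
    if (s < 1L || s + ason_len - 1L > 2L * L) next
    wseq <- substr(doubled, s, s + ason_len - 1L)
    if (!screen(wseq) || !cross_ok(wseq)) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("ason_", cc$id, "_", off), seq = revcomp(wseq),
      target = cc$id, junction_spanning = TRUE,
      region_start = s, region_end = s + ason_len - 1L)
    if (length(rows) >= n) break
  }
  if (length(rows) == 0L)
    return(structure(empty, reason = "no junction window passed screens"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
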