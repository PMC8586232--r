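#' In silico RNase R and RNase H + asON topology tests
#'
#' RNase R is a 3'->5' exoribonuclease that degrades linear RNA but spares
#' covalently closed circles; comparing qPCR copies before and after
#' digestion therefore reads out topology as an lg10(B/A) ratio. RNase H
#' cleaves the RNA strand of a DNA:RNA heteroduplex, so a BSJ-spanning
#' antisense oligonucleotide opens exactly the targeted circle: the
#' linearized molecule can no longer template a divergent-primer product.
#'
#' @name nuclease_models
NULL

#' Construct an RNA population
#'
#' @param members Data frame with columns `id`, `topology` (`"linear"` or
#'   `"circular"`) and `copies` (non-negative abundance).
#' @return An `rna_population` (the validated data frame, with a `cleaved`
#'   logical column added).
#' @export
new_rna_population <- function(members) {
  stopifnot(all(c("id", "topology", "copies") %in% names(members)))
  if (anyDuplicated(members$id)) stop("duplicate member ids")
  if (any(members$copies < 0)) stop("negative copies")
  if (!all(members$topology %in% c("linear", "circular")))
    stop("topology must be linear or circular")
  members <- as.data.frame(members)
  if (is.null(members$cleaved)) members$cleaved <- logical(nrow(members))
  structure(members, class = c("rna_population", "data.frame"))
}

#' Simulate RNase R digestion of an RNA population
#'
#' Copies are scaled by a topology-specific survival fraction and, when
#' `noise_sdlog > 0`, multiplied by seeded lognormal noise
#' (`meanlog = 0`). Defaults: 0.3 percent of linear copies survive,
#' circles are untouched.
#'
#' @param pop An [new_rna_population()].
#' @param linear_survival,circular_survival Surviving fraction per topology.
#' @param noise_sdlog Multiplicative lognormal noise (sd on the natural-log
#'   scale; 0 disables noise).
#' @param seed Optional RNG seed for reproducibility.
#' @return The digested `rna_population`.
#' @export
rnase_r_simulate <- function(pop, linear_survival = 0.003,
                             circular_survival = 1.0, noise_sdlog = 0,
                             seed = NULL) {
  stopifnot(linear_survival >= 0, linear_survival <= 1,
            circular_survival >= 0, circular_survival <= 1)
  if (!is.null(seed)) set.seed(seed)
  surv <- ifelse(pop$topology == "circular", circular_survival,
                 linear_survival)
  noise <- if (noise_sdlog > 0) stats::rlnorm(nrow(pop), 0, noise_sdlog)
           else rep(1, nrow(pop))
  out <- pop
  out$copies <- pop$copies * surv * noise
  out
}

#' lg10 copy ratio and topology call for an RNase R experiment
#'
#' @param A Copies without RNase R (must be > 0).
#' @param B Copies with RNase R (>= 0).
#' @param linear_max Call `linear-consistent` when the ratio is at or below
#'   this value (default -1.0, i.e. a reduction of at least one order of
#'   magnitude).
#' @param circular_min Call `circular-consistent` at or above this value
#'   (default -0.3); between the two thresholds the call is
#'   `indeterminate`.
#' @return List with `lg10_ratio` (2 decimals, half away from zero) and
#'   `topology_call`.
#' @export
rnase_r_ratio <- function(A, B, linear_max = -1.0, circular_min = -0.3) {
  if (A <= 0) stop("copies without RNase R must be positive")
  if (B < 0) stop("negative copies")
  if (B == 0)
    return(list(lg10_ratio = -Inf, topology_call = "linear-consistent"))
  r <- round_half_away(log10(B / A), 2)
  call <- if (r <= linear_max) "linear-consistent"
    else if (r >= circular_min) "circular-consistent"
    else "indeterminate"
  list(lg10_ratio = r, topology_call = call)
}

#' RNase H cleavage guided by an antisense oligonucleotide
#'
#' A member is cleaved iff its sequence contains a perfect complement of at
#' least `min_duplex` consecutive asON bases (the minimal DNA:RNA
#' heteroduplex RNase H acts on). A cleaved circle is converted to a linear
#' molecule opened at the cut; member count never changes.
#'
#' @param pop An [new_rna_population()] whose ids resolve in `locus`
#'   (transcript ids give spliced sequences, circRNA ids circular ones).
#' @param ason asON sequence (character) or one row of [select_ason()]
#'   output.
#' @param locus The `gene_locus`.
#' @param min_duplex Minimal perfect heteroduplex length (default 12 nt).
#' @return The transformed population; cleaved members have `cleaved =
#'   TRUE` and, when circular, topology switched to linear. The `sequences`
#'   attribute maps id to the (possibly linearized-at-cut) sequence.
#' @export
rnase_h_ason <- function(pop, ason, locus, min_duplex = 12L) {
  if (is.data.frame(ason)) ason <- ason$seq[1]
  ason <- toupper(ason)
  la <- nchar(ason)
  seqs <- list()
  out <- pop
  for (i in seq_len(nrow(pop))) {
    id <- pop$id[i]
    circular <- pop$topology[i] == "circular"
    s <- if (id %in% names(locus$transcripts)) spliced_sequence(id, locus)
         else circ_sequence(id, locus, warn_declared = FALSE)
    scan <- if (circular) strrep(s, 2L) else s
    cut <- NA_integer_
    if (la >= min_duplex) {
      for (off in 0:(la - min_duplex)) {
        duplex <- substr(ason, off + 1L, off + min_duplex)
        hit <- str_find_all(revcomp(duplex), scan)
        if (circular) hit <- hit[hit <= nchar(s)]
        if (length(hit) > 0L) { cut <- hit[1]; break }
      }
    }
    if (!is.na(cut)) {
      out$cleaved[i] <- TRUE
      if (circular) {
        out$topology[i] <- "linear"
        # open the circle at the cut site
        s <- paste0(substr(strrep(s, 2L), cut, cut + nchar(s) - 1L))
      }
    }
    seqs[[id]] <- s
  }
  attr(out, "sequences") <- seqs
  out
}

#' Predict per-primer-pair signal change between two populations
#'
#' Each member is rendered as a PCR template (circular members as circles,
#' everything else linear), amplicons are predicted per pair, and the
#' signal is the summed copies of amplifiable members. The change class
#' compares after/before: `lost` below `lost_below`, `reduced` below
#' `reduced_below`, otherwise `unchanged`; a population with no amplifiable
#' signal at all is `lost`.
#'
#' @param pop_before,pop_after [new_rna_population()] objects (the after
#'   population typically from [rnase_h_ason()]).
#' @param pairs List of [new_primer_pair()] objects.
#' @param locus The `gene_locus`.
#' @param max_len Amplicon cap (default 3000 nt).
#' @param lost_below,reduced_below Fold thresholds (defaults 0.1 and 0.67).
#' @return Data frame with `pair_id`, `signal_before`, `signal_after`,
#'   `change`.
#' @export
predict_readout <- function(pop_before, pop_after, pairs, locus,
                            max_len = 3000L, lost_below = 0.1,
                            reduced_below = 0.67) {
  member_template <- function(pop, i) {
    id <- pop$id[i]
    seqs <- attr(pop, "sequences")
    s <- if (!is.null(seqs) && !is.null(seqs[[id]])) seqs[[id]]
      else if (id %in% names(locus$transcripts)) spliced_sequence(id, locus)
      else circ_sequence(id, locus, warn_declared = FALSE)
    new_template(id, s, topology = if (pop$topology[i] == "circular")
      "circular" else "linear", copies = pop$copies[i])
  }
  signal <- function(pop, pair) {
    tot <- 0
    for (i in seq_len(nrow(pop))) {
      tpl <- member_template(pop, i)
      if (nrow(predict_amplicons(pair, tpl, max_len = max_len)) > 0L)
        tot <- tot + pop$copies[i]
    }
    tot
  }
  rows <- lapply(pairs, function(pair) {
    b <- signal(pop_before, pair)
    a <- signal(pop_after, pair)
    change <- if (a == 0) "lost"
      else if (b == 0) "unchanged"
      else if (a / b < lost_below) "lost"
      else if (a / b < reduced_below) "reduced"
      else "unchanged"
    data.frame(pair_id = pair$pair_id, signal_before = b, signal_after = a,
               change = change)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
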