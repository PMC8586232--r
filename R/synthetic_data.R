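#' Seeded generators for loci, clone libraries and expression tables
#'
#' Emulates the study material: an 11-exon gene on the reverse strand with
#' four predicted circRNAs, clone libraries containing linear fragments,
#' authentic BSJ amplicons and cloning/RT artifacts, and grouped expression
#' tables with configurable fold changes. Every generator is bit-
#' reproducible under the config seed.
#'
#' @name synthetic_data
NULL

#' Synthesis configuration
#'
#' @param seed RNG seed (integer).
#' @param n_exons Number of exons of the primary transcript (default 11).
#' @param exon_len_range,intron_len_range Length ranges in nt.
#' @param gc GC content of generated sequence.
#' @param strand Gene strand (default `"-"`).
#' @param circ_defs Named list of `c(acceptor, donor)` exon ranges; default
#'   the four circle architectures of the fixture locus (exons 4-5, 3-6,
#'   2-6, 1-5).
#' @param planted_inverted_repeat `NULL`, or a list with `length`,
#'   `identity` (fraction) and `circ` (id whose flanking intron pair
#'   receives the repeat).
#' @param clone_mix Named fractions over `linear`, each circ id and
#'   `artifact`; must sum to 1.
#' @param artifact_rates Named fractions over the artifact mechanisms
#'   `template_switch`, `primer_duplication`, `exon_skip` (relative weights
#'   within the artifact share).
#' @param expr_model Data frame `transcript_id`, `group`, `mean` of
#'   expected abundances; `NULL` defaults to equal means of 100.
#' @param expr_sdlog Lognormal sd (natural-log scale) of expression draws.
#' @param n_samples Samples per group entering a pool (default 7).
#' @param rc_repeat_p Geometric parameter for rolling-circle repeat counts
#'   (default 0.5).
#' @param sub_rate Uniform substitution rate applied to clone reads.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(seed = 1L, n_exons = 11L,
                             exon_len_range = c(80L, 300L),
                             intron_len_range = c(200L, 1200L), gc = 0.5,
                             strand = "-",
                             circ_defs = list(circA = c(4L, 5L),
                                              circB = c(3L, 6L),
                                              circC = c(2L, 6L),
                                              circD = c(1L, 5L)),
                             planted_inverted_repeat = NULL,
                             clone_mix = c(linear = 0.6, circB = 0.25,
                                           artifact = 0.15),
                             artifact_rates = c(template_switch = 1 / 3,
                                                primer_duplication = 1 / 3,
                                                exon_skip = 1 / 3),
                             expr_model = NULL, expr_sdlog = 0.1,
                             n_samples = 7L, rc_repeat_p = 0.5,
                             sub_rate = 0) {
  stopifnot(abs(sum(clone_mix) - 1) < 1e-9)
  circ_defs <- lapply(circ_defs, function(x) {
    stopifnot(length(x) == 2L, x[1] <= x[2], x[1] >= 1L)
    as.integer(x)
  })
  structure(list(seed = as.integer(seed), n_exons = as.integer(n_exons),
                 exon_len_range = exon_len_range,
                 intron_len_range = intron_len_range, gc = gc,
                 strand = strand, circ_defs = circ_defs,
                 planted_inverted_repeat = planted_inverted_repeat,
                 clone_mix = clone_mix, artifact_rates = artifact_rates,
                 expr_model = expr_model, expr_sdlog = expr_sdlog,
                 n_samples = as.integer(n_samples),
                 rc_repeat_p = rc_repeat_p, sub_rate = sub_rate),
            class = "synthesis_config")
}

# Mutate `frac` of the positions of a sequence to a different base.
mutate_seq <- function(seq, frac) {
  n <- nchar(seq)
  k <- round(n * frac)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate a random gene locus
#'
#' Builds the locus in transcript-sense space (exon and intron sequences
#' drawn at the configured GC), optionally plants an inverted repeat into
#' the flanking-intron pair of one circRNA, then lays the pre-mRNA onto the
#' chromosome forward strand honoring the configured gene strand, with
#' 150 nt random flanks.
#'
#' @param cfg A [synthesis_config()].
#' @return A `gene_locus` with one primary transcript (`"TX1"`) carrying
#'   all exons, plus the configured circRNAs.
#' @export
make_locus <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_exons
  ex_len <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]), n,
                   replace = TRUE)
  in_len <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
                   max(0L, n - 1L), replace = TRUE)
  ex_seq <- vapply(ex_len, random_dna, "", gc = cfg$gc)
  in_seq <- vapply(in_len, random_dna, "", gc = cfg$gc)

  pir <- cfg$planted_inverted_repeat
  if (!is.null(pir)) {
    def <- cfg$circ_defs[[pir$circ]]
    if (is.null(def)) stop("planted repeat references unknown circ '",
                           pir$circ, "'")
    up <- def[1] - 1L   # intron preceding the acceptor exon
    dn <- def[2]        # intron following the donor exon
    if (up < 1L || dn > n - 1L)
      stop("circ '", pir$circ, "' lacks a flanking intron for the repeat")
    if (pir$length + 10L > min(in_len[up], in_len[dn]))
      stop("planted repeat longer than a flanking intron")
    core <- random_dna(pir$length, cfg$gc)
    ins <- function(s, seg, at) paste0(substr(s, 1, at - 1L), seg,
                                       substr(s, at + nchar(seg), nchar(s)))
    in_seq[up] <- ins(in_seq[up], core, 6L)
    in_seq[dn] <- ins(in_seq[dn], mutate_seq(revcomp(core), 1 - pir$identity),
                      6L)
  }

  pre <- paste(c(rbind(ex_seq, c(in_seq, ""))), collapse = "")
  flank5 <- random_dna(150L, cfg$gc)
  flank3 <- random_dna(150L, cfg$gc)
  # transcript-sense coordinates of exons within the pre-mRNA
  starts <- cumsum(c(1L, utils::head(ex_len + c(in_len, 0L), -1L)))
  ends <- starts + ex_len - 1L
  L <- nchar(pre)
  if (cfg$strand == "+") {
    genome <- paste0(flank5, pre, flank3)
    g_start <- 150L + starts
    g_end <- 150L + ends
  } else {
    genome <- paste0(flank3, revcomp(pre), flank5)
    g_start <- 150L + (L - ends + 1L)
    g_end <- 150L + (L - starts + 1L)
  }
  tx <- new_transcript("TX1", data.frame(start = g_start, end = g_end),
                       strand = cfg$strand)
  circs <- lapply(names(cfg$circ_defs), function(id)
    new_circ_rna(id, "TX1", cfg$circ_defs[[id]][1], cfg$circ_defs[[id]][2]))
  new_gene_locus("synthetic_locus", genome, cfg$strand, list(tx), circs)
}

# One circRNA-derived clone read: rolling-circle cDNA, then the shortest
# divergent amplicon (PCR favors short products).
circ_read <- function(locus, circ_id, pair, rc_repeat_p, max_len = 3000L) {
  cs <- circ_sequence(circ_id, locus, warn_declared = FALSE)
  repeats <- 1L + stats::rgeom(1L, rc_repeat_p)
  offset <- sample.int(nchar(cs), 1L) - 1L
  conc <- rolling_circle_cdna(cs, repeats + 1L, offset, id = circ_id)
  amps <- predict_amplicons(pair, conc, max_len = max_len)
  if (nrow(amps) == 0L) {
    amps <- predict_amplicons(pair, new_template(circ_id, cs, "circular"),
                              max_len = max_len)
  }
  if (nrow(amps) == 0L) return(NULL)
  amps$seq[1]
}

#' Generate a clone library with a known truth table
#'
#' Reads are drawn from `cfg$clone_mix`: linear reads are runs of 1-3
#' consecutive exons of the primary transcript; circRNA reads are divergent
#' amplicons of rolling-circle cDNA; artifact reads apply one mechanism
#' (template switch between two reads, tandem primer duplication, or
#' internal exon skipping in a circle). Each read is reverse-complemented
#' with probability 0.5 (TA cloning is non-directional) and optionally hit
#' by uniform substitution noise.
#'
#' @param cfg A [synthesis_config()].
#' @param locus The locus from [make_locus()].
#' @param pair The amplifying [new_primer_pair()] (must amplify at least
#'   one configured circle).
#' @param n Number of clones.
#' @param seed RNG seed; default `cfg$seed`.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame `id`, `category`, `circ`, `mechanism`).
#' @export
make_clone_library <- function(cfg, locus, pair, n, seed = cfg$seed) {
  set.seed(seed)
  if (n == 0L)
    return(list(reads = character(0),
                truth = data.frame(id = character(0), category = character(0),
                                   circ = character(0),
                                   mechanism = character(0))))
  tx <- locus$transcripts[[1]]
  n_ex <- nrow(tx$exons)
  circ_ids <- intersect(names(cfg$clone_mix), names(locus$circRNAs))
  cats <- sample(names(cfg$clone_mix), n, replace = TRUE,
                 prob = cfg$clone_mix)

  linear_read <- function() {
    r <- sample.int(3L, 1L)
    s <- sample.int(n_ex - r + 1L, 1L)
    paste(vapply(seq(s, s + r - 1L),
                 function(i) exon_sequence(locus, tx, i), ""), collapse = "")
  }
  skip_read <- function(circ_id) {
    cc <- locus$circRNAs[[circ_id]]
    span <- seq(cc$acceptor_exon, cc$donor_exon)
    if (length(span) < 3L) return(NULL)
    drop <- sample(span[-c(1L, length(span))], 1L)
    cs <- paste(vapply(setdiff(span, drop),
                       function(i) exon_sequence(locus, tx, i), ""),
                collapse = "")
    amps <- predict_amplicons(pair, new_template(circ_id, cs, "circular"))
    if (nrow(amps) == 0L) return(NULL)
    amps$seq[1]
  }

  reads <- character(n)
  truth <- data.frame(id = sprintf("clone_%03d", seq_len(n)),
                      category = NA_character_, circ = NA_character_,
                      mechanism = NA_character_)
  for (i in seq_len(n)) {
    cat_i <- cats[i]
    if (cat_i == "linear") {
      reads[i] <- linear_read()
      truth$category[i] <- "linear"
    } else if (cat_i %in% circ_ids) {
      s <- circ_read(locus, cat_i, pair, cfg$rc_repeat_p)
      if (is.null(s)) stop("primer pair does not amplify circle '", cat_i, "'")
      reads[i] <- s
      truth$category[i] <- "circ_consistent"
      truth$circ[i] <- cat_i
    } else {  # artifact
      mech <- sample(names(cfg$artifact_rates), 1L,
                     prob = cfg$artifact_rates)
      base_circ <- sample(circ_ids, 1L)
      if (mech == "exon_skip") {
        s <- skip_read(base_circ)
        if (is.null(s)) { mech <- "primer_duplication"; s <- NULL }
      }
      if (mech == "primer_duplication") {
        s <- circ_read(locus, base_circ, pair, cfg$rc_repeat_p)
        p <- pair$fwd$seq
        at <- str_find_all(p, s)
        if (length(at) == 0L) { at <- 1L; }
        s <- paste0(substr(s, 1L, at[1] + nchar(p) - 1L), p,
                    substr(s, at[1] + nchar(p), nchar(s)))
      } else if (mech == "template_switch") {
        a <- circ_read(locus, base_circ, pair, cfg$rc_repeat_p)
        b <- linear_read()
        s <- paste0(substr(a, 1L, floor(nchar(a) / 2)),
                    substr(b, ceiling(nchar(b) / 2), nchar(b)))
      }
      reads[i] <- s
      truth$category[i] <- "artifact"
      truth$mechanism[i] <- mech
    }
    if (cfg$sub_rate > 0) reads[i] <- mutate_seq(reads[i], cfg$sub_rate)
    if (stats::runif(1) < 0.5) reads[i] <- revcomp(reads[i])
  }
  names(reads) <- truth$id
  list(reads = reads, truth = truth)
}

#' Generate grouped expression tables
#'
#' Per-sample abundances are drawn lognormally around the configured group
#' means (`value = mean * exp(N(0, sdlog))`); the pooled value per group is
#' the arithmetic mean over `n_samples` draws.
#'
#' @param cfg A [synthesis_config()] with a non-`NULL` `expr_model` (data
#'   frame `transcript_id`, `group`, `mean`).
#' @param seed RNG seed; default `cfg$seed`.
#' @return List with `samples` (long data frame `transcript_id`, `group`,
#'   `sample`, `value`) and `pooled` (data frame `transcript_id`, `group`,
#'   `value` of pooled means).
#' @export
make_expression_tables <- function(cfg, seed = cfg$seed) {
  em <- cfg$expr_model
  if (is.null(em)) stop("cfg$expr_model must be set")
  stopifnot(all(c("transcript_id", "group", "mean") %in% names(em)))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(em)), function(i) {
    v <- em$mean[i] * exp(stats::rnorm(cfg$n_samples, 0, cfg$expr_sdlog))
    data.frame(transcript_id = em$transcript_id[i], group = em$group[i],
               sample = seq_len(cfg$n_samples), value = v)
  })
  samples <- do.call(rbind, rows)
  pooled <- stats::aggregate(value ~ transcript_id + group, samples, mean)
  list(samples = samples, pooled = pooled)
}
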