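test_that("nearest-neighbor Tm is deterministic, GC-monotone and matches the thermodynamic sum", {
  expect_lt(melting_temperature(strrep("AT", 10)),
            melting_temperature(strrep("GC", 10)))
  expect_identical(melting_temperature("AGCGTACGTTAGCGTACGTT"),
                   melting_temperature("AGCGTACGTTAGCGTACGTT"))
  # frozen values from an independent hand computation of the unified
  # nearest-neighbor sum (50 mM Na+, 500 nM oligo)
  expect_equal(melting_temperature("AGCGTACGTTAGCGTACGTT"), 57.2841,
               tolerance = 1e-4)
  expect_equal(melting_temperature("ACGTACGTACGTACGT"), 49.9552,
               tolerance = 1e-4)
  expect_equal(melting_temperature("GGCCGGAACTGAAGCGCATT"), 61.4114,
               tolerance = 1e-4)
  expect_error(melting_temperature("ACGTN"), "non-ACGT")
})

test_that("BSJ primers span the junction and reject sibling circle and parent", {
  loc <- fixture_locus()
  cand <- design_bsj_primer("circTRAM1-56", loc)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$overhang >= design_constraints()$overhang_min))
  don <- fixture_exon(6)
  acc <- fixture_exon(3)
  others <- list(
    parent = new_template("p", spliced_sequence("TRAM1-201", loc), "linear"),
    sibling = new_template("s",
                           circ_sequence("circTRAM1-57", loc,
                                         warn_declared = FALSE), "circular"))
  for (i in seq_len(min(nrow(cand), 5))) {
    s <- cand$seq[i]
    up <- cand$length[i] - cand$overhang[i]
    expect_identical(substr(s, 1, up),
                     substr(don, nchar(don) - up + 1, nchar(don)))
    expect_identical(substr(s, up + 1, cand$length[i]),
                     substr(acc, 1, cand$overhang[i]))
    p <- new_primer("c", s)
    for (tp in others)
      expect_equal(nrow(find_binding_sites(p, tp)), 0,
                   label = paste("candidate", i, "vs", tp$id))
  }
})

test_that("a primer lying entirely in the shared donor exon is cross-reactive", {
  loc <- fixture_locus()
  don <- fixture_exon(6)
  p0 <- new_primer("e6only", substr(don, nchar(don) - 19, nchar(don)))
  parent <- new_template("p", spliced_sequence("TRAM1-201", loc), "linear")
  sibling <- new_template("s", circ_sequence("circTRAM1-57", loc,
                                             warn_declared = FALSE),
                          "circular")
  expect_gt(nrow(find_binding_sites(p0, parent)), 0)
  expect_gt(nrow(find_binding_sites(p0, sibling)), 0)
})

test_that("BSJ designer output is the exhaustive window enumeration that passes all rules", {
  loc <- fixture_locus()
  k <- design_constraints()
  cand <- design_bsj_primer("circTRAM1-56", loc)
  don <- fixture_exon(6)
  acc <- fixture_exon(3)
  others_seqs <- c(
    vapply(setdiff(names(loc$transcripts), character(0)),
           function(id) spliced_sequence(id, loc), ""),
    vapply(setdiff(names(loc$circRNAs), "circTRAM1-56"),
           function(id) strrep(circ_sequence(id, loc,
                                             warn_declared = FALSE), 2), ""))
  # independent enumeration of every BSJ-overlapping window
  brute <- character(0)
  for (len in k$primer_len_range[1]:k$primer_len_range[2]) {
    for (ov in k$overhang_min:(len - 1)) {
      s <- paste0(substr(don, nchar(don) - (len - ov) + 1, nchar(don)),
                  substr(acc, 1, ov))
      tm <- melting_temperature(s)
      if (tm < k$tm_min || tm > k$tm_max) next
      hits <- vapply(others_seqs, function(o)
        nrow(brute_sites(s, o)) > 0, TRUE)
      if (any(hits)) next
      brute <- c(brute, s)
    }
  }
  expect_true(all(cand$seq %in% brute))
})

test_that("raising overhang_min never enlarges the BSJ candidate set", {
  loc <- fixture_locus()
  sets <- lapply(c(4L, 8L, 12L), function(ov)
    design_bsj_primer("circTRAM1-56", loc,
                      k = design_constraints(overhang_min = ov))$seq)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("designed divergent pairs are divergent on the parent and amplify their circle", {
  for (seed in c(501, 502, 503, 504, 505)) {
    loc <- make_locus(synthesis_config(seed = seed))
    div <- design_divergent_pair("circB", loc, exon = 4L)
    if (is.null(div)) next
    parent <- spliced_sequence("TX1", loc)
    expect_equal(classify_pair_orientation(div, parent), "divergent")
    expect_equal(nrow(predict_amplicons(div, new_template("p", parent))), 0)
    cs <- circ_sequence("circB", loc)
    amps <- predict_amplicons(div, new_template("c", cs, "circular"))
    expect_equal(nrow(amps), 1, label = paste("seed", seed))
    # product length arithmetic: circle length minus the gap between sites
    fwd_s <- find_binding_sites(div$fwd, new_template("p", parent))
    rev_s <- find_binding_sites(div$rev, new_template("p", parent))
    gap <- fwd_s$start[1] - rev_s$end[1] - 1
    expect_equal(amps$length, nchar(cs) - gap)
  }
})

test_that("convergent placements honor product ranges and junction spanning", {
  loc <- fixture_locus()
  k <- design_constraints()
  lin <- new_template("p", spliced_sequence("TRAM1-201", loc), "linear")
  same <- design_convergent_pair("TRAM1-201", loc, placement = "same_exon",
                                 anchor_exon = 11L)
  amp <- predict_amplicons(same, lin)
  expect_equal(nrow(amp), 1)
  expect_gte(amp$length, k$product_min)
  expect_lte(amp$length, k$product_max)
  expect_equal(classify_pair_orientation(same, lin$seq), "convergent")

  js <- design_convergent_pair("TRAM1-201", loc,
                               placement = "junction_spanning",
                               anchor_exon = 4L)
  expect_false(is.null(js))
  # forward primer spans the exon 4/5 junction with >= 4 bases on each side
  e4 <- fixture_exon(4)
  e5 <- fixture_exon(5)
  hit <- regexpr(js$fwd$seq, paste0(e4, e5), fixed = TRUE)
  expect_gt(hit, 0)
  expect_lte(hit, nchar(e4) - 3)
  expect_gte(hit + attr(hit, "match.length") - 1, nchar(e4) + 4)
  # and the junction-spanning primer cannot bind genomic DNA
  g <- new_template("g", loc$sequence, "genomic")
  expect_equal(nrow(find_binding_sites(js$fwd, g)), 0)
})

test_that("asON selection respects pairing maps and BSJ spanning", {
  set.seed(12)
  target <- rand_dna(120)
  full <- select_ason(target, n = 5)
  expect_equal(nrow(full), 5)
  expect_false(any(full$junction_spanning))
  # single 12-nt unpaired window: all candidates inside it, shrunk to 12 nt
  pm <- rep(FALSE, 120)
  pm[41:52] <- TRUE
  win <- select_ason(target, pairing_map = pm, n = 5)
  expect_gt(nrow(win), 0)
  expect_true(all(win$region_start >= 41 & win$region_end <= 52))
  expect_true(all(win$seq == rc_chr(substr(target, 41, 52))))
  # no stretch long enough
  none <- select_ason(target, pairing_map = rep(FALSE, 120))
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "reason"), "unpaired")

  loc <- fixture_locus()
  circ_as <- select_ason("circTRAM1-56", loc, n = 3)
  expect_gt(nrow(circ_as), 0)
  expect_true(all(circ_as$junction_spanning))
  km <- bsj_kmer("circTRAM1-56", loc, 4)
  expect_true(all(grepl(rc_chr(km), circ_as$seq, fixed = TRUE)))
})

test_that("designed BSJ primers have zero off-target sites across seeded loci", {
  for (seed in c(601, 602, 603, 604, 605, 606, 607, 608, 609, 610)) {
    loc <- make_locus(synthesis_config(seed = seed))
    cand <- design_bsj_primer("circB", loc)
    if (nrow(cand) == 0) next
    p <- new_primer("b", cand$seq[1])
    others <- c(setdiff(names(loc$transcripts), character(0)),
                setdiff(names(loc$circRNAs), "circB"))
    for (id in others) {
      tp <- if (id %in% names(loc$transcripts))
        new_template(id, spliced_sequence(id, loc), "linear")
      else new_template(id, circ_sequence(id, loc, warn_declared = FALSE),
                        "circular")
      expect_equal(nrow(find_binding_sites(p, tp)), 0,
                   label = paste("seed", seed, "vs", id))
    }
  }
})
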