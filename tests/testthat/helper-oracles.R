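# Independent oracle implementations used to cross-check the package.
# These deliberately use naive algorithms and share no code with R/.

.fixture_env <- new.env()

fixture_locus <- function() {
  if (is.null(.fixture_env$loc)) .fixture_env$loc <- tram1_fixture_locus()
  .fixture_env$loc
}

fixture_exon <- function(i) {
  loc <- fixture_locus()
  t <- loc$transcripts[["TRAM1-201"]]
  e <- t$exons[t$exons$index == i, ]
  s <- substr(loc$sequence, e$start, e$end)
  # locus is on the minus strand: reverse complement by hand
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

rc_chr <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                            collapse = "")

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Naive primer-site scan: every window compared character by character.
brute_sites <- function(primer_seq, subject, seed = 10L, mm = 2L) {
  L <- nchar(primer_seq)
  n <- nchar(subject)
  out <- data.frame(start = integer(0), end = integer(0),
                    strand = character(0))
  if (n < L) return(out)
  sub_chr <- strsplit(subject, "")[[1]]
  check <- function(oligo, strand) {
    oc <- strsplit(oligo, "")[[1]]
    seed_idx <- if (strand == "+") (L - seed + 1L):L else 1:seed
    for (s in 1:(n - L + 1L)) {
      win <- sub_chr[s:(s + L - 1L)]
      mis <- which(win != oc)
      if (any(mis %in% seed_idx)) next
      if (length(mis) > mm) next
      out <<- rbind(out, data.frame(start = s, end = s + L - 1L,
                                    strand = strand))
    }
  }
  check(primer_seq, "+")
  check(rc_chr(primer_seq), "-")
  out
}

# Brute-force amplicon enumeration from brute_sites (both role assignments).
brute_amplicons <- function(pair, subject, max_len = 3000L, seed = 10L,
                            mm = 2L) {
  sf <- brute_sites(pair$fwd$seq, subject, seed, mm)
  sr <- brute_sites(pair$rev$seq, subject, seed, mm)
  lens <- integer(0)
  for (cfg in list(list(a = sf, b = sr), list(a = sr, b = sf))) {
    ap <- cfg$a[cfg$a$strand == "+", , drop = FALSE]
    bm <- cfg$b[cfg$b$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(ap))) for (j in seq_len(nrow(bm))) {
      if (ap$start[i] <= bm$start[j] && ap$end[i] <= bm$end[j]) {
        l <- bm$end[j] - ap$start[i] + 1L
        if (l <= max_len) lens <- c(lens, l)
      }
    }
  }
  sort(lens)
}

# Textbook Gotoh local alignment, plain R, best score only.
# Gap of length g costs open + (g - 1) * ext.
oracle_local_score <- function(a, b, match = 5, mismatch = -4, open = 12,
                               ext = 4) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac)
  m <- length(bc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      s <- if (ac[i - 1] == bc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Independent maximal-exact-match finder: full (read x exon) equality
# matrix, match-run lengths by diagonal recurrence.
oracle_segments <- function(read, ex_seqs, seed = 15L) {
  rx <- utf8ToInt(read)
  out <- list()
  for (e in seq_along(ex_seqs)) {
    ex <- utf8ToInt(ex_seqs[e])
    n <- length(rx)
    m <- length(ex)
    if (n < seed || m < seed) next
    eq <- outer(rx, ex, "==")
    run <- matrix(0L, n, m)
    run[1, ] <- eq[1, ] * 1L
    run[, 1] <- eq[, 1] * 1L
    for (i in 2:n)
      run[i, 2:m] <- ifelse(eq[i, 2:m], run[i - 1, 1:(m - 1)] + 1L, 0L)
    # a maximal run ends where the next diagonal cell is not a match
    ends <- which(run >= seed, arr.ind = TRUE)
    if (nrow(ends) == 0L) next
    keep <- vapply(seq_len(nrow(ends)), function(k) {
      i <- ends[k, 1]; j <- ends[k, 2]
      i == n || j == m || !eq[i + 1, j + 1]
    }, TRUE)
    ends <- ends[keep, , drop = FALSE]
    for (k in seq_len(nrow(ends))) {
      i <- ends[k, 1]; j <- ends[k, 2]; l <- run[i, j]
      out[[length(out) + 1L]] <- data.frame(
        exon = e, exon_start = j - l + 1L, exon_end = j,
        read_start = i - l + 1L, read_end = i)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Exhaustive best chain over the oracle segments: depth-first search over
# all subsets with ordered, non-overlapping read intervals.
oracle_chain <- function(segs) {
  if (is.null(segs) || nrow(segs) == 0L) return(segs)
  segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
  n <- nrow(segs)
  w <- segs$read_end - segs$read_start + 1L
  memo <- new.env()
  # best chain starting at or after segment index i, with read position > p
  best_from <- function(i, p) {
    key <- paste(i, p)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n) return(list(score = 0, idx = integer(0)))
    res <- list(score = 0, idx = integer(0))
    for (k in i:n) {
      if (segs$read_start[k] <= p) next
      sub <- best_from(k + 1L, segs$read_end[k])
      if (w[k] + sub$score > res$score)
        res <- list(score = w[k] + sub$score, idx = c(k, sub$idx))
    }
    memo[[key]] <- res
    res
  }
  r <- best_from(1L, 0L)
  segs[r$idx, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent half-away-from-zero rounding
round_oracle <- function(x, d = 2) sign(x) * trunc(abs(x) * 10^d + 0.5) / 10^d

# strand-corrected exon sequence of any locus (first transcript by default)
exon_sequence_of <- function(locus, i, tx = 1L) {
  t <- locus$transcripts[[tx]]
  e <- t$exons[t$exons$index == i, ]
  s <- substr(locus$sequence, e$start, e$end)
  if (t$strand == "-") rc_chr(s) else s
}
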