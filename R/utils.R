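#' @useDynLib circvalid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse complement of a plain character DNA string (ACGTN).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1]]),
        collapse = "")
}

# Random DNA sequence with a given GC content, from the session RNG.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Round half away from zero to `digits` decimals (commercial rounding, the
# convention used for all reported lg10 ratios; base round() is half-to-even).
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# All start positions (1-based) of exact occurrences of `pattern` in
# `subject`, overlapping occurrences included (zero-width lookahead scan).
str_find_all <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
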