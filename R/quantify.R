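#' Marker-candidate lg10(fold-change) arithmetic
#'
#' The marker statistic throughout is the base-10 logarithm of a
#' case/control abundance ratio, reported to two decimals with half-away-
#' from-zero rounding. Candidate pools (the transcripts jointly amplified
#' by one primer pair) are summarized by the unweighted arithmetic mean of
#' member abundances per group before taking the log ratio.
#'
#' @name quantify
NULL

#' lg10 fold change of two abundances
#'
#' @param case,control Positive abundances (TPM or normalized copies).
#' @param digits Decimals reported (default 2, half away from zero).
#' @return Rounded `log10(case/control)`.
#' @export
lg10_fc <- function(case, control, digits = 2) {
  if (any(case <= 0) || any(control <= 0))
    stop("lg10 fold change undefined for non-positive abundances")
  round_half_away(log10(case / control), digits)
}

#' Pool a candidate's member transcripts and compute its lg10 fold change
#'
#' @param records Data frame with columns `transcript_id`, `group`, `value`.
#' @param members Character vector of transcript ids forming the pool.
#' @param case_group,control_group Group labels.
#' @return A `marker_candidate`: list with `member_ids`, `group_means`
#'   (named numeric), `lg10_fc`, `direction` (`"down"` iff negative).
#' @export
pool_candidate <- function(records, members, case_group, control_group) {
  stopifnot(all(c("transcript_id", "group", "value") %in% names(records)))
  sel <- records[records$transcript_id %in% members &
                   records$group %in% c(case_group, control_group), ]
  for (m in members) for (g in c(case_group, control_group))
    if (!any(sel$transcript_id == m & sel$group == g))
      stop("member '", m, "' has no value in group '", g, "'")
  means <- tapply(sel$value, sel$group, mean)
  fc <- lg10_fc(means[[case_group]], means[[control_group]])
  structure(list(member_ids = members,
                 group_means = c(means[case_group], means[control_group]),
                 lg10_fc = fc,
                 direction = if (fc < 0) "down" else "up"),
            class = "marker_candidate")
}

#' Partition transcripts into the pooled down-candidate set
#'
#' Only species with negative lg10(fold change) enter the pooled primer
#' target set; non-negative ones are excluded from the pool but retained in
#' the output. Transcripts at transcript support level 5 are annotated as
#' low-support (their existence is uncertain).
#'
#' @param records Data frame with columns `transcript_id`, `group`, `value`.
#' @param case_group,control_group Group labels.
#' @param tsl Optional named integer vector of transcript support levels.
#' @return Data frame with per-transcript `lg10_fc`, `selection`
#'   (`"down-pool"` or `"excluded"`) and `rationale`.
#' @export
select_candidates <- function(records, case_group, control_group,
                              tsl = NULL) {
  ids <- unique(records$transcript_id)
  rows <- lapply(ids, function(id) {
    sub <- records[records$transcript_id == id, ]
    ca <- sub$value[sub$group == case_group]
    co <- sub$value[sub$group == control_group]
    fc <- lg10_fc(mean(ca), mean(co))
    sel <- if (fc < 0) "down-pool" else "excluded"
    rationale <- if (fc < 0) "negative lg10(fc)" else "non-negative lg10(fc)"
    if (!is.null(tsl) && !is.na(tsl[id]) && tsl[id] == 5L)
      rationale <- paste0(rationale, "; TSL 5, existence uncertain")
    data.frame(transcript_id = id, lg10_fc = fc, selection = sel,
               rationale = rationale)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a copy number to an internal 18S rRNA reference
#'
#' @param target_copies Target copies.
#' @param reference_copies 18S reference copies (> 0).
#' @return `target_copies / reference_copies`.
#' @export
normalize_18s <- function(target_copies, reference_copies) {
  if (any(reference_copies <= 0)) stop("reference copies must be positive")
  target_copies / reference_copies
}
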