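# Admissible FLAG values for the preliminary extraction rules.
# Left-clipped split reads (CIGAR aSbM) and right-clipped ones (aMbS) are
# admitted under different FLAG sets: a clip facing away from the mate implies
# a long apparent insert (proper-pair bit off), a clip facing the mate a normal
# insert (bit on). Contig-level references add the inverted-orientation cases.
flag_sets <- list(
  split_left = list(chromosome = c(145L, 81L, 99L, 163L), contig_extra = c(113L, 117L)),
  split_right = list(chromosome = c(97L, 161L, 147L, 83L), contig_extra = c(65L, 129L)),
  discordant = list(chromosome = c(97L, 145L, 81L, 161L), contig_extra = c(177L, 113L, 129L, 65L))
)

admissible_flags <- function(kind, mode) {
  fs <- flag_sets[[kind]]
  if (identical(mode, "contig")) c(fs$chromosome, fs$contig_extra) else fs$chromosome
}

# Lenient matching admits a flag if it equals an admissible value after
# clearing the proper-pair bit on both sides (same geometry, different
# aligner convention for 0x2).
flag_matches <- function(flag, admissible, lenient = FALSE) {
  if (!lenient) return(flag %in% admissible)
  bitwAnd(flag, bitwNot(2L)) %in% unique(bitwAnd(admissible, bitwNot(2L)))
}

#' Extract candidate split reads from an alignment tibble
#'
#' Preliminary split-read extraction: keeps mapped primary records whose CIGAR
#' is a one-sided clip pattern (`aSbM` or `aMbS`, `H` counted like `S`) with
#' both the clipped length `a` and the aligned length `b` inside
#' `clip_bounds`, and whose FLAG is in the admissible set for the clip side.
#' Records clipped at both ends are rejected. These are *candidates*: a
#' candidate is only accepted as junction evidence after local re-alignment by
#' [verify_split_reads()] establishes an overlapping split alignment.
#'
#' @param aln Alignment tibble ([read_sam()]).
#' @param mode `"chromosome"` (finished reference) or `"contig"` (draft
#'   assembly; admits additional relative orientations of the two loci).
#' @param clip_bounds Inclusive bounds on both the clipped and the aligned
#'   length, in bp. Default `c(10, 150)` for 2 x 150 bp libraries; the upper
#'   bound should be the read length.
#' @param lenient_flags Match FLAGs by geometry, ignoring the proper-pair bit
#'   (default `FALSE`: strict integer match).
#' @return The matching subset of `aln` with extra columns `clip_side`
#'   (`"left"`/`"right"`), `clip_len`, `aligned_len`, `orientation_class`
#'   (the matched FLAG) and `mode`.
#' @export
detect_split_candidates <- function(aln, mode = c("chromosome", "contig"),
                                    clip_bounds = c(10L, 150L),
                                    lenient_flags = FALSE) {
  mode <- match.arg(mode)
  if (nrow(aln) == 0L) return(mutate(aln, clip_side = character(),
                                     clip_len = integer(), aligned_len = integer(),
                                     orientation_class = integer(), mode = character()))
  # cheap structural pre-filter before per-row CIGAR work
  shape <- stringr::str_detect(aln$cigar, "^\\d+[SH]\\d+M$|^\\d+M\\d+[SH]$")
  cand <- aln[aln$is_mapped & shape, , drop = FALSE]
  if (nrow(cand) == 0L) return(mutate(cand, clip_side = character(),
                                      clip_len = integer(), aligned_len = integer(),
                                      orientation_class = integer(), mode = character()))
  prof <- clip_profile_fast(cand$cigar)
  left <- prof$lead_clip > 0L
  clip_len <- ifelse(left, prof$lead_clip, prof$tail_clip)
  ok_flag <- ifelse(
    left,
    flag_matches(cand$flag, admissible_flags("split_left", mode), lenient_flags),
    flag_matches(cand$flag, admissible_flags("split_right", mode), lenient_flags)
  )
  keep <- ok_flag &
    clip_len >= clip_bounds[1] & clip_len <= clip_bounds[2] &
    prof$aligned_len >= clip_bounds[1] & prof$aligned_len <= clip_bounds[2]
  out <- cand[keep, , drop = FALSE]
  mutate(out,
         clip_side = ifelse(left[keep], "left", "right"),
         clip_len = clip_len[keep],
         aligned_len = prof$aligned_len[keep],
         orientation_class = .data$flag,
         mode = .env$mode)
}

#' Extract candidate discordant read pairs from an alignment tibble
#'
#' Keeps mapped primary records aligned end-to-end (CIGAR a single `M` run of
#' length greater than `min_aligned`) whose FLAG is in the admissible
#' discordant set: pairs whose orientation or spacing is inconsistent with the
#' reference, supporting an excision (deletion-spanning) or circularization
#' (everted) junction.
#'
#' @inheritParams detect_split_candidates
#' @param min_aligned Exclusive lower bound on the aligned length (default
#'   130 bp).
#' @param require_cross_contig In contig mode, require the mate to map to a
#'   different reference sequence (default `TRUE`).
#' @return The matching subset of `aln` with `aligned_len`,
#'   `orientation_class` and `mode` columns.
#' @export
detect_discordant_candidates <- function(aln, mode = c("chromosome", "contig"),
                                         min_aligned = 130L,
                                         lenient_flags = FALSE,
                                         require_cross_contig = TRUE) {
  mode <- match.arg(mode)
  if (nrow(aln) == 0L) return(mutate(aln, aligned_len = integer(),
                                     orientation_class = integer(), mode = character()))
  m <- stringr::str_match(aln$cigar, "^(\\d+)M$")[, 2]
  aligned <- suppressWarnings(as.integer(m))
  base_ok <- aln$is_mapped & !is.na(aligned) & aligned > min_aligned
  chrom_ok <- base_ok & flag_matches(aln$flag, flag_sets$discordant$chromosome, lenient_flags)
  keep <- chrom_ok
  if (mode == "contig") {
    extra_ok <- base_ok & flag_matches(aln$flag, flag_sets$discordant$contig_extra, lenient_flags)
    cross <- aln$mate_rname != aln$rname
    keep <- chrom_ok | (extra_ok & (!require_cross_contig | cross))
  }
  out <- aln[keep, , drop = FALSE]
  mutate(out,
         aligned_len = aligned[keep],
         orientation_class = .data$flag,
         mode = .env$mode)
}
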