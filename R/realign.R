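# Smith-Waterman scoring used for re-alignment. The clipped and aligned parts
# of a junction read each re-align locally to one reference locus; because the
# att core is present at both loci, the two query intervals overlap by the
# core length.
sw_scores <- function(match = 1, mismatch = -2, gap_open = 3, gap_extend = 1) {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                      mismatch = mismatch,
                                                      baseOnly = FALSE),
       gap_open = gap_open, gap_extend = gap_extend)
}

# Best local alignment of `read` (DNAString) against subject window; returns
# NULL when the window is degenerate. Coordinates are within read / window.
sw_align <- function(read, window, scores) {
  if (length(window) < 1L) return(NULL)
  pa <- Biostrings::pairwiseAlignment(read, window, type = "local",
                                      substitutionMatrix = scores$mat,
                                      gapOpening = scores$gap_open,
                                      gapExtension = scores$gap_extend)
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  alen <- Biostrings::nchar(pa)
  if (alen == 0L) return(NULL)
  list(q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
       s_start = Biostrings::start(sub), s_end = Biostrings::end(sub),
       score = Biostrings::score(pa),
       identity = Biostrings::nmatch(pa) / alen)
}

# Align read against reference window [start, end] on `ref_name`, forward or
# reverse strand. Query coordinates are reported on the read as stored
# (reference-forward orientation); reference coordinates on the forward strand.
align_in_window <- function(read, ref, ref_name, start, end, strand, scores) {
  seq_len_ref <- Biostrings::width(ref)[match(ref_name, names(ref))]
  start <- max(1L, start)
  end <- min(seq_len_ref, end)
  if (is.na(seq_len_ref) || end - start + 1L < 5L) return(NULL)
  window <- Biostrings::subseq(ref[[ref_name]], start, end)
  qlen <- Biostrings::nchar(read)
  if (strand == "-") {
    hit <- sw_align(Biostrings::reverseComplement(read), window, scores)
    if (is.null(hit)) return(NULL)
    q_start <- qlen - hit$q_end + 1L
    q_end <- qlen - hit$q_start + 1L
  } else {
    hit <- sw_align(read, window, scores)
    if (is.null(hit)) return(NULL)
    q_start <- hit$q_start
    q_end <- hit$q_end
  }
  tibble(ref = ref_name, strand = strand,
         q_start = as.integer(q_start), q_end = as.integer(q_end),
         r_start = as.integer(start + hit$s_start - 1L),
         r_end = as.integer(start + hit$s_end - 1L),
         score = hit$score, identity = hit$identity)
}

# Locate candidate loci for the clipped part of the read by exact/near-exact
# seed matching, then refine by local alignment. Returns a tibble of segment
# alignments (possibly several loci).
seed_loci <- function(seed, ref, max_mismatch) {
  fwd <- Biostrings::vmatchPattern(seed, ref, max.mismatch = max_mismatch)
  rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(seed), ref,
                                   max.mismatch = max_mismatch)
  collect <- function(mi, strand) {
    hits <- lapply(seq_along(mi), function(i) {
      r <- mi[[i]]
      if (length(r) == 0L) return(NULL)
      tibble(ref = names(ref)[i], strand = strand,
             start = Biostrings::start(r), end = Biostrings::end(r))
    })
    bind_rows(hits)
  }
  bind_rows(collect(fwd, "+"), collect(rev, "-"))
}

#' Verify candidate split reads by local re-alignment
#'
#' For each candidate split read, re-aligns the read locally against the
#' reference: once around its mapped position (the anchor segment) and once
#' around every locus found by seeding the outer end of the clipped part. A
#' candidate is accepted as junction evidence when the two local alignments
#' cover a query prefix and a query suffix whose intervals overlap
#' (`R1 < R3 <= R2 < R4` with overlap `ov = R2 - R3 + 1`), each segment is at
#' least `min_segment` bp at identity at least `min_identity`, and the two
#' segments land on two different reference loci. The overlap is the att core;
#' its length approximates the att site length.
#'
#' Evidence on a single reference is classified `attB` (query prefix upstream:
#' the read jumps forward across the excised prophage) or `attP` (query prefix
#' downstream: the read crosses the circular-phage junction), and attachment
#' endpoints are inferred with [infer_att_endpoints()]. Evidence whose two
#' segments fall on different contigs is retained with `jtype = "cross"` for
#' [detect_cross_contig_candidates()].
#'
#' @param cands Candidate tibble from [detect_split_candidates()].
#' @param ref Reference genome ([Biostrings::DNAStringSet] or path to FASTA).
#' @param min_segment Minimum length of each split segment (bp, default 10).
#' @param min_identity Minimum per-segment alignment identity (default 0.95).
#' @param min_overlap Minimum query overlap of the two segments (default 1;
#'   set 0 to also admit abutting, non-overlapping splits).
#' @param seed_len Seed length for locating the second locus (default 14 bp).
#' @param seed_mismatch Mismatches tolerated in the seed (default 1).
#' @param pad Extra reference bases around each located locus for the final
#'   local alignment (default 50).
#' @param scores Alignment scoring from [sw_scores()].
#' @return A junction-evidence tibble: `read_id`, `flag`, `jtype`, the left
#'   and right segment coordinates (`l_q_start`, ..., `r_r_end`, `l_ref`,
#'   `r_ref`, strands, identities), overlap `ov`, and for same-reference
#'   evidence the inferred `attL_start`, `attL_end`, `attR_start`, `attR_end`.
#' @export
verify_split_reads <- function(cands, ref, min_segment = 10L,
                               min_identity = 0.95, min_overlap = 1L,
                               seed_len = 14L, seed_mismatch = 1L,
                               pad = 50L, scores = sw_scores()) {
  if (is.character(ref)) ref <- read_reference(ref)
  if (is.null(names(ref)) || anyDuplicated(names(ref))) {
    abort("reference sequences must have unique names", class = "attrace_config_error")
  }
  missing_ref <- setdiff(unique(cands$rname), names(ref))
  if (length(missing_ref) > 0L) {
    abort(paste0("SAM references absent from FASTA: ",
                 paste(missing_ref, collapse = ", ")),
          class = "attrace_config_error")
  }
  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    rows[[i]] <- verify_one(cands[i, ], ref, min_segment, min_identity,
                            min_overlap, seed_len, seed_mismatch, pad, scores)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty_evidence() else out
}

empty_evidence <- function() {
  tibble(read_id = character(), flag = integer(), jtype = character(),
         l_ref = character(), l_strand = character(),
         l_q_start = integer(), l_q_end = integer(),
         l_r_start = integer(), l_r_end = integer(), l_identity = double(),
         r_ref = character(), r_strand = character(),
         r_q_start = integer(), r_q_end = integer(),
         r_r_start = integer(), r_r_end = integer(), r_identity = double(),
         ov = integer(), attL_start = integer(), attL_end = integer(),
         attR_start = integer(), attR_end = integer())
}

verify_one <- function(cand, ref, min_segment, min_identity, min_overlap,
                       seed_len, seed_mismatch, pad, scores) {
  if (is.na(cand$seq) || cand$seq %in% c("*", "")) return(NULL)
  read <- Biostrings::DNAString(toupper(cand$seq))
  qlen <- Biostrings::nchar(read)

  # anchor segment: around the record's own mapped span
  prof <- clip_profile_fast(cand$cigar)
  ref_span <- cigar_ref_len(cand$cigar)
  anchor <- align_in_window(read, ref, cand$rname,
                            cand$pos - prof$lead_clip - pad,
                            cand$pos + ref_span + prof$tail_clip + pad,
                            "+", scores)
  if (is.null(anchor) || anchor$identity < min_identity ||
      anchor$q_end - anchor$q_start + 1L < min_segment) {
    return(NULL)
  }

  # second segment: seed the outer end of the clipped part
  clip_len <- if (cand$clip_side == "left") prof$lead_clip else prof$tail_clip
  k <- min(seed_len, clip_len)
  seed <- if (cand$clip_side == "left") {
    Biostrings::subseq(read, 1L, k)
  } else {
    Biostrings::subseq(read, qlen - k + 1L, qlen)
  }
  loci <- seed_loci(seed, ref, if (k >= seed_len) seed_mismatch else 0L)
  if (nrow(loci) == 0L) return(NULL)
  # drop seed hits inside the anchor's own locus
  same <- loci$ref == anchor$ref &
    loci$start <= anchor$r_end + 1L & loci$end >= anchor$r_start - 1L
  loci <- loci[!same, , drop = FALSE]
  if (nrow(loci) == 0L) return(NULL)

  segs <- vector("list", nrow(loci))
  for (j in seq_len(nrow(loci))) {
    segs[[j]] <- align_in_window(read, ref, loci$ref[j],
                                 loci$start[j] - qlen - pad,
                                 loci$end[j] + qlen + pad,
                                 loci$strand[j], scores)
  }
  segs <- bind_rows(segs)
  if (nrow(segs) == 0L) return(NULL)
  segs <- filter(segs,
                 .data$identity >= min_identity,
                 .data$q_end - .data$q_start + 1L >= min_segment,
                 !(.data$ref == anchor$ref &
                     .data$r_start <= anchor$r_end & .data$r_end >= anchor$r_start))
  segs <- distinct(segs, .data$ref, .data$strand, .data$r_start, .data$r_end,
                   .keep_all = TRUE)
  if (nrow(segs) == 0L) return(NULL)

  # overlap criterion against the anchor; pick the best admissible pair
  pair_of <- function(seg) {
    if (anchor$q_start <= seg$q_start) list(l = anchor, r = seg) else list(l = seg, r = anchor)
  }
  best <- NULL
  for (j in seq_len(nrow(segs))) {
    pr <- pair_of(segs[j, ])
    l <- pr$l; r <- pr$r
    ov <- l$q_end - r$q_start + 1L
    if (!(l$q_start < r$q_start && l$q_end < r$q_end)) next
    if (ov < min_overlap) next
    key <- c(total = (l$q_end - l$q_start + 1L) + (r$q_end - r$q_start + 1L),
             ident = l$identity + r$identity,
             coord = -(l$r_start + r$r_start))
    if (is.null(best) || compare_keys(key, best$key) > 0) {
      best <- list(l = l, r = r, ov = as.integer(ov), key = key)
    }
  }
  if (is.null(best)) return(NULL)
  l <- best$l; r <- best$r
  ev <- tibble(read_id = cand$qname, flag = cand$flag, jtype = NA_character_,
               l_ref = l$ref, l_strand = l$strand,
               l_q_start = l$q_start, l_q_end = l$q_end,
               l_r_start = l$r_start, l_r_end = l$r_end, l_identity = l$identity,
               r_ref = r$ref, r_strand = r$strand,
               r_q_start = r$q_start, r_q_end = r$q_end,
               r_r_start = r$r_start, r_r_end = r$r_end, r_identity = r$identity,
               ov = best$ov,
               attL_start = NA_integer_, attL_end = NA_integer_,
               attR_start = NA_integer_, attR_end = NA_integer_)
  if (l$ref != r$ref || l$strand != r$strand) {
    ev$jtype <- "cross"
    return(ev)
  }
  jt <- classify_junction(l, r)
  if (is.na(jt)) return(NULL)
  quad <- infer_att_endpoints(l$r_end, r$r_start, jt, best$ov)
  if (is.null(quad)) return(NULL)
  ev$jtype <- jt
  ev$attL_start <- quad[["attL_start"]]
  ev$attL_end <- quad[["attL_end"]]
  ev$attR_start <- quad[["attR_start"]]
  ev$attR_end <- quad[["attR_end"]]
  ev
}

compare_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(1L)
    if (a[i] < b[i]) return(-1L)
  }
  0L
}

#' Classify a verified split read as an attB or attP junction
#'
#' The query-prefix segment (`left`, smaller query start) maps upstream of the
#' query-suffix segment for an excision junction (`attB`: the read jumps
#' forward over the removed prophage) and downstream for a circularization
#' junction (`attP`: the read runs off the right phage end back onto its left
#' end). Segments whose reference intervals overlap are not classifiable.
#'
#' @param left,right One-row data frames (or lists) with `r_start`/`r_end`,
#'   the left one having the smaller query start.
#' @return `"attB"`, `"attP"`, or `NA_character_`.
#' @export
classify_junction <- function(left, right) {
  if (left$r_end < right$r_start) return("attB")
  if (right$r_end < left$r_start) return("attP")
  NA_character_
}

#' Infer attachment-site endpoints from a classified split alignment
#'
#' The four query endpoints of the overlapping split alignment correspond to
#' the endpoints of attL and attR. For attB evidence the query prefix ends at
#' `attL_end` and the suffix starts at `attR_start`; for attP evidence the
#' prefix ends at `attR_end` and the suffix starts at `attL_start`. Both att
#' copies share the core, so the remaining endpoints sit `ov - 1` bases away.
#'
#' @param left_r_end Reference end of the query-prefix segment.
#' @param right_r_start Reference start of the query-suffix segment.
#' @param jtype `"attB"` or `"attP"`.
#' @param ov Overlap length (att core length), >= 1.
#' @return Named integer vector `attL_start`, `attL_end`, `attR_start`,
#'   `attR_end`, or `NULL` when the geometry is inconsistent
#'   (`attL_end >= attR_start`).
#' @examples
#' infer_att_endpoints(785336, 797699, "attB", 49)
#' @export
infer_att_endpoints <- function(left_r_end, right_r_start, jtype, ov) {
  stopifnot(jtype %in% c("attB", "attP"), ov >= 0)
  if (jtype == "attB") {
    attL_end <- as.integer(left_r_end)
    attR_start <- as.integer(right_r_start)
    attL_start <- attL_end - as.integer(ov) + 1L
    attR_end <- attR_start + as.integer(ov) - 1L
  } else {
    attR_end <- as.integer(left_r_end)
    attL_start <- as.integer(right_r_start)
    attR_start <- attR_end - as.integer(ov) + 1L
    attL_end <- attL_start + as.integer(ov) - 1L
  }
  if (attL_end >= attR_start) return(NULL)
  c(attL_start = attL_start, attL_end = attL_end,
    attR_start = attR_start, attR_end = attR_end)
}
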