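#' Split a reference sequence into contigs
#'
#' Utility for emulating a draft (contig-level) assembly of a finished
#' genome: cuts the sequence after each position in `at` and returns the
#' contig set together with the coordinate map back to the source sequence.
#'
#' @param seq A character scalar or [Biostrings::DNAStringSet] of length 1.
#' @param at Integer positions; contig k ends at `at[k]`.
#' @param prefix Contig name prefix (default `"contig"`).
#' @return A list: `contigs` ([Biostrings::DNAStringSet]) and `map` (tibble
#'   with `contig`, `start`, `end` — source coordinates of each contig).
#' @export
split_reference <- function(seq, at, prefix = "contig") {
  if (inherits(seq, "DNAStringSet")) seq <- as.character(seq[[1]])
  n <- nchar(seq)
  at <- sort(unique(as.integer(at)))
  if (any(at < 1L | at >= n)) {
    abort("split positions must lie strictly inside the sequence",
          class = "attrace_param_error")
  }
  starts <- c(1L, at + 1L)
  ends <- c(at, n)
  contigs <- Biostrings::DNAStringSet(substring(seq, starts, ends))
  names(contigs) <- paste0(prefix, seq_along(starts))
  list(contigs = contigs,
       map = tibble(contig = names(contigs), start = starts, end = ends))
}

#' Map a contig coordinate back to the source genome
#'
#' @param map Contig map from [split_reference()].
#' @param contig Contig names.
#' @param pos Positions on those contigs.
#' @return Integer positions on the source sequence.
#' @export
lift_contig_coords <- function(map, contig, pos) {
  i <- match(contig, map$contig)
  as.integer(map$start[i] + pos - 1L)
}

#' Project truth alignments onto a contig-level reference
#'
#' Re-expresses alignment records produced against a finished genome in the
#' coordinates of a contig set from [split_reference()]. A record whose
#' aligned span crosses a contig boundary keeps its longer part aligned (the
#' remainder becomes additional soft clip), as an aligner would place it
#' against the fragmented assembly. The proper-pair bit is cleared for pairs
#' that end up on different contigs.
#'
#' @param sam Alignment tibble (truth records: CIGARs of the form
#'   `aS bM cS`).
#' @param map Contig map from [split_reference()].
#' @return Alignment tibble in contig coordinates.
#' @export
project_alignments <- function(sam, map) {
  prof <- clip_profile_fast(sam$cigar)
  m_len <- prof$aligned_len
  pos <- sam$pos
  end <- pos + m_len - 1L
  ci <- findInterval(pos, map$start)
  cs <- map$start[ci]
  ce <- map$end[ci]
  cross <- end > ce
  left_len <- pmin(end, ce) - pos + 1L
  right_len <- pmax(end - ce, 0L)
  use_left <- !cross | left_len >= right_len

  new_ref <- ifelse(use_left, map$contig[ci], map$contig[pmin(ci + 1L, nrow(map))])
  new_pos <- ifelse(use_left, pos - cs + 1L, 1L)
  new_m <- ifelse(use_left, left_len, right_len)
  new_lead <- prof$lead_clip + ifelse(use_left, 0L, left_len)
  new_tail <- prof$tail_clip + ifelse(use_left & cross, right_len, 0L)
  new_cigar <- paste0(ifelse(new_lead > 0L, paste0(new_lead, "S"), ""),
                      new_m, "M",
                      ifelse(new_tail > 0L, paste0(new_tail, "S"), ""))

  mi <- findInterval(sam$pnext, map$start)
  mate_ref <- map$contig[mi]
  mate_pos <- sam$pnext - map$start[mi] + 1L

  out <- sam
  out$rname <- new_ref
  out$pos <- as.integer(new_pos)
  out$cigar <- new_cigar
  out$rnext <- mate_ref
  out$mate_rname <- mate_ref
  out$pnext <- as.integer(mate_pos)
  same <- new_ref == mate_ref
  out$flag <- ifelse(!same & bitwAnd(out$flag, 2L) > 0L, out$flag - 2L, out$flag)
  out$tlen <- ifelse(same, out$tlen, 0L)
  out[names(decode_flags(0L))] <- decode_flags(out$flag)
  out
}

#' Build cross-contig prophage candidates from junction evidence
#'
#' Junction evidence whose two split segments verify on different contigs
#' indicates a prophage whose attL and attR fall on two contigs of a draft
#' assembly. Evidence is clustered per contig pair, segment orientation and
#' junction endpoints; each cluster reports the att core interval on each
#' contig, the relative orientation, an *approximate* size (the distance from
#' the att site to the junction-side end of its contig, summed over both
#' contigs — an underestimate whenever a third contig intervenes), and a
#' junction annotation in which `"contig ="` marks a junction at the right
#' end of a contig and `"= contig"` at the left end, joined by `"::"`.
#' Excision- versus circularization-junction identity cannot be read off the
#' reference order across contigs, so candidates carry the evidence count as
#' `n_reads` without an attB/attP split; the size filter applies its upper
#' bound only (the lower bound is waived because `approx_size` underestimates
#' the true size).
#'
#' @param evidence Evidence tibble from [verify_split_reads()] (rows with
#'   `jtype == "cross"` are used).
#' @param ref Contig reference ([Biostrings::DNAStringSet]), for contig
#'   lengths.
#' @param cfg A [filter_config()]; `cluster_tol` and `max_size` are used.
#' @return A tibble of class `attrace_cross_candidates`: `contig_a`
#'   (junction at its right end on the forward strand), `att_a_start`,
#'   `att_a_end`, `contig_b`, `att_b_start`, `att_b_end`, `orientation`
#'   (e.g. `"+/+"`), `ov`, `n_reads`, `approx_size`, `junction_annotation`.
#' @export
detect_cross_contig_candidates <- function(evidence, ref, cfg = filter_config()) {
  ev <- filter(evidence, .data$jtype == "cross")
  empty <- tibble(contig_a = character(), att_a_start = integer(),
                  att_a_end = integer(), contig_b = character(),
                  att_b_start = integer(), att_b_end = integer(),
                  orientation = character(), ov = integer(),
                  n_reads = integer(), approx_size = integer(),
                  junction_annotation = character())
  class(empty) <- c("attrace_cross_candidates", class(tibble()))
  if (nrow(ev) == 0L) return(empty)
  missing_ref <- setdiff(unique(c(ev$l_ref, ev$r_ref)), names(ref))
  if (length(missing_ref) > 0L) {
    abort(paste0("evidence contigs absent from reference: ",
                 paste(missing_ref, collapse = ", ")),
          class = "attrace_config_error")
  }
  clen <- setNames(Biostrings::width(ref), names(ref))

  # per read: the att core sits at the end of the query-prefix segment
  # (contig_a, junction rightward of the core on + strand) and at the start
  # of the query-suffix segment (contig_b, junction leftward of the core)
  ev <- mutate(ev,
               att_a_start = .data$l_r_end - .data$ov + 1L,
               att_a_end = .data$l_r_end,
               att_b_start = .data$r_r_start,
               att_b_end = .data$r_r_start + .data$ov - 1L,
               orientation = paste0(.data$l_strand, "/", .data$r_strand))

  key <- paste(ev$l_ref, ev$r_ref, ev$orientation)
  out <- list()
  for (k in unique(key)) {
    sub <- ev[key == k, , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      if (i == 1L) next
      for (j in seq_len(i - 1L)) {
        if (abs(sub$att_a_end[i] - sub$att_a_end[j]) <= cfg$cluster_tol &&
            abs(sub$att_b_start[i] - sub$att_b_start[j]) <= cfg$cluster_tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cid in unique(comp)) {
      m <- sub[comp == cid, , drop = FALSE]
      ca <- m$l_ref[1]; cb <- m$r_ref[1]
      a_end <- endpoint_mode(m$att_a_end)
      b_start <- endpoint_mode(m$att_b_start)
      ov <- endpoint_mode(m$ov)
      a_start <- a_end - ov + 1L
      b_end <- b_start + ov - 1L
      str_a <- m$l_strand[1]; str_b <- m$r_strand[1]
      dist_a <- if (str_a == "+") clen[[ca]] - a_start else a_end
      dist_b <- if (str_b == "+") b_start else clen[[cb]] - b_end + 1L
      approx <- as.integer(dist_a + dist_b)
      ann_a <- if (str_a == "+") paste0(ca, " = ") else paste0(" = ", ca)
      ann_b <- if (str_b == "+") paste0(" = ", cb) else paste0(cb, " = ")
      out[[length(out) + 1L]] <- tibble(
        contig_a = ca, att_a_start = as.integer(a_start),
        att_a_end = as.integer(a_end),
        contig_b = cb, att_b_start = as.integer(b_start),
        att_b_end = as.integer(b_end),
        orientation = m$orientation[1], ov = as.integer(ov),
        n_reads = n_distinct_reads(m),
        approx_size = approx,
        junction_annotation = paste0(ann_a, "::", ann_b)
      )
    }
  }
  res <- bind_rows(out)
  res <- filter(res, .data$approx_size < cfg$max_size)
  res <- arrange(res, .data$contig_a, .data$att_a_start)
  class(res) <- c("attrace_cross_candidates", class(tibble()))
  res
}

n_distinct_reads <- function(m) length(unique(m$read_id))
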