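#' Filtering configuration for candidate prophages
#'
#' Defaults follow common prophage biology: att cores longer than 2 bp,
#' element sizes between 5 kb and 150 kb, and at least one attB (excision) and
#' one attP (circularization) event each.
#'
#' @param min_att_len Exclusive lower bound on att core length (bp).
#' @param min_size,max_size Exclusive bounds on prophage size (bp).
#' @param min_attB_events,min_attP_events Minimum evidence counts (split reads
#'   plus discordant pairs) per junction type.
#' @param cluster_tol Per-endpoint tolerance when clustering evidence (bp).
#' @param drp_window Distance window for assigning discordant pairs to a
#'   cluster (bp).
#' @return A list of class `attrace_filter_config`.
#' @export
filter_config <- function(min_att_len = 2L, min_size = 5000L, max_size = 150000L,
                          min_attB_events = 1L, min_attP_events = 1L,
                          cluster_tol = 2L, drp_window = 1000L) {
  cfg <- list(min_att_len = as.integer(min_att_len),
              min_size = as.integer(min_size), max_size = as.integer(max_size),
              min_attB_events = as.integer(min_attB_events),
              min_attP_events = as.integer(min_attP_events),
              cluster_tol = as.integer(cluster_tol),
              drp_window = as.integer(drp_window))
  if (cfg$min_size >= cfg$max_size) {
    abort("min_size must be smaller than max_size", class = "attrace_config_error")
  }
  if (any(unlist(cfg) < 0L)) {
    abort("filter bounds must be non-negative", class = "attrace_config_error")
  }
  structure(cfg, class = "attrace_filter_config")
}

# statistical mode; ties broken toward the smallest value
endpoint_mode <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  winners <- as.integer(names(tb)[tb == tb[1]])
  min(winners)
}

#' Cluster junction evidence into candidate prophages
#'
#' Evidence records whose four attachment endpoints each differ by at most
#' `tol` bp are linked; connected components form clusters. The consensus
#' quad takes the per-endpoint statistical mode (ties toward the smaller
#' coordinate), so occasional 1-2 bp end-trimming jitter from the local
#' aligner does not move the boundary call.
#'
#' @param evidence Junction-evidence tibble from [verify_split_reads()]
#'   (same-reference rows; `cross` rows are ignored here).
#' @param tol Per-endpoint link tolerance in bp (default 2).
#' @return A tibble with one row per cluster: `ref`, consensus `attL_start`,
#'   `attL_end`, `attR_start`, `attR_end`, counts `sr_attB`, `sr_attP`,
#'   `drp_attB`, `drp_attP` (zero until [merge_discordant()]), and a
#'   list-column `members` of the contributing evidence rows.
#' @export
cluster_evidence <- function(evidence, tol = 2L) {
  ev <- filter(evidence, .data$jtype %in% c("attB", "attP"),
               !is.na(.data$attL_start))
  if (nrow(ev) == 0L) return(empty_clusters())
  out <- list()
  for (rf in unique(ev$l_ref)) {
    sub <- ev[ev$l_ref == rf, , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    quad <- as.matrix(sub[, c("attL_start", "attL_end", "attR_start", "attR_end")])
    for (i in seq_len(n)) {
      if (i == 1L) next
      for (j in seq_len(i - 1L)) {
        if (all(abs(quad[i, ] - quad[j, ]) <= tol)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cid in unique(comp)) {
      m <- sub[comp == cid, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        ref = rf,
        attL_start = endpoint_mode(m$attL_start),
        attL_end = endpoint_mode(m$attL_end),
        attR_start = endpoint_mode(m$attR_start),
        attR_end = endpoint_mode(m$attR_end),
        sr_attB = sum(m$jtype == "attB"),
        sr_attP = sum(m$jtype == "attP"),
        drp_attB = 0L, drp_attP = 0L,
        members = list(m)
      )
    }
  }
  arrange(bind_rows(out), .data$ref, .data$attL_start)
}

empty_clusters <- function() {
  tibble(ref = character(), attL_start = integer(), attL_end = integer(),
         attR_start = integer(), attR_end = integer(),
         sr_attB = integer(), sr_attP = integer(),
         drp_attB = integer(), drp_attP = integer(), members = list())
}

#' Merge discordant read pairs into evidence clusters
#'
#' A discordant pair supports an attB (excision) junction when its mates flank
#' the prophage from outside in deletion-spanning orientation: the forward
#' mate ends within `window` bp upstream of the att core at attL and the
#' reverse mate starts within `window` bp downstream of attR. It supports an
#' attP junction when the mates lie inside the prophage pointing outward
#' across the circular junction: the forward mate ends near `attR_end` and the
#' reverse mate starts near `attL_start`, everted on the reference. Each pair
#' is counted once, for the single cluster it brackets most tightly; pairs
#' matching no cluster are dropped (their count is kept in the
#' `dropped_drps` attribute).
#'
#' @param clusters Cluster tibble from [cluster_evidence()].
#' @param drps Discordant candidates from [detect_discordant_candidates()].
#' @param window Assignment window in bp (default 1000).
#' @return `clusters` with `drp_attB`/`drp_attP` incremented.
#' @export
merge_discordant <- function(clusters, drps, window = 1000L) {
  if (nrow(clusters) == 0L || is.null(drps) || nrow(drps) == 0L) {
    attr(clusters, "dropped_drps") <- if (is.null(drps)) 0L else nrow(drps)
    return(clusters)
  }
  pairs <- distinct(drps, .data$qname, .keep_all = TRUE)
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    # reconstruct mate geometry: positions of the forward and reverse read
    if (!p$is_reverse) {
      fwd_ref <- p$rname; fwd_pos <- p$pos; fwd_end <- p$pos + p$aligned_len - 1L
      rev_ref <- p$mate_rname; rev_pos <- p$pnext
    } else {
      fwd_ref <- p$mate_rname; fwd_pos <- p$pnext
      fwd_end <- p$pnext + p$aligned_len - 1L  # mate length approximated by own
      rev_ref <- p$rname; rev_pos <- p$pos
    }
    best <- NULL
    for (k in seq_len(nrow(clusters))) {
      cl <- clusters[k, ]
      if (fwd_ref != cl$ref || rev_ref != cl$ref) next
      is_attB <- fwd_end >= cl$attL_start - window & fwd_end <= cl$attL_end &
        rev_pos >= cl$attR_start & rev_pos <= cl$attR_end + window &
        fwd_pos < rev_pos
      is_attP <- fwd_end >= cl$attR_end - window & fwd_end <= cl$attR_end &
        rev_pos >= cl$attL_start & rev_pos <= cl$attL_end + window &
        rev_pos < fwd_pos
      if (!is_attB && !is_attP) next
      d <- if (is_attB) {
        (cl$attL_start - fwd_end) + (rev_pos - cl$attR_end)
      } else {
        (cl$attR_end - fwd_end) + (rev_pos - cl$attL_start)
      }
      key <- c(-d, -cl$attL_start)  # tightest bracket, then lower attL_start
      if (is.null(best) || compare_keys(key, best$key) > 0) {
        best <- list(k = k, type = if (is_attB) "attB" else "attP", key = key)
      }
    }
    if (is.null(best)) {
      dropped <- dropped + 1L
    } else if (best$type == "attB") {
      clusters$drp_attB[best$k] <- clusters$drp_attB[best$k] + 1L
    } else {
      clusters$drp_attP[best$k] <- clusters$drp_attP[best$k] + 1L
    }
  }
  attr(clusters, "dropped_drps") <- dropped
  clusters
}

#' Filter clusters and emit the candidate-prophage report
#'
#' Retains clusters with att core length above `min_att_len`, size strictly
#' between `min_size` and `max_size`, and at least the configured number of
#' attB and attP events (split reads plus discordant pairs). Candidates are
#' sorted by reference then position and named `P1`, `P2`, ...
#'
#' @param clusters Cluster tibble ([cluster_evidence()], optionally after
#'   [merge_discordant()]).
#' @param cfg A [filter_config()].
#' @return A tibble of class `attrace_candidates` with columns `prophage`,
#'   `contig`, `attL_start`, `attL_end`, `attR_start`, `attR_end`, `size`,
#'   `att_length`, `SR_attB`, `SR_attP`, `DRP_attB`, `DRP_attP` and
#'   `evidence_alignments` (human-readable split-alignment rendering for
#'   manual review of genes disrupted at the integration site).
#' @export
filter_candidates <- function(clusters, cfg = filter_config()) {
  summ <- summarize_candidates(clusters)
  keep <- summ$att_length > cfg$min_att_len &
    summ$size > cfg$min_size & summ$size < cfg$max_size &
    (summ$SR_attB + summ$DRP_attB) >= cfg$min_attB_events &
    (summ$SR_attP + summ$DRP_attP) >= cfg$min_attP_events
  out <- summ[keep, , drop = FALSE]
  out <- arrange(out, .data$contig, .data$attL_start)
  out$prophage <- paste0("P", seq_len(nrow(out)))
  class(out) <- c("attrace_candidates", class(tibble()))
  out
}

#' Summarize evidence clusters in report form (no filtering)
#'
#' `size = attR_start - attL_start` (the length of the excisable element:
#' one att core plus the internal sequence, equal to the circular phage
#' genome length) and `att_length = attL_end - attL_start + 1`.
#'
#' @param clusters Cluster tibble.
#' @return Report tibble (see [filter_candidates()]).
#' @export
summarize_candidates <- function(clusters) {
  if (nrow(clusters) == 0L) {
    out <- tibble(prophage = character(), contig = character(),
                  attL_start = integer(), attL_end = integer(),
                  attR_start = integer(), attR_end = integer(),
                  size = integer(), att_length = integer(),
                  SR_attB = integer(), SR_attP = integer(),
                  DRP_attB = integer(), DRP_attP = integer(),
                  evidence_alignments = character())
    class(out) <- c("attrace_candidates", class(tibble()))
    return(out)
  }
  # allow bare coordinate tables (e.g. published att coordinates) as input
  for (col in c("sr_attB", "sr_attP", "drp_attB", "drp_attP")) {
    if (!col %in% names(clusters)) clusters[[col]] <- 0L
  }
  if (!"members" %in% names(clusters)) {
    clusters$members <- rep(list(NULL), nrow(clusters))
  }
  if (!"ref" %in% names(clusters)) clusters$ref <- clusters$contig
  render <- vapply(seq_len(nrow(clusters)), function(i) {
    m <- clusters$members[[i]]
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(sprintf("%s [%s] q%d-%d=>%s:%d-%d | q%d-%d=>%s:%d-%d ov=%d",
                  m$read_id, m$jtype,
                  m$l_q_start, m$l_q_end, m$l_ref, m$l_r_start, m$l_r_end,
                  m$r_q_start, m$r_q_end, m$r_ref, m$r_r_start, m$r_r_end,
                  m$ov),
          collapse = "; ")
  }, character(1))
  out <- tibble(
    prophage = paste0("P", seq_len(nrow(clusters))),
    contig = clusters$ref,
    attL_start = as.integer(clusters$attL_start),
    attL_end = as.integer(clusters$attL_end),
    attR_start = as.integer(clusters$attR_start),
    attR_end = as.integer(clusters$attR_end),
    size = as.integer(clusters$attR_start - clusters$attL_start),
    att_length = as.integer(clusters$attL_end - clusters$attL_start + 1L),
    SR_attB = as.integer(clusters$sr_attB),
    SR_attP = as.integer(clusters$sr_attP),
    DRP_attB = as.integer(clusters$drp_attB),
    DRP_attP = as.integer(clusters$drp_attP),
    evidence_alignments = render
  )
  class(out) <- c("attrace_candidates", class(tibble()))
  out
}
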