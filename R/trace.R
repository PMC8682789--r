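#' Run the full prophage-detection pipeline
#'
#' Executes detect -> verify -> classify -> cluster -> merge -> filter on a
#' SAM alignment and its reference: extracts candidate split reads and
#' discordant pairs by FLAG/CIGAR semantics, verifies split candidates by
#' seeded local re-alignment under the overlapping split-alignment criterion,
#' infers attachment sites, clusters the evidence, folds in discordant-pair
#' support and applies the size/att-length/event-count filters. Zero retained
#' candidates is a valid outcome.
#'
#' @param sam Path to a SAM file or an alignment tibble ([read_sam()]).
#' @param ref Path to the reference FASTA or a [Biostrings::DNAStringSet].
#' @param mode `"chromosome"`, `"contig"`, or `"auto"` (contig rules when the
#'   reference holds more than one sequence and any candidate has its mate on
#'   another sequence).
#' @param cfg A [filter_config()].
#' @param clip_bounds,min_segment,min_identity,lenient_flags Passed to the
#'   detection and verification stages.
#' @param min_aligned Discordant-pair aligned-length bound (default 130).
#' @return An object of class `attrace_run`: a list with `candidates`
#'   (filtered report tibble), `cross_candidates` (contig mode),
#'   `clusters` (pre-filter), `evidence`, `counts` (per-stage record counts),
#'   `mode`, and `cfg`.
#' @export
run_trace <- function(sam, ref, mode = c("auto", "chromosome", "contig"),
                      cfg = filter_config(), clip_bounds = c(10L, 150L),
                      min_segment = 10L, min_identity = 0.95,
                      min_aligned = 130L, lenient_flags = FALSE) {
  mode <- match.arg(mode)
  aln <- if (is.character(sam)) read_sam(sam) else sam
  if (is.character(ref)) ref <- read_reference(ref)
  missing_ref <- setdiff(unique(aln$rname[aln$is_mapped]), names(ref))
  if (length(missing_ref) > 0L) {
    abort(paste0("SAM references absent from FASTA: ",
                 paste(missing_ref, collapse = ", ")),
          class = "attrace_config_error")
  }
  if (mode == "auto") {
    cross_mates <- any(aln$is_mapped & aln$mate_is_mapped &
                         aln$mate_rname != aln$rname)
    mode <- if (length(ref) > 1L && cross_mates) "contig" else "chromosome"
  }
  splits <- detect_split_candidates(aln, mode = mode, clip_bounds = clip_bounds,
                                    lenient_flags = lenient_flags)
  drps <- detect_discordant_candidates(aln, mode = mode,
                                       min_aligned = min_aligned,
                                       lenient_flags = lenient_flags)
  evidence <- verify_split_reads(splits, ref, min_segment = min_segment,
                                 min_identity = min_identity)
  clusters <- cluster_evidence(evidence, tol = cfg$cluster_tol)
  clusters <- merge_discordant(clusters, drps, window = cfg$drp_window)
  candidates <- filter_candidates(clusters, cfg)
  cross <- if (mode == "contig") {
    detect_cross_contig_candidates(evidence, ref, cfg)
  } else {
    NULL
  }
  counts <- tibble(
    records = nrow(aln),
    split_candidates = nrow(splits),
    discordant_candidates = nrow(drps),
    verified_junctions = nrow(evidence),
    clusters = nrow(clusters),
    candidates = nrow(candidates),
    cross_contig_candidates = if (is.null(cross)) 0L else nrow(cross),
    dropped_drps = attr(clusters, "dropped_drps") %||% 0L
  )
  structure(list(candidates = candidates, cross_candidates = cross,
                 clusters = clusters, evidence = evidence,
                 counts = counts, mode = mode, cfg = cfg),
            class = "attrace_run")
}

#' @export
print.attrace_run <- function(x, ...) {
  cat("<attrace_run>  mode:", x$mode, "\n")
  cat(sprintf("  records %d | split candidates %d | discordant %d | verified %d | clusters %d\n",
              x$counts$records, x$counts$split_candidates,
              x$counts$discordant_candidates, x$counts$verified_junctions,
              x$counts$clusters))
  cat("  retained candidates:", nrow(x$candidates), "\n")
  if (nrow(x$candidates) > 0L) {
    print(select(as_tibble(x$candidates), -"evidence_alignments"))
  }
  if (!is.null(x$cross_candidates) && nrow(x$cross_candidates) > 0L) {
    cat("  cross-contig candidates:\n")
    print(as_tibble(x$cross_candidates))
  }
  invisible(x)
}

#' Write the candidate report as TSV
#'
#' The main report (one row per retained candidate, Table-style columns) goes
#' to `path`; the per-candidate overlapping-alignment renderings go to
#' `evidence_path` when given (for manual review of disrupted genes).
#'
#' @param x `attrace_run` or `attrace_candidates`.
#' @param path Output TSV path.
#' @param evidence_path Optional companion text file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, evidence_path = NULL) {
  cand <- if (inherits(x, "attrace_run")) x$candidates else x
  main <- select(as_tibble(cand), -"evidence_alignments")
  utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(evidence_path)) {
    writeLines(paste0(cand$prophage, "\t", cand$evidence_alignments),
               evidence_path)
  }
  invisible(path)
}
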