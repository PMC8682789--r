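#' Evidence counts for one candidate under one condition
#'
#' @param sr_attB,sr_attP Split-read counts.
#' @param drp_attB,drp_attP Discordant-pair counts.
#' @param total_reads Library size used for normalization (total reads in the
#'   alignment stream, mapped plus unmapped, by default; any consistent
#'   library-size measure works as long as both conditions use the same one).
#' @param candidate Alternatively, a one-row `attrace_candidates` tibble from
#'   which the four counts are taken.
#' @return A list of class `attrace_condition_counts`.
#' @export
condition_counts <- function(sr_attB = 0L, sr_attP = 0L, drp_attB = 0L,
                             drp_attP = 0L, total_reads, candidate = NULL) {
  if (!is.null(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    sr_attB <- candidate$SR_attB
    sr_attP <- candidate$SR_attP
    drp_attB <- candidate$DRP_attB
    drp_attP <- candidate$DRP_attP
  }
  counts <- c(sr_attB, sr_attP, drp_attB, drp_attP)
  if (any(counts < 0) || total_reads <= 0) {
    abort("counts must be >= 0 and total_reads > 0",
          class = "attrace_param_error")
  }
  structure(list(sr_attB = sr_attB, sr_attP = sr_attP,
                 drp_attB = drp_attB, drp_attP = drp_attP,
                 total_reads = total_reads),
            class = "attrace_condition_counts")
}

#' Fold-change of prophage excision activity between two conditions
#'
#' For one candidate prophage observed under two conditions, the excision
#' signal of each evidence class is normalized by library size,
#' `rate = count / total_reads`, and the fold-change is
#' `rate(treated) / rate(control)`. Evidence classes: `attB` (excision
#' junctions: `sr_attB + drp_attB`, the excision-rate proxy), `attP`
#' (circularization junctions) and `combined` (all four counts). A zero
#' evidence count entering either rate is replaced by one before division and
#' flagged, so the ratio stays finite; the result is then a bound rather than
#' an estimate.
#'
#' @param treated,control [condition_counts()] objects.
#' @return A tibble of class `attrace_fc` with one row per evidence class:
#'   `count_treated`, `count_control`, `fold_change`,
#'   `zero_substituted_treated`, `zero_substituted_control`.
#' @examples
#' fold_change(condition_counts(sr_attB = 20, total_reads = 1e6),
#'             condition_counts(sr_attB = 2, total_reads = 1e6))
#' @export
fold_change <- function(treated, control) {
  stopifnot(inherits(treated, "attrace_condition_counts"),
            inherits(control, "attrace_condition_counts"))
  class_counts <- function(cc) {
    c(attB = cc$sr_attB + cc$drp_attB,
      attP = cc$sr_attP + cc$drp_attP,
      combined = cc$sr_attB + cc$drp_attB + cc$sr_attP + cc$drp_attP)
  }
  ct <- class_counts(treated)
  cc <- class_counts(control)
  zt <- ct == 0
  zc <- cc == 0
  num <- ifelse(zt, 1, ct) / treated$total_reads
  den <- ifelse(zc, 1, cc) / control$total_reads
  out <- tibble(
    evidence_class = names(ct),
    count_treated = as.integer(ct),
    count_control = as.integer(cc),
    rate_treated = unname(num),
    rate_control = unname(den),
    fold_change = unname(num / den),
    zero_substituted_treated = unname(zt),
    zero_substituted_control = unname(zc)
  )
  class(out) <- c("attrace_fc", class(tibble()))
  out
}

#' qPCR primer target windows around the attB and attP junctions
#'
#' Returns flanking windows suitable for designing primer pairs that amplify
#' across the attB junction (on the excised chromosome: one window upstream
#' of attL, one downstream of attR) and across the attP junction (on the
#' circular phage genome: one window just inside each prophage end), sized
#' for a 200-300 bp product.
#'
#' @param candidate One-row candidate tibble (`attL_start` ... `attR_end`,
#'   `contig`).
#' @param flank Window width in bp (default 150).
#' @return A tibble with `contig`, `start`, `end` (1-based closed), `name`,
#'   `junction` (`attB`/`attP`) — writable as BED via [write_bed()].
#' @export
primer_windows <- function(candidate, flank = 150L) {
  stopifnot(nrow(candidate) == 1L)
  with(candidate, tibble(
    contig = rep(contig, 4L),
    start = c(attL_start - flank, attR_end + 1L,
              attL_end + 1L, attR_start - flank),
    end = c(attL_start - 1L, attR_end + flank,
            attL_end + flank, attR_start - 1L),
    name = paste0(prophage, c("_attB_up", "_attB_down", "_attP_left", "_attP_right")),
    junction = c("attB", "attB", "attP", "attP")
  ))
}

#' Write genomic windows as BED
#'
#' @param windows Tibble with `contig`, `start`, `end` (1-based closed) and
#'   optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  bed <- tibble(chrom = windows$contig,
                start = pmax(windows$start - 1L, 0L),  # BED: 0-based half-open
                end = windows$end,
                name = windows$name %||% ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
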