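#' Decode SAM FLAG integers into logical fields
#'
#' @param flag Integer vector of SAM FLAG values.
#' @return A tibble with one row per flag: `is_paired`, `is_proper`,
#'   `is_mapped`, `mate_is_mapped`, `is_reverse`, `mate_is_reverse`,
#'   `is_first_in_pair`, `is_second_in_pair`, `is_secondary`, `is_qcfail`,
#'   `is_duplicate`, `is_supplementary`.
#' @examples
#' decode_flags(c(99L, 147L, 0L))
#' @export
decode_flags <- function(flag) {
  flag <- as.integer(flag)
  tibble(
    is_paired = bitwAnd(flag, 1L) > 0L,
    is_proper = bitwAnd(flag, 2L) > 0L,
    is_mapped = bitwAnd(flag, 4L) == 0L,
    mate_is_mapped = bitwAnd(flag, 8L) == 0L,
    is_reverse = bitwAnd(flag, 16L) > 0L,
    mate_is_reverse = bitwAnd(flag, 32L) > 0L,
    is_first_in_pair = bitwAnd(flag, 64L) > 0L,
    is_second_in_pair = bitwAnd(flag, 128L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_qcfail = bitwAnd(flag, 512L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L
  )
}

#' Re-encode decoded flag fields into a SAM FLAG integer
#'
#' Inverse of [decode_flags()] for the modeled bits.
#'
#' @param bits A data frame as returned by [decode_flags()].
#' @return Integer vector of FLAG values.
#' @export
encode_flags <- function(bits) {
  as.integer(
    1L * bits$is_paired +
      2L * bits$is_proper +
      4L * (!bits$is_mapped) +
      8L * (!bits$mate_is_mapped) +
      16L * bits$is_reverse +
      32L * bits$mate_is_reverse +
      64L * bits$is_first_in_pair +
      128L * bits$is_second_in_pair +
      256L * bits$is_secondary +
      512L * bits$is_qcfail +
      1024L * bits$is_duplicate +
      2048L * bits$is_supplementary
  )
}

#' Parse SAM alignment lines into an alignment tibble
#'
#' Parses tab-delimited SAM alignment records (header lines starting with `@`
#' are ignored) into a tibble with the eleven mandatory fields plus decomposed
#' FLAG bits. `"="` in the mate reference name is resolved to the record's own
#' reference. Coordinates are 1-based, closed, as in SAM.
#'
#' @param lines Character vector of SAM lines (alignment and/or header lines).
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, the fields of
#'   [decode_flags()], and `mate_rname` (resolved).
#' @examples
#' parse_sam_lines("r1\t0\tchr1\t100\t60\t4M\t*\t0\t0\tACGT\t*")
#' @export
parse_sam_lines <- function(lines) {
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_alignments())
  }
  parts <- stringr::str_split(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    abort(paste0("SAM line ", bad, " has ", nf[bad],
                 " fields; 11 mandatory fields required"),
          class = "attrace_parse_error")
  }
  field <- function(i) vapply(parts, `[[`, character(1), i)
  int_field <- function(i, name) {
    x <- field(i)
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(paste0("non-integer ", name, " '", x[bad], "' on SAM line ", bad),
            class = "attrace_parse_error")
    }
    v
  }
  aln <- tibble(
    qname = field(1),
    flag = int_field(2, "FLAG"),
    rname = field(3),
    pos = int_field(4, "POS"),
    mapq = int_field(5, "MAPQ"),
    cigar = field(6),
    rnext = field(7),
    pnext = int_field(8, "PNEXT"),
    tlen = int_field(9, "TLEN"),
    seq = field(10),
    qual = field(11)
  )
  aln <- bind_cols(aln, decode_flags(aln$flag))
  aln$mate_rname <- ifelse(aln$rnext == "=", aln$rname, aln$rnext)
  bad_pos <- aln$is_mapped & aln$pos < 1L
  if (any(bad_pos)) {
    abort(paste0("mapped record '", aln$qname[which(bad_pos)[1]],
                 "' has POS < 1"), class = "attrace_parse_error")
  }
  aln
}

empty_alignments <- function() {
  bind_cols(
    tibble(qname = character(), flag = integer(), rname = character(),
           pos = integer(), mapq = integer(), cigar = character(),
           rnext = character(), pnext = integer(), tlen = integer(),
           seq = character(), qual = character()),
    decode_flags(integer()),
    tibble(mate_rname = character())
  )
}

#' Read a SAM file into an alignment tibble
#'
#' @param path Path to a SAM text file.
#' @param drop_secondary Drop secondary and supplementary alignments
#'   (default `TRUE`; primary records carry the full read sequence needed for
#'   re-alignment).
#' @param dedup Drop coordinate-identical duplicates of the same read
#'   orientation (default `FALSE`; normally duplicate marking happens
#'   upstream).
#' @return An alignment tibble (see [parse_sam_lines()]).
#' @export
read_sam <- function(path, drop_secondary = TRUE, dedup = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("SAM file not found: ", path), class = "attrace_io_error")
  }
  aln <- parse_sam_lines(readLines(path, warn = FALSE))
  if (drop_secondary) {
    aln <- filter(aln, !.data$is_secondary, !.data$is_supplementary)
  }
  if (dedup) {
    aln <- distinct(aln, .data$rname, .data$pos, .data$flag, .data$cigar,
                    .keep_all = TRUE)
  }
  aln
}

#' Serialize an alignment tibble back to SAM lines
#'
#' @param aln Alignment tibble as produced by [parse_sam_lines()].
#' @param ref Optional named vector of reference sequence lengths used to
#'   emit `@SQ` header lines.
#' @param path Optional file path; when given, lines are written there.
#' @return (Invisibly when writing) the character vector of SAM lines.
#' @export
write_sam <- function(aln, ref = NULL, path = NULL) {
  header <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(ref)) {
    header <- c(header, paste0("@SQ\tSN:", names(ref), "\tLN:", as.integer(ref)))
  }
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext, aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a reference genome (FASTA) as a DNAStringSet
#'
#' Sequence names are truncated at the first whitespace, matching aligner
#' conventions for SAM reference names.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "attrace_io_error")
  }
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- stringr::str_split_i(names(ref), "\\s+", 1)
  ref
}
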