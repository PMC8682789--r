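#' Parse a CIGAR string into its operations
#'
#' @param cigar A single CIGAR string (e.g. `"60S90M"`), or `"*"`.
#' @return A tibble with columns `op` (character) and `len` (integer), one row
#'   per operation, in order. `"*"` yields zero rows.
#' @examples
#' cigar_ops("20S50M2I58M20S")
#' @export
cigar_ops <- function(cigar) {
  stopifnot(length(cigar) == 1L, is.character(cigar))
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(tibble(op = character(), len = integer()))
  }
  lens <- stringr::str_extract_all(cigar, "\\d+")[[1]]
  ops <- stringr::str_extract_all(cigar, "[MIDNSHP=X]")[[1]]
  if (length(lens) != length(ops) ||
      nchar(cigar) != sum(nchar(lens)) + length(ops)) {
    abort(paste0("malformed CIGAR string: '", cigar, "'"), class = "attrace_parse_error")
  }
  tibble(op = ops, len = as.integer(lens))
}

# ops that consume the query sequence
.query_ops <- c("M", "I", "S", "=", "X")
# ops that consume the reference
.ref_ops <- c("M", "D", "N", "=", "X")

#' Leading/trailing clip lengths and aligned length of a CIGAR
#'
#' Decomposes a CIGAR into the three quantities the split-read rules are
#' expressed over: the length of the leading clip, the query length consumed by
#' aligned (non-clip) operations, and the length of the trailing clip. Hard
#' clips (`H`) count toward the clip lengths; soft clips anywhere other than
#' the ends of the alignment are rejected.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return A tibble with one row per input and integer columns `lead_clip`,
#'   `aligned_len`, `tail_clip`.
#' @examples
#' cigar_clip_profile(c("60S90M", "90M60S", "150M"))
#' @export
cigar_clip_profile <- function(cigar) {
  out <- lapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    if (nrow(ops) == 0L) {
      return(c(lead_clip = NA_integer_, aligned_len = NA_integer_, tail_clip = NA_integer_))
    }
    clip <- ops$op %in% c("S", "H")
    n <- nrow(ops)
    lead <- 0L
    i <- 1L
    while (i <= n && clip[i]) {
      lead <- lead + ops$len[i]
      i <- i + 1L
    }
    tail_ <- 0L
    j <- n
    while (j >= i && clip[j]) {
      tail_ <- tail_ + ops$len[j]
      j <- j - 1L
    }
    if (i <= j && any(ops$op[i:j] == "S")) {
      abort(paste0("soft clip not at an end of CIGAR '", cg, "'"),
            class = "attrace_cigar_error")
    }
    mid <- if (i <= j) ops[i:j, , drop = FALSE] else ops[0, ]
    aligned <- sum(mid$len[mid$op %in% .query_ops])
    c(lead_clip = lead, aligned_len = as.integer(aligned), tail_clip = tail_)
  })
  m <- do.call(rbind, out)
  tibble(lead_clip = unname(m[, 1]), aligned_len = unname(m[, 2]),
         tail_clip = unname(m[, 3]))
}

#' Query and reference lengths implied by a CIGAR
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector: total length consumed on the query
#'   (`cigar_query_len`, soft clips included) or on the reference
#'   (`cigar_ref_len`). `NA` for `"*"`.
#' @export
cigar_query_len <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    if (nrow(ops) == 0L) return(NA_integer_)
    as.integer(sum(ops$len[ops$op %in% .query_ops]))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname cigar_query_len
#' @export
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    if (nrow(ops) == 0L) return(NA_integer_)
    as.integer(sum(ops$len[ops$op %in% .ref_ops]))
  }, integer(1), USE.NAMES = FALSE)
}

# Fast vectorized profile for the common one/two/three-op CIGARs seen in
# detection streams; falls back to cigar_clip_profile() row-wise for the rest.
# Internal: used on large simulated alignment tables.
clip_profile_fast <- function(cigar) {
  lead <- suppressWarnings(as.integer(stringr::str_match(cigar, "^(\\d+)[SH]")[, 2]))
  lead[is.na(lead)] <- 0L
  tail_ <- suppressWarnings(as.integer(stringr::str_match(cigar, "(\\d+)[SH]$")[, 2]))
  tail_[is.na(tail_)] <- 0L
  simple <- stringr::str_detect(cigar, "^(\\d+[SH])?\\d+M(\\d+[SH])?$")
  aligned <- suppressWarnings(as.integer(stringr::str_match(cigar, "(\\d+)M")[, 2]))
  res <- tibble(lead_clip = lead, aligned_len = aligned, tail_clip = tail_)
  if (any(!simple)) {
    res[!simple, ] <- cigar_clip_profile(cigar[!simple])
  }
  res
}
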