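#' Parameters for the prophage excision simulator
#'
#' Describes one simulated lysogen system: a host genome carrying a single
#' integrated prophage flanked by direct-repeat att cores, plus its two
#' excision products (the excised host chromosome carrying attB and the
#' circular phage genome carrying attP), and a paired-end library sampled
#' from a mixture of the three molecules.
#'
#' Defaults are the simulated study conditions: ~4 Mb host genomes with one
#' prophage each, att core drawn from 2-145 bp with a 1-2 bp mismatch between
#' the two copies when longer than 2 bp, prophage size drawn from 5-150 kb,
#' 2 x 150 bp reads, and a WT-dominated molecule mixture (1000:1:1).
#'
#' @param genome_len Host (wild-type) genome length in bp, prophage included.
#' @param gc GC content of the random genome (0.20-0.80).
#' @param att_len att core length in bp (`NULL`: drawn uniformly from 2-145).
#' @param att_mismatches Substitutions between the attL and attR copies
#'   (`NULL`: 1 or 2 when `att_len > 2`, else 0).
#' @param prophage_size Element size in bp: one att core plus the internal
#'   phage sequence (`NULL`: drawn uniformly from 5000-150000).
#' @param ratios Length-3 numeric, molecule copy-number ratio WT:attB:attP.
#' @param depth Library size expressed as fold-coverage of the WT genome.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd,insert_min,insert_max Fragment-length model
#'   (Gaussian, truncated).
#' @param error_rate Per-base substitution error rate.
#' @return A list of class `attrace_sim_params`.
#' @export
sim_params <- function(genome_len = 4e6, gc = 0.5, att_len = NULL,
                       att_mismatches = NULL, prophage_size = NULL,
                       ratios = c(1000, 1, 1), depth = 100,
                       read_len = 150L, insert_mean = 350, insert_sd = 50,
                       insert_min = 2L * read_len, insert_max = 1000L,
                       error_rate = 0.001) {
  if (gc < 0.20 || gc > 0.80) {
    abort("gc must be within [0.20, 0.80]", class = "attrace_param_error")
  }
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) == 0) {
    abort("ratios must be three non-negative numbers, not all zero",
          class = "attrace_param_error")
  }
  if (depth <= 0) abort("depth must be positive", class = "attrace_param_error")
  if (!is.null(att_len) && att_len < 2) {
    abort("att_len must be >= 2", class = "attrace_param_error")
  }
  if (!is.null(prophage_size) && !is.null(att_len) &&
      prophage_size <= att_len + 1) {
    abort("prophage_size must exceed att_len", class = "attrace_param_error")
  }
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 att_len = att_len, att_mismatches = att_mismatches,
                 prophage_size = prophage_size,
                 ratios = as.numeric(ratios), depth = depth,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 error_rate = error_rate),
            class = "attrace_sim_params")
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

substitute_bases <- function(seq, positions) {
  if (length(positions) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a host genome with one excisable prophage
#'
#' Generates a random genome at the requested GC content and inserts one
#' prophage at a uniformly random position: `H1 | attL | interior | attR | H2`
#' with the two att copies identical except for `att_mismatches` substitutions
#' (applied only when the core is longer than 2 bp). The two excision products
#' are built alongside: the excised host chromosome `H1 | attB | H2` (attB
#' core taken as the attL copy) and the circular phage genome, linearized as
#' `interior | attP` (attP core taken as the attR copy) so that its only
#' junction is the wrap-around.
#'
#' @param params An [sim_params()] object.
#' @param seed Optional integer seed (deterministic output for a given seed).
#' @return A list of class `genome_truth`: `wt`, `excised`, `circular`
#'   (character sequences), `ref_name`, `truth` (one-row tibble with the att
#'   quad, `size`, `att_len`), the realized `att_len`, `att_mismatches`,
#'   `prophage_size`, and the `params` used.
#' @export
simulate_prophage_genome <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  att_len <- params$att_len %||% sample(2:145, 1L)
  att_mm <- params$att_mismatches %||% (if (att_len > 2) sample(1:2, 1L) else 0L)
  if (att_len <= 2) att_mm <- 0L
  psize <- params$prophage_size %||% sample(5000:150000, 1L)
  if (psize >= params$genome_len) {
    abort("prophage_size must be smaller than genome_len",
          class = "attrace_param_error")
  }
  host_len <- params$genome_len - psize - att_len  # H1 + H2
  margin <- max(2L * params$read_len, params$insert_max)
  if (host_len < 2L * margin + 2L) {
    abort("genome too small for the prophage at this margin",
          class = "attrace_param_error")
  }
  h1_len <- sample(margin:(host_len - margin), 1L)
  attL <- random_dna(att_len, params$gc)
  attR <- if (att_mm > 0L) {
    substitute_bases(attL, sample.int(att_len, min(att_mm, att_len)))
  } else {
    attL
  }
  h1 <- random_dna(h1_len, params$gc)
  interior <- random_dna(psize - att_len, params$gc)
  h2 <- random_dna(host_len - h1_len, params$gc)
  wt <- paste0(h1, attL, interior, attR, h2)
  constructed <- c(attL_start = h1_len + 1L,
                   attL_end = h1_len + att_len,
                   attR_start = h1_len + 1L + psize,
                   attR_end = h1_len + psize + att_len)
  realized <- realized_att_quad(wt, constructed, context = params$read_len)
  truth <- tibble(ref = "sim_chr",
                  attL_start = realized[["attL_start"]],
                  attL_end = realized[["attL_end"]],
                  attR_start = realized[["attR_start"]],
                  attR_end = realized[["attR_end"]],
                  size = psize, att_len = realized[["attL_end"]] -
                    realized[["attL_start"]] + 1L)
  structure(list(
    wt = wt,
    excised = paste0(h1, attL, h2),
    circular = paste0(interior, attR),
    ref_name = "sim_chr",
    truth = truth,
    att_len = att_len, att_mismatches = att_mm, prophage_size = psize,
    params = params
  ), class = "genome_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The att core the sequencing data supports is the maximal-scoring shared
# context of the two attachment loci, not necessarily the core as
# constructed: chance identity of the flanking bases extends the realized
# direct repeat, and a mismatch placed at a core edge shortens the portion a
# score-maximal local alignment can report (+1 match / -2 mismatch, the
# re-alignment scoring). This computes the realized quad from the genome.
realized_att_quad <- function(wt, quad, context = 150L) {
  aLs <- quad[["attL_start"]]; aLe <- quad[["attL_end"]]
  aRs <- quad[["attR_start"]]; aRe <- quad[["attR_end"]]
  K <- min(context, aLs - 1L, aRs - aLe - 1L)
  chars <- function(a, b) strsplit(substring(wt, a, b), "")[[1]]
  # left edge: anchored on the right, best-scoring start over flank + core
  x <- chars(aLs - K, aLe); y <- chars(aRs - K, aRe)
  sc <- ifelse(x == y, 1, -2)
  pref <- c(0, cumsum(sc))
  s_off <- which.min(pref[seq_len(length(sc))]) - 1L  # bases dropped at left
  new_Ls <- aLs - K + s_off
  new_Rs <- aRs - K + s_off
  # right edge: anchored on the left, best-scoring extension into the flank
  Ke <- min(context, nchar(wt) - aRe, aRs - aLe - 1L)
  ext <- 0L
  if (Ke > 0L) {
    x2 <- chars(aLe + 1L, aLe + Ke); y2 <- chars(aRe + 1L, aRe + Ke)
    cum <- cumsum(ifelse(x2 == y2, 1, -2))
    if (max(cum) > 0) ext <- which.max(cum)
  }
  c(attL_start = as.integer(new_Ls), attL_end = as.integer(aLe + ext),
    attR_start = as.integer(new_Rs), attR_end = as.integer(aRe + ext))
}

#' Simulate a paired-end read mixture with truth alignments
#'
#' Draws fragments from the wild-type, excised and circular molecules with
#' probability proportional to `ratios * molecule length` until the library
#' reaches `depth` fold-coverage of the WT genome, then emits, for every read,
#' the alignment against the WT reference implied by its provenance: reads
#' crossing the attB junction (excised molecule) or the attP wrap-around
#' junction (circular molecule) get soft-clipped records with the primary
#' alignment on the longer split segment; all other reads get linear records.
#' The proper-pair FLAG bit is set from the mapped geometry (FR orientation
#' within `insert_max`), so junction reads fall into the admissible FLAG sets
#' of [detect_split_candidates()] exactly as an aligner would place them.
#'
#' @param truth A `genome_truth` from [simulate_prophage_genome()].
#' @param params An [sim_params()]; defaults to the one stored in `truth`.
#' @param seed Optional integer seed.
#' @param seq_policy `"clipped"` (default) materializes read sequences only
#'   for soft-clipped records (others carry SAM `SEQ "*"`, keeping large
#'   multi-replicate protocols cheap); `"all"` materializes every read, as
#'   needed for FASTQ output.
#' @return A list: `sam` (alignment tibble in [parse_sam_lines()] schema),
#'   `truth_quad` (one-row tibble), `n_pairs`.
#' @export
simulate_read_mixture <- function(truth, params = truth$params, seed = NULL,
                                  seq_policy = c("clipped", "all")) {
  seq_policy <- match.arg(seq_policy)
  if (!is.null(seed)) set.seed(seed)
  rl <- params$read_len
  tq <- truth$truth
  lens <- c(wt = nchar(truth$wt), attB = nchar(truth$excised),
            attP = nchar(truth$circular))
  if (any(lens[params$ratios > 0] < params$insert_min)) {
    abort("a sampled molecule is shorter than the minimum insert",
          class = "attrace_param_error")
  }
  w <- params$ratios * lens
  n_frags <- max(1L, as.integer(round(params$depth * lens[["wt"]] / (2 * rl))))
  mol <- sample.int(3L, n_frags, replace = TRUE, prob = w)
  ins <- as.integer(round(rnorm(n_frags, params$insert_mean, params$insert_sd)))
  ins <- pmax(params$insert_min, pmin(params$insert_max, ins))
  ins <- pmin(ins, lens[mol])
  L <- lens[mol]
  circ <- mol == 3L
  fs <- ifelse(circ,
               floor(runif(n_frags, 1, L + 1)),
               floor(runif(n_frags, 1, L - ins + 2)))
  fs <- as.integer(fs)

  # mate intervals in molecule coordinates (may exceed L for circular: wrap)
  a_s <- fs                   # forward read at fragment start
  a_e <- fs + rl - 1L
  b_s <- fs + ins - rl        # reverse read at fragment end
  b_e <- fs + ins - 1L

  map_a <- map_reads_to_wt(a_s, a_e, mol, tq, lens)
  map_b <- map_reads_to_wt(b_s, b_e, mol, tq, lens)

  swap <- runif(n_frags) < 0.5  # which physical mate is read 1
  qname <- sprintf("frag%07d", seq_len(n_frags))

  build_mate <- function(self, other, self_rev, self_first) {
    span_lo <- pmin(self$pos, other$pos)
    span_hi <- pmax(self$pos + self$ref_len - 1L, other$pos + other$ref_len - 1L)
    span <- span_hi - span_lo + 1L
    fwd_pos <- if (self_rev) other$pos else self$pos
    rev_pos <- if (self_rev) self$pos else other$pos
    proper <- span <= params$insert_max & fwd_pos <= rev_pos
    flag <- 1L + 2L * proper + 16L * self_rev + 32L * (!self_rev) +
      64L * self_first + 128L * (!self_first)
    tlen_sign <- ifelse(self$pos < other$pos |
                          (self$pos == other$pos & !self_rev), 1L, -1L)
    tibble(qname = qname, flag = as.integer(flag), rname = self$rname,
           pos = self$pos, mapq = 60L, cigar = self$cigar,
           rnext = other$rname, pnext = other$pos,
           tlen = tlen_sign * span,
           seq = NA_character_, qual = "*",
           src = c("wt", "attB", "attP")[mol],
           mol_start = self$mol_start, mol_end = self$mol_end,
           crosses_junction = self$crosses)
  }
  rec_a <- build_mate(map_a, map_b, self_rev = FALSE, self_first = TRUE)
  rec_b <- build_mate(map_b, map_a, self_rev = TRUE, self_first = FALSE)
  # library orientation: with prob .5 the fragment-end read is read 1
  rec_a$flag <- rec_a$flag + ifelse(swap, 64L, 0L)   #  64 -> 128
  rec_b$flag <- rec_b$flag - ifelse(swap, 64L, 0L)   # 128 ->  64

  sam <- bind_rows(rec_a, rec_b)
  need_seq <- if (seq_policy == "all") rep(TRUE, nrow(sam)) else grepl("S", sam$cigar, fixed = TRUE)
  if (any(need_seq)) {
    mols <- c(truth$wt, truth$excised, truth$circular)
    idx <- which(need_seq)
    src_i <- rep(mol, 2L)[idx]
    ms <- sam$mol_start[idx]
    me <- sam$mol_end[idx]
    Lm <- lens[src_i]
    wrap <- me > Lm
    seqs <- character(length(idx))
    seqs[!wrap] <- substring(mols[src_i[!wrap]], ms[!wrap], me[!wrap])
    if (any(wrap)) {
      seqs[wrap] <- paste0(substring(mols[src_i[wrap]], ms[wrap], Lm[wrap]),
                           substring(mols[src_i[wrap]], 1L, me[wrap] - Lm[wrap]))
    }
    seqs <- apply_read_errors(seqs, params$error_rate)
    sam$seq[idx] <- seqs
    sam$qual[idx] <- strrep("I", rl)
  }
  sam$seq[is.na(sam$seq)] <- "*"
  sam <- bind_cols(sam[, c("qname", "flag", "rname", "pos", "mapq", "cigar",
                           "rnext", "pnext", "tlen", "seq", "qual")],
                   decode_flags(sam$flag),
                   tibble(mate_rname = sam$rnext,
                          src = sam$src, crosses_junction = sam$crosses_junction))
  list(sam = sam, truth_quad = tq, n_pairs = n_frags)
}

# Map read intervals in molecule coordinates to WT-reference records.
# Molecule layouts (1-based):
#   wt:      identical coordinates.
#   attB:    [1, attL_end] -> same; (attL_end, Lb] -> +size (the junction at
#            attL_end is the excision junction; the att core is shared, so a
#            crossing read splits with overlapping query intervals).
#   attP:    linearized interior|attP maps as one block [1, Lc] ->
#            [attL_end + 1, attR_end]; only the wrap-around is a junction.
# Returns pos/cigar of the BWA-style primary record (longer split segment,
# remainder soft-clipped).
map_reads_to_wt <- function(s, e, mol, tq, lens) {
  n <- length(s)
  rl <- e[1] - s[1] + 1L
  pos <- integer(n); cigar <- character(n); crosses <- logical(n)
  ref_len <- integer(n)
  size <- tq$size
  ov <- tq$att_len
  Lc <- lens[["attP"]]

  wt_i <- mol == 1L
  pos[wt_i] <- s[wt_i]
  cigar[wt_i] <- paste0(e[wt_i] - s[wt_i] + 1L, "M")
  ref_len[wt_i] <- e[wt_i] - s[wt_i] + 1L

  b_i <- mol == 2L
  if (any(b_i)) {
    sb <- s[b_i]; eb <- e[b_i]
    cross <- sb < tq$attL_start & eb > tq$attL_end
    right_only <- sb >= tq$attL_start & eb > tq$attL_end
    left_only <- eb <= tq$attL_end
    len_left <- tq$attL_end - sb + 1L
    len_right <- eb - tq$attL_start + 1L
    p <- integer(sum(b_i)); cg <- character(sum(b_i)); rle_ <- integer(sum(b_i))
    p[left_only] <- sb[left_only]
    cg[left_only] <- paste0(rl, "M")
    rle_[left_only] <- rl
    p[right_only] <- sb[right_only] + size
    cg[right_only] <- paste0(rl, "M")
    rle_[right_only] <- rl
    if (any(cross)) {
      ll <- len_left[cross]; lr <- len_right[cross]
      use_left <- ll >= lr
      p[cross] <- ifelse(use_left, sb[cross], tq$attR_start)
      cg[cross] <- ifelse(use_left,
                          paste0(ll, "M", rl - ll, "S"),
                          paste0(rl - lr, "S", lr, "M"))
      rle_[cross] <- ifelse(use_left, ll, lr)
    }
    pos[b_i] <- p; cigar[b_i] <- cg; ref_len[b_i] <- rle_
    crosses[b_i] <- cross
  }

  c_i <- mol == 3L
  if (any(c_i)) {
    sc <- s[c_i]; ec <- e[c_i]
    wrap <- ec > Lc
    p <- integer(sum(c_i)); cg <- character(sum(c_i)); rle_ <- integer(sum(c_i))
    p[!wrap] <- tq$attL_end + sc[!wrap]
    cg[!wrap] <- paste0(rl, "M")
    rle_[!wrap] <- rl
    if (any(wrap)) {
      len_left <- Lc - sc[wrap] + 1L          # ends at attR_end on wt
      e2 <- ec[wrap] - Lc                     # tail length, maps from attL_end+1
      len_right <- ov + e2                    # extended back through the core
      pure_right <- len_left <= ov            # read starts inside the att core
      use_left <- len_left >= len_right & !pure_right
      p[wrap] <- ifelse(pure_right,
                        tq$attL_start + (sc[wrap] - (Lc - ov) - 1L),
                        ifelse(use_left,
                               tq$attL_end + sc[wrap],
                               tq$attL_start))
      cg[wrap] <- ifelse(pure_right,
                         paste0(rl, "M"),
                         ifelse(use_left,
                                paste0(len_left, "M", rl - len_left, "S"),
                                paste0(rl - len_right, "S", len_right, "M")))
      rle_[wrap] <- ifelse(pure_right, rl, ifelse(use_left, len_left, len_right))
      crosses[c_i][wrap] <- !pure_right
    }
    pos[c_i] <- p; cigar[c_i] <- cg; ref_len[c_i] <- rle_
  }

  list(rname = rep(tq$ref, n), pos = pos, cigar = cigar, ref_len = ref_len,
       mapped = rep(TRUE, n), mol_start = s, mol_end = e, crosses = crosses)
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    seqs[i] <- substitute_bases(seqs[i], sample.int(nchar(seqs[i]), nerr[i]))
  }
  seqs
}

#' Score calls against the simulated truth
#'
#' A call is a hit when each of its four attachment endpoints lies within
#' `tol` bp of the simulated truth quad (on the same reference).
#'
#' @param calls An `attrace_candidates` tibble.
#' @param truth A `genome_truth` or its one-row truth tibble.
#' @param tol Per-endpoint tolerance in bp (default 2).
#' @return A one-row tibble: `n_calls`, `hit` (logical), `max_dev` (largest
#'   endpoint deviation of the best call; `NA` when there are no calls).
#' @export
evaluate_calls <- function(calls, truth, tol = 2L) {
  tq <- if (inherits(truth, "genome_truth")) truth$truth else truth
  if (nrow(calls) == 0L) {
    return(tibble(n_calls = 0L, hit = FALSE, max_dev = NA_integer_))
  }
  dev <- pmax(abs(calls$attL_start - tq$attL_start),
              abs(calls$attL_end - tq$attL_end),
              abs(calls$attR_start - tq$attR_start),
              abs(calls$attR_end - tq$attR_end))
  dev[calls$contig != tq$ref] <- NA_integer_
  best <- suppressWarnings(min(dev, na.rm = TRUE))
  if (!is.finite(best)) best <- NA_integer_
  tibble(n_calls = nrow(calls), hit = isTRUE(best <= tol),
         max_dev = as.integer(best))
}

#' Write a simulated dataset to disk
#'
#' Writes the three molecules and the WT reference as FASTA, the truth
#' alignments as SAM, paired FASTQ when sequences are fully materialized, and
#' a JSON manifest with the parameters and truth quad.
#'
#' @param truth A `genome_truth`.
#' @param reads Result of [simulate_read_mixture()] (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- Biostrings::DNAStringSet(c(truth$wt))
  names(ref) <- truth$ref_name
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  mols <- Biostrings::DNAStringSet(c(truth$wt, truth$excised, truth$circular))
  names(mols) <- c("wild_type", "excised_host", "circular_phage")
  Biostrings::writeXStringSet(mols, file.path(dir, "molecules.fasta"))
  manifest <- list(ref_name = truth$ref_name,
                   truth_quad = as.list(truth$truth),
                   att_len = truth$att_len,
                   att_mismatches = truth$att_mismatches,
                   prophage_size = truth$prophage_size,
                   params = unclass(truth$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(reads)) {
    write_sam(reads$sam, ref = setNames(nchar(truth$wt), truth$ref_name),
              path = file.path(dir, "truth.sam"))
    if (!any(reads$sam$seq == "*")) {
      write_fastq_pair(reads$sam, dir)
    }
  }
  invisible(dir)
}

write_fastq_pair <- function(sam, dir) {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  }
  emit <- function(rows, path) {
    seqs <- ifelse(rows$is_reverse, revcomp(rows$seq), rows$seq)
    writeLines(paste0("@", rows$qname, "\n", seqs, "\n+\n", rows$qual), path)
  }
  emit(filter(sam, .data$is_first_in_pair), file.path(dir, "reads_R1.fastq"))
  emit(filter(sam, .data$is_second_in_pair), file.path(dir, "reads_R2.fastq"))
}
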