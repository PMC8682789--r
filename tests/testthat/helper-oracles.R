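# Shared fixtures and independent oracles, all built in code.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A toy two-locus junction system: the read is X-suffix + core + Y-prefix,
# locus A carries ...X core... and locus B carries ...core Y..., so the read
# splits with query intervals overlapping by the core length.
make_toy_junction <- function(x_len = 80, core_len = 20, y_len = 50,
                              spacer = 120, seed = 42) {
  set.seed(seed)
  x <- rand_dna(x_len)
  core <- rand_dna(core_len)
  y <- rand_dna(y_len)
  pad1 <- rand_dna(60)
  pad2 <- rand_dna(spacer)
  pad3 <- rand_dna(60)
  # pin the realized repeat to exactly core_len: the bases flanking the two
  # core copies must disagree, or the repeat (hence the overlap) extends
  other_than <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  if (substring(pad2, 1, 1) == substring(y, 1, 1)) {
    pad2 <- paste0(other_than(substring(y, 1, 1)), substring(pad2, 2))
  }
  if (substring(pad2, spacer, spacer) == substring(x, x_len, x_len)) {
    pad2 <- paste0(substring(pad2, 1, spacer - 1),
                   other_than(substring(x, x_len, x_len)))
  }
  ref <- paste0(pad1, x, core, pad2, core, y, pad3)
  list(
    read = paste0(x, core, y),
    ref = ref,
    # locus A: X+core; locus B: core+Y (1-based reference coordinates)
    a_start = 61, a_end = 60 + x_len + core_len,
    b_start = 60 + x_len + core_len + spacer + 1,
    b_end = 60 + x_len + core_len + spacer + core_len + y_len,
    core_len = core_len, x_len = x_len, y_len = y_len
  )
}

# Brute-force oracle: all maximal exact-match segments of `read` in `ref`
# of length >= min_len (forward strand). Independent of the package's
# seed-and-extend + Smith-Waterman path.
oracle_exact_segments <- function(read, ref, min_len = 10) {
  rchars <- strsplit(read, "")[[1]]
  gchars <- strsplit(ref, "")[[1]]
  L <- length(rchars); G <- length(gchars)
  segs <- list()
  for (q in seq_len(L)) {
    for (r in seq_len(G)) {
      # maximal means not extendable left
      if (q > 1 && r > 1 && rchars[q - 1] == gchars[r - 1]) next
      k <- 0
      while (q + k <= L && r + k <= G && rchars[q + k] == gchars[r + k]) k <- k + 1
      if (k >= min_len) {
        segs[[length(segs) + 1]] <- c(q_start = q, q_end = q + k - 1,
                                      r_start = r, r_end = r + k - 1)
      }
    }
  }
  do.call(rbind, segs)
}

# Brute-force clustering oracle: enumerate all partitions of the quads and
# return the coarsest partition in which every linked pair (all four
# endpoints within tol) is co-clustered and clusters are link-connected.
# Equivalent to connected components of the link graph, computed naively.
oracle_cluster <- function(quads, tol) {
  n <- nrow(quads)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- all(abs(quads[i, ] - quads[j, ]) <= tol)
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Small simulated dataset used by several tests (cheap; error-free).
small_sim <- function(seed = 1, ratios = c(90, 5, 5), depth = 60,
                      att_len = 30, att_mismatches = 0, genome_len = 80000,
                      prophage_size = 10000, error_rate = 0) {
  p <- sim_params(genome_len = genome_len, att_len = att_len,
                  att_mismatches = att_mismatches,
                  prophage_size = prophage_size, ratios = ratios,
                  depth = depth, error_rate = error_rate)
  tr <- simulate_prophage_genome(p, seed = seed)
  rd <- simulate_read_mixture(tr, seed = seed + 5000)
  ref <- Biostrings::DNAStringSet(tr$wt)
  names(ref) <- tr$ref_name
  list(truth = tr, reads = rd, ref = ref)
}

# Known active prophages of reference strains (published att coordinates).
known_prophages <- function() {
  path <- system.file("extdata", "known_prophages.csv", package = "attrace")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# minimal single-record alignment tibble for detection tests
mk_rec <- function(flag, cigar, rname = "c", pos = 1000L, mate_rname = rname,
                   seq = NULL) {
  qlen <- cigar_query_len(cigar)
  if (is.null(seq)) seq <- rand_dna(ifelse(is.na(qlen), 150L, qlen))
  dplyr::bind_cols(
    tibble::tibble(qname = "r", flag = as.integer(flag), rname = rname,
                   pos = pos, mapq = 60L, cigar = cigar, rnext = mate_rname,
                   pnext = 2000L, tlen = 0L, seq = seq, qual = "*"),
    decode_flags(as.integer(flag)),
    tibble::tibble(mate_rname = mate_rname)
  )
}

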