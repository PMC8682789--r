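test_that("a constructed junction read verifies with the expected overlap", {
  toy <- make_toy_junction(x_len = 80, core_len = 20, y_len = 50, seed = 42)
  ref <- Biostrings::DNAStringSet(toy$ref)
  names(ref) <- "toyref"

  # independent oracle: maximal exact segments of the read in the reference
  segs <- oracle_exact_segments(toy$read, toy$ref, min_len = 10)
  segs <- segs[order(-(segs[, "q_end"] - segs[, "q_start"])), , drop = FALSE]
  top2 <- segs[1:2, ][order(segs[1:2, "q_start"]), ]
  # the two segments cover a prefix and a suffix overlapping by the core
  expect_equal(unname(top2[1, c("q_start", "q_end")]), c(1, 100))
  expect_equal(unname(top2[2, c("q_start", "q_end")]), c(81, 150))

  # package path: candidate record -> seeded local realignment
  cand <- detect_split_candidates(
    mk_rec(97L, "100M50S", rname = "toyref", pos = toy$a_start - 79,
           seq = toy$read))
  ev <- verify_split_reads(cand, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ov, 20L)
  expect_equal(c(ev$l_q_start, ev$l_q_end), unname(top2[1, c("q_start", "q_end")]))
  expect_equal(c(ev$r_q_start, ev$r_q_end), unname(top2[2, c("q_start", "q_end")]))
  expect_equal(c(ev$l_r_start, ev$l_r_end), unname(top2[1, c("r_start", "r_end")]))
  expect_equal(ev$jtype, "attB")
  # overlap equals the att core length and the quad matches the construction
  expect_equal(ev$attL_end, toy$a_end)
  expect_equal(ev$attR_start, toy$b_start)
})

test_that("linear and abutting reads do not satisfy the overlap criterion", {
  set.seed(11)
  ref_seq <- rand_dna(600)
  ref <- Biostrings::DNAStringSet(ref_seq)
  names(ref) <- "r"
  # a read matching one locus end-to-end: no second locus
  lin <- mk_rec(97L, "100M50S", rname = "r", pos = 101,
                seq = substring(ref_seq, 101, 250))
  expect_equal(nrow(verify_split_reads(detect_split_candidates(lin), ref)), 0L)

  # abutting split (core length 0): rejected unless min_overlap = 0
  left <- substring(ref_seq, 51, 130)    # 80 bp at locus A
  right <- substring(ref_seq, 401, 470)  # 70 bp at locus B
  ab <- mk_rec(97L, "80M70S", rname = "r", pos = 51, seq = paste0(left, right))
  cand <- detect_split_candidates(ab)
  expect_equal(nrow(verify_split_reads(cand, ref)), 0L)
  ev0 <- verify_split_reads(cand, ref, min_overlap = 0L)
  expect_equal(nrow(ev0), 1L)
  expect_equal(ev0$ov, 0L)
})

test_that("junction classification follows reference order of the segments", {
  seg <- function(r_start, r_end) list(r_start = r_start, r_end = r_end)
  # the published Pf4 geometry: prefix ends upstream of where the suffix starts
  expect_equal(classify_junction(seg(785288, 785336), seg(797699, 797747)), "attB")
  # mirrored circular-junction geometry
  expect_equal(classify_junction(seg(797699, 797747), seg(785288, 785336)), "attP")
  # same-locus overlap on the reference: not classifiable
  expect_true(is.na(classify_junction(seg(100, 220), seg(150, 260))))
  # never both attB (antisymmetry)
  a <- seg(1000, 1100); b <- seg(5000, 5100)
  expect_false(classify_junction(a, b) == classify_junction(b, a))
})

test_that("att endpoint inference reproduces published quads", {
  expect_equal(infer_att_endpoints(785336, 797699, "attB", 49),
               c(attL_start = 785288, attL_end = 785336,
                 attR_start = 797699, attR_end = 797747))
  expect_equal(infer_att_endpoints(1538157, 1501853, "attP", 94),
               c(attL_start = 1501853, attL_end = 1501946,
                 attR_start = 1538064, attR_end = 1538157))
  expect_equal(infer_att_endpoints(1000, 2000, "attB", 1),
               c(attL_start = 1000, attL_end = 1000,
                 attR_start = 2000, attR_end = 2000))
  # inconsistent geometry is discarded
  expect_null(infer_att_endpoints(1000, 990, "attB", 49))
})

test_that("attB- and attP-derived quads agree and match the simulated truth", {
  sim <- small_sim(seed = 5, ratios = c(80, 10, 10), depth = 60)
  ev <- verify_split_reads(detect_split_candidates(sim$reads$sam), sim$ref)
  expect_gt(sum(ev$jtype == "attB"), 0)
  expect_gt(sum(ev$jtype == "attP"), 0)
  quads <- unique(ev[, c("attL_start", "attL_end", "attR_start", "attR_end")])
  expect_equal(nrow(quads), 1L)
  tq <- sim$truth$truth
  expect_equal(quads$attL_start, tq$attL_start)
  expect_equal(quads$attR_end, tq$attR_end)
  # error-free reads: overlap equals the realized att core length
  expect_true(all(ev$ov == tq$att_len))
})
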