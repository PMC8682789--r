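mk_ev <- function(quads, jtype = "attB", ref = "chr") {
  n <- nrow(quads)
  tibble::tibble(
    read_id = paste0("r", seq_len(n)), flag = 97L,
    jtype = rep_len(jtype, n),
    l_ref = ref, l_strand = "+",
    l_q_start = 1L, l_q_end = 100L,
    l_r_start = quads[, 1] - 60L, l_r_end = quads[, 2], l_identity = 1,
    r_ref = ref, r_strand = "+",
    r_q_start = 81L, r_q_end = 150L,
    r_r_start = quads[, 3], r_r_end = quads[, 4] + 50L, r_identity = 1,
    ov = quads[, 2] - quads[, 1] + 1L,
    attL_start = quads[, 1], attL_end = quads[, 2],
    attR_start = quads[, 3], attR_end = quads[, 4]
  )
}

q <- function(...) matrix(as.integer(c(...)), ncol = 4, byrow = TRUE)

test_that("identical and distant quads cluster as expected", {
  cl <- cluster_evidence(mk_ev(q(100, 110, 5000, 5010,
                                 100, 110, 5000, 5010,
                                 100, 110, 5000, 5010)), tol = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$sr_attB, 3L)
  expect_equal(c(cl$attL_start, cl$attL_end, cl$attR_start, cl$attR_end),
               c(100L, 110L, 5000L, 5010L))

  cl2 <- cluster_evidence(mk_ev(q(100, 110, 5000, 5010,
                                  100, 110, 5000, 5010,
                                  100, 110, 9000, 9010)), tol = 2)
  expect_equal(nrow(cl2), 2L)
  expect_equal(sort(cl2$attR_start), c(5000L, 9000L))
})

test_that("within-tolerance jitter forms one cluster with modal consensus", {
  quads <- q(100, 110, 5000, 5010,
             100, 111, 5000, 5010,
             100, 110, 5000, 5010)
  cl <- cluster_evidence(mk_ev(quads), tol = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$attL_end, 110L)  # mode of 110,111,110
  # grouping agrees with the brute-force link-component oracle
  expect_equal(length(unique(oracle_cluster(quads, 2))), 1L)
  far <- q(100, 110, 5000, 5010,
           100, 110, 5004, 5010)   # 4 > tol at attR_start
  expect_equal(nrow(cluster_evidence(mk_ev(far), tol = 2)),
               length(unique(oracle_cluster(far, 2))))
  # tie in the mode resolves to the smaller coordinate
  tie <- cluster_evidence(mk_ev(q(100, 110, 5000, 5010,
                                  100, 111, 5000, 5010)), tol = 2)
  expect_equal(tie$attL_end, 110L)
})

test_that("evidence is conserved across clustering", {
  set.seed(8)
  quads <- q(rep(c(100, 130, 8000, 8030), 5),
             rep(c(20000, 20040, 52000, 52040), 3))
  cl <- cluster_evidence(mk_ev(quads), tol = 2)
  expect_equal(sum(vapply(cl$members, nrow, integer(1))), nrow(quads))
  expect_equal(sum(cl$sr_attB + cl$sr_attP), nrow(quads))
})

mk_drp <- function(pos, pnext, reverse = FALSE, rname = "chr", qname = "d1",
                   len = 150L) {
  flag <- if (reverse) 81L else 97L
  dplyr::bind_cols(
    tibble::tibble(qname = qname, flag = flag, rname = rname, pos = pos,
                   mapq = 60L, cigar = paste0(len, "M"), rnext = rname,
                   pnext = pnext, tlen = 0L, seq = "*", qual = "*"),
    decode_flags(flag),
    tibble::tibble(mate_rname = rname, aligned_len = len,
                   orientation_class = flag, mode = "chromosome")
  )
}

test_that("discordant pairs increment the matching junction counter once", {
  cl <- cluster_evidence(mk_ev(q(10000, 10030, 40000, 40030)))
  # mates flanking from outside in deletion orientation -> attB
  m <- merge_discordant(cl, mk_drp(pos = 10000 - 300 - 149, pnext = 40030 + 250),
                        window = 1000)
  expect_equal(m$drp_attB, 1L)
  expect_equal(m$drp_attP, 0L)
  # everted pair inside the prophage -> attP
  m2 <- merge_discordant(cl, mk_drp(pos = 40030 - 400, pnext = 10000 + 50,
                                    reverse = FALSE, qname = "d2"))
  # forward read near attR_end, reverse mate near attL_start
  expect_equal(m2$drp_attP, 1L)
  # concordant pair within the prophage: no increment
  m3 <- merge_discordant(cl, mk_drp(pos = 15000, pnext = 15350, qname = "d3"))
  expect_equal(m3$drp_attB + m3$drp_attP, 0L)
  expect_equal(attr(m3, "dropped_drps"), 1L)
  # pair near an unrelated locus: dropped
  m4 <- merge_discordant(cl, mk_drp(pos = 300, pnext = 900, qname = "d4"))
  expect_equal(attr(m4, "dropped_drps"), 1L)
  # both records of one pair count once
  both <- dplyr::bind_rows(
    mk_drp(pos = 10000 - 300 - 149, pnext = 40030 + 250, qname = "p"),
    mk_drp(pos = 40030 + 250, pnext = 10000 - 300 - 149, reverse = TRUE, qname = "p"))
  expect_equal(merge_discordant(cl, both)$drp_attB, 1L)
})

test_that("candidate filters apply the documented bounds", {
  base <- mk_ev(q(785288, 785336, 797699, 797747))
  cl <- cluster_evidence(dplyr::bind_rows(base, dplyr::mutate(base, jtype = "attP")))
  got <- filter_candidates(cl, filter_config())
  expect_equal(nrow(got), 1L)
  expect_equal(got$size, 12411L)
  expect_equal(got$att_length, 49L)

  # size bounds are exclusive
  small <- cluster_evidence(dplyr::bind_rows(
    mk_ev(q(1000, 1030, 5800, 5830)),
    dplyr::mutate(mk_ev(q(1000, 1030, 5800, 5830)), jtype = "attP")))
  expect_equal(nrow(filter_candidates(small, filter_config())), 0L)  # size 4800
  expect_equal(nrow(filter_candidates(small, filter_config(min_size = 4000))), 1L)

  # att length bound is exclusive: 2 bp fails, 3 bp passes
  att2 <- cluster_evidence(dplyr::bind_rows(
    mk_ev(q(1000, 1001, 9000, 9001)),
    dplyr::mutate(mk_ev(q(1000, 1001, 9000, 9001)), jtype = "attP")))
  expect_equal(nrow(filter_candidates(att2, filter_config())), 0L)
  att3 <- cluster_evidence(dplyr::bind_rows(
    mk_ev(q(1000, 1002, 9000, 9002)),
    dplyr::mutate(mk_ev(q(1000, 1002, 9000, 9002)), jtype = "attP")))
  expect_equal(nrow(filter_candidates(att3, filter_config())), 1L)

  # both event classes required by default
  b_only <- cluster_evidence(mk_ev(q(rep(c(1000, 1030, 9000, 9030), 3))))
  expect_equal(nrow(filter_candidates(b_only, filter_config())), 0L)
  expect_equal(nrow(filter_candidates(b_only, filter_config(min_attP_events = 0))), 1L)
})

test_that("loosening any filter bound never removes a retained candidate", {
  set.seed(9)
  cl <- cluster_evidence(dplyr::bind_rows(
    mk_ev(q(1000, 1030, 9000, 9030)),
    dplyr::mutate(mk_ev(q(1000, 1030, 9000, 9030)), jtype = "attP"),
    mk_ev(q(50000, 50010, 58000, 58010))
  ))
  strict <- filter_candidates(cl, filter_config())
  for (loose in list(filter_config(min_att_len = 0),
                     filter_config(min_size = 100),
                     filter_config(max_size = 1e6),
                     filter_config(min_attB_events = 0),
                     filter_config(min_attP_events = 0))) {
    got <- filter_candidates(cl, loose)
    key <- function(x) paste(x$contig, x$attL_start, x$attR_start)
    expect_true(all(key(strict) %in% key(got)))
  }
})

test_that("summary identities hold for every published prophage row", {
  kp <- known_prophages()
  summ <- summarize_candidates(tibble::as_tibble(kp))
  expect_equal(summ$size, kp$size)
  expect_equal(summ$att_length, kp$att_length)
  # spot values
  expect_equal(summ$size[kp$prophage == "CP4So"], 36211L)
  expect_equal(summ$att_length[kp$prophage == "CP4So"], 94L)
  expect_equal(summ$size[kp$prophage == "LambdaSo"], 51841L)
  expect_equal(summ$att_length[kp$prophage == "Phi10403S"], 3L)
})
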