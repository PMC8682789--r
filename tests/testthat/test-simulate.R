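test_that("genome construction conserves lengths and determinism", {
  p <- sim_params(genome_len = 100000, att_len = 20, att_mismatches = 1,
                  prophage_size = 8000)
  tr <- simulate_prophage_genome(p, seed = 7)
  expect_equal(nchar(tr$wt), 100000L)
  expect_equal(nchar(tr$excised), 92000L)
  expect_equal(nchar(tr$circular), 8000L)
  expect_equal(tr$truth$size, 8000L)
  # excised and circular reconstruct from wt and the constructed boundaries
  expect_equal(nchar(tr$wt) - tr$truth$size, nchar(tr$excised))
  # determinism: same seed, identical output
  tr2 <- simulate_prophage_genome(p, seed = 7)
  expect_identical(tr$wt, tr2$wt)
  expect_identical(tr$truth, tr2$truth)
  # infeasible parameters
  expect_error(simulate_prophage_genome(
    sim_params(genome_len = 10000, prophage_size = 20000), seed = 1),
    class = "attrace_param_error")
  expect_error(sim_params(gc = 0.1), class = "attrace_param_error")
  expect_error(sim_params(depth = 0), class = "attrace_param_error")
  expect_error(sim_params(ratios = c(0, 0, 0)), class = "attrace_param_error")
})

test_that("a 2 bp att core carries no mismatch", {
  p <- sim_params(genome_len = 60000, att_len = 2, att_mismatches = NULL,
                  prophage_size = 6000)
  tr <- simulate_prophage_genome(p, seed = 9)
  expect_equal(tr$att_mismatches, 0L)
  # both copies identical at the constructed positions
  sub <- function(s, a, b) substring(s, a, b)
  expect_equal(sub(tr$wt, tr$truth$attL_start, tr$truth$attL_end),
               sub(tr$wt, tr$truth$attR_start, tr$truth$attR_end))
})

test_that("truth alignments are internally consistent SAM", {
  sim <- small_sim(seed = 16, ratios = c(80, 10, 10), depth = 25)
  sam <- sim$reads$sam
  # every record's CIGAR consumes exactly the read length
  expect_true(all(cigar_query_len(sam$cigar) == 150L))
  # materialized sequences have matching length
  has_seq <- sam$seq != "*"
  expect_true(all(nchar(sam$seq[has_seq]) == 150L))
  # soft-clipped records always carry their sequence
  expect_true(all(sam$seq[grepl("S", sam$cigar)] != "*"))
  # junction-crossing reads fall in the admissible preliminary FLAG sets
  crossing <- sam[sam$crosses_junction, ]
  expect_gt(nrow(crossing), 0)
  prof <- cigar_clip_profile(crossing$cigar)
  left <- prof$lead_clip > 0
  expect_true(all(crossing$flag[left] %in% c(145L, 81L, 99L, 163L)))
  expect_true(all(crossing$flag[!left] %in% c(97L, 161L, 147L, 83L)))
  # reads wholly inside the circular phage map linearly inside the prophage
  tq <- sim$truth$truth
  circ_linear <- sam$src == "attP" & !grepl("S", sam$cigar)
  expect_true(all(sam$pos[circ_linear] >= tq$attL_start))
  expect_true(all(sam$pos[circ_linear] + 149L <= tq$attR_end))
})

test_that("mixture weights follow ratio x molecule length and depth", {
  sim <- small_sim(seed = 17, ratios = c(90, 5, 5), depth = 40,
                   genome_len = 100000, prophage_size = 10000)
  sam <- sim$reads$sam
  n <- nrow(sam)
  expect_equal(n, 2L * round(40 * 100000 / 300))
  lens <- c(wt = 100000, attB = 90000, attP = 10000)
  w <- c(90, 5, 5) * lens
  obs <- table(sam$src)[names(w)]
  exp_n <- n * w / sum(w)
  # multinomial counts within 5 sigma
  sig <- sqrt(n * (w / sum(w)) * (1 - w / sum(w)))
  expect_true(all(abs(obs - exp_n) < 5 * sig))
})

test_that("junction-spanning read counts match coverage accounting", {
  # a read crosses a junction with core length ov when its start falls in a
  # window of (read_len - 1 - ov) positions; expected crossing reads are
  # coverage * window / read_len per junction
  p <- sim_params(genome_len = 100000, att_len = 20, att_mismatches = 0,
                  prophage_size = 10000, ratios = c(0, 1, 1), depth = 30,
                  error_rate = 0)
  tr <- simulate_prophage_genome(p, seed = 18)
  ov <- tr$truth$att_len
  counts <- vapply(1:8, function(i) {
    rd <- simulate_read_mixture(tr, seed = 300 + i)
    sum(rd$sam$crosses_junction)
  }, numeric(1))
  lens <- c(100000, 90000, 10000)
  w <- c(0, 1, 1) * lens
  depth_b <- 30 * 100000 * (w[2] / sum(w)) / 90000
  depth_p <- 30 * 100000 * (w[3] / sum(w)) / 10000
  lam <- (depth_b + depth_p) * (150 - 1 - ov) / 150
  m <- mean(counts)
  expect_lt(abs(m - lam), 3 * sqrt(lam / length(counts)))
})

test_that("a WT-only library never crosses a junction", {
  sim <- small_sim(seed = 19, ratios = c(1, 0, 0), depth = 20)
  expect_equal(sum(sim$reads$sam$crosses_junction), 0L)
  expect_true(all(sim$reads$sam$cigar == "150M"))
})

test_that("call evaluation scores hits at the endpoint tolerance", {
  sim <- small_sim(seed = 20)
  tq <- sim$truth$truth
  call <- summarize_candidates(tibble::tibble(
    ref = tq$ref, attL_start = tq$attL_start, attL_end = tq$attL_end,
    attR_start = tq$attR_start, attR_end = tq$attR_end))
  expect_true(evaluate_calls(call, sim$truth)$hit)
  shifted <- dplyr::mutate(call, attR_start = attR_start + 10L)
  expect_false(evaluate_calls(shifted, sim$truth)$hit)
  none <- call[0, ]
  expect_false(evaluate_calls(none, sim$truth)$hit)
  # 13 hits in 20 replicates -> sensitivity 0.65
  hits <- c(rep(TRUE, 13), rep(FALSE, 7))
  expect_equal(mean(hits), 0.65)
})

test_that("simulation output files round-trip", {
  dir <- withr::local_tempdir()
  p <- sim_params(genome_len = 50000, att_len = 15, att_mismatches = 0,
                  prophage_size = 6000, ratios = c(4, 1, 1), depth = 4,
                  error_rate = 0)
  tr <- simulate_prophage_genome(p, seed = 23)
  rd <- simulate_read_mixture(tr, seed = 24, seq_policy = "all")
  write_simulation(tr, rd, dir)
  ref <- read_reference(file.path(dir, "reference.fasta"))
  expect_equal(as.character(ref[[1]]), tr$wt)
  back <- read_sam(file.path(dir, "truth.sam"))
  expect_equal(nrow(back), nrow(rd$sam))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$truth_quad$attL_start, tr$truth$attL_start)
  expect_true(file.exists(file.path(dir, "reads_R1.fastq")))
  r1 <- readLines(file.path(dir, "reads_R1.fastq"))
  expect_equal(length(r1), 4L * rd$n_pairs)
})
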