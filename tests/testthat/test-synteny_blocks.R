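test_that("windowing follows the enumeration rule", {
  cfg <- synteny_config()
  # 20 kb contig: starts 0 and 10000; the trailing window has length == step
  # and is kept
  w20 <- window_genome(genome_index("c", 20000), cfg)
  expect_equal(w20$start, c(0, 10000))
  expect_equal(w20$end, c(20000, 20000))
  # 100 kb contig: 10 windows, last [90000, 100000)
  w100 <- window_genome(genome_index("c", 100000), cfg)
  expect_equal(nrow(w100), 10)
  expect_equal(w100$start, seq(0, 90000, 10000))
  expect_equal(w100$end[10], 100000)
  # sub-step contig keeps its single short window
  w5 <- window_genome(genome_index("c", 5000), cfg)
  expect_equal(nrow(w5), 1)
  expect_equal(unlist(w5[1, c("start", "end")], use.names = FALSE), c(0, 5000))
  # a trailing fragment shorter than the step is merged into its predecessor
  w95 <- window_genome(genome_index("c", 95000), cfg)
  expect_equal(nrow(w95), 9)
  expect_equal(w95$end[9], 95000)
  expect_equal(w95$start[9], 80000)
  # windows match the independent enumeration on assorted lengths
  for (len in c(7000, 10000, 20001, 33333, 100000, 123457)) {
    idx <- genome_index("c", len)
    expect_equal(as.data.frame(window_genome(idx, cfg)[c("contig", "start", "end")]),
                 oracle_windows(idx), ignore_attr = TRUE)
  }
})

test_that("window pairing projects alignments and applies the support floor", {
  cfg <- synteny_config()
  idx <- genome_index("c1", 100000)
  rw <- window_genome(idx, cfg); qw <- window_genome(idx, cfg)
  # identity alignment: every ref window pairs its coordinate-identical
  # query window, forward, with support equal to the window length
  p <- pair_windows(aln_row("c1", 0, 100000, "c1", 0, 100000), rw, qw, cfg)
  self <- p[p$ref_start == p$qry_start, ]
  expect_equal(nrow(self), nrow(rw))
  expect_true(all(self$support_bp == self$ref_end - self$ref_start))
  expect_true(all(p$orientation == "forward"))
  # a 20 kb alignment to a distant location pairs only query windows
  # overlapping its target interval
  p2 <- pair_windows(aln_row("c1", 0, 20000, "c1", 50000, 70000), rw, qw, cfg)
  expect_true(all(p2$ref_start %in% c(0, 10000)))
  expect_true(all(p2$qry_start >= 40000 & p2$qry_start <= 60000))
  # an alignment below min_support_bp inside one window pair emits nothing
  p3 <- pair_windows(aln_row("c1", 1000, 2500, "c1", 1000, 2500), rw, qw, cfg)
  expect_equal(nrow(p3), 0)
  expect_error(
    pair_windows(aln_row("cX", 0, 1000, "c1", 0, 1000), rw, qw, cfg),
    "unknown contig")
})

test_that("identity pairs merge into one full-span forward block per contig", {
  tr <- sample_rearrangement_truth(1, c(a = 80000, b = 120000, c = 55000))
  blocks <- call_synteny_blocks(truth_to_alignments(tr), tr$ref_index, tr$qry_index)
  expect_equal(nrow(blocks), 3)
  expect_equal(blocks$ref_start, rep(0, 3))
  expect_equal(blocks$ref_end[order(blocks$ref_contig)], c(80000, 120000, 55000))
  expect_true(all(blocks$orientation == "forward"))
  expect_true(all(blocks$qry_start == 0 & blocks$qry_end == blocks$ref_end))
})

test_that("a planted inversion yields three blocks with a reverse middle", {
  tr <- inversion_truth(100000, 20000, 40000)
  blocks <- call_synteny_blocks(truth_to_alignments(tr), tr$ref_index, tr$qry_index)
  expect_equal(nrow(blocks), 3)
  expect_equal(blocks$orientation, c("forward", "reverse", "forward"))
  # reference intervals tile without overlap in order
  expect_true(all(blocks$ref_start[-1] >= blocks$ref_end[-3]))
})

test_that("the two-segment swap yields two crossing forward blocks", {
  tr <- swap_truth(100000, 50000)
  blocks <- call_synteny_blocks(truth_to_alignments(tr), tr$ref_index, tr$qry_index)
  expect_equal(nrow(blocks), 2)
  expect_true(all(blocks$orientation == "forward"))
  # destinations cross: the earlier reference block maps to the later query
  expect_gt(blocks$qry_start[1], blocks$qry_start[2])
})

test_that("counting reports totals and per-contig breakdown", {
  tr <- sample_rearrangement_truth(1, c(a = 80000, b = 120000))
  blocks <- call_synteny_blocks(truth_to_alignments(tr), tr$ref_index, tr$qry_index)
  cnt <- count_blocks(blocks)
  expect_equal(cnt$total, 2)
  expect_equal(sort(cnt$per_contig$ref_contig), c("a", "b"))
  expect_true(all(cnt$per_contig$n_blocks == 1))
  expect_equal(count_blocks(blocks[0, ])$total, 0)
})

test_that("blocks match the brute-force oracle on planted instances", {
  cases <- list(
    inversion_truth(100000, 20000, 40000),
    inversion_truth(100000, 35000, 81000),
    swap_truth(100000, 50000),
    swap_truth(150000, 40000),
    sample_rearrangement_truth(13, c(c1 = 180000), 2, 1, min_segment = 15000),
    sample_rearrangement_truth(17, c(c1 = 90000, c2 = 110000), 1, 1, min_segment = 15000))
  for (tr in cases) {
    aln <- truth_to_alignments(tr)
    got <- blocks_as_df(call_synteny_blocks(aln, tr$ref_index, tr$qry_index))
    want <- oracle_synteny(aln, tr$ref_index, tr$qry_index)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("merge and trim are idempotent on their own output", {
  cases <- list(
    sample_rearrangement_truth(1, c(c1 = 100000)),
    inversion_truth(100000, 20000, 40000),
    swap_truth(100000, 50000),
    sample_rearrangement_truth(23, c(c1 = 200000), 2, 1, min_segment = 15000))
  cfg <- synteny_config()
  for (tr in cases) {
    blocks <- call_synteny_blocks(truth_to_alignments(tr), tr$ref_index,
                                  tr$qry_index, cfg)
    # re-feed each block as a single self-supporting pair
    pairs <- tibble::tibble(
      ref_contig = blocks$ref_contig, ref_start = blocks$ref_start,
      ref_end = blocks$ref_end, qry_contig = blocks$qry_contig,
      qry_start = blocks$qry_start, qry_end = blocks$qry_end,
      orientation = blocks$orientation, support_bp = blocks$support_bp,
      diag = ifelse(blocks$orientation == "forward",
                    blocks$qry_start - blocks$ref_start,
                    blocks$ref_start + blocks$qry_end))
    again <- merge_and_trim(pairs, cfg)
    expect_equal(blocks_as_df(again)[c("ref_contig", "ref_start", "ref_end",
                                       "qry_contig", "orientation")],
                 blocks_as_df(blocks)[c("ref_contig", "ref_start", "ref_end",
                                        "qry_contig", "orientation")])
  }
})

test_that("reference coverage is bounded and non-overlapping after trimming", {
  for (seed in 1:10) {
    tr <- sample_rearrangement_truth(seed, c(c1 = 150000), seed %% 2,
                                     (seed %/% 2) %% 2, min_segment = 15000)
    blocks <- call_synteny_blocks(truth_to_alignments(tr), tr$ref_index, tr$qry_index)
    by_contig <- split(blocks, blocks$ref_contig)
    for (b in by_contig) {
      b <- b[order(b$ref_start), ]
      expect_true(all(b$ref_end > b$ref_start))
      if (nrow(b) > 1) expect_true(all(b$ref_start[-1] >= b$ref_end[-nrow(b)]))
      expect_lte(sum(b$ref_end - b$ref_start),
                 tr$ref_index$length[tr$ref_index$contig == b$ref_contig[1]])
    }
  }
})

test_that("empty inputs yield empty results through the whole caller", {
  idx <- genome_index("c1", 50000)
  blocks <- call_synteny_blocks(truth_to_alignments(
    sample_rearrangement_truth(1, c(c1 = 50000)))[0, ], idx, idx)
  expect_equal(nrow(blocks), 0)
  expect_s3_class(blocks, "synteny_blocks")
})

test_that("configuration bounds are enforced", {
  expect_error(synteny_config(step_size = 0), "step_size")
  expect_error(synteny_config(step_size = 30000), "step_size")
  expect_error(synteny_config(min_support_bp = 30000), "min_support_bp")
})
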