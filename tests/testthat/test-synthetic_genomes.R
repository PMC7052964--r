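test_that("a no-event pair is the identity and generators are deterministic", {
  p1 <- make_rearranged_pair(1, c(c1 = 100000))
  expect_identical(as.character(p1$qry$c1), as.character(p1$ref$c1))
  sm <- p1$truth$segment_map
  expect_equal(nrow(sm), 1)
  expect_equal(unlist(sm[1, c("qry_start", "qry_end", "ref_start", "ref_end")],
                      use.names = FALSE), c(0, 100000, 0, 100000))
  expect_equal(sm$orientation, "forward")
  p2 <- make_rearranged_pair(1, c(c1 = 100000))
  expect_identical(as.character(p1$ref), as.character(p2$ref))
  expect_identical(as.character(p1$qry), as.character(p2$qry))
})

test_that("segment maps are consistent with the emitted sequences", {
  for (seed in c(2, 7, 19)) {
    pair <- make_rearranged_pair(seed, c(c1 = 150000, c2 = 120000), 2, 1, min_segment = 15000)
    sm <- pair$truth$segment_map
    # both genomes tiled without overlap
    for (side in list(c("qry_contig", "qry_start", "qry_end", "qry_index"),
                      c("ref_contig", "ref_start", "ref_end", "ref_index"))) {
      segs <- sm[order(sm[[side[1]]], sm[[side[2]]]), ]
      for (ct in unique(segs[[side[1]]])) {
        s <- segs[segs[[side[1]]] == ct, ]
        expect_equal(s[[side[2]]][1], 0)
        expect_equal(s[[side[3]]][nrow(s)],
                     pair$truth[[side[4]]]$length[pair$truth[[side[4]]]$contig == ct])
        if (nrow(s) > 1) expect_equal(s[[side[2]]][-1], s[[side[3]]][-nrow(s)])
      }
    }
    # substring equality segment by segment (revcomp for inversions)
    for (i in seq_len(nrow(sm))) {
      expected <- Biostrings::subseq(pair$ref[[sm$ref_contig[i]]],
                                     sm$ref_start[i] + 1, sm$ref_end[i])
      if (sm$orientation[i] == "reverse") {
        expected <- Biostrings::reverseComplement(expected)
      }
      got <- Biostrings::subseq(pair$qry[[sm$qry_contig[i]]],
                                sm$qry_start[i] + 1, sm$qry_end[i])
      expect_identical(as.character(got), as.character(expected))
    }
  }
})

test_that("event sampling respects min_segment and errors when unplaceable", {
  tr <- sample_rearrangement_truth(5, c(c1 = 300000), 1, 1, min_segment = 25000)
  seg_len <- tr$segment_map$qry_end - tr$segment_map$qry_start
  expect_true(all(seg_len >= 25000))
  expect_error(sample_rearrangement_truth(1, c(c1 = 30000), 1, 0),
               "min_segment")
})

test_that("truth converts to one perfect alignment record per segment", {
  tr <- sample_rearrangement_truth(3, c(c1 = 100000), 0, 1, min_segment = 15000)
  aln <- truth_to_alignments(tr)
  expect_equal(nrow(aln), nrow(tr$segment_map))
  expect_true(all(aln$identity_pct == 100))
  expect_equal(aln$aligned_length, aln$ref_end - aln$ref_start)
  expect_equal(sum(aln$orientation == "reverse"), 1)
  # identity truth: a single full-span forward record
  tr0 <- sample_rearrangement_truth(1, c(c1 = 100000))
  aln0 <- truth_to_alignments(tr0)
  expect_equal(nrow(aln0), 1)
  expect_equal(unlist(aln0[1, c("ref_start", "ref_end", "qry_start", "qry_end")],
                      use.names = FALSE), c(0, 100000, 0, 100000))
})

test_that("SNP counts follow the planned Poisson densities", {
  idx <- genome_index("h1", 100000)
  plan <- tibble::tibble(contig = "h1", start = 0, end = 100000, density = 3.2)
  # Monte-Carlo moment check against Poisson(320); 300 seeds keeps the test
  # fast, with the 3-sigma band widened accordingly (s.e. of the mean =
  # sqrt(320)/sqrt(300))
  counts <- vapply(1:300, function(s) nrow(simulate_snp_track(s, idx, plan)),
                   numeric(1))
  expect_lt(abs(mean(counts) - 320), 3 * sqrt(320) / sqrt(300))
  # zero density -> no SNPs; and the VCF written for it has no variant rows
  f <- withr::local_tempfile()
  empty <- simulate_snp_track(1, idx, tibble::tibble(
    contig = "h1", start = 0, end = 100000, density = 0), vcf_path = f)
  expect_equal(nrow(empty), 0)
  expect_false(any(!grepl("^#", readLines(f))))
})

test_that("SNPs never fall outside their planned region", {
  idx <- genome_index("h1", 60000)
  plan <- tibble::tibble(contig = "h1", start = c(0, 20000, 40000),
                         end = c(20000, 40000, 60000), density = c(5, 0, 5))
  for (seed in 1:20) {
    snps <- simulate_snp_track(seed, idx, plan)
    expect_false(any(snps$pos >= 20000 & snps$pos < 40000))
    expect_true(all(snps$pos >= 0 & snps$pos < 60000))
  }
  expect_error(simulate_snp_track(1, idx, tibble::tibble(
    contig = "h1", start = 0, end = 30000, density = 1)), "tile")
})

test_that("blast tables plant HGT proteins with reversed E-value regimes", {
  bt0 <- make_blast_table(4, 50, 0)
  expect_false(any(bt0$truth$is_hgt))
  bt <- make_blast_table(4, 200, 0.15)
  expect_equal(sum(bt$truth$is_hgt), 30)
  joined <- dplyr::inner_join(
    best_hits(assign_lineage(bt$hits, bt$lineage_map)), bt$truth,
    by = "query_id")
  planted <- joined[joined$is_hgt, ]
  # planted proteins: alien best hit at least 10^20-fold stronger
  expect_true(all(planted$best_e_alien < 1e-20 * planted$best_e_self))
  bt2 <- make_blast_table(4, 200, 0.15)
  expect_identical(bt$hits, bt2$hits)
})

test_that("count tables honour planted cells and the background", {
  tab <- make_count_table(1, 5, 10)
  expect_true(all(as.matrix(tab[, -1]) == 1L))
  tab2 <- make_count_table(1, 5, 10,
                           planted = tibble::tibble(orthogroup = 7, species = 1, count = 4))
  expect_equal(unlist(tab2[7, -1], use.names = FALSE), c(4L, 1L, 1L, 1L, 1L))
  tab3 <- make_count_table(2, 3, 50, background = function(n) rpois(n, 1.2))
  expect_identical(tab3, make_count_table(2, 3, 50, background = function(n) rpois(n, 1.2)))
})

test_that("codon alignments hit their target identity", {
  msa <- make_codon_msa(8, 4, 3000, 0.77)
  expect_true(all(Biostrings::width(msa) == 9000))
  ani <- unclass(ani_matrix(msa))
  off <- ani[upper.tri(ani)]
  expect_true(all(off >= 75 & off <= 79))
  ident <- ani_matrix(make_codon_msa(8, 3, 500, 1))
  expect_true(all(unclass(ident) == 100))
  expect_identical(as.character(make_codon_msa(8, 4, 100, 0.8)),
                   as.character(make_codon_msa(8, 4, 100, 0.8)))
  # gap columns are tolerated by the identity computation
  gappy <- make_codon_msa(8, 3, 2000, 0.9, gap_rate = 0.05)
  offg <- unclass(ani_matrix(gappy))
  expect_true(all(offg[upper.tri(offg)] >= 88 & offg[upper.tri(offg)] <= 92))
})

test_that("generators do not disturb the caller's RNG state", {
  set.seed(42)
  before <- .Random.seed
  invisible(make_count_table(1, 3, 3))
  invisible(simulate_snp_track(1, genome_index("h1", 50000),
                               tibble::tibble(contig = "h1", start = 0,
                                              end = 50000, density = 1)))
  expect_identical(.Random.seed, before)
})
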