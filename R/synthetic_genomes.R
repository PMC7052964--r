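# Seeded generators for every input the pipeline consumes. Each generator is
# a pure function of (seed, parameters): randomness flows through one local
# RNG scope (withr::with_seed-style, implemented locally to avoid a runtime
# dependency) and never touches the caller's .Random.seed.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    rlang::abort("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Segment maps are tibbles with one row per query segment, in query order:
# qry_contig, qry_start, qry_end, ref_contig, ref_start, ref_end, orientation.
# Ref intervals tile the reference genome; qry intervals tile the query.
identity_segment_map <- function(index) {
  tibble::tibble(
    qry_contig = index$contig, qry_start = 0, qry_end = index$length,
    ref_contig = index$contig, ref_start = 0, ref_end = index$length,
    orientation = "forward"
  )
}

# Split the segment list of one query contig at query coordinate `at`.
split_segments_at <- function(segs, at) {
  hit <- which(segs$qry_start < at & at < segs$qry_end)
  if (length(hit) == 0) return(segs)
  s <- segs[hit, ]
  off <- at - s$qry_start
  left <- s; right <- s
  left$qry_end <- at
  right$qry_start <- at
  if (s$orientation == "forward") {
    left$ref_end <- s$ref_start + off
    right$ref_start <- s$ref_start + off
  } else {
    left$ref_start <- s$ref_end - off
    right$ref_end <- s$ref_end - off
  }
  dplyr::bind_rows(segs[seq_len(hit - 1), ], left, right,
                   segs[-seq_len(hit), ])
}

recompute_qry_coords <- function(segs) {
  len <- segs$qry_end - segs$qry_start
  segs$qry_end <- cumsum(len)
  segs$qry_start <- segs$qry_end - len
  segs
}

flip_segments <- function(segs) {
  segs <- segs[rev(seq_len(nrow(segs))), ]
  segs$orientation <- ifelse(segs$orientation == "forward", "reverse", "forward")
  segs
}

qry_breakpoints <- function(segs) unique(c(segs$qry_start, segs$qry_end))

#' Sample a rearrangement truth (translocations and inversions)
#'
#' Builds the exact segment map relating a reference genome to a query
#' genome carrying sampled translocations and inversions. Events are drawn
#' sequentially, so extending `n_translocations`/`n_inversions` with the
#' same seed reuses the earlier events and appends new ones — this is what
#' makes block-count monotonicity testable across nested event sets.
#' Breakpoints are rejected (with bounded retries) when they fall closer
#' than `min_segment` to an existing breakpoint, keeping every truth segment
#' resolvable at window scale: the default of 30000 bp (window + step at the
#' default 20 kb / 10 kb windowing) guarantees each segment contains at
#' least one complete sliding window whatever its phase on the step grid.
#'
#' @param seed Integer RNG seed.
#' @param contig_lengths Named or unnamed vector of reference contig
#'   lengths (bp); unnamed contigs are called `ctg1`, `ctg2`, ...
#' @param n_translocations,n_inversions Event counts (>= 0).
#' @param min_segment Minimum distance between breakpoints (default 30000).
#' @return A list of class `rearrangement_truth`: `ref_index`, `qry_index`,
#'   `events` (tibble), `segment_map` (tibble in query order).
#' @export
sample_rearrangement_truth <- function(seed, contig_lengths,
                                       n_translocations = 0, n_inversions = 0,
                                       min_segment = 30000) {
  kinds <- c(rep("translocation", n_translocations), rep("inversion", n_inversions))
  if (length(kinds) > 0 && any(contig_lengths < 4 * min_segment)) {
    rlang::abort("each contig must be at least 4 * min_segment long")
  }
  nm <- names(contig_lengths)
  if (is.null(nm)) nm <- paste0("ctg", seq_along(contig_lengths))
  ref_index <- genome_index(nm, contig_lengths)

  with_local_seed(seed, {
    # per-query-contig segment lists
    segs <- lapply(seq_len(nrow(ref_index)), function(i) identity_segment_map(ref_index[i, ]))
    names(segs) <- ref_index$contig
    events <- list()

    pick_cut <- function(existing, lo, hi) {
      # one uniform cut in [lo, hi] at distance >= min_segment from `existing`
      for (try in 1:200) {
        x <- floor(stats::runif(1, lo, hi + 1))
        if (all(abs(x - existing) >= min_segment)) return(x)
      }
      NULL
    }

    for (kind in kinds) {
      placed <- FALSE
      for (try in 1:200) {
        ci <- sample.int(length(segs), 1,
                         prob = vapply(segs, function(s) max(s$qry_end), numeric(1)))
        s <- segs[[ci]]
        L <- max(s$qry_end)
        bps <- qry_breakpoints(s)
        a <- pick_cut(bps, min_segment, L - 2 * min_segment)
        if (is.null(a)) next
        b <- pick_cut(c(bps, a), a + min_segment, L - min_segment)
        if (is.null(b) || b <= a) next
        if (kind == "inversion") {
          s2 <- split_segments_at(split_segments_at(s, a), b)
          mid <- s2$qry_start >= a & s2$qry_end <= b
          s2 <- dplyr::bind_rows(s2[s2$qry_end <= a, ], flip_segments(s2[mid, ]),
                                 s2[s2$qry_start >= b, ])
          segs[[ci]] <- recompute_qry_coords(s2)
          events[[length(events) + 1]] <- tibble::tibble(
            kind = "inversion", contig = names(segs)[ci], start = a, end = b,
            dest_contig = names(segs)[ci], dest = a)
          placed <- TRUE
        } else {
          # translocation: excise [a, b) and reinsert at a breakpoint drawn on
          # the remaining sequence of a (possibly different) contig
          s2 <- split_segments_at(split_segments_at(s, a), b)
          moved <- s2[s2$qry_start >= a & s2$qry_end <= b, ]
          stay <- recompute_qry_coords(s2[s2$qry_end <= a | s2$qry_start >= b, ])
          segs[[ci]] <- stay
          di <- sample.int(length(segs), 1)
          d_segs <- segs[[di]]
          dL <- max(d_segs$qry_end)
          d <- pick_cut(qry_breakpoints(d_segs), min_segment, dL - min_segment)
          if (is.null(d)) { segs[[ci]] <- s; next }
          d2 <- split_segments_at(d_segs, d)
          segs[[di]] <- recompute_qry_coords(dplyr::bind_rows(
            d2[d2$qry_end <= d, ], moved, d2[d2$qry_start >= d, ]))
          events[[length(events) + 1]] <- tibble::tibble(
            kind = "translocation", contig = names(segs)[ci], start = a, end = b,
            dest_contig = names(segs)[di], dest = d)
          placed <- TRUE
        }
        if (placed) break
      }
      if (!placed) {
        rlang::abort("could not place a rearrangement without violating min_segment")
      }
    }

    segment_map <- dplyr::bind_rows(lapply(seq_along(segs), function(i) {
      s <- segs[[i]]
      s$qry_contig <- names(segs)[i]
      s
    }))
    qry_index <- genome_index(
      names(segs), vapply(segs, function(s) max(s$qry_end), numeric(1)))
    structure(list(
      ref_index = ref_index, qry_index = qry_index,
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(kind = character(), contig = character(), start = numeric(),
                       end = numeric(), dest_contig = character(), dest = numeric()),
      segment_map = segment_map
    ), class = "rearrangement_truth")
  })
}

#' Generate a rearranged genome pair with exact alignment truth
#'
#' Draws a random (i.i.d. uniform ACGT) reference genome, applies the
#' sampled translocations/inversions, and returns both sequences together
#' with the exact segment map. Substring equality holds segment by segment
#' (reverse-complement for inverted segments), which the test-suite checks.
#'
#' @inheritParams sample_rearrangement_truth
#' @param ref_path,qry_path Optional FASTA output paths.
#' @return A list: `ref` and `qry` ([Biostrings::DNAStringSet]) and `truth`
#'   (a `rearrangement_truth`).
#' @export
make_rearranged_pair <- function(seed, contig_lengths, n_translocations = 0,
                                 n_inversions = 0, min_segment = 30000,
                                 ref_path = NULL, qry_path = NULL) {
  truth <- sample_rearrangement_truth(seed, contig_lengths, n_translocations,
                                      n_inversions, min_segment)
  seqs <- with_local_seed(seed + 1L, {
    Biostrings::DNAStringSet(vapply(truth$ref_index$length, random_dna, character(1)))
  })
  names(seqs) <- truth$ref_index$contig
  qry <- vapply(truth$qry_index$contig, function(qc) {
    sm <- truth$segment_map[truth$segment_map$qry_contig == qc, ]
    pieces <- vapply(seq_len(nrow(sm)), function(i) {
      piece <- Biostrings::subseq(seqs[[sm$ref_contig[i]]],
                                  sm$ref_start[i] + 1, sm$ref_end[i])
      if (sm$orientation[i] == "reverse") piece <- Biostrings::reverseComplement(piece)
      as.character(piece)
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  qry <- Biostrings::DNAStringSet(qry)
  names(qry) <- truth$qry_index$contig
  if (!is.null(ref_path)) Biostrings::writeXStringSet(seqs, ref_path)
  if (!is.null(qry_path)) Biostrings::writeXStringSet(qry, qry_path)
  list(ref = seqs, qry = qry, truth = truth)
}

#' Convert a rearrangement truth to exact alignment records
#'
#' Stands in for the whole-genome aligner during testing: one perfect
#' (100% identity) alignment record per truth segment.
#'
#' @param truth A `rearrangement_truth`.
#' @return A normalized alignment tibble (see [read_coords()]).
#' @export
truth_to_alignments <- function(truth) {
  sm <- truth$segment_map
  aln <- new_alignment_tbl(
    ref_contig = sm$ref_contig, ref_start = sm$ref_start, ref_end = sm$ref_end,
    qry_contig = sm$qry_contig, qry_start = sm$qry_start, qry_end = sm$qry_end,
    orientation = sm$orientation,
    aligned_length = sm$ref_end - sm$ref_start, identity_pct = 100
  )
  dplyr::arrange(aln, .data$ref_contig, .data$ref_start)
}

#' Simulate a SNP-density mosaic
#'
#' Emulates a genome whose contigs carry regions of contrasting
#' heterozygous-SNP density — the signature used to call loss of
#' heterozygosity. Each region of the plan receives
#' `Poisson(density * length / 1000)` SNPs placed uniformly without
#' replacement.
#'
#' @param seed Integer RNG seed.
#' @param index Genome index tibble.
#' @param region_plan Tibble with columns `contig`, `start`, `end`,
#'   `density` (SNPs/kb); regions must tile each contig of the index.
#' @param vcf_path Optional path: write the simulated SNPs as VCF 4.2.
#' @return A tibble of SNPs (`contig`, `pos` 0-based, `ref`, `alt`) sorted
#'   by contig and position, with the plan attached as attribute `plan`.
#' @export
simulate_snp_track <- function(seed, index, region_plan, vcf_path = NULL) {
  if (any(region_plan$density < 0)) rlang::abort("densities must be >= 0")
  assert_index_contigs(region_plan$contig, index, "region plan")
  for (ct in unique(region_plan$contig)) {
    p <- dplyr::arrange(region_plan[region_plan$contig == ct, ], .data$start)
    len <- index$length[index$contig == ct]
    if (p$start[1] != 0 || p$end[nrow(p)] != len ||
        (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)]))) {
      rlang::abort(paste0("region plan does not tile contig ", ct))
    }
  }
  snps <- with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(region_plan)), function(i) {
      r <- region_plan[i, ]
      size <- r$end - r$start
      n <- stats::rpois(1, r$density * size / 1000)
      if (n > size) {
        rlang::abort("drawn SNP count exceeds region size; density too high")
      }
      if (n == 0) {
        return(tibble::tibble(contig = character(), pos = numeric()))
      }
      pos <- sort(sample.int(size, n)) - 1 + r$start
      tibble::tibble(contig = r$contig, pos = pos)
    })
    out <- dplyr::bind_rows(rows)
    bases <- c("A", "C", "G", "T")
    out$ref <- sample(bases, nrow(out), replace = TRUE)
    out$alt <- vapply(out$ref, function(b) sample(setdiff(bases, b), 1), character(1))
    out
  })
  snps <- dplyr::arrange(snps, match(.data$contig, index$contig), .data$pos)
  attr(snps, "plan") <- region_plan
  if (!is.null(vcf_path)) write_snp_vcf(snps, index, vcf_path)
  snps
}

#' Simulate a lineage-partitioned BLAST best-hit table
#'
#' Generates per-protein hits in two lineages (`self`, e.g. other fungi,
#' and `alien`, e.g. bacteria) with a planted fraction of horizontal-transfer
#' proteins whose best alien hit is far stronger than their best self hit.
#' E-values are drawn log10-uniformly from the supplied ranges: a native
#' protein draws its self hits from `e_strong` and alien hits from `e_weak`;
#' a planted HGT protein swaps the two. With the default ranges the two
#' regimes are separated by well over 10^20 odds, so the Alien Index screen
#' must recover the planted set exactly.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of query proteins.
#' @param hgt_fraction Fraction of proteins planted as HGT (rounded to a
#'   count).
#' @param e_strong,e_weak Length-2 numeric log10 E-value ranges for the
#'   matching and non-matching lineage (defaults `c(-150, -50)` and
#'   `c(-5, 0)`).
#' @param hits_per_lineage Hits drawn per protein per lineage (default 3).
#' @param alien_missing_rate Probability a native protein has no alien hits
#'   at all (default 0.2) — exercising the missing-E-value substitution.
#' @return A list: `hits` (tibble `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `lineage`), `lineage_map` (subject_id, lineage) and `truth`
#'   (tibble `query_id`, `is_hgt`).
#' @export
make_blast_table <- function(seed, n_proteins, hgt_fraction,
                             e_strong = c(-150, -50), e_weak = c(-5, 0),
                             hits_per_lineage = 3, alien_missing_rate = 0.2) {
  if (hgt_fraction < 0 || hgt_fraction > 1) rlang::abort("hgt_fraction must be in [0, 1]")
  with_local_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_proteins))
    n_hgt <- round(hgt_fraction * n_proteins)
    is_hgt <- rep(FALSE, n_proteins)
    if (n_hgt > 0) is_hgt[sample.int(n_proteins, n_hgt)] <- TRUE
    draw_e <- function(n, range) 10^stats::runif(n, range[1], range[2])
    rows <- lapply(seq_len(n_proteins), function(i) {
      self_range <- if (is_hgt[i]) e_weak else e_strong
      alien_range <- if (is_hgt[i]) e_strong else e_weak
      n_alien <- if (!is_hgt[i] && stats::runif(1) < alien_missing_rate) 0 else hits_per_lineage
      tibble::tibble(
        query_id = ids[i],
        subject_id = c(sprintf("fungal_sp%02d", sample.int(20, hits_per_lineage)),
                       sprintf("bacterial_sp%02d", sample.int(20, n_alien))),
        evalue = c(draw_e(hits_per_lineage, self_range), draw_e(n_alien, alien_range)),
        lineage = c(rep("self", hits_per_lineage), rep("alien", n_alien))
      )
    })
    hits <- dplyr::bind_rows(rows)
    hits$bitscore <- round(60 - 2 * log10(hits$evalue + 1e-300), 1)
    lineage_map <- tibble::tibble(
      subject_id = c(sprintf("fungal_sp%02d", 1:20), sprintf("bacterial_sp%02d", 1:20)),
      lineage = rep(c("self", "alien"), each = 20)
    )
    list(hits = hits, lineage_map = lineage_map,
         truth = tibble::tibble(query_id = ids, is_hgt = is_hgt))
  })
}

#' Simulate an orthogroup gene-count table with planted expansions
#'
#' Background counts default to 1 copy per species per orthogroup (the
#' single-copy norm for most yeast gene families); planted cells override
#' the background exactly.
#'
#' @param seed Integer RNG seed.
#' @param n_species,n_groups Table dimensions.
#' @param planted Tibble with columns `orthogroup`, `species`, `count`
#'   (integer row/column ids or names), or `NULL`.
#' @param background A function `n -> integer counts` (default: all 1).
#' @return A gene-count tibble (`orthogroup` + one column per species), as
#'   from [read_genecounts()].
#' @export
make_count_table <- function(seed, n_species, n_groups, planted = NULL,
                             background = function(n) rep(1L, n)) {
  with_local_seed(seed, {
    sp <- sprintf("sp%d", seq_len(n_species))
    og <- sprintf("OG%04d", seq_len(n_groups))
    m <- matrix(as.integer(background(n_species * n_groups)),
                nrow = n_groups, ncol = n_species)
    if (any(m < 0)) rlang::abort("background counts must be >= 0")
    if (!is.null(planted) && nrow(planted) > 0) {
      gi <- if (is.numeric(planted$orthogroup)) planted$orthogroup else match(planted$orthogroup, og)
      si <- if (is.numeric(planted$species)) planted$species else match(planted$species, sp)
      if (anyNA(gi) || anyNA(si)) rlang::abort("planted cell outside the table")
      m[cbind(gi, si)] <- as.integer(planted$count)
    }
    out <- tibble::as_tibble(as.data.frame(m))
    names(out) <- sp
    dplyr::bind_cols(tibble::tibble(orthogroup = og), out)
  })
}

#' Simulate a codon multiple sequence alignment at a target identity
#'
#' Each sequence is derived independently from a hidden common ancestor
#' with a per-site substitution probability q solved so that the expected
#' pairwise identity of any two emitted sequences equals `target_identity`
#' (match either when both sites are unmutated or when both mutated to the
#' same of the three alternatives): (1-q)^2 + q^2/3 = t, the star-topology
#' analogue of uniform divergence. Valid for t > 0.25 (the random-sequence
#' floor). Optional gap columns are injected per sequence at `gap_rate`.
#'
#' @param seed Integer RNG seed.
#' @param n_seqs Number of sequences (>= 2).
#' @param n_codons Alignment length in codons.
#' @param target_identity Target pairwise identity in (0.25, 1].
#' @param gap_rate Per-site gap probability per sequence (default 0).
#' @param path Optional aligned-FASTA output path.
#' @return A [Biostrings::DNAStringSet] of aligned sequences
#'   (`seq1..seqN`), length `3 * n_codons`.
#' @export
make_codon_msa <- function(seed, n_seqs, n_codons, target_identity,
                           gap_rate = 0, path = NULL) {
  t <- target_identity
  if (t <= 0.25 || t > 1) rlang::abort("target_identity must be in (0.25, 1]")
  if (n_seqs < 2) rlang::abort("need at least 2 sequences")
  # (1-q)^2 + q^2/3 = t  =>  (4/3) q^2 - 2 q + (1 - t) = 0, smaller root
  q <- (3 - sqrt(9 - 12 * (1 - t))) / 4
  n_sites <- 3 * n_codons
  bases <- c("A", "C", "G", "T")
  msa <- with_local_seed(seed, {
    anc <- sample(bases, n_sites, replace = TRUE)
    seqs <- vapply(seq_len(n_seqs), function(i) {
      s <- anc
      mut <- stats::runif(n_sites) < q
      if (any(mut)) {
        shift <- sample.int(3, sum(mut), replace = TRUE)
        s[mut] <- bases[((match(s[mut], bases) - 1 + shift) %% 4) + 1]
      }
      if (gap_rate > 0) s[stats::runif(n_sites) < gap_rate] <- "-"
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq%d", seq_len(n_seqs))
    seqs
  })
  out <- Biostrings::DNAStringSet(msa)
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}
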