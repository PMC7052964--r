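# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except files the tests write themselves.

# Construct a rearrangement truth directly from a segment map (query order).
make_truth <- function(segment_map, ref_index, qry_index = ref_index) {
  structure(list(ref_index = ref_index, qry_index = qry_index,
                 events = tibble::tibble(), segment_map = segment_map),
            class = "rearrangement_truth")
}

# Truth for a single inversion of [inv_start, inv_end) in a one-contig genome.
inversion_truth <- function(len, inv_start, inv_end, contig = "c1") {
  make_truth(
    tibble::tibble(
      qry_contig = contig,
      qry_start = c(0, inv_start, inv_end),
      qry_end = c(inv_start, inv_end, len),
      ref_contig = contig,
      ref_start = c(0, inv_start, inv_end),
      ref_end = c(inv_start, inv_end, len),
      orientation = c("forward", "reverse", "forward")),
    genome_index(contig, len))
}

# Truth for the two-segment swap: query = [cut, len) + [0, cut).
swap_truth <- function(len, cut, contig = "c1") {
  make_truth(
    tibble::tibble(
      qry_contig = contig,
      qry_start = c(0, len - cut),
      qry_end = c(len - cut, len),
      ref_contig = contig,
      ref_start = c(cut, 0),
      ref_end = c(len, cut),
      orientation = "forward"),
    genome_index(contig, len))
}

# One-alignment tibble in the package's normalized convention.
aln_row <- function(ref_contig, ref_start, ref_end, qry_contig, qry_start,
                    qry_end, orientation = "forward",
                    aligned_length = ref_end - ref_start, identity_pct = 100) {
  tibble::tibble(ref_contig = ref_contig, ref_start = ref_start,
                 ref_end = ref_end, qry_contig = qry_contig,
                 qry_start = qry_start, qry_end = qry_end,
                 orientation = orientation, aligned_length = aligned_length,
                 identity_pct = identity_pct)
}

# Write a minimal VCF 4.2 with explicit per-record REF/ALT/FILTER, for
# exercising the reader's SNP-only and FILTER rules.
write_test_vcf <- function(path, records,
                           contigs = tibble::tibble(contig = "chr1", length = 100000)) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", contigs$contig,
                      as.integer(contigs$length)),
              "##FILTER=<ID=LowQual,Description=\"Low quality\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t50\t%s\t.", records$contig, records$pos1,
                  records$ref, records$alt, records$filter)
  writeLines(c(header, rows), path)
  path
}

blocks_as_df <- function(blocks) {
  df <- as.data.frame(blocks)[c("ref_contig", "ref_start", "ref_end",
                                "qry_contig", "qry_start", "qry_end",
                                "orientation", "n_windows", "support_bp")]
  df <- df[order(df$ref_contig, df$ref_start), ]
  rownames(df) <- NULL
  df
}
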