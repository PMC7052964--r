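# Average nucleotide identity from codon alignments, plus the genome summary
# statistics (genic fraction, multi-copy orthogroup fraction) reported per
# assembly in comparative yeast studies.

#' Average nucleotide identity matrix from an aligned FASTA
#'
#' For each sequence pair, identity is `100 * matches / comparable_sites`,
#' where comparable sites are alignment columns in which both sequences
#' carry an unambiguous base (A/C/G/T; gaps and N are excluded pairwise, not
#' alignment-wide). A pair with no comparable site is reported `NA`.
#'
#' @param msa A [Biostrings::DNAStringSet] of equal-length aligned
#'   sequences, or a path to an aligned FASTA.
#' @return A symmetric matrix of class `ani_matrix` (percent identity,
#'   diagonal 100) with sequence names as dimnames.
#' @examples
#' m <- ani_matrix(Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGTACGA")))
#' m["a", "b"]  # 87.5
#' @export
ani_matrix <- function(msa) {
  if (is.character(msa)) msa <- Biostrings::readDNAStringSet(msa)
  if (length(msa) < 2) rlang::abort("ANI needs at least 2 sequences")
  if (length(unique(Biostrings::width(msa))) != 1) {
    rlang::abort("aligned sequences must all have equal length")
  }
  chars <- toupper(as.matrix(msa))  # seqs x columns
  valid <- chars %in% c("A", "C", "G", "T")
  dim(valid) <- dim(chars)
  n <- length(msa)
  vals <- diag(100, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      vals[i, j] <- vals[j, i] <-
        if (nc == 0) NA_real_ else 100 * sum(chars[i, comp] == chars[j, comp]) / nc
    }
  }
  dimnames(vals) <- list(names(msa), names(msa))
  structure(vals, class = c("ani_matrix", "matrix", "array"))
}

#' @export
print.ani_matrix <- function(x, digits = 1, ...) {
  cat("Average nucleotide identity (%), ", nrow(x), " taxa\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Tidy an ANI matrix into a long pair table
#'
#' @param x An `ani_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `taxon_a`, `taxon_b`,
#'   `ani_pct`.
#' @exportS3Method generics::tidy
tidy.ani_matrix <- function(x, ...) {
  taxa <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]],
                 ani_pct = unclass(x)[idx])
}

#' @exportS3Method generics::glance
glance.ani_matrix <- function(x, ...) {
  off <- unclass(x)[upper.tri(x)]
  tibble::tibble(n_taxa = nrow(x), min_ani = min(off, na.rm = TRUE),
                 mean_ani = mean(off, na.rm = TRUE),
                 max_ani = max(off, na.rm = TRUE))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ani_matrix <- function(object, digits = 1, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              responseName = "ani_pct"))
  names(df)[1:2] <- c("taxon_a", "taxon_b")
  ggplot2::ggplot(df, ggplot2::aes(.data$taxon_a, .data$taxon_b,
                                   fill = .data$ani_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$ani_pct, digits)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = "ANI (%)") +
    ggplot2::labs(x = NULL, y = NULL, title = "Average nucleotide identity") +
    ggplot2::theme_minimal()
}

#' Write an ANI matrix as TSV (one decimal place)
#'
#' @param x An `ani_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ani <- function(x, path) {
  df <- as.data.frame(round(unclass(x), 1))
  df <- cbind(taxon = rownames(x), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Genic fraction of a genome
#'
#' Length of the union of gene intervals as a percentage of total assembly
#' length. Overlapping and book-ended gene intervals are unioned before
#' summing, so the statistic is invariant to how genes are split into
#' adjacent sub-intervals.
#'
#' @param gene_intervals Tibble with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param index Genome index tibble.
#' @return A one-row tibble: `total_bp`, `genic_bp`, `genic_pct`.
#' @export
genic_fraction <- function(gene_intervals, index) {
  total_bp <- sum(index$length)
  if (nrow(gene_intervals) == 0) {
    return(tibble::tibble(total_bp = total_bp, genic_bp = 0, genic_pct = 0))
  }
  assert_index_contigs(gene_intervals$contig, index, "gene interval")
  len <- index$length[match(gene_intervals$contig, index$contig)]
  if (any(gene_intervals$start < 0) || any(gene_intervals$end > len) ||
      any(gene_intervals$end <= gene_intervals$start)) {
    rlang::abort("gene interval out of contig bounds or empty")
  }
  genic_bp <- sum(vapply(split(gene_intervals, gene_intervals$contig), function(g) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))))
  }, numeric(1)))
  tibble::tibble(total_bp = total_bp, genic_bp = genic_bp,
                 genic_pct = 100 * genic_bp / total_bp)
}

#' Fraction of a species' orthogroups with multiple copies
#'
#' Percent of orthogroups with >= 2 genes for the species, among
#' orthogroups in which the species has >= 1 gene — the per-assembly
#' duplication statistic of gene-family summaries.
#'
#' @param counts Gene-count tibble ([read_genecounts()] /
#'   [make_count_table()]).
#' @param species Species column name.
#' @return Percent (scalar).
#' @export
multicopy_fraction <- function(counts, species) {
  if (!species %in% names(counts)[-1]) {
    rlang::abort(paste0("unknown species: ", species))
  }
  v <- counts[[species]]
  present <- v >= 1
  if (!any(present)) rlang::abort("species has no orthogroup with >= 1 gene")
  100 * sum(v >= 2) / sum(present)
}
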