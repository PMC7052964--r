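# Loss-of-heterozygosity screen. In a heterozygous diploid, windowed
# heterozygous-SNP density is high genome-wide; LOH tracts collapse it by
# orders of magnitude. Contigs (or windows) are classified homozygous when
# their density falls below a threshold sitting between the two regimes.

#' Windowed SNP density
#'
#' Counts SNPs in sliding windows (same windowing rules as the synteny
#' caller) and reports density in SNPs per kb. Membership is half-open:
#' a SNP at a window's start position belongs to that window.
#'
#' @param snps SNP tibble (`contig`, `pos` 0-based) from [read_vcf_snps()]
#'   or [simulate_snp_track()].
#' @param index Genome index tibble.
#' @param window,step Window and step sizes in bp (defaults 20000/10000).
#' @return A tibble: `contig`, `start`, `end`, `n_snps`, `density`
#'   (SNPs/kb).
#' @export
snp_density <- function(snps, index, window = 20000, step = 10000) {
  assert_index_contigs(snps$contig, index, "SNP")
  len <- index$length[match(snps$contig, index$contig)]
  if (any(snps$pos >= len) || any(snps$pos < 0)) {
    rlang::abort("SNP position outside contig bounds")
  }
  wins <- window_genome(index, synteny_config(window_size = window, step_size = step))
  wins$n_snps <- vapply(seq_len(nrow(wins)), function(i) {
    p <- snps$pos[snps$contig == wins$contig[i]]
    sum(p >= wins$start[i] & p < wins$end[i])
  }, numeric(1))
  wins$density <- 1000 * wins$n_snps / (wins$end - wins$start)
  dplyr::select(wins, "contig", "start", "end", "n_snps", "density")
}

#' Classify contigs (or windows) as homozygous or heterozygous
#'
#' Compares mean SNP density per contig (default) or per window with a
#' threshold: below threshold is called `homozygous` (an LOH region),
#' otherwise `heterozygous`. The genome summary reports, per state class,
#' the aggregate density (total SNPs in the class / total bp in the class,
#' *not* the mean of per-contig densities) and the bp fraction of the
#' genome called homozygous.
#'
#' @inheritParams snp_density
#' @param threshold Classification threshold in SNPs/kb (default 0.5 —
#'   roughly the geometric midpoint of the ~100-fold separated density
#'   regimes seen in heterozygous yeast assemblies).
#' @param level `"contig"` (default) or `"window"`.
#' @param window,step Used only for `level = "window"`.
#' @return A list of class `loh_result`: `calls` (one row per unit:
#'   `contig`, `start`, `end`, `n_snps`, `mean_density`, `state`),
#'   `summary` (per-state aggregate density and bp), `homozygous_fraction`
#'   (bp fraction in the homozygous class) and `threshold`.
#' @export
classify_loh <- function(snps, index, threshold = 0.5,
                         level = c("contig", "window"),
                         window = 20000, step = 10000) {
  level <- match.arg(level)
  if (threshold <= 0) rlang::abort("threshold must be > 0")
  if (level == "contig") {
    assert_index_contigs(snps$contig, index, "SNP")
    calls <- index |>
      dplyr::mutate(start = 0, end = .data$length) |>
      dplyr::rowwise() |>
      dplyr::mutate(n_snps = sum(snps$contig == .data$contig)) |>
      dplyr::ungroup() |>
      dplyr::mutate(mean_density = 1000 * .data$n_snps / .data$length) |>
      dplyr::select("contig", "start", "end", "n_snps", "mean_density")
  } else {
    calls <- snp_density(snps, index, window, step) |>
      dplyr::rename(mean_density = "density")
  }
  calls$state <- ifelse(calls$mean_density < threshold, "homozygous", "heterozygous")
  summary <- calls |>
    dplyr::group_by(state = .data$state) |>
    dplyr::summarise(n_units = dplyr::n(),
                     total_bp = sum(.data$end - .data$start),
                     total_snps = sum(.data$n_snps), .groups = "drop") |>
    dplyr::mutate(aggregate_density = 1000 * .data$total_snps / .data$total_bp)
  hom_bp <- sum(summary$total_bp[summary$state == "homozygous"])
  structure(list(calls = calls, summary = summary,
                 homozygous_fraction = hom_bp / sum(summary$total_bp),
                 threshold = threshold),
            class = "loh_result")
}

#' @export
print.loh_result <- function(x, ...) {
  cat("LOH classification (threshold ", x$threshold, " SNPs/kb)\n", sep = "")
  print(x$summary)
  cat(sprintf("homozygous fraction of genome: %.1f%%\n",
              100 * x$homozygous_fraction))
  invisible(x)
}

#' Tidy an LOH result (one row per classified unit)
#'
#' @param x An `loh_result`.
#' @param ... Unused.
#' @return The `calls` tibble.
#' @exportS3Method generics::tidy
tidy.loh_result <- function(x, ...) x$calls

#' One-row summary of an LOH result
#'
#' @param x An `loh_result`.
#' @param ... Unused.
#' @return A one-row tibble with per-class aggregate densities and the
#'   homozygous bp fraction.
#' @exportS3Method generics::glance
glance.loh_result <- function(x, ...) {
  dens <- function(state) {
    v <- x$summary$aggregate_density[x$summary$state == state]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    n_units = sum(x$summary$n_units),
    homozygous_bp = sum(x$summary$total_bp[x$summary$state == "homozygous"]),
    homozygous_fraction = x$homozygous_fraction,
    density_homozygous = dens("homozygous"),
    density_heterozygous = dens("heterozygous"),
    threshold = x$threshold)
}

#' @exportS3Method ggplot2::autoplot
autoplot.loh_result <- function(object, ...) {
  df <- object$calls
  ggplot2::ggplot(df, ggplot2::aes(.data$contig, .data$mean_density,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "SNP density (SNPs/kb, log scale)",
                  title = "Loss-of-heterozygosity classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
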