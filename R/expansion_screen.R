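# Gene-family expansion screen: per orthogroup, the ratio of a focal
# species' gene count to the mean count across an averaging set; families
# with ratio >= 2 are flagged and fed to hypergeometric GO enrichment under
# Bonferroni family-wise error control.

#' Gene-family expansion ratios
#'
#' For every (orthogroup, focal species) cell, computes the ratio of the
#' gene count to the mean gene count over the averaging set (default: all
#' species in the table; pass a subset to average over, e.g., only the
#' focal clade). Orthogroups whose averaging-set mean is zero are skipped.
#'
#' @param counts Gene-count tibble (`orthogroup` + species columns).
#' @param focal_species Character vector of species columns to score
#'   (default: all).
#' @param threshold Flagging threshold on the ratio (default 2).
#' @param averaging_species Species whose counts form the mean (default:
#'   all species in the table).
#' @return A tibble: `orthogroup`, `species`, `count`, `mean_count`,
#'   `ratio`, `flagged` (`ratio >= threshold`).
#' @examples
#' tab <- make_count_table(1, 5, 3,
#'   planted = tibble::tibble(orthogroup = 1, species = 1, count = 4))
#' expansion_ratios(tab)  # OG0001/sp1: ratio 4/1.6 = 2.5, flagged
#' @export
expansion_ratios <- function(counts, focal_species = NULL, threshold = 2,
                             averaging_species = NULL) {
  species <- names(counts)[-1]
  if (is.null(focal_species)) focal_species <- species
  if (is.null(averaging_species)) averaging_species <- species
  if (threshold <= 0) rlang::abort("threshold must be > 0")
  bad <- setdiff(c(focal_species, averaging_species), species)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown species: ", paste(bad, collapse = ", ")))
  }
  if (length(averaging_species) == 0) rlang::abort("averaging set is empty")
  mean_count <- rowMeans(as.matrix(counts[averaging_species]))
  long <- counts |>
    dplyr::mutate(mean_count = mean_count) |>
    dplyr::filter(.data$mean_count > 0) |>
    tidyr::pivot_longer(dplyr::all_of(focal_species), names_to = "species",
                        values_to = "count") |>
    dplyr::transmute(.data$orthogroup, .data$species, .data$count,
                     .data$mean_count, ratio = .data$count / .data$mean_count,
                     flagged = .data$ratio >= threshold)
  dplyr::arrange(long, dplyr::desc(.data$ratio), .data$orthogroup, .data$species)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items from a
#' population of `N` containing `K` successes. Computed as a sum of
#' log-binomial terms (numerically stable; exact to more than 10
#' significant digits for N up to 1e4). Vectorized over its arguments.
#'
#' @param k Observed success count(s).
#' @param n Sample size(s).
#' @param K Population success count(s).
#' @param N Population size(s).
#' @return Upper-tail probability, same length as the longest argument.
#' @examples
#' hypergeom_tail(3, 3, 4, 10)  # C(4,3)/C(10,3) = 4/120
#' @export
hypergeom_tail <- function(k, n, K, N) {
  args <- vctrs_recycle(k, n, K, N)
  k <- args[[1]]; n <- args[[2]]; K <- args[[3]]; N <- args[[4]]
  if (any(k < 0) || any(n > N) || any(K > N) || any(k > n) || any(k > K)) {
    rlang::abort("need 0 <= k <= min(n, K) and n, K <= N")
  }
  vapply(seq_along(k), function(i) {
    hi <- min(n[i], K[i])
    x <- seq(k[i], hi)
    if (length(x) == 0) return(0)
    sum(exp(lchoose(K[i], x) + lchoose(N[i] - K[i], n[i] - x) - lchoose(N[i], n[i])))
  }, numeric(1))
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, function(a) rep_len(a, len))
}

#' Hypergeometric GO-term enrichment with Bonferroni correction
#'
#' Tests every term annotated to at least one study gene for
#' over-representation in the study set relative to the population, using
#' the upper-tail hypergeometric probability. The Bonferroni multiplier is
#' the number of tested terms; `significant` means the corrected p-value is
#' at or below `alpha`.
#'
#' @param study_genes Character vector (must be a subset of the
#'   population).
#' @param population_genes Character vector (the sampling frame).
#' @param gene2go Tibble with columns `gene`, `term` ([read_gene2go()]).
#' @param alpha Significance level on the corrected p-value (default 0.05).
#' @return A tibble sorted by `p_bonferroni` then term: `term`,
#'   `study_hits`, `study_size`, `population_hits`, `population_size`,
#'   `p_raw`, `p_bonferroni`, `significant`.
#' @export
go_enrichment <- function(study_genes, population_genes, gene2go,
                          alpha = 0.05) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  missing <- setdiff(study_genes, population_genes)
  if (length(missing) > 0) {
    rlang::abort(paste0("study gene(s) absent from population: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  anno <- dplyr::distinct(gene2go[gene2go$gene %in% population_genes, ])
  n <- length(study_genes)
  N <- length(population_genes)
  per_term <- anno |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(population_hits = dplyr::n(),
                     study_hits = sum(.data$gene %in% study_genes),
                     .groups = "drop") |>
    dplyr::filter(.data$study_hits >= 1)
  if (nrow(per_term) == 0) {
    return(tibble::tibble(term = character(), study_hits = integer(),
                          study_size = integer(), population_hits = integer(),
                          population_size = integer(), p_raw = numeric(),
                          p_bonferroni = numeric(), significant = logical()))
  }
  m <- nrow(per_term)
  per_term |>
    dplyr::mutate(
      study_size = n, population_size = N,
      p_raw = hypergeom_tail(.data$study_hits, n, .data$population_hits, N),
      p_bonferroni = pmin(1, .data$p_raw * m),
      significant = .data$p_bonferroni <= alpha) |>
    dplyr::select("term", "study_hits", "study_size", "population_hits",
                  "population_size", "p_raw", "p_bonferroni", "significant") |>
    dplyr::arrange(.data$p_bonferroni, .data$term)
}

#' Run the expansion screen end to end
#'
#' Flags expanded orthogroups ([expansion_ratios()]), maps the flagged
#' orthogroups' genes to a study set via an orthogroup-to-gene table, and
#' tests GO enrichment against the full gene population.
#'
#' @inheritParams expansion_ratios
#' @param orthogroup_genes Tibble with columns `orthogroup`, `gene` for the
#'   focal species.
#' @param gene2go Tibble (`gene`, `term`).
#' @param alpha Significance level (default 0.05).
#' @return A list: `ratios`, `study_genes`, `enrichment`.
#' @export
expansion_screen <- function(counts, orthogroup_genes, gene2go,
                             focal_species = NULL, threshold = 2,
                             averaging_species = NULL, alpha = 0.05) {
  ratios <- expansion_ratios(counts, focal_species, threshold, averaging_species)
  flagged_groups <- unique(ratios$orthogroup[ratios$flagged])
  study <- unique(orthogroup_genes$gene[orthogroup_genes$orthogroup %in% flagged_groups])
  population <- unique(orthogroup_genes$gene)
  enrichment <- go_enrichment(study, population, gene2go, alpha)
  list(ratios = ratios, study_genes = study, enrichment = enrichment)
}
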