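# Alien Index screen for horizontal gene transfer. For each protein the
# best (smallest) BLAST E-value in the recipient's own lineage (e.g. Fungi)
# is compared with the best E-value in the candidate donor lineage (e.g.
# Bacteria) on a natural-log scale:
#   AI = ln(best_e_self + c) - ln(best_e_alien + c),  c = 1e-200,
# with a missing lineage substituted by E = 1. Strongly positive AI means
# the alien hit is overwhelmingly better; proteins with AI > 20 are HGT
# candidates.

#' Assign lineages to BLAST hits
#'
#' @param hits BLAST hit tibble ([read_blast_hits()]), columns `query_id`,
#'   `subject_id`, `evalue`.
#' @param lineage_map Tibble (`subject_id`, `lineage` in
#'   \{`self`, `alien`\}), or `NULL` when `hits` already carries a
#'   `lineage` column.
#' @param on_missing `"error"` (default) or `"drop"` for subjects absent
#'   from the map — silent drops bias the Alien Index, so dropping must be
#'   requested explicitly.
#' @return `hits` with a `lineage` column.
#' @export
assign_lineage <- function(hits, lineage_map = NULL,
                           on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.null(lineage_map)) {
    if (!"lineage" %in% names(hits)) {
      rlang::abort("no lineage_map given and hits carry no lineage column")
    }
    return(hits)
  }
  lin <- lineage_map$lineage[match(hits$subject_id, lineage_map$subject_id)]
  if (anyNA(lin)) {
    if (on_missing == "error") {
      miss <- unique(hits$subject_id[is.na(lin)])
      rlang::abort(paste0("subject(s) absent from the lineage map: ",
                          paste(utils::head(miss, 5), collapse = ", ")))
    }
    hits <- hits[!is.na(lin), ]
    lin <- lin[!is.na(lin)]
  }
  hits$lineage <- lin
  hits
}

#' Best E-value per protein and lineage
#'
#' Minimum E-value among self-lineage rows and among alien-lineage rows,
#' after removing rows whose subject identifier contains any `exclude_taxa`
#' string (used to mask the recipient genus itself, which would otherwise
#' produce trivial self hits). Proteins left with no rows are omitted.
#'
#' @param hits Hit tibble with a `lineage` column ([assign_lineage()]).
#' @param exclude_taxa Character vector of substrings matched (fixed, case
#'   insensitive) against subject ids.
#' @return A tibble: `query_id`, `best_e_self`, `best_e_alien` (`NA` when a
#'   lineage has no hit).
#' @export
best_hits <- function(hits, exclude_taxa = character()) {
  if (any(hits$evalue < 0)) rlang::abort("E-values must be >= 0")
  keep <- rep(TRUE, nrow(hits))
  for (taxon in exclude_taxa) {
    keep <- keep & !stringr::str_detect(
      stringr::str_to_lower(hits$subject_id),
      stringr::fixed(stringr::str_to_lower(taxon)))
  }
  hits <- hits[keep, ]
  hits |>
    dplyr::group_by(query_id = .data$query_id) |>
    dplyr::summarise(
      best_e_self = suppressWarnings(min(.data$evalue[.data$lineage == "self"])),
      best_e_alien = suppressWarnings(min(.data$evalue[.data$lineage == "alien"])),
      .groups = "drop") |>
    dplyr::mutate(best_e_self = ifelse(is.finite(.data$best_e_self),
                                       .data$best_e_self, NA_real_),
                  best_e_alien = ifelse(is.finite(.data$best_e_alien),
                                        .data$best_e_alien, NA_real_))
}

#' Alien Index from a pair of best E-values
#'
#' `AI = ln(e_self + c) - ln(e_alien + c)`; a missing E-value (no hit in
#' that lineage) is substituted by `missing_e` before the pseudo-count is
#' added. The pseudo-count bounds the score: a perfect alien hit against a
#' missing self hit scores `ln(1 + c) - ln(c)` \eqn{\approx} 460.5.
#' Vectorized.
#'
#' @param best_e_self,best_e_alien Best E-values (`NA` = missing).
#' @param c Pseudo-count added to both E-values (default 1e-200).
#' @param missing_e Substitute for a missing E-value (default 1).
#' @return Numeric AI score(s).
#' @examples
#' alien_index(1e-5, 1e-50)  # 45 * log(10) = 103.62
#' @export
alien_index <- function(best_e_self, best_e_alien, c = 1e-200, missing_e = 1) {
  if (any(best_e_self < 0, na.rm = TRUE) || any(best_e_alien < 0, na.rm = TRUE)) {
    rlang::abort("E-values must be >= 0")
  }
  es <- ifelse(is.na(best_e_self), missing_e, best_e_self)
  ea <- ifelse(is.na(best_e_alien), missing_e, best_e_alien)
  log(es + c) - log(ea + c)
}

#' Alien Index HGT screen
#'
#' Computes per-protein Alien Index scores from a lineage-partitioned hit
#' table and flags candidates with `ai > threshold` (strictly greater).
#'
#' @inheritParams assign_lineage
#' @inheritParams best_hits
#' @inheritParams alien_index
#' @param threshold Candidate threshold (default 20).
#' @return A tibble of class `alien_index_result`, sorted by `ai`
#'   descending: `query_id`, `best_e_self`, `best_e_alien`, `ai`,
#'   `candidate`.
#' @export
alien_index_screen <- function(hits, lineage_map = NULL,
                               exclude_taxa = character(), threshold = 20,
                               c = 1e-200, missing_e = 1,
                               on_missing = c("error", "drop")) {
  hits <- assign_lineage(hits, lineage_map, on_missing)
  best <- best_hits(hits, exclude_taxa)
  out <- best |>
    dplyr::mutate(ai = alien_index(.data$best_e_self, .data$best_e_alien,
                                   c = c, missing_e = missing_e),
                  candidate = .data$ai > threshold) |>
    dplyr::arrange(dplyr::desc(.data$ai), .data$query_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("alien_index_result", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.alien_index_result <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- tibble::as_tibble(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$ai,
                                   colour = .data$candidate)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = "protein rank", y = "Alien Index",
                  title = "Alien Index screen",
                  colour = paste0("AI > ", thr)) +
    ggplot2::theme_minimal()
}
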