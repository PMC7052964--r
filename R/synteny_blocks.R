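# Window-based synteny-block caller. The reference and query genomes are cut
# into overlapping sliding windows (defaults: 20 kb windows, 10 kb steps),
# windows are paired through the whole-genome alignments, concordant
# overlapping/adjacent pairs are merged into blocks, and reference-overlapping
# discordant blocks are trimmed. Block counts are the rearrangement statistic:
# a perfectly collinear genome pair yields one block per contig, and every
# breakpoint adds blocks.

#' Synteny caller configuration
#'
#' @param window_size Window length in bp (default 20000).
#' @param step_size Step between window starts in bp (default 10000); must
#'   satisfy `0 < step_size <= window_size`.
#' @param min_support_bp Minimum aligned bp linking a window pair for it to
#'   be kept (default 2000, i.e. 10% of a full window).
#' @param max_gap_windows Maximum distance, in window steps, between the
#'   window starts of two pairs for them to count as overlapping/adjacent
#'   when merging (default 1, i.e. consecutive sliding windows).
#' @return A list of class `synteny_config`.
#' @export
synteny_config <- function(window_size = 20000, step_size = 10000,
                           min_support_bp = 2000, max_gap_windows = 1) {
  if (step_size <= 0 || step_size > window_size) {
    rlang::abort("need 0 < step_size <= window_size")
  }
  if (min_support_bp > window_size) rlang::abort("min_support_bp must be <= window_size")
  if (max_gap_windows < 0) rlang::abort("max_gap_windows must be >= 0")
  structure(list(window_size = window_size, step_size = step_size,
                 min_support_bp = min_support_bp,
                 max_gap_windows = max_gap_windows),
            class = "synteny_config")
}

#' Cut a genome into sliding windows
#'
#' Windows start at 0, step, 2*step, ... while the start lies inside the
#' contig; each window ends at `min(start + window_size, contig length)`.
#' A final truncated window shorter than the step is merged into its
#' predecessor (a contig shorter than the step keeps its single window), so
#' no window shorter than `step_size` exists except on sub-step contigs.
#'
#' @param index Genome index tibble (`contig`, `length`).
#' @param cfg A [synteny_config()].
#' @return A tibble: `contig`, `start`, `end`, `win` (1-based rank within
#'   its contig).
#' @export
window_genome <- function(index, cfg = synteny_config()) {
  w <- cfg$window_size; s <- cfg$step_size
  per_contig <- lapply(seq_len(nrow(index)), function(i) {
    len <- index$length[i]
    starts <- seq(0, len - 1, by = s)
    ends <- pmin(starts + w, len)
    k <- length(starts)
    if (k > 1 && (ends[k] - starts[k]) < s) {
      ends[k - 1] <- max(ends[k - 1], ends[k])
      starts <- starts[-k]; ends <- ends[-k]
      k <- k - 1
    }
    tibble::tibble(contig = index$contig[i], start = starts, end = ends,
                   win = seq_len(k))
  })
  dplyr::bind_rows(per_contig)
}

# Project reference coordinate x through an affine map of the alignment's
# ref interval onto its query interval (mirrored for reverse orientation).
# Rounding keeps coordinates integral; with exact truth alignments the map
# is the identity (scale 1) and rounding is a no-op.
project_to_query <- function(os, oe, rs, re, qs, qe, orientation) {
  scale <- (qe - qs) / (re - rs)
  if (orientation == "forward") {
    c(qs + round((os - rs) * scale), qs + round((oe - rs) * scale))
  } else {
    c(qe - round((oe - rs) * scale), qe - round((os - rs) * scale))
  }
}

#' Pair reference and query windows through alignments
#'
#' For every alignment, its overlap with each intersecting reference window
#' is projected linearly onto the query interval (mirrored for reverse
#' orientation) and attributed to the query windows that projection
#' intersects. Support for a (ref window, qry window, orientation) triple is
#' the summed projected overlap in query bp, capped at the shorter window;
#' triples below `min_support_bp` are dropped.
#'
#' @param alignments Normalized alignment tibble ([read_coords()] /
#'   [truth_to_alignments()]).
#' @param ref_windows,qry_windows Window tibbles from [window_genome()].
#' @param cfg A [synteny_config()].
#' @return A tibble of window pairs: ref/qry window coordinates,
#'   `orientation`, `support_bp`, and `diag` — the alignment diagonal of
#'   the dominant contribution (forward: `qry = ref + diag`; reverse:
#'   `qry = diag - ref`), used by [merge_and_trim()] to keep chains
#'   collinear.
#' @export
pair_windows <- function(alignments, ref_windows, qry_windows,
                         cfg = synteny_config()) {
  unknown_ref <- setdiff(alignments$ref_contig, ref_windows$contig)
  unknown_qry <- setdiff(alignments$qry_contig, qry_windows$contig)
  if (length(unknown_ref) || length(unknown_qry)) {
    rlang::abort(paste0("alignment references unknown contig(s): ",
                        paste(c(unknown_ref, unknown_qry), collapse = ", ")))
  }
  empty <- tibble::tibble(
    ref_contig = character(), ref_start = numeric(), ref_end = numeric(),
    qry_contig = character(), qry_start = numeric(), qry_end = numeric(),
    orientation = character(), support_bp = numeric(), diag = numeric())
  if (nrow(alignments) == 0) return(empty)

  rw_by_contig <- split(ref_windows, ref_windows$contig)
  qw_by_contig <- split(qry_windows, qry_windows$contig)

  acc <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    rw <- rw_by_contig[[a$ref_contig]]
    qw <- qw_by_contig[[a$qry_contig]]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(rw$start + 1, rw$end),
      IRanges::IRanges(a$ref_start + 1, a$ref_end))
    ri <- S4Vectors::queryHits(ov)
    if (length(ri) == 0) next
    rows <- lapply(ri, function(j) {
      os <- max(rw$start[j], a$ref_start)
      oe <- min(rw$end[j], a$ref_end)
      pq <- project_to_query(os, oe, a$ref_start, a$ref_end,
                             a$qry_start, a$qry_end, a$orientation)
      if (pq[2] <= pq[1]) return(NULL)
      qov <- IRanges::findOverlaps(
        IRanges::IRanges(qw$start + 1, qw$end),
        IRanges::IRanges(pq[1] + 1, pq[2]))
      qi <- S4Vectors::queryHits(qov)
      if (length(qi) == 0) return(NULL)
      # diag identifies the alignment diagonal this support sits on:
      # forward q = x + diag, reverse q = diag - x (x a ref coordinate)
      tibble::tibble(
        ref_contig = a$ref_contig, ref_start = rw$start[j], ref_end = rw$end[j],
        qry_contig = a$qry_contig, qry_start = qw$start[qi], qry_end = qw$end[qi],
        orientation = a$orientation,
        support_bp = pmin(pq[2], qw$end[qi]) - pmax(pq[1], qw$start[qi]),
        diag = if (a$orientation == "forward") pq[1] - os else os + pq[2])
    })
    acc[[i]] <- dplyr::bind_rows(rows)
  }
  pairs <- dplyr::bind_rows(acc)
  if (nrow(pairs) == 0) return(empty)
  # one row per (ref window, qry window, orientation): summed support, diag
  # of the dominant contribution (ties: smaller diag, for determinism)
  pairs <- pairs |>
    dplyr::group_by(.data$ref_contig, .data$ref_start, .data$ref_end,
                    .data$qry_contig, .data$qry_start, .data$qry_end,
                    .data$orientation) |>
    dplyr::arrange(dplyr::desc(.data$support_bp), .data$diag, .by_group = TRUE) |>
    dplyr::summarise(diag = .data$diag[1],
                     support_bp = sum(.data$support_bp), .groups = "drop") |>
    dplyr::mutate(support_bp = pmin(.data$support_bp,
                                    .data$ref_end - .data$ref_start,
                                    .data$qry_end - .data$qry_start)) |>
    dplyr::filter(.data$support_bp >= cfg$min_support_bp) |>
    dplyr::arrange(.data$ref_contig, .data$ref_start, .data$qry_contig,
                   .data$qry_start, .data$orientation)
  pairs
}

# Two window pairs are concordant when they lie on the same contig pair with
# the same orientation, their ref window starts lie within max_gap_windows
# steps (consecutive sliding windows overlap physically, so this is the
# overlap-or-adjacent rule expressed on the step grid), and they sit on the
# same alignment diagonal (|diag difference| strictly below one step).
# Matching window-grid coordinates alone is not enough: windows straddling a
# rearrangement breakpoint carry support from two different diagonals, and
# grid-level links through them would transitively fuse the blocks on either
# side. The diagonal coherence requirement is what makes chains collinear
# and splits them at breakpoints; query-window proximity follows from it.
pairs_concordant <- function(p, i, j, cfg) {
  if (p$ref_contig[i] != p$ref_contig[j] || p$qry_contig[i] != p$qry_contig[j] ||
      p$orientation[i] != p$orientation[j]) return(FALSE)
  allow <- cfg$max_gap_windows * cfg$step_size
  if (abs(p$ref_start[j] - p$ref_start[i]) > allow) return(FALSE)
  abs(p$diag[j] - p$diag[i]) < cfg$step_size
}

#' Merge concordant window pairs and trim discordant overlaps
#'
#' Maximal sets of mutually linked concordant pairs (transitive closure of
#' the same-diagonal, adjacent-window relation) are merged into one block
#' spanning the union of their reference and query intervals. Where the reference intervals of two remaining
#' (discordant) blocks overlap, the block with smaller support is trimmed
#' to remove the overlap (ties: the later block in reference order is
#' trimmed); a block whose trim would split it keeps its longer remaining
#' piece (tie: the left piece), and blocks trimmed to zero length are
#' dropped. Reference intervals of the result never overlap; query-side
#' overlaps are permitted (the output is reference-anchored).
#'
#' @param pairs Window-pair tibble from [pair_windows()].
#' @param cfg A [synteny_config()].
#' @return A tibble of class `synteny_blocks`, in reference order:
#'   ref/qry intervals, `orientation`, `n_windows`, `support_bp`.
#' @export
merge_and_trim <- function(pairs, cfg = synteny_config()) {
  empty <- tibble::tibble(
    ref_contig = character(), ref_start = numeric(), ref_end = numeric(),
    qry_contig = character(), qry_start = numeric(), qry_end = numeric(),
    orientation = character(), n_windows = numeric(), support_bp = numeric())
  if (nrow(pairs) == 0) {
    class(empty) <- c("synteny_blocks", class(empty))
    return(empty)
  }
  # union-find over pairs, restricted to (ref contig, qry contig, orientation)
  # strata and pruned by reference distance
  parent <- seq_len(nrow(pairs))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[rx] <<- ry }
  strata <- split(seq_len(nrow(pairs)),
                  paste(pairs$ref_contig, pairs$qry_contig, pairs$orientation))
  allow <- cfg$max_gap_windows * cfg$step_size
  for (idx in strata) {
    idx <- idx[order(pairs$ref_start[idx])]
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1)) {
        i <- idx[ii]; j <- idx[jj]
        if (pairs$ref_start[i] - pairs$ref_start[j] > allow) next
        if (pairs_concordant(pairs, i, j, cfg)) unite(i, j)
      }
    }
  }
  comp <- vapply(seq_len(nrow(pairs)), find, integer(1))
  blocks <- pairs |>
    dplyr::mutate(.comp = comp) |>
    dplyr::group_by(.data$.comp) |>
    dplyr::summarise(
      ref_contig = .data$ref_contig[1],
      rs = min(.data$ref_start), re = max(.data$ref_end),
      qry_contig = .data$qry_contig[1],
      qry_start = min(.data$qry_start), qry_end = max(.data$qry_end),
      orientation = .data$orientation[1],
      n_windows = as.numeric(dplyr::n_distinct(.data$ref_start)),
      support_bp = sum(.data$support_bp), .groups = "drop") |>
    dplyr::rename(ref_start = "rs", ref_end = "re") |>
    dplyr::select(-".comp")
  blocks <- trim_discordant(blocks)
  blocks <- dplyr::arrange(blocks, .data$ref_contig, .data$ref_start)
  class(blocks) <- c("synteny_blocks", class(blocks))
  blocks
}

# Resolve reference-interval overlaps between blocks. Iterates until no
# overlap remains; each resolution trims (or drops) the weaker block.
trim_discordant <- function(blocks) {
  repeat {
    blocks <- blocks[blocks$ref_end > blocks$ref_start, ]
    ord <- order(blocks$ref_contig, blocks$ref_start, blocks$ref_end)
    blocks <- blocks[ord, ]
    n <- nrow(blocks)
    if (n < 2) return(blocks)
    conflict <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (blocks$ref_contig[j] != blocks$ref_contig[i]) break
        if (blocks$ref_start[j] >= blocks$ref_end[i]) break
        conflict <- c(i, j); break
      }
      if (!is.null(conflict)) break
    }
    if (is.null(conflict)) return(blocks)
    i <- conflict[1]; j <- conflict[2]
    # loser: smaller support; tie -> the later block in reference order (j)
    loser <- if (blocks$support_bp[i] < blocks$support_bp[j]) i else j
    winner <- if (loser == i) j else i
    ws <- blocks$ref_start[winner]; we <- blocks$ref_end[winner]
    ls <- blocks$ref_start[loser]; le <- blocks$ref_end[loser]
    left <- c(ls, min(le, ws))   # piece of loser before the winner
    right <- c(max(ls, we), le)  # piece after
    left_len <- max(0, left[2] - left[1])
    right_len <- max(0, right[2] - right[1])
    if (left_len == 0 && right_len == 0) {
      blocks <- blocks[-loser, ]
    } else if (left_len >= right_len) {
      blocks$ref_start[loser] <- left[1]; blocks$ref_end[loser] <- left[2]
    } else {
      blocks$ref_start[loser] <- right[1]; blocks$ref_end[loser] <- right[2]
    }
  }
}

#' Call synteny blocks from alignments
#'
#' One-call wrapper: windows both genomes, pairs the windows through the
#' alignments, merges and trims.
#'
#' @param alignments Normalized alignment tibble.
#' @param ref_index,qry_index Genome index tibbles.
#' @param cfg A [synteny_config()].
#' @return A `synteny_blocks` tibble (see [merge_and_trim()]).
#' @export
call_synteny_blocks <- function(alignments, ref_index, qry_index,
                                cfg = synteny_config()) {
  pairs <- pair_windows(alignments, window_genome(ref_index, cfg),
                        window_genome(qry_index, cfg), cfg)
  merge_and_trim(pairs, cfg)
}

#' Count synteny blocks
#'
#' @param blocks A `synteny_blocks` tibble.
#' @return A list: `total` (integer) and `per_contig` (tibble of reference
#'   contig, block count, covered bp).
#' @export
count_blocks <- function(blocks) {
  per_contig <- blocks |>
    dplyr::group_by(ref_contig = .data$ref_contig) |>
    dplyr::summarise(n_blocks = dplyr::n(),
                     covered_bp = sum(.data$ref_end - .data$ref_start),
                     .groups = "drop")
  list(total = nrow(blocks), per_contig = per_contig)
}

#' @exportS3Method ggplot2::autoplot
autoplot.synteny_blocks <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_start / 1e3, xend = .data$ref_end / 1e3,
      y = .data$qry_contig, yend = .data$qry_contig,
      colour = .data$orientation), linewidth = 3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$ref_contig)) +
    ggplot2::labs(x = "reference position (kb)", y = "query contig",
                  colour = "orientation",
                  title = "Synteny blocks (reference-anchored)") +
    ggplot2::theme_minimal()
}
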