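# Independent brute-force oracles. These re-state the declared algorithm
# rules in naive base-R loops and exhaustive fixed-point searches, sharing no
# code with the package implementation; the synteny caller and the
# hypergeometric tail are required to agree with them exactly.

oracle_windows <- function(index, w = 20000, s = 10000) {
  out <- list()
  for (i in seq_len(nrow(index))) {
    len <- index$length[i]
    starts <- c(); ends <- c()
    start <- 0
    while (start < len) {
      starts <- c(starts, start)
      ends <- c(ends, min(start + w, len))
      start <- start + s
    }
    k <- length(starts)
    if (k > 1 && ends[k] - starts[k] < s) {
      ends[k - 1] <- max(ends[k - 1], ends[k])
      starts <- starts[-k]; ends <- ends[-k]
    }
    out[[i]] <- data.frame(contig = index$contig[i], start = starts,
                           end = ends, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# All (ref window, qry window, orientation) triples with summed projected
# support and the diagonal of their dominant contribution.
oracle_pairs <- function(aln, rw, qw, w = 20000, s = 10000, min_support = 2000) {
  contrib <- list()
  for (ai in seq_len(nrow(aln))) {
    a <- aln[ai, ]
    for (ri in seq_len(nrow(rw))) {
      if (rw$contig[ri] != a$ref_contig) next
      os <- max(rw$start[ri], a$ref_start)
      oe <- min(rw$end[ri], a$ref_end)
      if (oe <= os) next
      scale <- (a$qry_end - a$qry_start) / (a$ref_end - a$ref_start)
      if (a$orientation == "forward") {
        ps <- a$qry_start + round((os - a$ref_start) * scale)
        pe <- a$qry_start + round((oe - a$ref_start) * scale)
        dg <- ps - os
      } else {
        ps <- a$qry_end - round((oe - a$ref_start) * scale)
        pe <- a$qry_end - round((os - a$ref_start) * scale)
        dg <- os + pe
      }
      if (pe <= ps) next
      for (qi in seq_len(nrow(qw))) {
        if (qw$contig[qi] != a$qry_contig) next
        sup <- min(pe, qw$end[qi]) - max(ps, qw$start[qi])
        if (sup <= 0) next
        contrib[[length(contrib) + 1]] <- data.frame(
          ref_contig = rw$contig[ri], ref_start = rw$start[ri], ref_end = rw$end[ri],
          qry_contig = qw$contig[qi], qry_start = qw$start[qi], qry_end = qw$end[qi],
          orientation = a$orientation, support_bp = sup, diag = dg,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(contrib) == 0) return(NULL)
  d <- do.call(rbind, contrib)
  key <- paste(d$ref_contig, d$ref_start, d$qry_contig, d$qry_start, d$orientation)
  rows <- lapply(split(d, key), function(g) {
    g <- g[order(-g$support_bp, g$diag), ]
    out <- g[1, ]
    out$support_bp <- min(sum(g$support_bp), out$ref_end - out$ref_start,
                          out$qry_end - out$qry_start)
    out
  })
  d <- do.call(rbind, rows)
  d <- d[d$support_bp >= min_support, , drop = FALSE]
  rownames(d) <- NULL
  d
}

oracle_concordant <- function(p, i, j, s = 10000, max_gap = 1) {
  p$ref_contig[i] == p$ref_contig[j] &&
    p$qry_contig[i] == p$qry_contig[j] &&
    p$orientation[i] == p$orientation[j] &&
    abs(p$ref_start[j] - p$ref_start[i]) <= max_gap * s &&
    abs(p$diag[j] - p$diag[i]) < s
}

# Exhaustive fixed-point merging: repeatedly fuse any two groups containing
# a concordant pair of pairs, until stable.
oracle_merge <- function(pairs, s = 10000, max_gap = 1) {
  groups <- as.list(seq_len(nrow(pairs)))
  repeat {
    fused <- FALSE
    for (gi in seq_along(groups)) {
      if (fused) break
      for (gj in seq_along(groups)) {
        if (gj <= gi) next
        hit <- FALSE
        for (i in groups[[gi]]) {
          for (j in groups[[gj]]) {
            if (oracle_concordant(pairs, i, j, s, max_gap)) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) {
          groups[[gi]] <- c(groups[[gi]], groups[[gj]])
          groups[[gj]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  blocks <- lapply(groups, function(idx) {
    g <- pairs[idx, ]
    data.frame(ref_contig = g$ref_contig[1],
               ref_start = min(g$ref_start), ref_end = max(g$ref_end),
               qry_contig = g$qry_contig[1],
               qry_start = min(g$qry_start), qry_end = max(g$qry_end),
               orientation = g$orientation[1],
               n_windows = length(unique(g$ref_start)),
               support_bp = sum(g$support_bp), stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

# Exhaustive trimming: resolve the first (in reference sort order) pair of
# reference-overlapping blocks, repeat until none overlap.
oracle_trim <- function(blocks) {
  repeat {
    blocks <- blocks[blocks$ref_end > blocks$ref_start, , drop = FALSE]
    blocks <- blocks[order(blocks$ref_contig, blocks$ref_start, blocks$ref_end), ,
                     drop = FALSE]
    rownames(blocks) <- NULL
    n <- nrow(blocks)
    conflict <- NULL
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (blocks$ref_contig[j] != blocks$ref_contig[i]) next
          if (blocks$ref_start[j] < blocks$ref_end[i]) { conflict <- c(i, j); break }
        }
        if (!is.null(conflict)) break
      }
    }
    if (is.null(conflict)) return(blocks)
    i <- conflict[1]; j <- conflict[2]
    loser <- if (blocks$support_bp[i] < blocks$support_bp[j]) i else j
    winner <- setdiff(conflict, loser)
    ls <- blocks$ref_start[loser]; le <- blocks$ref_end[loser]
    ws <- blocks$ref_start[winner]; we <- blocks$ref_end[winner]
    left <- c(ls, min(le, ws)); right <- c(max(ls, we), le)
    llen <- max(0, left[2] - left[1]); rlen <- max(0, right[2] - right[1])
    if (llen == 0 && rlen == 0) {
      blocks <- blocks[-loser, , drop = FALSE]
    } else if (llen >= rlen) {
      blocks$ref_start[loser] <- left[1]; blocks$ref_end[loser] <- left[2]
    } else {
      blocks$ref_start[loser] <- right[1]; blocks$ref_end[loser] <- right[2]
    }
  }
}

oracle_synteny <- function(aln, ref_index, qry_index, w = 20000, s = 10000,
                           min_support = 2000, max_gap = 1) {
  rw <- oracle_windows(ref_index, w, s)
  qw <- oracle_windows(qry_index, w, s)
  pairs <- oracle_pairs(aln, rw, qw, w, s, min_support)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(ref_contig = character(), ref_start = numeric(),
                      ref_end = numeric(), qry_contig = character(),
                      qry_start = numeric(), qry_end = numeric(),
                      orientation = character(), n_windows = numeric(),
                      support_bp = numeric(), stringsAsFactors = FALSE))
  }
  out <- oracle_trim(oracle_merge(pairs, s, max_gap))
  out <- out[order(out$ref_contig, out$ref_start), ]
  out$n_windows <- as.numeric(out$n_windows)
  rownames(out) <- NULL
  out
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from a
# population with K successes and count draws with >= k successes.
oracle_hypergeom_tail <- function(k, n, K, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(idx) sum(pop[idx]) >= k))
}
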