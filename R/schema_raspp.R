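#' SCHEMA disruption energy of chimeras
#'
#' The SCHEMA energy E of a chimera is the weighted count of residue
#' contacts whose residue pair does not co-occur in any single parent: a
#' contact (i, j) is intact when some parent carries the chimera's residues
#' at both columns, otherwise it is broken and contributes its ensemble
#' weight to E. Parental chimeras have E = 0.
#'
#' @param chimeras character vector of block strings.
#' @param parents a [parent_set].
#' @param partition a [block_partition].
#' @param cm a [contact_map] on alignment columns.
#' @return numeric vector of E values, named by chimera.
#' @export
schema_E <- function(chimeras, parents, partition, cm) {
  cmd <- as.data.frame(cm)
  if (!nrow(cmd)) return(stats::setNames(numeric(length(chimeras)), chimeras))
  L <- partition$aligned_length
  if (any(cmd$i < 1L | cmd$j > L)) stop("contact map columns outside alignment")
  labs <- chimera_label_matrix(chimeras, parents, partition)
  seg <- column_segments(partition)
  np <- length(parents$names)
  E <- numeric(nrow(labs))
  for (k in seq_len(nrow(cmd))) {
    i <- cmd$i[k]; j <- cmd$j[k]
    ri <- parents$seq_mat[, i]; rj <- parents$seq_mat[, j]
    # broken[p, q]: is the (parent p at i, parent q at j) pair absent from
    # every single parent?
    parental_pairs <- paste0(ri, rj)
    broken <- matrix(!(outer(ri, rj, paste0) %in% parental_pairs), np, np)
    li <- match(labs[, seg[i] + 1L], parents$names)
    lj <- match(labs[, seg[j] + 1L], parents$names)
    E <- E + cmd$weight[k] * broken[cbind(li, lj)]
  }
  stats::setNames(E, chimeras)
}

#' Mutation level: distance to the closest parent
#'
#' Hamming distance, over aligned columns, between a chimera's sequence and
#' the nearest parent. Zero exactly for parental chimeras.
#'
#' @inheritParams schema_E
#' @return integer vector named by chimera.
#' @export
mutation_level <- function(chimeras, parents, partition) {
  labs <- chimera_label_matrix(chimeras, parents, partition)
  seg <- column_segments(partition)
  np <- length(parents$names)
  n_seg <- partition$n_blocks + 1L
  # D[s, l, p]: columns of segment s differing between parents l and p
  D <- array(0L, dim = c(n_seg, np, np))
  for (s in seq_len(n_seg) - 1L) {
    cols <- which(seg == s)
    for (l in seq_len(np)) for (p in seq_len(np)) {
      D[s + 1L, l, p] <- sum(parents$seq_mat[l, cols] !=
                             parents$seq_mat[p, cols])
    }
  }
  lidx <- matrix(match(labs, parents$names), nrow = nrow(labs))
  m <- vapply(seq_len(np), function(p) {
    tot <- numeric(nrow(labs))
    for (s in seq_len(n_seg)) {
      tot <- tot + D[cbind(s, lidx[, s], p)]
    }
    tot
  }, numeric(nrow(labs)))
  m <- apply(matrix(m, nrow = nrow(labs)), 1L, min)
  stats::setNames(as.integer(m), chimeras)
}

#' Library averages of disruption and mutation level
#'
#' Mean SCHEMA E and mean mutation level over the distinct chimera space of
#' a partition, by full enumeration.
#'
#' @inheritParams schema_E
#' @param ahr_options see [enumerate_space()].
#' @return list with `mean_E`, `mean_m` and `n` (library size).
#' @export
library_averages <- function(parents, partition, cm,
                             ahr_options = parents$names[1L]) {
  space <- enumerate_space(parents, partition, ahr_options)
  if (length(space) > 2e5) {
    stop("library too large for full enumeration (", length(space), ")")
  }
  list(mean_E = mean(schema_E(space, parents, partition, cm)),
       mean_m = mean(mutation_level(space, parents, partition)),
       n = length(space))
}

# Per-contact "savable" disruption: weight times the fraction of uniform
# parent-label pairs that break the contact. Contacts kept within a single
# block never break; the DP maximizes the saved weight inside blocks.
contact_break_fractions <- function(parents, cm) {
  cmd <- as.data.frame(cm)
  np <- length(parents$names)
  frac <- numeric(nrow(cmd))
  for (k in seq_len(nrow(cmd))) {
    ri <- parents$seq_mat[, cmd$i[k]]; rj <- parents$seq_mat[, cmd$j[k]]
    parental_pairs <- paste0(ri, rj)
    frac[k] <- mean(!(outer(ri, rj, paste0) %in% parental_pairs))
  }
  cmd$savable <- cmd$weight * frac
  cmd
}

#' RASPP breakpoint search
#'
#' Selects breakpoint placements that trade library-average disruption
#' \eqn{\langle E \rangle} against library-average mutation level
#' \eqn{\langle m \rangle}. For each (minimum, maximum) block-length
#' setting a dynamic program finds the partition minimizing the mean
#' disruption of a uniformly recombined library; candidates are then scored
#' exactly by enumeration, binned on integer \eqn{\langle m \rangle}, and
#' the per-bin minima reduced to a nondominated frontier.
#'
#' @param parents a [parent_set].
#' @param cm a [contact_map].
#' @param n_blocks number of blocks to produce.
#' @param allowed_columns alignment columns usable as breakpoints (block
#'   starts), e.g. columns compatible with the assembly chemistry; default
#'   every column of the recombined region.
#' @param min_block_len smallest admissible block length (default 4).
#' @param max_block_len largest admissible block length; default
#'   unrestricted.
#' @param ahr_options see [enumerate_space()].
#' @return object of class `raspp_result`: data.frame with columns
#'   `breakpoints` (comma-joined columns), `mean_E`, `mean_m`, plus a
#'   `partitions` attribute holding the [block_partition] objects.
#' @export
raspp <- function(parents, cm, n_blocks, allowed_columns = NULL,
                  min_block_len = 4L, max_block_len = NULL,
                  ahr_options = parents$names[1L]) {
  L <- parents$aligned_length
  atr_start <- parents$domain_split + 1L
  atr_len <- L - parents$domain_split
  if (is.null(allowed_columns)) {
    allowed_columns <- seq(atr_start + 1L, L)
  }
  allowed_columns <- sort(unique(as.integer(allowed_columns)))
  allowed_columns <- allowed_columns[allowed_columns > atr_start &
                                     allowed_columns <= L]
  if (n_blocks == 1L) {
    part <- block_partition(integer(), parents)
    av <- library_averages(parents, partition = part, cm = cm,
                           ahr_options = ahr_options)
    res <- data.frame(breakpoints = "", mean_E = av$mean_E,
                      mean_m = av$mean_m)
    return(structure(res, partitions = list(part), class = c("raspp_result",
                                                             "data.frame")))
  }
  if (!length(allowed_columns)) stop("allowed_columns is empty")
  if (is.null(max_block_len)) max_block_len <- atr_len
  cmd <- contact_break_fractions(parents, cm)
  nodes <- sort(unique(c(atr_start, allowed_columns, L + 1L)))
  savedmat <- saved_weight_matrix(cmd, nodes)
  cand <- list()
  lmax_grid <- unique(pmax(min_block_len,
                           seq(ceiling(atr_len / n_blocks), max_block_len)))
  for (lmax in lmax_grid) {
    bp <- raspp_dp(nodes, savedmat, atr_start, L, n_blocks,
                   min_block_len, lmax)
    if (!is.null(bp)) cand[[paste(bp, collapse = ",")]] <- bp
  }
  if (!length(cand)) {
    stop("no feasible partition: n_blocks = ", n_blocks,
         ", min_block_len = ", min_block_len,
         ", |allowed_columns| = ", length(allowed_columns))
  }
  parts <- lapply(cand, function(bp) block_partition(bp, parents))
  scores <- lapply(parts, function(p) {
    library_averages(parents, p, cm, ahr_options)
  })
  res <- data.frame(
    breakpoints = vapply(cand, paste, character(1), collapse = ","),
    mean_E = vapply(scores, `[[`, numeric(1), "mean_E"),
    mean_m = vapply(scores, `[[`, numeric(1), "mean_m"),
    row.names = NULL
  )
  # integer-width bins on mean_m: keep the lowest-E candidate per bin
  bin <- floor(res$mean_m)
  keep <- unlist(lapply(split(seq_len(nrow(res)), bin), function(idx) {
    idx[order(res$mean_E[idx], res$breakpoints[idx])][1L]
  }), use.names = FALSE)
  res <- res[keep, , drop = FALSE]
  parts <- parts[keep]
  # nondominated in (mean_E low, mean_m high)
  ord <- order(res$mean_E, -res$mean_m, res$breakpoints)
  res <- res[ord, , drop = FALSE]; parts <- parts[ord]
  best_m <- -Inf
  nd <- logical(nrow(res))
  for (k in seq_len(nrow(res))) {
    if (res$mean_m[k] > best_m) { nd[k] <- TRUE; best_m <- res$mean_m[k] }
  }
  res <- res[nd, , drop = FALSE]; parts <- parts[nd]
  rownames(res) <- NULL
  structure(res, partitions = unname(parts),
            class = c("raspp_result", "data.frame"))
}

# saved[a_idx, b_idx]: savable weight of contacts with both columns inside
# [nodes[a_idx], nodes[b_idx] - 1].
saved_weight_matrix <- function(cmd, nodes) {
  nn <- length(nodes)
  S <- matrix(0, nn, nn)
  for (k in seq_len(nrow(cmd))) {
    if (cmd$savable[k] == 0) next
    ia <- sum(nodes <= cmd$i[k])
    jb <- match(TRUE, nodes >= cmd$j[k] + 1L)
    if (ia < 1L || is.na(jb)) next
    S[seq_len(ia), jb:nn] <- S[seq_len(ia), jb:nn] + cmd$savable[k]
  }
  S
}

# Dynamic program: partition columns [atr_start, L] into n_blocks segments
# whose starts are atr_start or allowed columns, lengths within
# [lmin, lmax], maximizing the savable contact weight kept inside blocks.
# Returns the breakpoint columns (starts of blocks 2..n), or NULL if
# infeasible.
raspp_dp <- function(nodes, savedmat, atr_start, L, n_blocks, lmin, lmax) {
  nn <- length(nodes)
  idx_of <- function(col) match(col, nodes)
  NEG <- -Inf
  best <- matrix(NEG, n_blocks + 1L, nn)
  back <- matrix(NA_integer_, n_blocks + 1L, nn)
  best[1L, idx_of(atr_start)] <- 0
  for (b in seq_len(n_blocks)) {
    for (v in seq_len(nn)) {
      if (best[b, v] == NEG) next
      a <- nodes[v]
      for (w in seq_len(nn)) {
        bcol <- nodes[w]
        len <- bcol - a
        if (len < lmin || len > lmax) next
        if (b < n_blocks && bcol > L) next
        if (b == n_blocks && bcol != L + 1L) next
        val <- best[b, v] + savedmat[v, w]
        if (val > best[b + 1L, w]) {
          best[b + 1L, w] <- val
          back[b + 1L, w] <- v
        }
      }
    }
  }
  endi <- idx_of(L + 1L)
  if (best[n_blocks + 1L, endi] == NEG) return(NULL)
  path <- integer(n_blocks + 1L)
  path[n_blocks + 1L] <- endi
  for (b in seq(n_blocks + 1L, 2L)) {
    path[b - 1L] <- back[b, path[b]]
  }
  starts <- nodes[path]
  starts[-c(1L, n_blocks + 1L)]
}

#' Write a RASPP frontier as TSV
#' @param result a `raspp_result`.
#' @param path output file; breakpoints serialized 0-based.
#' @export
write_raspp <- function(result, path) {
  out <- as.data.frame(result)
  out$breakpoints <- vapply(strsplit(out$breakpoints, ","), function(b) {
    if (!length(b) || identical(b, "")) return("")
    paste(as.integer(b) - 1L, collapse = ",")
  }, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
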