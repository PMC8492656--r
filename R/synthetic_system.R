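#' Synthetic three-parent recombination system
#'
#' Generates a fully synthetic, desk-scale stand-in for a three-parent
#' chimeric enzyme library: three aligned parents (labels A, B, T) with a
#' fixed N-terminal domain and an eight-block recombined C-terminal
#' domain, and an ensemble-weighted contact map over the recombined
#' region. Block 6 of parents A and B is forced to be perfectly conserved,
#' so the distinct library size is 2 * 3^7 = 4374 — the combinatorics of a
#' three-parent, eight-block design with one conserved block pair. Pairwise
#' parent identity is around 60-80 percent, typical of recombinable
#' homolog sets.
#'
#' Everything here is synthetic (no real sequences or structures); it
#' defines the test-bed conditions for the closed-loop simulations.
#'
#' @param seed RNG seed fixing sequences and contacts (default 1).
#' @param n_ahr alignment columns in the fixed N-terminal domain
#'   (default 40).
#' @param block_len columns per recombined block (default 15).
#' @param n_blocks number of blocks (default 8).
#' @param mut_rate per-column substitution probabilities for parents B and
#'   T relative to A (default 0.3 and 0.4).
#' @param n_contacts contacts sampled for the map (default 300, about 2.5
#'   per recombined residue).
#' @param n_models nominal ensemble size behind the contact weights
#'   (default 100).
#' @param conserved_block block index forced identical between parents A
#'   and B (default 6; `NULL` for none).
#' @return list with `parents`, `partition`, `contact_map`.
#' @export
synthetic_system <- function(seed = 1L, n_ahr = 40L, block_len = 15L,
                             n_blocks = 8L, mut_rate = c(B = 0.3, T = 0.4),
                             n_contacts = 300L, n_models = 100L,
                             conserved_block = 6L) {
  if (!is.null(conserved_block) && conserved_block > n_blocks) {
    conserved_block <- NULL
  }
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  L <- n_ahr + block_len * n_blocks
  withr_seed(seed, {
    pa <- sample(aa, L, replace = TRUE)
    mutate <- function(base, rate) {
      out <- base
      flip <- stats::runif(L) < rate
      out[flip] <- vapply(which(flip), function(c) {
        sample(setdiff(aa, base[c]), 1L)
      }, character(1))
      out
    }
    pb <- mutate(pa, mut_rate[["B"]])
    pt <- mutate(pa, mut_rate[["T"]])
    starts <- n_ahr + 1L + block_len * (seq_len(n_blocks) - 1L)
    ends <- starts + block_len - 1L
    # the conserved block is forced identical between A and B; every other
    # block (and the conserved block for T) must differ between each
    # parent pair in at least one column
    if (!is.null(conserved_block)) {
      cb <- conserved_block
      pb[starts[cb]:ends[cb]] <- pa[starts[cb]:ends[cb]]
    }
    block_eq <- function(x, y, b) {
      cols <- starts[b]:ends[b]
      all(x[cols] == y[cols])
    }
    for (b in seq_len(n_blocks)) {
      if (is.null(conserved_block) || b != conserved_block) {
        while (block_eq(pb, pa, b)) {
          c1 <- sample(starts[b]:ends[b], 1L)
          pb[c1] <- sample(setdiff(aa, pa[c1]), 1L)
        }
      }
      while (block_eq(pt, pa, b) || block_eq(pt, pb, b)) {
        c1 <- sample(starts[b]:ends[b], 1L)
        pt[c1] <- sample(setdiff(aa, c(pa[c1], pb[c1])), 1L)
      }
    }
    parents <- parent_set(
      c(A = paste(pa, collapse = ""), B = paste(pb, collapse = ""),
        T = paste(pt, collapse = "")),
      domain_split = n_ahr
    )
    partition <- block_partition(starts[-1L], parents)
    atr_cols <- (n_ahr + 1L):L
    pairs <- unique(t(apply(
      cbind(sample(atr_cols, n_contacts * 2L, replace = TRUE),
            sample(atr_cols, n_contacts * 2L, replace = TRUE)),
      1L, sort)))
    pairs <- pairs[pairs[, 2L] - pairs[, 1L] >= 2L, , drop = FALSE]
    pairs <- pairs[seq_len(min(n_contacts, nrow(pairs))), , drop = FALSE]
    w <- sample(seq_len(n_models), nrow(pairs), replace = TRUE,
                prob = seq_len(n_models)) / n_models
    cm <- contact_map(data.frame(i = pairs[, 1L], j = pairs[, 2L],
                                 weight = w),
                      cutoff_angstrom = 4.5, n_models = n_models)
    list(parents = parents, partition = partition, contact_map = cm)
  })
}

#' Default synthetic fitness landscape
#'
#' The standard test-bed: the [synthetic_system()] library (4374 distinct
#' chimeras) under a [landscape_spec()] with its default calibration —
#' base titer about 10 mg/L, additive block effects spanning +/- 15 mg/L,
#' sparse pairwise epistasis, roughly 70 percent of the space inactivated
#' through the disruption-linked rule, and replicate noise around 20
#' percent of signal.
#'
#' @param seed landscape seed (effects, epistasis, inactivation draw).
#' @param system_seed seed of the underlying synthetic system; fixed by
#'   default so all landscapes share one library.
#' @param ... passed through to [landscape_spec()].
#' @return a [landscape_spec] (the system is attached as fields
#'   `parents`, `partition`, `cm`).
#' @export
default_landscape <- function(seed = 1L, system_seed = 1L, ...) {
  sys <- synthetic_system(system_seed)
  landscape_spec(sys$parents, sys$partition, sys$contact_map,
                 seed = seed, ...)
}

#' Random-search baseline campaign
#'
#' Measures a uniformly random sample of untested sequences with the same
#' total budget as a model-guided campaign; the comparison partner for
#' closed-loop benchmarks.
#'
#' @param oracle measurement oracle, as in [run_campaign()].
#' @param space enumerated library.
#' @param n_select sequences to draw (beyond `initial`).
#' @param initial block strings always measured first (default none).
#' @param n_replicates replicates per sequence.
#' @param seed RNG seed.
#' @return data.frame of assay records.
#' @export
random_search <- function(oracle, space, n_select, initial = character(0),
                          n_replicates = 3L, seed = 1L) {
  picks <- withr_seed(seed, sample(setdiff(space, initial), n_select))
  tab <- oracle(c(initial, picks), n_replicates, sub_seed(seed, 1L))
  tab$round <- NA_integer_
  tab
}
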