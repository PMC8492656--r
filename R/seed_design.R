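#' Gaussian entropy of a sequence subset
#'
#' Differential entropy of the Gaussian prior over a subset S of sequences
#' under the homogeneous linear kernel:
#' \eqn{H(S) = \frac{1}{2}\log\det(2\pi e (K_{SS} + jitter\,I))}.
#' Because the candidate set is a subset of the full landscape, the mutual
#' information between a chosen subset and the landscape reduces to this
#' entropy, which is what the greedy seed design maximizes.
#'
#' @param X encodings of the subset (rows = sequences; at least one).
#' @param sigma2 kernel variance (default 1; the greedy argmax is
#'   invariant to it at fixed subset size).
#' @param jitter_scale jitter added as `jitter_scale * mean(diag(K))`;
#'   keeps duplicated or near-duplicate encodings from collapsing the
#'   determinant to exactly zero.
#' @return entropy in nats.
#' @export
gaussian_entropy <- function(X, sigma2 = 1, jitter_scale = 1e-8) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("subset must be nonempty")
  K <- sigma2 * tcrossprod(X)
  jitter <- jitter_scale * max(mean(diag(K)), .Machine$double.eps)
  L <- chol(K + diag(jitter, nrow(K)))
  n <- nrow(K)
  0.5 * n * log(2 * pi * exp(1)) + sum(log(diag(L)))
}

#' Greedy maximally informative seed selection
#'
#' Starting from an initial set (by default the parental chimeras), greedily
#' adds the candidate whose inclusion yields the largest Gaussian entropy
#' \eqn{H(S \cup \{s\})}, repeating until `n_select` additions are made.
#' The marginal entropy gain of a candidate equals half the log of its
#' posterior variance given the current set (up to a constant), so each
#' sweep scores every candidate by its jittered posterior variance; ties
#' break on the alphabetically smallest block string. Entropy is submodular,
#' so the greedy trace has nonincreasing marginal gains and the usual
#' (1 - 1/e) near-optimality guarantee.
#'
#' @param space character vector of candidate block strings (the enumerated
#'   library).
#' @param parents a [parent_set].
#' @param partition a [block_partition].
#' @param n_select number of sequences to add (default 20). With
#'   `count_includes_initial = TRUE` it is instead the total size of the
#'   returned set including the initial members.
#' @param initial block strings the selection starts from; default the
#'   parental chimeras.
#' @param scheme,contact_map encoding scheme (default `"hamming"`).
#' @param sigma2,jitter_scale see [gaussian_entropy()].
#' @param count_includes_initial see `n_select`.
#' @return object of class `seed_plan`: list with `selected` (the added
#'   block strings, in pick order), `initial`, `objective_trace` (entropy
#'   of the growing set after each addition) and `kernel_scheme`.
#' @export
greedy_seed_select <- function(space, parents, partition, n_select = 20L,
                               initial = NULL,
                               scheme = "hamming", contact_map = NULL,
                               sigma2 = 1, jitter_scale = 1e-8,
                               count_includes_initial = FALSE) {
  if (is.null(initial)) initial <- parental_chimeras(parents, partition)
  initial <- intersect(initial, space)
  if (count_includes_initial) {
    n_select <- n_select - length(initial)
  }
  if (n_select < 0L) stop("n_select smaller than the initial set")
  if (n_select + length(initial) > length(space)) {
    stop("n_select exceeds the candidate space")
  }
  X <- encode_chimeras(space, parents, partition, scheme, contact_map)
  rownames(X) <- space
  sel <- character(0)
  trace <- numeric(0)
  current <- initial
  for (step in seq_len(n_select)) {
    avail <- setdiff(space, c(current, sel))
    v <- posterior_variances(X[c(current, sel), , drop = FALSE],
                             X[avail, , drop = FALSE], sigma2, jitter_scale)
    best <- avail[order(-v, avail)][1L]
    sel <- c(sel, best)
    trace <- c(trace, gaussian_entropy(X[c(current, sel), , drop = FALSE],
                                       sigma2, jitter_scale))
  }
  structure(list(selected = sel, initial = initial,
                 objective_trace = trace, kernel_scheme = scheme),
            class = "seed_plan")
}

# Jittered posterior variance of each candidate row of Xc given the
# (noise-free, jittered) observations Xs; the quantity whose log drives the
# greedy entropy gain.
posterior_variances <- function(Xs, Xc, sigma2, jitter_scale) {
  prior <- sigma2 * rowSums(Xc^2)
  jitter <- jitter_scale * max(mean(sigma2 * rowSums(Xs^2)),
                               mean(prior), .Machine$double.eps)
  if (!nrow(Xs)) return(prior + jitter)
  K <- sigma2 * tcrossprod(Xs) + diag(jitter, nrow(Xs))
  L <- t(chol(K))
  V <- forwardsolve(L, sigma2 * tcrossprod(Xs, Xc))
  pmax(prior - colSums(V^2), 0) + jitter
}

#' Write a seed plan as CSV
#' @param plan a `seed_plan`.
#' @param path output file (columns rank, block_string, entropy_after).
#' @export
write_seed_plan <- function(plan, path) {
  utils::write.csv(
    data.frame(rank = seq_along(plan$selected),
               block_string = plan$selected,
               entropy_after = plan$objective_trace),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
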