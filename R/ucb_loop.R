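#' Upper-confidence-bound acquisition scores
#'
#' Score each candidate as posterior mean plus `beta` posterior standard
#' deviations; `beta = 1` reproduces the mean-plus-one-sd criterion used
#' for the optimization rounds.
#'
#' @param model a fitted `gp_model`.
#' @param X candidate encodings.
#' @param beta standard-deviation multiplier (default 1).
#' @return numeric scores (one per candidate row).
#' @export
ucb_scores <- function(model, X, beta = 1) {
  p <- gp_predict(model, X)
  p$mean + beta * p$sd
}

#' Summed UCB over several strain models
#'
#' Round-one style acquisition: candidates are scored by the sum of their
#' per-strain UCB scores, so sequences promising in every strain rank
#' highest. All models must share the encoding scheme.
#'
#' @param models list of fitted `gp_model`s (one per strain).
#' @param X candidate encodings.
#' @param beta see [ucb_scores()].
#' @export
combined_ucb <- function(models, X, beta = 1) {
  dims <- vapply(models, function(m) ncol(m$X), integer(1))
  if (length(unique(dims[dims > 0])) > 1L ||
      (any(dims > 0) && any(dims[dims > 0] != ncol(X)))) {
    stop("strain models use different encoding dimensions")
  }
  Reduce(`+`, lapply(models, function(m) ucb_scores(m, X, beta)))
}

#' Batch-mode UCB selection with hallucinated refits
#'
#' Picks `batch_size` candidates one at a time: the current UCB argmax is
#' appended to the batch, the model is refit with a hallucinated
#' observation equal to that pick's posterior mean (same noise variance as
#' real data), and the UCB scores are recomputed. Hallucination collapses
#' the pick's variance so near-duplicates stop dominating, spreading the
#' batch over distinct regions. Hallucinated points exist only inside this
#' function; callers only ever see real measurements.
#'
#' @param model fitted `gp_model` (on real data).
#' @param pool_X encodings of the candidate pool.
#' @param pool_ids identifiers (block strings) of pool rows.
#' @param batch_size picks wanted; if the pool is smaller, a shorter batch
#'   is returned with a warning.
#' @param beta sd multiplier.
#' @return data.frame with columns `block_string`, `ucb`, `mean`, `sd` in
#'   pick order.
#' @export
batch_select <- function(model, pool_X, pool_ids, batch_size, beta = 1) {
  stopifnot(nrow(pool_X) == length(pool_ids), batch_size >= 1L)
  if (length(pool_ids) < batch_size) {
    warning("pool smaller than batch_size: returning ", length(pool_ids),
            " proposals")
    batch_size <- length(pool_ids)
  }
  Xh <- model$X
  yh <- model$y
  picks <- list()
  avail <- seq_along(pool_ids)
  fit <- model
  for (k in seq_len(batch_size)) {
    p <- gp_predict(fit, pool_X[avail, , drop = FALSE])
    score <- p$mean + beta * p$sd
    best <- order(-score, pool_ids[avail])[1L]
    idx <- avail[best]
    picks[[k]] <- data.frame(block_string = pool_ids[idx],
                             ucb = score[best], mean = p$mean[best],
                             sd = p$sd[best])
    Xh <- rbind(Xh, pool_X[idx, , drop = FALSE])
    yh <- c(yh, p$mean[best])
    avail <- setdiff(avail, idx)
    if (k < batch_size) {
      fit <- gp_fit(Xh, yh, model$sigma2, model$noise_var,
                    center = model$center)
    }
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Filter the candidate pool before acquisition
#'
#' Removes already-tested sequences, sequences the classifier predicts
#' inactive (posterior probability of activity below `cutoff`), and
#' optionally sequences more than `max_block_distance` block exchanges
#' away from every parent — the early-round trick that biases the search
#' toward functional sequences.
#'
#' @param space character vector, the enumerated library.
#' @param tested block strings already measured.
#' @param classifier optional fitted `gnb_model` (NULL disables the
#'   filter).
#' @param X encodings of `space` rows (required when `classifier` given).
#' @param parents,partition needed when `max_block_distance` is given.
#' @param max_block_distance optional integer; NULL disables.
#' @param cutoff classifier probability cutoff (default 0.5).
#' @return character vector, the retained pool; errors if empty.
#' @export
filter_pool <- function(space, tested, classifier = NULL, X = NULL,
                        parents = NULL, partition = NULL,
                        max_block_distance = NULL, cutoff = 0.5) {
  keep <- !(space %in% tested)
  if (!is.null(classifier)) {
    if (is.null(X)) stop("classifier filtering needs the space encodings X")
    keep <- keep & (gnb_predict(classifier, X) >= cutoff)
  }
  if (!is.null(max_block_distance)) {
    keep <- keep &
      (block_distance(space, parents, partition) <= max_block_distance)
  }
  pool <- space[keep]
  if (!length(pool)) {
    stop("candidate pool is empty; relax the classifier cutoff, ",
         "max_block_distance, or test fewer sequences")
  }
  pool
}

#' Run a closed-loop sequence optimization campaign
#'
#' Executes the full design-test-learn loop against a measurement oracle:
#' a greedy maximally informative seed round, then `n_rounds` of batch
#' UCB proposals. Each round refits the active/inactive classifier and the
#' GP regressor on all accumulated real measurements (hallucinations are
#' never kept), rescans the kernel variance by leave-one-out
#' cross-validation, filters the pool and proposes a batch. Fully
#' reproducible given `seed`.
#'
#' @param oracle function `(block_strings, n_replicates, seed)` returning
#'   an assay record data.frame (see [measure()]); typically
#'   [landscape_oracle()]. Rows with non-finite total titer are recorded
#'   as missing and excluded from fitting.
#' @param parents,partition,contact_map the library definition.
#' @param config list of campaign settings; see [campaign_config()].
#' @return object of class `campaign_state`: list with `table` (all real
#'   measurements), `rounds` (per-round records), `config`, `seed`.
#' @export
run_campaign <- function(oracle, parents, partition, contact_map = NULL,
                         config = campaign_config()) {
  seed <- config$seed
  space <- enumerate_space(parents, partition)
  X <- encode_chimeras(space, parents, partition, config$scheme,
                       contact_map)
  rownames(X) <- space
  threshold <- config$activity_threshold

  plan <- greedy_seed_select(space, parents, partition,
                             n_select = config$n_seed,
                             scheme = config$scheme,
                             contact_map = contact_map)
  seed_set <- unique(c(plan$initial, plan$selected))
  table <- oracle(seed_set, config$n_replicates, sub_seed(seed, 0L))
  table$round <- 0L
  rounds <- list()

  for (r in seq_len(config$n_rounds)) {
    agg <- aggregate_assays(table, threshold = threshold,
                            by_strain = FALSE)
    ok <- is.finite(agg$mean_titer)
    train_ids <- agg$block_string[ok]
    Xtr <- X[train_ids, , drop = FALSE]
    ytr <- agg$mean_titer[ok]
    act <- agg$active[ok]

    classifier <- NULL
    use_filter <- sum(act) >= 2L && sum(!act) >= 1L
    if (use_filter) classifier <- gnb_fit(Xtr, act)

    # regression set: all measured sequences, or the actives only (the
    # classifier then stands in for the inactive mass); falls back to all
    # data while actives are too few to cross-validate
    if (identical(config$gp_training, "active") && sum(act) >= 4L) {
      Xtr <- Xtr[act, , drop = FALSE]
      ytr <- ytr[act]
    }

    ysd <- stats::sd(ytr)
    if (!is.finite(ysd) || ysd == 0) ysd <- 1
    ys <- ytr / ysd
    cv <- loo_cv_scan(Xtr, ys, noise_var = config$noise_var)
    sigma2 <- attr(cv, "chosen")
    fit <- gp_fit(Xtr, ys, sigma2, config$noise_var)

    mbd <- round_setting(config$max_block_distance, r)
    pool <- filter_pool(space, tested = unique(table$block_string),
                        classifier = classifier, X = X,
                        parents = parents, partition = partition,
                        max_block_distance = mbd)
    batch <- batch_select(fit, X[pool, , drop = FALSE], pool,
                          batch_size = config$batch_size,
                          beta = config$beta)
    batch$mean <- batch$mean * ysd
    batch$sd <- batch$sd * ysd
    batch$ucb <- batch$ucb * ysd

    new <- oracle(batch$block_string, config$n_replicates, sub_seed(seed, r))
    new$round <- r
    table <- rbind(table, new)
    rounds[[r]] <- list(round = r, pool_size = length(pool),
                        proposals = batch, sigma2 = sigma2,
                        classifier_used = use_filter,
                        max_block_distance = mbd)
  }
  structure(list(table = table, rounds = rounds, config = config,
                 seed = seed),
            class = "campaign_state")
}

#' Campaign configuration
#'
#' @param n_rounds UCB rounds after the seed round (default 10).
#' @param batch_size proposals per round (default 10; the protocol used
#'   10-12).
#' @param n_seed greedy seed additions beyond the parents (default 20).
#' @param beta UCB sd multiplier (default 1).
#' @param n_replicates replicate measurements per proposed sequence.
#' @param activity_threshold titer (mg/L) above which a sequence counts as
#'   active (default 1).
#' @param scheme encoding scheme (default `"hamming"`).
#' @param noise_var GP observation noise on sd-scaled titers (default 1).
#' @param max_block_distance NULL, a single integer, or a vector giving a
#'   per-round cap on block exchanges (NA entries disable the cap for that
#'   round); default caps rounds 1-3 at 4 exchanges, then unrestricted.
#' @param gp_training `"all"` fits the regressor on every measured
#'   sequence; `"active"` fits it on the active subset only (the
#'   classifier screens candidates for the inactive mass), falling back to
#'   all data while fewer than 4 actives exist.
#' @param seed campaign master seed; all randomness derives from it.
#' @export
campaign_config <- function(n_rounds = 10L, batch_size = 10L, n_seed = 20L,
                            beta = 1, n_replicates = 3L,
                            activity_threshold = 1, scheme = "hamming",
                            noise_var = 1,
                            max_block_distance = c(4L, 4L, 4L),
                            gp_training = c("active", "all"),
                            seed = 1L) {
  list(n_rounds = as.integer(n_rounds), batch_size = as.integer(batch_size),
       n_seed = as.integer(n_seed), beta = beta,
       n_replicates = as.integer(n_replicates),
       activity_threshold = activity_threshold, scheme = scheme,
       noise_var = noise_var, max_block_distance = max_block_distance,
       gp_training = match.arg(gp_training), seed = as.integer(seed))
}

round_setting <- function(x, r) {
  if (is.null(x)) return(NULL)
  v <- if (length(x) >= r) x[[r]] else NA
  if (is.na(v)) NULL else as.integer(v)
}

# Derive a per-stage seed from the campaign master seed, kept within the
# 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               .Machine$integer.max)
}

#' Best measured sequence of a campaign
#' @param state a `campaign_state`.
#' @return one-row data.frame: block_string and its mean measured titer.
#' @export
campaign_best <- function(state) {
  agg <- aggregate_assays(state$table, by_strain = FALSE)
  agg[which.max(agg$mean_titer), c("block_string", "mean_titer")]
}

#' Persist a campaign as JSON
#' @param state a `campaign_state`.
#' @param path output path.
#' @export
write_campaign <- function(state, path) {
  jsonlite::write_json(
    list(seed = state$seed, config = state$config,
         table = state$table, rounds = state$rounds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
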