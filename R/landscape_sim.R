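#' Synthetic chimeric fitness landscape
#'
#' Defines a block-additive, pairwise-epistatic titer landscape over a
#' chimeric library, with an inactivation mechanism tied to structural
#' disruption and replicate measurement noise. It emulates the statistical
#' structure of an in vivo fatty-alcohol production assay — a base titer,
#' per-block donor effects, sparse epistasis, a large inactive fraction of
#' highly disrupted chimeras, and a C16/C14-dominated chain-length product
#' mixture — so the whole design-test-learn loop can be exercised at desk
#' scale. It is synthetic: it is not fit to any measured dataset.
#'
#' Effects are keyed by block label group, so chimeras that translate to
#' the same protein always receive the same titer.
#'
#' @param parents a [parent_set].
#' @param partition a [block_partition].
#' @param cm a [contact_map]; drives the disruption-linked inactivation.
#' @param base base titer (mg/L) of the reference parent (default 10).
#' @param effect_range half-width (mg/L) of the uniform distribution from
#'   which per-(block, label) additive effects are drawn (default 15).
#' @param n_epistasis number of random block-pair epistatic terms
#'   (default 12).
#' @param epistasis_range half-width (mg/L) of epistatic term draws
#'   (default 5).
#' @param inactive_fraction target fraction of the library rendered
#'   inactive; the logistic midpoint on SCHEMA E is placed at the matching
#'   library quantile (default 0.7).
#' @param inact_slope logistic slope on E (mg/L of E units); 0 gives a
#'   hard threshold at the midpoint (default 3).
#' @param noise_sd absolute replicate noise sd, mg/L (default 1).
#' @param noise_cv multiplicative noise: sd contribution proportional to
#'   the true titer (default 0.2, matching replicate spreads of roughly
#'   20 percent).
#' @param chain_weights chain-length mixture of the product (must sum
#'   to 1); default 70 percent C16, 25 percent C14, 5 percent C12.
#' @param strain strain tag stamped on assay records.
#' @param seed seed fixing effects, epistasis and the inactivation draw.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(parents, partition, cm,
                           base = 10, effect_range = 15,
                           n_epistasis = 12L, epistasis_range = 5,
                           inactive_fraction = 0.7, inact_slope = 3,
                           noise_sd = 1, noise_cv = 0.2,
                           chain_weights = c(C12 = 0.05, C14 = 0.25,
                                             C16 = 0.70),
                           strain = "sim", seed = 1L) {
  stopifnot(noise_sd >= 0, noise_cv >= 0,
            abs(sum(chain_weights) - 1) < 1e-8)
  space <- enumerate_space(parents, partition)
  groups <- block_label_groups(parents, partition)
  ref <- parents$names[1L]
  spec <- withr_seed(seed, {
    # Additive effects are relative to the reference parent (label-A
    # groups contribute 0, so that parent sits at the base titer). Draws
    # are redrawn until every parent's noiseless titer stays positive:
    # the landscape emulates a library built from functional parents.
    draw_effects <- function() {
      effects <- matrix(0, partition$n_blocks, length(parents$names),
                        dimnames = list(NULL, parents$names))
      for (b in seq_len(partition$n_blocks)) {
        reps <- unique(unname(groups[[b]]))
        draw <- stats::runif(length(reps), -effect_range, effect_range)
        names(draw) <- reps
        draw[groups[[b]][[ref]]] <- 0
        effects[b, ] <- draw[groups[[b]][parents$names]]
      }
      effects
    }
    effects <- draw_effects()
    for (try in seq_len(1000L)) {
      if (all(base + colSums(effects) > 0.2 * base)) break
      effects <- draw_effects()
    }
    epi <- NULL
    if (n_epistasis > 0L) {
      epi <- data.frame(
        block1 = sample(partition$n_blocks, n_epistasis, replace = TRUE),
        label1 = sample(parents$names, n_epistasis, replace = TRUE),
        block2 = sample(partition$n_blocks, n_epistasis, replace = TRUE),
        label2 = sample(parents$names, n_epistasis, replace = TRUE),
        value = stats::runif(n_epistasis, -epistasis_range, epistasis_range)
      )
      epi <- epi[epi$block1 != epi$block2, , drop = FALSE]
      epi$label1 <- vapply(seq_len(nrow(epi)), function(k) {
        groups[[epi$block1[k]]][[epi$label1[k]]]
      }, character(1))
      epi$label2 <- vapply(seq_len(nrow(epi)), function(k) {
        groups[[epi$block2[k]]][[epi$label2[k]]]
      }, character(1))
    }
    # Disruption-linked inactivation, calibrated so that the TOTAL
    # inactive fraction (rule-inactivated plus additively nonviable)
    # approaches the target; raw-nonviable chimeras are zero through the
    # clip regardless of the rule.
    E <- schema_E(space, parents, partition, cm)
    labs <- chimera_label_matrix(space, parents, partition)
    raw <- rep(base, length(space))
    for (b in seq_len(partition$n_blocks)) {
      raw <- raw + effects[b, ][labs[, b + 1L]]
    }
    if (inactive_fraction <= 0) {
      midpoint <- Inf
      active <- stats::setNames(rep(TRUE, length(space)), space)
    } else {
      p_rule_active <- min(1, (1 - inactive_fraction) / max(mean(raw > 0),
                                                            1e-12))
      midpoint <- as.numeric(stats::quantile(E, p_rule_active))
      p_inactive <- if (inact_slope > 0) {
        stats::plogis((E - midpoint) / inact_slope)
      } else {
        as.numeric(E > midpoint)
      }
      u <- stats::runif(length(space))
      active <- stats::setNames(u >= p_inactive, space)
    }
    # parents always express
    active[parental_chimeras(parents, partition)] <- TRUE
    list(effects = effects, epistasis = epi, inact_midpoint = midpoint,
         active = active)
  })
  structure(
    c(spec,
      list(parents = parents, partition = partition, cm = cm, base = base,
           inact_slope = inact_slope, noise_sd = noise_sd,
           noise_cv = noise_cv, chain_weights = chain_weights,
           strain = strain, seed = as.integer(seed), space = space,
           groups = groups)),
    class = "landscape_spec"
  )
}

#' Noiseless titer of chimeras under a synthetic landscape
#'
#' Base plus additive block effects plus epistasis, clipped at zero, and
#' zeroed for chimeras the disruption-linked inactivation rule marks
#' inactive. Deterministic given the spec.
#'
#' @param spec a [landscape_spec].
#' @param chimeras character vector of block strings (members of the
#'   spec's library).
#' @return numeric titers (mg/L), named by chimera.
#' @export
true_titer <- function(spec, chimeras) {
  canon <- canonical_chimeras(chimeras, spec$parents, spec$partition)
  if (any(!canon %in% spec$space)) {
    stop("chimera outside the landscape's library: ",
         chimeras[!canon %in% spec$space][[1L]])
  }
  labs <- chimera_label_matrix(canon, spec$parents, spec$partition)
  t <- rep(spec$base, length(chimeras))
  for (b in seq_len(spec$partition$n_blocks)) {
    t <- t + spec$effects[b, ][labs[, b + 1L]]
  }
  if (!is.null(spec$epistasis) && nrow(spec$epistasis)) {
    for (k in seq_len(nrow(spec$epistasis))) {
      e <- spec$epistasis[k, ]
      hit <- labs[, e$block1 + 1L] == e$label1 &
        labs[, e$block2 + 1L] == e$label2
      t <- t + e$value * hit
    }
  }
  t <- pmax(t, 0) * as.numeric(spec$active[canon])
  stats::setNames(t, chimeras)
}

#' Simulate replicate assay measurements
#'
#' Replicate totals are the true titer plus Gaussian noise with sd
#' `noise_sd + noise_cv * true`, clipped at zero; totals are split across
#' chain lengths by the spec's mixture weights.
#'
#' @param spec a [landscape_spec].
#' @param chimeras block strings to measure.
#' @param n_replicates replicates per chimera (>= 1).
#' @param seed RNG seed for the noise draws.
#' @return data.frame of assay records: `block_string`, `strain`,
#'   `replicate`, one column per chain length, `titer_total_mg_per_L`,
#'   `active`.
#' @export
measure <- function(spec, chimeras, n_replicates = 3L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  tt <- true_titer(spec, chimeras)
  n <- length(chimeras)
  totals <- withr_seed(seed, {
    sds <- spec$noise_sd + spec$noise_cv * tt
    pmax(0, rep(tt, each = n_replicates) +
           stats::rnorm(n * n_replicates, 0, rep(sds, each = n_replicates)))
  })
  rec <- data.frame(
    block_string = rep(chimeras, each = n_replicates),
    strain = spec$strain,
    replicate = rep(seq_len(n_replicates), times = n)
  )
  for (ch in names(spec$chain_weights)) {
    rec[[paste0("titer_", ch, "_mg_per_L")]] <-
      totals * spec$chain_weights[[ch]]
  }
  rec$titer_total_mg_per_L <- totals
  rec$active <- totals > 1
  rec
}

#' Measurement oracle for [run_campaign()]
#'
#' Wraps a [landscape_spec] as the `(chimeras, n_replicates, seed)`
#' function the campaign driver expects.
#'
#' @param spec a [landscape_spec].
#' @export
landscape_oracle <- function(spec) {
  function(chimeras, n_replicates, seed) {
    measure(spec, chimeras, n_replicates, seed)
  }
}

#' Internal-standard quantitation of GC peak areas
#'
#' Converts even-chain analyte peak areas to concentrations using the
#' bracketing odd-chain internal standards:
#' \deqn{C_i = A_i \cdot \mathrm{avg}(C_{i-1}, C_{i+1}) /
#'   \mathrm{avg}(A_{i-1}, A_{i+1})}
#' for even chain lengths i. Species missing a bracketing standard, or
#' bracketed by standards with nonpositive mean area, get `NA` with a
#' warning; the others are still computed.
#'
#' @param areas data.frame with columns `chain` (even integers) and
#'   `area`: the sample's analyte peak areas.
#' @param standards data.frame with columns `chain` (odd integers),
#'   `conc`, `area`: the internal standards.
#' @return data.frame `chain`, `conc` (same order as `areas`).
#' @export
quantitate_internal_standard <- function(areas, standards) {
  stopifnot(all(c("chain", "area") %in% names(areas)),
            all(c("chain", "conc", "area") %in% names(standards)))
  if (any(areas$chain %% 2L != 0L)) stop("analyte chains must be even")
  if (any(standards$chain %% 2L != 1L)) stop("standard chains must be odd")
  conc <- rep(NA_real_, nrow(areas))
  for (k in seq_len(nrow(areas))) {
    i <- areas$chain[k]
    lo <- standards[standards$chain == i - 1L, , drop = FALSE]
    hi <- standards[standards$chain == i + 1L, , drop = FALSE]
    if (nrow(lo) != 1L || nrow(hi) != 1L) {
      warning("chain C", i, ": missing bracketing standard; reported NA")
      next
    }
    abar <- mean(c(lo$area, hi$area))
    if (!is.finite(abar) || abar <= 0) {
      warning("chain C", i, ": nonpositive standard area; reported NA")
      next
    }
    conc[k] <- areas$area[k] * mean(c(lo$conc, hi$conc)) / abar
  }
  data.frame(chain = areas$chain, conc = conc)
}

#' Aggregate replicate assay records per chimera
#'
#' Per (chimera, strain) — or per chimera with `by_strain = FALSE` —
#' computes the mean total titer, sample standard deviation (n-1
#' denominator; 0 when n = 1), replicate count and the active flag from
#' the titer threshold.
#'
#' @param records assay records as produced by [measure()] or read with
#'   [read_function_table()].
#' @param threshold activity threshold in mg/L (default 1).
#' @param by_strain keep strains separate (default TRUE).
#' @return data.frame `block_string`, (`strain`,) `mean_titer`, `sd_titer`,
#'   `n`, `active`.
#' @export
aggregate_assays <- function(records, threshold = 1, by_strain = TRUE) {
  key <- if (by_strain && "strain" %in% names(records)) {
    interaction(records$block_string, records$strain, drop = TRUE,
                sep = "\r")
  } else {
    factor(records$block_string)
  }
  sp <- split(records$titer_total_mg_per_L, key)
  ids <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(
    block_string = vapply(ids, `[[`, character(1), 1L),
    mean_titer = vapply(sp, mean, numeric(1)),
    sd_titer = vapply(sp, function(x) {
      if (length(x) < 2L) 0 else stats::sd(x)
    }, numeric(1)),
    n = lengths(sp),
    row.names = NULL
  )
  if (by_strain && "strain" %in% names(records)) {
    out$strain <- vapply(ids, `[[`, character(1), 2L)
    out <- out[, c("block_string", "strain", "mean_titer", "sd_titer", "n")]
  }
  out$active <- out$mean_titer > threshold
  out
}

#' Read / write sequence-function tables
#'
#' CSV schema: `block_string`, `strain`, `replicate`,
#' `titer_total_mg_per_L`, plus optional per-chain-length titer columns.
#'
#' @param path CSV file.
#' @export
read_function_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block_string", "titer_total_mg_per_L")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("function table missing columns: ", paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_function_table
#' @param table the records to write.
#' @export
write_function_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean titer of chimeras matching a block pattern
#'
#' Splits a sequence-function table into chimeras matching a wildcard
#' block pattern (`X` matches any label, e.g. `"X-XXXBXXAB"`) and the
#' complement, and reports the mean of per-chimera mean total titers on
#' each side, along with record counts. Useful for quantifying the effect
#' of block combinations (such as the charge-carrying blocks of an
#' ACP-binding interface) in measured or deposited datasets.
#'
#' @param table a sequence-function table.
#' @param pattern wildcard block string.
#' @return list: `mean_match`, `mean_other`, `n_chimeras_match`,
#'   `n_chimeras_other`, `n_records`.
#' @export
block_pattern_stats <- function(table, pattern) {
  per <- tapply(table$titer_total_mg_per_L, table$block_string, mean)
  rx <- paste0("^", gsub("X", "[A-Za-z]", pattern, fixed = TRUE), "$")
  hit <- grepl(rx, names(per))
  list(mean_match = mean(per[hit]), mean_other = mean(per[!hit]),
       n_chimeras_match = sum(hit), n_chimeras_other = sum(!hit),
       n_records = nrow(table))
}
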