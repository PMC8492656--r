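test_that("true titers are additive, clipped and inactivation-linked", {
  sys <- small_system(seed = 11, n_blocks = 3, block_len = 5,
                      n_contacts = 40)
  # all-zero effects, no epistasis, no inactivation -> base everywhere
  flat <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                         effect_range = 0, n_epistasis = 0,
                         inactive_fraction = 0, seed = 1)
  sp <- enumerate_space(sys$parents, sys$partition)
  expect_equal(unname(true_titer(flat, sp)), rep(flat$base, length(sp)))

  # purely additive: a single-block difference equals the effect delta
  add <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                        n_epistasis = 0, inactive_fraction = 0, seed = 2)
  t1 <- true_titer(add, "A-ABA")[[1]]
  t2 <- true_titer(add, "A-ATA")[[1]]
  delta <- unname(add$effects[2, "B"] - add$effects[2, "T"])
  if (t1 > 0 && t2 > 0) expect_equal(t1 - t2, delta)

  # hard-threshold inactivation: every chimera with E above the midpoint
  # is dead (cross-check against schema_E)
  hard <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                         inact_slope = 0, inactive_fraction = 0.5, seed = 3)
  E <- schema_E(sp, sys$parents, sys$partition, sys$contact_map)
  dead <- sp[E > hard$inact_midpoint &
               !sp %in% parental_chimeras(sys$parents, sys$partition)]
  expect_equal(unname(true_titer(hard, dead)), rep(0, length(dead)))

  # chimeras outside the library are rejected
  expect_error(true_titer(flat, "A-XAA"), "label")
})

test_that("measurements have the configured noise and clip at zero", {
  sys <- small_system(seed = 13, n_blocks = 2, block_len = 5)
  spec <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                         effect_range = 0, n_epistasis = 0,
                         inactive_fraction = 0, noise_sd = 2,
                         noise_cv = 0, seed = 5)
  ch <- "A-AA"

  # zero noise: replicates equal the true titer exactly
  spec0 <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                          effect_range = 0, n_epistasis = 0,
                          inactive_fraction = 0, noise_sd = 0,
                          noise_cv = 0, seed = 5)
  rec0 <- measure(spec0, ch, n_replicates = 5, seed = 1)
  expect_equal(rec0$titer_total_mg_per_L,
               rep(true_titer(spec0, ch)[[1]], 5))

  # Monte-Carlo: sample sd within 5% of the spec sd at 1e4 replicates
  rec <- measure(spec, ch, n_replicates = 1e4, seed = 2)
  expect_equal(sd(rec$titer_total_mg_per_L), 2, tolerance = 0.05)
  expect_equal(mean(rec$titer_total_mg_per_L), spec$base, tolerance = 0.05)

  # chain-length split respects the mixture and sums to the total
  expect_equal(rec$titer_C16_mg_per_L / rec$titer_total_mg_per_L,
               rep(0.70, nrow(rec)), tolerance = 1e-10)
  chain_cols <- grep("^titer_C", names(rec), value = TRUE)
  expect_equal(rowSums(rec[chain_cols]), rec$titer_total_mg_per_L)

  # a dead chimera yields only nonnegative measurements
  spec_dead <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                              inact_slope = 0, inactive_fraction = 0.99,
                              noise_sd = 3, noise_cv = 0, seed = 6)
  sp <- enumerate_space(sys$parents, sys$partition)
  dead <- sp[true_titer(spec_dead, sp) == 0][1]
  recd <- measure(spec_dead, dead, n_replicates = 200, seed = 3)
  expect_true(all(recd$titer_total_mg_per_L >= 0))

  # reproducible under seed
  expect_equal(measure(spec, ch, 3, seed = 42),
               measure(spec, ch, 3, seed = 42))
})

test_that("internal-standard quantitation follows the bracketing formula", {
  # direct arithmetic: A=50 bracketed by standards at conc 15 with areas
  # 50 and 100 -> 50 * 15 / 75 = 10
  out <- quantitate_internal_standard(
    data.frame(chain = 6, area = 50),
    data.frame(chain = c(5, 7), conc = c(15, 15), area = c(50, 100)))
  expect_equal(out$conc, 10)

  # response factor 1: analyte area equal to both bracketing areas with
  # equal standard concentrations c returns exactly c
  out2 <- quantitate_internal_standard(
    data.frame(chain = 12, area = 77),
    data.frame(chain = c(11, 13), conc = c(4.2, 4.2), area = c(77, 77)))
  expect_equal(out2$conc, 4.2)

  # random tables match an independently coded oracle over all species
  set.seed(20)
  chains <- seq(2, 16, by = 2)
  areas <- data.frame(chain = chains, area = runif(8, 10, 200))
  stds <- data.frame(chain = seq(1, 17, by = 2), conc = runif(9, 1, 20),
                     area = runif(9, 10, 200))
  got <- quantitate_internal_standard(areas, stds)
  oracle <- vapply(seq_len(nrow(areas)), function(k) {
    i <- areas$chain[k]
    areas$area[k] *
      mean(stds$conc[stds$chain %in% c(i - 1, i + 1)]) /
      mean(stds$area[stds$chain %in% c(i - 1, i + 1)])
  }, numeric(1))
  expect_equal(got$conc, oracle)

  # homogeneity of degree 1 in analyte areas and standard concentrations
  scaled <- quantitate_internal_standard(
    transform(areas, area = area * 3), stds)
  expect_equal(scaled$conc, 3 * got$conc)
  scaled2 <- quantitate_internal_standard(
    areas, transform(stds, conc = conc * 2))
  expect_equal(scaled2$conc, 2 * got$conc)

  # a missing bracket fails that species only, with a warning
  expect_warning(
    part <- quantitate_internal_standard(
      data.frame(chain = c(6, 8), area = c(50, 60)),
      data.frame(chain = c(5, 7), conc = c(15, 15), area = c(50, 100))),
    "C8")
  expect_equal(part$conc[1], 10)
  expect_true(is.na(part$conc[2]))
})

test_that("replicate aggregation reports mean, sd, n and active flags", {
  rec <- data.frame(
    block_string = rep(c("A-AA", "A-AB"), c(4, 1)),
    strain = "sim", replicate = c(1:4, 1),
    titer_total_mg_per_L = c(43, 54, 65, 54, 0.2))
  agg <- aggregate_assays(rec, threshold = 1)
  row1 <- agg[agg$block_string == "A-AA", ]
  expect_equal(row1$mean_titer, 54)
  expect_equal(row1$sd_titer, sd(c(43, 54, 65, 54)))
  expect_equal(row1$sd_titer, 9.0, tolerance = 0.01)
  expect_equal(row1$n, 4L)
  expect_true(row1$active)

  # single replicate: sd 0, flagged n = 1, inactive below threshold
  row2 <- agg[agg$block_string == "A-AB", ]
  expect_equal(row2$sd_titer, 0)
  expect_equal(row2$n, 1L)
  expect_false(row2$active)

  # conservation: sum of group means times n equals the replicate total
  expect_equal(sum(agg$mean_titer * agg$n),
               sum(rec$titer_total_mg_per_L))

  # strains kept separate by default, merged on request
  rec2 <- rbind(rec, transform(rec, strain = "other"))
  expect_equal(nrow(aggregate_assays(rec2)), 4L)
  expect_equal(nrow(aggregate_assays(rec2, by_strain = FALSE)), 2L)
})

test_that("function tables round-trip and pattern statistics split means", {
  sys <- small_system(seed = 17, n_blocks = 3, block_len = 4)
  spec <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                         seed = 7)
  sp <- enumerate_space(sys$parents, sys$partition)
  tab <- measure(spec, sp[1:6], n_replicates = 2, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_function_table(tab, path)
  back <- read_function_table(path)
  expect_equal(back$block_string, tab$block_string)
  expect_equal(back$titer_total_mg_per_L, tab$titer_total_mg_per_L)
  expect_error(read_function_table(
    write_function_table(data.frame(x = 1), tempfile(fileext = ".csv"))),
    "missing columns")

  # wildcard pattern stats: constructed table with a known split
  tab2 <- data.frame(
    block_string = c("A-ABA", "A-BBA", "A-ATB", "A-TTT"),
    titer_total_mg_per_L = c(40, 44, 8, 8))
  ps <- block_pattern_stats(tab2, "X-XBX")
  expect_equal(ps$mean_match, 42)
  expect_equal(ps$mean_other, 8)
  expect_equal(ps$n_chimeras_match, 2L)
  expect_equal(ps$n_records, 4L)
})

test_that("the measure -> aggregate -> fit pipeline loses no records", {
  sys <- small_system(seed = 25, n_blocks = 3, block_len = 5)
  spec <- landscape_spec(sys$parents, sys$partition, sys$contact_map,
                         seed = 9)
  sp <- enumerate_space(sys$parents, sys$partition)
  set.seed(1)
  chims <- sample(sp, 10)
  rec <- measure(spec, chims, n_replicates = 3, seed = 2)
  agg <- aggregate_assays(rec, by_strain = FALSE)
  expect_setequal(agg$block_string, chims)
  expect_equal(sum(agg$n), nrow(rec))
  X <- encode_chimeras(agg$block_string, sys$parents, sys$partition)
  fit <- gp_fit(X, agg$mean_titer, 1, 1)
  expect_equal(nrow(fit$X), length(chims))
  cls <- gnb_fit(X, agg$active)
  expect_length(gnb_predict(cls, X), length(chims))
})
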