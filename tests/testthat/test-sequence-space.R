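test_that("chimera strings parse, validate and round-trip", {
  parents <- toy_parents3()
  partition <- toy_partition3(parents)
  ch <- parse_chimera("A-ATB", parents, partition)
  expect_s3_class(ch, "chimera")
  expect_equal(ch$ahr_parent, "A")
  expect_equal(ch$atr_blocks, c("A", "T", "B"))
  expect_equal(format_chimera(ch), "A-ATB")

  # round trip over every member of the full label grid
  grid <- expand.grid(rep(list(parents$names), 3), stringsAsFactors = FALSE)
  all <- paste0("A-", apply(as.matrix(grid), 1, paste, collapse = ""))
  for (s in all) {
    expect_equal(format_chimera(parse_chimera(s, parents, partition)), s)
  }

  expect_error(parse_chimera("A-AXB", parents, partition), "X")
  expect_error(parse_chimera("A-AB", parents, partition), "2")
  expect_error(parse_chimera("AATB", parents, partition), "malformed")
})

test_that("translate inherits blocks from the named parents", {
  parents <- toy_parents3()
  partition <- toy_partition3(parents)

  # identity: all-parental chimeras give back the parent sequences
  expect_equal(translate_chimera("A-AAA", parents, partition)[[1]],
               parents$sequences[1])
  expect_equal(translate_chimera("A-TTT", parents, partition)[[1]],
               paste0("MK", substr(parents$sequences[3], 3, 8)))

  # single block swap differs from parent A exactly at that block's
  # columns where A and B differ (column-by-column oracle)
  tr <- translate_chimera("A-BAA", parents, partition,
                          remove_gaps = FALSE)[[1]]
  a <- strsplit(parents$sequences[1], "")[[1]]
  b <- strsplit(parents$sequences[2], "")[[1]]
  got <- strsplit(tr, "")[[1]]
  expected <- a
  expected[3:4] <- b[3:4]
  expect_equal(got, expected)

  # swapping a block that is conserved between the two parents changes
  # nothing: block 2 of A and B are identical
  expect_equal(translate_chimera("A-ABA", parents, partition),
               translate_chimera("A-AAA", parents, partition),
               ignore_attr = TRUE)
})

test_that("gaps inherited from a parent's block are removed on translate", {
  parents <- parent_set(c(A = "MKAA--GG", B = "MKTTCCGG"), domain_split = 2L)
  partition <- block_partition(5L, parents)
  # block 2 from A carries the gap columns, which vanish from the protein
  expect_equal(translate_chimera("A-AA", parents, partition)[[1]], "MKAAGG")
  expect_equal(translate_chimera("A-AB", parents, partition)[[1]],
               "MKAACCGG")
  expect_equal(nchar(translate_chimera("A-AB", parents, partition,
                                       remove_gaps = FALSE)[[1]]), 8L)
})

test_that("enumerate_space counts distinct proteins and matches brute force", {
  # 2 parents, 2 blocks, all blocks distinct -> 2^2
  p2 <- toy_parents2(); q2 <- toy_partition2(p2)
  expect_length(enumerate_space(p2, q2), 4L)
  expect_equal(enumerate_space(p2, q2), brute_space(p2, q2))

  # 3 parents, one block conserved between two parents, one conserved
  # across all three: 3 * 2 * 1
  p3 <- toy_parents3(); q3 <- toy_partition3(p3)
  sp <- enumerate_space(p3, q3)
  expect_length(sp, 6L)
  expect_equal(sp, brute_space(p3, q3))
  # canonical representatives use the alphabetically smallest label
  expect_true(all(substr(sp, 4, 4) %in% c("A", "T")))  # block 2: A or T
  expect_true(all(substr(sp, 5, 5) == "A"))            # block 3 conserved

  # offering all parents for the fixed domain: toy3 parents share an
  # identical fixed domain, so the options collapse to one
  expect_equal(enumerate_space(p3, q3, ahr_options = p3$names),
               brute_space(p3, q3, ahr_options = p3$names))
  expect_length(enumerate_space(p3, q3, ahr_options = p3$names), 6L)

  # with genuinely distinct fixed domains the count multiplies
  pd <- parent_set(c(A = "QKAAGG", B = "WKCCGG"), domain_split = 2L)
  qd <- block_partition(5L, pd)
  # block 1 has two options, block 2 is conserved: 2 AHR x 2 ATR
  expect_length(enumerate_space(pd, qd, ahr_options = pd$names), 4L)
  expect_equal(enumerate_space(pd, qd, ahr_options = pd$names),
               brute_space(pd, qd, ahr_options = pd$names))

  # random small system agrees with translate-and-deduplicate
  sys <- small_system(seed = 5)
  expect_equal(enumerate_space(sys$parents, sys$partition),
               brute_space(sys$parents, sys$partition))
})

test_that("hamming encoding has the documented geometry", {
  parents <- toy_parents3()
  partition <- toy_partition3(parents)
  sp <- enumerate_space(parents, partition)
  X <- encode_chimeras(sp, parents, partition, scheme = "hamming")

  # feature count = sum of distinct options over variable columns
  census <- sum(vapply(seq_len(parents$aligned_length), function(c) {
    k <- length(unique(parents$seq_mat[, c]))
    if (k >= 2) k else 0L
  }, integer(1)))
  expect_equal(ncol(X), census)

  # dot product of two parents = number of variable columns sharing the
  # same residue option (sequence-identity count oracle)
  xa <- encode_chimeras("A-AAA", parents, partition)[1, ]
  xb <- encode_chimeras("A-BBB", parents, partition)[1, ]
  shared <- sum(vapply(seq_len(parents$aligned_length), function(c) {
    length(unique(parents$seq_mat[, c])) >= 2 &&
      parents$seq_mat["A", c] == parents$seq_mat["B", c]
  }, logical(1)))
  expect_equal(sum(xa * xb), shared)

  # injective on the distinct space; identical at variable columns ->
  # identical encodings
  expect_equal(anyDuplicated(X), 0L)
  x1 <- encode_chimeras("A-ABA", parents, partition)
  x2 <- encode_chimeras("A-AAA", parents, partition)
  expect_equal(unname(x1[1, ]), unname(x2[1, ]))

  # retaining conserved columns adds one always-on feature per column
  Xfull <- encode_chimeras(sp, parents, partition, drop_conserved = FALSE)
  expect_true(all(Xfull[, setdiff(colnames(Xfull), colnames(X))] == 1))
})

test_that("structure and block encodings behave", {
  parents <- toy_parents3()
  partition <- toy_partition3(parents)
  cm <- contact_map(data.frame(i = 3L, j = 5L, weight = 1))
  expect_error(encode_chimeras("A-AAA", parents, partition,
                               scheme = "structure"), "contact_map")
  Xs <- encode_chimeras(c("A-AAA", "A-TAA"), parents, partition,
                        scheme = "structure", contact_map = cm)
  # parental pairs at (3,5): AC, TC, GC -> 3 features; parent rows one-hot
  expect_equal(ncol(Xs), 3L)
  expect_equal(rowSums(Xs), c(`A-AAA` = 1, `A-TAA` = 1))

  Xb <- encode_chimeras(c("A-AAA", "A-TTA"), parents, partition,
                        scheme = "block")
  # block 1 has 3 options, block 2 has 2, block 3 conserved (dropped)
  expect_equal(ncol(Xb), 5L)
  expect_equal(unname(rowSums(Xb)), c(2, 2))
})

test_that("block_distance is the minimum block mismatch over parents", {
  parents <- toy_parents3()
  partition <- toy_partition3(parents)
  expect_equal(block_distance("A-AAA", parents, partition)[[1]], 0L)
  expect_equal(block_distance("A-BBB", parents, partition)[[1]], 0L)
  # conserved blocks count as inherited from either parent
  expect_equal(block_distance("A-ABA", parents, partition)[[1]], 0L)
  expect_equal(block_distance("A-TAA", parents, partition)[[1]], 1L)
  # "A-TTA" is parent T itself once conserved blocks are credited
  expect_equal(block_distance("A-TTA", parents, partition)[[1]], 0L)
  expect_equal(block_distance("A-TBA", parents, partition)[[1]], 1L)

  sys <- small_system(seed = 3)
  sp <- enumerate_space(sys$parents, sys$partition)
  d <- block_distance(sp, sys$parents, sys$partition)
  expect_true(all(d >= 0 & d <= sys$partition$n_blocks))
  # zero exactly for parental chimeras
  expect_equal(sort(names(d[d == 0])),
               sort(parental_chimeras(sys$parents, sys$partition)))
})

test_that("parents and partitions validate and serialize", {
  expect_error(parent_set(c(A = "MKA", B = "MK"), 1L), "identical length")
  expect_error(parent_set(c(A = "MKA", B = "MKV"), 3L), "strictly inside")
  parents <- toy_parents3()
  expect_error(block_partition(c(7L, 5L), parents), "increasing")
  expect_error(block_partition(2L, parents), "inside the recombined")

  partition <- toy_partition3(parents)
  path <- tempfile(fileext = ".json")
  write_partition(partition, path)
  back <- read_partition(path, parents)
  expect_equal(back$breakpoints, partition$breakpoints)
  expect_equal(back$starts, partition$starts)

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">A parent", "MKAACCGG", ">B parent", "MKTTCCGG",
               ">T parent", "MKGGCAGG"), fa)
  rp <- read_parents(fa, domain_split = 2L)
  expect_equal(rp$sequences, parents$sequences, ignore_attr = TRUE)

  # motif-based split: the split lands just before the conserved motif
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "MKLDPDLAA", ">B", "MQLDPDLCC"), fa2)
  rp2 <- read_parents(fa2, split_motif = "LDPDL")
  expect_equal(rp2$domain_split, 2L)
  expect_error(read_parents(fa2, split_motif = "WWW"), "not found")
})
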