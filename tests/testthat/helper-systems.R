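# Shared toy systems for the test suite. Everything is built in code at
# test time; no fixture files.

# Hand-crafted three-parent toy: 2 fixed-domain columns + 3 blocks of 2
# columns. Block 2 is conserved between A and B; block 3 is conserved
# across all three parents.
toy_parents3 <- function() {
  parent_set(c(A = "MKAACCGG",
               B = "MKTTCCGG",
               T = "MKGGCAGG"), domain_split = 2L)
}

toy_partition3 <- function(parents = toy_parents3()) {
  block_partition(c(5L, 7L), parents)
}

# Two-parent toy with every block distinct.
toy_parents2 <- function() {
  parent_set(c(A = "MAAQQ", B = "MCCWW"), domain_split = 1L)
}

toy_partition2 <- function(parents = toy_parents2()) {
  block_partition(3L, parents)
}

# Small random system reusing the synthetic generator.
small_system <- function(seed = 1, n_blocks = 3, block_len = 4,
                         n_ahr = 4, n_contacts = 30) {
  synthetic_system(seed = seed, n_ahr = n_ahr, block_len = block_len,
                   n_blocks = n_blocks, n_contacts = n_contacts)
}

# Brute-force enumeration oracle: all label combinations, translated and
# deduplicated on protein sequence, keeping the alphabetically smallest
# block string per protein.
brute_space <- function(parents, partition,
                        ahr_options = parents$names[1L]) {
  combos <- expand.grid(rep(list(parents$names), partition$n_blocks),
                        stringsAsFactors = FALSE)
  all <- as.vector(outer(
    ahr_options,
    apply(as.matrix(combos), 1L, paste, collapse = ""),
    function(a, b) paste0(a, "-", b)))
  prot <- translate_chimera(all, parents, partition)
  keep <- tapply(all, prot, function(x) sort(x)[1L])
  sort(unname(keep))
}

# Independent per-contact SCHEMA energy: iterate contacts on the
# translated (aligned) chimera sequence and check co-occurrence in any
# single parent.
brute_schema_E <- function(chimera, parents, partition, cm) {
  s <- strsplit(translate_chimera(chimera, parents, partition,
                                  remove_gaps = FALSE)[[1L]], "")[[1L]]
  tot <- 0
  for (k in seq_len(nrow(cm))) {
    i <- cm$i[k]; j <- cm$j[k]
    intact <- any(vapply(parents$names, function(p) {
      parents$seq_mat[p, i] == s[i] && parents$seq_mat[p, j] == s[j]
    }, logical(1)))
    if (!intact) tot <- tot + cm$weight[k]
  }
  tot
}
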