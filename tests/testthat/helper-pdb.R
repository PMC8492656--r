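# Build small PDB files in code for contact-map and interface tests.

# atoms: data.frame(resno, chain, name, elem, x, y, z)
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(k) {
    a <- atoms[k, ]
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            k, substr(paste0(" ", a$name), 1, 4), "ALA", a$chain, a$resno,
            a$x, a$y, a$z, 1, 0, a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# n residues on a jittered line, `atoms_per_res` heavy atoms each.
random_toy_atoms <- function(n_res = 10, atoms_per_res = 3, spacing = 4,
                             jitter = 2, chain = "A") {
  out <- list()
  for (r in seq_len(n_res)) {
    for (a in seq_len(atoms_per_res)) {
      out[[length(out) + 1L]] <- data.frame(
        resno = r, chain = chain,
        name = c("N", "CA", "C")[((a - 1L) %% 3L) + 1L], elem = "C",
        x = r * spacing + stats::runif(1, -jitter, jitter),
        y = stats::runif(1, -jitter, jitter),
        z = stats::runif(1, -jitter, jitter))
    }
  }
  do.call(rbind, out)
}

# Brute-force residue contact oracle on an atom table.
brute_contacts <- function(atoms, cutoff, min_seq_sep = 2) {
  res <- sort(unique(atoms$resno))
  hits <- list()
  for (ii in seq_along(res)) for (jj in seq_along(res)) {
    i <- res[ii]; j <- res[jj]
    if (j - i < min_seq_sep) next
    ai <- atoms[atoms$resno == i, c("x", "y", "z")]
    aj <- atoms[atoms$resno == j, c("x", "y", "z")]
    mind <- min(apply(ai, 1, function(p) {
      sqrt(colSums((t(aj) - as.numeric(p))^2))
    }))
    if (mind <= cutoff) hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) return(data.frame(i = integer(), j = integer()))
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("i", "j")
  out[order(out$i, out$j), , drop = FALSE]
}
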