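#' Parent set: aligned parental sequences and the domain split
#'
#' Bundles the aligned parent sequences that donate sequence blocks to a
#' recombination library. Sequences must come from a single multiple
#' alignment (equal length, gaps allowed). The alignment is divided into an
#' N-terminal domain (kept intact, e.g. an aldehyde reductase domain) and a
#' C-terminal domain that is recombined (e.g. an acyl-thioester reductase
#' domain); `domain_split` gives the number of alignment columns belonging
#' to the N-terminal domain.
#'
#' All alignment columns are 1-based inside R; serialized interchange files
#' (JSON/TSV) use 0-based, half-open coordinates.
#'
#' @param sequences named character vector of aligned amino-acid sequences
#'   (names are single-letter parent labels, e.g. `A`, `B`, `T`).
#' @param domain_split integer, number of alignment columns in the fixed
#'   N-terminal domain; must lie strictly inside the alignment.
#' @return an object of class `parent_set` with elements `names`,
#'   `sequences`, `seq_mat` (parents x columns character matrix),
#'   `domain_split`, `aligned_length`.
#' @export
parent_set <- function(sequences, domain_split) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("parent sequences must be named with single-character labels")
  }
  labels <- names(sequences)
  if (any(nchar(labels) != 1L)) {
    stop("parent labels must be single characters, got: ",
         paste(labels[nchar(labels) != 1L], collapse = ", "))
  }
  if (anyDuplicated(labels)) stop("duplicate parent labels")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have identical length; got lengths ",
         paste(lens, collapse = ", "))
  }
  L <- lens[[1L]]
  domain_split <- as.integer(domain_split)
  if (domain_split < 1L || domain_split >= L) {
    stop("domain_split must lie strictly inside the alignment (1..",
         L - 1L, ")")
  }
  seq_mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(seq_mat) <- labels
  structure(
    list(names = labels, sequences = as.character(sequences),
         seq_mat = seq_mat, domain_split = domain_split,
         aligned_length = L),
    class = "parent_set"
  )
}

#' @export
print.parent_set <- function(x, ...) {
  cat("parent_set:", length(x$names), "parents (",
      paste(x$names, collapse = ", "), "), aligned length",
      x$aligned_length, ", domain split after column", x$domain_split, "\n")
  invisible(x)
}

#' Read aligned parents from a FASTA alignment
#'
#' Reads an aligned FASTA file (>= 2 records) and builds a [parent_set].
#' Record names are truncated to their first character, which becomes the
#' parent label.
#'
#' @param path FASTA file of aligned sequences.
#' @param domain_split see [parent_set()]; if `NULL`, `split_motif` is used.
#' @param split_motif optional ungapped amino-acid motif (e.g. `"LDPDL"`)
#'   conserved across parents; the domain split is placed immediately
#'   before the motif's first alignment column.
#' @export
read_parents <- function(path, domain_split = NULL, split_motif = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) < 2L) stop("alignment must contain at least 2 records")
  seqs <- as.character(aln)
  names(seqs) <- substr(sub("\\s.*$", "", names(aln)), 1L, 1L)
  if (is.null(domain_split)) {
    if (is.null(split_motif)) {
      stop("either domain_split or split_motif must be given")
    }
    domain_split <- locate_split_motif(seqs, split_motif)
  }
  parent_set(seqs, domain_split)
}

# Find the first alignment column of a conserved motif shared by all
# parents; the split is placed just before it.
locate_split_motif <- function(seqs, motif) {
  hits <- vapply(seqs, function(s) {
    cols <- which(strsplit(s, "")[[1L]] != "-")
    ungapped <- gsub("-", "", s)
    at <- regexpr(motif, ungapped, fixed = TRUE)
    if (at < 0L) return(NA_integer_)
    cols[[at]]
  }, integer(1))
  if (anyNA(hits)) stop("motif '", motif, "' not found in every parent")
  if (length(unique(hits)) != 1L) {
    stop("motif '", motif, "' does not align to a single column across parents")
  }
  hits[[1L]] - 1L
}

#' Block partition of the recombined domain
#'
#' Describes how the C-terminal (recombined) region of the alignment is cut
#' into contiguous sequence blocks. `breakpoints` are the 1-based alignment
#' columns at which new blocks begin (the starts of blocks 2..n); the
#' blocks tile the recombined region exactly.
#'
#' @param breakpoints strictly increasing integer columns, each strictly
#'   inside the recombined region.
#' @param parents the [parent_set] the partition applies to.
#' @return object of class `block_partition` with `breakpoints`,
#'   `n_blocks`, `starts`, `ends` (inclusive block bounds) and
#'   `domain_split`.
#' @export
block_partition <- function(breakpoints, parents) {
  stopifnot(inherits(parents, "parent_set"))
  breakpoints <- as.integer(breakpoints)
  L <- parents$aligned_length
  atr_start <- parents$domain_split + 1L
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE)) {
      stop("breakpoints must be strictly increasing")
    }
    if (breakpoints[1L] <= atr_start || breakpoints[length(breakpoints)] > L) {
      stop("breakpoints must lie strictly inside the recombined region (",
           atr_start + 1L, "..", L, ")")
    }
  }
  starts <- c(atr_start, breakpoints)
  ends <- c(breakpoints - 1L, L)
  structure(
    list(breakpoints = breakpoints, n_blocks = length(breakpoints) + 1L,
         starts = starts, ends = ends, domain_split = parents$domain_split,
         aligned_length = L),
    class = "block_partition"
  )
}

#' @export
print.block_partition <- function(x, ...) {
  cat("block_partition:", x$n_blocks, "blocks over columns",
      x$starts[1L], "-", x$aligned_length, "\n")
  for (b in seq_len(x$n_blocks)) {
    cat(sprintf("  block %d: columns %d-%d\n", b, x$starts[b], x$ends[b]))
  }
  invisible(x)
}

#' Write / read a block partition as JSON
#'
#' The interchange format uses 0-based half-open coordinates:
#' `{"breakpoints": [...], "domain_split": ...}` where `domain_split` is
#' the 0-based column at which the recombined region starts and each
#' breakpoint is the 0-based first column of a block.
#'
#' @param partition a [block_partition].
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(
    list(breakpoints = partition$breakpoints - 1L,
         domain_split = partition$domain_split,
         aligned_length = partition$aligned_length),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_partition
#' @param parents the [parent_set] the partition applies to.
#' @export
read_partition <- function(path, parents) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$domain_split) &&
      as.integer(obj$domain_split) != parents$domain_split) {
    stop("partition file domain_split (", obj$domain_split,
         ") disagrees with parents (", parents$domain_split, ")")
  }
  block_partition(as.integer(obj$breakpoints) + 1L, parents)
}

#' Parse a chimera block string
#'
#' A chimera is written `"<ahr>-<blocks>"`, e.g. `"A-ATBBAAAB"`: the letter
#' before the dash names the parent donating the intact N-terminal domain,
#' the letters after it name the parent donating each recombined block in
#' order.
#'
#' @param text block string.
#' @param parents a [parent_set] giving the allowed labels.
#' @param partition a [block_partition] giving the block count.
#' @return list of class `chimera` with `ahr_parent` and `atr_blocks`.
#' @export
parse_chimera <- function(text, parents, partition) {
  stopifnot(length(text) == 1L, is.character(text))
  parts <- strsplit(text, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || nchar(parts[1L]) != 1L) {
    stop("malformed chimera string '", text,
         "': expected '<label>-<", partition$n_blocks, " labels>'")
  }
  blocks <- strsplit(parts[2L], "")[[1L]]
  if (length(blocks) != partition$n_blocks) {
    stop("chimera '", text, "' has ", length(blocks),
         " block labels; expected ", partition$n_blocks)
  }
  labs <- c(parts[1L], blocks)
  bad <- setdiff(labs, parents$names)
  if (length(bad)) {
    stop("unknown parent label '", bad[[1L]], "' in chimera '", text, "'")
  }
  structure(list(ahr_parent = parts[1L], atr_blocks = blocks),
            class = "chimera")
}

#' @rdname parse_chimera
#' @param chimera a `chimera` object.
#' @export
format_chimera <- function(chimera) {
  paste0(chimera$ahr_parent, "-", paste(chimera$atr_blocks, collapse = ""))
}

#' @export
print.chimera <- function(x, ...) {
  cat("chimera", format_chimera(x), "\n")
  invisible(x)
}

# Label matrix for a vector of block strings: n x (1 + n_blocks) characters,
# validated against the parent alphabet.
chimera_label_matrix <- function(chimeras, parents, partition) {
  n_blocks <- partition$n_blocks
  ok <- grepl(paste0("^[A-Za-z]-[A-Za-z]{", n_blocks, "}$"), chimeras)
  if (!all(ok)) {
    stop("malformed chimera string '", chimeras[!ok][[1L]], "'")
  }
  labs <- do.call(rbind, strsplit(gsub("-", "", chimeras), ""))
  bad <- setdiff(unique(as.vector(labs)), parents$names)
  if (length(bad)) stop("unknown parent label '", bad[[1L]], "'")
  rownames(labs) <- chimeras
  labs
}

# Segment id of every alignment column: 0 = fixed N-terminal domain,
# 1..n_blocks = recombined blocks.
column_segments <- function(partition) {
  seg <- integer(partition$aligned_length)
  for (b in seq_len(partition$n_blocks)) {
    seg[partition$starts[b]:partition$ends[b]] <- b
  }
  seg
}

# Residue matrix (n_chimeras x aligned_length) for a vector of block
# strings; each column's residue is inherited from the donating parent.
chimera_residues <- function(chimeras, parents, partition) {
  labs <- chimera_label_matrix(chimeras, parents, partition)
  seg <- column_segments(partition)
  pidx <- matrix(match(labs[, seg + 1L, drop = FALSE], parents$names),
                 nrow = nrow(labs))
  L <- partition$aligned_length
  res <- matrix(parents$seq_mat[cbind(as.vector(pidx),
                                      rep(seq_len(L), each = nrow(labs)))],
                nrow = nrow(labs))
  rownames(res) <- chimeras
  res
}

#' Translate a chimera into its protein sequence
#'
#' Builds the amino-acid sequence of a chimera by inheriting the fixed
#' N-terminal domain from its first-position parent and each recombined
#' block from the parent named at that block. Gap characters inherited from
#' the donating parent are removed by default, yielding the actual
#' construct sequence.
#'
#' @param chimeras character vector of block strings.
#' @inheritParams parse_chimera
#' @param remove_gaps drop alignment gaps from the output (default TRUE).
#' @return character vector of protein sequences, named by block string.
#' @export
translate_chimera <- function(chimeras, parents, partition,
                              remove_gaps = TRUE) {
  res <- chimera_residues(chimeras, parents, partition)
  out <- apply(res, 1L, paste, collapse = "")
  if (remove_gaps) out <- gsub("-", "", out)
  stats::setNames(out, chimeras)
}

# Per-block label groups: parents donating identical block sequences are
# collapsed; representative = alphabetically smallest label. Returns, for
# each block, a named character vector mapping label -> representative.
block_label_groups <- function(parents, partition) {
  lapply(seq_len(partition$n_blocks), function(b) {
    cols <- partition$starts[b]:partition$ends[b]
    frag <- apply(parents$seq_mat[, cols, drop = FALSE], 1L, paste,
                  collapse = "")
    reps <- vapply(frag, function(f) {
      min(parents$names[frag == f])
    }, character(1))
    stats::setNames(reps, parents$names)
  })
}

# Canonicalize block strings: replace each block label by its group
# representative so that protein-identical chimeras share one name.
canonical_chimeras <- function(chimeras, parents, partition) {
  labs <- chimera_label_matrix(chimeras, parents, partition)
  groups <- block_label_groups(parents, partition)
  for (b in seq_len(partition$n_blocks)) {
    labs[, b + 1L] <- groups[[b]][labs[, b + 1L]]
  }
  paste0(labs[, 1L], "-",
         apply(labs[, -1L, drop = FALSE], 1L, paste, collapse = ""))
}

#' Enumerate the distinct chimeric sequence space
#'
#' Enumerates one canonical representative per distinct protein sequence.
#' Parents donating an identical block sequence are collapsed for that
#' block (their chimeras translate to the same protein); the canonical
#' representative uses the alphabetically smallest label.
#'
#' @inheritParams parse_chimera
#' @param ahr_options parent labels offered for the fixed N-terminal
#'   domain; defaults to the first parent only, matching a library in which
#'   that domain is not recombined.
#' @return character vector of canonical block strings, sorted.
#' @export
enumerate_space <- function(parents, partition,
                            ahr_options = parents$names[1L]) {
  stopifnot(all(ahr_options %in% parents$names))
  groups <- block_label_groups(parents, partition)
  opts <- lapply(groups, function(g) sort(unique(unname(g))))
  # parents with identical fixed-domain sequences collapse as well
  ahr_cols <- seq_len(parents$domain_split)
  ahr_seq <- apply(parents$seq_mat[, ahr_cols, drop = FALSE], 1L, paste,
                   collapse = "")
  ahr_reps <- vapply(ahr_options, function(p) {
    cand <- parents$names[ahr_seq == ahr_seq[[p]]]
    min(intersect(cand, ahr_options))
  }, character(1))
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)[, rev(seq_along(opts)), drop = FALSE]
  atr <- apply(as.matrix(grid), 1L, paste, collapse = "")
  out <- as.vector(outer(sort(unique(ahr_reps)), atr,
                         function(a, b) paste0(a, "-", b)))
  sort(out)
}

#' Block distance to the closest parent
#'
#' Number of recombined blocks not inherited from a parent, minimized over
#' parents. Blocks whose sequence is conserved between parents count as
#' inherited from either. Zero exactly for parental chimeras.
#'
#' @param chimeras character vector of block strings.
#' @inheritParams parse_chimera
#' @return integer vector.
#' @export
block_distance <- function(chimeras, parents, partition) {
  labs <- chimera_label_matrix(chimeras, parents, partition)
  groups <- block_label_groups(parents, partition)
  reps <- labs[, -1L, drop = FALSE]
  for (b in seq_len(partition$n_blocks)) {
    reps[, b] <- groups[[b]][labs[, b + 1L]]
  }
  d <- vapply(parents$names, function(p) {
    prep <- vapply(seq_len(partition$n_blocks),
                   function(b) groups[[b]][[p]], character(1))
    rowSums(reps != matrix(prep, nrow(reps), ncol(reps), byrow = TRUE))
  }, numeric(nrow(labs)))
  d <- apply(matrix(d, nrow = nrow(labs)), 1L, min)
  stats::setNames(as.integer(d), chimeras)
}

#' Parental chimeras of a library
#'
#' @inheritParams parse_chimera
#' @param ahr_parent label donating the fixed N-terminal domain.
#' @export
parental_chimeras <- function(parents, partition,
                              ahr_parent = parents$names[1L]) {
  canonical_chimeras(
    paste0(ahr_parent, "-",
           vapply(parents$names, function(p) {
             paste(rep(p, partition$n_blocks), collapse = "")
           }, character(1))),
    parents, partition
  )
}

#' One-hot encode chimeras for kernel models
#'
#' Three schemes are offered. `hamming` places one 0/1 indicator per
#' distinct parental residue option at each alignment column (the one-hot
#' encoding behind the Hamming kernel). `structure` places one indicator
#' per parental residue-pair combination at each contacting column pair of
#' a [contact_map]. `block` is a coarse per-block label one-hot.
#' Columns conserved across all parents carry no information for a linear
#' kernel and are dropped unless `drop_conserved = FALSE`, which retains
#' one always-on feature per conserved column.
#'
#' @param chimeras character vector of block strings.
#' @inheritParams parse_chimera
#' @param scheme `"hamming"`, `"structure"` or `"block"`.
#' @param contact_map required for `scheme = "structure"`.
#' @param drop_conserved drop invariant columns (default TRUE).
#' @return numeric 0/1 matrix, rows named by chimera, with attributes
#'   `scheme` and `feature_index` (a data.frame describing every feature).
#' @export
encode_chimeras <- function(chimeras, parents, partition,
                            scheme = c("hamming", "structure", "block"),
                            contact_map = NULL, drop_conserved = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "structure" && is.null(contact_map)) {
    stop("scheme = 'structure' requires a contact_map")
  }
  switch(scheme,
    hamming = encode_hamming(chimeras, parents, partition, drop_conserved),
    structure = encode_structure(chimeras, parents, partition, contact_map),
    block = encode_block(chimeras, parents, partition)
  )
}

encode_hamming <- function(chimeras, parents, partition, drop_conserved) {
  res <- chimera_residues(chimeras, parents, partition)
  L <- partition$aligned_length
  feats <- list()
  for (col in seq_len(L)) {
    opts <- sort(unique(parents$seq_mat[, col]))
    if (drop_conserved && length(opts) < 2L) next
    feats[[length(feats) + 1L]] <- data.frame(
      column = col, option = opts, stringsAsFactors = FALSE)
  }
  fidx <- do.call(rbind, feats)
  X <- matrix(0, nrow(res), nrow(fidx),
              dimnames = list(chimeras, paste0("c", fidx$column, ".",
                                               fidx$option)))
  for (f in seq_len(nrow(fidx))) {
    X[, f] <- as.numeric(res[, fidx$column[f]] == fidx$option[f])
  }
  structure(X, scheme = "hamming", feature_index = fidx)
}

encode_structure <- function(chimeras, parents, partition, contact_map) {
  res <- chimera_residues(chimeras, parents, partition)
  cm <- as.data.frame(contact_map)
  feats <- list()
  for (k in seq_len(nrow(cm))) {
    pairs <- unique(paste0(parents$seq_mat[, cm$i[k]],
                           parents$seq_mat[, cm$j[k]]))
    feats[[k]] <- data.frame(i = cm$i[k], j = cm$j[k], pair = sort(pairs),
                             stringsAsFactors = FALSE)
  }
  fidx <- do.call(rbind, feats)
  X <- matrix(0, nrow(res), nrow(fidx),
              dimnames = list(chimeras,
                              paste0("p", fidx$i, ".", fidx$j, ".", fidx$pair)))
  obs <- matrix(paste0(res[, fidx$i], res[, fidx$j]), nrow = nrow(res))
  for (f in seq_len(nrow(fidx))) {
    X[, f] <- as.numeric(obs[, f] == fidx$pair[f])
  }
  structure(X, scheme = "structure", feature_index = fidx)
}

encode_block <- function(chimeras, parents, partition) {
  labs <- chimera_label_matrix(chimeras, parents, partition)
  groups <- block_label_groups(parents, partition)
  feats <- list()
  for (b in seq_len(partition$n_blocks)) {
    reps <- sort(unique(unname(groups[[b]])))
    if (length(reps) < 2L) next
    feats[[length(feats) + 1L]] <- data.frame(
      block = b, option = reps, stringsAsFactors = FALSE)
  }
  fidx <- do.call(rbind, feats)
  X <- matrix(0, nrow(labs), nrow(fidx),
              dimnames = list(chimeras, paste0("b", fidx$block, ".",
                                               fidx$option)))
  for (f in seq_len(nrow(fidx))) {
    b <- fidx$block[f]
    X[, f] <- as.numeric(groups[[b]][labs[, b + 1L]] == fidx$option[f])
  }
  structure(X, scheme = "block", feature_index = fidx)
}
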