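#' Ensemble-weighted residue contact map
#'
#' A contact map records which residue pairs are in physical contact in a
#' structural ensemble, with each contact weighted by the fraction of
#' models in which it appears. Contacts are stored on alignment columns
#' (1-based in R; serialized 0-based).
#'
#' @param contacts data.frame with integer columns `i`, `j` (i < j) and
#'   numeric `weight` in (0, 1].
#' @param cutoff_angstrom distance threshold used (default 4.5).
#' @param n_models ensemble size the weights refer to.
#' @return object of class `contact_map` (a data.frame with attributes).
#' @export
contact_map <- function(contacts, cutoff_angstrom = 4.5, n_models = 1L) {
  stopifnot(all(c("i", "j", "weight") %in% names(contacts)))
  contacts <- as.data.frame(contacts)[, c("i", "j", "weight")]
  if (any(contacts$i >= contacts$j)) stop("contacts require i < j")
  if (anyDuplicated(contacts[, c("i", "j")])) {
    stop("duplicate (i, j) contact pairs")
  }
  if (any(contacts$weight <= 0 | contacts$weight > 1)) {
    stop("contact weights must lie in (0, 1]")
  }
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(contacts, cutoff_angstrom = cutoff_angstrom,
            n_models = as.integer(n_models),
            class = c("contact_map", "data.frame"))
}

# Heavy-atom coordinates of one model: data.frame(resno, x, y, z).
# Accepts a bio3d pdb object or a file path. Hydrogens and alternate
# conformers beyond the first are discarded.
model_atoms <- function(model, chain = NULL) {
  if (is.character(model)) model <- bio3d::read.pdb(model, verbose = FALSE)
  at <- model$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elt <- ifelse(is.na(at$elesy) | at$elesy == "",
                substr(gsub("[0-9]", "", at$elety), 1L, 1L),
                at$elesy)
  at <- at[toupper(elt) != "H", , drop = FALSE]
  data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z)
}

# All residue pairs with any-atom distance <= cutoff in one model.
# Returns a character vector "resno_i:resno_j" with i < j.
residue_contact_pairs <- function(atoms, cutoff, min_seq_sep) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  ri <- atoms$resno[hit[, 1L]]
  rj <- atoms$resno[hit[, 2L]]
  keep <- (rj - ri) >= min_seq_sep
  if (!any(keep)) return(character(0))
  unique(paste0(ri[keep], ":", rj[keep]))
}

#' Build a contact map from an ensemble of structural models
#'
#' Two residues are in contact when any pair of their heavy atoms lies
#' within `cutoff` angstroms. Each contact is weighted by the fraction of
#' ensemble models in which it is present. Residue numbers are mapped to
#' alignment columns through the modeled parent's gap pattern
#' (`column_map`); sequence-adjacent pairs carry no recombination signal
#' and are excluded via `min_seq_sep`.
#'
#' @param models list of bio3d `pdb` objects or PDB file paths.
#' @param cutoff contact distance threshold in angstroms (default 4.5).
#' @param column_map optional integer vector mapping residue number ->
#'   alignment column; built with [residue_column_map()]. Identity when
#'   `NULL`.
#' @param min_seq_sep minimum |i - j| (on residue numbers) for a pair to
#'   count; default 2 excludes bonded neighbours.
#' @param chain restrict to one chain id, or `NULL` for all.
#' @return a [contact_map].
#' @export
compute_contact_map <- function(models, cutoff = 4.5, column_map = NULL,
                                min_seq_sep = 2L, chain = NULL) {
  if (!length(models)) stop("empty model ensemble")
  counts <- new.env(parent = emptyenv())
  for (m in models) {
    atoms <- model_atoms(m, chain = chain)
    for (p in residue_contact_pairs(atoms, cutoff, min_seq_sep)) {
      counts[[p]] <- (if (is.null(counts[[p]])) 0L else counts[[p]]) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(contact_map(data.frame(i = integer(), j = integer(),
                                  weight = numeric()),
                       cutoff_angstrom = cutoff, n_models = length(models)))
  }
  ij <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
  if (!is.null(column_map)) {
    if (anyNA(column_map[i]) || anyNA(column_map[j])) {
      stop("residue numbers not mappable to alignment columns")
    }
    i <- column_map[i]; j <- column_map[j]
  }
  w <- vapply(keys, function(k) counts[[k]], integer(1)) / length(models)
  contact_map(data.frame(i = i, j = j, weight = unname(w)),
              cutoff_angstrom = cutoff, n_models = length(models))
}

#' Map residue numbers of one parent's structure to alignment columns
#'
#' The structure is assumed to be of a single parent; its residue `k` is
#' the parent's k-th non-gap alignment column.
#'
#' @param parents a [parent_set].
#' @param label which parent is modeled.
#' @return integer vector: `map[resno] == alignment column`.
#' @export
residue_column_map <- function(parents, label) {
  row <- parents$seq_mat[label, ]
  which(row != "-")
}

#' Serialize a contact map
#'
#' TSV columns `i`, `j`, `weight` with 0-based column indices.
#' @param cm a [contact_map].
#' @param path output file.
#' @export
write_contact_map <- function(cm, path) {
  out <- as.data.frame(cm)
  out$i <- out$i - 1L; out$j <- out$j - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @param cutoff_angstrom,n_models metadata restored on read.
#' @export
read_contact_map <- function(path, cutoff_angstrom = 4.5, n_models = 1L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  tab$i <- tab$i + 1L; tab$j <- tab$j + 1L
  contact_map(tab, cutoff_angstrom = cutoff_angstrom, n_models = n_models)
}

#' Select enzyme residues at a binding interface
#'
#' Returns every enzyme residue having at least one heavy atom within
#' `radius` angstroms of any heavy atom of the partner chain in a docked
#' complex.
#'
#' @param complex a bio3d `pdb` object or PDB path of the docked complex.
#' @param enzyme_chain,partner_chain chain identifiers.
#' @param radius selection radius in angstroms (default 10).
#' @param column_map optional residue-number -> alignment-column map.
#' @return object of class `interface_set`: list with `positions` (sorted
#'   integer columns), `radius_angstrom`, `partner_chain`.
#' @export
select_interface <- function(complex, enzyme_chain, partner_chain,
                             radius = 10, column_map = NULL) {
  if (is.character(complex)) {
    complex <- bio3d::read.pdb(complex, verbose = FALSE)
  }
  chains <- unique(complex$atom$chain)
  if (!enzyme_chain %in% chains) stop("missing chain id '", enzyme_chain, "'")
  if (!partner_chain %in% chains) stop("missing chain id '", partner_chain, "'")
  enz <- model_atoms(complex, chain = enzyme_chain)
  par <- model_atoms(complex, chain = partner_chain)
  exyz <- as.matrix(enz[, c("x", "y", "z")])
  pxyz <- as.matrix(par[, c("x", "y", "z")])
  d2 <- outer(rowSums(exyz^2), rowSums(pxyz^2), "+") - 2 * exyz %*% t(pxyz)
  near <- apply(d2, 1L, min) <= radius^2 + 1e-9
  pos <- sort(unique(enz$resno[near]))
  if (!is.null(column_map)) pos <- sort(column_map[pos])
  structure(list(positions = pos, radius_angstrom = radius,
                 partner_chain = partner_chain),
            class = "interface_set")
}

#' @rdname select_interface
#' @param x an `interface_set`.
#' @param path JSON file path.
#' @export
write_interface <- function(x, path) {
  jsonlite::write_json(list(positions = x$positions - 1L,
                            radius_angstrom = x$radius_angstrom,
                            partner_chain = x$partner_chain),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname select_interface
#' @export
read_interface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(positions = as.integer(obj$positions) + 1L,
                 radius_angstrom = obj$radius_angstrom,
                 partner_chain = obj$partner_chain),
            class = "interface_set")
}

#' Net charge of interface residues
#'
#' Number of positively charged residues (K, R; optionally H) minus the
#' number of negatively charged residues (D, E) at the interface positions
#' of a sequence. Histidine is neutral by default.
#'
#' @param sequence amino-acid string, indexed by the interface positions
#'   (an aligned sequence when positions are alignment columns).
#' @param interface an `interface_set` or integer position vector.
#' @param count_his_positive count H as +1 (default FALSE).
#' @return integer net charge.
#' @export
net_interface_charge <- function(sequence, interface,
                                 count_his_positive = FALSE) {
  pos <- if (inherits(interface, "interface_set")) interface$positions
         else as.integer(interface)
  if (!length(pos)) return(0L)
  chars <- strsplit(sequence, "")[[1L]]
  if (any(pos < 1L | pos > length(chars))) {
    stop("interface positions outside sequence bounds")
  }
  aa <- chars[pos]
  positive <- c("K", "R", if (count_his_positive) "H")
  sum(aa %in% positive) - sum(aa %in% c("D", "E"))
}

#' Correlate interface charge with measured titer
#'
#' Computes each chimera's net interface charge (on aligned coordinates)
#' and the Pearson correlation between charge and mean total titer.
#'
#' @param table a sequence-function table (see [aggregate_assays()] /
#'   [read_function_table()]), one or more rows per chimera.
#' @param interface an `interface_set` on alignment columns.
#' @param parents a [parent_set].
#' @param partition a [block_partition].
#' @param count_his_positive see [net_interface_charge()].
#' @return list with `r` (Pearson coefficient, `NA` with a warning when the
#'   correlation is undefined) and `data` (chimera, charge, mean_titer).
#' @export
charge_titer_correlation <- function(table, interface, parents, partition,
                                     count_his_positive = FALSE) {
  titers <- tapply(table$titer_total_mg_per_L, table$block_string, mean)
  chim <- names(titers)
  if (length(chim) < 3L) stop("need titers for at least 3 chimeras")
  aligned <- translate_chimera(chim, parents, partition, remove_gaps = FALSE)
  charge <- vapply(aligned, net_interface_charge, integer(1),
                   interface = interface,
                   count_his_positive = count_his_positive)
  dat <- data.frame(block_string = chim, charge = as.integer(charge),
                    mean_titer = as.numeric(titers), row.names = NULL)
  r <- if (stats::var(dat$charge) == 0 || stats::var(dat$mean_titer) == 0) {
    warning("correlation undefined: zero variance in charge or titer")
    NA_real_
  } else {
    stats::cor(dat$charge, dat$mean_titer)
  }
  list(r = r, data = dat)
}
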