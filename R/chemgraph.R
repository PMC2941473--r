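#' Graph-level structure consistency check
#'
#' Checks a parsed structure at graph level: connected-component count
#' (multi-molecule inputs are flagged), atoms whose explicit bond-order
#' sum exceeds their maximal default valence plus the charge allowance,
#' and the degenerate empty graph. Findings are warnings, never errors:
#' the prediction workflow reports them and lets the caller decide
#' whether to continue.
#'
#' @param g an `mt_graph`.
#' @return a list of class `mt_structure_report`: `components`,
#'   `warnings` (character vector, possibly empty) and `ok`
#'   (`TRUE` when no warnings).
#' @export
check_structure <- function(g) {
  stopifnot(inherits(g, "mt_graph"))
  warnings <- character(0)
  if (nrow(g$atoms) == 0L) {
    warnings <- c(warnings, "empty structure (no atoms)")
  }
  if (g$components > 1L) {
    warnings <- c(warnings, sprintf(
      "input contains %d disconnected molecules", g$components))
  }
  bondsum <- numeric(nrow(g$atoms))
  for (k in seq_len(nrow(g$bonds))) {
    bondsum[g$bonds$a[k]] <- bondsum[g$bonds$a[k]] + g$bonds$order[k]
    bondsum[g$bonds$b[k]] <- bondsum[g$bonds$b[k]] + g$bonds$order[k]
  }
  for (j in seq_len(nrow(g$atoms))) {
    el <- g$atoms$element[j]
    allowed <- max(DEFAULT_VALENCES[[el]]) + abs(g$atoms$charge[j])
    bs <- ceiling(bondsum[j]) + g$atoms$implicit_h[j]
    if (bs > allowed) {
      warnings <- c(warnings, sprintf(
        "valence warning: atom %d (%s) has bond-order sum %d > allowed %d",
        j, el, bs, allowed))
    }
  }
  structure(list(components = g$components, warnings = warnings,
                 ok = length(warnings) == 0L),
            class = "mt_structure_report")
}

#' @export
print.mt_structure_report <- function(x, ...) {
  cat(sprintf("Structure check: %d component(s), %d warning(s)\n",
              x$components, length(x$warnings)))
  for (w in x$warnings) cat(" -", w, "\n")
  invisible(x)
}

#' Physico-chemical descriptors of a molecular graph
#'
#' Computes the six fixed descriptors: molecular weight `MW` (g/mol,
#' implicit hydrogens included, standard atomic weights to 3 decimals),
#' `HeavyAtoms` (non-hydrogen atom count), `Rings` (cyclomatic ring count
#' = bonds - atoms + components), `AromaticAtoms`, `HBD` (N or O bearing
#' at least one hydrogen, Lipinski-style) and `HBA` (count of N and O
#' atoms).
#'
#' @param g a non-empty `mt_graph`.
#' @return a named numeric vector with the six descriptor names.
#' @examples
#' molecular_descriptors(parse_smiles("CCO"))[["MW"]]  # 46.069
#' @export
molecular_descriptors <- function(g) {
  stopifnot(inherits(g, "mt_graph"))
  if (nrow(g$atoms) == 0L) mt_abort("empty graph has no descriptors", "mt_graph_error")
  at <- g$atoms
  mw <- sum(ATOMIC_MASSES[at$element]) + sum(at$implicit_h) * ATOMIC_MASSES[["H"]]
  # explicit H neighbours also count toward donor status
  h_nbrs <- integer(nrow(at))
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    if (at$element[b] == "H") h_nbrs[a] <- h_nbrs[a] + 1L
    if (at$element[a] == "H") h_nbrs[b] <- h_nbrs[b] + 1L
  }
  is_no <- at$element %in% c("N", "O")
  c(
    MW = unname(mw),
    HeavyAtoms = sum(at$element != "H"),
    Rings = nrow(g$bonds) - nrow(at) + g$components,
    AromaticAtoms = sum(at$aromatic),
    HBD = sum(is_no & (at$implicit_h + h_nbrs) >= 1L),
    HBA = sum(is_no)
  )
}

DESCRIPTOR_NAMES <- c("MW", "HeavyAtoms", "Rings", "AromaticAtoms", "HBD", "HBA")

#' Linear-path substructure fingerprint
#'
#' Enumerates every simple path of 1 to `max_path_atoms` atoms, labels it
#' by its atom and bond symbols read in the lexicographically smaller
#' direction, and hashes each label (FNV-1a 64-bit) to a bit position
#' modulo `L`. The label multiset is retained for interpretability; the
#' fingerprint is a deterministic function of the graph, independent of
#' atom input order.
#'
#' @param g an `mt_graph`.
#' @param max_path_atoms maximum atoms per path (default 7).
#' @param L fingerprint length in bits (default 1024, minimum 64).
#' @return an object of class `mt_fingerprint`: `length`, `bits` (sorted
#'   0-based bit indices) and `labels` (named integer vector of path-label
#'   counts).
#' @examples
#' fp <- path_fingerprint(parse_smiles("CCC"), max_path_atoms = 3)
#' names(fp$labels)  # "C" "C-C" "C-C-C"
#' @export
path_fingerprint <- function(g, max_path_atoms = 7L, L = 1024L) {
  stopifnot(inherits(g, "mt_graph"))
  if (max_path_atoms < 1L) mt_abort("max_path_atoms must be >= 1", "mt_param_error")
  if (L < 64L) mt_abort("fingerprint length L must be >= 64", "mt_param_error")
  labels <- enumerate_path_labels(g, max_path_atoms)
  fingerprint_from_labels(labels, L)
}

fingerprint_from_labels <- function(labels, L) {
  bits <- if (length(labels)) {
    sort(unique(fnv1a64_mod(unique(names(labels)), as.integer(L))))
  } else integer(0)
  structure(list(length = as.integer(L), bits = bits, labels = labels),
            class = "mt_fingerprint")
}

# Path labels as a named count vector. Each undirected path is counted
# once (kept when start index <= end index); labels use the canonical
# (lexicographically smaller) reading direction.
enumerate_path_labels <- function(g, max_path_atoms) {
  na <- nrow(g$atoms)
  if (na == 0L) return(setNames(integer(0), character(0)))
  adj <- graph_adjacency(g)
  atok <- path_atom_token(g)
  out <- character(0)

  extend <- function(path, orders) {
    last <- path[length(path)]
    if (path[1] <= last) {
      out[[length(out) + 1L]] <<- path_label(atok, path, orders)
    }
    if (length(path) == max_path_atoms) return(invisible(NULL))
    nb <- adj[[last]]
    for (ii in seq_len(nrow(nb))) {
      v <- nb$nbr[ii]
      if (!(v %in% path)) extend(c(path, v), c(orders, nb$order[ii]))
    }
    invisible(NULL)
  }
  for (s in seq_len(na)) extend(s, numeric(0))
  tab <- table(unlist(out))
  setNames(as.integer(tab), names(tab))
}

path_atom_token <- function(g) {
  sym <- ifelse(g$atoms$aromatic, tolower(g$atoms$element), g$atoms$element)
  ch <- g$atoms$charge
  suffix <- ifelse(ch == 0L, "",
                   ifelse(ch == 1L, "+", ifelse(ch == -1L, "-", sprintf("%+d", ch))))
  paste0(sym, suffix)
}

path_label <- function(atok, path, orders) {
  btok <- vapply(orders, function(o) {
    if (o == 1) "-" else if (o == 2) "=" else if (o == 3) "#" else ":"
  }, character(1))
  np <- length(path)
  fwd <- atok[path[1]]
  for (i in seq_len(np - 1L)) fwd <- paste0(fwd, btok[i], atok[path[i + 1L]])
  if (np == 1L) return(fwd)
  rev_path <- rev(path); rev_b <- rev(btok)
  bwd <- atok[rev_path[1]]
  for (i in seq_len(np - 1L)) bwd <- paste0(bwd, rev_b[i], atok[rev_path[i + 1L]])
  sort_c(c(fwd, bwd))[1]
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the fingerprints' bit sets. Two
#' empty fingerprints (possible only for empty graphs) are defined to
#' have similarity 1.
#'
#' @param a,b `mt_fingerprint` objects of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "mt_fingerprint"), inherits(b, "mt_fingerprint"))
  if (a$length != b$length) {
    mt_abort("fingerprint lengths differ", "mt_param_error")
  }
  tanimoto_bits(a$bits, b$bits)
}

tanimoto_bits <- function(ba, bb) {
  u <- length(ba) + length(bb) - (i <- length(intersect(ba, bb)))
  if (u == 0L) return(1)
  i / u
}
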