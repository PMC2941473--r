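#' Canonical SMILES for a molecular graph
#'
#' Produces a deterministic SMILES string that is identical for every atom
#' ordering of the same graph, so that structural identity can be tested
#' by string equality (duplicate detection, exact-structure search).
#' Atom ranks are obtained by iterative neighbourhood refinement seeded by
#' (element, aromatic flag, charge, degree, hydrogen count); remaining
#' ties are broken by individualizing each tied atom in turn and keeping
#' the lexicographically smallest resulting string. The output is
#' implementation-canonical: stable within this package, not required to
#' match any external toolkit.
#'
#' @param g an `mt_graph` from [parse_smiles()].
#' @return a single SMILES string; re-parsing it yields an isomorphic
#'   graph (same elements, charges, aromatic flags, hydrogen counts and
#'   bonds).
#' @examples
#' canonical_smiles(parse_smiles("OCC")) == canonical_smiles(parse_smiles("CCO"))
#' @export
canonical_smiles <- function(g) {
  stopifnot(inherits(g, "mt_graph"))
  if (nrow(g$atoms) == 0L) mt_abort("empty graph", "mt_graph_error")
  adj <- graph_adjacency(g)
  seed <- initial_codes(g)
  canon_search(g, adj, seed)
}

# Canonicalization of a raw SMILES string is pure; memoised because the
# store and the workflows canonicalize the same inputs repeatedly.
.mt_canon_cache <- new.env(parent = emptyenv())

cached_canonical <- function(smiles) {
  can <- get0(smiles, envir = .mt_canon_cache, ifnotfound = NULL)
  if (is.null(can)) {
    can <- canonical_smiles(parse_smiles(smiles))
    assign(smiles, can, envir = .mt_canon_cache)
  }
  can
}

initial_codes <- function(g) {
  deg <- numeric(nrow(g$atoms))
  for (k in seq_len(nrow(g$bonds))) {
    deg[g$bonds$a[k]] <- deg[g$bonds$a[k]] + 1
    deg[g$bonds$b[k]] <- deg[g$bonds$b[k]] + 1
  }
  key <- sprintf("%s|%d|%+d|%02d|%d",
                 g$atoms$element, as.integer(g$atoms$aromatic),
                 g$atoms$charge, as.integer(deg), g$atoms$implicit_h)
  match(key, sort_c(unique(key)))
}

# Iterative (Morgan-style) partition refinement over (rank, sorted
# neighbour (bond-order, rank) multiset) until stable.
refine_ranks <- function(adj, ranks) {
  repeat {
    keys <- vapply(seq_along(adj), function(j) {
      nb <- adj[[j]]
      if (nrow(nb) == 0L) return(sprintf("%06d|", ranks[j]))
      codes <- sprintf("%03.1f:%06d", nb$order, ranks[nb$nbr])
      sprintf("%06d|%s", ranks[j], paste(sort_c(codes), collapse = ","))
    }, character(1))
    new <- match(keys, sort_c(unique(keys)))
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

# Complete the ranking: refine; while ties remain, individualize each atom
# of the lowest-ranked tied class and keep the smallest final string.
canon_search <- function(g, adj, ranks) {
  ranks <- refine_ranks(adj, ranks)
  tied <- ranks[duplicated(ranks)]
  if (length(tied) == 0L) return(write_smiles(g, adj, ranks))
  cls <- min(tied)
  candidates <- which(ranks == cls)
  best <- NULL
  for (a in candidates) {
    r2 <- ifelse(seq_along(ranks) == a, ranks - 0.5, ranks)
    r2 <- match(r2, sort(unique(r2)))
    s <- canon_search(g, adj, r2)
    if (is.null(best) || s < best) best <- s
  }
  best
}

# Emit a SMILES string following canonical ranks: components sorted by
# their own string; DFS from the lowest-ranked atom, children in rank
# order; ring-closure digits allocated in emission order and reused.
write_smiles <- function(g, adj, ranks) {
  na <- nrow(g$atoms)
  comp <- component_ids(na, g$bonds)
  parts <- vapply(sort(unique(comp)), function(ci) {
    write_component(g, adj, ranks, which(comp == ci))
  }, character(1))
  paste(sort_c(parts), collapse = ".")
}

component_ids <- function(n_atoms, bdf) {
  parent <- seq_len(n_atoms)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_len(nrow(bdf))) {
    ra <- find(bdf$a[k]); rb <- find(bdf$b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n_atoms), find, numeric(1))
  match(roots, unique(roots))
}

write_component <- function(g, adj, ranks, members) {
  start <- members[which.min(ranks[members])]

  # Pass 1: DFS (children in rank order) to find visit order and back
  # (ring) edges.
  visited <- logical(nrow(g$atoms))
  visit_pos <- integer(nrow(g$atoms))
  tree_children <- vector("list", nrow(g$atoms))
  back_edges <- list()   # list(c(u, v, order)); v visited before u
  used_edge <- character(0)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  ctr <- 0L

  dfs1 <- function(u, parent) {
    visited[u] <<- TRUE
    ctr <<- ctr + 1L
    visit_pos[u] <<- ctr
    nb <- adj[[u]]
    ord_idx <- order(ranks[nb$nbr], visit_pos[nb$nbr])
    for (ii in ord_idx) {
      v <- nb$nbr[ii]
      if (ekey(u, v) %in% used_edge) next
      used_edge <<- c(used_edge, ekey(u, v))
      if (!visited[v]) {
        tree_children[[u]] <<- c(tree_children[[u]], v)
        dfs1(v, u)
      } else {
        back_edges[[length(back_edges) + 1L]] <<- c(v, u, nb$order[ii])
      }
    }
  }
  dfs1(start, NA)

  # Ring digits: opening at the earlier-visited endpoint, closing at the
  # later one. Openings at an atom ordered by the closing atom's visit
  # position so digit allocation is deterministic.
  opens <- vector("list", nrow(g$atoms))
  closes <- vector("list", nrow(g$atoms))
  if (length(back_edges)) {
    for (ei in seq_along(back_edges)) {
      be <- back_edges[[ei]]
      opens[[be[1]]] <- c(opens[[be[1]]], ei)
      closes[[be[2]]] <- c(closes[[be[2]]], ei)
    }
    for (j in seq_along(opens)) {
      if (length(opens[[j]]) > 1L) {
        cpos <- vapply(opens[[j]], function(ei) visit_pos[back_edges[[ei]][2]],
                       numeric(1))
        opens[[j]] <- opens[[j]][order(cpos)]
      }
    }
  }

  digit_of <- integer(length(back_edges))
  free_digits <- 1:9

  emit <- function(u, via_order, from_aromatic) {
    s <- bond_token(via_order, from_aromatic, g$atoms$aromatic[u])
    s <- paste0(s, atom_token(g, u))
    for (ei in opens[[u]]) {
      if (length(free_digits) == 0L) {
        mt_abort("more than 9 simultaneously open ring closures", "mt_graph_error")
      }
      d <- free_digits[1]; free_digits <<- free_digits[-1]
      digit_of[ei] <<- d
      be <- back_edges[[ei]]
      s <- paste0(s, bond_token(be[3], g$atoms$aromatic[be[1]],
                                g$atoms$aromatic[be[2]]), d)
    }
    for (ei in closes[[u]]) {
      d <- digit_of[ei]
      free_digits <<- sort(c(free_digits, d))
      s <- paste0(s, d)
    }
    kids <- tree_children[[u]]
    if (length(kids)) {
      kord <- vapply(kids, function(v) {
        nb <- adj[[u]]
        nb$order[nb$nbr == v][1]
      }, numeric(1))
      nk <- length(kids)
      for (ii in seq_len(nk)) {
        child_s <- emit(kids[ii], kord[ii], g$atoms$aromatic[u])
        s <- if (ii < nk) paste0(s, "(", child_s, ")") else paste0(s, child_s)
      }
    }
    s
  }
  emit(start, NA_real_, FALSE)
}

bond_token <- function(order, arom_a, arom_b) {
  if (is.na(order)) return("")
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 1.5) return(if (arom_a && arom_b) "" else ":")
  if (order == 1 && arom_a && arom_b) return("-")
  ""
}

atom_token <- function(g, j) {
  el <- g$atoms$element[j]
  arom <- g$atoms$aromatic[j]
  sym <- if (arom) tolower(el) else el
  charge <- g$atoms$charge[j]
  # bond-order sum as written equals the graph's bond-order sum
  nb_orders <- c(g$bonds$order[g$bonds$a == j], g$bonds$order[g$bonds$b == j])
  default_h <- implicit_h_for(el, sum(nb_orders))
  needs_bracket <- charge != 0L || el == "H" ||
    g$atoms$implicit_h[j] != default_h
  if (!needs_bracket) return(sym)
  h <- g$atoms$implicit_h[j]
  htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ctok <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-"
          else sprintf("%+d", charge)
  paste0("[", sym, htok, ctok, "]")
}
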