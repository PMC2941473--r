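#' Parse a SMILES string into a molecular graph
#'
#' Parses a subset of the SMILES grammar: the organic subset
#' B, C, N, O, P, S, F, Cl, Br, I; aromatic lowercase b, c, n, o, p, s;
#' bracket atoms with an explicit hydrogen count and a formal charge in
#' -2..+2; branches; single-digit ring closures (digits are reusable once
#' closed); bond symbols `-`, `=`, `#`, `:`; and dot-separated components.
#' Stereochemistry, isotopes and wildcard atoms are not supported.
#'
#' Implicit hydrogens on non-bracket atoms are assigned from default
#' valences (B 3; C 4; N 3; O 2; P 3 or 5; S 2, 4 or 6; halogens 1), using
#' the smallest default valence not below the bond-order sum; aromatic
#' bonds count 1.5 and the sum is rounded up. Bracket atoms carry exactly
#' their written hydrogen count.
#'
#' @param text a single non-empty SMILES string.
#' @return an object of class `mt_graph`: a list with `atoms` (data.frame
#'   of `element`, `charge`, `aromatic`, `implicit_h`, `bracket`), `bonds`
#'   (data.frame of `a`, `b`, `order`, where aromatic bonds have order
#'   1.5) and `components` (number of connected components).
#' @examples
#' g <- parse_smiles("CCO")
#' g$atoms$implicit_h  # 3 2 1
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    mt_abort("SMILES input must be a single non-empty string", "mt_parse_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(element, charge, aromatic, implicit_h, bracket)
  bonds <- list()   # each: c(a, b, order)
  prev <- NA_integer_
  pending_bond <- NA_real_
  pending_pos <- NA_integer_
  branch_stack <- integer(0)
  rings <- list()   # digit -> list(atom, bond, pos)

  perr <- function(msg, pos) {
    mt_abort(sprintf("SMILES parse error at position %d: %s", pos, msg),
             "mt_parse_error", position = pos)
  }

  add_atom <- function(element, charge, aromatic, hcount, bracket, pos) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, charge = charge, aromatic = aromatic,
      implicit_h = hcount, bracket = bracket
    )
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && aromatic) 1.5 else 1
      }
      add_bond(prev, idx, ord, pos)
    }
    pending_bond <<- NA_real_
    pending_pos <<- NA_integer_
    prev <<- idx
  }

  add_bond <- function(a, b, ord, pos) {
    if (a == b) perr("ring bond to self", pos)
    for (bd in bonds) {
      if ((bd[1] == a && bd[2] == b) || (bd[1] == b && bd[2] == a)) {
        perr("duplicate bond between the same atom pair", pos)
      }
    }
    bonds[[length(bonds) + 1L]] <<- c(a, b, ord)
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""

    if (ch == "(") {
      if (is.na(prev)) perr("branch open with no preceding atom", i)
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) perr("unbalanced ')'", i)
      if (!is.na(pending_bond)) perr("bond symbol with no following atom", pending_pos)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.na(pending_bond)) perr("bond symbol with no following atom", pending_pos)
      prev <- NA_integer_
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (!is.na(pending_bond)) perr("two consecutive bond symbols", i)
      pending_bond <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5)
      pending_pos <- i
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      if (is.na(prev)) perr("ring-closure digit with no preceding atom", i)
      if (!is.null(rings[[ch]])) {
        op <- rings[[ch]]
        ord <- pending_bond
        if (is.na(ord)) ord <- op$bond
        if (is.na(ord)) {
          ord <- if (atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic) 1.5 else 1
        }
        add_bond(op$atom, prev, ord, i)
        rings[[ch]] <- NULL
      } else {
        rings[[ch]] <- list(atom = prev, bond = pending_bond, pos = i)
      }
      pending_bond <- NA_real_
      pending_pos <- NA_integer_
      i <- i + 1L
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, 0L, FALSE, NA_integer_, FALSE, i)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, 0L, FALSE, NA_integer_, FALSE, i)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), 0L, TRUE, NA_integer_, FALSE, i)
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (length(close) == 0L) perr("unterminated bracket atom", i)
      close <- close[1]
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([A-IK-PR-Za-ik-pr-z][a-z]?)(H[0-9]?)?(\\+\\+|--|[+-][0-9]?)?$", body
      ))[[1]]
      if (length(m) == 0L) perr(sprintf("malformed bracket atom '[%s]'", body), i)
      sym <- m[2]
      aromatic <- grepl("^[a-z]", sym)
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      if (!(element %in% names(ATOMIC_MASSES))) {
        perr(sprintf("unknown atom symbol '%s'", sym), i)
      }
      if (aromatic && !(element %in% AROMATIC_OK)) {
        perr(sprintf("element '%s' cannot be aromatic", element), i)
      }
      hcount <- 0L
      if (nzchar(m[3])) {
        hcount <- if (m[3] == "H") 1L else as.integer(substring(m[3], 2))
      }
      charge <- 0L
      if (nzchar(m[4])) {
        cs <- m[4]
        charge <- switch(cs,
          "+" = 1L, "-" = -1L, "++" = 2L, "--" = -2L,
          {
            sgn <- if (substr(cs, 1, 1) == "+") 1L else -1L
            sgn * as.integer(substring(cs, 2))
          }
        )
      }
      if (charge < -2L || charge > 2L) {
        perr(sprintf("formal charge %+d outside supported range [-2,+2]", charge), i)
      }
      add_atom(element, charge, aromatic, hcount, TRUE, i)
      i <- close + 1L
    } else {
      perr(sprintf("unknown atom symbol '%s'", ch), i)
    }
  }

  if (!is.na(pending_bond)) perr("bond symbol with no following atom", pending_pos)
  if (length(branch_stack) > 0L) perr("unbalanced '(' (unclosed branch)", n)
  if (length(rings) > 0L) {
    op <- rings[[1]]
    perr(sprintf("unclosed ring-closure digit '%s'", names(rings)[1]), op$pos)
  }
  if (length(atoms) == 0L) perr("no atoms found", 1L)

  build_graph(atoms, bonds)
}

# Assemble an mt_graph from parsed atom/bond lists: assign implicit H,
# count components.
build_graph <- function(atoms, bonds) {
  na <- length(atoms)
  adf <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    implicit_h = vapply(atoms, `[[`, integer(1), "implicit_h"),
    bracket = vapply(atoms, `[[`, logical(1), "bracket"),
    stringsAsFactors = FALSE
  )
  bdf <- if (length(bonds)) {
    data.frame(
      a = vapply(bonds, `[`, numeric(1), 1),
      b = vapply(bonds, `[`, numeric(1), 2),
      order = vapply(bonds, `[`, numeric(1), 3)
    )
  } else {
    data.frame(a = numeric(0), b = numeric(0), order = numeric(0))
  }

  bondsum <- numeric(na)
  for (k in seq_len(nrow(bdf))) {
    bondsum[bdf$a[k]] <- bondsum[bdf$a[k]] + bdf$order[k]
    bondsum[bdf$b[k]] <- bondsum[bdf$b[k]] + bdf$order[k]
  }
  for (j in seq_len(na)) {
    if (!adf$bracket[j]) {
      adf$implicit_h[j] <- implicit_h_for(adf$element[j], bondsum[j])
    }
  }

  g <- structure(
    list(atoms = adf, bonds = bdf, components = count_components(na, bdf)),
    class = "mt_graph"
  )
  g
}

implicit_h_for <- function(element, bondsum) {
  vals <- DEFAULT_VALENCES[[element]]
  bs <- ceiling(bondsum)
  ok <- vals[vals >= bs]
  if (length(ok) == 0L) return(0L)
  as.integer(ok[1] - bs)
}

count_components <- function(n_atoms, bdf) {
  if (n_atoms == 0L) return(0L)
  parent <- seq_len(n_atoms)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_len(nrow(bdf))) {
    ra <- find(bdf$a[k]); rb <- find(bdf$b[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n_atoms), find, numeric(1))))
}

# Adjacency list: for each atom, data.frame(nbr, order).
graph_adjacency <- function(g) {
  na <- nrow(g$atoms)
  adj <- vector("list", na)
  for (j in seq_len(na)) adj[[j]] <- data.frame(nbr = numeric(0), order = numeric(0))
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
    adj[[a]] <- rbind(adj[[a]], data.frame(nbr = b, order = o))
    adj[[b]] <- rbind(adj[[b]], data.frame(nbr = a, order = o))
  }
  adj
}

#' Permute the atom order of a molecular graph
#'
#' Relabels atoms by a permutation, yielding an isomorphic graph. Used to
#' verify that canonicalization and fingerprints are independent of atom
#' input order.
#'
#' @param g an `mt_graph`.
#' @param perm a permutation of `seq_len(nrow(g$atoms))`; `perm[i]` is the
#'   new position of atom `i`.
#' @return the permuted `mt_graph`.
#' @export
permute_atoms <- function(g, perm) {
  na <- nrow(g$atoms)
  stopifnot(length(perm) == na, all(sort(perm) == seq_len(na)))
  atoms <- g$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  bonds$a <- perm[g$bonds$a]
  bonds$b <- perm[g$bonds$b]
  structure(list(atoms = atoms, bonds = bonds, components = g$components),
            class = "mt_graph")
}

#' @export
print.mt_graph <- function(x, ...) {
  cat(sprintf("<mt_graph: %d atoms, %d bonds, %d component(s)>\n",
              nrow(x$atoms), nrow(x$bonds), x$components))
  invisible(x)
}
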