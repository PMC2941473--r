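#' Read a minimal SDF (V2000) file into a dataset
#'
#' Parses V2000 molblocks (coordinates ignored; bond type 4 is read as
#' aromatic; `M  CHG` charge lines honoured) and the `> <NAME>` data
#' items of each record. Structures are canonicalized and deduplicated
#' by canonical form; each data-item name becomes a feature (numeric
#' when every value parses as a number, else string) with `has_source`
#' set to the dataset URI.
#'
#' @param store an `mt_store`.
#' @param path SDF file path.
#' @param title dataset title (defaults to the file name).
#' @return the stored `mt_dataset`.
#' @export
read_sdf_v2000_minimal <- function(store, path, title = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)

  duri <- mt_uri(store, "dataset")
  parsed <- lapply(seq_along(recs), function(ri) parse_sdf_record(recs[[ri]], ri))

  item_names <- sort_c(unique(unlist(lapply(parsed, function(p) names(p$items)))))
  feat_kind <- vapply(item_names, function(nm) {
    vals <- unlist(lapply(parsed, function(p) p$items[[nm]]))
    if (length(vals) && !anyNA(suppressWarnings(as.numeric(vals))))
      "numeric" else "string"
  }, character(1))
  feats <- lapply(item_names, function(nm) {
    new_feature(store, nm, feat_kind[[nm]], has_source = duri)
  })
  names(feats) <- vapply(feats, `[[`, character(1), "uri")

  compounds <- list(); values <- list()
  for (p in parsed) {
    cp <- add_compound(store, p$smiles,
                       names = if (nzchar(p$name)) p$name else character(0),
                       origin_inventory = title)
    if (is.null(values[[cp$uri]])) {
      compounds[[length(compounds) + 1L]] <- cp
      values[[cp$uri]] <- list()
    }
    for (nm in names(p$items)) {
      fu <- names(feats)[vapply(feats, function(ft) ft$name == nm, logical(1))]
      v <- if (feat_kind[[nm]] == "numeric") as.numeric(p$items[[nm]]) else
        p$items[[nm]]
      values[[cp$uri]][[fu]] <- v
    }
  }
  d <- structure(list(
    uri = duri, title = title,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    compounds = setNames(compounds, vapply(compounds, `[[`, character(1), "uri")),
    features = feats,
    entries = values
  ), class = "mt_dataset")
  d$snapshot_hash <- dataset_snapshot_hash(d)
  store_dataset(store, d)
  store$datasets[[duri]]
}

sdf_int <- function(line, from, to) {
  v <- suppressWarnings(as.integer(trimws(substr(line, from, to))))
  v
}

parse_sdf_record <- function(rec, ri) {
  if (length(rec) < 4L) {
    mt_abort(sprintf("SDF record %d: truncated molblock", ri), "mt_sdf_error")
  }
  name <- trimws(rec[1])
  counts <- rec[4]
  natoms <- sdf_int(counts, 1, 3)
  nbonds <- sdf_int(counts, 4, 6)
  if (is.na(natoms) || is.na(nbonds)) {
    mt_abort(sprintf("SDF record %d: malformed counts line '%s'", ri, counts),
             "mt_sdf_error")
  }
  if (length(rec) < 4L + natoms + nbonds) {
    mt_abort(sprintf("SDF record %d: %d atom + %d bond lines declared but block is short",
                     ri, natoms, nbonds), "mt_sdf_error")
  }
  atoms <- vector("list", natoms)
  for (i in seq_len(natoms)) {
    ln <- rec[4L + i]
    el <- trimws(substr(ln, 32, 34))
    if (!nzchar(el)) el <- strsplit(trimws(ln), "\\s+")[[1]][4]
    if (!(el %in% names(ATOMIC_MASSES))) {
      mt_abort(sprintf("SDF record %d: unsupported element '%s'", ri, el),
               "mt_sdf_error")
    }
    atoms[[i]] <- list(element = el, charge = 0L, aromatic = FALSE,
                       implicit_h = NA_integer_, bracket = FALSE)
  }
  bonds <- vector("list", nbonds)
  for (i in seq_len(nbonds)) {
    ln <- rec[4L + natoms + i]
    a <- sdf_int(ln, 1, 3); b <- sdf_int(ln, 4, 6); o <- sdf_int(ln, 7, 9)
    if (is.na(a) || is.na(b) || is.na(o) ||
        a < 1L || a > natoms || b < 1L || b > natoms) {
      mt_abort(sprintf("SDF record %d: bond line %d references a missing atom",
                       ri, i), "mt_sdf_error")
    }
    ord <- if (o == 4L) 1.5 else as.numeric(o)
    bonds[[i]] <- c(a, b, ord)
    if (o == 4L) {
      atoms[[a]]$aromatic <- TRUE
      atoms[[b]]$aromatic <- TRUE
    }
  }
  # properties block: charges
  for (ln in rec) {
    if (startsWith(ln, "M  CHG")) {
      toks <- strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]
      ncg <- as.integer(toks[1])
      for (j in seq_len(ncg)) {
        ai <- as.integer(toks[2 * j])
        cg <- as.integer(toks[2 * j + 1])
        atoms[[ai]]$charge <- cg
        atoms[[ai]]$bracket <- TRUE
        atoms[[ai]]$implicit_h <- 0L
      }
    }
  }
  g <- build_graph(atoms, bonds)
  # aromatic charged atoms written via molblock: recompute implicit H
  # from the valence rule minus charge only for bracket atoms is not
  # possible without explicit counts; molblock atoms follow the default
  # valence rule.
  smiles <- canonical_smiles(g)

  items <- list()
  i <- 1L
  while (i <= length(rec)) {
    m <- regmatches(rec[i], regexec("^>.*<([^>]+)>", rec[i]))[[1]]
    if (length(m)) {
      vals <- character(0)
      j <- i + 1L
      while (j <= length(rec) && nzchar(trimws(rec[j])) && rec[j] != "$$$$") {
        vals <- c(vals, trimws(rec[j]))
        j <- j + 1L
      }
      items[[m[2]]] <- paste(vals, collapse = "\n")
      i <- j
    }
    i <- i + 1L
  }
  list(name = name, smiles = smiles, items = items)
}
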