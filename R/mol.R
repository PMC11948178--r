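# Default valences used to fill implicit hydrogens (MOL V2000 convention).
DEFAULT_VALENCE <- c(
  H = 1L, C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
  F = 1L, Cl = 1L, Br = 1L, I = 1L, Na = 1L, K = 1L
)

#' Construct a molecular graph
#'
#' The core container for the linker-payload structure: heavy atoms with
#' implicit hydrogens, bonds with ring flags, and one attachment atom
#' marking the conjugation site (the atom through which the moiety is
#' bonded to an antibody cysteine).
#'
#' @param atoms tibble with columns `element`, `charge`, `implicit_h`.
#' @param bonds tibble with columns `i`, `j`, `order`, `is_ring`.
#' @param attachment_atom 1-based index of the conjugation-site atom.
#' @param title molecule name (from the MOL header).
#' @return an object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, attachment_atom, title = "") {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  n <- nrow(atoms)
  if (!all(atoms$element %in% names(ELEMENT_MONO))) {
    bad <- setdiff(atoms$element, names(ELEMENT_MONO))
    abort(paste0("unknown element symbol: '", bad[1], "'"))
  }
  if (nrow(bonds) && (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))) {
    abort("bond references an atom index outside the atom block")
  }
  if (length(attachment_atom) != 1L || is.na(attachment_atom) ||
      attachment_atom < 1L || attachment_atom > n) {
    abort("attachment_atom must be a single valid atom index")
  }
  ig <- igraph::make_graph(edges = as.integer(rbind(bonds$i, bonds$j)),
                           n = n, directed = FALSE)
  if (igraph::components(ig)$no != 1L) {
    abort("structure is disconnected; a single connected molecule is required")
  }
  structure(
    list(atoms = atoms, bonds = bonds,
         attachment_atom = as.integer(attachment_atom), title = title),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$title, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), "  bonds: ", nrow(x$bonds),
      " (", sum(x$bonds$is_ring), " ring)\n", sep = "")
  cat("  formula: ", formula_string(mol_formula(x)),
      "  attachment atom: ", x$attachment_atom,
      " (", x$atoms$element[x$attachment_atom], ")\n", sep = "")
  invisible(x)
}

mol_igraph <- function(graph) {
  igraph::make_graph(
    edges = as.integer(rbind(graph$bonds$i, graph$bonds$j)),
    n = nrow(graph$atoms), directed = FALSE
  )
}

#' Elemental formula of a molecular graph (or an atom subset)
#'
#' Implicit hydrogens are included; `extra_h` adds cap hydrogens.
#'
#' @param graph a `mol_graph`.
#' @param atom_idx atom indices to include (default: all).
#' @param extra_h additional hydrogens to add (bond-cleavage caps).
#' @return named integer vector of element counts.
#' @export
mol_formula <- function(graph, atom_idx = NULL, extra_h = 0L) {
  a <- graph$atoms
  if (!is.null(atom_idx)) a <- a[atom_idx, , drop = FALSE]
  els <- table(a$element)
  v <- setNames(as.integer(els), names(els))
  h <- sum(a$implicit_h) + as.integer(extra_h)
  formula_sum(v, c(H = as.integer(h)))
}

implicit_h_count <- function(element, charge, bond_order_sum) {
  dv <- DEFAULT_VALENCE[element]
  if (is.na(dv)) return(0L)
  adj <- switch(element,
    N = , P = dv + charge,
    O = , S = dv + charge,
    C = dv - abs(charge),
    dv - abs(charge)
  )
  max(0L, as.integer(adj) - as.integer(bond_order_sum))
}

validate_mol_lines <- function(lines) {
  if (length(lines) < 4L) abort("malformed MOL block at line 1: fewer than 4 lines")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    abort("malformed MOL block at line 4: cannot read the counts line")
  }
  if (length(lines) < 4L + natoms + nbonds) {
    abort(paste0("malformed MOL block at line ", length(lines),
                 ": atom/bond blocks truncated"))
  }
  for (k in seq_len(natoms)) {
    ln <- lines[4L + k]
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(fields) < 4L ||
        anyNA(suppressWarnings(as.numeric(fields[1:3])))) {
      abort(paste0("malformed MOL block at line ", 4L + k,
                   ": cannot read atom coordinates/element"))
    }
  }
  for (k in seq_len(nbonds)) {
    ln <- lines[4L + natoms + k]
    i <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    j <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    if (is.na(i) || is.na(j)) {
      abort(paste0("malformed MOL block at line ", 4L + natoms + k,
                   ": cannot read bond atom indices"))
    }
  }
  list(natoms = natoms, nbonds = nbonds)
}

# Formal charges: old-style atom-line codes, overridden by M CHG properties.
mol_charges <- function(lines, natoms) {
  code_to_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                      `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  ch <- integer(natoms)
  for (k in seq_len(natoms)) {
    fields <- strsplit(trimws(lines[4L + k]), "\\s+")[[1]]
    if (length(fields) >= 6L) {
      code <- suppressWarnings(as.integer(fields[6]))
      if (!is.na(code)) ch[k] <- code_to_charge[as.character(code)] %||% 0L
    }
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg_lines) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    npairs <- fields[1]
    if (npairs > 0) {
      idx <- fields[seq(2, by = 2, length.out = npairs)]
      ch[idx] <- fields[seq(3, by = 2, length.out = npairs)]
    }
  }
  ch
}

#' Parse a MOL V2000 / SDF structure into a molecular graph
#'
#' Reads a single-record MOL V2000 block (or SDF containing one record),
#' fills implicit hydrogens by standard valence rules, flags ring bonds by
#' cycle membership, and resolves the conjugation-site attachment atom.
#'
#' @param mol_text the MOL/SDF content as a single string or character
#'   vector of lines; a path to an existing file is also accepted.
#' @param attachment either a 1-based atom index, or a substructure pattern
#'   created by [mol_pattern()] (e.g. [maleimide_pattern()]) that must match
#'   exactly one attachment atom.
#' @return a [mol_graph()].
#' @export
#' @examples
#' eth <- parse_structure(example_mol("ethanol"), attachment = 1)
#' sum(eth$bonds$is_ring)  # acyclic: 0
parse_structure <- function(mol_text, attachment = 1L) {
  if (length(mol_text) == 1L && !grepl("\n", mol_text) && file.exists(mol_text)) {
    lines <- readLines(mol_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(mol_text, collapse = "\n"), "\n", fixed = TRUE))
  }
  info <- validate_mol_lines(lines)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  body <- lines
  if (!any(grepl("^\\$\\$\\$\\$", body))) body <- c(body, "$$$$")
  writeLines(body, tmp)
  sdf <- tryCatch(ChemmineR::read.SDFset(tmp),
                  error = function(e) abort(paste0("malformed MOL block: ",
                                                   conditionMessage(e))))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- gsub("_.*$", "", rownames(ab))
  charges <- mol_charges(lines, info$natoms)
  bonds <- tibble::tibble(
    i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  order_sum <- vapply(seq_along(elements), function(a) {
    sum(bonds$order[bonds$i == a | bonds$j == a])
  }, integer(1))
  atoms <- tibble::tibble(
    element = elements, charge = charges,
    implicit_h = vapply(seq_along(elements), function(a) {
      implicit_h_count(elements[a], charges[a], order_sum[a])
    }, integer(1))
  )
  ig <- igraph::make_graph(edges = as.integer(rbind(bonds$i, bonds$j)),
                           n = nrow(atoms), directed = FALSE)
  br <- igraph::bridges(ig)
  bonds$is_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  g0 <- list(atoms = atoms, bonds = bonds, title = trimws(lines[1]))
  att <- if (inherits(attachment, "mol_pattern")) {
    match_attachment(g0, attachment)
  } else {
    as.integer(attachment)
  }
  mol_graph(atoms, bonds, att, title = trimws(lines[1]))
}

#' Define a substructure attachment pattern
#'
#' The pattern is itself a small MOL block; `mapped_atom` names which atom of
#' the pattern marks the conjugation site. Matching is exact on element and
#' (optionally) bond order via VF2 subgraph isomorphism.
#'
#' @param mol_text MOL V2000 text of the pattern.
#' @param mapped_atom 1-based index of the pattern atom that maps to the
#'   attachment site.
#' @param match_bond_order require bond orders to agree (default TRUE).
#' @export
mol_pattern <- function(mol_text, mapped_atom, match_bond_order = TRUE) {
  g <- parse_structure(mol_text, attachment = mapped_atom)
  structure(list(graph = g, mapped_atom = as.integer(mapped_atom),
                 match_bond_order = match_bond_order),
            class = "mol_pattern")
}

#' Built-in maleimide attachment pattern
#'
#' Matches the five-membered maleimide ring (two carbonyls flanking the ring
#' nitrogen, one C=C). The mapped atom is the ring nitrogen: because ring
#' bonds are never cleaved, any maleimide ring atom identifies the same
#' retained fragment, and the nitrogen is the unique choice that matches a
#' single atom even on a symmetric maleimide.
#'
#' @export
maleimide_pattern <- function() {
  mol_pattern(maleimide_mol_text(), mapped_atom = 1L)
}

maleimide_mol_text <- function() {
  paste(c(
    "maleimide", "  adcbiotx", "",
    "  7  7  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.9511    0.3090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5878   -0.8090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.5878   -0.8090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.9511    0.3090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9021    0.6180    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.9021    0.6180    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "  3  4  2  0  0  0  0",
    "  4  5  1  0  0  0  0",
    "  5  1  1  0  0  0  0",
    "  2  6  2  0  0  0  0",
    "  5  7  2  0  0  0  0",
    "M  END"), collapse = "\n")
}

match_attachment <- function(graph, pattern) {
  tg <- igraph::make_graph(edges = as.integer(rbind(graph$bonds$i, graph$bonds$j)),
                           n = nrow(graph$atoms), directed = FALSE)
  pgraph <- pattern$graph
  pg <- mol_igraph(pgraph)
  all_el <- unique(c(graph$atoms$element, pgraph$atoms$element))
  tcol <- as.integer(factor(graph$atoms$element, levels = all_el))
  pcol <- as.integer(factor(pgraph$atoms$element, levels = all_el))
  args <- list(pattern = pg, target = tg, method = "vf2",
               vertex.color1 = tcol, vertex.color2 = pcol)
  if (isTRUE(pattern$match_bond_order)) {
    args$edge.color1 <- as.integer(graph$bonds$order)
    args$edge.color2 <- as.integer(pgraph$bonds$order)
  }
  maps <- do.call(igraph::subgraph_isomorphisms, args)
  hits <- unique(vapply(maps, function(m) as.integer(m)[pattern$mapped_atom],
                        integer(1)))
  if (length(hits) == 0L) {
    abort("attachment pattern matched no atoms in the structure")
  }
  if (length(hits) > 1L) {
    abort(paste0("attachment pattern is ambiguous: mapped atom matches ",
                 length(hits), " distinct atoms (", paste(hits, collapse = ", "), ")"))
  }
  hits
}

#' Small example structures
#'
#' MOL V2000 text for a few tiny molecules used in examples and tests.
#'
#' @param name one of `"ethanol"`, `"benzene"`, `"n_methylmaleimide"`.
#' @return MOL block as a single string.
#' @export
example_mol <- function(name = c("ethanol", "benzene", "n_methylmaleimide")) {
  name <- match.arg(name)
  switch(name,
    ethanol = paste(c(
      "ethanol", "  adcbiotx", "",
      "  3  2  0  0  0  0  0  0  0  0999 V2000",
      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
      "  1  2  1  0  0  0  0",
      "  2  3  1  0  0  0  0",
      "M  END"), collapse = "\n"),
    benzene = paste(c(
      "benzene", "  adcbiotx", "",
      "  6  6  0  0  0  0  0  0  0  0999 V2000",
      "    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    0.0000   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "   -0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "  1  2  2  0  0  0  0",
      "  2  3  1  0  0  0  0",
      "  3  4  2  0  0  0  0",
      "  4  5  1  0  0  0  0",
      "  5  6  2  0  0  0  0",
      "  6  1  1  0  0  0  0",
      "M  END"), collapse = "\n"),
    n_methylmaleimide = paste(c(
      "N-methylmaleimide", "  adcbiotx", "",
      "  8  8  0  0  0  0  0  0  0  0999 V2000",
      "    0.0000    1.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
      "    0.9511    0.3090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    0.5878   -0.8090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "   -0.5878   -0.8090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "   -0.9511    0.3090    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    1.9021    0.6180    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
      "   -1.9021    0.6180    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
      "    0.0000    2.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "  1  2  1  0  0  0  0",
      "  2  3  1  0  0  0  0",
      "  3  4  2  0  0  0  0",
      "  4  5  1  0  0  0  0",
      "  5  1  1  0  0  0  0",
      "  2  6  2  0  0  0  0",
      "  5  7  2  0  0  0  0",
      "  1  8  1  0  0  0  0",
      "M  END"), collapse = "\n")
  )
}
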