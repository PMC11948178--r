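#' Enumerate constrained bond cleavages of a linker-payload
#'
#' Considers every subset of 1..`max_bonds` non-ring bonds, removes the
#' subset, and keeps the connected component containing the attachment atom
#' (cleavages are filtered by the conjugation site: only fragments still
#' bonded to the antibody cysteine are observable on the intact protein).
#' A subset is valid only when every broken bond touches the retained
#' component; otherwise the cut duplicates a smaller one. Each broken-bond
#' stub on the retained fragment is capped (one hydrogen by default).
#'
#' @param graph a [mol_graph()].
#' @param max_bonds maximum bonds broken simultaneously (1..3; default 2,
#'   with ring bonds never broken).
#' @param cap stub chemistry on the retained fragment: `"H"` adds one
#'   hydrogen per stub (homolysis + H transfer, the common metabolite-software
#'   default), `"minusH"` removes one, `"none"` leaves the bare stub.
#' @return tibble with one row per cleavage product: `broken_bonds`
#'   (bond ids joined by `+`), `n_bonds`, `retained_formula`, `loss_formula`
#'   (the lost atoms, uncapped), `n_caps`, `mono_mass`, `avg_mass`,
#'   `retained_atoms` (list column), and `duplicate_formula` flagging
#'   products whose retained formula occurs more than once.
#' @export
#' @examples
#' g <- parse_structure(example_mol("ethanol"), attachment = 1)
#' enumerate_cleavages(g)
enumerate_cleavages <- function(graph, max_bonds = 2L,
                                cap = c("H", "minusH", "none")) {
  cap <- match.arg(cap)
  stopifnot(inherits(graph, "mol_graph"))
  if (max_bonds < 1L || max_bonds > 3L) {
    abort("max_bonds must be between 1 and 3")
  }
  cap_h <- switch(cap, H = 1L, minusH = -1L, none = 0L)
  cleavable <- which(!graph$bonds$is_ring)
  if (!length(cleavable)) {
    return(empty_cleavage_tbl())
  }
  ig <- mol_igraph(graph)
  att <- graph$attachment_atom
  rows <- list()
  for (k in seq_len(min(max_bonds, length(cleavable)))) {
    subsets <- combn(cleavable, k, simplify = FALSE)
    for (S in subsets) {
      g2 <- igraph::delete_edges(ig, S)
      memb <- igraph::components(g2)$membership
      comp <- which(memb == memb[att])
      ends_in <- vapply(S, function(b) {
        (graph$bonds$i[b] %in% comp) + (graph$bonds$j[b] %in% comp)
      }, numeric(1))
      if (any(ends_in == 0)) next  # bond not incident: duplicates a smaller cut
      n_caps <- sum(ends_in == 1)
      retained <- mol_formula(graph, comp, extra_h = cap_h * n_caps)
      lost <- mol_formula(graph, setdiff(seq_len(nrow(graph$atoms)), comp))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        broken_bonds = paste(S, collapse = "+"),
        n_bonds = k,
        retained_formula = formula_string(retained),
        loss_formula = formula_string(lost),
        n_caps = n_caps,
        mono_mass = formula_mass(retained, "monoisotopic"),
        avg_mass = formula_mass(retained, "average"),
        retained_atoms = list(comp)
      )
    }
  }
  if (!length(rows)) return(empty_cleavage_tbl())
  out <- dplyr::bind_rows(rows)
  out$duplicate_formula <- duplicated(out$retained_formula) |
    duplicated(out$retained_formula, fromLast = TRUE)
  out
}

empty_cleavage_tbl <- function() {
  tibble::tibble(
    broken_bonds = character(), n_bonds = integer(),
    retained_formula = character(), loss_formula = character(),
    n_caps = integer(), mono_mass = double(), avg_mass = double(),
    retained_atoms = list(), duplicate_formula = logical()
  )
}

#' Built-in linker-payload biotransformations
#'
#' The modification scheme applied on top of cleavage products: hydrolysis
#' (+H2O, the thiosuccinimide ring-opening chemistry), oxidative deamidation
#' to the alcohol (R-NH2 to R-OH, net -NH+O), and the two combined.
#'
#' @return tibble with `name`, `formula_delta` (signed formula string),
#'   `mono_delta`, `avg_delta`.
#' @export
default_biotransformations <- function() {
  deltas <- list(
    hydrolysis = c(H = 2L, O = 1L),
    deamidation = c(N = -1L, H = -1L, O = 1L),
    `hydrolysis + deamidation` = c(H = 1L, O = 2L, N = -1L)
  )
  tibble::tibble(
    name = names(deltas),
    formula_delta = vapply(deltas, formula_string, character(1)),
    mono_delta = vapply(deltas, formula_mass, numeric(1), mode = "monoisotopic"),
    avg_delta = vapply(deltas, formula_mass, numeric(1), mode = "average")
  )
}

#' Expand cleavages and biotransformations into a delta-mass library
#'
#' Builds the candidate space used for peak matching: every cleavage
#' product unmodified, every cleavage product combined with each
#' biotransformation, and the intact parent conjugate with each
#' biotransformation. The unmodified parent is not an entry (it is the
#' reference conjugate), so the library size is
#' `(1 + n_mods) * n_cleavages + n_mods`.
#'
#' @param cleavages tibble from [enumerate_cleavages()]; may be empty.
#' @param biotransformations tibble as [default_biotransformations()].
#' @param parent the parent linker-payload: a [mol_graph()] or a formula
#'   string; needed for parent-only entries and for deltas vs the parent.
#' @return tibble with `name`, `formula_delta_vs_parent`,
#'   `neutral_mono_mass`, `neutral_avg_mass`, `delta_mono`, `delta_avg`,
#'   `source`, `duplicate_formula`. Names are disambiguated with numeric
#'   suffixes when needed. Entries whose absolute formula would go negative
#'   (e.g. deamidation of a nitrogen-free fragment) are skipped with a
#'   warning.
#' @export
expand_library <- function(cleavages,
                           biotransformations = default_biotransformations(),
                           parent) {
  parent_f <- if (inherits(parent, "mol_graph")) mol_formula(parent)
              else parse_formula(parent)
  parent_mono <- formula_mass(parent_f, "monoisotopic")
  parent_avg <- formula_mass(parent_f, "average")
  mods <- biotransformations
  rows <- list()
  skipped <- 0L
  add_entry <- function(name, abs_f, source, dup) {
    if (any(abs_f < 0L)) {
      skipped <<- skipped + 1L
      return(invisible(NULL))
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name,
      formula_delta_vs_parent = formula_string(formula_sum(abs_f, -parent_f)),
      neutral_mono_mass = formula_mass(abs_f, "monoisotopic"),
      neutral_avg_mass = formula_mass(abs_f, "average"),
      delta_mono = formula_mass(abs_f, "monoisotopic") - parent_mono,
      delta_avg = formula_mass(abs_f, "average") - parent_avg,
      source = source,
      duplicate_formula = dup
    )
  }
  if (nrow(cleavages)) {
    for (r in seq_len(nrow(cleavages))) {
      cf <- parse_formula(cleavages$retained_formula[r])
      base_name <- paste0("loss of ", cleavages$loss_formula[r])
      src <- paste0("bonds ", cleavages$broken_bonds[r])
      add_entry(base_name, cf, src, cleavages$duplicate_formula[r])
      for (m in seq_len(nrow(mods))) {
        add_entry(paste0(base_name, " + ", mods$name[m]),
                  formula_sum(cf, parse_formula(mods$formula_delta[m])),
                  paste0(src, "; ", mods$name[m]),
                  cleavages$duplicate_formula[r])
      }
    }
  }
  for (m in seq_len(nrow(mods))) {
    add_entry(mods$name[m],
              formula_sum(parent_f, parse_formula(mods$formula_delta[m])),
              paste0("parent; ", mods$name[m]), FALSE)
  }
  if (skipped > 0L) {
    warn(paste0(skipped, " entr", if (skipped == 1L) "y" else "ies",
                " skipped: modification gives a non-physical formula"))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  if (any(out$neutral_mono_mass <= 0)) {
    abort("library entry with non-positive neutral mass")
  }
  # disambiguate repeated names with numeric suffixes
  out <- out |>
    dplyr::group_by(.data$name) |>
    dplyr::mutate(.n = dplyr::row_number(), .sz = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(name = ifelse(.data$.sz > 1L,
                                paste0(.data$name, " (", .data$.n, ")"),
                                .data$name)) |>
    dplyr::select(-".n", -".sz")
  out
}

#' Write a delta-mass library to CSV
#'
#' @param entries tibble from [expand_library()].
#' @param path output CSV path (UTF-8, header row, '.' decimal separator).
#' @export
write_library <- function(entries, path) {
  if (!nrow(entries)) abort("refusing to write an empty library")
  readr::write_csv(
    entries[, c("name", "formula_delta_vs_parent",
                "neutral_mono_mass", "neutral_avg_mass", "source")],
    path
  )
  invisible(path)
}

#' Read a delta-mass library from CSV
#'
#' Restores the columns written by [write_library()]; mass deltas are
#' recomputed from the signed delta formula so the file round-trips.
#'
#' @param path CSV path.
#' @export
read_library <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         name = "c", formula_delta_vs_parent = "c",
                         neutral_mono_mass = "d", neutral_avg_mass = "d",
                         source = "c"))
  x$formula_delta_vs_parent[is.na(x$formula_delta_vs_parent)] <- ""
  x$delta_mono <- vapply(x$formula_delta_vs_parent, formula_mass, numeric(1),
                         mode = "monoisotopic", USE.NAMES = FALSE)
  x$delta_avg <- vapply(x$formula_delta_vs_parent, formula_mass, numeric(1),
                        mode = "average", USE.NAMES = FALSE)
  x
}
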