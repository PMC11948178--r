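# Residue (not free amino acid) elemental compositions, one-letter codes.
AA_FORMULA <- list(
  G = c(C = 2L, H = 3L, N = 1L, O = 1L),
  A = c(C = 3L, H = 5L, N = 1L, O = 1L),
  S = c(C = 3L, H = 5L, N = 1L, O = 2L),
  P = c(C = 5L, H = 7L, N = 1L, O = 1L),
  V = c(C = 5L, H = 9L, N = 1L, O = 1L),
  T = c(C = 4L, H = 7L, N = 1L, O = 2L),
  C = c(C = 3L, H = 5L, N = 1L, O = 1L, S = 1L),
  L = c(C = 6L, H = 11L, N = 1L, O = 1L),
  I = c(C = 6L, H = 11L, N = 1L, O = 1L),
  N = c(C = 4L, H = 6L, N = 2L, O = 2L),
  D = c(C = 4L, H = 5L, N = 1L, O = 3L),
  Q = c(C = 5L, H = 8L, N = 2L, O = 2L),
  K = c(C = 6L, H = 12L, N = 2L, O = 1L),
  E = c(C = 5L, H = 7L, N = 1L, O = 3L),
  M = c(C = 5L, H = 9L, N = 1L, O = 1L, S = 1L),
  H = c(C = 6L, H = 7L, N = 3L, O = 1L),
  F = c(C = 9L, H = 9L, N = 1L, O = 1L),
  R = c(C = 6L, H = 12L, N = 4L, O = 1L),
  Y = c(C = 9L, H = 9L, N = 1L, O = 2L),
  W = c(C = 11L, H = 10L, N = 2L, O = 1L)
)

# Glycan compositions as residue (dehydrated monosaccharide) counts; the
# summed residue masses equal the standard net glycan addition mass.
GLYCAN_COMPOSITION <- list(
  none = character(0),
  G0   = c(HexNAc = 4L, Hex = 3L),
  G0F  = c(HexNAc = 4L, Hex = 3L, Fuc = 1L),
  G1F  = c(HexNAc = 4L, Hex = 4L, Fuc = 1L),
  G2F  = c(HexNAc = 4L, Hex = 5L, Fuc = 1L),
  Man5 = c(HexNAc = 2L, Hex = 5L)
)

MONOSACCHARIDE_FORMULA <- list(
  Hex = c(C = 6L, H = 10L, O = 5L),
  HexNAc = c(C = 8L, H = 13L, N = 1L, O = 5L),
  Fuc = c(C = 6L, H = 10L, O = 4L)
)

# Cysteinylation: capping of a free thiol by free cysteine via disulfide,
# net addition of a disulfide-linked cysteinyl group.
CYSTEINYL_FORMULA <- c(C = 3L, H = 5L, N = 1L, O = 2L, S = 1L)

h_mass <- function(mode) {
  if (mode == "monoisotopic") ELEMENT_MONO[["H"]] else ELEMENT_AVG[["H"]]
}

chain_formula <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(AA_FORMULA))
  if (length(bad)) {
    abort(paste0("invalid residue code '", aa[bad[1]], "' at position ", bad[1]))
  }
  counts <- table(aa)
  parts <- lapply(names(counts), function(r) AA_FORMULA[[r]] * as.integer(counts[[r]]))
  do.call(formula_sum, c(parts, list(c(H = 2L, O = 1L))))
}

#' Mass of a protein chain
#'
#' Residue masses plus one water, minus two hydrogens per intrachain
#' disulfide bond.
#'
#' @param sequence amino-acid string (standard one-letter codes).
#' @param n_disulfides number of intrachain disulfide bonds.
#' @param mode `"monoisotopic"` or `"average"`.
#' @return mass in Da.
#' @export
#' @examples
#' chain_mass("G")               # glycine, 75.03203
#' chain_mass("CC", n_disulfides = 1)
chain_mass <- function(sequence, n_disulfides = 0L,
                       mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  formula_mass(chain_formula(sequence), mode) - 2 * n_disulfides * h_mass(mode)
}

#' Mass delta from common fixed antibody modifications
#'
#' C-terminal lysine loss and N-terminal glutamine-to-pyroglutamate
#' conversion (-NH3), each applied when the sequence termini allow it and
#' the rule is enabled.
#'
#' @param sequence amino-acid string.
#' @param lys_loss apply C-terminal K loss when the chain ends in K.
#' @param pyro_glu apply pyroGlu conversion when the chain starts with Q.
#' @param mode mass scale.
#' @return signed mass delta in Da (0 when neither rule fires).
#' @export
apply_fixed_mods <- function(sequence, lys_loss = TRUE, pyro_glu = TRUE,
                             mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  d <- 0
  if (lys_loss && grepl("K$", sequence)) {
    d <- d - formula_mass(AA_FORMULA[["K"]], mode)
  }
  if (pyro_glu && grepl("^Q", sequence)) {
    d <- d - formula_mass(c(N = 1L, H = 3L), mode)
  }
  d
}

#' Mass of a common IgG N-glycan
#'
#' @param glycan_name one of `r paste(names(GLYCAN_COMPOSITION), collapse = ", ")`.
#' @param mode mass scale.
#' @return net glycan addition mass in Da (0 for `"none"`).
#' @export
#' @examples
#' glycan_mass("G0F")  # 1444.5339 monoisotopic
glycan_mass <- function(glycan_name, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (!glycan_name %in% names(GLYCAN_COMPOSITION)) {
    abort(paste0("unknown glycan name: '", glycan_name, "'"))
  }
  comp <- GLYCAN_COMPOSITION[[glycan_name]]
  if (!length(comp)) return(0)
  sum(vapply(names(comp), function(m) {
    comp[[m]] * formula_mass(MONOSACCHARIDE_FORMULA[[m]], mode)
  }, numeric(1)))
}

#' Read antibody chains from FASTA
#'
#' The first token of each description line is the chain id; conjugation
#' sites and intrachain disulfide counts default to the IgG1 cysteine-
#' conjugate convention (LC: 1 site, 2 disulfides; HC: 3 sites, 4
#' disulfides) by chain-id prefix, overridable per chain.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param n_sites,n_disulfides optional named vectors (by chain id)
#'   overriding the defaults.
#' @return tibble with `chain_id`, `sequence`, `n_sites`, `n_disulfides`.
#' @export
read_chains <- function(path, n_sites = NULL, n_disulfides = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) abort("no sequences in FASTA file")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  def_sites <- ifelse(grepl("^LC", ids), 1L, ifelse(grepl("^HC", ids), 3L, 0L))
  def_ss <- ifelse(grepl("^LC", ids), 2L, ifelse(grepl("^HC", ids), 4L, 0L))
  tibble::tibble(
    chain_id = ids,
    sequence = as.character(ss),
    n_sites = as.integer(if (is.null(n_sites)) def_sites
                         else dplyr::coalesce(unname(n_sites[ids]), def_sites)),
    n_disulfides = as.integer(if (is.null(n_disulfides)) def_ss
                              else dplyr::coalesce(unname(n_disulfides[ids]), def_ss))
  )
}

# All multisets of size d over options 1..n, as count vectors.
multiset_counts <- function(n, d) {
  if (d == 0L) return(list(integer(n)))
  if (n == 1L) return(list(d))
  out <- list()
  for (k in 0:d) {
    for (rest in multiset_counts(n - 1L, d - k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

mod_label_part <- function(name, count) {
  if (name == "hydrolysis") return(paste0(count, "H2O"))
  if (name == "deamidation") return(paste0(count, "Deam"))
  if (grepl("[ +]", name)) return(paste0(count, "×[", name, "]"))
  paste0(count, "×", name)
}

#' Enumerate candidate proteoforms for an antibody chain
#'
#' Cartesian enumeration over drug load (DAR), glycans, cysteinylation of
#' unconjugated sites, and per-payload modification assignments drawn from
#' the delta-mass library (payloads are indistinguishable, so assignments
#' are multisets; a DAR-3 chain with a hydrolysis-only library yields the
#' 0..3 x H2O ladder).
#'
#' @param chains tibble as from [read_chains()] (or one row of it).
#' @param conjugate_mono,conjugate_avg neutral mass of the intact parent
#'   linker-payload addition, per scale.
#' @param library delta-mass library tibble ([expand_library()] /
#'   [read_library()]) or NULL for conjugate-intact-only candidates.
#' @param dar_range integer vector of payload counts to consider per chain
#'   (default `0:n_sites`).
#' @param glycans character vector of glycan names applied to HC-like
#'   chains; chains with 0 disulfide-free context still get `"none"`.
#' @param cys_cap allow cysteinylation of each unconjugated site.
#' @param lys_loss,pyro_glu fixed-modification switches.
#' @param max_candidates combinatorial guard; exceeding it is an error
#'   suggesting a narrower `dar_range` or library.
#' @return tibble of candidates: `chain_id`, `dar`, `glycan`, `caps`,
#'   `mods`, `label`, `theo_mono_mass`, `theo_avg_mass`, sorted by
#'   theoretical mass and unique by label.
#' @export
enumerate_candidates <- function(chains, conjugate_mono, conjugate_avg = NULL,
                                 library = NULL, dar_range = NULL,
                                 glycans = "none", cys_cap = TRUE,
                                 lys_loss = TRUE, pyro_glu = TRUE,
                                 max_candidates = 50000L) {
  if (is.null(conjugate_avg)) conjugate_avg <- conjugate_mono
  if (is.null(library) || !nrow(library)) {
    library <- tibble::tibble(name = character(), delta_mono = double(),
                              delta_avg = double())
  }
  L <- nrow(library)
  bad_g <- setdiff(glycans, names(GLYCAN_COMPOSITION))
  if (length(bad_g)) abort(paste0("unknown glycan name: '", bad_g[1], "'"))
  rows <- list()
  for (ci in seq_len(nrow(chains))) {
    ch <- chains[ci, ]
    dr <- if (is.null(dar_range)) 0:ch$n_sites else intersect(dar_range, 0:ch$n_sites)
    total <- sum(vapply(dr, function(d) {
      choose(d + L, L) * (if (cys_cap) ch$n_sites - d + 1L else 1L) * length(glycans)
    }, numeric(1)))
    if (total > max_candidates) {
      abort(paste0("candidate space for chain ", ch$chain_id, " has ", total,
                   " combinations (> ", max_candidates,
                   "); restrict dar_range or the delta-mass library"))
    }
    base_mono <- chain_mass(ch$sequence, ch$n_disulfides, "monoisotopic") +
      apply_fixed_mods(ch$sequence, lys_loss, pyro_glu, "monoisotopic")
    base_avg <- chain_mass(ch$sequence, ch$n_disulfides, "average") +
      apply_fixed_mods(ch$sequence, lys_loss, pyro_glu, "average")
    for (d in dr) {
      assignments <- multiset_counts(L + 1L, d)  # slot 1 = intact payload
      caps_opts <- if (cys_cap) 0:(ch$n_sites - d) else 0L
      for (asg in assignments) {
        modded <- asg[-1]
        mod_mono <- if (L) sum(modded * library$delta_mono) else 0
        mod_avg <- if (L) sum(modded * library$delta_avg) else 0
        mod_lab <- if (L && any(modded > 0)) {
          paste(mapply(mod_label_part, library$name[modded > 0],
                       modded[modded > 0]), collapse = " + ")
        } else ""
        for (cc in caps_opts) {
          for (g in glycans) {
            lab <- paste(c(
              ch$chain_id,
              if (d > 0) paste0(d, "PL"),
              if (cc > 0) paste0(cc, "Cys"),
              if (nzchar(mod_lab)) mod_lab,
              if (g != "none") g
            ), collapse = " + ")
            rows[[length(rows) + 1L]] <- tibble::tibble(
              chain_id = ch$chain_id, dar = d, glycan = g, caps = cc,
              mods = mod_lab, label = lab,
              theo_mono_mass = base_mono + d * conjugate_mono + mod_mono +
                cc * formula_mass(CYSTEINYL_FORMULA, "monoisotopic") +
                glycan_mass(g, "monoisotopic"),
              theo_avg_mass = base_avg + d * conjugate_avg + mod_avg +
                cc * formula_mass(CYSTEINYL_FORMULA, "average") +
                glycan_mass(g, "average")
            )
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$label, .keep_all = TRUE) |>
    dplyr::arrange(.data$theo_mono_mass)
  if (any(out$theo_mono_mass <= 0)) abort("candidate with non-positive mass")
  out
}

#' Parse a proteoform candidate label back into its components
#'
#' Inverse of the label written by [enumerate_candidates()].
#'
#' @param label label string such as `"HC + 2PL + 1Cys + 1H2O + G0F"`.
#' @return list with `chain_id`, `dar`, `caps`, `mods` (named counts),
#'   `glycan`.
#' @export
parse_label <- function(label) {
  # bracketed mod names may themselves contain " + "; rejoin tokens until
  # brackets balance
  raw <- strsplit(label, " + ", fixed = TRUE)[[1]]
  parts <- character(0)
  buf <- ""
  for (tok in raw) {
    buf <- if (nzchar(buf)) paste(buf, tok, sep = " + ") else tok
    n_open <- nchar(gsub("[^[]", "", buf))
    n_close <- nchar(gsub("[^]]", "", buf))
    if (n_open == n_close) {
      parts <- c(parts, buf)
      buf <- ""
    }
  }
  if (nzchar(buf)) abort(paste0("unbalanced brackets in label: '", label, "'"))
  out <- list(chain_id = parts[1], dar = 0L, caps = 0L,
              mods = integer(0), glycan = "none")
  for (p in parts[-1]) {
    if (grepl("^[0-9]+PL$", p)) {
      out$dar <- as.integer(sub("PL$", "", p))
    } else if (grepl("^[0-9]+Cys$", p)) {
      out$caps <- as.integer(sub("Cys$", "", p))
    } else if (grepl("^[0-9]+H2O$", p)) {
      out$mods <- c(out$mods, setNames(as.integer(sub("H2O$", "", p)), "hydrolysis"))
    } else if (grepl("^[0-9]+Deam$", p)) {
      out$mods <- c(out$mods, setNames(as.integer(sub("Deam$", "", p)), "deamidation"))
    } else if (grepl("^[0-9]+×", p)) {
      n <- as.integer(sub("×.*$", "", p))
      nm <- sub("^[0-9]+×", "", p)
      nm <- sub("^\\[(.*)\\]$", "\\1", nm)
      out$mods <- c(out$mods, setNames(n, nm))
    } else if (p %in% names(GLYCAN_COMPOSITION)) {
      out$glycan <- p
    } else {
      abort(paste0("cannot parse label component: '", p, "'"))
    }
  }
  out
}

#' Write proteoform candidates to CSV
#' @param candidates tibble from [enumerate_candidates()].
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  readr::write_csv(candidates, path)
  invisible(path)
}

#' Read proteoform candidates from CSV
#' @param path CSV written by [write_candidates()].
#' @export
read_candidates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chain_id = "c", dar = "i", glycan = "c", caps = "i",
                    mods = "c", label = "c",
                    theo_mono_mass = "d", theo_avg_mass = "d")) |>
    dplyr::mutate(mods = dplyr::coalesce(.data$mods, ""))
}
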