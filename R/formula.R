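#' @importFrom rlang .data abort warn
#' @importFrom stats approx dnorm median mad rbinom rnorm runif setNames sd
#' @importFrom utils combn head tail
NULL

# Mass of a proton (Da); used for m/z <-> neutral conversions.
PROTON_MASS <- 1.00727646

# Monoisotopic masses: most abundant isotope (CODATA/AME values, 1e-6 Da).
ELEMENT_MONO <- c(
  H = 1.00782503, C = 12.0, N = 14.00307401, O = 15.99491462,
  S = 31.97207117, P = 30.97376200, F = 18.99840316, Cl = 34.96885268,
  Br = 78.91833760, I = 126.90447300, Na = 22.98976928, K = 38.96370649
)

# Standard atomic weights (IUPAC 2021, conventional values).
ELEMENT_AVG <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.973762, F = 18.998403, Cl = 35.45,
  Br = 79.904, I = 126.90447, Na = 22.98976928, K = 39.0983
)

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas such as `"C6H12O6"` or `"H2O"`. Two-letter
#' element symbols are recognised (`Cl`, `Br`, `Na`, ...). Signed formulas
#' (deltas) may interleave `+`/`-` signs before element runs, e.g.
#' `"-C2H4+O"`.
#'
#' @param x a single formula string; the empty string is the empty formula.
#' @return named integer vector of element counts (possibly negative for
#'   signed delta formulas), empty for the empty formula.
#' @export
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("-NH+O")  # deamidation to alcohol
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("\\s", "", x)
  if (x == "" || x == "0") {
    return(setNames(integer(0), character(0)))
  }
  m <- gregexpr("([+-])|([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    abort(paste0("cannot parse formula: '", x, "'"))
  }
  counts <- list()
  sign <- 1L
  for (tk in toks) {
    if (tk == "+") { sign <- 1L; next }
    if (tk == "-") { sign <- -1L; next }
    el <- gsub("[0-9]", "", tk)
    n <- gsub("[^0-9]", "", tk)
    n <- if (n == "") 1L else as.integer(n)
    if (!el %in% names(ELEMENT_MONO)) {
      abort(paste0("unknown element symbol: '", el, "'"))
    }
    counts[[el]] <- (counts[[el]] %||% 0L) + sign * n
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine element-count vectors
#'
#' @param ... named integer vectors (element counts), as from
#'   [parse_formula()]. Counts for shared elements are summed.
#' @return named integer vector; zero-count elements are dropped.
#' @export
formula_sum <- function(...) {
  vs <- list(...)
  els <- unique(unlist(lapply(vs, names)))
  out <- setNames(integer(length(els)), els)
  for (v in vs) {
    if (length(v)) out[names(v)] <- out[names(v)] + v
  }
  out[out != 0L]
}

#' Negate an element-count vector
#' @param v named integer vector.
#' @export
formula_negate <- function(v) -v

#' Format an element-count vector as a Hill-order formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetical. Negative
#' counts produce a signed string (`"-C2H4+O"` style), used for delta
#' formulas relative to a parent molecule.
#'
#' @param v named integer vector of element counts.
#' @return formula string; `""` for the empty formula.
#' @export
formula_string <- function(v) {
  v <- v[v != 0L]
  if (!length(v)) return("")
  ord <- function(els) {
    els[order(match(els, c("C", "H"), nomatch = 3L), els)]
  }
  part <- function(w, prefix) {
    els <- ord(names(w))
    paste0(prefix, paste0(els, ifelse(w[els] == 1L, "", w[els]), collapse = ""))
  }
  pos <- v[v > 0L]
  neg <- -v[v < 0L]
  if (!length(neg)) return(part(pos, ""))
  if (!length(pos)) return(part(neg, "-"))
  paste0(part(pos, "+"), part(neg, "-"))
}

#' Mass of a molecular formula
#'
#' @param formula a formula string or a named element-count vector.
#' @param mode `"monoisotopic"` (most abundant isotope per element) or
#'   `"average"` (standard atomic weights).
#' @return mass in Da; 0 for the empty formula. Signed formulas give a
#'   signed mass delta.
#' @export
#' @examples
#' formula_mass("H2O")                # 18.010565
#' formula_mass("H2O", "average")     # 18.015
formula_mass <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  v <- if (is.character(formula)) parse_formula(formula) else formula
  if (!length(v)) return(0)
  tab <- if (mode == "monoisotopic") ELEMENT_MONO else ELEMENT_AVG
  bad <- setdiff(names(v), names(tab))
  if (length(bad)) abort(paste0("unknown element symbol: '", bad[1], "'"))
  sum(tab[names(v)] * v)
}

#' Convert an MH+ ion mass to a neutral mass
#'
#' Metabolite software commonly exports singly protonated monoisotopic
#' masses; subtracting one proton gives the neutral species mass.
#'
#' @param mh_mass MH+ mass in Da; must exceed the proton mass.
#' @return neutral mass in Da.
#' @export
#' @examples
#' mh_to_neutral(19.017841)  # water
mh_to_neutral <- function(mh_mass) {
  if (any(mh_mass <= PROTON_MASS)) {
    abort("MH+ mass must exceed the proton mass (1.00727646 Da)")
  }
  mh_mass - PROTON_MASS
}
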