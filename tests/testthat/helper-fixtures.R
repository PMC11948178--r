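# MOL text builder for test molecules (elements + bond matrix i, j, order).
make_mol <- function(title, elements, bonds) {
  n <- length(elements)
  bm <- if (length(bonds)) do.call(rbind, bonds) else matrix(0L, 0, 3)
  header <- c(title, "  test", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bm)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   seq_len(n) * 0.1, 0, 0, elements)
  bl <- if (nrow(bm)) sprintf("%3d%3d%3d  0  0  0  0", bm[, 1], bm[, 2], bm[, 3])
        else character(0)
  paste(c(header, atoms, bl, "M  END"), collapse = "\n")
}

# Linear chain of carbons: C1-C2-...-Cn.
chain_mol <- function(n) {
  make_mol(paste0("chain", n), rep("C", n),
           lapply(seq_len(n - 1), function(i) c(i, i + 1, 1L)))
}

# Star: centre C with three methyl branches.
star_mol <- function() {
  make_mol("star", rep("C", 4), list(c(1, 2, 1L), c(1, 3, 1L), c(1, 4, 1L)))
}

# Brute-force cleavage oracle, independent of the package internals:
# plain adjacency-list BFS, exhaustive subsets of ALL bonds, the same
# validity rule (skip ring bonds; every broken bond incident to the
# attachment component), H-capped retained formulas.
brute_force_cleavages <- function(graph, max_bonds = 2L) {
  nb <- nrow(graph$bonds)
  natoms <- nrow(graph$atoms)
  bi <- graph$bonds$i
  bj <- graph$bonds$j
  comp_of <- function(removed) {
    adj <- vector("list", natoms)
    for (b in seq_len(nb)) {
      if (b %in% removed) next
      adj[[bi[b]]] <- c(adj[[bi[b]]], bj[b])
      adj[[bj[b]]] <- c(adj[[bj[b]]], bi[b])
    }
    seen <- logical(natoms)
    queue <- graph$attachment_atom
    seen[queue] <- TRUE
    while (length(queue)) {
      a <- queue[1]
      queue <- queue[-1]
      for (x in adj[[a]]) if (!seen[x]) { seen[x] <- TRUE; queue <- c(queue, x) }
    }
    which(seen)
  }
  # ring bond: endpoints still connected after removing the bond alone
  is_ring <- vapply(seq_len(nb), function(b) {
    comp <- comp_of(b)
    bi[b] %in% comp == bj[b] %in% comp
  }, logical(1))
  out <- character(0)
  for (k in seq_len(max_bonds)) {
    if (k > nb) break
    for (S in utils::combn(seq_len(nb), k, simplify = FALSE)) {
      if (any(is_ring[S])) next
      comp <- comp_of(S)
      ends_in <- vapply(S, function(b) (bi[b] %in% comp) + (bj[b] %in% comp),
                        numeric(1))
      if (any(ends_in == 0)) next
      f <- mol_formula(graph, comp, extra_h = sum(ends_in == 1))
      out <- c(out, formula_string(f))
    }
  }
  out
}

# Candidates table for annotation tests.
toy_candidates <- function(theo, labels = paste0("cand", seq_along(theo)),
                           chain = "LC") {
  tibble::tibble(chain_id = chain, label = labels,
                 theo_avg_mass = theo, theo_mono_mass = theo)
}
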