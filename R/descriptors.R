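# Molecular descriptor panel.
#
# Twelve structure-only descriptors in a fixed order; the 3- and 6-descriptor
# panels are ordered prefixes of the 12-panel:
#   1 mw             average molecular weight (g/mol, implicit H included)
#   2 logp           octanol-water partition estimate, coarse atomic
#                    contributions (Crippen-style scheme documented below)
#   3 exact_mass     monoisotopic molecular mass (g/mol)
#   4 rotatable_bonds  non-ring single bonds between two non-terminal heavy atoms
#   5 hbd            H-bond donors: N or O bearing at least one H
#   6 hba            H-bond acceptors: any N or O (Lipinski-style count)
#   7 aromatic_rings perceived smallest rings whose bonds are all aromatic
#   8 frac_csp3      fraction of carbons with only single non-aromatic bonds
#   9 n_count        nitrogen atoms
#  10 o_count        oxygen atoms
#  11 tpsa           topological polar surface area, Ertl-style N/O fragment
#                    contributions (S and P contribute 0), Angstrom^2
#  12 radical_electrons  unpaired electrons (0 for all closed-shell input this
#                    parser accepts; kept for panel completeness)

DESCRIPTOR_NAMES <- c("mw", "logp", "exact_mass", "rotatable_bonds", "hbd",
                      "hba", "aromatic_rings", "frac_csp3", "n_count",
                      "o_count", "tpsa", "radical_electrons")

AVERAGE_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998403, P = 30.973762, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.90447)

MONOISOTOPIC_MASS <- c(H = 1.00782503, B = 11.00930536, C = 12.0,
                       N = 14.00307401, O = 15.99491462, F = 18.99840316,
                       P = 30.97376200, S = 31.97207117, Cl = 34.96885268,
                       Br = 78.91833760, I = 126.90447190)

# coarse atomic logP contributions; heavy atom by class plus per-H terms
.LOGP_HEAVY <- function(el, aromatic, sp3, carbonyl_o) {
  if (el == "C") {
    if (aromatic) 0.29 else if (sp3) 0.13 else 0.08
  } else if (el == "N") {
    if (aromatic) -0.35 else -0.60
  } else if (el == "O") {
    if (aromatic) -0.05 else if (carbonyl_o) -0.25 else -0.40
  } else switch(el,
    S = 0.55, P = -0.50, F = 0.42, Cl = 0.65, Br = 0.86, I = 1.20, B = -0.10,
    0.0)
}
.LOGP_H_ON_C <- 0.123
.LOGP_H_ON_HET <- -0.30

# Ertl-style TPSA contributions for N and O environments.
# Keyed on (element, aromatic, charge sign, H count, #single, #double, #triple).
.tpsa_contrib <- function(el, aromatic, charge, h, n1, n2, n3) {
  if (el == "N") {
    if (charge > 0L) {
      if (n2 >= 1L) return(11.68)          # nitro-type N+
      if (h == 0L) return(0.00)            # quaternary N+
      if (h == 1L) return(4.44)
      if (h == 2L) return(16.61)
      return(27.64)
    }
    if (aromatic) {
      if (h >= 1L) return(15.79)           # pyrrole-type [nH]
      if (n1 + n2 >= 3L) return(4.93)      # substituted aromatic n
      return(12.89)                        # pyridine-type n
    }
    if (n3 >= 1L) return(23.79)            # nitrile
    if (n2 >= 1L) return(12.36)            # imine-type =N-
    if (h == 0L) return(3.24)
    if (h == 1L) return(12.03)
    return(26.02)
  }
  if (el == "O") {
    if (charge < 0L) return(23.06)
    if (aromatic) return(13.14)
    if (n2 >= 1L) return(17.07)            # carbonyl O
    if (h >= 1L) return(20.23)             # hydroxyl
    return(9.23)                           # ether/ester O
  }
  0.0
}

.atom_bond_counts <- function(mol) {
  n <- nrow(mol$atoms)
  cnt <- matrix(0L, n, 3)   # columns: single, double, triple (aromatic -> single)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- min(mol$bonds$order[k], 3L)
    cnt[mol$bonds$a1[k], o] <- cnt[mol$bonds$a1[k], o] + 1L
    cnt[mol$bonds$a2[k], o] <- cnt[mol$bonds$a2[k], o] + 1L
  }
  cnt
}

#' Molecular descriptors of a parsed molecule
#'
#' Computes the descriptor panel (see the package vignette for definitions and
#' provenance of each quantity). The three panels are ordered prefixes:
#' `D3` (molecular weight, logP, exact mass) is the head of `D6` (adds
#' rotatable bonds, H-bond donors, H-bond acceptors), which is the head of
#' `D12` (adds aromatic rings, sp3-carbon fraction, N count, O count, TPSA,
#' radical electrons). All values are computed from the structure only.
#'
#' @param mol A `mol_record` from [parse_smiles()].
#' @param descriptor_set One of `"D3"`, `"D6"`, `"D12"`.
#' @return An object of class `descriptor_vector`: list with named numeric
#'   `values` and `descriptor_set`.
#' @export
descriptors <- function(mol, descriptor_set = c("D12", "D6", "D3")) {
  stopifnot(is_mol_record(mol))
  descriptor_set <- match.arg(descriptor_set)
  atoms <- mol$atoms
  bonds <- mol$bonds
  cnt <- .atom_bond_counts(mol)
  n <- nrow(atoms)

  h_tot <- sum(atoms$h_count)
  mw <- sum(AVERAGE_MASS[atoms$element]) + h_tot * AVERAGE_MASS[["H"]]
  exact_mass <- sum(MONOISOTOPIC_MASS[atoms$element]) +
    h_tot * MONOISOTOPIC_MASS[["H"]]

  carbonyl_o <- atoms$element == "O" & cnt[, 2] >= 1L & !atoms$aromatic
  sp3 <- cnt[, 2] == 0L & cnt[, 3] == 0L & !atoms$aromatic
  logp <- 0
  for (i in seq_len(n)) {
    logp <- logp + .LOGP_HEAVY(atoms$element[i], atoms$aromatic[i],
                               sp3[i], carbonyl_o[i])
    hterm <- if (atoms$element[i] == "C") .LOGP_H_ON_C else .LOGP_H_ON_HET
    logp <- logp + atoms$h_count[i] * hterm
  }

  heavy_degree <- atoms$degree
  rotatable <- 0L
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] == 1L && !bonds$aromatic[k] && !bonds$in_ring[k] &&
        heavy_degree[bonds$a1[k]] >= 2L && heavy_degree[bonds$a2[k]] >= 2L) {
      rotatable <- rotatable + 1L
    }
  }

  hbd <- sum(atoms$element %in% c("N", "O") & atoms$h_count >= 1L)
  hba <- sum(atoms$element %in% c("N", "O"))

  aromatic_rings <- 0L
  for (ring in mol$rings) {
    kset <- bonds$a1 %in% ring & bonds$a2 %in% ring & bonds$in_ring
    if (any(kset) && all(bonds$aromatic[kset])) {
      aromatic_rings <- aromatic_rings + 1L
    }
  }

  is_c <- atoms$element == "C"
  frac_csp3 <- if (sum(is_c) == 0L) 0 else sum(is_c & sp3) / sum(is_c)

  tpsa <- 0
  for (i in seq_len(n)) {
    tpsa <- tpsa + .tpsa_contrib(atoms$element[i], atoms$aromatic[i],
                                 atoms$charge[i], atoms$h_count[i],
                                 cnt[i, 1], cnt[i, 2], cnt[i, 3])
  }

  values <- c(
    mw = unname(mw), logp = logp, exact_mass = unname(exact_mass),
    rotatable_bonds = as.numeric(rotatable), hbd = as.numeric(hbd),
    hba = as.numeric(hba), aromatic_rings = as.numeric(aromatic_rings),
    frac_csp3 = frac_csp3, n_count = as.numeric(sum(atoms$element == "N")),
    o_count = as.numeric(sum(atoms$element == "O")), tpsa = tpsa,
    radical_electrons = 0
  )
  keep <- switch(descriptor_set, D3 = 1:3, D6 = 1:6, D12 = 1:12)
  structure(list(values = values[keep], descriptor_set = descriptor_set),
            class = "descriptor_vector")
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat(sprintf("<descriptor_vector %s>\n", x$descriptor_set))
  print(round(x$values, 4))
  invisible(x)
}
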