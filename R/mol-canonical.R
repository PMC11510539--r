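# Canonical atom ranking (Morgan-style iterative refinement with deterministic
# tie-breaking) and a canonical SMILES writer. The canonical form depends only
# on the perceived graph, so any two spellings of the same molecule write the
# same string.

bond_code <- function(bonds, k) {
  if (bonds$aromatic[k]) 4L else bonds$order[k]
}

# dense ranks of a character key vector
.dense_rank <- function(keys) match(keys, sort(unique(keys)))

canonical_ranks <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  adj <- vector("list", n)    # list of (neighbor, bond_code)
  for (k in seq_len(nrow(bonds))) {
    bc <- bond_code(bonds, k)
    a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
    adj[[a1]] <- rbind(adj[[a1]], c(a2, bc))
    adj[[a2]] <- rbind(adj[[a2]], c(a1, bc))
  }
  keys <- paste(atoms$element, atoms$aromatic, atoms$charge,
                atoms$h_count, atoms$degree, sep = "|")
  ranks <- .dense_rank(keys)
  refine <- function(ranks) {
    repeat {
      keys <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        nbkey <- if (is.null(nb)) "" else {
          pairs <- paste(nb[, 2], ranks[nb[, 1]], sep = ":")
          paste(sort(pairs), collapse = ",")
        }
        paste(ranks[i], nbkey, sep = "#")
      }, "")
      new_ranks <- .dense_rank(keys)
      if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
      ranks <- new_ranks
    }
  }
  ranks <- refine(ranks)
  # break remaining ties deterministically: promote the lowest-index atom of
  # the lowest tied rank, then re-refine
  while (length(unique(ranks)) < n) {
    tied <- which(tabulate(ranks) > 1L)[1L]
    i <- which(ranks == tied)[1L]
    keys <- sprintf("%09d.%d", ranks, as.integer(seq_len(n) != i))
    ranks <- refine(.dense_rank(keys))
  }
  ranks
}

# H count an organic-subset (non-bracket) spelling would imply for atom i
.implied_h <- function(mol, i) {
  el <- mol$atoms$element[i]
  if (!el %in% ORGANIC_SUBSET) return(NA_integer_)
  bsum <- 0
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$a1[k] == i || mol$bonds$a2[k] == i) {
      bsum <- bsum + mol$bonds$order[k]
    }
  }
  if (mol$atoms$aromatic[i] && !el %in% c("O", "S")) bsum <- bsum + 1
  vs <- DEFAULT_VALENCES[[el]]
  v <- vs[vs >= bsum][1]
  if (is.na(v)) return(NA_integer_)
  as.integer(v - bsum)
}

.atom_token <- function(mol, i) {
  el <- mol$atoms$element[i]
  aromatic <- mol$atoms$aromatic[i]
  sym <- if (aromatic && el %in% c("B", "C", "N", "O", "P", "S")) tolower(el)
         else el
  needs_bracket <- mol$atoms$charge[i] != 0L ||
    !is.na(mol$atoms$isotope[i]) ||
    !el %in% ORGANIC_SUBSET ||
    !identical(.implied_h(mol, i), mol$atoms$h_count[i])
  if (!needs_bracket) return(sym)
  h <- mol$atoms$h_count[i]
  htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  q <- mol$atoms$charge[i]
  qtok <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
          else sprintf("%+d", q)
  iso <- if (is.na(mol$atoms$isotope[i])) "" else as.character(mol$atoms$isotope[i])
  paste0("[", iso, sym, htok, qtok, "]")
}

.bond_token <- function(mol, k) {
  if (mol$bonds$aromatic[k]) return("")
  o <- mol$bonds$order[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl bridge)
  if (mol$atoms$aromatic[mol$bonds$a1[k]] && mol$atoms$aromatic[mol$bonds$a2[k]]) {
    return("-")
  }
  ""
}

#' Canonical SMILES for a parsed molecule
#'
#' Writes a canonical SMILES string using iteratively refined atom ranks, so
#' the output is identical for every spelling of the same molecule. Parsing
#' the canonical form yields a graph identical to the original (same atoms,
#' bonds, aromaticity and hydrogen counts up to atom reordering).
#'
#' @param mol A `mol_record` from [parse_smiles()].
#' @return A single SMILES string.
#' @export
canonical_smiles <- function(mol) {
  stopifnot(is_mol_record(mol))
  n <- nrow(mol$atoms)
  ranks <- canonical_ranks(mol)
  bonds <- mol$bonds
  nb_idx <- vector("list", n)   # bond indices touching each atom
  for (k in seq_len(nrow(bonds))) {
    nb_idx[[bonds$a1[k]]] <- c(nb_idx[[bonds$a1[k]]], k)
    nb_idx[[bonds$a2[k]]] <- c(nb_idx[[bonds$a2[k]]], k)
  }
  other <- function(k, i) if (bonds$a1[k] == i) bonds$a2[k] else bonds$a1[k]

  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, nrow(bonds))
  ring_num <- 0L
  ring_label <- new.env(parent = emptyenv())  # bond index -> digit string
  pieces <- character(0)

  # pre-pass: identify ring-closure bonds via DFS in canonical order
  closure_at <- vector("list", n)  # atom -> bond indices closing here
  dfs_mark <- function(i) {
    visited[i] <<- TRUE
    ks <- nb_idx[[i]]
    ks <- ks[order(ranks[vapply(ks, other, 0L, i = i)])]
    for (k in ks) {
      if (bond_used[k]) next
      j <- other(k, i)
      if (visited[j]) {
        bond_used[k] <<- TRUE
        ring_num <<- ring_num + 1L
        lbl <- if (ring_num <= 9L) as.character(ring_num)
               else sprintf("%%%02d", ring_num)
        assign(as.character(k), lbl, envir = ring_label)
        closure_at[[i]] <<- c(closure_at[[i]], k)
        closure_at[[j]] <<- c(closure_at[[j]], k)
      } else {
        bond_used[k] <<- TRUE
        dfs_mark(j)
      }
    }
  }

  write_atom <- function(i, via_bond) {
    out <- character(0)
    if (!is.null(via_bond)) out <- c(out, .bond_token(mol, via_bond))
    out <- c(out, .atom_token(mol, i))
    for (k in closure_at[[i]]) {
      out <- c(out, .bond_token(mol, k), get(as.character(k), envir = ring_label))
    }
    kids <- nb_idx[[i]]
    kids <- kids[!vapply(kids, function(k) {
      is.null(tree_child[[as.character(k)]]) ||
        tree_child[[as.character(k)]][1] != i
    }, NA)]
    kids <- kids[order(ranks[vapply(kids, function(k)
      tree_child[[as.character(k)]][2], 0L)])]
    nk <- length(kids)
    for (z in seq_along(kids)) {
      k <- kids[z]
      j <- tree_child[[as.character(k)]][2]
      sub <- write_atom(j, k)
      if (z < nk) sub <- c("(", sub, ")")
      out <- c(out, sub)
    }
    out
  }

  # build the spanning tree explicitly (parent -> child per tree bond)
  tree_child <- new.env(parent = emptyenv())
  visited2 <- rep(FALSE, n)
  bond_used2 <- rep(FALSE, nrow(bonds))
  build_tree <- function(i) {
    visited2[i] <<- TRUE
    ks <- nb_idx[[i]]
    ks <- ks[order(ranks[vapply(ks, other, 0L, i = i)])]
    for (k in ks) {
      if (bond_used2[k]) next
      j <- other(k, i)
      if (!visited2[j]) {
        bond_used2[k] <<- TRUE
        assign(as.character(k), c(i, j), envir = tree_child)
        build_tree(j)
      }
    }
  }

  roots <- integer(0)
  comp_seen <- rep(FALSE, n)
  frags <- character(0)
  repeat {
    todo <- which(!visited)
    if (length(todo) == 0L) break
    root <- todo[which.min(ranks[todo])]
    dfs_mark(root)
    build_tree(root)
    frags <- c(frags, paste0(write_atom(root, NULL), collapse = ""))
  }
  paste(frags, collapse = ".")
}
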