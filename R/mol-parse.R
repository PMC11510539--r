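# SMILES parsing and molecular graph construction.
#
# The molecular graph is a plain list: $atoms is a data.frame with one row per
# heavy atom (element, aromatic, charge, isotope, h_count, in_ring, degree),
# $bonds a data.frame of (a1, a2, order, aromatic, in_ring). Hydrogens are
# implicit counts on their heavy atom, never graph nodes. Supported SMILES:
# organic-subset atoms (B C N O P S F Cl Br I and aromatic b c n o p s),
# bracket atoms with isotope/chirality/H-count/charge, bonds - = # : / \,
# branches, ring-closure digits and %nn, and dot-disconnected fragments.
# Stereo markers are accepted and discarded (the downstream features are
# 2D-topological).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# default valence lists in increasing order; implicit H fills to the smallest
# valence that accommodates the explicit bond order sum
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

ATOMIC_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

mol_parse_error <- function(smiles, reason) {
  structure(
    class = c("ddimage_parse_error", "ddimage_error", "error", "condition"),
    list(message = sprintf("SMILES parse failure for %s: %s",
                           encodeString(smiles, quote = "'"), reason),
         call = NULL, smiles = smiles, reason = reason)
  )
}

#' Parse a SMILES string into a molecule record
#'
#' Converts a SMILES string into a molecular graph with perceived rings and
#' aromaticity and computed implicit hydrogen counts. Kekule spellings of
#' aromatic rings (alternating single/double bonds) and lowercase aromatic
#' spellings of the same molecule yield identical graphs, so every feature
#' computed downstream (fingerprints, descriptors, images) is invariant to
#' the SMILES spelling.
#'
#' @param smiles A single non-empty SMILES string.
#' @param drug_id Identifier attached to the record (opaque).
#' @return An object of class `mol_record`: a list with `drug_id`, `smiles`,
#'   `atoms` (data.frame: element, aromatic, charge, isotope, h_count,
#'   in_ring, degree), `bonds` (data.frame: a1, a2, order, aromatic, in_ring)
#'   and `rings` (list of integer atom-index vectors, one per perceived
#'   smallest ring).
#' @details Unparseable input signals a classed condition
#'   (`ddimage_parse_error`) carrying the offending string; it never crashes
#'   with an unstructured error. Use [filter_invalid()] to partition a batch.
#' @examples
#' m <- parse_smiles("CC(=O)Nc1ccc(O)cc1", "acetaminophen")
#' nrow(m$atoms)  # 11 heavy atoms
#' @export
parse_smiles <- function(smiles, drug_id = "") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop(mol_parse_error(if (is.character(smiles) && length(smiles) == 1L)
      smiles else "<non-string>", "input is not a non-empty string"))
  }
  tok <- smiles_tokenize(smiles)
  g <- smiles_build_graph(smiles, tok)
  g <- perceive_rings(g)
  g <- assign_implicit_h(smiles, g)
  g <- perceive_aromaticity(smiles, g)
  structure(
    list(drug_id = drug_id, smiles = smiles,
         atoms = g$atoms, bonds = g$bonds, rings = g$rings),
    class = "mol_record"
  )
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record %s: %d atoms, %d bonds, %d rings, formula-ish %s>\n",
              x$drug_id, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              paste0(names(table(x$atoms$element)), table(x$atoms$element),
                     collapse = "")))
  invisible(x)
}

is_mol_record <- function(x) inherits(x, "mol_record")

# -- tokenizer ---------------------------------------------------------------

smiles_tokenize <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", n)
  nt <- 0L
  i <- 1L
  push <- function(type, value) {
    nt <<- nt + 1L
    toks[[nt]] <<- list(type = type, value = value)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(mol_parse_error(smiles, "unclosed bracket atom"))
      push("bracket", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "$")) {
      push("bond", ch); i <- i + 1L
    } else if (ch == "(") {
      push("open", "("); i <- i + 1L
    } else if (ch == ")") {
      push("close", ")"); i <- i + 1L
    } else if (ch == ".") {
      push("dot", "."); i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      push("ring", as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]$", chars[i + 1L]) ||
          !grepl("^[0-9]$", chars[i + 2L])) {
        stop(mol_parse_error(smiles, "malformed %nn ring closure"))
      }
      push("ring", as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push("atom", paste0(ch, chars[i + 1L])); i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      push("atom", ch); i <- i + 1L
    } else if (ch %in% AROMATIC_ORGANIC) {
      push("atom", ch); i <- i + 1L
    } else {
      stop(mol_parse_error(smiles, sprintf("unexpected character '%s'", ch)))
    }
  }
  toks[seq_len(nt)]
}

# bracket atom body, e.g. "13C@H2+", "N+", "O-", "nH"
parse_bracket_atom <- function(smiles, body) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Za-z][a-z]?)(@@|@)?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) {
    stop(mol_parse_error(smiles, sprintf("malformed bracket atom [%s]", body)))
  }
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_ORGANIC
  element <- if (aromatic) toupper(sym) else sym
  if (!element %in% names(ATOMIC_NUMBERS)) {
    stop(mol_parse_error(smiles, sprintf("unsupported element '%s'", sym)))
  }
  htok <- m[5]
  h <- if (!nzchar(htok)) 0L
       else if (htok == "H") 1L
       else as.integer(substring(htok, 2))
  ctok <- m[6]
  charge <- 0L
  if (nzchar(ctok)) {
    sign <- if (substring(ctok, 1, 1) == "+") 1L else -1L
    rest <- substring(ctok, 2)
    charge <- if (!nzchar(rest)) sign
              else if (grepl("^[0-9]+$", rest)) sign * as.integer(rest)
              else sign * nchar(ctok)
  }
  isotope <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
  list(element = element, aromatic = aromatic, charge = charge,
       h_count = h, isotope = isotope, bracket = TRUE)
}

# -- graph builder -----------------------------------------------------------

smiles_build_graph <- function(smiles, toks) {
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  pending_bond <- NULL
  stack <- integer(0)
  ring_open <- list()   # ring number -> list(atom, bond)

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  add_bond <- function(a1, a2, sym) {
    aromatic_default <- is.null(sym) &&
      atoms[[a1]]$aromatic && atoms[[a2]]$aromatic
    order <- if (is.null(sym)) 1L
             else switch(sym, "-" = 1L, "/" = 1L, "\\" = 1L,
                         "=" = 2L, "#" = 3L, "$" = 4L, ":" = 1L)
    aromatic <- aromatic_default || identical(sym, ":")
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = order,
                                         aromatic = aromatic)
  }

  for (tk in toks) {
    if (tk$type %in% c("atom", "bracket")) {
      a <- if (tk$type == "bracket") parse_bracket_atom(smiles, tk$value)
           else {
             sym <- tk$value
             aromatic <- sym %in% AROMATIC_ORGANIC
             list(element = if (aromatic) toupper(sym) else sym,
                  aromatic = aromatic, charge = 0L, h_count = NA_integer_,
                  isotope = NA_integer_, bracket = FALSE)
           }
      idx <- add_atom(a)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      prev <- idx
      pending_bond <- NULL
    } else if (tk$type == "bond") {
      if (!is.null(pending_bond)) {
        stop(mol_parse_error(smiles, "two consecutive bond symbols"))
      }
      pending_bond <- tk$value
    } else if (tk$type == "open") {
      if (is.na(prev)) stop(mol_parse_error(smiles, "branch before any atom"))
      stack <- c(stack, prev)
    } else if (tk$type == "close") {
      if (length(stack) == 0L) {
        stop(mol_parse_error(smiles, "unmatched closing parenthesis"))
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pending_bond <- NULL
    } else if (tk$type == "dot") {
      prev <- NA_integer_
      pending_bond <- NULL
    } else if (tk$type == "ring") {
      if (is.na(prev)) {
        stop(mol_parse_error(smiles, "ring closure before any atom"))
      }
      key <- as.character(tk$value)
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      } else {
        opener <- ring_open[[key]]
        sym <- if (!is.null(pending_bond)) pending_bond else opener$bond
        if (opener$atom == prev) {
          stop(mol_parse_error(smiles, "ring closure to same atom"))
        }
        add_bond(opener$atom, prev, sym)
        ring_open[[key]] <- NULL
      }
      pending_bond <- NULL
    }
  }
  if (length(stack) > 0L) {
    stop(mol_parse_error(smiles, "unmatched opening parenthesis"))
  }
  open_rings <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_rings) > 0L) {
    stop(mol_parse_error(smiles, sprintf("unclosed ring bond(s): %s",
                                         paste(open_rings, collapse = ", "))))
  }
  if (length(atoms) == 0L) stop(mol_parse_error(smiles, "no atoms"))
  dup <- duplicated(t(vapply(bonds, function(b) as.numeric(sort(c(b$a1, b$a2))),
                             numeric(2))))
  if (length(bonds) > 0L && any(dup)) {
    stop(mol_parse_error(smiles, "duplicate bond between the same atom pair"))
  }

  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, NA, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    isotope = vapply(atoms, `[[`, NA_integer_, "isotope"),
    h_count = vapply(atoms, `[[`, NA_integer_, "h_count"),
    bracket = vapply(atoms, `[[`, NA, "bracket"),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (length(bonds) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
               aromatic = logical(0))
  } else {
    data.frame(
      a1 = vapply(bonds, `[[`, 0L, "a1"),
      a2 = vapply(bonds, `[[`, 0L, "a2"),
      order = vapply(bonds, `[[`, 0L, "order"),
      aromatic = vapply(bonds, `[[`, NA, "aromatic")
    )
  }
  list(atoms = atoms_df, bonds = bonds_df)
}

# -- ring perception ---------------------------------------------------------

mol_adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  adj
}

# shortest path from src to dst avoiding the direct edge (src,dst); BFS
shortest_cycle_through <- function(adj, src, dst) {
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  visited[src] <- TRUE
  queue <- src
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (cur == src && nb == dst) next  # skip the closing edge itself
      if (!visited[nb]) {
        visited[nb] <- TRUE
        parent[nb] <- cur
        if (nb == dst) {
          path <- dst
          while (!is.na(parent[path[1L]])) path <- c(parent[path[1L]], path)
          return(path)
        }
        queue <- c(queue, nb)
      }
    }
  }
  NULL
}

# Perceive the smallest ring through every ring bond; record ring membership
# on atoms and bonds and keep the deduplicated ring list (an SSSR-style set,
# adequate for the fused systems the generator and fixtures use).
perceive_rings <- function(g) {
  n <- nrow(g$atoms)
  adj <- mol_adjacency(n, g$bonds)
  g$atoms$in_ring <- rep(FALSE, n)
  g$bonds$in_ring <- rep(FALSE, nrow(g$bonds))
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(g$bonds))) {
    cyc <- shortest_cycle_through(adj, g$bonds$a1[k], g$bonds$a2[k])
    if (!is.null(cyc)) {
      g$bonds$in_ring[k] <- TRUE
      g$atoms$in_ring[cyc] <- TRUE
      key <- paste(sort(cyc), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- cyc
      }
    }
  }
  g$atoms$degree <- vapply(adj, length, 0L)
  g$rings <- rings
  g
}

# -- implicit hydrogens ------------------------------------------------------

assign_implicit_h <- function(smiles, g) {
  n <- nrow(g$atoms)
  bond_sum <- rep(0, n)
  for (k in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[k]
    bond_sum[g$bonds$a1[k]] <- bond_sum[g$bonds$a1[k]] + o
    bond_sum[g$bonds$a2[k]] <- bond_sum[g$bonds$a2[k]] + o
  }
  for (i in seq_len(n)) {
    if (g$atoms$bracket[i]) next  # explicit H count from the bracket
    el <- g$atoms$element[i]
    vs <- DEFAULT_VALENCES[[el]]
    eff <- bond_sum[i]
    # lowercase aromatic atoms carry one delocalised double bond unless the
    # element is a lone-pair donor (O, S)
    if (g$atoms$aromatic[i] && !el %in% c("O", "S")) eff <- eff + 1
    v <- vs[vs >= eff][1]
    if (is.na(v)) {
      stop(mol_parse_error(smiles, sprintf(
        "valence of atom %d (%s) exceeds maximum (%g explicit bonds)",
        i, el, eff)))
    }
    g$atoms$h_count[i] <- as.integer(v - eff)
  }
  g$bond_order_sum <- bond_sum
  g
}

# -- aromaticity -------------------------------------------------------------

# Hueckel-style perception over perceived rings of size 5-7. An atom
# contributes 1 pi electron if it carries a double bond to another ring
# member (of any ring: fused Kekule systems keep their shared double bonds),
# 0 if its double bond is exocyclic to a non-ring atom, 2 if it is a
# heteroatom (N, O, S) or carbanion lone-pair donor, otherwise the ring is
# not aromatic. A ring is aromatic when the total is 4n + 2.
perceive_aromaticity <- function(smiles, g) {
  n <- nrow(g$atoms)
  has_double_to_ring <- rep(FALSE, n)
  has_double_to_nonring <- rep(FALSE, n)
  has_triple <- rep(FALSE, n)
  for (k in seq_len(nrow(g$bonds))) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    if (g$bonds$order[k] == 2L) {
      if (g$atoms$in_ring[a2]) has_double_to_ring[a1] <- TRUE
      else has_double_to_nonring[a1] <- TRUE
      if (g$atoms$in_ring[a1]) has_double_to_ring[a2] <- TRUE
      else has_double_to_nonring[a2] <- TRUE
    } else if (g$bonds$order[k] >= 3L) {
      has_triple[a1] <- TRUE; has_triple[a2] <- TRUE
    }
  }
  for (ring in g$rings) {
    if (length(ring) < 5L || length(ring) > 7L) next
    pi <- 0L
    ok <- TRUE
    for (a in ring) {
      el <- g$atoms$element[a]
      if (has_triple[a]) { ok <- FALSE; break }
      if (g$atoms$aromatic[a]) {
        # lowercase input: one electron from C/N/B/P, two from O/S and from
        # pyrrole-type [nH] / substituted n with three connections
        contrib <- if (el %in% c("O", "S")) 2L
                   else if (el == "N" &&
                            (isTRUE(g$atoms$h_count[a] >= 1L) ||
                             g$atoms$degree[a] >= 3L)) 2L
                   else if (el == "C" && g$atoms$charge[a] == -1L) 2L
                   else 1L
        pi <- pi + contrib
      } else if (has_double_to_ring[a]) {
        pi <- pi + 1L
      } else if (has_double_to_nonring[a]) {
        pi <- pi + 0L
      } else if (el %in% c("N", "O", "S")) {
        pi <- pi + 2L
      } else if (el == "C" && g$atoms$charge[a] == -1L) {
        pi <- pi + 2L
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi %% 4L == 2L) {
      g$atoms$aromatic[ring] <- TRUE
      in_ring_set <- seq_len(nrow(g$bonds))[
        g$bonds$a1 %in% ring & g$bonds$a2 %in% ring & g$bonds$in_ring]
      g$bonds$aromatic[in_ring_set] <- TRUE
    }
  }
  # an aromatic flag (from lowercase input) on an atom outside any ring is
  # not chemically meaningful
  bad <- which(g$atoms$aromatic & !g$atoms$in_ring)
  if (length(bad) > 0L) {
    stop(mol_parse_error(smiles, sprintf(
      "aromatic atom(s) outside any ring: %s", paste(bad, collapse = ", "))))
  }
  # a default bond between two aromatic atoms that is not part of a ring
  # (e.g. biphenyl) is a single bond
  g$bonds$aromatic <- g$bonds$aromatic & g$bonds$in_ring
  # normalise aromatic bonds to order 1 + flag so Kekule and lowercase
  # spellings produce identical graphs
  g$bonds$order[g$bonds$aromatic] <- 1L
  g
}

# -- batch validation --------------------------------------------------------

#' Partition a batch of SMILES into parseable and dropped records
#'
#' Applies [parse_smiles()] to every (drug_id, smiles) row, keeping order.
#' Parse failures never raise: they are routed to the dropped table with the
#' failure reason, mirroring the preprocessing step that removes structures
#' whose SMILES cannot be converted.
#'
#' @param records A data.frame with columns `drug_id` and `smiles` (a list of
#'   such pairs is also accepted).
#' @return A list with `valid` (list of `mol_record`, named by drug_id) and
#'   `dropped` (data.frame: drug_id, reason).
#' @export
filter_invalid <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- data.frame(
      drug_id = vapply(records, function(r) as.character(r[[1]]), ""),
      smiles = vapply(records, function(r) as.character(r[[2]]), ""),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(records),
            all(c("drug_id", "smiles") %in% names(records)))
  valid <- list()
  dropped_id <- character(0)
  dropped_reason <- character(0)
  for (i in seq_len(nrow(records))) {
    rec <- tryCatch(
      parse_smiles(records$smiles[i], records$drug_id[i]),
      ddimage_parse_error = function(e) e
    )
    if (is_mol_record(rec)) {
      valid[[records$drug_id[i]]] <- rec
    } else {
      dropped_id <- c(dropped_id, records$drug_id[i])
      dropped_reason <- c(dropped_reason, rec$reason)
    }
  }
  list(valid = valid,
       dropped = data.frame(drug_id = dropped_id, reason = dropped_reason,
                            stringsAsFactors = FALSE))
}

#' Write the dropped-record report produced by [filter_invalid()]
#'
#' @param dropped The `dropped` data.frame from [filter_invalid()].
#' @param path Output TSV path (columns drug_id, reason).
#' @export
write_dropped_report <- function(dropped, path) {
  utils::write.table(dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
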