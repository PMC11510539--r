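# Hashed circular (Morgan/ECFP-style) fingerprints.
#
# Each atom starts from an invariant of its immediate properties; each
# iteration hashes the atom's current identifier together with the sorted
# (bond, neighbor-identifier) list, growing the encoded environment by one
# bond radius. All identifiers collected at radii 0..radius are folded into
# n_bits positions. The hash is a fixed 31-bit multiplicative mix (documented
# below) so fingerprints are bit-for-bit reproducible across runs and
# platforms; parity with any external toolkit's hash is not a contract.

.HASH_MOD <- 2147483647   # 2^31 - 1; products stay exact in doubles
.HASH_MUL <- 1000003

hash_seq <- function(xs) {
  h <- 40503
  for (x in xs) {
    h <- (h * .HASH_MUL + (x %% .HASH_MOD)) %% .HASH_MOD
  }
  h
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Computes a hashed binary fingerprint encoding every atom environment up to
#' `radius` bonds, folded into `n_bits` positions. Identical for any two
#' SMILES spellings of the same molecule, because it is computed from the
#' perceived graph (aromaticity normalised), not from the input string.
#'
#' @param mol A `mol_record` from [parse_smiles()].
#' @param radius Environment radius in bonds (default 2, the ECFP4-equivalent
#'   setting).
#' @param n_bits Fingerprint length (default 2048).
#' @return An object of class `fingerprint_vector`: list with `bits`
#'   (integer 0/1 vector of length `n_bits`), `n_bits`, `radius`.
#' @examples
#' fp <- morgan_fingerprint(parse_smiles("c1ccccc1", "benzene"))
#' sum(fp$bits)
#' @export
morgan_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  stopifnot(is_mol_record(mol), radius >= 0L, n_bits >= 1L)
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  adj <- vector("list", n)  # rows (neighbor, bond_code)
  for (k in seq_len(nrow(bonds))) {
    bc <- bond_code(bonds, k)
    a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
    adj[[a1]] <- rbind(adj[[a1]], c(a2, bc))
    adj[[a2]] <- rbind(adj[[a2]], c(a1, bc))
  }
  ids <- vapply(seq_len(n), function(i) {
    hash_seq(c(
      ATOMIC_NUMBERS[[atoms$element[i]]],
      atoms$degree[i],
      atoms$h_count[i],
      atoms$charge[i] + 10L,
      as.integer(atoms$in_ring[i]),
      as.integer(atoms$aromatic[i])
    ))
  }, 0)
  features <- ids
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        parts <- c(r, ids[i])
        if (!is.null(nb)) {
          ord <- order(nb[, 2], ids[nb[, 1]])
          for (z in ord) parts <- c(parts, nb[z, 2], ids[nb[z, 1]])
        }
        hash_seq(parts)
      }, 0)
      ids <- new_ids
      features <- c(features, ids)
    }
  }
  bits <- integer(n_bits)
  bits[(unique(features) %% n_bits) + 1L] <- 1L
  structure(list(bits = bits, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint_vector")
}

#' @export
print.fingerprint_vector <- function(x, ...) {
  cat(sprintf("<fingerprint_vector: %d bits, radius %d, popcount %d>\n",
              x$n_bits, x$radius, sum(x$bits)))
  invisible(x)
}
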