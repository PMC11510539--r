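# Fixture molecules, each spelled two ways (aromatic + Kekule or reordered),
# with reference values computed once with an independent cheminformatics
# toolkit (RDKit 2024.09) and frozen here. TPSA reference is NA where the
# package's charged-nitro convention differs from the toolkit's.
fixture_molecules <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", text = '
name smi1 smi2 heavy mw exact ncount ocount arings fcsp3 hbd tpsa
benzene c1ccccc1 C1=CC=CC=C1 6 78.114 78.0470 0 0 1 0.0000 0 0.00
acetaminophen CC(=O)Nc1ccc(O)cc1 CC(=O)NC1=CC=C(O)C=C1 11 151.165 151.0633 1 2 1 0.1250 2 49.33
naphthalene c1ccc2ccccc2c1 C1=CC2=CC=CC=C2C=C1 10 128.174 128.0626 0 0 2 0.0000 0 0.00
pyrrole c1cc[nH]c1 C1=CC=CN1 5 67.091 67.0422 1 0 1 0.0000 1 15.79
furan c1ccoc1 C1=CC=CO1 5 68.075 68.0262 0 1 1 0.0000 0 13.14
pyridine c1ccncc1 C1=CC=NC=C1 6 79.102 79.0422 1 0 1 0.0000 0 12.89
toluene Cc1ccccc1 CC1=CC=CC=C1 7 92.141 92.0626 0 0 1 0.1429 0 0.00
phenol Oc1ccccc1 OC1=CC=CC=C1 7 94.113 94.0419 0 1 1 0.0000 1 20.23
aniline Nc1ccccc1 NC1=CC=CC=C1 7 93.129 93.0578 1 0 1 0.0000 1 26.02
thiophene c1ccsc1 C1=CC=CS1 5 84.143 84.0034 0 0 1 0.0000 0 0.00
nitrobenzene c1ccc(cc1)[N+](=O)[O-] C1=CC=C(C=C1)[N+](=O)[O-] 9 123.111 123.0320 1 2 1 0.0000 0 NA
ethanol CCO OCC 3 46.069 46.0419 0 1 0 1.0000 1 20.23
isopropanol CC(C)O OC(C)C 4 60.096 60.0575 0 1 0 1.0000 1 20.23
pentane CCCCC CCCCC 5 72.151 72.0939 0 0 0 1.0000 0 0.00
chlorobenzene c1ccc(Cl)cc1 ClC1=CC=CC=C1 7 112.559 112.0080 0 0 1 0.0000 0 0.00
acetonitrile CC#N N#CC 3 41.053 41.0265 1 0 0 0.5000 0 23.79
acetic_acid CC(=O)O OC(C)=O 4 60.052 60.0211 0 2 0 0.5000 1 37.30
phenyl_nitrite c1ccc(ON=O)cc1 O(N=O)c1ccccc1 9 123.111 123.0320 1 2 1 0.0000 0 38.66
dimethylamine CNC CNC 3 45.085 45.0578 1 0 0 1.0000 1 12.03
biphenyl c1ccc(cc1)c1ccccc1 C1=CC=C(C=C1)C1=CC=CC=C1 12 154.212 154.0783 0 0 2 0.0000 0 0.00
')
  tab
}

# independent naive recount of structural descriptors straight off the parsed
# atom/bond tables (deliberately loop-based, separate from descriptors())
brute_force_counts <- function(mol) {
  n_count <- 0L; o_count <- 0L; hbd <- 0L; hba <- 0L
  for (i in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[i]
    if (el == "N") n_count <- n_count + 1L
    if (el == "O") o_count <- o_count + 1L
    if (el %in% c("N", "O")) {
      hba <- hba + 1L
      if (mol$atoms$h_count[i] >= 1L) hbd <- hbd + 1L
    }
  }
  rot <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order == 1L && !b$aromatic && !b$in_ring) {
      deg1 <- sum(mol$bonds$a1 == b$a1) + sum(mol$bonds$a2 == b$a1)
      deg2 <- sum(mol$bonds$a1 == b$a2) + sum(mol$bonds$a2 == b$a2)
      if (deg1 >= 2L && deg2 >= 2L) rot <- rot + 1L
    }
  }
  arings <- 0L
  for (ring in mol$rings) {
    all_arom <- TRUE
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      if (b$in_ring && b$a1 %in% ring && b$a2 %in% ring && !b$aromatic) {
        all_arom <- FALSE
      }
    }
    if (all_arom) arings <- arings + 1L
  }
  list(n_count = n_count, o_count = o_count, hbd = hbd, hba = hba,
       rotatable = rot, aromatic_rings = arings)
}

# tiny random image set for network tests
random_images <- function(n, side, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) matrix(stats::rnorm(side * side), side))
  names(out) <- sprintf("D%04d", seq_len(n))
  out
}

random_pairs <- function(ids, n, seed = 1) {
  set.seed(seed)
  a <- sample(ids, n, replace = TRUE)
  b <- sample(ids, n, replace = TRUE)
  keep <- a != b
  data.frame(drug_a = a[keep], drug_b = b[keep],
             label = sample(0:1, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}
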