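# Synthetic drug/pair generator with planted interaction rules.
#
# Drugs are assembled from a fragment grammar: an aromatic or aliphatic
# scaffold with one or two substituent slots, filled from a substituent pool.
# The default planted rule is substructure-based: two drugs interact iff BOTH
# carry the nitro substituent [N+](=O)[O-] in their first slot. Drugs without
# the motif carry the isomeric nitrite-ester decoy O-N=O (same atomic
# formula, NO2, same H count) in that slot instead, so molecular weight,
# exact mass and the atomic-contribution logP are identical in distribution
# between the two groups: the three-descriptor panel is blind to the motif by
# construction while fingerprint bits see it directly. This makes the
# fingerprint-vs-descriptor ablation contrast a construction-level guarantee
# rather than a tuning outcome.
# An alternative descriptor-threshold rule (both drugs' TPSA above a cut)
# plants a signal the descriptor panels can see.

NITRO_SUB <- "[N+](=O)[O-]"
NITRITE_DECOY <- "ON=O"

default_fragment_grammar <- function() {
  list(
    # each scaffold is the character pieces between which substituents drop;
    # length 2 = one slot, length 3 = two slots
    scaffolds = list(
      c("c1ccc(", ")cc1"),
      c("c1ccc(", ")nc1"),
      c("c1ccc(", ")s1"),
      c("c1ccc(", ")o1"),
      c("C1CCC(", ")CC1"),
      c("CCC(", ")CC"),
      c("c1cc(", ")cc(", ")c1"),
      c("C1CC(", ")CC(", ")C1")
    ),
    substituents = c("C", "CC", "O", "N", "Cl", "F", "C(C)C", "OC", "C#N",
                     "CO", "C=O", "CCO"),
    motif = NITRO_SUB,
    decoy = NITRITE_DECOY
  )
}

#' Synthetic dataset specification
#'
#' @param n_drugs Number of drugs to generate.
#' @param n_pairs Total labeled pairs (positives + negatives).
#' @param rule Planted interaction predicate: `"substructure"` (both drugs
#'   carry the nitro motif; fingerprint-visible, mass-blind) or
#'   `"descriptor"` (both drugs' TPSA above `tpsa_cut`).
#' @param noise_rate Probability of independently flipping each label
#'   (0 <= eps < 0.5).
#' @param negative_ratio Negatives per positive.
#' @param motif_prob Probability a drug receives the planted motif as its
#'   first substituent (substructure rule).
#' @param tpsa_cut TPSA threshold in Angstrom^2 (descriptor rule).
#' @param grammar Fragment grammar (see `default_fragment_grammar`).
#' @param seed Integer seed; generation is fully reproducible.
#' @export
synthetic_spec <- function(n_drugs = 100L, n_pairs = 1000L,
                           rule = c("substructure", "descriptor"),
                           noise_rate = 0, negative_ratio = 1.0,
                           motif_prob = 0.5, tpsa_cut = 40,
                           grammar = default_fragment_grammar(),
                           seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(n_drugs >= 4L, n_pairs >= 2L, noise_rate >= 0, noise_rate < 0.5,
            negative_ratio > 0, motif_prob > 0, motif_prob < 1)
  structure(list(n_drugs = as.integer(n_drugs), n_pairs = as.integer(n_pairs),
                 rule = rule, noise_rate = noise_rate,
                 negative_ratio = negative_ratio, motif_prob = motif_prob,
                 tpsa_cut = tpsa_cut, grammar = grammar,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic drug table and labeled pair table
#'
#' Builds `n_drugs` molecules from the fragment grammar, validates that every
#' SMILES parses (aborting with the offenders listed if the grammar is
#' broken), labels sampled drug pairs by the planted rule, flips each label
#' independently with probability `noise_rate`, and balances positives and
#' negatives by `negative_ratio`. Byte-identical outputs for identical specs.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `drugs` (data.frame: drug_id, smiles, has_motif, tpsa),
#'   `pairs` (data.frame: drug_a, drug_b, label, true_label) and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  g <- spec$grammar

  n <- spec$n_drugs
  has_motif <- stats::runif(n) < spec$motif_prob
  smiles <- character(n)
  for (i in seq_len(n)) {
    sc <- g$scaffolds[[sample.int(length(g$scaffolds), 1L)]]
    n_slots <- length(sc) - 1L
    subs <- sample(g$substituents, n_slots, replace = TRUE)
    # slot 1 carries the motif or its isomeric decoy; remaining slots are
    # motif-independent, so only fingerprint-visible structure separates
    # the two groups
    subs[1L] <- if (has_motif[i]) g$motif else g$decoy
    pieces <- character(0)
    for (z in seq_len(n_slots)) pieces <- c(pieces, sc[z], subs[z])
    smiles[i] <- paste0(c(pieces, sc[n_slots + 1L]), collapse = "")
  }
  drug_id <- sprintf("D%04d", seq_len(n))

  flt <- filter_invalid(data.frame(drug_id = drug_id, smiles = smiles,
                                   stringsAsFactors = FALSE))
  if (nrow(flt$dropped) > 0L) {
    stop(ddimage_config_error(paste0(
      "fragment grammar produced unparseable SMILES: ",
      paste(sprintf("%s (%s)", flt$dropped$drug_id, flt$dropped$reason),
            collapse = "; "))))
  }
  tpsa <- vapply(flt$valid[drug_id], function(m)
    descriptors(m, "D12")$values[["tpsa"]], 0)

  interacts <- switch(spec$rule,
    substructure = function(i, j) has_motif[i] && has_motif[j],
    descriptor = function(i, j) tpsa[i] > spec$tpsa_cut &&
                                tpsa[j] > spec$tpsa_cut)
  all_ij <- t(utils::combn(n, 2L))
  truth <- vapply(seq_len(nrow(all_ij)),
                  function(r) interacts(all_ij[r, 1], all_ij[r, 2]), NA)
  pos_pool <- which(truth)
  neg_pool <- which(!truth)

  n_pos <- min(round(spec$n_pairs / (1 + spec$negative_ratio)),
               length(pos_pool))
  n_neg <- min(round(n_pos * spec$negative_ratio), length(neg_pool))
  if (n_pos < 1L || n_neg < 1L) {
    stop(ddimage_config_error(
      "planted rule yields too few positive or negative candidate pairs"))
  }
  take <- c(sample(pos_pool, n_pos), sample(neg_pool, n_neg))
  true_label <- as.integer(truth[take])
  flips <- stats::runif(length(take)) < spec$noise_rate
  label <- ifelse(flips, 1L - true_label, true_label)

  pairs <- normalize_pairs(data.frame(
    drug_a = drug_id[all_ij[take, 1]],
    drug_b = drug_id[all_ij[take, 2]],
    label = label, true_label = true_label,
    stringsAsFactors = FALSE))
  ord <- order(pairs$drug_a, pairs$drug_b)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL

  drugs <- data.frame(drug_id = drug_id, smiles = smiles,
                      has_motif = has_motif, tpsa = unname(tpsa),
                      stringsAsFactors = FALSE)
  list(drugs = drugs, pairs = pairs, spec = spec)
}
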