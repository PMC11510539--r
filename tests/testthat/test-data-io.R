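test_that("pair tables round-trip and enforce the schema", {
  tmp <- withr::local_tempdir()
  pairs <- data.frame(drug_a = c("a1", "a2", "a3"),
                      drug_b = c("b1", "b2", "b3"),
                      label = c(1L, 0L, 1L), stringsAsFactors = FALSE)
  path <- file.path(tmp, "pairs.tsv")
  write_pair_table(pairs, path)
  got <- read_pair_table(path)
  expect_equal(got, pairs)
  csv <- file.path(tmp, "pairs.csv")
  write_pair_table(pairs, csv)
  expect_equal(read_pair_table(csv), pairs)

  # missing column named in the error
  writeLines(c("drug_a\tlabel", "x\t1"), file.path(tmp, "bad1.tsv"))
  expect_error(read_pair_table(file.path(tmp, "bad1.tsv")), "drug_b",
               class = "ddimage_io_error")

  # non-binary label reported with its line number
  writeLines(c("drug_a\tdrug_b\tlabel", "x\ty\t1", "u\tv\tyes"),
             file.path(tmp, "bad2.tsv"))
  expect_error(read_pair_table(file.path(tmp, "bad2.tsv")), "line 3",
               class = "ddimage_io_error")

  # self pairs and conflicting duplicates rejected
  writeLines(c("drug_a\tdrug_b\tlabel", "x\tx\t1"),
             file.path(tmp, "bad3.tsv"))
  expect_error(read_pair_table(file.path(tmp, "bad3.tsv")),
               class = "ddimage_io_error")
  writeLines(c("drug_a\tdrug_b\tlabel", "x\ty\t1", "y\tx\t0"),
             file.path(tmp, "bad4.tsv"))
  expect_error(read_pair_table(file.path(tmp, "bad4.tsv")),
               class = "ddimage_io_error")

  # unordered duplicates with agreeing labels collapse to one row
  writeLines(c("drug_a\tdrug_b\tlabel", "y\tx\t1", "x\ty\t1"),
             file.path(tmp, "dup.tsv"))
  expect_equal(nrow(read_pair_table(file.path(tmp, "dup.tsv"))), 1)
})

test_that("sample_negatives excludes positives and respects capacity", {
  ids <- sprintf("D%02d", 1:10)
  positives <- data.frame(drug_a = ids[1:5], drug_b = ids[6:10],
                          label = 1L, stringsAsFactors = FALSE)
  neg <- sample_negatives(positives, ids, ratio = 1.0, seed = 5)
  expect_equal(nrow(neg), 5)
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$drug_a < neg$drug_b))
  pos_keys <- paste(pmin(positives$drug_a, positives$drug_b),
                    pmax(positives$drug_a, positives$drug_b))
  expect_false(any(paste(neg$drug_a, neg$drug_b) %in% pos_keys))

  # exhaustive exclusion on a small instance: request every available pair
  small <- sprintf("S%d", 1:5)   # C(5,2) = 10 pairs
  pos_small <- data.frame(drug_a = c("S1", "S1"), drug_b = c("S2", "S3"),
                          label = 1L)
  neg_all <- sample_negatives(pos_small, small, ratio = 4.0, seed = 6)
  expect_equal(nrow(neg_all), 8)
  expect_false(any(paste(neg_all$drug_a, neg_all$drug_b) %in%
                   paste(pos_small$drug_a, pos_small$drug_b)))

  expect_error(sample_negatives(pos_small, small, ratio = 5.0, seed = 6),
               class = "ddimage_config_error")

  expect_identical(sample_negatives(positives, ids, 1.0, seed = 9),
                   sample_negatives(positives, ids, 1.0, seed = 9))
})

test_that("the synthetic generator is valid, noise-calibrated and reproducible", {
  spec0 <- synthetic_spec(n_drugs = 50, n_pairs = 200, noise_rate = 0,
                          seed = 15)
  sim <- generate_synthetic(spec0)
  expect_equal(nrow(sim$drugs), 50)
  flt <- filter_invalid(sim$drugs)
  expect_equal(nrow(flt$dropped), 0)
  # noise-free labels equal the planted rule output exactly
  expect_identical(sim$pairs$label, sim$pairs$true_label)
  motif <- setNames(sim$drugs$has_motif, sim$drugs$drug_id)
  expect_identical(sim$pairs$true_label,
                   as.integer(motif[sim$pairs$drug_a] &
                              motif[sim$pairs$drug_b]))
  # unordered convention, no self pairs, resolvable ids
  expect_true(all(sim$pairs$drug_a < sim$pairs$drug_b))
  expect_true(all(c(sim$pairs$drug_a, sim$pairs$drug_b) %in%
                  sim$drugs$drug_id))

  # realized label noise stays within the binomial band
  spec3 <- synthetic_spec(n_drugs = 80, n_pairs = 1000, noise_rate = 0.3,
                          seed = 16)
  sim3 <- generate_synthetic(spec3)
  flipped <- mean(sim3$pairs$label != sim3$pairs$true_label)
  expect_gte(flipped, 0.27)
  expect_lte(flipped, 0.33)

  # byte-identical reproducibility
  expect_identical(generate_synthetic(spec0), generate_synthetic(spec0))

  # the descriptor-threshold rule plants a TPSA-visible signal
  simd <- generate_synthetic(synthetic_spec(n_drugs = 40, n_pairs = 100,
                                            rule = "descriptor", seed = 17))
  tpsa <- setNames(simd$drugs$tpsa, simd$drugs$drug_id)
  pos <- simd$pairs[simd$pairs$true_label == 1L, ]
  expect_true(all(tpsa[pos$drug_a] > 40 & tpsa[pos$drug_b] > 40))
})

test_that("the D3 panel cannot see the planted motif but fingerprints can", {
  sim <- generate_synthetic(synthetic_spec(n_drugs = 30, n_pairs = 60,
                                           seed = 19))
  mols <- filter_invalid(sim$drugs)$valid
  d3 <- t(vapply(mols, function(m) descriptors(m, "D3")$values, numeric(3)))
  # swapping a drug's motif for the isomeric decoy leaves D3 unchanged
  nitro <- parse_smiles("c1ccc([N+](=O)[O-])cc1", "n")
  decoy <- parse_smiles("c1ccc(ON=O)cc1", "d")
  expect_equal(descriptors(nitro, "D3")$values,
               descriptors(decoy, "D3")$values, tolerance = 1e-12)
  expect_false(identical(morgan_fingerprint(nitro)$bits,
                         morgan_fingerprint(decoy)$bits))
  # motif and non-motif drugs have overlapping D3 ranges (no separation)
  motif_mw <- d3[sim$drugs$has_motif, "mw"]
  plain_mw <- d3[!sim$drugs$has_motif, "mw"]
  expect_lt(min(motif_mw), max(plain_mw))
  expect_lt(min(plain_mw), max(motif_mw))
})
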