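test_that("parse_smiles builds the expected molecular graphs", {
  m <- parse_smiles("CC(=O)Nc1ccc(O)cc1", "acetaminophen")
  expect_s3_class(m, "mol_record")
  expect_equal(nrow(m$atoms), 11)
  expect_equal(sum(m$atoms$aromatic), 6)
  expect_equal(length(m$rings), 1)

  m1 <- parse_smiles("C", "methane")
  expect_equal(nrow(m1$atoms), 1)
  expect_equal(m1$atoms$h_count, 4L)

  expect_error(parse_smiles("not_a_smiles", "x"),
               class = "ddimage_parse_error")
  expect_error(parse_smiles("", "x"), class = "ddimage_parse_error")
  expect_error(parse_smiles("C1CC", "x"), class = "ddimage_parse_error")
  expect_error(parse_smiles("C(C", "x"), class = "ddimage_parse_error")
  expect_error(parse_smiles("CFC", "x"), class = "ddimage_parse_error")
  # the condition carries the offending string
  err <- tryCatch(parse_smiles("xyz", "bad"),
                  ddimage_parse_error = function(e) e)
  expect_equal(err$smiles, "xyz")
})

test_that("filter_invalid partitions preserving order and reasons", {
  recs <- data.frame(
    drug_id = c("a", "b", "c"),
    smiles = c("CCO", "c1ccccc1", "garbage(("),
    stringsAsFactors = FALSE)
  flt <- filter_invalid(recs)
  expect_equal(names(flt$valid), c("a", "b"))
  expect_equal(flt$dropped$drug_id, "c")
  expect_true(nzchar(flt$dropped$reason))

  empty <- filter_invalid(data.frame(drug_id = character(0),
                                     smiles = character(0)))
  expect_equal(length(empty$valid), 0)
  expect_equal(nrow(empty$dropped), 0)

  sim <- generate_synthetic(synthetic_spec(n_drugs = 10, n_pairs = 10,
                                           seed = 3))
  flt2 <- filter_invalid(sim$drugs)
  expect_equal(length(flt2$valid), 10)
  expect_equal(nrow(flt2$dropped), 0)
})

test_that("morgan fingerprints are spelling-invariant and deterministic", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    f1 <- morgan_fingerprint(parse_smiles(fx$smi1[i], fx$name[i]))
    f2 <- morgan_fingerprint(parse_smiles(fx$smi2[i], fx$name[i]))
    expect_identical(f1$bits, f2$bits, label = fx$name[i])
    expect_equal(f1$n_bits, 2048L)
    expect_true(all(f1$bits %in% c(0L, 1L)))
  }
  # repeated calls identical
  m <- parse_smiles(fx$smi1[2], "x")
  expect_identical(morgan_fingerprint(m)$bits, morgan_fingerprint(m)$bits)
  # distinct molecules hit distinct bit patterns
  fb <- morgan_fingerprint(parse_smiles("c1ccccc1", "benzene"))
  fp <- morgan_fingerprint(parse_smiles("c1ccncc1", "pyridine"))
  expect_false(identical(fb$bits, fp$bits))
})

test_that("methane fingerprint popcount is bounded by its environments", {
  # a single-atom graph has exactly one distinct environment per radius
  fp <- morgan_fingerprint(parse_smiles("C", "methane"), radius = 2)
  expect_gte(sum(fp$bits), 1)
  expect_lte(sum(fp$bits), 3)
  fp0 <- morgan_fingerprint(parse_smiles("C", "methane"), radius = 0)
  expect_equal(sum(fp0$bits), 1)
})

test_that("fingerprint length and folding follow n_bits", {
  m <- parse_smiles("CC(=O)Nc1ccc(O)cc1", "x")
  fp <- morgan_fingerprint(m, n_bits = 128)
  expect_length(fp$bits, 128)
  expect_gte(sum(fp$bits), 1)
})

test_that("descriptor panels match the frozen toolkit reference values", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    m <- parse_smiles(fx$smi1[i], fx$name[i])
    expect_equal(nrow(m$atoms), fx$heavy[i], label = fx$name[i])
    d <- descriptors(m, "D12")$values
    expect_equal(unname(d[["mw"]]), fx$mw[i], tolerance = 3e-4,
                 label = paste(fx$name[i], "mw"))
    expect_equal(unname(d[["exact_mass"]]), fx$exact[i], tolerance = 1e-5,
                 label = paste(fx$name[i], "exact_mass"))
    expect_equal(unname(d[["n_count"]]), fx$ncount[i],
                 label = paste(fx$name[i], "n_count"))
    expect_equal(unname(d[["o_count"]]), fx$ocount[i],
                 label = paste(fx$name[i], "o_count"))
    expect_equal(unname(d[["aromatic_rings"]]), fx$arings[i],
                 label = paste(fx$name[i], "aromatic_rings"))
    expect_equal(unname(d[["frac_csp3"]]), fx$fcsp3[i], tolerance = 1e-3,
                 label = paste(fx$name[i], "frac_csp3"))
    expect_equal(unname(d[["hbd"]]), fx$hbd[i],
                 label = paste(fx$name[i], "hbd"))
    if (!is.na(fx$tpsa[i])) {
      expect_equal(unname(d[["tpsa"]]), fx$tpsa[i], tolerance = 1e-8,
                   label = paste(fx$name[i], "tpsa"))
    }
  }
})

test_that("descriptor counts agree with an independent brute-force recount", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    m <- parse_smiles(fx$smi1[i], fx$name[i])
    d <- descriptors(m, "D12")$values
    bf <- brute_force_counts(m)
    expect_equal(unname(d[["n_count"]]), bf$n_count, label = fx$name[i])
    expect_equal(unname(d[["o_count"]]), bf$o_count, label = fx$name[i])
    expect_equal(unname(d[["hbd"]]), bf$hbd, label = fx$name[i])
    expect_equal(unname(d[["hba"]]), bf$hba, label = fx$name[i])
    expect_equal(unname(d[["rotatable_bonds"]]), bf$rotatable,
                 label = fx$name[i])
    expect_equal(unname(d[["aromatic_rings"]]), bf$aromatic_rings,
                 label = fx$name[i])
  }
})

test_that("descriptor sets are ordered prefixes (D3 < D6 < D12)", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    m <- parse_smiles(fx$smi1[i], fx$name[i])
    d3 <- descriptors(m, "D3")$values
    d6 <- descriptors(m, "D6")$values
    d12 <- descriptors(m, "D12")$values
    expect_length(d3, 3)
    expect_length(d6, 6)
    expect_length(d12, 12)
    expect_identical(unname(d6[1:3]), unname(d3))
    expect_identical(unname(d12[1:6]), unname(d6))
  }
})

test_that("methane descriptors hit the degenerate single-carbon values", {
  d <- descriptors(parse_smiles("C", "methane"), "D12")$values
  expect_equal(unname(d[["rotatable_bonds"]]), 0)
  expect_equal(unname(d[["hbd"]]), 0)
  expect_equal(unname(d[["hba"]]), 0)
  expect_equal(unname(d[["aromatic_rings"]]), 0)
  expect_equal(unname(d[["frac_csp3"]]), 1)
  expect_equal(unname(d[["radical_electrons"]]), 0)
})

test_that("build_feature_vector concatenates, scales and clips", {
  m <- parse_smiles("CC(=O)Nc1ccc(O)cc1", "x")
  fp <- morgan_fingerprint(m)
  desc <- descriptors(m, "D12")
  scaling <- list(min = desc$values - 1, max = desc$values + 1)
  fv <- build_feature_vector(fp, desc, scaling)
  expect_length(fv$values, 2060)
  expect_equal(fv$layout$start, c(1L, 2049L))
  expect_equal(fv$layout$end, c(2048L, 2060L))
  expect_equal(fv$layout$segment, c("fp", "desc"))
  expect_true(all(fv$values >= 0 & fv$values <= 1))
  # every descriptor sits mid-range under this scaling
  expect_equal(unname(fv$values[2049:2060]), rep(0.5, 12))

  # descriptor-only D3 vector
  d3 <- descriptors(m, "D3")
  sc3 <- list(min = d3$values, max = d3$values + 1)
  fv3 <- build_feature_vector(desc = d3, scaling = sc3)
  expect_length(fv3$values, 3)
  # value at the training minimum scales to exactly 0
  expect_equal(unname(fv3$values), rep(0, 3))

  # out-of-range test values clip
  sc_low <- list(min = d3$values + 10, max = d3$values + 20)
  expect_equal(unname(build_feature_vector(desc = d3,
                                           scaling = sc_low)$values),
               rep(0, 3))

  expect_error(build_feature_vector(), class = "ddimage_config_error")
  expect_error(build_feature_vector(desc = d3), class = "ddimage_config_error")
})

test_that("canonical SMILES writing is stable under reparsing", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    m1 <- parse_smiles(fx$smi1[i], fx$name[i])
    m2 <- parse_smiles(fx$smi2[i], fx$name[i])
    cs <- canonical_smiles(m1)
    expect_identical(cs, canonical_smiles(m2), label = fx$name[i])
    m3 <- parse_smiles(cs, fx$name[i])
    expect_identical(canonical_smiles(m3), cs, label = fx$name[i])
    expect_identical(morgan_fingerprint(m3)$bits,
                     morgan_fingerprint(m1)$bits, label = fx$name[i])
  }
})

test_that("drug table readers handle SMI and CSV/TSV with dropped report", {
  tmp <- withr::local_tempdir()
  drugs <- data.frame(drug_id = c("d1", "d2"), smiles = c("CCO", "c1ccccc1"),
                      stringsAsFactors = FALSE)
  smi <- file.path(tmp, "drugs.smi")
  write_drug_table(drugs, smi)
  expect_equal(read_drug_table(smi)[, c("drug_id", "smiles")],
               drugs[, c("drug_id", "smiles")])
  csv <- file.path(tmp, "drugs.csv")
  write_drug_table(drugs, csv)
  expect_equal(read_drug_table(csv), drugs)
  expect_error(read_drug_table(file.path(tmp, "absent.tsv")),
               class = "ddimage_io_error")

  rep_path <- file.path(tmp, "dropped.tsv")
  write_dropped_report(data.frame(drug_id = "x", reason = "unparseable"),
                       rep_path)
  got <- read.delim(rep_path)
  expect_equal(got$drug_id, "x")
})
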