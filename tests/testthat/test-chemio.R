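# Murcko scaffold expectations below were produced by an independent
# reference scaffold-decomposition implementation (RDKit MurckoScaffold) on
# the same molecules; strings are compared after canonicalization so the two
# toolkits' canonical spellings can differ.
MURCKO_ORACLE <- list(
  c("CCO", ""),
  c("ClC(Cl)Cl", ""),
  c("c1ccccc1", "c1ccccc1"),
  c("OCCc1ccccc1", "c1ccccc1"),
  c("CC(=O)c1ccccc1", "c1ccccc1"),
  c("CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1"),
  c("NCCc1ccc(O)c(O)c1", "c1ccccc1"),
  c("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccccc1"),
  c("O=C(c1ccccc1)c1ccccc1", "O=C(c1ccccc1)c1ccccc1"),
  c("O=C1CCCCC1", "O=C1CCCCC1"),
  c("c1ccc2ccccc2c1", "c1ccc2ccccc2c1"),
  c("C1CCNCC1", "C1CCNCC1"),
  c("Cc1ccncc1", "c1ccncc1"),
  c("CN1CCC1=O", "O=C1CCN1"),
  c("Cn1cnc2c1c(=O)n(C)c(=O)n2C", "O=c1[nH]c(=O)c2[nH]cnc2[nH]1"),
  c("c1ccccc1CCc1ccccc1", "c1ccc(CCc2ccccc2)cc1"),
  c("C1CC1CC2CC2", "C1CC1CC1CC1"),
  c("OC(=O)C1CCCN1", "C1CCNC1"),
  c("c1ccsc1", "c1ccsc1"),
  c("O=S(=O)(N)c1ccccc1", "c1ccccc1")
)

test_that("canonicalization maps equivalent spellings to one string and is idempotent", {
  out <- canonicalize(c("OCC", "CCO"))
  expect_identical(out[1], out[2])
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1", "C[N+](C)(C)C")) {
    c1 <- canonicalize(s)
    expect_identical(canonicalize(c1), c1)
  }
})

test_that("malformed SMILES raise parse errors", {
  expect_error(canonicalize("C(("), class = "parse_error")
  expect_error(canonicalize("C1CC"), class = "parse_error")
  expect_error(canonicalize("X"), class = "parse_error")
  expect_error(canonicalize(""), class = "parse_error")
  expect_error(enumerate_randomized("C((", 5), class = "parse_error")
  expect_error(murcko_scaffold("Zz1"), class = "parse_error")
})

test_that("enumerated views round-trip to the same molecule and respect the cap", {
  mols <- c("OCCc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2ccccc2c1")
  for (s in mols) {
    views <- enumerate_randomized(s, 10, seed = 5)
    expect_gte(length(views), 1)
    expect_lte(length(views), 10)
    expect_identical(anyDuplicated(views), 0L)
    expect_true(all(canonicalize(views) == canonicalize(s)))
  }
  # cap: a multi-ring molecule asked for 200 views returns at most 50
  many <- enumerate_randomized("CC(=O)Oc1ccccc1C(=O)c1ccc2ccccc2c1", 200,
                               seed = 1)
  expect_lte(length(many), 50)
  # single atom admits exactly one spelling
  expect_identical(enumerate_randomized("C", 10, seed = 1), "C")
})

test_that("enumeration is deterministic under seed", {
  a <- enumerate_randomized("OCCc1ccncc1", 15, seed = 99)
  b <- enumerate_randomized("OCCc1ccncc1", 15, seed = 99)
  expect_identical(a, b)
})

test_that("murcko_scaffold matches the reference decomposition oracle", {
  for (case in MURCKO_ORACLE) {
    got <- murcko_scaffold(case[1])
    if (case[2] == "") {
      expect_identical(got, "", label = case[1])
    } else {
      expect_identical(canonicalize(got), canonicalize(case[2]),
                       label = case[1])
    }
  }
})

test_that("scaffolds are canonical, valid and idempotent", {
  ring_mols <- c("OCCc1ccccc1", "CC(=O)c1ccc2ccccc2c1", "CN1CCC1=O",
                 "O=S(=O)(N)c1ccccc1")
  for (s in ring_mols) {
    sc <- murcko_scaffold(s)
    expect_identical(canonicalize(sc), sc)     # canonical, parses
    expect_identical(murcko_scaffold(sc), sc)  # idempotent
  }
})

test_that("circular fingerprints are deterministic with the configured width", {
  f1 <- circular_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
  f2 <- circular_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(f1$bits, f2$bits)
  expect_identical(length(f1$bits), 2048L)
  expect_identical(f1$radius, 2L)
  expect_identical(length(circular_fingerprint("CCO", n_bits = 512L)$bits),
                   512L)
  expect_true(all(f1$bits %in% c(0L, 1L)))
})

test_that("tanimoto agrees with a brute-force popcount oracle", {
  fb <- circular_fingerprint("c1ccccc1")
  ft <- circular_fingerprint("Cc1ccccc1")
  inter <- sum(fb$bits == 1L & ft$bits == 1L)
  uni <- sum(fb$bits == 1L | ft$bits == 1L)
  expect_equal(tanimoto(fb, ft), inter / uni, tolerance = 1e-12)
  expect_equal(tanimoto(fb, fb), 1)
})

test_that("molecule tables load, skip bad rows, and round-trip to disk", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,name", "CCO,ethanol", "c1ccccc1,benzene",
               "OCCc1ccccc1,phenethanol"), tmp)
  tab <- load_molecule_table(tmp, "smiles", id_column = "name")
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$id[1], "ethanol")
  expect_identical(tab$scaffold[1], "")
  expect_identical(tab$scaffold[2], canonicalize("c1ccccc1"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles", "CCO", "C((", "CCN", "c1ccccc1", "CCC", "CCCC"), bad)
  expect_warning(tab2 <- load_molecule_table(bad, "smiles"),
                 "skipped 1")
  expect_identical(nrow(tab2), 5L)

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_identical(nrow(load_molecule_table(empty, "smiles")), 0L)

  expect_error(load_molecule_table("/nonexistent/x.csv", "smiles"),
               class = "io_error")
  expect_error(load_molecule_table(tmp, "nope"), class = "schema_error")

  out <- withr::local_tempfile(fileext = ".csv")
  write_molecule_table(tab, out)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_identical(back$smiles_canonical, tab$smiles_canonical)
})

test_that("smi files with optional identifiers are read", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol_a", "c1ccccc1 mol_b"), tmp)
  tab <- load_molecule_table(tmp)
  expect_identical(tab$id, c("mol_a", "mol_b"))
})

test_that("pair tables load with a stable label registry", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug1_smiles,drug2_smiles,label",
               "CCO,c1ccccc1,sedation",
               "c1ccccc1,CCN,headache",
               "CCO,CCN,sedation"), tmp)
  tab <- load_pair_table(tmp)
  expect_identical(attr(tab, "label_levels"), c("headache", "sedation"))
  expect_identical(tab$label, c(1L, 0L, 1L))
  expect_error(load_pair_table(tmp, label_column = "nope"),
               class = "schema_error")
})
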