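test_that("SMILES files are read with ids, defaults and ordering", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol"), f)
  mols <- read_smiles_file(f)
  expect_length(mols, 1L)
  expect_equal(mols[[1]]$id, "ethanol")
  expect_equal(heavy_atom_count(mols[[1]]$graph), 3L)

  writeLines(c("CCO", "c1ccccc1 benzene"), f)
  mols <- read_smiles_file(f)
  expect_equal(vapply(mols, `[[`, character(1), "id"), c("mol1", "benzene"))
})

test_that("unparseable SMILES lines are skipped with a warning, strict aborts", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a", "C1CC broken", "CCN b"), f)
  expect_false(rdkit_valid("C1CC")) # independent parser agrees the line is bad
  expect_warning(mols <- read_smiles_file(f), "C1CC")
  expect_length(mols, 2L)
  expect_equal(attr(mols, "n_skipped"), 1L)
  expect_error(suppressWarnings(read_smiles_file(f, strict = TRUE)),
               class = "retrofrag_input_error")
})

test_that("duplicate ids, empty files and all-bad files are fatal", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO x", "CCN x"), f)
  expect_error(read_smiles_file(f), "x")
  writeLines(c("# only a comment"), f)
  expect_error(read_smiles_file(f), class = "retrofrag_input_error")
  writeLines(c("C1CC"), f)
  expect_error(suppressWarnings(read_smiles_file(f)),
               class = "retrofrag_input_error")
  expect_error(read_smiles_file(file.path(tempdir(), "no-such-file.smi")),
               class = "retrofrag_input_error")
})

test_that("rule files parse names, reject missing maps and empty files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("ester_O_C\tC(=O)[O:1][C:2]", f)
  rules <- read_rules_file(f)
  expect_length(rules, 1L)
  expect_equal(rules[[1]]$name, "ester_O_C")

  writeLines("C(=O)[O:1][C:2]", f)
  expect_equal(read_rules_file(f)[[1]]$name, "rule1")

  writeLines("[C:1](=O)N", f)
  expect_error(read_rules_file(f), ":1")
  writeLines("[C:1](=O)[N:3]", f)
  expect_error(read_rules_file(f), class = "retrofrag_input_error")
  writeLines("[C:1].[N:2]", f)  # maps present but not bonded
  expect_error(read_rules_file(f), "bonded")
  writeLines(character(0), f)
  expect_error(read_rules_file(f), class = "retrofrag_input_error")
  writeLines("name\t[C:1](((", f)
  expect_error(read_rules_file(f), "compile")
})

test_that("canonicalization identifies isomorphic inputs and is idempotent", {
  expect_equal(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_equal(canonical_smiles("C1=CC=CC=C1"), canonical_smiles("c1ccccc1"))
  cans <- canonical_smiles(c("CCO", "CC(=O)OCC", "c1ccccc1", "CC(=O)O"))
  expect_equal(canonical_smiles(cans), cans)
})

test_that("canonical equality matches an independent canonicalizer on random atom orders", {
  for (smi in c("CC(=O)OCc1ccccc1", "CC(=O)OCC(COC(C)=O)OC(C)=O", "c1ccoc1C(=O)O")) {
    variants <- unique(rdkit_random_smiles(smi, 50, seed = 7))
    ours <- unique(canonical_smiles(variants))
    expect_length(ours, 1L)
    expect_equal(ours, canonical_smiles(smi))
  }
  # distinct molecules stay distinct
  expect_false(canonical_smiles("CCO") == canonical_smiles("CCN"))
})

test_that("heavy atom counting ignores hydrogens and survives canonicalization", {
  expect_equal(heavy_atom_count("CCO"), 3L)
  expect_equal(heavy_atom_count("[H][H]"), 0L)
  expect_equal(heavy_atom_count("CC(=O)O"), 4L)
  for (smi in c("CCO", "c1ccccc1", "CC(=O)OCC")) {
    expect_equal(heavy_atom_count(canonical_smiles(smi)), heavy_atom_count(smi))
  }
})

test_that(".frag files round-trip exactly, including empty sets", {
  f <- withr::local_tempfile(fileext = ".frag")
  t1 <- frag_table("mol1", "CC(=O)OCC",
                   list(canonical_smiles(c("CC(=O)O", "CC"))))
  write_frag_file(t1, f)
  line <- readLines(f)
  expect_equal(line, paste0("mol1\tCC(=O)OCC\t",
                            paste(sort(canonical_smiles(c("CC", "CC(=O)O"))),
                                  collapse = ",")))
  expect_equal(read_frag_file(f), t1)

  t2 <- frag_table(c("a", "b"), c("CCCC", "CCO"),
                   list(character(0), canonical_smiles("CCO")))
  write_frag_file(t2, f)
  expect_match(readLines(f)[1], "\t-$")
  expect_equal(read_frag_file(f), t2)
})

test_that(".frag round trip holds for 100 random toy rows", {
  pool <- canonical_smiles(c("CC", "CC(=O)O", "CCO", "c1ccccc1", "CCN",
                             "CC(=O)N", "Cc1ccccc1", "CCCC", "CCC(C)C"))
  set.seed(42)
  sets <- replicate(100, sample(pool, sample(0:6, 1)), simplify = FALSE)
  tbl <- frag_table(sprintf("m%03d", 1:100), rep("CCO", 100), sets)
  f <- withr::local_tempfile(fileext = ".frag")
  write_frag_file(tbl, f)
  expect_equal(read_frag_file(f), tbl)
})

test_that("malformed .frag lines are fatal with a line number", {
  f <- withr::local_tempfile(fileext = ".frag")
  writeLines(c("mol1\tCCO"), f)
  expect_error(read_frag_file(f), "3 tab-separated")
  writeLines(c("mol1\tCCO\tOCC"), f)  # OCC is not canonical
  expect_error(read_frag_file(f), "not canonical")
  writeLines(c("mol1\tCCO\tCC,CC"), f)
  expect_error(read_frag_file(f), "duplicate")
})
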