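rules <- toy_rules()

test_that("cut_bonds splits ethyl acetate into hydrogen-capped fragments", {
  mol <- parse_smiles(canonical_smiles("CC(=O)OCC"))
  bonds <- match_cleavable_bonds(mol, rules)
  frags <- cut_bonds(mol, bonds)
  expect_setequal(vapply(frags, `[[`, character(1), "smiles"),
                  canonical_smiles(c("CC(=O)O", "CC")))
  expect_equal(sum(vapply(frags, `[[`, numeric(1), "heavy_atoms")),
               heavy_atom_count(mol))
})

test_that("cutting nothing returns the whole molecule; ring cuts are refused", {
  mol <- parse_smiles(canonical_smiles("CC(=O)OCC"))
  whole <- cut_bonds(mol, integer(0))
  expect_length(whole, 1L)
  expect_equal(whole[[1]]$smiles, canonical_smiles("CC(=O)OCC"))
  benzene <- parse_smiles(canonical_smiles("c1ccccc1"))
  expect_error(cut_bonds(benzene, 1L), "ring")
})

test_that("cutting k acyclic bonds yields k+1 fragments and conserves heavy atoms", {
  mol <- parse_smiles(canonical_smiles("CCOC(=O)CCC(=O)OCC"))
  bonds <- match_cleavable_bonds(mol, rules)
  expect_length(bonds, 2L)
  frags <- cut_bonds(mol, bonds)
  expect_length(frags, 3L)
  expect_setequal(unique(vapply(frags, `[[`, character(1), "smiles")),
                  canonical_smiles(c("CC", "OC(=O)CCC(=O)O")))
  expect_equal(sum(vapply(frags, `[[`, numeric(1), "heavy_atoms")),
               heavy_atom_count(mol))
})

test_that("compatibility graph nodes are solo-feasible and edges pairwise-feasible", {
  mol <- parse_smiles(canonical_smiles("CCOC(=O)CCC(=O)OCC"))
  cand <- match_cleavable_bonds(mol, rules)
  cg2 <- build_compatibility_graph(mol, cand, 2)
  expect_length(cg2$nodes, 2L)
  expect_equal(nrow(cg2$edges), 1L)
  cg3 <- build_compatibility_graph(mol, cand, 3)
  expect_length(cg3$nodes, 0L)  # each solo cut leaves an undersized ethyl
  ea <- parse_smiles(canonical_smiles("CC(=O)OCC"))
  cg1 <- build_compatibility_graph(ea, match_cleavable_bonds(ea, rules), 1)
  expect_length(cg1$nodes, 1L)
  expect_equal(nrow(cg1$edges), 0L)
})

test_that("maximal cliques: triangle, path, isolated nodes", {
  tri <- list(n = 3L, edges = rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(maximal_cliques(tri), list(1:3))
  path <- list(n = 3L, edges = rbind(c(1, 2), c(2, 3)))
  expect_equal(maximal_cliques(path), list(c(1L, 2L), c(2L, 3L)))
  iso <- list(n = 3L, edges = matrix(integer(0), ncol = 2))
  expect_equal(maximal_cliques(iso), list(1L, 2L, 3L))
  expect_equal(maximal_cliques(list(n = 0L, edges = NULL)), list())
})

test_that("maximal cliques equal exhaustive subset enumeration on random graphs", {
  set.seed(11)
  for (rep in 1:30) {
    g <- random_graph(sample(2:8, 1), sample(c(0.2, 0.5, 0.8), 1))
    expect_equal(clique_set_key(maximal_cliques(g)),
                 clique_set_key(brute_force_cliques(g$n, g$edges)))
  }
})

test_that("extensive fragmentation reproduces hand-enumerated results", {
  # diethyl succinate: subsets {b1}, {b2} each give an ethyl plus the
  # 8-atom half-ester; {b1,b2} gives two ethyls and succinic acid
  ds <- fragment_extensive("CCOC(=O)CCC(=O)OCC", rules, 2)
  expect_setequal(ds$fragments,
                  canonical_smiles(c("CC", "CCOC(=O)CCC(=O)O",
                                     "OC(=O)CCC(=O)O")))
  expect_equal(fragment_extensive("CC(=O)OCC", rules, 4)$fragments, character(0))
  ea <- fragment_extensive("CC(=O)OCC", rules, 2)
  expect_setequal(ea$fragments, canonical_smiles(c("CC(=O)O", "CC")))
  # two solo-infeasible-pair cliques: diethyl ether at min_size 2
  de <- fragment_extensive("CCOCC", rules, 2)
  expect_setequal(de$fragments, canonical_smiles(c("CC", "CCO")))
})

test_that("single mode is the deterministic greedy fragmentation", {
  # greedy accepts both ester bonds and returns only that one cut set
  ds <- fragment_single("CCOC(=O)CCC(=O)OCC", rules, 2)
  expect_setequal(ds$fragments, canonical_smiles(c("CC", "OC(=O)CCC(=O)O")))
  expect_equal(fragment_single("CCCC", rules, 2)$fragments, character(0))
  # rerun gives identical output
  expect_identical(fragment_single("CCOC(=O)CCC(=O)OCC", rules, 2),
                   fragment_single("CCOC(=O)CCC(=O)OCC", rules, 2))
})

test_that("single-mode output is always contained in extensive output", {
  for (mol in toy_molecules()) {
    for (ms in c(2L, 4L)) {
      single <- fragment_single(mol, rules, ms)$fragments
      ext <- fragment_extensive(mol, rules, ms)$fragments
      expect_true(all(single %in% ext),
                  info = sprintf("%s min_size=%d", mol$id, ms))
    }
  }
})

test_that("every emitted fragment meets the size threshold", {
  for (mol in toy_molecules()) {
    for (ms in 1:5) {
      frags <- fragment_extensive(mol, rules, ms)$fragments
      if (length(frags) > 0L) {
        expect_true(all(vapply(frags, heavy_atom_count, integer(1)) >= ms))
      }
    }
  }
})

test_that("fragment_library keeps one row per molecule in input order", {
  mols <- toy_molecules()
  tbl <- suppressMessages(fragment_library(mols, rules, 4))
  expect_s3_class(tbl, "frag_table")
  expect_equal(tbl$id, vapply(mols, `[[`, character(1), "id"))
  expect_equal(tbl$fragments[[which(tbl$id == "butane")]], character(0))
  # a threshold larger than every molecule empties all rows
  big <- suppressMessages(fragment_library(mols, rules, 50))
  expect_true(all(lengths(big$fragments) == 0L))
})

test_that("symmetric diester produces one deduplicated acid fragment per molecule", {
  res <- fragment_extensive("CC(=O)OCCOC(C)=O", rules, 4)
  # both ester cuts give acetic acid; per-molecule sets deduplicate it
  expect_true(canonical_smiles("CC(=O)O") %in% res$fragments)
  expect_equal(sum(res$fragments == canonical_smiles("CC(=O)O")), 1L)
})
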