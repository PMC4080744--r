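# Independent oracles used across the suite.
#
# RDKit (via the system python) provides an independent SMILES parser,
# SMARTS matcher and canonicalizer; it never stands in for the package's
# own implementation.

run_python <- function(code, args = character()) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  out <- suppressWarnings(system2("python", c(script, shQuote(args)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed (exit ", status, ")")
  }
  out
}

rdkit_valid <- function(smiles) {
  out <- run_python(c(
    "import sys",
    "from rdkit import Chem",
    "m = Chem.MolFromSmiles(sys.argv[1])",
    "print('ok' if m is not None else 'bad')"
  ), args = smiles)
  identical(out[length(out)], "ok")
}

rdkit_canonical <- function(smiles) {
  run_python(c(
    "import sys",
    "from rdkit import Chem",
    "for s in sys.argv[1:]:",
    "    print(Chem.CanonSmiles(s))"
  ), args = smiles)
}

# number of distinct (unordered) atom sets matched by a SMARTS pattern
rdkit_num_matches <- function(smiles, smarts) {
  out <- run_python(c(
    "import sys",
    "from rdkit import Chem",
    "m = Chem.MolFromSmiles(sys.argv[1])",
    "p = Chem.MolFromSmarts(sys.argv[2])",
    "print(len(m.GetSubstructMatches(p, uniquify=True)))"
  ), args = c(smiles, smarts))
  as.integer(out[length(out)])
}

# number of embeddings (ordered matches); distinguishes the two directions
# of a symmetric pattern
rdkit_num_embeddings <- function(smiles, smarts) {
  out <- run_python(c(
    "import sys",
    "from rdkit import Chem",
    "m = Chem.MolFromSmiles(sys.argv[1])",
    "p = Chem.MolFromSmarts(sys.argv[2])",
    "print(len(m.GetSubstructMatches(p, uniquify=False)))"
  ), args = c(smiles, smarts))
  as.integer(out[length(out)])
}

# random-atom-order rewrites of a SMILES (independent generator for
# order-invariance properties)
rdkit_random_smiles <- function(smiles, n, seed = 0L) {
  run_python(c(
    "import sys, random",
    "from rdkit import Chem",
    "smi, n, seed = sys.argv[1], int(sys.argv[2]), int(sys.argv[3])",
    "random.seed(seed)",
    "m = Chem.MolFromSmiles(smi)",
    "for i in range(n):",
    "    print(Chem.MolToSmiles(m, canonical=False, doRandom=True))"
  ), args = c(smiles, n, seed))
}

# exhaustive maximal-clique enumeration over all vertex subsets
brute_force_cliques <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      adj[edges[k, 1], edges[k, 2]] <- TRUE
      adj[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    if (length(members) >= 2L) {
      pairs <- utils::combn(members, 2)
      ok <- all(adj[t(pairs)])
    }
    if (ok) cliques[[length(cliques) + 1L]] <- members
  }
  keys <- vapply(cliques, paste, character(1), collapse = ",")
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      j != i && length(cliques[[j]]) > length(cliques[[i]]) &&
        all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  unname(cliques[maximal])
}

clique_set_key <- function(cliques) {
  sort(vapply(cliques, function(cl) paste(sort(cl), collapse = ","), character(1)))
}

random_graph <- function(n, p) {
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < p) edges <- rbind(edges, c(i, j))
    }
  }
  list(n = n, edges = edges)
}

# direct hypergeometric upper tail by summing the pmf as binomial-coefficient
# ratios (exact in double precision for small N)
direct_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# fragment tables built in code for enrichment tests
make_table <- function(frag_sets, prefix = "m") {
  ids <- sprintf("%s%02d", prefix, seq_along(frag_sets))
  frag_table(ids, rep("C", length(frag_sets)), frag_sets)
}

write_toy_rules_file <- function(path) {
  writeLines(c(
    "ester\tC(=O)[O:1][C:2]",
    "amide\t[C;X3:1](=O)[N:2]",
    "ether\t[C;X4:1][O:2][C;X4]"
  ), path)
  path
}

write_toy_molecules_file <- function(path) {
  writeLines(c(
    "CCCC butane",
    "c1ccccc1 benzene",
    "CC(=O)OCC ethyl_acetate",
    "CC(=O)OCc1ccccc1 benzyl_acetate",
    "CCOC(=O)CCC(=O)OCC diethyl_succinate",
    "CC(=O)OCCOC(C)=O glycol_diacetate",
    "CC(=O)NCC N_ethylacetamide",
    "CCOCC diethyl_ether",
    "CC(=O)OCC(COC(C)=O)OC(C)=O triacetin",
    "CCOC(=O)c1ccccc1 ethyl_benzoate"
  ), path)
  path
}

# are all maximal cliques of the compatibility graph jointly feasible?
all_cliques_jointly_feasible <- function(mol, rules, min_size) {
  cg <- build_compatibility_graph(mol, match_cleavable_bonds(mol, rules), min_size)
  for (cl in maximal_cliques(cg)) {
    cut <- cut_bonds(mol, cg$nodes[cl])
    if (any(vapply(cut, `[[`, numeric(1), "heavy_atoms") < min_size)) return(FALSE)
  }
  TRUE
}
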