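fp_of_bits <- function(bits, width = 8L) {
  structure(list(width = as.integer(width), bits = as.integer(sort(bits)),
                 popcount = length(bits)), class = "fingerprint")
}

test_that("path fingerprints follow the FP2-style conventions", {
  expect_equal(linear_path_fingerprint("C")$popcount, 0L)   # lone aliphatic C excluded
  expect_gt(linear_path_fingerprint("Cl")$popcount, 0L)     # halogens are kept
  expect_identical(linear_path_fingerprint("CCO")$bits,
                   linear_path_fingerprint("OCC")$bits)
  expect_equal(linear_path_fingerprint("CCO", width = 64L)$width, 64L)
})

test_that("fingerprints are invariant to input atom ordering", {
  for (smi in c("CC(=O)OCc1ccccc1", "c1ccoc1C(=O)O", "CCC(C)C")) {
    ref <- linear_path_fingerprint(canonical_smiles(smi))
    for (v in unique(rdkit_random_smiles(smi, 50, seed = 3))) {
      expect_identical(linear_path_fingerprint(v)$bits, ref$bits, info = v)
    }
  }
})

test_that("tanimoto follows the set definition and its edge cases", {
  a <- fp_of_bits(c(1, 2, 3)); b <- fp_of_bits(c(2, 3, 4))
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(fp_of_bits(c(1, 2)), fp_of_bits(c(3, 4))), 0.0)
  expect_equal(tanimoto(fp_of_bits(integer(0)), fp_of_bits(integer(0))), 0.0)
  expect_error(tanimoto(a, fp_of_bits(1, width = 16L)), "width")
  # symmetry and bounds on molecular fingerprints
  fps <- lapply(c("CCO", "CC(=O)O", "c1ccccc1", "CCN"), linear_path_fingerprint)
  for (i in 1:3) for (j in (i + 1):4) {
    s <- tanimoto(fps[[i]], fps[[j]])
    expect_equal(s, tanimoto(fps[[j]], fps[[i]]))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("threshold clustering extracts connected components", {
  sim <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.1,
                  0.1, 0.1, 1), 3, 3,
                dimnames = list(c("f1", "f2", "f3"), c("f1", "f2", "f3")))
  cl <- cluster_fragments(c("f1", "f2", "f3"), 0.8, sim = sim)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$members, c("f1", "f2"))   # biggest cluster first
  expect_equal(cl[[2]]$members, "f3")
  expect_equal(cl[[2]]$representative, "f3")

  all_one <- cluster_fragments(c("f1", "f2", "f3"), 0.0, sim = sim)
  expect_length(all_one, 1L)
  expect_error(cluster_fragments(c("f1", "f2"), 2.0, sim = sim), "\\[0, 1\\]")
})

test_that("threshold 1 with distinct fingerprints gives singletons", {
  frags <- canonical_smiles(c("CCO", "CCN", "CC(=O)O", "c1ccccc1"))
  cl <- cluster_fragments(frags, 1.0)
  expect_length(cl, length(frags))
})

test_that("clusters partition the input and refine monotonically in the threshold", {
  set.seed(5)
  n <- 12
  frag_names <- sprintf("f%02d", 1:n)
  for (rep in 1:10) {
    sim <- matrix(stats::runif(n * n), n, n,
                  dimnames = list(frag_names, frag_names))
    sim <- (sim + t(sim)) / 2; diag(sim) <- 1
    lo <- cluster_fragments(frag_names, 0.4, sim = sim)
    hi <- cluster_fragments(frag_names, 0.7, sim = sim)
    expect_setequal(unlist(lapply(lo, `[[`, "members")), frag_names)
    expect_setequal(unlist(lapply(hi, `[[`, "members")), frag_names)
    # refinement: every high-threshold cluster sits inside one low-threshold cluster
    member_of <- function(cls) {
      out <- character(0)
      for (cl in cls) out[cl$members] <- cl$members[1]
      out
    }
    lo_of <- member_of(lo)
    for (cl in hi) expect_length(unique(lo_of[cl$members]), 1L)
  }
})

test_that("components agree with a transitive-closure oracle", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    frag_names <- sprintf("f%02d", 1:n)
    sim <- matrix(stats::runif(n * n), n, n,
                  dimnames = list(frag_names, frag_names))
    sim <- (sim + t(sim)) / 2; diag(sim) <- 1
    thr <- sample(c(0.3, 0.5, 0.8), 1)
    cl <- cluster_fragments(frag_names, thr, sim = sim)
    # oracle: boolean reachability by repeated matrix closure
    reach <- sim >= thr
    repeat {
      nxt <- reach | (reach %*% reach > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    key_ours <- sort(vapply(cl, function(x) paste(x$members, collapse = ","),
                            character(1)))
    key_oracle <- sort(unique(apply(reach, 1, function(r) {
      paste(sort(frag_names[r]), collapse = ",")
    })))
    expect_equal(key_ours, key_oracle)
  }
})

test_that("representatives maximize mean similarity with lexicographic ties", {
  sim <- matrix(c(1, 0.9, 0.7,
                  0.9, 1, 0.7,
                  0.7, 0.7, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(select_representative(c("a", "b", "c"), sim), "a") # tie a/b -> lexicographic
  sim2 <- matrix(c(1, 0.8, 0.5,
                   0.8, 1, 0.8,
                   0.5, 0.8, 1), 3, 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(select_representative(c("x", "y", "z"), sim2), "y")
  expect_equal(select_representative("solo", sim2[1, 1, drop = FALSE]), "solo")
  expect_equal(select_representative(c("x", "z"), sim2), "x")     # pair is always a tie
})
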