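# ---------------------------------------------------------------------------
# Linear-path fingerprints, Tanimoto similarity, threshold-graph clustering
# and representative selection.
# ---------------------------------------------------------------------------

# deterministic string hash (documented): h <- (h * 131 + byte) mod (2^31 - 1)
.path_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

#' Linear-path fingerprint
#'
#' A hashed bit-vector fingerprint in the style of OpenBabel's FP2: every
#' simple path of 1-7 heavy atoms is encoded as the sequence of
#' (element, aromatic flag, formal charge) atom labels and bond orders,
#' read in the lexicographically smaller of its two directions, and hashed
#' to one bit position. Single-atom paths of uncharged non-aromatic C, N and
#' O are excluded (the FP2 convention); hydrogens are ignored. The layout is
#' this package's own — all similarity contracts are expressed through the
#' Tanimoto coefficient of these fingerprints, and bit-exact FP2
#' compatibility is not claimed.
#'
#' @param x a `molgraph` or SMILES string.
#' @param width fingerprint width in bits (default 1024).
#' @return an object of class `fingerprint`: list with `width`, `bits`
#'   (sorted positions of set bits, 1-based) and `popcount`.
#' @export
linear_path_fingerprint <- function(x, width = 1024L) {
  g <- if (inherits(x, "molgraph")) x else parse_smiles(x)
  stopifnot(width >= 1L)
  heavy <- which(g$atoms$element != "H")
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
      if (g$atoms$element[i] == "H" || g$atoms$element[j] == "H") next
      adj[[i]] <- rbind(adj[[i]], c(j, b))
      adj[[j]] <- rbind(adj[[j]], c(i, b))
    }
  }
  atom_label <- vapply(seq_len(n), function(v) {
    paste0(g$atoms$element[v], if (g$atoms$aromatic[v]) "a" else "A",
           g$atoms$charge[v])
  }, character(1))

  paths <- character(0)
  emit <- function(atom_seq, bond_seq) {
    fwd <- paste(c(rbind(atom_label[atom_seq],
                         c(g$bonds$order[bond_seq], "")))[seq_len(2L * length(atom_seq) - 1L)],
                 collapse = "|")
    rev_atoms <- rev(atom_seq); rev_bonds <- rev(bond_seq)
    bwd <- paste(c(rbind(atom_label[rev_atoms],
                         c(g$bonds$order[rev_bonds], "")))[seq_len(2L * length(atom_seq) - 1L)],
                 collapse = "|")
    paths[[length(paths) + 1L]] <<- if (fwd <= bwd) fwd else bwd
    invisible(NULL)
  }
  walk <- function(atom_seq, bond_seq) {
    v <- atom_seq[length(atom_seq)]
    if (length(atom_seq) > 1L ||
        !(g$atoms$element[v] %in% c("C", "N", "O") &&
          !g$atoms$aromatic[v] && g$atoms$charge[v] == 0L)) {
      emit(atom_seq, bond_seq)
    }
    if (length(atom_seq) == 7L) return(invisible(NULL))
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible(NULL))
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (w %in% atom_seq) next
      walk(c(atom_seq, w), c(bond_seq, nb[r, 2]))
    }
    invisible(NULL)
  }
  for (v in heavy) walk(v, integer(0))

  bits <- sort(unique(vapply(unique(paths), function(p) {
    as.integer(.path_hash(p) %% width) + 1L
  }, integer(1))))
  structure(list(width = as.integer(width), bits = bits,
                 popcount = length(bits)),
            class = "fingerprint")
}

#' Tanimoto coefficient of two fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over the set bits; defined as 0 when both
#' fingerprints are all-zero, so similarity of featureless fragments is
#' well defined.
#'
#' @param a,b `fingerprint` objects of equal width.
#' @return a similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$width != b$width) rf_abort("fingerprint widths differ")
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

# pairwise Tanimoto matrix for a fragment set
.similarity_matrix <- function(fragments, width = 1024L) {
  fps <- lapply(fragments, linear_path_fingerprint, width = width)
  n <- length(fragments)
  sim <- diag(1, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sim[i, j] <- sim[j, i] <- tanimoto(fps[[i]], fps[[j]])
      }
    }
  }
  dimnames(sim) <- list(fragments, fragments)
  sim
}

#' Select the representative fragment of a cluster
#'
#' The representative is the member with the highest mean similarity to the
#' other members (the only member for singletons); ties are broken by the
#' lexicographically smallest fragment string.
#'
#' @param members character vector of fragment strings (nonempty).
#' @param sim similarity matrix with members among its row/column names.
#' @return a single fragment string.
#' @export
select_representative <- function(members, sim) {
  stopifnot(length(members) > 0L)
  if (length(members) == 1L) return(members)
  means <- vapply(members, function(f) {
    mean(sim[f, setdiff(members, f)])
  }, numeric(1))
  best <- members[means == max(means)]
  sort(best, method = "radix")[1]
}

#' Cluster fragments by Tanimoto similarity
#'
#' Builds a graph with one node per fragment and an edge between every pair
#' whose Tanimoto similarity is at least `threshold` (inclusive), and takes
#' its connected components as clusters. Cluster ids are assigned by
#' descending cluster size, then by the representative string; every
#' fragment belongs to exactly one cluster.
#'
#' @param fragments character vector of distinct fragment strings.
#' @param threshold Tanimoto cutoff in \[0, 1\].
#' @param sim optional precomputed similarity matrix (row/column names =
#'   fragments); when `NULL`, fingerprints of width `fp_bits` are computed
#'   from the fragment SMILES.
#' @param fp_bits fingerprint width when `sim` is computed here.
#' @return a list of `fragment_cluster` objects (fields `cluster_id`,
#'   `members` sorted, `representative`).
#' @export
cluster_fragments <- function(fragments, threshold, sim = NULL,
                              fp_bits = 1024L) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    rf_abort("similarity threshold must lie in [0, 1]")
  }
  if (anyDuplicated(fragments)) rf_abort("fragments must be unique")
  n <- length(fragments)
  if (n == 0L) return(list())
  if (is.null(sim)) sim <- .similarity_matrix(fragments, width = fp_bits)
  stopifnot(all(fragments %in% rownames(sim)))
  sim <- sim[fragments, fragments, drop = FALSE]

  comp <- seq_len(n)          # union-find over threshold edges
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sim[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(fragments, root)
  clusters <- lapply(groups, function(members) {
    members <- sort(members, method = "radix")
    list(members = members,
         representative = select_representative(members, sim))
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  reps <- vapply(clusters, `[[`, character(1), "representative")
  ord <- order(-sizes, reps, method = "radix")
  out <- vector("list", length(clusters))
  for (k in seq_along(ord)) {
    cl <- clusters[[ord[k]]]
    out[[k]] <- structure(list(cluster_id = k, members = cl$members,
                               representative = cl$representative),
                          class = "fragment_cluster")
  }
  out
}
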