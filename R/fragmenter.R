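# ---------------------------------------------------------------------------
# Retrosynthetic fragmentation: rule matching, bond cutting, the
# bond-compatibility graph, Bron-Kerbosch maximal cliques, and the extensive
# and single fragmentation modes.
# ---------------------------------------------------------------------------

.as_molgraph <- function(mol) {
  if (inherits(mol, "molecule_record")) mol$graph
  else if (inherits(mol, "molgraph")) mol
  else parse_smiles(canonical_smiles(mol))
}

.mol_id <- function(mol) {
  if (inherits(mol, "molecule_record")) mol$id else NA_character_
}

#' Find cleavable bonds
#'
#' Applies each cleavage rule to the molecule and returns one cleavable bond
#' per distinct (bond, rule) pair: a bond matched in both atom orders counts
#' once. Ring bonds are never cleavable — cutting a single ring bond does
#' not split the molecule — and are dropped here.
#'
#' @param mol a `molecule_record`, `molgraph`, or SMILES string.
#' @param rules a list of `cleavage_rule` objects from [read_rules_file()]
#'   or [toy_rules()].
#' @return a list of `cleavable_bond` objects (fields `bond_index`,
#'   `atom_pair` = atoms matched to maps 1 and 2, `rule_name`), ordered by
#'   bond index then rule order.
#' @export
match_cleavable_bonds <- function(mol, rules) {
  g <- .as_molgraph(mol)
  out <- list()
  seen <- character(0)
  for (r_idx in seq_along(rules)) {
    rule <- rules[[r_idx]]
    maps <- vapply(rule$pattern$atoms, function(a) a$map, integer(1))
    q1 <- which(maps == 1L); q2 <- which(maps == 2L)
    for (m in match_smarts(g, rule$pattern)) {
      i <- m[q1]; j <- m[q2]
      b <- which((g$bonds$a1 == i & g$bonds$a2 == j) |
                 (g$bonds$a1 == j & g$bonds$a2 == i))
      if (length(b) == 0L) next
      b <- b[1]
      if (g$bonds$ring[b]) next
      key <- paste(b, r_idx, sep = "/")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- structure(
        list(bond_index = b, atom_pair = c(i, j), rule_name = rule$name,
             rule_order = r_idx),
        class = "cleavable_bond")
    }
  }
  ord <- order(vapply(out, `[[`, integer(1), "bond_index"),
               vapply(out, `[[`, integer(1), "rule_order"))
  out[ord]
}

# collapse per-(bond, rule) records to one record per bond (first rule wins),
# preserving match order
.unique_bonds <- function(bonds) {
  idx <- vapply(bonds, `[[`, integer(1), "bond_index")
  bonds[!duplicated(idx)]
}

.bond_indices <- function(bonds) {
  if (is.numeric(bonds)) as.integer(bonds)
  else vapply(bonds, `[[`, integer(1), "bond_index")
}

# connected-component membership after deleting `drop` bond indices
.components_after_cut <- function(g, drop) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  keep <- setdiff(seq_len(nrow(g$bonds)), drop)
  for (b in keep) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s; comp[s] <- cid
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; stack <- c(stack, w) }
    }
  }
  comp
}

# heavy-atom size of every component after cutting; cheap feasibility probe
.cut_sizes <- function(g, drop) {
  comp <- .components_after_cut(g, drop)
  heavy <- g$atoms$element != "H"
  as.integer(tapply(heavy, comp, sum))
}

#' Cut a set of bonds and collect the fragments
#'
#' Deletes the given acyclic bonds and returns the resulting connected
#' components as hydrogen-capped canonical fragments. Cutting `k` distinct
#' acyclic bonds of a connected molecule yields exactly `k + 1` fragments,
#' and no heavy atom is gained or lost.
#'
#' @param mol a `molecule_record`, `molgraph`, or SMILES string.
#' @param bonds a list of `cleavable_bond`s or a vector of bond indices;
#'   must be distinct non-ring bonds.
#' @return a list of fragments, each a list with `smiles` (canonical),
#'   `atoms` (parent atom indices) and `heavy_atoms`.
#' @export
cut_bonds <- function(mol, bonds) {
  g <- .as_molgraph(mol)
  drop <- unique(.bond_indices(bonds))
  if (length(drop) != length(.bond_indices(bonds))) {
    rf_abort("bonds to cut must be distinct")
  }
  if (any(drop < 1L | drop > nrow(g$bonds))) rf_abort("bond index out of range")
  if (any(g$bonds$ring[drop])) {
    rf_abort("refusing to cut a ring bond: it does not split the molecule")
  }
  base <- max(.components_after_cut(g, integer(0)))
  comp <- .components_after_cut(g, drop)
  n_comp <- max(comp)
  stopifnot(n_comp == base + length(drop))

  # hydrogen capping: implicit-valence atoms re-fill automatically; atoms
  # with an explicit hydrogen count gain one H per incident cut
  hplus <- integer(nrow(g$atoms))
  for (b in drop) {
    for (v in c(g$bonds$a1[b], g$bonds$a2[b])) {
      if (!is.na(g$atoms$hcount[v])) hplus[v] <- hplus[v] + 1L
    }
  }
  heavy <- g$atoms$element != "H"
  raw <- character(n_comp)
  atom_sets <- vector("list", n_comp)
  for (cid in seq_len(n_comp)) {
    atoms <- which(comp == cid)
    atom_sets[[cid]] <- atoms
    raw[cid] <- molgraph_to_smiles(g, atom_ids = atoms, drop_bonds = drop,
                                   hplus = hplus)
  }
  can <- canonical_smiles(raw)
  lapply(seq_len(n_comp), function(cid) {
    list(smiles = can[cid], atoms = atom_sets[[cid]],
         heavy_atoms = sum(heavy[atom_sets[[cid]]]))
  })
}

#' Build the bond-compatibility graph
#'
#' Nodes are the candidate bonds whose solo cut yields only fragments of at
#' least `min_size` heavy atoms; an edge joins two nodes iff cutting both
#' bonds simultaneously also leaves no fragment below `min_size`. Maximal
#' cliques of this graph are the maximal sets of bonds that can be cleaved
#' together (up to the pairwise approximation discussed in the vignette).
#'
#' @param mol a `molecule_record`, `molgraph`, or SMILES string.
#' @param candidate_bonds output of [match_cleavable_bonds()].
#' @param min_size minimum fragment size in heavy atoms (>= 1).
#' @return an object of class `compat_graph`: list with `nodes` (cleavable
#'   bonds) and `edges` (two-column matrix of node indices).
#' @export
build_compatibility_graph <- function(mol, candidate_bonds, min_size) {
  stopifnot(min_size >= 1L)
  g <- .as_molgraph(mol)
  cand <- .unique_bonds(candidate_bonds)
  solo <- vapply(cand, function(b) {
    all(.cut_sizes(g, b$bond_index) >= min_size)
  }, logical(1))
  nodes <- cand[solo]
  n <- length(nodes)
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sizes <- .cut_sizes(g, c(nodes[[i]]$bond_index, nodes[[j]]$bond_index))
        if (all(sizes >= min_size)) edges <- rbind(edges, c(i, j))
      }
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "compat_graph")
}

#' Enumerate maximal cliques (Bron-Kerbosch)
#'
#' Bron-Kerbosch enumeration with pivoting. Every returned set is a clique,
#' no returned set contains another, and every clique of the graph extends
#' to some returned set. Isolated nodes are returned as singleton cliques.
#'
#' @param graph a `compat_graph`, or a list with elements `n` (node count)
#'   and `edges` (two-column matrix of node indices).
#' @return a list of sorted integer vectors, ordered lexicographically.
#' @export
maximal_cliques <- function(graph) {
  if (inherits(graph, "compat_graph")) {
    n <- length(graph$nodes); edges <- graph$edges
  } else {
    n <- graph$n; edges <- graph$edges
  }
  if (n == 0L) return(list())
  nbr <- vector("list", n)
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  nbr <- lapply(nbr, function(x) sort(unique(x)))
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      cliques[[length(cliques) + 1L]] <<- sort(R)
      return(invisible(NULL))
    }
    # pivot: vertex of P union X with most neighbours in P
    px <- c(P, X)
    deg <- vapply(px, function(u) length(intersect(nbr[[u]], P)), integer(1))
    u <- px[which.max(deg)]
    for (v in setdiff(P, nbr[[u]])) {
      bk(c(R, v), intersect(P, nbr[[v]]), intersect(X, nbr[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible(NULL)
  }
  bk(integer(0), seq_len(n), integer(0))
  key <- vapply(cliques, function(cl) {
    paste(formatC(cl, width = 8, flag = "0"), collapse = ",")
  }, character(1))
  cliques[order(key)]
}

.filter_min_size <- function(frags, min_size) {
  keep <- vapply(frags, function(f) f$heavy_atoms >= min_size, logical(1))
  vapply(frags[keep], `[[`, character(1), "smiles")
}

.fragmentation_result <- function(mol, fragments) {
  structure(list(molecule_id = .mol_id(mol),
                 fragments = sort(unique(fragments), method = "radix")),
            class = "fragmentation_result")
}

#' Extensive fragmentation
#'
#' Generates every fragment of at least `min_size` heavy atoms that any
#' simultaneous cleavage can produce. The bond-compatibility graph is built,
#' its maximal cliques are enumerated with Bron-Kerbosch, and each clique is
#' processed in turn: every jointly feasible subset of its bonds (no
#' resulting fragment below `min_size`) is cut and its fragments collected.
#' Because any feasible cut set is a clique and therefore lies inside some
#' maximal clique, this yields the complete union of fragments over all
#' feasible fragmentations, with duplicates merged by canonical SMILES. A
#' molecule with no feasible cleavable bond yields an empty set.
#'
#' @inheritParams build_compatibility_graph
#' @param rules a list of `cleavage_rule` objects.
#' @return a `fragmentation_result`: list with `molecule_id` and sorted
#'   character vector `fragments`.
#' @export
fragment_extensive <- function(mol, rules, min_size) {
  g <- .as_molgraph(mol)
  cand <- match_cleavable_bonds(g, rules)
  cg <- build_compatibility_graph(g, cand, min_size)
  frags <- character(0)
  done <- character(0)   # cut sets shared between overlapping cliques
  for (cl in maximal_cliques(cg)) {
    idx <- vapply(cg$nodes[cl], `[[`, integer(1), "bond_index")
    m <- length(idx)
    if (m > 20L) {
      rf_abort(sprintf("maximal clique of %d cleavable bonds exceeds the subset-enumeration limit", m))
    }
    for (mask in seq_len(2^m - 1L)) {
      sel <- sort(idx[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L])
      key <- paste(sel, collapse = ",")
      if (key %in% done) next
      done <- c(done, key)
      if (!all(.cut_sizes(g, sel) >= min_size)) next
      frags <- c(frags, .filter_min_size(cut_bonds(g, sel), min_size))
    }
  }
  .fragmentation_result(mol, frags)
}

#' Single (non-extensive) fragmentation
#'
#' Returns one deterministic fragmentation: cleavable bonds are added
#' greedily, in match order, to a cut set, skipping any bond whose addition
#' would leave a fragment below `min_size`. The final cut set is cleaved
#' once and its fragments returned.
#'
#' @inheritParams fragment_extensive
#' @return a `fragmentation_result`.
#' @export
fragment_single <- function(mol, rules, min_size) {
  stopifnot(min_size >= 1L)
  g <- .as_molgraph(mol)
  cand <- .unique_bonds(match_cleavable_bonds(g, rules))
  cut_set <- integer(0)
  for (b in cand) {
    trial <- c(cut_set, b$bond_index)
    if (all(.cut_sizes(g, trial) >= min_size)) cut_set <- trial
  }
  if (length(cut_set) == 0L) return(.fragmentation_result(mol, character(0)))
  frags <- .filter_min_size(cut_bonds(g, cut_set), min_size)
  .fragmentation_result(mol, frags)
}

#' Fragment a molecule library
#'
#' Runs [fragment_extensive()] (or [fragment_single()]) over a list of
#' molecules and assembles a [frag_table()], one row per input molecule in
#' input order (molecules with no fragments keep an empty row). Results are
#' memoised per (canonical parent, rule set, `min_size`, mode) within the
#' session.
#'
#' @param molecules a list of `molecule_record`s from [read_smiles_file()].
#' @param rules a list of `cleavage_rule` objects.
#' @param min_size minimum fragment size in heavy atoms (>= 1).
#' @param extensive logical; enumerate all maximal-clique fragmentations
#'   (default) or the single greedy fragmentation.
#' @return a `frag_table`.
#' @export
fragment_library <- function(molecules, rules, min_size, extensive = TRUE) {
  stopifnot(length(molecules) > 0L, min_size >= 1L)
  rules_sig <- paste(vapply(rules, `[[`, character(1), "smarts"), collapse = ";")
  frags <- vector("list", length(molecules))
  for (k in seq_along(molecules)) {
    mol <- molecules[[k]]
    key <- paste(mol$canonical, rules_sig, min_size, extensive, sep = "\r")
    hit <- .rf_env$fragcache[[key]]
    if (!is.null(hit)) {
      frags[[k]] <- hit
    } else {
      res <- if (extensive) fragment_extensive(mol, rules, min_size)
             else fragment_single(mol, rules, min_size)
      .rf_env$fragcache[[key]] <- res$fragments
      frags[[k]] <- res$fragments
    }
  }
  ids <- vapply(molecules, `[[`, character(1), "id")
  smis <- vapply(molecules, `[[`, character(1), "smiles")
  tbl <- frag_table(ids, smis, frags)
  message(sprintf("fragmented %d molecules: %d distinct fragments (min size %d, %s mode)",
                  length(molecules), length(unique(unlist(frags))), min_size,
                  if (extensive) "extensive" else "single"))
  tbl
}
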