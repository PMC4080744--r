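#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# standard valences used for implicit-hydrogen assignment; alternates for S/P/N
.valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, As = 33, Se = 34, Br = 35, I = 53
)

rf_abort <- function(msg, class = "retrofrag_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# ---------------------------------------------------------------------------
# SMILES parsing
#
# The parser covers the organic subset, bracket atoms (charge, explicit H;
# isotopes and chirality are read but ignored), branches, ring closures
# (including %nn), aromatic lowercase atoms and dot-separated components.
# Stereo bond symbols / and \ are read as single bonds.
# ---------------------------------------------------------------------------

#' Parse a SMILES string into a molecular graph
#'
#' Builds an annotated molecular graph: one row per heavy (or explicit) atom
#' with element, aromaticity, formal charge and any explicit hydrogen count,
#' and one row per bond with its order and a ring-membership flag (a bond is
#' in a ring iff it is not a bridge of the graph).
#'
#' @param smiles a single SMILES string.
#' @return an object of class `molgraph`: a list with data frames `atoms`
#'   (`element`, `aromatic`, `charge`, `hcount` — `NA` means implicit) and
#'   `bonds` (`a1`, `a2`, `order` one of `-`, `=`, `#`, `:`, and `ring`).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  parsed <- .parse_chain(smiles, smarts = FALSE)
  atoms <- do.call(rbind, lapply(parsed$atoms, function(a) {
    data.frame(element = a$element, aromatic = a$aromatic, charge = a$charge,
               hcount = a$hcount, stringsAsFactors = FALSE)
  }))
  bonds <- .finalize_bonds(parsed$bonds, atoms)
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

.finalize_bonds <- function(bond_list, atoms) {
  if (length(bond_list) == 0L) {
    return(data.frame(a1 = integer(), a2 = integer(), order = character(),
                      ring = logical(), stringsAsFactors = FALSE))
  }
  bonds <- do.call(rbind, lapply(bond_list, function(b) {
    data.frame(a1 = b$a1, a2 = b$a2, order = b$order %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  # default bond: aromatic between two aromatic atoms, else single
  def <- is.na(bonds$order)
  both_arom <- atoms$aromatic[bonds$a1] & atoms$aromatic[bonds$a2]
  bonds$order[def & both_arom] <- ":"
  bonds$order[def & !both_arom] <- "-"
  bonds$ring <- .ring_bond_flags(nrow(atoms), bonds)
  # an aromatic-default bond outside any ring is a plain single bond
  # (e.g. the biaryl bond of biphenyl written without an explicit "-")
  bonds$order[bonds$order == ":" & !bonds$ring] <- "-"
  bonds
}

.ring_bond_flags <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  ring <- rep(TRUE, nrow(bonds))
  ring[as.integer(igraph::bridges(g))] <- FALSE
  ring
}

# shared chain walker for SMILES and SMARTS
.parse_chain <- function(s, smarts) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  stack <- integer()
  pending <- NULL
  ringmap <- list()

  add_atom <- function(atom) {
    atoms[[length(atoms) + 1L]] <<- atom
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx, order = pending)
    }
    prev <<- idx
    pending <<- NULL
  }
  handle_ring <- function(key) {
    if (is.na(prev)) rf_abort(sprintf("ring closure '%s' before any atom in '%s'", key, s))
    if (!is.null(ringmap[[key]])) {
      op <- ringmap[[key]]
      if (op$atom == prev) rf_abort(sprintf("self ring closure in '%s'", s))
      bonds[[length(bonds) + 1L]] <<- list(a1 = op$atom, a2 = prev,
                                           order = op$sym %||% pending)
      ringmap[[key]] <<- NULL
    } else {
      ringmap[[key]] <<- list(atom = prev, sym = pending)
    }
    pending <<- NULL
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == " " || ch == "\t") {
      break # trailing fields (identifiers) are not part of the SMILES
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) rf_abort(sprintf("unbalanced ')' in '%s'", s))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~", "/", "\\", "@")) {
      if (!smarts && ch %in% c("~", "@")) {
        rf_abort(sprintf("'%s' bond is SMARTS-only: '%s'", ch, s))
      }
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) rf_abort(sprintf("truncated %% ring closure in '%s'", s))
      handle_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      handle_ring(ch); i <- i + 1L
    } else if (ch == "[") {
      close <- .find_bracket_close(chars, i)
      content <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      atom <- if (smarts) .parse_smarts_bracket(content, s)
              else .parse_smiles_bracket(content, s)
      add_atom(atom)
      i <- close + 1L
    } else {
      parsed <- .parse_plain_atom(chars, i, smarts, s)
      add_atom(parsed$atom)
      i <- parsed$next_i
    }
  }
  if (length(stack) > 0L) rf_abort(sprintf("unbalanced '(' in '%s'", s))
  if (length(ringmap) > 0L) rf_abort(sprintf("unclosed ring bond in '%s'", s))
  if (length(atoms) == 0L) rf_abort(sprintf("no atoms in '%s'", s))
  list(atoms = atoms, bonds = bonds)
}

.find_bracket_close <- function(chars, i) {
  j <- i + 1L
  while (j <= length(chars) && chars[j] != "]") j <- j + 1L
  if (j > length(chars)) {
    rf_abort(sprintf("unmatched '[' in '%s'", paste(chars, collapse = "")))
  }
  j
}

.parse_plain_atom <- function(chars, i, smarts, s) {
  two <- if (i + 1L <= length(chars)) paste0(chars[i], chars[i + 1L]) else ""
  if (two %in% c("Cl", "Br")) {
    return(list(atom = .make_atom(two, FALSE, smarts), next_i = i + 2L))
  }
  ch <- chars[i]
  if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
    return(list(atom = .make_atom(ch, FALSE, smarts), next_i = i + 1L))
  }
  if (ch %in% c("b", "c", "n", "o", "p", "s")) {
    return(list(atom = .make_atom(toupper(ch), TRUE, smarts), next_i = i + 1L))
  }
  if (smarts && ch == "*") {
    return(list(atom = .smarts_atom(.single_prim("any")), next_i = i + 1L))
  }
  if (smarts && ch == "A") {
    return(list(atom = .smarts_atom(.single_prim("arom", FALSE)), next_i = i + 1L))
  }
  if (smarts && ch == "a") {
    return(list(atom = .smarts_atom(.single_prim("arom", TRUE)), next_i = i + 1L))
  }
  rf_abort(sprintf("unsupported atom symbol '%s' in '%s'", ch, s))
}

.make_atom <- function(element, aromatic, smarts) {
  if (smarts) {
    .smarts_atom(.single_prim("elem", list(symbol = element, aromatic = aromatic)))
  } else {
    list(element = element, aromatic = aromatic, charge = 0L, hcount = NA_integer_)
  }
}

.parse_smiles_bracket <- function(content, s) {
  m <- regmatches(content, regexec(
    "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
    content))[[1]]
  if (length(m) == 0L) {
    rf_abort(sprintf("cannot parse bracket atom '[%s]' in '%s'", content, s))
  }
  sym <- m[3]
  aromatic <- grepl("^[a-z]", sym)
  element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  hfield <- m[5]
  hcount <- if (hfield == "") 0L
            else if (hfield == "H") 1L
            else as.integer(substring(hfield, 2))
  cfield <- m[6]
  charge <- if (cfield == "") 0L
            else if (cfield == "+") 1L
            else if (cfield == "-") -1L
            else if (grepl("^\\++$", cfield)) nchar(cfield)
            else if (grepl("^-+$", cfield)) -nchar(cfield)
            else as.integer(cfield)
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       hcount = hcount)
}

# ---------------------------------------------------------------------------
# implicit hydrogens, heavy atoms, atom properties
# ---------------------------------------------------------------------------

.bond_order_value <- function(order) {
  unname(c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5)[order])
}

# total hydrogen count per atom: explicit bracket count, or filled to the
# element's next standard valence for organic-subset atoms
total_hcounts <- function(g) {
  n <- nrow(g$atoms)
  bsum <- numeric(n)
  if (nrow(g$bonds) > 0L) {
    v <- .bond_order_value(g$bonds$order)
    for (b in seq_len(nrow(g$bonds))) {
      bsum[g$bonds$a1[b]] <- bsum[g$bonds$a1[b]] + v[b]
      bsum[g$bonds$a2[b]] <- bsum[g$bonds$a2[b]] + v[b]
    }
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(g$atoms$hcount[i])) { out[i] <- g$atoms$hcount[i]; next }
    vals <- .valences[[g$atoms$element[i]]]
    if (is.null(vals) || g$atoms$charge[i] != 0L) { out[i] <- 0L; next }
    need <- ceiling(bsum[i])
    fit <- vals[vals >= need]
    out[i] <- if (length(fit) == 0L) 0L else as.integer(fit[1] - need)
  }
  out
}

#' Count heavy (non-hydrogen) atoms
#'
#' Fragment size throughout the package is measured as the number of heavy
#' atoms, i.e. all atoms that are not hydrogen.
#'
#' @param x a `molgraph`, or a SMILES string.
#' @return a non-negative integer.
#' @export
heavy_atom_count <- function(x) {
  g <- if (inherits(x, "molgraph")) x else parse_smiles(x)
  sum(g$atoms$element != "H")
}

# atom-level properties consumed by the SMARTS matcher
.atom_props <- function(g) {
  n <- nrow(g$atoms)
  degree <- integer(n)
  in_ring <- logical(n)
  if (nrow(g$bonds) > 0L) {
    heavy <- g$atoms$element != "H"
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
      if (heavy[j]) degree[i] <- degree[i] + 1L
      if (heavy[i]) degree[j] <- degree[j] + 1L
      if (g$bonds$ring[b]) in_ring[c(i, j)] <- TRUE
    }
  }
  data.frame(element = g$atoms$element, aromatic = g$atoms$aromatic,
             charge = g$atoms$charge, hct = total_hcounts(g),
             degree = degree, in_ring = in_ring, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# SMILES writing
# ---------------------------------------------------------------------------

# Serialize (part of) a molgraph back to SMILES. `atom_ids` selects atoms
# (connected components among them are dot-joined), `drop_bonds` removes bond
# indices (used for bond cutting), and `hplus` adds hydrogens at cut sites of
# atoms that carry an explicit hydrogen count.
molgraph_to_smiles <- function(g, atom_ids = seq_len(nrow(g$atoms)),
                               drop_bonds = integer(),
                               hplus = integer(nrow(g$atoms))) {
  n_atoms <- nrow(g$atoms)
  inset <- logical(n_atoms); inset[atom_ids] <- TRUE
  live <- setdiff(seq_len(nrow(g$bonds)), drop_bonds)
  live <- live[inset[g$bonds$a1[live]] & inset[g$bonds$a2[live]]]

  # adjacency: per atom, matrix of (neighbour, bond index into g$bonds)
  adj <- vector("list", n_atoms)
  for (b in live) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    adj[[i]] <- rbind(adj[[i]], c(j, b))
    adj[[j]] <- rbind(adj[[j]], c(i, b))
  }

  visited <- logical(n_atoms)
  ring_counter <- 0L
  pieces <- character(0)

  for (start in sort(atom_ids)) {
    if (visited[start]) next
    # DFS from `start`: tree edges drive the traversal, remaining edges
    # become ring closures
    parent_bond <- rep(NA_integer_, n_atoms)
    children <- vector("list", n_atoms)
    back_edges <- integer(0)
    seen_bond <- logical(max(1L, nrow(g$bonds)))
    stack <- start
    visited[start] <- TRUE
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in order(nb[, 1])) {
        w <- nb[r, 1]; b <- nb[r, 2]
        if (seen_bond[b]) next
        seen_bond[b] <- TRUE
        if (!visited[w]) {
          visited[w] <- TRUE
          parent_bond[w] <- b
          children[[v]] <- c(children[[v]], w)
          stack <- c(stack, w)
        } else {
          back_edges <- c(back_edges, b)
        }
      }
    }
    # ring-closure labels, one per back edge, noted at both endpoints
    closure_at <- vector("list", n_atoms)
    for (b in back_edges) {
      ring_counter <- ring_counter + 1L
      lab <- if (ring_counter < 10L) as.character(ring_counter)
             else sprintf("%%%02d", ring_counter)
      i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
      closure_at[[i]] <- c(closure_at[[i]], setNames(lab, b))
      closure_at[[j]] <- c(closure_at[[j]], setNames(lab, b))
    }

    emitted_closure <- character(0)
    rec <- function(v) {
      out <- .atom_token(g, v, hplus[v])
      cls <- closure_at[[v]]
      for (k in seq_along(cls)) {
        b <- names(cls)[k]
        sym <- if (b %in% emitted_closure) "" else .bond_token(g, as.integer(b))
        emitted_closure <<- c(emitted_closure, b)
        out <- paste0(out, sym, cls[[k]])
      }
      kids <- children[[v]]
      if (length(kids) > 0L) {
        strs <- vapply(sort(kids), function(w) {
          paste0(.bond_token(g, parent_bond[w]), rec(w))
        }, character(1))
        if (length(strs) > 1L) {
          out <- paste0(out, paste0("(", strs[-length(strs)], ")", collapse = ""),
                        strs[length(strs)])
        } else {
          out <- paste0(out, strs)
        }
      }
      out
    }
    pieces <- c(pieces, rec(start))
  }
  paste(pieces, collapse = ".")
}

.bond_token <- function(g, bond_idx) {
  order <- g$bonds$order[bond_idx]
  if (order == ":") return("")
  if (order == "-") {
    both_arom <- g$atoms$aromatic[g$bonds$a1[bond_idx]] &&
      g$atoms$aromatic[g$bonds$a2[bond_idx]]
    return(if (both_arom) "-" else "")
  }
  order
}

.atom_token <- function(g, v, extra_h = 0L) {
  el <- g$atoms$element[v]
  arom <- g$atoms$aromatic[v]
  charge <- g$atoms$charge[v]
  hcount <- g$atoms$hcount[v]
  sym <- if (arom) tolower(el) else el
  needs_bracket <- charge != 0L || !(el %in% .organic_subset) || !is.na(hcount)
  if (!needs_bracket) return(sym)
  h <- if (is.na(hcount)) 0L else hcount + extra_h
  htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ctok <- if (charge == 0L) ""
          else if (charge == 1L) "+"
          else if (charge == -1L) "-"
          else if (charge > 0L) paste0("+", charge)
          else as.character(charge)
  paste0("[", sym, htok, ctok, "]")
}
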