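# ---------------------------------------------------------------------------
# SMARTS subset: parsing and substructure matching
#
# Supported atom primitives: element symbols (aliphatic uppercase, aromatic
# lowercase), #n atomic number, * any, A aliphatic, a aromatic, Hn total
# hydrogen count, Dn heavy-atom degree, Xn total connections (degree + H),
# R / R0 / Rn ring membership, +/- charges, and atom maps :n. Logical
# operators: ! (not), & or juxtaposition (high-precedence and), , (or),
# ; (low-precedence and). Bond expressions: default (single-or-aromatic),
# -, =, #, : and ~ (any), @ (ring bond). Recursive SMARTS ($(...)) is not
# supported; the shipped rule files are encoded within this subset.
# ---------------------------------------------------------------------------

.single_prim <- function(type, value = NULL) {
  list(list(list(list(neg = FALSE, type = type, value = value))))
}

.smarts_atom <- function(constraint, map = NA_integer_) {
  list(constraint = constraint, map = map)
}

#' Compile a SMARTS pattern
#'
#' Parses a SMARTS pattern (within the package's documented subset, see
#' Details in the package vignette) into a query graph of atom constraints
#' and bond constraints, keeping any atom maps (`:n`).
#'
#' @param smarts a single SMARTS string.
#' @return an object of class `smarts_pattern` with elements `atoms`
#'   (constraint + atom map per query atom), `bonds` (query bonds with their
#'   constraint symbol), and `smarts` (the source string).
#' @export
parse_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L)
  parsed <- .parse_chain(smarts, smarts = TRUE)
  atoms <- parsed$atoms
  bonds <- if (length(parsed$bonds) == 0L) {
    data.frame(a1 = integer(), a2 = integer(), order = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(parsed$bonds, function(b) {
      data.frame(a1 = b$a1, a2 = b$a2, order = b$order %||% "default",
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(atoms = atoms, bonds = bonds, smarts = smarts),
            class = "smarts_pattern")
}

# bracket atom expression: AND(';') of OR(',') of AND('&'/juxtaposed) of
# possibly negated primitives; an atom map may close the expression
.parse_smarts_bracket <- function(content, s) {
  map <- NA_integer_
  mm <- regmatches(content, regexec("^(.*?):([0-9]+)$", content))[[1]]
  if (length(mm) == 3L) {
    map <- as.integer(mm[3])
    content <- mm[2]
  }
  if (content == "") rf_abort(sprintf("empty bracket atom in '%s'", s))
  parts <- strsplit(content, ";", fixed = TRUE)[[1]]
  constraint <- lapply(parts, function(part) {
    alts <- strsplit(part, ",", fixed = TRUE)[[1]]
    lapply(alts, function(alt) .parse_and_chain(alt, s))
  })
  .smarts_atom(constraint, map)
}

.parse_and_chain <- function(txt, s) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  prims <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "&") { i <- i + 1L; next }
    neg <- FALSE
    while (i <= length(chars) && chars[i] == "!") { neg <- !neg; i <- i + 1L }
    if (i > length(chars)) rf_abort(sprintf("dangling '!' in SMARTS '%s'", s))
    p <- .parse_smarts_prim(chars, i, s)
    p$prim$neg <- neg
    prims[[length(prims) + 1L]] <- p$prim
    i <- p$next_i
  }
  if (length(prims) == 0L) rf_abort(sprintf("empty atom expression in '%s'", s))
  prims
}

.parse_smarts_prim <- function(chars, i, s) {
  ch <- chars[i]
  take_num <- function(j, default = NA_integer_) {
    k <- j
    while (k <= length(chars) && grepl("^[0-9]$", chars[k])) k <- k + 1L
    if (k == j) list(val = default, next_i = j)
    else list(val = as.integer(paste(chars[j:(k - 1L)], collapse = "")), next_i = k)
  }
  prim <- NULL; next_i <- i + 1L
  two <- if (i + 1L <= length(chars)) paste0(ch, chars[i + 1L]) else ""
  if (two %in% c("Cl", "Br", "Si", "Se", "As")) {
    prim <- list(type = "elem", value = list(symbol = two, aromatic = FALSE))
    next_i <- i + 2L
  } else if (ch == "#") {
    num <- take_num(i + 1L)
    if (is.na(num$val)) rf_abort(sprintf("'#' without atomic number in '%s'", s))
    sym <- names(.atomic_numbers)[match(num$val, .atomic_numbers)]
    if (is.na(sym)) rf_abort(sprintf("unsupported atomic number %d in '%s'", num$val, s))
    prim <- list(type = "elem", value = list(symbol = sym, aromatic = NA))
    next_i <- num$next_i
  } else if (ch == "*") {
    prim <- list(type = "any")
  } else if (ch == "a") {
    prim <- list(type = "arom", value = TRUE)
  } else if (ch == "A") {
    prim <- list(type = "arom", value = FALSE)
  } else if (ch == "H") {
    num <- take_num(i + 1L, default = 1L)
    prim <- list(type = "hcount", value = num$val); next_i <- num$next_i
  } else if (ch == "D") {
    num <- take_num(i + 1L, default = 1L)
    prim <- list(type = "degree", value = num$val); next_i <- num$next_i
  } else if (ch == "X") {
    num <- take_num(i + 1L, default = 1L)
    prim <- list(type = "conn", value = num$val); next_i <- num$next_i
  } else if (ch == "R") {
    num <- take_num(i + 1L)
    inring <- is.na(num$val) || num$val >= 1L
    prim <- list(type = "ring", value = inring); next_i <- num$next_i
  } else if (ch == "+" || ch == "-") {
    sign <- if (ch == "+") 1L else -1L
    num <- take_num(i + 1L)
    reps <- 1L; j <- i + 1L
    if (is.na(num$val)) {
      while (j <= length(chars) && chars[j] == ch) { reps <- reps + 1L; j <- j + 1L }
      prim <- list(type = "charge", value = sign * reps); next_i <- j
    } else {
      prim <- list(type = "charge", value = sign * num$val); next_i <- num$next_i
    }
  } else if (grepl("^[A-Z]$", ch)) {
    if (!ch %in% names(.atomic_numbers)) {
      rf_abort(sprintf("unsupported element '%s' in SMARTS '%s'", ch, s))
    }
    prim <- list(type = "elem", value = list(symbol = ch, aromatic = FALSE))
  } else if (grepl("^[a-z]$", ch)) {
    el <- toupper(ch)
    if (!el %in% c("B", "C", "N", "O", "P", "S")) {
      rf_abort(sprintf("unsupported aromatic symbol '%s' in SMARTS '%s'", ch, s))
    }
    prim <- list(type = "elem", value = list(symbol = el, aromatic = TRUE))
  } else {
    rf_abort(sprintf("unsupported SMARTS primitive at '%s' in '%s'", ch, s))
  }
  list(prim = prim, next_i = next_i)
}

# ---------------------------------------------------------------------------
# evaluation and matching
# ---------------------------------------------------------------------------

.eval_prim <- function(prim, props, v) {
  hit <- switch(prim$type,
    any    = TRUE,
    arom   = props$aromatic[v] == prim$value,
    elem   = {
      ok <- props$element[v] == prim$value$symbol
      if (ok && !is.na(prim$value$aromatic)) {
        ok <- props$aromatic[v] == prim$value$aromatic
      }
      ok
    },
    hcount = props$hct[v] == prim$value,
    degree = props$degree[v] == prim$value,
    conn   = props$degree[v] + props$hct[v] == prim$value,
    ring   = props$in_ring[v] == prim$value,
    charge = props$charge[v] == prim$value,
    rf_abort(sprintf("unknown primitive type '%s'", prim$type))
  )
  if (prim$neg) !hit else hit
}

.eval_atom_constraint <- function(constraint, props, v) {
  for (part in constraint) {            # AND over ';' groups
    part_ok <- FALSE
    for (alt in part) {                 # OR over ',' alternatives
      alt_ok <- TRUE
      for (prim in alt) {               # AND of primitives
        if (!.eval_prim(prim, props, v)) { alt_ok <- FALSE; break }
      }
      if (alt_ok) { part_ok <- TRUE; break }
    }
    if (!part_ok) return(FALSE)
  }
  TRUE
}

.eval_bond_constraint <- function(sym, order, ring) {
  switch(sym,
    "default" = order %in% c("-", ":"),
    "-" = order == "-",
    "=" = order == "=",
    "#" = order == "#",
    ":" = order == ":",
    "~" = TRUE,
    "@" = ring,
    rf_abort(sprintf("unsupported bond expression '%s'", sym))
  )
}

#' Find all embeddings of a SMARTS pattern in a molecule
#'
#' Enumerates every injective assignment of query atoms to molecule atoms
#' that satisfies all atom and bond constraints. The query must be connected.
#'
#' @param g a `molgraph`.
#' @param pattern a `smarts_pattern` from [parse_smarts()].
#' @return a list of integer vectors; element `i` of a vector is the molecule
#'   atom matched by query atom `i`.
#' @export
match_smarts <- function(g, pattern) {
  stopifnot(inherits(pattern, "smarts_pattern"))
  if (!inherits(g, "molgraph")) g <- parse_smiles(g)
  props <- .atom_props(g)
  np <- length(pattern$atoms)
  nm <- nrow(g$atoms)
  if (nm == 0L) return(list())

  # molecule adjacency with bond rows
  madj <- vector("list", nm)
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
      madj[[i]] <- rbind(madj[[i]], c(j, b))
      madj[[j]] <- rbind(madj[[j]], c(i, b))
    }
  }

  # query traversal order: DFS so that every atom after the first has an
  # already-placed neighbour (anchor)
  qadj <- vector("list", np)
  if (nrow(pattern$bonds) > 0L) {
    for (b in seq_len(nrow(pattern$bonds))) {
      i <- pattern$bonds$a1[b]; j <- pattern$bonds$a2[b]
      qadj[[i]] <- c(qadj[[i]], j)
      qadj[[j]] <- c(qadj[[j]], i)
    }
  }
  order_q <- integer(0)
  seen <- logical(np)
  stack <- 1L; seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_q <- c(order_q, v)
    for (w in qadj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  if (!all(seen)) rf_abort(sprintf("disconnected SMARTS pattern '%s'", pattern$smarts))

  # per query atom (in traversal order), bonds to already-placed query atoms
  placed_rank <- match(seq_len(np), order_q)
  back_bonds <- vector("list", np)
  if (nrow(pattern$bonds) > 0L) {
    for (b in seq_len(nrow(pattern$bonds))) {
      i <- pattern$bonds$a1[b]; j <- pattern$bonds$a2[b]
      late <- if (placed_rank[i] > placed_rank[j]) i else j
      back_bonds[[late]] <- c(back_bonds[[late]], b)
    }
  }

  results <- list()
  assign_vec <- rep(NA_integer_, np)
  used <- logical(nm)

  try_place <- function(k) {
    if (k > np) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    q <- order_q[k]
    cands <- if (k == 1L) seq_len(nm) else {
      # candidates adjacent to the anchor implied by the first back bond
      b0 <- back_bonds[[q]][1]
      other <- if (placed_rank[pattern$bonds$a1[b0]] < placed_rank[q]) {
        pattern$bonds$a1[b0]
      } else pattern$bonds$a2[b0]
      nb <- madj[[assign_vec[other]]]
      if (is.null(nb)) integer(0) else nb[, 1]
    }
    for (v in cands) {
      if (used[v]) next
      if (!.eval_atom_constraint(pattern$atoms[[q]]$constraint, props, v)) next
      ok <- TRUE
      for (b in back_bonds[[q]]) {
        i <- pattern$bonds$a1[b]; j <- pattern$bonds$a2[b]
        other <- if (i == q) j else i
        mv <- assign_vec[other]
        # find the molecule bond between v and mv
        nb <- madj[[v]]
        row <- if (is.null(nb)) integer(0) else which(nb[, 1] == mv)
        if (length(row) == 0L) { ok <- FALSE; break }
        bm <- nb[row[1], 2]
        if (!.eval_bond_constraint(pattern$bonds$order[b],
                                   g$bonds$order[bm], g$bonds$ring[bm])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[q] <<- v; used[v] <<- TRUE
      try_place(k + 1L)
      assign_vec[q] <<- NA_integer_; used[v] <<- FALSE
    }
    invisible(NULL)
  }
  try_place(1L)
  results
}
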