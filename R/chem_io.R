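# ---------------------------------------------------------------------------
# External representations: SMILES molecule files, SMARTS rule files, the
# .frag fragment-table interchange format, and the analysis output table.
# ---------------------------------------------------------------------------

.read_content_lines <- function(path) {
  if (!file.exists(path)) rf_abort(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a SMILES molecule file
#'
#' One molecule per line: `SMILES` optionally followed by whitespace and an
#' identifier. Lines starting with `#` and blank lines are ignored.
#' Molecules without an identifier are named `mol<k>` by their 1-based
#' position among the molecule lines. Lines whose SMILES cannot be parsed
#' are skipped with a warning (or abort under `strict = TRUE`).
#'
#' @param path path to the SMILES file.
#' @param strict logical; promote unparseable lines from warnings to errors.
#' @return a list of `molecule_record` objects (fields `id`, `smiles` as
#'   read, `canonical`, and `graph`, a [parse_smiles()] graph of the
#'   canonical form), with attribute `n_skipped`.
#' @export
read_smiles_file <- function(path, strict = FALSE) {
  content <- .read_content_lines(path)
  if (length(content$lines) == 0L) {
    rf_abort(sprintf("no molecules in '%s'", path))
  }
  fields <- regmatches(content$lines,
                       regexec("^\\s*(\\S+)(?:\\s+(\\S+))?\\s*$", content$lines))
  records <- list()
  ids <- character(0)
  n_skipped <- 0L
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) == 0L) {
      rf_abort(sprintf("%s:%d: malformed line", path, content$lineno[k]))
    }
    smi <- f[2]
    id <- if (is.na(f[3]) || f[3] == "") sprintf("mol%d", k) else f[3]
    can <- canonicalize_or_na(smi)
    if (is.na(can)) {
      msg <- sprintf("%s:%d: skipping unparseable SMILES '%s'",
                     path, content$lineno[k], smi)
      if (strict) rf_abort(msg)
      warning(msg, call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    if (id %in% ids) {
      rf_abort(sprintf("%s: duplicate molecule ID '%s'", path, id))
    }
    ids <- c(ids, id)
    records[[length(records) + 1L]] <- structure(
      list(id = id, smiles = smi, canonical = can, graph = parse_smiles(can)),
      class = "molecule_record")
  }
  if (length(records) == 0L) {
    rf_abort(sprintf("no valid molecules in '%s'", path))
  }
  attr(records, "n_skipped") <- n_skipped
  records
}

#' Read a cleavage-rule file
#'
#' One rule per line: a SMARTS pattern, optionally preceded by a name and a
#' tab. Every rule must carry atom maps `:1` and `:2` on two bonded atoms;
#' the mapped bond is the one that gets cut. Unnamed rules are called
#' `rule<k>`.
#'
#' @param path path to the rules file.
#' @return a list of `cleavage_rule` objects (fields `name`, `smarts`,
#'   `pattern`).
#' @export
read_rules_file <- function(path) {
  content <- .read_content_lines(path)
  if (length(content$lines) == 0L) {
    rf_abort(sprintf("no rules in '%s'", path))
  }
  rules <- vector("list", length(content$lines))
  for (k in seq_along(content$lines)) {
    line <- content$lines[k]
    lineno <- content$lineno[k]
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    parts <- parts[parts != ""]
    if (length(parts) == 1L) {
      name <- sprintf("rule%d", k); smarts <- trimws(parts[1])
    } else if (length(parts) == 2L) {
      name <- trimws(parts[1]); smarts <- trimws(parts[2])
    } else {
      rf_abort(sprintf("%s:%d: expected '[name<TAB>]SMARTS'", path, lineno))
    }
    pattern <- tryCatch(parse_smarts(smarts), error = function(e) {
      rf_abort(sprintf("%s:%d: SMARTS does not compile: %s",
                       path, lineno, conditionMessage(e)))
    })
    maps <- vapply(pattern$atoms, function(a) a$map, integer(1))
    mapped <- which(!is.na(maps))
    if (!setequal(maps[mapped], c(1L, 2L)) || length(mapped) != 2L) {
      rf_abort(sprintf("%s:%d: rule must carry exactly atom maps :1 and :2",
                       path, lineno))
    }
    i <- mapped[which(maps[mapped] == 1L)]
    j <- mapped[which(maps[mapped] == 2L)]
    bonded <- any((pattern$bonds$a1 == i & pattern$bonds$a2 == j) |
                  (pattern$bonds$a1 == j & pattern$bonds$a2 == i))
    if (!bonded) {
      rf_abort(sprintf("%s:%d: mapped atoms :1 and :2 must be bonded",
                       path, lineno))
    }
    rules[[k]] <- structure(list(name = name, smarts = smarts,
                                 pattern = pattern),
                            class = "cleavage_rule")
  }
  rules
}

# ---------------------------------------------------------------------------
# fragment tables and the .frag format
# ---------------------------------------------------------------------------

#' Construct a fragment table
#'
#' A fragment table holds, per molecule, the set of canonical fragment
#' strings produced by fragmentation. This is the interchange object between
#' the fragmentation stage and the analysis stage.
#'
#' @param id character vector of molecule identifiers (must be unique).
#' @param smiles parent SMILES, same length.
#' @param fragments list of character vectors of canonical fragment SMILES;
#'   duplicates within a row are collapsed and rows are stored sorted.
#' @return an object of class `frag_table` (a data frame with a `fragments`
#'   list column).
#' @export
frag_table <- function(id, smiles, fragments) {
  stopifnot(length(id) == length(smiles), length(id) == length(fragments))
  if (anyDuplicated(id)) {
    rf_abort(sprintf("duplicate molecule ID '%s' in fragment table",
                     id[duplicated(id)][1]))
  }
  fragments <- lapply(fragments, function(f) {
    sort(unique(as.character(f)), method = "radix")
  })
  out <- data.frame(id = as.character(id), smiles = as.character(smiles),
                    stringsAsFactors = FALSE)
  out$fragments <- fragments
  class(out) <- c("frag_table", "data.frame")
  out
}

#' Write / read a fragment table (`.frag` format)
#'
#' The `.frag` format is this package's own plain-text dialect (the layout
#' is not standardised elsewhere): a TSV with three columns — molecule id,
#' parent SMILES, and the comma-separated canonical fragment SMILES sorted
#' lexicographically (byte order), with `-` denoting an empty fragment set.
#' `read_frag_file(write_frag_file(t))` is lossless.
#'
#' @param table a `frag_table`.
#' @param path output (or input) file path.
#' @return `write_frag_file` returns `invisible(path)`; `read_frag_file`
#'   returns a `frag_table`.
#' @export
write_frag_file <- function(table, path) {
  stopifnot(inherits(table, "frag_table"))
  fr <- vapply(table$fragments, function(f) {
    if (length(f) == 0L) "-" else paste(f, collapse = ",")
  }, character(1))
  writeLines(paste(table$id, table$smiles, fr, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_frag_file
#' @export
read_frag_file <- function(path) {
  if (!file.exists(path)) rf_abort(sprintf("cannot read file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  ids <- character(0); smis <- character(0); frags <- list()
  for (k in keep) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      rf_abort(sprintf("%s:%d: expected 3 tab-separated fields, got %d",
                       path, k, length(parts)))
    }
    f <- if (parts[3] == "-") character(0)
         else strsplit(parts[3], ",", fixed = TRUE)[[1]]
    if (anyDuplicated(f)) {
      rf_abort(sprintf("%s:%d: duplicate fragment '%s'",
                       path, k, f[duplicated(f)][1]))
    }
    if (length(f) > 0L) {
      can <- canonicalize_or_na(f)
      bad <- which(is.na(can) | can != f)
      if (length(bad) > 0L) {
        rf_abort(sprintf("%s:%d: fragment '%s' is not canonical",
                         path, k, f[bad[1]]))
      }
    }
    ids <- c(ids, parts[1]); smis <- c(smis, parts[2])
    frags[[length(frags) + 1L]] <- f
  }
  frag_table(ids, smis, frags)
}

# analysis output table (TSV, header row); "-" fills unused columns
write_analysis_table <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "-", vapply(x, function(v) sprintf("%.6g", v), character(1)))
    } else {
      ifelse(is.na(x), "-", as.character(x))
    }
  }
  header <- c("fragment", "cluster", "fg_count", "bg_count", "p_value", "fdr")
  stopifnot(identical(names(df), header))
  body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}
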