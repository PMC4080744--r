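# OpenBabel-backed canonical SMILES with an in-session cache.

.rf_env <- new.env(parent = emptyenv())
.rf_env$canon <- new.env(parent = emptyenv())
.rf_env$fragcache <- new.env(parent = emptyenv())

# raw OpenBabel canonicalization of a character vector; NA for strings
# OpenBabel rejects. Batch conversion stops at the first invalid line, so a
# count mismatch triggers a per-line fallback.
.ob_canonical <- function(smis) {
  if (length(smis) == 0L) return(character(0))
  one <- function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) "")
    line <- strsplit(out, "\n", fixed = TRUE)[[1]]
    if (length(line) == 0L || line[1] == "") return(NA_character_)
    strsplit(line[1], "\t", fixed = TRUE)[[1]][1]
  }
  batch <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(paste(smis, collapse = "\n"), "\n"))),
    error = function(e) "")
  lines <- strsplit(batch, "\n", fixed = TRUE)[[1]]
  if (length(lines) == length(smis) && !any(lines == "")) {
    vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
           character(1), USE.NAMES = FALSE)
  } else {
    vapply(smis, one, character(1), USE.NAMES = FALSE)
  }
}

# cached canonicalization; returns NA for invalid SMILES
canonicalize_or_na <- function(smis) {
  out <- rep(NA_character_, length(smis))
  key <- smis
  hit <- vapply(key, function(k) !is.null(.rf_env$canon[[k]]), logical(1),
                USE.NAMES = FALSE)
  out[hit] <- vapply(key[hit], function(k) .rf_env$canon[[k]], character(1),
                     USE.NAMES = FALSE)
  todo <- which(!hit)
  if (length(todo) > 0L) {
    fresh <- .ob_canonical(smis[todo])
    for (i in seq_along(todo)) {
      if (!is.na(fresh[i])) .rf_env$canon[[key[todo[i]]]] <- fresh[i]
    }
    out[todo] <- fresh
  }
  # cached values are canonical already: canonical(canonical(x)) = canonical(x)
  ok <- !is.na(out)
  for (i in which(ok)) .rf_env$canon[[out[i]]] <- out[i]
  out
}

#' Canonical SMILES
#'
#' Maps a molecular graph (or SMILES strings) to a unique canonical SMILES
#' string per graph-isomorphism class, so that identical fragments obtained
#' from different parent molecules compare equal. Canonicalization is
#' delegated to OpenBabel and is idempotent.
#'
#' @param x a `molgraph`, or a character vector of SMILES strings.
#' @return a character vector of canonical SMILES.
#' @export
canonical_smiles <- function(x) {
  if (inherits(x, "molgraph")) x <- molgraph_to_smiles(x)
  stopifnot(is.character(x))
  out <- canonicalize_or_na(x)
  if (anyNA(out)) {
    rf_abort(sprintf("invalid SMILES: '%s'", x[which(is.na(out))[1]]))
  }
  out
}
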