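# ---------------------------------------------------------------------------
# Deterministic toy inputs and brute-force references: a hand-verified rule
# set, a small golden molecule library, seeded planted-enrichment library
# generation, and an exhaustive fragmentation oracle.
# ---------------------------------------------------------------------------

#' Toy cleavage rules
#'
#' Three hand-verified mapped-SMARTS rules covering common linker chemistry:
#' ester (cut the alkoxy O-C bond), amide (cut the carbonyl C-N bond) and
#' dialkyl ether (cut a C-O bond; the `X4` constraints keep ester oxygens
#' from matching). These drive all correctness fixtures.
#'
#' @return a list of `cleavage_rule` objects.
#' @export
toy_rules <- function() {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(c(
    "ester\tC(=O)[O:1][C:2]",
    "amide\t[C;X3:1](=O)[N:2]",
    "ether\t[C;X4:1][O:2][C;X4]"
  ), tf)
  read_rules_file(tf)
}

#' Golden toy molecule library
#'
#' Ten small molecules, fixed once, covering the structural cases the
#' fragmenter must handle: no cleavable bonds, one, two, and three or more;
#' an aromatic ring; a symmetric diester producing duplicate fragments in
#' one molecule; and a triester (triacetin) whose three cleavable bonds are
#' pairwise compatible at `min_size = 4` yet jointly leave an undersized
#' glyceryl core — the case where whole-clique cutting and subset
#' enumeration legitimately differ.
#'
#' @return a list of `molecule_record` objects.
#' @export
toy_molecules <- function() {
  lines <- c(
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
  )
  tf <- tempfile(fileext = ".smi")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  read_smiles_file(tf)
}

#' Brute-force fragmentation oracle
#'
#' Exhaustively tries every nonempty subset of the candidate cleavable
#' bonds, keeps the subsets whose cut leaves no fragment below `min_size`
#' heavy atoms, and returns the union of their fragments. Exponential in
#' the number of candidate bonds, so it refuses more than 12; intended as
#' an independent reference for [fragment_extensive()] in tests.
#'
#' @inheritParams fragment_extensive
#' @return sorted character vector of canonical fragment SMILES.
#' @export
brute_force_fragmenter <- function(mol, rules, min_size) {
  stopifnot(min_size >= 1L)
  g <- .as_molgraph(mol)
  cand <- .unique_bonds(match_cleavable_bonds(g, rules))
  nb <- length(cand)
  if (nb > 12L) rf_abort(sprintf("%d candidate bonds exceed the oracle's limit of 12", nb))
  if (nb == 0L) return(character(0))
  idx <- vapply(cand, `[[`, integer(1), "bond_index")
  frags <- character(0)
  for (mask in seq_len(2^nb - 1L)) {
    sel <- idx[bitwAnd(mask, 2^(seq_len(nb) - 1L)) > 0L]
    if (!all(.cut_sizes(g, sel) >= min_size)) next
    cut <- cut_bonds(g, sel)
    frags <- c(frags, vapply(cut, `[[`, character(1), "smiles"))
  }
  sort(unique(frags), method = "radix")
}

# scaffold pools for the planted-enrichment design: molecules are esters
# LEFT-C(=O)-O-RIGHT with exactly one cleavable (ester) bond, so that
# fragmentation at min_size = 4 yields one acid and one alkane/arene
# fragment per molecule
.planted_left <- "c1ccccc1"                                   # benzoyl -> benzoic acid
.other_lefts <- c("C1CCCCC1", "CCCC", "c1ccoc1")              # cyclohexyl, butyl, furyl acyls
.right_pool  <- c("CCCC", "Cc1ccccc1", "CCC(C)C", "CC1CCCCC1")

.assemble_ester <- function(left, right) paste0(left, "C(=O)O", right)

#' Generate a seeded library with a planted enriched fragment
#'
#' Builds a background library of single-ester molecules and draws a
#' foreground as a subset of it (so the background always contains the
#' foreground, as enrichment requires). A planted acyl moiety — whose acid
#' fragment is `planted_fragment` in the returned truth record — appears in
#' a fraction `rate_bg` of background molecules and `rate_fg` of foreground
#' molecules; the remaining molecules draw their acyl group and all
#' molecules their alkoxy group uniformly from fixed scaffold pools.
#' Identical seeds give byte-identical files.
#'
#' @param n_bg,n_fg background and foreground sizes (foreground is a subset
#'   of the background).
#' @param rate_fg,rate_bg planted-moiety rates in \[0, 1\]; `rate_fg <=
#'   rate_bg` is a degenerate design and is recorded as a warning in the
#'   truth record.
#' @param seed integer RNG seed; fully determines the output.
#' @param outdir optional directory; when given, `foreground.smi`,
#'   `background.smi` and `truth.json` are written there.
#' @return invisibly, a list with `background` / `foreground` (data frames
#'   with `smiles`, `id`), `truth` (planted fragment, carrier ids, params,
#'   `degenerate` flag) and, when `outdir` is given, the file paths.
#' @export
make_enriched_library <- function(n_bg = 40L, n_fg = 10L, rate_fg = 1.0,
                                  rate_bg = 0.25, seed = 1L, outdir = NULL) {
  stopifnot(n_bg >= 2L, n_fg >= 1L, n_fg <= n_bg,
            rate_fg >= 0, rate_fg <= 1, rate_bg >= 0, rate_bg <= 1)
  degenerate <- rate_fg <= rate_bg
  n_carrier_bg <- round(rate_bg * n_bg)
  n_carrier_fg <- round(rate_fg * n_fg)
  if (n_carrier_fg > n_carrier_bg ||
      (n_fg - n_carrier_fg) > (n_bg - n_carrier_bg)) {
    rf_abort("foreground composition is not drawable from the background")
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  res <- withr_seed({
    carrier <- c(rep(TRUE, n_carrier_bg), rep(FALSE, n_bg - n_carrier_bg))
    lefts <- ifelse(carrier, .planted_left,
                    sample(.other_lefts, n_bg, replace = TRUE))
    rights <- sample(.right_pool, n_bg, replace = TRUE)
    fg_idx <- sort(c(sample(which(carrier), n_carrier_fg),
                     sample(which(!carrier), n_fg - n_carrier_fg)))
    list(lefts = lefts, rights = rights, carrier = carrier, fg_idx = fg_idx)
  })
  ids <- sprintf("bg%03d", seq_len(n_bg))
  smiles <- .assemble_ester(res$lefts, res$rights)
  background <- data.frame(smiles = smiles, id = ids, stringsAsFactors = FALSE)
  foreground <- background[res$fg_idx, , drop = FALSE]
  planted <- canonical_smiles(.assemble_ester(.planted_left, ""))  # benzoic acid
  truth <- list(
    planted_fragment = planted,
    carriers_bg = ids[res$carrier],
    carriers_fg = intersect(ids[res$carrier], foreground$id),
    foreground_ids = foreground$id,
    params = list(n_bg = n_bg, n_fg = n_fg, rate_fg = rate_fg,
                  rate_bg = rate_bg, seed = seed),
    degenerate = degenerate
  )
  if (degenerate && rate_fg < rate_bg) {
    warning("rate_fg <= rate_bg: planted design is degenerate", call. = FALSE)
  }
  out <- list(background = background, foreground = foreground, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    bg_path <- file.path(outdir, "background.smi")
    fg_path <- file.path(outdir, "foreground.smi")
    truth_path <- file.path(outdir, "truth.json")
    writeLines(paste(background$smiles, background$id), bg_path)
    writeLines(paste(foreground$smiles, foreground$id), fg_path)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- list(background = bg_path, foreground = fg_path,
                      truth = truth_path)
  }
  invisible(out)
}
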