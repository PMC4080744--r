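# ---------------------------------------------------------------------------
# Fragment frequency distributions, hypergeometric enrichment against a
# background, and Benjamini-Hochberg FDR control.
# ---------------------------------------------------------------------------

#' Fragment frequency distribution
#'
#' Counts, for every fragment, the number of molecules whose fragment set
#' contains it. Multiple instances of a fragment within one molecule count
#' once (fragment sets are already deduplicated per molecule).
#'
#' @param table a `frag_table`.
#' @return a list with `counts` (named integer vector, fragment -> molecule
#'   count) and `n_molecules` (number of table rows, including rows with an
#'   empty fragment set).
#' @export
count_frequencies <- function(table) {
  stopifnot(inherits(table, "frag_table"))
  all_frags <- unlist(lapply(table$fragments, unique), use.names = FALSE)
  counts <- if (length(all_frags) == 0L) {
    integer(0)
  } else {
    tab <- base::table(all_frags)
    setNames(as.integer(tab), names(tab))
  }
  list(counts = counts, n_molecules = nrow(table))
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim}Hypergeometric(population `N`, `K`
#' marked, `n` drawn), computed through the survival function of
#' [stats::phyper] for numerical stability.
#'
#' @param k observed count of marked draws.
#' @param K marked items in the population.
#' @param n number of draws.
#' @param N population size.
#' @return a probability in (0, 1].
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || n > N || K > N) {
    rf_abort(sprintf(
      "inconsistent hypergeometric counts: k=%s K=%s n=%s N=%s", k, K, n, N))
  }
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' The step-up procedure: with `m` hypotheses and sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value of \eqn{p_{(i)}}
#' is \eqn{\min_{j \ge i} m\, p_{(j)} / j}, capped at 1. Output order
#' matches input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of FDR values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    rf_abort("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# per-unit molecule counts at fragment or cluster level; a molecule counts
# once per cluster if it contains at least one member fragment
.unit_counts <- function(table, clusters) {
  if (is.null(clusters)) {
    count_frequencies(table)
  } else {
    frag2cl <- unlist(lapply(clusters, function(cl) {
      setNames(rep(cl$cluster_id, length(cl$members)), cl$members)
    }))
    per_mol <- lapply(table$fragments, function(f) {
      unique(unname(frag2cl[f[f %in% names(frag2cl)]]))
    })
    hits <- unlist(per_mol, use.names = FALSE)
    counts <- if (length(hits) == 0L) integer(0) else {
      tab <- base::table(hits)
      setNames(as.integer(tab), names(tab))
    }
    list(counts = counts, n_molecules = nrow(table))
  }
}

#' Fragment or cluster enrichment against a background
#'
#' Tests, for every unit (fragment, or fragment cluster when `clusters` is
#' given) present in the foreground, whether it occurs more often than
#' expected under hypergeometric sampling from the background. Two sampling
#' universes are available: `"occurrences"` (the default; the population is
#' the multiset of background fragment occurrences, `N` = sum of background
#' unit counts, `n` = sum of foreground unit counts) and `"molecules"`
#' (GO-style; `N` and `n` are the background and foreground molecule
#' counts). Every foreground fragment must be present in the background.
#' Benjamini-Hochberg FDRs are computed across all tested units.
#'
#' @param foreground,background `frag_table` objects; the background must
#'   contain every foreground fragment.
#' @param clusters optional list of `fragment_cluster`s partitioning the
#'   background fragment universe; switches the analysis to cluster level.
#' @param universe `"occurrences"` or `"molecules"`.
#' @return a data frame of class `enrichment_result` with columns `unit`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fdr`, sorted by ascending p-value.
#' @export
enrich <- function(foreground, background, clusters = NULL,
                   universe = c("occurrences", "molecules")) {
  universe <- match.arg(universe)
  stopifnot(inherits(foreground, "frag_table"), inherits(background, "frag_table"))
  fg_frags <- unique(unlist(foreground$fragments, use.names = FALSE))
  bg_frags <- unique(unlist(background$fragments, use.names = FALSE))
  missing <- setdiff(fg_frags, bg_frags)
  if (length(missing) > 0L) {
    rf_abort(sprintf(
      "foreground fragment '%s' is absent from the background; the background set must contain the foreground fragments",
      missing[1]))
  }
  if (!is.null(clusters)) {
    members <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
    if (anyDuplicated(members) || !all(bg_frags %in% members)) {
      rf_abort("clusters must partition the background fragment universe")
    }
  }
  fg <- .unit_counts(foreground, clusters)
  bg <- .unit_counts(background, clusters)
  units <- sort(names(fg$counts), method = "radix")
  if (length(units) == 0L) {
    rf_abort("foreground contains no fragments to test")
  }
  if (universe == "occurrences") {
    N <- sum(bg$counts); n <- sum(fg$counts)
  } else {
    N <- bg$n_molecules; n <- fg$n_molecules
  }
  k <- as.integer(fg$counts[units])
  K <- as.integer(bg$counts[units])
  bad <- which(k > K)
  if (length(bad) > 0L) {
    rf_abort(sprintf(
      "unit '%s' occurs more often in the foreground (%d) than in the background (%d); the background must contain the foreground molecules",
      units[bad[1]], k[bad[1]], K[bad[1]]))
  }
  p <- vapply(seq_along(units), function(i) {
    hypergeometric_upper_tail(k[i], K[i], n, N)
  }, numeric(1))
  fdr <- benjamini_hochberg(p)
  out <- data.frame(unit = units, k = k, n = n, K = K, N = N,
                    p_value = p, fdr = fdr, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$k, out$unit, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @describeIn enrich enrichment in the molecule universe (`N`, `n` are
#'   molecule counts), equivalent to `enrich(..., universe = "molecules")`.
#' @export
molecule_universe_enrich <- function(foreground, background, clusters = NULL) {
  enrich(foreground, background, clusters, universe = "molecules")
}
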