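# All-pairs Fisher exact testing, BH adjustment, and edge styling.
#
# These statistics are deliberately independent of the structure
# learner: they annotate learned edges (and build standalone "Fisher
# networks") with the direction and strength of pairwise association.
# Odds ratio < 1 reads as mutual exclusivity, > 1 as co-occurrence.

#' 2x2 contingency table of two events
#'
#' @param m an [event_matrix()].
#' @param a,b distinct event names.
#' @return A `contingency_table`: counts `n11`, `n10`, `n01`, `n00`
#'   (joint presence/absence of `a` and `b` across samples).
#' @export
contingency_table <- function(m, a, b) {
  if (identical(a, b)) stop("need two distinct events")
  for (ev in c(a, b)) if (!ev %in% event_names(m))
    stop("unknown event: ", ev)
  va <- unclass(m)[, a]
  vb <- unclass(m)[, b]
  structure(list(n11 = sum(va == 1 & vb == 1),
                 n10 = sum(va == 1 & vb == 0),
                 n01 = sum(va == 0 & vb == 1),
                 n00 = sum(va == 0 & vb == 0)),
            class = "contingency_table")
}

as_matrix_ct <- function(t) {
  matrix(c(t$n11, t$n01, t$n10, t$n00), nrow = 2,
         dimnames = list(a = c("1", "0"), b = c("1", "0")))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value under the noncentral hypergeometric null and
#' the conditional maximum-likelihood odds ratio, as computed by
#' [stats::fisher.test()]. With the sample estimator
#' (`estimator = "sample"`) the cross-product ratio `n11*n00/(n10*n01)`
#' is returned instead. Degenerate tables (a zero margin) carry no
#' information about association: they are reported as `p = 1`,
#' `odds_ratio = 1` and flagged `degenerate = TRUE`. Zero cells in
#' informative tables yield odds ratios of 0 or `Inf`.
#'
#' @param t a [contingency_table()].
#' @param estimator `"cmle"` (default, conditional MLE) or `"sample"`.
#' @return List with `odds_ratio`, `p_value`, `degenerate`.
#' @export
fisher_exact <- function(t, estimator = c("cmle", "sample")) {
  estimator <- match.arg(estimator)
  mat <- as_matrix_ct(t)
  degenerate <- any(rowSums(mat) == 0) || any(colSums(mat) == 0)
  if (degenerate)
    return(list(odds_ratio = 1, p_value = 1, degenerate = TRUE))
  ft <- stats::fisher.test(mat)
  or <- if (estimator == "cmle") unname(ft$estimate)
    else (t$n11 * t$n00) / (t$n10 * t$n01)
  list(odds_ratio = or, p_value = min(ft$p.value, 1), degenerate = FALSE)
}

classify_direction <- function(or) {
  if (or > 1) "co_occurrence" else if (or < 1) "mutual_exclusivity"
  else "neutral"
}

#' Fisher exact tests for all event pairs with BH correction
#'
#' Tests every unordered pair of events (a single multiple-testing
#' family of `choose(V, 2)` tests) and adjusts p-values, by default with
#' Benjamini-Hochberg. Pairs are ordered by event column order, so the
#' output is deterministic.
#'
#' @param m an [event_matrix()] with at least 2 events.
#' @param adjust any method accepted by [stats::p.adjust()]
#'   (default `"BH"`).
#' @param estimator odds-ratio estimator, see [fisher_exact()].
#' @return A `pair_stats` data frame: `event_a`, `event_b`, `n11`,
#'   `n10`, `n01`, `n00`, `odds_ratio`, `p_value`, `q_value`,
#'   `direction`, `degenerate`.
#' @export
all_pairs_fisher <- function(m, adjust = "BH",
                             estimator = c("cmle", "sample")) {
  estimator <- match.arg(estimator)
  evs <- event_names(m)
  if (length(evs) < 2) stop("need at least 2 events")
  pairs <- utils::combn(evs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ct <- contingency_table(m, a, b)
    fe <- fisher_exact(ct, estimator)
    data.frame(event_a = a, event_b = b,
               n11 = ct$n11, n10 = ct$n10, n01 = ct$n01, n00 = ct$n00,
               odds_ratio = fe$odds_ratio, p_value = fe$p_value,
               direction = classify_direction(fe$odds_ratio),
               degenerate = fe$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = adjust)
  out <- out[, c("event_a", "event_b", "n11", "n10", "n01", "n00",
                 "odds_ratio", "p_value", "q_value", "direction",
                 "degenerate")]
  class(out) <- c("pair_stats", "data.frame")
  out
}

#' Write the pair-statistics table as TSV
#' @param stats a `pair_stats` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rendering style for one annotated edge
#'
#' Colour encodes direction (green = co-occurrence, yellow = mutual
#' exclusivity), line type encodes significance (solid iff adjusted p <
#' `alpha`), width grows with the strength of association:
#' `width_scale * max(OR, 1/OR)`, capped at `max_width`, so a mutual
#' exclusivity of OR = 1/4 is drawn as wide as a co-occurrence of
#' OR = 4. With the default `width_scale = 0.5` an odds ratio of 4 maps
#' to width 2, the reference width drawn in legends.
#'
#' @param odds_ratio,q_value the pair's statistics (a one-row slice of
#'   [all_pairs_fisher()] output works via `edge_style_row`).
#' @param alpha significance level for solid lines (default 0.05).
#' @param width_scale width per unit of folded odds ratio (default 0.5).
#' @param max_width cap on rendered width (default 8).
#' @return An `edge_style` list: `colour`, `line`, `width`, `neutral`.
#' @export
edge_style <- function(odds_ratio, q_value, alpha = 0.05,
                       width_scale = 0.5, max_width = 8) {
  dir <- classify_direction(odds_ratio)
  folded <- if (odds_ratio == 0 || is.infinite(odds_ratio)) Inf
    else max(odds_ratio, 1 / odds_ratio)
  width <- min(width_scale * folded, max_width)
  if (dir == "neutral") width <- width_scale  # minimal width at OR = 1
  structure(list(
    colour = if (dir == "co_occurrence") "green" else "yellow",
    line = if (q_value < alpha) "solid" else "dotted",
    width = width,
    neutral = dir == "neutral"),
    class = "edge_style")
}

edge_style_row <- function(row, ...) {
  edge_style(row$odds_ratio, row$q_value, ...)
}

#' Styles for the edges of a DAG from the pair-statistics table
#'
#' @param dag a `bn_dag`.
#' @param stats output of [all_pairs_fisher()] covering all DAG edges.
#' @param ... passed to [edge_style()].
#' @return Named list of `edge_style` objects, one per DAG edge, named
#'   `"a|b"` with `a`, `b` sorted.
#' @export
dag_edge_styles <- function(dag, stats, ...) {
  e <- dag_edges(dag)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  skey <- key(stats$event_a, stats$event_b)
  out <- list()
  for (r in seq_len(nrow(e))) {
    k <- key(e[r, 1], e[r, 2])
    j <- match(k, skey)
    if (is.na(j)) stop("no pair statistic for edge ", k)
    out[[k]] <- edge_style_row(stats[j, ], ...)
  }
  out
}

#' Standalone network of significantly associated event pairs
#'
#' An undirected graph whose nodes are all events and whose edges are
#' exactly the pairs with adjusted p below `alpha`; the purely pairwise
#' counterpart of a learned network.
#'
#' @param stats output of [all_pairs_fisher()].
#' @param alpha significance threshold on `q_value` (default 0.05).
#' @return An [igraph::graph_from_data_frame()] undirected graph with
#'   edge attributes `odds_ratio`, `p_value`, `q_value`, `direction`.
#' @export
fisher_network <- function(stats, alpha = 0.05) {
  # preserve the order events first appear in the pair table (= column
  # order when stats came from all_pairs_fisher)
  nodes <- unique(as.vector(rbind(stats$event_a, stats$event_b)))
  sig <- stats[stats$q_value < alpha, , drop = FALSE]
  igraph::graph_from_data_frame(
    sig[, c("event_a", "event_b", "odds_ratio", "p_value", "q_value",
            "direction")],
    directed = FALSE,
    vertices = data.frame(name = nodes))
}
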