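# Globally optimal DAG search over a complete local-score table.
#
# The searcher is an exact dynamic program over variable subsets
# (Silander-Myllymaki): first, for every variable v and every candidate
# set S not containing v, the best admissible parent set within S is
# tabulated by a max-transform over the subset lattice; second, the
# best network over each subset is built up by choosing its best sink.
# The returned DAG therefore attains the maximum total penalised score
# over all DAGs respecting max_parents — the same optimality contract
# as ILP-based solvers, without an external solver.

# popcount of every mask in 0..2^V-1, one vectorised pass per bit
popcounts <- function(V) {
  pc <- integer(2^V)
  masks <- 0:(2^V - 1)
  for (b in 0:(V - 1))
    pc <- pc + (bitwAnd(masks, bitwShiftL(1L, b)) > 0)
  pc
}

# total order used for tie-breaking among equal-score parent sets:
# smaller set first, then lexicographic on sorted member positions.
# Returns a rank (smaller = preferred) for every mask in 0..2^V-1,
# Inf for masks larger than maxp.
tiebreak_ranks <- function(V, maxp) {
  masks <- 0:(2^V - 1)
  pc <- popcounts(V)
  adm <- which(pc <= maxp)
  key <- matrix(Inf, nrow = length(adm), ncol = maxp + 1)
  key[, 1] <- pc[adm]
  for (r in seq_along(adm)) {
    idx <- mask_to_idx(masks[adm[r]], V)
    if (length(idx) > 0) key[r, 1 + seq_along(idx)] <- idx
  }
  ord <- do.call(order, as.data.frame(key))
  rank <- rep(Inf, 2^V)
  rank[adm[ord]] <- seq_along(ord)
  rank
}

# best admissible parent set within every candidate subset, for one
# variable. Returns list(score = numeric(2^V), choice = integer(2^V));
# entries indexed by candidate-set mask + 1.
best_parents_table <- function(table, i, rank) {
  V <- length(table$variables)
  full <- 2^V
  sc <- rep(-Inf, full)
  ch <- rep(NA_integer_, full)
  s <- table$scores[[i]]
  sc[s$masks + 1L] <- s$score
  ch[s$masks + 1L] <- s$masks
  all_masks <- 0:(full - 1)
  for (b in 0:(V - 1)) {
    if (b == i - 1) next  # candidate sets never contain the child
    bit <- bitwShiftL(1L, b)
    idx <- which(bitwAnd(all_masks, bit) > 0)
    prev <- idx - bit
    rp <- ifelse(is.na(ch[prev]), Inf, rank[ch[prev] + 1L])
    rc <- ifelse(is.na(ch[idx]), Inf, rank[ch[idx] + 1L])
    better <- (sc[prev] > sc[idx]) |
      (sc[prev] == sc[idx] & is.finite(sc[prev]) & rp < rc)
    better[is.na(better)] <- FALSE
    sc[idx[better]] <- sc[prev[better]]
    ch[idx[better]] <- ch[prev[better]]
  }
  list(score = sc, choice = ch)
}

#' Learn the globally optimal DAG for a score table
#'
#' Exact dynamic programming over variable subsets. The result maximises
#' the total penalised score (sum of family entries in `table`) over
#' every DAG whose parent sets respect the table's `max_parents`;
#' tie-breaking is deterministic (smaller parent sets, then
#' lexicographic by canonical variable order; lexicographically smallest
#' sink), so repeated runs return bit-identical structures.
#'
#' Memory and time grow as `2^V`; above `hard_limit` variables the
#' search refuses to run — either raise the limit (at your own desk's
#' peril), reduce the variable count with a stricter mu filter, or
#' export the table with [write_jaakkola()] for an external ILP solver.
#'
#' @param table a `score_table` from [build_score_table()].
#' @param hard_limit refuse problems with more variables than this
#'   (default 20).
#' @return A `bn_search_result`: `dag`, `total_score`, `edge_count`,
#'   `optimum_certificate = "dp_exact"`.
#' @export
learn_optimal_dag <- function(table, hard_limit = 20) {
  vars <- table$variables
  V <- length(vars)
  if (V > hard_limit)
    stop(V, " variables exceeds the exact-search limit of ", hard_limit,
         "; raise hard_limit, reduce variables with a stricter mu, ",
         "or export the score table for an external solver")
  full <- 2^V
  rank <- tiebreak_ranks(V, table$config$max_parents)
  bps <- lapply(seq_len(V), function(i) best_parents_table(table, i, rank))

  all_masks <- 0:(full - 1)
  by_level <- split(all_masks, popcounts(V))
  best <- rep(-Inf, full)
  best[1] <- 0
  sink <- rep(NA_integer_, full)
  for (lev in seq_len(V)) {
    ms <- by_level[[as.character(lev)]]
    for (v in seq_len(V)) {  # ascending: first (smallest) sink wins ties
      bit <- bitwShiftL(1L, v - 1L)
      has <- ms[bitwAnd(ms, bit) > 0]
      prev <- has - bit
      cand <- best[prev + 1L] + bps[[v]]$score[prev + 1L]
      upd <- cand > best[has + 1L]
      upd[is.na(upd)] <- FALSE
      best[has[upd] + 1L] <- cand[upd]
      sink[has[upd] + 1L] <- v
    }
  }

  parents <- stats::setNames(vector("list", V), vars)
  S <- as.integer(full - 1)
  while (S > 0) {
    v <- sink[S + 1L]
    rest <- S - bitwShiftL(1L, v - 1L)
    pmask <- bps[[v]]$choice[rest + 1L]
    parents[[vars[v]]] <- vars[mask_to_idx(pmask, V)]
    S <- rest
  }
  dag <- bn_dag(vars, parents)
  # re-sum the family scores in canonical variable order so the total
  # is independent of the DP's accumulation order
  total <- network_score(dag, table)
  if (abs(total - best[full]) > 1e-6)
    warning("DP total and recomputed network score disagree")
  structure(list(dag = dag,
                 total_score = total,
                 edge_count = nrow(dag_edges(dag)),
                 optimum_certificate = "dp_exact"),
            class = "bn_search_result")
}

#' @export
print.bn_search_result <- function(x, ...) {
  cat(sprintf("optimal DAG (%s): %d variables, %d edges, score %.6f\n",
              x$optimum_certificate, length(x$dag$variables),
              x$edge_count, x$total_score))
  invisible(x)
}

#' Exhaustive brute-force optimal DAG (testing oracle)
#'
#' Enumerates every labelled DAG over the table's variables (respecting
#' `max_parents`) by crossing all admissible per-variable parent sets
#' and discarding cyclic combinations, then returns the argmax of the
#' total penalised score. Intended as an independent check of
#' [learn_optimal_dag()]; limited to 5 variables.
#'
#' @param table a `score_table`.
#' @return A `bn_search_result` with
#'   `optimum_certificate = "brute_force"` and an extra field
#'   `n_dags_enumerated`, the number of acyclic structures examined.
#' @export
brute_force_optimal_dag <- function(table) {
  vars <- table$variables
  V <- length(vars)
  if (V > 5) stop("brute force limited to 5 variables")
  full <- as.integer(2^V - 1)
  choices <- lapply(seq_len(V), function(i) table$scores[[i]]$masks)
  grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  storage.mode(grid) <- "integer"

  # vectorised acyclicity: repeatedly mark variables whose parents are
  # all already marked; a combination is a DAG iff all get marked
  removed <- integer(nrow(grid))
  for (round in seq_len(V)) {
    for (v in seq_len(V)) {
      bit <- bitwShiftL(1L, v - 1L)
      can <- bitwAnd(removed, bit) == 0L &
        bitwAnd(grid[, v], bitwAnd(bitwNot(removed), full)) == 0L
      removed[can] <- bitwOr(removed[can], bit)
    }
  }
  acyclic <- removed == full

  total <- numeric(nrow(grid))
  for (v in seq_len(V)) {
    lut <- rep(NA_real_, full + 1L)
    lut[table$scores[[v]]$masks + 1L] <- table$scores[[v]]$score
    total <- total + lut[grid[, v] + 1L]
  }
  total[!acyclic] <- -Inf
  winner <- which.max(total)
  parents <- stats::setNames(lapply(seq_len(V), function(v)
    vars[mask_to_idx(grid[winner, v], V)]), vars)
  dag <- bn_dag(vars, parents)
  structure(list(dag = dag,
                 total_score = network_score(dag, table),
                 edge_count = nrow(dag_edges(dag)),
                 optimum_certificate = "brute_force",
                 n_dags_enumerated = sum(acyclic)),
            class = "bn_search_result")
}

#' Total penalised score of a DAG under a score table
#'
#' Sum of the table entries of the DAG's families; errors if any family
#' is not in the table (parent set too large or unknown variable).
#'
#' @param dag a `bn_dag` over the table's variables.
#' @param table a `score_table`.
#' @return Log score (numeric scalar).
#' @export
network_score <- function(dag, table) {
  vars <- table$variables
  if (!setequal(dag$variables, vars))
    stop("DAG and table variables differ")
  total <- 0
  for (v in dag$variables) {
    i <- match(v, vars)
    idx <- match(dag$parents[[v]], vars)
    mask <- if (length(idx) == 0) 0L else
      as.integer(sum(bitwShiftL(1L, idx - 1L)))
    total <- total + table_lookup(table, i, mask)
  }
  total
}

undirected_edge_keys <- function(dag) {
  e <- dag_edges(dag)
  if (nrow(e) == 0) return(character(0))
  apply(e, 1, function(r) paste(sort(r), collapse = "\r"))
}

#' Learn networks over a range of edge penalties
#'
#' Builds one score table, re-penalises it at each epsilon, and runs the
#' exact search; useful for choosing the sparsity level and for checking
#' that denser networks nest the sparser ones.
#'
#' @param m an [event_matrix()].
#' @param cfg a [score_config()]; its `epsilon` field is ignored.
#' @param epsilons numeric vector of edge penalties to sweep.
#' @param hard_limit passed to [learn_optimal_dag()].
#' @return A list with `results` (one `bn_search_result` per epsilon,
#'   named) and `summary` (data frame: epsilon, edges, total_score).
#' @export
epsilon_sweep <- function(m, cfg = score_config(), epsilons = 1:20,
                          hard_limit = 20) {
  base <- build_score_table(m, cfg)
  results <- lapply(epsilons, function(eps)
    learn_optimal_dag(with_epsilon(base, eps), hard_limit))
  names(results) <- as.character(epsilons)
  list(results = results,
       summary = data.frame(
         epsilon = epsilons,
         edges = vapply(results, function(r) r$edge_count, integer(1)),
         total_score = vapply(results, function(r) r$total_score,
                              numeric(1))))
}

#' Edge-nesting report across an epsilon sweep
#'
#' For every ordered pair (sparser network at a higher epsilon, denser
#' network at a lower epsilon) the fraction of the sparser network's
#' undirected edges present in the denser one is computed; the report
#' aggregates these into one overall retention fraction. High values
#' indicate that increasing the penalty prunes a nested hierarchy of
#' networks rather than rewiring them.
#'
#' @param sweep result of [epsilon_sweep()].
#' @return A list with `overall` (pooled fraction of sparse edges found
#'   in denser networks) and `pairs` (data frame: epsilon_sparse,
#'   epsilon_dense, edges_sparse, retained, fraction).
#' @export
edge_nesting_report <- function(sweep) {
  eps <- sweep$summary$epsilon
  keys <- lapply(sweep$results, function(r) undirected_edge_keys(r$dag))
  rows <- list()
  for (i in seq_along(eps)) for (j in seq_along(eps)) {
    if (eps[i] <= eps[j]) next  # i sparser (higher penalty), j denser
    ks <- keys[[i]]
    kd <- keys[[j]]
    rows[[length(rows) + 1]] <- data.frame(
      epsilon_sparse = eps[i], epsilon_dense = eps[j],
      edges_sparse = length(ks), retained = sum(ks %in% kd),
      fraction = if (length(ks) == 0) NA_real_ else mean(ks %in% kd))
  }
  pairs <- do.call(rbind, rows)
  overall <- if (is.null(pairs) || sum(pairs$edges_sparse) == 0) NA_real_
    else sum(pairs$retained) / sum(pairs$edges_sparse)
  list(overall = overall, pairs = pairs)
}
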