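# Decomposable local scores (BDeu / BIC) with the integer edge penalty.
#
# The learning objective is the log posterior of a structure M given
# data D: log P(M|D) = log P(D|M) + log P(M) + const, where the
# structure prior P(M) is proportional to exp(-n * epsilon) for a
# network with n edges. Both terms decompose over families, so every
# (child, parent set) pair gets one penalised local score:
# raw local score - epsilon * |parent set|  (natural-log units).

#' Scoring configuration
#'
#' @param score_kind `"bdeu"` (Bayesian Dirichlet equivalent uniform
#'   marginal likelihood; default) or `"bic"`.
#' @param ess equivalent sample size of the BDeu Dirichlet prior
#'   (default 1).
#' @param epsilon non-negative integer edge penalty: each edge costs
#'   `epsilon` nats of log posterior. The second tuning knob of the
#'   workflow; typical values 1-20.
#' @param max_parents maximum parent-set size considered (default 3).
#' @return A `score_config` object.
#' @export
score_config <- function(score_kind = c("bdeu", "bic"), ess = 1,
                         epsilon = 1, max_parents = 3) {
  score_kind <- match.arg(score_kind)
  if (ess <= 0) stop("ess must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (max_parents < 1) stop("max_parents must be >= 1")
  structure(list(score_kind = score_kind, ess = ess,
                 epsilon = as.numeric(epsilon),
                 max_parents = as.integer(max_parents)),
            class = "score_config")
}

# counts of (parent configuration, child value): returns list(n1, n0),
# each of length 2^|parents|
family_counts <- function(m, child, parent_set) {
  vals <- unclass(m)
  idx <- config_index(vals[, parent_set, drop = FALSE])
  q <- 2^length(parent_set)
  cv <- vals[, child]
  list(n1 = tabulate(idx[cv == 1L], nbins = q),
       n0 = tabulate(idx[cv == 0L], nbins = q))
}

#' BDeu local score of one family
#'
#' Natural-log BDeu marginal likelihood of a binary child given a parent
#' set: with q = 2^|parents| parent configurations, prior weights
#' `a_j = ess / q` per configuration and `a_jk = ess / (2q)` per cell,
#' the score is
#' `sum_j [ lgamma(a_j) - lgamma(a_j + N_j) +
#'          sum_k ( lgamma(a_jk + N_jk) - lgamma(a_jk) ) ]`.
#' Finite for any data; 0 for an empty data set. Markov-equivalent
#' structures receive equal total scores (likelihood equivalence).
#'
#' @param child child event name.
#' @param parent_set character vector of parent event names (may be
#'   empty).
#' @param m an [event_matrix()].
#' @param ess equivalent sample size, > 0.
#' @return Log score (numeric scalar).
#' @export
bdeu_local_score <- function(child, parent_set, m, ess = 1) {
  if (ess <= 0) stop("ess must be > 0")
  if (child %in% parent_set) stop("child cannot be its own parent")
  cn <- family_counts(m, child, parent_set)
  q <- 2^length(parent_set)
  aj <- ess / q
  ajk <- ess / (2 * q)
  nj <- cn$n1 + cn$n0
  sum(lgamma(aj) - lgamma(aj + nj) +
        lgamma(ajk + cn$n1) - lgamma(ajk) +
        lgamma(ajk + cn$n0) - lgamma(ajk))
}

#' BIC local score of one family
#'
#' Maximised multinomial log likelihood minus `(log N / 2) * 2^|parents|`
#' (one free parameter per parent configuration for a binary child).
#'
#' @inheritParams bdeu_local_score
#' @return Log score (numeric scalar).
#' @export
bic_local_score <- function(child, parent_set, m) {
  if (child %in% parent_set) stop("child cannot be its own parent")
  n <- nrow(m)
  if (n == 0) return(0)
  cn <- family_counts(m, child, parent_set)
  nj <- cn$n1 + cn$n0
  # terms with njk = 0 contribute 0; nj > 0 wherever njk > 0
  loglik <- sum(ifelse(cn$n1 > 0, cn$n1 * log(cn$n1 / pmax(nj, 1)), 0)) +
    sum(ifelse(cn$n0 > 0, cn$n0 * log(cn$n0 / pmax(nj, 1)), 0))
  loglik - log(n) / 2 * 2^length(parent_set)
}

raw_local_score <- function(child, parent_set, m, cfg) {
  switch(cfg$score_kind,
         bdeu = bdeu_local_score(child, parent_set, m, cfg$ess),
         bic = bic_local_score(child, parent_set, m))
}

#' Penalised local score of one family
#'
#' Raw local score minus `epsilon * |parent set|`: summed over all
#' families of a DAG this realises the edge-penalty structure prior
#' `P(M) proportional to exp(-n * epsilon)` with `n` the edge count.
#'
#' @inheritParams bdeu_local_score
#' @param cfg a [score_config()].
#' @return Penalised log score.
#' @export
penalized_local_score <- function(child, parent_set, m, cfg) {
  if (length(parent_set) > cfg$max_parents)
    stop("parent set exceeds max_parents = ", cfg$max_parents)
  raw_local_score(child, parent_set, m, cfg) -
    cfg$epsilon * length(parent_set)
}

# all subsets (as bit masks over positions 1..V) of `others` with size
# <= maxp; deterministic order: by size, then lexicographic on sorted
# member positions
admissible_masks <- function(others, maxp) {
  out <- list(0L)
  for (k in seq_len(min(maxp, length(others)))) {
    # combn over positions: combn(x, k) with scalar x would read as 1:x
    combs <- utils::combn(length(others), k)
    for (j in seq_len(ncol(combs)))
      out <- c(out, sum(bitwShiftL(1L, others[combs[, j]] - 1L)))
  }
  as.integer(unlist(out))
}

mask_to_idx <- function(mask, V) which(bitwAnd(mask, bitwShiftL(1L, 0:(V - 1))) > 0)

#' Build the complete table of penalised local scores
#'
#' For every variable and every parent set of size up to
#' `cfg$max_parents`, the penalised local score is precomputed. This
#' table is the sole input of the structure search.
#'
#' @param m an [event_matrix()] with at least 2 events.
#' @param cfg a [score_config()].
#' @return A `score_table`: variables, config, and per variable the
#'   vectors `masks` (parent sets as bit masks over variable positions)
#'   and `score` (penalised log scores, aligned with `masks`).
#' @export
build_score_table <- function(m, cfg = score_config()) {
  vars <- event_names(m)
  V <- length(vars)
  if (V < 2) stop("need at least 2 events")
  counts <- event_counts(m)
  if (any(counts == 0 | counts == nrow(m)))
    warning("constant column(s): ",
            paste(vars[counts == 0 | counts == nrow(m)], collapse = ", "))
  scores <- vector("list", V)
  names(scores) <- vars
  for (i in seq_len(V)) {
    masks <- admissible_masks(setdiff(seq_len(V), i), cfg$max_parents)
    sc <- vapply(masks, function(msk) {
      ps <- vars[mask_to_idx(msk, V)]
      raw_local_score(vars[i], ps, m, cfg) - cfg$epsilon * length(ps)
    }, numeric(1))
    scores[[i]] <- list(masks = masks, score = sc)
  }
  structure(list(variables = vars, config = cfg, scores = scores),
            class = "score_table")
}

#' Re-penalise a score table at a different epsilon
#'
#' The raw likelihood part of every entry is unchanged; only the linear
#' edge penalty is swapped, so sweeping epsilon does not recompute any
#' marginal likelihoods.
#'
#' @param table a `score_table`.
#' @param epsilon new non-negative edge penalty.
#' @return A `score_table` with the same raw scores penalised at
#'   `epsilon`.
#' @export
with_epsilon <- function(table, epsilon) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  delta <- epsilon - table$config$epsilon
  V <- length(table$variables)
  for (i in seq_len(V)) {
    sizes <- vapply(table$scores[[i]]$masks,
                    function(msk) length(mask_to_idx(msk, V)), numeric(1))
    table$scores[[i]]$score <- table$scores[[i]]$score - delta * sizes
  }
  table$config$epsilon <- as.numeric(epsilon)
  table
}

#' @export
print.score_table <- function(x, ...) {
  n_entries <- sum(vapply(x$scores, function(s) length(s$masks), integer(1)))
  cat(sprintf("score_table: %d variables, %d entries (%s, ess %g, epsilon %g, max_parents %d)\n",
              length(x$variables), n_entries, x$config$score_kind,
              x$config$ess, x$config$epsilon, x$config$max_parents))
  invisible(x)
}

# penalised local score of (variable index i, parent mask); error if absent
table_lookup <- function(table, i, mask) {
  s <- table$scores[[i]]
  j <- match(mask, s$masks)
  if (is.na(j))
    stop("no table entry for variable ", table$variables[i],
         " with parent set {",
         paste(table$variables[mask_to_idx(mask, length(table$variables))],
               collapse = ","), "}")
  s$score[j]
}

#' Export a score table in the plain-text parent-set score format
#'
#' The "Jaakkola" dialect consumed by exact structure-learning solvers:
#' first line the variable count; then, per variable, a header
#' `"<name> <number of parent sets>"` followed by one line per set:
#' `"<score> <k> <parent...>"`.
#'
#' @param table a `score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaakkola <- function(table, path) {
  vars <- table$variables
  V <- length(vars)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(V), con)
  for (i in seq_len(V)) {
    s <- table$scores[[i]]
    writeLines(sprintf("%s %d", vars[i], length(s$masks)), con)
    for (j in seq_along(s$masks)) {
      ps <- vars[mask_to_idx(s$masks[j], V)]
      writeLines(paste(c(format(s$score[j], digits = 17),
                         length(ps), ps), collapse = " "), con)
    }
  }
  invisible(path)
}
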