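# Discrete (binary) Bayesian networks: structure, CPTs, sampling.

#' Construct a directed acyclic graph over named variables
#'
#' @param variables character vector; its order is the canonical event
#'   order used for deterministic tie-breaking everywhere downstream.
#' @param parents named list mapping a variable to the character vector
#'   of its parents; variables absent from the list are roots.
#' @return A `bn_dag` object.
#' @export
bn_dag <- function(variables, parents = list()) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stop("duplicate variable names")
  full <- stats::setNames(vector("list", length(variables)), variables)
  for (v in variables) full[[v]] <- character(0)
  for (v in names(parents)) {
    if (!v %in% variables) stop("unknown variable in parents map: ", v)
    ps <- as.character(parents[[v]])
    if (v %in% ps) stop("self-loop at ", v)
    if (!all(ps %in% variables))
      stop("unknown parent(s) of ", v, ": ",
           paste(setdiff(ps, variables), collapse = ", "))
    if (anyDuplicated(ps)) stop("duplicated parent of ", v)
    # canonical order: position in `variables`
    full[[v]] <- ps[order(match(ps, variables))]
  }
  dag <- structure(list(variables = variables, parents = full),
                   class = "bn_dag")
  if (is.null(topological_order(dag, error = FALSE)))
    stop("graph contains a cycle")
  dag
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; among simultaneously available nodes the one first
#' in canonical variable order is emitted, so the order is deterministic.
#'
#' @param dag a `bn_dag`.
#' @param error error on a cyclic graph (default) or return `NULL`.
#' @return Character vector of the variables in topological order.
#' @export
topological_order <- function(dag, error = TRUE) {
  vars <- dag$variables
  indeg <- vapply(dag$parents[vars], length, integer(1))
  children <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) for (p in dag$parents[[v]])
    children[[p]] <- c(children[[p]], v)
  out <- character(0)
  avail <- vars[indeg == 0]
  while (length(avail) > 0) {
    v <- avail[order(match(avail, vars))][1]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) avail <- c(avail, ch)
    }
  }
  if (length(out) != length(vars)) {
    if (error) stop("graph contains a cycle")
    return(NULL)
  }
  out
}

#' Edge list of a DAG
#' @param dag a `bn_dag`.
#' @return Two-column character matrix (from = parent, to = child); zero
#'   rows for an empty graph.
#' @export
dag_edges <- function(dag) {
  from <- unlist(dag$parents, use.names = FALSE)
  to <- rep(names(dag$parents), vapply(dag$parents, length, integer(1)))
  cbind(from = as.character(from), to = as.character(to))
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("bn_dag: %d variables, %d edges\n",
              length(x$variables), nrow(dag_edges(x))))
  invisible(x)
}

#' Decompose a DAG into its families
#'
#' A family is one child node plus all its parents; it is the unit of
#' scoring, heatmap visualisation, and gate fitting. Every variable
#' yields exactly one family (roots have empty parent lists).
#'
#' @param dag a `bn_dag`.
#' @return List of `bn_family` objects (`child`, `parents`), one per
#'   variable in canonical order.
#' @export
families_of <- function(dag) {
  lapply(dag$variables, function(v)
    structure(list(child = v, parents = dag$parents[[v]]),
              class = "bn_family"))
}

#' @export
print.bn_family <- function(x, ...) {
  if (length(x$parents) == 0)
    cat(sprintf("family %s (root)\n", x$child))
  else
    cat(sprintf("family %s <- {%s}\n", x$child,
                paste(x$parents, collapse = ", ")))
  invisible(x)
}

# parent configuration index, 1-based; first parent is the least
# significant bit. `pvals` is a matrix (rows = cases, cols = parents).
config_index <- function(pvals) {
  if (ncol(pvals) == 0) return(rep(1L, nrow(pvals)))
  as.integer(pvals %*% 2^(seq_len(ncol(pvals)) - 1)) + 1L
}

#' Conditional probability table for one binary child
#'
#' @param child variable name.
#' @param parents character vector of parent names (order fixed).
#' @param p1 numeric vector of length `2^length(parents)`:
#'   `p(child = 1 | parent configuration)`, configurations indexed with
#'   the first parent as the least significant bit (so index 1 is the
#'   all-zero configuration).
#' @return A `bn_cpt` object.
#' @export
bn_cpt <- function(child, parents, p1) {
  parents <- as.character(parents)
  if (length(p1) != 2^length(parents))
    stop("p1 must have 2^|parents| entries")
  if (any(p1 < -1e-12 | p1 > 1 + 1e-12))
    stop("probabilities outside [0,1]")
  p1 <- pmin(pmax(p1, 0), 1)
  structure(list(child = child, parents = parents, p1 = as.numeric(p1)),
            class = "bn_cpt")
}

#' Assemble a discrete Bayesian network
#'
#' @param dag a `bn_dag`.
#' @param cpts named list of [bn_cpt()] objects, one per variable; CPT
#'   parents must match the DAG's.
#' @return A `discrete_bn` object.
#' @export
discrete_bn <- function(dag, cpts) {
  for (v in dag$variables) {
    cpt <- cpts[[v]]
    if (is.null(cpt)) stop("missing CPT for ", v)
    if (!identical(cpt$parents, dag$parents[[v]]))
      stop("CPT parents for ", v, " do not match DAG parents")
  }
  structure(list(dag = dag, cpts = cpts[dag$variables]),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  print(x$dag)
  invisible(x)
}

#' Joint probability of a full assignment
#'
#' The defining factorisation of a Bayesian network: the joint is the
#' product over families of `p(child | parents)`.
#'
#' @param bn a `discrete_bn`.
#' @param assignment named vector of 0/1 values covering every variable.
#' @return Probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  vars <- bn$dag$variables
  if (!all(vars %in% names(assignment)))
    stop("assignment must cover all variables; missing: ",
         paste(setdiff(vars, names(assignment)), collapse = ", "))
  if (!all(assignment[vars] %in% c(0, 1)))
    stop("assignment values must be 0/1")
  prob <- 1
  for (v in vars) {
    cpt <- bn$cpts[[v]]
    idx <- config_index(matrix(assignment[cpt$parents], nrow = 1))
    p1 <- cpt$p1[idx]
    prob <- prob * if (assignment[[v]] == 1) p1 else 1 - p1
  }
  prob
}

#' Forward-sample a synthetic cohort from a Bayesian network
#'
#' Ancestral sampling: variables are drawn in topological order, each
#' from its CPT row given the already-sampled parent values. A fixed
#' seed gives a bit-reproducible matrix (R's default Mersenne-Twister
#' generator).
#'
#' @param bn a `discrete_bn`.
#' @param n number of samples (rows) to draw.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return An [event_matrix()] with rows `S1..Sn` and one column per
#'   variable, in canonical variable order.
#' @export
forward_sample <- function(bn, n, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  vars <- bn$dag$variables
  ord <- topological_order(bn$dag)
  out <- matrix(0L, nrow = n, ncol = length(vars),
                dimnames = list(if (n > 0) paste0("S", seq_len(n)), vars))
  for (v in ord) {
    cpt <- bn$cpts[[v]]
    idx <- config_index(out[, cpt$parents, drop = FALSE])
    p1 <- cpt$p1[idx]
    if (n > 0) out[, v] <- as.integer(stats::runif(n) < p1)
  }
  event_matrix(out)
}

#' Fit CPTs for a given structure from data
#'
#' Conditional frequency estimation with an optional symmetric Dirichlet
#' pseudocount: each CPT row is
#' `(count + pseudocount) / (row total + 2 * pseudocount)`. With
#' `pseudocount = 0`, parent configurations never observed in the data
#' get a uniform row and a warning.
#'
#' @param dag a `bn_dag` whose variables all appear in `m`.
#' @param m an [event_matrix()].
#' @param pseudocount non-negative smoothing constant (default 0).
#' @return A `discrete_bn` with the given structure and fitted CPTs.
#' @export
fit_cpts <- function(dag, m, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (!all(dag$variables %in% event_names(m)))
    stop("matrix lacks variable(s): ",
         paste(setdiff(dag$variables, event_names(m)), collapse = ", "))
  cpts <- list()
  unseen <- character(0)
  for (v in dag$variables) {
    ps <- dag$parents[[v]]
    q <- 2^length(ps)
    idx <- config_index(unclass(m)[, ps, drop = FALSE])
    n1 <- vapply(seq_len(q), function(j) sum(m[idx == j, v]), numeric(1))
    nt <- tabulate(idx, nbins = q)
    p1 <- (n1 + pseudocount) / (nt + 2 * pseudocount)
    if (pseudocount == 0 && any(nt == 0)) {
      p1[nt == 0] <- 0.5
      unseen <- c(unseen, v)
    }
    cpts[[v]] <- bn_cpt(v, ps, p1)
  }
  if (length(unseen) > 0)
    warning("unobserved parent configuration(s) for ",
            paste(unseen, collapse = ", "), "; rows set to uniform")
  discrete_bn(dag, cpts)
}

# CPT for a noisy gate: p(child = gate output) = fidelity for every
# parent configuration. `gate_fun` maps a 0/1 parent matrix to 0/1.
noisy_gate_cpt <- function(child, parents, gate_fun, fidelity) {
  q <- 2^length(parents)
  configs <- as.matrix(expand.grid(rep(list(0:1), length(parents))))
  out <- gate_fun(configs)
  p1 <- ifelse(out == 1, fidelity, 1 - fidelity)
  bn_cpt(child, parents, p1)
}

#' The packaged five-node example network
#'
#' A small binary network over `A, B, C, D, E` used throughout the
#' package for simulation studies: `A`, `B`, `D` are `Bernoulli(0.5)`
#' roots, `C` depends on `A` and `B`, `E` on `C` and `D`. The
#' conditional tables are noisy logic gates with fidelity 0.8: for every
#' parent configuration the child equals the gate output
#' (`C = A AND NOT B`, `E = C OR D`) with probability 0.8 and its
#' complement with probability 0.2; in particular
#' `p(C = 1 | A = 0, B = 0) = 0.2`.
#'
#' @return A `discrete_bn`.
#' @export
example_bn <- function() {
  dag <- bn_dag(c("A", "B", "C", "D", "E"),
                list(C = c("A", "B"), E = c("C", "D")))
  cpts <- list(
    A = bn_cpt("A", character(0), 0.5),
    B = bn_cpt("B", character(0), 0.5),
    D = bn_cpt("D", character(0), 0.5),
    C = noisy_gate_cpt("C", c("A", "B"),
                       function(x) as.integer(x[, 1] == 1 & x[, 2] == 0),
                       0.8),
    E = noisy_gate_cpt("E", c("C", "D"),
                       function(x) as.integer(x[, 1] == 1 | x[, 2] == 1),
                       0.8)
  )
  discrete_bn(dag, cpts)
}

#' Write a discrete Bayesian network as JSON
#'
#' Schema: `{"variables": [...], "parents": {v: [...]},
#' "cpts": {v: [{"given": [0,1,...], "p1": x}, ...]}}` with one `cpts`
#' entry per parent configuration in index order (first parent = least
#' significant bit).
#'
#' @param bn a `discrete_bn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bn_json <- function(bn, path) {
  vars <- bn$dag$variables
  cpts <- lapply(bn$cpts, function(cpt) {
    np <- length(cpt$parents)
    configs <- if (np == 0) matrix(integer(0), nrow = 1, ncol = 0)
      else as.matrix(expand.grid(rep(list(0:1), np)))
    lapply(seq_along(cpt$p1), function(j)
      list(given = as.integer(configs[j, ]), p1 = cpt$p1[j]))
  })
  obj <- list(variables = vars,
              parents = bn$dag$parents,
              cpts = cpts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a discrete Bayesian network from JSON
#'
#' Validates the schema written by [write_bn_json()]: acyclic structure,
#' CPT parents matching the DAG, `2^|parents|` rows per table.
#'
#' @param path path to a JSON file.
#' @return A `discrete_bn`.
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- vapply(obj$variables, as.character, character(1))
  parents <- lapply(obj$parents, function(p)
    vapply(p, as.character, character(1)))
  dag <- bn_dag(vars, parents)
  cpts <- list()
  for (v in vars) {
    rows <- obj$cpts[[v]]
    ps <- dag$parents[[v]]
    raw_ps <- if (v %in% names(parents)) parents[[v]] else character(0)
    if (length(rows) != 2^length(ps))
      stop("CPT for ", v, " must have 2^|parents| rows")
    p1 <- rep(NA_real_, length(rows))
    for (r in rows) {
      given <- as.integer(unlist(r$given))  # in the file's parent order
      if (length(given) != length(ps))
        stop("CPT row arity mismatch for ", v)
      idx <- if (length(ps) == 0) 1L else
        config_index(matrix(given[match(ps, raw_ps)], nrow = 1))
      p1[idx] <- as.numeric(r$p1)
    }
    if (anyNA(p1)) stop("CPT for ", v, " misses a parent configuration")
    cpts[[v]] <- bn_cpt(v, ps, p1)
  }
  discrete_bn(dag, cpts)
}
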