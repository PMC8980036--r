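# Boolean logic-gate fitting to BN families.
#
# A learned family (child + parents) can often be summarised by a logic
# gate: the child vector is compared, by Fisher's exact test, with the
# vector obtained by applying a boolean formula to the parent columns,
# and the formula with the smallest p-value wins. Formulas use each
# parent exactly once; internal nodes are AND/OR/XOR (XOR is n-ary
# parity), with optional NOT decorations on leaves.

GATE_OPS <- c("AND", "OR", "XOR")
# preference among gates when p-values tie: XOR over OR over AND
GATE_PRECEDENCE <- c(XOR = 1, OR = 2, AND = 3)

gate_leaf <- function(name, neg = FALSE) {
  structure(list(op = "VAR", name = name, neg = neg),
            class = "gate_formula")
}

gate_node <- function(op, args) {
  stopifnot(op %in% GATE_OPS, length(args) >= 2)
  structure(list(op = op, args = args), class = "gate_formula")
}

is_leaf <- function(f) f$op == "VAR"

#' Canonical string of a gate formula
#'
#' Leaves render as `A` / `NOT A`; internal nodes as `OP(arg,...)`,
#' e.g. `"AND(A,NOT B)"`.
#'
#' @param f a gate formula.
#' @return Character scalar.
#' @export
formula_string <- function(f) {
  if (is_leaf(f))
    return(if (f$neg) paste("NOT", f$name) else f$name)
  paste0(f$op, "(",
         paste(vapply(f$args, formula_string, character(1)),
               collapse = ","), ")")
}

#' @export
print.gate_formula <- function(x, ...) {
  cat(formula_string(x), "\n")
  invisible(x)
}

formula_leaves <- function(f) {
  if (is_leaf(f)) return(f$name)
  unlist(lapply(f$args, formula_leaves))
}

formula_size <- function(f) {
  if (is_leaf(f)) return(1L)
  1L + sum(vapply(f$args, formula_size, integer(1)))
}

#' Flatten associative gate runs into n-ary gates
#'
#' Nested applications of the same gate are merged into one multi-input
#' gate, e.g. `((A AND B) AND C)` becomes `AND(A,B,C)`; XOR flattening
#' keeps parity semantics, so evaluation is unchanged. Already-flat
#' formulas are fixed points.
#'
#' @param f a gate formula.
#' @return A gate formula with no gate node whose direct child uses the
#'   same gate.
#' @export
simplify_formula <- function(f) {
  if (is_leaf(f)) return(f)
  args <- lapply(f$args, simplify_formula)
  flat <- list()
  for (a in args) {
    if (!is_leaf(a) && a$op == f$op) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  gate_node(f$op, flat)
}

# flatten + sort commutative children by their canonical string: two
# syntactically different but commutatively equal trees get one form
canonical_formula <- function(f) {
  f <- simplify_formula(f)
  if (is_leaf(f)) return(f)
  args <- lapply(f$args, canonical_formula)
  args <- args[order(vapply(args, formula_string, character(1)))]
  gate_node(f$op, args)
}

#' Evaluate a gate formula on event columns
#'
#' @param f a gate formula whose leaves are event names.
#' @param m an [event_matrix()] (or any 0/1 matrix with named columns)
#'   containing every leaf.
#' @return Integer 0/1 vector, one value per row of `m`.
#' @export
evaluate_formula <- function(f, m) {
  vals <- unclass(m)
  miss <- setdiff(unique(formula_leaves(f)), colnames(vals))
  if (length(miss) > 0)
    stop("missing event(s): ", paste(miss, collapse = ", "))
  ev <- function(g) {
    if (is_leaf(g)) {
      x <- vals[, g$name] == 1
      return(if (g$neg) !x else x)
    }
    parts <- lapply(g$args, ev)
    switch(g$op,
           AND = Reduce(`&`, parts),
           OR = Reduce(`|`, parts),
           XOR = Reduce(xor, parts))
  }
  as.integer(ev(f))
}

# all binary-tree formulas over exactly the given leaves
enumerate_trees <- function(leaves, gates, allow_not) {
  if (length(leaves) == 1) {
    out <- list(gate_leaf(leaves, FALSE))
    if (allow_not) out <- c(out, list(gate_leaf(leaves, TRUE)))
    return(out)
  }
  out <- list()
  rest <- leaves[-1]
  # splits: the first leaf anchors the left part, avoiding mirror splits
  for (k in 0:(length(rest) - 1)) {
    subsets <- if (k == 0) list(integer(0)) else {
      cmb <- utils::combn(length(rest), k)
      lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    }
    for (sel in subsets) {
      left <- c(leaves[1], rest[sel])
      right <- rest[setdiff(seq_along(rest), sel)]
      for (lf in enumerate_trees(left, gates, allow_not))
        for (rf in enumerate_trees(right, gates, allow_not))
          for (g in gates)
            out <- c(out, list(gate_node(g, list(lf, rf))))
    }
  }
  out
}

# deterministic preference among formulas tied on p: smaller tree,
# then gate precedence (XOR > OR > AND) at the root, then canonical
# string
formula_pref_key <- function(f) {
  root <- if (is_leaf(f)) 0 else GATE_PRECEDENCE[[f$op]]
  sprintf("%03d|%d|%s", formula_size(f), root, formula_string(f))
}

#' Enumerate candidate gate formulas over a parent set
#'
#' Generates every boolean formula that uses each parent exactly once,
#' with the enabled gates at internal nodes and (optionally) NOT on
#' leaves, then removes duplicates: formulas with the same truth table
#' over the parents collapse to one candidate (the preferred
#' representative under the deterministic order: smaller tree, XOR over
#' OR over AND at the root, canonical string).
#'
#' @param parents character vector of parent names (length >= 1).
#' @param gates subset of `c("AND", "OR", "XOR")` (default all three).
#' @param allow_not allow negated leaves (default `FALSE`).
#' @return List of canonical gate formulas, in preference order.
#' @export
enumerate_gate_formulas <- function(parents, gates = GATE_OPS,
                                    allow_not = FALSE) {
  if (length(parents) < 1) stop("need at least one parent")
  if (length(parents) >= 2 && length(gates) == 0)
    stop("no gates enabled for a multi-parent family")
  if (length(gates) > 0)
    gates <- match.arg(gates, GATE_OPS, several.ok = TRUE)
  cands <- lapply(enumerate_trees(parents, gates, allow_not),
                  canonical_formula)
  # truth-table deduplication over all 2^p parent assignments
  p <- length(parents)
  grid <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(grid) <- parents
  tt <- vapply(cands, function(f)
    paste(evaluate_formula(f, grid), collapse = ""), character(1))
  key <- vapply(cands, formula_pref_key, character(1))
  ord <- order(tt, key)
  cands <- cands[ord][!duplicated(tt[ord])]
  cands[order(vapply(cands, formula_pref_key, character(1)))]
}

#' Fit the best logic gate to one BN family
#'
#' Every candidate formula over the family's parents is evaluated on
#' the cohort and compared with the child column by Fisher's exact
#' test; the formula minimising the p-value is returned. Ties (distinct
#' tables with p within 1e-12, or identical tables) are resolved by the
#' deterministic preference order, which in particular prefers XOR over
#' OR when both produce identical output vectors. A constant child (or
#' candidate output) makes the test degenerate; such fits are flagged
#' and carry `p = 1`.
#'
#' @param fam a `bn_family` with at least one parent (see
#'   [families_of()]).
#' @param m an [event_matrix()] containing the family's members.
#' @param gates,allow_not passed to [enumerate_gate_formulas()].
#' @return A `gate_fit`: `family`, `formula`, `output` (fitted gate's
#'   0/1 vector), `p_value`, `odds_ratio`, `degenerate`.
#' @export
fit_family_gate <- function(fam, m, gates = GATE_OPS, allow_not = FALSE) {
  if (length(fam$parents) == 0) stop("family has no parents")
  cands <- enumerate_gate_formulas(fam$parents, gates, allow_not)
  child <- unclass(m)[, fam$child]
  best <- NULL
  for (f in cands) {
    out <- evaluate_formula(f, m)
    ct <- structure(list(n11 = sum(out == 1 & child == 1),
                         n10 = sum(out == 1 & child == 0),
                         n01 = sum(out == 0 & child == 1),
                         n00 = sum(out == 0 & child == 0)),
                    class = "contingency_table")
    fe <- fisher_exact(ct)
    fit <- list(formula = f, output = out, p_value = fe$p_value,
                odds_ratio = fe$odds_ratio, degenerate = fe$degenerate,
                # a two-sided p cannot tell a gate from its complement;
                # prefer the positively associated orientation
                anti = fe$odds_ratio < 1)
    # identical output vectors give bit-identical p; distinct tables
    # within relative 1e-12 are treated as tied
    tied <- !is.null(best) &&
      abs(fit$p_value - best$p_value) <=
        1e-12 * max(fit$p_value, best$p_value)
    if (is.null(best) || (!tied && fit$p_value < best$p_value) ||
        (tied && best$anti && !fit$anti))
      best <- fit
    # otherwise p ties (within 1e-12) keep the earlier candidate:
    # `cands` is already in static preference order
  }
  structure(list(family = fam, formula = best$formula,
                 output = best$output, p_value = best$p_value,
                 odds_ratio = best$odds_ratio,
                 degenerate = best$degenerate),
            class = "gate_fit")
}

#' @export
print.gate_fit <- function(x, ...) {
  cat(sprintf("%s = %s  (p = %.3g%s)\n", x$family$child,
              formula_string(x$formula), x$p_value,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Fit gates to every multi-parent family of a DAG
#'
#' @param dag a `bn_dag`.
#' @param m an [event_matrix()].
#' @param gates,allow_not passed to [fit_family_gate()].
#' @param adjust optional [stats::p.adjust()] method; when given, an
#'   adjusted p-value across the fitted families is attached to each
#'   fit as `q_value`.
#' @return List of `gate_fit` objects, one per family with >= 1 parent,
#'   in canonical variable order.
#' @export
fit_all_gates <- function(dag, m, gates = GATE_OPS, allow_not = FALSE,
                          adjust = NULL) {
  fams <- Filter(function(f) length(f$parents) > 0, families_of(dag))
  fits <- lapply(fams, fit_family_gate, m = m, gates = gates,
                 allow_not = allow_not)
  if (!is.null(adjust) && length(fits) > 0) {
    q <- stats::p.adjust(vapply(fits, function(f) f$p_value, numeric(1)),
                         method = adjust)
    for (i in seq_along(fits)) fits[[i]]$q_value <- q[i]
  }
  fits
}

#' Write gate fits as JSON
#'
#' One record per family: child, canonical formula string, p-value,
#' odds ratio, degeneracy flag (and `q_value` when present).
#'
#' @param fits list of `gate_fit` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gate_fits <- function(fits, path) {
  obj <- lapply(fits, function(f) {
    rec <- list(child = f$family$child,
                parents = f$family$parents,
                formula = formula_string(f$formula),
                p_value = f$p_value,
                odds_ratio = f$odds_ratio,
                degenerate = f$degenerate)
    if (!is.null(f$q_value)) rec$q_value <- f$q_value
    rec
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
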