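mk_family <- function(child, parents)
  structure(list(child = child, parents = parents),
            class = "bn_family")

test_that("formula enumeration matches truth-table reachability", {
  # 1 parent: identity only (plus negation when allowed)
  expect_length(enumerate_gate_formulas("A", allow_not = FALSE), 1)
  expect_length(enumerate_gate_formulas("A", allow_not = TRUE), 2)
  # 2 parents, no NOT: one commutative gate choice each
  f2 <- enumerate_gate_formulas(c("A", "B"))
  expect_setequal(vapply(f2, formula_string, character(1)),
                  c("AND(A,B)", "OR(A,B)", "XOR(A,B)"))
  # 2 parents with NOT: candidates = distinct truth tables among
  # gate(+-A, +-B); count that reachable set independently
  grid <- as.matrix(expand.grid(A = 0:1, B = 0:1))
  reach <- character(0)
  for (g in c("AND", "OR", "XOR")) for (na in c(F, T)) for (nb in c(F, T)) {
    a <- if (na) 1 - grid[, 1] else grid[, 1]
    b <- if (nb) 1 - grid[, 2] else grid[, 2]
    out <- switch(g, AND = a & b, OR = a | b, XOR = xor(a, b))
    reach <- union(reach, paste(as.integer(out), collapse = ""))
  }
  fn <- enumerate_gate_formulas(c("A", "B"), allow_not = TRUE)
  expect_length(fn, length(reach))
  expect_lte(length(fn), 12)
  # candidates have pairwise distinct truth tables
  tts <- vapply(fn, function(f)
    paste(evaluate_formula(f, grid), collapse = ""), character(1))
  expect_false(any(duplicated(tts)))
  expect_error(enumerate_gate_formulas(c("A", "B"),
                                       gates = character(0)),
               "no gates")
})

test_that("formula evaluation follows boolean semantics", {
  m <- em(cbind(A = c(1, 1, 0), B = c(1, 0, 0)))
  and_ab <- enumerate_gate_formulas(c("A", "B"))[[
    which(vapply(enumerate_gate_formulas(c("A", "B")), formula_string,
                 character(1)) == "AND(A,B)")]]
  expect_equal(evaluate_formula(and_ab, m), c(1L, 0L, 0L))
  # XOR = OR - AND elementwise
  fs <- enumerate_gate_formulas(c("A", "B"))
  names(fs) <- vapply(fs, formula_string, character(1))
  expect_equal(evaluate_formula(fs[["XOR(A,B)"]], m),
               evaluate_formula(fs[["OR(A,B)"]], m) -
                 evaluate_formula(fs[["AND(A,B)"]], m))
  expect_error(evaluate_formula(fs[[1]], em(cbind(A = 1))),
               "missing event")
})

test_that("simplification flattens associative runs without changing output", {
  leaf <- gatedbn:::gate_leaf
  node <- gatedbn:::gate_node
  nested <- node("AND", list(node("AND", list(leaf("A"), leaf("B"))),
                             leaf("C")))
  expect_equal(formula_string(simplify_formula(nested)), "AND(A,B,C)")
  flat <- node("OR", list(leaf("A"), leaf("B")))
  expect_equal(formula_string(simplify_formula(flat)), "OR(A,B)")
  xnest <- node("XOR", list(node("XOR", list(leaf("A"), leaf("B"))),
                            leaf("C")))
  xflat <- simplify_formula(xnest)
  expect_equal(formula_string(xflat), "XOR(A,B,C)")
  grid <- as.matrix(expand.grid(A = 0:1, B = 0:1, C = 0:1))
  expect_equal(evaluate_formula(xflat, grid),
               evaluate_formula(xnest, grid))
  # exhaustive: simplification preserves evaluation for every candidate
  for (f in enumerate_gate_formulas(c("A", "B", "C")))
    expect_equal(evaluate_formula(simplify_formula(f), grid),
                 evaluate_formula(f, grid))
})

test_that("noiseless gates are recovered, including with NOT", {
  for (g in c("AND", "OR", "XOR")) for (p in 2:3) {
    grid <- as.matrix(expand.grid(rep(list(0:1), p)))
    colnames(grid) <- LETTERS[seq_len(p)]
    out <- switch(g,
                  AND = apply(grid, 1, min),
                  OR = apply(grid, 1, max),
                  XOR = rowSums(grid) %% 2)
    m <- em(cbind(grid, CH = as.integer(out))[rep(seq_len(2^p), 20), ])
    fit <- fit_family_gate(mk_family("CH", LETTERS[seq_len(p)]), m)
    expect_equal(evaluate_formula(fit$formula, grid), as.integer(out),
                 info = paste(g, p))
  }
  # C = A AND NOT B, exhaustively scored against all candidates
  grid <- as.matrix(expand.grid(A = 0:1, B = 0:1))
  ch <- as.integer(grid[, "A"] == 1 & grid[, "B"] == 0)
  m <- em(cbind(grid, CH = ch)[rep(1:4, 25), ])
  fit <- fit_family_gate(mk_family("CH", c("A", "B")), m,
                         allow_not = TRUE)
  expect_equal(formula_string(fit$formula), "AND(A,NOT B)")
  ps <- vapply(enumerate_gate_formulas(c("A", "B"), allow_not = TRUE),
               function(f) {
                 out <- evaluate_formula(f, m)
                 v <- unclass(m)[, "CH"]
                 ct <- structure(list(n11 = sum(out & v),
                                      n10 = sum(out & !v),
                                      n01 = sum(!out & v),
                                      n00 = sum(!out & !v)),
                                 class = "contingency_table")
                 fisher_exact(ct)$p_value
               }, numeric(1))
  expect_lte(fit$p_value, min(ps) + 1e-12)
})

test_that("XOR is preferred over OR on identical statistics", {
  # disjoint parents: OR and XOR produce identical vectors
  m <- em(cbind(P1 = c(1, 0, 0, 1, 0, 0, 1, 0),
                P2 = c(0, 1, 0, 0, 1, 0, 0, 1),
                CH = c(1, 1, 0, 1, 1, 0, 1, 1)))
  fit <- fit_family_gate(mk_family("CH", c("P1", "P2")), m)
  expect_equal(formula_string(fit$formula), "XOR(P1,P2)")
})

test_that("fits carry the family, output vector, and Fisher statistics", {
  # child identical to its single parent: identity, strongest p
  x <- rep(c(1L, 0L), 30)
  m <- em(cbind(P = x, CH = x))
  fit <- fit_family_gate(mk_family("CH", "P"), m)
  expect_equal(formula_string(fit$formula), "P")
  expect_equal(fit$output, x)
  expect_lt(fit$p_value, 1e-10)
  # constant child -> degenerate, p = 1
  mc <- em(cbind(P = x, CH = rep(1L, 60)))
  fitc <- fit_family_gate(mk_family("CH", "P"), mc)
  expect_true(fitc$degenerate)
  expect_equal(fitc$p_value, 1)
  # no enumerated candidate beats the chosen one (<= 3 parents)
  set.seed(81)
  m3 <- em(matrix(rbinom(4 * 50, 1, 0.5), ncol = 4,
                  dimnames = list(NULL, c("X", "Y", "Z", "CH"))))
  fit3 <- fit_family_gate(mk_family("CH", c("X", "Y", "Z")), m3)
  allp <- vapply(enumerate_gate_formulas(c("X", "Y", "Z")),
                 function(f) {
                   out <- evaluate_formula(f, m3)
                   v <- unclass(m3)[, "CH"]
                   ct <- structure(list(n11 = sum(out & v),
                                        n10 = sum(out & !v),
                                        n01 = sum(!out & v),
                                        n00 = sum(!out & !v)),
                                   class = "contingency_table")
                   fisher_exact(ct)$p_value
                 }, numeric(1))
  expect_lte(fit3$p_value, min(allp) + 1e-12)
})

test_that("whole-network gate fitting annotates every non-root family", {
  fix <- example_bn()
  m <- forward_sample(fix, 1500, seed = 90)
  fits <- fit_all_gates(fix$dag, m, adjust = "BH")
  expect_length(fits, 2)
  children <- vapply(fits, function(f) f$family$child, character(1))
  expect_setequal(children, c("C", "E"))
  expect_true(all(vapply(fits, function(f) !is.null(f$q_value),
                         logical(1))))
  # E was generated as a noisy OR of C and D; OR/XOR should fit it
  e_fit <- fits[[which(children == "E")]]
  expect_true(formula_string(e_fit$formula) %in%
                c("OR(C,D)", "XOR(C,D)"))
  path <- tempfile(fileext = ".json")
  write_gate_fits(fits, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 2)
  expect_true(all(c("child", "formula", "p_value", "odds_ratio") %in%
                    names(parsed[[1]])))
})
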