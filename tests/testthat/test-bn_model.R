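test_that("DAG construction rejects cycles and self-loops", {
  expect_error(bn_dag(c("A", "B"), list(A = "B", B = "A")), "cycle")
  expect_error(bn_dag(c("A"), list(A = "A")), "self-loop")
  expect_error(bn_dag(c("A", "B"), list(A = "Z")), "unknown parent")
  dag <- bn_dag(c("A", "B", "C"), list(C = c("B", "A")))
  # parent order is canonicalised to the variable order
  expect_equal(dag$parents$C, c("A", "B"))
})

test_that("topological order is deterministic and respects edges", {
  dag <- bn_dag(c("A", "B", "C", "D", "E"),
                list(C = c("A", "B"), E = c("C", "D")))
  ord <- topological_order(dag)
  expect_equal(ord, c("A", "B", "C", "D", "E"))
  for (e in seq_len(nrow(dag_edges(dag)))) {
    edge <- dag_edges(dag)[e, ]
    expect_lt(match(edge["from"], ord), match(edge["to"], ord))
  }
})

test_that("families decompose the DAG edge set exactly", {
  dag0 <- bn_dag(c("A", "B"))
  fams0 <- families_of(dag0)
  expect_length(fams0, 2)
  expect_true(all(vapply(fams0, function(f) length(f$parents) == 0,
                         logical(1))))

  fix <- example_bn()
  fams <- families_of(fix$dag)
  expect_length(fams, 5)
  byc <- setNames(fams, vapply(fams, function(f) f$child, character(1)))
  expect_equal(byc$C$parents, c("A", "B"))
  expect_equal(byc$E$parents, c("C", "D"))
  pairs <- do.call(rbind, lapply(fams, function(f)
    if (length(f$parents)) cbind(f$parents, f$child)))
  expect_setequal(paste(pairs[, 1], pairs[, 2]),
                  paste(dag_edges(fix$dag)[, 1], dag_edges(fix$dag)[, 2]))

  chain <- bn_dag(c("A", "B", "C"), list(B = "A", C = "B"))
  byc <- setNames(families_of(chain),
                  c("A", "B", "C"))
  expect_equal(byc$B$parents, "A")
  expect_equal(byc$C$parents, "B")
})

test_that("joint probability factorises and normalises", {
  root <- discrete_bn(bn_dag("X"), list(X = bn_cpt("X", character(0), 0.3)))
  expect_equal(joint_probability(root, c(X = 1)), 0.3)
  expect_error(joint_probability(root, c(Y = 1)), "missing")

  fix <- example_bn()
  oracle <- exact_joint_table(fix)
  total <- 0
  for (r in seq_len(nrow(oracle$grid))) {
    asg <- oracle$grid[r, ]
    expect_equal(joint_probability(fix, asg), oracle$p[r])
    total <- total + joint_probability(fix, asg)
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("fixture encodes the stated gates and CPT entry", {
  fix <- example_bn()
  e <- dag_edges(fix$dag)
  expect_setequal(paste(e[, 1], e[, 2]),
                  c("A C", "B C", "C E", "D E"))
  # p(C=1 | A=0, B=0) = 0.2
  expect_equal(fix$cpts$C$p1[1], 0.2)
  # high-probability child value follows the gate: C = A AND NOT B
  cfg <- as.matrix(expand.grid(A = 0:1, B = 0:1))
  gate_c <- as.integer(cfg[, "A"] == 1 & cfg[, "B"] == 0)
  expect_equal(as.integer(fix$cpts$C$p1 > 0.5), gate_c)
  gate_e <- as.integer(expand.grid(C = 0:1, D = 0:1)[, 1] == 1 |
                         expand.grid(C = 0:1, D = 0:1)[, 2] == 1)
  expect_equal(as.integer(fix$cpts$E$p1 > 0.5), gate_e)
})

test_that("forward sampling is seeded, deterministic, and calibrated", {
  fix <- example_bn()
  m1 <- forward_sample(fix, 500, seed = 99)
  m2 <- forward_sample(fix, 500, seed = 99)
  expect_identical(unclass(m1), unclass(m2))

  # a deterministic BN yields its unique consistent assignment
  det <- discrete_bn(bn_dag(c("X", "Y"), list(Y = "X")),
                     list(X = bn_cpt("X", character(0), 1),
                          Y = bn_cpt("Y", "X", c(0, 1))))
  md <- forward_sample(det, 50, seed = 1)
  expect_true(all(md == 1))

  # root mean within 5 binomial SEs of its probability
  root <- discrete_bn(bn_dag("X"), list(X = bn_cpt("X", character(0), 0.5)))
  mr <- forward_sample(root, 10000, seed = 4)
  expect_lt(abs(mean(mr[, "X"]) - 0.5), 5 * sqrt(0.25 / 10000))
})

test_that("empirical joint matches the exact joint (chi-square GOF)", {
  fix <- example_bn()
  m <- forward_sample(fix, 50000, seed = 2024)
  oracle <- exact_joint_table(fix)
  cell <- gatedbn:::config_index(unclass(m))
  obs <- tabulate(cell, nbins = 32)
  key <- gatedbn:::config_index(oracle$grid[, fix$dag$variables])
  expected_p <- numeric(32)
  expected_p[key] <- oracle$p
  gof <- suppressWarnings(chisq.test(obs, p = expected_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("CPT fitting counts, smooths, and recovers parameters", {
  # repeated single assignment, no smoothing -> degenerate CPTs
  m <- em(matrix(rep(c(1L, 0L), each = 10), ncol = 2), c("A", "B"))
  dag <- bn_dag(c("A", "B"), list(B = "A"))
  fit <- suppressWarnings(fit_cpts(dag, m, 0))
  expect_equal(fit$cpts$A$p1, 1)
  expect_equal(fit$cpts$B$p1[2], 0)  # p(B=1 | A=1) = 0

  # direct counting: child 0,0 under parent 0,1 -> p(child=1|parent=0)=0.5
  m2 <- em(cbind(P = c(0L, 0L), CH = c(0L, 1L)))
  dag2 <- bn_dag(c("P", "CH"), list(CH = "P"))
  expect_warning(fit_cpts(dag2, m2, 0), "unobserved")
  fit2 <- suppressWarnings(fit_cpts(dag2, m2, 0))
  expect_equal(fit2$cpts$CH$p1[1], 0.5)
  expect_equal(fit2$cpts$CH$p1[2], 0.5)  # unseen config -> uniform

  # recovery improves with sample size; within 0.02 at n = 1e5
  fix <- example_bn()
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    refit <- fit_cpts(fix$dag, forward_sample(fix, n, seed = 5))
    max(vapply(fix$dag$variables, function(v)
      max(abs(refit$cpts[[v]]$p1 - fix$cpts[[v]]$p1)), numeric(1)))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("BN JSON serialisation round-trips", {
  fix <- example_bn()
  path <- tempfile(fileext = ".json")
  write_bn_json(fix, path)
  back <- read_bn_json(path)
  expect_equal(back$dag$variables, fix$dag$variables)
  expect_equal(back$dag$parents, fix$dag$parents)
  for (v in fix$dag$variables)
    expect_equal(back$cpts[[v]]$p1, fix$cpts[[v]]$p1)
})
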