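test_that("contingency tables count joint presence correctly", {
  m <- em(cbind(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0)))
  ct <- contingency_table(m, "A", "B")
  expect_equal(unlist(ct[c("n11", "n10", "n01", "n00")]),
               c(n11 = 0, n10 = 1, n01 = 1, n00 = 2))
  x <- c(1, 1, 1, 0, 0)
  m2 <- em(cbind(A = x, B = x))
  ct2 <- contingency_table(m2, "A", "B")
  expect_equal(ct2$n11, 3)
  expect_equal(ct2$n10 + ct2$n01, 0)
  expect_equal(ct2$n00, 2)
  expect_error(contingency_table(m, "A", "A"), "distinct")
  expect_error(contingency_table(m, "A", "Z"), "unknown event")
  # symmetric up to transpose
  ctr <- contingency_table(m, "B", "A")
  expect_equal(ctr$n10, ct$n01)
  expect_equal(ctr$n11, ct$n11)
})

test_that("Fisher test matches hypergeometric enumeration", {
  # perfect independence
  t1 <- structure(list(n11 = 1, n10 = 1, n01 = 1, n00 = 1),
                  class = "contingency_table")
  f1 <- fisher_exact(t1)
  expect_equal(f1$p_value, 1)
  expect_equal(f1$odds_ratio, 1)
  # (3,0,0,3): only the observed table and its mirror are as extreme:
  # P(X=3) + P(X=0) = 1/20 + 1/20 = 0.1
  t2 <- structure(list(n11 = 3, n10 = 0, n01 = 0, n00 = 3),
                  class = "contingency_table")
  f2 <- fisher_exact(t2)
  expect_equal(f2$p_value, 0.1, tolerance = 1e-12)
  expect_gt(f2$odds_ratio, 1)
  # disjoint events point towards mutual exclusivity
  t3 <- structure(list(n11 = 0, n10 = 5, n01 = 5, n00 = 0),
                  class = "contingency_table")
  expect_lt(fisher_exact(t3)$odds_ratio, 1)
  # degenerate margin carries no information
  t4 <- structure(list(n11 = 0, n10 = 0, n01 = 3, n00 = 7),
                  class = "contingency_table")
  f4 <- fisher_exact(t4)
  expect_true(f4$degenerate)
  expect_equal(f4$p_value, 1)
  # invariant under swapping the two events
  t5 <- structure(list(n11 = 4, n10 = 2, n01 = 7, n00 = 11),
                  class = "contingency_table")
  t5r <- structure(list(n11 = 4, n10 = 7, n01 = 2, n00 = 11),
                   class = "contingency_table")
  expect_equal(fisher_exact(t5)$p_value, fisher_exact(t5r)$p_value)
})

test_that("sample odds-ratio estimator is the cross-product ratio", {
  t <- structure(list(n11 = 6, n10 = 2, n01 = 3, n00 = 9),
                 class = "contingency_table")
  expect_equal(fisher_exact(t, estimator = "sample")$odds_ratio,
               6 * 9 / (2 * 3))
})

test_that("all-pairs testing forms one BH family over C(V,2) tests", {
  set.seed(71)
  m <- em(matrix(rbinom(300, 1, 0.4), ncol = 5))
  stats <- all_pairs_fisher(m)
  expect_equal(nrow(stats), choose(5, 2))
  expect_true(all(stats$q_value >= stats$p_value - 1e-15))
  # q monotone in p
  ord <- order(stats$p_value)
  expect_true(all(diff(stats$q_value[ord]) >= -1e-15))
  # single pair: q = p
  m2 <- em(matrix(rbinom(40, 1, 0.5), ncol = 2))
  s2 <- all_pairs_fisher(m2)
  expect_equal(s2$q_value, s2$p_value)
  # direction is consistent with the sample log odds when all cells > 0
  pos <- stats[stats$n11 > 0 & stats$n10 > 0 & stats$n01 > 0 &
                 stats$n00 > 0, ]
  lor <- log(pos$n11 * pos$n00 / (pos$n10 * pos$n01))
  expect_true(all(sign(lor[pos$direction == "co_occurrence"]) > 0))
  expect_true(all(sign(lor[pos$direction == "mutual_exclusivity"]) < 0))
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  # p = (0.01, 0.02, 0.03, 0.04), m = 4:
  # q_(i) = min_j>=i ( m p_(j) / j ) = (0.04, 0.04, 0.04, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("edge styles encode direction, significance, and width", {
  s <- edge_style(odds_ratio = 4, q_value = 0.049)
  expect_equal(s$colour, "green")
  expect_equal(s$line, "solid")
  expect_equal(s$width, 2)  # the legend calibration: OR = 4 -> width 2
  s2 <- edge_style(odds_ratio = 0.2, q_value = 0.5)
  expect_equal(s2$colour, "yellow")
  expect_equal(s2$line, "dotted")
  # reciprocal folding: OR = 0.25 as wide as OR = 4
  expect_equal(edge_style(0.25, 0.01)$width, edge_style(4, 0.01)$width)
  s3 <- edge_style(odds_ratio = 1, q_value = 0.5)
  expect_true(s3$neutral)
  expect_equal(s3$line, "dotted")
  expect_equal(s3$width, 0.5)
  # infinite OR is capped
  expect_equal(edge_style(Inf, 0.001)$width, 8)
})

test_that("the Fisher network keeps all nodes, edges only if significant", {
  set.seed(73)
  x <- rbinom(100, 1, 0.5)
  m <- em(cbind(A = x, B = x, C = rbinom(100, 1, 0.5)))
  stats <- all_pairs_fisher(m)
  g <- fisher_network(stats, alpha = 0.05)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  ee <- igraph::as_edgelist(g)
  expect_equal(nrow(ee), 1)
  expect_setequal(as.vector(ee), c("A", "B"))
  # all-insignificant -> empty edge set, monotone in alpha
  null_stats <- stats
  null_stats$q_value <- rep(0.7, nrow(stats))
  g0 <- fisher_network(null_stats, alpha = 0.05)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 3)
  alphas <- c(1e-6, 1e-3, 0.05, 0.5)
  counts <- vapply(alphas, function(a)
    igraph::ecount(fisher_network(stats, a)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("type-I error is controlled on independent columns", {
  set.seed(75)
  reps <- 100
  fdr <- vapply(seq_len(reps), function(r) {
    m <- em(matrix(rbinom(10 * 60, 1, 0.3), ncol = 10))
    stats <- all_pairs_fisher(m)
    disc <- sum(stats$q_value < 0.05)
    disc / max(disc, 1)  # all discoveries are false under the null
  }, numeric(1))
  expect_lte(mean(fdr), 0.05)
})
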