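# Shared fixtures and independent oracles, built in code.

# small event matrix from a plain matrix, auto-named
em <- function(vals, events = NULL) {
  vals <- as.matrix(vals)
  if (is.null(events)) events <- colnames(vals)
  if (is.null(events)) events <- LETTERS[seq_len(ncol(vals))]
  colnames(vals) <- events
  event_matrix(vals)
}

# write a matrix to a temp TSV and return the path
write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# score table filled with arbitrary values (for search tests, where
# scores need not come from data)
random_score_table <- function(V, max_parents = 3, seed = 1) {
  set.seed(seed)
  vars <- LETTERS[seq_len(V)]
  scores <- vector("list", V)
  names(scores) <- vars
  for (i in seq_len(V)) {
    masks <- gatedbn:::admissible_masks(setdiff(seq_len(V), i),
                                        max_parents)
    scores[[i]] <- list(masks = masks,
                        score = stats::rnorm(length(masks), sd = 3))
  }
  structure(list(variables = vars,
                 config = score_config(epsilon = 0,
                                       max_parents = max_parents),
                 scores = scores),
            class = "score_table")
}

# a random sparse binary BN over V variables: each variable gets at
# most 2 parents among its predecessors, CPT rows drawn uniformly
random_bn <- function(V, seed = 1, max_parents = 2) {
  set.seed(seed)
  vars <- LETTERS[seq_len(V)]
  parents <- list()
  for (i in seq_len(V)) {
    k <- min(i - 1, sample(0:max_parents, 1))
    if (k > 0)
      parents[[vars[i]]] <- sample(vars[seq_len(i - 1)], k)
  }
  dag <- bn_dag(vars, parents)
  cpts <- lapply(vars, function(v) {
    q <- 2^length(dag$parents[[v]])
    bn_cpt(v, dag$parents[[v]], stats::runif(q, 0.05, 0.95))
  })
  names(cpts) <- vars
  discrete_bn(dag, cpts)
}

# independent oracle: BDeu local score as the log of the sequential
# (prequential) predictive product under the same Dirichlet prior
prequential_bdeu <- function(child, parent_set, m, ess) {
  vals <- unclass(m)
  q <- 2^length(parent_set)
  aj <- ess / q
  ajk <- ess / (2 * q)
  idx <- gatedbn:::config_index(vals[, parent_set, drop = FALSE])
  n1 <- numeric(q); n0 <- numeric(q)
  total <- 0
  for (t in seq_len(nrow(vals))) {
    j <- idx[t]
    x <- vals[t, child]
    num <- if (x == 1) ajk + n1[j] else ajk + n0[j]
    total <- total + log(num / (aj + n1[j] + n0[j]))
    if (x == 1) n1[j] <- n1[j] + 1 else n0[j] <- n0[j] + 1
  }
  total
}

# independent oracle: exact joint of a small BN by direct factor
# multiplication over an explicit assignment table
exact_joint_table <- function(bn) {
  vars <- bn$dag$variables
  grid <- as.matrix(expand.grid(rep(list(0:1), length(vars))))
  colnames(grid) <- vars
  p <- vapply(seq_len(nrow(grid)), function(r) {
    prob <- 1
    for (v in vars) {
      cpt <- bn$cpts[[v]]
      j <- gatedbn:::config_index(grid[r, cpt$parents, drop = FALSE])
      p1 <- cpt$p1[j]
      prob <- prob * if (grid[r, v] == 1) p1 else 1 - p1
    }
    prob
  }, numeric(1))
  list(grid = grid, p = p)
}

skeleton_of <- function(dag) {
  e <- dag_edges(dag)
  sort(apply(e, 1, function(r) paste(sort(r), collapse = "-")))
}
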