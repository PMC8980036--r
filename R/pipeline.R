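# End-to-end pipeline: filter -> score -> learn -> annotate -> gate ->
# report, plus the cohort simulator. Everything is a pure function of
# (input file, configuration), so re-running with the same config
# reproduces identical non-image artifacts.

#' Pipeline configuration
#'
#' The two headline knobs are `mu` (minimum event count; rarer events
#' are dropped) and `epsilon` (edge penalty; larger values give sparser
#' networks). Everything else has defaults that rarely need touching.
#'
#' @param input path to the event-matrix TSV/CSV.
#' @param mu minimum event count (default 0 = keep everything).
#' @param epsilon integer edge penalty (default 1).
#' @param max_parents maximum parents per node (default 3).
#' @param score_kind `"bdeu"` or `"bic"`.
#' @param ess BDeu equivalent sample size (default 1).
#' @param alpha significance level for solid edges (default 0.05).
#' @param adjust multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @param gates gates considered in gate fitting (default AND/OR/XOR).
#' @param allow_not allow negated gate inputs (default `FALSE`).
#' @param fit_gates fit logic gates to families (default `TRUE`).
#' @param delimiter input field separator (default tab).
#' @param seed optional integer seed recorded in the log (the learning
#'   pipeline itself is deterministic).
#' @param hard_limit variable-count limit of the exact search.
#' @param out_dir output directory, created if absent.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, mu = 0, epsilon = 1,
                       max_parents = 3, score_kind = "bdeu", ess = 1,
                       alpha = 0.05, adjust = "BH", gates = GATE_OPS,
                       allow_not = FALSE, fit_gates = TRUE,
                       delimiter = "\t", seed = NULL, hard_limit = 20) {
  cfg <- list(input = input, out_dir = out_dir, mu = mu,
              epsilon = epsilon, max_parents = max_parents,
              score_kind = score_kind, ess = ess, alpha = alpha,
              adjust = adjust, gates = gates, allow_not = allow_not,
              fit_gates = fit_gates, delimiter = delimiter, seed = seed,
              hard_limit = hard_limit)
  # validate the score part eagerly so bad values fail at parse time
  score_config(score_kind, ess, epsilon, max_parents)
  if (mu < 0) stop("mu must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Reads a binary event matrix, applies the mu filter, learns the
#' optimal network at the configured epsilon, annotates edges with
#' Fisher statistics, fits logic gates, and writes every artifact into
#' the output directory: `config.json`, `filter_report.tsv`,
#' `pairs.tsv`, `network.json`, `network.dot`, `network.graphml`,
#' `gated_network.dot`, `gates.json`, one `heatmap_<child>.png` per
#' multi-parent family, and `run_log.txt`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a manifest list: `files` (named artifact paths),
#'   `result` (the `bn_search_result`), `pair_stats`, `gate_fits`,
#'   `filter_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)
  log_lines <- c(sprintf("gatedbn %s",
                         as.character(utils::packageVersion("gatedbn"))),
                 sprintf("mu = %d, epsilon = %g, score = %s (ess %g), max_parents = %d",
                         as.integer(cfg$mu), cfg$epsilon, cfg$score_kind,
                         cfg$ess, cfg$max_parents),
                 sprintf("alpha = %g, adjust = %s, gates = %s, allow_not = %s",
                         cfg$alpha, cfg$adjust,
                         paste(cfg$gates, collapse = ","), cfg$allow_not),
                 sprintf("seed = %s",
                         if (is.null(cfg$seed)) "none" else cfg$seed))
  cfg_out <- unclass(cfg)
  cfg_out$seed <- if (is.null(cfg$seed)) NA else cfg$seed
  jsonlite::write_json(cfg_out, pth("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  m <- stage("read", read_event_matrix(cfg$input, cfg$delimiter))
  log_lines <- c(log_lines, sprintf("input: %d samples x %d events",
                                    nrow(m), ncol(m)))
  flt <- stage("filter", filter_by_mu(m, cfg$mu))
  write_filter_report(flt$report, pth("filter_report.tsv"))
  m <- flt$matrix
  log_lines <- c(log_lines, sprintf("after mu filter: %d events", ncol(m)))

  scfg <- score_config(cfg$score_kind, cfg$ess, cfg$epsilon,
                       cfg$max_parents)
  table <- stage("score", build_score_table(m, scfg))
  res <- stage("learn", learn_optimal_dag(table, cfg$hard_limit))
  log_lines <- c(log_lines,
                 sprintf("learned network: %d edges, score %.6f",
                         res$edge_count, res$total_score))
  jsonlite::write_json(
    list(variables = res$dag$variables, parents = res$dag$parents,
         edges = apply(dag_edges(res$dag), 1, paste, collapse = "--"),
         total_score = res$total_score, edge_count = res$edge_count,
         mu = cfg$mu, epsilon = cfg$epsilon),
    pth("network.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stats <- stage("fisher", all_pairs_fisher(m, cfg$adjust))
  write_pair_stats(stats, pth("pairs.tsv"))
  styles <- dag_edge_styles(res$dag, stats, alpha = cfg$alpha)
  emph <- emphasis_nodes(m)
  stage("export", {
    export_network(res$dag, styles, pth("network.dot"), emphasis = emph)
    export_network(res$dag, styles, pth("network.graphml"),
                   emphasis = emph)
  })

  fits <- list()
  if (cfg$fit_gates) {
    fits <- stage("gates", fit_all_gates(res$dag, m, cfg$gates,
                                         cfg$allow_not,
                                         adjust = cfg$adjust))
    write_gate_fits(fits, pth("gates.json"))
    stage("export_gated",
          export_network(res$dag, styles, pth("gated_network.dot"),
                         emphasis = emph, gated = fits))
  }

  heatmaps <- character(0)
  for (fam in Filter(function(f) length(f$parents) > 0,
                     families_of(res$dag))) {
    hp <- pth(sprintf("heatmap_%s.png", fam$child))
    stage("heatmap",
          render_family_heatmap(family_heatmap_matrix(fam, m), hp))
    heatmaps <- c(heatmaps, hp)
  }

  writeLines(log_lines, pth("run_log.txt"))
  files <- c(config = pth("config.json"),
             filter_report = pth("filter_report.tsv"),
             pairs = pth("pairs.tsv"),
             network_json = pth("network.json"),
             network_dot = pth("network.dot"),
             network_graphml = pth("network.graphml"),
             log = pth("run_log.txt"))
  if (cfg$fit_gates)
    files <- c(files, gates = pth("gates.json"),
               gated_network_dot = pth("gated_network.dot"))
  invisible(list(files = files, heatmaps = heatmaps, result = res,
                 pair_stats = stats, gate_fits = fits,
                 filter_report = flt$report))
}

#' Sample a synthetic cohort from a network file
#'
#' Reads a network in the JSON schema of [write_bn_json()], draws `n`
#' samples ancestrally, and writes them as an event-matrix TSV.
#'
#' @param network_path path to the network JSON.
#' @param n number of samples.
#' @param seed integer seed (same seed, same file).
#' @param out_path output TSV path.
#' @return The sampled [event_matrix()], invisibly.
#' @export
run_simulator <- function(network_path, n, seed, out_path) {
  bn <- read_bn_json(network_path)
  m <- forward_sample(bn, n, seed)
  write_event_matrix(m, out_path)
  invisible(m)
}
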