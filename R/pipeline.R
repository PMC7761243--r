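#' Pipeline configuration
#'
#' Collects every stage's settings for [run_pipeline()].  The single
#' `seed` controls all stochastic stages through per-stage derived
#' seeds, so one value reproduces a whole run.
#'
#' @param input path to the input CSV/TSV, or an `ExpressionMatrix`.
#' @param outdir output directory.
#' @param group_column group column (or row) name in the input file.
#' @param log_transform logical; natural-log transform intensities.
#' @param aggregate aggregation mode (`"none"`, `"data_driven"`,
#'   `"knowledge_driven"`, `"hybrid"`).
#' @param tolerance aggregation tolerance.
#' @param grouping_file optional path to a feature grouping file.
#' @param n_iterations stability-selection iterations.
#' @param tau selection-probability threshold.
#' @param subsample logical; balanced group subsampling.
#' @param alpha,beta balanced-subsampling constants.
#' @param lambda optional fixed penalty (otherwise BIC-selected).
#' @param cluster_runs consensus clustering runs.
#' @param edge_keep consensus edge-retention fraction.
#' @param min_size minimum subnetwork size.
#' @param fdr significance threshold flagged in the results file.
#' @param seed master seed.
#' @param verbose logical; log stage summaries.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(input, outdir, group_column = "group",
                       log_transform = TRUE,
                       aggregate = c("none", "data_driven",
                                     "knowledge_driven", "hybrid"),
                       tolerance = 0.5, grouping_file = NULL,
                       n_iterations = 500, tau = 0.9, subsample = FALSE,
                       alpha = 1.3, beta = 0.9, lambda = NULL,
                       cluster_runs = 50, edge_keep = 0.8, min_size = 5,
                       fdr = 0.05, seed = 1, verbose = TRUE) {
  aggregate <- match.arg(aggregate)
  if (aggregate %in% c("knowledge_driven", "hybrid") &&
      is.null(grouping_file)) {
    stop("aggregation mode '", aggregate,
         "' requires a grouping file")
  }
  structure(list(input = input, outdir = outdir,
                 group_column = group_column,
                 log_transform = log_transform, aggregate = aggregate,
                 tolerance = tolerance, grouping_file = grouping_file,
                 n_iterations = n_iterations, tau = tau,
                 subsample = subsample, alpha = alpha, beta = beta,
                 lambda = lambda, cluster_runs = cluster_runs,
                 edge_keep = edge_keep, min_size = min_size, fdr = fdr,
                 seed = as.integer(seed), verbose = verbose),
            class = "RunConfig")
}

#' Run the full differential network enrichment pipeline
#'
#' Executes read, preprocessing (log transform, optional aggregation,
#' autoscaling), stability-selected joint network estimation, consensus
#' clustering, topology-aware enrichment testing and per-feature
#' statistics, then writes `edgelist.csv`, `nodelist.csv`,
#' `netgsa_results.csv`, a run log and a config snapshot into the
#' output directory.  Identical config and seed give identical outputs;
#' on error, partially written outputs are removed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the intermediate objects (`data`,
#'   `aggregation`, `network`, `partition`, `enrichment`, `edges`,
#'   `nodes`) and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  log_path <- file.path(config$outdir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  written <- file.path(config$outdir,
                       c("edgelist.csv", "nodelist.csv",
                         "netgsa_results.csv", "run.log", "config.txt"))
  on_fail <- function(e) {
    unlink(written[file.exists(written)])
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  }

  result <- tryCatch({
    em <- if (inherits(config$input, "ExpressionMatrix")) {
      config$input
    } else {
      read_input_table(config$input, group_column = config$group_column)
    }
    say("input: ", nrow(em$values), " samples x ", ncol(em$values),
        " features; groups ",
        paste(levels(em$group), table(em$group), sep = "=",
              collapse = ", "))

    if (config$log_transform) em <- log_transform(em)
    agg <- NULL
    if (config$aggregate != "none") {
      grouping <- if (!is.null(config$grouping_file)) {
        read_grouping_file(config$grouping_file)
      }
      agg <- aggregate_features(em, mode = config$aggregate,
                                tolerance = config$tolerance,
                                grouping = grouping)
      em <- agg$data
      say("aggregation (", config$aggregate, ", tolerance ",
          config$tolerance, "): ", length(unlist(agg$map)),
          " features -> ", ncol(em$values))
    }
    em <- autoscale(em)

    xg <- split_by_group(em)
    cfg <- stability_config(n_iterations = config$n_iterations,
                            tau = config$tau, alpha = config$alpha,
                            beta = config$beta,
                            subsampling = config$subsample,
                            lambda = config$lambda,
                            seed = config$seed)
    sel <- stability_select(xg, cfg)
    supp_n <- function(P) sum(P[upper.tri(P)] > config$tau)
    say("stability selection (", config$n_iterations,
        " iterations, lambda ", signif(sel$lambda[1], 4), "): edges at tau=",
        config$tau, ": group1=", supp_n(sel$P1), ", group2=",
        supp_n(sel$P2))

    R1 <- estimate_partial_correlations(xg[[1]], sel$P1, tau = config$tau)
    R2 <- estimate_partial_correlations(xg[[2]], sel$P2, tau = config$tau)
    net <- joint_network(sel$P1, sel$P2, R1, R2, tau = config$tau)

    set.seed(config$seed + 1L)
    part <- consensus_cluster(net, n_runs = config$cluster_runs,
                              edge_keep_frac = config$edge_keep,
                              min_size = config$min_size)
    say("consensus clustering: ", length(part$members),
        " subnetworks; ", sum(part$labels == 0), " unassigned nodes")

    lam1 <- influence_matrix(R1)
    lam2 <- influence_matrix(R2)
    enr <- netgsa_test(xg, list(lam1, lam2), part, net = net)
    enr$significant <- !is.na(enr$adj_pvalue) &
      enr$adj_pvalue < config$fdr
    say("enrichment: ", sum(enr$significant), " of ", nrow(enr),
        " subnetworks significant at FDR < ", config$fdr)

    edges <- edge_table(net)
    nodes <- node_table(em, part)
    write_outputs(edges, nodes, as.data.frame(enr), config$outdir)
    writeLines(config_snapshot(config),
               file.path(config$outdir, "config.txt"))
    writeLines(log_lines, log_path)
    list(data = em, aggregation = agg, network = net, partition = part,
         enrichment = enr, edges = edges, nodes = nodes,
         paths = written)
  }, error = on_fail)
  invisible(result)
}

config_snapshot <- function(config) {
  flat <- config[!vapply(config, is.null, logical(1))]
  flat <- flat[!vapply(flat, inherits, logical(1), "ExpressionMatrix")]
  vapply(names(flat), function(k) {
    paste0(k, "=", paste(format(flat[[k]]), collapse = ","))
  }, character(1))
}
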