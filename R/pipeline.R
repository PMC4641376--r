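#' Default pipeline configuration
#'
#' All tunable parameters of the four analysis stages with their default
#' values: the 0.1 / 0.05 / 1.5 / 200 / 1% tiered feature selection, the
#' strict HT2 tail, restart probability 0.7 with a 5% partner cutoff and
#' the strict 0.001 crosstalk threshold on the differential network, and
#' the 0.05 subtype-factor screen with floors of 3.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    inputs = list(expr = NULL, conditions = NULL, gmt = NULL,
                  network = NULL, clinical = NULL,
                  clinical_types = NULL,
                  score_column = NULL, min_score = NULL,
                  string_scale = FALSE),
    features = list(fdr1 = 0.1, p2 = 0.05, fc2 = 1.5, top_frac = 0.01,
                    min_genes = 200, var_equal = FALSE,
                    log_scale = TRUE),
    enrich = list(inclusive = FALSE),
    crosstalk = list(lambda = 0.7, weighting = "topology",
                     top_frac = 0.05, alpha = 0.001,
                     alpha_edge = 0.05, use_diffnet = TRUE,
                     tol = 1e-10, max_iter = 10000),
    subtypes = list(alpha = 0.05, min_devg = 3, min_cluster = 3,
                    method = "hierarchical"),
    stages = c("features", "enrich", "crosstalk", "subtypes"),
    plots = FALSE,
    seed = 1
  )
}

merge_config <- function(user, defaults) {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: '", key, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key '", key, "' must be a mapping")
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  merge_config(config, default_config())
}

#' Run the full analysis pipeline
#'
#' Orchestrates feature-gene classification, HT2 pathway enrichment,
#' crosstalk mapping and subtype-factor screening as one reproducible
#' run.  The effective configuration (defaults resolved) is written to
#' the output directory; unknown configuration keys are rejected before
#' any computation; every dropped gene, edge or pathway is counted in
#' `log.txt`.  A stage failure aborts with the stage named, retaining
#' the outputs of earlier stages.
#'
#' @param config a nested list, or the path to a YAML/JSON file,
#'   following [default_config]; `inputs` must name the expression,
#'   condition, GMT and (for the crosstalk/subtype stages) network and
#'   clinical files.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results
#'   (`labeling`, `enrichment`, `map`, `subtypes`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  log_lines <- c(paste("ieatools", as.character(
    utils::packageVersion("ieatools"))), paste("seed", cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  dataset <- stage("input", {
    if (is.null(cfg$inputs$expr) || is.null(cfg$inputs$conditions))
      stop("inputs$expr and inputs$conditions are required")
    read_expression(cfg$inputs$expr, cfg$inputs$conditions)
  })
  log_lines <- c(log_lines,
                 paste("genes", nrow(dataset$values)),
                 paste("samples", ncol(dataset$values)),
                 paste("dropped_na_rows", attr(dataset, "n_dropped_na")),
                 paste("collapsed_rows", attr(dataset, "n_collapsed")))

  if ("features" %in% cfg$stages) {
    res$labeling <- stage("features", with_local_seed(cfg$seed, {
      f <- cfg$features
      classify_genes(dataset, fdr1 = f$fdr1, p2 = f$p2, fc2 = f$fc2,
                     top_frac = f$top_frac, min_genes = f$min_genes,
                     var_equal = f$var_equal, log_scale = f$log_scale)
    }))
    write_table(res$labeling$stats, file.path(out_dir, "genes.tsv"))
    log_lines <- c(log_lines,
                   paste("x1_deg", res$labeling$x1),
                   paste("x2_devg", res$labeling$x2),
                   paste("deg_tier", res$labeling$tier[["DEG"]]),
                   paste("devg_tier", res$labeling$tier[["DEVG"]]))
  }

  collection <- NULL
  if (!is.null(cfg$inputs$gmt))
    collection <- stage("input", read_gmt(cfg$inputs$gmt))

  if ("enrich" %in% cfg$stages) {
    res$enrichment <- stage("enrich", {
      if (is.null(collection)) stop("inputs$gmt is required")
      enrich_pathways(res$labeling, collection,
                      inclusive = cfg$enrich$inclusive)
    })
    write_table(res$enrichment, file.path(out_dir, "enrich.tsv"))
    log_lines <- c(log_lines,
                   paste("pathways_scored", nrow(res$enrichment)),
                   paste("pathways_skipped",
                         attr(res$enrichment, "n_skipped")))
    if (isTRUE(cfg$plots)) {
      grDevices::pdf(file.path(out_dir, "gene_distribution.pdf"))
      plot_gene_distribution(res$enrichment)
      grDevices::dev.off()
    }
  }

  if ("crosstalk" %in% cfg$stages) {
    res$map <- stage("crosstalk", {
      if (is.null(cfg$inputs$network)) stop("inputs$network is required")
      ct <- cfg$crosstalk
      net <- read_network(cfg$inputs$network,
                          score_column = cfg$inputs$score_column,
                          min_score = cfg$inputs$min_score,
                          string_scale = cfg$inputs$string_scale)
      if (isTRUE(ct$use_diffnet))
        net <- suppressWarnings(
          differential_network(net, dataset,
                               alpha_edge = ct$alpha_edge))
      if (ct$weighting == "correlation")
        net <- correlation_weights(net, dataset)
      rc <- rwr_config(lambda = ct$lambda, weighting = ct$weighting,
                       tol = ct$tol, max_iter = ct$max_iter,
                       top_frac = ct$top_frac)
      m <- build_pathway_map(collection, res$labeling, net,
                             config = rc, alpha = ct$alpha)
      detect_modules(m)
    })
    write_pathway_map(res$map, file.path(out_dir, "map"))
    log_lines <- c(log_lines,
                   paste("crosstalk_edges", nrow(res$map$edges)),
                   paste("map_pathways",
                         igraph::vcount(res$map$graph)))
  }

  if ("subtypes" %in% cfg$stages) {
    res$subtypes <- stage("subtypes", {
      if (is.null(cfg$inputs$clinical))
        stop("inputs$clinical is required")
      ts <- cfg$inputs$clinical_types
      if (is.null(ts)) stop("inputs$clinical_types is required")
      clinical <- read_clinical(cfg$inputs$clinical, unlist(ts))
      st <- cfg$subtypes
      screen_subtype_factors(dataset, res$labeling, collection,
                             clinical, alpha = st$alpha,
                             min_devg = st$min_devg,
                             min_cluster = st$min_cluster,
                             method = st$method, seed = cfg$seed)
    })
    write_table(res$subtypes, file.path(out_dir, "subtypes.tsv"))
    log_lines <- c(log_lines,
                   paste("subtype_records", nrow(res$subtypes)),
                   paste("subtype_flagged", sum(res$subtypes$flagged)),
                   paste("subtype_skipped",
                         attr(res$subtypes, "n_skipped")))
  }

  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(res)
}
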