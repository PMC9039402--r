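#' Run the full regulatory-network pipeline
#'
#' Orchestrates the stages end to end from a single declarative
#' configuration: synthetic-data generation (or TSV/FASTA/BED inputs),
#' differential expression, candidate-edge construction with the negative
#' correlation filter, network topology with the degree-preserving null,
#' MCODE modules, the ceRNA network, TF-lncRNA crosstalk with PWM
#' scanning, survival analysis and infiltration correlation. Every
#' stochastic step is seeded deterministically from the single master
#' seed, so two runs with the same config produce byte-identical outputs.
#'
#' The config is a named list (or the path of a YAML file) with optional
#' sections `seed`, `stages` (subset of `de`, `network`, `modules`,
#' `cerna`, `tf`, `survival`, `association`; later stages that depend on
#' skipped ones are skipped too), `synthdata` (arguments to
#' [synth_config()]) or `inputs` (file paths), and `thresholds` (`fc`,
#' `p`, `pcc`, `fimo_p`, `hub_fraction`, `n_null`, `flank`).
#'
#' @param config Named list or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run summary (also written as
#'   `run_summary.json`). Stage tables are written as TSV, networks also
#'   as GraphML.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  th <- utils::modifyList(
    list(fc = 2, p = 0.05, pcc = 0.9, fimo_p = 1e-4,
         hub_fraction = 0.2, n_null = 1000L, flank = 2000L),
    config$thresholds %||% list())
  seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("de", "network", "modules", "cerna", "tf",
                  "survival", "association")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))

  data <- load_pipeline_inputs(config, seed)
  summary <- list(seed = seed, thresholds = th,
                  stages_requested = as.list(stages),
                  stages_run = list(), skipped = list(), outputs = list())
  wr <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    summary$outputs[[name]] <<- list(file = basename(path), rows = nrow(df))
  }
  wr_net <- function(net, name) {
    igraph::write_graph(net, file.path(out_dir, paste0(name, ".graphml")),
                        format = "graphml")
  }
  ran <- character(0)
  fail <- NULL
  run_stage <- function(name, deps, fun) {
    if (!is.null(fail)) return(invisible())
    if (!name %in% stages || !all(deps %in% ran)) {
      summary$skipped[[length(summary$skipped) + 1L]] <<- name
      return(invisible())
    }
    res <- tryCatch({ fun(); TRUE },
                    error = function(e) conditionMessage(e))
    if (isTRUE(res)) {
      ran <<- c(ran, name)
      summary$stages_run[[length(summary$stages_run) + 1L]] <<- name
    } else {
      fail <<- list(stage = name, error = res)
    }
    invisible()
  }

  env <- new.env()
  run_stage("de", character(0), function() {
    for (cl in c("miRNA", "lncRNA", "mRNA")) {
      res <- de_test(data$expr[[cl]], data$groups)
      sel <- select_de(res, th$fc, th$p)
      env[[paste0("de_", cl)]] <- res
      env[[paste0("sel_", cl)]] <- sel
      wr(res, paste0("de_", tolower(cl)))
    }
    wr(data.frame(feature_id = c(env$sel_miRNA, env$sel_lncRNA, env$sel_mRNA),
                  class = rep(c("miRNA", "lncRNA", "mRNA"),
                              c(length(env$sel_miRNA), length(env$sel_lncRNA),
                                length(env$sel_mRNA)))), "de_selected")
  })

  run_stage("network", "de", function() {
    log2e <- lapply(data$expr, log2_standardize)
    env$log2e <- log2e
    # miRNA-mRNA: curated table mapped to DE endpoints, negative correlation
    cand_m <- map_de_edges(
      data$interactions[data$interactions$target_class == "mRNA", ],
      env$sel_miRNA, env$sel_mRNA)
    w_m <- correlation_filter(cand_m, log2e$miRNA, log2e$mRNA, th$p)
    # miRNA-lncRNA: seed-match candidates, negative correlation
    cand_l <- if (!is.null(data$sequences)) {
      sc <- seed_scan_all(data$sequences$mirna[env$sel_miRNA],
                          data$sequences$lncrna[env$sel_lncRNA])
      sc$edges
    } else map_de_edges(
      data$interactions[data$interactions$target_class == "lncRNA", ],
      env$sel_miRNA, env$sel_lncRNA)
    w_l <- correlation_filter(cand_l, log2e$miRNA, log2e$lncRNA, th$p)
    classes <- c(node_class_map(rownames(data$expr$miRNA), "miRNA"),
                 node_class_map(rownames(data$expr$lncRNA), "lncRNA"),
                 node_class_map(rownames(data$expr$mRNA), "mRNA"))
    env$net_mm <- build_network(w_m, classes)
    env$net_ml <- build_network(w_l, classes)
    wr(w_m, "edges_mirna_mrna"); wr_net(env$net_mm, "net_mirna_mrna")
    wr(w_l, "edges_mirna_lncrna"); wr_net(env$net_ml, "net_mirna_lncrna")
    topo_rows <- list()
    for (nm in c("net_mm", "net_ml")) {
      g <- env[[nm]]
      if (igraph::vcount(g) >= 2L) {
        tp <- topology(g)
        nr <- if (igraph::ecount(g) >= 2L)
          degree_preserving_null(g, "clustering", th$n_null,
                                 seed = seed + 101L)
        else list(empirical_p = NA_real_, observed = tp$mean_clustering)
        topo_rows[[nm]] <- data.frame(
          network = nm, n_nodes = tp$n_nodes, n_edges = tp$n_edges,
          mean_clustering = tp$mean_clustering,
          avg_path_length = tp$avg_path_length,
          powerlaw_r2 = tp$powerlaw_r2,
          clustering_null_p = nr$empirical_p, stringsAsFactors = FALSE)
      }
    }
    env$topology <- if (length(topo_rows)) do.call(rbind, topo_rows)
      else data.frame()
    wr(env$topology, "topology")
    hubs <- tryCatch(
      select_hubs(env$net_ml, th$hub_fraction, c("miRNA", "lncRNA")),
      error = function(e) character(0))
    wr(data.frame(node = hubs), "hubs_mirna_lncrna")
  })

  run_stage("modules", "network", function() {
    mods <- find_modules(env$net_mm, mcode_params())
    df <- if (length(mods)) do.call(rbind, lapply(seq_along(mods), function(i)
      data.frame(module = i, score = mods[[i]]$score,
                 seed_node = mods[[i]]$seed_node,
                 nodes = paste(mods[[i]]$nodes, collapse = ","),
                 stringsAsFactors = FALSE)))
      else data.frame(module = integer(0), score = numeric(0),
                      seed_node = character(0), nodes = character(0))
    wr(df, "mcode_modules")
  })

  run_stage("cerna", "network", function() {
    pr <- shared_pairs(env$net_mm, env$net_ml)
    cn <- cerna_network(pr, env$log2e$lncRNA, env$log2e$mRNA, th$pcc)
    env$cerna <- cn
    wr(cn$pairs[setdiff(names(cn$pairs), "shared_mirnas")], "cerna_pairs")
    wr(cn$triplets, "cerna_triplets")
    if (igraph::vcount(cn$network) > 0L) wr_net(cn$network, "net_cerna")
  })

  run_stage("tf", "network", function() {
    pairs <- tf_lncrna_pairs(env$net_mm, env$net_ml, data$tf_list, th$p)
    wr(pairs[setdiff(names(pairs), "shared_mirnas")], "tf_lncrna_pairs")
    if (!is.null(data$pwms) && !is.null(data$promoters)) {
      enh_seqs <- NULL  # enhancer sequences supplied only via synthdata promoters here
      calls <- binding_calls(data$pwms, data$promoters,
                             p_threshold = th$fimo_p)
      wr(calls, "tf_binding")
    }
  })

  run_stage("survival", "de", function() {
    if (is.null(data$clinical)) stop("no clinical table in inputs")
    log2e <- env$log2e %||% lapply(data$expr, log2_standardize)
    all_log2 <- expression_matrix(
      rbind(unclass(log2e$miRNA), unclass(log2e$lncRNA),
            unclass(log2e$mRNA)),
      feature_class = "mRNA", scale = "log2")
    # signature = the 20 most differentially expressed features overall
    de_all <- rbind(env$de_miRNA, env$de_lncRNA, env$de_mRNA)
    de_all <- de_all[order(de_all$p_value), ]
    feats <- utils::head(de_all$feature_id, 20L)
    frm <- fit_risk_model(all_log2[, data$clinical$sample_id],
                          data$clinical, feats)
    strat <- risk_score(frm$model, all_log2[, data$clinical$sample_id])
    km <- km_logrank(data$clinical, strat$group)
    auc <- roc_auc(strat$score, data$clinical$event)
    env$survival <- list(fits = frm$fits, strat = strat, km = km, auc = auc)
    wr(frm$fits, "cox_fits")
    wr(as.data.frame(strat), "risk_groups")
    wr(km$curves, "km_curves")
    wr(data.frame(logrank_chi2 = km$logrank_chi2, logrank_p = km$logrank_p,
                  roc_auc = auc), "survival_summary")
  })

  run_stage("association", "de", function() {
    if (is.null(data$infiltration)) stop("no infiltration table in inputs")
    log2e <- env$log2e %||% lapply(data$expr, log2_standardize)
    ic <- infiltration_correlation(log2e$lncRNA, data$infiltration)
    df <- data.frame(lncrna_id = rep(rownames(ic$r), ncol(ic$r)),
                     cell_type = rep(colnames(ic$r), each = nrow(ic$r)),
                     r = as.vector(ic$r), p = as.vector(ic$p),
                     stringsAsFactors = FALSE)
    wr(df, "infiltration_correlation")
  })

  if (!is.null(fail)) summary$failure <- fail
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(out_dir, "run_summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

node_class_map <- function(ids, cls) stats::setNames(rep(cls, length(ids)), ids)

# resolve the config's data source: a synthdata block or explicit file paths
load_pipeline_inputs <- function(config, seed) {
  if (!is.null(config$synthdata)) {
    args <- config$synthdata
    if (is.null(args$seed)) args$seed <- seed
    study <- generate_study(do.call(synth_config, args))
    return(study)
  }
  inp <- config$inputs
  if (is.null(inp)) stop("config needs a 'synthdata' or 'inputs' section")
  req <- c("mirna_expr", "lncrna_expr", "mrna_expr", "groups")
  for (nm in req) if (is.null(inp[[nm]])) stop("missing input: ", nm)
  paths <- unlist(inp[vapply(inp, is.character, logical(1))])
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  groups_df <- utils::read.delim(inp$groups, stringsAsFactors = FALSE)
  list(expr = list(miRNA = read_expression_tsv(inp$mirna_expr, "miRNA"),
                   lncRNA = read_expression_tsv(inp$lncrna_expr, "lncRNA"),
                   mRNA = read_expression_tsv(inp$mrna_expr, "mRNA")),
       groups = factor(groups_df$group, levels = unique(groups_df$group)),
       clinical = if (!is.null(inp$clinical)) read_clinical_tsv(inp$clinical),
       interactions = if (!is.null(inp$interactions))
         read_interactions_tsv(inp$interactions)
       else data.frame(regulator_id = character(0), target_id = character(0),
                       target_class = character(0)),
       sequences = if (!is.null(inp$mirna_fasta) && !is.null(inp$lncrna_fasta))
         list(mirna = read_fasta(inp$mirna_fasta),
              lncrna = read_fasta(inp$lncrna_fasta)),
       pwms = NULL, promoters = NULL,
       tf_list = if (!is.null(inp$tf_list))
         utils::read.delim(inp$tf_list, stringsAsFactors = FALSE)[[1L]]
       else character(0),
       infiltration = if (!is.null(inp$infiltration)) {
         df <- utils::read.delim(inp$infiltration, row.names = 1L)
         as.matrix(df)
       })
}
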