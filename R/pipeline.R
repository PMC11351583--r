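#' Run the interactome filter cascade
#'
#' Convenience wrapper chaining [consensus_pairs()],
#' [apply_validation_filter()] (annotation only),
#' [pearson_pair_correlations()] and [select_final_pairs()], returning every
#' intermediate stage. DEMs/DEGs are the `called` features of the two DE
#' results. Stage counts are non-increasing along the cascade.
#'
#' @param de_mirna,de_mrna `de_result` data.frames from [nb_wald_test()].
#' @param mirna_counts,mrna_counts [count_matrix()] objects over the same
#'   samples.
#' @param predictions a `prediction_table`.
#' @param validated a `validation_table`.
#' @param cfg an [interactome_config()].
#' @return list with elements `consensus`, `validated`, `shared`
#'   (stage pair data.frames), `correlations`, and `edges`
#'   (the final `interactome_edges`).
#' @export
run_interactome <- function(de_mirna, de_mrna, mirna_counts, mrna_counts,
                            predictions, validated,
                            cfg = interactome_config()) {
  dems <- de_mirna$feature_id[de_mirna$called]
  degs <- de_mrna$feature_id[de_mrna$called]
  cons <- consensus_pairs(dems, degs, predictions, k = cfg$min_tools)
  annotated <- apply_validation_filter(cons, validated, require = FALSE)
  after_validation <- if (cfg$require_validated) {
    annotated[annotated$validated, , drop = FALSE]
  } else {
    annotated
  }
  rownames(after_validation) <- NULL
  after_shared <- apply_shared_target_filter(after_validation, cfg$min_sharing)
  correlations <- if (nrow(cons) > 0) {
    pearson_pair_correlations(cons, mirna_counts, mrna_counts, cfg = cfg)
  } else {
    data.frame(mirna = character(), gene = character(), r = numeric(),
               p = numeric(), n = integer(), skipped = logical())
  }
  edges <- select_final_pairs(annotated, correlations, de_mirna, de_mrna, cfg)
  list(consensus = cons, validated = after_validation, shared = after_shared,
       correlations = correlations, edges = edges)
}

pipeline_defaults <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    simulation = list(),
    inputs = list(),
    de = list(fdr = 0.05, lfc = 0.5, call_rule = "fdr", min_total_count = 10),
    interactome = list(min_tools = 3, min_sharing = 2, r_max = -0.7,
                       p_max = 0.05, require_validated = TRUE,
                       require_anticorrelation_sign = TRUE,
                       correlation_input = "log2_normalized"),
    enrichment = list(alpha = 0.05, use_q = FALSE),
    verbose = TRUE
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, differential expression (mRNA and miRNA),
#' interactome construction and over-representation analysis from one
#' configuration, writing every stage's table under `outdir` plus a
#' machine-readable `summary.json` (written last) and a timestamped
#' `run.log`. With a fixed seed, re-running overwrites the outputs with
#' byte-identical content.
#'
#' The configuration is a YAML mapping (or an equivalent R list) with keys:
#' * `mode`: `"synthetic"` (simulate inputs) or `"files"`.
#' * `seed`: integer used for all randomness (synthetic mode).
#' * `simulation`: [simulation_config()] fields (synthetic mode).
#' * `inputs`: in file mode, paths `mrna_counts`, `mirna_counts`, `samples`,
#'   `predictions`, `validation`, and optionally `gmt`.
#' * `de`, `interactome`, `enrichment`: stage options
#'   (see [de_config()], [interactome_config()], [hypergeom_ora()]).
#'
#' @param config path to a YAML file, or a named list.
#' @param outdir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @return the run summary (named list, class `run_summary`), invisibly
#'   identical to the content of `summary.json`.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(pipeline_defaults(), user)
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  unlink(logfile)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logfile, append = TRUE)
    if (isTRUE(cfg$verbose)) message(msg)
  }

  # --- stage: inputs -------------------------------------------------------
  if (identical(cfg$mode, "synthetic")) {
    log_line("stage inputs: simulating paired experiment (seed ", cfg$seed, ")")
    simcfg <- do.call(simulation_config, c(cfg$simulation, list(seed = cfg$seed)))
    sim <- simulate_paired_experiment(simcfg)
    mrna <- sim$mrna
    mirna <- sim$mirna
    samples <- sim$samples
    predictions <- simulate_prediction_db(sim$truth, simcfg)
    validated <- simulate_validation_db(sim$truth, simcfg)
    collections <- list(synthetic_sets = simulate_gene_sets(simcfg))
    write_truth_json(sim$truth, file.path(outdir, "truth.json"))
  } else {
    paths <- cfg$inputs
    need <- c("mrna_counts", "mirna_counts", "samples", "predictions", "validation")
    miss <- need[!vapply(need, function(k) !is.null(paths[[k]]) && file.exists(paths[[k]]), TRUE)]
    if (length(miss) > 0) {
      stop("missing input file(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    log_line("stage inputs: loading tables")
    mrna <- read_count_matrix(paths$mrna_counts)
    mirna <- read_count_matrix(paths$mirna_counts)
    samples <- read_sample_table(paths$samples)
    predictions <- read_pair_table(paths$predictions, "prediction")
    validated <- read_pair_table(paths$validation, "validation")
    collections <- if (!is.null(paths$gmt)) {
      setNames(list(read_gmt(paths$gmt)),
               tools::file_path_sans_ext(basename(paths$gmt)))
    } else {
      list()
    }
  }
  write_count_matrix(mrna, file.path(outdir, "mrna_counts.tsv"))
  write_count_matrix(mirna, file.path(outdir, "mirna_counts.tsv"))
  write_sample_table(samples, file.path(outdir, "samples.tsv"))
  write_pair_table(predictions, file.path(outdir, "predictions.tsv"))
  write_pair_table(validated, file.path(outdir, "validation.tsv"))

  # --- stage: differential expression -------------------------------------
  decfg <- do.call(de_config, cfg$de)
  log_line("stage de: testing ", nrow(mrna), " genes and ", nrow(mirna), " miRNAs")
  de_mrna <- nb_wald_test(mrna, samples, decfg)
  de_mirna <- nb_wald_test(mirna, samples, decfg)
  write_de_results(de_mrna, file.path(outdir, "de_mrna.tsv"))
  write_de_results(de_mirna, file.path(outdir, "de_mirna.tsv"))

  # --- stage: interactome --------------------------------------------------
  icfg <- do.call(interactome_config, cfg$interactome)
  log_line("stage interactome: filter cascade")
  stages <- run_interactome(de_mirna, de_mrna, mirna, mrna,
                            predictions, validated, icfg)
  write_stage_pairs(stages$consensus, file.path(outdir, "pairs_consensus.tsv"))
  write_stage_pairs(stages$validated, file.path(outdir, "pairs_validated.tsv"))
  write_stage_pairs(stages$shared, file.path(outdir, "pairs_shared.tsv"))
  export_network(stages$edges, file.path(outdir, "edges.tsv"), "edge_tsv")
  export_network(stages$edges, file.path(outdir, "network.graphml"), "graphml")

  # --- stage: enrichment ---------------------------------------------------
  enr_counts <- list()
  if (length(collections) > 0) {
    log_line("stage enrichment: ", length(collections), " collection(s)")
    res <- suppressWarnings(
      enrich_collection(de_mrna, collections,
                        alpha = cfg$enrichment$alpha,
                        use_q = isTRUE(cfg$enrichment$use_q))
    )
    for (nm in names(res)) {
      write_ora_results(res[[nm]], file.path(outdir, paste0("enrichment_", nm, ".tsv")))
      enr_counts[[nm]] <- sum(res[[nm]]$significant)
    }
  } else {
    log_line("stage enrichment: skipped (no gene-set collection)")
  }

  summary <- structure(list(
    tool = paste0("mirweave ", as.character(utils::packageVersion("mirweave"))),
    seed = cfg$seed,
    mode = cfg$mode,
    input_dims = list(
      mrna = list(features = nrow(mrna), samples = ncol(mrna)),
      mirna = list(features = nrow(mirna), samples = ncol(mirna)),
      n_case = sum(samples$condition == "case"),
      n_control = sum(samples$condition == "control")
    ),
    de = list(
      mrna_tested = nrow(de_mrna),
      mirna_tested = nrow(de_mirna),
      deg_up = sum(de_mrna$called & de_mrna$log2fc > 0),
      deg_down = sum(de_mrna$called & de_mrna$log2fc < 0),
      dem_up = sum(de_mirna$called & de_mirna$log2fc > 0),
      dem_down = sum(de_mirna$called & de_mirna$log2fc < 0)
    ),
    interactome = list(
      consensus = nrow(stages$consensus),
      validated = nrow(stages$validated),
      shared = nrow(stages$shared),
      final_edges = nrow(stages$edges)
    ),
    enrichment = list(significant_sets = enr_counts),
    config = cfg[c("mode", "seed", "de", "interactome", "enrichment")]
  ), class = "run_summary")
  jsonlite::write_json(unclass(summary), file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline complete: ", nrow(stages$edges), " final edge(s)")
  invisible(summary)
}

write_stage_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Verify a pipeline run directory against its summary
#'
#' Recomputes the headline counts (features tested, DEG/DEM up/down calls,
#' per-stage pair counts, final edge count) from the stage TSVs of a
#' [run_pipeline()] output directory and checks them against the stored
#' `summary.json`, raising an integrity error naming the first mismatching
#' stage.
#'
#' @param outdir a pipeline output directory.
#' @return the verified summary (named list), invisibly.
#' @export
summarize_run <- function(outdir) {
  need <- c("summary.json", "de_mrna.tsv", "de_mirna.tsv", "pairs_consensus.tsv",
            "pairs_validated.tsv", "pairs_shared.tsv", "edges.tsv")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing) > 0) {
    stop("run directory ", outdir, " is missing artifact(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  summary <- jsonlite::read_json(file.path(outdir, "summary.json"),
                                 simplifyVector = TRUE)
  de_mrna <- read_de_results(file.path(outdir, "de_mrna.tsv"))
  de_mirna <- read_de_results(file.path(outdir, "de_mirna.tsv"))
  check <- function(stage, expected, actual) {
    if (!identical(as.integer(expected), as.integer(actual))) {
      stop("integrity error in stage '", stage, "': summary says ", expected,
           " but artifacts give ", actual, call. = FALSE)
    }
  }
  check("de", summary$de$mrna_tested, nrow(de_mrna))
  check("de", summary$de$mirna_tested, nrow(de_mirna))
  check("de", summary$de$deg_up, sum(de_mrna$called & de_mrna$log2fc > 0))
  check("de", summary$de$deg_down, sum(de_mrna$called & de_mrna$log2fc < 0))
  check("de", summary$de$dem_up, sum(de_mirna$called & de_mirna$log2fc > 0))
  check("de", summary$de$dem_down, sum(de_mirna$called & de_mirna$log2fc < 0))
  nrows <- function(f) {
    length(readLines(file.path(outdir, f), warn = FALSE)) - 1L
  }
  check("interactome", summary$interactome$consensus, nrows("pairs_consensus.tsv"))
  check("interactome", summary$interactome$validated, nrows("pairs_validated.tsv"))
  check("interactome", summary$interactome$shared, nrows("pairs_shared.tsv"))
  check("interactome", summary$interactome$final_edges, nrows("edges.tsv"))
  invisible(summary)
}
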