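#' Simulation configuration
#'
#' Parameters of the paired miRNA/mRNA count simulator. Counts are drawn per
#' feature f and sample j from a negative binomial with mean
#' `mu_fj = s_j * q_f * 2^(beta_f * x_j)` (x_j = 1 for cases) and dispersion
#' `alpha` (variance `mu + alpha * mu^2`), where `s_j` is a log-normal
#' sample-specific library-size factor and `q_f` a baseline mean drawn
#' log-uniformly from `baseline_mean_log_range` (log10 scale). A subset of
#' features receives a planted log2 fold change of magnitude `de_log2fc`;
#' planted miRNA-target pairs additionally share latent log2-scale variation
#' so their profiles are negatively correlated (see
#' [simulate_paired_experiment()]).
#'
#' The default design is 8 vs 8 — large enough that planted-pair recovery is
#' adequately powered; `preset = "paper_scale"` switches to the 4-case
#' vs 3-control design of the motivating study, for illustration only.
#' Planted pairs are laid out as blocks of (by default) two distinct miRNAs
#' per target gene so that a shared-target filter requiring two miRNAs per
#' gene is satisfiable by construction.
#'
#' @param n_case,n_control samples per group (default 8 / 8).
#' @param n_genes,n_mirnas feature counts (default 2000 / 300).
#' @param baseline_mean_log_range log10 range of baseline means
#'   (default c(1.5, 3.5), i.e. means between ~30 and ~3000).
#' @param dispersion NB dispersion alpha > 0 (default 0.05).
#' @param size_factor_log_sd sd of log size factors (default 0.15).
#' @param n_de_genes,n_de_mirnas planted DE features (default 60 / 8).
#' @param de_log2fc magnitude of planted log2 fold changes (default 2).
#' @param n_true_pairs planted regulatory pairs (default 24, i.e. 12 genes
#'   with 2 miRNA partners each).
#' @param pair_correlation target latent log-scale correlation, in (-1, 0)
#'   (default -0.9).
#' @param latent_log2_sd sd of the shared latent log2 variation of planted
#'   pair members (default 0.4).
#' @param tool_names prediction-tool vocabulary (8 generic names).
#' @param tool_sensitivity per-tool probability of listing a true pair
#'   (default 0.95).
#' @param tool_fp_rate per-tool probability of listing any non-true
#'   (miRNA, gene) combination (default 0.02).
#' @param validated_fraction probability a true pair appears in the
#'   validation table (default 1).
#' @param validation_contamination probability a non-true candidate
#'   combination appears in the validation table (default 0).
#' @param seed integer RNG seed; each generator derives its own stream from
#'   it with a fixed offset, so calls do not perturb one another.
#' @param preset `"default"` or `"paper_scale"` (4 vs 3).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 8, n_control = 8,
                              n_genes = 2000, n_mirnas = 300,
                              baseline_mean_log_range = c(1.5, 3.5),
                              dispersion = 0.05,
                              size_factor_log_sd = 0.15,
                              n_de_genes = 60, n_de_mirnas = 8,
                              de_log2fc = 2,
                              n_true_pairs = 24,
                              pair_correlation = -0.9,
                              latent_log2_sd = 0.4,
                              tool_names = paste0("tool_", LETTERS[1:8]),
                              tool_sensitivity = 0.95,
                              tool_fp_rate = 0.02,
                              validated_fraction = 1,
                              validation_contamination = 0,
                              seed = 1L,
                              preset = c("default", "paper_scale")) {
  preset <- match.arg(preset)
  if (preset == "paper_scale") {
    if (missing(n_case)) n_case <- 4
    if (missing(n_control)) n_control <- 3
  }
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              baseline_mean_log_range = as.numeric(baseline_mean_log_range),
              dispersion = dispersion,
              size_factor_log_sd = size_factor_log_sd,
              n_de_genes = as.integer(n_de_genes),
              n_de_mirnas = as.integer(n_de_mirnas),
              de_log2fc = de_log2fc,
              n_true_pairs = as.integer(n_true_pairs),
              pair_correlation = pair_correlation,
              latent_log2_sd = latent_log2_sd,
              tool_names = as.character(tool_names),
              tool_sensitivity = tool_sensitivity,
              tool_fp_rate = tool_fp_rate,
              validated_fraction = validated_fraction,
              validation_contamination = validation_contamination,
              seed = as.integer(seed), preset = preset)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_case < 1 || n_control < 1) stop("need at least one sample per group", call. = FALSE)
    if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
    if (size_factor_log_sd < 0) stop("size_factor_log_sd must be >= 0", call. = FALSE)
    if (length(baseline_mean_log_range) != 2 ||
        diff(baseline_mean_log_range) < 0) {
      stop("baseline_mean_log_range must be an increasing pair", call. = FALSE)
    }
    probs <- c(tool_sensitivity, tool_fp_rate, validated_fraction,
               validation_contamination)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
    if (pair_correlation <= -1 || pair_correlation >= 0) {
      stop("pair_correlation must lie in (-1, 0)", call. = FALSE)
    }
    if (n_de_genes > n_genes || n_de_mirnas > n_mirnas) {
      stop("more planted DE features than features", call. = FALSE)
    }
    if (n_true_pairs > n_de_mirnas * n_de_genes) {
      stop("infeasible config: n_true_pairs exceeds n_de_mirnas * n_de_genes",
           call. = FALSE)
    }
    if (n_true_pairs > 0 && ceiling(n_true_pairs / 2) > n_de_genes) {
      stop("infeasible config: not enough DE genes for the planted pair blocks",
           call. = FALSE)
    }
    if (n_true_pairs > 0 && n_de_mirnas < 1) {
      stop("infeasible config: planted pairs require DE miRNAs", call. = FALSE)
    }
    if (de_log2fc <= 0) stop("de_log2fc must be > 0", call. = FALSE)
    if (latent_log2_sd < 0) stop("latent_log2_sd must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

#' Simulate a paired miRNA/mRNA experiment with ground truth
#'
#' Draws mRNA and miRNA count matrices under the model of
#' [simulation_config()]. Differentially expressed miRNAs receive balanced
#' up/down signs; planted pairs are built as blocks of two same-signed
#' miRNAs per target gene (one, if only one miRNA of a sign class exists),
#' with the gene's planted log2FC of the opposite sign. Pair members share
#' latent log2-scale variation: each planted miRNA carries an i.i.d. standard
#' normal latent deviation per sample (scaled by `latent_log2_sd`), and each
#' planted gene's deviation is a linear mix of its partners' deviations with
#' mixing weight chosen so the within-condition latent correlation of each
#' pair equals `pair_correlation` (capped at `-1/sqrt(#partners)` when the
#' gene has several independent partners). Observed count correlations are
#' attenuated by counting noise and reinforced, across the pooled groups, by
#' the opposite-signed condition effects.
#'
#' Identical configurations (including `seed`) yield identical output.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `mrna`, `mirna` ([count_matrix()]), `samples`
#'   ([sample_table()]), and `truth` (class `synthetic_truth`: named log2FC
#'   vectors `de_genes` and `de_mirnas`, data.frame `true_pairs` with
#'   columns `mirna`, `gene`, `target_correlation`, the `size_factors`
#'   used, and the `baselines` (per-feature baseline means `q_f`)).
#' @export
simulate_paired_experiment <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_control
  samp_ids <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  samples <- sample_table(samp_ids, rep(c("case", "control"),
                                        c(cfg$n_case, cfg$n_control)))
  x <- as.numeric(samples$condition == "case")
  s <- exp(rnorm(n, 0, cfg$size_factor_log_sd))

  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("hsa-miR-sim-%03d", seq_len(cfg$n_mirnas))

  # planted DE miRNAs, balanced signs
  de_mirnas <- sort(sample(mirna_ids, cfg$n_de_mirnas))
  m_signs <- setNames(sample(rep(c(1, -1), length.out = cfg$n_de_mirnas)),
                      de_mirnas)
  de_genes <- sort(sample(gene_ids, cfg$n_de_genes))

  # pair blocks: two same-signed miRNA partners per target gene when possible
  pairs <- plant_pair_blocks(de_mirnas, m_signs, de_genes, cfg$n_true_pairs,
                             cfg$pair_correlation)
  pair_genes <- unique(pairs$gene)
  g_signs <- setNames(sample(rep(c(1, -1), length.out = cfg$n_de_genes)),
                      de_genes)
  if (nrow(pairs) > 0) {
    # gene sign opposite its partners' (partners share one sign by design)
    first_partner <- vapply(split(pairs$mirna, pairs$gene), `[[`, "", 1L)
    g_signs[names(first_partner)] <- -m_signs[first_partner]
  }

  beta_g <- setNames(rep(0, cfg$n_genes), gene_ids)
  beta_g[de_genes] <- cfg$de_log2fc * g_signs[de_genes]
  beta_m <- setNames(rep(0, cfg$n_mirnas), mirna_ids)
  beta_m[de_mirnas] <- cfg$de_log2fc * m_signs[de_mirnas]

  # latent shared variation for planted pair members
  lat_g <- matrix(0, cfg$n_genes, n, dimnames = list(gene_ids, samp_ids))
  lat_m <- matrix(0, cfg$n_mirnas, n, dimnames = list(mirna_ids, samp_ids))
  if (nrow(pairs) > 0 && cfg$latent_log2_sd > 0) {
    pmirnas <- unique(pairs$mirna)
    D <- matrix(rnorm(length(pmirnas) * n), length(pmirnas), n,
                dimnames = list(pmirnas, samp_ids))
    lat_m[pmirnas, ] <- cfg$latent_log2_sd * D
    for (g in pair_genes) {
      partners <- pairs$mirna[pairs$gene == g]
      mix <- colSums(D[partners, , drop = FALSE]) / sqrt(length(partners))
      cmix <- min(1, abs(cfg$pair_correlation) * sqrt(length(partners)))
      dev <- -(cmix * mix + sqrt(max(0, 1 - cmix^2)) * rnorm(n))
      lat_g[g, ] <- cfg$latent_log2_sd * dev
    }
  }

  mrna <- draw_nb_counts(gene_ids, samp_ids, cfg, s, x, beta_g, lat_g)
  mirna <- draw_nb_counts(mirna_ids, samp_ids, cfg, s, x, beta_m, lat_m)

  truth <- structure(list(
    de_genes = beta_g[de_genes],
    de_mirnas = beta_m[de_mirnas],
    true_pairs = pairs,
    size_factors = setNames(s, samp_ids),
    baselines = list(genes = mrna$q, mirnas = mirna$q)
  ), class = "synthetic_truth")
  list(mrna = mrna$counts, mirna = mirna$counts, samples = samples,
       truth = truth)
}

plant_pair_blocks <- function(de_mirnas, m_signs, de_genes, n_true_pairs,
                              pair_correlation = -0.9) {
  pairs <- data.frame(mirna = character(), gene = character(),
                      target_correlation = numeric())
  if (n_true_pairs == 0) return(pairs)
  pools <- list(up = names(m_signs)[m_signs > 0],
                dn = names(m_signs)[m_signs < 0])
  pools <- pools[lengths(pools) > 0]
  if (length(pools) == 0) {
    stop("infeasible config: no DE miRNA available for pairing", call. = FALSE)
  }
  gene_pool <- sample(de_genes)
  gi <- 1
  left <- n_true_pairs
  blocks <- list()
  while (left > 0) {
    pool <- pools[[sample(length(pools), 1)]]
    k <- min(2, length(pool), left)
    partners <- if (length(pool) == 1) pool else sample(pool, k)
    g <- gene_pool[gi]
    gi <- gi + 1
    np <- length(partners)
    achieved <- -min(1, abs(pair_correlation) * sqrt(np)) / sqrt(np)
    blocks[[length(blocks) + 1]] <- data.frame(mirna = partners, gene = g,
                                               target_correlation = achieved)
    left <- left - np
  }
  pairs <- do.call(rbind, blocks)
  pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

draw_nb_counts <- function(ids, samp_ids, cfg, s, x, beta, latent) {
  nf <- length(ids)
  n <- length(samp_ids)
  q <- 10^runif(nf, cfg$baseline_mean_log_range[1], cfg$baseline_mean_log_range[2])
  log2mu <- log2(q) + outer(beta[ids], x) + latent[ids, , drop = FALSE]
  mu <- sweep(2^log2mu, 2, s, "*")
  counts <- matrix(rnbinom(nf * n, mu = mu, size = 1 / cfg$dispersion),
                   nf, n, dimnames = list(ids, samp_ids))
  list(counts = count_matrix(counts), q = setNames(q, ids))
}

#' Simulate a prediction database
#'
#' Each true pair is listed by each tool independently with probability
#' `tool_sensitivity`; every other (miRNA, gene) combination of the
#' simulated feature universe is listed by each tool independently with
#' probability `tool_fp_rate`. Uses its own RNG stream (`cfg$seed + 1`).
#'
#' @param truth `synthetic_truth` from [simulate_paired_experiment()].
#' @param cfg the same [simulation_config()].
#' @param mirna_ids,gene_ids the feature universes (default: regenerated
#'   from `cfg` dimensions).
#' @return a `prediction_table` (see [read_pair_table()]).
#' @export
simulate_prediction_db <- function(truth, cfg,
                                   mirna_ids = sprintf("hsa-miR-sim-%03d", seq_len(cfg$n_mirnas)),
                                   gene_ids = sprintf("gene_%04d", seq_len(cfg$n_genes))) {
  set.seed(cfg$seed + 1L)
  tools <- cfg$tool_names
  tp <- truth$true_pairs
  recs <- list()
  if (nrow(tp) > 0 && cfg$tool_sensitivity > 0) {
    hit <- matrix(rbinom(nrow(tp) * length(tools), 1, cfg$tool_sensitivity),
                  nrow(tp), length(tools)) == 1
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      recs[[1]] <- data.frame(mirna = tp$mirna[idx[, 1]],
                              gene = tp$gene[idx[, 1]],
                              tool = tools[idx[, 2]])
    }
  }
  if (cfg$tool_fp_rate > 0) {
    ncomb <- length(mirna_ids) * length(gene_ids)
    truekey <- paste(tp$mirna, tp$gene, sep = "\r")
    for (t in seq_along(tools)) {
      sel <- which(rbinom(ncomb, 1, cfg$tool_fp_rate) == 1)
      if (length(sel) == 0) next
      mi <- ((sel - 1) %% length(mirna_ids)) + 1
      gi <- ((sel - 1) %/% length(mirna_ids)) + 1
      d <- data.frame(mirna = mirna_ids[mi], gene = gene_ids[gi],
                      tool = tools[t])
      d <- d[!paste(d$mirna, d$gene, sep = "\r") %in% truekey, , drop = FALSE]
      recs[[length(recs) + 1]] <- d
    }
  }
  if (length(recs) == 0) {
    return(pair_table(character(), character(), character(), kind = "prediction"))
  }
  all <- do.call(rbind, recs)
  all <- all[order(all$mirna, all$gene, all$tool), , drop = FALSE]
  pair_table(all$mirna, all$gene, all$tool, kind = "prediction")
}

#' Simulate a validation database
#'
#' Each true pair is included with probability `validated_fraction` under a
#' random source label; non-true combinations are included with probability
#' `validation_contamination` (0 by default). Uses its own RNG stream
#' (`cfg$seed + 2`).
#'
#' @inheritParams simulate_prediction_db
#' @return a `validation_table` (see [read_pair_table()]).
#' @export
simulate_validation_db <- function(truth, cfg,
                                   mirna_ids = sprintf("hsa-miR-sim-%03d", seq_len(cfg$n_mirnas)),
                                   gene_ids = sprintf("gene_%04d", seq_len(cfg$n_genes))) {
  set.seed(cfg$seed + 2L)
  sources <- c("synthetic_db_A", "synthetic_db_B")
  tp <- truth$true_pairs
  recs <- list()
  if (nrow(tp) > 0 && cfg$validated_fraction > 0) {
    keep <- rbinom(nrow(tp), 1, cfg$validated_fraction) == 1
    if (any(keep)) {
      recs[[1]] <- data.frame(mirna = tp$mirna[keep], gene = tp$gene[keep],
                              source = sample(sources, sum(keep), replace = TRUE))
    }
  }
  if (cfg$validation_contamination > 0) {
    ncomb <- length(mirna_ids) * length(gene_ids)
    sel <- which(rbinom(ncomb, 1, cfg$validation_contamination) == 1)
    if (length(sel) > 0) {
      mi <- ((sel - 1) %% length(mirna_ids)) + 1
      gi <- ((sel - 1) %/% length(mirna_ids)) + 1
      d <- data.frame(mirna = mirna_ids[mi], gene = gene_ids[gi],
                      source = sample(sources, length(sel), replace = TRUE))
      truekey <- paste(tp$mirna, tp$gene, sep = "\r")
      d <- d[!paste(d$mirna, d$gene, sep = "\r") %in% truekey, , drop = FALSE]
      recs[[length(recs) + 1]] <- d
    }
  }
  if (length(recs) == 0) {
    return(pair_table(character(), character(), character(), kind = "validation"))
  }
  all <- do.call(rbind, recs)
  all <- all[order(all$mirna, all$gene, all$source), , drop = FALSE]
  pair_table(all$mirna, all$gene, all$source, kind = "validation")
}

#' Simulate a gene-set collection over the simulated gene universe
#'
#' Random sets drawn without replacement from the gene universe; used by the
#' pipeline's synthetic mode so the enrichment stage has an input. Uses its
#' own RNG stream (`cfg$seed + 3`).
#'
#' @param cfg a [simulation_config()].
#' @param n_sets number of sets (default 20).
#' @param set_size members per set (default 50).
#' @param gene_ids the gene universe.
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(cfg, n_sets = 20, set_size = 50,
                               gene_ids = sprintf("gene_%04d", seq_len(cfg$n_genes))) {
  set.seed(cfg$seed + 3L)
  sets <- lapply(seq_len(n_sets), function(i) sample(gene_ids, set_size))
  names(sets) <- sprintf("set_%02d", seq_len(n_sets))
  gene_set_collection(sets, universe = gene_ids)
}

#' Write synthetic truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    de_genes = as.list(truth$de_genes),
    de_mirnas = as.list(truth$de_mirnas),
    true_pairs = truth$true_pairs,
    size_factors = as.list(truth$size_factors)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)  # baselines omitted: bulky and reproducible from the seed
  invisible(path)
}
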