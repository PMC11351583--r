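#' Interactome filter configuration
#'
#' Controls the candidate-pair filter cascade: prediction-tool consensus
#' (`min_tools`), experimental validation (`require_validated`), shared
#' targets (`min_sharing`: the gene must be paired with at least this many
#' distinct miRNAs in the surviving candidate set), and the Pearson
#' anti-correlation screen (`r_max`, `p_max`; both must hold). With
#' `require_anticorrelation_sign`, the miRNA and gene must additionally have
#' opposite differential-expression log2FC signs.
#'
#' @param min_tools minimum distinct prediction tools per pair (default 3).
#' @param min_sharing minimum distinct miRNAs per retained gene (default 2).
#' @param r_max Pearson threshold, pairs kept when `r < r_max` (default -0.7).
#' @param p_max correlation p-value threshold (default 0.05).
#' @param require_validated drop pairs absent from the validation table
#'   (default TRUE).
#' @param require_anticorrelation_sign require opposite DE signs
#'   (default TRUE).
#' @param correlation_input values correlated across samples:
#'   `"log2_normalized"` (log2(count/s + 1), default), `"normalized"`, or
#'   `"raw"`.
#' @return list of class `interactome_config`.
#' @export
interactome_config <- function(min_tools = 3, min_sharing = 2, r_max = -0.7,
                               p_max = 0.05, require_validated = TRUE,
                               require_anticorrelation_sign = TRUE,
                               correlation_input = c("log2_normalized",
                                                     "normalized", "raw")) {
  correlation_input <- match.arg(correlation_input)
  stopifnot(min_tools >= 1, min_sharing >= 1,
            r_max > -1, r_max < 0, p_max > 0, p_max < 1)
  structure(list(min_tools = min_tools, min_sharing = min_sharing,
                 r_max = r_max, p_max = p_max,
                 require_validated = isTRUE(require_validated),
                 require_anticorrelation_sign = isTRUE(require_anticorrelation_sign),
                 correlation_input = correlation_input),
            class = "interactome_config")
}

#' Prediction-consensus candidate pairs
#'
#' Restricts a prediction table to (DEM x DEG) pairs and keeps those
#' predicted by at least `k` distinct tools.
#'
#' @param dems character vector of differentially expressed miRNA ids.
#' @param degs character vector of differentially expressed gene ids.
#' @param predictions a `prediction_table` (see [read_pair_table()]).
#' @param k minimum number of distinct tools.
#' @param tool_vocabulary optional declared tool names; predictions under
#'   other tool labels trigger a warning (not an error).
#' @return data.frame with columns `mirna`, `gene`, `tool_count`, `tools`
#'   (comma-joined, sorted), sorted by (mirna, gene).
#' @export
consensus_pairs <- function(dems, degs, predictions, k = 3,
                            tool_vocabulary = NULL) {
  stopifnot(k >= 1)
  df <- as.data.frame(predictions)
  if (!is.null(tool_vocabulary)) {
    unknown <- setdiff(unique(df$tool), tool_vocabulary)
    if (length(unknown) > 0) {
      warning("prediction table contains undeclared tool(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  df <- df[df$mirna %in% dems & df$gene %in% degs, , drop = FALSE]
  if (nrow(df) == 0) return(empty_pairs())
  key <- paste(df$mirna, df$gene, sep = "\r")
  tools_by_pair <- lapply(split(df$tool, key), function(t) sort(unique(t)))
  counts <- lengths(tools_by_pair)
  keep <- counts >= k
  if (!any(keep)) return(empty_pairs())
  ids <- strsplit(names(tools_by_pair)[keep], "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(ids, `[[`, "", 1L),
                    gene = vapply(ids, `[[`, "", 2L),
                    tool_count = unname(counts[keep]),
                    tools = vapply(tools_by_pair[keep], paste, "", collapse = ","),
                    row.names = NULL)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(mirna = character(), gene = character(),
             tool_count = integer(), tools = character())
}

#' Pearson correlations for candidate miRNA-gene pairs
#'
#' For each candidate pair, computes the Pearson correlation `r` between the
#' configured transform of the miRNA's and the gene's counts across all
#' shared samples (cases and controls pooled), and the two-sided p-value via
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom. Pairs
#' whose miRNA or gene is missing from its matrix are reported with
#' `skipped = TRUE`; zero-variance vectors yield `r = NA` and are excluded
#' downstream.
#'
#' @param pairs data.frame with columns `mirna`, `gene`.
#' @param mirna_counts,mrna_counts [count_matrix()] objects over an identical
#'   sample set (order reconciled by id; n >= 3).
#' @param s_mirna,s_mrna size factors (default: recomputed per matrix).
#' @param cfg an [interactome_config()] (for `correlation_input`).
#' @return data.frame with columns `mirna`, `gene`, `r`, `p`, `n`, `skipped`.
#' @export
pearson_pair_correlations <- function(pairs, mirna_counts, mrna_counts,
                                      s_mirna = size_factors(mirna_counts),
                                      s_mrna = size_factors(mrna_counts),
                                      cfg = interactome_config()) {
  shared <- colnames(mirna_counts)
  if (!setequal(shared, colnames(mrna_counts))) {
    stop("miRNA and mRNA matrices must cover the same samples", call. = FALSE)
  }
  if (length(shared) < 3) stop("need at least 3 shared samples", call. = FALSE)
  xm <- correlation_transform(mirna_counts[, shared, drop = FALSE], s_mirna[shared], cfg)
  xg <- correlation_transform(mrna_counts[, shared, drop = FALSE], s_mrna[shared], cfg)
  n <- length(shared)
  out <- data.frame(mirna = as.character(pairs$mirna),
                    gene = as.character(pairs$gene),
                    r = NA_real_, p = NA_real_, n = n,
                    skipped = FALSE)
  for (i in seq_len(nrow(out))) {
    if (!out$mirna[i] %in% rownames(xm) || !out$gene[i] %in% rownames(xg)) {
      out$skipped[i] <- TRUE
      next
    }
    rp <- pearson_r_p(xm[out$mirna[i], ], xg[out$gene[i], ])
    out$r[i] <- rp[1]
    out$p[i] <- rp[2]
  }
  nbad <- sum(!out$skipped & is.na(out$r))
  if (nbad > 0) message(nbad, " pair(s) with zero-variance profiles: r undefined")
  out
}

correlation_transform <- function(counts, s, cfg) {
  m <- unclass(counts) + 0.0
  switch(cfg$correlation_input,
         raw = m,
         normalized = sweep(m, 2, s, "/"),
         log2_normalized = log2(sweep(m, 2, s, "/") + 1))
}

# Pearson r and its two-sided t-test p; returns c(r, p). NA r for
# zero-variance input; r clamped to [-1, 1] against rounding.
pearson_r_p <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0) return(c(NA_real_, NA_real_))
  r <- max(-1, min(1, sum(xc * yc) / denom))
  if (abs(r) == 1) return(c(r, 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r, 2 * pt(-abs(tt), df = n - 2))
}

#' Experimental-validation filter
#'
#' Annotates each candidate pair with whether it appears in a validation
#' table (under any source) and with the comma-joined sources; when
#' `require = TRUE`, unvalidated pairs are dropped.
#'
#' @param pairs data.frame with columns `mirna`, `gene`.
#' @param validated a `validation_table` (see [read_pair_table()]).
#' @param require drop unvalidated pairs (default TRUE).
#' @return input data.frame plus columns `validated`, `sources`.
#' @export
apply_validation_filter <- function(pairs, validated, require = TRUE) {
  vdf <- as.data.frame(validated)
  key <- paste(pairs$mirna, pairs$gene, sep = "\r")
  vkey <- paste(vdf$mirna, vdf$gene, sep = "\r")
  src <- vapply(key, function(k) {
    paste(sort(unique(vdf$source[vkey == k])), collapse = ",")
  }, "", USE.NAMES = FALSE)
  pairs$validated <- key %in% vkey
  pairs$sources <- src
  if (require) pairs <- pairs[pairs$validated, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Shared-target filter
#'
#' Keeps pairs whose gene is paired with at least `m` distinct miRNAs within
#' the current (already filtered) pair list.
#'
#' @param pairs data.frame with columns `mirna`, `gene`.
#' @param m minimum number of distinct miRNAs per gene (default 2).
#' @return filtered data.frame.
#' @export
apply_shared_target_filter <- function(pairs, m = 2) {
  stopifnot(m >= 1)
  if (nrow(pairs) == 0) return(pairs)
  n_mirnas <- vapply(split(pairs$mirna, pairs$gene),
                     function(x) length(unique(x)), 0L)
  keep <- pairs$gene %in% names(n_mirnas)[n_mirnas >= m]
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Final interactome edge selection
#'
#' Applies the filter cascade, in order: consensus (assumed already applied
#' to `pairs` via [consensus_pairs()]), validation (if
#' `cfg$require_validated`; `pairs` must carry `validated`/`sources` columns
#' from [apply_validation_filter()] with `require = FALSE`), shared-target
#' (recomputed on the survivors), then the anti-correlation screen
#' (`r < cfg$r_max` and `p < cfg$p_max`; undefined correlations drop the
#' pair). With `cfg$require_anticorrelation_sign`, the miRNA's and gene's DE
#' log2 fold changes must have opposite signs.
#'
#' @param pairs consensus candidate pairs (columns `mirna`, `gene`,
#'   `tool_count`, `tools`, and optionally `validated`, `sources`).
#' @param correlations output of [pearson_pair_correlations()] covering
#'   `pairs`.
#' @param de_mirna,de_mrna `de_result` data.frames (for DE directions).
#' @param cfg an [interactome_config()].
#' @return data.frame of class `interactome_edges` with columns `mirna`,
#'   `gene`, `tool_count`, `tools`, `validated`, `sources`, `r`, `p`, `n`,
#'   `mirna_log2fc`, `gene_log2fc`, sorted by (r ascending, mirna, gene).
#' @export
select_final_pairs <- function(pairs, correlations, de_mirna, de_mrna,
                               cfg = interactome_config()) {
  if (nrow(pairs) == 0) return(empty_edges())
  if (!"validated" %in% names(pairs)) {
    pairs$validated <- NA
    pairs$sources <- ""
  }
  if (cfg$require_validated) {
    pairs <- pairs[pairs$validated %in% TRUE, , drop = FALSE]
  }
  pairs <- apply_shared_target_filter(pairs, cfg$min_sharing)
  if (nrow(pairs) == 0) return(empty_edges())

  key <- paste(pairs$mirna, pairs$gene, sep = "\r")
  ckey <- paste(correlations$mirna, correlations$gene, sep = "\r")
  idx <- match(key, ckey)
  pairs$r <- correlations$r[idx]
  pairs$p <- correlations$p[idx]
  pairs$n <- correlations$n[idx]
  ok <- !is.na(pairs$r) & pairs$r < cfg$r_max & pairs$p < cfg$p_max
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_edges())

  pairs$mirna_log2fc <- de_mirna$log2fc[match(pairs$mirna, de_mirna$feature_id)]
  pairs$gene_log2fc <- de_mrna$log2fc[match(pairs$gene, de_mrna$feature_id)]
  if (cfg$require_anticorrelation_sign) {
    opp <- sign(pairs$mirna_log2fc) * sign(pairs$gene_log2fc) < 0
    pairs <- pairs[opp %in% TRUE, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(empty_edges())
  pairs <- pairs[order(pairs$r, pairs$mirna, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("interactome_edges", class(pairs))
  pairs
}

empty_edges <- function() {
  out <- data.frame(mirna = character(), gene = character(),
                    tool_count = integer(), tools = character(),
                    validated = logical(), sources = character(),
                    r = numeric(), p = numeric(), n = integer(),
                    mirna_log2fc = numeric(), gene_log2fc = numeric())
  class(out) <- c("interactome_edges", class(out))
  out
}

#' Export the interactome as a bipartite network
#'
#' Writes the edge list either as GraphML (via igraph; node attribute `type`
#' is `"mirna"` or `"gene"`, edge attributes `tool_count`, `validated`, `r`,
#' `p`) or as a flat TSV preserving all evidence columns. Node and edge
#' ordering is deterministic (miRNAs sorted, then genes; edges as sorted by
#' [select_final_pairs()]).
#'
#' @param edges an `interactome_edges` data.frame (columns `mirna`, `gene`
#'   at minimum).
#' @param path output file path.
#' @param format `"edge_tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  df <- as.data.frame(edges)
  if (format == "edge_tsv") {
    out <- df
    for (col in intersect(c("r", "p", "mirna_log2fc", "gene_log2fc"), names(out))) {
      out[[col]] <- format_num(out[[col]])
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  mirnas <- sort(unique(df$mirna))
  genes <- sort(unique(df$gene))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(mirnas) + length(genes),
                            name = c(mirnas, genes),
                            type = c(rep("mirna", length(mirnas)),
                                     rep("gene", length(genes))))
  if (nrow(df) > 0) {
    ev <- rbind(match(df$mirna, c(mirnas, genes)),
                match(df$gene, c(mirnas, genes)))
    g <- igraph::add_edges(g, as.vector(ev))
    for (attr in intersect(c("tool_count", "validated", "r", "p"), names(df))) {
      g <- igraph::set_edge_attr(g, attr, value = df[[attr]])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_network
#' @export
read_network_edges <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  for (col in intersect(c("tool_count", "n"), names(df))) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(c("r", "p", "mirna_log2fc", "gene_log2fc"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("validated" %in% names(df)) df$validated <- as.logical(df$validated)
  if ("sources" %in% names(df)) df$sources[is.na(df$sources)] <- ""
  class(df) <- c("interactome_edges", class(df))
  df
}
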