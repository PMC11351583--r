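#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the overlap `k` between the selected list
#' (size `n` within the universe) and the set (size `K` within the universe,
#' universe size `N`) is larger than expected under uniform sampling:
#' `p = P(X >= k)` for X hypergeometric. Selected genes outside the universe
#' are dropped (with a message giving the count); set members outside the
#' universe do not count towards `K`. Adjusted p-values are BH over the
#' collection. Significance defaults to the raw-p rule `p < alpha`
#' (the usual convention for this analysis even though it is
#' anticonservative); set `use_q = TRUE` for the BH rule.
#'
#' @param selected character vector of selected (e.g. DE) gene ids.
#' @param collection a [gene_set_collection()].
#' @param alpha significance threshold (default 0.05).
#' @param use_q if `TRUE`, flag significance on `q` instead of raw `p`.
#' @return data.frame of class `ora_result` with columns `set_name`, `N`,
#'   `K`, `n`, `k`, `ratio` (fold enrichment, (k/n)/(K/N)), `p`, `q`,
#'   `significant`, sorted by p ascending with ties broken by set name.
#' @examples
#' coll <- gene_set_collection(list(S1 = c("A", "B", "C")),
#'                             universe = LETTERS[1:10])
#' hypergeom_ora(c("A", "B"), coll)
#' @export
hypergeom_ora <- function(selected, collection, alpha = 0.05, use_q = FALSE) {
  if (!inherits(collection, "gene_set_collection")) {
    stop("collection must be a gene_set_collection", call. = FALSE)
  }
  universe <- collection$universe
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  selected <- unique(as.character(selected))
  dropped <- sum(!selected %in% universe)
  if (dropped > 0) {
    message(dropped, " selected feature(s) outside the universe dropped")
  }
  selected <- selected[selected %in% universe]
  if (length(selected) == 0) stop("no selected feature lies in the universe", call. = FALSE)
  N <- length(universe)
  n <- length(selected)
  K <- vapply(collection$sets, function(s) sum(unique(s) %in% universe), 0L)
  k <- vapply(collection$sets, function(s) sum(selected %in% s), 0L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(set_name = names(collection$sets),
                    N = N, K = K, n = n, k = k,
                    ratio = ifelse(K > 0, (k / n) / (K / N), NA_real_),
                    p = p, q = q,
                    significant = if (use_q) q < alpha else p < alpha,
                    row.names = NULL)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", class(out))
  out
}

#' Over-representation analysis of DE calls against several collections
#'
#' Runs [hypergeom_ora()] on the features with `called = TRUE` of a
#' differential-expression result, against each supplied collection. By
#' default the background universe of each collection is replaced by the set
#' of all features that were tested (the post-filter DE input), the standard
#' background correction; pass `universe_from_de = FALSE` to keep each
#' collection's own universe. An empty DE call set yields empty results with
#' a warning.
#'
#' @param de a `de_result` data.frame from [nb_wald_test()].
#' @param collections named list of [gene_set_collection()] objects.
#' @param alpha,use_q significance rule, as in [hypergeom_ora()].
#' @param universe_from_de use the tested features as background (default).
#' @return named list of `ora_result` data.frames.
#' @export
enrich_collection <- function(de, collections, alpha = 0.05, use_q = FALSE,
                              universe_from_de = TRUE) {
  selected <- de$feature_id[de$called]
  if (length(selected) == 0) {
    warning("no feature called differentially expressed; returning empty results",
            call. = FALSE)
    return(lapply(collections, function(coll) {
      out <- data.frame(set_name = character(), N = integer(), K = integer(),
                        n = integer(), k = integer(), ratio = numeric(),
                        p = numeric(), q = numeric(), significant = logical())
      class(out) <- c("ora_result", class(out))
      out
    }))
  }
  lapply(collections, function(coll) {
    if (universe_from_de) {
      coll <- gene_set_collection(coll$sets, coll$descriptions,
                                  universe = de$feature_id)
    }
    hypergeom_ora(selected, coll, alpha = alpha, use_q = use_q)
  })
}

#' @rdname hypergeom_ora
#' @param x an `ora_result`.
#' @param path TSV path.
#' @export
write_ora_results <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("ratio", "p", "q")) df[[col]] <- format_num(df[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
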