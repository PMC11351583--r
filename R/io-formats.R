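#' Construct a count matrix
#'
#' A `count_matrix` is an integer feature-by-sample matrix with unique row
#' (feature) and column (sample) identifiers, the common currency of all
#' differential-expression and correlation functions in this package.
#'
#' @param counts numeric matrix of non-negative integers (features x samples).
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an integer matrix of class `count_matrix` with dimnames set.
#' @examples
#' m <- count_matrix(matrix(0:5, 3, 2), c("g1", "g2", "g3"), c("s1", "s2"))
#' feature_ids(m)
#' @export
count_matrix <- function(counts, feature_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("count_matrix requires feature and sample identifiers", call. = FALSE)
  }
  if (length(feature_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop("identifier length does not match matrix shape", call. = FALSE)
  }
  feature_ids <- trimws(as.character(feature_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at feature '%s', sample '%s': %s",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(feature_ids, sample_ids)
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname count_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' Read a count matrix from TSV
#'
#' Expects a header row of sample identifiers; the first column holds feature
#' identifiers. Cells must be non-negative integers (the canonical dialect is
#' UTF-8, tab-separated, `.` decimal, no thousands separators). Row and column
#' order are preserved from the file.
#'
#' @param path path to a TSV file.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("count matrix file needs a feature column and at least one sample: ", path,
                         call. = FALSE)
  ids <- trimws(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric count at feature '%s', column '%s' in %s",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]], path), call. = FALSE)
  }
  count_matrix(num, feature_ids = ids, sample_ids = colnames(vals))
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]; writing then reading reproduces the file
#' byte-for-byte for the canonical dialect.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample metadata table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param condition character/factor with levels `control` and `case`
#'   (`"ACM"` is accepted as an alias for `case`).
#' @return data.frame of class `sample_table` with columns `sample_id`,
#'   `condition` (factor, levels control then case).
#' @export
sample_table <- function(sample_id, condition) {
  sample_id <- trimws(as.character(sample_id))
  condition <- as.character(condition)
  condition[condition %in% c("ACM", "acm")] <- "case"
  if (!all(condition %in% c("case", "control"))) {
    stop("condition must be 'case' ('ACM') or 'control'", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in sample table", call. = FALSE)
  out <- data.frame(sample_id = sample_id,
                    condition = factor(condition, levels = c("control", "case")))
  class(out) <- c("sample_table", class(out))
  out
}

#' Read/write a sample table (TSV with columns sample_id, condition)
#' @param path TSV path.
#' @return [sample_table()] for the reader; `path` invisibly for the writer.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns sample_id, condition: ", path, call. = FALSE)
  }
  sample_table(df$sample_id, df$condition)
}

#' @rdname read_sample_table
#' @param x a [sample_table()].
#' @export
write_sample_table <- function(x, path) {
  write.table(data.frame(sample_id = x$sample_id,
                         condition = as.character(x$condition)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split a sample_table into case/control id vectors, checking group sizes
condition_groups <- function(samples, min_per_group = 1) {
  case <- samples$sample_id[samples$condition == "case"]
  ctrl <- samples$sample_id[samples$condition == "control"]
  if (length(case) < min_per_group || length(ctrl) < min_per_group) {
    stop("need at least ", min_per_group, " samples per condition", call. = FALSE)
  }
  list(case = case, control = ctrl)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' The universe defaults to the union of all members unless supplied.
#'
#' @param path GMT file path.
#' @param universe optional character vector of gene ids to use as the
#'   background universe.
#' @return a list of class `gene_set_collection` with elements `sets` (named
#'   list of character vectors), `descriptions` (named character) and
#'   `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path, call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(names_))
  if (length(dup) > 0) {
    stop("duplicate gene-set name '", names_[dup[1]], "' at GMT line ", dup[1],
         " in ", path, call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- names_
  descriptions <- setNames(vapply(fields, `[[`, "", 2L), names_)
  gene_set_collection(sets, descriptions, universe)
}

#' @rdname read_gmt
#' @param sets named list of character member vectors (all non-empty).
#' @param descriptions named character vector (defaults to set names).
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("empty gene set not allowed", call. = FALSE)
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-gene pair table
#'
#' Prediction tables carry one row per (miRNA, gene, tool) triple; validation
#' tables one row per (miRNA, gene, source) triple. Duplicate triples are
#' collapsed with a warning giving the number removed.
#'
#' @param path TSV path with columns `mirna`, `gene` and `tool` (prediction)
#'   or `source` (validation).
#' @param kind `"prediction"` or `"validation"`.
#' @return data.frame of class `prediction_table` or `validation_table`.
#' @export
read_pair_table <- function(path, kind = c("prediction", "validation")) {
  kind <- match.arg(kind)
  df <- read.delim(path, sep = "\t", check.names = FALSE, colClasses = "character")
  third <- if (kind == "prediction") "tool" else "source"
  need <- c("mirna", "gene", third)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pair table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pair_table(df$mirna, df$gene, df[[third]], kind = kind)
}

#' @rdname read_pair_table
#' @param mirna,gene,annot character vectors: miRNA id, gene id, and tool or
#'   source label.
#' @export
pair_table <- function(mirna, gene, annot, kind = c("prediction", "validation")) {
  kind <- match.arg(kind)
  third <- if (kind == "prediction") "tool" else "source"
  df <- data.frame(mirna = trimws(as.character(mirna)),
                   gene = trimws(as.character(gene)),
                   x = trimws(as.character(annot)))
  names(df)[3] <- third
  ndup <- sum(duplicated(df))
  if (ndup > 0) {
    warning(ndup, " duplicate (mirna, gene, ", third, ") triple(s) collapsed",
            call. = FALSE)
    df <- df[!duplicated(df), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c(paste0(kind, "_table"), class(df))
  df
}

#' @rdname read_pair_table
#' @param x a prediction or validation table.
#' @export
write_pair_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled fixtures from the source study
#'
#' Small plain-text fixtures transcribed from the study's printed results for
#' worked examples and regression tests:
#'
#' * `table2_counts`: the printed per-sample miRNA count table, 59 mature
#'   miRNAs by 7 right-ventricle samples (cases A1R, A2R, A4R, A6R; controls
#'   B1R, B2R, B5R). The published caption describes predicted miRNA-gene
#'   interactions, but the body of the table is a per-sample count matrix
#'   (its column headers are sample identifiers); it is treated as counts
#'   here, with the printed thousands separators stripped at transcription.
#'   The published rows for hsa-miR-486-5p and hsa-miR-486-3p are identical,
#'   as printed. The study recruited four controls, but the printed table
#'   carries only the three shown.
#' * `published_pairs`: the 11 reported negatively correlated miRNA-target
#'   pairs (5 miRNAs, 11 genes).
#' * `dem_list`: the 8 reported differentially expressed miRNAs with their
#'   direction in cases (3 up, 5 down).
#'
#' @param name one of `"table2_counts"`, `"published_pairs"`, `"dem_list"`.
#' @return `table2_counts`: a [count_matrix()]; `published_pairs`: a
#'   data.frame with columns `mirna`, `gene`; `dem_list`: a data.frame with
#'   columns `mirna`, `direction`.
#' @examples
#' tab2 <- load_fixture("table2_counts")
#' dim(tab2)
#' @export
load_fixture <- function(name = c("table2_counts", "published_pairs", "dem_list")) {
  name <- match.arg(name)
  f <- function(file) system.file("extdata", file, package = "mirweave", mustWork = TRUE)
  switch(name,
    table2_counts = read_count_matrix(f("table2_mirna_counts.tsv")),
    published_pairs = read.delim(f("published_pairs.tsv"), sep = "\t",
                                 colClasses = "character"),
    dem_list = read.delim(f("dem_list.tsv"), sep = "\t", colClasses = "character")
  )
}

#' Sample table matching the `table2_counts` fixture
#'
#' Four case (A*) and three control (B*) right-ventricle samples.
#' @return a [sample_table()].
#' @export
table2_samples <- function() {
  sample_table(c("A1R", "A2R", "A4R", "A6R", "B1R", "B2R", "B5R"),
               c(rep("case", 4), rep("control", 3)))
}
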