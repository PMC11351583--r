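#' Differential-expression configuration
#'
#' Thresholds and numerical knobs for [nb_wald_test()] and DE calling. The
#' default rule calls a feature differentially expressed when the BH-adjusted
#' p-value is at most `fdr` and |log2 fold change| is at least `lfc`
#' (q <= 0.05, |log2FC| >= 0.5). An alternative raw-p rule (p < 0.05 with
#' |log2FC| > 1, i.e. fold change > 2) can be selected with
#' `call_rule = "raw_p"`.
#'
#' @param fdr adjusted-p threshold for the default call rule (default 0.05).
#' @param lfc minimum |log2 fold change| (default 0.5; 1.0 under `raw_p`).
#' @param call_rule `"fdr"` (default) or `"raw_p"`.
#' @param min_total_count features with total count below this are dropped
#'   before testing (default 10); stabilizes the moments dispersion estimate
#'   at small n.
#' @param dispersion_floor lower bound for the dispersion estimate
#'   (default 1e-8).
#' @param pseudocount added to counts of features where one group is all
#'   zero, and to CPM values with a zero group mean (default 1).
#' @param wald_ref reference distribution for the Wald statistic: `"t"`
#'   (default; t with n - 2 degrees of freedom, matching the degrees of
#'   freedom of the pooled dispersion estimate — without this small-sample
#'   correction the test is markedly anticonservative at n = 7) or
#'   `"normal"` (the asymptotic standard-normal reference).
#' @return list of class `de_config`.
#' @export
de_config <- function(fdr = 0.05, lfc = 0.5, call_rule = c("fdr", "raw_p"),
                      min_total_count = 10, dispersion_floor = 1e-8,
                      pseudocount = 1, wald_ref = c("t", "normal")) {
  call_rule <- match.arg(call_rule)
  wald_ref <- match.arg(wald_ref)
  if (call_rule == "raw_p" && missing(lfc)) lfc <- 1
  stopifnot(fdr >= 0, lfc >= 0, min_total_count >= 0,
            dispersion_floor >= 0, pseudocount >= 0)
  structure(list(fdr = fdr, lfc = lfc, call_rule = call_rule,
                 min_total_count = min_total_count,
                 dispersion_floor = dispersion_floor,
                 pseudocount = pseudocount, wald_ref = wald_ref),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over features f (restricted to
#' features with strictly positive counts in every sample) of
#' `counts[f, j] / geomean_f`, where `geomean_f` is the geometric mean of
#' feature f across samples. Even-length medians use the midpoint.
#'
#' @param counts a [count_matrix()] (or integer matrix with dimnames).
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    stop("no feature has strictly positive counts in every sample; ",
         "consider adding a pseudocount", call. = FALSE)
  }
  lg <- log(m[keep, , drop = FALSE])
  loggeo <- rowMeans(lg)
  s <- apply(exp(lg - loggeo), 2, median)
  setNames(s, colnames(m))
}

#' Divide counts by per-sample size factors
#'
#' @param counts a [count_matrix()].
#' @param s named size-factor vector covering every sample in `counts`.
#' @return numeric matrix of normalized counts, same dimnames.
#' @export
normalize_counts <- function(counts, s = size_factors(counts)) {
  m <- unclass(counts)
  if (is.null(names(s)) || !all(colnames(m) %in% names(s))) {
    stop("size factors must be named and cover every sample", call. = FALSE)
  }
  sweep(m + 0.0, 2, s[colnames(m)], "/")
}

#' Method-of-moments NB dispersion
#'
#' Per feature, `alpha = max(floor, (v - mu) / mu^2)` where `mu` is the grand
#' mean of the normalized counts and `v` the pooled within-group variance
#' (group-centred sum of squares over n - G degrees of freedom). Degenerate
#' features (constant, or variance at or below the mean) return the floor.
#'
#' @param norm numeric matrix of normalized counts.
#' @param samples a [sample_table()] covering the columns of `norm`.
#' @param floor lower bound on the estimate.
#' @return named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(norm, samples, floor = 1e-8) {
  groups <- condition_groups(samples, min_per_group = 2)
  norm <- norm[, samples$sample_id, drop = FALSE]
  n <- ncol(norm)
  ss <- 0
  for (g in groups) {
    sub <- norm[, g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / (n - 2)
  mu <- rowMeans(norm)
  alpha <- ifelse(mu > 0, (v - mu) / mu^2, 0)
  setNames(pmax(floor, alpha), rownames(norm))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Negative-binomial Wald differential expression
#'
#' Fits, per feature, the log-link NB GLM
#' `log mu_j = log s_j + b0 + b1 * x_j` (x_j = 1 for case samples) by
#' iteratively reweighted least squares with the dispersion fixed at the
#' method-of-moments estimate, and tests `b1 = 0` with the Wald statistic
#' `W = b1_hat / se(b1_hat)` (two-sided). Because the dispersion entering
#' the standard error is itself estimated from n - 2 residual degrees of
#' freedom, the default reference distribution is t(n - 2) rather than the
#' asymptotic standard normal; at n = 7 the normal reference roughly doubles
#' the nominal type-I error (see [de_config()]). Fold
#' changes are reported on the log2 scale, positive when the case mean
#' exceeds the control mean. Features where one group is all zero are refit
#' with `cfg$pseudocount` added to every count and flagged.
#'
#' This engine is a self-contained reimplementation of the standard
#' DESeq2-style stage and is deliberately not output-compatible with DESeq2:
#' there is no dispersion shrinkage, independent filtering or outlier
#' handling.
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_table()] covering all columns (>= 2 per group).
#' @param cfg a [de_config()].
#' @param s optional precomputed size factors.
#' @return data.frame of class `de_result`: `feature_id`, `base_mean`
#'   (mean normalized count), `log2fc`, `se`, `wald`, `p`, `q`, `called`,
#'   `zero_group` (pseudocount fallback flag).
#' @export
nb_wald_test <- function(counts, samples, cfg = de_config(), s = NULL) {
  groups <- condition_groups(samples, min_per_group = 2)
  m <- unclass(counts)[, samples$sample_id, drop = FALSE]
  keep <- rowSums(m) >= cfg$min_total_count
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no feature passes the minimum-count pre-filter", call. = FALSE)
  if (is.null(s)) s <- size_factors(m)
  s <- s[colnames(m)]
  norm <- sweep(m + 0.0, 2, s, "/")
  alpha <- estimate_dispersion(norm, samples, floor = cfg$dispersion_floor)

  is_case <- colnames(m) %in% groups$case
  zero_group <- rowSums(m[, is_case, drop = FALSE]) == 0 |
    rowSums(m[, !is_case, drop = FALSE]) == 0
  y <- m + 0.0
  if (any(zero_group)) y[zero_group, ] <- y[zero_group, ] + cfg$pseudocount

  fit <- nb_irls_two_group(y, s, is_case, alpha)

  log2fc <- fit$b1 / log(2)
  se <- fit$se / log(2)
  wald <- fit$b1 / fit$se
  p <- if (cfg$wald_ref == "t") {
    2 * pt(-abs(wald), df = ncol(m) - 2)
  } else {
    2 * pnorm(-abs(wald))
  }
  q <- bh_adjust(p)
  called <- if (cfg$call_rule == "fdr") {
    q <= cfg$fdr & abs(log2fc) >= cfg$lfc
  } else {
    p < cfg$fdr & abs(log2fc) >= cfg$lfc
  }
  out <- data.frame(feature_id = rownames(m),
                    base_mean = rowMeans(norm),
                    log2fc = log2fc, se = se, wald = wald, p = p, q = q,
                    called = called & !is.na(called),
                    zero_group = zero_group,
                    row.names = NULL)
  class(out) <- c("de_result", class(out))
  out
}

# Vectorized IRLS across features for the two-group NB GLM with log link and
# offset log(s). Weighted LS on [1, x] reduces to weighted group means of the
# working response. Weights w = mu / (1 + alpha * mu).
nb_irls_two_group <- function(y, s, is_case, alpha, maxit = 50, tol = 1e-10) {
  off <- matrix(log(s), nrow(y), ncol(y), byrow = TRUE)
  mu <- pmax(y, 0.5)
  b0 <- b1 <- rep(0, nrow(y))
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- log(mu) - off + (y - mu) / mu   # working response minus offset
    wz <- w * z
    sw_case <- rowSums(w[, is_case, drop = FALSE])
    sw_ctrl <- rowSums(w[, !is_case, drop = FALSE])
    mean_case <- rowSums(wz[, is_case, drop = FALSE]) / sw_case
    mean_ctrl <- rowSums(wz[, !is_case, drop = FALSE]) / sw_ctrl
    b0_new <- mean_ctrl
    b1_new <- mean_case - mean_ctrl
    delta <- max(abs(b0_new - b0), abs(b1_new - b1))
    b0 <- b0_new
    b1 <- b1_new
    eta <- off + b0 + outer(b1, as.numeric(is_case))
    mu <- pmax(exp(eta), 1e-10)
    if (delta < tol) break
  }
  w <- mu / (1 + alpha * mu)
  sw_case <- rowSums(w[, is_case, drop = FALSE])
  sw_ctrl <- rowSums(w[, !is_case, drop = FALSE])
  list(b0 = b0, b1 = b1, se = sqrt(1 / sw_case + 1 / sw_ctrl))
}

#' Features detected in every sample
#'
#' Detection = strictly positive count in all samples.
#'
#' @param counts a [count_matrix()].
#' @return character vector of detected feature ids.
#' @export
detected_features <- function(counts) {
  m <- unclass(counts)
  rn <- rownames(m)
  if (is.null(rn)) return(character(0))
  rn[rowSums(m > 0) == ncol(m)]
}

#' CPM group log2 fold change
#'
#' Per-sample CPM = 1e6 * count / column total (column totals of the supplied
#' matrix); returns `log2(mean CPM in cases / mean CPM in controls)` for one
#' feature. A zero group mean falls back to adding `pseudocount` on the CPM
#' scale to both group means.
#'
#' @param counts a [count_matrix()].
#' @param samples a [sample_table()].
#' @param feature feature id.
#' @param pseudocount CPM-scale fallback offset for zero group means.
#' @return signed log2 fold change (numeric scalar).
#' @export
cpm_group_log2fc <- function(counts, samples, feature, pseudocount = 1) {
  m <- unclass(counts)
  if (!feature %in% rownames(m)) stop("feature not found: ", feature, call. = FALSE)
  groups <- condition_groups(samples)
  cpm <- sweep(m + 0.0, 2, colSums(m), "/") * 1e6
  a <- mean(cpm[feature, groups$case])
  b <- mean(cpm[feature, groups$control])
  if (a == 0 || b == 0) {
    a <- a + pseudocount
    b <- b + pseudocount
  }
  log2(a / b)
}

#' Read/write differential-expression results as TSV
#' @param x a `de_result` data.frame.
#' @param path TSV path.
#' @return the data.frame (reader) or `path` invisibly (writer).
#' @export
write_de_results <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("base_mean", "log2fc", "se", "wald", "p", "q")) {
    df[[col]] <- format_num(df[[col]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  df$feature_id <- as.character(df$feature_id)
  class(df) <- c("de_result", class(df))
  df
}

# deterministic, locale-independent number formatting for TSV outputs
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.10g", v)
  }, "")
  out
}
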