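test_that("consensus filter keeps pairs with enough distinct tools", {
  pred <- pair_table(c("m1", "m1", "m1", "m2", "m2"),
                     c("g1", "g1", "g1", "g1", "g1"),
                     c("T1", "T2", "T3", "T1", "T2"), "prediction")
  cons <- consensus_pairs("m1", "g1", pred, k = 3)
  expect_identical(nrow(cons), 1L)
  expect_identical(cons$tool_count, 3L)
  expect_identical(cons$tools, "T1,T2,T3")
  expect_identical(nrow(consensus_pairs(c("m1", "m2"), "g1", pred, k = 3)), 1L)
  expect_identical(nrow(consensus_pairs("m2", "g1", pred, k = 3)), 0L)
  # pairs outside DEM x DEG are excluded entirely
  expect_identical(nrow(consensus_pairs("m9", "g1", pred, k = 1)), 0L)
  expect_warning(consensus_pairs("m1", "g1", pred, k = 1,
                                 tool_vocabulary = c("T1", "T2")),
                 "undeclared")
})

test_that("raising the consensus threshold shrinks the pair set", {
  set.seed(20)
  for (i in 1:100) {
    pred <- random_prediction_table()
    dems <- paste0("m", 1:5)
    degs <- paste0("g", 1:8)
    k3 <- consensus_pairs(dems, degs, pred, k = 3)
    k4 <- consensus_pairs(dems, degs, pred, k = 4)
    expect_true(all(paste(k4$mirna, k4$gene) %in% paste(k3$mirna, k3$gene)))
  }
})

test_that("pair correlations match the direct formula and cor.test", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    rp <- mirweave:::pearson_r_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(rp[1], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(rp[2], ct$p.value, tolerance = 1e-10)
  }
  # r = -0.7 at n = 7: two-sided p ~ 0.0799 via the t transform
  tt <- -0.7 * sqrt(5 / (1 - 0.49))
  expect_equal(2 * pt(tt, 5), 0.0799, tolerance = 1e-3)
})

test_that("pair correlation records handle identity, fixtures and degeneracy", {
  tab2 <- load_fixture("table2_counts")
  # self-correlation through the full transform is exactly 1
  pairs <- data.frame(mirna = "hsa-miR-1-3p", gene = "hsa-miR-1-3p")
  rec <- pearson_pair_correlations(pairs, tab2, tab2)
  expect_equal(rec$r, 1)
  # the two identically printed miR-486 arms correlate at exactly 1
  rec2 <- pearson_pair_correlations(
    data.frame(mirna = "hsa-miR-486-5p", gene = "hsa-miR-486-3p"), tab2, tab2)
  expect_equal(rec2$r, 1)
  expect_identical(rec2$n, 7L)

  # missing feature -> skipped; zero variance -> NA r
  cm <- count_matrix(rbind(flat = rep(5L, 4), v = c(1L, 5L, 3L, 9L)),
                     sample_ids = paste0("s", 1:4))
  recs <- suppressMessages(pearson_pair_correlations(
    data.frame(mirna = c("flat", "nope"), gene = c("v", "v")), cm, cm,
    s_mirna = setNames(rep(1, 4), paste0("s", 1:4)),
    s_mrna = setNames(rep(1, 4), paste0("s", 1:4)),
    cfg = interactome_config(correlation_input = "raw")))
  expect_true(recs$skipped[2])
  expect_true(is.na(recs$r[1]))
})

test_that("validation and shared-target filters follow their definitions", {
  pairs <- data.frame(mirna = c("m1", "m2", "m3"), gene = c("g1", "g1", "g2"))
  val <- pair_table(c("m1", "m1"), c("g1", "g1"), c("dbA", "dbB"), "validation")
  kept <- apply_validation_filter(pairs, val, require = TRUE)
  expect_identical(kept$mirna, "m1")
  expect_identical(kept$sources, "dbA,dbB")
  annotated <- apply_validation_filter(pairs, val, require = FALSE)
  expect_identical(nrow(annotated), 3L)
  expect_identical(annotated$validated, c(TRUE, FALSE, FALSE))

  shared <- apply_shared_target_filter(pairs, m = 2)
  expect_setequal(shared$gene, "g1")
  expect_identical(nrow(apply_shared_target_filter(pairs, m = 1)), 3L)

  set.seed(22)
  for (i in 1:100) {
    rp <- data.frame(mirna = sample(paste0("m", 1:6), 12, TRUE),
                     gene = sample(paste0("g", 1:5), 12, TRUE))
    rp <- rp[!duplicated(rp), , drop = FALSE]
    m <- sample(1:3, 1)
    got <- apply_shared_target_filter(rp, m)
    want <- shared_oracle(rp, m)
    expect_equal(paste(got$mirna, got$gene), paste(want$mirna, want$gene))
  }
})

test_that("the full cascade selects exactly the hand-enumerated toy edge", {
  # four candidates; only (m1, g1) passes validation + sharing + correlation
  pairs <- data.frame(mirna = c("m1", "m2", "m1", "m3"),
                      gene = c("g1", "g1", "g2", "g2"),
                      tool_count = c(4L, 3L, 5L, 3L),
                      tools = "T1,T2,T3")
  val <- pair_table(c("m1", "m2", "m3"), c("g1", "g1", "g2"),
                    rep("dbA", 3), "validation")
  pairs <- apply_validation_filter(pairs, val, require = FALSE)
  correlations <- data.frame(mirna = c("m1", "m2", "m1", "m3"),
                             gene = c("g1", "g1", "g2", "g2"),
                             r = c(-0.9, -0.2, -0.95, -0.85),
                             p = c(0.001, 0.6, 0.001, 0.002),
                             n = 7L, skipped = FALSE)
  de_mirna <- data.frame(feature_id = c("m1", "m2", "m3"),
                         log2fc = c(2, 2, -2))
  de_mrna <- data.frame(feature_id = c("g1", "g2"), log2fc = c(-2, 2))
  # hand enumeration: (m1,g2) is unvalidated and falls first, which leaves
  # g2 with the single partner m3, so (m3,g2) falls at sharing; (m2,g1)
  # fails the correlation screen; (m1,g1) passes every filter.
  edges <- select_final_pairs(pairs, correlations, de_mirna, de_mrna)
  expect_identical(paste(edges$mirna, edges$gene), "m1 g1")

  # with a stricter sharing level nothing survives the toy
  expect_identical(nrow(select_final_pairs(pairs, correlations, de_mirna,
                                           de_mrna,
                                           interactome_config(min_sharing = 3))),
                   0L)
  # empty candidate list -> empty edges
  expect_identical(nrow(select_final_pairs(mirweave:::empty_pairs(),
                                           correlations, de_mirna, de_mrna)),
                   0L)
})

test_that("joint r/p thresholds at n = 7 reduce to a single r cutoff", {
  # two-sided p < 0.05 at df = 5 corresponds to |r| > t*/sqrt(df + t*^2)
  tstar <- qt(0.975, 5)
  r_cut <- tstar / sqrt(5 + tstar^2)
  expect_equal(round(-r_cut, 4), -0.7545)

  de_mirna <- data.frame(feature_id = "m", log2fc = 2)
  de_mrna <- data.frame(feature_id = "g", log2fc = -2)
  decide <- function(r) {
    pairs <- data.frame(mirna = "m", gene = "g", tool_count = 3L,
                        tools = "a,b,c", validated = TRUE, sources = "dbA")
    tt <- r * sqrt(5 / (1 - r^2))
    correlations <- data.frame(mirna = "m", gene = "g", r = r,
                               p = 2 * pt(-abs(tt), 5), n = 7L,
                               skipped = FALSE)
    nrow(select_final_pairs(pairs, correlations, de_mirna, de_mrna,
                            interactome_config(min_sharing = 1))) == 1L
  }
  for (r in seq(-0.99, -0.05, by = 0.01)) {
    expect_identical(decide(r), r < -r_cut)
  }
  expect_false(decide(-0.72))
  expect_true(decide(-0.76))
})

test_that("stricter configurations always produce edge subsets", {
  set.seed(23)
  for (i in 1:100) {
    npairs <- sample(5:15, 1)
    pairs <- unique(data.frame(mirna = sample(paste0("m", 1:5), npairs, TRUE),
                               gene = sample(paste0("g", 1:6), npairs, TRUE)))
    pairs$tool_count <- sample(1:8, nrow(pairs), TRUE)
    pairs$tools <- vapply(pairs$tool_count,
                          function(k) paste(paste0("T", 1:k), collapse = ","), "")
    pairs$validated <- runif(nrow(pairs)) < 0.8
    pairs$sources <- ifelse(pairs$validated, "dbA", "")
    r <- -runif(nrow(pairs), 0.2, 0.99)
    correlations <- data.frame(mirna = pairs$mirna, gene = pairs$gene, r = r,
                               p = 2 * pt(-abs(r * sqrt(5 / (1 - r^2))), 5),
                               n = 7L, skipped = FALSE)
    de_mirna <- data.frame(feature_id = paste0("m", 1:5),
                           log2fc = sample(c(-2, 2), 5, TRUE))
    de_mrna <- data.frame(feature_id = paste0("g", 1:6),
                          log2fc = sample(c(-2, 2), 6, TRUE))
    lax <- interactome_config(min_sharing = 1, r_max = -0.5, p_max = 0.2)
    strict <- interactome_config(min_sharing = sample(1:2, 1),
                                 r_max = -0.75, p_max = 0.04)
    # consensus stringency handled on the candidate side
    cand_lax <- pairs[pairs$tool_count >= 2, , drop = FALSE]
    cand_strict <- pairs[pairs$tool_count >= 4, , drop = FALSE]
    e_lax <- select_final_pairs(cand_lax, correlations, de_mirna, de_mrna, lax)
    e_strict <- select_final_pairs(cand_strict, correlations, de_mirna,
                                   de_mrna, strict)
    expect_true(all(paste(e_strict$mirna, e_strict$gene) %in%
                      paste(e_lax$mirna, e_lax$gene)))
  }
})

test_that("network export writes the published pairs as a bipartite graph", {
  pubs <- load_fixture("published_pairs")
  edges <- data.frame(mirna = pubs$mirna, gene = pubs$gene,
                      tool_count = 3L, validated = TRUE,
                      r = -0.8, p = 0.01)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(edges, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(as.integer(igraph::vcount(g)), 16L)   # 5 miRNAs + 11 genes
  expect_identical(as.integer(igraph::ecount(g)), 11L)
  expect_setequal(unique(igraph::V(g)$type), c("mirna", "gene"))

  # empty edge list -> a valid empty graph file
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(mirweave:::empty_edges(), gml2, format = "graphml")
  g2 <- igraph::read_graph(gml2, format = "graphml")
  expect_identical(as.integer(igraph::ecount(g2)), 0L)

  # TSV roundtrip preserves all evidence columns
  full <- data.frame(mirna = "m1", gene = "g1", tool_count = 4L,
                     tools = "a,b,c,d", validated = TRUE, sources = "dbA",
                     r = -0.912345, p = 0.0042, n = 7L,
                     mirna_log2fc = 1.5, gene_log2fc = -2.25)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(full, tsv, format = "edge_tsv")
  back <- read_network_edges(tsv)
  expect_equal(as.data.frame(back), full, tolerance = 1e-9)
})
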