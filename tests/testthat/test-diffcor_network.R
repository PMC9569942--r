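# Per-group pair correlations, Fisher r-to-z differential-correlation
# testing, network assembly and lossless export.

mk_catalog <- function(src, tgt, type = "miRNA-target", evidence = "validated") {
  data.frame(source = src, target = tgt, edge_type = type,
             evidence = evidence, stringsAsFactors = FALSE)
}

test_that("catalog validation enforces types and uniqueness", {
  good <- mk_catalog(c("m1", "m1"), c("g1", "g2"))
  expect_s3_class(validate_catalog(good), "data.frame")
  expect_error(validate_catalog(mk_catalog("m1", "g1", type = "bogus")),
               "edge_type")
  expect_error(validate_catalog(rbind(good, good[1, ])), "duplicate")
})

test_that("pair correlations match hand-computed Spearman and closed forms", {
  meta <- data.frame(sample_id = paste0("S", 1:10),
                     group = rep(c("BCR", "BRF"), each = 5))
  x <- c(1, 2, 3, 4, 5);  y <- c(2, 1, 4, 3, 5)
  es <- rbind(m1 = c(x, 5:1))
  colnames(es) <- meta$sample_id
  et <- rbind(g1 = c(y, 1:5))
  colnames(et) <- meta$sample_id
  pc <- pair_correlations(es, et, meta, mk_catalog("m1", "g1"))
  # r_s = 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  expect_equal(pc$r_s[pc$group == "BCR"], 0.8)
  expect_equal(pc$r_s[pc$group == "BRF"], -1)  # strictly decreasing
  # y = 2x exactly: all statistics saturate
  et2 <- rbind(g1 = 2 * c(x, 5:1))
  colnames(et2) <- meta$sample_id
  es2 <- rbind(m1 = c(x, 5:1))
  colnames(es2) <- meta$sample_id
  pc2 <- pair_correlations(es2, et2, meta, mk_catalog("m1", "g1"))
  expect_equal(pc2$r_s, c(1, 1))
  expect_equal(pc2$r_p, c(1, 1))
  expect_equal(pc2$adj_r2, c(1, 1))
})

test_that("Spearman path equals midrank Pearson-on-ranks oracle under ties", {
  set.seed(23)
  meta <- rand_groups_meta(8)
  for (i in 1:20) {
    xv <- sample(1:6, 16, replace = TRUE)  # forced ties
    yv <- sample(1:6, 16, replace = TRUE)
    if (sd(xv) == 0 || sd(yv) == 0) next
    es <- rbind(m1 = xv); et <- rbind(g1 = yv)
    colnames(es) <- colnames(et) <- meta$sample_id
    pc <- pair_correlations(es, et, meta, mk_catalog("m1", "g1"))
    for (g in c("BCR", "BRF")) {
      idx <- if (g == "BCR") 1:8 else 9:16
      if (sd(xv[idx]) == 0 || sd(yv[idx]) == 0) next
      expect_equal(pc$r_s[pc$group == g],
                   cor(rank(xv[idx]), rank(yv[idx])), tolerance = 1e-12)
    }
  }
})

test_that("adjusted R2 matches the linear-model summary", {
  set.seed(9)
  meta <- rand_groups_meta(10)
  xv <- rnorm(20); yv <- 0.6 * xv + rnorm(20)
  es <- rbind(m1 = xv); et <- rbind(g1 = yv)
  colnames(es) <- colnames(et) <- meta$sample_id
  pc <- pair_correlations(es, et, meta, mk_catalog("m1", "g1"))
  for (g in c("BCR", "BRF")) {
    idx <- which(meta$group == g)
    fit <- summary(lm(yv[idx] ~ xv[idx]))
    expect_equal(pc$adj_r2[pc$group == g], fit$adj.r.squared,
                 tolerance = 1e-12)
  }
})

test_that("missing features and zero-variance vectors are skipped with reasons", {
  meta <- rand_groups_meta(5)
  es <- rbind(m1 = rnorm(10), m2 = rep(1, 10))
  et <- rbind(g1 = rnorm(10))
  colnames(es) <- colnames(et) <- meta$sample_id
  cat3 <- mk_catalog(c("m1", "m2", "mX"), c("g1", "g1", "g1"))
  pc <- pair_correlations(es, et, meta, cat3)
  expect_equal(unique(pc$pair_id), "m1|g1")
  sk <- attr(pc, "skipped")
  expect_true(any(grepl("feature absent", sk$reason)))
  expect_true(any(grepl("zero variance", sk$reason)))
})

test_that("Fisher r-to-z matches its closed form and symmetries", {
  expect_equal(fisher_z_diff(0.5, 30, 0.5, 30)$z, 0)
  expect_equal(fisher_z_diff(0.5, 30, 0.5, 30)$p, 1)
  fz <- fisher_z_diff(0.8, 28, 0.2, 28)
  expect_equal(fz$z, (atanh(0.8) - atanh(0.2)) / sqrt(2 / 25),
               tolerance = 1e-12)
  expect_equal(fz$z, 3.1674, tolerance = 1e-4)
  expect_equal(fz$p, 0.0015, tolerance = 0.05)
  neg <- fisher_z_diff(-0.8, 28, -0.2, 28)
  expect_equal(neg$z, -fz$z)
  expect_equal(neg$p, fz$p)
  expect_error(fisher_z_diff(0.5, 3, 0.5, 30), "n >= 4")
  # clamping keeps perfect correlations finite
  expect_true(is.finite(fisher_z_diff(1, 10, 0, 10)$z))
})

test_that("differential-correlation scan is antisymmetric under group swap", {
  set.seed(31)
  meta <- rand_groups_meta(10)
  es <- matrix(rnorm(3 * 20), 3, dimnames = list(paste0("m", 1:3),
                                                 meta$sample_id))
  et <- matrix(rnorm(3 * 20), 3, dimnames = list(paste0("g", 1:3),
                                                 meta$sample_id))
  ctl <- mk_catalog(paste0("m", 1:3), paste0("g", 1:3))
  pc <- pair_correlations(es, et, meta, ctl)
  meta_sw <- meta
  meta_sw$group <- ifelse(meta$group == "BCR", "BRF", "BCR")
  pc_sw <- pair_correlations(es, et, meta_sw, ctl)
  dc <- differential_correlation_scan(pc)
  dc_sw <- differential_correlation_scan(pc_sw)
  expect_equal(dc_sw$delta, -dc$delta)
  expect_equal(dc_sw$z, -dc$z)
  expect_equal(dc_sw$p, dc$p)
  expect_equal(dc_sw$selected, dc$selected)
})

test_that("scan skips pairs missing a group and supports FDR selection", {
  pcs <- data.frame(
    pair_id = c("a|b", "a|b", "c|d"), source = c("a", "a", "c"),
    target = c("b", "b", "d"), edge_type = "miRNA-target",
    group = c("BCR", "BRF", "BCR"), n = 30,
    r_s = c(0.9, -0.5, 0.2), r_p = c(0.9, -0.5, 0.2),
    adj_r2 = 0.5, stringsAsFactors = FALSE)
  dc <- differential_correlation_scan(pcs)
  expect_equal(dc$pair_id, "a|b")
  expect_equal(attr(dc, "skipped")$pair_id, "c|d")
  dc_fdr <- differential_correlation_scan(pcs, selection = "fdr")
  expect_equal(dc_fdr$selected, dc_fdr$fdr <= 0.05)
})

test_that("planted differential correlation is detected with high power", {
  detected <- 0
  n_rep <- 60
  for (s in 1:n_rep) {
    set.seed(5000 + s)
    cc_b <- generate_correlated_counts(100, 100, 0.1, 0.1, 0.8, 30)
    cc_f <- generate_correlated_counts(100, 100, 0.1, 0.1, -0.2, 30)
    r1 <- cor(cc_b$x, cc_b$y, method = "spearman")
    r2 <- cor(cc_f$x, cc_f$y, method = "spearman")
    detected <- detected + (fisher_z_diff(r1, 30, r2, 30)$p <= 0.05)
  }
  expect_gte(detected / n_rep, 0.9)
})

mk_mini_network <- function() {
  dc <- data.frame(
    pair_id = c("m1|g1", "m2|g2", "g1|g2"),
    source = c("m1", "m2", "g1"), target = c("g1", "g2", "g2"),
    edge_type = c("miRNA-target", "miRNA-target", "PPI"),
    n_bcr = 30, n_brf = 30,
    r_s_bcr = c(0.8, 0.1, 0.3), r_s_brf = c(-0.4, 0.0, 0.2),
    r_p_bcr = 0.5, r_p_brf = 0.1, adj_r2_bcr = 0.3, adj_r2_brf = 0.05,
    delta = c(1.2, 0.1, 0.1), z = c(4.5, 0.4, 0.4),
    p = c(1e-5, 0.7, 0.7), fdr = c(3e-5, 0.7, 0.7),
    selected = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  ctl <- validate_catalog(data.frame(
    source = c("m1", "m2", "g1"), target = c("g1", "g2", "g2"),
    edge_type = c("miRNA-target", "miRNA-target", "PPI"),
    evidence = c("validated", "predicted", "n/a"),
    stringsAsFactors = FALSE))
  de_ann <- data.frame(id = c("g1", "m1"), cohort = c("B", "A"),
                       is_de = c(TRUE, FALSE), direction = c("up", "none"),
                       stringsAsFactors = FALSE)
  list(dc = dc, catalog = ctl, de = de_ann)
}

test_that("network assembly keeps selected edges, types and DE flags", {
  mm <- mk_mini_network()
  net <- build_network(mm$dc, mm$catalog, mm$de)
  expect_equal(sort(net$nodes$id), c("g1", "m1"))
  expect_equal(nrow(net$edges), 1)  # only the selected miRNA-target edge
  expect_equal(net$edges$pair_id, "m1|g1")
  expect_equal(net$nodes$node_type[net$nodes$id == "m1"], "miRNA")
  expect_equal(net$nodes$node_type[net$nodes$id == "g1"], "gene")
  # DE only in cohort B is flagged B-only
  expect_false(net$nodes$de_A[net$nodes$id == "g1"])
  expect_true(net$nodes$de_B[net$nodes$id == "g1"])
  # edge count never exceeds scanned pairs; nodes <= 2x edges
  expect_lte(nrow(net$edges), nrow(mm$dc))
  expect_lte(nrow(net$nodes), 2 * nrow(net$edges))
})

test_that("shared targets collapse to single nodes with correct degree", {
  dc <- data.frame(
    pair_id = c("m1|g1", "m2|g1"), source = c("m1", "m2"),
    target = c("g1", "g1"), edge_type = "miRNA-target",
    n_bcr = 30, n_brf = 30, r_s_bcr = 0.8, r_s_brf = -0.4,
    r_p_bcr = 0.5, r_p_brf = 0.1, adj_r2_bcr = 0.3, adj_r2_brf = 0.05,
    delta = 1.2, z = 4.5, p = 1e-5, fdr = 2e-5, selected = TRUE,
    stringsAsFactors = FALSE)
  ctl <- validate_catalog(data.frame(
    source = c("m1", "m2"), target = c("g1", "g1"),
    edge_type = "miRNA-target", evidence = "validated",
    stringsAsFactors = FALSE))
  net <- build_network(dc, ctl)
  expect_equal(sum(net$nodes$id == "g1"), 1)
  deg <- network_degree_table(net)
  expect_equal(deg$degree[deg$id == "g1"], 2)
})

test_that("network export round-trips across all formats", {
  mm <- mk_mini_network()
  net <- build_network(mm$dc, mm$catalog, mm$de)
  for (fmt in c("graphml", "json", "tsv")) {
    path <- file.path(tempdir(), paste0("net.", fmt,
                                        if (fmt == "tsv") "" else ""))
    path <- file.path(tempdir(), switch(fmt, graphml = "net.graphml",
                                        json = "net.json", tsv = "net.tsv"))
    export_network(net, path, fmt)
    back <- import_network(path, fmt)
    ord <- function(df) {
      df <- df[order(df[[1]]), sort(names(df)), drop = FALSE]
      rownames(df) <- NULL
      df
    }
    expect_equal(ord(back$nodes), ord(net$nodes), tolerance = 1e-12,
                 info = fmt)
    expect_equal(ord(back$edges), ord(net$edges), tolerance = 1e-12,
                 info = fmt)
  }
  expect_error(export_network(net, tempfile(), "dot"))
})

test_that("empty networks export and re-import as valid empty documents", {
  dc0 <- differential_correlation_scan(
    data.frame(pair_id = character(), source = character(),
               target = character(), edge_type = character(),
               group = character(), n = integer(), r_s = numeric(),
               r_p = numeric(), adj_r2 = numeric()))
  ctl <- validate_catalog(mk_catalog("m1", "g1"))
  net <- build_network(dc0, ctl)
  expect_equal(nrow(net$nodes), 0)
  for (fmt in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_network(net, path, fmt)
    back <- import_network(path, fmt)
    expect_equal(nrow(back$edges), 0)
  }
})

test_that("GraphML output is well-formed XML in the GraphML namespace", {
  skip_if_not_installed("xml2")
  mm <- mk_mini_network()
  net <- build_network(mm$dc, mm$catalog, mm$de)
  path <- tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  doc <- xml2::read_xml(path)  # errors if malformed
  expect_equal(xml2::xml_name(doc), "graphml")
  ns <- xml2::xml_ns(doc)
  expect_true(any(grepl("graphml", unlist(ns))))
  # igraph can parse its own emission
  expect_s3_class(import_network(path, "graphml"), "interactome_network")
})
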