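# Differential miRNA-target correlation: per-group Spearman/Pearson
# statistics over catalog-defined pairs, the Fisher r-to-z two-sample test
# on the Spearman difference (BCR minus BRF), and assembly/export of the
# typed interactome network.

#' Validate a typed interaction catalog
#'
#' An edge list with columns `source`, `target`, `edge_type` (one of
#' miRNA-target, PPI, TF-target, lncRNA-target), `evidence` (validated,
#' predicted or n/a) and optionally `source_db`. Duplicate
#' (source, target, edge_type) triples are rejected.
#'
#' @param catalog data.frame edge list.
#' @return the validated catalog with a `pair_id` column added
#'   (`source|target`).
#' @export
validate_catalog <- function(catalog) {
  need <- c("source", "target", "edge_type", "evidence")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  types <- c("miRNA-target", "PPI", "TF-target", "lncRNA-target")
  if (!all(catalog$edge_type %in% types)) {
    stop("edge_type must be one of: ", paste(types, collapse = ", "))
  }
  if (any(!nzchar(catalog$source)) || any(!nzchar(catalog$target))) {
    stop("edge endpoints must be nonempty identifiers")
  }
  key <- paste(catalog$source, catalog$target, catalog$edge_type, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (source, target, edge_type) triples")
  if (is.null(catalog$source_db)) catalog$source_db <- "n/a"
  catalog$pair_id <- paste(catalog$source, catalog$target, sep = "|")
  catalog
}

#' Per-group correlation statistics for catalog pairs
#'
#' For every catalog pair and each group: Spearman correlation (midranks),
#' Pearson correlation, and the adjusted coefficient of determination from
#' the simple linear regression of target on source,
#' adjR2 = 1 - (1 - r_p^2)(n - 1)/(n - 2). Pairs referencing features
#' absent from the matrices, or with a zero-variance vector in a group, are
#' skipped with a reason (attribute `"skipped"`).
#'
#' @param expr_source,expr_target expression matrices (log2CPM scale),
#'   features x samples, sample-aligned with `meta`.
#' @param meta sample metadata (`sample_id`, `group`).
#' @param pairs interaction catalog (see [validate_catalog()]); only rows
#'   whose source is in `expr_source` and target in `expr_target` are
#'   computable.
#' @return data.frame with columns `pair_id`, `source`, `target`,
#'   `edge_type`, `group`, `n`, `r_s`, `r_p`, `adj_r2`.
#' @export
pair_correlations <- function(expr_source, expr_target, meta, pairs) {
  pairs <- validate_catalog(pairs)
  meta <- validate_meta(meta, colnames(expr_source))
  if (!identical(colnames(expr_source), colnames(expr_target))) {
    stop("expression matrices must share an identical sample order")
  }
  groups <- c("BCR", "BRF")
  for (g in groups) {
    if (sum(meta$group == g) < 4) {
      stop("group ", g, " has fewer than 4 samples; correlations need n >= 4")
    }
  }
  out <- vector("list", nrow(pairs) * 2L)
  skipped <- list()
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$source[i]; t <- pairs$target[i]
    if (!(s %in% rownames(expr_source)) || !(t %in% rownames(expr_target))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(pair_id = pairs$pair_id[i], reason = "feature absent")
      next
    }
    for (g in groups) {
      cols <- meta$sample_id[meta$group == g]
      x <- expr_source[s, cols]
      y <- expr_target[t, cols]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(pair_id = pairs$pair_id[i],
                     reason = paste0("zero variance in ", g))
        next
      }
      n <- length(x)
      r_p <- stats::cor(x, y)
      k <- k + 1L
      out[[k]] <- data.frame(
        pair_id = pairs$pair_id[i], source = s, target = t,
        edge_type = pairs$edge_type[i], group = g, n = n,
        r_s = stats::cor(x, y, method = "spearman"),
        r_p = r_p,
        adj_r2 = 1 - (1 - r_p^2) * (n - 1) / (n - 2),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res)) {
    res <- data.frame(pair_id = character(), source = character(),
                      target = character(), edge_type = character(),
                      group = character(), n = integer(), r_s = numeric(),
                      r_p = numeric(), adj_r2 = numeric())
  }
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}

#' Fisher r-to-z two-sample correlation test
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(v/(n1 - 3) + v/(n2 - 3)), two-sided
#' p from the standard normal. `variance = 1` is the classical Fisher
#' value; 1.06 (Fieller-Hartley-Pearson) is a common correction for
#' Spearman correlations. Inputs are clamped to magnitude 1 - 1e-7 before
#' the atanh transform.
#'
#' @param r1,r2 correlation coefficients (vectorized).
#' @param n1,n2 group sizes, both at least 4.
#' @param variance numerator of the per-group variance term (default 1).
#' @return list with `z` and `p` (same length as the inputs).
#' @export
fisher_z_diff <- function(r1, n1, r2, n2, variance = 1) {
  if (any(n1 <= 3) || any(n2 <= 3)) {
    stop("Fisher z variance 1/(n - 3) requires n >= 4 in both groups")
  }
  clamp <- function(r) pmax(pmin(r, 1 - 1e-7), -1 + 1e-7)
  z <- (atanh(clamp(r1)) - atanh(clamp(r2))) /
    sqrt(variance / (n1 - 3) + variance / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Differential-correlation scan over paired group correlations
#'
#' For every pair with both groups present: delta = r_s(BCR) - r_s(BRF),
#' the Fisher r-to-z statistic and two-sided p on the Spearman
#' coefficients, BH FDR across all scanned pairs, and the selection flag
#' `p <= alpha & |delta| >= min_abs_delta`. Pearson and adjusted R2 are
#' carried along per group but do not drive selection.
#'
#' @param paircorrs output of [pair_correlations()].
#' @param alpha selection threshold (default 0.05).
#' @param min_abs_delta minimum |delta| for selection (default 0).
#' @param variance Fisher-z variance numerator (see [fisher_z_diff()]).
#' @param selection apply `alpha` to the raw p-value (`"p"`, default) or
#'   to the BH-adjusted value (`"fdr"`); with hundreds of catalog pairs
#'   scanned at once the FDR rule keeps decoy contamination of the
#'   selected set near `alpha`.
#' @return data.frame with one row per scanned pair: `pair_id`, `source`,
#'   `target`, `edge_type`, per-group `n`, `r_s`, `r_p`, `adj_r2`
#'   (suffixed `_bcr`/`_brf`), `delta`, `z`, `p`, `fdr`, `selected`.
#' @export
differential_correlation_scan <- function(paircorrs, alpha = 0.05,
                                          min_abs_delta = 0, variance = 1,
                                          selection = c("p", "fdr")) {
  selection <- match.arg(selection)
  bcr <- paircorrs[paircorrs$group == "BCR", , drop = FALSE]
  brf <- paircorrs[paircorrs$group == "BRF", , drop = FALSE]
  common <- intersect(bcr$pair_id, brf$pair_id)
  only <- setdiff(unique(paircorrs$pair_id), common)
  bcr <- bcr[match(common, bcr$pair_id), , drop = FALSE]
  brf <- brf[match(common, brf$pair_id), , drop = FALSE]
  if (length(common) == 0) {
    res <- data.frame(pair_id = character(), source = character(),
                      target = character(), edge_type = character(),
                      n_bcr = integer(), n_brf = integer(),
                      r_s_bcr = numeric(), r_s_brf = numeric(),
                      r_p_bcr = numeric(), r_p_brf = numeric(),
                      adj_r2_bcr = numeric(), adj_r2_brf = numeric(),
                      delta = numeric(), z = numeric(), p = numeric(),
                      fdr = numeric(), selected = logical())
  } else {
    fz <- fisher_z_diff(bcr$r_s, bcr$n, brf$r_s, brf$n, variance = variance)
    res <- data.frame(
      pair_id = common, source = bcr$source, target = bcr$target,
      edge_type = bcr$edge_type,
      n_bcr = bcr$n, n_brf = brf$n,
      r_s_bcr = bcr$r_s, r_s_brf = brf$r_s,
      r_p_bcr = bcr$r_p, r_p_brf = brf$r_p,
      adj_r2_bcr = bcr$adj_r2, adj_r2_brf = brf$adj_r2,
      delta = bcr$r_s - brf$r_s,
      z = fz$z, p = fz$p,
      fdr = bh_adjust(fz$p),
      stringsAsFactors = FALSE
    )
    crit <- if (selection == "fdr") res$fdr else res$p
    res$selected <- crit <= alpha & abs(res$delta) >= min_abs_delta
  }
  attr(res, "skipped") <- if (length(only)) {
    data.frame(pair_id = only, reason = "missing group")
  } else NULL
  res
}

#' Assemble the typed interactome network
#'
#' Nodes are the endpoints of selected miRNA-target differential-correlation
#' edges, typed by their role in the catalog (miRNA, gene, TF, lncRNA) and
#' annotated with per-cohort DE status. Edges carry the edge type, evidence,
#' per-group correlation statistics and the differential-correlation test.
#' Catalog edges of other types (PPI, TF-target, lncRNA-target) joining two
#' included nodes are appended with their own correlation annotations when
#' available.
#'
#' @param diffcor result of [differential_correlation_scan()].
#' @param catalog the interaction catalog.
#' @param de_annotations optional data.frame (`id`, `cohort`, `is_de`,
#'   `direction`) used to flag nodes per cohort.
#' @return object of class `interactome_network`: list with `nodes` and
#'   `edges` data.frames.
#' @export
build_network <- function(diffcor, catalog, de_annotations = NULL) {
  catalog <- validate_catalog(catalog)
  sel <- diffcor[diffcor$selected & diffcor$edge_type == "miRNA-target", ,
                 drop = FALSE]
  node_ids <- unique(c(sel$source, sel$target))
  edges <- sel[, c("pair_id", "source", "target", "edge_type",
                   "r_s_bcr", "r_s_brf", "r_p_bcr", "r_p_brf",
                   "adj_r2_bcr", "adj_r2_brf", "delta", "z", "p", "fdr")]
  ev <- catalog$evidence[match(paste(edges$pair_id, edges$edge_type),
                               paste(catalog$pair_id, catalog$edge_type))]
  edges$evidence <- ev
  # supplement with other-type catalog edges among included nodes
  extra <- catalog[catalog$edge_type != "miRNA-target" &
                     catalog$source %in% node_ids &
                     catalog$target %in% node_ids, , drop = FALSE]
  if (nrow(extra)) {
    ann <- diffcor[match(paste(extra$pair_id, extra$edge_type),
                         paste(diffcor$pair_id, diffcor$edge_type)), ,
                   drop = FALSE]
    extra_edges <- data.frame(
      pair_id = extra$pair_id, source = extra$source, target = extra$target,
      edge_type = extra$edge_type,
      r_s_bcr = ann$r_s_bcr, r_s_brf = ann$r_s_brf,
      r_p_bcr = ann$r_p_bcr, r_p_brf = ann$r_p_brf,
      adj_r2_bcr = ann$adj_r2_bcr, adj_r2_brf = ann$adj_r2_brf,
      delta = ann$delta, z = ann$z, p = ann$p, fdr = ann$fdr,
      evidence = extra$evidence,
      stringsAsFactors = FALSE
    )
    edges <- rbind(edges, extra_edges)
  }
  node_type <- function(id) {
    if (any(catalog$source == id & catalog$edge_type == "miRNA-target")) return("miRNA")
    if (any(catalog$source == id & catalog$edge_type == "TF-target")) return("TF")
    if (any(catalog$source == id & catalog$edge_type == "lncRNA-target")) return("lncRNA")
    "gene"
  }
  nodes <- data.frame(
    id = node_ids,
    node_type = vapply(node_ids, node_type, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  cohorts <- if (!is.null(de_annotations)) unique(de_annotations$cohort) else character()
  for (co in cohorts) {
    ann <- de_annotations[de_annotations$cohort == co, , drop = FALSE]
    m <- match(nodes$id, ann$id)
    nodes[[paste0("de_", co)]] <- !is.na(m) & ann$is_de[m]
    nodes[[paste0("direction_", co)]] <-
      ifelse(!is.na(m) & ann$is_de[m], ann$direction[m], "none")
  }
  structure(list(nodes = nodes, edges = edges), class = "interactome_network")
}

#' @export
print.interactome_network <- function(x, ...) {
  cat("interactome network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) print(table(x$edges$edge_type))
  invisible(x)
}

#' Node degree table for a network
#'
#' @param network an `interactome_network`.
#' @return data.frame (`id`, `node_type`, `degree`) sorted by decreasing
#'   degree.
#' @export
network_degree_table <- function(network) {
  deg <- table(c(network$edges$source, network$edges$target))
  d <- as.integer(deg[match(network$nodes$id, names(deg))])
  d[is.na(d)] <- 0L
  out <- data.frame(id = network$nodes$id, node_type = network$nodes$node_type,
                    degree = d, stringsAsFactors = FALSE)
  out[order(-out$degree, out$id), , drop = FALSE]
}

#' Export an interactome network
#'
#' Formats: `"graphml"` (via igraph), `"json"` (nodes + edges document), or
#' `"tsv"` (edge table at `path`, node table at `path` with a `_nodes.tsv`
#' suffix). All three round-trip losslessly through [import_network()].
#'
#' @param network an `interactome_network`.
#' @param path output file path.
#' @param format one of "graphml", "json", "tsv".
#' @return the path, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(nodes = network$nodes, edges = network$edges),
                         path, digits = NA, auto_unbox = FALSE, na = "null")
  } else if (format == "tsv") {
    write_tsv(network$edges, path)
    write_tsv(network$nodes, sub("\\.tsv$", "_nodes.tsv", path))
  } else {
    nodes <- network$nodes
    # igraph graphml writes logicals as 0/1 numerics; encode as character
    lg <- vapply(nodes, is.logical, logical(1))
    nodes[lg] <- lapply(nodes[lg], function(v) ifelse(v, "true", "false"))
    if (nrow(network$edges)) {
      g <- igraph::graph_from_data_frame(
        network$edges[, c("source", "target",
                          setdiff(names(network$edges), c("source", "target")))],
        directed = TRUE, vertices = nodes)
    } else {
      g <- igraph::make_empty_graph(directed = TRUE)
      if (nrow(nodes)) {
        g <- igraph::add_vertices(g, nrow(nodes))
        igraph::V(g)$name <- nodes$id
        for (cn in setdiff(names(nodes), "id")) {
          g <- igraph::set_vertex_attr(g, cn, value = nodes[[cn]])
        }
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import an interactome network written by [export_network()]
#'
#' @param path file path.
#' @param format one of "graphml", "json", "tsv".
#' @return an `interactome_network`.
#' @export
import_network <- function(path, format = c("graphml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path)
    nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(doc$edges, stringsAsFactors = FALSE)
  } else if (format == "tsv") {
    edges <- read_tsv(path)
    nodes <- read_tsv(sub("\\.tsv$", "_nodes.tsv", path))
    lg <- grep("^de_", names(nodes))
    nodes[lg] <- lapply(nodes[lg], as.logical)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::as_data_frame(g, what = "vertices")
    nodes$id <- NULL  # igraph re-imports the graphml node id as an attribute
    names(nodes)[names(nodes) == "name"] <- "id"
    rownames(nodes) <- NULL
    lg <- grep("^de_", names(nodes))
    nodes[lg] <- lapply(nodes[lg], function(v) v == "true")
    edges <- igraph::as_data_frame(g, what = "edges")
    names(edges)[names(edges) == "from"] <- "source"
    names(edges)[names(edges) == "to"] <- "target"
    front <- intersect(c("pair_id", "source", "target", "edge_type"),
                       names(edges))
    edges <- edges[, c(front, setdiff(names(edges), front)), drop = FALSE]
  }
  if (nrow(edges) == 0 && !"pair_id" %in% names(edges)) {
    edges <- data.frame(pair_id = character(), source = character(),
                        target = character(), edge_type = character())
  }
  structure(list(nodes = nodes, edges = edges), class = "interactome_network")
}
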