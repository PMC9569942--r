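# Hypergeometric over-representation analysis of network members against
# gene-set collections, with miRNA membership supplied by an annotation
# table rather than live database queries.

#' Upper-tail hypergeometric enrichment p-value
#'
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated items when `n` items are drawn from a universe of
#' `N` containing `K` annotated ones.
#'
#' @param k overlap size(s).
#' @param K set size in the universe.
#' @param n query size in the universe.
#' @param N universe size.
#' @return p-value(s) in (0, 1].
#' @export
ora_test <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0
  if (any(bad)) stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n) and K, n <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a gene-set collection
#'
#' @param sets named list; each element is `list(name = , ontology = ,
#'   members = )` (`members` a character vector of ids).
#' @param universe optional explicit universe; default is the union of all
#'   set members (possibly extended by a miRNA annotation at test time).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named")
  }
  for (s in sets) {
    if (length(s$members) == 0) stop("every set needs at least one member")
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set id, description, then member ids. An
#' ontology label may be embedded in the description as
#' `"ontology|display name"`; otherwise the ontology is `NA`.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    list(name = if (length(desc) > 1) desc[2] else f[2],
         ontology = if (length(desc) > 1) desc[1] else NA_character_,
         members = f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  gene_set_collection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    desc <- if (is.na(s$ontology)) s$name else paste(s$ontology, s$name, sep = "|")
    paste(c(id, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-to-set annotation table
#'
#' Two-column TSV (`mirna`, `set_id`) mapping miRNAs into gene sets, the
#' file-based stand-in for a miRNA-pathway database.
#'
#' @param path TSV path.
#' @return data.frame with columns `mirna`, `set_id`.
#' @export
read_mirna_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("mirna", "set_id") %in% names(df))) {
    stop("annotation must have columns 'mirna' and 'set_id'")
  }
  df
}

#' Over-representation analysis of a query set
#'
#' miRNA members of the query are mapped into sets through the annotation
#' table; each set is then tested with the upper-tail hypergeometric test
#' against the universe (default: union of all set members after miRNA
#' extension). Significance is `p < alpha` on the raw p-value; BH-adjusted
#' values are reported when `adjust = TRUE` and significance is then judged
#' on the adjusted values.
#'
#' @param query character vector of gene and miRNA ids.
#' @param collection a [gene_set_collection()].
#' @param mirna_annotation optional data.frame (`mirna`, `set_id`).
#' @param alpha significance threshold (default 0.05, strict `<`).
#' @param adjust apply BH correction (default FALSE).
#' @return data.frame sorted by p: `set_id`, `name`, `ontology`, `k`, `K`,
#'   `n`, `N`, `overlap_genes`, `overlap_mirnas`, `p` (and `fdr` when
#'   adjusting), `significant`.
#' @export
run_ora <- function(query, collection, mirna_annotation = NULL,
                    alpha = 0.05, adjust = FALSE) {
  if (length(query) == 0) stop("query must be nonempty")
  query <- unique(query)
  members <- lapply(collection$sets, `[[`, "members")
  mirnas <- character()
  if (!is.null(mirna_annotation)) {
    mirnas <- unique(mirna_annotation$mirna)
    for (id in names(members)) {
      add <- mirna_annotation$mirna[mirna_annotation$set_id == id]
      members[[id]] <- unique(c(members[[id]], add))
    }
  }
  universe <- collection$universe
  if (is.null(universe)) universe <- unique(unlist(members))
  if (length(universe) == 0) stop("empty universe")
  q <- intersect(query, universe)
  rows <- lapply(names(members), function(id) {
    set_u <- intersect(members[[id]], universe)
    ov <- intersect(q, set_u)
    data.frame(
      set_id = id,
      name = collection$sets[[id]]$name,
      ontology = collection$sets[[id]]$ontology,
      k = length(ov), K = length(set_u), n = length(q), N = length(universe),
      overlap_genes = paste(sort(setdiff(ov, mirnas)), collapse = " "),
      overlap_mirnas = paste(sort(intersect(ov, mirnas)), collapse = " "),
      p = ora_test(length(ov), length(set_u), length(q), length(universe)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (adjust) {
    res$fdr <- bh_adjust(res$p)
    res$significant <- res$fdr < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
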