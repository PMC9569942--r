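# qPCR delta-CT relative quantification and the group-comparison
# statistics used to validate sequencing-derived markers: technical
# replicates are averaged, each assay's mean CT is referenced against the
# matched control assay (a control gene for mRNA targets, a control miRNA
# for miRNA targets), and relative expression 2^(-dCT) is compared
# between recurrence groups by Mann-Whitney and by Spearman correlation
# with the group indicator.

#' Validate a CT table
#'
#' Long-format qPCR table with one row per technical replicate.
#'
#' @param ct data.frame with columns `sample_id`, `assay_id`, `replicate`,
#'   `ct`; CT values must be finite and positive.
#' @return the validated table.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample_id", "assay_id", "replicate", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("CT table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("CT values must be finite and > 0")
  }
  ct
}

#' Delta-CT relative expression
#'
#' Technical replicates are averaged (arithmetic mean CT) per
#' (sample, assay). Each target assay is referenced against the matched
#' control: gene assays against the control gene, miRNA assays against the
#' control miRNA. dCT = mean CT(target) - mean CT(reference) and relative
#' expression is 2^(-dCT); a reference assay referenced against itself has
#' dCT = 0 and relative expression 1. Samples missing a required reference
#' assay are skipped with a message (recorded in the `"skipped"`
#' attribute).
#'
#' @param ct a CT table (see [validate_ct_table()]).
#' @param assay_types named character vector mapping assay ids to
#'   `"gene"` or `"mirna"`.
#' @param references named character vector
#'   `c(gene = <control gene assay>, mirna = <control miRNA assay>)`;
#'   either entry may be omitted if no assay of that type is present.
#' @return data.frame (`sample_id`, `assay_id`, `mean_ct`, `delta_ct`,
#'   `rel_expr`) with skipped samples in `attr(, "skipped")`.
#' @export
relative_expression <- function(ct, assay_types, references) {
  ct <- validate_ct_table(ct)
  if (!all(ct$assay_id %in% names(assay_types))) {
    stop("assay(s) without a declared type: ",
         paste(setdiff(unique(ct$assay_id), names(assay_types)),
               collapse = ", "))
  }
  types_present <- unique(unname(assay_types[unique(ct$assay_id)]))
  if (!all(types_present %in% names(references))) {
    stop("no reference assay declared for type(s): ",
         paste(setdiff(types_present, names(references)), collapse = ", "))
  }
  agg <- stats::aggregate(ct ~ sample_id + assay_id, data = ct, FUN = mean)
  names(agg)[names(agg) == "ct"] <- "mean_ct"
  out <- list()
  skipped <- list()
  for (s in unique(agg$sample_id)) {
    rows <- agg[agg$sample_id == s, , drop = FALSE]
    ref_ct <- vapply(names(references), function(ty) {
      i <- match(references[[ty]], rows$assay_id)
      if (is.na(i)) NA_real_ else rows$mean_ct[i]
    }, numeric(1))
    need_ty <- unique(unname(assay_types[rows$assay_id]))
    if (any(is.na(ref_ct[need_ty]))) {
      message("sample ", s, " skipped: missing reference assay")
      skipped[[length(skipped) + 1L]] <- data.frame(
        sample_id = s, reason = "missing reference assay",
        stringsAsFactors = FALSE)
      next
    }
    rows$delta_ct <- rows$mean_ct - ref_ct[assay_types[rows$assay_id]]
    rows$rel_expr <- 2^(-rows$delta_ct)
    out[[length(out) + 1L]] <- rows
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), assay_id = character(),
               mean_ct = numeric(), delta_ct = numeric(),
               rel_expr = numeric())
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}

#' Group-comparison statistics on qPCR relative expression
#'
#' Per assay: fold change as the ratio of group summaries of relative
#' expression (medians by default, means by flag) annotated up/down for the
#' BCR group, the two-sided Mann-Whitney p-value, the Spearman correlation
#' between relative expression and the binary group indicator (BCR = 1)
#' with its p-value, and an exclusion flag for assays whose Mann-Whitney p
#' exceeds `alpha` (the rule that removed the non-validated marker from
#' the model).
#'
#' @param records output of [relative_expression()].
#' @param meta sample metadata (`sample_id`, `group` BCR/BRF).
#' @param alpha exclusion threshold (default 0.05).
#' @param fc_method `"median"` (default) or `"mean"` group summary.
#' @param exclude_assays assays to drop from testing (e.g. the reference
#'   assays themselves); default none.
#' @return data.frame (`assay_id`, `fc`, `direction`, `p_mw`, `r_s`,
#'   `p_rs`, `excluded`).
#' @export
qpcr_group_stats <- function(records, meta, alpha = 0.05,
                             fc_method = c("median", "mean"),
                             exclude_assays = character()) {
  fc_method <- match.arg(fc_method)
  meta <- validate_meta(meta)
  records <- records[!(records$assay_id %in% exclude_assays), , drop = FALSE]
  records$group <- meta$group[match(records$sample_id, meta$sample_id)]
  if (any(is.na(records$group))) stop("sample(s) missing from meta")
  out <- list()
  for (a in unique(records$assay_id)) {
    rows <- records[records$assay_id == a, , drop = FALSE]
    x <- rows$rel_expr[rows$group == "BCR"]
    y <- rows$rel_expr[rows$group == "BRF"]
    if (length(x) == 0 || length(y) == 0) {
      message("assay ", a, " skipped: only one group measured")
      next
    }
    summ <- if (fc_method == "median") stats::median else mean
    fc <- summ(x) / summ(y)
    mw <- mw_test(x, y)
    ind <- as.numeric(rows$group == "BCR")
    ctest <- suppressWarnings(
      stats::cor.test(rows$rel_expr, ind, method = "spearman",
                      exact = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      assay_id = a, fc = fc,
      direction = ifelse(fc >= 1, "up", "down"),
      p_mw = mw$p,
      r_s = unname(ctest$estimate), p_rs = ctest$p.value,
      excluded = mw$p > alpha,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(assay_id = character(), fc = numeric(),
               direction = character(), p_mw = numeric(), r_s = numeric(),
               p_rs = numeric(), excluded = logical())
  rownames(res) <- NULL
  res
}
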