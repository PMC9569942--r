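# Differential expression between recurrence (BCR) and recurrence-free (BRF)
# groups: TMM normalization, CPM/log2CPM, Mann-Whitney testing with BH
# correction, per-cohort DE calls and direction-consistent cross-cohort
# intersection.

#' TMM normalization factors
#'
#' Trimmed mean of M-values (Robinson & Oshlack) scaling factors. The
#' reference sample is the one whose upper quartile of library-size-scaled
#' counts is closest to the mean upper quartile. For each sample, M-values
#' (log2 ratio of scaled counts vs the reference) and A-values (average log2
#' abundance) are computed over features nonzero in both samples; the M
#' distribution is trimmed by `logratio_trim` and the A distribution by
#' `sum_trim` (both double-sided), and the factor is 2 to the
#' precision-weighted mean of the surviving M-values (delta-method binomial
#' weights). Factors are rescaled to geometric mean 1.
#'
#' @param counts feature-by-sample count matrix (see [validate_counts()]).
#' @param logratio_trim fraction of M-values trimmed from each tail (default
#'   0.30).
#' @param sum_trim fraction of A-values trimmed from each tail (default 0.05).
#' @param do_weighting use inverse-variance weights (default TRUE).
#' @return data.frame with columns `sample_id`, `lib_size`, `norm_factor`;
#'   the factors multiply to 1 geometrically.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- validate_counts(counts)
  if (ncol(counts) < 2) stop("TMM normalization needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref_i <- if (stats::median(uq) < 1e-20) which.max(lib) else
    which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref_i], lib[j], lib[ref_i],
                    logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = colnames(counts), lib_size = unname(lib),
             norm_factor = unname(f), stringsAsFactors = FALSE)
}

# One observed-vs-reference TMM factor (internal).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.30, sum_trim = 0.05,
                            do_weighting = TRUE) {
  # only features nonzero in both samples yield finite M and A values
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- (log2(p_o) + log2(p_r)) / 2
  # delta-method variance of the M-value under binomial sampling
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  keep <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[keep]; a <- a[keep]; v <- v[keep]
  if (length(m) < 2) {
    warning("fewer than 2 shared nonzero features; factor set to 1")
    return(1)
  }
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  fval <- if (do_weighting) {
    sum(m[keep2] / v[keep2], na.rm = TRUE) / sum(1 / v[keep2], na.rm = TRUE)
  } else {
    mean(m[keep2], na.rm = TRUE)
  }
  if (!is.finite(fval)) fval <- 0
  2^fval
}

#' Counts per million with TMM-adjusted library sizes
#'
#' CPM = count / (library size x TMM factor) x 1e6. The log variant returns
#' log2(CPM + prior), with prior 1 by default so zero counts map to 0.
#'
#' @param counts count matrix.
#' @param factors output of [tmm_factors()] for the same samples; NULL means
#'   all factors 1.
#' @param log return log2(CPM + prior) instead of CPM.
#' @param prior prior count added inside the log (default 1).
#' @return real matrix of the same dimensions as `counts`.
#' @export
cpm_matrix <- function(counts, factors = NULL, log = FALSE, prior = 1) {
  counts <- validate_counts(counts)
  lib <- colSums(counts)
  if (is.null(factors)) {
    f <- rep(1, ncol(counts))
  } else {
    if (!setequal(factors$sample_id, colnames(counts))) {
      stop("normalization factors do not match the count matrix samples")
    }
    f <- factors$norm_factor[match(colnames(counts), factors$sample_id)]
  }
  cpm <- sweep(counts, 2, lib * f, "/") * 1e6
  if (log) log2(cpm + prior) else cpm
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact permutation distribution of U when the pooled sample size is at most
#' 20 and there are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric vectors (the two groups), each nonempty.
#' @return list with `U` (statistic for `x` relative to `y`) and `p`
#'   (two-sided p-value).
#' @export
mw_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    # fully tied data carry no ordering information
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  if (ties && (length(x) + length(y)) <= 20) {
    message("ties present; using the tie-corrected normal approximation")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-feature differential expression between BCR and BRF
#'
#' Normalizes with TMM, computes CPM and log2CPM, and for every feature
#' reports the CPM-mean fold change (BCR over BRF) with up/down direction,
#' the mean log2CPM abundance, the two-sided Mann-Whitney p-value computed on
#' log2CPM values, its BH-adjusted FDR, and the DE call `p <= alpha`
#' (threshold on the raw p-value, with FDR reported alongside).
#'
#' @param counts count matrix.
#' @param meta data.frame with `sample_id` and `group` (BCR/BRF).
#' @param alpha DE threshold on the Mann-Whitney p-value (default 0.05).
#' @param min_abundance drop features with mean log2CPM below this before
#'   testing (default 0 = keep all).
#' @param log_prior prior count for log2CPM (default 1).
#' @return data.frame with columns `feature_id`, `fc`, `direction`,
#'   `log2cpm`, `p_mw`, `fdr`, `is_de`.
#' @export
call_de <- function(counts, meta, alpha = 0.05, min_abundance = 0,
                    log_prior = 1) {
  counts <- validate_counts(counts)
  meta <- validate_meta(meta, colnames(counts))
  for (g in c("BCR", "BRF")) {
    if (sum(meta$group == g) < 2) {
      stop("group ", g, " has fewer than 2 samples")
    }
  }
  factors <- tmm_factors(counts)
  cpm <- cpm_matrix(counts, factors)
  lcpm <- cpm_matrix(counts, factors, log = TRUE, prior = log_prior)
  abundance <- rowMeans(lcpm)
  keep <- abundance >= min_abundance
  cpm <- cpm[keep, , drop = FALSE]
  lcpm <- lcpm[keep, , drop = FALSE]
  bcr <- meta$group == "BCR"
  mean_bcr <- rowMeans(cpm[, bcr, drop = FALSE])
  mean_brf <- rowMeans(cpm[, !bcr, drop = FALSE])
  fc <- mean_bcr / mean_brf
  p <- vapply(seq_len(nrow(lcpm)), function(i) {
    mw_test(lcpm[i, bcr], lcpm[i, !bcr])$p
  }, numeric(1))
  data.frame(
    feature_id = rownames(lcpm),
    fc = fc,
    direction = ifelse(fc >= 1, "up", "down"),
    log2cpm = abundance[keep],
    p_mw = p,
    fdr = bh_adjust(p),
    is_de = p <= alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Direction-consistent cross-cohort DE intersection
#'
#' Features called DE in both cohorts with the same direction (the
#' two-cohort Venn logic), plus the per-cohort up/down partitions.
#'
#' @param res_a,res_b DE result tables from [call_de()] for the two cohorts.
#' @return list with `shared` (feature ids, DE in both with identical
#'   direction), `shared_up`, `shared_down`, and per-cohort `up_a`, `down_a`,
#'   `up_b`, `down_b`.
#' @export
cross_cohort_de <- function(res_a, res_b) {
  part <- function(res, dir) res$feature_id[res$is_de & res$direction == dir]
  up_a <- part(res_a, "up"); down_a <- part(res_a, "down")
  up_b <- part(res_b, "up"); down_b <- part(res_b, "down")
  shared_up <- intersect(up_a, up_b)
  shared_down <- intersect(down_a, down_b)
  list(shared = c(shared_up, shared_down),
       shared_up = shared_up, shared_down = shared_down,
       up_a = up_a, down_a = down_a, up_b = up_b, down_b = down_b)
}

#' Abundance and detection filter for shared DE features
#'
#' Operationalizes "high level and stable distribution of expression": a
#' feature is kept when its median log2CPM is at least `min_median_log2cpm`
#' in every group of every cohort, and it is detected (count > 0) in at
#' least `min_detection_rate` of the samples of every group. This rule is an
#' interpretation of a qualitative criterion; both thresholds are
#' configurable.
#'
#' @param features candidate feature ids.
#' @param cohorts named list; each element is `list(counts = , meta = )` for
#'   one cohort.
#' @param min_median_log2cpm abundance floor (default 1.0).
#' @param min_detection_rate detection floor per group (default 0.8).
#' @return the surviving feature ids.
#' @export
expression_stability_filter <- function(features, cohorts,
                                        min_median_log2cpm = 1.0,
                                        min_detection_rate = 0.8) {
  keep <- rep(TRUE, length(features))
  for (co in cohorts) {
    counts <- validate_counts(co$counts)
    meta <- validate_meta(co$meta, colnames(counts))
    lcpm <- cpm_matrix(counts, tmm_factors(counts), log = TRUE)
    for (g in unique(meta$group)) {
      cols <- meta$sample_id[meta$group == g]
      present <- features %in% rownames(counts)
      med <- rep(-Inf, length(features))
      det <- rep(0, length(features))
      idx <- match(features[present], rownames(counts))
      med[present] <- apply(lcpm[idx, cols, drop = FALSE], 1, stats::median)
      det[present] <- rowMeans(counts[idx, cols, drop = FALSE] > 0)
      keep <- keep & present & med >= min_median_log2cpm &
        det >= min_detection_rate
    }
  }
  features[keep]
}
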