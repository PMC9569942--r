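# Synthetic two-group cohort generator with recorded ground truth:
# negative-binomial count marginals with lognormal library sizes, planted
# fold changes, group-specific miRNA-mRNA correlations planted through a
# Gaussian copula, outcome-associated clinical covariates, interaction
# catalogs, gene sets, and qPCR CT tables. Every downstream stage of the
# pipeline is testable against the recorded truth without external data.

#' Simulation configuration
#'
#' Defaults emulate a locally advanced prostate-cancer cohort split into
#' biochemical-recurrence (BCR) and recurrence-free (BRF) groups: negative
#' binomial counts with lognormal baseline means and gamma-distributed
#' dispersions, lognormal library sizes (CV about 30% so TMM normalization
#' is exercised nontrivially), a fraction of features with a planted
#' multiplicative fold change, optional miRNA-mRNA pairs with
#' group-specific latent correlations, and clinical covariates (ISUP 1-5,
#' pT, Gleason 6-10, preoperative PSA) whose distributions shift with the
#' recurrence label according to log-odds style coefficients.
#'
#' @param n_samples_per_group samples per group (>= 4; Fisher's z needs
#'   n - 3 > 0).
#' @param n_mirna,n_mrna feature counts for the two matrices.
#' @param frac_de fraction of features per matrix with a planted fold
#'   change.
#' @param de_fc planted multiplicative fold change (> 0), applied up for
#'   half the DE features and down for the other half.
#' @param nb_mean_log_mu,nb_mean_log_sigma lognormal parameters of baseline
#'   per-feature means.
#' @param nb_dispersion_shape,nb_dispersion_rate gamma parameters of
#'   per-feature NB dispersions.
#' @param lib_size_cv coefficient of variation of lognormal per-sample
#'   library-size factors.
#' @param planted_pairs data.frame (`mirna`, `mrna`, `rho_bcr`, `rho_brf`)
#'   of latent-correlation pairs; feature ids must exist under the naming
#'   scheme `miR-sim-###` / `gene-sim-####` (see [default_planted_pairs()]).
#' @param n_decoy_edges decoy miRNA-target edges for the catalog.
#' @param clinical_effects named numeric vector of association strengths
#'   (latent-scale shifts for the BCR group): `isup`, `pt`, `gleason`,
#'   `log_psa`.
#' @param ct_intercept,ct_slope,ct_noise_sd qPCR generation parameters:
#'   CT = intercept - slope * log2(expression) + Normal(0, noise).
#' @param seed integer RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples_per_group = 30,
                       n_mirna = 120, n_mrna = 240,
                       frac_de = 0.1, de_fc = 3,
                       nb_mean_log_mu = 4, nb_mean_log_sigma = 1.5,
                       nb_dispersion_shape = 2, nb_dispersion_rate = 20,
                       lib_size_cv = 0.3,
                       planted_pairs = NULL,
                       n_decoy_edges = 0,
                       clinical_effects = c(isup = 0.8, pt = 0.6,
                                            gleason = 0.8, log_psa = 0.5),
                       ct_intercept = 25, ct_slope = 1, ct_noise_sd = 0.15,
                       seed = 1L) {
  if (n_samples_per_group < 4) {
    stop("n_samples_per_group must be >= 4: Fisher's r-to-z variance ",
         "1/(n - 3) requires n - 3 > 0")
  }
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
  if (de_fc <= 0) stop("de_fc must be > 0")
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(mirna = character(), mrna = character(),
                                rho_bcr = numeric(), rho_brf = numeric())
  }
  if (nrow(planted_pairs)) {
    if (any(abs(planted_pairs$rho_bcr) >= 1) ||
        any(abs(planted_pairs$rho_brf) >= 1)) {
      stop("latent correlations must be in (-1, 1)")
    }
  }
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              frac_de = frac_de, de_fc = de_fc,
              nb_mean_log_mu = nb_mean_log_mu,
              nb_mean_log_sigma = nb_mean_log_sigma,
              nb_dispersion_shape = nb_dispersion_shape,
              nb_dispersion_rate = nb_dispersion_rate,
              lib_size_cv = lib_size_cv,
              planted_pairs = planted_pairs,
              n_decoy_edges = as.integer(n_decoy_edges),
              clinical_effects = clinical_effects,
              ct_intercept = ct_intercept, ct_slope = ct_slope,
              ct_noise_sd = ct_noise_sd,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# Feature naming scheme shared by the generator and helpers.
mirna_ids <- function(n) sprintf("miR-sim-%03d", seq_len(n))
gene_ids <- function(n) sprintf("gene-sim-%04d", seq_len(n))

#' Default planted differential-correlation pairs
#'
#' Pairs the last `n_pairs` miRNAs with the last `n_pairs` mRNAs of a
#' configuration's feature namespace (kept disjoint from the leading
#' DE-planted block) with constant latent correlations per group.
#'
#' @param n_pairs number of pairs.
#' @param n_mirna,n_mrna matrix sizes of the target configuration.
#' @param rho_bcr,rho_brf latent (Gaussian-copula) correlations in the two
#'   groups, each in (-1, 1).
#' @return data.frame usable as `planted_pairs` in [sim_config()].
#' @export
default_planted_pairs <- function(n_pairs, n_mirna = 120, n_mrna = 240,
                                  rho_bcr = 0.8, rho_brf = -0.2) {
  stopifnot(n_pairs <= n_mirna, n_pairs <= n_mrna)
  data.frame(
    mirna = mirna_ids(n_mirna)[(n_mirna - n_pairs + 1):n_mirna],
    mrna = gene_ids(n_mrna)[(n_mrna - n_pairs + 1):n_mrna],
    rho_bcr = rho_bcr, rho_brf = rho_brf,
    stringsAsFactors = FALSE
  )
}

#' Spearman correlation implied by a Gaussian-copula latent correlation
#'
#' Closed form for bivariate normal latents: r_s = (6/pi) asin(rho/2).
#'
#' @param rho latent correlation(s) in (-1, 1).
#' @return implied population Spearman correlation(s).
#' @export
copula_spearman <- function(rho) (6 / pi) * asin(rho / 2)

#' Correlated negative-binomial count pair via a Gaussian copula
#'
#' Draws a latent bivariate normal vector with correlation `rho` and maps
#' each margin through the NB quantile function, so the marginals are
#' NB(mu, dispersion) (variance mu + dispersion * mu^2) and the rank
#' dependence approaches the copula closed form
#' [copula_spearman()] for continuous margins.
#'
#' @param mu_x,mu_y NB means (scalar or length `n`, e.g. library-size
#'   scaled).
#' @param dispersion_x,dispersion_y NB dispersions (0 gives Poisson).
#' @param rho latent correlation, |rho| < 1.
#' @param n number of paired draws (>= 4).
#' @return list with integer vectors `x` and `y` of length `n`.
#' @export
generate_correlated_counts <- function(mu_x, mu_y, dispersion_x,
                                       dispersion_y = dispersion_x,
                                       rho, n) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (n < 4) stop("n must be >= 4")
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  qcount <- function(u, mu, disp) {
    if (disp <= 0) stats::qpois(u, lambda = mu)
    else stats::qnbinom(u, mu = mu, size = 1 / disp)
  }
  list(x = qcount(stats::pnorm(z1), mu_x, dispersion_x),
       y = qcount(stats::pnorm(z2), mu_y, dispersion_y))
}

# Ordinal covariate from a shifted latent normal: baseline category
# probabilities define thresholds; the BCR group's latent mean is shifted
# by `effect`, which tilts the distribution toward higher categories.
sample_ordinal <- function(n, baseline_probs, shift) {
  thr <- stats::qnorm(cumsum(baseline_probs))[-length(baseline_probs)]
  u <- stats::rnorm(n) + shift
  findInterval(u, thr) + 1L
}

#' Generate a synthetic two-group cohort
#'
#' Produces miRNA and mRNA count matrices, sample metadata with clinical
#' covariates, and the recorded ground truth (planted DE features, planted
#' correlation pairs with their implied Spearman targets, informative
#' predictors, labels). Deterministic given the configuration seed.
#'
#' DE features occupy the leading `round(frac_de * n_features)` rows of each
#' matrix (alternating up/down); planted correlation pairs must reference
#' features outside that block. Marginal counts are NB with lognormal
#' library-size factors; planted pairs are drawn jointly per group through
#' the Gaussian copula.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: list with `counts_mirna`,
#'   `counts_mrna`, `meta`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples_per_group
  sample_id <- sprintf("S%03d", seq_len(2 * n))
  group <- rep(c("BCR", "BRF"), each = n)
  eff <- config$clinical_effects
  shift <- function(name) ifelse(group == "BCR", eff[[name]], 0)
  # marginals loosely follow the published cohort tables
  meta <- data.frame(
    sample_id = sample_id, group = group,
    isup = sample_ordinal(2 * n, c(0.14, 0.27, 0.28, 0.12, 0.19), shift("isup")),
    pt = c("pT3a", "pT3b", "pT4")[
      sample_ordinal(2 * n, c(0.52, 0.45, 0.03), shift("pt"))],
    gleason = 5L + sample_ordinal(2 * n, c(0.14, 0.56, 0.12, 0.17, 0.01),
                                  shift("gleason")),
    psa = exp(log(12) + 0.6 * stats::rnorm(2 * n) + shift("log_psa")),
    stringsAsFactors = FALSE
  )

  make_matrix <- function(n_feat, ids, planted_idx, planted_rho) {
    mu <- stats::rlnorm(n_feat, config$nb_mean_log_mu, config$nb_mean_log_sigma)
    disp <- stats::rgamma(n_feat, config$nb_dispersion_shape,
                          config$nb_dispersion_rate)
    lib <- stats::rlnorm(2 * n, 0, sqrt(log(1 + config$lib_size_cv^2)))
    n_de <- round(config$frac_de * n_feat)
    de_idx <- seq_len(n_de)
    de_dir <- rep_len(c("up", "down"), n_de)
    if (length(planted_idx) && any(planted_idx %in% de_idx)) {
      stop("planted correlation pairs must not overlap the DE feature block")
    }
    mu_mat <- outer(mu, lib)  # feature x sample expected counts
    if (n_de > 0) {
      fcvec <- ifelse(de_dir == "up", config$de_fc, 1 / config$de_fc)
      mu_mat[de_idx, group == "BCR"] <-
        mu_mat[de_idx, group == "BCR", drop = FALSE] * fcvec
    }
    counts <- matrix(0, n_feat, 2 * n, dimnames = list(ids, sample_id))
    indep <- setdiff(seq_len(n_feat), planted_idx)
    counts[indep, ] <- stats::rnbinom(length(indep) * 2 * n,
                                      mu = mu_mat[indep, , drop = FALSE],
                                      size = 1 / disp[indep])
    list(counts = counts, mu_mat = mu_mat, disp = disp,
         de = if (n_de > 0) data.frame(feature_id = ids[de_idx],
                                       direction = de_dir,
                                       fc = ifelse(de_dir == "up",
                                                   config$de_fc,
                                                   1 / config$de_fc),
                                       stringsAsFactors = FALSE)
              else data.frame(feature_id = character(),
                              direction = character(), fc = numeric()))
  }

  mir_ids <- mirna_ids(config$n_mirna)
  mrna_ids_ <- gene_ids(config$n_mrna)
  pp <- config$planted_pairs
  if (nrow(pp)) {
    if (!all(pp$mirna %in% mir_ids) || !all(pp$mrna %in% mrna_ids_)) {
      stop("planted pairs reference features absent from the configuration")
    }
  }
  mir <- make_matrix(config$n_mirna, mir_ids, match(pp$mirna, mir_ids), pp)
  mrna <- make_matrix(config$n_mrna, mrna_ids_, match(pp$mrna, mrna_ids_), pp)

  # planted pairs: joint draw per group through the Gaussian copula
  if (nrow(pp)) {
    for (i in seq_len(nrow(pp))) {
      mi <- match(pp$mirna[i], mir_ids)
      gi <- match(pp$mrna[i], mrna_ids_)
      for (g in c("BCR", "BRF")) {
        cols <- which(group == g)
        rho <- if (g == "BCR") pp$rho_bcr[i] else pp$rho_brf[i]
        cc <- generate_correlated_counts(
          mu_x = mir$mu_mat[mi, cols], mu_y = mrna$mu_mat[gi, cols],
          dispersion_x = mir$disp[mi], dispersion_y = mrna$disp[gi],
          rho = rho, n = length(cols))
        mir$counts[mi, cols] <- cc$x
        mrna$counts[gi, cols] <- cc$y
      }
    }
  }

  de_features <- rbind(
    if (nrow(mir$de)) cbind(mir$de, matrix_name = "mirna") else NULL,
    if (nrow(mrna$de)) cbind(mrna$de, matrix_name = "mrna") else NULL
  )
  if (is.null(de_features)) {
    de_features <- data.frame(feature_id = character(), direction = character(),
                              fc = numeric(), matrix_name = character())
  }
  truth <- list(
    de_features = de_features,
    diffcor_pairs = if (nrow(pp)) {
      cbind(pp,
            spearman_bcr = copula_spearman(pp$rho_bcr),
            spearman_brf = copula_spearman(pp$rho_brf))
    } else {
      data.frame(mirna = character(), mrna = character(),
                 rho_bcr = numeric(), rho_brf = numeric(),
                 spearman_bcr = numeric(), spearman_brf = numeric())
    },
    informative_predictors = names(eff)[abs(eff) > 0],
    labels = data.frame(sample_id = sample_id, group = group,
                        stringsAsFactors = FALSE),
    features = list(mirna = mir_ids, mrna = mrna_ids_)
  )
  structure(list(counts_mirna = mir$counts, counts_mrna = mrna$counts,
                 meta = meta, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", ncol(x$counts_mirna), "samples,",
      nrow(x$counts_mirna), "miRNAs,", nrow(x$counts_mrna), "mRNAs,",
      nrow(x$truth$de_features), "planted DE features,",
      nrow(x$truth$diffcor_pairs), "planted correlation pairs\n")
  invisible(x)
}

#' Generate a typed interaction catalog around the planted truth
#'
#' All planted pairs enter as validated miRNA-target edges; `n_decoy_edges`
#' additional miRNA-target edges are sampled uniformly among non-planted
#' (miRNA, mRNA) combinations. Optional PPI, TF-target and lncRNA-target
#' decoy edges among/into the mRNA namespace can be appended. No duplicate
#' (source, target, type) triples are produced.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param n_decoy_edges decoy miRNA-target edges.
#' @param n_ppi,n_tf,n_lnc optional decoy edges of the other types.
#' @param seed RNG seed for decoy sampling.
#' @return a catalog data.frame (see [validate_catalog()]).
#' @export
generate_interaction_catalog <- function(truth, n_decoy_edges = 0,
                                         n_ppi = 0, n_tf = 0, n_lnc = 0,
                                         seed = 1L) {
  set.seed(seed)
  mir <- truth$features$mirna
  genes <- truth$features$mrna
  planted_key <- paste(truth$diffcor_pairs$mirna, truth$diffcor_pairs$mrna)
  n_avail <- length(mir) * length(genes) - length(planted_key)
  if (n_decoy_edges > n_avail) {
    stop("requested ", n_decoy_edges, " decoys but only ", n_avail,
         " non-planted (miRNA, mRNA) pairs exist")
  }
  edges <- list()
  if (length(planted_key)) {
    edges$planted <- data.frame(
      source = truth$diffcor_pairs$mirna, target = truth$diffcor_pairs$mrna,
      edge_type = "miRNA-target", evidence = "validated",
      source_db = "synthetic-planted", stringsAsFactors = FALSE)
  }
  if (n_decoy_edges > 0) {
    got <- character(0)
    while (length(got) < n_decoy_edges) {
      cand <- paste(sample(mir, n_decoy_edges, replace = TRUE),
                    sample(genes, n_decoy_edges, replace = TRUE))
      got <- utils::head(unique(c(got, setdiff(cand, planted_key))),
                         n_decoy_edges)
    }
    sp <- strsplit(got, " ", fixed = TRUE)
    edges$decoy <- data.frame(
      source = vapply(sp, `[`, character(1), 1),
      target = vapply(sp, `[`, character(1), 2),
      edge_type = "miRNA-target",
      evidence = sample(c("validated", "predicted"), n_decoy_edges,
                        replace = TRUE),
      source_db = "synthetic-decoy", stringsAsFactors = FALSE)
  }
  pick_pairs <- function(n_edges, src_pool, tgt_pool, type) {
    if (n_edges == 0) return(NULL)
    got <- character(0)
    while (length(got) < n_edges) {
      cand <- paste(sample(src_pool, n_edges, replace = TRUE),
                    sample(tgt_pool, n_edges, replace = TRUE))
      cand <- cand[vapply(strsplit(cand, " "), function(v) v[1] != v[2],
                          logical(1))]
      got <- utils::head(unique(c(got, cand)), n_edges)
    }
    sp <- strsplit(got, " ", fixed = TRUE)
    data.frame(source = vapply(sp, `[`, character(1), 1),
               target = vapply(sp, `[`, character(1), 2),
               edge_type = type, evidence = "n/a",
               source_db = "synthetic-decoy", stringsAsFactors = FALSE)
  }
  edges$ppi <- pick_pairs(n_ppi, genes, genes, "PPI")
  edges$tf <- pick_pairs(n_tf, genes, genes, "TF-target")
  if (n_lnc > 0) {
    lnc <- sprintf("lnc-sim-%03d", seq_len(max(3, ceiling(n_lnc / 3))))
    edges$lnc <- pick_pairs(n_lnc, lnc, genes, "lncRNA-target")
  }
  validate_catalog(do.call(rbind, edges[!vapply(edges, is.null, logical(1))]))
}

#' Generate synthetic gene-set collection and miRNA annotation
#'
#' Builds `n_sets` random gene sets over the cohort's mRNA namespace plus
#' one "signal" set seeded with the planted-pair targets (and their miRNAs
#' in the annotation table), so enrichment of the recovered network is
#' detectable by construction.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param n_sets number of random sets.
#' @param set_size_range inclusive range of random set sizes.
#' @param seed RNG seed.
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `mirna_annotation` (data.frame `mirna`, `set_id`).
#' @export
generate_gene_sets <- function(truth, n_sets = 20,
                               set_size_range = c(10, 40), seed = 1L) {
  set.seed(seed)
  genes <- truth$features$mrna
  sets <- list()
  for (i in seq_len(n_sets)) {
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    sets[[sprintf("SET%03d", i)]] <- list(
      name = sprintf("synthetic pathway %03d", i),
      ontology = sample(c("KEGG", "GO:BP", "Reactome"), 1),
      members = sample(genes, min(sz, length(genes))))
  }
  ann <- data.frame(mirna = character(), set_id = character())
  if (nrow(truth$diffcor_pairs)) {
    signal_members <- unique(truth$diffcor_pairs$mrna)
    filler <- sample(setdiff(genes, signal_members),
                     min(10, length(genes) - length(signal_members)))
    sets[["SET-SIGNAL"]] <- list(name = "planted interactome pathway",
                                 ontology = "KEGG",
                                 members = c(signal_members, filler))
    ann <- data.frame(mirna = unique(truth$diffcor_pairs$mirna),
                      set_id = "SET-SIGNAL", stringsAsFactors = FALSE)
  }
  list(collection = gene_set_collection(sets), mirna_annotation = ann)
}

#' Generate a qPCR CT table from known expression
#'
#' CT = intercept - slope * log2(expression) + Normal(0, noise), with
#' `n_replicates` technical replicates per (sample, assay). Reference
#' assays must be among the expression columns so every sample carries
#' reference rows.
#'
#' @param expression positive matrix, samples x assays, with dimnames.
#' @param reference_assays character vector of reference assay names
#'   (must be columns of `expression`).
#' @param ct_intercept,ct_slope,ct_noise_sd generation parameters.
#' @param n_replicates technical replicates (default 3).
#' @param seed RNG seed.
#' @return data.frame (`sample_id`, `assay_id`, `replicate`, `ct`).
#' @export
generate_ct_table <- function(expression, reference_assays,
                              ct_intercept = 25, ct_slope = 1,
                              ct_noise_sd = 0.15, n_replicates = 3,
                              seed = 1L) {
  if (any(expression <= 0)) stop("expression must be strictly positive")
  if (!all(reference_assays %in% colnames(expression))) {
    stop("reference assays must be columns of the expression matrix")
  }
  set.seed(seed)
  grid <- expand.grid(sample_id = rownames(expression),
                      assay_id = colnames(expression),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expr <- expression[cbind(grid$sample_id, grid$assay_id)]
  grid$ct <- ct_intercept - ct_slope * log2(expr) +
    if (ct_noise_sd > 0) stats::rnorm(nrow(grid), 0, ct_noise_sd) else 0
  grid <- grid[order(grid$sample_id, grid$assay_id, grid$replicate), ]
  rownames(grid) <- NULL
  attr(grid, "reference_assays") <- reference_assays
  grid
}

#' Write synthetic-cohort artifacts to a directory
#'
#' Counts TSVs, metadata TSV and the truth as JSON; deterministic file
#' content given the generator seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "cohort").
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts_mirna = file.path(dir, paste0(prefix, "_counts_mirna.tsv")),
    counts_mrna = file.path(dir, paste0(prefix, "_counts_mrna.tsv")),
    meta = file.path(dir, paste0(prefix, "_meta.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_count_matrix(cohort$counts_mirna, paths["counts_mirna"])
  write_count_matrix(cohort$counts_mrna, paths["counts_mrna"])
  write_tsv(cohort$meta, paths["meta"])
  jsonlite::write_json(cohort$truth, paths["truth"], digits = NA,
                       auto_unbox = FALSE)
  invisible(paths)
}

#' Read a truth record written by [write_cohort()]
#'
#' @param path JSON path.
#' @return the truth list (data.frames restored).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::fromJSON(path)
  tr$features <- list(mirna = unlist(tr$features$mirna),
                      mrna = unlist(tr$features$mrna))
  tr$informative_predictors <- unlist(tr$informative_predictors)
  tr
}

#' Simulate a predictor table for classifier benchmarking
#'
#' Emulates the six-predictor design of the recurrence model: three gene
#' relative-expression predictors, one miRNA predictor, and two ordinal
#' clinical covariates (ISUP 1-5, pT encoded 1-3), each shifted in the BCR
#' group by a standardized effect. Labels are balanced.
#'
#' @param n_per_group samples per class.
#' @param gene_effect standardized shift for the three gene predictors
#'   (default 1.5).
#' @param mirna_effect shift for the miRNA predictor (default 1.0).
#' @param isup_effect,pt_effect latent shifts for the ordinal covariates.
#' @param seed RNG seed.
#' @return list with `x` (numeric matrix, named columns), `y` (0/1 labels,
#'   BCR = 1).
#' @export
generate_predictor_table <- function(n_per_group = 200,
                                     gene_effect = 1.5, mirna_effect = 1.0,
                                     isup_effect = 0.8, pt_effect = 0.6,
                                     seed = 1L) {
  set.seed(seed)
  n <- 2 * n_per_group
  y <- rep(c(1, 0), each = n_per_group)
  shift <- function(e) ifelse(y == 1, e, 0)
  x <- cbind(
    ALDH3A2 = stats::rnorm(n) - shift(gene_effect),  # down in recurrence
    ODF2 = stats::rnorm(n) + shift(gene_effect),
    QSOX2 = stats::rnorm(n) + shift(gene_effect),
    `miR-503` = stats::rnorm(n) + shift(mirna_effect),
    ISUP = sample_ordinal(n, c(0.14, 0.27, 0.28, 0.12, 0.19),
                          shift(isup_effect)),
    pT = sample_ordinal(n, c(0.52, 0.45, 0.03), shift(pt_effect))
  )
  rownames(x) <- sprintf("P%03d", seq_len(n))
  list(x = x, y = y)
}
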