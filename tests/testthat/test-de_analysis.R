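# TMM/CPM normalization, Mann-Whitney testing, BH correction, DE calls
# and cross-cohort intersection.

test_that("TMM factors are 1 for identical and proportional columns", {
  m <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(tmm_factors(m)$norm_factor, rep(1, 3))
  m2 <- cbind(s1 = c(10, 20, 30, 40), s2 = 2 * c(10, 20, 30, 40))
  rownames(m2) <- paste0("g", 1:4)
  expect_equal(tmm_factors(m2)$norm_factor, rep(1, 2))
})

test_that("TMM factors match the unvectorized oracle transcription", {
  fx <- tmm_fixture()
  got <- tmm_factors(fx)$norm_factor
  want <- oracle_tmm_factors(fx)
  expect_equal(got, want, tolerance = 1e-12)
  # random matrices, including zeros
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(rnbinom(20 * 4, mu = 100, size = 1), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    expect_equal(tmm_factors(m)$norm_factor, oracle_tmm_factors(m),
                 tolerance = 1e-12)
  }
})

test_that("TMM factors multiply to 1 and are column-scale invariant", {
  set.seed(7)
  m <- matrix(rnbinom(30 * 5, mu = 300, size = 2), 30, 5,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:5)))
  f <- tmm_factors(m)$norm_factor
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  m2 <- m
  m2[, 2] <- m2[, 2] * 7  # scalar absorbed by the library size
  # exact invariance holds for the unweighted trimmed mean; the
  # inverse-variance weights depend on absolute counts, so the weighted
  # default is only approximately invariant
  expect_equal(tmm_factors(m2, do_weighting = FALSE)$norm_factor,
               tmm_factors(m, do_weighting = FALSE)$norm_factor,
               tolerance = 1e-12)
  expect_equal(tmm_factors(m2)$norm_factor, f, tolerance = 0.05)
})

test_that("TMM rejects zero library sizes and degenerate overlap warns", {
  m <- cbind(s1 = c(1, 2, 0), s2 = c(0, 0, 0))
  rownames(m) <- paste0("g", 1:3)
  expect_error(tmm_factors(m), "zero library size")
  # single shared nonzero feature -> factor 1 with warning
  m2 <- cbind(s1 = c(5, 10, 0), s2 = c(7, 0, 3))
  rownames(m2) <- paste0("g", 1:3)
  expect_warning(f <- tmm_factors(m2), "fewer than 2 shared")
  expect_equal(f$norm_factor, rep(1, 2))
})

test_that("CPM obeys its normalization identities", {
  m <- matrix(c(100, rep(0, 3), 999900, 10), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  m[, 1] <- c(100, 999900, 0)
  m[, 2] <- c(10, 20, 70)
  cpm <- cpm_matrix(m)
  expect_equal(cpm["g1", "a"], 100)  # count 100 in a 1e6 library
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  lcpm <- cpm_matrix(m, log = TRUE)
  expect_equal(lcpm["g3", "a"], 0)  # zero count -> log2(0 + 1) = 0
  # with factors, column sums are 1e6 / factor
  set.seed(5)
  m2 <- matrix(rnbinom(40 * 3, mu = 200, size = 1), 40, 3,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:3)))
  f <- tmm_factors(m2)
  cpm2 <- cpm_matrix(m2, f)
  expect_equal(unname(colSums(cpm2)),
               1e6 / f$norm_factor[match(colnames(m2), f$sample_id)])
  expect_error(cpm_matrix(m2, tmm_factors(m2[, 1:2])), "do not match")
})

test_that("Mann-Whitney exact path equals full enumeration for all small tie-free inputs", {
  # every rank configuration for every split with pooled size <= 10
  for (s in 2:10) {
    for (m in 1:(s - 1)) {
      labelings <- utils::combn(s, m)
      # enumerating every labeling as data covers all rank configurations
      cols <- seq_len(ncol(labelings))
      if (length(cols) > 40) {
        set.seed(s * 100 + m)
        cols <- sample(cols, 40)
      }
      for (ci in cols) {
        x <- as.numeric(labelings[, ci])
        y <- as.numeric(setdiff(1:s, x))
        got <- mw_test(x, y)
        want <- oracle_mw_exact(x, y)
        expect_equal(got$U, want$U)
        expect_equal(got$p, want$p, tolerance = 1e-12)
      }
    }
  }
})

test_that("Mann-Whitney handles the documented examples and edge cases", {
  expect_equal(mw_test(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mw_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mw_test(c(1, 2), c(3, 4))$p, 1 / 3)
  suppressMessages(
    expect_equal(mw_test(rep(1, 5), rep(1, 5))$p, 1)  # identical constants
  )
  expect_error(mw_test(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment equals the hand step-up oracle and its properties hold", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q <= 1) && all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "within")
})

test_that("DE calling is calibrated under the null", {
  # no planted signal: rejection fraction at alpha within 3 binomial SEs
  cfg <- sim_config(n_samples_per_group = 15, n_mirna = 1000, n_mrna = 10,
                    frac_de = 0, seed = 2024)
  co <- generate_cohort(cfg)
  res <- call_de(co$counts_mirna, co$meta)
  frac <- mean(res$is_de)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), 3 * se + 1e-12)
  # p-values roughly uniform (KS on discrete MW p-values is approximate)
  expect_gt(suppressWarnings(ks.test(res$p_mw, "punif")$p.value), 1e-4)
})

test_that("a strongly fold-changed abundant feature is consistently detected", {
  hits <- 0
  for (s in 1:60) {
    cfg <- sim_config(n_samples_per_group = 12, n_mirna = 40, n_mrna = 10,
                      frac_de = 1 / 40, de_fc = 4, nb_mean_log_mu = 6,
                      seed = 9000 + s)
    co <- generate_cohort(cfg)
    res <- call_de(co$counts_mirna, co$meta)
    row <- res[res$feature_id == co$truth$de_features$feature_id[1], ]
    hits <- hits + (row$is_de && row$direction == "up")
  }
  expect_gte(hits / 60, 0.95)
})

test_that("cross-cohort intersection requires identical direction", {
  mk <- function(ids, dirs, de = TRUE) {
    data.frame(feature_id = ids, fc = ifelse(dirs == "up", 2, 0.5),
               direction = dirs, log2cpm = 5, p_mw = 0.01, fdr = 0.05,
               is_de = de, stringsAsFactors = FALSE)
  }
  a <- mk(c("m1", "m2", "m3", "m5"), c("up", "up", "up", "up"))
  b <- mk(c("m2", "m3", "m4", "m5"), c("up", "up", "up", "down"))
  cc <- cross_cohort_de(a, b)
  expect_setequal(cc$shared, c("m2", "m3"))
  expect_false("m5" %in% cc$shared)  # discordant direction
  none_de <- mk("m9", "up", de = FALSE)
  expect_length(cross_cohort_de(a, none_de)$shared, 0)
})

test_that("stability filter applies abundance and detection rules", {
  set.seed(3)
  n <- 10
  meta <- rand_groups_meta(n)
  mk_counts <- function() {
    ids <- c("hi", "dropout", "lo", paste0("filler", 1:20))
    m <- matrix(rnbinom(23 * 2 * n, mu = 5000, size = 5), 23, 2 * n,
                dimnames = list(ids, meta$sample_id))
    m["dropout", which(meta$group == "BCR")[1:(n / 2)]] <- 0  # 50% zeros in one group
    m["lo", ] <- rbinom(2 * n, 1, 0.5)  # near-absent feature
    m
  }
  cohorts <- list(A = list(counts = mk_counts(), meta = meta),
                  B = list(counts = mk_counts(), meta = meta))
  kept <- expression_stability_filter(c("hi", "dropout", "lo"), cohorts)
  expect_equal(kept, "hi")
  # degenerate thresholds make the filter the identity on present features
  all_kept <- expression_stability_filter(
    c("hi", "dropout", "lo"), cohorts,
    min_median_log2cpm = 0, min_detection_rate = 0)
  expect_setequal(all_kept, c("hi", "dropout", "lo"))
})

test_that("TMM agrees with the reference Bioconductor implementation", {
  skip_if_not_installed("edgeR")
  set.seed(19)
  for (i in 1:3) {
    m <- matrix(rnbinom(200 * 6, mu = rlnorm(200, 4, 1.5), size = 2), 200, 6,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
    fe <- suppressWarnings(
      edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors)
    expect_equal(tmm_factors(m)$norm_factor, fe, tolerance = 1e-10)
  }
})
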