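# Independent oracle implementations used to verify the package's
# statistical primitives. These are deliberately written in a different
# style (explicit loops, closed-form enumeration) from the implementations
# they check and must stay independent of R/ code paths.

# Unvectorized transcription of the trimmed-weighted-mean TMM procedure.
oracle_tmm_factors <- function(counts, logratio_trim = 0.30,
                               sum_trim = 0.05) {
  n_samples <- ncol(counts)
  lib <- numeric(n_samples)
  for (j in 1:n_samples) lib[j] <- sum(counts[, j])
  # reference: upper quartile of scaled counts closest to the mean
  uq <- numeric(n_samples)
  for (j in 1:n_samples) {
    uq[j] <- as.numeric(stats::quantile(counts[, j], 0.75)) / lib[j]
  }
  ref <- 1
  best <- Inf
  for (j in 1:n_samples) {
    d <- abs(uq[j] - mean(uq))
    if (d < best) { best <- d; ref <- j }
  }
  f <- numeric(n_samples)
  for (j in 1:n_samples) {
    ms <- c(); as_ <- c(); vs <- c()
    for (g in 1:nrow(counts)) {
      o <- counts[g, j]; r <- counts[g, ref]
      if (o > 0 && r > 0) {
        ms <- c(ms, log2((o / lib[j]) / (r / lib[ref])))
        as_ <- c(as_, 0.5 * (log2(o / lib[j]) + log2(r / lib[ref])))
        vs <- c(vs, (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
      }
    }
    if (length(ms) < 2 || max(abs(ms)) < 1e-6) { f[j] <- 1; next }
    n <- length(ms)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
    num <- 0; den <- 0
    for (i in 1:n) {
      m_rank <- sum(ms < ms[i]) + (sum(ms == ms[i]) + 1) / 2
      a_rank <- sum(as_ < as_[i]) + (sum(as_ == as_[i]) + 1) / 2
      if (m_rank >= lo_m && m_rank <= hi_m && a_rank >= lo_a && a_rank <= hi_a) {
        num <- num + ms[i] / vs[i]
        den <- den + 1 / vs[i]
      }
    }
    f[j] <- 2^(num / den)
  }
  geo <- exp(mean(log(f)))
  f / geo
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(m+n, m) group labelings of the pooled sample (tie-free data).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  u_stat <- function(xs, ys) {
    u <- 0
    for (xi in xs) for (yj in ys) u <- u + (xi > yj)
    u
  }
  u_obs <- u_stat(x, y)
  labelings <- utils::combn(m + n, m)
  us <- apply(labelings, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Hand step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, unsorted order kept.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in m:1) {
    val <- p[o[i]] * m / i
    q_sorted[i] <- if (i == m) min(1, val) else min(q_sorted[i + 1], val, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric probability by direct summation of the mass
# function written with binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  total <- 0
  for (i in k:min(K, n)) {
    total <- total + choose(K, i) * choose(N - K, n - i)
  }
  total / choose(N, n)
}

# AUC as the pairwise concordance probability (ties count one half).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Parameter count of a dense stack by the counting formula.
oracle_param_count <- function(sizes) {
  total <- 0
  for (l in 1:(length(sizes) - 1)) {
    total <- total + (sizes[l] + 1) * sizes[l + 1]
  }
  total
}

# Small deterministic count fixture: 6 genes x 3 samples, sample 3
# carrying one 10-fold inflated gene.
tmm_fixture <- function() {
  m <- matrix(c(100, 200, 300, 400, 500, 600,
                110, 190, 310, 390, 510, 590,
                100, 200, 300, 400, 500, 6000),
              nrow = 6, ncol = 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  m
}

# Random two-group expression for correlation tests.
rand_groups_meta <- function(n_per_group) {
  data.frame(sample_id = sprintf("S%02d", 1:(2 * n_per_group)),
             group = rep(c("BCR", "BRF"), each = n_per_group),
             stringsAsFactors = FALSE)
}
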