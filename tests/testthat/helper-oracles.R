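# Independent oracles and fixture builders used across the suite.

# quadratic all-pairs membership scan (half-open intervals)
brute_force_overlap <- function(sites, intervals) {
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(intervals))) {
      if (sites$chrom[i] == intervals$chrom[j] &&
            sites$pos[i] >= intervals$start[j] &&
            sites$pos[i] < intervals$end[j]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(site = integer(), interval = integer()))
  m <- do.call(rbind, hits)
  data.frame(site = m[, 1L], interval = m[, 2L])
}

# OLS via the normal equations, with classical t-statistics
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * sigma2))
  tval <- as.numeric(beta) / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = as.numeric(beta), se = se, t = tval, p = p, df = df)
}

# Benjamini-Hochberg step-up: q_i = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][i:m] / (i:m))
  }
  pmin(q_sorted, 1)[order(o)]
}

# textbook Welch two-sample t-test
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (mean(x) - mean(y)) / se
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), se = se)
}

# textbook Student pooled-variance two-sample t-test
student_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(x) - mean(y)) / se
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), se = se)
}

# random fixtures -----------------------------------------------------

random_site_calls <- function(n, chroms = c("chr1", "chr2"),
                              max_pos = 1000L, mark = "mc") {
  pos <- sample.int(max_pos, n, replace = TRUE) - 1L
  cs <- stats::rpois(n, 12)
  cm <- stats::rbinom(n, cs, stats::runif(n))
  data.frame(chrom = sample(chroms, n, replace = TRUE), pos = pos,
             mark = mark, called_sites = cs, called_modified = cm,
             modified_fraction = ifelse(cs > 0L, cm / cs, NA_real_),
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1000L,
                             labels = c("Enh", "TssA", "Quies"),
                             cell_types = "PBMC") {
  s <- sample.int(max_pos - 10L, n, replace = TRUE) - 1L
  w <- sample.int(60L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = s,
             end = s + w, label = sample(labels, n, replace = TRUE),
             cell_type = sample(cell_types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small quick cohort configuration for pipeline-level tests
tiny_config <- function(seed = 11, n_intervals = 40,
                        sites_per_interval = 20, n_tf = 6,
                        n_effect_tf = 2, tf_intervals_per_tf = 15, ...) {
  prof <- default_region_profile()
  prof <- prof[prof$label %in% c("Enh", "TssA", "Tx", "Quies"), ]
  sim_config(region_profile = prof, n_intervals = n_intervals,
             sites_per_interval = sites_per_interval,
             timepoints = c(0, 12), n_tf = n_tf,
             n_effect_tf = n_effect_tf,
             tf_intervals_per_tf = tf_intervals_per_tf, seed = seed, ...)
}
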