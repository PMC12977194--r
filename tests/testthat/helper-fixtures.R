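# Shared fixture builders for the test suite.

# Minimal epoch object wrapping a given envelope matrix (raw/hg mirrors).
make_epochs <- function(env, times_ms, alignment = "stimulus",
                        site_id = "site", fs = 1000) {
  env <- as.matrix(env)
  structure(list(raw = env, hg = env, env = env, times_ms = times_ms,
                 alignment = alignment, fs = fs,
                 trial_index = seq_len(nrow(env)), site_id = site_id),
            class = "hg_epochs")
}

# Minimal ERBP object from a values matrix.
make_erbp <- function(values, times_ms, alignment = "stimulus",
                      site_id = "site") {
  values <- as.matrix(values)
  structure(list(values = values, times_ms = times_ms, alignment = alignment,
                 trial_index = seq_len(nrow(values)), site_id = site_id,
                 baseline_db = rep(0, nrow(values))),
            class = "hg_erbp")
}

# Three-trial event table: two targets (one pressed) and one nontarget.
make_events <- function() {
  data.frame(onset_s = c(1, 3, 5), duration_s = 0.3,
             label = c("cat", "five", "dog"),
             is_target = c(TRUE, FALSE, TRUE),
             press_s = c(1.8, NA, NA),
             rt_ms = c(800, NA, NA),
             outcome = NA_character_, stringsAsFactors = FALSE)
}

# Brute-force two-sided Fisher exact p by hypergeometric enumeration.
fisher_enum <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x)
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k), 0)
  p <- exp(logp)
  pobs <- p[a - lo + 1]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Hand step-up BH adjustment straight from the definition.
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(o)]
}

# Exact two-sided one-sample Wilcoxon signed-rank p by enumerating all
# sign assignments (requires distinct nonzero magnitudes).
wilcox_enum <- function(v) {
  stopifnot(all(v != 0), !any(duplicated(abs(v))))
  n <- length(v)
  r <- rank(abs(v))
  vobs <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vd <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vd <= vobs), mean(vd >= vobs)))
}

# Spearman rho by explicit average-ranking and the Pearson product-moment
# formula on the ranks.
spearman_brute <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
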