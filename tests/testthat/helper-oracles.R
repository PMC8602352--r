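# independent oracles: written against the definitions, not the package code

# Poisson upper tail P(X >= k | lambda) by direct series accumulation
pois_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  terms <- exp(-lambda) * cumprod(c(1, lambda / seq_len(max(k - 1, 0))))
  max(1 - sum(terms), 0)
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration
hyper_tail_oracle <- function(k, N, K, n) {
  j <- max(k, max(0, n - (N - K))):min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# BH step-up by the definitional formula
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  sapply(seq_len(m), function(i)
    min(1, (m * p[p >= p[i]] / r[p >= p[i]])))
}

# brute-force island caller: same definitions, independent mechanics.
# Enumerates every candidate run by scanning, computes eligibility and
# scores with series-based tails and the definitional BH.
island_oracle <- function(ip_counts, input_counts, w, chrom_len, ip_lib,
                          input_lib, gap = 3, p0 = 0.2, q_max = 0.05,
                          floor_factor = 1) {
  lambda_w <- ip_lib * w / chrom_len
  n <- length(ip_counts)
  elig <- vapply(seq_len(n), function(i)
    ip_counts[i] >= 1 && pois_tail_oracle(ip_counts[i], lambda_w) <= p0,
    logical(1))
  # enumerate candidates: walk every eligible start not preceded (within
  # gap) by another eligible window, extend while gaps stay <= gap
  cands <- list()
  i <- 1
  while (i <= n) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i; k <- i
    while (k < n) {
      nxt <- NA
      for (g in 1:(gap + 1)) {
        if (k + g <= n && elig[k + g]) { nxt <- k + g; break }
      }
      if (is.na(nxt)) break
      k <- nxt
    }
    cands[[length(cands) + 1]] <- c(i, k)
    i <- k + 1
  }
  if (!length(cands))
    return(data.frame(start = integer(), end = integer(),
                      ip_count = integer(), expected = numeric(),
                      fold = numeric(), p = numeric(), q = numeric()))
  rows <- lapply(cands, function(ck) {
    sel <- ck[1]:ck[2]
    ipc <- sum(ip_counts[sel]); inc <- sum(input_counts[sel])
    start <- (ck[1] - 1) * w; end <- min(ck[2] * w, chrom_len)
    scale <- if (input_lib > 0) ip_lib / input_lib else 0
    expected <- max(inc * scale,
                    floor_factor * (end - start) * ip_lib / chrom_len)
    data.frame(start = start, end = end, ip_count = ipc,
               expected = expected, fold = ipc / expected,
               p = pois_tail_oracle(ipc, expected))
  })
  res <- do.call(rbind, rows)
  res$q <- bh_oracle(res$p)
  res[res$q <= q_max & res$fold > 1, , drop = FALSE]
}

# brute-force GSEA running-sum statistic
gsea_es_oracle <- function(scores, gene_set, p = 1) {
  ord <- order(scores, decreasing = TRUE)
  g <- names(scores)[ord]; s <- scores[ord]
  hit <- g %in% gene_set
  nh <- sum(abs(s[hit])^p)
  run <- 0; best <- 0
  for (i in seq_along(g)) {
    run <- run + if (hit[i]) abs(s[i])^p / nh else -1 / (length(g) - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# simulate an NB null count matrix for DE calibration
simulate_null_counts <- function(n_genes, mu_log_mean = log(200),
                                 mu_log_sd = 1, alpha = 0.05, n_rep = 3,
                                 seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, mu_log_mean, mu_log_sd))
  m <- matrix(rnbinom(n_genes * 2 * n_rep, mu = rep(mu, 2 * n_rep),
                      size = 1 / alpha), nrow = n_genes)
  rownames(m) <- sprintf("g%05d", seq_len(n_genes))
  colnames(m) <- c(paste0("A_r", 1:n_rep), paste0("B_r", 1:n_rep))
  count_matrix(m, stages = rep(c("A", "B"), each = n_rep),
               gene_lengths = stats::setNames(rep(1000, n_genes),
                                              rownames(m)))
}
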