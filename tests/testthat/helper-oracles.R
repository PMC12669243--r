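# Independent brute-force oracles used to check the fast implementations.
# Everything here enumerates explicitly and is deliberately naive.

# window scan: enumerate every window with loops
oracle_window_scan <- function(calls, params) {
  s <- length(calls)
  if (s == 0) return(logical(0))
  w <- params$window_snp
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  windows <- if (s < w) list(seq_len(s)) else
    lapply(seq_len(s - w + 1), function(i) i:(i + w - 1))
  pass <- vapply(windows, function(ix)
    sum(het[ix]) <= params$window_het_max &&
      sum(mis[ix]) <= params$window_missing_max, logical(1))
  first <- vapply(windows, min, numeric(1))
  last <- vapply(windows, max, numeric(1))
  flags <- logical(s)
  for (j in seq_len(s)) {
    containing <- first <= j & j <= last
    flags[j] <- sum(pass[containing]) / sum(containing) >=
      params$window_threshold
  }
  flags
}

# segment assembly: naive loop over eligible runs with explicit gap splits
oracle_call_segments <- function(eligible, pos, params) {
  segs <- NULL
  i <- 1
  s <- length(eligible)
  while (i <= s) {
    if (!eligible[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= s && eligible[j + 1] &&
           (pos[j + 1] - pos[j]) / 1000 <= params$max_gap_kb) j <- j + 1
    n <- j - i + 1
    len_kb <- (pos[j] - pos[i] + 1) / 1000
    if (n >= params$min_snp && len_kb >= params$min_kb &&
        len_kb / n <= params$max_density_kb_per_snp)
      segs <- rbind(segs, data.frame(pos_start = pos[i], pos_end = pos[j],
                                     n_snps = n))
    i <- j + 1
  }
  segs
}

# HWE exact test by direct enumeration with plain factorials (exact for
# small N); independent of the log-space implementation
oracle_hwe <- function(n1, nh, n2) {
  n <- n1 + nh + n2
  nm <- 2 * min(n1, n2) + nh
  if (nm == 0 || nm == 2 * n) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  weights <- sapply(hets, function(h) {
    a <- (nm - h) / 2
    b <- n - h - a
    factorial(n) / (factorial(a) * factorial(h) * factorial(b)) * 2^h
  })
  probs <- weights / sum(weights)
  obs <- probs[hets == nh]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# exact permutation p-value for Spearman correlation (tiny n only)
oracle_spearman_perm <- function(x, y) {
  n <- length(x)
  perms <- permutations_of(seq_len(n))
  r_obs <- abs(cor(rank(x), rank(y)))
  rs <- apply(perms, 1, function(pp) abs(cor(rank(x), rank(y[pp]))))
  mean(rs >= r_obs - 1e-12)
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# bp-level Jaccard between two segment tables over a cohort
segment_jaccard <- function(called, truth) {
  inter <- 0; len_called <- 0; len_truth <- 0
  keys <- unique(rbind(truth[, c("sample_id", "chrom")],
                       data.frame(sample_id = called$sample_id,
                                  chrom = called$chrom)))
  for (k in seq_len(nrow(keys))) {
    tr <- truth[truth$sample_id == keys$sample_id[k] &
                  truth$chrom == keys$chrom[k], , drop = FALSE]
    ca <- called[called$sample_id == keys$sample_id[k] &
                   called$chrom == keys$chrom[k], , drop = FALSE]
    len_truth <- len_truth + sum(tr$end - tr$start + 1)
    len_called <- len_called + sum(ca$pos_end - ca$pos_start + 1)
    for (a in seq_len(nrow(tr))) for (b in seq_len(nrow(ca)))
      inter <- inter + max(0, min(tr$end[a], ca$pos_end[b]) -
                             max(tr$start[a], ca$pos_start[b]) + 1)
  }
  inter / (len_called + len_truth - inter)
}
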