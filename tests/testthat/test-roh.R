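test_that("window scan flags the degenerate extremes", {
  p <- roh_params()
  expect_false(any(window_scan(rep(1L, 300), p)))      # all heterozygous
  flags <- window_scan(rep(0L, 300), p)                # all homozygous
  expect_true(all(flags))
  # chromosome shorter than one window: single truncated window
  expect_true(all(window_scan(rep(2L, 20), p)))
  expect_false(any(window_scan(c(rep(2L, 18), 1L, 1L), p)))
})

test_that("window scan equals the brute-force window enumerator", {
  p <- roh_params()
  set.seed(101)
  for (i in 1:30) {
    s <- sample(30:400, 1)
    calls <- sample(c(0L, 1L, 2L, NA), s, replace = TRUE,
                    prob = c(0.45, 0.07, 0.45, 0.03))
    # salt with homozygous tracts so some windows pass
    tr <- sort(sample(s, 2))
    calls[tr[1]:tr[2]] <- sample(c(0L, 2L), tr[2] - tr[1] + 1, replace = TRUE)
    expect_identical(window_scan(calls, p), oracle_window_scan(calls, p))
  }
})

test_that("segments form on homozygous tracts and honor the minimums", {
  p <- roh_params()
  pos <- seq(1e6, by = 2e6 / 299, length.out = 300)  # 300 SNPs over 2 Mb
  calls <- rep(2L, 300)
  segs <- call_segments(window_scan(calls, p), pos, calls, p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 300)
  expect_equal(segs$length_kb, (pos[300] - pos[1] + 1) / 1000)
  # 90-SNP homozygous run (< min_snp) amid heterozygous flanks: no segment
  calls <- rep(1L, 300)
  calls[100:189] <- 0L
  pos <- seq_len(300) * 2e4
  segs <- call_segments(window_scan(calls, p), pos, calls, p)
  expect_equal(nrow(segs), 0)
})

test_that("a gap above max_gap_kb splits an otherwise eligible run", {
  p <- roh_params()
  pos <- c(seq_len(150) * 1e4, 3e6 + seq_len(150) * 1e4)  # 1.51 Mb gap
  calls <- rep(0L, 300)
  segs <- call_segments(rep(TRUE, 300), pos, calls, p)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_snps, c(150, 150))
})

test_that("caller matches the brute-force oracle on random mosaics", {
  p <- roh_params(min_snp = 20, min_kb = 150)  # so small instances can fire
  set.seed(202)
  for (i in 1:40) {
    s <- sample(100:500, 1)
    calls <- sample(c(0L, 1L, 2L, NA), s, replace = TRUE,
                    prob = c(0.4, 0.15, 0.4, 0.05))
    n_tracts <- sample(1:3, 1)
    for (k in seq_len(n_tracts)) {
      tr <- sort(sample(s, 2))
      calls[tr[1]:tr[2]] <- sample(c(0L, 2L), tr[2] - tr[1] + 1,
                                   replace = TRUE)
    }
    pos <- cumsum(1 + round(rexp(s, 1e-4)))
    flags <- window_scan(calls, p)
    mine <- call_segments(flags, pos, calls, p)
    orc <- oracle_call_segments(oracle_window_scan(calls, p), pos, p)
    if (is.null(orc)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(nrow(mine), nrow(orc))
      expect_equal(mine$pos_start, orc$pos_start)
      expect_equal(mine$pos_end, orc$pos_end)
      expect_equal(mine$n_snps, orc$n_snps)
    }
  }
})

test_that("eligibility and emission respond monotonically to thresholds", {
  set.seed(303)
  calls <- sample(c(0L, 1L, 2L), 400, replace = TRUE, prob = c(.45, .1, .45))
  calls[100:350] <- sample(c(0L, 2L), 251, replace = TRUE)
  pos <- seq_len(400) * 1e4
  loose <- window_scan(calls, roh_params(window_threshold = 0.02))
  tight <- window_scan(calls, roh_params(window_threshold = 0.05))
  expect_true(all(loose >= tight))   # lowering threshold never removes a SNP
  p_lo <- roh_params(min_snp = 50, min_kb = 500)
  p_hi <- roh_params(min_snp = 50, min_kb = 2000)
  n_lo <- nrow(call_segments(tight, pos, calls, p_lo))
  n_hi <- nrow(call_segments(tight, pos, calls, p_hi))
  expect_gte(n_lo, n_hi)             # raising min_kb never adds a segment
})

test_that("inclusion matrix places boundary SNPs inside", {
  variants <- data.frame(chrom = "1", id = paste0("v", 1:4), cm = 0,
                         pos = c(99, 100, 200, 201),
                         allele1 = "A", allele2 = "C")
  seg <- data.frame(sample_id = "s1", chrom = "1", pos_start = 100,
                    pos_end = 200, n_snps = 2L)
  r <- inclusion_matrix(seg, variants, c("s1", "s2"))
  expect_equal(unname(r["s1", ]), c(0L, 1L, 1L, 0L))
  expect_equal(unname(r["s2", ]), rep(0L, 4))
  expect_equal(unname(inclusion_matrix(seg[0, ], variants, "s1")[1, ]),
               rep(0L, 4))
  expect_error(inclusion_matrix(
    data.frame(sample_id = "ghost", chrom = "1", pos_start = 1,
               pos_end = 2, n_snps = 1L), variants, "s1"), "unknown")
})

test_that("froh follows its defining ratio and is order-invariant", {
  p <- roh_params()   # genome 3e9
  segs <- data.frame(sample_id = c("a", "a", "b"), chrom = c("1", "2", "3"),
                     pos_start = c(1, 1, 1),
                     pos_end = c(1e8, 5e7, 1.35e8),
                     n_snps = 100L)
  f <- froh(segs, c("a", "b", "c"), p)
  expect_equal(unname(f["a"]), 0.05)       # 150 Mb / 3 Gb
  expect_equal(unname(f["b"]), 0.045)      # 135 Mb (a cohort-mean-like value)
  expect_equal(unname(f["c"]), 0)
  shuffled <- segs[c(3, 1, 2), ]
  expect_equal(froh(shuffled, c("a", "b", "c"), p), f)
})

test_that("cohort summary reproduces the carrier-class arithmetic", {
  # 455 samples: 18 with no segments, 6 with only short (<= 1.6 Mb),
  # the rest with one long segment each
  n <- 455
  samples <- sprintf("i%03d", seq_len(n))
  long_ids <- samples[25:n]
  segs <- rbind(
    data.frame(sample_id = samples[19:24], chrom = "1", pos_start = 1,
               pos_end = 1.2e6, n_snps = 150L),
    data.frame(sample_id = long_ids, chrom = "1", pos_start = 1,
               pos_end = 3e6, n_snps = 300L))
  s <- summarize_roh(segs, samples)
  expect_equal(s$cohort$pct_no_roh, 4.0)
  expect_equal(s$cohort$pct_short_only, 1.3)
  expect_equal(s$cohort$pct_any_long, 94.7)
  expect_equal(s$cohort$n_no_roh + s$cohort$n_short_only +
                 s$cohort$n_any_long, n)
  # 10 samples, 5 segments total -> average 0.5 runs per sample
  s2 <- summarize_roh(segs[1:5, ], samples[15:24])
  expect_equal(s2$cohort$avg_n_roh, 0.5)
  expect_error(summarize_roh(segs, character(0)), "no samples")
})

test_that("carrier percentages round to one decimal", {
  expect_equal(carrier_pct(96, 455), 21.1)
  expect_equal(carrier_pct(0, 455), 0.0)
  expect_equal(carrier_pct(455, 455), 100.0)
})

test_that("region_frequency merges contiguous enriched runs", {
  samples <- sprintf("s%02d", 1:20)
  variants <- data.frame(chrom = "1", id = paste0("v", 1:10), cm = 0,
                         pos = seq_len(10) * 1e3, allele1 = "A",
                         allele2 = "C")
  # variants 4-6 inside ROH of 5 samples (25%), variant 9 in 3 (15%)
  segs <- rbind(
    data.frame(sample_id = samples[1:5], chrom = "1", pos_start = 4e3,
               pos_end = 6e3, n_snps = 3L),
    data.frame(sample_id = samples[6:8], chrom = "1", pos_start = 9e3,
               pos_end = 9e3, n_snps = 1L))
  r <- inclusion_matrix(segs, variants, samples)
  rf <- region_frequency(r, variants, thresholds = c(0.20, 0.15))
  expect_equal(rf$frequency$freq[4:6], rep(0.25, 3))
  at20 <- rf$regions[rf$regions$threshold == 0.20, ]
  expect_equal(nrow(at20), 1)
  expect_equal(c(at20$start, at20$end, at20$n_snps), c(4e3, 6e3, 3))
  expect_equal(at20$carrier_pct, 25.0)
  at15 <- rf$regions[rf$regions$threshold == 0.15, ]
  expect_equal(nrow(at15), 2)   # the 25% run plus the 15% singleton
  # carrier rule sensitivity: requiring every SNP of the region can only
  # reduce the carrier count relative to the >= 1 SNP rule
  cols <- 4:6
  any_rule <- sum(rowSums(r[, cols]) > 0)
  all_rule <- sum(rowSums(r[, cols]) == length(cols))
  expect_gte(any_rule, all_rule)
  expect_equal(at20$n_carriers, any_rule)
})

test_that("call_roh output is invariant to sample order", {
  g <- hwe_genotypes(n = 6, m = 600, seed = 21, n_chrom = 2)
  g$calls[2, 100:300] <- sample(c(0L, 2L), 201, replace = TRUE)
  p <- roh_params(min_snp = 50, min_kb = 400)
  a <- call_roh(g, p)
  perm <- c(4, 2, 6, 1, 3, 5)
  b <- call_roh(subset_genotypes(g, samples = perm), p)
  key <- function(s) s[order(s$sample_id, s$chrom, s$pos_start),
                       c("sample_id", "chrom", "pos_start", "pos_end",
                         "n_snps")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})
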