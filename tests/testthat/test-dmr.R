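# evenly spaced CpG positions well inside the default max_gap
pos_seq <- function(n, from = 1000, by = 100) seq(from, by = by,
                                                  length.out = n)

test_that("candidate windows require 5 CpGs within the gap limit", {
  mk <- function(n) toy_pair(pos_seq(n), rep(5, n), rep(5, n),
                             rep(5, n), rep(5, n))
  expect_equal(nrow(segment_candidates(mk(4))), 0L)
  expect_equal(nrow(segment_candidates(mk(5))), 1L)
  cands <- segment_candidates(mk(20))
  expect_equal(nrow(cands), 16L)
  # brute-force enumeration oracle
  pos <- pos_seq(20)
  expected <- lapply(1:16, function(i) pos[i:(i + 4)])
  got <- lapply(seq_len(nrow(cands)), function(i) {
    idx <- cands$site_idx[[i]]
    attr(cands, "sites")$pos[idx]
  })
  expect_equal(got, expected, ignore_attr = TRUE)
  # a large gap splits the run
  pos2 <- c(pos_seq(5), pos_seq(5, from = 10000))
  split <- segment_candidates(toy_pair(pos2, rep(5, 10), rep(5, 10),
                                       rep(5, 10), rep(5, 10)))
  expect_equal(nrow(split), 2L)
  # CHG/CHH sites never enter windows
  s_mixed <- list(
    toy_sample("T1", "tumor", pos_seq(6), rep(5, 6), rep(5, 6),
               context = c(rep("CG", 4), "CHH", "CG")),
    toy_sample("N1", "normal", pos_seq(6), rep(5, 6), rep(5, 6),
               context = c(rep("CG", 4), "CHH", "CG")))
  expect_equal(nrow(segment_candidates(s_mixed)), 1L)
})

test_that("region statistics match exact enumeration and the fold rule", {
  # identical pooled counts -> fold 1, p 1
  sam <- toy_pair(pos_seq(5), rep(10, 5), rep(10, 5), rep(10, 5),
                  rep(10, 5))
  cand <- segment_candidates(sam)
  st <- region_test(cand[1, ], attr(cand, "sites"))
  expect_equal(st$fold, 1)
  expect_equal(st$p_value, 1)

  # hypergeometric enumeration oracle on the pooled 2x2 table
  # (five sites of 8m/2u vs 2m/8u pool to 40/10 vs 10/40)
  sam2 <- toy_pair(pos_seq(5), rep(8, 5), rep(2, 5),
                   rep(2, 5), rep(8, 5))
  cand2 <- segment_candidates(sam2)
  st2 <- region_test(cand2[1, ], attr(cand2, "sites"))
  expect_equal(st2$p_value, fisher_p_enum(40, 10, 10, 40),
               tolerance = 1e-12)
  expect_equal(st2$p_value,
               stats::fisher.test(matrix(c(40, 10, 10, 40), 2))$p.value)

  # regularized fold: levels 0.80 vs 0.20 -> (0.81)/(0.21)
  sam3 <- toy_pair(1000, 80, 20, 20, 80)
  sites3 <- usable_sites(sam3)
  st3 <- region_test(list(site_idx = 1L), sites3)
  expect_equal(st3$fold, 0.81 / 0.21)
  expect_equal(st3$direction, "hyper")
})

test_that("a fold of exactly 2 after regularization is rejected", {
  # pooled levels 0.99 and 0.49 give (0.99+0.01)/(0.49+0.01) = 2
  n <- 5
  sam <- toy_pair(pos_seq(n), rep(99, n), rep(1, n), rep(49, n),
                  rep(51, n))
  sites <- usable_sites(sam)
  st <- region_test(list(site_idx = seq_len(n)), sites)
  expect_equal(st$fold, 2)
  expect_lt(st$p_value, 0.05)
  expect_equal(nrow(call_dmrs(sam)), 0L)
})

test_that("planted regions are called with the right direction", {
  # strong hyper block flanked by background
  pos <- pos_seq(30)
  mu_t <- c(rep(0.3, 10), rep(0.8, 8), rep(0.3, 12))
  mu_n <- c(rep(0.3, 10), rep(0.2, 8), rep(0.3, 12))
  set.seed(101)
  mk <- function(mu, id, grp) {
    cov <- rep(30L, 30)
    m <- rbinom(30, cov, mu)
    toy_sample(id, grp, pos, m, cov - m)
  }
  samples <- list(mk(mu_t, "T1", "tumor"), mk(mu_t, "T2", "tumor"),
                  mk(mu_t, "T3", "tumor"), mk(mu_n, "N1", "normal"),
                  mk(mu_n, "N2", "normal"), mk(mu_n, "N3", "normal"))
  dmrs <- call_dmrs(samples)
  expect_gte(nrow(dmrs), 1L)
  expect_true(all(dmrs$direction == "hyper"))
  planted <- c(pos[11] - 1, pos[18])
  expect_true(any(dmrs$start < planted[2] & dmrs$end > planted[1]))
})

test_that("every emitted DMR re-verifies the full criterion", {
  st <- small_study(seed = 23, n_dmr = 4, n_genes = 30)
  dmrs <- merge_dmrs(call_dmrs(st$meth$samples))
  sites <- attr(dmrs, "sites")
  expect_gte(nrow(dmrs), 1L)
  for (i in seq_len(nrow(dmrs))) {
    idx <- which(sites$chrom == dmrs$chrom[i] &
                 sites$pos > dmrs$start[i] & sites$pos <= dmrs$end[i])
    stt <- region_test(list(site_idx = idx), sites)
    expect_gte(length(idx), 5L)
    expect_gt(stt$fold, 2)
    expect_lt(stt$p_value, 0.05)
    expect_equal(stt$direction, dmrs$direction[i])
    expect_equal(stt$level_tumor, dmrs$level_tumor[i])
    expect_equal(stt$level_normal, dmrs$level_normal[i])
  }
})

test_that("the caller matches a naive window-enumeration oracle", {
  # random small instances, <= 30 CpGs, mixed directions
  for (seed in c(1, 2, 5, 8)) {
    set.seed(seed * 100)
    n <- sample(10:30, 1)
    pos <- cumsum(sample(c(50, 100, 200, 500), n, replace = TRUE))
    mu_t <- sample(c(0.1, 0.3, 0.8), n, replace = TRUE)
    mu_n <- ifelse(mu_t == 0.8, 0.15,
                   ifelse(mu_t == 0.1, 0.75, 0.3))
    cov <- rep(40L, n)
    samples <- list()
    for (r in 1:2) {
      m <- rbinom(n, cov, mu_t)
      samples[[r]] <- toy_sample(paste0("T", r), "tumor", pos, m, cov - m)
    }
    for (r in 1:2) {
      m <- rbinom(n, cov, mu_n)
      samples[[2 + r]] <- toy_sample(paste0("N", r), "normal", pos, m,
                                     cov - m)
    }
    got <- call_dmrs(samples)
    want <- naive_dmr_call(usable_sites(samples))
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start, info = paste("seed", seed))
      expect_equal(got$end, want$end)
      expect_equal(got$n_cpg, want$n_cpg)
      expect_equal(got$direction, want$direction)
    }
  }
})

test_that("adjacent same-direction DMRs merge when the span qualifies", {
  # two strong hyper blocks separated by tumor-high CpGs whose windows
  # are individually too weak
  pos <- pos_seq(16)
  mu_t <- c(rep(0.85, 5), rep(0.75, 6), rep(0.85, 5))
  mu_n <- c(rep(0.15, 5), rep(0.45, 6), rep(0.15, 5))
  cov <- 60L
  # expected counts, no sampling noise
  m_t <- round(cov * mu_t); m_n <- round(cov * mu_n)
  samples <- toy_pair(pos, m_t, cov - m_t, m_n, cov - m_n)
  dmrs <- call_dmrs(samples)
  merged <- merge_dmrs(dmrs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_cpg, 16L)
  # idempotence
  expect_equal(merge_dmrs(merged, attr(merged, "sites")), merged,
               ignore_attr = TRUE)
  # the merged span re-verifies with the independent enumeration oracle
  sites <- attr(merged, "sites")
  p_oracle <- fisher_p_enum(sum(sites$m_tumor), sum(sites$u_tumor),
                            sum(sites$m_normal), sum(sites$u_normal))
  expect_equal(merged$p_value, p_oracle, tolerance = 1e-10)

  # single DMR passes through unchanged
  one <- dmrs[1, , drop = FALSE]
  attr(one, "sites") <- attr(dmrs, "sites")
  expect_equal(merge_dmrs(one), one, ignore_attr = TRUE)
})

test_that("opposite-direction neighbours never merge", {
  pos <- pos_seq(10)
  m_t <- c(rep(50, 5), rep(5, 5))
  m_n <- c(rep(5, 5), rep(50, 5))
  samples <- toy_pair(pos, m_t, 60 - m_t, m_n, 60 - m_n)
  dmrs <- call_dmrs(samples)
  expect_equal(sort(unique(dmrs$direction)), c("hyper", "hypo"))
  merged <- merge_dmrs(dmrs)
  expect_equal(nrow(merged), nrow(dmrs))
  expect_error(merge_dmrs(dmrs[c(2, 1), ], attr(dmrs, "sites")),
               "sorted")
})

test_that("null data yield nominal window significance and no DMRs", {
  cfg <- sim_config(seed = 11, n_genes = 0L, chrom_length = 3e5,
                    n_cpg_sites = 2000L, other_context_fraction = 0,
                    baseline_cg_level = 0.3, overdispersion_rho = 0)
  sim <- simulate_methylome(cfg)
  dmrs <- call_dmrs(sim$samples)
  ws <- attr(dmrs, "window_stats")
  expect_gt(nrow(ws), 1000)
  frac <- mean(ws$p_value < 0.05)
  # windows overlap, but the marginal rate should sit near 0.05
  expect_lt(abs(frac - 0.05), 0.02)
  expect_lte(nrow(dmrs), 2L)
})
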