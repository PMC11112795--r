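test_that("DMR-to-gene assignment matches a quadratic overlap oracle", {
  expect_equal(assign_dmrs_to_genes(
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character()),
    data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 100L,
               start = 100L, end = 500L))$hyper_dmg, character())

  genes1 <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       tss = 10000L, start = 10000L, end = 15000L)
  one <- data.frame(chrom = "chr1", start = 8500L, end = 8600L,
                    direction = "hyper")
  expect_equal(assign_dmrs_to_genes(one, genes1)$hyper_dmg, "g1")
  # outside the promoter in promoter-only scope
  body_dmr <- data.frame(chrom = "chr1", start = 12000L, end = 12100L,
                         direction = "hyper")
  expect_equal(assign_dmrs_to_genes(body_dmr, genes1,
                                    scope = "promoter")$hyper_dmg,
               character())
  expect_equal(assign_dmrs_to_genes(body_dmr, genes1)$hyper_dmg, "g1")

  # random instance vs brute-force all-pairs scan, both scopes
  set.seed(77)
  cfg <- sim_config(seed = 77, n_genes = 50L, chrom_length = 1e6)
  genes <- simulate_annotation(cfg)
  dmrs <- data.frame(chrom = "chrS",
                     start = sort(sample.int(999000, 20)))
  dmrs$end <- dmrs$start + sample(200:3000, 20, replace = TRUE)
  dmrs$direction <- sample(c("hyper", "hypo"), 20, replace = TRUE)
  for (scope in c("gene_region", "promoter")) {
    got <- assign_dmrs_to_genes(dmrs, genes, scope = scope)
    up <- 2000L; down <- 500L
    hyper <- hypo <- character()
    for (i in seq_len(nrow(genes))) {
      if (genes$strand[i] == "+") {
        ps <- genes$tss[i] - up; pe <- genes$tss[i] + down
      } else {
        ps <- genes$tss[i] - down + 1L; pe <- genes$tss[i] + up + 1L
      }
      fs <- if (scope == "promoter") ps else min(ps, genes$start[i])
      fe <- if (scope == "promoter") pe else max(pe, genes$end[i])
      for (j in seq_len(nrow(dmrs))) {
        if (dmrs$start[j] < fe && dmrs$end[j] > fs) {
          if (dmrs$direction[j] == "hyper")
            hyper <- c(hyper, genes$gene_id[i])
          else hypo <- c(hypo, genes$gene_id[i])
        }
      }
    }
    expect_setequal(got$hyper_dmg, unique(hyper))
    expect_setequal(got$hypo_dmg, unique(hypo))
    expect_setequal(got$both, intersect(unique(hyper), unique(hypo)))
  }
})

test_that("the DEG screen applies inclusive thresholds on log2FC", {
  # identical groups: all neutral at log2FC 0
  counts <- matrix(rep(c(100L, 200L, 300L), each = 4), nrow = 3,
                   byrow = TRUE,
                   dimnames = list(paste0("g", 1:3),
                                   c("T1", "T2", "N1", "N2")))
  degs <- deg_screen(counts, c("tumor", "tumor", "normal", "normal"))
  expect_true(all(degs$log2fc == 0))
  expect_true(all(degs$label == "neutral"))

  # construct a gene whose log2FC is exactly -1 with a tiny p value:
  # library sizes are padded to exactly 1e6 so counts are CPM
  g1 <- c(499998, 500000, 999998, 1000000)
  filler <- 1e6 - g1
  m <- matrix(c(g1, filler), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "fill"),
                              c("T1", "T2", "N1", "N2")))
  d <- deg_screen(m, c("tumor", "tumor", "normal", "normal"))
  gA <- d[d$gene_id == "gA", ]
  expect_identical(gA$log2fc, -1)
  expect_lt(gA$p_value, 0.05)
  expect_equal(gA$label, "down")

  # all-zero gene: neutral, p = 1, flagged
  z <- rbind(m, gZ = c(0, 0, 0, 0))
  dz <- deg_screen(z, c("tumor", "tumor", "normal", "normal"))
  expect_equal(dz$label[dz$gene_id == "gZ"], "neutral")
  expect_equal(dz$p_value[dz$gene_id == "gZ"], 1)
  expect_equal(dz$flag[dz$gene_id == "gZ"], "all_zero")
  expect_error(deg_screen(m, c("tumor", "tumor", "tumor", "normal")),
               "2 samples")
})

test_that("log2FC shifts by k when one group is scaled by 2^k", {
  set.seed(5)
  counts <- matrix(rnbinom(400 * 6, mu = 500, size = 10), nrow = 400,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   c("T1", "T2", "T3", "N1", "N2", "N3")))
  base <- deg_screen(counts, rep(c("tumor", "normal"), each = 3))
  # quadrupling one gene's tumor counts shifts its log2FC by ~2 (the
  # gene is small relative to the library, so normalization and the
  # pseudo-count barely move)
  scaled <- counts
  scaled["g007", 1:3] <- scaled["g007", 1:3] * 4L
  shifted <- deg_screen(scaled, rep(c("tumor", "normal"), each = 3))
  delta <- shifted$log2fc[shifted$gene_id == "g007"] -
    base$log2fc[base$gene_id == "g007"]
  expect_lt(abs(delta - 2), 0.1)
})

test_that("planted DEG labels are recovered from synthetic counts", {
  cfg <- sim_config(seed = 19, n_genes = 300L, chrom_length = 4.5e6,
                    n_cpg_sites = 300L, nb_dispersion = 0.1,
                    planted_deg_log2fc = 2, coupling_prob = 1,
                    planted_dmrs = c(
                      replicate(15, planted_dmr(8, 0.8, 0.2),
                                simplify = FALSE),
                      replicate(15, planted_dmr(8, 0.2, 0.8),
                                simplify = FALSE)))
  genes <- simulate_annotation(cfg)
  meth <- simulate_methylome(cfg, genes)
  expr <- simulate_expression(cfg, genes, meth$truth)
  degs <- deg_screen(expr$counts, expr$groups)
  truth <- expr$truth$deg_labels
  planted <- names(truth)[truth != "neutral"]
  hit <- degs$label[match(planted, degs$gene_id)] == truth[planted]
  expect_gte(mean(hit), 0.8)
})

test_that("crossover sets are exact intersections with consistent Venn", {
  degs <- data.frame(gene_id = c("A", "B", "C", "D"),
                     log2fc = c(-2, -2, 2, 0),
                     p_value = c(0.01, 0.01, 0.01, 0.5),
                     label = c("down", "down", "up", "neutral"))
  cs <- crossover_sets(c("A", "B"), c("C"), degs[-1, ])
  expect_equal(cs$hyper_down, "B")
  expect_equal(cs$hypo_up, "C")
  expect_equal(unname(cs$venn_counts$hyper_down),
               c(1, 1, 0))
  # disjoint inputs
  cs2 <- crossover_sets(c("X", "Y"), character(), degs)
  expect_equal(cs2$hyper_down, character())
  expect_equal(unname(cs2$venn_counts$hyper_down), c(2, 0, 2))

  # random instance vs an independent set-algebra oracle
  set.seed(33)
  universe <- sprintf("g%03d", 1:200)
  hyper <- sample(universe, 60)
  hypo <- sample(universe, 40)
  lab <- sample(c("up", "down", "neutral"), 200, replace = TRUE)
  rdegs <- data.frame(gene_id = universe, log2fc = 0, p_value = 1,
                      label = lab)
  cs3 <- crossover_sets(hyper, hypo, rdegs)
  oracle_hd <- sort(universe[universe %in% hyper &
                             lab == "down"])
  oracle_hu <- sort(universe[universe %in% hypo & lab == "up"])
  expect_identical(cs3$hyper_down, oracle_hd)
  expect_identical(cs3$hypo_up, oracle_hu)
  expect_true(all(cs3$hyper_down %in% cs3$hyper_dmg))
  expect_true(all(cs3$hyper_down %in% cs3$down_deg))
})

test_that("the Spearman screen matches a rank-formula oracle", {
  mat <- matrix(c(1, 2, 3, 4, 5,
                  10, 20, 30, 40, 50,   # monotone transform
                  5, 4, 3, 2, 1),       # reversed
                nrow = 3, byrow = TRUE,
                dimnames = list(c("anchor", "mono", "rev"), NULL))
  res <- spearman_screen(mat, "anchor", threshold = 0)
  expect_equal(res$rho[res$gene_id == "mono"], 1)
  expect_equal(res$rho[res$gene_id == "rev"], -1)

  set.seed(8)
  rmat <- matrix(sample(1:40, 80, replace = TRUE), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  scr <- spearman_screen(rmat, "g01", threshold = 0)
  avg_rank <- function(x) rank(x, ties.method = "average")
  ra <- avg_rank(rmat["g01", ])
  for (g in setdiff(rownames(rmat), "g01")) {
    rg <- avg_rank(rmat[g, ])
    # Pearson product-moment on average ranks, written out
    num <- sum((ra - mean(ra)) * (rg - mean(rg)))
    den <- sqrt(sum((ra - mean(ra))^2) * sum((rg - mean(rg))^2))
    expect_equal(scr$rho[scr$gene_id == g], num / den,
                 tolerance = 1e-12)
  }
  # the retention threshold applies to |rho|
  kept <- spearman_screen(rmat, "g01", threshold = 0.3)
  expect_true(all(abs(kept$rho) >= 0.3))
  const <- rbind(rmat, flat = rep(3, 8))
  expect_error(spearman_screen(const, "flat"), "constant")
})

test_that("the 2x2 chi-square reproduces the printed statistics", {
  expect_equal(round_half_away(chi_square_2x2(29, 24, 13, 18)$statistic, 3),
               1.278)
  expect_equal(round_half_away(chi_square_2x2(31, 22, 11, 20)$statistic, 3),
               4.141)
  expect_equal(round_half_away(chi_square_2x2(13, 6, 29, 36)$statistic, 3),
               3.333)
  # proportional rows -> statistic 0
  expect_equal(chi_square_2x2(10, 20, 5, 10)$statistic, 0)
  # transposition invariance and direct O/E oracle
  set.seed(3)
  for (i in 1:20) {
    x <- sample(1:50, 4)
    r <- chi_square_2x2(x[1], x[2], x[3], x[4])
    rt <- chi_square_2x2(x[1], x[3], x[2], x[4])
    expect_equal(r$statistic, rt$statistic, tolerance = 1e-12)
    O <- matrix(c(x[1], x[3], x[2], x[4]), 2)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(r$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
    expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("promoter-coupled genes flow through to the crossover set", {
  st <- small_study(seed = 41, n_dmr = 10, n_genes = 100, coupling = 1)
  dmrs <- merge_dmrs(call_dmrs(st$meth$samples))
  dmg <- assign_dmrs_to_genes(dmrs, st$genes)
  degs <- deg_screen(st$expr$counts, st$expr$groups)
  cs <- crossover_sets(dmg$hyper_dmg, dmg$hypo_dmg, degs)
  planted <- sort(st$meth$truth$dmr_intervals$gene_id)
  # every planted gene is hyper-DMG; most clear the DEG screen too
  expect_true(all(planted %in% dmg$hyper_dmg))
  expect_gte(mean(planted %in% cs$hyper_down), 0.7)
  expect_true(all(cs$hyper_down %in% dmg$hyper_dmg))
})
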