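# Fixture builders and independent oracles shared across test files.

# One methylome sample from parallel vectors of counts.
toy_sample <- function(id, group, pos, n_meth, n_unmeth,
                       chrom = "chr1", context = "CG",
                       strand = "+") {
  methylome_sample(id, group, data.frame(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context = context, n_meth = as.integer(n_meth),
    n_unmeth = as.integer(n_unmeth)))
}

# One tumor + one normal sample carrying exactly the given pooled counts.
toy_pair <- function(pos, m_t, u_t, m_n, u_n, chrom = "chr1") {
  list(toy_sample("T1", "tumor", pos, m_t, u_t, chrom = chrom),
       toy_sample("N1", "normal", pos, m_n, u_n, chrom = chrom))
}

# Two-sided Fisher exact P by explicit hypergeometric enumeration:
# sum of the probabilities of all tables (fixed margins) no more likely
# than the observed one.
fisher_p_enum <- function(m_t, u_t, m_n, u_n) {
  n1 <- m_t + u_t
  n2 <- m_n + u_n
  k <- m_t + m_n
  support <- max(0, k - n2):min(k, n1)
  # log-space to survive large read totals
  probs <- exp(lchoose(n1, support) + lchoose(n2, k - support) -
               lchoose(n1 + n2, k))
  p_obs <- probs[support == m_t]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive, self-contained DMR caller used as the oracle on small inputs:
# enumerate every 5-CpG window by double loop, test it from pooled
# counts, union overlapping significant windows of a direction by a
# linear sweep, and re-test each union over all usable sites inside.
naive_dmr_call <- function(sites, min_fold = 2, max_p = 0.05,
                           max_gap = 300, w = 5, eps = 0.01) {
  test_rows <- function(rows) {
    mt <- sum(rows$m_tumor); ut <- sum(rows$u_tumor)
    mn <- sum(rows$m_normal); un <- sum(rows$u_normal)
    lt <- mt / (mt + ut); ln <- mn / (mn + un)
    list(fold = (max(lt, ln) + eps) / (min(lt, ln) + eps),
         p = fisher_p_enum(mt, ut, mn, un),
         dir = if (lt > ln) "hyper" else "hypo",
         lt = lt, ln = ln)
  }
  wins <- list()
  for (ch in unique(sites$chrom)) {
    sub <- sites[sites$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    n <- nrow(sub)
    if (n < w) next
    for (i in 1:(n - w + 1)) {
      rows <- sub[i:(i + w - 1), ]
      if (any(diff(rows$pos) > max_gap)) next
      st <- test_rows(rows)
      if (st$fold > min_fold && st$p < max_p) {
        wins[[length(wins) + 1]] <- data.frame(
          chrom = ch, start = rows$pos[1] - 1, end = rows$pos[w],
          dir = st$dir)
      }
    }
  }
  if (length(wins) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      direction = character()))
  }
  wins <- do.call(rbind, wins)
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sub <- wins[wins$dir == dir, ]
    if (nrow(sub) == 0) next
    for (ch in unique(sub$chrom)) {
      iv <- sub[sub$chrom == ch, c("start", "end")]
      iv <- iv[order(iv$start), ]
      # linear union sweep
      cs <- iv$start[1]; ce <- iv$end[1]
      regions <- list()
      if (nrow(iv) > 1) {
        for (i in 2:nrow(iv)) {
          if (iv$start[i] < ce) ce <- max(ce, iv$end[i])
          else { regions[[length(regions) + 1]] <- c(cs, ce)
                 cs <- iv$start[i]; ce <- iv$end[i] }
        }
      }
      regions[[length(regions) + 1]] <- c(cs, ce)
      for (r in regions) {
        rows <- sites[sites$chrom == ch & sites$pos > r[1] &
                      sites$pos <= r[2], ]
        st <- test_rows(rows)
        if (nrow(rows) >= 5 && st$fold > min_fold && st$p < max_p &&
            st$dir == dir) {
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = r[1], end = r[2], n_cpg = nrow(rows),
            direction = dir)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# Small seeded synthetic study reused by integration-level tests.
small_study <- function(seed = 3L, n_dmr = 5L, n_genes = 40L,
                        coupling = 1, lfc = 2,
                        level_tumor = 0.8, level_normal = 0.2) {
  cfg <- sim_config(
    seed = seed, n_genes = n_genes, chrom_length = n_genes * 15000,
    n_cpg_sites = 500L, planted_deg_log2fc = lfc,
    coupling_prob = coupling,
    planted_dmrs = replicate(n_dmr,
      planted_dmr(8L, level_tumor, level_normal), simplify = FALSE))
  genes <- simulate_annotation(cfg)
  meth <- simulate_methylome(cfg, genes)
  expr <- simulate_expression(cfg, genes, meth$truth)
  list(cfg = cfg, genes = genes, meth = meth, expr = expr)
}
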