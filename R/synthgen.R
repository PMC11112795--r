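#' Synthetic WGBS + RNA-seq study generator
#'
#' The generator emulates a small paired tumor/normal design: a single
#' synthetic chromosome carrying non-overlapping genes, per-cytosine
#' methylation counts for `n_per_group` tumor and `n_per_group` normal
#' samples with differentially methylated regions (DMRs) planted in gene
#' promoters, and a coupled gene-level expression count matrix in which
#' promoter-hypermethylated genes can be planted as downregulated (and
#' promoter-hypomethylated genes as upregulated). Every random quantity is
#' driven by `seed`, so an identical configuration reproduces identical
#' data byte for byte.
#'
#' @section Count models:
#' Site coverage is Poisson(`coverage_mean`) truncated at 1 so every
#' emitted site is covered. Methylated counts are beta-binomial with mean
#' equal to the site's true level and overdispersion `overdispersion_rho`
#' (shape `a = mu*(1-rho)/rho`, `b = (1-mu)*(1-rho)/rho`); `rho = 0`
#' degenerates to an exact binomial, which the calibration tests exploit.
#' Expression counts are negative binomial with gene-specific log-normal
#' baseline means and dispersion `nb_dispersion`.
#'
#' @param seed integer seed driving all randomness.
#' @param n_per_group samples per group (tumor and normal).
#' @param chrom chromosome name of the simulated chromosome.
#' @param chrom_length chromosome length in bases.
#' @param n_cpg_sites number of background CG-context cytosines.
#' @param other_context_fraction fraction of all simulated cytosines that
#'   are CHG/CHH context (human non-CG methylation is near zero, but the
#'   records must exist for context summaries).
#' @param baseline_cg_level true methylation level of background CG sites,
#'   in \[0,1\], identical in both groups.
#' @param baseline_non_cg_level true level of CHG/CHH sites (default 0.01,
#'   matching the ~1% non-CG methylation seen in human tissue).
#' @param planted_dmrs list of planted DMR descriptions built with
#'   [planted_dmr()].
#' @param coverage_mean mean read coverage per site (> 0).
#' @param overdispersion_rho beta-binomial overdispersion in \[0,1).
#' @param n_genes number of genes to place.
#' @param nb_dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param planted_deg_log2fc absolute log2 fold change planted into
#'   coupled differentially expressed genes; 0 plants nothing.
#' @param coupling_prob probability that a promoter-hyper-DMR gene is also
#'   planted as a down-DEG (symmetrically hypo -> up).
#' @param demeth_units named list of per-CpG-unit methylation levels for
#'   the demethylation panel: each element `c(untreated, treated)` or
#'   `c(untreated, treated, reference)`. The default is a four-unit
#'   MassArray-style panel of a hypermethylated promoter in a tumor line
#'   before/after 5-azacytidine alongside a normal-hepatocyte reference.
#' @param read_length read length for FASTQ fixtures.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 3L,
                       chrom = "chrS",
                       chrom_length = 1e6,
                       n_cpg_sites = 2000L,
                       other_context_fraction = 0.3,
                       baseline_cg_level = 0.3,
                       baseline_non_cg_level = 0.01,
                       planted_dmrs = list(),
                       coverage_mean = 30,
                       overdispersion_rho = 0,
                       n_genes = 50L,
                       nb_dispersion = 0.1,
                       planted_deg_log2fc = 2,
                       coupling_prob = 1,
                       demeth_units = list(
                         CpG_1 = c(0.81, 0.10, 0.12),
                         CpG_2 = c(0.51, 0.27, 0.22),
                         CpG_3 = c(0.61, 0.61, 0.37),
                         CpG_4 = c(0.96, 0.89, 0.35)),
                       read_length = 100L) {
  if (!is_count(seed)) ms_stop("seed must be a non-negative integer")
  if (!is_count(n_per_group) || n_per_group < 1)
    ms_stop("n_per_group must be a positive integer")
  if (!is_count(chrom_length) || chrom_length < 1)
    ms_stop("chrom_length must be a positive integer")
  if (!is_count(n_cpg_sites)) ms_stop("n_cpg_sites must be a count")
  if (!is_fraction(other_context_fraction))
    ms_stop("other_context_fraction must lie in [0,1]")
  if (!is_fraction(baseline_cg_level) || !is_fraction(baseline_non_cg_level))
    ms_stop("baseline methylation levels must lie in [0,1]")
  if (!is.numeric(coverage_mean) || coverage_mean <= 0)
    ms_stop("coverage_mean must be > 0")
  if (!is.numeric(overdispersion_rho) || overdispersion_rho < 0 ||
      overdispersion_rho >= 1)
    ms_stop("overdispersion_rho must lie in [0,1)")
  if (!is_count(n_genes)) ms_stop("n_genes must be a count")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    ms_stop("nb_dispersion must be > 0")
  if (!is.numeric(coupling_prob) || !is_fraction(coupling_prob))
    ms_stop("coupling_prob must lie in [0,1]")
  for (d in planted_dmrs) {
    if (!inherits(d, "planted_dmr"))
      ms_stop("planted_dmrs must be a list of planted_dmr() objects")
  }
  for (u in demeth_units) {
    if (any(u < 0) || any(u > 1))
      ms_stop("demeth_units levels must lie in [0,1]")
  }
  structure(list(
    seed = as.integer(seed), n_per_group = as.integer(n_per_group),
    chrom = chrom, chrom_length = as.integer(chrom_length),
    n_cpg_sites = as.integer(n_cpg_sites),
    other_context_fraction = other_context_fraction,
    baseline_cg_level = baseline_cg_level,
    baseline_non_cg_level = baseline_non_cg_level,
    planted_dmrs = planted_dmrs,
    coverage_mean = coverage_mean,
    overdispersion_rho = overdispersion_rho,
    n_genes = as.integer(n_genes), nb_dispersion = nb_dispersion,
    planted_deg_log2fc = planted_deg_log2fc,
    coupling_prob = coupling_prob,
    demeth_units = demeth_units,
    read_length = as.integer(read_length)),
    class = "sim_config")
}

#' Describe one planted differentially methylated region
#'
#' @param width_in_cpgs number of consecutive CpG sites in the region
#'   (at least 5, matching the DMR calling criterion).
#' @param level_tumor,level_normal true methylation levels in the tumor
#'   and normal groups, each in \[0,1\] and unequal.
#' @return object of class `planted_dmr`.
#' @export
planted_dmr <- function(width_in_cpgs = 8L, level_tumor = 0.8,
                        level_normal = 0.2) {
  if (!is_count(width_in_cpgs) || width_in_cpgs < 5)
    ms_stop("width_in_cpgs must be an integer >= 5")
  if (!is_fraction(level_tumor) || !is_fraction(level_normal))
    ms_stop("planted levels must lie in [0,1]")
  if (level_tumor == level_normal)
    ms_stop("planted levels must differ so the region has a direction")
  structure(list(width_in_cpgs = as.integer(width_in_cpgs),
                 level_tumor = level_tumor, level_normal = level_normal,
                 direction = if (level_tumor > level_normal) "hyper"
                             else "hypo"),
            class = "planted_dmr")
}

# spacing (bp) between consecutive CpGs planted inside a promoter; well
# below the default max_gap of the DMR caller
PLANT_SPACING <- 100L
PROMOTER_UP <- 2000L
PROMOTER_DOWN <- 500L

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping gene bodies on the simulated
#' chromosome, alternating strands, each with room for a strand-aware
#' promoter (2 kb upstream / 0.5 kb downstream of the TSS) that does not
#' run off the chromosome. Coordinates are 0-based half-open (BED
#' convention); `tss` is the 0-based position of the first transcribed
#' base.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `tss`, `start`, `end`, sorted by coordinate.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      start = integer(), end = integer()))
  }
  slot <- floor(config$chrom_length / config$n_genes)
  # each slot must hold promoter margin + a >= 2 kb body on both sides
  need <- 2L * (PROMOTER_UP + PROMOTER_DOWN) + 2000L + 200L
  if (slot < need) {
    ms_stop("annotation does not fit: ", config$n_genes, " genes on ",
            config$chrom_length, " bp need slots of >= ", need,
            " bp but only ", slot, " bp are available per gene")
  }
  with_seed(config$seed + 1L, {
    margin <- PROMOTER_UP + PROMOTER_DOWN
    starts <- ends <- integer(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      lo <- (i - 1L) * slot + margin
      hi <- i * slot - margin
      max_len <- min(8000L, hi - lo - 100L)
      len <- sample(2000L:max_len, 1L)
      s <- lo + sample.int(hi - lo - len, 1L)
      starts[i] <- s
      ends[i] <- s + len
    }
    strand <- rep(c("+", "-"), length.out = config$n_genes)
    data.frame(
      gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
      chrom = config$chrom, strand = strand,
      tss = ifelse(strand == "+", starts, ends - 1L),
      start = starts, end = ends)
  })
}

# internal: strand-aware promoter intervals (0-based half-open)
promoter_intervals <- function(genes, up = PROMOTER_UP, down = PROMOTER_DOWN,
                               chrom_length = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - down + 1L)
  end <- ifelse(plus, genes$tss + down, genes$tss + up + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand)
}

# internal: beta-binomial draw, mean mu, overdispersion rho; rho = 0 is
# exact binomial
rbetabinom <- function(n, size, mu, rho) {
  if (rho == 0) return(rbinom(n, size, mu))
  p <- numeric(n)
  fixed <- mu <= 0 | mu >= 1
  p[fixed] <- mu[fixed]
  if (any(!fixed)) {
    a <- mu[!fixed] * (1 - rho) / rho
    b <- (1 - mu[!fixed]) * (1 - rho) / rho
    p[!fixed] <- rbeta(sum(!fixed), a, b)
  }
  rbinom(n, size, p)
}

# internal: Poisson truncated at >= 1
rpois_trunc1 <- function(n, lambda) {
  qpois(runif(n, ppois(0, lambda), 1), lambda)
}

#' Simulate per-cytosine methylomes with planted DMRs
#'
#' Background CG sites sit at `baseline_cg_level` in both groups; CHG/CHH
#' sites at `baseline_non_cg_level`. Each planted DMR is anchored in the
#' promoter of a distinct gene: `width_in_cpgs` CpG sites spaced 100 bp
#' apart, at the planted tumor/normal levels. Per sample and site,
#' coverage is truncated-Poisson and the methylated count beta-binomial
#' (see [sim_config()]).
#'
#' @param config a [sim_config()].
#' @param genes annotation from [simulate_annotation()]; required when
#'   `planted_dmrs` is non-empty.
#' @return list with `samples` (a list of [methylome_sample()] objects,
#'   tumor first) and `truth` (planted intervals, per-site true levels).
#' @export
simulate_methylome <- function(config, genes = simulate_annotation(config)) {
  stopifnot(inherits(config, "sim_config"))
  n_dmr <- length(config$planted_dmrs)
  if (n_dmr > nrow(genes))
    ms_stop("more planted DMRs (", n_dmr, ") than genes (", nrow(genes), ")")
  with_seed(config$seed + 2L, {
    ## background sites
    n_cg <- config$n_cpg_sites
    f <- config$other_context_fraction
    n_other <- if (f >= 1) 0L else as.integer(round(n_cg * f / (1 - f)))
    n_bg <- n_cg + n_other
    pos <- sort(sample.int(config$chrom_length, n_bg))
    context <- rep("CG", n_bg)
    if (n_other > 0) {
      idx <- sample.int(n_bg, n_other)
      context[idx] <- sample(c("CHG", "CHH"), n_other, replace = TRUE,
                             prob = c(0.2, 0.8))
    }
    level_t <- ifelse(context == "CG", config$baseline_cg_level,
                      config$baseline_non_cg_level)
    level_n <- level_t

    ## planted DMR sites, anchored in promoters of distinct genes
    truth_int <- data.frame(chrom = character(), start = integer(),
                            end = integer(), direction = character(),
                            gene_id = character())
    if (n_dmr > 0) {
      host <- sample.int(nrow(genes), n_dmr)
      prom <- promoter_intervals(genes[host, , drop = FALSE],
                                 chrom_length = config$chrom_length)
      for (k in seq_len(n_dmr)) {
        d <- config$planted_dmrs[[k]]
        first <- prom$start[k] + 50L  # 0-based; 1-based pos = first + 1
        p <- first + 1L + PLANT_SPACING * (seq_len(d$width_in_cpgs) - 1L)
        if (max(p) > config$chrom_length || max(p) > prom$end[k])
          ms_stop("planted DMR ", k, " does not fit inside its promoter")
        pos <- c(pos, p)
        context <- c(context, rep("CG", length(p)))
        level_t <- c(level_t, rep(d$level_tumor, length(p)))
        level_n <- c(level_n, rep(d$level_normal, length(p)))
        truth_int <- rbind(truth_int, data.frame(
          chrom = config$chrom, start = min(p) - 1L, end = max(p),
          direction = d$direction, gene_id = prom$gene_id[k]))
      }
    }
    ord <- order(pos)
    keep <- !duplicated(pos[ord])        # planted sites may hit background
    ord <- ord[keep]
    pos <- pos[ord]; context <- context[ord]
    level_t <- level_t[ord]; level_n <- level_n[ord]
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)

    site_levels <- data.frame(chrom = config$chrom, pos = pos,
                              context = context, level_tumor = level_t,
                              level_normal = level_n)

    draw_sample <- function(id, group, mu) {
      cov <- rpois_trunc1(length(pos), config$coverage_mean)
      m <- rbetabinom(length(pos), cov, mu, config$overdispersion_rho)
      methylome_sample(id, group, data.frame(
        chrom = config$chrom, pos = pos, strand = strand,
        context = context, n_meth = m, n_unmeth = cov - m))
    }
    samples <- c(
      lapply(seq_len(config$n_per_group), function(i)
        draw_sample(sprintf("T%d", i), "tumor", level_t)),
      lapply(seq_len(config$n_per_group), function(i)
        draw_sample(sprintf("N%d", i), "normal", level_n)))

    list(samples = samples,
         truth = list(dmr_intervals = truth_int, site_levels = site_levels,
                      deg_labels = NULL))
  })
}

#' Simulate a coupled expression count matrix
#'
#' Gene baseline means are log-normal; counts are negative binomial with
#' dispersion `nb_dispersion`. A gene hosting a planted promoter
#' hyper-DMR is planted as a down-DEG with probability `coupling_prob`
#' (hypo -> up symmetrically), receiving a symmetric split of
#' `planted_deg_log2fc` between the groups; all other genes are neutral.
#'
#' @param config a [sim_config()].
#' @param genes annotation from [simulate_annotation()].
#' @param truth truth list from [simulate_methylome()].
#' @return list with `counts` (genes x samples integer matrix), `groups`
#'   (per-column group labels) and `truth` with `deg_labels` filled in for
#'   every gene.
#' @export
simulate_expression <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) ms_stop("nb_dispersion must be > 0")
  with_seed(config$seed + 3L, {
    ng <- nrow(genes)
    labels <- setNames(rep("neutral", ng), genes$gene_id)
    if (config$planted_deg_log2fc != 0 &&
        nrow(truth$dmr_intervals) > 0) {
      for (k in seq_len(nrow(truth$dmr_intervals))) {
        g <- truth$dmr_intervals$gene_id[k]
        if (runif(1) <= config$coupling_prob && config$coupling_prob > 0) {
          labels[g] <- if (truth$dmr_intervals$direction[k] == "hyper")
            "down" else "up"
        }
      }
    }
    lfc <- ifelse(labels == "down", -abs(config$planted_deg_log2fc),
                  ifelse(labels == "up", abs(config$planted_deg_log2fc), 0))
    base <- rlnorm(ng, meanlog = log(200), sdlog = 1)
    mu_t <- base * 2^(lfc / 2)
    mu_n <- base * 2^(-lfc / 2)
    size <- 1 / config$nb_dispersion
    np <- config$n_per_group
    counts <- cbind(
      matrix(rnbinom(ng * np, mu = rep(mu_t, np), size = size), ncol = np),
      matrix(rnbinom(ng * np, mu = rep(mu_n, np), size = size), ncol = np))
    dimnames(counts) <- list(genes$gene_id,
                             c(sprintf("T%d", seq_len(np)),
                               sprintf("N%d", seq_len(np))))
    truth$deg_labels <- labels
    list(counts = counts,
         groups = rep(c("tumor", "normal"), each = np),
         truth = truth)
  })
}

#' Build the demethylation-assay panel configured in a `sim_config`
#'
#' @param config a [sim_config()]; `demeth_units` carries the per-unit
#'   untreated/treated (and optional normal-reference) levels.
#' @return a `data.frame` panel accepted by [panel_response()], one row
#'   per CpG unit in configuration order.
#' @export
simulate_demeth_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  units <- config$demeth_units
  if (length(units) == 0) {
    return(data.frame(unit_id = character(), level_untreated = numeric(),
                      level_treated = numeric(), level_reference = numeric()))
  }
  data.frame(
    unit_id = names(units),
    level_untreated = vapply(units, `[`, numeric(1), 1L),
    level_treated = vapply(units, `[`, numeric(1), 2L),
    level_reference = vapply(units, function(u)
      if (length(u) >= 3) u[3L] else NA_real_, numeric(1)),
    row.names = NULL)
}

#' Simulate FASTQ reads for the read-QC rule
#'
#' Each read independently becomes an "unknown base" read with probability
#' `frac_n` (12% of its positions set to N, past the 10% flag threshold)
#' or otherwise a low-quality read with probability `frac_lowq` (12% of
#' positions dropped to Phred 10); remaining reads are clean (no N, all
#' qualities >= 30).
#'
#' @param config a [sim_config()].
#' @param n_reads number of reads.
#' @param frac_n,frac_lowq corruption probabilities in \[0,1\].
#' @return `data.frame` with columns `id`, `seq`, `qual` (Sanger
#'   Phred+33).
#' @export
simulate_fastq <- function(config, n_reads, frac_n = 0, frac_lowq = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n_reads)) ms_stop("n_reads must be a non-negative count")
  if (!is_fraction(frac_n) || !is_fraction(frac_lowq))
    ms_stop("frac_n and frac_lowq must lie in [0,1]")
  L <- config$read_length
  n_corrupt <- ceiling(0.12 * L)   # > 10% of positions
  with_seed(config$seed + 4L, {
    seqs <- quals <- character(n_reads)
    u <- runif(n_reads)
    v <- runif(n_reads)
    for (i in seq_len(n_reads)) {
      b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      q <- sample(30:40, L, replace = TRUE)
      if (u[i] < frac_n) {
        b[sample.int(L, n_corrupt)] <- "N"
      } else if (v[i] < frac_lowq) {
        q[sample.int(L, n_corrupt)] <- 10L
      }
      seqs[i] <- paste(b, collapse = "")
      quals[i] <- intToUtf8(q + 33L)
    }
    data.frame(id = sprintf("read%06d", seq_len(n_reads)),
               seq = seqs, qual = quals)
  })
}

#' Write simulated reads as FASTQ
#' @param reads `data.frame` from [simulate_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}

#' Read a FASTQ file into the simulate_fastq layout
#' @param path FASTQ path (uncompressed).
#' @return `data.frame` with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) ms_stop("truncated FASTQ: ", path)
  i <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", sub(" .*", "", lines[i])),
             seq = lines[i + 1], qual = lines[i + 3])
}

#' Write a gene annotation as BED6
#' @param genes annotation `data.frame` (0-based half-open coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 gene annotation
#'
#' The TSS is taken as the 5' end of the record given its strand.
#' @param path BED6 path.
#' @return gene `data.frame` as produced by [simulate_annotation()].
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t",
                           col.names = c("chrom", "start", "end", "gene_id",
                                         "score", "strand"))
  data.frame(gene_id = bed$gene_id, chrom = bed$chrom, strand = bed$strand,
             tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             start = bed$start, end = bed$end)
}
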