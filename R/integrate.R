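#' Annotate DMRs to genes
#'
#' A gene joins the hypermethylated set when any hyper DMR overlaps its
#' gene region (strand-aware promoter plus gene body; `scope =
#' "promoter"` restricts to the promoter window), and symmetrically for
#' hypo. Each gene appears at most once per set; genes hit by DMRs of
#' both directions join both sets and are reported in `both`.
#'
#' @param dmrs DMR table ([call_dmrs()] / [read_dmr_bed()]), 0-based
#'   half-open coordinates.
#' @param genes gene annotation (0-based half-open, strand-aware TSS).
#' @param promoter_window `c(upstream, downstream)` bp around the TSS
#'   (default 2000, 500).
#' @param scope `"gene_region"` (promoter union body, default) or
#'   `"promoter"`.
#' @return list with sorted character vectors `hyper_dmg`, `hypo_dmg`,
#'   and `both` (genes present in both sets).
#' @export
assign_dmrs_to_genes <- function(dmrs, genes,
                                 promoter_window = c(2000L, 500L),
                                 scope = c("gene_region", "promoter")) {
  scope <- match.arg(scope)
  if (nrow(dmrs) == 0 || nrow(genes) == 0)
    return(list(hyper_dmg = character(), hypo_dmg = character(),
                both = character()))
  unknown <- setdiff(unique(dmrs$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    warning("DMR chromosome(s) not in annotation, skipped: ",
            paste(unknown, collapse = ", "))
    dmrs <- dmrs[dmrs$chrom %in% genes$chrom, , drop = FALSE]
    if (nrow(dmrs) == 0)
      return(list(hyper_dmg = character(), hypo_dmg = character(),
                  both = character()))
  }
  prom <- promoter_intervals(genes, promoter_window[1], promoter_window[2])
  feat_start <- prom$start
  feat_end <- prom$end
  if (scope == "gene_region") {
    feat_start <- pmin(feat_start, genes$start)
    feat_end <- pmax(feat_end, genes$end)
  }
  feat <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(feat_start + 1L, feat_end))
  dgr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  hits <- GenomicRanges::findOverlaps(dgr, feat)
  hit_gene <- genes$gene_id[S4Vectors::subjectHits(hits)]
  hit_dir <- dmrs$direction[S4Vectors::queryHits(hits)]
  hyper <- sort(unique(hit_gene[hit_dir == "hyper"]))
  hypo <- sort(unique(hit_gene[hit_dir == "hypo"]))
  list(hyper_dmg = hyper, hypo_dmg = hypo,
       both = intersect(hyper, hypo))
}

#' Threshold-based differential expression screen
#'
#' Counts are normalized to counts per million (CPM) per sample. The
#' log2 fold change of a gene is
#' `log2((mean CPM tumor + 1) / (mean CPM normal + 1))` and its P value
#' comes from a two-sided Welch t-test on `log2(CPM + 1)`. A gene is
#' labelled `down` when `log2FC <= -1` and P < 0.05, `up` when
#' `log2FC >= 1` and P < 0.05 (thresholds inclusive), otherwise
#' `neutral`. Genes with zero counts in every sample are `neutral` with
#' P = 1 and flagged.
#'
#' @param counts genes x samples matrix of non-negative counts with row
#'   (gene) and column (sample) names.
#' @param groups character vector of per-column group labels
#'   (`"tumor"` / `"normal"`), at least 2 samples per group.
#' @param lfc_threshold absolute log2FC threshold (default 1).
#' @param p_threshold P value threshold (default 0.05).
#' @return `data.frame` with `gene_id`, `log2fc`, `p_value`, `label`,
#'   `flag` (`"all_zero"` or `""`).
#' @export
deg_screen <- function(counts, groups, lfc_threshold = 1,
                       p_threshold = 0.05) {
  if (any(counts < 0)) ms_stop("negative counts")
  groups <- match.arg(groups, c("tumor", "normal"), several.ok = TRUE)
  if (sum(groups == "tumor") < 2 || sum(groups == "normal") < 2)
    ms_stop("need at least 2 samples per group")
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  cpm <- t(t(counts) / lib) * 1e6
  logcpm <- log2(cpm + 1)
  tum <- groups == "tumor"
  log2fc <- log2((rowMeans(cpm[, tum, drop = FALSE]) + 1) /
                 (rowMeans(cpm[, !tum, drop = FALSE]) + 1))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tryCatch(stats::t.test(logcpm[i, tum], logcpm[i, !tum])$p.value,
             error = function(e) 1)
  }, numeric(1))
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  log2fc[all_zero] <- 0
  label <- rep("neutral", nrow(counts))
  label[log2fc <= -lfc_threshold & p < p_threshold] <- "down"
  label[log2fc >= lfc_threshold & p < p_threshold] <- "up"
  data.frame(gene_id = rownames(counts), log2fc = log2fc, p_value = p,
             label = label,
             flag = ifelse(all_zero, "all_zero", ""),
             row.names = NULL)
}

#' Crossover candidate gene sets
#'
#' Intersects the direction-matched methylation and expression sets:
#' hypermethylated genes that are downregulated (`hyper_down`, the
#' methylation-silenced tumor-suppressor candidates) and hypomethylated
#' genes that are upregulated (`hypo_up`). Gene order is lexicographic;
#' Venn counts cover both 2-set diagrams.
#'
#' @param hyper_dmg,hypo_dmg character vectors of differentially
#'   methylated genes by direction.
#' @param degs DEG table from [deg_screen()].
#' @return object of class `CandidateGeneSets`: a list with the four
#'   parent sets, the two intersections, and `venn_counts`.
#' @export
crossover_sets <- function(hyper_dmg, hypo_dmg, degs) {
  up_deg <- sort(degs$gene_id[degs$label == "up"])
  down_deg <- sort(degs$gene_id[degs$label == "down"])
  hyper_dmg <- sort(unique(hyper_dmg))
  hypo_dmg <- sort(unique(hypo_dmg))
  hyper_down <- intersect(hyper_dmg, down_deg)
  hypo_up <- intersect(hypo_dmg, up_deg)
  structure(list(
    hyper_dmg = hyper_dmg, hypo_dmg = hypo_dmg,
    up_deg = up_deg, down_deg = down_deg,
    hyper_down = hyper_down, hypo_up = hypo_up,
    venn_counts = list(
      hyper_down = c(dmg_only = length(hyper_dmg) - length(hyper_down),
                     intersection = length(hyper_down),
                     deg_only = length(down_deg) - length(hyper_down)),
      hypo_up = c(dmg_only = length(hypo_dmg) - length(hypo_up),
                  intersection = length(hypo_up),
                  deg_only = length(up_deg) - length(hypo_up)))),
    class = "CandidateGeneSets")
}

#' @export
print.CandidateGeneSets <- function(x, ...) {
  cat("Candidate gene sets\n")
  cat(sprintf("  hyper-DMG: %d   down-DEG: %d   hyper&down: %d\n",
              length(x$hyper_dmg), length(x$down_deg),
              length(x$hyper_down)))
  cat(sprintf("  hypo-DMG:  %d   up-DEG:   %d   hypo&up:    %d\n",
              length(x$hypo_dmg), length(x$up_deg), length(x$hypo_up)))
  invisible(x)
}

#' Spearman co-expression screen around an anchor gene
#'
#' Ranks every other gene's expression against the anchor across samples
#' (average ranks for ties) and retains genes with `|rho|` at or above
#' the threshold.
#'
#' @param mat genes x samples expression matrix with gene row names.
#' @param anchor_gene row name of the anchor.
#' @param threshold minimum `|rho|` to retain (default 0.3).
#' @return `data.frame` with `gene_id`, `rho`, sorted by decreasing
#'   `|rho|` then gene id; the anchor itself is excluded.
#' @export
spearman_screen <- function(mat, anchor_gene, threshold = 0.3) {
  if (!anchor_gene %in% rownames(mat))
    ms_stop("anchor gene '", anchor_gene, "' not in matrix")
  if (ncol(mat) < 3) ms_stop("need at least 3 samples")
  anchor <- mat[anchor_gene, ]
  if (length(unique(anchor)) == 1)
    ms_stop("anchor expression is constant; correlation undefined")
  others <- setdiff(rownames(mat), anchor_gene)
  rho <- vapply(others, function(g)
    suppressWarnings(stats::cor(anchor, mat[g, ], method = "spearman")),
    numeric(1))
  keep <- !is.na(rho) & abs(rho) >= threshold
  out <- data.frame(gene_id = others[keep], rho = rho[keep],
                    row.names = NULL)
  out[order(-abs(out$rho), out$gene_id), , drop = FALSE]
}

#' Pearson chi-square test on a 2x2 table
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with P from the
#' chi-square distribution on 1 degree of freedom (no Yates continuity
#' correction).
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`. Both
#'   margins must be positive.
#' @return list of class `ContingencyResult`: `statistic`, `p_value`,
#'   `table`, `expected`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(tab < 0)) ms_stop("negative cell counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    ms_stop("chi-square undefined: zero margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 table = tab, expected = ht$expected),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("Pearson chi-square (1 df, no correction): X2 = %.3f, p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Read / write an expression count matrix (genes x samples TSV)
#' @param path TSV with a header of sample names and gene ids in the
#'   first column.
#' @return integer matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression_tsv
#' @param counts genes x samples matrix.
#' @export
write_expression_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
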