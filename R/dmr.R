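#' DMR calling parameters
#'
#' A differentially methylated region (DMR) is a run of at least 5
#' CG-context cytosines whose pooled methylation levels differ by more
#' than 2-fold between the tumor and normal groups with P < 0.05 (both
#' strict). Candidate construction and the remaining knobs are:
#'
#' @param min_coverage minimum reads per site in every sample for the
#'   site to be usable (default 4).
#' @param max_gap maximum distance in bp between consecutive usable CpGs
#'   inside a candidate window (default 300).
#' @param window_cpgs window width in CpG sites (default 5, the minimum
#'   the criterion allows); windows slide one CpG at a time.
#' @param epsilon regularizer added to both pooled levels before the
#'   fold ratio, so fully unmethylated regions have a finite fold
#'   (default 0.01).
#' @param min_fold fold-change threshold; a region qualifies only when
#'   its fold strictly exceeds this (default 2).
#' @param max_p significance threshold; strictly below (default 0.05).
#' @return list of class `dmr_params`.
#' @export
dmr_params <- function(min_coverage = 4L, max_gap = 300L, window_cpgs = 5L,
                       epsilon = 0.01, min_fold = 2, max_p = 0.05) {
  if (window_cpgs < 5)
    ms_stop("window_cpgs must be >= 5 (a DMR needs at least 5 CpG loci)")
  structure(list(min_coverage = as.integer(min_coverage),
                 max_gap = as.integer(max_gap),
                 window_cpgs = as.integer(window_cpgs),
                 epsilon = epsilon, min_fold = min_fold, max_p = max_p),
            class = "dmr_params")
}

#' Usable CpG sites with pooled group counts
#'
#' A site is usable when it is CG context and covered by at least
#' `min_coverage` reads in every sample of both groups. Returns one row
#' per usable site with the per-group pooled methylated/unmethylated
#' counts (summed over samples).
#'
#' @param samples list of [methylome_sample()] objects containing at
#'   least one tumor and one normal sample.
#' @param params a [dmr_params()].
#' @return `data.frame` with `chrom`, `pos`, `m_tumor`, `u_tumor`,
#'   `m_normal`, `u_normal`, sorted by (chrom, pos).
#' @export
usable_sites <- function(samples, params = dmr_params()) {
  groups <- vapply(samples, function(s) s$group, character(1))
  if (!any(groups == "tumor") || !any(groups == "normal"))
    ms_stop("need at least one sample per group")
  per <- lapply(samples, function(s) {
    cg <- s$calls[s$calls$context == "CG" &
                  s$calls$n_meth + s$calls$n_unmeth >= params$min_coverage,
                  c("chrom", "pos", "strand", "n_meth", "n_unmeth")]
    cg$key <- paste(cg$chrom, cg$pos, cg$strand, sep = ":")
    cg
  })
  common <- Reduce(intersect, lapply(per, `[[`, "key"))
  if (length(common) == 0) {
    message("no usable CpG sites at min_coverage = ", params$min_coverage)
    return(data.frame(chrom = character(), pos = integer(),
                      m_tumor = integer(), u_tumor = integer(),
                      m_normal = integer(), u_normal = integer()))
  }
  base <- per[[1]][match(common, per[[1]]$key), c("chrom", "pos")]
  mt <- ut <- mn <- un <- integer(length(common))
  for (i in seq_along(samples)) {
    d <- per[[i]][match(common, per[[i]]$key), ]
    if (groups[i] == "tumor") {
      mt <- mt + d$n_meth; ut <- ut + d$n_unmeth
    } else {
      mn <- mn + d$n_meth; un <- un + d$n_unmeth
    }
  }
  out <- data.frame(chrom = base$chrom, pos = base$pos,
                    m_tumor = mt, u_tumor = ut,
                    m_normal = mn, u_normal = un)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: stats for one set of site rows (pooled 2x2 Fisher + fold)
site_set_stats <- function(sites, params) {
  mt <- sum(sites$m_tumor); ut <- sum(sites$u_tumor)
  mn <- sum(sites$m_normal); un <- sum(sites$u_normal)
  if (mt + ut == 0 || mn + un == 0)
    ms_stop("zero pooled coverage in a group")
  lt <- mt / (mt + ut)
  ln <- mn / (mn + un)
  e <- params$epsilon
  fold <- (max(lt, ln) + e) / (min(lt, ln) + e)
  p <- stats::fisher.test(matrix(c(mt, ut, mn, un), nrow = 2))$p.value
  list(level_tumor = lt, level_normal = ln, fold = fold,
       p_value = min(p, 1),
       direction = if (lt > ln) "hyper" else "hypo")
}

#' Candidate regions: sliding windows of consecutive usable CpGs
#'
#' Emits every window of `window_cpgs` consecutive usable CG sites
#' (step one site) whose consecutive gaps are all at most `max_gap` bp,
#' in coordinate order. CHG/CHH sites never enter a window.
#'
#' @inheritParams usable_sites
#' @param sites optionally, a precomputed [usable_sites()] table.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open),
#'   `n_cpg`, and a list column `site_idx` of row indices into the
#'   usable-site table (returned as attribute `sites`).
#' @export
segment_candidates <- function(samples, params = dmr_params(),
                               sites = NULL) {
  if (is.null(sites)) sites <- usable_sites(samples, params)
  w <- params$window_cpgs
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer())
  empty$site_idx <- list()
  if (nrow(sites) < w) {
    attr(empty, "sites") <- sites
    return(empty)
  }
  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    n <- length(idx)
    if (n < w) next
    gap_ok <- diff(pos) <= params$max_gap
    for (i in seq_len(n - w + 1L)) {
      if (all(gap_ok[i:(i + w - 2L)])) {
        rows <- idx[i:(i + w - 1L)]
        out[[length(out) + 1L]] <- list(chrom = ch,
                                        start = pos[i] - 1L,
                                        end = pos[i + w - 1L],
                                        n_cpg = w, site_idx = rows)
      }
    }
  }
  if (length(out) == 0) {
    message("no candidate windows (gaps exceed max_gap)")
    attr(empty, "sites") <- sites
    return(empty)
  }
  res <- data.frame(chrom = vapply(out, `[[`, character(1), "chrom"),
                    start = vapply(out, `[[`, integer(1), "start"),
                    end = vapply(out, `[[`, integer(1), "end"),
                    n_cpg = vapply(out, `[[`, integer(1), "n_cpg"))
  res$site_idx <- lapply(out, `[[`, "site_idx")
  attr(res, "sites") <- sites
  res
}

#' Test one candidate region
#'
#' Pools methylated/unmethylated counts over the region's sites within
#' each group, takes the pooled levels `sum(m) / sum(m + u)`, computes
#' the regularized fold `(max(Lt,Ln)+eps) / (min(Lt,Ln)+eps)`, and a
#' two-sided Fisher exact P value on the pooled 2x2 table
#' (methylated/unmethylated x tumor/normal).
#'
#' @param region one row of [segment_candidates()] output (with its
#'   `site_idx`), or any object with a `site_idx` vector.
#' @param sites the usable-site table the indices refer to.
#' @param params a [dmr_params()].
#' @return list with `level_tumor`, `level_normal`, `fold`, `p_value`,
#'   `direction`.
#' @export
region_test <- function(region, sites, params = dmr_params()) {
  idx <- if (is.data.frame(region)) region$site_idx[[1]] else region$site_idx
  site_set_stats(sites[idx, , drop = FALSE], params)
}

# internal: stats for every window, vectorized over windows
window_stats <- function(cands, sites, params) {
  n <- nrow(cands)
  stats_df <- data.frame(level_tumor = numeric(n), level_normal = numeric(n),
                         fold = numeric(n), p_value = numeric(n),
                         direction = character(n))
  for (i in seq_len(n)) {
    st <- site_set_stats(sites[cands$site_idx[[i]], , drop = FALSE], params)
    stats_df$level_tumor[i] <- st$level_tumor
    stats_df$level_normal[i] <- st$level_normal
    stats_df$fold[i] <- st$fold
    stats_df$p_value[i] <- st$p_value
    stats_df$direction[i] <- st$direction
  }
  cbind(cands[c("chrom", "start", "end", "n_cpg")], stats_df,
        site_idx = I(cands$site_idx))
}

#' Call differentially methylated regions
#'
#' Slides 5-CpG windows over the usable sites, keeps windows with fold
#' strictly above `min_fold` and P strictly below `max_p`, unions
#' overlapping significant windows of the same direction into maximal
#' regions, recomputes each merged region's statistics over all usable
#' CpGs it contains, and keeps only regions that still satisfy the full
#' criterion. Same-direction output regions never overlap.
#'
#' @inheritParams usable_sites
#' @return `data.frame` of DMRs: `chrom`, `start`, `end` (0-based
#'   half-open), `n_cpg`, `level_tumor`, `level_normal`, `fold`,
#'   `p_value`, `direction`, sorted by coordinate, with the usable-site
#'   table as attribute `sites`.
#' @export
call_dmrs <- function(samples, params = dmr_params()) {
  sites <- usable_sites(samples, params)
  cands <- segment_candidates(samples, params, sites = sites)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      level_tumor = numeric(), level_normal = numeric(),
                      fold = numeric(), p_value = numeric(),
                      direction = character())
  if (nrow(cands) == 0) {
    attr(empty, "sites") <- sites
    attr(empty, "window_stats") <- empty
    return(empty)
  }
  ws <- window_stats(cands, sites, params)
  sig <- ws[ws$fold > params$min_fold & ws$p_value < params$max_p &
            ws$n_cpg >= 5L, , drop = FALSE]
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sub <- sig[sig$direction == dir, , drop = FALSE]
    if (nrow(sub) == 0) next
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start + 1L, sub$end)))
    for (j in seq_along(gr)) {
      ch <- as.character(GenomicRanges::seqnames(gr))[j]
      s0 <- GenomicRanges::start(gr)[j] - 1L
      e0 <- GenomicRanges::end(gr)[j]
      idx <- which(sites$chrom == ch & sites$pos > s0 & sites$pos <= e0)
      st <- site_set_stats(sites[idx, , drop = FALSE], params)
      if (st$fold > params$min_fold && st$p_value < params$max_p &&
          length(idx) >= 5L && st$direction == dir) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = s0, end = e0, n_cpg = length(idx),
          level_tumor = st$level_tumor, level_normal = st$level_normal,
          fold = st$fold, p_value = st$p_value, direction = dir)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "sites") <- sites
  attr(res, "window_stats") <- ws
  res
}

#' Merge adjacent same-direction DMRs
#'
#' Scans the sorted DMR list left to right: for each pair of consecutive
#' DMRs on the same chromosome with the same direction (no
#' opposite-direction DMR between them), the full span from the start of
#' the first to the end of the second is evaluated over all usable CpGs
#' it contains; when that span itself satisfies the DMR criterion
#' (> 2-fold, P < 0.05, >= 5 CpGs, same direction), the pair is replaced
#' by the merged region. The scan iterates to a fixpoint, so the
#' operation is idempotent and every output still satisfies the
#' criterion.
#'
#' @param dmrs sorted DMR table from [call_dmrs()].
#' @param sites usable-site table (defaults to the `sites` attribute of
#'   `dmrs`).
#' @param params a [dmr_params()].
#' @return merged DMR table, same columns as [call_dmrs()].
#' @export
merge_dmrs <- function(dmrs, sites = attr(dmrs, "sites"),
                       params = dmr_params()) {
  if (nrow(dmrs) <= 1) return(dmrs)
  if (!identical(order(dmrs$chrom, dmrs$start), seq_len(nrow(dmrs))))
    ms_stop("dmrs must be sorted by (chrom, start)")
  if (is.null(sites)) ms_stop("usable-site table required for merging")
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(dmrs)) {
      a <- dmrs[i, ]; b <- dmrs[i + 1L, ]
      if (a$chrom == b$chrom && a$direction == b$direction) {
        idx <- which(sites$chrom == a$chrom & sites$pos > a$start &
                     sites$pos <= b$end)
        st <- site_set_stats(sites[idx, , drop = FALSE], params)
        if (length(idx) >= 5L && st$fold > params$min_fold &&
            st$p_value < params$max_p && st$direction == a$direction) {
          span <- data.frame(chrom = a$chrom, start = a$start, end = b$end,
                             n_cpg = length(idx),
                             level_tumor = st$level_tumor,
                             level_normal = st$level_normal,
                             fold = st$fold, p_value = st$p_value,
                             direction = a$direction)
          dmrs <- rbind(dmrs[seq_len(i - 1L), , drop = FALSE], span,
                        if (i + 2L <= nrow(dmrs))
                          dmrs[(i + 2L):nrow(dmrs), , drop = FALSE])
          rownames(dmrs) <- NULL
          merged <- TRUE
          next  # retry at the same i with the merged region
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  attr(dmrs, "sites") <- sites
  dmrs
}

#' Write DMRs as BED6+ / TSV
#'
#' BED columns: chrom, start, end, name (`DMR_<n>`), score
#' (`-log10(p)`), strand (`.`), then `n_cpg`, `level_tumor`,
#' `level_normal`, `fold`, `p_value`, `direction`.
#'
#' @param dmrs DMR table.
#' @param path output path.
#' @param header write a header line (TSV mirror) instead of bare BED.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path, header = FALSE) {
  if (nrow(dmrs) == 0) {
    cols <- c("chrom", "start", "end", "name", "score", "strand", "n_cpg",
              "level_tumor", "level_normal", "fold", "p_value", "direction")
    writeLines(if (header) paste(cols, collapse = "\t") else character(),
               path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = sprintf("DMR_%d", seq_len(nrow(dmrs))),
                    score = round(-log10(pmax(dmrs$p_value, 1e-300)), 3),
                    strand = ".",
                    n_cpg = dmrs$n_cpg,
                    level_tumor = signif(dmrs$level_tumor, 6),
                    level_normal = signif(dmrs$level_normal, 6),
                    fold = signif(dmrs$fold, 6),
                    p_value = signif(dmrs$p_value, 6),
                    direction = dmrs$direction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a DMR BED6+ file written by [write_dmr_bed()]
#' @param path input path.
#' @param header whether the file has a header line.
#' @return DMR table.
#' @export
read_dmr_bed <- function(path, header = FALSE) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "n_cpg",
            "level_tumor", "level_normal", "fold", "p_value", "direction")
  if (length(readLines(path)) == (if (header) 1L else 0L)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      level_tumor = numeric(), level_normal = numeric(),
                      fold = numeric(), p_value = numeric(),
                      direction = character())
    return(out)
  }
  bed <- utils::read.table(path, sep = "\t", header = header,
                           col.names = if (header) NULL else cols)
  names(bed) <- cols
  bed[c("chrom", "start", "end", "n_cpg", "level_tumor", "level_normal",
        "fold", "p_value", "direction")]
}
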