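#' Construct a methylome sample from per-cytosine calls
#'
#' @param sample_id sample label.
#' @param group group label, `"tumor"` or `"normal"`.
#' @param calls `data.frame` with columns `chrom`, `pos` (1-based),
#'   `strand` (`+`/`-`), `context` (`CG`, `CHG`, `CHH`), `n_meth`,
#'   `n_unmeth`. Rows are sorted by (chrom, pos) and must be unique on
#'   (chrom, pos, strand); every site must carry at least one read.
#' @return object of class `MethylomeSample`.
#' @export
methylome_sample <- function(sample_id, group, calls) {
  group <- match.arg(group, c("tumor", "normal"))
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  if (!all(req %in% names(calls)))
    ms_stop("calls must have columns ", paste(req, collapse = ", "))
  if (nrow(calls) > 0) {
    bad_ctx <- !calls$context %in% c("CG", "CHG", "CHH")
    if (any(bad_ctx))
      ms_stop("unknown context token(s): ",
              paste(unique(calls$context[bad_ctx]), collapse = ", "))
    if (any(!calls$strand %in% c("+", "-")))
      ms_stop("strand must be '+' or '-'")
    if (any(calls$n_meth < 0) || any(calls$n_unmeth < 0))
      ms_stop("negative read counts")
    if (any(calls$n_meth + calls$n_unmeth < 1))
      ms_stop("every site must be covered by at least one read")
    calls <- calls[order(calls$chrom, calls$pos, calls$strand), ,
                   drop = FALSE]
    key <- paste(calls$chrom, calls$pos, calls$strand)
    if (anyDuplicated(key))
      ms_stop("duplicate loci: ", key[duplicated(key)][1])
    rownames(calls) <- NULL
  }
  structure(list(sample_id = sample_id, group = group, calls = calls),
            class = "MethylomeSample")
}

#' @export
print.MethylomeSample <- function(x, ...) {
  cat(sprintf("MethylomeSample %s (%s): %d cytosine records\n",
              x$sample_id, x$group, nrow(x$calls)))
  invisible(x)
}

#' Parse a per-cytosine methylation call table
#'
#' Two tab-delimited dialects are auto-detected by column count:
#' the native 6-column layout (`chrom, pos, strand, context, n_meth,
#' n_unmeth`) and a Bismark CX-report variant (`chrom, pos, strand,
#' n_meth, n_unmeth, context, trinucleotide`). Positions are 1-based.
#' Malformed rows raise an error naming the first offending line;
#' zero-coverage rows are dropped with a warning.
#'
#' @param path path to the table.
#' @param sample_id sample label (default: file name without extension).
#' @param group `"tumor"` or `"normal"`.
#' @return a [methylome_sample()].
#' @export
parse_cytosine_table <- function(path, sample_id = NULL, group = "tumor") {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty cytosine table: ", path)
    return(methylome_sample(sample_id, group, data.frame(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), n_meth = integer(), n_unmeth = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (!all(ncol %in% c(6L, 7L)) || length(unique(ncol)) != 1)
    ms_stop("line ", which(!ncol %in% c(6L, 7L))[1],
            ": expected 6 or 7 tab-separated fields")
  m <- do.call(rbind, fields)
  if (ncol[1] == 6L) {
    df <- data.frame(chrom = m[, 1], pos = m[, 2], strand = m[, 3],
                     context = m[, 4], n_meth = m[, 5], n_unmeth = m[, 6])
  } else {
    df <- data.frame(chrom = m[, 1], pos = m[, 2], strand = m[, 3],
                     context = m[, 6], n_meth = m[, 4], n_unmeth = m[, 5])
  }
  check_int <- function(x, what) {
    bad <- !grepl("^[0-9]+$", x)
    if (any(bad))
      ms_stop("line ", which(bad)[1], ": non-integer ", what, " '",
              x[bad][1], "'")
    as.integer(x)
  }
  df$pos <- check_int(df$pos, "position")
  df$n_meth <- check_int(df$n_meth, "methylated count")
  df$n_unmeth <- check_int(df$n_unmeth, "unmethylated count")
  bad_ctx <- !df$context %in% c("CG", "CHG", "CHH")
  if (any(bad_ctx))
    ms_stop("line ", which(bad_ctx)[1], ": unknown context token '",
            df$context[bad_ctx][1], "'")
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand))
    ms_stop("line ", which(bad_strand)[1], ": bad strand '",
            df$strand[bad_strand][1], "'")
  uncov <- df$n_meth + df$n_unmeth < 1
  if (any(uncov)) {
    warning(sum(uncov), " zero-coverage row(s) dropped from ", path)
    df <- df[!uncov, , drop = FALSE]
  }
  key <- paste(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key))
    ms_stop("line ", which(duplicated(key))[1], ": duplicate locus ",
            key[duplicated(key)][1])
  methylome_sample(sample_id, group, df)
}

#' Write a methylome sample as a 6-column cytosine table
#' @param sample a [methylome_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_table <- function(sample, path) {
  utils::write.table(sample$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flag a read under the low-quality read rule
#'
#' A read fails when more than 10% of its bases are unknown (`N`,
#' case-insensitive) or more than 10% have Phred quality below 20; exactly
#' 10% passes. When both conditions hold, the unknown-base flag takes
#' precedence.
#'
#' @param bases a single sequence string or character vector of bases.
#' @param qualities numeric Phred scores, one per base.
#' @return `"pass"`, `"fail_n"`, or `"fail_quality"`.
#' @export
qc_flag_read <- function(bases, qualities) {
  if (is.character(bases) && length(bases) == 1L && nchar(bases) > 1L)
    bases <- strsplit(bases, "")[[1]]
  if (length(bases) != length(qualities))
    ms_stop("bases and qualities differ in length (", length(bases),
            " vs ", length(qualities), ")")
  if (length(bases) < 1L) ms_stop("empty read")
  n_frac <- mean(toupper(bases) == "N")
  if (n_frac > 0.10) return("fail_n")
  if (mean(qualities < 20) > 0.10) return("fail_quality")
  "pass"
}

#' Decode a Sanger Phred+33 quality string
#' @param qual quality string.
#' @return integer Phred scores.
#' @export
phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' Per-cytosine methylation level
#'
#' The level of a cytosine is the number of reads reporting it methylated
#' divided by all reads covering it: `n_meth / (n_meth + n_unmeth)`.
#'
#' @param n_meth,n_unmeth non-negative read counts (vectorized); each site
#'   must be covered by at least one read.
#' @return fraction(s) in \[0,1\].
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0) || any(n_unmeth < 0)) ms_stop("negative counts")
  cov <- n_meth + n_unmeth
  if (any(cov < 1))
    ms_stop("undefined level at zero coverage; filter uncovered sites first")
  n_meth / cov
}

#' Context composition of methylated cytosines
#'
#' Counts methylated cytosines (mC) per sequence context and their share
#' of all mC, plus the mean methylation level per context. The default mC
#' rule calls a site methylated when it has at least one methylated read.
#'
#' @param sample a [methylome_sample()].
#' @param mc_rule function of (n_meth, n_unmeth) returning a logical mC
#'   call per site; default `n_meth >= 1`.
#' @return `data.frame` with one row per context (`CG`, `CHG`, `CHH`):
#'   `n_mc` (mC count), `share_pct` (share of all mC, in percent, rounded
#'   to 3 decimals; `NA` when the sample has no mC), `mean_level_pct`
#'   (mean level over covered sites of that context, percent). Attributes
#'   `total_mc` and `pct_mc_of_covered_c` summarize the whole sample.
#' @export
context_share <- function(sample,
                          mc_rule = function(n_meth, n_unmeth) n_meth >= 1) {
  calls <- sample$calls
  if (nrow(calls) == 0) ms_stop("empty sample")
  ctx <- factor(calls$context, levels = c("CG", "CHG", "CHH"))
  is_mc <- mc_rule(calls$n_meth, calls$n_unmeth)
  n_mc <- tapply(is_mc, ctx, sum, default = 0L)
  total <- sum(n_mc)
  share <- if (total == 0) rep(NA_real_, 3)
           else round_half_away(100 * n_mc / total, 3)
  lev <- methylation_level(calls$n_meth, calls$n_unmeth)
  mean_lev <- round_half_away(
    100 * tapply(lev, ctx, mean, default = NA_real_), 3)
  out <- data.frame(context = c("CG", "CHG", "CHH"),
                    n_mc = as.integer(n_mc),
                    share_pct = as.numeric(share),
                    mean_level_pct = as.numeric(mean_lev))
  attr(out, "total_mc") <- as.integer(total)
  attr(out, "pct_mc_of_covered_c") <-
    round_half_away(100 * total / nrow(calls), 3)
  out
}

#' Context shares from pre-tabulated mC counts
#'
#' Convenience for recomputing the percent composition from published
#' per-context methylcytosine counts.
#'
#' @param n_mcg,n_mchg,n_mchh methylcytosine counts per context.
#' @return named numeric vector of shares in percent, rounded to 3
#'   decimals.
#' @export
context_share_from_counts <- function(n_mcg, n_mchg, n_mchh) {
  total <- n_mcg + n_mchg + n_mchh
  if (total <= 0) ms_stop("no methylated cytosines")
  round_half_away(
    100 * c(CG = n_mcg, CHG = n_mchg, CHH = n_mchh) / total, 3)
}

#' Group mean and sample standard deviation
#'
#' Summary rows of the per-sample methylome tables report mean plus or
#' minus the sample (n-1) standard deviation, rounded to 3 decimals, half
#' away from zero.
#'
#' @param values numeric vector (percentages); at least 2 values are
#'   needed for the standard deviation.
#' @param label optional row label.
#' @param with_sd report the standard deviation (default `TRUE`); set
#'   `FALSE` for a mean-only row from a single value.
#' @return `data.frame` row with `label`, `mean`, `sd` (rounded) and
#'   attributes `mean_raw`, `sd_raw`.
#' @export
group_mean_sd <- function(values, label = "", with_sd = TRUE) {
  if (length(values) < 1) ms_stop("no values")
  if (with_sd && length(values) < 2)
    ms_stop("standard deviation is undefined for a single value")
  m <- mean(values)
  s <- if (with_sd) stats::sd(values) else NA_real_
  out <- data.frame(label = label, mean = round_half_away(m, 3),
                    sd = if (with_sd) round_half_away(s, 3) else NA_real_)
  attr(out, "mean_raw") <- m
  attr(out, "sd_raw") <- s
  out
}

#' Regional methylation profile over an annotation
#'
#' Partitions sites into promoter (strand-aware window around the TSS),
#' gene body, and intergenic features — promoter taking precedence over
#' gene body where they overlap — and reports the coverage-weighted mean
#' methylation level per feature and context. Features with no covered
#' site are reported as `NA`, not zero.
#'
#' @param sample a [methylome_sample()].
#' @param genes gene annotation (0-based half-open, as from
#'   [simulate_annotation()] / [read_gene_bed()]).
#' @param promoter_window `c(upstream, downstream)` in bp around the TSS.
#' @return `data.frame` with `feature`, `context`, `n_sites`,
#'   `mean_level` (coverage-weighted fraction, `NA` when no sites).
#' @export
regional_profile <- function(sample, genes,
                             promoter_window = c(2000L, 500L)) {
  calls <- sample$calls
  if (nrow(genes) > 0 &&
      !all(genes$chrom %in% unique(calls$chrom))) {
    missing <- setdiff(unique(genes$chrom), unique(calls$chrom))
    warning("annotation chromosome(s) absent from sample, skipped: ",
            paste(missing, collapse = ", "))
    genes <- genes[genes$chrom %in% unique(calls$chrom), , drop = FALSE]
  }
  feature <- rep("intergenic", nrow(calls))
  if (nrow(genes) > 0 && nrow(calls) > 0) {
    sites <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos, calls$pos))
    body <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    prom_df <- promoter_intervals(genes, promoter_window[1],
                                  promoter_window[2])
    prom <- GenomicRanges::GRanges(
      prom_df$chrom, IRanges::IRanges(prom_df$start + 1L, prom_df$end))
    in_body <- IRanges::overlapsAny(sites, body)
    in_prom <- IRanges::overlapsAny(sites, prom)
    feature[in_body] <- "gene_body"
    feature[in_prom] <- "promoter"   # promoter wins over body
  }
  grid <- expand.grid(feature = c("promoter", "gene_body", "intergenic"),
                      context = c("CG", "CHG", "CHH"),
                      stringsAsFactors = FALSE)
  grid$n_sites <- 0L
  grid$mean_level <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- feature == grid$feature[i] & calls$context == grid$context[i]
    grid$n_sites[i] <- sum(sel)
    if (any(sel)) {
      grid$mean_level[i] <- sum(calls$n_meth[sel]) /
        sum(calls$n_meth[sel] + calls$n_unmeth[sel])
    }
  }
  grid
}
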