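#' Pipeline configuration
#'
#' Bundles every stage parameter with its documented default:
#' the synthetic-study configuration ([sim_config()]), DMR calling
#' parameters ([dmr_params()]), the promoter window and annotation
#' scope, the DEG thresholds, and the Spearman retention threshold. The
#' configuration serializes to JSON ([write_pipeline_config()]) and
#' round-trips exactly.
#'
#' @param sim a [sim_config()].
#' @param dmr a [dmr_params()].
#' @param promoter_window `c(upstream, downstream)` bp around the TSS.
#' @param dmg_scope DMR-to-gene scope, `"gene_region"` or `"promoter"`.
#' @param lfc_threshold,p_threshold DEG screen thresholds.
#' @param spearman_threshold minimum `|rho|` for the co-expression
#'   screen.
#' @param outdir output directory for stage artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            dmr = dmr_params(),
                            promoter_window = c(2000L, 500L),
                            dmg_scope = "gene_region",
                            lfc_threshold = 1,
                            p_threshold = 0.05,
                            spearman_threshold = 0.3,
                            outdir = tempfile("methylscreen_run_")) {
  structure(list(sim = sim, dmr = dmr,
                 promoter_window = as.integer(promoter_window),
                 dmg_scope = dmg_scope,
                 lfc_threshold = lfc_threshold,
                 p_threshold = p_threshold,
                 spearman_threshold = spearman_threshold,
                 outdir = outdir),
            class = "pipeline_config")
}

# internal: artifact paths under the config's outdir
stage_paths <- function(config) {
  o <- config$outdir
  np <- config$sim$n_per_group
  ids <- c(sprintf("T%d", seq_len(np)), sprintf("N%d", seq_len(np)))
  list(genes = file.path(o, "genes.bed"),
       cytosine = setNames(file.path(o, paste0(ids, ".cytosine.tsv")), ids),
       counts = file.path(o, "expression_counts.tsv"),
       truth = file.path(o, "truth.json"),
       panel = file.path(o, "demeth_panel.tsv"),
       fastq = file.path(o, "reads.fastq"),
       qc = file.path(o, "read_qc.tsv"),
       context = file.path(o, "context_summary.tsv"),
       groups = file.path(o, "group_summary.tsv"),
       dmr_bed = file.path(o, "dmrs.bed"),
       dmr_tsv = file.path(o, "dmrs.tsv"),
       deg = file.path(o, "deg.tsv"),
       candidates = file.path(o, "candidate_sets.tsv"),
       venn = file.path(o, "venn_counts.json"),
       response = file.path(o, "demeth_response.tsv"),
       manifest = file.path(o, "manifest.json"))
}

# internal: load the simulated samples back from disk
load_samples <- function(paths, np) {
  ids <- names(paths$cytosine)
  lapply(seq_along(ids), function(i)
    parse_cytosine_table(paths$cytosine[[i]], sample_id = ids[i],
                         group = if (grepl("^T", ids[i])) "tumor"
                                 else "normal"))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` writes the full synthetic study (annotation,
#' per-sample cytosine tables, expression counts, demethylation panel,
#' FASTQ fixture, truth JSON); `qc` flags the FASTQ reads; `summarize`
#' writes context and group methylome summaries; `dmr` calls and merges
#' DMRs; `deg` runs the expression screen; `integrate` builds the
#' crossover candidate sets; `demeth` quantifies the panel response;
#' `run-all` runs everything and writes a manifest of per-stage record
#' counts. All randomness flows from `config$sim$seed`; no stage mutates
#' its inputs.
#'
#' @param name stage name (see above).
#' @param config a [pipeline_config()].
#' @return named list of per-stage record counts, invisibly for
#'   `run-all`.
#' @export
run_subcommand <- function(name, config = pipeline_config()) {
  name <- match.arg(name, c("simulate", "qc", "summarize", "dmr", "deg",
                            "integrate", "demeth", "run-all"))
  paths <- stage_paths(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  if (name %in% c("simulate", "run-all")) {
    genes <- simulate_annotation(config$sim)
    write_gene_bed(genes, paths$genes)
    meth <- simulate_methylome(config$sim, genes)
    for (s in meth$samples)
      write_cytosine_table(s, paths$cytosine[[s$sample_id]])
    expr <- simulate_expression(config$sim, genes, meth$truth)
    write_expression_tsv(expr$counts, paths$counts)
    panel <- simulate_demeth_panel(config$sim)
    utils::write.table(panel, paths$panel, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    reads <- simulate_fastq(config$sim, n_reads = 200, frac_n = 0.05,
                            frac_lowq = 0.05)
    write_fastq(reads, paths$fastq)
    truth <- expr$truth
    jsonlite::write_json(
      list(dmr_intervals = truth$dmr_intervals,
           deg_labels = as.list(truth$deg_labels)),
      paths$truth, auto_unbox = TRUE, digits = NA)
    counts$genes <- nrow(genes)
    counts$cytosine_sites <- nrow(meth$samples[[1]]$calls)
    counts$planted_dmrs <- nrow(truth$dmr_intervals)
    counts$reads <- nrow(reads)
  }
  if (name %in% c("qc", "run-all")) {
    reads <- read_fastq(paths$fastq)
    flags <- vapply(seq_len(nrow(reads)), function(i)
      qc_flag_read(reads$seq[i], phred_scores(reads$qual[i])),
      character(1))
    utils::write.table(data.frame(id = reads$id, flag = flags), paths$qc,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$reads_pass <- sum(flags == "pass")
  }
  samples <- NULL
  if (name %in% c("summarize", "dmr", "run-all")) {
    samples <- load_samples(paths, config$sim$n_per_group)
  }
  if (name %in% c("summarize", "run-all")) {
    ctx <- do.call(rbind, lapply(samples, function(s) {
      cs <- context_share(s)
      cbind(sample_id = s$sample_id, group = s$group, cs,
            total_mc = attr(cs, "total_mc"))
    }))
    utils::write.table(ctx, paths$context, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mc_pct <- vapply(samples, function(s) {
      lev <- methylation_level(s$calls$n_meth, s$calls$n_unmeth)
      100 * mean(lev)
    }, numeric(1))
    grp <- vapply(samples, function(s) s$group, character(1))
    rows <- rbind(group_mean_sd(mc_pct[grp == "tumor"], "tumor"),
                  group_mean_sd(mc_pct[grp == "normal"], "normal"),
                  group_mean_sd(mc_pct, "all"))
    utils::write.table(rows, paths$groups, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$summarized_samples <- length(samples)
  }
  dmrs <- NULL
  if (name %in% c("dmr", "run-all")) {
    dmrs <- merge_dmrs(call_dmrs(samples, config$dmr), params = config$dmr)
    write_dmr_bed(dmrs, paths$dmr_bed)
    write_dmr_bed(dmrs, paths$dmr_tsv, header = TRUE)
    counts$dmrs <- nrow(dmrs)
  }
  degs <- NULL
  if (name %in% c("deg", "run-all")) {
    mat <- read_expression_tsv(paths$counts)
    groups <- ifelse(grepl("^T", colnames(mat)), "tumor", "normal")
    degs <- deg_screen(mat, groups, config$lfc_threshold,
                       config$p_threshold)
    utils::write.table(degs, paths$deg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$up_deg <- sum(degs$label == "up")
    counts$down_deg <- sum(degs$label == "down")
  }
  if (name %in% c("integrate", "run-all")) {
    genes <- read_gene_bed(paths$genes)
    if (is.null(dmrs)) dmrs <- read_dmr_bed(paths$dmr_bed)
    if (is.null(degs)) degs <- utils::read.table(paths$deg, header = TRUE,
                                                 sep = "\t")
    dmg <- assign_dmrs_to_genes(dmrs, genes, config$promoter_window,
                                config$dmg_scope)
    sets <- crossover_sets(dmg$hyper_dmg, dmg$hypo_dmg, degs)
    set_df <- function(nm, genes) {
      if (length(genes) == 0)
        data.frame(set = character(), gene_id = character())
      else data.frame(set = nm, gene_id = genes)
    }
    long <- rbind(set_df("hyper_down", sets$hyper_down),
                  set_df("hypo_up", sets$hypo_up))
    utils::write.table(long, paths$candidates, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(lapply(sets$venn_counts, as.list), paths$venn,
                         auto_unbox = TRUE)
    counts$hyper_down <- length(sets$hyper_down)
    counts$hypo_up <- length(sets$hypo_up)
  }
  if (name %in% c("demeth", "run-all")) {
    panel <- read_demeth_panel(paths$panel)
    resp <- panel_response(panel)
    utils::write.table(resp$records, paths$response, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    counts$demeth_units <- nrow(resp$records)
  }
  if (name == "run-all") {
    manifest <- list(
      tool = paste("methylscreen",
                   as.character(utils::packageVersion("methylscreen"))),
      seed = config$sim$seed,
      config = list(
        n_per_group = config$sim$n_per_group,
        n_cpg_sites = config$sim$n_cpg_sites,
        n_genes = config$sim$n_genes,
        min_coverage = config$dmr$min_coverage,
        max_gap = config$dmr$max_gap,
        window_cpgs = config$dmr$window_cpgs,
        epsilon = config$dmr$epsilon,
        promoter_window = config$promoter_window,
        dmg_scope = config$dmg_scope,
        lfc_threshold = config$lfc_threshold,
        p_threshold = config$p_threshold,
        spearman_threshold = config$spearman_threshold),
      input_checksums = {
        cs <- tools::md5sum(c(paths$genes, paths$counts,
                              unname(paths$cytosine)))
        as.list(setNames(unname(cs), basename(names(cs))))
      },
      record_counts = counts,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(counts)
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round-trip of every stage parameter, including planted DMR
#' descriptions; `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces `cfg` exactly (the output directory included).
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `path` invisibly; `read_pipeline_config` returns the
#'   restored [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  sim <- unclass(config$sim)
  sim$planted_dmrs <- lapply(sim$planted_dmrs, function(d)
    unclass(d)[c("width_in_cpgs", "level_tumor", "level_normal")])
  obj <- list(sim = sim, dmr = unclass(config$dmr),
              promoter_window = config$promoter_window,
              dmg_scope = config$dmg_scope,
              lfc_threshold = config$lfc_threshold,
              p_threshold = config$p_threshold,
              spearman_threshold = config$spearman_threshold,
              outdir = config$outdir)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- obj$sim
  sim_args$planted_dmrs <- if (is.data.frame(sim_args$planted_dmrs)) {
    lapply(seq_len(nrow(sim_args$planted_dmrs)), function(i)
      planted_dmr(sim_args$planted_dmrs$width_in_cpgs[i],
                  sim_args$planted_dmrs$level_tumor[i],
                  sim_args$planted_dmrs$level_normal[i]))
  } else {
    lapply(sim_args$planted_dmrs, function(d)
      planted_dmr(d$width_in_cpgs, d$level_tumor, d$level_normal))
  }
  sim_args$demeth_units <- lapply(sim_args$demeth_units, unlist)
  sim <- do.call(sim_config, sim_args)
  pipeline_config(sim = sim,
                  dmr = do.call(dmr_params, obj$dmr),
                  promoter_window = obj$promoter_window,
                  dmg_scope = obj$dmg_scope,
                  lfc_threshold = obj$lfc_threshold,
                  p_threshold = obj$p_threshold,
                  spearman_threshold = obj$spearman_threshold,
                  outdir = obj$outdir)
}
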