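#' Build a validated run configuration
#'
#' Either a synthetic run (`synthetic` holds [synth_config()] arguments) or
#' a file-based run (`gtf`, `counts`, `fragments`: a nested list
#' stage -> channel ("ip"/"input") -> vector of BED paths). Thresholds
#' default to the pipeline's standard values.
#'
#' @param x optional YAML path or list of fields to merge over the defaults.
#' @param ... individual fields overriding `x`.
#' @return a `run_config` list.
#' @export
run_config <- function(x = NULL, ...) {
  defaults <- list(
    synthetic = NULL, gtf = NULL, counts = NULL, fragments = NULL,
    chrom_sizes = NULL, gmt = NULL, background = NULL,
    padj = 0.05, lfc = 1, tpm_threshold = 0.5, flank = 5000,
    w = 200, gap = 3, p0 = 0.2, q_max = 0.05, floor_factor = 1,
    eps = 0.1, delta = 0, mapq_min = 20, prior_df = 20,
    n_perm = 500, seed = 1, out_dir = NULL, write_fragments = TRUE)
  if (is.character(x)) x <- yaml::read_yaml(x)
  cfg <- utils::modifyList(defaults, c(x %||% list(), list(...)))
  for (f in c("padj", "lfc", "tpm_threshold", "flank", "w", "q_max", "eps"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("'", f, "' must be a non-negative number")
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$gtf) || is.null(cfg$counts) || is.null(cfg$fragments)))
    stop("provide either 'synthetic' or gtf + counts + fragments")
  structure(cfg, class = "run_config")
}

#' Run the full promoter-mark / expression integration pipeline
#'
#' Executes, in order: synthetic data generation (if requested), TPM and
#' expression-level classification, differential expression over successive
#' stage transitions, fragment filtering, stage-level island calling
#' (replicates pooled), promoter signal quantification, peak annotation and
#' promoter-modified gene sets, transition-cluster integration into the
#' HDEG set, and (when gene sets are supplied) enrichment. Every
#' intermediate is persisted under `out_dir`; identical config and seed
#' give identical summaries. Set-logic invariants are asserted on every
#' run.
#'
#' @param config a [run_config()] (or a list / YAML path coerced to one).
#' @param quiet suppress stage messages.
#' @return a `promark_run` list: `summary`, the main tables, and (synthetic
#'   runs) `recovery` metrics against the planted ground truth.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  say <- function(...) if (!quiet) pm_msg(...)
  out_dir <- config$out_dir %||% tempfile("promark_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    scfg <- if (inherits(config$synthetic, "synth_config")) config$synthetic
            else do.call(synth_config,
                         utils::modifyList(config$synthetic,
                                           list(seed = config$seed)))
    say("generating synthetic data (%d genes, %d stages)",
        scfg$n_genes, scfg$n_stages)
    genome <- generate_genome(scfg)
    chip <- generate_chip(scfg, genome)
    truth <- chip$truth
    fragments <- chip$fragments
    cm <- generate_counts(scfg, genome, truth)
    write_genome(genome, out_dir)
    data.table::fwrite(
      data.table::data.table(gene_id = rownames(cm$counts), cm$counts),
      file.path(out_dir, "counts.tsv"), sep = "\t")
    jsonlite::write_json(
      list(planted_domains = cbind(truth$planted_domains,
                                   as.data.frame(truth$presence)),
           planted_degs = truth$planted_degs,
           true_hdegs = truth$true_hdegs, decoys = truth$decoys),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    say("reading inputs")
    cs <- NULL
    if (!is.null(config$chrom_sizes)) {
      tab <- data.table::fread(config$chrom_sizes, header = FALSE)
      cs <- stats::setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
    }
    genome <- read_gtf_genes(config$gtf, chrom_sizes = cs)
    cm <- read_counts_tsv(config$counts,
                          stats::setNames(genome$genes$exonic_length,
                                          genome$genes$gene_id))
    fragments <- lapply(config$fragments, function(st)
      lapply(st, function(paths)
        lapply(paths, read_fragments_bed)))
  }
  stages <- unique(cm$stages)

  # ---- expression -----------------------------------------------------
  say("expression: TPM, level classes, differential expression")
  tpm_mat <- tpm(cm)
  expr <- classify_expression(tpm_mat, cm$stages,
                              expressed_threshold = config$tpm_threshold)
  expressed_genes <- names(expr$expressed)[expr$expressed]
  de_list <- lapply(seq_len(length(stages) - 1), function(t)
    de_test(cm, stages[t], stages[t + 1], genes = expressed_genes,
            prior_df = config$prior_df, padj_max = config$padj,
            lfc_min = config$lfc))
  names(de_list) <- paste(stages[-length(stages)], stages[-1], sep = "->")
  degs <- call_degs(de_list)
  stage_max <- stage_max_assignment(expr, degs$genes)
  flows <- level_transition_table(expr, degs$genes)
  for (nm in names(de_list))
    data.table::fwrite(de_list[[nm]],
                       file.path(out_dir, paste0("de_", gsub("->", "_to_", nm),
                                                 ".tsv")), sep = "\t")
  data.table::fwrite(
    data.table::data.table(gene_id = rownames(expr$levels),
                           expressed = expr$expressed,
                           expr$stage_mean, level = expr$levels),
    file.path(out_dir, "expression_table.tsv"), sep = "\t")

  # ---- ChIP: filtering, islands, promoter signal ----------------------
  say("ChIP: filtering fragments and calling islands per stage")
  filtered <- lapply(fragments, function(st)
    lapply(st, function(reps) lapply(reps, filter_fragments,
                                     mapq_min = config$mapq_min)))
  if (!is.null(config$synthetic) && config$write_fragments)
    for (st in names(filtered))
      for (ch in names(filtered[[st]]))
        for (r in seq_along(filtered[[st]][[ch]]))
          write_fragments_bed(filtered[[st]][[ch]][[r]],
                              file.path(out_dir,
                                        sprintf("%s_%s_r%d.bed", st, ch, r)))
  windows <- promoter_windows(genome$genes, genome$chrom_sizes,
                              flank = config$flank)
  stage_islands <- list()
  levels_mat <- matrix(NA_real_, nrow(genome$genes), length(stages),
                       dimnames = list(genome$genes$gene_id, stages))
  for (st in stages) {
    isl <- call_islands(filtered[[st]]$ip, filtered[[st]]$input,
                        genome$chrom_sizes, w = config$w, gap = config$gap,
                        p0 = config$p0, q_max = config$q_max,
                        floor_factor = config$floor_factor)
    stage_islands[[st]] <- isl
    write_islands_bed(isl, file.path(out_dir, paste0("islands_", st, ".bed")))
    ipr <- sapply(filtered[[st]]$ip, promoter_rpkm, windows = windows)
    inr <- sapply(filtered[[st]]$input, promoter_rpkm, windows = windows)
    levels_mat[, st] <- h3k27me3_level(ipr, inr, eps = config$eps)
  }
  data.table::fwrite(
    data.table::data.table(gene_id = rownames(levels_mat), levels_mat),
    file.path(out_dir, "promoter_levels.tsv"), sep = "\t")

  # ---- annotation -----------------------------------------------------
  say("annotating peaks and building promoter gene sets")
  annotated <- lapply(stages, function(st)
    annotate_peaks(stage_islands[[st]], genome, windows))
  names(annotated) <- stages
  all_ann <- do.call(rbind, c(annotated, make.row.names = FALSE))
  feat_dist <- if (nrow(all_ann)) genomic_distribution(all_ann) else NULL
  psets <- promoter_gene_sets(stage_islands, windows)
  data.table::fwrite(all_ann, file.path(out_dir, "annotated_peaks.tsv"),
                     sep = "\t")
  jsonlite::write_json(list(per_stage = lapply(psets$per_stage, length),
                            venn = as.list(psets$venn),
                            union = length(psets$union)),
                       file.path(out_dir, "promoter_sets.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- integration ----------------------------------------------------
  say("integrating expression and promoter-mark changes")
  clusters <- transition_clusters(de_list, levels_mat, delta = config$delta)
  negcorr <- negative_correlation_set(clusters)
  hd <- hdeg_set(negcorr, psets$union, degs = degs$genes,
                 universe = genome$genes$gene_id)
  irec <- clusters
  irec$negcorr <- irec$gene %in% negcorr
  irec$modified <- irec$gene %in% psets$union
  irec$hdeg <- irec$gene %in% hd$hdegs
  data.table::fwrite(irec, file.path(out_dir, "integration.tsv"), sep = "\t")

  # ---- enrichment -----------------------------------------------------
  enr <- NULL
  if (!is.null(config$gmt)) {
    say("enrichment: ORA of HDEGs and GSEA on the first transition")
    sets <- if (is.list(config$gmt)) config$gmt else read_gmt(config$gmt)
    bg <- config$background %||% expressed_genes
    ora <- if (length(hd$hdegs)) ora_test(hd$hdegs, sets, bg) else NULL
    rnk <- stats::setNames(de_list[[1]]$log2fc, de_list[[1]]$gene)
    gs <- lapply(sets, function(s)
      tryCatch(gsea(rnk, s, n_perm = config$n_perm, seed = config$seed),
               error = function(e) NULL))
    enr <- list(ora = ora, gsea = gs)
    if (!is.null(ora))
      data.table::fwrite(ora, file.path(out_dir, "ora.tsv"), sep = "\t")
  }

  # ---- audits (asserted on every run) ---------------------------------
  stopifnot(all(hd$hdegs %in% negcorr),
            all(negcorr %in% degs$genes),
            all(hd$hdegs %in% psets$union))
  nz <- colSums(cm$counts) > 0
  stopifnot(all(abs(colSums(tpm_mat)[nz] - 1e6) < 1e-6 * 1e6))
  for (d in de_list) stopifnot(all(d$padj >= d$p - 1e-12))
  stopifnot(length(stage_max) == length(degs$genes),
            !any(duplicated(names(stage_max))))

  # ---- summary --------------------------------------------------------
  cluster_counts <- vapply(grep("^c[0-9]+$", names(clusters), value = TRUE),
                           function(cc) sum(clusters[[cc]]), integer(1))
  summary <- list(
    stages = stages,
    n_genes = nrow(genome$genes),
    n_expressed = length(expressed_genes),
    peak_counts = vapply(stage_islands, nrow, integer(1)),
    feature_fractions = as.list(feat_dist),
    n_deg = length(degs$genes),
    stage_max_counts = as.list(table(factor(stage_max, levels = stages))),
    cluster_counts = as.list(cluster_counts),
    n_negcorr = length(negcorr),
    n_modified = length(psets$union),
    n_hdeg = hd$n_hdeg,
    n_discordant = hd$n_discordant,
    seed = config$seed)
  recovery <- NULL
  if (!is.null(truth)) {
    tp <- intersect(hd$hdegs, truth$true_hdegs)
    recovery <- list(
      sensitivity = length(tp) / max(1, length(truth$true_hdegs)),
      fdp = length(setdiff(hd$hdegs, truth$true_hdegs)) /
        max(1, length(hd$hdegs)),
      n_true = length(truth$true_hdegs), n_called = length(hd$hdegs),
      domain_recovery = .domain_recovery(truth, stage_islands, stages))
    summary$recovery <- recovery
  }
  cfg_echo <- unclass(config)
  cfg_echo$synthetic <- if (!is.null(config$synthetic))
    unclass(if (inherits(config$synthetic, "synth_config"))
      config$synthetic else scfg)
  yaml::write_yaml(.yaml_safe(cfg_echo), file.path(out_dir, "config.yaml"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %d DEGs, %d negatively correlated, %d modified, %d HDEGs",
      summary$n_deg, summary$n_negcorr, summary$n_modified, summary$n_hdeg)
  structure(list(summary = summary, expr = expr, de = de_list, degs = degs,
                 stage_max = stage_max, flows = flows,
                 stage_islands = stage_islands, annotated = annotated,
                 promoter_sets = psets, levels = levels_mat,
                 clusters = clusters, negcorr = negcorr, hdeg = hd,
                 enrichment = enr, recovery = recovery, truth = truth,
                 genome = genome, counts = cm, windows = windows,
                 filtered = filtered, out_dir = out_dir),
            class = "promark_run")
}

# fraction of planted-domain (domain, active stage) pairs covered >= 80%
# by retained islands
.domain_recovery <- function(truth, stage_islands, stages) {
  dom <- truth$planted_domains
  if (!nrow(dom)) return(NA_real_)
  hits <- 0L; tot <- 0L
  for (s in seq_along(stages)) {
    act <- which(truth$presence[, s] == 1L)
    if (!length(act)) next
    isl <- stage_islands[[stages[s]]]
    gr_i <- GenomicRanges::GRanges(isl$chrom,
                                   IRanges::IRanges(isl$start + 1L, isl$end))
    gr_d <- GenomicRanges::GRanges(dom$chrom[act],
                                   IRanges::IRanges(dom$start[act] + 1L,
                                                    dom$end[act]))
    cov <- GenomicRanges::intersect(gr_i, gr_d)
    ov <- GenomicRanges::findOverlaps(gr_d, cov)
    covered <- tapply(
      IRanges::width(cov)[S4Vectors::subjectHits(ov)],
      factor(S4Vectors::queryHits(ov), levels = seq_along(gr_d)), sum)
    covered[is.na(covered)] <- 0
    hits <- hits + sum(covered / IRanges::width(gr_d) >= 0.8)
    tot <- tot + length(act)
  }
  if (tot == 0L) NA_real_ else hits / tot
}

# drop non-scalar/NULL-unfriendly entries for the YAML echo
.yaml_safe <- function(x) {
  rapply(x, function(v) v, how = "replace",
         classes = c("numeric", "integer", "character", "logical"))
}
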