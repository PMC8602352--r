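#' Write a genome's chromosome sizes and gene models
#'
#' Gene models go to GTF (1-based closed coordinates) with gene, exon and
#' UTR records; chromosome sizes to a two-column TSV.
#'
#' @param genome a `synth_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs_path <- file.path(dir, "chrom.sizes")
  data.table::fwrite(data.table::data.table(chrom = names(genome$chrom_sizes),
                                            size = genome$chrom_sizes),
                     cs_path, sep = "\t", col.names = FALSE)
  gtf_path <- file.path(dir, "genes.gtf")
  g <- genome$genes; f <- genome$features
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", gene_id = g$gene_id)
  strand_f <- g$strand[match(f$gene_id, g$gene_id)]
  gr_feat <- GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start + 1L, f$end), strand = strand_f,
    type = f$type, gene_id = f$gene_id)
  rtracklayer::export(c(gr_gene, gr_feat), gtf_path, format = "gtf")
  invisible(c(cs_path, gtf_path))
}

#' Read gene models from a GTF/GFF file
#'
#' One TSS per gene: when a gene has several transcripts, the longest
#' transcript's span defines the model. Exon and UTR records become the
#' feature table (UTR classes are unreachable for GTFs without UTR records;
#' a notice is logged). Coordinates are converted to 0-based half-open.
#'
#' @param path GTF/GFF path.
#' @param chrom_sizes optional named sizes; inferred from the data extent
#'   otherwise.
#' @return a list compatible with `synth_genome` (chrom_sizes, genes,
#'   features).
#' @export
read_gtf_genes <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$gene_id)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = type, gene_id = gid, stringsAsFactors = FALSE)
  if ("transcript_id" %in% names(md) &&
      any(!is.na(md$transcript_id) & type == "transcript")) {
    tx <- df[type == "transcript", , drop = FALSE]
    tx$tx_id <- as.character(md$transcript_id[type == "transcript"])
    tx$span <- tx$end - tx$start
    tx <- tx[order(tx$gene_id, -tx$span), ]
    keep_tx <- tx$tx_id[!duplicated(tx$gene_id)]
    gdf <- tx[!duplicated(tx$gene_id), , drop = FALSE]
    sub <- df[!is.na(md$transcript_id) &
              as.character(md$transcript_id) %in% keep_tx, , drop = FALSE]
  } else {
    gdf <- df[type == "gene", , drop = FALSE]
    sub <- df
  }
  if (!nrow(gdf)) {  # derive gene extents from exons
    ex <- df[type == "exon", , drop = FALSE]
    sp <- split(ex, ex$gene_id)
    gdf <- do.call(rbind, lapply(sp, function(e)
      data.frame(chrom = e$chrom[1], start = min(e$start), end = max(e$end),
                 strand = e$strand[1], gene_id = e$gene_id[1],
                 stringsAsFactors = FALSE)))
  }
  utr_types <- c("five_prime_utr", "three_prime_utr", "5UTR", "3UTR",
                 "five_prime_UTR", "three_prime_UTR")
  feats <- sub[sub$type %in% c("exon", utr_types), , drop = FALSE]
  feats$type[feats$type %in% utr_types[c(1, 3, 5)]] <- "five_prime_utr"
  feats$type[feats$type %in% utr_types[c(2, 4, 6)]] <- "three_prime_utr"
  if (!any(feats$type != "exon"))
    pm_msg("no UTR records in GTF: UTR feature classes are unreachable")
  exl <- vapply(split(feats[feats$type == "exon", ],
                      feats$gene_id[feats$type == "exon"]),
                function(e) {
                  ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
                  sum(IRanges::width(ir))
                }, numeric(1))
  genes <- data.frame(gene_id = gdf$gene_id, chrom = gdf$chrom,
                      start = gdf$start, end = gdf$end, strand = gdf$strand,
                      tss = ifelse(gdf$strand == "-", gdf$end, gdf$start),
                      tes = ifelse(gdf$strand == "-", gdf$start, gdf$end),
                      exonic_length = ifelse(is.na(exl[gdf$gene_id]),
                                             gdf$end - gdf$start,
                                             exl[gdf$gene_id]),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(chrom_sizes)) {
    mx <- tapply(c(genes$end, feats$end), c(genes$chrom, feats$chrom), max)
    chrom_sizes <- stats::setNames(as.integer(mx + 1e4), names(mx))
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes,
                 features = feats[, c("gene_id", "chrom", "start", "end",
                                      "type")]),
            class = "synth_genome")
}

#' Write a fragment set as 6-column BED
#'
#' BED is 0-based half-open; the name column carries the fragment MAPQ.
#'
#' @param fs a `fragment_set`.
#' @param path output path.
#' @export
write_fragments_bed <- function(fs, path) {
  f <- fs$frags
  data.table::fwrite(data.table::data.table(
    chrom = f$chrom, start = f$start, end = f$end,
    name = if ("mapq" %in% names(f)) f$mapq else ".",
    score = 0L, strand = "."), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a fragment BED file
#'
#' The MAPQ is taken from the name column when it is numeric (the score
#' column otherwise); with neither, all fragments pass the MAPQ filter
#' downstream.
#'
#' @param path BED path.
#' @param stage,rep,channel sample labels.
#' @return a `fragment_set`.
#' @export
read_fragments_bed <- function(path, stage = NA, rep = NA, channel = NA) {
  gr <- rtracklayer::import(path, format = "bed")
  f <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) {
    q <- suppressWarnings(as.integer(as.character(md$name)))
    if (!all(is.na(q))) f$mapq <- q
  }
  if (!"mapq" %in% names(f) && "score" %in% names(md) &&
      !all(is.na(md$score))) f$mapq <- as.integer(md$score)
  fragment_set(f, stage = stage, rep = rep, channel = channel)
}

#' Read a gene-level count TSV
#'
#' First column is the gene id; remaining columns are samples named
#' `<stage>_r<replicate>`.
#'
#' @param path TSV path.
#' @param gene_lengths named exonic lengths (e.g. from [read_gtf_genes()]).
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, gene_lengths) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  stages <- sub("_r[0-9]+$", "", colnames(m))
  count_matrix(m, stages = stages, gene_lengths = gene_lengths)
}

#' Write retained islands as BED6+ with score = -10 log10(q)
#'
#' @param islands retained islands from [call_islands()].
#' @param path output path.
#' @export
write_islands_bed <- function(islands, path) {
  score <- round(pmin(-10 * log10(pmax(islands$q, 1e-300)), 1000))
  data.table::fwrite(data.table::data.table(
    chrom = islands$chrom, start = islands$start, end = islands$end,
    name = sprintf("island_%d", seq_len(nrow(islands))), score = score,
    strand = ".", ip_count = islands$ip_count,
    expected = signif(islands$expected, 6), fold = signif(islands$fold, 6),
    p = islands$p, q = islands$q), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' Values are counts per million fragments per window.
#'
#' @param track a `binned_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$counts), function(cn) {
    v <- track$counts[[cn]]
    nb <- length(v)
    data.table::data.table(
      chrom = cn, start = (seq_len(nb) - 1L) * track$w,
      end = pmin(seq_len(nb) * track$w, track$chrom_sizes[[cn]]),
      value = signif(v / max(track$library_size, 1) * 1e6, 6))
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
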