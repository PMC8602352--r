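#' Strand-resolved promoter windows around the TSS
#'
#' The promoter is [TSS - flank, TSS + flank) clipped to the chromosome.
#'
#' @param genes gene table with gene_id, chrom, tss.
#' @param chrom_sizes named chromosome lengths.
#' @param flank half-width in bp.
#' @return data.frame with gene_id, chrom, start, end (0-based half-open).
#' @export
promoter_windows <- function(genes, chrom_sizes, flank = 5000) {
  if (!all(genes$chrom %in% names(chrom_sizes)))
    stop("gene on unknown chromosome")
  cs <- chrom_sizes[genes$chrom]
  if (any(genes$tss < 0 | genes$tss > cs))
    stop("TSS outside chromosome")
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(pmax(genes$tss - flank, 0)),
             end = as.integer(pmin(genes$tss + flank, cs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate islands with a genomic feature class and the nearest gene
#'
#' The island midpoint is classified with precedence promoter > 5'UTR >
#' 3'UTR > exon > intron > intergenic; the nearest gene minimizes
#' |midpoint - TSS| (ties broken toward the smaller gene id) and the
#' distance is signed in gene orientation (negative = upstream of the TSS).
#'
#' @param islands island data.frame (chrom, start, end).
#' @param genome a `synth_genome` or compatible list with `genes`,
#'   `features`, `chrom_sizes`.
#' @param windows promoter windows from [promoter_windows()].
#' @return the islands with feature, nearest_gene, distance_to_tss added.
#' @export
annotate_peaks <- function(islands, genome, windows) {
  genes <- genome$genes
  if (nrow(islands) && !all(islands$chrom %in% names(genome$chrom_sizes)))
    stop("island on unknown chromosome")
  mid <- (islands$start + islands$end) %/% 2L
  pts <- GenomicRanges::GRanges(islands$chrom,
                                IRanges::IRanges(mid + 1L, mid + 1L))
  in_any <- function(df) {
    if (!nrow(df)) return(rep(FALSE, length(pts)))
    GenomicRanges::countOverlaps(
      pts, GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start + 1L, df$end))) > 0
  }
  feat <- genome$features
  is_prom <- in_any(windows)
  is_utr5 <- in_any(feat[feat$type == "five_prime_utr", , drop = FALSE])
  is_utr3 <- in_any(feat[feat$type == "three_prime_utr", , drop = FALSE])
  is_exon <- in_any(feat[feat$type == "exon", , drop = FALSE])
  is_gene <- in_any(genes)
  feature <- ifelse(is_prom, "promoter",
               ifelse(is_utr5, "5'UTR",
                 ifelse(is_utr3, "3'UTR",
                   ifelse(is_exon, "exon",
                     ifelse(is_gene, "intron", "intergenic")))))
  nearest_gene <- character(nrow(islands))
  dist_tss <- integer(nrow(islands))
  ord <- order(genes$gene_id)
  for (i in seq_len(nrow(islands))) {
    cand <- ord[genes$chrom[ord] == islands$chrom[i]]
    if (!length(cand)) { nearest_gene[i] <- NA; dist_tss[i] <- NA; next }
    d <- abs(mid[i] - genes$tss[cand])
    j <- cand[which.min(d)]  # ties: first in gene-id order
    nearest_gene[i] <- genes$gene_id[j]
    dist_tss[i] <- if (genes$strand[j] == "+") mid[i] - genes$tss[j]
                   else genes$tss[j] - mid[i]
  }
  cbind(islands,
        data.frame(feature = feature, nearest_gene = nearest_gene,
                   distance_to_tss = dist_tss, stringsAsFactors = FALSE))
}

#' Feature-class distribution of annotated peaks
#'
#' @param annotated result of [annotate_peaks()].
#' @return named numeric vector of six fractions summing to 1.
#' @export
genomic_distribution <- function(annotated) {
  if (!nrow(annotated)) stop("empty peak list")
  cls <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "intergenic")
  tab <- table(factor(annotated$feature, levels = cls))
  as.numeric(tab) / sum(tab) -> fr
  stats::setNames(fr, cls)
}

#' Per-stage promoter-modified gene sets with shared/specific decomposition
#'
#' A gene is promoter-modified at a stage if at least one retained island's
#' midpoint lies in its promoter window. Returns the per-stage sets, the
#' 7-cell Venn decomposition over three stages, and the across-stage union
#' (the modified-gene universe used for the HDEG intersection).
#'
#' @param stage_islands named list (stage -> retained island data.frame).
#' @param windows promoter windows from [promoter_windows()].
#' @return list with `per_stage` (list of gene-id vectors), `union`,
#'   `venn` (named counts) and `specific` (per-stage-specific sets).
#' @export
promoter_gene_sets <- function(stage_islands, windows) {
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  per_stage <- lapply(stage_islands, function(isl) {
    if (!nrow(isl)) return(character(0))
    mid <- (isl$start + isl$end) %/% 2L
    pts <- GenomicRanges::GRanges(isl$chrom,
                                  IRanges::IRanges(mid + 1L, mid + 1L))
    ov <- GenomicRanges::findOverlaps(pts, win)
    unique(windows$gene_id[S4Vectors::subjectHits(ov)])
  })
  uni <- unique(unlist(per_stage))
  venn <- NULL; specific <- NULL
  if (length(per_stage) == 3L) {
    st <- names(per_stage)
    if (!length(uni)) {
      venn <- table(character(0))
      specific <- stats::setNames(rep(list(character(0)), 3L), st)
      return(list(per_stage = per_stage, union = character(0),
                  venn = venn, specific = specific))
    }
    inset <- sapply(per_stage, function(s) uni %in% s)
    if (length(uni) == 1L) inset <- matrix(inset, nrow = 1L,
                                           dimnames = list(NULL, st))
    cell <- apply(inset, 1, function(r) paste(st[r], collapse = "&"))
    venn <- table(cell)
    specific <- lapply(seq_along(st), function(i)
      uni[inset[, i] & rowSums(inset) == 1L])
    names(specific) <- st
  }
  list(per_stage = per_stage, union = uni, venn = venn, specific = specific)
}
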