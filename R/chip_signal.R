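#' Filter ChIP fragments by mapping quality and deduplicate
#'
#' Removes malformed intervals (start >= end, count reported), fragments
#' with MAPQ below `mapq_min`, and collapses exact-coordinate duplicates
#' (same chrom, start, end, and strand if present) to a single fragment.
#' If no MAPQ column is present all fragments pass that filter, with a
#' logged notice.
#'
#' @param x a `fragment_set` or a data.frame of fragments.
#' @param mapq_min minimum mapping quality retained (default 20; a MAPQ of
#'   exactly 20 is kept).
#' @return a `fragment_set` with updated `library_size`.
#' @export
filter_fragments <- function(x, mapq_min = 20) {
  fs <- if (inherits(x, "fragment_set")) x else fragment_set(x)
  f <- fs$frags
  bad <- f$start >= f$end
  if (any(bad)) {
    pm_msg("rejected %d malformed fragment(s) with start >= end", sum(bad))
    f <- f[!bad, , drop = FALSE]
  }
  if ("mapq" %in% names(f)) {
    f <- f[f$mapq >= mapq_min, , drop = FALSE]
  } else pm_msg("no MAPQ column: all fragments pass the MAPQ filter")
  key_cols <- intersect(c("chrom", "start", "end", "strand"), names(f))
  f <- f[!duplicated(f[, key_cols, drop = FALSE]), , drop = FALSE]
  rownames(f) <- NULL
  fs$frags <- f
  fs$library_size <- nrow(f)
  fs
}

#' Bin fragment counts on a fixed window grid
#'
#' Each fragment is assigned to exactly one window by its midpoint, so the
#' bin totals conserve the library size.
#'
#' @param fs a `fragment_set`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param w window width in bp.
#' @return a `binned_track` list: `w`, `counts` (per-chromosome integer
#'   vectors; the last window may be short), `library_size`, `chrom_sizes`.
#' @export
bin_counts <- function(fs, chrom_sizes, w = 200) {
  stopifnot(inherits(fs, "fragment_set"))
  f <- fs$frags
  if (nrow(f)) {
    if (!all(f$chrom %in% names(chrom_sizes)))
      stop("fragment on unknown chromosome")
    if (any(f$start < 0) || any(f$end > chrom_sizes[f$chrom]))
      stop("fragment beyond chromosome end")
  }
  counts <- lapply(names(chrom_sizes), function(cn) {
    nb <- as.integer(ceiling(chrom_sizes[[cn]] / w))
    sel <- f$chrom == cn
    if (!any(sel)) return(integer(nb))
    mid <- (f$start[sel] + f$end[sel]) %/% 2L
    tabulate(mid %/% w + 1L, nbins = nb)
  })
  names(counts) <- names(chrom_sizes)
  structure(list(w = w, counts = counts, library_size = nrow(f),
                 chrom_sizes = chrom_sizes, channel = fs$channel),
            class = "binned_track")
}

# pooled fragment midpoints of one or more fragment sets, plus library size
.pooled_midpoints <- function(sets) {
  if (inherits(sets, "fragment_set")) sets <- list(sets)
  parts <- lapply(sets, function(s)
    data.frame(chrom = s$frags$chrom,
               mid = (s$frags$start + s$frags$end) %/% 2L))
  list(mids = do.call(rbind, parts),
       lib = sum(vapply(sets, function(s) s$library_size, numeric(1))))
}

#' Fragment density (RPKM) over promoter windows
#'
#' RPKM_g = n_g / (L_g/1000 * library_size/1e6), where n_g counts fragments
#' whose midpoint lies in gene g's promoter window of length L_g bp.
#'
#' @param fs a (filtered) `fragment_set`.
#' @param windows data.frame from [promoter_windows()] with columns
#'   gene_id, chrom, start, end.
#' @return named numeric vector of RPKM values, one per window.
#' @export
promoter_rpkm <- function(fs, windows) {
  stopifnot(inherits(fs, "fragment_set"))
  if (fs$library_size == 0) stop("library_size is zero")
  mid <- (fs$frags$start + fs$frags$end) %/% 2L
  pts <- GenomicRanges::GRanges(fs$frags$chrom,
                                IRanges::IRanges(mid + 1L, mid + 1L))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  hits <- GenomicRanges::countOverlaps(win, pts)
  len <- windows$end - windows$start
  stats::setNames(hits / (len / 1000 * fs$library_size / 1e6),
                  windows$gene_id)
}

#' Promoter mark level as the replicate-averaged IP/input ratio
#'
#' The level is mean over paired replicates of (ip + eps) / (input + eps)
#' (ratio-then-average); `method = "average_then_ratio"` instead averages
#' the channel RPKMs across replicates before taking one ratio.
#'
#' @param ip_rpkm,input_rpkm numeric vectors or genes-x-replicates matrices
#'   of promoter RPKM; replicates are paired by index.
#' @param eps pseudocount in RPKM units stabilizing empty promoters.
#' @param method "ratio_then_average" (default) or "average_then_ratio".
#' @return numeric vector of positive levels, one per gene.
#' @export
h3k27me3_level <- function(ip_rpkm, input_rpkm, eps = 0.1,
                           method = c("ratio_then_average",
                                      "average_then_ratio")) {
  method <- match.arg(method)
  ip <- as.matrix(ip_rpkm); inp <- as.matrix(input_rpkm)
  if (!all(dim(ip) == dim(inp)))
    stop("IP and input replicate counts differ")
  if (method == "ratio_then_average") rowMeans((ip + eps) / (inp + eps))
  else (rowMeans(ip) + eps) / (rowMeans(inp) + eps)
}

# per-gene per-bin midpoint counts around the TSS, strand-oriented
.tss_bin_counts <- function(mids, genes, flank, profile_bin) {
  nb <- as.integer(2 * flank / profile_bin)
  pts <- GenomicRanges::GRanges(mids$chrom,
                                IRanges::IRanges(mids$mid + 1L, mids$mid + 1L))
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(genes$tss - flank, 0) + 1L,
                                                 genes$tss + flank))
  ov <- GenomicRanges::findOverlaps(pts, win)
  gi <- S4Vectors::subjectHits(ov)
  off <- mids$mid[S4Vectors::queryHits(ov)] - (genes$tss[gi] - flank)
  bin <- off %/% profile_bin
  ok <- bin >= 0 & bin < nb
  m <- matrix(tabulate((gi[ok] - 1L) * nb + bin[ok] + 1L,
                       nbins = nrow(genes) * nb),
              nrow = nrow(genes), ncol = nb, byrow = TRUE)
  neg <- genes$strand == "-"
  m[neg, ] <- m[neg, nb:1, drop = FALSE]
  m
}

#' TSS-anchored mean enrichment profiles stratified by expression class
#'
#' For each expression stratum, the mean over genes of the library-size-
#' normalized log2 IP/input ratio (pseudocount `eps`, RPKM units) in fixed
#' bins across [-flank, +flank] around the strand-oriented TSS (upstream is
#' left for both strands).
#'
#' @param ip_sets,input_sets `fragment_set`s (or lists of replicate sets,
#'   pooled) for one stage.
#' @param genes gene table with chrom, tss, strand, gene_id.
#' @param strata named character vector gene_id -> class label.
#' @param flank half-window around the TSS in bp.
#' @param profile_bin bin width in bp.
#' @param eps RPKM pseudocount.
#' @return list with `profile` (strata x positions matrix of mean log2
#'   ratios), `positions` (bin centers relative to the TSS) and `n_genes`.
#' @export
tss_profile <- function(ip_sets, input_sets, genes, strata, flank = 5000,
                        profile_bin = 100, eps = 0.1) {
  ip <- .pooled_midpoints(ip_sets); inp <- .pooled_midpoints(input_sets)
  genes <- genes[genes$gene_id %in% names(strata), , drop = FALSE]
  m_ip <- .tss_bin_counts(ip$mids, genes, flank, profile_bin)
  m_in <- .tss_bin_counts(inp$mids, genes, flank, profile_bin)
  norm <- function(m, lib) m / (profile_bin / 1000 * lib / 1e6)
  lr <- log2((norm(m_ip, ip$lib) + eps) / (norm(m_in, inp$lib) + eps))
  labs <- strata[genes$gene_id]
  classes <- unique(labs)
  rows <- list(); n_genes <- integer(0)
  for (cl in classes) {
    sel <- labs == cl
    if (!any(sel)) { warning("empty stratum: ", cl); next }
    rows[[cl]] <- colMeans(lr[sel, , drop = FALSE])
    n_genes[cl] <- sum(sel)
  }
  nb <- 2 * flank / profile_bin
  list(profile = do.call(rbind, rows),
       positions = -flank + profile_bin * (seq_len(nb) - 0.5),
       n_genes = n_genes)
}

#' Scaled TSS-to-TES metagene profile
#'
#' Gene bodies are rescaled to `n_body_bins` equal-width bins; flanks use
#' fixed `profile_bin` bp bins. The curve is the mean over genes of the
#' normalized log2 IP/input ratio, oriented so the TSS side is left. Genes
#' shorter than `n_body_bins` bp are skipped (count reported).
#'
#' @inheritParams tss_profile
#' @param n_body_bins number of equal-width bins across the gene body.
#' @return list with `curve` (length 2*flank/profile_bin + n_body_bins),
#'   `segment` (labels upstream/body/downstream per point) and `n_used`.
#' @export
scaled_metagene <- function(ip_sets, input_sets, genes, flank = 2000,
                            profile_bin = 100, n_body_bins = 30, eps = 0.1) {
  ip <- .pooled_midpoints(ip_sets); inp <- .pooled_midpoints(input_sets)
  width <- genes$end - genes$start
  short <- width < n_body_bins
  if (any(short))
    pm_msg("skipped %d gene(s) shorter than %d bp", sum(short), n_body_bins)
  genes <- genes[!short, , drop = FALSE]
  width <- width[!short]
  nf <- as.integer(flank / profile_bin)
  npts <- 2L * nf + n_body_bins
  bin_one <- function(mids, lib) {
    pts <- GenomicRanges::GRanges(mids$chrom,
                                  IRanges::IRanges(mids$mid + 1L, mids$mid + 1L))
    win <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(pmax(genes$start - flank, 0) + 1L,
                                                   genes$end + flank))
    ov <- GenomicRanges::findOverlaps(pts, win)
    gi <- S4Vectors::subjectHits(ov)
    rel <- mids$mid[S4Vectors::queryHits(ov)] - (genes$start[gi] - flank)
    wdt <- width[gi]
    bin <- ifelse(rel < 0, -1L,
            ifelse(rel < flank, rel %/% profile_bin,
             ifelse(rel < flank + wdt,
                    nf + pmin(floor((rel - flank) / wdt * n_body_bins),
                              n_body_bins - 1L),
                    nf + n_body_bins + (rel - flank - wdt) %/% profile_bin)))
    ok <- bin >= 0 & bin < npts
    m <- matrix(tabulate((gi[ok] - 1L) * npts + bin[ok] + 1L,
                         nbins = nrow(genes) * npts),
                nrow = nrow(genes), ncol = npts, byrow = TRUE)
    # per-kb per-million density; body bin width varies per gene
    bw <- cbind(matrix(profile_bin, nrow(genes), nf),
                matrix(rep(width / n_body_bins, n_body_bins), ncol = n_body_bins),
                matrix(profile_bin, nrow(genes), nf))
    dens <- m / (bw / 1000 * lib / 1e6)
    neg <- genes$strand == "-"
    dens[neg, ] <- dens[neg, npts:1, drop = FALSE]
    dens
  }
  d_ip <- bin_one(ip$mids, ip$lib)
  d_in <- bin_one(inp$mids, inp$lib)
  lr <- log2((d_ip + eps) / (d_in + eps))
  list(curve = colMeans(lr),
       segment = rep(c("upstream", "body", "downstream"),
                     c(nf, n_body_bins, nf)),
       n_used = nrow(genes), n_skipped = sum(short))
}
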