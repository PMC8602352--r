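#' Construct a gene-level count matrix
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param stages character vector, one stage label per column.
#' @param gene_lengths named numeric vector of exonic lengths in bp.
#' @return a validated `count_matrix` list.
#' @export
count_matrix <- function(counts, stages, gene_lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(length(stages) == ncol(counts))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0))
    stop("every gene needs a positive length")
  structure(list(counts = counts, stages = stages,
                 gene_lengths = gene_lengths), class = "count_matrix")
}

#' Transcripts per kilobase million
#'
#' Length-normalized rates rescaled so each sample sums to 1e6. An all-zero
#' sample yields an all-zero column with a warning.
#'
#' @param cm a [count_matrix()], or a counts matrix if `gene_lengths` given.
#' @param gene_lengths optional named lengths when `cm` is a bare matrix.
#' @return matrix of TPM values, same dimensions as the counts.
#' @export
tpm <- function(cm, gene_lengths = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts; gene_lengths <- cm$gene_lengths
  } else counts <- cm
  rate <- counts / (gene_lengths[rownames(counts)] / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) warning("all-zero sample(s): ",
                             paste(colnames(counts)[tot == 0], collapse = ", "))
  out <- sweep(rate, 2, ifelse(tot == 0, 1, tot), "/") * 1e6
  out[, tot == 0] <- 0
  out
}

#' Classify genes into expression level classes per stage
#'
#' A gene is expressed if its TPM reaches `expressed_threshold` in at least
#' one sample of any stage; genes never expressed are silent everywhere.
#' Per stage, quartiles of the stage-mean TPM over expressed genes define
#' high (>= upper quartile), low (<= lower quartile) and medium (strictly
#' between) classes.
#'
#' @param tpm_mat TPM matrix (genes x samples).
#' @param stages stage label per column.
#' @param expressed_threshold TPM threshold for the expressed rule.
#' @param quantile_type quantile estimator passed to [stats::quantile()]
#'   (7 = linear interpolation).
#' @return an `expression_table` list: `expressed` (named logical),
#'   `stage_mean` (genes x stages), `levels` (genes x stages character
#'   matrix with values high/medium/low/silent) and the quartiles used.
#' @export
classify_expression <- function(tpm_mat, stages, expressed_threshold = 0.5,
                                quantile_type = 7) {
  u_st <- unique(stages)
  expressed <- apply(tpm_mat >= expressed_threshold, 1, any)
  if (sum(expressed) < 4)
    stop("fewer than 4 expressed genes: quartiles undefined")
  stage_mean <- sapply(u_st, function(s)
    rowMeans(tpm_mat[, stages == s, drop = FALSE]))
  lev <- matrix("silent", nrow(tpm_mat), length(u_st),
                dimnames = list(rownames(tpm_mat), u_st))
  qs <- matrix(NA_real_, 2, length(u_st), dimnames = list(c("Q1", "Q3"), u_st))
  for (s in u_st) {
    m <- stage_mean[expressed, s]
    q <- stats::quantile(m, c(0.25, 0.75), type = quantile_type, names = FALSE)
    qs[, s] <- q
    x <- stage_mean[, s]
    lev[expressed, s] <- ifelse(x[expressed] >= q[2], "high",
                           ifelse(x[expressed] <= q[1], "low", "medium"))
  }
  structure(list(expressed = expressed, stage_mean = stage_mean,
                 levels = lev, quartiles = qs, stages = u_st),
            class = "expression_table")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes (genes with a nonzero
#' count in every sample) of the ratio count / geometric mean across samples.
#'
#' @param counts counts matrix or [count_matrix()].
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  logc <- log(counts)
  ref <- rowSums(is.finite(logc)) == ncol(counts)
  if (!any(ref)) stop("no gene has nonzero counts in all samples")
  logmean <- rowMeans(logc[ref, , drop = FALSE])
  apply(logc[ref, , drop = FALSE], 2,
        function(x) exp(stats::median(x - logmean)))
}

#' Negative-binomial Wald test for differential expression
#'
#' A moderated NB Wald test: counts are normalized by median-of-ratios size
#' factors; per-gene method-of-moments dispersions are shrunk toward a
#' mean-dispersion trend (alpha ~ a0 + a1/mu fitted by regression across
#' genes) with empirical-Bayes weight df_resid / (df_resid + prior_df);
#' the log2 fold change of normalized stage means (pseudocount 0.5) is
#' tested with a Wald z statistic whose variance follows from the NB
#' mean-variance relation, and BH adjustment runs over the tested genes.
#'
#' @param cm a [count_matrix()].
#' @param stageA,stageB earlier and later stage labels; `log2fc` is
#'   later over earlier, so upregulation at the transition is positive.
#' @param genes optional gene universe to test (e.g. expressed genes);
#'   defaults to all genes. Genes with zero counts in every sample of the
#'   matrix are excluded from testing.
#' @param prior_df prior degrees of freedom of the dispersion trend.
#' @param padj_max,lfc_min DEG thresholds (inclusive): padj <= `padj_max`
#'   and |log2fc| >= `lfc_min`.
#' @param sf size factors; computed from the full matrix by default.
#' @return data.frame with gene, meanA, meanB, log2fc, se, stat, p, padj,
#'   is_deg; attribute `transition` records the stage pair.
#' @export
de_test <- function(cm, stageA, stageB, genes = NULL, prior_df = 20,
                    padj_max = 0.05, lfc_min = 1, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  ia <- which(cm$stages == stageA); ib <- which(cm$stages == stageB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 replicates per stage for the dispersion estimate")
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  keep <- rowSums(cm$counts) > 0
  if (!is.null(genes)) keep <- keep & rownames(cm$counts) %in% genes
  nA <- norm[keep, ia, drop = FALSE]; nB <- norm[keep, ib, drop = FALSE]
  mA <- rowMeans(nA); mB <- rowMeans(nB)
  vA <- apply(nA, 1, stats::var); vB <- apply(nB, 1, stats::var)
  a_mom <- pmax(((vA - mA) + (vB - mB)) / pmax(mA^2 + mB^2, 1e-8), 0)
  mu <- (mA + mB) / 2
  ok <- mu > 0
  a_tr <- if (sum(ok) >= 10) {
    fit <- stats::lm(a_mom[ok] ~ I(1 / mu[ok]))
    pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / pmax(mu, 1e-8), 1e-8)
  } else rep(max(mean(a_mom[ok]), 1e-8, na.rm = TRUE), length(mu))
  df_resid <- length(ia) + length(ib) - 2
  w <- df_resid / (df_resid + prior_df)
  a_fin <- pmax(w * a_mom + (1 - w) * a_tr, 1e-8)
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  VA <- (mA / length(ia) + a_fin * mA^2 / length(ia)) /
    ((mA + 0.5)^2 * log(2)^2)
  VB <- (mB / length(ib) + a_fin * mB^2 / length(ib)) /
    ((mB + 0.5)^2 * log(2)^2)
  se <- sqrt(VA + VB)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- bh_adjust(p)
  res <- data.frame(gene = rownames(norm)[keep], meanA = mA, meanB = mB,
                    log2fc = lfc, se = se, stat = stat, p = p, padj = padj,
                    is_deg = padj <= padj_max & abs(lfc) >= lfc_min,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "transition") <- c(stageA, stageB)
  res
}

#' Call the DEG set across successive-stage transitions
#'
#' A gene is a DEG if it passes the (inclusive) padj and fold thresholds in
#' at least one transition; the direction per transition is recorded.
#'
#' @param de_list list of [de_test()] results, one per transition.
#' @return list with `genes` (the DEG set), and `direction` (data.frame of
#'   gene, transition, log2fc, direction "up"/"down").
#' @export
call_degs <- function(de_list) {
  rows <- list()
  for (d in de_list) {
    tr <- paste(attr(d, "transition"), collapse = "->")
    hit <- d[d$is_deg, , drop = FALSE]
    if (nrow(hit))
      rows[[tr]] <- data.frame(gene = hit$gene, transition = tr,
                               log2fc = hit$log2fc,
                               direction = ifelse(hit$log2fc > 0, "up", "down"),
                               stringsAsFactors = FALSE)
  }
  dir <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(gene = character(), transition = character(),
               log2fc = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  list(genes = unique(dir$gene), direction = dir)
}

#' Assign each DEG to its stage of maximal expression
#'
#' Ties break toward the earliest stage. The assignment is a partition of
#' the DEG set.
#'
#' @param expr an [classify_expression()] result.
#' @param degs character vector of DEG ids.
#' @return named character vector: DEG -> stage label.
#' @export
stage_max_assignment <- function(expr, degs) {
  stopifnot(inherits(expr, "expression_table"))
  degs <- intersect(degs, rownames(expr$stage_mean))
  m <- expr$stage_mean[degs, , drop = FALSE]
  stats::setNames(colnames(m)[apply(m, 1, which.max)], degs)
}

#' Level-class flow tables between successive stages
#'
#' For each successive stage pair, a 4x4 matrix counting DEGs moving from
#' each level class (high/medium/low/silent) at the earlier stage to each
#' class at the later stage. Every matrix sums to the DEG count.
#'
#' @param expr an [classify_expression()] result.
#' @param degs character vector of DEG ids.
#' @return named list of 4x4 integer matrices, one per transition.
#' @export
level_transition_table <- function(expr, degs) {
  stopifnot(inherits(expr, "expression_table"))
  degs <- intersect(degs, rownames(expr$levels))
  cls <- c("high", "medium", "low", "silent")
  out <- list()
  st <- expr$stages
  for (i in seq_len(length(st) - 1)) {
    a <- factor(expr$levels[degs, st[i]], levels = cls)
    b <- factor(expr$levels[degs, st[i + 1]], levels = cls)
    out[[paste(st[i], st[i + 1], sep = "->")]] <- table(from = a, to = b)
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' @param dct_treated,dct_control delta-Ct values (target minus reference
#'   gene) for the treated and control conditions.
#' @return fold change 2^-(dct_treated - dct_control).
#' @examples
#' relative_expression(1, 1) # 1
#' relative_expression(2, 1) # 0.5
#' @export
relative_expression <- function(dct_treated, dct_control) {
  stopifnot(all(is.finite(dct_treated)), all(is.finite(dct_control)))
  2^(-(dct_treated - dct_control))
}
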