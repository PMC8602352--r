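#' Fold enrichment of a gene list against a set
#'
#' The proportion of set genes in the list over the proportion of set genes
#' in the background: (k/n) / (K/N).
#'
#' @param k hits in the list, @param n list size, @param K hits in the
#'   background, @param N background size.
#' @return the ratio; 0 when k = 0.
#' @export
fold_enrichment <- function(k, n, K, N) {
  stopifnot(n > 0, N > 0)
  if (K == 0) stop("K = 0: fold enrichment undefined")
  (k / n) / (K / N)
}

#' Read gene sets from a GMT file
#'
#' @param path path to a GMT file.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation test
#'
#' For each set, p = P(X >= k) under the hypergeometric null of drawing the
#' list from the background; q is BH across sets; fold enrichment per
#' [fold_enrichment()]. Set members outside the universe are dropped
#' (empty post-intersection sets skipped with a warning), as are list genes
#' outside the universe (logged).
#'
#' @param gene_list character vector of genes of interest.
#' @param sets named list of gene-id vectors (e.g. [read_gmt()]).
#' @param universe background gene ids.
#' @return data.frame: set, k, n, K, N, fold_enrichment, p, q.
#' @export
ora_test <- function(gene_list, sets, universe) {
  if (!length(gene_list)) stop("empty gene list")
  out_univ <- setdiff(gene_list, universe)
  if (length(out_univ))
    pm_msg("dropped %d list gene(s) outside the universe", length(out_univ))
  gl <- intersect(unique(gene_list), universe)
  if (!length(gl)) stop("no list genes in the universe")
  N <- length(unique(universe)); n <- length(gl)
  rows <- list()
  for (nm in names(sets)) {
    S <- intersect(unique(sets[[nm]]), universe)
    if (!length(S)) { warning("set '", nm, "' empty after intersection"); next }
    K <- length(S); k <- length(intersect(gl, S))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, k = k, n = n, K = K, N = N,
                             fold_enrichment = fold_enrichment(k, n, K, N),
                             p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(),
                      fold_enrichment = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$q <- bh_adjust(res$p)
  res
}

#' Gene-set enrichment analysis by weighted running sum
#'
#' Genes are ranked by score (decreasing); walking down the ranking, hits
#' increment the running sum proportionally to |score|^p (normalized) and
#' misses decrement by 1/(N-K). ES is the deviation of maximal magnitude.
#' The null is built by gene-label permutation (random sets of the same
#' size); NES = ES / mean(|ES_null| of matching sign) and the permutation
#' p-value uses +1 smoothing.
#'
#' @param scores named numeric vector (gene -> ranking score), any order.
#' @param gene_set character vector of set member ids.
#' @param p weight exponent on |score| (1 = weighted, 0 = Kolmogorov).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with es, nes, perm_p, n_hits, and the running-sum `curve`.
#' @export
gsea <- function(scores, gene_set, p = 1, n_perm = 1000, seed = 1) {
  stopifnot(all(is.finite(scores)))
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  hit <- names(sc) %in% gene_set
  K <- sum(hit); N <- length(sc)
  if (K == 0) stop("gene set has no genes in the ranking")
  if (K == N) stop("gene set covers the whole ranking")
  es_stat <- function(hit) {
    wts <- abs(sc)^p
    inc <- ifelse(hit, wts / sum(wts[hit]), -1 / (N - sum(hit)))
    run <- cumsum(inc)
    unname(run[which.max(abs(run))])
  }
  es <- es_stat(hit)
  wts <- abs(sc)^p
  inc <- ifelse(hit, wts / sum(wts[hit]), -1 / (N - K))
  curve <- cumsum(inc)
  null_es <- with_substream(seed, "gsea_perm", {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(N); h[sample.int(N, K)] <- TRUE
      es_stat(h)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  perm_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, perm_p = perm_p, n_hits = K, curve = curve)
}
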