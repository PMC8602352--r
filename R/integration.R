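#' Assign anti-correlated transition clusters
#'
#' For the first transition, cluster 1 holds DEGs upregulated (log2FC >= +1,
#' padj passing) whose promoter mark level decreased, and cluster 2 DEGs
#' downregulated with an increasing mark; clusters 3 and 4 are the analogous
#' pair for the second transition. The mark change is
#' Dlevel = log2(level_later / level_earlier) on the eps-stabilized levels,
#' and must exceed `delta` in magnitude (default 0: sign-only).
#'
#' @param de_list list of [de_test()] results, one per successive transition
#'   (in stage order).
#' @param levels_mat genes x stages matrix of promoter mark levels from
#'   [h3k27me3_level()].
#' @param delta minimum |Dlevel| (log2) for a mark change to count.
#' @return data.frame per gene with logical cluster columns c1..c4 (c3/c4
#'   present only with >= 2 transitions) and the per-transition Dlevel;
#'   DEGs lacking promoter signal are excluded with a logged count.
#' @export
transition_clusters <- function(de_list, levels_mat, delta = 0) {
  n_tr <- length(de_list)
  stopifnot(n_tr >= 1, ncol(levels_mat) >= n_tr + 1)
  genes <- rownames(levels_mat)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  dropped <- 0L
  for (t in seq_len(n_tr)) {
    d <- de_list[[t]]
    miss <- setdiff(d$gene[d$is_deg], genes)
    dropped <- dropped + length(miss)
    dl <- log2(levels_mat[, t + 1] / levels_mat[, t])
    idx <- match(genes, d$gene)
    lfc <- d$log2fc[idx]; deg <- d$is_deg[idx]
    deg[is.na(deg)] <- FALSE; lfc[is.na(lfc)] <- 0
    up <- deg & lfc >= 1 & dl < -delta
    dn <- deg & lfc <= -1 & dl > delta
    out[[paste0("dlevel_t", t)]] <- dl
    out[[paste0("c", 2 * t - 1)]] <- up
    out[[paste0("c", 2 * t)]] <- dn
  }
  if (dropped) pm_msg("%d DEG(s) lacked promoter signal and were excluded",
                      dropped)
  out
}

#' Genes negatively correlated in at least one transition
#'
#' @param clusters result of [transition_clusters()].
#' @return character vector of genes holding at least one cluster label.
#' @export
negative_correlation_set <- function(clusters) {
  cc <- grep("^c[0-9]+$", names(clusters), value = TRUE)
  any_c <- Reduce(`|`, clusters[cc])
  unique(clusters$gene[any_c])
}

#' Intersect the negative-correlation set with promoter-modified genes
#'
#' HDEGs are DEGs whose promoter mark change opposes their expression change
#' in at least one transition AND which carry a significant promoter island
#' in at least one stage. Also reports the discordant class: promoter-
#' modified DEGs outside the negative-correlation set.
#'
#' @param negcorr character vector from [negative_correlation_set()].
#' @param modified across-stage union of promoter-modified genes.
#' @param degs the DEG set (for the discordant class).
#' @param universe optional full gene universe; when given, both inputs
#'   must draw from it (guards against mismatched id spaces). Without it a
#'   heuristic flags two non-empty inputs sharing no ids.
#' @return list with `hdegs`, `discordant` and sizes.
#' @export
hdeg_set <- function(negcorr, modified, degs = NULL, universe = NULL) {
  if (!is.null(universe)) {
    if ((length(negcorr) && !any(negcorr %in% universe)) ||
        (length(modified) && !any(modified %in% universe)))
      stop("gene universes share no ids")
  } else {
    lhs <- union(negcorr, degs)
    if (length(lhs) && length(modified) && !any(modified %in% lhs))
      stop("gene universes share no ids")
  }
  hd <- intersect(negcorr, modified)
  disc <- if (!is.null(degs)) setdiff(intersect(modified, degs), negcorr)
          else character(0)
  list(hdegs = hd, discordant = disc,
       n_hdeg = length(hd), n_discordant = length(disc))
}
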