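#' Window eligibility under the Poisson background
#'
#' A window with count k is eligible iff k >= 1 and the Poisson upper tail
#' P(X >= k | lambda_w) is at most `p0`.
#'
#' @param counts integer vector of per-window IP counts.
#' @param lambda_w expected IP count per window under the background.
#' @param p0 eligibility tail probability threshold.
#' @return logical mask, same length as `counts`.
#' @export
eligible_windows <- function(counts, lambda_w, p0 = 0.2) {
  stopifnot(lambda_w > 0)
  counts >= 1L & stats::ppois(counts - 1L, lambda_w, lower.tail = FALSE) <= p0
}

#' Merge eligible windows into candidate islands
#'
#' Maximal runs of eligible windows allowing at most `gap_windows`
#' consecutive ineligible windows inside; candidates start and end on
#' eligible windows.
#'
#' @param mask logical eligibility mask on the window grid.
#' @param gap_windows maximum internal gap, in windows.
#' @return data.frame with columns `start_win`, `end_win` (0-based,
#'   half-open on the window grid).
#' @export
merge_islands <- function(mask, gap_windows = 3) {
  idx <- which(mask)
  if (!length(idx))
    return(data.frame(start_win = integer(), end_win = integer()))
  brk <- which(diff(idx) > gap_windows + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  data.frame(start_win = starts - 1L, end_win = ends)
}

#' Score candidate islands against the input channel
#'
#' The expectation is the input count in the island rescaled by the IP/input
#' library ratio, floored at `floor_factor` times the island length times the
#' genome-wide IP rate (so empty input never yields a zero expectation).
#' p is the Poisson upper tail P(X >= ip_count | expected); fold is
#' ip_count / expected; q is BH over all candidates.
#'
#' @param cands per-chromosome candidate list as produced inside
#'   [call_islands()]: data.frame with chrom, start_win, end_win.
#' @param ip_track,input_track `binned_track`s for IP and input.
#' @param floor_factor background floor multiplier.
#' @return data.frame of islands (chrom, start, end in bp, ip_count,
#'   input_count, expected, fold, p, q).
#' @export
score_islands <- function(cands, ip_track, input_track, floor_factor = 1) {
  w <- ip_track$w
  genome_len <- sum(ip_track$chrom_sizes)
  ip_rate <- ip_track$library_size / genome_len
  scale <- if (input_track$library_size > 0)
    ip_track$library_size / input_track$library_size else 0
  if (!nrow(cands))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), ip_count = integer(),
                      input_count = integer(), expected = numeric(),
                      fold = numeric(), p = numeric(), q = numeric()))
  ip_n <- integer(nrow(cands)); in_n <- integer(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    sel <- (cands$start_win[i] + 1L):cands$end_win[i]
    ip_n[i] <- sum(ip_track$counts[[cands$chrom[i]]][sel])
    in_n[i] <- sum(input_track$counts[[cands$chrom[i]]][sel])
  }
  start <- cands$start_win * w
  end <- pmin(cands$end_win * w, ip_track$chrom_sizes[cands$chrom])
  len <- end - start
  expected <- pmax(in_n * scale, floor_factor * len * ip_rate)
  p <- stats::ppois(ip_n - 1L, expected, lower.tail = FALSE)
  data.frame(chrom = cands$chrom, start = as.integer(start),
             end = as.integer(end), ip_count = ip_n, input_count = in_n,
             expected = expected, fold = ip_n / expected, p = p,
             q = bh_adjust(p), row.names = NULL, stringsAsFactors = FALSE)
}

#' Call broad enriched islands from IP and input fragments
#'
#' Composition of [bin_counts()], [eligible_windows()], [merge_islands()]
#' and [score_islands()]; retained islands satisfy q <= `q_max` and
#' fold > 1 (strict), sorted by coordinate.
#'
#' @param ip,input filtered `fragment_set`s. Pass a list of replicate sets
#'   to pool them before calling (stage-level calls).
#' @param chrom_sizes named chromosome lengths.
#' @param w window width in bp.
#' @param gap maximum internal gap in windows.
#' @param p0 window eligibility threshold.
#' @param q_max BH q-value threshold for retention.
#' @param floor_factor background floor multiplier for the expectation.
#' @return data.frame of retained islands; the full candidate table is
#'   attached as attribute `candidates`.
#' @export
call_islands <- function(ip, input, chrom_sizes, w = 200, gap = 3,
                         p0 = 0.2, q_max = 0.05, floor_factor = 1) {
  pool <- function(x) {
    if (inherits(x, "fragment_set")) return(x)
    f <- do.call(rbind, lapply(x, function(s) s$frags))
    fragment_set(f, stage = x[[1]]$stage, channel = x[[1]]$channel)
  }
  ip <- pool(ip); input <- pool(input)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), ip_count = integer(),
                      input_count = integer(), expected = numeric(),
                      fold = numeric(), p = numeric(), q = numeric())
  if (ip$library_size == 0) {
    warning("empty IP fragment set: no islands called")
    attr(empty, "candidates") <- empty
    return(empty)
  }
  ip_track <- bin_counts(ip, chrom_sizes, w)
  in_track <- bin_counts(input, chrom_sizes, w)
  lambda_w <- ip_track$library_size * w / sum(chrom_sizes)
  cands <- list()
  for (cn in names(chrom_sizes)) {
    mask <- eligible_windows(ip_track$counts[[cn]], lambda_w, p0)
    cc <- merge_islands(mask, gap)
    if (nrow(cc)) cands[[cn]] <- cbind(chrom = cn, cc)
  }
  cands <- if (length(cands))
    do.call(rbind, c(cands, make.row.names = FALSE)) else
    data.frame(chrom = character(), start_win = integer(),
               end_win = integer())
  scored <- score_islands(cands, ip_track, in_track, floor_factor)
  keep <- scored[scored$q <= q_max & scored$fold > 1, , drop = FALSE]
  keep <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  stopifnot(all(keep$q <= q_max), all(keep$fold > 1))
  attr(keep, "candidates") <- scored
  keep
}
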