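#' Derive a reproducible substream seed from a master seed and a label
#'
#' Every stochastic output of the package draws from its own RNG stream,
#' keyed by a stable string label mixed with the master seed. Adding a new
#' labelled output therefore never perturbs existing ones.
#'
#' @param master integer master seed.
#' @param label character label identifying the stream.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master), length(label) == 1L)
  key <- paste0(format(master, scientific = FALSE), ":", label)
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a labelled RNG substream
#'
#' Saves and restores the global RNG state so callers are unaffected.
#'
#' @param master integer master seed.
#' @param label character stream label.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(master, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(master, label))
  expr
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validated wrapper around the standard step-up procedure: q_i is the
#' minimum over j with p_j >= p_i of m * p_j / rank_j, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.04)) # 0.02, 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

pm_msg <- function(...) message("[promark] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
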