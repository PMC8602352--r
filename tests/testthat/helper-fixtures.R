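# shared fixtures, memoized so expensive runs are computed once per session
.fix_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fix_env)) assign(key, force(expr), envir = .fix_env)
  get(key, envir = .fix_env)
}

# a small but complete synthetic study used by several files
small_cfg <- function(seed = 42, ...) {
  args <- list(n_chroms = 2, chrom_length = 1.2e6, n_genes = 300,
               n_true_hdegs = 20, n_decoys = 20, n_bg_domains = 5,
               seed = seed)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

small_run <- function() fixture("small_run", {
  suppressMessages(run_pipeline(
    run_config(synthetic = list(n_chroms = 2, chrom_length = 1.2e6,
                                n_genes = 300, n_true_hdegs = 20,
                                n_decoys = 20, n_bg_domains = 5),
               seed = 42, write_fragments = FALSE,
               out_dir = file.path(tempdir(), "promark_small_run")),
    quiet = TRUE))
})

# the full-size study conditions (used by the recovery and profile checks)
default_run <- function() fixture("default_run", {
  suppressMessages(run_pipeline(
    run_config(synthetic = list(), seed = 20260929,
               write_fragments = FALSE,
               out_dir = file.path(tempdir(), "promark_default_run")),
    quiet = TRUE))
})

frag_df <- function(chrom, start, end, mapq = NULL) {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  stringsAsFactors = FALSE)
  if (!is.null(mapq)) d$mapq <- mapq
  d
}

mk_cm <- function(counts, stages, lengths = NULL) {
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  count_matrix(counts, stages, stats::setNames(lengths, rownames(counts)))
}

# hand-built two-gene genome for annotation unit tests
toy_genome <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(20000L, 60000L), end = c(30000L, 70000L),
    strand = c("+", "-"),
    tss = c(20000L, 70000L), tes = c(30000L, 60000L),
    exonic_length = c(4000L, 4000L), stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    chrom = "chr1",
    start = c(20000L, 20000L, 28000L, 60000L, 69000L),
    end = c(24000L, 21000L, 30000L, 64000L, 70000L),
    type = c("exon", "five_prime_utr", "three_prime_utr", "exon",
             "five_prime_utr"), stringsAsFactors = FALSE)
  list(chrom_sizes = c(chr1 = 100000L), genes = genes, features = features)
}
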