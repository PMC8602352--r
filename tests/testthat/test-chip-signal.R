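test_that("fragment filtering drops low MAPQ, duplicates and malformed", {
  f <- frag_df("chr1", c(0, 100, 100, 100, 500, 900),
               c(150, 250, 250, 250, 400, 1050),
               mapq = c(19, 20, 20, 20, 60, 30))
  suppressMessages(fs <- filter_fragments(fragment_set(f)))
  # mapq 19 dropped, triplicate collapsed, start >= end rejected
  expect_equal(fs$library_size, 2)
  expect_setequal(fs$frags$start, c(100, 900))
  empty <- suppressMessages(filter_fragments(fragment_set(frag_df(
    character(0), integer(0), integer(0)))))
  expect_equal(empty$library_size, 0)
  nomapq <- fragment_set(frag_df("chr1", 0, 150))
  expect_message(out <- filter_fragments(nomapq), "no MAPQ")
  expect_equal(out$library_size, 1)
})

test_that("binning assigns fragments by midpoint and conserves totals", {
  cs <- c(chr1 = 1000L)
  fs <- fragment_set(frag_df("chr1", c(0, 190), c(150, 340)))
  bt <- bin_counts(fs, cs, w = 200)
  expect_equal(bt$counts$chr1[1], 1)  # midpoint 75
  expect_equal(bt$counts$chr1[2], 1)  # midpoint 265
  expect_equal(sum(unlist(bt$counts)), fs$library_size)
  expect_error(bin_counts(fragment_set(frag_df("chr1", 900, 1050)), cs),
               "beyond chromosome end")
  expect_error(bin_counts(fragment_set(frag_df("chrX", 0, 100)), cs),
               "unknown chromosome")
  set.seed(2)
  big <- fragment_set(frag_df("chr1", s <- sample(0:800, 500, TRUE),
                              s + 150))
  expect_equal(sum(unlist(bin_counts(big, cs)$counts)), 500)
})

test_that("promoter RPKM implements the density formula", {
  win <- data.frame(gene_id = "g1", chrom = "chr1", start = 0, end = 10000,
                    stringsAsFactors = FALSE)
  starts <- seq(0, 9000, length.out = 100)
  fs <- fragment_set(frag_df("chr1", starts, starts + 150))
  fs$library_size <- 1e7
  expect_equal(unname(promoter_rpkm(fs, win)["g1"]), 1.0)
  fs2 <- fs; fs2$library_size <- 2e7
  expect_equal(unname(promoter_rpkm(fs2, win)["g1"]), 0.5)
  none <- data.frame(gene_id = "g2", chrom = "chr1", start = 50000,
                     end = 60000, stringsAsFactors = FALSE)
  expect_equal(unname(promoter_rpkm(fs, none)), 0)
  fs0 <- fragment_set(frag_df(character(0), integer(0), integer(0)))
  expect_error(promoter_rpkm(fs0, win), "library_size")
})

test_that("promoter level is the replicate-averaged stabilized ratio", {
  expect_equal(h3k27me3_level(cbind(c(1)), cbind(c(1))), 1)
  ip <- matrix(c(2, 4), 1, 2); inp <- matrix(c(1, 1), 1, 2)
  lv <- h3k27me3_level(ip, inp, eps = 0)
  expect_equal(unname(lv), 3)
  expect_equal(unname(h3k27me3_level(matrix(0), matrix(0))), 1)
  expect_error(h3k27me3_level(matrix(1, 1, 2), matrix(1, 1, 1)),
               "replicate counts differ")
  avg <- h3k27me3_level(ip, inp, eps = 0, method = "average_then_ratio")
  expect_equal(unname(avg), 3)  # equal inputs: both readings agree here
  inp2 <- matrix(c(1, 3), 1, 2)
  expect_false(
    isTRUE(all.equal(h3k27me3_level(ip, inp2, eps = 0),
                     h3k27me3_level(ip, inp2, eps = 0,
                                    method = "average_then_ratio"))))
})

test_that("TSS profiles are flat at zero for identical channels", {
  g <- generate_genome(small_cfg(seed = 5))
  set.seed(5)
  n <- 5000
  cn <- sample(names(g$chrom_sizes), n, TRUE)
  st <- floor(runif(n, 0, g$chrom_sizes[cn] - 150))
  fs <- fragment_set(frag_df(cn, st, st + 150))
  strata <- stats::setNames(rep("all", nrow(g$genes)), g$genes$gene_id)
  pr <- tss_profile(fs, fs, g$genes, strata)
  expect_true(all(abs(pr$profile) < 1e-12))
  expect_equal(ncol(pr$profile), 100)
  expect_equal(length(pr$positions), 100)
})

test_that("minus-strand genes are profiled in transcription orientation", {
  genes <- data.frame(gene_id = "gm", chrom = "chr1", start = 50000,
                      end = 60000, strand = "-", tss = 60000, tes = 50000,
                      exonic_length = 5000, stringsAsFactors = FALSE)
  # cluster of IP fragments 1 kb genomically downstream (= upstream in gene
  # orientation) of the TSS; uniform input
  ip_starts <- rep(seq(60900, 61090, by = 10), 20)
  ip <- fragment_set(frag_df("chr1", ip_starts, ip_starts + 150))
  in_starts <- seq(0, 99000, by = 50)
  inp <- fragment_set(frag_df("chr1", in_starts, in_starts + 150))
  pr <- tss_profile(ip, inp, genes, c(gm = "all"), flank = 5000,
                    profile_bin = 100)
  peak_pos <- pr$positions[which.max(pr$profile["all", ])]
  expect_lt(abs(peak_pos - (-1000)), 200)
})

test_that("scaled metagene has the declared geometry and null behavior", {
  g <- generate_genome(small_cfg(seed = 6))
  set.seed(6)
  n <- 4000
  cn <- sample(names(g$chrom_sizes), n, TRUE)
  st <- floor(runif(n, 0, g$chrom_sizes[cn] - 150))
  fs <- fragment_set(frag_df(cn, st, st + 150))
  mg <- suppressMessages(scaled_metagene(fs, fs, g$genes, flank = 2000,
                                         profile_bin = 100, n_body_bins = 30))
  expect_length(mg$curve, 2 * 20 + 30)
  expect_true(all(abs(mg$curve) < 1e-12))
  expect_equal(mg$segment[21], "body")
  shorty <- rbind(g$genes,
                  data.frame(gene_id = "tiny", chrom = "chr1", start = 100,
                             end = 120, strand = "+", tss = 100, tes = 120,
                             exonic_length = 20))
  expect_message(mg2 <- scaled_metagene(fs, fs, shorty, n_body_bins = 30),
                 "skipped 1")
  expect_equal(mg2$n_skipped, 1)
})
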