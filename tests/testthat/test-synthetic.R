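test_that("config validation rejects inconsistent studies", {
  expect_error(synth_config(n_true_hdegs = 300, n_decoys = 0, n_genes = 200),
               "exceed")
  expect_error(synth_config(domain_fold = 0.5), "domain_fold")
  expect_error(synth_config(n_genes = -1), "non-negative")
})

test_that("genome generation handles the empty case and packs genes", {
  g0 <- generate_genome(synth_config(n_genes = 0, n_true_hdegs = 0,
                                     n_decoys = 0))
  expect_equal(nrow(g0$genes), 0)
  expect_length(g0$chrom_sizes, 4)
  expect_error(generate_genome(synth_config(n_genes = 500, n_chroms = 1,
                                            chrom_length = 1e5)),
               "infeasible packing")
  g <- generate_genome(small_cfg())
  expect_equal(nrow(g$genes), 300)
  # non-overlapping, fully inside chromosomes, both strands
  for (cn in names(g$chrom_sizes)) {
    gg <- g$genes[g$genes$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start >= 0 & gg$end <= g$chrom_sizes[[cn]]))
    if (nrow(gg) > 1) expect_true(all(utils::head(gg$end, -1) <= gg$start[-1]))
  }
  expect_setequal(unique(g$genes$strand), c("+", "-"))
  expect_true(all(g$genes$exonic_length > 0))
})

test_that("genome generation is deterministic under the seed", {
  a <- generate_genome(small_cfg(seed = 7))
  b <- generate_genome(small_cfg(seed = 7))
  expect_identical(a, b)
  c <- generate_genome(small_cfg(seed = 8))
  expect_false(identical(a$genes, c$genes))
})

test_that("every promoter window on a generated genome is well-formed", {
  cfg <- synth_config(n_genes = 200, n_chroms = 4, seed = 7)
  g <- generate_genome(cfg)
  w <- promoter_windows(g$genes, g$chrom_sizes, flank = 5000)
  expect_true(all(w$start >= 0))
  expect_true(all(w$end <= g$chrom_sizes[w$chrom]))
  expect_true(all(w$start < w$end))
  expect_true(all(w$end - w$start <= 10000))
})

test_that("ChIP generator is deterministic and respects bg_rate = 0", {
  cfg <- small_cfg(seed = 3)
  g <- generate_genome(cfg)
  a <- generate_chip(cfg, g)
  b <- generate_chip(cfg, g)
  expect_identical(a$fragments, b$fragments)
  cfg0 <- small_cfg(seed = 3, bg_rate = 0, n_true_hdegs = 0, n_decoys = 0,
                    coupling = c(silent = 0, low = 0, medium = 0, high = 0))
  g0 <- generate_genome(cfg0)
  ch0 <- generate_chip(cfg0, g0)
  expect_equal(ch0$fragments$d33$ip[[1]]$library_size, 0)
})

test_that("IP enrichment inside planted domains matches domain_fold", {
  cfg <- synth_config(n_chroms = 2, chrom_length = 1e6, n_genes = 60,
                      n_true_hdegs = 10, n_decoys = 0, n_bg_domains = 0,
                      domain_fold = 8, domain_width = 10000, seed = 1,
                      frac_lowmapq = 0, dup_frac = 0,
                      coupling = c(silent = 0, low = 0, medium = 0, high = 0))
  g <- generate_genome(cfg)
  ch <- generate_chip(cfg, g)
  dom <- ch$truth$planted_domains
  act <- dom[ch$truth$presence[, 1] == 1, ]
  ip <- do.call(rbind, lapply(ch$fragments$d33$ip, function(s) s$frags))
  mid <- (ip$start + ip$end) %/% 2
  in_dom <- rep(FALSE, nrow(ip))
  for (i in seq_len(nrow(act)))
    in_dom <- in_dom | (ip$chrom == act$chrom[i] & mid >= act$start[i] &
                        mid < act$end[i])
  L_in <- sum(act$end - act$start)
  L_out <- sum(g$chrom_sizes) - sum(dom$end - dom$start)
  out_dom <- !in_dom
  for (i in seq_len(nrow(dom)))  # exclude all planted intervals from "outside"
    out_dom <- out_dom & !(ip$chrom == dom$chrom[i] & mid >= dom$start[i] &
                           mid < dom$end[i])
  n_in <- sum(in_dom); n_out <- sum(out_dom)
  ratio <- (n_in / L_in) / (n_out / L_out)
  se_log <- sqrt(1 / n_in + 1 / n_out)
  expect_lt(abs(log(ratio / 8)), 3 * se_log)
})

test_that("ground truth anti-couples every true HDEG's domain and sign", {
  tr <- small_run()$truth
  for (g in tr$true_hdegs) {
    d <- tr$planted_degs[tr$planted_degs$gene_id == g, ]
    i <- which(tr$planted_domains$gene_id == g &
               tr$planted_domains$kind == "hdeg")
    flip <- tr$presence[i, d$transition + 1] - tr$presence[i, d$transition]
    expect_equal(unname(sign(flip)), -d$sign)
  }
  # decoys get exactly one of the two changes
  for (j in seq_len(nrow(tr$decoys))) {
    g <- tr$decoys$gene_id[j]
    has_deg <- g %in% tr$planted_degs$gene_id
    has_dom <- g %in% tr$planted_domains$gene_id
    if (tr$decoys$mode[j] == "expression_only")
      expect_true(has_deg && !has_dom)
    else expect_true(has_dom && !has_deg)
  }
})

test_that("count generator plants fold changes and is deterministic", {
  cfg <- small_cfg(seed = 9, reps_rna = 40, nb_dispersion = 0.01)
  g <- generate_genome(cfg)
  tr <- plan_truth(cfg, g)
  cm1 <- generate_counts(cfg, g, tr)
  cm2 <- generate_counts(cfg, g, tr)
  expect_identical(cm1$counts, cm2$counts)
  pd <- tr$planted_degs[1, ]
  st <- unique(cm1$stages)
  mA <- mean(cm1$counts[pd$gene_id, cm1$stages == st[pd$transition]])
  mB <- mean(cm1$counts[pd$gene_id, cm1$stages == st[pd$transition + 1]])
  expect_lt(abs(log2(mB / mA) - pd$log2fc), 0.4)
})

test_that("zero-dispersion counts approach the Poisson limit", {
  cfg <- synth_config(n_chroms = 1, chrom_length = 5e5, n_genes = 30,
                      n_true_hdegs = 0, n_decoys = 0, reps_rna = 200,
                      nb_dispersion = 0, n_bg_domains = 0, seed = 4)
  g <- generate_genome(cfg)
  tr <- plan_truth(cfg, g)
  cm <- generate_counts(cfg, g, tr)
  hi <- names(sort(tr$baseline_mu, decreasing = TRUE))[1]
  x <- cm$counts[hi, cm$stages == "d33"]
  expect_lt(abs(mean(x) / tr$baseline_mu[[hi]] - 1), 0.1)
  expect_lt(abs(var(x) / mean(x) - 1), 0.3)
})
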