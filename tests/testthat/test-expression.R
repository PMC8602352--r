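test_that("TPM normalizes length-corrected rates to one million", {
  m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s1_r1"))
  cm <- mk_cm(m, "s1", lengths = c(1000, 2000))
  tp <- tpm(cm)
  expect_equal(tp[, 1], c(g1 = 2e6 / 3, g2 = 1e6 / 3), tolerance = 1e-9)
  one <- mk_cm(matrix(7, 1, 1, dimnames = list("g1", "s1_r1")), "s1")
  expect_equal(as.numeric(tpm(one)), 1e6)
  z <- mk_cm(matrix(c(0, 5, 0, 0), 2, 2,
                    dimnames = list(c("g1", "g2"), c("a", "b"))), c("A", "B"))
  expect_warning(tz <- tpm(z), "all-zero")
  expect_equal(tz[, "b"], c(g1 = 0, g2 = 0))
  expect_equal(tz["g1", "a"], 0)
  set.seed(1)
  r <- mk_cm(matrix(rpois(60, 20), 10, 6), rep(c("A", "B", "C"), each = 2),
             lengths = sample(500:3000, 10))
  expect_equal(unname(colSums(tpm(r))), rep(1e6, 6), tolerance = 1e-6)
})

test_that("expression classes follow the expressed rule and quartiles", {
  # 8 expressed genes with stage means 1..8 plus one silent gene
  tp <- matrix(c(1:8, 0), ncol = 1,
               dimnames = list(paste0("g", 1:9), "s1_r1"))
  et <- classify_expression(tp, "s1")
  q <- stats::quantile(1:8, c(0.25, 0.75), type = 7)  # 2.75, 6.25
  lv <- et$levels[, "s1"]
  expect_setequal(names(lv[lv == "low"]), paste0("g", which(1:8 <= q[1])))
  expect_setequal(names(lv[lv == "high"]), paste0("g", which(1:8 >= q[2])))
  expect_setequal(names(lv[lv == "medium"]),
                  paste0("g", which(1:8 > q[1] & 1:8 < q[2])))
  expect_equal(unname(lv["g9"]), "silent")
  # exactly-0.5 TPM in a single sample counts as expressed
  tp2 <- matrix(c(0.5, 10, 10, 10, 0,   # sample a
                  0, 10, 10, 10, 0),    # sample b
                5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  et2 <- classify_expression(tp2, c("A", "B"))
  expect_true(et2$expressed["g1"])
  expect_false(et2$expressed["g5"])
  expect_equal(unname(et2$levels["g5", ]), c("silent", "silent"))
  expect_error(classify_expression(tp2[1:3, , drop = FALSE], c("A", "B")),
               "fewer than 4")
})

test_that("per-stage class counts partition the expressed genes", {
  et <- small_run()$expr
  for (s in et$stages) {
    lv <- et$levels[, s]
    expect_equal(sum(lv != "silent"), sum(et$expressed))
    expect_true(all(names(lv[lv == "silent"]) %in%
                    names(et$expressed)[!et$expressed]))
  }
})

test_that("median-of-ratios size factors recover scaling", {
  m <- matrix(rep(c(10, 20, 40, 80), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))
  m2 <- cbind(A = c(10, 20, 40, 80), B = 2 * c(10, 20, 40, 80))
  rownames(m2) <- paste0("g", 1:4)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # genes with a zero are excluded from the reference set
  m3 <- rbind(m2, g5 = c(0, 1e6))
  expect_equal(size_factors(m3), sf)
  m4 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  expect_error(size_factors(m4), "no gene")
})

test_that("the NB Wald test behaves on degenerate and planted genes", {
  m <- matrix(50, 4, 6, dimnames = list(paste0("g", 1:4), NULL))
  m[2, ] <- c(100, 90, 110, 100, 110, 90)
  m[3, ] <- rpois(6, 30)
  m[4, ] <- c(20, 25, 22, 21, 19, 24)
  cm <- mk_cm(m, rep(c("A", "B"), each = 3))
  res <- de_test(cm, "A", "B", sf = rep(1, 6))
  expect_equal(res$log2fc[res$gene == "g1"], 0)
  expect_true(all(res$padj >= res$p - 1e-12))
  expect_error(de_test(mk_cm(m[, 1:3], c("A", "A", "B")), "A", "B"),
               ">= 2 replicates")
  # a strongly planted gene is called, its is_deg consistent with thresholds
  cmp <- fixture("de_planted", {
    cm2 <- simulate_null_counts(800, seed = 11)
    cm2$counts[1:10, 4:6] <- matrix(
      rnbinom(30, mu = 8 * rowMeans(cm2$counts[1:10, 1:3]), size = 20), 10, 3)
    cm2
  })
  r2 <- de_test(cmp, "A", "B")
  expect_true(all(r2$is_deg == (r2$padj <= 0.05 & abs(r2$log2fc) >= 1)))
  expect_true(mean(r2$is_deg[1:10]) >= 0.9)
  expect_lt(mean(r2$is_deg[-(1:10)]), 0.02)
})

test_that("DE estimates agree with an established NB engine", {
  cm <- fixture("de_planted", {
    cm2 <- simulate_null_counts(800, seed = 11)
    cm2$counts[1:10, 4:6] <- matrix(
      rnbinom(30, mu = 8 * rowMeans(cm2$counts[1:10, 1:3]), size = 20), 10, 3)
    cm2
  })
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cm$counts, S4Vectors::DataFrame(cond = factor(cm$stages)), ~cond)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  mine <- de_test(cm, "A", "B")
  common <- intersect(rownames(ref), mine$gene)
  lfc_ref <- ref[common, "log2FoldChange"]
  lfc_my <- mine$log2fc[match(common, mine$gene)]
  expect_gt(cor(lfc_ref, lfc_my), 0.97)
  # strong planted genes are called by both engines
  both <- ref[mine$gene[1:10], "padj"] <= 0.05
  expect_true(all(both, na.rm = TRUE))
})

test_that("DEG calling uses inclusive thresholds and the union rule", {
  mk_de <- function(genes, lfc, padj, tr) {
    d <- data.frame(gene = genes, log2fc = lfc, p = padj / 2, padj = padj,
                    is_deg = padj <= 0.05 & abs(lfc) >= 1,
                    stringsAsFactors = FALSE)
    attr(d, "transition") <- tr
    d
  }
  d1 <- mk_de(c("g1", "g2", "g3"), c(1, 0.9, -2), c(0.05, 0.04, 0.01),
              c("d33", "d65"))
  d2 <- mk_de(c("g1", "g2", "g3"), c(0, 0, 2), c(0.9, 0.9, 0.001),
              c("d65", "d90"))
  out <- call_degs(list(d1, d2))
  expect_setequal(out$genes, c("g1", "g3"))  # g2 fails the fold rule
  expect_equal(out$direction$direction[out$direction$gene == "g1"], "up")
  dirs <- out$direction[out$direction$gene == "g3", ]
  expect_setequal(dirs$direction, c("down", "up"))
})

test_that("stage-maximal assignment partitions DEGs, ties to earliest", {
  sm <- matrix(c(10, 2, 2, 2, 2, 10, 5, 5, 1), 3, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("d33", "d65", "d90")))
  et <- structure(list(stage_mean = sm, stages = colnames(sm),
                       levels = NULL, expressed = NULL),
                  class = "expression_table")
  a <- stage_max_assignment(et, c("g1", "g2", "g3"))
  expect_equal(unname(a[c("g1", "g2", "g3")]), c("d33", "d90", "d33"))
  run <- small_run()
  asg <- run$stage_max
  expect_length(asg, length(run$degs$genes))
  expect_setequal(names(asg), run$degs$genes)
})

test_that("level transition tables conserve the DEG count", {
  run <- small_run()
  for (tab in run$flows) expect_equal(sum(tab), length(run$degs$genes))
  lv <- matrix("high", 3, 2, dimnames = list(paste0("g", 1:3), c("A", "B")))
  et <- structure(list(levels = lv, stages = c("A", "B")),
                  class = "expression_table")
  tab <- level_transition_table(et, paste0("g", 1:3))[[1]]
  expect_equal(unname(tab["high", "high"]), 3)
  expect_equal(sum(tab) - tab["high", "high"], 0)
})

test_that("2^-ddCt fold changes", {
  expect_equal(relative_expression(1, 1), 1)
  expect_equal(relative_expression(2, 1), 0.5)
  expect_equal(relative_expression(-1, 1), 4)
  expect_error(relative_expression(NA, 1))
})
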