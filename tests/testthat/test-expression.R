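mk_expr <- function(counts, lengths, tissues) {
  samples <- data.frame(sample_id = colnames(counts),
                        tissue = tissues,
                        replicate = stats::ave(seq_along(tissues), tissues,
                                               FUN = seq_along))
  expression_matrix(counts, lengths, samples)
}

test_that("TPM normalizes length-corrected rates to one million per sample", {
  counts <- matrix(c(30, 10), 2, 1,
                   dimnames = list(c("gA", "gB"), "s1"))
  e <- mk_expr(counts, c(gA = 3000, gB = 1000), "t1")
  tp <- tpm(e)
  expect_equal(unname(tp$values[, 1]), c(500000, 500000))

  single <- matrix(c(7, 0), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  tp1 <- tpm(mk_expr(single, c(gA = 500, gB = 1000), "t1"))
  expect_equal(unname(tp1$values["gA", 1]), 1e6)

  # 3-gene hand computation
  counts3 <- matrix(c(10, 20, 30), 3, 1,
                    dimnames = list(c("a", "b", "c"), "s1"))
  lens <- c(a = 1000, b = 2000, c = 500)
  rates <- c(10 / 1000, 20 / 2000, 30 / 500)
  tp3 <- tpm(mk_expr(counts3, lens, "t1"))
  expect_equal(unname(tp3$values[, 1]), 1e6 * rates / sum(rates))
})

test_that("TPM columns sum to 1e6 and all-zero samples are flagged", {
  set.seed(1)
  counts <- matrix(rpois(50 * 6, 40), 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:6)))
  counts[, 6] <- 0L
  e <- mk_expr(counts, stats::setNames(sample(500:3000, 50),
                                       rownames(counts)),
               rep(c("t1", "t2"), each = 3))
  expect_warning(tp <- tpm(e), "all-zero")
  expect_equal(unname(colSums(tp$values[, 1:5])), rep(1e6, 5),
               tolerance = 1e-6)
  expect_true(all(tp$values[, 6] == 0))
  expect_identical(tp$zero_samples, "s6")
})

test_that("cross-species expression ratios average replicates first", {
  mk_sp <- function(vals) {
    counts <- matrix(vals, 2, 2,
                     dimnames = list(c("gX", "gY"), c("m:1", "m:2")))
    tpm(mk_expr(counts, c(gX = 1000, gY = 1000), c("m", "m")))
  }
  # equal lengths: TPM split by relative counts
  tpms <- list(foc = mk_sp(c(300, 100, 300, 100)),   # gX TPM 750000
               c1 = mk_sp(c(100, 100, 100, 100)),    # gX TPM 500000
               c2 = mk_sp(c(50, 150, 50, 150)))      # gX TPM 250000
  gm <- data.frame(group_id = rep(c("og1", "og2"), each = 3),
                   species = rep(c("foc", "c1", "c2"), 2),
                   gene_id = rep(c("gX", "gY"), each = 3))
  r <- expression_ratio(tpms, gm, "foc", c("c1", "c2"), "m")
  expect_equal(r$ratio[r$group_id == "og1"], 750000 / 375000)
  expect_equal(r$ratio[r$group_id == "og2"], 250000 / 625000)
  expect_error(expression_ratio(tpms, gm, "foc", c("c1", "c2"), "liver"),
               "missing")
})

test_that("cumulative family TPM sums member means and partitions totals", {
  counts <- matrix(c(10, 20, 30, 40,
                     20, 30, 40, 50), 4, 2,
                   dimnames = list(c("a", "b", "c", "d"), c("m:1", "m:2")))
  tp <- tpm(mk_expr(counts, c(a = 1000, b = 1000, c = 1000, d = 1000),
                    c("m", "m")))
  fams <- list(f1 = c("a", "b"), f2 = c("c", "d"))
  cf <- cumulative_family_tpm(tp, fams, "m")
  means <- rowMeans(tp$values)
  expect_equal(cf[["f1"]], sum(means[c("a", "b")]))
  # disjoint families covering all genes partition the total
  expect_equal(sum(cf), sum(means))
  # single-gene family equals that gene's mean
  expect_equal(cumulative_family_tpm(tp, list(one = "a"), "m")[["one"]],
               means[["a"]])
  expect_warning(cf0 <- cumulative_family_tpm(tp, list(gone = "zz"), "m"),
                 "no gene")
  expect_equal(cf0[["gone"]], 0)
})

test_that("tissue-specific calls require fold change and minimum expression", {
  counts <- matrix(c(100, 50, 0,
                     100, 50, 0,
                     1, 50, 80,
                     1, 50, 80), 3, 4,
                   dimnames = list(c("mantle_only", "uniform", "gill_high"),
                                   c("m:1", "m:2", "g:1", "g:2")))
  tp <- tpm(mk_expr(counts, c(mantle_only = 1000, uniform = 1000,
                              gill_high = 1000),
                    c("m", "m", "g", "g")))
  hits <- tissue_specific_genes(tp, "m", fold = 2, min_tpm = 1)
  expect_true("mantle_only" %in% hits)
  expect_false("uniform" %in% hits)
  expect_false("gill_high" %in% hits)
  expect_error(tissue_specific_genes(tp, "liver"), "unknown tissue")
})

test_that("adjacency is |r|^beta on log2(TPM + 1) with zero diagonal", {
  # build deterministic TPM profiles via a fake TPMMatrix
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = 2 * (c(1, 2, 3, 4, 5, 6) + 1) - 1,  # log2(g2+1) linear in log2(g1+1)
                g3 = c(2, 1, 4, 3, 6, 5),
                g4 = c(5, 5, 5, 5, 5, 5))             # zero variance
  tp <- structure(list(values = vals,
                       samples = data.frame(sample_id = sprintf("s%d", 1:6),
                                            tissue = "t", replicate = 1:6)),
                  class = "TPMMatrix")
  expect_message(a <- coexpression_network(tp, beta = 6), "zero-variance")
  expect_identical(rownames(a), c("g1", "g2", "g3"))
  expect_true(all(diag(a) == 0))
  x <- log2(vals[1:3, ] + 1)
  r <- stats::cor(t(x))
  expect_equal(a["g1", "g3"], abs(r["g1", "g3"])^6, tolerance = 1e-12)
  expect_equal(a["g1", "g2"], 1, tolerance = 1e-10)
  expect_error(coexpression_network(structure(
    list(values = vals[, 1:3], samples = tp$samples[1:3, ]),
    class = "TPMMatrix")), "4 samples")
})

test_that("uncorrelated profiles give zero adjacency", {
  vals <- rbind(g1 = c(1, -1, 1, -1) + 10,
                g2 = c(1, 1, -1, -1) + 10)
  # log2 transform breaks exact orthogonality; test the formula directly
  tp <- structure(list(values = 2^vals - 1,
                       samples = data.frame(sample_id = sprintf("s%d", 1:4),
                                            tissue = "t", replicate = 1:4)),
                  class = "TPMMatrix")
  a <- coexpression_network(tp, beta = 6)
  expect_equal(a["g1", "g2"], 0, tolerance = 1e-12)
})

test_that("module detection separates perfect blocks and pools small clusters", {
  genes <- sprintf("g%02d", 1:12)
  a <- matrix(0, 12, 12, dimnames = list(genes, genes))
  a[1:6, 1:6] <- 1; a[7:12, 7:12] <- 1
  diag(a) <- 0
  mods <- detect_modules(a, cut_height = 0.5, min_size = 3)
  expect_identical(length(mods), 2L)
  expect_identical(sort(unlist(lapply(mods, `[[`, "genes"))), genes)
  expect_identical(mods[[1]]$genes, genes[1:6])

  none <- matrix(0, 12, 12, dimnames = list(genes, genes))
  mods0 <- detect_modules(none, cut_height = 0.5, min_size = 3)
  expect_identical(length(mods0), 1L)
  expect_identical(mods0[[1]]$module_id, "module_0")

  # gene-order permutation invariance
  set.seed(9)
  perm <- sample(12)
  mods_p <- detect_modules(a[perm, perm], cut_height = 0.5, min_size = 3)
  expect_identical(lapply(mods, `[[`, "genes"),
                   lapply(mods_p, `[[`, "genes"))
})

test_that("intramodular connectivity sums within-module adjacencies", {
  genes <- c("a", "b", "c", "d")
  adj <- matrix(1, 4, 4, dimnames = list(genes, genes))
  adj["d", ] <- 0; adj[, "d"] <- 0
  diag(adj) <- 0
  mod <- structure(list(module_id = "module_1", genes = genes),
                   class = "CoexpressionModule")
  kw <- intramodular_connectivity(adj, mod)
  expect_equal(unname(kw[c("a", "b", "c")]), rep(2, 3))
  expect_equal(kw[["d"]], 0)  # isolated gene
  expect_error(intramodular_connectivity(adj[1:3, 1:3], mod), "absent")
})

test_that("hub ranking is deterministic with id tie-breaks and capped size", {
  kw <- c(z = 5, a = 5, m = 7, q = 1)
  expect_identical(top_hubs(kw, 3), c("m", "a", "z"))
  expect_identical(top_hubs(kw, 40), c("m", "a", "z"))  # min(40, n-1) = 3
  expect_identical(top_hubs(c(only = 1), 40), character())
})

test_that("module gene-set enrichment delegates to the hypergeometric test", {
  bg <- sprintf("g%02d", 1:20)
  mod <- structure(list(module_id = "module_1", genes = bg[1:5]),
                   class = "CoexpressionModule")
  res <- module_gene_set_enrichment(mod, c(bg[1:3], bg[10:11]), bg)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  # disjoint set: p = 1 (whole support)
  res0 <- module_gene_set_enrichment(mod, bg[6:10], bg)
  expect_equal(res0$p_value, 1)
})
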