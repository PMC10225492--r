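test_that("genome generation hits the requested genic fraction exactly", {
  gs <- gen_genome_set(2, c(1e5, 2e5), c(0.3, 0.55), 50, seed = 3)
  for (i in 1:2) {
    p <- partition(gs$annotations[[i]])
    target <- round(c(0.3, 0.55)[i] * c(1e5, 2e5)[i])
    expect_equal(p$genic_size, target)
    # non-overlapping by construction: union equals sum of lengths
    g <- gs$annotations[[i]]$genes
    expect_equal(sum(g$end - g$start + 1), target)
  }
  # single forced gene
  one <- gen_genome_set(1, 1000, 0.4, 1, seed = 1)$annotations[[1]]
  expect_equal(one$genes$end - one$genes$start + 1, 400)
  expect_error(gen_genome_set(1, 100, 0.05, 10, seed = 1), "infeasible")
})

test_that("generators are deterministic given a seed and leave the RNG alone", {
  d1 <- tempfile(); d2 <- tempfile(); dir.create(d1); dir.create(d2)
  set.seed(99); before <- runif(1)
  g1 <- gen_genome_set(2, 5e4, 0.4, 20, seed = 5, dir = d1)
  set.seed(99)
  g2 <- gen_genome_set(2, 5e4, 0.4, 20, seed = 5, dir = d2)
  expect_identical(g1$annotations, g2$annotations)
  expect_identical(md5(file.path(d1, "sp01.gff3")),
                   md5(file.path(d2, "sp01.gff3")))
  set.seed(99); expect_identical(runif(1), before)

  t1 <- gen_te_copies(c(5, 20), 30, 500, 0.002, seed = 5)
  t2 <- gen_te_copies(c(5, 20), 30, 500, 0.002, seed = 5)
  expect_identical(t1$records$divergence_d, t2$records$divergence_d)

  o1 <- gen_ortholog_table(50, c("a", "b", "c"), "a", 10, 0.3, 0.1, seed = 5)
  o2 <- gen_ortholog_table(50, c("a", "b", "c"), "a", 10, 0.3, 0.1, seed = 5)
  expect_identical(o1$table, o2$table)

  m1 <- gen_domain_counts(20, c("a", "b", "c"), "a", seed = 5)
  m2 <- gen_domain_counts(20, c("a", "b", "c"), "a", seed = 5)
  expect_identical(m1$matrix$counts, m2$matrix$counts)

  e1 <- gen_expression(60, c(t1 = 2, t2 = 2), data.frame(size = 20, cor = 0.5),
                       seed = 5)
  e2 <- gen_expression(60, c(t1 = 2, t2 = 2), data.frame(size = 20, cor = 0.5),
                       seed = 5)
  expect_identical(e1$expr$counts, e2$expr$counts)

  p1 <- gen_pathways(5, sprintf("g%03d", 1:100), 0.5,
                     sprintf("g%03d", 1:20), seed = 5)
  p2 <- gen_pathways(5, sprintf("g%03d", 1:100), 0.5,
                     sprintf("g%03d", 1:20), seed = 5)
  expect_identical(p1$pathways, p2$pathways)
})

test_that("TE copy divergence follows the Jukes-Cantor expectation", {
  # age 0: no substitutions at all
  t0 <- gen_te_copies(0, 50, 1000, 0.002, seed = 2)
  expect_true(all(t0$records$divergence_d == 0))
  # closed-form mean mismatch proportion at K = 2rT
  tc <- gen_te_copies(50, 5000, 2000, 0.002, seed = 2)
  p <- 0.75 * (1 - exp(-8 * 0.002 * 50 / 3))
  expect_equal(p, 0.1755537, tolerance = 1e-6)
  se <- sqrt(p * (1 - p) / (2000 * 5000))
  expect_lt(abs(mean(tc$records$divergence_d) - p), 3 * se + 0.01 * p)
  # truth maps every copy
  expect_identical(sort(names(tc$truth$te_true_ages)),
                   sort(tc$records$copy_id))
  expect_error(gen_te_copies(1e6, 10, 100, 0.002, seed = 1), "saturation")
})

test_that("planted ortholog reductions shorten only the focal species", {
  sp <- c("foc", "c1", "c2")
  ot <- gen_ortholog_table(100, sp, "foc", 20, effect = 0.3, noise_sd = 0,
                           seed = 6)
  tab <- ot$table
  planted <- ot$truth$planted_reduced_groups
  expect_identical(length(planted), 20L)
  for (g in planted[1:5]) {
    foc_len <- tab$length[tab$group_id == g & tab$species == "foc"]
    base <- tab$length[tab$group_id == g & tab$species == "c1"]
    expect_equal(foc_len / base, 0.7, tolerance = 2 / base)
  }
  # non-planted groups identical across species at zero noise
  null_g <- setdiff(unique(tab$group_id), planted)[1]
  expect_identical(length(unique(tab$length[tab$group_id == null_g])), 1L)
  # n_reduced = 0 leaves the truth empty
  ot0 <- gen_ortholog_table(10, sp, "foc", 0, 0.3, 0, seed = 1)
  expect_identical(length(ot0$truth$planted_reduced_groups), 0L)
})

test_that("planted domain folds shift the focal mean as requested", {
  sp <- sprintf("s%d", 1:4)
  dc <- gen_domain_counts(300, sp, "s1",
                          planted = stats::setNames(rep(0.2, 100),
                                                    sprintf("dom%03d", 1:100)),
                          baseline_mean = 100, seed = 3)
  planted <- names(dc$truth$planted_shifted_domains)
  focal_mean <- mean(dc$matrix$counts["s1", planted])
  other_mean <- mean(dc$matrix$counts["s2", planted])
  expect_lt(abs(focal_mean - 20), 5)
  expect_lt(abs(other_mean - 100), 10)
  expect_identical(unname(dc$truth$planted_shifted_domains[1]), "contracted")
  d0 <- gen_domain_counts(5, sp, "s1", seed = 1)
  expect_identical(length(d0$truth$planted_shifted_domains), 0L)
})

test_that("near-unit within-correlation without count noise gives near-unit correlations", {
  ge <- gen_expression(40, c(t1 = 3, t2 = 3, t3 = 3, t4 = 3),
                       data.frame(size = 20, cor = 0.999),
                       hub_per_module = 0, seed = 4, poisson = FALSE)
  mod_genes <- names(ge$truth$module_assignment)
  x <- log2(ge$expr$counts[mod_genes, ] + 1)
  r <- stats::cor(t(x))
  expect_gt(min(r[upper.tri(r)]), 0.99)
})

test_that("planted pathway overlap limits behave as specified", {
  genes <- sprintf("g%03d", 1:200)
  target <- genes[1:40]
  full <- gen_pathways(3, genes, 1.0, target, seed = 2)
  expect_identical(full$pathways[[full$truth$enriched_pathway]],
                   sort(target))
  none <- gen_pathways(3, genes, 0.0, target, seed = 2)
  expect_identical(
    length(intersect(none$pathways[[none$truth$enriched_pathway]], target)),
    0L)
})

test_that("every generated file round-trips through the module readers", {
  dir <- tempfile(); dir.create(dir)
  gs <- gen_genome_set(1, 5e4, 0.35, 30, seed = 8, dir = dir)
  ann <- read_annotation(file.path(dir, "sp01.gff3"),
                         file.path(dir, "sp01.seqlen.tsv"), species = "sp01")
  expect_identical(ann$genes$start, as.integer(gs$annotations[[1]]$genes$start))
  expect_identical(ann$genes$gene_id, gs$annotations[[1]]$genes$gene_id)
  expect_equal(ann$seq_lengths, gs$annotations[[1]]$seq_lengths)

  tc <- gen_te_copies(c(10, 50), 25, 800, 0.002, seed = 8, dir = dir)
  rec <- read_repeatmasker_out(tc$out_path)
  expect_identical(rec$copy_id, tc$records$copy_id)
  expect_identical(rec$te_class, tc$records$te_class)
  expect_equal(rec$divergence_d, tc$records$divergence_d, tolerance = 1e-6)

  ot <- gen_ortholog_table(30, c("a", "b"), "a", 5, 0.3, 0.1, seed = 8,
                           dir = dir)
  back <- read_ortholog_table(ot$path)
  expect_equal(as.data.frame(back), as.data.frame(ot$table))

  dc <- gen_domain_counts(15, c("a", "b", "c"), "a",
                          planted = c(dom001 = 0.2), seed = 8, dir = dir)
  dback <- read_domain_counts(dc$path)
  expect_identical(dback$counts, dc$matrix$counts)
  expect_identical(dback$totals, dc$matrix$totals)

  ge <- gen_expression(30, c(t1 = 2, t2 = 2), data.frame(size = 10, cor = 0.5),
                       seed = 8, dir = dir)
  eback <- read_expression(ge$path)
  expect_identical(eback$counts, ge$expr$counts)
  expect_equal(eback$gene_lengths, ge$expr$gene_lengths)
  expect_identical(eback$samples$tissue, ge$expr$samples$tissue)

  pw <- gen_pathways(4, sprintf("g%03d", 1:50), 0.5, sprintf("g%03d", 1:10),
                     seed = 8, dir = dir)
  pback <- read_gmt(pw$path)
  expect_identical(lapply(pback, as.character),
                   lapply(pw$pathways, as.character))
})
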