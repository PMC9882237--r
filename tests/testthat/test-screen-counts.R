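# Count ingestion, filtering, normalization, fold changes, and the
# non-targeting empirical null.

test_that("a toy count table round-trips through read and write bit-identically", {
  cm <- toy_count_matrix(n_genes = 1, guides_per_gene = 3, n_nt = 0)
  cm$counts[] <- matrix(c(5, 10, 15, 20, 25, 30, 1, 2, 3, 4, 6, 8,
                          9, 7, 11, 13, 17, 19), nrow = 3, byrow = TRUE)[, 1:6]
  d <- withr::local_tempdir()
  f1 <- file.path(d, "counts.tsv"); s1 <- file.path(d, "samples.csv")
  write_counts(cm, f1, s1)
  cm2 <- read_counts(f1, s1)
  f2 <- file.path(d, "counts2.tsv")
  write_counts(cm2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(cm2$counts, cm$counts)
})

test_that("a negative count is rejected naming the offending cell", {
  cm <- toy_count_matrix(n_genes = 2, n_nt = 0)
  counts <- cm$counts
  counts["G002_sg1", "untreated_2"] <- -3
  expect_error(count_matrix(counts, cm$guides, cm$samples),
               "G002_sg1.*untreated_2")
})

test_that("a sample sheet without T0 warns but still builds the object", {
  expect_warning(
    cm <- toy_count_matrix(conditions = c("untreated", "treated")),
    "no 'T0' samples"
  )
  expect_s3_class(cm, "count_matrix")
})

test_that("duplicate sgRNA ids are rejected", {
  cm <- toy_count_matrix(n_genes = 2, n_nt = 0)
  guides <- cm$guides
  guides$sgrna_id[2] <- guides$sgrna_id[1]
  expect_error(count_matrix(cm$counts, guides, cm$samples), "duplicate sgRNA")
})

test_that("bottom-5% trimming removes exactly the lowest guides, ties lexicographic", {
  cm <- toy_count_matrix(n_genes = 20, guides_per_gene = 2, n_nt = 60, base = 100)
  # 100 guides total; make 4 clearly lowest and 2 tied at the 5th-from-bottom count
  low <- c("G001_sg1", "G002_sg1", "G003_sg1", "G004_sg1")
  cm$counts[low, ] <- 1
  cm$counts[c("NT_010", "NT_009"), ] <- 3  # tied; NT_009 sorts first
  filtered <- filter_guides(cm, bottom_frac = 0.05)
  removed <- attr(filtered, "removal_log")$sgrna_id
  expect_length(removed, 5)
  expect_setequal(removed, c(low, "NT_009"))
  expect_true("NT_010" %in% filtered$guides$sgrna_id)
})

test_that("miRNA guides are removed and their absence makes the step a no-op", {
  cm <- toy_count_matrix(n_genes = 20, guides_per_gene = 2, n_nt = 60,
                         mirna_genes = "G010")
  filtered <- filter_guides(cm)
  expect_false(any(filtered$guides$gene == "G010"))
  cm0 <- toy_count_matrix(n_genes = 20, guides_per_gene = 2, n_nt = 60)
  log0 <- attr(filter_guides(cm0), "removal_log")
  expect_false(any(log0$reason == "miRNA"))
})

test_that("a bottleneck (whole genes lost) aborts filtering", {
  cm <- toy_count_matrix(n_genes = 10, guides_per_gene = 1, n_nt = 10)
  cm$counts[sprintf("G%03d_sg1", 1:3), ] <- 0  # 30% of genes in the bottom
  expect_error(filter_guides(cm, bottom_frac = 0.15), "bottleneck")
})

test_that("non-targeting-anchored size factors equalize scaled samples", {
  cm <- suppressWarnings(
    toy_count_matrix(n_genes = 5, n_nt = 60,
                     conditions = c("untreated", "treated"), n_replicates = 1)
  )
  set.seed(42)
  cm$counts[, 1] <- rpois(nrow(cm$counts), 200) + 1
  cm$counts[, 2] <- 2 * cm$counts[, 1]
  norm <- normalize_depth(cm, min_nontargeting = 50)
  expect_equal(unname(norm$size_factors[2] / norm$size_factors[1]), 2)
  expect_equal(norm$counts[, 1], norm$counts[, 2])
})

test_that("identical samples get unit size factors and normalization is idempotent", {
  cm <- toy_count_matrix(base = 150)
  norm <- normalize_depth(cm, min_nontargeting = 50)
  expect_equal(unname(norm$size_factors), rep(1, ncol(cm$counts)))
  renorm <- normalize_depth(norm, min_nontargeting = 50)
  expect_equal(unname(renorm$size_factors), rep(1, ncol(cm$counts)))
})

test_that("perturbing a targeting gene leaves non-targeting size factors unchanged", {
  cm <- toy_count_matrix(n_genes = 5, n_nt = 60, base = 100)
  sf0 <- normalize_depth(cm, min_nontargeting = 50)$size_factors
  cm$counts[cm$guides$gene == "G001", 1] <- 900
  sf1 <- normalize_depth(cm, min_nontargeting = 50)$size_factors
  expect_equal(sf1, sf0)
})

test_that("guide-level L2FC matches direct evaluation", {
  cm <- toy_count_matrix(n_genes = 1, guides_per_gene = 3, n_nt = 60)
  cm$counts["G001_sg1", cm$samples$condition == "treated"] <- 400
  cm$counts["G001_sg1", cm$samples$condition == "untreated"] <- 100
  cm$counts["G001_sg2", ] <- 100
  cm$counts["G001_sg3", cm$samples$condition == "treated"] <- 0
  cm$counts["G001_sg3", cm$samples$condition == "untreated"] <- 100
  l2fc <- compute_l2fc(cm, c("treated", "untreated"), pseudocount = 0)
  expect_equal(l2fc$l2fc[l2fc$sgrna_id == "G001_sg1"], 2)
  expect_equal(l2fc$l2fc[l2fc$sgrna_id == "G001_sg2"], 0)
  l2fc_pc <- compute_l2fc(cm, c("treated", "untreated"), pseudocount = 1)
  expect_equal(l2fc_pc$l2fc[l2fc_pc$sgrna_id == "G001_sg3"], log2(1 / 101))
})

test_that("gene collapse is the mean of surviving guides", {
  gv <- data.frame(gene = c("A", "A", "A", "B", "C", "C"),
                   l2fc = c(-1, 0, 1, 0.7, 2, 2))
  gg <- collapse_genes(gv)
  expect_equal(gg$l2fc[gg$gene == "A"], 0)
  expect_equal(gg$l2fc[gg$gene == "B"], 0.7)   # single guide passes through
  expect_equal(gg$l2fc[gg$gene == "C"], 2)     # equal guides return the value
  expect_equal(gg$n_guides, c(3, 1, 2))
})

test_that("doubling every guide of one gene in the numerator gives exactly +1", {
  cm <- toy_count_matrix(n_genes = 4, guides_per_gene = 3, n_nt = 60, base = 120)
  tx <- cm$samples$condition == "treated"
  cm$counts[cm$guides$gene == "G002", tx] <- 240
  gl <- compute_l2fc(cm, c("treated", "untreated"), pseudocount = 0)
  gg <- collapse_genes(gl[!gl$is_nontargeting, ])
  expect_equal(gg$l2fc[gg$gene == "G002"], 1)
  expect_equal(gg$l2fc[gg$gene == "G001"], 0)
})

test_that("pseudo-gene construction is deterministic, sized, and leftover-discarding", {
  ids <- sprintf("NT_%04d", 1:1000)
  pg <- make_pseudo_genes(ids, guides_per_gene = 6, seed = 17)
  expect_equal(length(unique(pg$pseudo_gene)), 166)
  expect_equal(nrow(pg), 996)
  expect_true(all(table(pg$pseudo_gene) == 6))
  expect_identical(pg, make_pseudo_genes(ids, 6, seed = 17))
  pg2 <- make_pseudo_genes(ids, 6, seed = 18)
  expect_false(identical(pg, pg2))
  one <- make_pseudo_genes(ids[1:6], 6, seed = 1)
  expect_equal(length(unique(one$pseudo_gene)), 1)
  expect_error(make_pseudo_genes(ids[1:5], 6, seed = 1), ">= 6")
})

test_that("z-scores and empirical p-values behave against a known null", {
  null <- with(list(), {set.seed(1); rnorm(5000)})
  sc <- score_vs_null(c(mean(null), mean(null) + 3 * sd(null)), null,
                      n_boot = 200000, seed = 2)
  expect_equal(sc$z[1], 0, tolerance = 1e-12)
  expect_gt(sc$p_empiric[1], 0.95)
  expect_equal(sc$z[2], 3, tolerance = 1e-12)
  expect_equal(sc$p_empiric[2], 0.0027, tolerance = 0.35)
  expect_error(score_vs_null(1, rep(2, 40)), "zero spread")
})

test_that("genes drawn from the null are calibrated under BH", {
  set.seed(7)
  null <- rnorm(200)
  genes <- rnorm(2000)
  sc <- score_vs_null(genes, null, n_boot = 10000, seed = 3)
  expect_lte(mean(sc$fdr < 0.1), 0.1 + 2 * sqrt(0.1 * 0.9 / 2000))
  # BH step-up: adjusted values are non-decreasing in p
  ord <- order(sc$p_empiric)
  expect_true(all(diff(sc$fdr[ord]) >= -1e-12))
})

test_that("concordance odds ratios and tail probabilities match hand calculations", {
  r1 <- concordance_test(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(r1$odds_ratio, 81)
  expect_false(r1$corrected)
  expect_lt(r1$p_value, 0.05)

  r2 <- concordance_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r2$odds_ratio, 1)
  expect_gt(r2$p_value, 0.5)

  r3 <- concordance_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_true(r3$corrected)
  expect_equal(r3$odds_ratio, 441)
})

test_that("pseudo-gene L2FC is symmetric about zero under exchangeable conditions", {
  cm <- suppressWarnings(
    toy_count_matrix(n_genes = 2, n_nt = 120, base = 0,
                     conditions = c("untreated", "treated"), n_replicates = 2)
  )
  set.seed(11)
  cm$counts[] <- rpois(length(cm$counts), 300)
  cm <- normalize_depth(cm, min_nontargeting = 50)
  gl <- compute_l2fc(cm, c("treated", "untreated"))
  pg <- make_pseudo_genes(cm, 6, seed = 4)
  gl$gene[match(pg$sgrna_id, gl$sgrna_id)] <- pg$pseudo_gene
  gg <- collapse_genes(gl[startsWith(gl$gene, "NT_PSEUDO_"), ])
  expect_lt(abs(median(gg$l2fc)), 0.1)
  expect_lt(abs(mean(gg$l2fc > 0) - 0.5), 0.25)
})
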