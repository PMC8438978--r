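test_that("readers validate their inputs", {
  d <- withr::local_tempdir()
  # duplicate gene ids
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), file.path(d, "dup.tsv"))
  expect_error(read_counts(file.path(d, "dup.tsv")), "duplicate gene")
  # non-integer counts
  writeLines(c("gene\ts1\ts2", "g1\t1.5\t2"), file.path(d, "frac.tsv"))
  expect_error(read_counts(file.path(d, "frac.tsv")), "non-negative integers")
  # orphan control reference
  sheet <- toy_sheet("T1", "FRC")
  sheet$control_for[sheet$control_for != ""] <- "nonexistent"
  p <- file.path(d, "orphan.tsv")
  write_sample_sheet(sheet, p)
  expect_error(read_sample_sheet(p), "missing control group")
  # 3 genes x 4 samples shape
  writeLines(c("gene\ta\tb\tc\td", "g1\t1\t2\t3\t4", "g2\t0\t0\t1\t1",
               "g3\t5\t5\t5\t5"), file.path(d, "ok.tsv"))
  expect_equal(dim(read_counts(file.path(d, "ok.tsv"))), c(3L, 4L))
})

test_that("low-expression filter removes genes at the ceiling boundary", {
  # 170 samples: a gene with 43 zeros goes, one with 42 stays
  m <- matrix(1L, 3, 170, dimnames = list(c("g42", "g43", "gfull"), NULL))
  colnames(m) <- sprintf("s%03d", 1:170)
  m["g42", 1:42] <- 0L
  m["g43", 1:43] <- 0L
  kept <- rownames(filter_low_expression(m))
  expect_setequal(kept, c("g42", "gfull"))
  # 8 samples: boundary at ceiling(0.25 * 8) = 2 zeros
  m8 <- matrix(1L, 4, 8, dimnames = list(paste0("z", 0:3), paste0("s", 1:8)))
  for (k in 0:3) if (k > 0) m8[k + 1, seq_len(k)] <- 0L
  expect_identical(rownames(filter_low_expression(m8)), c("z0", "z1"))
  # all-nonzero matrix unchanged, order stable
  expect_identical(filter_low_expression(m8[c("z1", "z0"), ]),
                   m8[c("z1", "z0"), ])
  expect_warning(filter_low_expression(m8[2:4, ], max_zero_fraction = 1e-6),
                 "every gene")
})

test_that("size factors reproduce median-of-ratios arithmetic", {
  # column B = 2 x column A -> factors proportional to (1, 2)
  a <- c(10L, 20L, 40L)
  m <- cbind(A = a, B = 2L * a)
  rownames(m) <- paste0("g", 1:3)
  sf <- size_factors(m)
  expect_equal(sf[["B"]] / sf[["A"]], 2)
  # identical columns -> all 1
  m2 <- cbind(A = a, B = a, C = a); rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # 3x3 worksheet: geometric means per gene, ratio medians per sample
  m3 <- matrix(c(2L, 4L, 8L,
                 9L, 3L, 3L,
                 16L, 4L, 4L), 3, 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  gm <- apply(m3, 1, function(x) exp(mean(log(x))))
  expected <- apply(m3 / gm, 2, median)
  expect_equal(unname(size_factors(m3)), unname(expected))
  # a zero in every gene somewhere -> no reference gene
  m4 <- matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(m4), "no gene")
})

test_that("internal DE reproduces the fold-change arithmetic", {
  # craft counts with unit size factors: most genes constant, one contrast
  sheet <- toy_sheet("T1", "FRC", nrep = 4)
  n_bg <- 30
  bg <- matrix(rep(c(100L, 200L, 400L, 50L, 25L), length.out = n_bg * 8),
               n_bg, 8)
  counts <- rbind(matrix(c(rep(10L, 4), rep(40L, 4)), 1), bg)
  rownames(counts) <- c("hit", sprintf("bg%02d", 1:n_bg))
  colnames(counts) <- sheet$sample   # first 4 are controls, last 4 treated
  det <- differential_expression(counts, sheet)
  expect_equal(unname(table(det$treatment)[["T1"]]), n_bg + 1)
  sf <- size_factors(counts)
  expect_equal(unname(sf), rep(1, 8))
  expect_equal(det$log2fc[det$gene == "hit"], log2(40.5 / 10.5),
               tolerance = 1e-12)
  # constant genes: exact zero fold change
  expect_true(all(det$log2fc[det$gene != "hit"] == 0))
  expect_true(all(det$padj >= det$p))
})

test_that("internal DE recovers planted fold changes", {
  # planted effects on 10% of genes; mean recovery within +-0.25
  cfg <- sim_config(n_genes = 2000, n_classes = 1, treatments_per_class = 1,
                    n_other_treatments = 0, module_sizes = list(200L),
                    replicates_per_treatment = 8, effect_size_log2 = 2,
                    effect_sd_log2 = 0, dispersion = 0.1, seed = 21)
  sim <- generate_compendium(cfg)
  det <- differential_expression(sim$counts, sim$samples)
  planted <- sim$truth$planted_lfc[det$gene, 1]
  mod <- planted > 0
  expect_lt(abs(mean(det$log2fc[mod] - planted[mod])), 0.25)
})

test_that("external DE tables are ingested verbatim", {
  d <- withr::local_tempdir()
  det <- toy_de(c("g1", "g2"), c("T1", "T2"), log2fc = 1:4 / 2,
                p = c(0.01, 0.2, 0.5, 0.9))
  p <- file.path(d, "de.tsv")
  write_de_table(det, p)
  sheet <- toy_sheet(c("T1", "T2"), c("FRC", "other"))
  got <- differential_expression(matrix(1L, 2, 2), sheet,
                                 method = "external_table", external_path = p)
  expect_equal(got, det)
  writeLines(c("gene\ttreatment\tlfc", "g1\tT1\t1"), file.path(d, "bad.tsv"))
  expect_error(read_de_table(file.path(d, "bad.tsv")), "columns")
})

test_that("DE-based gene filter counts significant comparisons", {
  genes <- paste0("g", 1:5)
  trts <- paste0("T", 1:4)
  # hand-set padj: g1 significant in 4, g2 in 3, g3 in 2, g4 in 1, g5 in 0
  padj <- c(rep(0.01, 4), c(0.01, 0.01, 0.01, 0.9), c(0.01, 0.01, 0.9, 0.9),
            c(0.01, 0.9, 0.9, 0.9), rep(0.9, 4))
  det <- data.frame(gene = rep(genes, each = 4), treatment = rep(trts, 5),
                    log2fc = 0, p = padj, padj = padj,
                    stringsAsFactors = FALSE)
  expect_identical(filter_de_genes(det), c("g1", "g2"))
  expect_identical(filter_de_genes(det, min_comparisons = 2),
                   c("g1", "g2", "g3"))
  expect_identical(filter_de_genes(det, alpha = 1), genes)  # all kept
  # order stability: survivors keep input order
  det2 <- det[order(rev(seq_len(nrow(det)))), ]
  expect_identical(filter_de_genes(det2), c("g2", "g1"))
})

test_that("fold-change matrix is assembled cellwise", {
  det <- toy_de(c("g1", "g2"), c("T1", "T2"), log2fc = c(1, 2, 3, 4))
  fc <- build_fc_matrix(det, c("g2", "g1"))
  expect_identical(rownames(fc), c("g2", "g1"))  # row order from gene list
  expect_identical(colnames(fc), c("T1", "T2"))
  for (r in seq_len(nrow(det)))
    expect_equal(fc[det$gene[r], det$treatment[r]], det$log2fc[r])
  expect_error(build_fc_matrix(det, c("g1", "gX")), "absent")
  expect_error(build_fc_matrix(det[-1, ], c("g1", "g2")), "missing")
})

test_that("Ward clustering separates planted classes and handles edges", {
  sim <- small_compendium()
  cm <- filter_low_expression(sim$counts)
  det <- differential_expression(cm, sim$samples)
  genes <- filter_de_genes(det)
  fc <- build_fc_matrix(det, genes)
  classes <- sapply(colnames(fc), function(t)
    unique(sim$samples$class[sim$samples$treatment == t]))
  # class treatments respond with planted structure; k = 3 recovers them
  cl <- ward_cluster_treatments(fc, k = 3)
  expect_equal(adjusted_rand_index(cl$clusters, as.integer(factor(classes))), 1)
  # k = n gives singletons
  cln <- ward_cluster_treatments(fc, k = ncol(fc))
  expect_equal(length(unique(cln$clusters)), ncol(fc))
  # duplicated column co-clusters with its twin at any k
  fc2 <- cbind(fc, dup = fc[, 1])
  cl2 <- ward_cluster_treatments(fc2, k = 5)
  expect_equal(unname(cl2$clusters["dup"]), unname(cl2$clusters[colnames(fc)[1]]))
  expect_error(ward_cluster_treatments(fc, k = 0))
})

test_that("responsive-chemical counting applies the criteria", {
  det <- data.frame(
    gene = rep("g1", 4), treatment = paste0("T", 1:4),
    log2fc = c(2, 0.5, -3, 1.2),
    p = c(0.001, 0.001, 0.2, 0.03),
    padj = c(0.01, 0.01, 0.6, 0.2), stringsAsFactors = FALSE)
  # padj < 0.05, no lfc cutoff: T1, T2
  expect_equal(count_responsive_chemicals(det, "g1"), 2)
  # raw p < 0.05 and |lfc| > 1: T1 and T4
  crit <- response_criteria(alpha = 0.05, min_abs_lfc = 1, use_adjusted = FALSE)
  expect_equal(count_responsive_chemicals(det, "g1", crit = crit), 2)
  # class filter restricts the treatments considered
  expect_equal(count_responsive_chemicals(det, "g1", treatments = "T3"), 0)
  expect_error(count_responsive_chemicals(det, "nope"), "unknown gene")
  # impossible criterion -> zero
  crit0 <- response_criteria(alpha = 1e-12, min_abs_lfc = 10)
  expect_equal(count_responsive_chemicals(det, "g1", crit = crit0), 0)
})
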