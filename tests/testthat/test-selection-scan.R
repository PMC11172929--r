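test_that("z_transform standardizes with the n-1 sd convention", {
  z <- z_transform(c(1, 2, 3))
  expect_equal(z[3], 1.0)
  set.seed(1)
  x <- c(rnorm(50), NA, Inf)
  z2 <- z_transform(x)
  expect_true(is.na(z2[51]) && is.na(z2[52]))
  expect_equal(mean(z2, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z2, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_false(is.unsorted(z_transform(sort(rnorm(20)))))
  expect_error(z_transform(rep(2, 5)), "zero spread")
})

test_that("ln_pi_ratio flags zero diversity instead of infinities", {
  expect_equal(ln_pi_ratio(1e-3, 1e-3), 0)
  expect_equal(ln_pi_ratio(5e-4, 1e-3), log(0.5))
  expect_true(is.na(ln_pi_ratio(0, 1e-3)))
  expect_true(is.na(ln_pi_ratio(1e-3, 0)))
})

fake_records <- function(values, chrom = "1") {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * 1000,
             end = seq_len(n) * 1000, stat = values,
             stringsAsFactors = FALSE)
}

test_that("select_tail flags exactly ceil(qW) windows deterministically", {
  set.seed(2)
  rec <- fake_records(rnorm(1000))
  top <- select_tail(rec, "stat", "upper", 0.005)
  expect_equal(nrow(top), 5)
  expect_setequal(top$stat, sort(rec$stat, decreasing = TRUE)[1:5])

  rec2 <- fake_records(rnorm(100))
  expect_equal(nrow(select_tail(rec2, "stat", "upper", 0.005)), 1)

  # ties at the cutoff: earliest genomic windows win, stably
  rec3 <- fake_records(c(rep(5, 10), rnorm(90)))
  t1 <- select_tail(rec3, "stat", "upper", 0.005)  # k = 1 of 100
  t2 <- select_tail(rec3, "stat", "upper", 0.005)
  expect_identical(t1, t2)
  expect_equal(t1$start, 0)
  low <- select_tail(rec, "stat", "lower", 0.01)
  expect_equal(nrow(low), 10)
  expect_setequal(low$stat, sort(rec$stat)[1:10])
})

test_that("merge_windows merges overlap/book-ends and is idempotent", {
  fl <- data.frame(chrom = "1", start = c(0, 50000, 200000),
                   end = c(100000, 150000, 300000),
                   stat = c(1, 3, 2), stringsAsFactors = FALSE)
  r <- merge_windows(fl, "ZFST", "stat", "upper")
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(0, 200000))
  expect_equal(r$end, c(150000, 300000))
  expect_equal(r$peak, c(3, 2))
  r2 <- merge_windows(r, "ZFST", "peak", "upper")
  expect_equal(r2$start, r$start)
  expect_equal(r2$end, r$end)
  expect_equal(nrow(merge_windows(fl[0, ], "ZFST")), 0)
})

test_that("annotate_regions uses half-open >= 1 bp overlap", {
  genes <- data.frame(gene_id = "SLC4A4", gene_name = "SLC4A4",
                      biotype = "protein_coding", chrom = "6",
                      start = 86381836, end = 86809131)
  hit <- annotate_regions(
    data.frame(chrom = "6", start = 86400000, end = 86500000,
               method = "ZFST"), genes)
  expect_equal(hit$gene_id, "SLC4A4")

  # region ending exactly at the gene's (0-based) start: no hit
  none <- annotate_regions(
    data.frame(chrom = "6", start = 86000000, end = 86381835,
               method = "ZFST"), genes)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(annotate_regions(genes[0, c("chrom", "start", "end")],
                                     genes)), 0)
  expect_error(annotate_regions(
    data.frame(chrom = "7", start = 1, end = 10), genes), "7")
})

test_that("intersect_methods computes shared genes and Venn counts", {
  res <- intersect_methods(list(ZFST = c("a", "b", "c"),
                                ZHP = c("b", "c", "d"),
                                PI_RATIO = c("c", "e")))
  expect_equal(res$shared, "c")
  expect_equal(unname(res$venn[["ZFST+ZHP+PI_RATIO"]]), 1)
  expect_equal(sum(res$venn), 5)   # size of the union

  same <- intersect_methods(list(A = c("x", "y"), B = c("x", "y"),
                                 C = c("x", "y")))
  expect_setequal(same$shared, c("x", "y"))
  disj <- intersect_methods(list(A = "x", B = "y", C = "z"))
  expect_equal(length(disj$shared), 0)
  expect_equal(sum(disj$venn), 3)
})

test_that("gene_region_profile localizes a planted sweep", {
  sims <- small_sweep_sims(10)
  cfg <- scan_config(window_size = 1e4, step = 5e3,
                     min_snps_per_window = 5)
  ok <- vapply(sims, function(sim) {
    iv <- sim$truth$sweep_interval
    gene <- list(chrom = "1", start = floor(iv[1]) + 1, end = ceiling(iv[2]))
    prof <- gene_region_profile(sim$g, gene, "POP1", c("POP2", "POP3"),
                                flank_bp = 2e5, cfg = cfg)
    fst_max_in <- prof$in_gene[which.max(prof$fst)]
    tajd_min_in <- prof$in_gene[which.min(prof$tajd)]
    fst_max_in && tajd_min_in
  }, logical(1))
  expect_gte(sum(ok), 8)
})

test_that("gene_region_profile with zero flank stays on the gene span", {
  g <- random_genotype_matrix(10, 50, seed = 12, chrom_length = 1e5)
  gene <- list(chrom = "1", start = 20001, end = 60000)
  prof <- gene_region_profile(g, gene, "P1", "P2", flank_bp = 0,
                              cfg = scan_config(window_size = 1e4,
                                                step = 1e4))
  expect_true(all(prof$start < 60000 & prof$end > 20000))
  expect_true(all(prof$in_gene))
})

test_that("run_selection_scan wires tails, regions and gene intersection", {
  sim <- small_sweep_sims(10)[[1]]
  cfg <- scan_config(window_size = 5000, step = 2500,
                     min_snps_per_window = 10)
  st <- compute_window_stats(sim$g, "POP1", c("POP2", "POP3"), cfg,
                             chrom_lengths = c(`1` = 1e6))
  genes <- tile_genes(1e6, sim$truth$sweep_interval)
  scan <- run_selection_scan(st, genes, cfg)
  expect_named(scan$regions, c("ZFST", "ZHP", "PI_RATIO"))
  W <- sum(is.finite(st$fst))
  expect_equal(nrow(scan$flagged$ZFST), ceiling(0.005 * W))
  expect_true(all(vapply(scan$regions, nrow, integer(1)) >= 1))
  expect_true(is.list(scan$intersection))
  expect_true(all(c("shared", "venn", "membership") %in%
                    names(scan$intersection)))
  # Venn counts always sum to the union of annotated genes
  expect_equal(sum(scan$intersection$venn),
               nrow(scan$intersection$membership))
})
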