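test_that("make_windows enumerates sliding and tiling windows", {
  cfg <- scan_config(window_size = 1e5, step = 5e4)
  w <- make_windows(c(`1` = 1e6), cfg)
  expect_equal(nrow(w), 20)
  expect_equal(sum(w$span == 1e5), 19)            # full windows
  expect_equal(w$start[w$span < 1e5], 950000)     # trailing partial
  expect_equal(w$end[20], 1e6)

  w2 <- make_windows(c(`1` = 1e5), cfg)
  expect_equal(nrow(w2), 2)
  expect_equal(unlist(w2[2, c("start", "end")], use.names = FALSE),
               c(50000, 100000))

  tiling <- make_windows(c(`1` = 3e5),
                         scan_config(window_size = 1e5, step = 1e5))
  expect_equal(tiling$start, c(0, 1e5, 2e5))
  expect_equal(sum(tiling$span), 3e5)             # union covers chromosome
  expect_error(scan_config(window_size = 1e4, step = 5e4), "step")
})

test_that("site_pi matches pairwise enumeration", {
  expect_equal(site_pi(2, 4), 4 / 6)
  expect_equal(site_pi(0, 4), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))
  expect_error(site_pi(5, 4), "alt_count")
})

test_that("window_pi does hand arithmetic and scales with span", {
  # 2 samples (4 haplotypes): site pi 2/3 and 1/2 inside a 100 bp window
  g <- gm_from_dosages(rbind(c(1L, 1L), c(1L, 0L)), pos = c(10L, 20L))
  w <- list(chrom = "1", start = 0, end = 100)
  expect_equal(window_pi(g, w, "P1"), (2 / 3 + 1 / 2) / 100)
  w2 <- list(chrom = "1", start = 0, end = 200)
  expect_equal(window_pi(g, w2, "P1"), (2 / 3 + 1 / 2) / 200)
  expect_equal(window_pi(g, list(chrom = "1", start = 50, end = 90), "P1"),
               0)  # empty window
})

test_that("Weir-Cockerham components match the published special cases", {
  fixed <- wc_fst_site(10, 1, 0, 10, 0, 0)
  expect_equal(fixed$a, 0.5)
  expect_equal(fixed$b, 0)
  expect_equal(fixed$c, 0)
  expect_equal(fixed$a / (fixed$a + fixed$b + fixed$c), 1)

  # identical frequency/heterozygosity/size: negative expectation
  same <- wc_fst_site(10, 0.5, 0.5, 10, 0.5, 0.5)
  expect_lte(same$a / (same$a + same$b + same$c), 0)
  # against the independent scalar implementation
  d1 <- c(0L, 1L, 1L, 0L, 2L, 1L, 0L, 1L, 1L, 0L)
  d2 <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)  # monomorphic
  bf <- bf_wc_site(d1, d2)
  n1 <- 10; p1 <- sum(d1) / 20; h1 <- mean(d1 == 1)
  got <- wc_fst_site(n1, p1, h1, 10, 0, 0)
  expect_equal(got$a, bf$a, tolerance = 1e-12)
  expect_equal(got$b, bf$b, tolerance = 1e-12)
  expect_equal(got$c, bf$c, tolerance = 1e-12)
})

test_that("windowed_fst hits the fixed-difference and identity limits", {
  # 5 + 5 samples, all sites fixed differences
  d <- rbind(matrix(2L, 5, 4), matrix(0L, 5, 4))
  g <- gm_from_dosages(d, pops = rep(c("A", "B"), each = 5))
  w <- list(chrom = "1", start = 0, end = 100)
  expect_equal(windowed_fst(g, w, "A", "B"), 1.0)

  set.seed(8)
  dd <- matrix(rbinom(40, 2, 0.4), nrow = 10)
  g2 <- gm_from_dosages(rbind(dd[1:5, ], dd[1:5, ]),
                        pops = rep(c("A", "B"), each = 5))
  expect_lte(windowed_fst(g2, w, "A", "B"), 0)
})

test_that("pairwise_fst_matrix is symmetric and orders divergence", {
  p <- sim_params(n_pops = 3, samples_per_pop = 30, n_snps = 4000,
                  chrom_length = 1e6, fst_target = c(0.02, 0.02, 0.2),
                  seed = 31)
  sim <- simulate_balding_nichols(p)
  m <- pairwise_fst_matrix(sim$g, cfg = scan_config(window_size = 1e5,
                                                    step = 1e5))
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  big <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_true("POP3" %in% rownames(m)[big])
})

test_that("hp_window does the pooled-heterozygosity arithmetic", {
  # 5 samples (10 haplotypes); counts (maj,min) = (9,1) and (8,2)
  g <- gm_from_dosages(rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L),
                             c(0L, 0L), c(0L, 0L)))
  w <- list(chrom = "1", start = 0, end = 100)
  expect_equal(hp_window(g, w, "P1"), 2 * 17 * 3 / 20^2)

  mono <- gm_from_dosages(matrix(2L, 4, 3))
  expect_equal(hp_window(mono, w, "P1"), 0)
  half <- gm_from_dosages(matrix(1L, 4, 3))
  expect_equal(hp_window(half, w, "P1"), 0.5)
})

test_that("Tajima's D constants and flags are right", {
  k <- tajima_constants(10)
  expect_equal(k$a1, sum(1 / 1:9))
  expect_equal(k$a2, sum(1 / (1:9)^2))
  g <- gm_from_dosages(rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L)))
  w <- list(chrom = "1", start = 0, end = 100)
  expect_true(is.na(tajimas_d(g, w, "P1")))  # S = 1 < 2: flagged
})

test_that("windowed statistics equal brute-force oracles on random data", {
  for (seed in 1:25) {
    n_samp <- sample(4:10, 1)
    g <- random_genotype_matrix(n_samples = n_samp,
                                n_sites = sample(5:50, 1),
                                missing_rate = 0.15, seed = 200 + seed)
    w <- list(chrom = "1", start = 0, end = 1e5)
    expect_equal(window_pi(g, w, "P1"), bf_window_pi(g, w, "P1"),
                 tolerance = 1e-12)
    expect_equal(windowed_fst(g, w, "P1", "P2"),
                 bf_windowed_fst(g, w, "P1", "P2"), tolerance = 1e-12)
    expect_equal(hp_window(g, w, "P1"), bf_hp_window(g, w, "P1"),
                 tolerance = 1e-12)
    expect_equal(tajimas_d(g, w, "P1"), bf_tajimas_d(g, w, "P1"),
                 tolerance = 1e-12)
  }
})

test_that("statistics are invariant under sample permutation", {
  g <- random_genotype_matrix(10, 40, missing_rate = 0.1, seed = 77)
  set.seed(78)
  perm <- sample(g$samples)
  gp <- genotype_matrix(g$geno[perm, , drop = FALSE], g$sites, g$pop)
  w <- list(chrom = "1", start = 0, end = 1e5)
  for (f in list(window_pi, hp_window, tajimas_d))
    expect_equal(f(g, w, "P1"), f(gp, w, "P1"))
  expect_equal(windowed_fst(g, w, "P1", "P2"),
               windowed_fst(gp, w, "P1", "P2"))
})

test_that("compute_window_stats flags under-filled windows", {
  g <- random_genotype_matrix(10, 30, missing_rate = 0, seed = 5,
                              chrom_length = 2e5)
  cfg <- scan_config(window_size = 1e5, step = 5e4,
                     min_snps_per_window = 10)
  st <- compute_window_stats(g, "P1", "P2", cfg,
                             chrom_lengths = c(`1` = 2e5))
  expect_true(all(is.na(st$fst[st$n_snps < 10])))
  expect_true(all(st$n_snps >= 0))
  # full-window statistics agree with the single-window operations
  full <- which(st$n_snps >= 10)
  for (i in full) {
    w <- st[i, c("chrom", "start", "end")]
    expect_equal(st$fst[i], windowed_fst(g, w, "P1", "P2"))
    expect_equal(st$hp[i], hp_window(g, w, "P1"))
    expect_equal(st$tajd[i], tajimas_d(g, w, "P1"))
    expect_equal(st$pi_P1[i], window_pi(g, w, "P1"))
  }
})
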