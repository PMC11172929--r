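# genotype matrix with one sample whose genome is heterozygous background
# with fully homozygous tracts planted at given bp intervals
planted_roh_matrix <- function(tracts, chrom_length = 2e7, spacing = 1e4) {
  pos <- seq(spacing, chrom_length, by = spacing)
  geno <- rep(1L, length(pos))
  for (tr in tracts)
    geno[pos >= tr[1] & pos <= tr[2]] <- 2L
  gm_from_dosages(matrix(geno, nrow = 1), pos = pos)
}

test_that("detect_roh recovers a planted 1.2 Mb tract with tight bounds", {
  tr <- c(5e6, 6.2e6)
  g <- planted_roh_matrix(list(tr))
  seg <- detect_roh(g, "S01")
  expect_equal(nrow(seg), 1)
  expect_equal(as.character(seg$size_class), "1-2Mb")
  expect_lte(abs(seg$start - tr[1]), 1e4)  # within one inter-SNP gap
  expect_lte(abs(seg$end - tr[2]), 1e4)
})

test_that("detect_roh ignores all-het genomes and sub-threshold tracts", {
  g_het <- planted_roh_matrix(list())
  expect_equal(nrow(detect_roh(g_het, "S01")), 0)
  g_small <- planted_roh_matrix(list(c(5e6, 5.4e6)))  # 0.4 Mb
  expect_equal(nrow(detect_roh(g_small, "S01")), 0)
})

test_that("summarize_roh tabulates classes and totals", {
  g <- planted_roh_matrix(list(c(5e6, 6.2e6)))
  seg <- detect_roh(g, "S01")
  s <- summarize_roh(seg)
  expect_equal(unname(unlist(s$per_sample[1, c("0.5-1Mb", "1-2Mb", ">2Mb")])),
               c(0, 1, 0))
  expect_equal(s$per_sample$total_bp, seg$length_bp)
  empty <- summarize_roh(seg[0, ], populations = c(S01 = "P1"))
  expect_equal(empty$per_sample$total_bp, 0)
  expect_equal(empty$per_population$total_bp, 0)
})

test_that("strong drift accumulates more ROH than weak drift", {
  roh_total <- function(F, seed) {
    # focal drifted population + weakly drifted outgroup that keeps the
    # site panel polymorphic (as a joint call set would)
    p <- sim_params(n_pops = 2, samples_per_pop = 10, chrom_length = 1e7,
                    n_snps = 2000, fst_target = c(F, 0.02), seed = seed)
    sim <- simulate_balding_nichols(p)
    focal <- sim$g$samples[pop_rows(sim$g, "POP1")]
    segs <- do.call(rbind, lapply(focal, function(s) detect_roh(sim$g, s)))
    if (is.null(segs) || !nrow(segs)) 0 else sum(segs$length_bp)
  }
  # deep drift pushes frequencies to the edges: homozygous tracts emerge
  expect_gt(roh_total(0.95, 61), roh_total(0.3, 61))
})

test_that("ld_r2 equals squared Pearson correlation of dosages", {
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)), 1.0)
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), 2 - c(0, 1, 2, 0, 1, 2)), 1.0)
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 1, 2, 2)), 0.25)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  # block path agrees with the scalar path under missingness
  set.seed(3)
  x <- rbinom(30, 2, 0.4); M <- matrix(rbinom(150, 2, 0.5), 30)
  x[sample(30, 4)] <- NA; M[sample(150, 15)] <- NA
  blk <- sweepscan:::r2_block(x, M)
  ref <- apply(M, 2, function(col) ld_r2(x, col))
  expect_equal(blk, unname(ref), tolerance = 1e-12)
})

test_that("ld_decay distinguishes structured from shuffled columns", {
  set.seed(4)
  n <- 60; S <- 120
  base <- rbinom(n, 2, 0.5)
  flip <- function(v, k) { i <- sample(n, k); v[i] <- 2 - v[i]; v }
  # neighboring sites are near-copies: r2 decays with index distance
  cols <- matrix(0L, n, S)
  cols[, 1] <- base
  for (j in 2:S) cols[, j] <- flip(cols[, j - 1], 3)
  g <- gm_from_dosages(cols, pos = seq_len(S) * 1000L)
  curve <- ld_decay(g, "P1", max_dist = 5e4, bin_width = 1e4)
  r2 <- curve$mean_r2[curve$n_pairs > 0]
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_gt(r2[1], tail(r2, 1))  # decay with distance

  shuffled <- gm_from_dosages(cols[, sample(S)], pos = seq_len(S) * 1000L)
  curve2 <- ld_decay(shuffled, "P1", max_dist = 5e4, bin_width = 1e4)
  r2s <- curve2$mean_r2[curve2$n_pairs > 0]
  expect_lt(max(r2s) - min(r2s), max(r2) - min(r2))  # flat background
})

test_that("ld_prune drops duplicates, keeps independents, is deterministic", {
  set.seed(5)
  x <- rbinom(100, 2, 0.5)
  dup <- cbind(x, x, rbinom(100, 2, 0.5))
  expect_equal(ld_prune(gm_from_dosages(dup)), c(1, 3))

  indep <- matrix(rbinom(100 * 30, 2, 0.5), nrow = 100)
  kept <- ld_prune(gm_from_dosages(indep))
  expect_gte(length(kept), 25)
  expect_identical(kept, ld_prune(gm_from_dosages(indep)))
  # post-condition: no surviving in-window pair exceeds the threshold
  for (ii in seq_along(kept)) {
    jmax <- min(ii + 49, length(kept))
    if (jmax <= ii) next
    for (jj in (ii + 1):jmax) {
      r2 <- ld_r2(indep[, kept[ii]], indep[, kept[jj]])
      expect_false(!is.na(r2) && r2 > 0.2)
    }
  }
})

test_that("pca_genotypes separates diverged populations on PC1", {
  p <- sim_params(n_pops = 2, samples_per_pop = 20, n_snps = 2000,
                  chrom_length = 1e6, fst_target = 0.3, seed = 41)
  sim <- simulate_balding_nichols(p)
  pc <- pca_genotypes(sim$g)
  expect_true(all(diff(pc$percent_var) <= 1e-9))
  expect_lte(sum(pc$percent_var), 100 + 1e-6)
  a <- pc$scores[pop_rows(sim$g, "POP1"), 1]
  b <- pc$scores[pop_rows(sim$g, "POP2"), 1]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("duplicating every sample leaves PC directions unchanged", {
  g <- random_genotype_matrix(12, 200, missing_rate = 0, seed = 51)
  pc1 <- pca_genotypes(g)$scores[, 1]
  geno2 <- rbind(g$geno, g$geno)
  ids <- sprintf("T%02d", seq_len(24))
  rownames(geno2) <- ids
  g2 <- genotype_matrix(geno2, g$sites,
                        setNames(rep(unname(g$pop), 2), ids))
  pc2 <- pca_genotypes(g2)$scores[1:12, 1]
  expect_gt(abs(cor(pc1, pc2)), 0.999)
})

test_that("IBS distances hit the identity and opposite-homozygote limits", {
  d <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L))
  g <- gm_from_dosages(d, pops = c("A", "A", "B"))
  D <- ibs_distance_matrix(g, "sample")
  expect_equal(D[1, 2], 0)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
  opp <- gm_from_dosages(rbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(ibs_distance_matrix(opp, "sample")[1, 2], 1)
})

test_that("nj_tree reconstructs the classic additive 4-taxon matrix", {
  D <- matrix(c(0, 3, 6, 7,
                3, 0, 7, 8,
                6, 7, 0, 7,
                7, 8, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  res <- nj_tree(D)
  pat <- ape::cophenetic.phylo(res$tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pat, D, tolerance = 1e-10)
  # branch lengths: A:1, B:2, C:3, D:4, internal 2
  ext <- setNames(res$tree$edge.length[res$tree$edge[, 2] <= 4],
                  res$tree$tip.label[res$tree$edge[res$tree$edge[, 2] <= 4,
                                                   2]])
  expect_equal(ext[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))

  # 3-taxon closed form
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  r3 <- nj_tree(D3)
  pat3 <- ape::cophenetic.phylo(r3$tree)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(pat3, D3, tolerance = 1e-10)

  # label permutation leaves the unrooted topology unchanged
  perm <- c(3, 1, 4, 2)
  Dp <- D[perm, perm]
  rp <- nj_tree(Dp)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(res$tree),
                                         ape::unroot(rp$tree))), 0)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})
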