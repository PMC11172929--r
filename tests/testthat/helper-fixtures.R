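# Programmatic fixtures shared across test files.

random_genotype_matrix <- function(n_samples = 8, n_sites = 30,
                                   n_pops = 2, missing_rate = 0.1,
                                   chrom_length = 1e5, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_sites))
  freq <- runif(n_sites, 0.05, 0.95)
  geno <- matrix(rbinom(n_samples * n_sites, 2L, rep(freq, each = n_samples)),
                 nrow = n_samples)
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  ids <- sprintf("S%02d", seq_len(n_samples))
  rownames(geno) <- ids
  pops <- setNames(rep(sprintf("P%d", seq_len(n_pops)),
                       length.out = n_samples), ids)
  genotype_matrix(geno,
                  data.frame(chrom = "1", pos = pos, ref = "A", alt = "C"),
                  pops)
}

# matrix built from an explicit dosage table (sites in columns)
gm_from_dosages <- function(dosages, pops = NULL, pos = NULL, chrom = "1") {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  ids <- sprintf("S%02d", seq_len(n))
  rownames(dosages) <- ids
  if (is.null(pops)) pops <- rep("P1", n)
  pops <- setNames(pops, ids)
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 10L
  genotype_matrix(dosages,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C"),
                  pops)
}

whole_window <- function(g) {
  list(chrom = g$sites$chrom[1], start = 0,
       end = max(g$sites$pos))
}

# small planted-sweep simulations reused by several files (1 Mb chromosome)
.sweep_cache <- new.env(parent = emptyenv())
small_sweep_sims <- function(n_seeds = 10) {
  key <- paste0("n", n_seeds)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  sims <- lapply(seq_len(n_seeds), function(s) {
    p <- sim_params(n_pops = 3, samples_per_pop = 25, chrom_length = 1e6,
                    pop_size_N = 200, mutation_rate = 1.25e-6,
                    recomb_rate = 1e-7, split_gen = 150,
                    sweep = list(pos = 5e5, s = 0.1, test_pop = 1),
                    seed = 1000 + s)
    simulate_wright_fisher(p)
  })
  .sweep_cache[[key]] <- sims
  sims
}
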