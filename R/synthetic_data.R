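#' Simulation parameters
#'
#' Bundles every knob of the two genotype simulators.  The defaults describe
#' a deliberately scaled-down study system: a 5 Mb chromosome and a diploid
#' population size of a few hundred, with the per-bp mutation and
#' recombination rates raised so that the population-scaled densities
#' (\eqn{\theta = 4N\mu \approx 10^{-3}}/bp, \eqn{\rho/\theta \approx 0.1})
#' stay in the range typical of cattle whole-genome data.
#'
#' @param n_pops number of diploid populations (K)
#' @param samples_per_pop diploid individuals sampled per population
#' @param chrom_length chromosome length in bp
#' @param n_snps number of SNPs (Balding-Nichols mode only)
#' @param fst_target Balding-Nichols divergence parameter F in [0,1);
#'   scalar (shared) or one value per population
#' @param pop_size_N Wright-Fisher diploid population size
#' @param mutation_rate per-bp per-generation mutation rate (WF mode)
#' @param recomb_rate per-bp per-generation recombination rate (WF sweep
#'   hitchhiking)
#' @param split_gen generations since the populations split (WF mode)
#' @param sweep `NULL`, or `list(pos=, s=, test_pop=)`: a hard sweep at
#'   0-based position `pos` with selection coefficient `s` completing at
#'   sampling time in population `test_pop`
#' @param missing_rate i.i.d. per-call missingness fraction in [0,1)
#' @param restart_budget maximum restarts when conditioning the sweep on
#'   fixation within `split_gen` generations
#' @param seed integer seed; fully determines the output
#' @return list of class `sim_params`
#' @export
sim_params <- function(n_pops = 2L, samples_per_pop = 25L,
                       chrom_length = 1e6, n_snps = 10000L,
                       fst_target = 0.1, pop_size_N = 200L,
                       mutation_rate = 1.25e-6, recomb_rate = 1e-7,
                       split_gen = 150L, sweep = NULL,
                       missing_rate = 0, restart_budget = 1000L,
                       seed = 1L) {
  p <- list(n_pops = as.integer(n_pops),
            samples_per_pop = as.integer(samples_per_pop),
            chrom_length = as.numeric(chrom_length),
            n_snps = as.integer(n_snps),
            fst_target = as.numeric(fst_target),
            pop_size_N = as.integer(pop_size_N),
            mutation_rate = as.numeric(mutation_rate),
            recomb_rate = as.numeric(recomb_rate),
            split_gen = as.integer(split_gen),
            sweep = sweep,
            missing_rate = as.numeric(missing_rate),
            restart_budget = as.integer(restart_budget),
            seed = as.integer(seed))
  if (any(p$fst_target < 0) || any(p$fst_target >= 1))
    stop("fst_target must lie in [0, 1)")
  if (p$missing_rate < 0 || p$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!is.null(sweep)) {
    if (is.null(sweep$pos) || is.null(sweep$s))
      stop("sweep must provide pos and s")
    if (sweep$s < 0) stop("selection coefficient s must be >= 0")
    if (sweep$pos < 0 || sweep$pos >= p$chrom_length)
      stop("sweep position must lie in [0, chrom_length)")
    if (is.null(sweep$test_pop)) p$sweep$test_pop <- 1L
  }
  class(p) <- "sim_params"
  p
}

pop_labels <- function(k) sprintf("POP%d", seq_len(k))

sample_ids <- function(params) {
  unlist(lapply(seq_len(params$n_pops), function(k)
    sprintf("%s_%02d", pop_labels(params$n_pops)[k],
            seq_len(params$samples_per_pop))))
}

random_bases <- function(n) {
  b <- c("A", "C", "G", "T")
  ri <- sample.int(4L, n, replace = TRUE)
  ai <- ((ri - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  list(ref = b[ri], alt = b[ai])
}

# Assemble the genotype_matrix from per-population allele frequencies.
# freq: K x S matrix of population alt-allele frequencies; pos1: 1-based
# site positions.  Sites monomorphic in the pooled sample are dropped
# (they would not appear in a VCF).
sample_genotypes <- function(freq, pos1, params, keep_pos1 = integer(0)) {
  K <- nrow(freq); S <- ncol(freq); n <- params$samples_per_pop
  geno <- matrix(NA_integer_, nrow = K * n, ncol = S)
  for (k in seq_len(K)) {
    gk <- matrix(rbinom(n * S, 2L, rep(freq[k, ], each = n)), nrow = n)
    geno[(k - 1L) * n + seq_len(n), ] <- gk
  }
  ids <- sample_ids(params)
  rownames(geno) <- ids
  tot <- colSums(geno)
  seg <- tot > 0L & tot < 2L * nrow(geno)
  seg <- seg | (pos1 %in% keep_pos1)
  idx <- which(seg)[order(pos1[seg])]  # retained sites, position order
  geno <- geno[, idx, drop = FALSE]
  pos1 <- pos1[idx]
  if (params$missing_rate > 0) {
    drop <- matrix(runif(length(geno)) < params$missing_rate,
                   nrow = nrow(geno))
    geno[drop] <- NA_integer_
  }
  al <- random_bases(length(pos1))
  sites <- data.frame(chrom = "1", pos = pos1, ref = al$ref, alt = al$alt,
                      stringsAsFactors = FALSE)
  pops <- rep(pop_labels(K), each = n)
  names(pops) <- ids
  list(g = genotype_matrix(geno, sites, pops), kept = idx)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per site, an ancestral frequency p ~ Uniform(0.05, 0.95) is drawn; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) (exactly p when
#' F = 0), so that the between-population frequency variance is
#' F p (1 - p) and the expected Weir-Cockerham \eqn{F_{ST}} equals F.
#' Genotypes are Binomial(2, p_pop); positions are uniform-unique on the
#' chromosome and sorted.
#'
#' @param params a [sim_params()]; uses `n_pops`, `samples_per_pop`,
#'   `chrom_length`, `n_snps`, `fst_target` (scalar or per-population),
#'   `missing_rate`, `seed`.
#' @return `list(g = genotype_matrix, truth = sim_truth)`; the truth carries
#'   the per-site ancestral frequencies and the generating F.
#' @export
simulate_balding_nichols <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_snps < 1L) stop("n_snps must be >= 1")
  if (params$n_snps > params$chrom_length)
    stop("n_snps exceeds chrom_length: cannot place unique positions")
  set.seed(params$seed)
  K <- params$n_pops
  S <- params$n_snps
  Fv <- rep_len(params$fst_target, K)
  pos1 <- sort(sample.int(params$chrom_length, S))
  p_anc <- runif(S, 0.05, 0.95)
  freq <- matrix(0, nrow = K, ncol = S)
  for (k in seq_len(K)) {
    if (Fv[k] == 0) {
      freq[k, ] <- p_anc
    } else {
      shape <- (1 - Fv[k]) / Fv[k]
      freq[k, ] <- rbeta(S, p_anc * shape, (1 - p_anc) * shape)
    }
  }
  res <- sample_genotypes(freq, pos1, params)
  truth <- structure(list(sweep_interval = NULL, fst_target = Fv,
                          seed = params$seed, anc_freq = p_anc[res$kept],
                          params = params),
                     class = "sim_truth")
  list(g = res$g, truth = truth)
}

# One conditioned sweep trajectory: frequency path of the beneficial allele
# from 1/2N to fixation under p' = p(1+s)/(1+ps) plus binomial drift,
# restarted (up to restart_budget times) until it fixes within max_gen
# generations.
sweep_trajectory <- function(twoN, s, max_gen, budget) {
  for (i in seq_len(budget)) {
    p <- 1 / twoN
    traj <- p
    while (p > 0 && p < 1 && length(traj) <= max_gen) {
      psel <- p * (1 + s) / (1 + p * s)
      p <- rbinom(1L, twoN, psel) / twoN
      traj <- c(traj, p)
    }
    if (p == 1) return(traj)
  }
  stop("sweep failed to fix within ", max_gen,
       " generations after ", budget, " restarts; ",
       "increase split_gen, s or restart_budget")
}

#' Simulate genotypes under a forward Wright-Fisher model
#'
#' K populations split from a common ancestor `split_gen` generations ago.
#' The ancestral population is initialized at the neutral stationary
#' frequency spectrum (allele-count classes with weight 1/i), after which
#' each population evolves by per-generation binomial resampling of allele
#' frequencies with infinite-sites mutation influx at rate \eqn{\mu} per bp.
#' An optional hard sweep introduces a beneficial allele (selection
#' coefficient s, update \eqn{p' = p(1+s)/(1+ps)} plus drift) in the test
#' population, conditioned on fixation at sampling time by restart.
#' Hitchhiking is mechanistic: each neutral site's allele frequency is
#' tracked separately on the beneficial and wild-type backgrounds, with
#' recombination (rate `recomb_rate` per bp) exchanging alleles between
#' backgrounds and drift acting within each background.
#'
#' @param params a [sim_params()]
#' @return `list(g = genotype_matrix, truth = sim_truth)`; when a sweep is
#'   simulated, `truth$sweep_interval` is the 0-based half-open interval
#'   `pos +/- s / (2 r ln 2N)` (the physical scale over which recombination
#'   fails to break linkage during the sweep), clipped to the chromosome.
#' @export
simulate_wright_fisher <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  N <- params$pop_size_N
  if (N < 2L) stop("pop_size_N must be >= 2")
  if (params$split_gen < 0L) stop("split_gen must be >= 0")
  set.seed(params$seed)
  twoN <- 2L * N
  K <- params$n_pops
  L <- params$chrom_length
  mu <- params$mutation_rate
  T_split <- params$split_gen

  ## stationary standing variation shared by all populations at the split
  theta_L <- 4 * N * mu * L
  wts <- 1 / seq_len(twoN - 1L)
  S0 <- rpois(1L, theta_L * sum(wts))
  S0 <- min(S0, L - 1)
  pos1 <- sort(sample.int(L, S0))
  cls <- sample.int(twoN - 1L, S0, replace = TRUE, prob = wts)
  p0 <- cls / twoN
  freq <- matrix(rep(p0, each = K), nrow = K)
  anc <- p0

  sweep <- params$sweep
  G_s <- 0L
  traj <- NULL
  if (!is.null(sweep)) {
    max_gen <- T_split
    traj <- sweep_trajectory(twoN, sweep$s, max_gen, params$restart_budget)
    G_s <- length(traj) - 1L
  }

  # one batch of new mutations for all populations: positions + a K x M
  # frequency block with one founding copy in the originating population
  influx_batch <- function(m_per_pop) {
    M <- sum(m_per_pop)
    if (M == 0L) return(NULL)
    nf <- matrix(0, nrow = K, ncol = M)
    origin <- rep(seq_len(K), m_per_pop)
    nf[cbind(origin, seq_len(M))] <- 1 / twoN
    list(pos = sample.int(L, M), freq = nf, origin = origin)
  }
  add_sites <- function(p_new, f_new) {
    pos1 <<- c(pos1, p_new)
    freq <<- cbind(freq, f_new)
    anc <<- c(anc, rep(0, length(p_new)))
  }
  clean <- function() {
    cs <- colSums(freq)
    live <- (cs > 0 & cs < K) | colSums(freq > 0 & freq < 1) > 0
    pos1 <<- pos1[live]; freq <<- freq[, live, drop = FALSE]
    anc <<- anc[live]
  }

  lambda_new <- 2 * N * mu * L
  neutral_gens <- T_split - G_s
  for (gen in seq_len(neutral_gens)) {
    freq <- matrix(rbinom(length(freq), twoN, freq), nrow = K) / twoN
    nw <- influx_batch(rpois(K, lambda_new))
    if (!is.null(nw)) add_sites(nw$pos, nw$freq)
    clean()
  }

  truth_interval <- NULL
  if (!is.null(sweep)) {
    kt <- sweep$test_pop
    spos1 <- floor(sweep$pos) + 1L
    q <- freq[kt, ]
    B <- rbinom(length(q), 1L, q)
    qB <- as.numeric(B)
    qw <- (twoN * q - B) / (twoN - 1L)
    qw <- pmin(pmax(qw, 0), 1)
    rvec <- pmin(0.5, params$recomb_rate * abs(pos1 - spos1))
    others <- setdiff(seq_len(K), kt)
    for (gstep in seq_len(G_s)) {
      pB0 <- traj[gstep]; pB1 <- traj[gstep + 1L]
      ## recombination between backgrounds, then drift within backgrounds
      qB_n <- qB + rvec * (1 - pB0) * (qw - qB)
      qw_n <- qw + rvec * pB0 * (qB - qw)
      nB <- round(twoN * pB1); nW <- twoN - nB
      qB <- if (nB > 0L) rbinom(length(qB_n), nB, qB_n) / nB else qB_n
      qw <- if (nW > 0L) rbinom(length(qw_n), nW, qw_n) / nW else qw_n
      ## other populations keep drifting neutrally
      if (length(others))
        freq[others, ] <- matrix(
          rbinom(length(others) * ncol(freq), twoN,
                 freq[others, , drop = FALSE]),
          nrow = length(others)) / twoN
      ## mutation influx; test-pop mutants land on a background
      nw <- influx_batch(rpois(K, lambda_new))
      if (!is.null(nw)) {
        is_test <- nw$origin == kt
        onB <- is_test & rbinom(length(nw$origin), 1L, pB1) == 1L
        fB <- ifelse(onB & nB > 0L, 1 / max(nB, 1L), 0)
        fw <- ifelse(is_test & !onB & nW > 0L, 1 / max(nW, 1L), 0)
        nw$freq[kt, ] <- 0
        qB <- c(qB, fB); qw <- c(qw, fw)
        add_sites(nw$pos, nw$freq)
        rvec <- c(rvec, pmin(0.5, params$recomb_rate * abs(nw$pos - spos1)))
      }
      freq[kt, ] <- pB1 * qB + (1 - pB1) * qw
      if (gstep < G_s) {  # drop globally lost/fixed sites, keep alignment
        cs <- colSums(freq)
        live <- (cs > 0 & cs < K) | colSums(freq > 0 & freq < 1) > 0
        if (!all(live)) {
          pos1 <- pos1[live]; freq <- freq[, live, drop = FALSE]
          anc <- anc[live]; qB <- qB[live]; qw <- qw[live]
          rvec <- rvec[live]
        }
      }
    }
    freq[kt, ] <- qB  # beneficial background fixed
    ## the beneficial site itself: fixed difference test vs others
    pos1 <- c(pos1, spos1)
    bcol <- rep(0, K); bcol[kt] <- 1
    freq <- cbind(freq, bcol)
    anc <- c(anc, 0)
    half <- sweep$s / (2 * params$recomb_rate * log(twoN))
    truth_interval <- c(max(0, sweep$pos - half),
                        min(L, sweep$pos + half))
  }

  ## deduplicate colliding positions (rare), keep first occurrence
  dup <- duplicated(pos1)
  if (any(dup)) {
    pos1 <- pos1[!dup]; freq <- freq[, !dup, drop = FALSE]; anc <- anc[!dup]
  }
  keep_pos <- if (!is.null(sweep)) floor(sweep$pos) + 1L else integer(0)
  res <- sample_genotypes(freq, pos1, params, keep_pos1 = keep_pos)
  truth <- structure(list(sweep_interval = truth_interval,
                          fst_target = NA_real_, seed = params$seed,
                          anc_freq = anc[res$kept], params = params),
                     class = "sim_truth")
  list(g = res$g, truth = truth)
}

#' Default conditions for the end-to-end sweep-recovery experiment
#'
#' Three populations (one test, two references) split 150 generations ago
#' at diploid size 200, a 5 Mb chromosome at \eqn{\theta = 4N\mu = 10^{-3}}
#' per bp, recombination \eqn{10^{-7}} per bp, and one hard sweep
#' (s = 0.1) completing at sampling time in the middle of the test
#' population's chromosome.  Scanned with 5 kb windows stepping 2.5 kb
#' (2,000 windows) at the 0.5\% empirical tails, this reproduces the
#' study design at desk scale.
#'
#' @param seed integer seed
#' @return a [sim_params()]
#' @export
sweep_study_params <- function(seed) {
  sim_params(n_pops = 3L, samples_per_pop = 25L, chrom_length = 5e6,
             pop_size_N = 200L, mutation_rate = 1.25e-6,
             recomb_rate = 1e-7, split_gen = 150L,
             sweep = list(pos = 2.5e6, s = 0.1, test_pop = 1L),
             seed = seed)
}

#' @rdname sweep_study_params
#' @export
sweep_study_scan_config <- function() {
  scan_config(window_size = 5000, step = 2500, tail_fraction = 0.005,
              min_snps_per_window = 10)
}

#' Tile toy gene models over a chromosome
#'
#' Protein-coding genes of `gene_span` bp separated by `gene_gap` bp;
#' when a sweep interval is given, one extra gene (`SWEEPGENE`) covering
#' it exactly is added.
#'
#' @param chrom_length chromosome length (bp)
#' @param sweep_interval optional 0-based half-open `(start, end)`
#' @param gene_span,gene_gap tiling geometry in bp
#' @param chrom chromosome name
#' @return data.frame as from [read_gff3()] (1-based inclusive)
#' @export
tile_genes <- function(chrom_length, sweep_interval = NULL,
                       gene_span = 5e4, gene_gap = 5e4, chrom = "1") {
  starts <- seq(1, chrom_length - gene_span, by = gene_span + gene_gap)
  genes <- data.frame(chrom = chrom, start = starts,
                      end = pmin(starts + gene_span - 1, chrom_length),
                      stringsAsFactors = FALSE)
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  if (!is.null(sweep_interval))
    genes <- rbind(genes, data.frame(
      chrom = chrom, start = floor(sweep_interval[1]) + 1,
      end = ceiling(sweep_interval[2]), gene_id = "SWEEPGENE"))
  genes <- genes[order(genes$start), ]
  genes$gene_name <- genes$gene_id
  genes$biotype <- "protein_coding"
  rownames(genes) <- NULL
  genes[, c("gene_id", "gene_name", "biotype", "chrom", "start", "end")]
}

#' Write a simulated dataset to disk as standard files
#'
#' Emits a VCF 4.2 (diploid GT, one ALT per record), a sample->population
#' map TSV, a toy GFF3 with protein-coding genes tiled over the chromosome
#' (plus, when a sweep was planted, one gene covering the truth sweep
#' interval) and a truth JSON.
#'
#' @param g a `genotype_matrix`
#' @param truth a `sim_truth` from the simulators
#' @param out_dir output directory (created if needed)
#' @param gene_span,gene_gap bp length of each tiled gene and gap between
#'   consecutive genes
#' @return named character vector of written paths
#'   (`vcf`, `pop_map`, `gff3`, `truth`)
#' @export
emit_fixture <- function(g, truth, out_dir, gene_span = 5e4, gene_gap = 5e4) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  L <- truth$params$chrom_length
  vcf <- file.path(out_dir, "sim.vcf")
  map <- file.path(out_dir, "pop_map.tsv")
  gff <- file.path(out_dir, "genes.gff3")
  tj <- file.path(out_dir, "truth.json")

  write_vcf(g, vcf, contig_lengths = c(`1` = L))
  write.table(data.frame(sample = g$samples, population = unname(g$pop)),
              map, sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- tile_genes(L, truth$sweep_interval, gene_span, gene_gap)
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region 1 1 %d", as.integer(L)), con)
  writeLines(sprintf(
    "1\tsweepscan\tgene\t%d\t%d\t.\t+\t.\tID=gene:%s;Name=%s;biotype=protein_coding",
    as.integer(genes$start), as.integer(genes$end),
    genes$gene_id, genes$gene_id), con)
  close(con)

  jsonlite::write_json(
    list(sweep_interval = truth$sweep_interval,
         fst_target = truth$fst_target, seed = truth$seed,
         chrom_length = L, anc_freq = truth$anc_freq),
    tj, auto_unbox = TRUE, digits = NA, null = "null")
  c(vcf = vcf, pop_map = map, gff3 = gff, truth = tj)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param g a `genotype_matrix`
#' @param path output path
#' @param contig_lengths optional named vector of contig lengths for the
#'   header
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=sweepscan", con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), as.integer(contig_lengths)),
               con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(g$geno), ncol = ncol(g$geno))
  ok <- !is.na(g$geno)
  gt[ok] <- gt_code[g$geno[ok] + 1L]
  lines <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                 ".", "PASS", ".", "GT", sep = "\t")
  body <- apply(gt, 2L, paste, collapse = "\t")
  writeLines(paste(lines, body, sep = "\t"), con)
  invisible(path)
}
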