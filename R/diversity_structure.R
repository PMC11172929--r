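#' ROH detection parameters
#'
#' PLINK-style defaults: 50-SNP scanning windows tolerating at most 1
#' heterozygote and 2 missing calls, a SNP enters the homozygous state when
#' more than 5\% of the windows covering it are eligible, and called
#' segments must span at least 50 SNPs, 500 kb, and 1 SNP per 50 kb.
#'
#' @param window_snps scanning window size in SNPs
#' @param max_het,max_missing tolerated heterozygous / missing calls per
#'   window
#' @param hit_fraction minimum fraction of eligible covering windows
#' @param min_snps,min_length_bp,max_gap_density_bp segment filters
#'   (`max_gap_density_bp`: at least one SNP per this many bp)
#' @return list of class `roh_params`
#' @export
roh_params <- function(window_snps = 50L, max_het = 1L, max_missing = 2L,
                       hit_fraction = 0.05, min_snps = 50L,
                       min_length_bp = 5e5, max_gap_density_bp = 5e4) {
  structure(list(window_snps = as.integer(window_snps),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 hit_fraction = hit_fraction,
                 min_snps = as.integer(min_snps),
                 min_length_bp = min_length_bp,
                 max_gap_density_bp = max_gap_density_bp),
            class = "roh_params")
}

roh_size_class <- function(len_bp) {
  cut(len_bp, breaks = c(5e5, 1e6, 2e6, Inf),
      labels = c("0.5-1Mb", "1-2Mb", ">2Mb"),
      right = FALSE, include.lowest = TRUE)
}

#' Detect runs of homozygosity for one sample
#'
#' Sliding-SNP-window scan: windows of `window_snps` consecutive SNPs are
#' eligible when they contain at most `max_het` heterozygous and
#' `max_missing` missing calls; a SNP enters the homozygous state when the
#' fraction of eligible windows covering it exceeds `hit_fraction`.  Runs
#' of state SNPs are then expanded to the maximal surrounding stretch free
#' of heterozygous calls (so that a fully homozygous tract is recovered to
#' its first/last homozygous SNP), merged, and filtered by
#' `min_snps` / `min_length_bp` / SNP density.  Chromosomes with fewer SNPs
#' than one window are skipped.
#'
#' @param g a [genotype_matrix()]
#' @param sample sample ID
#' @param params a [roh_params()]
#' @return data.frame with `sample`, `chrom`, `start`, `end` (bp of first
#'   and last SNP, 1-based), `n_snps`, `length_bp`, `size_class`
#' @export
detect_roh <- function(g, sample, params = roh_params()) {
  stopifnot(sample %in% g$samples)
  geno <- g$geno[sample, ]
  out <- list()
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    S <- length(idx)
    W <- params$window_snps
    if (S < W) next
    het <- as.integer(!is.na(geno[idx]) & geno[idx] == 1L)
    mis <- as.integer(is.na(geno[idx]))
    cs_h <- c(0L, cumsum(het)); cs_m <- c(0L, cumsum(mis))
    n_win <- S - W + 1L
    wh <- cs_h[(W + 1L):(S + 1L)] - cs_h[1:n_win]
    wm <- cs_m[(W + 1L):(S + 1L)] - cs_m[1:n_win]
    elig <- as.integer(wh <= params$max_het & wm <= params$max_missing)
    ## per-SNP: eligible / covering window counts
    cs_e <- c(0L, cumsum(elig))
    snp_i <- seq_len(S)
    first_w <- pmax(1L, snp_i - W + 1L)
    last_w <- pmin(n_win, snp_i)
    cover <- pmax(last_w - first_w + 1L, 0L)
    e_cnt <- cs_e[pmax(last_w, first_w - 1L) + 1L] - cs_e[first_w]
    state <- cover > 0L & e_cnt / pmax(cover, 1L) > params$hit_fraction
    if (!any(state)) next
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    ## expand each run over the surrounding het-free stretch
    blocked <- het == 1L
    br <- rle(blocked)
    bend <- cumsum(br$lengths); bstart <- bend - br$lengths + 1L
    block_id <- rep(seq_along(br$lengths), br$lengths)
    expand <- function(i0, i1) {
      lo <- if (blocked[i0]) i0 else bstart[block_id[i0]]
      hi <- if (blocked[i1]) i1 else bend[block_id[i1]]
      c(lo, hi)
    }
    ex <- t(apply(runs, 1L, function(rr) expand(rr[1], rr[2])))
    ## merge overlapping expanded runs
    ord <- order(ex[, 1])
    ex <- ex[ord, , drop = FALSE]
    merged <- list(ex[1, ])
    if (nrow(ex) > 1) for (i in 2:nrow(ex)) {
      last <- merged[[length(merged)]]
      if (ex[i, 1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], ex[i, 2]))
      else merged[[length(merged) + 1L]] <- ex[i, ]
    }
    pos <- g$sites$pos[idx]
    for (m in merged) {
      n_snp <- m[2] - m[1] + 1L
      len <- pos[m[2]] - pos[m[1]] + 1L
      if (n_snp < params$min_snps) next
      if (len < params$min_length_bp) next
      if (len / n_snp > params$max_gap_density_bp) next
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, chrom = ch, start = pos[m[1]], end = pos[m[2]],
        n_snps = n_snp, length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length_bp = integer(0),
                      size_class = factor(character(0),
                                          levels = c("0.5-1Mb", "1-2Mb",
                                                     ">2Mb"))))
  res <- do.call(rbind, out)
  res$size_class <- roh_size_class(res$length_bp)
  rownames(res) <- NULL
  res
}

#' Summarize ROH segments per sample and population
#'
#' @param segments data.frame from [detect_roh()] (possibly rbind-ed over
#'   samples)
#' @param populations named character vector sample -> population (e.g.
#'   `g$pop`); when supplied, per-population means are returned as well
#' @return list with `per_sample` (counts per size class + total length per
#'   sample) and `per_population` (mean counts per class and mean total
#'   length; `NULL` when `populations` is missing)
#' @export
summarize_roh <- function(segments, populations = NULL) {
  classes <- c("0.5-1Mb", "1-2Mb", ">2Mb")
  samples <- unique(segments$sample)
  if (!is.null(populations)) samples <- union(samples, names(populations))
  per_sample <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (cl in classes)
    per_sample[[cl]] <- vapply(samples, function(s)
      sum(segments$sample == s & segments$size_class == cl), integer(1))
  per_sample$total_bp <- vapply(samples, function(s)
    sum(segments$length_bp[segments$sample == s]), numeric(1))
  rownames(per_sample) <- NULL
  per_population <- NULL
  if (!is.null(populations)) {
    per_sample$population <- unname(populations[per_sample$sample])
    agg <- aggregate(per_sample[, c(classes, "total_bp")],
                     by = list(population = per_sample$population), mean)
    per_population <- agg
  }
  list(per_sample = per_sample, per_population = per_population)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages over jointly-called
#' samples (the unphased composite measure).
#'
#' @param geno_i,geno_j dosage vectors (0/1/2, `NA` = missing)
#' @return r^2 in [0,1]; `NA` when either site has zero variance or fewer
#'   than 2 jointly-called samples
#' @export
ld_r2 <- function(geno_i, geno_j) {
  ok <- !is.na(geno_i) & !is.na(geno_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- geno_i[ok]; y <- geno_j[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# r^2 of one site against a block of sites, pairwise-complete, vectorized.
# Returns NA where a pair has < 2 joint calls or zero variance.
r2_block <- function(x, M) {
  vx <- !is.na(x)
  x0 <- ifelse(vx, x, 0)
  M0 <- M; M0[is.na(M0)] <- 0
  V <- (!is.na(M)) & vx              # joint-call indicator, recycled by col
  n <- colSums(V)
  sx <- colSums(x0 * V)
  sxx <- colSums(x0^2 * V)
  sy <- colSums(M0 * vx)
  syy <- colSums(M0^2 * vx)
  sxy <- colSums(M0 * x0)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  out <- ifelse(n >= 2 & den > 0, num^2 / den, NA_real_)
  unname(out)
}

#' LD decay curve
#'
#' Mean r^2 of all intra-chromosomal site pairs within `max_dist`, binned by
#' physical distance.
#'
#' @param g a [genotype_matrix()] (apply the MAF filter first)
#' @param population population label(s); samples restricted accordingly
#' @param max_dist maximum pair distance in bp
#' @param bin_width distance bin width in bp
#' @return data.frame `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs` (empty
#'   bins keep `n_pairs = 0`, `mean_r2 = NA`)
#' @export
ld_decay <- function(g, population, max_dist = 5e5, bin_width = 1e3) {
  rows <- pop_rows(g, population)
  sub <- g$geno[rows, , drop = FALSE]
  n_bins <- ceiling(max_dist / bin_width)
  sum_r2 <- numeric(n_bins)
  n_pair <- integer(n_bins)
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[idx]
    S <- length(idx)
    if (S < 2) next
    X <- sub[, idx, drop = FALSE]
    for (i in seq_len(S - 1L)) {
      jmax <- findInterval(pos[i] + max_dist, pos)
      if (jmax <= i) next
      js <- (i + 1L):jmax
      d <- pos[js] - pos[i]
      r2 <- r2_block(X[, i], X[, js, drop = FALSE])
      ok <- !is.na(r2)
      if (!any(ok)) next
      b <- pmax(pmin(ceiling(d[ok] / bin_width), n_bins), 1L)
      agg_s <- tapply(r2[ok], b, sum)
      agg_n <- tapply(r2[ok], b, length)
      bi <- as.integer(names(agg_s))
      sum_r2[bi] <- sum_r2[bi] + as.numeric(agg_s)
      n_pair[bi] <- n_pair[bi] + as.integer(agg_n)
    }
  }
  data.frame(dist_lo = (seq_len(n_bins) - 1L) * bin_width,
             dist_hi = seq_len(n_bins) * bin_width,
             mean_r2 = ifelse(n_pair > 0, sum_r2 / pmax(n_pair, 1L),
                              NA_real_),
             n_pairs = n_pair)
}

#' Greedy pairwise LD pruning
#'
#' The `--indep-pairwise`-style greedy scan: proceeding left to right, any
#' pair of surviving sites lying within `window_snps` consecutive surviving
#' SNPs with r^2 above `r2_max` has its later site dropped; passes repeat
#' until stable.  Every window offset is examined, so on output no
#' surviving pair within any window of `window_snps` consecutive surviving
#' SNPs exceeds `r2_max`.  Deterministic given the input order.
#'
#' @param g a [genotype_matrix()] or a dosage matrix (samples x sites)
#' @param window_snps,r2_max scan parameters (PLINK-convention defaults
#'   50, 0.2)
#' @param step_snps accepted for interface compatibility with the
#'   `50 10 0.2` convention; the scan examines every offset, which is
#'   strictly stronger than stepping
#' @return integer vector of kept site indices (increasing)
#' @export
ld_prune <- function(g, window_snps = 50L, step_snps = 10L, r2_max = 0.2) {
  X <- if (inherits(g, "genotype_matrix")) g$geno else as.matrix(g)
  S <- ncol(X)
  kept <- seq_len(S)
  repeat {
    dropped_any <- FALSE
    alive <- rep(TRUE, length(kept))
    len <- length(kept)
    if (len < 2) break
    for (ii in seq_len(len - 1L)) {
      if (!alive[ii]) next
      jmax <- min(ii + window_snps - 1L, len)
      if (jmax <= ii) next
      jj <- (ii + 1L):jmax
      jj <- jj[alive[jj]]
      if (!length(jj)) next
      r2 <- r2_block(X[, kept[ii]], X[, kept[jj], drop = FALSE])
      bad <- !is.na(r2) & r2 > r2_max
      if (any(bad)) {
        alive[jj[bad]] <- FALSE
        dropped_any <- TRUE
      }
    }
    kept <- kept[alive]
    if (!dropped_any) break
  }
  kept
}

#' Genotype principal component analysis
#'
#' Sites are mean-imputed, centered by \eqn{2\hat p} and scaled by
#' \eqn{\sqrt{2\hat p(1-\hat p)}} (the Patterson convention), then
#' decomposed by [stats::prcomp()].  Monomorphic sites are dropped.
#'
#' @param g a [genotype_matrix()] (prune and filter first)
#' @param n_components number of components to report
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `percent_var` (per component, non-increasing), `populations`
#' @export
pca_genotypes <- function(g, n_components = 10L) {
  if (n_samples(g) < 2) stop("need at least 2 samples for PCA")
  X <- g$geno
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  X <- X[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  for (j in seq_len(ncol(X))) {
    mis <- is.na(X[, j])
    if (any(mis)) X[mis, j] <- 2 * p_hat[j]
  }
  Xs <- sweep(X, 2L, 2 * p_hat, "-")
  Xs <- sweep(Xs, 2L, sqrt(2 * p_hat * (1 - p_hat)), "/")
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 percent_var = pct[seq_len(k)],
                 populations = g$pop),
            class = "pca_result")
}

#' Identity-by-state distance matrix
#'
#' Distance = 1 - IBS, IBS being the mean over jointly-called sites of
#' \eqn{(2 - |d_i - d_j|)/2} for dosages d.  At `level = "population"`,
#' entries are averages of 1 - IBS over cross-population sample pairs.
#'
#' @param g a [genotype_matrix()]
#' @param level `"sample"` or `"population"`
#' @return symmetric matrix with zero diagonal
#' @export
ibs_distance_matrix <- function(g, level = c("sample", "population")) {
  level <- match.arg(level)
  X <- g$geno
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (!any(ok))
      stop("samples ", g$samples[i], " and ", g$samples[j],
           " share no called sites")
    d <- 1 - mean((2 - abs(X[i, ok] - X[j, ok])) / 2)
    D[i, j] <- D[j, i] <- d
  }
  if (level == "sample") return(D)
  pops <- populations_of(g)
  P <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)) for (b in seq_len(a - 1L)) {
    ra <- pop_rows(g, pops[a]); rb <- pop_rows(g, pops[b])
    P[a, b] <- P[b, a] <- mean(D[ra, rb])
  }
  P
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero with a warning; the unrooted tree is serialized with a
#' trifurcating root in newick format.
#'
#' @param d symmetric numeric matrix with zero diagonal, >= 3 taxa
#' @return list with `tree` (an `ape::phylo`) and `newick` (character)
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  list(tree = tr, newick = ape::write.tree(tr))
}
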