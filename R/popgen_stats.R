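#' Sliding-window scan configuration
#'
#' Defaults are the standard livestock-WGS scan settings: 100 kb windows
#' sliding by 50 kb, empirical 0.5\% tails, and at least 10 SNPs per window
#' for a window to enter the Z-score distributions.
#'
#' @param window_size window size in bp
#' @param step step between window starts in bp; must satisfy
#'   `0 < step <= window_size`
#' @param tail_fraction empirical tail fraction q in (0, 0.5)
#' @param min_snps_per_window windows with fewer SNPs are flagged and their
#'   statistics set to `NA`
#' @param ratio_tail which tail of \eqn{\ln(\pi_{test}/\pi_{ref})} marks
#'   candidate sweeps: `"lower"` (diversity trough in the test population,
#'   default) or `"upper"`
#' @param fst_mode `"weighted"` (ratio of summed variance components,
#'   default) or `"mean"` (mean of per-site ratios)
#' @return list of class `scan_config`
#' @export
scan_config <- function(window_size = 100000, step = 50000,
                        tail_fraction = 0.005, min_snps_per_window = 10,
                        ratio_tail = "lower", fst_mode = "weighted") {
  if (step <= 0 || step > window_size)
    stop("step must satisfy 0 < step <= window_size")
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must lie in (0, 0.5)")
  if (!ratio_tail %in% c("lower", "upper"))
    stop("ratio_tail must be 'lower' or 'upper'")
  if (!fst_mode %in% c("weighted", "mean"))
    stop("fst_mode must be 'weighted' or 'mean'")
  structure(list(window_size = window_size, step = step,
                 tail_fraction = tail_fraction,
                 min_snps_per_window = min_snps_per_window,
                 ratio_tail = ratio_tail, fst_mode = fst_mode),
            class = "scan_config")
}

#' Tile sliding windows over chromosomes
#'
#' Window starts run 0, step, 2*step, ... while start < chromosome length;
#' each window ends at `min(start + window_size, chrom_length)` (0-based
#' half-open coordinates), so trailing windows may be partial; their `span`
#' column flags them.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @param cfg a [scan_config()]
#' @return data.frame with columns `chrom`, `start`, `end`, `span`
#' @export
make_windows <- function(chrom_lengths, cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = cfg$step)
    ends <- pmin(starts + cfg$window_size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               span = ends - starts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

as_window <- function(w) {
  if (is.data.frame(w)) w <- as.list(w[1, ])
  stopifnot(!is.null(w$chrom), !is.null(w$start), !is.null(w$end),
            w$start < w$end)
  w
}

# Index range of sites (1-based, sorted positions pos0 = pos - 1) falling in
# the 0-based half-open interval [start, end).  Returns c(lo, hi); empty
# windows have hi < lo.
site_range <- function(pos0, start, end) {
  c(findInterval(start - 0.5, pos0) + 1L, findInterval(end - 0.5, pos0))
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference at one site: with `a` alt alleles among `n`
#' called haplotypes, \eqn{\pi = a (n - a) / \binom{n}{2}}.
#'
#' @param alt_count alt-allele count(s)
#' @param called_haplotypes number(s) of called haplotypes
#' @return numeric; `NA` where fewer than 2 haplotypes are called
#' @examples
#' site_pi(2, 4)  # 4/6
#' @export
site_pi <- function(alt_count, called_haplotypes) {
  if (any(alt_count < 0 | alt_count > called_haplotypes, na.rm = TRUE))
    stop("alt_count must lie in [0, called_haplotypes]")
  n <- called_haplotypes
  ifelse(n >= 2, alt_count * (n - alt_count) / (n * (n - 1) / 2), NA_real_)
}

# per-site pi vector for a set of rows; sites with < 2 called haplotypes
# contribute 0 to window sums
site_pi_vector <- function(g, rows) {
  sc <- site_counts(g, rows)
  pi <- site_pi(sc$alt, sc$n_hap)
  pi[is.na(pi)] <- 0
  pi
}

#' Windowed nucleotide diversity (per bp)
#'
#' Sum of per-site \eqn{\pi} over in-window SNPs of the population, divided
#' by the window span; invariant positions contribute only through the
#' denominator.
#'
#' @param g a [genotype_matrix()]
#' @param w window: list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open)
#' @param population population label(s); multiple labels are pooled
#' @return per-bp diversity (0 when the window holds no SNPs)
#' @export
window_pi <- function(g, w, population) {
  w <- as_window(w)
  rows <- pop_rows(g, population)
  on_chrom <- g$sites$chrom == w$chrom
  pos0 <- g$sites$pos[on_chrom] - 1
  rg <- site_range(pos0, w$start, w$end)
  if (rg[2] < rg[1]) return(0)
  idx <- which(on_chrom)[rg[1]:rg[2]]
  sc <- site_counts(g, rows)
  pi <- site_pi(sc$alt[idx], sc$n_hap[idx])
  sum(pi, na.rm = TRUE) / (w$end - w$start)
}

#' Weir-Cockerham (1984) per-site variance components, two populations
#'
#' Returns the among-population (a), among-individual-within-population (b)
#' and within-individual (c) components from per-population sample sizes
#' (called diploids), alt-allele frequencies and observed heterozygosity
#' fractions.  \eqn{\theta = a / (a + b + c)}; the weighted multi-site
#' estimator is the ratio of component sums.  All arguments vectorize over
#' sites.
#'
#' @param n1,n2 called diploid counts per population
#' @param p1,p2 alt-allele frequencies
#' @param h1,h2 observed heterozygote fractions
#' @return data.frame with columns `a`, `b`, `c` (`NA` rows where a
#'   population has no called genotypes or both have a single one)
#' @examples
#' wc_fst_site(10, 1, 0, 10, 0, 0)  # fixed difference: a=0.5, b=c=0
#' @export
wc_fst_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

# WC components for two sample-row sets over all sites
wc_components <- function(g, rows1, rows2) {
  s1 <- site_counts(g, rows1)
  s2 <- site_counts(g, rows2)
  p1 <- ifelse(s1$n_hap > 0, s1$alt / s1$n_hap, NA_real_)
  p2 <- ifelse(s2$n_hap > 0, s2$alt / s2$n_hap, NA_real_)
  h1 <- ifelse(s1$n_dip > 0, s1$het / s1$n_dip, NA_real_)
  h2 <- ifelse(s2$n_dip > 0, s2$het / s2$n_dip, NA_real_)
  wc_fst_site(s1$n_dip, p1, h1, s2$n_dip, p2, h2)
}

#' Windowed Weir-Cockerham F_ST
#'
#' The weighted (ratio-of-sums) estimator
#' \eqn{\sum a / \sum (a + b + c)} over in-window sites; negative values are
#' retained (clamping would bias the empirical null used for Z-scores).
#' `mode = "mean"` instead averages per-site ratios.
#'
#' @param g a [genotype_matrix()]
#' @param w window (list or one-row data.frame, 0-based half-open)
#' @param pop_test,pop_ref population label(s); multiple labels are pooled
#' @param mode `"weighted"` or `"mean"`
#' @return F_ST estimate; `NA` when no usable site or zero denominator
#' @export
windowed_fst <- function(g, w, pop_test, pop_ref, mode = "weighted") {
  w <- as_window(w)
  on_chrom <- g$sites$chrom == w$chrom
  pos0 <- g$sites$pos[on_chrom] - 1
  rg <- site_range(pos0, w$start, w$end)
  if (rg[2] < rg[1]) return(NA_real_)
  idx <- which(on_chrom)[rg[1]:rg[2]]
  comp <- wc_components(g, pop_rows(g, pop_test), pop_rows(g, pop_ref))
  fst_from_components(comp$a[idx], comp$b[idx], comp$c[idx], mode)
}

fst_from_components <- function(a, b, cc, mode = "weighted") {
  ok <- !is.na(a)
  if (!any(ok)) return(NA_real_)
  if (mode == "weighted") {
    den <- sum(a[ok] + b[ok] + cc[ok])
    if (den == 0) return(NA_real_)
    sum(a[ok]) / den
  } else {
    den <- a + b + cc
    use <- ok & den != 0
    if (!any(use)) return(NA_real_)
    mean(a[use] / den[use])
  }
}

#' Genome-wide pairwise F_ST matrix
#'
#' For every unordered pair of populations, the genome-wide mean of windowed
#' weighted Weir-Cockerham F_ST.
#'
#' @param g a [genotype_matrix()]
#' @param populations labels to include (default: all in `g`)
#' @param cfg a [scan_config()]
#' @param chrom_lengths optional named lengths; defaults to the maximum
#'   observed position per chromosome
#' @return symmetric numeric matrix with `NA` diagonal; pairs involving a
#'   population with fewer than 2 samples are skipped with a warning
#' @export
pairwise_fst_matrix <- function(g, populations = NULL, cfg = scan_config(),
                                chrom_lengths = NULL) {
  if (is.null(populations)) populations <- populations_of(g)
  if (length(populations) < 2) stop("need at least 2 populations")
  if (is.null(chrom_lengths)) chrom_lengths <- chrom_lengths_of(g)
  wins <- make_windows(chrom_lengths, cfg)
  m <- matrix(NA_real_, length(populations), length(populations),
              dimnames = list(populations, populations))
  for (i in seq_along(populations)) for (j in seq_len(i - 1L)) {
    pi_ <- populations[i]; pj <- populations[j]
    if (length(pop_rows(g, pi_)) < 2 || length(pop_rows(g, pj)) < 2) {
      warning("population with < 2 samples; skipping pair ", pi_, "-", pj)
      next
    }
    comp <- wc_components(g, pop_rows(g, pi_), pop_rows(g, pj))
    vals <- window_apply(g, wins, function(idx)
      fst_from_components(comp$a[idx], comp$b[idx], comp$c[idx], cfg$fst_mode))
    m[i, j] <- m[j, i] <- mean(vals, na.rm = TRUE)
  }
  m
}

chrom_lengths_of <- function(g) {
  tapply(g$sites$pos, g$sites$chrom, max)
}

# apply f(site_index_vector) over windows; returns numeric vector
window_apply <- function(g, wins, f) {
  out <- rep(NA_real_, nrow(wins))
  for (ch in unique(wins$chrom)) {
    on_chrom <- which(g$sites$chrom == ch)
    pos0 <- g$sites$pos[on_chrom] - 1
    wi <- which(wins$chrom == ch)
    lo <- findInterval(wins$start[wi] - 0.5, pos0) + 1L
    hi <- findInterval(wins$end[wi] - 0.5, pos0)
    for (k in seq_along(wi)) {
      if (hi[k] < lo[k]) next
      out[wi[k]] <- f(on_chrom[lo[k]:hi[k]])
    }
  }
  out
}

#' Windowed pooled heterozygosity (Hp)
#'
#' \deqn{Hp = 2 \Sigma n_{MAJ} \Sigma n_{MIN} /
#'   (\Sigma n_{MAJ} + \Sigma n_{MIN})^2}
#' with per-site major/minor allele counts in the population summed over
#' in-window SNPs.  Bounded in [0, 0.5]; depressed in swept regions.
#'
#' @param g a [genotype_matrix()]
#' @param w window (0-based half-open)
#' @param population population label(s)
#' @return Hp; `NA` when the window has no called SNPs
#' @export
hp_window <- function(g, w, population) {
  w <- as_window(w)
  on_chrom <- g$sites$chrom == w$chrom
  pos0 <- g$sites$pos[on_chrom] - 1
  rg <- site_range(pos0, w$start, w$end)
  if (rg[2] < rg[1]) return(NA_real_)
  idx <- which(on_chrom)[rg[1]:rg[2]]
  sc <- site_counts(g, pop_rows(g, population))
  hp_from_counts(sum(pmax(sc$alt, sc$n_hap - sc$alt)[idx]),
                 sum(pmin(sc$alt, sc$n_hap - sc$alt)[idx]))
}

hp_from_counts <- function(sum_maj, sum_min) {
  tot <- sum_maj + sum_min
  if (tot == 0) return(NA_real_)
  2 * sum_maj * sum_min / tot^2
}

#' Tajima's D constants
#'
#' The standard normalization constants for `n` haplotypes:
#' \eqn{a_1 = \sum_{i<n} 1/i}, \eqn{a_2 = \sum_{i<n} 1/i^2},
#' \eqn{b_1, b_2, c_1, c_2, e_1, e_2} as in the original derivation.
#'
#' @param n number of haplotypes (>= 4)
#' @return named list `a1, a2, b1, b2, c1, c2, e1, e2`
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' \deqn{D = (\pi_{sum} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}
#' where S counts sites segregating in the population within the window and
#' \eqn{\pi_{sum}} is the un-normalized pairwise-difference sum.  With
#' missing data the per-site called haplotype count varies; the constants
#' use `n = round(mean(called haplotypes at segregating sites))`.
#'
#' @param g a [genotype_matrix()]
#' @param w window (0-based half-open)
#' @param population population label(s)
#' @return D; `NA` (flagged) when S < 2, n < 4 or the variance term is 0
#' @export
tajimas_d <- function(g, w, population) {
  w <- as_window(w)
  on_chrom <- g$sites$chrom == w$chrom
  pos0 <- g$sites$pos[on_chrom] - 1
  rg <- site_range(pos0, w$start, w$end)
  if (rg[2] < rg[1]) return(NA_real_)
  idx <- which(on_chrom)[rg[1]:rg[2]]
  sc <- site_counts(g, pop_rows(g, population))
  tajd_from_counts(sc$alt[idx], sc$n_hap[idx])
}

tajd_from_counts <- function(alt, n_hap) {
  seg <- alt > 0 & alt < n_hap & n_hap >= 2
  S <- sum(seg)
  if (S < 2) return(NA_real_)
  n <- round(mean(n_hap[seg]))
  if (n < 4) return(NA_real_)
  k <- tajima_constants(n)
  pi_sum <- sum(site_pi(alt[seg], n_hap[seg]))
  vr <- k$e1 * S + k$e2 * S * (S - 1)
  if (vr <= 0) return(NA_real_)
  (pi_sum - S / k$a1) / sqrt(vr)
}

#' Compute the full windowed statistic table
#'
#' One row per sliding window with SNP count, per-population \eqn{\pi},
#' pooled-reference \eqn{\pi}, weighted Weir-Cockerham F_ST (test vs pooled
#' references), pooled heterozygosity and Tajima's D in the test population,
#' and \eqn{\ln(\pi_{test}/\pi_{ref})}.  Windows with fewer than
#' `cfg$min_snps_per_window` SNPs keep their coordinates but have their
#' statistics set to `NA` so they stay out of the Z-score distributions.
#'
#' @param g a [genotype_matrix()]
#' @param test test-population label
#' @param refs character vector of reference-population labels (pooled for
#'   F_ST and the \eqn{\pi} ratio; per-population \eqn{\pi} also reported)
#' @param cfg a [scan_config()]
#' @param chrom_lengths optional named chromosome lengths
#' @return data.frame of windowed statistics (`window_stats`)
#' @export
compute_window_stats <- function(g, test, refs, cfg = scan_config(),
                                 chrom_lengths = NULL) {
  stopifnot(inherits(cfg, "scan_config"))
  if (test %in% refs) stop("test population must not be a reference")
  if (is.null(chrom_lengths)) chrom_lengths <- chrom_lengths_of(g)
  wins <- make_windows(chrom_lengths, cfg)
  pops <- populations_of(g)

  pi_site <- lapply(pops, function(p) site_pi_vector(g, pop_rows(g, p)))
  names(pi_site) <- pops
  pi_ref <- site_pi_vector(g, pop_rows(g, refs))
  comp <- wc_components(g, pop_rows(g, test), pop_rows(g, refs))
  sct <- site_counts(g, pop_rows(g, test))
  nmaj <- pmax(sct$alt, sct$n_hap - sct$alt)
  nmin <- pmin(sct$alt, sct$n_hap - sct$alt)

  n <- nrow(wins)
  res <- wins
  res$n_snps <- 0L
  for (p in pops) res[[paste0("pi_", p)]] <- 0
  res$pi_ref_pooled <- 0
  res$fst <- NA_real_; res$hp <- NA_real_; res$tajd <- NA_real_

  for (ch in unique(wins$chrom)) {
    on_chrom <- which(g$sites$chrom == ch)
    pos0 <- g$sites$pos[on_chrom] - 1
    wi <- which(wins$chrom == ch)
    lo <- findInterval(wins$start[wi] - 0.5, pos0) + 1L
    hi <- findInterval(wins$end[wi] - 0.5, pos0)
    wsum <- function(v) {
      cs <- c(0, cumsum(v))
      cs[pmax(hi, lo - 1L) + 1L] - cs[lo]
    }
    res$n_snps[wi] <- pmax(hi - lo + 1L, 0L)
    span <- wins$span[wi]
    for (p in pops)
      res[[paste0("pi_", p)]][wi] <- wsum(pi_site[[p]][on_chrom]) / span
    res$pi_ref_pooled[wi] <- wsum(pi_ref[on_chrom]) / span
    a_ok <- comp$a[on_chrom]; b_ok <- comp$b[on_chrom]
    c_ok <- comp$c[on_chrom]
    usable <- !is.na(a_ok)
    z <- function(v) { v[!usable] <- 0; v }
    sum_a <- wsum(z(a_ok))
    sum_abc <- wsum(z(a_ok + b_ok + c_ok))
    if (cfg$fst_mode == "weighted") {
      fst <- ifelse(sum_abc != 0, sum_a / sum_abc, NA_real_)
    } else {
      den <- a_ok + b_ok + c_ok
      ratio <- ifelse(usable & den != 0, a_ok / den, 0)
      cnt <- wsum(as.numeric(usable & den != 0))
      fst <- ifelse(cnt > 0, wsum(ratio) / cnt, NA_real_)
    }
    res$fst[wi] <- fst
    smaj <- wsum(nmaj[on_chrom]); smin <- wsum(nmin[on_chrom])
    tot <- smaj + smin
    res$hp[wi] <- ifelse(tot > 0, 2 * smaj * smin / tot^2, NA_real_)
    for (k in seq_along(wi)) {
      if (hi[k] < lo[k]) next
      idx <- on_chrom[lo[k]:hi[k]]
      res$tajd[wi[k]] <- tajd_from_counts(sct$alt[idx], sct$n_hap[idx])
    }
  }
  res$ln_pi_ratio <- ln_pi_ratio(res[[paste0("pi_", test)]],
                                 res$pi_ref_pooled)
  low <- res$n_snps < cfg$min_snps_per_window
  for (col in c(paste0("pi_", pops), "pi_ref_pooled", "fst", "hp", "tajd",
                "ln_pi_ratio"))
    res[[col]][low] <- NA_real_
  attr(res, "test") <- test
  attr(res, "refs") <- refs
  class(res) <- c("window_stats", "data.frame")
  res
}
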