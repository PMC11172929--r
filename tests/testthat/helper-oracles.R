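# Independent brute-force implementations used as oracles.  These work from
# first principles (explicit allele multisets, pairwise enumeration, scalar
# per-site loops) and share no code with the package's vectorized paths.

# alleles carried by a vector of dosages (0/1/2, NA dropped)
bf_alleles <- function(dosages) {
  out <- integer(0)
  for (d in dosages) {
    if (is.na(d)) next
    out <- c(out, switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L)))
  }
  out
}

bf_sites_in_window <- function(g, w) {
  which(g$sites$chrom == w$chrom &
          (g$sites$pos - 1) >= w$start & (g$sites$pos - 1) < w$end)
}

# per-site pi by enumerating every haplotype pair
bf_site_pi <- function(dosages) {
  al <- bf_alleles(dosages)
  n <- length(al)
  if (n < 2) return(NA_real_)
  diff <- 0L; pairs <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1L
    if (al[i] != al[j]) diff <- diff + 1L
  }
  diff / pairs
}

bf_window_pi <- function(g, w, population) {
  rows <- which(g$pop %in% population)
  idx <- bf_sites_in_window(g, w)
  tot <- 0
  for (s in idx) {
    v <- bf_site_pi(g$geno[rows, s])
    if (!is.na(v)) tot <- tot + v
  }
  tot / (w$end - w$start)
}

# Weir & Cockerham (1984) components, scalar, straight from the published
# two-allele r-population formulas with r = 2
bf_wc_site <- function(d1, d2) {
  stats_of <- function(d) {
    d <- d[!is.na(d)]
    n <- length(d)
    if (n == 0) return(NULL)
    list(n = n, p = sum(d) / (2 * n), h = sum(d == 1) / n)
  }
  s1 <- stats_of(d1); s2 <- stats_of(d2)
  if (is.null(s1) || is.null(s2)) return(NULL)
  r <- 2
  n_i <- c(s1$n, s2$n); p_i <- c(s1$p, s2$p); h_i <- c(s1$h, s2$h)
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  C2 <- sum((n_i - nbar)^2) / ((r - 1) * nbar^2)  # squared CV of sizes
  nc <- nbar * (1 - C2 / r * (r - 1))             # == nbar(1 - C2/2) for r=2
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2v <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2v - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

bf_windowed_fst <- function(g, w, pop1, pop2) {
  r1 <- which(g$pop %in% pop1); r2 <- which(g$pop %in% pop2)
  idx <- bf_sites_in_window(g, w)
  num <- 0; den <- 0; any_site <- FALSE
  for (s in idx) {
    comp <- bf_wc_site(g$geno[r1, s], g$geno[r2, s])
    if (is.null(comp)) next
    any_site <- TRUE
    num <- num + comp$a
    den <- den + comp$a + comp$b + comp$c
  }
  if (!any_site || den == 0) return(NA_real_)
  num / den
}

bf_hp_window <- function(g, w, population) {
  rows <- which(g$pop %in% population)
  idx <- bf_sites_in_window(g, w)
  smaj <- 0L; smin <- 0L
  for (s in idx) {
    al <- bf_alleles(g$geno[rows, s])
    n1 <- sum(al == 1L); n0 <- sum(al == 0L)
    smaj <- smaj + max(n0, n1)
    smin <- smin + min(n0, n1)
  }
  if (smaj + smin == 0) return(NA_real_)
  2 * smaj * smin / (smaj + smin)^2
}

bf_tajimas_d <- function(g, w, population) {
  rows <- which(g$pop %in% population)
  idx <- bf_sites_in_window(g, w)
  pis <- c(); ns <- c()
  for (s in idx) {
    al <- bf_alleles(g$geno[rows, s])
    if (length(al) >= 2 && length(unique(al)) == 2) {  # segregating
      pis <- c(pis, bf_site_pi(g$geno[rows, s]))
      ns <- c(ns, length(al))
    }
  }
  S <- length(pis)
  if (S < 2) return(NA_real_)
  n <- round(sum(ns) / S)
  if (n < 4) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vr <- e1 * S + e2 * S * (S - 1)
  if (vr <= 0) return(NA_real_)
  (sum(pis) - S / a1) / sqrt(vr)
}
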