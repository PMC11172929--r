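#' Genotype matrix container
#'
#' The central data structure: biallelic SNP sites with alt-allele dosages
#' (0/1/2, `NA` = missing) for a set of samples carrying population labels.
#' Positions are stored 1-based (as in VCF) and must be strictly increasing
#' within each chromosome; interval arithmetic elsewhere in the package is
#' 0-based half-open, converted only at I/O boundaries.
#'
#' @param geno integer matrix, samples x sites, values in \{0,1,2,NA\}
#'   (alt-allele dosage).  Row names, if present, must equal `samples`.
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (integer, 1-based), `ref`, `alt` (single bases).
#' @param populations named character vector mapping sample ID -> population
#'   label; every sample must be present.
#' @param samples character vector of sample IDs ordered as the rows of
#'   `geno`; defaults to `rownames(geno)` or `names(populations)`.
#' @return object of class `genotype_matrix`: a list with elements `geno`,
#'   `sites`, `samples`, `pop`.
#' @examples
#' g <- genotype_matrix(
#'   geno = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   sites = data.frame(chrom = "1", pos = c(100L, 200L),
#'                      ref = "A", alt = "C"),
#'   populations = c(s1 = "P1", s2 = "P2"))
#' n_sites(g)
#' @export
genotype_matrix <- function(geno, sites, populations, samples = NULL) {
  if (is.null(samples)) {
    samples <- rownames(geno)
    if (is.null(samples)) samples <- names(populations)
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples) || length(samples) != nrow(geno))
    stop("cannot determine sample IDs for ", nrow(geno), " genotype rows")
  rownames(geno) <- samples
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == ncol(geno))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  missing_pop <- setdiff(samples, names(populations))
  if (length(missing_pop))
    stop("samples without a population label: ",
         paste(missing_pop, collapse = ", "))
  pop <- as.character(populations[samples])
  names(pop) <- samples
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(geno = geno, sites = sites, samples = samples, pop = pop),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`
#' @export
n_sites <- function(g) ncol(g$geno)

#' @rdname genotype_matrix
#' @export
n_samples <- function(g) nrow(g$geno)

#' @rdname genotype_matrix
#' @export
populations_of <- function(g) unique(unname(g$pop))

#' Row indices of the samples belonging to one or more populations
#'
#' @param g a `genotype_matrix`
#' @param population character vector of population labels; labels are pooled.
#' @return integer vector of row indices into `g$geno`
#' @export
pop_rows <- function(g, population) {
  unknown <- setdiff(population, g$pop)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  which(g$pop %in% population)
}

#' Subset a genotype matrix by site index or by sample ID
#'
#' @param g a `genotype_matrix`
#' @param sites integer/logical index into sites (order preserved)
#' @param samples character vector of sample IDs to keep
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  geno <- g$geno
  st <- g$sites
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  keep <- g$samples
  if (!is.null(samples)) keep <- intersect(keep, samples)
  genotype_matrix(geno[keep, , drop = FALSE], st, g$pop[keep], samples = keep)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$pop)
  cat("genotype_matrix:", n_samples(x), "samples x", n_sites(x), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

# Per-site allele summaries for a set of sample rows.  Everything downstream
# (pi, FST, Hp, Tajima's D) is built from these counts; missing genotypes
# simply reduce the per-site called count.
site_counts <- function(g, rows) {
  sub <- g$geno[rows, , drop = FALSE]
  called <- colSums(!is.na(sub))
  alt <- colSums(sub, na.rm = TRUE)
  het <- colSums(sub == 1L, na.rm = TRUE)
  list(n_dip = called, n_hap = 2L * called, alt = alt, het = het)
}
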