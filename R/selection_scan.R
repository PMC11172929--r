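#' Genome-wide Z-standardization
#'
#' \eqn{z_i = (x_i - mean) / sd} over all finite values (the `sd` uses the
#' n-1 denominator).  `NA`s (flagged windows) are preserved and excluded
#' from the mean/sd.  Order-preserving.
#'
#' @param values numeric vector
#' @return numeric vector of z-scores, same length
#' @export
z_transform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need >= 2 finite values to Z-transform")
  s <- sd(values[ok])
  if (s == 0) stop("zero spread: cannot Z-transform")
  out <- rep(NA_real_, length(values))
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' Log ratio of test to reference diversity
#'
#' \eqn{\ln(\pi_{test} / \pi_{ref})}; reference \eqn{\pi} is computed on the
#' pooled reference samples.  Windows where either term is zero (or
#' negative) are flagged `NA` rather than propagating infinities.
#'
#' @param pi_test,pi_ref_pooled per-bp diversities (vectorized)
#' @return numeric vector
#' @export
ln_pi_ratio <- function(pi_test, pi_ref_pooled) {
  ifelse(is.finite(pi_test) & is.finite(pi_ref_pooled) &
           pi_test > 0 & pi_ref_pooled > 0,
         log(pi_test / pi_ref_pooled), NA_real_)
}

#' Flag the empirical tail of a windowed statistic
#'
#' Flags exactly `k = ceiling(q * W)` windows, where W is the number of
#' windows with a finite value of the statistic.  Ties at the cutoff are
#' broken by genomic order (chromosome, then start), so the output is
#' deterministic.
#'
#' @param records window-statistic data.frame (e.g. from
#'   [compute_window_stats()])
#' @param statistic column name to rank
#' @param side `"upper"` or `"lower"`
#' @param q tail fraction in (0, 0.5)
#' @return the flagged rows of `records`, in genomic order, with the ranked
#'   column intact
#' @export
select_tail <- function(records, statistic, side = c("upper", "lower"),
                        q = 0.005) {
  side <- match.arg(side)
  if (q <= 0 || q >= 0.5) stop("q must lie in (0, 0.5)")
  v <- records[[statistic]]
  if (is.null(v)) stop("no such statistic column: ", statistic)
  ok <- which(is.finite(v))
  if (!length(ok)) stop("no finite values of ", statistic)
  k <- ceiling(q * length(ok))
  key <- if (side == "upper") -v[ok] else v[ok]
  gi <- order(records$chrom[ok], records$start[ok])
  grank <- integer(length(ok)); grank[gi] <- seq_along(ok)
  chosen <- ok[order(key, grank)][seq_len(k)]
  out <- records[sort(chosen), , drop = FALSE]
  attr(out, "k") <- k
  attr(out, "W") <- length(ok)
  out
}

#' Merge flagged windows into candidate regions
#'
#' Overlapping or book-ended flagged windows on the same chromosome are
#' merged into maximal regions; the extreme ("peak") value of the flagged
#' statistic is retained.  Idempotent.
#'
#' @param flagged data.frame of flagged windows (`chrom`, `start`, `end`
#'   0-based half-open), e.g. from [select_tail()]
#' @param method method label stored with each region (e.g. `"ZFST"`)
#' @param statistic column whose extreme value becomes the region peak
#' @param peak_side `"upper"` or `"lower"`: which extreme is the peak
#' @return data.frame with `chrom`, `start`, `end`, `method`, `peak`,
#'   `n_windows`
#' @export
merge_windows <- function(flagged, method = NA_character_,
                          statistic = NULL, peak_side = "upper") {
  if (!nrow(flagged))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), method = character(0),
                      peak = numeric(0), n_windows = integer(0)))
  flagged <- flagged[order(flagged$chrom, flagged$start, flagged$end), ,
                     drop = FALSE]
  vals <- if (!is.null(statistic)) flagged[[statistic]] else
    rep(NA_real_, nrow(flagged))
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               method = method,
               peak = if (peak_side == "upper") max(cur$vals, na.rm = FALSE)
                      else min(cur$vals, na.rm = FALSE),
               n_windows = cur$n, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(flagged))) {
    if (!is.null(cur) && flagged$chrom[i] == cur$chrom &&
        flagged$start[i] <= cur$end) {
      cur$end <- max(cur$end, flagged$end[i])
      cur$vals <- c(cur$vals, vals[i])
      cur$n <- cur$n + 1L
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = flagged$chrom[i], start = flagged$start[i],
                  end = flagged$end[i], vals = vals[i], n = 1L)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate candidate regions with overlapping genes
#'
#' A gene is hit iff its span overlaps a region by at least 1 bp in 0-based
#' half-open arithmetic (gene GFF3 coordinates are converted internally); a
#' region ending exactly where a gene starts does not hit it.
#'
#' @param regions data.frame from [merge_windows()] (or any frame with
#'   `chrom`, `start`, `end` 0-based half-open, optional `method`)
#' @param genes data.frame from [read_gff3()] (1-based inclusive)
#' @return data.frame, one row per gene x overlapping region, with gene
#'   columns, `method` and the region coordinates; zero rows when no hit
#' @export
annotate_regions <- function(regions, genes) {
  empty <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), gene_start = numeric(0),
                      gene_end = numeric(0), method = character(0),
                      region_start = numeric(0), region_end = numeric(0))
  if (!nrow(regions)) return(empty)
  unmatched <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(unmatched))
    stop("chromosome names absent from the gene annotation: ",
         paste(unmatched, collapse = ", "))
  g0 <- genes$start - 1  # to 0-based half-open
  g1 <- genes$end
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    ov <- genes$chrom == regions$chrom[i] &
      g0 < regions$end[i] & g1 > regions$start[i]
    if (!any(ov)) next
    hits[[length(hits) + 1L]] <- data.frame(
      gene_id = genes$gene_id[ov], gene_name = genes$gene_name[ov],
      chrom = genes$chrom[ov], gene_start = genes$start[ov],
      gene_end = genes$end[ov],
      method = if ("method" %in% names(regions)) regions$method[i]
               else NA_character_,
      region_start = regions$start[i], region_end = regions$end[i],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}

#' Intersect gene hits across scan methods
#'
#' @param hits_by_method named list (one element per method) of character
#'   vectors of gene IDs
#' @return list with `shared` (genes present in every method), `venn`
#'   (named counts of every exclusive membership pattern, names like
#'   `"ZFST+ZHP"`), and `membership` (data.frame gene_id x per-method
#'   logicals)
#' @export
intersect_methods <- function(hits_by_method) {
  methods <- names(hits_by_method)
  stopifnot(length(methods) >= 2)
  hits_by_method <- lapply(hits_by_method, unique)
  genes <- unique(unlist(hits_by_method, use.names = FALSE))
  mem <- as.data.frame(lapply(hits_by_method, function(h) genes %in% h))
  membership <- cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE),
                      mem)
  pattern <- apply(as.matrix(mem), 1L, function(r)
    paste(methods[r], collapse = "+"))
  venn <- if (length(genes)) table(pattern) else
    table(factor(character(0)))
  shared <- genes[rowSums(as.matrix(mem)) == length(methods)]
  list(shared = shared, venn = c(venn), membership = membership)
}

#' F_ST and Tajima's D profile around a gene
#'
#' Windowed F_ST (test vs pooled references) and test-population Tajima's D
#' across the gene span plus a flank on each side, as a plot-ready table.
#'
#' @param g a [genotype_matrix()]
#' @param gene one-row data.frame (or list) with `chrom`, `start`, `end`
#'   (1-based inclusive, as from [read_gff3()])
#' @param test,refs population labels
#' @param flank_bp flank on each side of the gene (default 500 kb)
#' @param cfg a [scan_config()]
#' @return data.frame with window coordinates, `in_gene` flag, `fst`, `tajd`
#' @export
gene_region_profile <- function(g, gene, test, refs, flank_bp = 5e5,
                                cfg = scan_config()) {
  if (is.data.frame(gene)) gene <- as.list(gene[1, ])
  if (!gene$chrom %in% g$sites$chrom)
    stop("gene chromosome ", gene$chrom, " absent from the genotype matrix")
  g0 <- gene$start - 1; g1 <- gene$end
  lo <- max(0, g0 - flank_bp)
  hi <- g1 + flank_bp
  starts <- seq(0, max(0, hi - 1), by = cfg$step)
  wins <- data.frame(chrom = gene$chrom, start = starts,
                     end = starts + cfg$window_size)
  wins <- wins[wins$start < hi & wins$end > lo, , drop = FALSE]
  rownames(wins) <- NULL
  comp <- wc_components(g, pop_rows(g, test), pop_rows(g, refs))
  sct <- site_counts(g, pop_rows(g, test))
  fst <- window_apply(g, wins, function(idx)
    fst_from_components(comp$a[idx], comp$b[idx], comp$c[idx], cfg$fst_mode))
  tajd <- window_apply(g, wins, function(idx)
    tajd_from_counts(sct$alt[idx], sct$n_hap[idx]))
  data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
             in_gene = wins$start < g1 & wins$end > g0,
             fst = fst, tajd = tajd, stringsAsFactors = FALSE)
}

#' Run the three-method selection scan
#'
#' The full scan layer over a windowed statistic table: Z-transform F_ST and
#' Hp genome-wide, flag the empirical tails (\eqn{ZF_{ST}} upper,
#' \eqn{ZHp} lower, \eqn{\ln(\pi_{test}/\pi_{ref})} lower by default), merge
#' flagged windows into candidate regions, annotate against gene models and
#' intersect the per-method gene lists.
#'
#' @param stats a `window_stats` table from [compute_window_stats()]
#' @param genes gene models from [read_gff3()] (or `NULL` to skip
#'   annotation)
#' @param cfg the [scan_config()] used for the stats
#' @return list with `stats` (input plus `zfst`, `zhp` columns), `flagged`
#'   (per-method flagged windows), `regions` (per-method candidate
#'   regions), `hits` (per-method gene hits), `intersection`
#'   (from [intersect_methods()]; `NULL` when `genes` is `NULL`)
#' @export
run_selection_scan <- function(stats, genes = NULL, cfg = scan_config()) {
  q <- cfg$tail_fraction
  stats$zfst <- z_transform(stats$fst)
  stats$zhp <- z_transform(stats$hp)
  flagged <- list(
    ZFST = select_tail(stats, "zfst", "upper", q),
    ZHP = select_tail(stats, "zhp", "lower", q),
    PI_RATIO = select_tail(stats, "ln_pi_ratio",
                           if (cfg$ratio_tail == "lower") "lower"
                           else "upper", q))
  regions <- list(
    ZFST = merge_windows(flagged$ZFST, "ZFST", "zfst", "upper"),
    ZHP = merge_windows(flagged$ZHP, "ZHP", "zhp", "lower"),
    PI_RATIO = merge_windows(flagged$PI_RATIO, "PI_RATIO", "ln_pi_ratio",
                             if (cfg$ratio_tail == "lower") "lower"
                             else "upper"))
  hits <- NULL
  inter <- NULL
  if (!is.null(genes)) {
    hits <- lapply(regions, annotate_regions, genes = genes)
    inter <- intersect_methods(lapply(hits, function(h) h$gene_id))
  }
  list(stats = stats, flagged = flagged, regions = regions, hits = hits,
       intersection = inter)
}
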