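#' Read a multi-sample VCF and population map into a genotype matrix
#'
#' Only biallelic SNP records are retained; multiallelic and non-SNP records
#' are skipped and counted.  Genotypes are collapsed to alt-allele dosage
#' (0/1/2); `./.` and half-calls (e.g. `./1`) become missing.  Phasing is
#' ignored.  VCF positions (1-based) are retained in the site table.
#'
#' @param path VCF path (plain or bgzipped; anything [vcfR::read.vcfR()]
#'   accepts)
#' @param pop_map_path TSV with header columns `sample`, `population`;
#'   every VCF sample must be present
#' @return a [genotype_matrix()]; the number of skipped records is attached
#'   as attribute `n_skipped`
#' @export
read_vcf <- function(path, pop_map_path) {
  pm <- read.table(pop_map_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(pm)))
    stop("population map must have columns 'sample' and 'population'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(v@gt)[-1]
  missing_from_map <- setdiff(samples, pm$sample)
  if (length(missing_from_map))
    stop("VCF samples missing from the population map: ",
         paste(missing_from_map, collapse = ", "))
  gt <- gt[is_snp, , drop = FALSE]
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "./." = NA_integer_, "./0" = NA_integer_, "0/." = NA_integer_,
            "./1" = NA_integer_, "1/." = NA_integer_, "." = NA_integer_)
  unknown <- matrix(!(gt %in% names(code)), nrow = nrow(gt))
  if (any(unknown)) {
    idx <- which(unknown, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt[unknown][1], "' at record ", idx[1],
         " (kept-SNP index), sample ", samples[idx[2]])
  }
  dosage <- matrix(code[gt], nrow = nrow(gt))
  sites <- data.frame(chrom = fix[is_snp, "CHROM"],
                      pos = as.integer(fix[is_snp, "POS"]),
                      ref = ref[is_snp], alt = alt[is_snp],
                      stringsAsFactors = FALSE)
  pops <- setNames(pm$population, pm$sample)
  g <- genotype_matrix(t(dosage), sites, pops, samples = samples)
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Site filter configuration
#'
#' Defaults follow standard WGS practice for scan input: minor allele
#' frequency at least 0.05 and at most 10\% missing genotypes, autosomes
#' only.  MAF is computed over all non-missing calls pooled across samples.
#' The MAF comparator is exposed because both inclusive and strict
#' conventions circulate; the inclusive rule (keep iff MAF >= maf_min) is
#' the default.
#'
#' @param maf_min minimum minor allele frequency in [0, 0.5)
#' @param missing_max maximum missing-call fraction in [0, 1]
#' @param autosomes_only drop chromosomes whose names are not purely
#'   numeric (X/Y/MT and unplaced contigs); names are taken verbatim, no
#'   "chr"-prefix normalization
#' @param maf_comparator `">="` (inclusive, default) or `">"`
#' @return list of class `filter_config`
#' @export
filter_config <- function(maf_min = 0.05, missing_max = 0.10,
                          autosomes_only = TRUE, maf_comparator = ">=") {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  if (missing_max < 0 || missing_max > 1)
    stop("missing_max must lie in [0, 1]")
  if (!maf_comparator %in% c(">=", ">"))
    stop("maf_comparator must be '>=' or '>'")
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 autosomes_only = autosomes_only,
                 maf_comparator = maf_comparator),
            class = "filter_config")
}

#' Filter sites by MAF and missingness
#'
#' A site is kept iff its pooled-sample MAF satisfies the configured
#' comparator against `maf_min` AND its missing-call fraction is at most
#' `missing_max`.  Site order is preserved; the filter is idempotent.
#' Removing every site yields an empty matrix with a warning, not an error.
#'
#' @param g a [genotype_matrix()]
#' @param f a [filter_config()]
#' @return filtered `genotype_matrix`
#' @export
filter_sites <- function(g, f = filter_config()) {
  stopifnot(inherits(f, "filter_config"))
  keep_chrom <- rep(TRUE, n_sites(g))
  if (isTRUE(f$autosomes_only))
    keep_chrom <- grepl("^[0-9]+$", g$sites$chrom)
  called <- colSums(!is.na(g$geno))
  alt <- colSums(g$geno, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), 0)
  maf <- pmin(af, 1 - af)
  miss_frac <- 1 - called / nrow(g$geno)
  keep_maf <- if (f$maf_comparator == ">=") maf >= f$maf_min
              else maf > f$maf_min
  keep <- keep_chrom & keep_maf & miss_frac <= f$missing_max
  if (!any(keep)) {
    warning("all sites removed by filter")
    return(subset_genotypes(g, sites = integer(0)))
  }
  subset_genotypes(g, sites = which(keep))
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`-type features; by default only protein-coding genes are
#' returned (from the `biotype`/`gene_biotype` attribute; features with no
#' biotype attribute are kept).  Coordinates stay 1-based inclusive, as in
#' GFF3.
#'
#' @param path GFF3 path
#' @param protein_coding_only logical (default TRUE)
#' @return data.frame with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `start`, `end`
#' @export
read_gff3 <- function(path, protein_coding_only = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  md <- as.data.frame(gr)
  biotype <- rep(NA_character_, nrow(md))
  for (col in c("biotype", "gene_biotype"))
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      biotype[is.na(biotype) & !is.na(v)] <- v[is.na(biotype) & !is.na(v)]
    }
  gene_id <- if ("ID" %in% names(md)) sub("^gene:", "", as.character(md$ID))
             else sprintf("gene%04d", seq_len(nrow(md)))
  gene_name <- if ("Name" %in% names(md)) as.character(md$Name) else gene_id
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  out <- data.frame(gene_id = gene_id, gene_name = gene_name,
                    biotype = biotype,
                    chrom = as.character(md$seqnames),
                    start = md$start, end = md$end,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end))
    stop("malformed gene coordinates (start > end) in ", path)
  if (protein_coding_only)
    out <- out[is.na(out$biotype) | out$biotype == "protein_coding", ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pipeline result tables, regions and trees
#'
#' Window-statistic tables go to TSV, candidate regions to BED (0-based
#' half-open) plus a TSV with method and peak columns, trees to newick.
#'
#' @param tables named list of data.frames (written as `<name>.tsv`)
#' @param trees named list of `phylo` objects (written as `<name>.nwk`)
#' @param regions named list of candidate-region data.frames with columns
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `method`,
#'   `peak` (written as `<name>.bed` and `<name>.tsv`)
#' @param out_dir output directory (created if needed)
#' @return named character vector of written paths
#' @export
write_outputs <- function(tables = list(), trees = list(),
                          regions = list(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(tables[[nm]], p, sep = "\t", na = "NA")
    paths[nm] <- p
  }
  for (nm in names(regions)) {
    r <- regions[[nm]]
    pb <- file.path(out_dir, paste0(nm, ".bed"))
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    if (nrow(r))
      bed <- data.frame(chrom = r$chrom, start = as.integer(r$start),
                        end = as.integer(r$end))
    data.table::fwrite(bed, pb, sep = "\t", col.names = FALSE)
    if (!nrow(bed)) file.create(pb)  # fwrite skips empty frames' body only
    pt <- file.path(out_dir, paste0(nm, "_regions.tsv"))
    data.table::fwrite(r, pt, sep = "\t", na = "NA")
    paths[paste0(nm, "_bed")] <- pb
    paths[paste0(nm, "_tsv")] <- pt
  }
  for (nm in names(trees)) {
    p <- file.path(out_dir, paste0(nm, ".nwk"))
    ape::write.tree(trees[[nm]], file = p)
    paths[nm] <- p
  }
  paths
}
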