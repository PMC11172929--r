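default_pipeline_config <- function() {
  list(
    vcf = NULL, pop_map = NULL, gff3 = NULL,
    test_pop = NULL, ref_pops = NULL,
    out_dir = "sweepscan_out", seed = 1L,
    filter = list(maf_min = 0.05, missing_max = 0.10,
                  autosomes_only = TRUE, maf_comparator = ">="),
    scan = list(window_size = 100000, step = 50000, tail_fraction = 0.005,
                min_snps_per_window = 10, ratio_tail = "lower",
                fst_mode = "weighted"),
    roh = list(window_snps = 50, max_het = 1, max_missing = 2,
               hit_fraction = 0.05, min_snps = 50, min_length_bp = 5e5,
               max_gap_density_bp = 5e4),
    ld = list(max_dist = 5e5, bin_width = 1e3, prune_window = 50,
              prune_step = 10, prune_r2 = 0.2),
    pca = list(n_components = 10),
    tree = list(level = "population"))
}

suggest_key <- function(key, known) {
  d <- utils::adist(key, known)
  known[which.min(d)]
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key '", full, "'; did you mean '",
           suggest_key(key, names(defaults)), "'?")
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be a block")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a nested list; unknown keys are rejected with a
#' suggestion, defaults (100 kb/50 kb windows, q = 0.005, MAF 0.05,
#' missingness 0.10, PLINK-style ROH/LD parameters) are injected, and
#' cross-field invariants are enforced (test population not among the
#' references, required inputs present).
#'
#' @param cfg YAML file path or nested list
#' @return normalized config list of class `pipeline_config`
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  full <- merge_config(default_pipeline_config(), cfg)
  for (key in c("vcf", "pop_map", "gff3", "test_pop", "ref_pops"))
    if (is.null(full[[key]]))
      stop("config key '", key, "' is required")
  if (full$test_pop %in% full$ref_pops)
    stop("test_pop must not appear in ref_pops")
  q <- full$scan$tail_fraction
  if (!is.numeric(q) || q <= 0 || q >= 0.5)
    stop("scan.tail_fraction must lie in (0, 0.5)")
  fc <- do.call(filter_config, full$filter)
  sc <- do.call(scan_config, full$scan)
  rp <- do.call(roh_params, full$roh)
  full$filter <- unclass(fc); full$scan <- unclass(sc)
  full$roh <- unclass(rp)
  class(full) <- c("pipeline_config", "list")
  full
}

# deterministic 40-bit polynomial rolling hash (stays in exact-double range)
config_hash_of <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  mod <- 2^40
  for (b in bytes) h <- (h * 127 + b) %% mod
  sprintf("%05x%05x", as.integer(h %/% 2^20), as.integer(h %% 2^20))
}

#' Run the full scan pipeline
#'
#' Executes filter -> windowed statistics -> three-method selection scan ->
#' gene annotation and intersection -> diversity/structure layer (ROH, LD
#' decay, LD pruning, PCA, IBS distances, NJ tree), writes every table,
#' BED and newick output plus a JSON manifest, and returns the manifest.
#' Rerunning with the same config and inputs reproduces identical outputs.
#'
#' @param cfg a [validate_config()] result, raw list, or YAML path
#' @return the manifest (invisibly written to `manifest.json` in
#'   `out_dir`): config, config hash, seed, per-stage row counts, output
#'   paths
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  set.seed(cfg$seed)
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  stage <- function(name, expr) {
    message("[sweepscan] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }
  counts <- list()

  g <- stage("read_vcf", read_vcf(cfg$vcf, cfg$pop_map))
  counts$sites_raw <- n_sites(g)
  counts$samples <- n_samples(g)
  pops <- c(cfg$test_pop, cfg$ref_pops)
  missing_pops <- setdiff(pops, populations_of(g))
  if (length(missing_pops))
    stop("populations not present in the data: ",
         paste(missing_pops, collapse = ", "))

  fc <- do.call(filter_config, cfg$filter)
  g <- stage("filter_sites", filter_sites(g, fc))
  counts$sites_filtered <- n_sites(g)
  genes <- stage("read_gff3", read_gff3(cfg$gff3))
  counts$genes <- nrow(genes)

  sc <- do.call(scan_config, cfg$scan)
  stats <- stage("window_stats",
                 compute_window_stats(g, cfg$test_pop, cfg$ref_pops, sc))
  counts$windows <- nrow(stats)
  scan <- stage("selection_scan", run_selection_scan(stats, genes, sc))
  counts$candidate_regions <- vapply(scan$regions, nrow, integer(1))
  counts$shared_genes <- length(scan$intersection$shared)

  rp <- do.call(roh_params, cfg$roh)
  roh <- stage("roh", do.call(rbind, lapply(g$samples, function(s)
    detect_roh(g, s, rp))))
  roh_sum <- summarize_roh(roh, g$pop)
  counts$roh_segments <- nrow(roh)

  ld_curves <- stage("ld_decay", {
    cl <- lapply(pops, function(p) {
      cv <- ld_decay(g, p, cfg$ld$max_dist, cfg$ld$bin_width)
      cv$population <- p
      cv
    })
    do.call(rbind, cl)
  })

  kept <- stage("ld_prune", ld_prune(g, cfg$ld$prune_window,
                                     cfg$ld$prune_step, cfg$ld$prune_r2))
  counts$sites_pruned <- length(kept)
  gp <- subset_genotypes(g, sites = kept)
  pca <- stage("pca", pca_genotypes(gp, cfg$pca$n_components))
  dmat <- stage("ibs", ibs_distance_matrix(gp, cfg$tree$level))
  tre <- stage("nj", nj_tree(dmat))

  intersection_tab <- scan$intersection$membership
  paths <- write_outputs(
    tables = list(
      window_stats = scan$stats,
      gene_hits = do.call(rbind, scan$hits),
      intersection = intersection_tab,
      roh_segments = roh,
      roh_summary = roh_sum$per_population,
      ld_decay = ld_curves,
      pca_scores = data.frame(sample = rownames(pca$scores),
                              population = unname(pca$populations),
                              pca$scores),
      pca_variance = data.frame(component = seq_along(pca$percent_var),
                                percent_var = pca$percent_var)),
    regions = setNames(scan$regions,
                       paste0("regions_", tolower(names(scan$regions)))),
    trees = list(nj_tree = tre$tree),
    out_dir = out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = config_hash_of(yaml::as.yaml(unclass(cfg))),
    counts = counts,
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
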