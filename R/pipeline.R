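#' Assemble a pipeline run configuration
#'
#' Bundles every knob of the analysis chain (filter -> one-SNP-per-locus ->
#' population scheme -> polarize -> psi -> origin scan -> IBD test -> PCoA /
#' heterozygosity) into one serializable object. Every run writes its
#' resolved configuration beside its results, and all randomness flows from
#' `seed` (no wall-clock seeding).
#'
#' @param genotypes path to a genotype table (or `NULL` when a table is
#'   passed to [run_pipeline()] directly).
#' @param samples path to the sample metadata TSV (or `NULL`).
#' @param format genotype file format, `"tsv"` or `"vcf"`.
#' @param selection a [selection_config()].
#' @param outgroup_taxon restrict polarization to one outgroup taxon
#'   (`NULL` = use all outgroup samples).
#' @param m psi projection size in chromosomes.
#' @param B bootstrap resamples for psi standard errors (0 = off).
#' @param spacing_deg,padding_fraction origin-scan grid settings.
#' @param n_perm permutations for the expansion-vs-IBD test.
#' @param pcoa_axes number of PCoA axes to report.
#' @param out_dir output directory (`NULL` = return results only).
#' @param seed master integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes = NULL, samples = NULL,
                       format = c("tsv", "vcf"),
                       selection = selection_config(),
                       outgroup_taxon = NULL,
                       m = 2L, B = 0L,
                       spacing_deg = 0.25, padding_fraction = 0.5,
                       n_perm = 199L,
                       pcoa_axes = 2L,
                       out_dir = NULL,
                       seed = 1L) {
  structure(list(genotypes = genotypes, samples = samples,
                 format = match.arg(format),
                 selection = selection,
                 outgroup_taxon = outgroup_taxon,
                 m = as.integer(m), B = as.integer(B),
                 spacing_deg = spacing_deg,
                 padding_fraction = padding_fraction,
                 n_perm = as.integer(n_perm),
                 pcoa_axes = as.integer(pcoa_axes),
                 out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full range-expansion pipeline
#'
#' Executes filtering, one-SNP-per-locus selection, the population scheme,
#' outgroup polarization, the psi matrix, the TDOA origin scan, the
#' expansion-vs-IBD permutation test, PCoA and per-population
#' heterozygosity. PCoA and heterozygosity are computed on the site-filtered
#' table before per-population sample subsetting (structure assessment uses
#' all individuals). Any stage error propagates with the stage name.
#'
#' @param cfg a [run_config()].
#' @param table optionally, an in-memory `snp_table` (overrides
#'   `cfg$genotypes`).
#' @param info optionally, an in-memory `sample_info`.
#' @return A `run_summary` list: best origin, slope, r2, p-value, boundary
#'   flag, site counts per stage, the psi matrix, the origin surface, the
#'   PCoA embedding, heterozygosity, the resolved config, and the output
#'   manifest when `cfg$out_dir` is set.
#' @export
run_pipeline <- function(cfg, table = NULL, info = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(table)) {
    if (is.null(cfg$genotypes)) stop("no genotype input configured")
    table <- with_stage("read", read_genotype_table(cfg$genotypes, cfg$format))
  }
  if (is.null(info)) {
    if (is.null(cfg$samples)) stop("no sample metadata configured")
    info <- with_stage("read", read_sample_info(cfg$samples))
  }
  sel <- cfg$selection
  counts_in <- nrow(table$sites)

  table <- with_stage("filter", {
    t2 <- filter_locus_sets(table, sel$locus_sets)
    t2 <- filter_min_samples(t2, sel$min_samples_per_snp)
    if (sel$require_outgroup_presence) t2 <- filter_outgroup_presence(t2, info)
    t2
  })
  n_filtered <- nrow(table$sites)
  table <- with_stage("snp_choice",
                      select_one_snp_per_locus(table, sel$snp_choice_mode,
                                               seed = sel$seed))
  n_loci <- nrow(table$sites)

  # structure & heterozygosity on all individuals, before sample subsetting
  ing_ids <- info$sample_id[info$role == "ingroup" &
                              info$sample_id %in% sample_ids(table)]
  embedding <- with_stage("pcoa", {
    d <- euclidean_distance_matrix(subset_snp_table(table,
                                                    samples = ing_ids))
    pcoa_embed(d, axes = cfg$pcoa_axes)
  })
  het <- with_stage("heterozygosity", population_heterozygosity(table, info))

  sub <- with_stage("population_scheme",
                    apply_population_scheme(table, info, sel))
  counts <- with_stage("polarize",
                       polarize_table(sub$table, sub$info,
                                      outgroup_taxon = cfg$outgroup_taxon))
  psi <- with_stage("psi",
                    compute_psi_matrix(counts, m = cfg$m, B = cfg$B,
                                       seed = cfg$seed))
  grid <- with_stage("grid",
                     make_grid(sub$info, spacing_deg = cfg$spacing_deg,
                               padding_fraction = cfg$padding_fraction))
  surface <- with_stage("origin_scan", origin_scan(psi, sub$info, grid))
  test <- with_stage("ibd_test",
                     test_expansion_vs_ibd(psi, sub$info, grid,
                                           n_perm = cfg$n_perm,
                                           seed = cfg$seed))
  surface$pvalue <- test$pvalue

  summary <- list(best_origin = surface$best[c("lat", "lon")],
                  slope = surface$best$slope,
                  r2 = surface$best$r2,
                  pvalue = test$pvalue,
                  boundary = surface$boundary,
                  n_sites = list(input = counts_in, filtered = n_filtered,
                                 one_per_locus = n_loci,
                                 polarized = nrow(counts$sites),
                                 polarization_failed = counts$n_failed,
                                 monomorphic_dropped = counts$n_monomorphic),
                  populations = psi$populations,
                  heterozygosity = as.list(het),
                  settings = cfg[setdiff(names(cfg), c("out_dir"))],
                  seed = cfg$seed)

  manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    manifest <- with_stage("write",
                           write_outputs(psi, surface, embedding, cfg$out_dir,
                                         summary = summary["n_sites"]))
  }
  structure(list(summary = summary, psi = psi, surface = surface,
                 test = test, embedding = embedding, heterozygosity = het,
                 counts = counts, config = cfg, manifest = manifest),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("run_summary: origin (%.3f, %.3f), slope %.3g psi/km, ",
                     "r2 %.3f, p = %.4g%s\n"),
              s$best_origin$lat, s$best_origin$lon, s$slope, s$r2, s$pvalue,
              if (s$boundary) " [origin on grid boundary]" else ""))
  invisible(x)
}

set_cfg_path <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1L) {
    cfg[[keys]] <- value
  } else if (length(keys) == 2L) {
    cfg[[keys[1L]]][[keys[2L]]] <- value
  } else stop("config paths nest at most two levels: ", path)
  cfg
}

#' Run the analysis matrix
#'
#' Runs [run_pipeline()] over the Cartesian product of option values — the
#' consistency assessment across outgroup choice, SNP choice mode, locus
#' set, population scheme, ploidy inclusion and group subset. Axis names are
#' config paths such as `"outgroup_taxon"`, `"m"`,
#' `"selection.snp_choice_mode"` or `"selection.include_tetraploids"`.
#' A failing cell is recorded in the `error` column; other cells continue.
#'
#' @param base_cfg a [run_config()] supplying defaults.
#' @param axes named list of value vectors (empty list = single base run).
#' @param table,info optional in-memory inputs (see [run_pipeline()]).
#' @return data.frame with one row per cell: the axis settings, then
#'   `origin_lat`, `origin_lon`, `slope`, `r2`, `pvalue`, `boundary`,
#'   `error`.
#' @export
run_matrix <- function(base_cfg, axes = list(), table = NULL, info = NULL) {
  if (!length(axes)) {
    cells <- data.frame(row.names = 1L)
  } else {
    cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  }
  out <- vector("list", max(1L, nrow(cells)))
  for (r in seq_len(max(1L, nrow(cells)))) {
    cfg <- base_cfg
    if (ncol(cells)) {
      for (ax in names(cells)) cfg <- set_cfg_path(cfg, ax, cells[[ax]][r])
    }
    res <- tryCatch(run_pipeline(cfg, table = table, info = info),
                    error = function(e) e)
    row <- if (ncol(cells)) cells[r, , drop = FALSE]
           else data.frame(row.names = 1L)
    if (inherits(res, "error")) {
      row$origin_lat <- NA_real_; row$origin_lon <- NA_real_
      row$slope <- NA_real_; row$r2 <- NA_real_; row$pvalue <- NA_real_
      row$boundary <- NA
      row$error <- conditionMessage(res)
    } else {
      s <- res$summary
      row$origin_lat <- s$best_origin$lat
      row$origin_lon <- s$best_origin$lon
      row$slope <- s$slope; row$r2 <- s$r2; row$pvalue <- s$pvalue
      row$boundary <- s$boundary
      row$error <- NA_character_
    }
    out[[r]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
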