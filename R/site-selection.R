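#' Selection configuration
#'
#' Collects the SNP retention filters, one-SNP-per-locus choice scheme and
#' population/sample subsetting scheme applied before polarization.
#' "Present in a sample" means a non-missing genotype call of any kind.
#'
#' @param min_samples_per_snp minimum non-missing calls to retain a SNP
#'   (default 4, the usual GBS retention threshold).
#' @param require_outgroup_presence keep only SNPs with at least one
#'   non-missing outgroup call (default `TRUE`).
#' @param snp_choice_mode `"random"` or `"rare_allele_bias"` for the
#'   one-SNP-per-locus pick. Under `"rare_allele_bias"` the candidate set is
#'   restricted to SNPs whose minor-allele copy count (over non-missing calls,
#'   outgroup included) is at least 2, falling back to all SNPs of the locus
#'   when none qualify.
#' @param per_population_scheme `"one_individual"` (one seeded-random ingroup
#'   sample per population) or `"downsample_to_common"` (each population
#'   reduced to the minimum population size by seeded sampling without
#'   replacement).
#' @param include_tetraploids keep tetraploid populations (default `TRUE`).
#' @param group_filter optional character vector of group labels; populations
#'   outside these groups are removed (requires a `group` column in the
#'   sample metadata).
#' @param locus_sets subset of `c("assembled", "unassembled")` to keep.
#' @param seed integer seed driving every random choice.
#' @return A `selection_config` list.
#' @export
selection_config <- function(min_samples_per_snp = 4L,
                             require_outgroup_presence = TRUE,
                             snp_choice_mode = c("random", "rare_allele_bias"),
                             per_population_scheme = c("one_individual",
                                                       "downsample_to_common"),
                             include_tetraploids = TRUE,
                             group_filter = NULL,
                             locus_sets = c("assembled", "unassembled"),
                             seed = 1L) {
  stopifnot(min_samples_per_snp >= 1L)
  locus_sets <- match.arg(locus_sets, several.ok = TRUE)
  structure(list(min_samples_per_snp = as.integer(min_samples_per_snp),
                 require_outgroup_presence = isTRUE(require_outgroup_presence),
                 snp_choice_mode = match.arg(snp_choice_mode),
                 per_population_scheme = match.arg(per_population_scheme),
                 include_tetraploids = isTRUE(include_tetraploids),
                 group_filter = group_filter,
                 locus_sets = locus_sets,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Retain SNPs present in at least `min_samples` samples
#' @param table a `snp_table`.
#' @param min_samples minimum number of non-missing calls.
#' @return A `snp_table` with sites in their original order.
#' @export
filter_min_samples <- function(table, min_samples = 4L) {
  stopifnot(min_samples >= 1L)
  keep <- rowSums(!is.na(table$geno)) >= min_samples
  if (!any(keep)) warning("no sites pass the min-samples filter")
  subset_snp_table(table, sites = keep)
}

#' Retain SNPs present in at least one outgroup sample
#' @param table a `snp_table`.
#' @param info a `sample_info` data.frame.
#' @return A `snp_table`.
#' @export
filter_outgroup_presence <- function(table, info) {
  og <- info$sample_id[info$role == "outgroup"]
  og <- intersect(og, sample_ids(table))
  if (!length(og)) stop("no outgroup samples available for presence filter")
  keep <- rowSums(!is.na(table$geno[, og, drop = FALSE])) >= 1L
  subset_snp_table(table, sites = keep)
}

#' Restrict a table to one or both locus sets
#' @param table a `snp_table`.
#' @param locus_sets subset of `c("assembled", "unassembled")`.
#' @return A `snp_table`.
#' @export
filter_locus_sets <- function(table, locus_sets) {
  keep <- table$sites$locus_set %in% locus_sets
  if (!any(keep)) warning("no sites in the requested locus set(s)")
  subset_snp_table(table, sites = keep)
}

minor_copy_counts <- function(table) {
  b <- rowSums(table$geno, na.rm = TRUE)
  n <- 2L * rowSums(!is.na(table$geno))
  pmin(b, n - b)
}

#' Select a single SNP per locus
#'
#' Under `mode = "random"` one SNP is drawn uniformly per locus. Under
#' `mode = "rare_allele_bias"` the draw is uniform over the locus's SNPs with
#' minor-allele copy count >= 2 (over non-missing calls), falling back to all
#' of the locus's SNPs when none qualify. Output site order follows first
#' appearance of each locus. Deterministic given `seed`.
#'
#' @param table a `snp_table`.
#' @param mode `"random"` or `"rare_allele_bias"`.
#' @param seed integer seed.
#' @return A `snp_table` with exactly one site per locus.
#' @export
select_one_snp_per_locus <- function(table,
                                     mode = c("random", "rare_allele_bias"),
                                     seed = 1L) {
  mode <- match.arg(mode)
  loci <- table$sites$locus_id
  mc <- if (mode == "rare_allele_bias") minor_copy_counts(table) else NULL
  set.seed(as.integer(seed))
  picks <- integer(0)
  for (locus in unique(loci)) {
    idx <- which(loci == locus)
    cand <- idx
    if (mode == "rare_allele_bias") {
      ok <- idx[mc[idx] >= 2L]
      if (length(ok)) cand <- ok
    }
    picks <- c(picks, if (length(cand) == 1L) cand else sample(cand, 1L))
  }
  subset_snp_table(table, sites = sort(picks))
}

#' Apply a population/sample subsetting scheme
#'
#' Implements the per-population sampling schemes (one random individual per
#' population, or downsampling every population to the common minimum size),
#' optional exclusion of tetraploid populations, and an optional group
#' filter. Outgroup samples are always kept.
#'
#' @param table a `snp_table`.
#' @param info a `sample_info` data.frame.
#' @param cfg a `selection_config`.
#' @return A list with elements `table` and `info`, both subset consistently.
#' @export
apply_population_scheme <- function(table, info, cfg) {
  info <- info[info$sample_id %in% sample_ids(table), , drop = FALSE]
  ing <- info[info$role == "ingroup", , drop = FALSE]
  og <- info[info$role == "outgroup", , drop = FALSE]

  if (!cfg$include_tetraploids) {
    ing <- ing[ing$ploidy != "tetraploid", , drop = FALSE]
  }
  if (!is.null(cfg$group_filter)) {
    if (!"group" %in% names(ing)) {
      stop("group_filter set but sample metadata has no 'group' column")
    }
    ing <- ing[ing$group %in% cfg$group_filter, , drop = FALSE]
  }
  if (!nrow(ing)) stop("no populations left after filtering")

  set.seed(cfg$seed)
  pops <- split(ing$sample_id, ing$population_id)
  keep <- switch(cfg$per_population_scheme,
    one_individual = vapply(pops, function(s) {
      if (length(s) == 1L) s else sample(s, 1L)
    }, character(1)),
    downsample_to_common = {
      m <- min(lengths(pops))
      unlist(lapply(pops, function(s) {
        if (length(s) == m) s else sample(s, m)
      }), use.names = FALSE)
    })
  keep <- c(unname(keep), og$sample_id)
  info_out <- info[match(keep, info$sample_id), , drop = FALSE]
  rownames(info_out) <- NULL
  class(info_out) <- c("sample_info", "data.frame")
  list(table = subset_snp_table(table, samples = keep), info = info_out)
}
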