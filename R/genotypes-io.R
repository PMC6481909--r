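#' SNP genotype tables
#'
#' A `snp_table` holds biallelic SNP genotype calls for a set of samples.
#' Internally each call is stored as the number of copies of `allele_b`
#' carried by the sample (0, 1 or 2; `NA` = missing). Genotypes are
#' diploid-coded even for tetraploid plants, since GBS callers emit diploid
#' calls; tetraploidy is handled downstream as a population-level
#' inclusion/exclusion flag.
#'
#' @param sites data.frame with columns `locus_id`, `snp_index`, `locus_set`
#'   (`"assembled"` or `"unassembled"`), `allele_a`, `allele_b`.
#' @param geno integer matrix, sites x samples, values in `{0, 1, 2, NA}` =
#'   copies of `allele_b`; column names are sample ids.
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(sites, geno) {
  stopifnot(is.data.frame(sites), is.matrix(geno))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("locus_id", "snp_index", "locus_set", "allele_a", "allele_b")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sites) != nrow(geno)) {
    stop("sites and geno disagree on the number of SNPs")
  }
  samples <- colnames(geno)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("geno must have unique sample ids as column names")
  }
  storage.mode(geno) <- "integer"
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0, 1 or 2 copies of allele_b (or NA)")
  }
  if (!all(sites$locus_set %in% c("assembled", "unassembled"))) {
    stop("locus_set must be 'assembled' or 'unassembled'")
  }
  if (any(sites$allele_a == sites$allele_b)) {
    stop("allele_a and allele_b must differ at every site")
  }
  key <- paste(sites$locus_id, sites$snp_index)
  if (anyDuplicated(key)) stop("duplicate locus_id + snp_index")
  sites$snp_index <- as.integer(sites$snp_index)
  rownames(geno) <- NULL
  structure(list(sites = sites, geno = geno), class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$sites), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.snp_table <- function(x) c(nrow(x$sites), ncol(x$geno))

#' Sample ids of a genotype table
#' @param table a `snp_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(table) colnames(table$geno)

#' Subset a genotype table by site and/or sample
#' @param table a `snp_table`.
#' @param sites integer or logical index over sites.
#' @param samples integer, logical or character index over samples.
#' @return A `snp_table`.
#' @export
subset_snp_table <- function(table, sites = NULL, samples = NULL) {
  geno <- table$geno
  site_df <- table$sites
  if (!is.null(sites)) {
    geno <- geno[sites, , drop = FALSE]
    site_df <- site_df[sites, , drop = FALSE]
    rownames(site_df) <- NULL
  }
  if (!is.null(samples)) geno <- geno[, samples, drop = FALSE]
  snp_table(site_df, geno)
}

parse_call <- function(call) {
  # "A/G" -> c("A", "G"); "./." -> NA
  if (call %in% c("./.", ".", "")) return(NULL)
  strsplit(call, "/", fixed = TRUE)[[1]]
}

#' Read a SNP genotype table
#'
#' Reads either the package's TSV genotype dialect (one row per site with
#' columns `locus_id`, `snp_index`, `locus_set`, `allele_a`, `allele_b`, then
#' one column per sample with calls like `"A/G"` or `"./."`) or a VCF
#' (v4.x, GT field, diploid-coded; requires the VariantAnnotation package).
#'
#' Sites with more than two observed alleles are dropped with a logged count,
#' as are sites that are empty or monomorphic across all non-missing calls.
#' Drop counts are attached as the `"dropped"` attribute.
#'
#' @param path path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A validated `snp_table`.
#' @export
read_genotype_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  tab <- switch(format,
                tsv = read_genotype_tsv(path),
                vcf = read_genotype_vcf(path))
  tab
}

read_genotype_tsv <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  meta_cols <- c("locus_id", "snp_index", "locus_set", "allele_a", "allele_b")
  if (!all(meta_cols %in% names(raw))) {
    stop("TSV genotype table must start with columns: ",
         paste(meta_cols, collapse = ", "))
  }
  samples <- setdiff(names(raw), meta_cols)
  if (!length(samples)) stop("TSV genotype table has no sample columns")
  if (anyDuplicated(samples)) stop("duplicate sample id in genotype table")

  n <- nrow(raw)
  geno <- matrix(NA_integer_, n, length(samples),
                 dimnames = list(NULL, samples))
  keep <- rep(TRUE, n)
  n_multi <- 0L
  n_mono <- 0L
  for (i in seq_len(n)) {
    a <- raw$allele_a[i]; b <- raw$allele_b[i]
    obs <- character(0)
    row_ok <- TRUE
    for (s in seq_along(samples)) {
      al <- parse_call(raw[[samples[s]]][i])
      if (is.null(al)) next
      obs <- union(obs, al)
      if (!all(al %in% c(a, b))) { row_ok <- FALSE; next }
      geno[i, s] <- sum(al == b)
    }
    if (!row_ok || length(obs) > 2L) {
      keep[i] <- FALSE; n_multi <- n_multi + 1L
    } else if (length(obs) < 2L) {
      keep[i] <- FALSE; n_mono <- n_mono + 1L
    }
  }
  if (n_multi) message(n_multi, " site(s) dropped: >2 observed alleles")
  if (n_mono) message(n_mono, " site(s) dropped: monomorphic or empty")
  if (!any(keep)) stop("empty table: no biallelic sites after validation")
  sites <- raw[keep, meta_cols]
  sites$snp_index <- as.integer(sites$snp_index)
  rownames(sites) <- NULL
  out <- snp_table(sites, geno[keep, , drop = FALSE])
  attr(out, "dropped") <- list(multiallelic = n_multi, monomorphic = n_mono)
  out
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1L] <- as.character(unlist(altl))[cumsum(n_alt)[n_alt >= 1L] -
                                                    n_alt[n_alt >= 1L] + 1L]
  chrom <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf)))

  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicate sample id in VCF")
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  geno <- apply(gt, 2, code)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(gt))
  colnames(geno) <- samples

  snv <- !is.na(alt1) & nchar(ref) == 1L & nchar(alt1) == 1L & n_alt == 1L
  n_multi <- sum(n_alt > 1L)
  nonmiss <- rowSums(!is.na(geno))
  # monomorphic across non-missing calls (all hom-ref or all hom-alt or empty)
  alt_copies <- rowSums(geno, na.rm = TRUE)
  poly <- nonmiss > 0L & alt_copies > 0L & alt_copies < 2L * nonmiss
  keep <- snv & poly
  n_mono <- sum(snv & !poly)
  if (n_multi) message(n_multi, " site(s) dropped: >2 alleles")
  if (n_mono) message(n_mono, " site(s) dropped: monomorphic or empty")
  if (!any(keep)) stop("empty table: no biallelic sites after validation")

  chrom_k <- chrom[keep]
  idx <- stats::ave(seq_along(chrom_k), chrom_k, FUN = seq_along) - 1L
  sites <- data.frame(locus_id = chrom_k,
                      snp_index = idx,
                      locus_set = "assembled",
                      allele_a = ref[keep],
                      allele_b = alt1[keep],
                      stringsAsFactors = FALSE)
  out <- snp_table(sites, geno[keep, , drop = FALSE])
  attr(out, "dropped") <- list(multiallelic = n_multi, monomorphic = n_mono)
  out
}

#' Write a SNP genotype table in the TSV dialect
#' @param table a `snp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  sites <- table$sites
  geno <- table$geno
  calls <- matrix("./.", nrow(geno), ncol(geno),
                  dimnames = dimnames(geno))
  a <- sites$allele_a; b <- sites$allele_b
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    calls[, j] <- ifelse(is.na(g), "./.",
                         ifelse(g == 0L, paste0(a, "/", a),
                                ifelse(g == 1L, paste0(a, "/", b),
                                       paste0(b, "/", b))))
  }
  out <- cbind(sites[, c("locus_id", "snp_index", "locus_set",
                         "allele_a", "allele_b")],
               as.data.frame(calls, stringsAsFactors = FALSE,
                             check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV with columns `sample_id`, `population_id`, `latitude`,
#' `longitude`, `ploidy` (`diploid`/`tetraploid`), `role`
#' (`ingroup`/`outgroup`) and optionally `outgroup_taxon` and `group`.
#' Outgroup samples may have empty coordinates; ingroup samples must not.
#' All samples of one population must share one coordinate pair and one
#' ploidy label.
#'
#' @param path path to the metadata TSV.
#' @return A `sample_info` data.frame.
#' @export
read_sample_info <- function(path) {
  if (!file.exists(path)) stop("cannot read sample metadata: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  as_sample_info(raw)
}

#' Validate and normalize sample metadata
#' @param df data.frame with the columns documented in [read_sample_info()].
#' @return A `sample_info` data.frame.
#' @export
as_sample_info <- function(df) {
  needed <- c("sample_id", "population_id", "latitude", "longitude",
              "ploidy", "role")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("sample metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"outgroup_taxon" %in% names(df)) df$outgroup_taxon <- NA_character_
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$ploidy %in% c("diploid", "tetraploid"))) {
    stop("ploidy must be 'diploid' or 'tetraploid'")
  }
  if (!all(df$role %in% c("ingroup", "outgroup"))) {
    stop("role must be 'ingroup' or 'outgroup'")
  }
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  lat_ok <- is.na(df$latitude) | (df$latitude >= -90 & df$latitude <= 90)
  if (!all(lat_ok)) stop("latitude out of [-90, 90]")
  # normalize longitude to [-180, 180]
  lon <- df$longitude
  lon <- ((lon + 180) %% 360) - 180
  df$longitude <- ifelse(is.na(df$longitude), NA_real_, lon)

  ing <- df$role == "ingroup"
  if (any(ing & (!is.finite(df$latitude) | !is.finite(df$longitude)))) {
    stop("every ingroup sample needs finite coordinates")
  }
  for (pop in unique(df$population_id[ing])) {
    rows <- df[ing & df$population_id == pop, ]
    if (length(unique(rows$latitude)) > 1L ||
        length(unique(rows$longitude)) > 1L) {
      stop("population '", pop, "' has mixed coordinates")
    }
    if (length(unique(rows$ploidy)) > 1L) {
      stop("population '", pop, "' has mixed ploidy labels")
    }
  }
  class(df) <- c("sample_info", "data.frame")
  df
}

#' Write a sample metadata table
#' @param info a `sample_info` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(info, path) {
  utils::write.table(as.data.frame(info), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write pipeline outputs
#'
#' Writes the psi, SE and informative-SNP-count matrices, the TDOA origin
#' surface, the PCoA coordinates and a JSON run summary into `out_dir` with a
#' deterministic column order, and returns the manifest of files created.
#'
#' @param psi a `psi_matrix`.
#' @param surface an `origin_surface`, or `NULL` to skip.
#' @param embedding a `pcoa_result`, or `NULL` to skip.
#' @param out_dir output directory (created if needed).
#' @param summary optional named list merged into the JSON run summary.
#' @return Character vector of files written (the manifest), invisibly.
#' @export
write_outputs <- function(psi, surface = NULL, embedding = NULL, out_dir,
                          summary = list()) {
  if (length(psi$populations) < 2L) stop("need >=2 populations")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- character(0)

  wm <- function(m, file) {
    df <- data.frame(population = rownames(m), m, check.names = FALSE)
    p <- file.path(out_dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  manifest <- c(manifest, wm(psi$psi, "psi.tsv"))
  manifest <- c(manifest, wm(psi$se, "psi_se.tsv"))
  manifest <- c(manifest, wm(psi$n_informative, "psi_n_informative.tsv"))

  if (!is.null(surface)) {
    p <- file.path(out_dir, "origin_surface.tsv")
    utils::write.table(surface$grid[, c("lat", "lon", "rss", "r2", "slope")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, p)
  }
  if (!is.null(embedding)) {
    p <- file.path(out_dir, "pcoa_coordinates.tsv")
    df <- data.frame(sample_id = rownames(embedding$points),
                     embedding$points, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, p)
  }

  summ <- c(list(populations = psi$populations, psi_settings = psi$settings),
            if (!is.null(surface)) list(
              best_origin = surface$best[c("lat", "lon")],
              slope = surface$best$slope,
              r2 = surface$best$r2,
              pvalue = surface$pvalue,
              boundary = surface$boundary),
            summary)
  p <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  manifest <- c(manifest, p)
  invisible(manifest)
}
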