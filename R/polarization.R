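#' Infer the ancestral allele of a site from outgroup calls
#'
#' Applies a strict unanimity rule: the ancestral state is accepted iff every
#' non-missing outgroup call is homozygous for the same allele and that
#' allele is one of the site's two alleles. Heterozygous, conflicting or
#' off-alphabet outgroup calls fail polarization for the site.
#'
#' @param allele_a,allele_b the site's two alleles (single bases).
#' @param outgroup_calls character vector of calls like `"A/A"`, `"A/G"`,
#'   `"./."`.
#' @return The ancestral base, or `NA_character_` on failure.
#' @export
infer_ancestral_allele <- function(allele_a, allele_b, outgroup_calls) {
  alleles <- lapply(outgroup_calls, parse_call)
  alleles <- alleles[!vapply(alleles, is.null, logical(1))]
  if (!length(alleles)) {
    stop("all outgroup calls missing; site should have been filtered")
  }
  hom <- vapply(alleles, function(a) length(unique(a)) == 1L, logical(1))
  if (!all(hom)) return(NA_character_)
  states <- unique(vapply(alleles, `[`, character(1), 1L))
  if (length(states) != 1L) return(NA_character_)
  if (!states %in% c(allele_a, allele_b)) return(NA_character_)
  states
}

#' Polarize a genotype table against its outgroup
#'
#' Assigns ancestral/derived states per site by outgroup unanimity (see
#' [infer_ancestral_allele()]) and counts derived-allele copies per ingroup
#' population. Sites failing polarization, and sites monomorphic across all
#' ingroup calls after polarization, are dropped with logged counts.
#'
#' @param table a `snp_table` that passed the outgroup-presence filter.
#' @param info a `sample_info` data.frame.
#' @param outgroup_taxon optional: restrict the outgroup to samples with this
#'   `outgroup_taxon` label (the analysis is usually repeated per taxon).
#' @return A `polarized_counts` object: per-site ancestral/derived alleles
#'   and matrices `k` (derived copies) and `n` (sampled chromosomes), sites x
#'   populations.
#' @export
polarize_table <- function(table, info, outgroup_taxon = NULL) {
  info <- info[info$sample_id %in% sample_ids(table), , drop = FALSE]
  og <- info[info$role == "outgroup", , drop = FALSE]
  if (!is.null(outgroup_taxon) && !is.na(outgroup_taxon)) {
    og <- og[!is.na(og$outgroup_taxon) & og$outgroup_taxon == outgroup_taxon, ,
             drop = FALSE]
  }
  if (!nrow(og)) stop("no outgroup samples for polarization")
  ing <- info[info$role == "ingroup", , drop = FALSE]
  if (!nrow(ing)) stop("no ingroup samples to polarize")

  og_geno <- table$geno[, og$sample_id, drop = FALSE]
  # unanimity on encoded calls: all non-missing outgroup calls 0 (hom allele_a)
  # or all 2 (hom allele_b)
  n_og <- rowSums(!is.na(og_geno))
  all0 <- rowSums(og_geno == 0L, na.rm = TRUE) == n_og & n_og > 0L
  all2 <- rowSums(og_geno == 2L, na.rm = TRUE) == n_og & n_og > 0L
  polarized <- all0 | all2
  n_fail <- sum(n_og > 0L) - sum(polarized)
  if (any(n_og == 0L)) {
    stop("table contains sites with no outgroup call; ",
         "run filter_outgroup_presence first")
  }
  if (n_fail) message(n_fail, " site(s) dropped: polarization failed")

  pops <- unique(ing$population_id)
  sub <- which(polarized)
  k <- matrix(0L, length(sub), length(pops), dimnames = list(NULL, pops))
  n <- matrix(0L, length(sub), length(pops), dimnames = list(NULL, pops))
  anc_is_b <- all2[sub]
  for (p in seq_along(pops)) {
    cols <- ing$sample_id[ing$population_id == pops[p]]
    g <- table$geno[sub, cols, drop = FALSE]
    nn <- 2L * rowSums(!is.na(g))
    bb <- as.integer(rowSums(g, na.rm = TRUE))
    # derived copies: allele_b copies when ancestral = allele_a, else flipped
    k[, p] <- ifelse(anc_is_b, nn - bb, bb)
    n[, p] <- nn
  }
  tot_k <- rowSums(k)
  tot_n <- rowSums(n)
  mono <- tot_k == 0L | tot_k == tot_n
  if (any(mono)) {
    message(sum(mono), " site(s) dropped: monomorphic after polarization")
  }
  keep <- !mono
  sites <- table$sites[sub[keep], , drop = FALSE]
  anc_b <- anc_is_b[keep]
  sites$ancestral <- ifelse(anc_b, sites$allele_b, sites$allele_a)
  sites$derived <- ifelse(anc_b, sites$allele_a, sites$allele_b)
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 k = k[keep, , drop = FALSE],
                 n = n[keep, , drop = FALSE],
                 populations = pops,
                 n_failed = n_fail,
                 n_monomorphic = sum(mono)),
            class = "polarized_counts")
}

#' @export
print.polarized_counts <- function(x, ...) {
  cat(sprintf("polarized_counts: %d sites x %d populations\n",
              nrow(x$sites), length(x$populations)))
  invisible(x)
}

#' Hypergeometric projection of derived-allele counts
#'
#' Deterministic downsampling: the distribution of the number of derived
#' copies in a sample of `m` chromosomes drawn without replacement from `n`
#' chromosomes of which `k` are derived,
#' \deqn{P(j) = C(k, j) C(n-k, m-j) / C(n, m).}
#' Its mean is `m k / n`, so projection leaves the expected derived-allele
#' frequency unchanged.
#'
#' @param k derived copies in the full sample, `0 <= k <= n`.
#' @param n sampled chromosomes.
#' @param m projection size, `1 <= m <= n`.
#' @return Numeric probability vector over `0..m` (sums to 1).
#' @export
project_counts <- function(k, n, m) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(m) == 1L)
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  if (m < 1) stop("need m >= 1")
  if (m > n) stop("projection unavailable: m > n")
  j <- 0:m
  p <- choose(k, j) * choose(n - k, m - j) / choose(n, m)
  p
}
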