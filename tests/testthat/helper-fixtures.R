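# Hand-built fixtures shared across test files. Everything is constructed in
# code; no binary data.

# snp_table from a bare genotype matrix (sites x samples, 0/1/2/NA = copies
# of allele_b), one locus per site unless locus_id given
make_table <- function(geno, locus_id = NULL, snp_index = NULL,
                       locus_set = "assembled",
                       allele_a = "A", allele_b = "G") {
  geno <- as.matrix(geno)
  S <- nrow(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("s%d", seq_len(ncol(geno)))
  }
  if (is.null(locus_id)) locus_id <- sprintf("L%03d", seq_len(S))
  if (is.null(snp_index)) {
    snp_index <- stats::ave(seq_len(S), locus_id, FUN = seq_along) - 1L
  }
  sites <- data.frame(locus_id = locus_id, snp_index = snp_index,
                      locus_set = rep_len(locus_set, S),
                      allele_a = rep_len(allele_a, S),
                      allele_b = rep_len(allele_b, S),
                      stringsAsFactors = FALSE)
  snp_table(sites, geno)
}

# 3 ingroup populations x 2 samples + 3 outgroup samples (2 taxa)
toy_info <- function() {
  as_sample_info(data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6", "o1", "o2", "o3"),
    population_id = c("p1", "p1", "p2", "p2", "p3", "p3",
                      "out", "out", "out"),
    latitude = c(-22, -22, -24, -24, -26, -26, NA, NA, NA),
    longitude = c(120, 120, 123, 123, 126, 126, NA, NA, NA),
    ploidy = c(rep("diploid", 4), rep("tetraploid", 2), rep("diploid", 3)),
    role = c(rep("ingroup", 6), rep("outgroup", 3)),
    outgroup_taxon = c(rep(NA, 6), "outA", "outA", "outB"),
    stringsAsFactors = FALSE))
}

# polarized_counts from k and n matrices (sites x populations)
make_counts <- function(k, n) {
  k <- as.matrix(k); n <- as.matrix(n)
  pops <- colnames(k)
  if (is.null(pops)) pops <- sprintf("p%d", seq_len(ncol(k)))
  colnames(k) <- colnames(n) <- pops
  S <- nrow(k)
  sites <- data.frame(locus_id = sprintf("L%03d", seq_len(S)),
                      snp_index = 0L, locus_set = "assembled",
                      allele_a = "A", allele_b = "G",
                      ancestral = "A", derived = "G",
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, k = k, n = n, populations = pops,
                 n_failed = 0L, n_monomorphic = 0L),
            class = "polarized_counts")
}

# metadata for populations laid out on a line, one sample per population
line_info <- function(n_pops, lat0 = -24, lon0 = 120, dlon = 0.5) {
  as_sample_info(data.frame(
    sample_id = sprintf("p%02d_s1", seq_len(n_pops)),
    population_id = sprintf("p%02d", seq_len(n_pops)),
    latitude = lat0,
    longitude = lon0 + dlon * (seq_len(n_pops) - 1L),
    ploidy = "diploid", role = "ingroup",
    outgroup_taxon = NA_character_,
    stringsAsFactors = FALSE))
}

# panmictic split: one pool of S SNPs, two pseudo-populations of n_dip
# diploids each, counts drawn binomially from shared frequencies
panmictic_counts <- function(S, n_dip, seed) {
  set.seed(seed)
  freq <- draw_sfs_freqs(S)
  k1 <- stats::rbinom(S, 2L * n_dip, freq)
  k2 <- stats::rbinom(S, 2L * n_dip, freq)
  n <- matrix(2L * n_dip, S, 2)
  make_counts(cbind(a = k1, b = k2), n)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

draw_sfs_freqs <- function(S, chroms = 200L) {
  counts <- seq_len(chroms - 1L)
  w <- 1 / counts
  sample(counts, S, replace = TRUE, prob = w / sum(w)) / chroms
}
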