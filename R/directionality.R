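#' Pairwise directionality index psi
#'
#' psi for an ordered population pair (i, j) is the mean, over informative
#' shared derived SNPs, of the derived-allele frequency difference
#' f_j - f_i. Under a serial-founder expansion, allele surfing makes derived
#' alleles more frequent further from the origin, so psi(i, j) > 0 indicates
#' population j lies farther from the origin than population i.
#'
#' A site enters the comparison when both populations have at least `m`
#' sampled chromosomes (the projection size), and is informative when the
#' derived allele is present on both sides (k > 0 in both) and the pair is
#' not jointly fixed for it (not k = n in both). The hypergeometric
#' projection to `m` chromosomes leaves the expected frequency k/n
#' unchanged, so psi is computed from the unprojected frequencies.
#'
#' @param counts a `polarized_counts` object.
#' @param pop_i,pop_j population ids.
#' @param m projection size in chromosomes (default 2, the smallest size
#'   compatible with one diploid individual per population).
#' @return A `psi_estimate` list: `pop_i`, `pop_j`, `psi` (NA when no
#'   informative sites exist), `se` (NA unless bootstrapped),
#'   `n_informative`, `m`.
#' @export
compute_psi_pair <- function(counts, pop_i, pop_j, m = 2L) {
  stopifnot(m >= 1L)
  d <- psi_pair_differences(counts, pop_i, pop_j, m)
  psi <- if (length(d)) mean(d) else NA_real_
  structure(list(pop_i = pop_i, pop_j = pop_j, psi = psi, se = NA_real_,
                 n_informative = length(d), m = as.integer(m)),
            class = "psi_estimate")
}

# per-site frequency differences f_j - f_i over informative sites
psi_pair_differences <- function(counts, pop_i, pop_j, m) {
  pops <- counts$populations
  if (!pop_i %in% pops || !pop_j %in% pops) {
    stop("unknown population id: ",
         paste(setdiff(c(pop_i, pop_j), pops), collapse = ", "))
  }
  ki <- counts$k[, pop_i]; ni <- counts$n[, pop_i]
  kj <- counts$k[, pop_j]; nj <- counts$n[, pop_j]
  usable <- ni >= m & nj >= m
  informative <- usable & ki > 0L & kj > 0L & !(ki == ni & kj == nj)
  kj[informative] / nj[informative] - ki[informative] / ni[informative]
}

#' Compute the full antisymmetric psi matrix
#'
#' Evaluates every unordered population pair once and fills psi(j, i) =
#' -psi(i, j), so antisymmetry holds exactly by construction. Optionally
#' attaches bootstrap standard errors (see [bootstrap_psi()]).
#'
#' @param counts a `polarized_counts` object.
#' @param m projection size in chromosomes.
#' @param B number of bootstrap resamples for standard errors; 0 disables.
#' @param seed integer seed for the bootstrap.
#' @return A `psi_matrix`: `populations`, matrices `psi`, `se`,
#'   `n_informative`, and `settings` (m, B, seed).
#' @export
compute_psi_matrix <- function(counts, m = 2L, B = 0L, seed = 1L) {
  pops <- counts$populations
  if (length(pops) < 2L) stop("need >=2 populations for a psi matrix")
  P <- length(pops)
  psi <- matrix(0, P, P, dimnames = list(pops, pops))
  se <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  ninf <- matrix(0L, P, P, dimnames = list(pops, pops))
  diag(se) <- 0
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      d <- psi_pair_differences(counts, pops[i], pops[j], m)
      ninf[i, j] <- ninf[j, i] <- length(d)
      psi[i, j] <- if (length(d)) mean(d) else NA_real_
      psi[j, i] <- -psi[i, j]
      if (B >= 100L && length(d) >= 2L) {
        bs <- bootstrap_differences(d, B, pair_seed(seed, i, j))
        se[i, j] <- se[j, i] <- bs$se
      }
    }
  }
  structure(list(populations = pops, psi = psi, se = se,
                 n_informative = ninf,
                 settings = list(m = as.integer(m), B = as.integer(B),
                                 seed = as.integer(seed))),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("psi_matrix: %d populations (m = %d)\n",
              length(x$populations), x$settings$m))
  invisible(x)
}

# deterministic per-pair seed, independent of pair evaluation order
pair_seed <- function(seed, i, j) {
  (as.integer(seed) + 7919L * i + 104729L * j) %% 2147483647L
}

bootstrap_differences <- function(d, B, seed) {
  set.seed(seed)
  S <- length(d)
  reps <- vapply(seq_len(B),
                 function(b) mean(d[sample.int(S, S, replace = TRUE)]),
                 numeric(1))
  list(se = stats::sd(reps),
       ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
       psi_boot = reps)
}

#' Bootstrap standard error of psi for one pair
#'
#' Resamples the informative sites with replacement `B` times and returns
#' the standard deviation and percentile interval of the bootstrap psi
#' replicates. Deterministic given `seed`.
#'
#' @param counts a `polarized_counts` object.
#' @param pop_i,pop_j population ids.
#' @param m projection size.
#' @param B number of resamples (>= 100).
#' @param seed integer seed.
#' @return List with `psi`, `se` (NA with `undefined = TRUE` when fewer than
#'   2 informative sites), `ci` (2.5/97.5 percentiles), `n_informative`, `B`.
#' @export
bootstrap_psi <- function(counts, pop_i, pop_j, m = 2L, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L)
  d <- psi_pair_differences(counts, pop_i, pop_j, m)
  if (length(d) < 2L) {
    return(list(psi = if (length(d)) mean(d) else NA_real_, se = NA_real_,
                ci = c(NA_real_, NA_real_), n_informative = length(d),
                B = as.integer(B), undefined = TRUE))
  }
  bs <- bootstrap_differences(d, B, as.integer(seed))
  list(psi = mean(d), se = bs$se, ci = bs$ci, n_informative = length(d),
       B = as.integer(B), undefined = FALSE)
}
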