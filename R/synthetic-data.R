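#' Configuration for the serial-founder expansion simulator
#'
#' Describes a forward-time Wright-Fisher world on a deme lattice: a single
#' origin deme holds standing variation with a neutral-SFS-like (1/f)
#' derived-frequency spectrum; a colonization wave founds each new deme with
#' `founder_size` individuals drawn from a random already-colonized
#' neighbour (allele surfing), after which demes grow to `deme_size` and
#' exchange migrants with lattice neighbours. Sampling emits diploid GBS-like
#' genotypes with per-call missingness plus an outgroup fixed for the
#' ancestral allele (mispolarized at a configurable fraction of sites).
#'
#' @param lattice integer c(rows, cols) of demes.
#' @param origin_deme integer c(row, col) of the origin.
#' @param deme_size K, diploid individuals per established deme.
#' @param founder_size F <= K, founders of each newly colonized deme.
#' @param migration_rate m, per-individual per-generation migration
#'   probability to adjacent demes.
#' @param generations_per_colonization generations between colonization
#'   waves.
#' @param total_snps number of unlinked SNPs (one per locus).
#' @param mispolarization_rate fraction of sites where the outgroup carries
#'   the derived allele instead of the ancestral one.
#' @param missingness_rate per-call missing probability (GBS-style).
#' @param sampled_demes integer matrix / data.frame of (row, col) demes to
#'   sample, or `NULL` to spread 15 demes evenly over the lattice.
#' @param samples_per_deme diploid individuals sampled per deme.
#' @param tetraploid_demes optional (row, col) matrix of demes to label
#'   tetraploid (calls stay diploid-coded; the label only drives
#'   inclusion/exclusion downstream).
#' @param n_outgroup number of outgroup samples.
#' @param km_per_step geographic scale of one lattice step.
#' @param anchor_lat,anchor_lon coordinates of deme (1, 1); defaults sit in
#'   arid central Australia purely for realism of map output.
#' @param seed integer seed.
#' @return An `expansion_sim_config` list.
#' @export
expansion_sim_config <- function(lattice = c(8L, 8L),
                                 origin_deme = c(1L, 1L),
                                 deme_size = 100L,
                                 founder_size = 10L,
                                 migration_rate = 0.05,
                                 generations_per_colonization = 1L,
                                 total_snps = 2000L,
                                 mispolarization_rate = 0,
                                 missingness_rate = 0.1,
                                 sampled_demes = NULL,
                                 samples_per_deme = 2L,
                                 tetraploid_demes = NULL,
                                 n_outgroup = 3L,
                                 km_per_step = 50,
                                 anchor_lat = -23.5,
                                 anchor_lon = 125,
                                 seed = 1L) {
  stopifnot(length(lattice) == 2L, all(lattice >= 1L),
            length(origin_deme) == 2L,
            founder_size <= deme_size, founder_size >= 1L,
            migration_rate >= 0, migration_rate <= 1,
            mispolarization_rate >= 0, mispolarization_rate <= 1,
            missingness_rate >= 0, missingness_rate <= 1,
            generations_per_colonization >= 1L,
            total_snps >= 1L, samples_per_deme >= 1L, n_outgroup >= 1L)
  if (origin_deme[1L] < 1L || origin_deme[1L] > lattice[1L] ||
      origin_deme[2L] < 1L || origin_deme[2L] > lattice[2L]) {
    stop("origin_deme must lie on the lattice")
  }
  if (is.null(sampled_demes)) {
    sampled_demes <- default_sampled_demes(lattice, 15L)
  }
  sampled_demes <- as.matrix(sampled_demes)
  if (any(sampled_demes[, 1L] < 1L | sampled_demes[, 1L] > lattice[1L] |
          sampled_demes[, 2L] < 1L | sampled_demes[, 2L] > lattice[2L])) {
    stop("sampled demes must lie on the lattice")
  }
  structure(list(lattice = as.integer(lattice),
                 origin_deme = as.integer(origin_deme),
                 deme_size = as.integer(deme_size),
                 founder_size = as.integer(founder_size),
                 migration_rate = migration_rate,
                 generations_per_colonization =
                   as.integer(generations_per_colonization),
                 total_snps = as.integer(total_snps),
                 mispolarization_rate = mispolarization_rate,
                 missingness_rate = missingness_rate,
                 sampled_demes = sampled_demes,
                 samples_per_deme = as.integer(samples_per_deme),
                 tetraploid_demes = if (is.null(tetraploid_demes)) NULL
                                    else as.matrix(tetraploid_demes),
                 n_outgroup = as.integer(n_outgroup),
                 km_per_step = km_per_step,
                 anchor_lat = anchor_lat, anchor_lon = anchor_lon,
                 seed = as.integer(seed)),
            class = "expansion_sim_config")
}

#' Configuration for the stepping-stone isolation-by-distance null
#'
#' As [expansion_sim_config()] but with every deme occupied from generation
#' zero at full size from one shared ancestral pool, with no colonization
#' wave; migration-drift equilibrium is approximated by burn-in.
#'
#' @inheritParams expansion_sim_config
#' @param burn_in_generations generations of migration + drift before
#'   sampling; at least 10 * `deme_size` is recommended (a warning is logged
#'   otherwise).
#' @return An `ibd_sim_config` list.
#' @export
ibd_sim_config <- function(lattice = c(8L, 8L),
                           deme_size = 100L,
                           migration_rate = 0.05,
                           total_snps = 2000L,
                           burn_in_generations = 10L * deme_size,
                           mispolarization_rate = 0,
                           missingness_rate = 0.1,
                           sampled_demes = NULL,
                           samples_per_deme = 2L,
                           tetraploid_demes = NULL,
                           n_outgroup = 3L,
                           km_per_step = 50,
                           anchor_lat = -23.5,
                           anchor_lon = 125,
                           seed = 1L) {
  cfg <- expansion_sim_config(lattice = lattice, origin_deme = c(1L, 1L),
                              deme_size = deme_size, founder_size = deme_size,
                              migration_rate = migration_rate,
                              total_snps = total_snps,
                              mispolarization_rate = mispolarization_rate,
                              missingness_rate = missingness_rate,
                              sampled_demes = sampled_demes,
                              samples_per_deme = samples_per_deme,
                              tetraploid_demes = tetraploid_demes,
                              n_outgroup = n_outgroup,
                              km_per_step = km_per_step,
                              anchor_lat = anchor_lat,
                              anchor_lon = anchor_lon, seed = seed)
  cfg$origin_deme <- NULL
  cfg$founder_size <- NULL
  cfg$generations_per_colonization <- NULL
  cfg$burn_in_generations <- as.integer(burn_in_generations)
  class(cfg) <- "ibd_sim_config"
  cfg
}

default_sampled_demes <- function(lattice, n) {
  # near-uniform spatial coverage: a k x k sub-grid of evenly spaced demes,
  # trimmed to n by dropping the cells nearest the lattice centroid (the
  # periphery defines the sampled extent, as field sampling tends to)
  n <- min(n, prod(lattice))
  k <- ceiling(sqrt(n))
  rows <- unique(round(seq(1, lattice[1L], length.out = min(k, lattice[1L]))))
  cols <- unique(round(seq(1, lattice[2L], length.out = min(k, lattice[2L]))))
  g <- as.matrix(expand.grid(row = rows, col = cols))
  while (nrow(g) < n) {  # thin lattices: fill with remaining demes in order
    all <- as.matrix(expand.grid(row = seq_len(lattice[1L]),
                                 col = seq_len(lattice[2L])))
    extra <- all[!paste(all[, 1], all[, 2]) %in% paste(g[, 1], g[, 2]), ,
                 drop = FALSE]
    g <- rbind(g, extra[seq_len(min(n - nrow(g), nrow(extra))), ,
                        drop = FALSE])
  }
  if (nrow(g) > n) {
    cen <- (lattice + 1) / 2
    d2 <- (g[, 1] - cen[1])^2 + (g[, 2] - cen[2])^2
    g <- g[order(-d2, seq_len(nrow(g)))[seq_len(n)], , drop = FALSE]
    g <- g[order(g[, 1], g[, 2]), , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  g
}

deme_index <- function(r, c, lattice) (r - 1L) * lattice[2L] + c

deme_neighbours <- function(lattice, king = FALSE) {
  R <- lattice[1L]; C <- lattice[2L]
  steps <- if (king) {
    cbind(rep(-1:1, each = 3), rep(-1:1, times = 3))[-5, , drop = FALSE]
  } else {
    rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  }
  lapply(seq_len(R * C), function(d) {
    r <- (d - 1L) %/% C + 1L
    c <- (d - 1L) %% C + 1L
    nb <- cbind(r + steps[, 1L], c + steps[, 2L])
    nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= R &
               nb[, 2L] >= 1L & nb[, 2L] <= C, , drop = FALSE]
    deme_index(nb[, 1L], nb[, 2L], lattice)
  })
}

deme_coordinates <- function(lattice, km_per_step, anchor_lat, anchor_lon) {
  # local tangent-plane mapping; one degree latitude ~ 110.574 km, one degree
  # longitude scaled by cos(anchor latitude)
  r <- rep(seq_len(lattice[1L]), each = lattice[2L])
  c <- rep(seq_len(lattice[2L]), times = lattice[1L])
  lat <- anchor_lat - (r - 1L) * km_per_step / 110.574
  lon <- anchor_lon + (c - 1L) * km_per_step /
    (111.320 * cos(anchor_lat * pi / 180))
  cbind(lat = lat, lon = lon)
}

# P(frequency) ~ 1/count, counts 1..(2K - 1): neutral-SFS-like standing
# variation conditioned on polymorphism
draw_initial_freqs <- function(S, K) {
  counts <- seq_len(2L * K - 1L)
  w <- 1 / counts
  sample(counts, S, replace = TRUE, prob = w / sum(w)) / (2 * K)
}

migrate_drift <- function(p, occ, nbrs, m, K) {
  # p: demes x S frequency matrix; one generation of migration then drift
  # over the occupied demes
  occ_idx <- which(occ)
  pm <- p
  for (d in occ_idx) {
    nb <- nbrs[[d]][occ[nbrs[[d]]]]
    if (length(nb)) {
      nb_mean <- if (length(nb) == 1L) p[nb, ] else colMeans(p[nb, , drop = FALSE])
      pm[d, ] <- (1 - m) * p[d, ] + m * nb_mean
    }
  }
  S <- ncol(p)
  draws <- stats::rbinom(length(occ_idx) * S, 2L * K,
                         as.vector(pm[occ_idx, , drop = FALSE]))
  p[occ_idx, ] <- matrix(draws / (2 * K), length(occ_idx), S)
  p
}

sample_genotypes <- function(cfg, p, truth_extra = NULL) {
  S <- cfg$total_snps
  sd_mat <- cfg$sampled_demes
  n_demes <- nrow(sd_mat)
  coords <- deme_coordinates(cfg$lattice, cfg$km_per_step,
                             cfg$anchor_lat, cfg$anchor_lon)
  pop_ids <- sprintf("d%02d_%02d", sd_mat[, 1L], sd_mat[, 2L])

  n_ing <- n_demes * cfg$samples_per_deme
  geno <- matrix(NA_integer_, S, n_ing + cfg$n_outgroup)
  ids <- character(n_ing + cfg$n_outgroup)
  meta <- vector("list", n_ing + cfg$n_outgroup)
  col <- 0L
  tetra <- rep(FALSE, n_demes)
  if (!is.null(cfg$tetraploid_demes)) {
    tkey <- paste(cfg$tetraploid_demes[, 1L], cfg$tetraploid_demes[, 2L])
    tetra <- paste(sd_mat[, 1L], sd_mat[, 2L]) %in% tkey
  }
  for (d in seq_len(n_demes)) {
    di <- deme_index(sd_mat[d, 1L], sd_mat[d, 2L], cfg$lattice)
    for (s in seq_len(cfg$samples_per_deme)) {
      col <- col + 1L
      geno[, col] <- stats::rbinom(S, 2L, p[di, ])
      ids[col] <- sprintf("%s_s%d", pop_ids[d], s)
      meta[[col]] <- data.frame(sample_id = ids[col],
                                population_id = pop_ids[d],
                                latitude = coords[di, "lat"],
                                longitude = coords[di, "lon"],
                                ploidy = if (tetra[d]) "tetraploid"
                                         else "diploid",
                                role = "ingroup",
                                outgroup_taxon = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  flipped <- stats::runif(S) < cfg$mispolarization_rate
  for (o in seq_len(cfg$n_outgroup)) {
    col <- col + 1L
    geno[, col] <- ifelse(flipped, 2L, 0L)
    ids[col] <- sprintf("outgroup_s%d", o)
    meta[[col]] <- data.frame(sample_id = ids[col],
                              population_id = "outgroup",
                              latitude = NA_real_, longitude = NA_real_,
                              ploidy = "diploid", role = "outgroup",
                              outgroup_taxon = "virtual_outgroup",
                              stringsAsFactors = FALSE)
  }
  colnames(geno) <- ids
  miss <- matrix(stats::runif(length(geno)) < cfg$missingness_rate,
                 nrow(geno), ncol(geno))
  geno[miss] <- NA_integer_

  # allele bases; allele_a is ancestral by construction
  a <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
              character(1))
  sites <- data.frame(locus_id = sprintf("locus%05d", seq_len(S)),
                      snp_index = 0L,
                      locus_set = sample(c("assembled", "unassembled"), S,
                                         replace = TRUE),
                      allele_a = unname(a), allele_b = unname(b),
                      stringsAsFactors = FALSE)
  # keep sites polymorphic across all non-missing calls
  nonmiss <- rowSums(!is.na(geno))
  bcopies <- rowSums(geno, na.rm = TRUE)
  keep <- nonmiss > 0L & bcopies > 0L & bcopies < 2L * nonmiss
  table <- snp_table(sites[keep, , drop = FALSE], geno[keep, , drop = FALSE])
  info <- as_sample_info(do.call(rbind, meta))
  truth <- c(list(populations = pop_ids,
                  deme_row = sd_mat[, 1L], deme_col = sd_mat[, 2L],
                  pop_lat = coords[deme_index(sd_mat[, 1L], sd_mat[, 2L],
                                              cfg$lattice), "lat"],
                  pop_lon = coords[deme_index(sd_mat[, 1L], sd_mat[, 2L],
                                              cfg$lattice), "lon"],
                  derived_allele = table$sites$allele_b,
                  mispolarized = flipped[keep],
                  km_per_step = cfg$km_per_step,
                  seed = cfg$seed),
             truth_extra)
  list(table = table, info = info, truth = truth)
}

#' Simulate a serial-founder range expansion
#'
#' Forward-time binomial Wright-Fisher per deme per unlinked SNP. The
#' colonization wave advances from the origin by lattice-graph distance:
#' each newly colonized deme is founded by `founder_size` diploid
#' individuals drawn binomially from a random already-colonized neighbour,
#' then grows to `deme_size` and joins migration. Repeated founder
#' bottlenecks make derived alleles surf, producing the frequency clines the
#' directionality index detects.
#'
#' @param cfg an `expansion_sim_config`.
#' @return List with `table` (a `snp_table`), `info` (a `sample_info`) and
#'   `truth` (origin coordinates, per-population colonization order and
#'   per-site derived alleles, sufficient to score origin recovery without
#'   re-reading the config).
#' @export
simulate_expansion <- function(cfg) {
  stopifnot(inherits(cfg, "expansion_sim_config"))
  set.seed(cfg$seed)
  R <- cfg$lattice[1L]; C <- cfg$lattice[2L]
  ndemes <- R * C
  S <- cfg$total_snps
  K <- cfg$deme_size
  nbrs <- deme_neighbours(cfg$lattice)

  # the wavefront advances at constant speed in space (circular front), as
  # the TDOA model assumes: demes are colonized in order of Euclidean
  # lattice distance from the origin, grouped into unit-distance rings
  r <- rep(seq_len(R), each = C)
  c <- rep(seq_len(C), times = R)
  dist0 <- sqrt((r - cfg$origin_deme[1L])^2 + (c - cfg$origin_deme[2L])^2)
  ring <- ceiling(dist0)

  p <- matrix(0, ndemes, S)
  origin <- deme_index(cfg$origin_deme[1L], cfg$origin_deme[2L], cfg$lattice)
  p[origin, ] <- draw_initial_freqs(S, K)
  occ <- dist0 == 0

  # founders come from an established (previous-ring) king-move neighbour,
  # so every deme sits at the end of a founder chain of length = its ring:
  # drift accumulates in proportion to distance from the origin
  nbrs8 <- deme_neighbours(cfg$lattice, king = TRUE)
  for (step in seq_len(max(ring))) {
    wave <- which(ring == step)
    for (d in wave[order(dist0[wave])]) {
      src_cand <- nbrs8[[d]][occ[nbrs8[[d]]] & ring[nbrs8[[d]]] < ring[d]]
      if (!length(src_cand)) {
        src_cand <- nbrs8[[d]][occ[nbrs8[[d]]] & dist0[nbrs8[[d]]] < dist0[d]]
      }
      src <- if (length(src_cand) == 1L) src_cand else sample(src_cand, 1L)
      p[d, ] <- stats::rbinom(S, 2L * cfg$founder_size, p[src, ]) /
        (2 * cfg$founder_size)
      occ[d] <- TRUE
    }
    for (g in seq_len(cfg$generations_per_colonization)) {
      p <- migrate_drift(p, occ, nbrs, cfg$migration_rate, K)
    }
  }

  coords <- deme_coordinates(cfg$lattice, cfg$km_per_step,
                             cfg$anchor_lat, cfg$anchor_lon)
  sd_mat <- cfg$sampled_demes
  order_step <- ring[deme_index(sd_mat[, 1L], sd_mat[, 2L], cfg$lattice)]
  sample_genotypes(cfg, p, truth_extra = list(
    origin_lat = coords[origin, "lat"],
    origin_lon = coords[origin, "lon"],
    origin_deme = cfg$origin_deme,
    colonization_step = order_step))
}

#' Simulate a stepping-stone isolation-by-distance null
#'
#' Every deme starts occupied at full size with the same standing variation
#' (one shared ancestral pool), then drifts and migrates for
#' `burn_in_generations`. There is no colonization order and no origin, so
#' any directionality signal is spurious — this is the null world against
#' which the expansion test's size is checked.
#'
#' @param cfg an `ibd_sim_config`.
#' @return List with `table` and `info` as [simulate_expansion()].
#' @export
simulate_ibd <- function(cfg) {
  stopifnot(inherits(cfg, "ibd_sim_config"))
  if (cfg$burn_in_generations < 10L * cfg$deme_size) {
    message("burn-in below the recommended 10 * deme_size generations; ",
            "equilibrium may be approximate")
  }
  set.seed(cfg$seed)
  ndemes <- prod(cfg$lattice)
  S <- cfg$total_snps
  K <- cfg$deme_size
  nbrs <- deme_neighbours(cfg$lattice)
  p0 <- draw_initial_freqs(S, K)
  p <- matrix(rep(p0, each = ndemes), ndemes, S)
  occ <- rep(TRUE, ndemes)
  for (g in seq_len(cfg$burn_in_generations)) {
    p <- migrate_drift(p, occ, nbrs, cfg$migration_rate, K)
  }
  out <- sample_genotypes(cfg, p)
  out["truth"] <- NULL
  out
}

#' Plant an exactly linear psi field around a known origin
#'
#' Direct generator for exact TDOA tests: psi(i, j) = slope * (d(origin, j)
#' - d(origin, i)) plus optional Gaussian noise applied to unordered pairs,
#' antisymmetrized by construction. Values are clipped to [-1, 1] with a
#' warning if clipping occurs.
#'
#' @param info a `sample_info` (its ingroup populations are used).
#' @param origin c(lat, lon) of the planted origin.
#' @param slope psi per kilometre.
#' @param noise_sd standard deviation of pair-level Gaussian noise.
#' @param seed integer seed.
#' @return A `psi_matrix`.
#' @export
plant_linear_psi <- function(info, origin, slope, noise_sd = 0, seed = 1L) {
  stopifnot(is.finite(slope), noise_sd >= 0)
  pc <- population_coordinates(info)
  pops <- pc$population_id
  P <- length(pops)
  d <- geodesic_distance(origin[1L], origin[2L], pc$lat, pc$lon)
  psi <- outer(d, d, function(di, dj) slope * (dj - di))
  # note: outer gives psi[i, j] = slope * (d_j - d_i) — row i, column j
  set.seed(as.integer(seed))
  if (noise_sd > 0) {
    eps <- matrix(0, P, P)
    eps[upper.tri(eps)] <- stats::rnorm(P * (P - 1L) / 2L, 0, noise_sd)
    eps <- eps - t(eps)
    psi <- psi + eps
  }
  if (any(abs(psi) > 1)) {
    warning("planted psi clipped to [-1, 1]")
    psi[psi > 1] <- 1
    psi[psi < -1] <- -1
    psi <- (psi - t(psi)) / 2
  }
  dimnames(psi) <- list(pops, pops)
  se <- matrix(0, P, P, dimnames = list(pops, pops))
  ninf <- matrix(1L, P, P, dimnames = list(pops, pops))
  diag(ninf) <- 0L
  structure(list(populations = pops, psi = psi, se = se,
                 n_informative = ninf,
                 settings = list(m = NA_integer_, B = 0L,
                                 seed = as.integer(seed), planted = TRUE,
                                 slope = slope, noise_sd = noise_sd)),
            class = "psi_matrix")
}
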