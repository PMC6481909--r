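test_that("simulators are deterministic under a fixed seed", {
  cfg <- expansion_sim_config(lattice = c(3, 3), total_snps = 200,
                              deme_size = 30, founder_size = 5,
                              sampled_demes = cbind(1:3, 1:3), seed = 99)
  a <- simulate_expansion(cfg)
  b <- simulate_expansion(cfg)
  expect_identical(a$table$geno, b$table$geno)
  expect_identical(a$table$sites, b$table$sites)
  expect_identical(a$info, b$info)
  expect_identical(a$truth, b$truth)

  icfg <- ibd_sim_config(lattice = c(3, 3), deme_size = 20, total_snps = 150,
                         burn_in_generations = 200,
                         sampled_demes = cbind(1:3, 1:3), seed = 99)
  ia <- simulate_ibd(icfg)
  ib <- simulate_ibd(icfg)
  expect_identical(ia$table$geno, ib$table$geno)
})

test_that("simulator output passes genotype validation and truth is usable", {
  cfg <- expansion_sim_config(lattice = c(4, 4), total_snps = 300,
                              deme_size = 40, founder_size = 8,
                              tetraploid_demes = rbind(c(4, 4)),
                              sampled_demes = cbind(c(1, 2, 3, 4),
                                                    c(1, 2, 3, 4)),
                              seed = 12)
  sim <- simulate_expansion(cfg)
  # re-validating through the constructor must succeed
  expect_s3_class(snp_table(sim$table$sites, sim$table$geno), "snp_table")
  expect_s3_class(as_sample_info(as.data.frame(sim$info)), "sample_info")
  expect_true("tetraploid" %in% sim$info$ploidy)
  # truth records score origin recovery without re-reading the config
  expect_true(all(c("origin_lat", "origin_lon", "colonization_step",
                    "populations", "pop_lat", "pop_lon") %in%
                    names(sim$truth)))
  expect_equal(sim$truth$colonization_step[1], 0L)  # origin deme sampled
  # config errors
  expect_error(expansion_sim_config(origin_deme = c(9, 1)), "lattice")
  expect_error(expansion_sim_config(founder_size = 200, deme_size = 100),
               "founder_size")
  expect_error(expansion_sim_config(sampled_demes = cbind(5, 9),
                                    lattice = c(4, 4)), "lattice")
})

test_that("missingness lands near its configured rate", {
  cfg <- expansion_sim_config(lattice = c(4, 4), total_snps = 1000,
                              deme_size = 40, founder_size = 8,
                              missingness_rate = 0.2,
                              sampled_demes = default_sampled_demes(c(4L, 4L), 15L),
                              samples_per_deme = 2, seed = 77)
  sim <- simulate_expansion(cfg)
  # observed missing fraction concentrates around 0.2 (binomial)
  expect_lt(abs(mean(is.na(sim$table$geno)) - 0.2), 0.02)
})

test_that("founder effects drive the directionality signal", {
  mean_ordered_psi <- function(F, seed) {
    sim <- simulate_expansion(expansion_sim_config(
      lattice = c(1, 6), origin_deme = c(1, 1), deme_size = 40,
      founder_size = F, migration_rate = 0, total_snps = 500,
      generations_per_colonization = 1, missingness_rate = 0,
      sampled_demes = cbind(1, 1:6), samples_per_deme = 3, seed = seed))
    counts <- suppressMessages(polarize_table(sim$table, sim$info))
    psi <- compute_psi_matrix(counts, m = 2)
    ord <- match(sim$truth$populations, psi$populations)
    mean(psi$psi[ord, ord][upper.tri(psi$psi)])
  }
  with_founder <- mean(vapply(1:4, function(s) mean_ordered_psi(8, 500 + s),
                              numeric(1)))
  no_founder <- mean(vapply(1:4, function(s) mean_ordered_psi(40, 500 + s),
                            numeric(1)))
  # F = K removes the founder effect: clines collapse toward zero
  expect_gt(with_founder, no_founder)
  expect_gt(with_founder, 0.01)
  expect_lt(abs(no_founder), 0.02)
})

test_that("derived-allele frequency increases with colonization order", {
  # 1D world with a long founder chain per sampled population, where the
  # surfing signal is expressed most directly
  ok <- vapply(1:10, function(s) {
    sim <- simulate_expansion(expansion_sim_config(
      lattice = c(1, 8), origin_deme = c(1, 1), deme_size = 50,
      founder_size = 10, total_snps = 600, missingness_rate = 0.05,
      sampled_demes = cbind(1, 1:8), samples_per_deme = 2,
      seed = 700 + s))
    counts <- suppressMessages(polarize_table(
      filter_outgroup_presence(filter_min_samples(sim$table, 4), sim$info),
      sim$info))
    shared <- rowSums(counts$k > 0) == length(counts$populations)
    freq <- colSums(counts$k[shared, , drop = FALSE]) /
      pmax(1, colSums(counts$n[shared, , drop = FALSE]))
    ord <- sim$truth$colonization_step[match(counts$populations,
                                             sim$truth$populations)]
    stats::cor(freq, ord, method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the IBD null has no directionality and shows distance decay", {
  reps <- lapply(1:20, function(s) {
    cfg <- ibd_sim_config(lattice = c(4, 4), deme_size = 25,
                          total_snps = 300, burn_in_generations = 250,
                          missingness_rate = 0.05,
                          sampled_demes = default_sampled_demes(c(4L, 4L), 8L),
                          seed = 900 + s)
    sim <- simulate_ibd(cfg)
    counts <- suppressMessages(polarize_table(
      filter_outgroup_presence(filter_min_samples(sim$table, 4), sim$info),
      sim$info))
    psi <- compute_psi_matrix(counts, m = 2)
    pc <- sim$info[sim$info$role == "ingroup" & !duplicated(sim$info$population_id), ]
    pc <- pc[match(psi$populations, pc$population_id), ]
    gd <- outer(seq_along(psi$populations), seq_along(psi$populations),
                function(i, j) geodesic_distance(pc$latitude[i], pc$longitude[i],
                                                 pc$latitude[j], pc$longitude[j]))
    fr <- counts$k / pmax(1, counts$n)
    gen_d <- as.matrix(stats::dist(t(fr)))
    ut <- upper.tri(gd)
    list(mean_psi = mean(psi$psi[ut], na.rm = TRUE),
         mantel_r = stats::cor(gd[ut], gen_d[ut], method = "spearman"))
  })
  mean_psis <- vapply(reps, `[[`, numeric(1), "mean_psi")
  # no systematic directionality: |mean over replicates| < 2 SE
  expect_lt(abs(mean(mean_psis)),
            2 * stats::sd(mean_psis) / sqrt(length(mean_psis)))
  # differentiation increases with distance in >= 18/20 replicates
  expect_gte(sum(vapply(reps, `[[`, numeric(1), "mantel_r") > 0), 18L)
})

test_that("plant_linear_psi is antisymmetric and exact at zero noise", {
  info <- line_info(5)
  psi <- plant_linear_psi(info, c(-24, 118), slope = 3e-4,
                          noise_sd = 0.02, seed = 4)
  expect_equal(psi$psi, -t(psi$psi))
  expect_equal(unname(diag(psi$psi)), rep(0, 5))
  psi0 <- plant_linear_psi(info, c(-24, 118), slope = 0)
  expect_true(all(psi0$psi == 0))
  expect_warning(plant_linear_psi(info, c(-24, 118), slope = 1),
                 "clipped")
})
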