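test_that("genome layout: even marker spacing, QTL at midpoints, exact counts", {
  cfg <- genome_config(n_chr = 1L, markers_per_chr = 5L, n_qtl = 2L)
  gen <- build_genome(cfg, seed = 1L)
  mpos <- gen$loci$pos[gen$marker_idx]
  expect_equal(mpos, c(0.1, 0.3, 0.5, 0.7, 0.9))
  qpos <- gen$loci$pos[gen$qtl_idx]
  expect_true(all(qpos %in% c(0.2, 0.4, 0.6, 0.8)))
  expect_false(any(qpos %in% mpos))

  # counts exact on the scaled config; QTL split evenly over chromosomes
  sc <- scaled_config()
  gsc <- build_genome(sc$genome, seed = 2L)
  expect_equal(length(gsc$marker_idx), 400L)
  expect_equal(length(gsc$qtl_idx), 20L)
  expect_equal(as.vector(table(gsc$loci$chr[gsc$qtl_idx])), c(10L, 10L))
  expect_error(build_genome(genome_config(n_chr = 1L, markers_per_chr = 3L,
                                          n_qtl = 5L)), "slots")
})

test_that("meiosis: crossover rate matches the Morgan map length", {
  set.seed(5)
  L <- 210L
  pos <- seq(0.0025, 0.9975, length.out = L)
  h1 <- rep(0L, L); h2 <- rep(1L, L)
  switches <- replicate(10000, {
    gam <- singlestep:::meiose(h1, h2, pos, 1.0, murate = 0)
    sum(diff(gam) != 0L)
  })
  # each crossover produces one observable switch (collisions in the same
  # inter-locus gap are rare), so the mean tracks the Poisson mean 1.0
  expect_gt(mean(switches), 0.92)
  expect_lt(mean(switches), 1.05)
  # with no mutation, every allele is a parental copy
  gam <- singlestep:::meiose(h1, h2, pos, 1.0, murate = 0)
  expect_true(all(gam %in% 0:1))
})

test_that("one generation of drift has Wright-Fisher variance", {
  cfg <- genome_config(n_chr = 2L, markers_per_chr = 200L, n_qtl = 2L,
                       marker_mutation = 0, qtl_mutation = 0)
  gen <- build_genome(cfg, seed = 3L)
  pc <- population_config(gen_sizes = c(10L, 10L),
                          burnin_generations = 1L, burnin_size = 200L)
  set.seed(4)
  # start from a concrete pool, advance one generation, measure delta p
  pool0 <- run_burn_in(gen, population_config(gen_sizes = c(10L, 10L),
                                              burnin_generations = 30L,
                                              burnin_size = 200L), seed = 6L)
  p0 <- sapply(pool0$haplotypes, colMeans)
  pool1 <- pool0
  # one more generation: rerun a single-generation burn-in from pool0 state
  N <- pool0$n
  set.seed(11)
  parents <- sample.int(N, 2L * N, replace = TRUE)
  for (ci in seq_along(pool0$chrs)) {
    H <- pool0$haplotypes[[ci]]
    Hn <- H
    for (j in seq_len(2L * N)) {
      Hn[j, ] <- singlestep:::meiose(H[2L * parents[j] - 1L, ],
                                     H[2L * parents[j], ],
                                     pool0$pos[[ci]], 1.0, 0)
    }
    pool1$haplotypes[[ci]] <- Hn
  }
  p1 <- sapply(pool1$haplotypes, colMeans)
  dp <- as.numeric(p1 - p0)
  pq <- as.numeric(p0 * (1 - p0))
  seg <- pq > 0.05
  ratio <- stats::var(dp[seg]) / mean(pq[seg] / (2 * N))
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("QTL effect pairs hit the target correlation", {
  e1 <- sample_qtl_effects(50L, rg = 1, seed = 2L)
  expect_equal(e1[, 1L], e1[, 2L], tolerance = 1e-12)
  e2 <- sample_qtl_effects(10000L, rg = 0.7, seed = 3L)
  expect_lt(abs(stats::cor(e2[, 1L], e2[, 2L]) - 0.7), 0.02)
  e3 <- sample_qtl_effects(10000L, rg = 0, seed = 4L)
  expect_lt(abs(stats::cor(e3[, 1L], e3[, 2L])), 0.03)
})

test_that("recent generations: pedigree structure and Mendelian consistency", {
  cfg <- scaled_config(gen_sizes = c(60L, 60L, 60L))
  cfg$genome$marker_mutation <- 0      # mutation off for the scan
  cfg$genome$qtl_mutation <- 0
  cfg$population$burnin_generations <- 20L
  pop <- simulate_population(cfg$genome, cfg$population, cfg$traits,
                             seed = 13L)
  ped <- pop$ped
  expect_equal(nrow(ped), 180L)
  # every non-founder's parents sit in the previous generation
  nf <- which(!is.na(ped$sire))
  gp <- ped$generation[match(ped$sire[nf], ped$animal)]
  expect_true(all(gp == ped$generation[nf] - 1L))
  expect_true(all(ped$generation[match(ped$dam[nf], ped$animal)] ==
                    ped$generation[nf] - 1L))
  # Mendelian consistency of dosages at every locus
  dos <- cbind(pop$panel$dosage, pop$qtl_dosage)
  for (i in sample(nf, 40L)) {
    ds <- dos[ped$sire[i], ]; dd <- dos[ped$dam[i], ]; dk <- dos[ped$animal[i], ]
    lo <- (ds == 2L) + (dd == 2L)
    hi <- 2L - ((ds == 0L) + (dd == 0L))
    expect_true(all(dk >= lo & dk <= hi))
  }
})

test_that("phenotypes decompose into fixed + TBV + residual with target h2", {
  pop <- tiny_population(seed = 21L, gen_sizes = rep(400L, 3L))
  # sex-generation effects live in [0,1]
  expect_true(all(pop$phen$fixed1 >= 0 & pop$phen$fixed1 <= 1))
  final <- pop$ped$generation == 3L
  rp <- realized_parameters(pop)
  expect_lt(abs(rp$h2[1] - 0.1), 0.05)
  expect_lt(abs(rp$h2[2] - 0.3), 0.07)
  # TBV equals QTL dosage x scaled effects
  expect_equal(unname(pop$qtl_dosage %*% pop$qtl_effects), unname(pop$tbv),
               tolerance = 1e-10)
  # final-generation TBV variance is calibrated exactly
  expect_equal(stats::var(pop$tbv[final, 2L]), 0.3, tolerance = 1e-10)
})

test_that("scenarios are deterministic, disjoint, and size-checked", {
  pop <- tiny_population(seed = 30L)
  s1 <- make_scenario(pop, ref_size = 50L, n_validation = 60L, seed = 8L)
  s2 <- make_scenario(pop, ref_size = 50L, n_validation = 60L, seed = 8L)
  expect_identical(s1, s2)
  expect_length(s1$reference_ids, 50L)
  expect_length(s1$validation_ids, 60L)
  expect_length(intersect(s1$reference_ids, s1$validation_ids), 0L)
  expect_true(all(pop$ped$generation[match(s1$validation_ids,
                                           pop$ped$animal)] == 3L))
  expect_error(make_scenario(pop, ref_size = 1e6, seed = 1L), "exceeds")
})

test_that("simulate_dataset emits consistent, reloadable, seed-stable files", {
  dir <- withr::local_tempdir()
  cfg <- scaled_config(gen_sizes = c(50L, 50L))
  cfg$population$burnin_generations <- 10L
  pop <- simulate_dataset(dir, cfg$genome, cfg$population, cfg$traits,
                          seed = 5L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_markers, 400L)
  expect_equal(man$n_qtl, 20L)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  phen <- read_phenotypes(file.path(dir, "phenotypes.csv"),
                          traits = c("trait1", "trait2"),
                          factors = "sexgen")
  panel <- read_genotypes(file.path(dir, "genotypes.raw"),
                          file.path(dir, "markers.map"))
  expect_setequal(ped$animal, phen$animal)
  expect_setequal(rownames(panel$dosage), ped$animal)
  expect_identical(panel$dosage, pop$panel$dosage)
  # same seed, same bytes
  dir2 <- withr::local_tempdir()
  simulate_dataset(dir2, cfg$genome, cfg$population, cfg$traits, seed = 5L)
  expect_identical(readLines(file.path(dir, "genotypes.raw")),
                   readLines(file.path(dir2, "genotypes.raw")))
})
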