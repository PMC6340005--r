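#' Genome configuration for the simulator
#'
#' Defaults describe a pig-like genome: 18 chromosomes of 1 Morgan each
#' carrying 2,834 evenly spaced markers (51,012 in total) and 306 QTL,
#' with per-locus per-meiosis mutation rates of 1.25e-3 for markers and
#' 2.5e-3 for QTL.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_length Chromosome length in Morgan (all equal).
#' @param markers_per_chr Evenly spaced markers per chromosome.
#' @param n_qtl Total QTL count, spread as evenly as possible across
#'   chromosomes.
#' @param marker_mutation Marker mutation rate (allele flip per locus per
#'   meiosis).
#' @param qtl_mutation QTL mutation rate.
#' @return List of class `genome_config`.
#' @export
genome_config <- function(n_chr = 18L, chr_length = 1.0,
                          markers_per_chr = 2834L, n_qtl = 306L,
                          marker_mutation = 1.25e-3, qtl_mutation = 2.5e-3) {
  stopifnot(n_chr >= 1L, chr_length > 0, markers_per_chr >= 2L, n_qtl >= 1L,
            marker_mutation >= 0, marker_mutation < 1,
            qtl_mutation >= 0, qtl_mutation < 1)
  structure(list(n_chr = as.integer(n_chr), chr_length = chr_length,
                 markers_per_chr = as.integer(markers_per_chr),
                 n_qtl = as.integer(n_qtl),
                 marker_mutation = marker_mutation,
                 qtl_mutation = qtl_mutation),
            class = "genome_config")
}

#' Trait configuration for the simulator
#'
#' Two traits with heritabilities 0.1 and 0.3 and additive-genetic
#' correlation 0.7 by default; phenotypic variance is 1 per trait, and
#' residuals are uncorrelated across traits unless `residual_cor` says
#' otherwise.
#'
#' @param h2 Numeric vector of heritabilities in (0, 1), one per trait.
#' @param rg Genetic correlation between the two traits, |rg| <= 1.
#' @param var_p Phenotypic variance per trait.
#' @param residual_cor Residual correlation between traits.
#' @return List of class `trait_config`.
#' @export
trait_config <- function(h2 = c(0.1, 0.3), rg = 0.7, var_p = 1.0,
                         residual_cor = 0.0) {
  stopifnot(length(h2) == 2L, all(h2 > 0 & h2 < 1), abs(rg) <= 1,
            var_p > 0, abs(residual_cor) <= 1)
  structure(list(h2 = h2, rg = rg, var_p = var_p,
                 residual_cor = residual_cor),
            class = "trait_config")
}

#' Population configuration for the simulator
#'
#' The default recent population is 10 discrete generations of 3,000
#' individuals (30,000 in total) preceded by a random-mating Wright-Fisher
#' burn-in of 400 generations at size 200 that establishes linkage
#' disequilibrium and an allele-frequency spectrum.
#'
#' @param gen_sizes Integer vector: individuals per recent generation.
#' @param burnin_generations Burn-in generations.
#' @param burnin_size Diploid burn-in population size.
#' @return List of class `population_config`.
#' @export
population_config <- function(gen_sizes = rep(3000L, 10L),
                              burnin_generations = 400L,
                              burnin_size = 200L) {
  stopifnot(all(gen_sizes >= 2L), burnin_generations >= 1L,
            burnin_size >= 2L)
  structure(list(gen_sizes = as.integer(gen_sizes),
                 burnin_generations = as.integer(burnin_generations),
                 burnin_size = as.integer(burnin_size)),
            class = "population_config")
}

#' Lay out marker and QTL positions
#'
#' Markers are evenly spaced along each chromosome at the midpoint-offset
#' positions (k - 0.5)/m * L; QTL sit at randomly chosen inter-marker
#' midpoints so a QTL never coincides with a marker. The QTL total is
#' split across chromosomes as evenly as possible.
#'
#' @param cfg A `genome_config`.
#' @param seed Integer seed for QTL placement.
#' @return List with `loci` (data frame: `id`, `chr`, `pos`, `type`,
#'   `mutation`, ordered by chromosome and position), and index vectors
#'   `marker_idx`, `qtl_idx` into `loci`.
#' @export
build_genome <- function(cfg = genome_config(), seed = 1L) {
  stopifnot(inherits(cfg, "genome_config"))
  qtl_per_chr <- rep(cfg$n_qtl %/% cfg$n_chr, cfg$n_chr)
  extra <- cfg$n_qtl %% cfg$n_chr
  if (extra > 0L) qtl_per_chr[seq_len(extra)] <- qtl_per_chr[seq_len(extra)] + 1L
  if (any(qtl_per_chr > cfg$markers_per_chr - 1L)) {
    stop("more QTL than inter-marker slots on some chromosome")
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  m <- cfg$markers_per_chr
  mpos <- (seq_len(m) - 0.5) / m * cfg$chr_length
  mid <- (mpos[-1L] + mpos[-m]) / 2
  chunks <- vector("list", cfg$n_chr)
  for (ch in seq_len(cfg$n_chr)) {
    qpos <- sort(sample(mid, qtl_per_chr[ch]))
    df <- rbind(
      data.frame(chr = ch, pos = mpos, type = "marker",
                 mutation = cfg$marker_mutation),
      data.frame(chr = ch, pos = qpos, type = "qtl",
                 mutation = cfg$qtl_mutation)
    )
    chunks[[ch]] <- df[order(df$pos), ]
  }
  loci <- do.call(rbind, chunks)
  rownames(loci) <- NULL
  midx <- which(loci$type == "marker")
  qidx <- which(loci$type == "qtl")
  loci$id <- NA_character_
  loci$id[midx] <- paste0("M", seq_along(midx))
  loci$id[qidx] <- paste0("Q", seq_along(qidx))
  list(loci = loci[, c("id", "chr", "pos", "type", "mutation")],
       marker_idx = midx, qtl_idx = qidx, cfg = cfg)
}

# Form one gamete: Poisson crossovers at rate = chromosome length (Morgan),
# uniform crossover placement, random starting phase, then recurrent
# mutation (allele flip) at the per-locus rates.
meiose <- function(h1, h2, pos, len, murate) {
  k <- stats::rpois(1L, len)
  if (k == 0L) {
    gam <- if (stats::runif(1L) < 0.5) h1 else h2
  } else {
    xo <- sort(stats::runif(k, 0, len))
    seg <- findInterval(pos, xo) + stats::rbinom(1L, 1L, 0.5)
    gam <- h2
    take1 <- seg %% 2L == 0L
    gam[take1] <- h1[take1]
  }
  mut <- stats::runif(length(gam)) < murate
  if (any(mut)) gam[mut] <- 1L - gam[mut]
  gam
}

#' Wright-Fisher burn-in establishing LD and allele frequencies
#'
#' Starts every locus segregating at frequency 0.5 and drifts a
#' random-mating diploid population (random union of gametes) for the
#' configured number of generations, with Poisson recombination and
#' recurrent mutation. Returns the final pool of haplotypes, one matrix
#' per chromosome.
#'
#' @param genome From [build_genome()].
#' @param pop_cfg A `population_config`.
#' @param seed Integer seed.
#' @return List of per-chromosome haplotype matrices (2N rows; haplotypes
#'   2i-1 and 2i belong to diploid i), plus the locus bookkeeping.
#' @export
run_burn_in <- function(genome, pop_cfg = population_config(), seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  N <- pop_cfg$burnin_size
  loci <- genome$loci
  chrs <- sort(unique(loci$chr))
  len <- genome$cfg$chr_length
  pool <- lapply(chrs, function(ch) {
    L <- sum(loci$chr == ch)
    matrix(as.integer(stats::runif(2L * N * L) < 0.5), nrow = 2L * N)
  })
  pos_l <- lapply(chrs, function(ch) loci$pos[loci$chr == ch])
  mu_l <- lapply(chrs, function(ch) loci$mutation[loci$chr == ch])
  for (g in seq_len(pop_cfg$burnin_generations)) {
    parents <- matrix(sample.int(N, 2L * N, replace = TRUE), ncol = 1L)
    for (ci in seq_along(chrs)) {
      H <- pool[[ci]]
      Hnew <- H
      for (j in seq_len(2L * N)) {
        pp <- parents[j, 1L]
        Hnew[j, ] <- meiose(H[2L * pp - 1L, ], H[2L * pp, ],
                            pos_l[[ci]], len, mu_l[[ci]])
      }
      pool[[ci]] <- Hnew
    }
  }
  list(haplotypes = pool, pos = pos_l, mutation = mu_l, chrs = chrs,
       n = N, genome = genome)
}

#' Sample correlated QTL effects for two traits
#'
#' i.i.d. bivariate normal effects with unit marginal variances and
#' correlation `rg` (the genetic correlation target); scaling to the
#' heritabilities happens in [assign_phenotypes()].
#'
#' @param n_qtl Number of QTL.
#' @param rg Correlation.
#' @param seed Integer seed.
#' @return n_qtl x 2 matrix of effects.
#' @export
sample_qtl_effects <- function(n_qtl, rg, seed = 1L) {
  stopifnot(abs(rg) <= 1)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  z <- matrix(stats::rnorm(2L * n_qtl), ncol = 2L)
  cbind(z[, 1L], rg * z[, 1L] + sqrt(1 - rg^2) * z[, 2L])
}

#' Breed the recorded recent generations
#'
#' Draws founders of generation 1 from the burn-in haplotype pool
#' (pedigree parents unknown), then mates random sires and dams from the
#' previous generation for each subsequent one, recording the pedigree.
#' Sexes are assigned at random with both sexes guaranteed per
#' generation.
#'
#' @param pool Burn-in result from [run_burn_in()].
#' @param pop_cfg A `population_config` (its `gen_sizes` are used).
#' @param seed Integer seed.
#' @return List with `ped` (data frame `animal`, `sire`, `dam`, `sex`,
#'   `generation`), `dosage` (individuals x all loci), and the genome.
#' @export
breed_recent_generations <- function(pool, pop_cfg, seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  sizes <- pop_cfg$gen_sizes
  n_total <- sum(sizes)
  genome <- pool$genome
  L_all <- nrow(genome$loci)
  len <- genome$cfg$chr_length
  dosage <- matrix(0L, n_total, L_all)
  ped <- data.frame(animal = paste0("ID", seq_len(n_total)),
                    sire = NA_character_, dam = NA_character_,
                    sex = NA_character_,
                    generation = rep(seq_along(sizes), sizes),
                    stringsAsFactors = FALSE)
  col_ranges <- lapply(seq_along(pool$chrs), function(ci) {
    which(genome$loci$chr == pool$chrs[ci])
  })
  draw_sex <- function(n) {
    s <- sample(c("M", "F"), n, replace = TRUE)
    if (!all(c("M", "F") %in% s)) {        # guarantee both sexes
      s[sample.int(n, 2L)] <- c("M", "F")
    }
    s
  }
  cur <- vector("list", length(pool$chrs))   # haplotypes of current gen
  offset <- 0L
  for (g in seq_along(sizes)) {
    n_g <- sizes[g]
    rows <- offset + seq_len(n_g)
    ped$sex[rows] <- draw_sex(n_g)
    if (g == 1L) {
      par1 <- sample.int(pool$n, n_g, replace = TRUE)
      par2 <- (par1 + sample.int(pool$n - 1L, n_g, replace = TRUE) - 1L) %%
        pool$n + 1L                          # a different diploid
      for (ci in seq_along(pool$chrs)) {
        H <- pool$haplotypes[[ci]]
        Hg <- matrix(0L, 2L * n_g, ncol(H))
        for (k in seq_len(n_g)) {
          Hg[2L * k - 1L, ] <- meiose(H[2L * par1[k] - 1L, ],
                                      H[2L * par1[k], ],
                                      pool$pos[[ci]], len, pool$mutation[[ci]])
          Hg[2L * k, ] <- meiose(H[2L * par2[k] - 1L, ], H[2L * par2[k], ],
                                 pool$pos[[ci]], len, pool$mutation[[ci]])
        }
        cur[[ci]] <- Hg
        dosage[rows, col_ranges[[ci]]] <- Hg[seq(1L, 2L * n_g, by = 2L), ] +
          Hg[seq(2L, 2L * n_g, by = 2L), ]
      }
    } else {
      prev_rows <- (offset - sizes[g - 1L]) + seq_len(sizes[g - 1L])
      males <- which(ped$sex[prev_rows] == "M")
      females <- which(ped$sex[prev_rows] == "F")
      sire_k <- sample(males, n_g, replace = TRUE)
      dam_k <- sample(females, n_g, replace = TRUE)
      ped$sire[rows] <- ped$animal[prev_rows[sire_k]]
      ped$dam[rows] <- ped$animal[prev_rows[dam_k]]
      for (ci in seq_along(pool$chrs)) {
        H <- cur[[ci]]
        Hg <- matrix(0L, 2L * n_g, ncol(H))
        for (k in seq_len(n_g)) {
          Hg[2L * k - 1L, ] <- meiose(H[2L * sire_k[k] - 1L, ],
                                      H[2L * sire_k[k], ],
                                      pool$pos[[ci]], len, pool$mutation[[ci]])
          Hg[2L * k, ] <- meiose(H[2L * dam_k[k] - 1L, ], H[2L * dam_k[k], ],
                                 pool$pos[[ci]], len, pool$mutation[[ci]])
        }
        cur[[ci]] <- Hg
        dosage[rows, col_ranges[[ci]]] <- Hg[seq(1L, 2L * n_g, by = 2L), ] +
          Hg[seq(2L, 2L * n_g, by = 2L), ]
      }
    }
    offset <- offset + n_g
  }
  rownames(dosage) <- ped$animal
  colnames(dosage) <- genome$loci$id
  list(ped = ped, dosage = dosage, genome = genome)
}

#' Attach true breeding values and phenotypes
#'
#' TBV = QTL dosage x effects, with effects rescaled per trait so that
#' the TBV variance in the final generation equals h2 * var_p (the
#' evaluation generation is the calibration target). Phenotype = fixed
#' sex-generation effect (level values drawn Uniform(0,1)) + TBV +
#' normal residual with variance (1 - h2) * var_p.
#'
#' @param skel Result of [breed_recent_generations()].
#' @param tcfg A `trait_config`.
#' @param seed Integer seed (drives effects, fixed-effect values and
#'   residuals).
#' @return A `sim_population`: list with `ped`, `panel` (marker
#'   `genotype_panel`), `qtl_dosage`, `tbv` (n x 2), `phen` (data frame
#'   `animal`, `sexgen`, `fixed1`, `fixed2`, `trait1`, `trait2`), the
#'   QTL effects, the truth variance components (`M`, `R`), and configs.
#' @export
assign_phenotypes <- function(skel, tcfg = trait_config(), seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  genome <- skel$genome
  Q <- skel$dosage[, genome$qtl_idx, drop = FALSE]
  eff <- sample_qtl_effects(ncol(Q), tcfg$rg,
                            seed = sample.int(.Machine$integer.max, 1L))
  tbv_raw <- Q %*% eff
  final <- skel$ped$generation == max(skel$ped$generation)
  n <- nrow(Q)
  tbv <- matrix(0, n, 2L)
  sc <- numeric(2L)
  for (t in 1:2) {
    v <- stats::var(tbv_raw[final, t])
    if (v <= 0) stop("no segregating QTL for trait ", t,
                     " (TBV variance is zero)")
    sc[t] <- sqrt(tcfg$h2[t] * tcfg$var_p / v)
    tbv[, t] <- tbv_raw[, t] * sc[t]
  }
  se2 <- (1 - tcfg$h2) * tcfg$var_p
  rc <- tcfg$residual_cor
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  e1 <- sqrt(se2[1L]) * z[, 1L]
  e2 <- sqrt(se2[2L]) * (rc * z[, 1L] + sqrt(1 - rc^2) * z[, 2L])
  sexgen <- paste0(skel$ped$sex, skel$ped$generation)
  levs <- sort(unique(sexgen))
  fx1 <- stats::runif(length(levs))
  fx2 <- stats::runif(length(levs))
  names(fx1) <- names(fx2) <- levs
  phen <- data.frame(animal = skel$ped$animal,
                     sexgen = sexgen,
                     fixed1 = fx1[sexgen], fixed2 = fx2[sexgen],
                     trait1 = fx1[sexgen] + tbv[, 1L] + e1,
                     trait2 = fx2[sexgen] + tbv[, 2L] + e2,
                     row.names = NULL, stringsAsFactors = FALSE)
  midx <- genome$marker_idx
  map <- data.frame(marker = genome$loci$id[midx],
                    chr = genome$loci$chr[midx],
                    pos = genome$loci$pos[midx])
  panel <- genotype_panel(skel$dosage[, midx, drop = FALSE], map)
  sg2 <- tcfg$h2 * tcfg$var_p
  M <- matrix(c(sg2[1L], tcfg$rg * sqrt(sg2[1L] * sg2[2L]),
                tcfg$rg * sqrt(sg2[1L] * sg2[2L]), sg2[2L]), 2L, 2L)
  R <- matrix(c(se2[1L], rc * sqrt(se2[1L] * se2[2L]),
                rc * sqrt(se2[1L] * se2[2L]), se2[2L]), 2L, 2L)
  rownames(tbv) <- skel$ped$animal
  structure(list(ped = skel$ped, panel = panel,
                 qtl_dosage = Q, qtl_effects = eff * rep(sc, each = nrow(eff)),
                 tbv = tbv, phen = phen, M = M, R = R,
                 trait_cfg = tcfg, genome = genome),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated population:", nrow(x$ped), "individuals,",
      max(x$ped$generation), "generations,",
      ncol(x$panel$dosage), "markers,", ncol(x$qtl_dosage), "QTL\n")
  invisible(x)
}

#' Simulate a complete population
#'
#' Convenience wrapper: genome layout, burn-in, recent generations,
#' trait assignment, all driven by one seed.
#'
#' @param genome_cfg,pop_cfg,tcfg Configuration objects.
#' @param seed Integer master seed.
#' @return A `sim_population`.
#' @export
simulate_population <- function(genome_cfg = genome_config(),
                                pop_cfg = population_config(),
                                tcfg = trait_config(),
                                seed = 1L) {
  genome <- build_genome(genome_cfg, seed = seed)
  pool <- run_burn_in(genome, pop_cfg, seed = seed + 1L)
  skel <- breed_recent_generations(pool, pop_cfg, seed = seed + 2L)
  assign_phenotypes(skel, tcfg, seed = seed + 3L)
}

#' Reduced-scale simulation settings
#'
#' A small genome (2 chromosomes, 200 markers each, 20 QTL) and a short
#' burn-in used throughout the test-suite and for desk-scale replications
#' of the reference-population-size study; trait settings keep the
#' nominal heritabilities 0.1/0.3 and genetic correlation 0.7.
#'
#' @param gen_sizes Recent generation sizes (default five generations of
#'   500).
#' @return List with `genome`, `population`, `traits` config objects.
#' @export
scaled_config <- function(gen_sizes = rep(500L, 5L)) {
  list(genome = genome_config(n_chr = 2L, markers_per_chr = 200L,
                              n_qtl = 20L),
       population = population_config(gen_sizes = gen_sizes,
                                      burnin_generations = 100L,
                                      burnin_size = 200L),
       traits = trait_config())
}

#' Carve a reference/validation scenario out of a simulated population
#'
#' Validation animals (default 1,000) are drawn from the final
#' generation; the genotyped reference of the requested size is drawn
#' from a configurable earlier generation (default two generations before
#' the last, matching a reference at generation 8 of 10). Validation
#' animals are genotyped but their phenotypes are to be masked; everyone
#' else contributes pedigree and phenotype only.
#'
#' @param pop A `sim_population`.
#' @param ref_size Reference population size.
#' @param n_validation Validation population size.
#' @param seed Integer seed for the two draws.
#' @param ref_generation Generation the reference is sampled from.
#' @return List with `reference_ids`, `validation_ids`, `genotyped_ids`,
#'   `ref_size`, `seed`.
#' @export
make_scenario <- function(pop, ref_size, n_validation = 1000L, seed = 1L,
                          ref_generation = max(pop$ped$generation) - 2L) {
  stopifnot(inherits(pop, "sim_population"))
  gmax <- max(pop$ped$generation)
  gen_ref <- pop$ped$animal[pop$ped$generation == ref_generation]
  gen_val <- pop$ped$animal[pop$ped$generation == gmax]
  if (ref_size > length(gen_ref)) {
    stop("ref_size ", ref_size, " exceeds generation ", ref_generation,
         " size ", length(gen_ref))
  }
  if (n_validation > length(gen_val)) {
    stop("n_validation exceeds final-generation size")
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  val <- sample(gen_val, n_validation)
  ref <- sample(gen_ref, ref_size)
  list(reference_ids = ref, validation_ids = val,
       genotyped_ids = c(ref, val), ref_size = ref_size, seed = seed)
}

# Seed hygiene: functions that consume randomness set the seed locally and
# restore the caller's RNG state on exit.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
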