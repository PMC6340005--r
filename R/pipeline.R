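#' Simulate a population and write it to disk
#'
#' Runs the forward-in-time simulator and emits the standard text files:
#' `pedigree.csv`, `phenotypes.csv`, `genotypes.raw`, `markers.map`,
#' `tbv.csv` and a `manifest.json` recording counts, configs and the
#' seed. Same seed, same bytes.
#'
#' @param dir Output directory (created if needed).
#' @param genome_cfg,pop_cfg,tcfg Simulator configuration objects.
#' @param seed Integer master seed.
#' @return The `sim_population`, invisibly; files as a side effect.
#' @export
simulate_dataset <- function(dir, genome_cfg = genome_config(),
                             pop_cfg = population_config(),
                             tcfg = trait_config(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(genome_cfg, pop_cfg, tcfg, seed = seed)
  write_pedigree(pop$ped[, c("animal", "sire", "dam")],
                 file.path(dir, "pedigree.csv"))
  write_phenotypes(pop$phen, file.path(dir, "phenotypes.csv"))
  write_genotypes(pop$panel, file.path(dir, "genotypes.raw"),
                  file.path(dir, "markers.map"))
  utils::write.table(
    data.frame(animal = rownames(pop$tbv), tbv1 = pop$tbv[, 1L],
               tbv2 = pop$tbv[, 2L]),
    file.path(dir, "tbv.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = seed,
    n_individuals = nrow(pop$ped),
    n_generations = max(pop$ped$generation),
    n_markers = ncol(pop$panel$dosage),
    n_qtl = ncol(pop$qtl_dosage),
    h2 = tcfg$h2, rg = tcfg$rg,
    genome = unclass(genome_cfg),
    population = unclass(pop_cfg)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(pop)
}

#' Evaluation dataset for a simulated scenario
#'
#' Restricts the genotype panel to the scenario's genotyped animals
#' (reference plus validation), applies marker QC and imputation, and
#' packages phenotypes, truth variance components and TBV reference
#' values for the solvers.
#'
#' @param pop A `sim_population`.
#' @param scenario From [make_scenario()].
#' @param qc List of QC thresholds (`maf_min`, `call_min`, `hwe_p_min`).
#' @return An `eval_data` with `reference_kind = "TBV"`.
#' @export
sim_eval_data <- function(pop, scenario,
                          qc = list(maf_min = 0.05, call_min = 0.90,
                                    hwe_p_min = 1e-7)) {
  stopifnot(inherits(pop, "sim_population"))
  gids <- scenario$genotyped_ids
  sub <- genotype_panel(pop$panel$dosage[gids, , drop = FALSE], pop$panel$map)
  filt <- qc_filter(sub, qc$maf_min, qc$call_min, qc$hwe_p_min)
  panel <- naive_impute(filt$panel)
  h2 <- pop$trait_cfg$h2
  vp <- pop$trait_cfg$var_p
  vc <- lapply(1:2, function(t) list(sigma_g2 = h2[t] * vp,
                                     sigma_e2 = (1 - h2[t]) * vp))
  refs <- list(trait1 = stats::setNames(pop$tbv[, 1L], rownames(pop$tbv)),
               trait2 = stats::setNames(pop$tbv[, 2L], rownames(pop$tbv)))
  eval_data(ped = pop$ped[, c("animal", "sire", "dam")],
            phen = pop$phen,
            panel = panel,
            traits = c("trait1", "trait2"),
            factors = "sexgen",
            vc = vc,
            reference_values = refs,
            reference_kind = "TBV",
            M = pop$M, R = pop$R)
}

#' Accuracy and unbiasedness across reference population sizes
#'
#' Replays the reference-size study on a simulated population: one fixed
#' validation set from the final generation, genotyped references of
#' increasing size from an earlier generation, and for each method the
#' validation animals' phenotypes are masked, the model refitted, and
#' r(TBV, PBV) and b(TBV, PBV) recorded.
#'
#' @param pop A `sim_population`.
#' @param ref_sizes Integer vector of reference sizes.
#' @param methods Subset of `c("blup", "gblup", "ssgblup", "ssgblup2")`.
#' @param n_validation Validation set size.
#' @param seed Integer seed driving the scenario draws.
#' @param w Blending weight for Gw.
#' @param traits Which of the two traits to report (default both).
#' @return Data frame: `method`, `trait`, `ref_size`, `r`, `b`.
#' @export
evaluate_reference_sizes <- function(pop, ref_sizes = c(50L, 100L, 300L,
                                                        500L, 1000L, 2000L,
                                                        3000L),
                                     methods = c("blup", "gblup", "ssgblup",
                                                 "ssgblup2"),
                                     n_validation = 1000L, seed = 1L,
                                     w = 0.95, traits = c("trait1", "trait2")) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (rs in ref_sizes) {
    scen <- make_scenario(pop, rs, n_validation = n_validation, seed = seed)
    data <- sim_eval_data(pop, scen)
    mats <- prediction_matrices(data, w = w)
    for (m in methods) {
      pbv <- predict_masked(data, m, scen$validation_ids, mats)
      for (tr in intersect(traits, names(pbv))) {
        ref <- data$reference_values[[tr]][scen$validation_ids]
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, trait = tr, ref_size = rs,
          r = accuracy(ref, pbv[[tr]][scen$validation_ids]),
          b = unbiasedness(ref, pbv[[tr]][scen$validation_ids]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Realized simulation parameters of a population
#'
#' The quantities the simulator is supposed to deliver: per-trait
#' realized heritability Var(TBV) / Var(phenotype - fixed effects) and
#' the realized genetic correlation cor(TBV1, TBV2), computed over the
#' final generation (the evaluation generation).
#'
#' @param pop A `sim_population`.
#' @return List with `h2` (length 2) and `rg`.
#' @export
realized_parameters <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  final <- pop$ped$generation == max(pop$ped$generation)
  adj1 <- pop$phen$trait1[final] - pop$phen$fixed1[final]
  adj2 <- pop$phen$trait2[final] - pop$phen$fixed2[final]
  list(h2 = c(stats::var(pop$tbv[final, 1L]) / stats::var(adj1),
              stats::var(pop$tbv[final, 2L]) / stats::var(adj2)),
       rg = stats::cor(pop$tbv[final, 1L], pop$tbv[final, 2L]))
}
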