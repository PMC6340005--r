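#' Replicated k-fold cross-validation plans
#'
#' Randomly partitions the ids into k nearly equal validation sets per
#' replicate (sizes differing by at most one), deterministically given
#' the master seed; every method evaluated against the same plans sees
#' identical validation sets.
#'
#' @param ids Character vector of (genotyped) animal ids.
#' @param k Folds per replicate (>= 2).
#' @param replicates Number of replicates.
#' @param seed Integer master seed; replicate r uses `seed + r`.
#' @return List of fold plans, each a list with `replicate`, `fold`,
#'   `validation_ids`, `reference_ids`.
#' @export
make_folds <- function(ids, k = 5L, replicates = 20L, seed = 1L) {
  if (k > length(ids)) stop("k = ", k, " exceeds number of ids (", length(ids), ")")
  if (k < 2L) stop("k must be >= 2")
  plans <- list()
  for (r in seq_len(replicates)) {
    old <- set_local_seed(seed + r)
    perm <- sample(ids)
    restore_seed(old)
    fold_of <- rep_len(seq_len(k), length(ids))  # sizes differ by <= 1
    for (f in seq_len(k)) {
      val <- perm[fold_of == f]
      plans[[length(plans) + 1L]] <- list(
        replicate = r, fold = f,
        validation_ids = val,
        reference_ids = setdiff(ids, val)
      )
    }
  }
  plans
}

#' Prediction accuracy
#'
#' Pearson correlation between reference values (TBV in simulation, EBV
#' or corrected phenotypes for real data) and predicted breeding values
#' in the validation set.
#'
#' @param reference_values,pbv Paired numeric vectors.
#' @return Correlation r, or `NA` (with a warning) when fewer than 3
#'   complete pairs or either input has zero variance.
#' @export
accuracy <- function(reference_values, pbv) {
  ok <- stats::complete.cases(reference_values, pbv)
  x <- reference_values[ok]; y <- pbv[ok]
  if (length(x) < 3L) {
    warning("fewer than 3 complete pairs; accuracy undefined")
    return(NA_real_)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Unbiasedness (dispersion) of prediction
#'
#' Regression coefficient of the reference values on the predictions,
#' b = Cov(reference, PBV) / Var(PBV); b = 1 means neither inflation nor
#' deflation of the predicted breeding values.
#'
#' @inheritParams accuracy
#' @return Slope b, or `NA` with a warning when Var(PBV) = 0.
#' @export
unbiasedness <- function(reference_values, pbv) {
  ok <- stats::complete.cases(reference_values, pbv)
  x <- reference_values[ok]; y <- pbv[ok]
  if (length(x) < 3L) {
    warning("fewer than 3 complete pairs; unbiasedness undefined")
    return(NA_real_)
  }
  if (stats::var(y) == 0) {
    warning("zero variance of PBV; unbiasedness undefined")
    return(NA_real_)
  }
  stats::cov(x, y) / stats::var(y)
}

#' Assemble an evaluation dataset
#'
#' Bundles everything the solvers need: the sorted pedigree, phenotypes,
#' the (complete, post-QC) genotype panel, variance components per trait,
#' and reference values to score predictions against.
#'
#' @param ped Pedigree data frame or `ordered_pedigree`.
#' @param phen Phenotype data frame with an `animal` column.
#' @param panel `genotype_panel` over the genotyped animals (no missing
#'   calls).
#' @param traits Trait column names (1 or 2).
#' @param factors,covariates Fixed-effect columns.
#' @param vc List per trait: `list(sigma_g2 =, sigma_e2 =)`.
#' @param reference_values List per trait of named numeric vectors (TBV,
#'   EBV or yc) used as surrogate truth.
#' @param reference_kind One of `"TBV"`, `"EBV"`, `"yc"`.
#' @param M,R 2x2 (co)variance matrices for the two-trait model
#'   (required for method `"ssgblup2"`).
#' @return List of class `eval_data`.
#' @export
eval_data <- function(ped, phen, panel, traits, factors = character(),
                      covariates = character(), vc, reference_values,
                      reference_kind = c("TBV", "EBV", "yc"),
                      M = NULL, R = NULL) {
  if (!inherits(ped, "ordered_pedigree")) ped <- topological_sort(ped)
  reference_kind <- match.arg(reference_kind)
  stopifnot(inherits(panel, "genotype_panel"), !anyNA(panel$dosage))
  structure(list(ped = ped, phen = phen, panel = panel, traits = traits,
                 factors = factors, covariates = covariates, vc = vc,
                 reference_values = reference_values,
                 reference_kind = reference_kind, M = M, R = R),
            class = "eval_data")
}

#' Precompute the relationship matrices of an evaluation
#'
#' Builds A^-1 over the pedigree, A22 over the genotyped animals (by the
#' indirect method, no dense A needed), the adjusted and blended genomic
#' matrix Gw, and H^-1. Masking phenotypes never changes these, so they
#' are shared across folds and methods.
#'
#' @param data An `eval_data`.
#' @param w Blending weight for Gw.
#' @param Gw_override Optional matrix used in place of the blended
#'   genomic matrix (e.g. `A22` to collapse ssGBLUP onto pedigree BLUP).
#' @return List with `Ainv`, `A22`, `A22inv`, `G`, `Ga`, `Gw`, `Hinv`,
#'   `beta`, `alpha`, `genotyped_ids`.
#' @export
prediction_matrices <- function(data, w = 0.95, Gw_override = NULL) {
  stopifnot(inherits(data, "eval_data"))
  ped <- data$ped
  Fc <- inbreeding(ped)
  Ainv <- build_A_inverse(ped, F = Fc)
  gids <- rownames(data$panel$dosage)
  A22 <- build_A22(ped, gids, F = Fc)
  A22inv <- chol2inv(chol(A22))
  dimnames(A22inv) <- dimnames(A22)
  G <- build_G(data$panel)
  adj <- adjust_G(G, A22)
  Gw <- if (is.null(Gw_override)) blend_Gw(adj$Ga, A22, w) else Gw_override
  Hinv <- build_H_inverse(Ainv, A22inv, Gw)
  list(Ainv = Ainv, A22 = A22, A22inv = A22inv, G = G, Ga = adj$Ga,
       Gw = Gw, Hinv = Hinv, beta = adj$beta, alpha = adj$alpha,
       genotyped_ids = gids)
}

# Fit one method with the given animals' phenotypes masked and return the
# named PBV vector(s), one per trait.
predict_masked <- function(data, method, masked_ids, mats) {
  phen <- data$phen
  for (tr in data$traits) {
    phen[[tr]][phen$animal %in% masked_ids] <- NA_real_
  }
  ids <- data$ped$id
  out <- list()
  if (method %in% c("blup", "ssgblup")) {
    Kinv <- if (method == "blup") mats$Ainv else mats$Hinv
    for (ti in seq_along(data$traits)) {
      d <- build_design(phen, data$traits[ti], data$factors,
                        data$covariates, ids)
      fit <- solve_single_trait(d$y, d$X, d$Z, Kinv, data$vc[[ti]],
                                method = method)
      out[[ti]] <- fit$g
    }
  } else if (method == "gblup") {
    for (ti in seq_along(data$traits)) {
      d <- build_design(phen, data$traits[ti], data$factors,
                        data$covariates, ids)
      full <- solve_single_trait(d$y, d$X, d$Z, mats$Ainv, data$vc[[ti]],
                                 method = "blup")
      yc <- corrected_phenotype(full)
      yc <- yc[intersect(names(yc), mats$genotyped_ids)]
      fit <- solve_gblup(yc, mats$Gw, data$vc[[ti]])
      out[[ti]] <- fit$g
    }
  } else if (method == "ssgblup2") {
    if (length(data$traits) != 2L || is.null(data$M) || is.null(data$R)) {
      stop("method 'ssgblup2' needs two traits and M, R covariance matrices")
    }
    d1 <- build_design(phen, data$traits[1L], data$factors,
                       data$covariates, ids)
    d2 <- build_design(phen, data$traits[2L], data$factors,
                       data$covariates, ids)
    fit <- solve_two_trait(d1, d2, mats$Hinv, data$M, data$R)
    out <- list(fit$trait1$g, fit$trait2$g)
  } else {
    stop("unknown method '", method, "'")
  }
  names(out) <- data$traits[seq_along(out)]
  out
}

#' Run replicated cross-validation for one method
#'
#' For every fold: mask the validation animals' phenotypes, refit the
#' model, and score the validation predictions against the reference
#' values by [accuracy()] and [unbiasedness()]. All methods fed the same
#' fold plans see identical validation sets.
#'
#' @param data An `eval_data`.
#' @param method One of `"blup"`, `"gblup"`, `"ssgblup"`, `"ssgblup2"`.
#' @param fold_plans From [make_folds()].
#' @param w Blending weight.
#' @param matrices Optional precomputed [prediction_matrices()] (shared
#'   across methods for speed, or carrying a `Gw_override`).
#' @return A `cv_report`: data frame with columns `method`, `trait`,
#'   `replicate`, `fold`, `r`, `b`, and attribute `reference_kind`.
#' @export
run_cv <- function(data, method, fold_plans, w = 0.95, matrices = NULL) {
  stopifnot(inherits(data, "eval_data"))
  if (method %in% c("gblup", "ssgblup", "ssgblup2") &&
      is.null(data$panel)) {
    stop("method '", method, "' needs genotypes")
  }
  if (is.null(matrices)) matrices <- prediction_matrices(data, w = w)
  rows <- list()
  for (plan in fold_plans) {
    pbv <- predict_masked(data, method, plan$validation_ids, matrices)
    for (tr in names(pbv)) {
      ref <- data$reference_values[[tr]]
      val <- intersect(plan$validation_ids, names(ref))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, trait = tr,
        replicate = plan$replicate, fold = plan$fold,
        r = accuracy(ref[val], pbv[[tr]][val]),
        b = unbiasedness(ref[val], pbv[[tr]][val]),
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- do.call(rbind, rows)
  attr(rep_df, "reference_kind") <- data$reference_kind
  class(rep_df) <- c("cv_report", class(rep_df))
  rep_df
}

#' Summarise a cross-validation report
#'
#' Mean and SD of accuracy and unbiasedness per method and trait, both
#' over all replicate-by-fold cells and over per-replicate fold averages
#' (the "20 averaged accuracies" convention).
#'
#' @param report A `cv_report` from [run_cv()] (reports from several
#'   methods can be `rbind`-ed first).
#' @return Data frame with one row per method and trait.
#' @export
summarize_cv <- function(report) {
  sp <- split(as.data.frame(report), list(report$method, report$trait),
              drop = TRUE)
  out <- lapply(sp, function(d) {
    per_rep_r <- tapply(d$r, d$replicate, mean, na.rm = TRUE)
    per_rep_b <- tapply(d$b, d$replicate, mean, na.rm = TRUE)
    data.frame(method = d$method[1L], trait = d$trait[1L],
               n_cells = nrow(d),
               r_mean = mean(d$r, na.rm = TRUE),
               r_sd = stats::sd(d$r, na.rm = TRUE),
               b_mean = mean(d$b, na.rm = TRUE),
               b_sd = stats::sd(d$b, na.rm = TRUE),
               r_sd_reps = stats::sd(per_rep_r),
               b_sd_reps = stats::sd(per_rep_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
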