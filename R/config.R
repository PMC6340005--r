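#' Run configuration
#'
#' Bundles the knobs of a genomic-evaluation run: the model, variance
#' components, the genomic/pedigree blending weight w, cross-validation
#' settings, marker QC thresholds and simulator parameters. Values not
#' supplied fall back to the package defaults shown below.
#'
#' @param model One of `"blup"`, `"gblup"`, `"ssgblup"`, `"ssgblup2"`.
#' @param w Blending weight on the adjusted genomic matrix, in (0, 1].
#' @param variance_components List with `sigma_g2`, `sigma_e2` (single
#'   trait) and optionally `M`, `R` (2x2 matrices, two-trait); `NULL`
#'   means estimate by REML where supported.
#' @param cv List with `k` (folds, >= 2), `replicates`, `seed`.
#' @param qc List with `maf_min`, `call_min`, `hwe_p_min`, all in (0, 1).
#' @param simulation List of simulator parameter overrides (see
#'   [genome_config()], [population_config()], [trait_config()]).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(model = "ssgblup",
                       w = 0.95,
                       variance_components = NULL,
                       cv = list(k = 5L, replicates = 20L, seed = 1L),
                       qc = list(maf_min = 0.05, call_min = 0.90,
                                 hwe_p_min = 1e-7),
                       simulation = list()) {
  model <- match.arg(model, c("blup", "gblup", "ssgblup", "ssgblup2"))
  stopifnot(is.numeric(w), length(w) == 1L)
  if (!(w > 0 && w <= 1)) stop("w must be in (0, 1]")
  cv <- utils::modifyList(list(k = 5L, replicates = 20L, seed = 1L), cv)
  if (cv$k < 2L) stop("cv$k must be >= 2")
  qc <- utils::modifyList(list(maf_min = 0.05, call_min = 0.90,
                               hwe_p_min = 1e-7), qc)
  for (th in c("maf_min", "call_min", "hwe_p_min")) {
    if (!(qc[[th]] > 0 && qc[[th]] < 1)) {
      stop("QC threshold ", th, " must be in (0, 1)")
    }
  }
  structure(list(model = model, w = w,
                 variance_components = variance_components,
                 cv = cv, qc = qc, simulation = simulation),
            class = "run_config")
}

#' Read a run configuration from a YAML (or JSON) file
#'
#' The file is a key tree mirroring the arguments of [run_config()];
#' supplied keys override defaults, `overrides` (e.g. parsed command-line
#' flags) override the file.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file contents.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (length(overrides)) raw <- utils::modifyList(raw, overrides)
  args <- raw[intersect(names(raw),
                        c("model", "w", "variance_components", "cv", "qc",
                          "simulation"))]
  do.call(run_config, args)
}
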