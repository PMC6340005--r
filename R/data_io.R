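#' Genotype panel constructor
#'
#' A genotype panel couples an individuals-by-markers dosage matrix
#' (integers 0/1/2, `NA` for missing) with a genetic map giving each
#' marker's chromosome and position in Morgan. Positions must be
#' non-decreasing within chromosome; matrix dimnames carry the individual
#' and marker ids.
#'
#' @param dosage Integer matrix, individuals in rows (rownames = ids),
#'   markers in columns (colnames = marker ids).
#' @param map Data frame with columns `marker`, `chr`, `pos` in the same
#'   marker order as the columns of `dosage`.
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(map), all(c("marker", "chr", "pos") %in% names(map)))
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " markers but map has ", nrow(map))
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  if (!identical(colnames(dosage), as.character(map$marker))) {
    stop("marker ids in dosage columns and map disagree")
  }
  if (is.null(rownames(dosage))) {
    stop("dosage matrix must have individual ids as rownames")
  }
  bad <- which(!(dosage %in% c(0L, 1L, 2L)) & !is.na(dosage))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(dosage))
    stop("invalid dosage ", dosage[bad[1L]], " at individual ",
         rownames(dosage)[rc[1L]], ", marker ", colnames(dosage)[rc[2L]],
         " (must be 0, 1, 2 or NA)")
  }
  ooo <- tapply(map$pos, map$chr, function(p) any(diff(p) < 0))
  if (any(unlist(ooo))) {
    stop("marker positions are not non-decreasing within chromosome(s) ",
         paste(names(ooo)[unlist(ooo)], collapse = ", "))
  }
  structure(list(dosage = dosage, map = as.data.frame(map)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers;",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

dosage_matrix <- function(panel) {
  if (inherits(panel, "genotype_panel")) panel$dosage else as.matrix(panel)
}

#' Read a pedigree file
#'
#' Delimited text with three columns (animal, sire, dam); unknown parents
#' coded "0" or empty, normalised internally to `NA`. Records are returned
#' in file order; sorting for relationship algebra is done by
#' [topological_sort()].
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param header Does the file carry a header row? Default `TRUE`.
#' @return Data frame with character columns `animal`, `sire`, `dam`.
#' @export
read_pedigree <- function(path, sep = ",", header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character",
                          strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(df) < 3L) stop("pedigree file needs 3 columns (animal, sire, dam)")
  df <- df[, 1:3]
  names(df) <- c("animal", "sire", "dam")
  for (col in c("sire", "dam")) {
    df[[col]][df[[col]] %in% c("0", "", "NA")] <- NA_character_
  }
  if (any(df$animal == "" | is.na(df$animal))) stop("empty animal id in pedigree")
  dup <- unique(df$animal[duplicated(df$animal)])
  if (length(dup)) {
    stop("duplicate animal id(s) in pedigree: ", paste(dup, collapse = ", "))
  }
  self <- df$animal == df$sire | df$animal == df$dam
  self[is.na(self)] <- FALSE
  if (any(self)) {
    stop("animal listed as its own parent: ",
         paste(df$animal[self], collapse = ", "))
  }
  df
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]; unknown parents are written as "0".
#'
#' @param ped Data frame with `animal`, `sire`, `dam` (or an
#'   `ordered_pedigree`).
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  df <- as_pedigree_df(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited text with a header; must contain an `animal` column, the
#' named factors (kept as character), covariates and traits (numeric;
#' empty cells become `NA` and the row is retained, which is what
#' cross-validation masking relies on).
#'
#' @param path File path.
#' @param traits Character vector of trait column names.
#' @param factors Character vector of fixed-effect factor column names.
#' @param covariates Character vector of covariate column names.
#' @param sep Field separator.
#' @return Data frame with `animal` plus the requested columns.
#' @export
read_phenotypes <- function(path, traits, factors = character(),
                            covariates = character(), sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", strip.white = TRUE)
  need <- c("animal", traits, factors, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("phenotype file is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- df[, need, drop = FALSE]
  for (col in c(traits, covariates)) {
    v <- out[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      stop("non-numeric value in column '", col, "'")
    }
    if (any(is.infinite(num))) stop("non-finite value in column '", col, "'")
    out[[col]] <- num
  }
  out
}

#' Write a phenotype table
#'
#' @param phen Data frame as returned by [read_phenotypes()].
#' @param path Output path.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read genotypes from a RAW-style dosage file plus map
#'
#' The genotype file is a whitespace table: a header row of marker ids
#' preceded by an individual-id column name, then one row per individual
#' with dosages 0/1/2 or NA. The map file has three whitespace-separated
#' columns: marker id, chromosome, position in Morgan. Markers are
#' returned in map order.
#'
#' @param path Genotype file path.
#' @param map_path Map file path.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path, map_path) {
  map <- utils::read.table(map_path, header = TRUE,
                           col.names = c("marker", "chr", "pos"),
                           colClasses = c("character", "integer", "numeric"))
  geno <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
  ids <- geno[[1L]]
  markers <- names(geno)[-1L]
  if (!setequal(markers, map$marker) || length(markers) != nrow(map)) {
    stop("marker ids in genotype header and map file disagree")
  }
  M <- as.matrix(geno[, -1L, drop = FALSE])
  M[M == "NA" | M == ""] <- NA
  num <- suppressWarnings(matrix(as.integer(M), nrow(M), ncol(M)))
  bad <- which((is.na(num) & !is.na(M)) | !(num %in% c(0L, 1L, 2L, NA)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(M))
    stop("invalid dosage '", M[bad[1L]], "' for individual ", ids[rc[1L]],
         ", marker ", markers[rc[2L]])
  }
  dimnames(num) <- list(ids, markers)
  num <- num[, map$marker, drop = FALSE]
  genotype_panel(num, map)
}

#' Write genotypes as a RAW-style dosage file plus map
#'
#' Inverse of [read_genotypes()].
#'
#' @param panel A `genotype_panel`.
#' @param path Genotype output path.
#' @param map_path Map output path.
#' @export
write_genotypes <- function(panel, path, map_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(IID = rownames(panel$dosage),
                   panel$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                     na = "NA")
  utils::write.table(panel$map, map_path, sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
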