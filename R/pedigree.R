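#' Topologically sort a pedigree
#'
#' Orders pedigree records so that every parent precedes its offspring, the
#' layout required by the tabular method for the numerator relationship
#' matrix A and by Henderson's rules for its sparse inverse. Animals that
#' appear only as parents are added as founders. The sort is stable:
#' within a "generation" (animals whose parents are already placed) the
#' original record order is kept, founders first.
#'
#' @param ped A data frame with character columns `animal`, `sire`, `dam`
#'   (as returned by [read_pedigree()]). Unknown parents are `NA`.
#' @return An object of class `ordered_pedigree`: a list with elements
#'   `id` (character vector in sorted order), `sire` and `dam` (integer
#'   indices into `id`, `0L` for unknown), and `n`.
#' @export
topological_sort <- function(ped) {
  ped <- as_pedigree_df(ped)
  ids <- ped$animal
  if (anyDuplicated(ids)) {
    stop("duplicate animal id(s) in pedigree: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  self <- which(!is.na(ped$sire) & ped$sire == ids |
                !is.na(ped$dam) & ped$dam == ids)
  if (length(self)) {
    stop("animal listed as its own parent: ", paste(ids[self], collapse = ", "))
  }
  parents <- unique(c(ped$sire, ped$dam))
  parents <- parents[!is.na(parents)]
  missing_par <- setdiff(parents, ids)
  if (length(missing_par)) {
    ped <- rbind(
      data.frame(animal = missing_par, sire = NA_character_,
                 dam = NA_character_, stringsAsFactors = FALSE),
      ped
    )
    ids <- ped$animal
  }
  n <- nrow(ped)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  placed <- logical(n)
  order_out <- integer(n)
  filled <- 0L
  repeat {
    ready <- which(!placed &
                   (si == 0L | placed[pmax(si, 1L)]) &
                   (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    order_out[filled + seq_along(ready)] <- ready
    filled <- filled + length(ready)
    placed[ready] <- TRUE
  }
  if (filled < n) {
    cyc <- find_pedigree_cycle(si, di, placed)
    stop("pedigree contains a cycle (animal is its own ancestor): ",
         paste(ids[cyc], collapse = " -> "))
  }
  pos <- integer(n)
  pos[order_out] <- seq_len(n)
  structure(
    list(
      id   = ids[order_out],
      sire = ifelse(si[order_out] == 0L, 0L, pos[pmax(si[order_out], 1L)]),
      dam  = ifelse(di[order_out] == 0L, 0L, pos[pmax(di[order_out], 1L)]),
      n    = n
    ),
    class = "ordered_pedigree"
  )
}

# Walk parent pointers from an unplaced node until a repeat: one cycle.
find_pedigree_cycle <- function(si, di, placed) {
  start <- which(!placed)[1L]
  path <- integer(0)
  cur <- start
  while (!(cur %in% path)) {
    path <- c(path, cur)
    nxt <- if (si[cur] != 0L && !placed[si[cur]]) si[cur] else di[cur]
    cur <- nxt
  }
  c(path[which(path == cur):length(path)], cur)
}

as_pedigree_df <- function(ped) {
  if (inherits(ped, "ordered_pedigree")) {
    return(data.frame(
      animal = ped$id,
      sire = ifelse(ped$sire == 0L, NA_character_, ped$id[pmax(ped$sire, 1L)]),
      dam  = ifelse(ped$dam == 0L, NA_character_, ped$id[pmax(ped$dam, 1L)]),
      stringsAsFactors = FALSE
    ))
  }
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  norm <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  data.frame(animal = as.character(ped$animal),
             sire = norm(ped$sire),
             dam = norm(ped$dam),
             stringsAsFactors = FALSE)
}

#' @export
print.ordered_pedigree <- function(x, ...) {
  nf <- sum(x$sire == 0L & x$dam == 0L)
  cat("Ordered pedigree:", x$n, "animals (", nf, "founders )\n")
  invisible(x)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the inbreeding coefficient F for every animal of a sorted
#' pedigree without forming the dense relationship matrix, by accumulating
#' each animal's row of the Cholesky factor of A over its ancestors
#' (Meuwissen & Luo 1992). F is exact: `diag(A) == 1 + F`.
#'
#' @param ped An `ordered_pedigree` from [topological_sort()].
#' @return Numeric vector of inbreeding coefficients, named by animal id.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "ordered_pedigree"))
  n <- ped$n
  s <- ped$sire
  d <- ped$dam
  F <- numeric(n)
  D <- numeric(n)     # Mendelian-sampling variance, filled in pedigree order
  L <- numeric(n)
  mark <- logical(n)
  fpar <- function(p) if (p == 0L) -1 else F[p]  # F of a phantom parent is -1
  for (i in seq_len(n)) {
    D[i] <- 0.5 - 0.25 * (fpar(s[i]) + fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) next          # F stays 0
    # gather the distinct ancestors of i (including i)
    stack <- i
    anc <- integer(0)
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (mark[j]) next
      mark[j] <- TRUE
      anc <- c(anc, j)
      if (s[j] > 0L) stack <- c(stack, s[j])
      if (d[j] > 0L) stack <- c(stack, d[j])
    }
    anc <- sort.int(anc, decreasing = TRUE)
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      lj <- L[j]
      aii <- aii + lj * lj * D[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      L[j] <- 0
    }
    mark[anc] <- FALSE
    F[i] <- aii - 1
  }
  names(F) <- ped$id
  F
}

# Mendelian-sampling variances d_i given parental inbreeding.
# Both parents known: 0.5 - 0.25 (F_s + F_d); one: 0.75 - 0.25 F_p; none: 1.
mendelian_variance <- function(ped, F = NULL, use_inbreeding = TRUE) {
  if (is.null(F)) F <- if (use_inbreeding) inbreeding(ped) else numeric(ped$n)
  if (!use_inbreeding) F <- numeric(ped$n)
  fs <- ifelse(ped$sire == 0L, -1, F[pmax(ped$sire, 1L)])
  fd <- ifelse(ped$dam == 0L, -1, F[pmax(ped$dam, 1L)])
  0.5 - 0.25 * (fs + fd)
}

#' Numerator relationship matrix A (tabular method)
#'
#' Builds the dense additive genetic relationship matrix by the tabular
#' recurrence: a(x,y) = 0.5 (a(sire_x, y) + a(dam_x, y)) for y preceding x,
#' and a(x,x) = 1 + 0.5 a(sire_x, dam_x); unknown parents contribute 0.
#' Dense storage: intended for pedigrees up to roughly 10,000 animals. For
#' the genotyped-block relationship only, [build_A22()] avoids the full
#' matrix.
#'
#' @param ped An `ordered_pedigree`.
#' @return A dense symmetric matrix with dimnames set to animal ids and
#'   attribute `tag = "A"`.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "ordered_pedigree"))
  n <- ped$n
  A <- matrix(0, n, n)
  s <- ped$sire
  d <- ped$dam
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      as_ <- if (s[i] > 0L) A[prev, s[i]] else 0
      ad_ <- if (d[i] > 0L) A[prev, d[i]] else 0
      v <- 0.5 * (as_ + ad_)
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  attr(A, "tag") <- "A"
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Constructs A^-1 directly from the pedigree via Henderson's rules with
#' inbreeding: A^-1 = (I - P)' D^-1 (I - P), where P carries 0.5 at each
#' (animal, parent) position and D holds the Mendelian-sampling variances
#' derived from parental inbreeding coefficients. The result is sparse:
#' each animal contributes entries only for itself and its parents.
#'
#' @param ped An `ordered_pedigree`.
#' @param F Optional precomputed inbreeding coefficients (from
#'   [inbreeding()]); computed if `NULL` and `use_inbreeding` is `TRUE`.
#' @param use_inbreeding If `FALSE`, all F are treated as 0 (the classic
#'   non-inbred rules). Default `TRUE`.
#' @return A sparse symmetric `Matrix` with id dimnames, `tag = "Ainv"`.
#' @export
build_A_inverse <- function(ped, F = NULL, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "ordered_pedigree"))
  n <- ped$n
  dvec <- mendelian_variance(ped, F, use_inbreeding)
  if (any(dvec <= 0)) {
    stop("non-positive Mendelian-sampling variance for animal(s) ",
         paste(ped$id[dvec <= 0], collapse = ", "),
         " (corrupt pedigree or inconsistent inbreeding)")
  }
  has_s <- ped$sire > 0L
  has_d <- ped$dam > 0L
  ii <- c(seq_len(n), which(has_s), which(has_d))
  jj <- c(seq_len(n), ped$sire[has_s], ped$dam[has_d])
  xx <- c(rep(1, n), rep(-0.5, sum(has_s)), rep(-0.5, sum(has_d)))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Ainv <- Matrix::crossprod(W * sqrt(1 / dvec))  # rows of W scaled by 1/sqrt(d)
  dimnames(Ainv) <- list(ped$id, ped$id)
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "tag") <- "Ainv"
  Ainv
}

#' Pedigree relationship among a subset without forming all of A
#'
#' Computes the A22 block (relationships among a chosen subset, typically
#' the genotyped animals) using the factorisation A = (I-P)^-1 D (I-P)^-T,
#' so only sparse triangular solves of size n by |subset| are needed
#' (Colleau's indirect method).
#'
#' @param ped An `ordered_pedigree`.
#' @param ids Character vector of animal ids (must be in the pedigree).
#' @param F Optional inbreeding coefficients.
#' @return Dense symmetric matrix over `ids` (in the given order),
#'   `tag = "A22"`.
#' @export
build_A22 <- function(ped, ids, F = NULL) {
  stopifnot(inherits(ped, "ordered_pedigree"))
  idx <- match(ids, ped$id)
  if (anyNA(idx)) {
    stop("genotyped id(s) absent from pedigree: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  n <- ped$n
  dvec <- mendelian_variance(ped, F)
  has_s <- ped$sire > 0L
  has_d <- ped$dam > 0L
  ii <- c(seq_len(n), which(has_s), which(has_d))
  jj <- c(seq_len(n), ped$sire[has_s], ped$dam[has_d])
  xx <- c(rep(1, n), rep(-0.5, sum(has_s)), rep(-0.5, sum(has_d)))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(n, length(idx)))
  U <- Matrix::solve(Matrix::t(W), E)          # (I-P)^-T E
  V <- U * dvec                                # D (I-P)^-T E
  AE <- Matrix::solve(W, V)                    # A E
  A22 <- as.matrix(AE[idx, , drop = FALSE])
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(ids, ids)
  attr(A22, "tag") <- "A22"
  A22
}

#' Partition A into non-genotyped / genotyped blocks
#'
#' Splits the numerator relationship matrix into the A11 (non-genotyped),
#' A12 (cross) and A22 (genotyped) blocks used by single-step GBLUP, and
#' returns the dense inverse of A22 (which is *not* the genotyped block of
#' A^-1).
#'
#' @param A Dense relationship matrix with id dimnames (from [build_A()]).
#' @param genotyped_ids Character vector of genotyped animal ids.
#' @return List with `A11`, `A12`, `A22`, `A22inv`, and the id vectors
#'   `nongenotyped_ids`, `genotyped_ids`.
#' @export
partition_A <- function(A, genotyped_ids) {
  ids <- rownames(A)
  miss <- setdiff(genotyped_ids, ids)
  if (length(miss)) {
    stop("genotyped id(s) absent from pedigree: ", paste(miss, collapse = ", "))
  }
  g <- match(genotyped_ids, ids)
  ng <- setdiff(seq_along(ids), g)
  A11 <- A[ng, ng, drop = FALSE]
  A12 <- A[ng, g, drop = FALSE]
  A22 <- A[g, g, drop = FALSE]
  attr(A11, "tag") <- "A11"
  attr(A12, "tag") <- "A12"
  attr(A22, "tag") <- "A22"
  A22inv <- if (length(g)) chol2inv(chol(A22)) else A22
  dimnames(A22inv) <- dimnames(A22)
  attr(A22inv, "tag") <- "A22inv"
  list(A11 = A11, A12 = A12, A22 = A22, A22inv = A22inv,
       nongenotyped_ids = ids[ng], genotyped_ids = ids[g])
}
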