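#' VanRaden genomic relationship matrix
#'
#' Builds G (VanRaden method 1) from a complete 0/1/2 dosage matrix:
#' Z = M - 2p centers each marker at twice its allele frequency, and
#' G = ZZ' / (2 * sum p (1 - p)). With frequencies estimated from the same
#' panel, mean(diag(G)) is close to 1.
#'
#' @param panel A `genotype_panel` (see [genotype_panel()]) or a plain
#'   individuals-by-markers dosage matrix with no missing values.
#' @param freqs Per-marker frequency of the counted allele; if `NULL`,
#'   estimated from the panel as `colMeans(dosage)/2`.
#' @return Dense symmetric matrix over individual ids, `tag = "G"`.
#' @export
build_G <- function(panel, freqs = NULL) {
  M <- dosage_matrix(panel)
  if (anyNA(M)) stop("genotype panel has missing dosages; impute first")
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  if (length(freqs) != ncol(M)) stop("length(freqs) must equal marker count")
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("fixed marker(s) present (allele frequency 0 or 1); ",
         "run QC before building G")
  }
  Z <- sweep(M, 2L, 2 * freqs)
  denom <- 2 * sum(freqs * (1 - freqs))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "tag") <- "G"
  G
}

#' Adjust G to the scale of the pedigree relationship matrix
#'
#' G and A22 refer to different base populations, so their coefficients
#' differ in scale and location. Following the common practice for
#' single-step evaluation, Ga = G beta + alpha where (beta, alpha) solve
#' the 2x2 system equating the average diagonal and average off-diagonal
#' of Ga with those of A22:
#' \deqn{Avg.diag(G) \beta + \alpha = Avg.diag(A22)}
#' \deqn{Avg.offdiag(G) \beta + \alpha = Avg.offdiag(A22)}
#'
#' @param G Genomic relationship matrix.
#' @param A22 Pedigree relationship matrix among the same animals, same
#'   id order.
#' @return List with `Ga` (adjusted matrix, `tag = "Ga"`), `beta`, `alpha`.
#' @export
adjust_G <- function(G, A22) {
  check_same_ids(G, A22)
  n <- nrow(G)
  if (n < 2L) stop("adjustment needs at least 2 animals")
  dg <- mean(diag(G))
  og <- offdiag_mean(G)
  da <- mean(diag(A22))
  oa <- offdiag_mean(A22)
  if (abs(dg - og) < 1e-12) {
    stop("average diagonal and off-diagonal of G are equal; ",
         "adjustment system is singular")
  }
  beta <- (da - oa) / (dg - og)
  alpha <- da - dg * beta
  Ga <- G * beta + alpha
  attr(Ga, "tag") <- "Ga"
  list(Ga = Ga, beta = beta, alpha = alpha)
}

offdiag_mean <- function(M) {
  n <- nrow(M)
  (sum(M) - sum(diag(M))) / (n * (n - 1))
}

check_same_ids <- function(X, Y) {
  if (!identical(dim(X), dim(Y))) stop("matrix dimensions differ")
  rx <- rownames(X); ry <- rownames(Y)
  if (!is.null(rx) && !is.null(ry) && !identical(rx, ry)) {
    stop("matrices are not indexed by the same ids in the same order")
  }
  invisible(TRUE)
}

#' Blend the adjusted genomic matrix with A22
#'
#' Gw = w * Ga + (1 - w) * A22. The blend keeps Gw positive definite (A22
#' typically is) so that Gw can be inverted inside H^-1; w = 0.95 is the
#' conventional weight. Setting Gw = A22 (w with Ga = A22) collapses
#' single-step GBLUP to pedigree BLUP.
#'
#' @param Ga Adjusted genomic relationship matrix.
#' @param A22 Pedigree relationship matrix, same id order.
#' @param w Blending weight on the genomic component, in (0, 1].
#' @return Dense matrix `tag = "Gw"`.
#' @export
blend_Gw <- function(Ga, A22, w = 0.95) {
  check_same_ids(Ga, A22)
  stopifnot(is.numeric(w), length(w) == 1L, w > 0, w <= 1)
  Gw <- w * Ga + (1 - w) * A22
  attr(Gw, "tag") <- "Gw"
  Gw
}

#' Inverse of the single-step relationship matrix H
#'
#' The combined relationship matrix H merges pedigree and genomic
#' information; its inverse is simply A^-1 plus a correction in the
#' genotyped block:
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G_w^{-1} - A_{22}^{-1} \end{bmatrix}}
#' with animals ordered non-genotyped first, genotyped second (the order
#' is taken from the dimnames, so any consistent ordering works).
#'
#' @param Ainv Sparse pedigree relationship inverse over all animals.
#' @param A22inv Dense inverse of the genotyped block of A.
#' @param Gw Blended genomic relationship matrix (positive definite),
#'   same ids/order as `A22inv`.
#' @return Sparse symmetric matrix over all animals, `tag = "Hinv"`.
#' @export
build_H_inverse <- function(Ainv, A22inv, Gw) {
  ids <- rownames(Ainv)
  gids <- rownames(Gw)
  check_same_ids(Gw, A22inv)
  if (length(gids) == 0L) {
    Hinv <- Ainv
    attr(Hinv, "tag") <- "Hinv"
    return(Hinv)
  }
  gidx <- match(gids, ids)
  if (anyNA(gidx)) {
    stop("genotyped id(s) absent from Ainv: ",
         paste(gids[is.na(gidx)], collapse = ", "))
  }
  Gwinv <- tryCatch(chol2inv(chol(Gw)), error = function(e) {
    stop("Gw is not positive definite; blend with A22 (see blend_Gw)")
  })
  delta <- Gwinv - A22inv
  n <- nrow(Ainv)
  ng <- length(gidx)
  Dg <- Matrix::sparseMatrix(
    i = rep(gidx, times = ng),
    j = rep(gidx, each = ng),
    x = as.numeric(delta),
    dims = c(n, n)
  )
  Hinv <- Matrix::forceSymmetric(Ainv + Dg)
  dimnames(Hinv) <- list(ids, ids)
  attr(Hinv, "tag") <- "Hinv"
  Hinv
}

#' Dense single-step relationship matrix H (small instances)
#'
#' Direct block construction, mainly a testing aid for verifying
#' [build_H_inverse()]:
#' H11 = A11 + A12 A22^-1 (Gw - A22) A22^-1 A12',
#' H12 = A12 A22^-1 Gw, H22 = Gw.
#'
#' @param A11,A12,A22,A22inv Blocks from [partition_A()].
#' @param Gw Blended genomic matrix over the genotyped animals.
#' @return Dense symmetric matrix ordered non-genotyped first, `tag = "H"`.
#' @export
build_H_direct <- function(A11, A12, A22, A22inv, Gw) {
  check_same_ids(A22, Gw)
  B <- A12 %*% A22inv
  H11 <- A11 + B %*% (Gw - A22) %*% t(B)
  H12 <- B %*% Gw
  H <- rbind(cbind(H11, H12), cbind(t(H12), Gw))
  H <- (H + t(H)) / 2
  ids <- c(rownames(A11), rownames(Gw))
  dimnames(H) <- list(ids, ids)
  attr(H, "tag") <- "H"
  H
}
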