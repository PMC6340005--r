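#' Build design matrices for a single-trait animal model
#'
#' Assembles y, the fixed-effect design X (intercept, factor dummies with
#' treatment contrasts, covariates), and the sparse incidence matrix Z
#' mapping records to animals, for the model y = Xb + Zg + e. Records with
#' a missing trait value are excluded (this is how cross-validation masks
#' the validation animals). Factor levels left without records are dropped
#' with a warning, and X is reduced to full column rank if factors are
#' confounded.
#'
#' @param phen Phenotype data frame (see [read_phenotypes()]).
#' @param trait Name of the trait column.
#' @param factors Character vector of factor column names.
#' @param covariates Character vector of covariate column names (fitted as
#'   regressions, never constrained).
#' @param animal_ids Ordered ids of all animals carried by the
#'   relationship matrix; every record's animal must be among them.
#' @return List with `y`, `X` (dense), `Z` (sparse), `animal` (record-wise
#'   animal ids), `ids` (= `animal_ids`).
#' @export
build_design <- function(phen, trait, factors = character(),
                         covariates = character(), animal_ids) {
  stopifnot(trait %in% names(phen), "animal" %in% names(phen))
  keep <- !is.na(phen[[trait]])
  rec <- phen[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no records with non-missing trait '", trait, "'")
  miss <- setdiff(rec$animal, animal_ids)
  if (length(miss)) {
    stop("record animal(s) absent from relationship ids: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  y <- rec[[trait]]
  terms <- "1"
  for (f in factors) {
    lv_all <- unique(phen[[f]])
    lv_obs <- unique(rec[[f]])
    gone <- setdiff(lv_all, lv_obs)
    if (length(gone)) {
      warning("factor '", f, "': level(s) without records dropped: ",
              paste(gone, collapse = ", "))
    }
    rec[[f]] <- factor(rec[[f]])
    terms <- c(terms, f)
  }
  terms <- c(terms, covariates)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = rec)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(rec)),
                            j = match(rec$animal, animal_ids),
                            x = 1,
                            dims = c(nrow(rec), length(animal_ids)))
  colnames(Z) <- animal_ids
  list(y = y, X = X, Z = Z, animal = rec$animal, ids = animal_ids)
}

#' Solve the single-trait mixed-model equations
#'
#' Henderson's MME for y = Xb + Zg + e with g ~ N(0, K sigma_g2) and
#' e ~ N(0, I sigma_e2), where K is supplied through its inverse (A^-1
#' for pedigree BLUP, H^-1 for single-step GBLUP, G^-1 for GBLUP):
#' \deqn{\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1}
#'   \end{bmatrix} \begin{bmatrix} \hat b \\ \hat g \end{bmatrix} =
#'   \begin{bmatrix} X'y \\ Z'y \end{bmatrix}, \quad
#'   \lambda = \sigma_e^2 / \sigma_g^2.}
#' Solved by sparse Cholesky. Breeding values are returned for every
#' animal in K, including record-less ones.
#'
#' @param y,X,Z Design components from [build_design()].
#' @param Kinv Relationship inverse (sparse or dense), dimnames = ids.
#' @param vc List with `sigma_g2` and `sigma_e2` (> 0).
#' @param method Tag stored on the fit.
#' @return A `model_fit`: list with `b`, `g` (named PBV vector),
#'   `residuals`, `fitted`, `animal`, `vc`, `method`, `y`.
#' @export
solve_single_trait <- function(y, X, Z, Kinv, vc, method = "blup") {
  stopifnot(is.list(vc), vc$sigma_g2 > 0, vc$sigma_e2 > 0)
  lambda <- vc$sigma_e2 / vc$sigma_g2
  ids <- rownames(Kinv)
  if (ncol(Z) != nrow(Kinv)) stop("Z and Kinv dimensions disagree")
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  XtX <- Matrix::crossprod(Xs)
  XtZ <- Matrix::crossprod(Xs, Z)
  ZtZ <- Matrix::crossprod(Z)
  C <- rbind(cbind(XtX, XtZ),
             cbind(Matrix::t(XtZ), ZtZ + lambda * Kinv))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(C), rhs)),
    error = function(e) stop("mixed-model equations are singular: ",
                             conditionMessage(e))
  )
  p <- ncol(X)
  b <- sol[seq_len(p)]
  names(b) <- colnames(X)
  g <- sol[p + seq_len(ncol(Z))]
  names(g) <- ids
  fitted <- as.numeric(X %*% b + Z %*% g)
  structure(list(b = b, g = g, residuals = y - fitted, fitted = fitted,
                 animal = if (!is.null(colnames(Z)))
                   colnames(Z)[apply_record_animal(Z)] else NULL,
                 vc = vc, method = method, y = y),
            class = "model_fit")
}

apply_record_animal <- function(Z) {
  # column index of the single 1 in each record row of the incidence matrix
  Zt <- methods::as(Z, "TsparseMatrix")
  idx <- integer(nrow(Z))
  idx[Zt@i + 1L] <- Zt@j + 1L
  idx
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Animal-model fit (", x$method, "): ", length(x$y), " records, ",
      length(x$g), " breeding values\n", sep = "")
  cat("  sigma_g2 =", format(x$vc$sigma_g2), " sigma_e2 =",
      format(x$vc$sigma_e2), "\n")
  invisible(x)
}

#' Corrected phenotypes
#'
#' yc(i) = PBV(i) + mean residual of animal i's records; the response
#' variable of GBLUP. Animals without records get no corrected phenotype.
#'
#' @param fit A `model_fit` from [solve_single_trait()] on the full data.
#' @return Named numeric vector over animals with records.
#' @export
corrected_phenotype <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  ebar <- tapply(fit$residuals, fit$animal, mean)
  yc <- fit$g[names(ebar)] + as.numeric(ebar)
  names(yc) <- names(ebar)
  yc
}

#' GBLUP on corrected phenotypes
#'
#' Fits yc = 1u + Za + e with a ~ N(0, G sigma_a2) over the genotyped
#' animals. Animals present in G but without a corrected phenotype (e.g.
#' validation candidates) receive predictions through their genomic
#' relationships.
#'
#' @param yc Named vector of corrected phenotypes (names = animal ids;
#'   only ids present in G are used).
#' @param G Genomic relationship matrix (positive definite; blend with
#'   A22 if singular).
#' @param vc List with `sigma_g2`, `sigma_e2`.
#' @return A `model_fit` with `g` holding genomic breeding values for all
#'   animals in G.
#' @export
solve_gblup <- function(yc, G, vc) {
  ids <- rownames(G)
  yc <- yc[!is.na(yc)]
  use <- intersect(names(yc), ids)
  if (length(use) < 2L) stop("need at least 2 corrected phenotypes in G")
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) {
    stop("G is singular; blend with A22 (see blend_Gw) before GBLUP")
  })
  dimnames(Ginv) <- dimnames(G)
  yv <- as.numeric(yc[use])
  X <- matrix(1, length(use), 1, dimnames = list(NULL, "(Intercept)"))
  Z <- Matrix::sparseMatrix(i = seq_along(use), j = match(use, ids), x = 1,
                            dims = c(length(use), length(ids)))
  colnames(Z) <- ids
  solve_single_trait(yv, X, Z, Ginv, vc, method = "gblup")
}

#' Solve the two-trait mixed-model equations
#'
#' Bivariate animal model
#' \deqn{\begin{bmatrix} y_1 \\ y_2 \end{bmatrix} =
#'   \begin{bmatrix} X_1 & 0 \\ 0 & X_2 \end{bmatrix} b +
#'   \begin{bmatrix} Z_1 & 0 \\ 0 & Z_2 \end{bmatrix} g + e,}
#' with g ~ N(0, M (x) K) over trait-major stacked breeding values and
#' e ~ N(0, I (x) R) record-wise. Records where only one trait is
#' observed contribute through the corresponding sub-block of R (the
#' design lists already exclude missing-trait records). The random-effect
#' penalty is M^-1 (x) K^-1.
#'
#' @param d1,d2 Design lists from [build_design()] for trait 1 and 2,
#'   sharing the same `ids`.
#' @param Kinv Relationship inverse over the shared animal ids.
#' @param M 2x2 genetic (co)variance matrix.
#' @param R 2x2 residual (co)variance matrix.
#' @return List with elements `trait1`, `trait2`, each a `model_fit`.
#' @export
solve_two_trait <- function(d1, d2, Kinv, M, R) {
  stopifnot(identical(d1$ids, d2$ids),
            identical(dim(M), c(2L, 2L)), identical(dim(R), c(2L, 2L)))
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("genetic covariance matrix M is not positive definite")
  }
  Rinv2 <- tryCatch(solve(R), error = function(e) {
    stop("residual covariance matrix R is singular")
  })
  n1 <- length(d1$y); n2 <- length(d2$y)
  q <- length(d1$ids)
  # residual precision over the stacked records: couple the two records of
  # an animal observed for both traits, scalar precision otherwise
  both <- intersect(d1$animal, d2$animal)
  i1 <- match(both, d1$animal)          # one record per animal per trait
  i2 <- n1 + match(both, d2$animal)
  only1 <- setdiff(seq_len(n1), i1)
  only2 <- setdiff(n1 + seq_len(n2), i2)
  ii <- c(i1, i2, i1, i2, only1, only2)
  jj <- c(i1, i2, i2, i1, only1, only2)
  xx <- c(rep(Rinv2[1, 1], length(both)), rep(Rinv2[2, 2], length(both)),
          rep(Rinv2[1, 2], length(both)), rep(Rinv2[2, 1], length(both)),
          rep(1 / R[1, 1], length(only1)), rep(1 / R[2, 2], length(only2)))
  Rinv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = c(n1 + n2, n1 + n2))
  p1 <- ncol(d1$X); p2 <- ncol(d2$X)
  TT <- rbind(
    cbind(Matrix::Matrix(d1$X, sparse = TRUE),
          Matrix::Matrix(0, n1, p2), d1$Z, Matrix::Matrix(0, n1, q)),
    cbind(Matrix::Matrix(0, n2, p1),
          Matrix::Matrix(d2$X, sparse = TRUE), Matrix::Matrix(0, n2, q), d2$Z)
  )
  y <- c(d1$y, d2$y)
  Gpen <- Matrix::kronecker(solve(M), Kinv)
  C <- Matrix::crossprod(TT, Rinv %*% TT) +
    Matrix::bdiag(Matrix::Matrix(0, p1 + p2, p1 + p2), Gpen)
  rhs <- as.numeric(Matrix::crossprod(TT, Rinv %*% y))
  sol <- as.numeric(Matrix::solve(Matrix::forceSymmetric(C), rhs))
  b1 <- sol[seq_len(p1)]
  b2 <- sol[p1 + seq_len(p2)]
  g1 <- sol[p1 + p2 + seq_len(q)]
  g2 <- sol[p1 + p2 + q + seq_len(q)]
  names(g1) <- names(g2) <- d1$ids
  names(b1) <- colnames(d1$X); names(b2) <- colnames(d2$X)
  mkfit <- function(d, b, g, sg2, se2) {
    fitted <- as.numeric(d$X %*% b + d$Z %*% g)
    structure(list(b = b, g = g, residuals = d$y - fitted, fitted = fitted,
                   animal = d$animal,
                   vc = list(sigma_g2 = sg2, sigma_e2 = se2, M = M, R = R),
                   method = "ssgblup2", y = d$y),
              class = "model_fit")
  }
  list(trait1 = mkfit(d1, b1, g1, M[1, 1], R[1, 1]),
       trait2 = mkfit(d2, b2, g2, M[2, 2], R[2, 2]))
}

#' Single-trait EM-REML variance components
#'
#' Estimates sigma_g2 and sigma_e2 for y = Xb + Zg + e, g ~ N(0, K
#' sigma_g2), by expectation-maximisation over the mixed-model equations:
#' \deqn{\sigma_g^{2(t+1)} = (\hat g' K^{-1} \hat g +
#'   \sigma_e^{2(t)} tr(K^{-1} C^{gg})) / q}
#' \deqn{\sigma_e^{2(t+1)} = (y'y - \hat b' X'y - \hat g' Z'y) / (n - p)}
#' where C^gg is the breeding-value block of the inverted coefficient
#' matrix. After absorbing the fixed effects, C^gg = (Z'SZ + lambda
#' K^-1)^-1 with S the projection orthogonal to X; a one-time generalised
#' eigendecomposition of (Z'SZ, K^-1) makes every EM step closed-form, so
#' iterations cost O(q) after an O(q^3) setup.
#'
#' @param y,X,Z Design components ([build_design()]); X must be full
#'   column rank.
#' @param Kinv Relationship inverse (positive definite).
#' @param init List with starting `sigma_g2`, `sigma_e2`; default splits
#'   the phenotypic variance evenly.
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return List with `sigma_g2`, `sigma_e2`, `h2`, `iterations`,
#'   `converged`, and `trace` (per-iteration estimates).
#' @export
em_reml_single <- function(y, X, Z, Kinv, init = NULL, tol = 1e-6,
                           max_iter = 1000L) {
  n <- length(y)
  p <- ncol(X)
  q <- nrow(Kinv)
  if (n <= p + 1L) stop("too few records to separate variance components")
  vy <- stats::var(y)
  if (vy <= 1e-24) {
    warning("variance component at boundary (phenotypes are constant); ",
            "estimates unreliable")
    return(list(sigma_g2 = 1e-12, sigma_e2 = 1e-12, h2 = NA_real_,
                iterations = 0L, converged = TRUE,
                trace = data.frame(sigma_g2 = numeric(0),
                                   sigma_e2 = numeric(0))))
  }
  if (is.null(init)) init <- list(sigma_g2 = vy / 2, sigma_e2 = vy / 2)
  Kinv <- as.matrix(Kinv)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  Zd <- as.matrix(Z)
  Zty <- crossprod(Zd, y)
  XtZ <- crossprod(X, Zd)
  yty <- sum(y * y)
  # absorb X: B = Z'SZ, then simultaneous diagonalisation with Kinv
  XtXi <- chol2inv(chol(XtX))
  B <- crossprod(Zd) - t(XtZ) %*% XtXi %*% XtZ
  Rk <- chol(Kinv)                       # Kinv = Rk'Rk
  Minner <- backsolve(Rk, t(backsolve(Rk, t(B), transpose = TRUE)),
                      transpose = TRUE)
  Minner <- (Minner + t(Minner)) / 2
  ev <- eigen(Minner, symmetric = TRUE)
  lam_i <- pmax(ev$values, 0)
  Q <- backsolve(Rk, ev$vectors)         # Q' Kinv Q = I, Q' B Q = diag(lam_i)
  ZtSy <- Zty - t(XtZ) %*% (XtXi %*% Xty)
  w <- as.numeric(crossprod(Q, ZtSy))
  sg <- init$sigma_g2
  se <- init$sigma_e2
  trace <- matrix(NA_real_, max_iter, 2,
                  dimnames = list(NULL, c("sigma_g2", "sigma_e2")))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lambda <- se / sg
    denom <- lam_i + lambda
    gcoef <- w / denom
    ghat <- as.numeric(Q %*% gcoef)
    gKg <- sum(gcoef * gcoef)            # ghat' Kinv ghat
    trKC <- sum(1 / denom)               # tr(Kinv Cgg) / sigma_e2-free form
    sg_new <- (gKg + se * trKC) / q
    bhat <- as.numeric(XtXi %*% (Xty - XtZ %*% ghat))
    se_new <- (yty - sum(bhat * Xty) - sum(ghat * Zty)) / (n - p)
    trace[it, ] <- c(sg_new, se_new)
    if (sg_new < 1e-12 || se_new < 1e-12) {
      warning("variance component at boundary (",
              if (sg_new < 1e-12) "sigma_g2" else "sigma_e2",
              " < 1e-12); estimates unreliable")
      sg <- max(sg_new, 1e-12); se <- max(se_new, 1e-12)
      converged <- TRUE
      break
    }
    delta <- max(abs(sg_new - sg) / sg, abs(se_new - se) / se)
    sg <- sg_new
    se <- se_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("EM-REML did not converge in ", max_iter, " iterations ",
         "(last sigma_g2 = ", format(sg), ", sigma_e2 = ", format(se), ")")
  }
  list(sigma_g2 = sg, sigma_e2 = se, h2 = sg / (sg + se),
       iterations = it, converged = converged,
       trace = as.data.frame(trace[seq_len(it), , drop = FALSE]))
}
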