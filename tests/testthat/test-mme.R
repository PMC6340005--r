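test_that("build_design assembles X, Z and masks missing traits", {
  phen <- data.frame(animal = c("a", "b", "b", "c"),
                     y = c(1, 2, NA, 3),
                     sex = c("m", "f", "m", "f"))
  d <- build_design(phen, "y", factors = "sex",
                    animal_ids = c("a", "b", "c", "d"))
  expect_equal(length(d$y), 3L)               # NA record excluded
  expect_equal(ncol(d$X), 2L)                 # intercept + 1 sex dummy
  expect_equal(dim(d$Z), c(3L, 4L))
  # an animal with 2 records gets two 1s in its Z column
  phen2 <- data.frame(animal = c("a", "b", "b"), y = 1:3)
  d2 <- build_design(phen2, "y", animal_ids = c("a", "b"))
  expect_equal(Matrix::colSums(d2$Z), c(a = 1, b = 2))
  # X is reduced to full rank when factors are confounded
  phen3 <- data.frame(animal = c("a", "b", "c", "d"), y = 1:4,
                      f1 = c("u", "u", "v", "v"),
                      f2 = c("p", "p", "q", "q"))   # f2 aliases f1
  d3 <- build_design(phen3, "y", factors = c("f1", "f2"),
                     animal_ids = letters[1:4])
  expect_equal(ncol(d3$X), qr(cbind(1, phen3$f1 == "v", phen3$f2 == "q"))$rank)
  expect_error(build_design(phen, "y", animal_ids = c("a", "b")), "absent")
})

test_that("single-trait MME solutions equal dense GLS", {
  toy <- make_toy(seed = 42L)
  d <- build_design(toy$phen, "y", factors = "sex", covariates = "wt",
                    animal_ids = toy$op$id)
  Kinv <- build_A_inverse(toy$op)
  fit <- solve_single_trait(d$y, d$X, d$Z, Kinv,
                            list(sigma_g2 = toy$sg2, sigma_e2 = toy$se2))
  oracle <- gls_oracle(d$y, d$X, d$Z, toy$K, toy$sg2, toy$se2)
  expect_lt(max(abs(fit$b - oracle$b)), 1e-8)
  expect_lt(max(abs(fit$g - oracle$g)), 1e-8)
  # y is reproduced exactly on observed records
  expect_lt(max(abs(d$X %*% fit$b + d$Z %*% fit$g + fit$residuals - d$y)),
            1e-10)
})

test_that("shrinkage limit and record-less animals behave", {
  toy <- make_toy(seed = 7L)
  d <- build_design(toy$phen, "y", factors = "sex", covariates = "wt",
                    animal_ids = toy$op$id)
  Kinv <- build_A_inverse(toy$op)
  # sigma_g2 -> 0: PBV -> 0 and fixed effects -> least squares
  fit0 <- solve_single_trait(d$y, d$X, d$Z, Kinv,
                             list(sigma_g2 = 1e-10, sigma_e2 = 1))
  expect_lt(max(abs(fit0$g)), 1e-6)
  expect_equal(unname(fit0$b), unname(coef(lm(d$y ~ d$X - 1))),
               tolerance = 1e-6)
  # an unrelated record-less founder gets PBV exactly 0
  ped <- rbind(as_pd <- data.frame(animal = "LONER", sire = "0", dam = "0"),
               data.frame(animal = c("p1", "p2", "k"),
                          sire = c("0", "0", "p1"),
                          dam = c("0", "0", "p2")))
  op <- topological_sort(ped)
  phen <- data.frame(animal = c("p1", "p2", "k"), y = c(1.2, 0.8, 1.5))
  d2 <- build_design(phen, "y", animal_ids = op$id)
  fit2 <- solve_single_trait(d2$y, d2$X, d2$Z, build_A_inverse(op),
                             list(sigma_g2 = 0.5, sigma_e2 = 0.5))
  expect_equal(unname(fit2$g["LONER"]), 0, tolerance = 1e-10)
})

test_that("corrected phenotypes: identity, averaging, shift invariance", {
  toy <- make_toy(seed = 3L, n_rec = 40L)
  d <- build_design(toy$phen, "y", factors = "sex", covariates = "wt",
                    animal_ids = toy$op$id)
  Kinv <- build_A_inverse(toy$op)
  vc <- list(sigma_g2 = toy$sg2, sigma_e2 = toy$se2)
  fit <- solve_single_trait(d$y, d$X, d$Z, Kinv, vc)
  yc <- corrected_phenotype(fit)
  # single-record animals: yc = y - X bhat (record-wise identity)
  xb <- as.numeric(d$X %*% fit$b)
  single <- names(which(table(toy$phen$animal) == 1L))
  for (an in single[1:5]) {
    i <- which(toy$phen$animal == an)
    expect_equal(unname(yc[an]), d$y[i] - xb[i], tolerance = 1e-10)
  }
  # invariance to adding a constant to all phenotypes
  fit2 <- solve_single_trait(d$y + 100, d$X, d$Z, Kinv, vc)
  yc2 <- corrected_phenotype(fit2)
  expect_equal(yc2, yc, tolerance = 1e-8)  # constant absorbed by intercept
})

test_that("GBLUP equals the generic solver with K = G and handles twins", {
  set.seed(12)
  panel <- random_panel(25L, 80L, seed = 12L)
  G <- build_G(panel)
  G <- 0.98 * G + 0.02 * diag(nrow(G))   # keep PD
  dimnames(G) <- list(rownames(panel$dosage), rownames(panel$dosage))
  yc <- setNames(rnorm(20), rownames(G)[1:20])  # 5 animals unphenotyped
  vc <- list(sigma_g2 = 0.4, sigma_e2 = 0.6)
  fit <- solve_gblup(yc, G, vc)
  Ginv <- chol2inv(chol(G)); dimnames(Ginv) <- dimnames(G)
  X <- matrix(1, 20, 1)
  Z <- Matrix::sparseMatrix(i = 1:20, j = match(names(yc), rownames(G)),
                            x = 1, dims = c(20, 25))
  colnames(Z) <- rownames(G)
  ref <- solve_single_trait(as.numeric(yc), X, Z, Ginv, vc)
  expect_equal(fit$g, ref$g, tolerance = 1e-10)

  # duplicate individual (identical G row/col and yc) -> identical GEBV
  Gd <- G
  Gd["I2", ] <- Gd["I1", ]; Gd[, "I2"] <- Gd[, "I1"]
  Gd["I2", "I2"] <- Gd["I1", "I1"]
  Gd["I1", "I2"] <- Gd["I2", "I1"] <- Gd["I1", "I1"] - 1e-6  # near-clone, PD
  ycd <- yc; ycd["I2"] <- ycd["I1"]
  fitd <- solve_gblup(ycd, Gd, vc)
  expect_equal(unname(fitd$g["I1"]), unname(fitd$g["I2"]), tolerance = 1e-3)
})

test_that("two-trait solver decouples, is symmetric, and matches GLS", {
  toy <- make_toy(n_animals = 40L, n_rec = 40L, seed = 5L)
  set.seed(99)
  phen <- toy$phen[!duplicated(toy$phen$animal), ]  # one record/animal/trait
  phen$y2 <- 3 + 0.5 * (phen$sex == "m") + 0.7 * phen$y + rnorm(nrow(phen))
  ids <- toy$op$id
  d1 <- build_design(phen, "y", factors = "sex", animal_ids = ids)
  d2 <- build_design(phen, "y2", factors = "sex", animal_ids = ids)
  Kinv <- build_A_inverse(toy$op)

  # zero covariances: equals two single-trait solves
  M0 <- diag(c(0.4, 0.5)); R0 <- diag(c(0.6, 0.5))
  tt <- solve_two_trait(d1, d2, Kinv, M0, R0)
  s1 <- solve_single_trait(d1$y, d1$X, d1$Z, Kinv,
                           list(sigma_g2 = 0.4, sigma_e2 = 0.6))
  s2 <- solve_single_trait(d2$y, d2$X, d2$Z, Kinv,
                           list(sigma_g2 = 0.5, sigma_e2 = 0.5))
  expect_lt(max(abs(tt$trait1$g - s1$g)), 1e-8)
  expect_lt(max(abs(tt$trait2$g - s2$g)), 1e-8)

  # swapping trait labels swaps the fits
  M <- matrix(c(0.4, 0.2, 0.2, 0.5), 2)
  R <- matrix(c(0.6, 0.1, 0.1, 0.5), 2)
  a <- solve_two_trait(d1, d2, Kinv, M, R)
  bsw <- solve_two_trait(d2, d1, Kinv, M[2:1, 2:1], R[2:1, 2:1])
  expect_equal(a$trait1$g, bsw$trait2$g, tolerance = 1e-10)
  expect_equal(a$trait2$g, bsw$trait1$g, tolerance = 1e-10)

  # dense GLS oracle on the stacked system (both traits observed)
  q <- length(ids)
  Zs <- as.matrix(Matrix::bdiag(d1$Z, d2$Z))
  Xs <- as.matrix(Matrix::bdiag(d1$X, d2$X))
  ys <- c(d1$y, d2$y)
  Kfull <- kronecker(M, toy$K)
  # residual covariance couples the two records of each animal; record
  # order is identical across traits here
  n <- nrow(phen)
  Rfull <- matrix(0, 2 * n, 2 * n)
  Rfull[cbind(1:n, 1:n)] <- R[1, 1]
  Rfull[cbind(n + 1:n, n + 1:n)] <- R[2, 2]
  Rfull[cbind(1:n, n + 1:n)] <- R[1, 2]
  Rfull[cbind(n + 1:n, 1:n)] <- R[1, 2]
  V <- Zs %*% Kfull %*% t(Zs) + Rfull
  Vi <- solve(V)
  bh <- solve(t(Xs) %*% Vi %*% Xs, t(Xs) %*% Vi %*% ys)
  gh <- Kfull %*% t(Zs) %*% Vi %*% (ys - Xs %*% bh)
  expect_lt(max(abs(c(a$trait1$g, a$trait2$g) - as.numeric(gh))), 1e-8)
})

test_that("EM-REML matches a restricted-likelihood grid on a small toy", {
  set.seed(20)
  op <- topological_sort(gen_pedigree(5L, 5L, seed = 20L))
  K <- build_A(op)
  n <- op$n
  g <- as.numeric(t(chol(K)) %*% rnorm(n)) * sqrt(0.5)
  y <- 1 + g + rnorm(n, sd = sqrt(0.5))
  X <- matrix(1, n, 1)
  Z <- diag(n); colnames(Z) <- op$id
  Kinv <- build_A_inverse(op)
  est <- em_reml_single(y, X, Z, Kinv, tol = 1e-8)
  # grid oracle over (sigma_g2, sigma_e2)
  grid <- expand.grid(sg = seq(0.05, 2, by = 0.05),
                      se = seq(0.05, 2, by = 0.05))
  ll <- mapply(function(sg, se) reml_loglik(y, X, Z, K, sg, se),
               grid$sg, grid$se)
  best <- grid[which.max(ll), ]
  ll_em <- reml_loglik(y, X, Z, K, est$sigma_g2, est$sigma_e2)
  expect_gte(ll_em, max(ll) - 1e-6)    # EM reaches the grid optimum
  expect_lt(abs(est$sigma_g2 - best$sg), 0.051)
  expect_lt(abs(est$sigma_e2 - best$se), 0.051)
})

test_that("EM-REML flags degenerate noise-free data", {
  set.seed(2)
  op <- topological_sort(gen_pedigree(3L, 8L, seed = 2L))
  n <- op$n
  y <- rep(2, n)                      # y = Xb exactly, no noise
  X <- matrix(1, n, 1)
  Z <- diag(n)
  Kinv <- build_A_inverse(op)
  expect_warning(em_reml_single(y, X, Z, Kinv), "boundary")
})
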