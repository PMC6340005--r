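# Shared fixture builders. Everything is generated in code; seeds are fixed
# per call site so tests are deterministic.

# Random generation-structured pedigree: `gens` discrete generations of
# `size`, parents drawn from the previous generation (can create inbreeding
# because half/full sibs may mate).
gen_pedigree <- function(gens, size, seed = 1L) {
  set.seed(seed)
  n <- gens * size
  ids <- paste0("P", seq_len(n))
  ped <- data.frame(animal = ids, sire = "0", dam = "0",
                    stringsAsFactors = FALSE)
  half <- max(1L, size %/% 2L)
  for (g in seq_len(gens - 1L)) {
    rows <- g * size + seq_len(size)
    prev <- (g - 1L) * size + seq_len(size)
    ped$sire[rows] <- ids[sample(prev[seq_len(half)], size, replace = TRUE)]
    ped$dam[rows] <- ids[sample(prev[(half + 1L):size], size, replace = TRUE)]
  }
  ped
}

# Random messy pedigree: some unknown parents, shuffled record order.
messy_pedigree <- function(n, seed = 1L, p_unknown = 0.3) {
  set.seed(seed)
  ids <- paste0("A", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in 3:n) {
    if (stats::runif(1) > p_unknown) sire[i] <- ids[sample.int(i - 1L, 1L)]
    if (stats::runif(1) > p_unknown) {
      cand <- setdiff(seq_len(i - 1L), match(sire[i], ids))
      if (length(cand)) dam[i] <- ids[sample(cand, 1L)]
    }
  }
  ped <- data.frame(animal = ids, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  ped[sample.int(n), ]
}

# Small dosage panel with controllable missingness.
random_panel <- function(n_ind = 20L, n_mark = 30L, seed = 1L,
                         miss_rate = 0) {
  set.seed(seed)
  p <- stats::runif(n_mark, 0.1, 0.9)
  M <- sapply(p, function(pp) stats::rbinom(n_ind, 2L, pp))
  M[1L, ] <- 0L; M[2L, ] <- 2L   # guarantee every marker is polymorphic
  dimnames(M) <- list(paste0("I", seq_len(n_ind)),
                      paste0("M", seq_len(n_mark)))
  if (miss_rate > 0) {
    drop <- which(matrix(stats::runif(length(M)) < miss_rate, nrow(M)))
    M[drop] <- NA_integer_
  }
  map <- data.frame(marker = colnames(M),
                    chr = rep(1L, n_mark),
                    pos = seq_len(n_mark) / n_mark)
  genotype_panel(M, map)
}

# Tiny simulated population shared by the heavier end-to-end tests.
tiny_population <- function(seed = 7L, gen_sizes = rep(120L, 3L)) {
  cfg <- scaled_config(gen_sizes = gen_sizes)
  cfg$population$burnin_generations <- 40L
  simulate_population(cfg$genome, cfg$population, cfg$traits, seed = seed)
}

# Small animal-model dataset on a generation-structured pedigree with a
# sex factor and a weight covariate; truth variance components included.
make_toy <- function(n_animals = 30L, n_rec = 30L, seed = 1L,
                     h2 = 0.4, gens = 3L) {
  set.seed(seed)
  op <- topological_sort(gen_pedigree(gens, ceiling(n_animals / gens),
                                      seed = seed))
  K <- build_A(op)
  sg2 <- h2; se2 <- 1 - h2
  g <- as.numeric(t(chol(K)) %*% rnorm(op$n)) * sqrt(sg2)
  rec_an <- sample(op$id, n_rec, replace = TRUE)
  sex <- sample(c("m", "f"), n_rec, replace = TRUE)
  wt <- runif(n_rec, 80, 120)
  y <- 5 + ifelse(sex == "m", 0.8, 0) + 0.02 * wt +
    g[match(rec_an, op$id)] + rnorm(n_rec, sd = sqrt(se2))
  phen <- data.frame(animal = rec_an, y = y, sex = sex, wt = wt,
                     stringsAsFactors = FALSE)
  list(op = op, K = K, phen = phen, sg2 = sg2, se2 = se2)
}

# Dense GLS solutions for y = Xb + Zg + e, the oracle the MME solvers are
# checked against: V = Z K Z' sg2 + I se2, bhat = (X'V^-1X)^-1 X'V^-1 y,
# ghat = sg2 K Z' V^-1 (y - X bhat).
gls_oracle <- function(y, X, Z, K, sg2, se2) {
  Z <- as.matrix(Z)
  V <- Z %*% K %*% t(Z) * sg2 + diag(length(y)) * se2
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ghat <- sg2 * K %*% t(Z) %*% Vi %*% (y - X %*% bhat)
  list(b = as.numeric(bhat), g = as.numeric(ghat))
}

# Restricted log-likelihood (up to a constant) for the EM-REML grid oracle.
reml_loglik <- function(y, X, Z, K, sg2, se2) {
  Z <- as.matrix(Z)
  V <- Z %*% K %*% t(Z) * sg2 + diag(length(y)) * se2
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            as.numeric(t(y) %*% P %*% y))
}
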