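test_that("topological sort places parents before offspring and is stable", {
  ped <- data.frame(animal = c("C", "A", "B"),
                    sire = c("A", "0", "0"),
                    dam = c("B", "0", "0"))
  op <- topological_sort(ped)
  expect_equal(op$id, c("A", "B", "C"))
  expect_equal(op$sire[3], 1L)
  expect_equal(op$dam[3], 2L)

  # parents appearing only as parent ids are added as founders
  op2 <- topological_sort(data.frame(animal = "X", sire = "S", dam = "D"))
  expect_equal(op2$n, 3L)
  expect_true(all(c("S", "D") %in% op2$id))

  # random pedigree: every parent index precedes the child index
  op3 <- topological_sort(messy_pedigree(500L, seed = 3L))
  idx <- seq_len(op3$n)
  expect_true(all(op3$sire == 0L | op3$sire < idx))
  expect_true(all(op3$dam == 0L | op3$dam < idx))
})

test_that("pedigree errors: cycles, self-parenting, duplicates", {
  cyc <- data.frame(animal = c("A", "B"), sire = c("B", "A"),
                    dam = c("0", "0"))
  expect_error(topological_sort(cyc), "cycle")
  expect_error(topological_sort(
    data.frame(animal = "C", sire = "C", dam = "B")), "own parent")
  expect_error(topological_sort(
    data.frame(animal = c("A", "A"), sire = "0", dam = "0")), "duplicate")
})

test_that("inbreeding matches the tabular-method diagonal", {
  # founders have F = 0
  op <- topological_sort(data.frame(animal = c("A", "B"),
                                    sire = "0", dam = "0"))
  expect_equal(unname(inbreeding(op)), c(0, 0))

  # offspring of full sibs: F = 0.25
  ped <- data.frame(
    animal = c("S", "D", "K1", "K2", "X"),
    sire = c("0", "0", "S", "S", "K1"),
    dam = c("0", "0", "D", "D", "K2"))
  F <- inbreeding(topological_sort(ped))
  expect_equal(unname(F[c("K1", "K2", "X")]), c(0, 0, 0.25))

  # random pedigree with inbreeding loops: F == diag(A) - 1
  op2 <- topological_sort(gen_pedigree(5L, 40L, seed = 11L))
  A <- build_A(op2)
  expect_lt(max(abs(inbreeding(op2) - (diag(A) - 1))), 1e-12)
  expect_gt(max(inbreeding(op2)), 0)  # fixture actually contains inbreeding
})

test_that("tabular A: base cases, symmetry, positive semi-definiteness", {
  op <- topological_sort(data.frame(animal = c("A", "B"),
                                    sire = "0", dam = "0"))
  expect_equal(unname(build_A(op)), diag(2), ignore_attr = TRUE)

  trio <- topological_sort(data.frame(animal = c("S", "D", "O"),
                                      sire = c("0", "0", "S"),
                                      dam = c("0", "0", "D")))
  A <- build_A(trio)
  expect_equal(A["O", "S"], 0.5)
  expect_equal(A["O", "D"], 0.5)
  expect_equal(A["O", "O"], 1)

  op2 <- topological_sort(messy_pedigree(50L, seed = 5L, p_unknown = 0.2))
  A2 <- build_A(op2)
  expect_equal(A2, t(A2))
  ev <- eigen(A2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("Henderson's A-inverse agrees with dense inversion of tabular A", {
  # founders only
  op <- topological_sort(data.frame(animal = c("A", "B", "C"),
                                    sire = "0", dam = "0"))
  expect_equal(unname(as.matrix(build_A_inverse(op))), diag(3))

  # non-inbred trio, known closed form
  trio <- topological_sort(data.frame(animal = c("S", "D", "O"),
                                      sire = c("0", "0", "S"),
                                      dam = c("0", "0", "D")))
  expect_equal(unname(as.matrix(build_A_inverse(trio))),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)

  # random inbred pedigree, n = 300: A %*% Ainv == I
  op2 <- topological_sort(gen_pedigree(6L, 50L, seed = 2L))
  A <- build_A(op2)
  Ainv <- build_A_inverse(op2)
  expect_lt(max(abs(as.matrix(A %*% Ainv) - diag(op2$n))), 1e-8)

  # ignoring inbreeding gives the classic rules (differs on inbred data)
  Ainv0 <- build_A_inverse(op2, use_inbreeding = FALSE)
  expect_gt(max(abs(Ainv0 - Ainv)), 1e-6)
})

test_that("A partition blocks reassemble and A22 shortcut matches", {
  op <- topological_sort(gen_pedigree(4L, 5L, seed = 9L))
  A <- build_A(op)
  g <- sample(op$id, 8L)
  part <- partition_A(A, g)
  perm <- c(part$nongenotyped_ids, part$genotyped_ids)
  reassembled <- rbind(cbind(part$A11, part$A12),
                       cbind(t(part$A12), part$A22))
  expect_equal(unname(reassembled), unname(A[perm, perm]))
  expect_equal(unname(part$A22inv %*% part$A22), diag(8), tolerance = 1e-10)
  # indirect A22 equals the dense submatrix
  expect_equal(build_A22(op, g), A[g, g], ignore_attr = TRUE,
               tolerance = 1e-10)

  # degenerate partitions
  all_g <- partition_A(A, op$id)
  expect_equal(dim(all_g$A11), c(0L, 0L))
  expect_equal(unname(all_g$A22), unname(A), ignore_attr = TRUE)
  none_g <- partition_A(A, character(0))
  expect_equal(unname(none_g$A11), unname(A), ignore_attr = TRUE)
  expect_error(partition_A(A, "nope"), "absent")
})
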