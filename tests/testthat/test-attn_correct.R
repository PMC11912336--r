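test_that("layer_contribution validates and averages heads", {
  I2 <- diag(2)
  expect_equal(layer_contribution(I2), I2)
  flip <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(layer_contribution(list(I2, flip)),
               matrix(0.5, 2, 2))
  bad <- matrix(c(0.4, 0.4, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(layer_contribution(bad), "row 1")
})

test_that("compose_contributions multiplies last-to-first", {
  I3 <- diag(3)
  expect_equal(compose_contributions(list(I3, I3)), I3)
  # 3-atom path with uniform closed-neighborhood attention, two layers:
  # hand multiplication of U %*% U with U = [[1/2,1/2,0],[1/3,1/3,1/3],
  # [0,1/2,1/2]] gives rows [5/12,5/12,1/6], [5/18,4/9,5/18], [1/6,5/12,5/12]
  U <- matrix(c(1/2, 1/2, 0, 1/3, 1/3, 1/3, 0, 1/2, 1/2), 3, 3, byrow = TRUE)
  expected <- matrix(c(5/12, 5/12, 1/6,
                       5/18, 4/9, 5/18,
                       1/6, 5/12, 5/12), 3, 3, byrow = TRUE)
  expect_equal(compose_contributions(list(U, U)), expected)
  expect_equal(compose_contributions(list(U)), U)
  expect_error(compose_contributions(list(U, diag(2))), "not 3x3")
})

test_that("composition is associative-consistent and stays stochastic", {
  set.seed(21)
  for (rep in 1:5) {
    m <- sample(3:7, 1)
    Cs <- replicate(3, rand_stochastic(m), simplify = FALSE)
    full <- compose_contributions(Cs)
    partial <- compose_contributions(list(compose_contributions(Cs[1:2]),
                                          Cs[[3]]))
    expect_equal(full, partial, tolerance = 1e-12)
    expect_equal(rowSums(full), rep(1, m), tolerance = 1e-9)
    expect_true(all(full >= 0))
  }
})

test_that("correct_attention builds M with row sums 2 and unit scores", {
  I4 <- diag(4)
  ca <- correct_attention(list(I4), I4)
  expect_equal(ca$matrix, 2 * I4)
  expect_equal(ca$atom_scores, rep(1 / 4, 4))
  one <- correct_attention(list(matrix(1, 1, 1)), matrix(1, 1, 1))
  expect_equal(ca1 <- one$matrix, matrix(2, 1, 1))
  expect_equal(one$atom_scores, 1)
  set.seed(33)
  A1 <- rand_stochastic(5); A2 <- rand_stochastic(5)
  C <- rand_stochastic(5)
  ca2 <- correct_attention(list(A1, A2), C)
  expect_equal(rowSums(ca2$matrix), rep(2, 5), tolerance = 1e-6)
  expect_equal(sum(ca2$atom_scores), 1, tolerance = 1e-6)
  expect_error(correct_attention(list(rand_stochastic(4)), C), "not 5x5")
})

test_that("star-graph center receives the highest corrected score", {
  # star with 4 leaves; uniform closed-neighborhood attention at every layer
  m <- 5
  A <- matrix(0, m, m); A[1, 2:5] <- 1; A[2:5, 1] <- 1
  closed <- A + diag(m)
  U <- closed / rowSums(closed)
  C <- compose_contributions(list(U, U, U))
  ca <- correct_attention(list(rand_stochastic(m)), C)
  expect_true(all(ca$atom_scores[1] > ca$atom_scores[2:5]))
})

test_that("select_substructures follows the above-mean component policy", {
  path3 <- featurize("CCO")
  subs <- select_substructures(path3, c(0.5, 0.3, 0.2))
  expect_length(subs, 1)
  expect_equal(subs[[1]]$atoms, 1L)
  expect_warning(empty <- select_substructures(path3, rep(1 / 3, 3)),
                 "above the mean")
  expect_length(empty, 0)
  path4 <- featurize("CCCO")
  subs4 <- select_substructures(path4, c(0.4, 0.05, 0.4, 0.15))
  expect_length(subs4, 2)
  expect_setequal(vapply(subs4, function(s) s$atoms, integer(1)), c(1L, 3L))
  # cap: all 8 ring+tail atoms above mean, trimmed to max_atoms keeping
  # connectivity
  ring <- featurize("c1ccccc1CC")
  sc <- c(rep(0.2, 6), 0.15, 0.05)
  sc <- sc / sum(sc)
  capped <- select_substructures(ring, c(rep(2, 6), 1.5, 0.5) / 13,
                                 max_atoms = 4)
  expect_length(capped, 1)
  expect_length(capped[[1]]$atoms, 4)
  expect_true(toxgat:::.is_connected(ring$adjacency, capped[[1]]$atoms))
})

test_that("corrected_atom_scores closes the loop on a trained-shape model", {
  st <- init_model(small_config(layers = 3), seed = 12)
  g <- featurize("NC(=S)Nc1ccccc1")
  ca <- corrected_atom_scores(st, g)
  m <- n_atoms(g)
  expect_equal(rowSums(ca$matrix), rep(2, m), tolerance = 1e-5)
  expect_equal(sum(ca$atom_scores), 1, tolerance = 1e-6)
  expect_true(all(ca$atom_scores >= 0))
})
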