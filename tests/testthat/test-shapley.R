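test_that("build_game restricts players to the L-bond context", {
  path7 <- featurize("CCCCCCC")
  game <- build_game(path7, 1, L = 4)
  expect_equal(game$context, 2:5)
  expect_length(game$context, 4)
  whole <- build_game(path7, 1:7, L = 4)
  expect_length(whole$context, 0)
  path12 <- featurize("CCCCCCCCCCCC")
  g12 <- build_game(path12, 1, L = 4)
  expect_equal(g12$context, 2:5)  # atoms 6..12 permanently masked
  expect_error(build_game(path7, integer(0)), "empty")
  expect_error(build_game(path7, c(1, 3)), "connected")
  expect_error(build_game(path7, 99), "out of range")
})

test_that("value_function evaluates masked coalitions", {
  mock <- additive_mock_model()
  g <- featurize("CCO")  # weights 0.5, 0.5, -0.7
  game <- build_game(g, 1, L = 4)
  expect_equal(value_function(mock, game, E = integer(0), include_S = TRUE),
               0.5)
  expect_equal(value_function(mock, game, E = c(2, 3), include_S = TRUE), 0.3)
  expect_equal(value_function(mock, game, E = integer(0), include_S = FALSE),
               0)
  expect_error(value_function(mock, game, E = 99), "subset")
  const <- mock_model(function(graph) 7)
  expect_equal(value_function(const, game, E = 2, include_S = FALSE), 7)
})

test_that("additive models give exactly the sum of member atom weights", {
  cfgS <- synthetic_config()
  mock <- additive_mock_model(cfgS)
  for (smi in c("CCO", "c1ccccc1", "NC(=S)N", "CCCl", "c1ccncc1")) {
    g <- featurize(smi)
    truth <- atom_contributions(smi, cfgS)
    for (atoms in connected_subsets(g, max_size = 4)) {
      for (L in c(0L, 4L)) {
        game <- build_game(g, atoms, L = L)
        r <- shapley(mock, game)
        expect_equal(r$phi, sum(truth[atoms]), tolerance = 1e-9,
                     label = sprintf("%s atoms %s L=%d", smi,
                                     paste(atoms, collapse = ","), L))
      }
    }
  }
})

test_that("constant model and gamma = 0 edge cases", {
  const <- mock_model(function(graph) 3.5)
  g <- featurize("CCO")
  expect_equal(shapley(const, build_game(g, 1))$phi, 0)
  st <- init_model(small_config(), seed = 2)
  whole <- build_game(g, 1:3)
  r <- shapley(st, whole)
  expect_equal(r$n_evaluations, 2L)
  expect_equal(r$phi,
               forward(st, apply_mask(g, 1:3)) -
                 forward(st, apply_mask(g, integer(0))),
               tolerance = 1e-9)
})

test_that("gamma beyond exact_cap demands sampling", {
  g <- featurize("CCCCCCC")
  game <- build_game(g, 4, L = 4)
  expect_error(shapley(st <- mock_model(function(x) 0), game, exact_cap = 2),
               "shapley_sampled")
})

test_that("efficiency, dummy player and symmetry axioms", {
  st <- init_model(small_config(), seed = 6)
  g <- featurize("CCOC")
  game <- build_game(g, 1, L = 4)
  ap <- shapley_all_players(st, game)
  expect_equal(ap$total, ap$v_grand - ap$v_empty, tolerance = 1e-6)
  # dummy: an atom whose features are already all zero contributes nothing
  gm <- apply_mask(g, setdiff(1:4, 3))
  game_m <- build_game(gm, 1, L = 4)
  ap_m <- shapley_all_players(st, game_m)
  expect_equal(unname(ap_m$phi_context["3"]), 0, tolerance = 1e-9)
  # benzene: all single-carbon substructures are exchangeable
  benz <- featurize("c1ccccc1")
  phis <- vapply(1:6, function(a) {
    shapley(st, build_game(benz, a, L = 4))$phi
  }, numeric(1))
  expect_lt(max(phis) - min(phis), 1e-5)
})

test_that("restricted game equals the full game once L covers the diameter", {
  st <- init_model(small_config(), seed = 10)
  smis <- c("CCO", "CCN", "c1ccccc1", "CC(C)O", "CCCl", "NC(=S)N", "C#CC",
            "CCOC", "c1ccncc1", "CS")
  for (smi in smis) {
    g <- featurize(smi)
    L <- graph_diameter(g)
    r <- shapley(st, build_game(g, 1, L = L))
    bf <- brute_force_full_shapley(st, g, 1)
    expect_equal(r$phi, bf, tolerance = 1e-6, label = smi)
  }
})

test_that("sampling is unbiased, seeded and exact for additive models", {
  mock <- additive_mock_model()
  g <- featurize("NC(=S)Nc1ccccc1")
  game <- build_game(g, 1:4, L = 4)
  exact <- shapley(mock, game)$phi
  s1 <- shapley_sampled(mock, game, n_permutations = 25, seed = 4)
  # additive model: every permutation gives the same marginal
  expect_equal(s1$phi, exact, tolerance = 1e-9)
  expect_lt(s1$se, 1e-9)
  s2 <- shapley_sampled(mock, game, n_permutations = 25, seed = 4)
  expect_identical(s1$phi, s2$phi)
  # nonadditive model: estimate within 3 standard errors most of the time
  st <- init_model(small_config(), seed = 3)
  g2 <- featurize("CCOCC")
  game2 <- build_game(g2, 1, L = 4)
  ex2 <- shapley(st, game2)$phi
  hits <- 0L
  for (s in 1:10) {
    est <- shapley_sampled(st, game2, n_permutations = 200, seed = s)
    if (abs(est$phi - ex2) < 3 * max(est$se, 1e-12)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
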