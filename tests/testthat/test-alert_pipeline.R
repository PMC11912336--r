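test_that("categorize_substructure applies the stated precedence", {
  thi <- featurize("NC(=S)Nc1ccccc1")
  expect_equal(categorize_substructure(1:4, thi), "nitrogen-sulfur")
  arCl <- featurize("c1ccccc1Cl")
  expect_equal(categorize_substructure(6:7, arCl), "halogen")
  phen <- featurize("c1ccccc1O")
  expect_equal(categorize_substructure(6:7, phen), "other")
  amine <- featurize("CCN")
  expect_equal(categorize_substructure(2:3, amine), "nitrogen")
  thiol <- featurize("CCS")
  expect_equal(categorize_substructure(3, thiol), "sulfur")
  # N + halogen with no S falls through to other
  nhal <- featurize("NCCl")
  expect_equal(categorize_substructure(1:3, nhal), "other")
})

test_that("explain_molecule recovers analytic signs with mock models", {
  cfgS <- synthetic_config()
  tox <- mock_model(function(graph) {
    X <- graph$node_features
    s_col <- match("atom_S", feature_layout()$node$column)
    sum(X[, s_col])  # +1 per unmasked sulfur
  }, head_kind = "binary-classification")
  lipo <- mock_model(function(graph) {
    X <- graph$node_features
    s_col <- match("atom_S", feature_layout()$node$column)
    -sum(X[, s_col])
  })
  df <- explain_molecule(tox, lipo, "CCS", substructures = list(3L))
  expect_equal(nrow(df), 1)
  expect_gt(df$phi_tox, 0)
  expect_lt(df$phi_lipo, 0)
  expect_equal(df$category, "sulfur")
  df2 <- explain_molecule(tox, lipo, "CCS", substructures = list(3L))
  expect_identical(df, df2)
})

test_that("explain_molecule with a trained-shape model is deterministic and
          empty on uniform scores", {
  tox <- init_model(small_config(head_kind = "binary-classification",
                                 layers = 3), seed = 5)
  lipo <- init_model(small_config(layers = 3), seed = 6)
  df <- explain_molecule(tox, lipo, "NC(=S)Nc1ccccc1", alert_config())
  expect_identical(df, explain_molecule(tox, lipo, "NC(=S)Nc1ccccc1",
                                        alert_config()))
  # single atom: one score, never strictly above the mean -> empty result
  dfe <- explain_molecule(tox, lipo, "C", alert_config())
  expect_equal(nrow(dfe), 0)
})

test_that("aggregate_alerts groups, filters and orders deterministically", {
  s_col <- match("atom_S", feature_layout()$node$column)
  n_col <- match("atom_N", feature_layout()$node$column)
  tox <- mock_model(function(graph) {
    sum(graph$node_features[, s_col]) + 0.5 * sum(graph$node_features[, n_col])
  }, head_kind = "binary-classification")
  lipo <- additive_mock_model()
  ds <- data.frame(
    smiles = c("CCS", "CCCS", "CCN", "CCCN", "CCO"),
    stringsAsFactors = FALSE)
  # mocks carry no attention; score fixed patterns via score_pattern_alert
  recS <- score_pattern_alert(ds, "CS", tox, lipo)
  expect_equal(recS$support, 2)
  expect_gt(recS$phi_tox, 0)
  expect_gt(recS$phi_lipo, 0)  # C 0.5 + S 0.2
  expect_equal(recS$moa_flag, "baseline-consistent")
  recN <- score_pattern_alert(ds, "CN", tox, lipo)
  expect_equal(recN$support, 2)
  expect_gt(recN$phi_tox, 0)
  expect_lt(recN$phi_lipo, 0)  # C 0.5 + N -1.0
  expect_equal(recN$moa_flag, "specific-moa-candidate")
  expect_equal(nrow(score_pattern_alert(ds, "Br", tox, lipo)), 0)
})

test_that("aggregate_alerts is invariant to dataset row order", {
  tox <- init_model(small_config(head_kind = "binary-classification",
                                 layers = 2, embed = 8), seed = 7)
  lipo <- init_model(small_config(layers = 2, embed = 8), seed = 8)
  ds <- data.frame(smiles = gen_molecules(6, seed = 99),
                   stringsAsFactors = FALSE)
  cfg <- alert_config(min_support = 1, exact_cap = 12)
  a <- aggregate_alerts(ds, tox, lipo, cfg)
  b <- aggregate_alerts(ds[rev(seq_len(nrow(ds))), , drop = FALSE],
                        tox, lipo, cfg)
  expect_equal(a, b)
  # min_support = Inf empties the list
  empty <- aggregate_alerts(ds, tox, lipo,
                            alert_config(min_support = .Machine$integer.max))
  expect_equal(nrow(empty), 0)
})

test_that("distribution_overlap matches its boundary cases", {
  set.seed(13)
  x <- stats::rnorm(100)
  expect_gte(distribution_overlap(x, x), 0.99)
  y <- stats::rnorm(200)
  far <- stats::rnorm(200) + 10
  expect_lte(distribution_overlap(y, far), 0.01)
  expect_identical(distribution_overlap(y, far),
                   distribution_overlap(far, y))
  expect_error(distribution_overlap(1:3, 1:10), "at least 5")
  expect_warning(distribution_overlap(rep(1, 10), stats::rnorm(10)),
                 "degenerate")
  ov <- suppressWarnings(distribution_overlap(rep(1, 10), rep(1, 10)))
  expect_gte(ov, 0.99)
})
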