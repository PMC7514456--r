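test_that("multiway table invariants hold", {
  tb <- random_table(c(3, 4, 2), seed = 1)
  expect_equal(sum(tb$p), 1)
  for (m in seq_along(tb$modes)) {
    expect_equal(sum(tb$margins[[m]]), 1)
    expect_equal(unname(tb$margins[[m]]), unname(apply(tb$p, m, sum)))
  }
  expect_error(multiway_table(array(-1, c(2, 2),
                                    dimnames = list(a = 1:2, b = 1:2))),
               "non-negative")
})

test_that("occurrence table accumulates unit weights per label combination", {
  lab <- data.frame(S = rep("s1", 3), C = rep("c1", 3), unit_id = 1:3)
  tb <- occurrence_table(lab, modes = c("S", "C"))
  expect_equal(sum(tb$values), 3)
  expect_equal(tb$values["s1", "c1"], 3)
  expect_equal(tb$N, 3)
})

test_that("patch counting collapses cells to one count per patch", {
  # 2 spatial patches of one category, sizes 3 and 1
  lab <- data.frame(
    Si = factor(c(">2", ">2", ">2", "1"),
                levels = spatial_size_classes()),
    category = "A",
    sp_id = c("p1", "p1", "p1", "p2"))
  cell_tb <- occurrence_table(lab, modes = c("Si", "category"),
                              count_unit = "cell")
  expect_equal(unname(cell_tb$values[">2", "A"]), 3)
  expect_equal(unname(cell_tb$values["1", "A"]), 1)
  patch_tb <- occurrence_table(lab, modes = c("Si", "category"),
                               count_unit = "patch")
  expect_equal(unname(patch_tb$values[">2", "A"]), 1)
  expect_equal(unname(patch_tb$values["1", "A"]), 1)
  expect_equal(patch_tb$kind, "patch-occurrence")
})

test_that("factor levels give tables of fixed shape (7 x 8 x 11)", {
  lab <- data.frame(
    Si = factor("1", levels = spatial_size_classes()),
    Ti = factor("2", levels = temporal_size_classes()),
    category = factor("pft1", levels = paste0("pft", 1:11)))
  tb <- occurrence_table(lab, modes = c("Si", "Ti", "category"))
  expect_equal(dim(tb$values), c(7, 8, 11))
})

test_that("basic co-occurrence counting follows the collocation rule", {
  spec <- proximity_spec(order_k = 3, d_eps_s = 1, d_border = 0)
  # 3 points pairwise within d_eps, same category
  obs <- pts_obs(c(0, 0.5, 0.25), c(0, 0, 0.4), category = "A")
  tb <- cooccurrence_table(obs, spec)
  expect_equal(sum(tb$values), 1)
  # collinear at spacing 0.6: max pairwise distance 1.2 > 1
  obs2 <- pts_obs(c(0, 0.6, 1.2), c(0, 0, 0), category = "A")
  tb2 <- cooccurrence_table(obs2, spec)
  expect_equal(sum(tb2$values), 0)
  # too few observations: empty table with warning
  expect_warning(tb3 <- cooccurrence_table(pts_obs(0, 0, "A"), spec),
                 "fewer")
  expect_equal(sum(tb3$values), 0)
})

test_that("co-occurrence counts equal exhaustive triple enumeration", {
  set.seed(13)
  n <- 20
  x <- runif(n, 0, 3); y <- runif(n, 0, 3)
  cat <- sample(c("A", "B"), n, replace = TRUE)
  obs <- pts_obs(x, y, cat)
  spec <- proximity_spec(order_k = 3, d_eps_s = 1, d_border = 0)
  tb <- cooccurrence_table(obs, spec)
  oracle <- c(A = 0, B = 0)
  cm <- combn(n, 3)
  for (j in seq_len(ncol(cm))) {
    s <- cm[, j]
    if (length(unique(cat[s])) > 1) next
    dmax <- max(dist(cbind(x[s], y[s])))
    if (dmax <= 1) oracle[cat[s[1]]] <- oracle[cat[s[1]]] + 1
  }
  expect_equal(unname(tb$values["u1", "0", "A"]), unname(oracle["A"]))
  expect_equal(unname(tb$values["u1", "0", "B"]), unname(oracle["B"]))
})

test_that("co-occurrence counts are order-invariant and monotone in d_eps", {
  set.seed(5)
  n <- 12
  x <- runif(n); y <- runif(n)
  cat <- sample(c("A", "B"), n, replace = TRUE)
  obs <- pts_obs(x, y, cat)
  perm <- sample(n)
  obs_p <- pts_obs(x[perm], y[perm], cat[perm])
  totals <- vapply(c(0.3, 0.6, 1.2), function(eps) {
    spec <- proximity_spec(order_k = 3, d_eps_s = eps, d_border = 0)
    t1 <- sum(cooccurrence_table(obs, spec)$values)
    t2 <- sum(cooccurrence_table(obs_p, spec)$values)
    expect_equal(t1, t2)
    t1
  }, 0)
  expect_true(all(diff(totals) >= 0))
})

test_that("asymmetric and symmetric co-occurrences agree in the degenerate setting", {
  set.seed(8)
  # two snapshots (same time, two units) with spatial separation
  x <- c(runif(6, 0, 1), runif(6, 10, 11))
  y <- runif(12)
  cat <- sample(c("A", "B"), 12, replace = TRUE)
  unit <- rep(c("u1", "u2"), each = 6)
  obs <- observation_set(data.frame(x = x, y = y, t = 0, category = cat,
                                    weight = 1, unit_id = unit,
                                    t_label = "0"))
  spec <- proximity_spec(order_k = 3, d_eps_s = 0.8, d_eps_t = 0,
                         d_eps_c = 0, d_border = 0,
                         categorisation_rule = "strict")
  asym <- cooccurrence_table(obs, spec, grouping = "snapshot")
  sym <- cooccurrence_table(obs, spec, grouping = "none")
  expect_equal(asym$values, sym$values)
})

test_that("border overlap admits close outside observations", {
  # two units; one point of u2 sits right next to the u1 pair
  obs <- observation_set(data.frame(
    x = c(0, 0.3, 0.5, 9), y = 0, t = 0, category = "A", weight = 1,
    unit_id = c("u1", "u1", "u2", "u2"), t_label = "0"))
  no_border <- proximity_spec(order_k = 3, d_eps_s = 1, d_border = 0)
  with_border <- proximity_spec(order_k = 3, d_eps_s = 1, d_border = 0.4)
  t0 <- cooccurrence_table(obs, no_border)
  t1 <- cooccurrence_table(obs, with_border)
  expect_equal(sum(t0$values), 0)        # u1 alone has only 2 points
  expect_equal(unname(t1$values["u1", "0", "A"]), 1)
})

test_that("distance-ratio matches hand-computed pair distances", {
  # 4 points in one snapshot: two of category A at distance 1,
  # two of category B at x = 10 and 11
  obs <- observation_set(data.frame(
    x = c(0, 1, 10, 11), y = 0, t = 0,
    category = c("A", "A", "B", "B"), weight = 1,
    unit_id = "u1", t_label = "0"))
  spec <- proximity_spec(order_k = 2, d_eps_s = 1)
  tb <- distance_ratio_table(obs, spec, mode = "local-asymmetric")
  # within-A mean distance 1; between means over pairs (0,10),(0,11),(1,10),(1,11)
  mb <- mean(c(10, 11, 9, 10))
  expect_equal(unname(tb$values["u1", "0", "A"]), 1 / mb,
               tolerance = 1e-12)
})

test_that("coincident category points give ratio near zero; mixed sampling gives ratio near one", {
  obs <- observation_set(data.frame(
    x = c(0, 0, 0, 5, -5, 8), y = c(0, 0, 0, 5, 3, -8),
    category = c("A", "A", "A", "B", "B", "B"), t = 0, weight = 1,
    unit_id = "u1", t_label = "0"))
  spec <- proximity_spec(order_k = 2, d_eps_s = 1)
  tb <- distance_ratio_table(obs, spec, mode = "local-asymmetric")
  expect_equal(unname(tb$values["u1", "0", "A"]), 0)

  set.seed(99)
  n <- 500
  obs2 <- observation_set(data.frame(
    x = runif(n), y = runif(n),
    category = sample(c("A", "B"), n, replace = TRUE), t = 0, weight = 1,
    unit_id = "u1", t_label = "0"))
  tb2 <- distance_ratio_table(obs2, spec, mode = "local-asymmetric")
  raw <- tb2$values  # stored cell values are the raw ratios
  expect_equal(unname(raw["u1", "0", "A"]), 1, tolerance = 0.1)
  expect_equal(unname(raw["u1", "0", "B"]), 1, tolerance = 0.1)
})

test_that("empty between-set cells are flagged undefined", {
  obs <- observation_set(data.frame(
    x = c(0, 1), y = 0, t = 0, category = "A", weight = 1,
    unit_id = "u1", t_label = "0"))
  spec <- proximity_spec(order_k = 2, d_eps_s = 1)
  tb <- distance_ratio_table(obs, spec, mode = "local-asymmetric")
  expect_true(length(attr(tb, "undefined")) > 0)
  expect_equal(sum(tb$values), 0)
})

test_that("multiway tables round-trip through CSV + JSON sidecar", {
  tb <- random_table(c(3, 4, 2), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_multiway(tb, path)
  tb2 <- read_multiway(path)
  expect_equal(tb2$values, tb$values, tolerance = 1e-12)
  expect_equal(tb2$kind, tb$kind)
  expect_equal(tb2$modes, tb$modes)
  unlink(c(path, paste0(tools::file_path_sans_ext(path), ".json")))
})
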