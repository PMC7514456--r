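test_that("ratio tensor reduces to ones under independence and reconstructs p", {
  pS <- c(0.4, 0.6); pC <- c(0.3, 0.3, 0.4)
  prod_tb <- multiway_table(array(outer(pS, pC), c(2, 3),
                                  dimnames = list(S = 1:2, C = 1:3)))
  irt <- independence_ratio_tensor(prod_tb)
  expect_equal(max(abs(irt$ratio - 1)), 0, tolerance = 1e-12)

  diag_tb <- multiway_table(array(c(0.5, 0, 0, 0.5), c(2, 2),
                                  dimnames = list(S = 1:2, C = 1:2)))
  expect_equal(as.vector(independence_ratio_tensor(diag_tb)$ratio),
               c(2, 0, 0, 2))

  tb <- random_table(c(3, 4, 2), seed = 41)
  irt3 <- independence_ratio_tensor(tb)
  expect_equal(irt3$ratio * Reduce(`%o%`, irt3$margins), tb$p,
               tolerance = 1e-12, ignore_attr = TRUE)

  # empty labels are dropped with a report
  v <- tb$values; v[, 2, ] <- 0
  tb0 <- multiway_table(v)
  irt0 <- independence_ratio_tensor(tb0)
  expect_equal(irt0$dropped$T, "b2")
  expect_equal(dim(irt0$ratio), c(3, 3, 2))
})

test_that("chi-square matches the direct formula", {
  pS <- c(0.4, 0.6); pC <- c(0.3, 0.7)
  prod_tb <- multiway_table(array(outer(pS, pC), c(2, 2),
                                  dimnames = list(S = 1:2, C = 1:2)))
  expect_equal(chi_square(prod_tb), 0, tolerance = 1e-12)
  diag_tb <- multiway_table(array(c(0.5, 0, 0, 0.5), c(2, 2),
                                  dimnames = list(S = 1:2, C = 1:2)))
  expect_equal(chi_square(diag_tb), 1.0)
})

test_that("component 0 is the exact independence term", {
  tb <- random_table(c(4, 3, 5), seed = 51)
  f <- decompose_fca(tb, n_components = 2, seed = 1)
  c0 <- f$components[[1]]
  expect_equal(c0$sigma, 1)
  for (v in c0$vectors) expect_equal(unname(v), rep(1, length(v)))
  # product table: all later sigmas vanish
  pS <- c(0.4, 0.6); pC <- c(0.3, 0.3, 0.4)
  prod_tb <- multiway_table(array(outer(pS, pC), c(2, 3),
                                  dimnames = list(S = 1:2, C = 1:3)))
  fp <- decompose_fca(prod_tb, n_components = 1, seed = 1)
  expect_lt(fp$components[[2]]$sigma, 1e-10)
})

test_that("the symmetric 2x2 example gives sigma_1 = 0.2 (phi coefficient)", {
  tb <- multiway_table(array(c(0.3, 0.2, 0.2, 0.3), c(2, 2),
                             dimnames = list(S = 1:2, C = 1:2)))
  f <- decompose_fca(tb, n_components = 1, seed = 1)
  expect_equal(f$components[[2]]$sigma, 0.2, tolerance = 1e-10)
})

test_that("2-mode decomposition matches a classical CA / SVD oracle", {
  for (seed in 1:5) {
    tb <- random_table(c(5, 7), seed = 200 + seed)
    f <- decompose_fca(tb, n_components = 4, seed = 1)
    orac <- ca_oracle(tb$p)
    sig <- vapply(f$components[-1], `[[`, 0, "sigma")
    expect_equal(sig, orac$sigma[1:4], tolerance = 1e-8)
    # vectors agree up to sign, in the margin-weighted normalisation
    for (r in 1:2) {
      vS <- f$components[[r + 1]]$vectors$S
      oS <- orac$u[, r]
      expect_equal(abs(sum(tb$margins$S * vS * oS)), 1, tolerance = 1e-8)
    }
    # completeness: full decomposition closes the chi-square identity
    full <- decompose_fca(tb, n_components = 4, seed = 1)
    expect_equal(1 + sum(vapply(full$components[-1], `[[`, 0, "sigma")^2),
                 1 + chi_square(tb), tolerance = 1e-8)
  }
})

test_that("weighted normalisation of component vectors holds", {
  tb <- random_table(c(4, 3, 5), seed = 61)
  f <- decompose_fca(tb, n_components = 3, seed = 1)
  for (cp in f$components[-1])
    for (m in f$modes)
      expect_equal(sum(f$margins[[m]] * cp$vectors[[m]]^2), 1,
                   tolerance = 1e-8)
})

test_that("a planted rank-one perturbation is recovered", {
  for (seed in c(2, 9)) {
    tb <- make_rank_structured_table(c(4, 3, 5), sigma_star = 0.04,
                                     seed = seed)
    f <- decompose_fca(tb, n_components = 1, seed = 1)
    expect_equal(f$components[[2]]$sigma, 0.04, tolerance = 1e-6)
  }
})

test_that("greedy extraction is nested: sigma_1 identical for R = 1 and R = 3", {
  tb <- random_table(c(4, 5, 3), seed = 71)
  f1 <- decompose_fca(tb, n_components = 1, seed = 1)
  f3 <- decompose_fca(tb, n_components = 3, seed = 1)
  expect_equal(f1$components[[2]]$sigma, f3$components[[2]]$sigma,
               tolerance = 1e-12)
  # deterministic under a fixed seed
  f3b <- decompose_fca(tb, n_components = 3, seed = 1)
  expect_identical(vapply(f3$components, `[[`, 0, "sigma"),
                   vapply(f3b$components, `[[`, 0, "sigma"))
})

test_that("CTR vectors are distributions and component 0's CTR is the margin product", {
  tb <- random_table(c(4, 3, 5), seed = 81)
  f <- decompose_fca(tb, n_components = 2, seed = 1)
  ct0 <- ctr(f, 0)
  expect_equal(ct0$tensor, Reduce(`%o%`, f$margins), tolerance = 1e-12)
  for (r in 0:2) {
    ctr_r <- ctr(f, r)
    for (m in f$modes) {
      expect_true(all(ctr_r$by_mode[[m]] >= 0))
      expect_equal(sum(ctr_r$by_mode[[m]]), 1, tolerance = 1e-8)
      expect_equal(sum(abs(ctr_r$signed_percent[[m]])), 100,
                   tolerance = 1e-6)
    }
  }
})

test_that("a synthetic rank-one table concentrates its CTR where constructed", {
  tb <- make_rank_structured_table(c(4, 3, 5), sigma_star = 0.04, seed = 3)
  f <- decompose_fca(tb, n_components = 1, seed = 1)
  vecs <- attr(tb, "vectors")
  ct <- ctr(f, 1)
  for (m in seq_along(vecs)) {
    got <- ct$by_mode[[m]]
    want <- f$margins[[m]] * vecs[[m]]^2
    expect_equal(unname(got), unname(want), tolerance = 1e-5)
  }
})

test_that("CTR entropy combines by log-cardinality weights (published values)", {
  ce <- ctr_entropy(hu = c(0.786, 0.595, 0.894), cardinalities = c(7, 8, 11))
  expect_equal(ce$combined, 0.764, tolerance = 1e-3)
  # uniform CTR vectors give 1
  expect_equal(ctr_entropy(hu = c(1, 1, 1), cardinalities = c(3, 4, 5))$combined, 1)
  # identity with the direct Hu of the product tensor
  set.seed(14)
  vecs <- lapply(c(4, 3, 6), function(k) { v <- rexp(k); v / sum(v) })
  hu <- vapply(vecs, function(v) normalized_entropy(v), 0)
  card <- lengths(vecs)
  direct <- shannon_entropy(Reduce(`%o%`, vecs)) / log(prod(card))
  expect_equal(ctr_entropy(hu = hu, cardinalities = card)$combined, direct,
               tolerance = 1e-12)
})

test_that("the positive split reconstructs exactly with orthogonal terms", {
  tb <- random_table(c(4, 3, 5), seed = 91)
  f <- decompose_fca(tb, n_components = 2, seed = 1)
  for (r in 1:2) {
    sp <- positive_split(f, r)
    expect_lte(length(sp$positive), 4)
    expect_lte(length(sp$negative), 4)
    st <- split_tensors(sp)
    cp <- f$components[[r + 1]]
    target <- cp$sigma * Reduce(`%o%`, mapply(function(m, v) m * v,
                                              f$margins, cp$vectors,
                                              SIMPLIFY = FALSE))
    expect_equal(st$tensor, target, tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(st$positive >= 0))
    expect_true(all(st$negative >= 0))
    # pairwise orthogonality of all terms (as flattened tensors)
    terms <- c(sp$positive, sp$negative)
    flat <- lapply(terms, function(tm) as.vector(Reduce(`%o%`, tm$factors)))
    for (i in seq_along(flat)) for (j in seq_along(flat))
      if (i < j) expect_lt(abs(sum(flat[[i]] * flat[[j]])), 1e-12)
  }
})

test_that("all-non-negative factors give an empty negative part", {
  factors <- list(S = c(0.2, 0.3), T = c(0.1, 0.4), C = c(0.5, 0.25))
  sp <- patchentropy:::split_rank_one(factors)
  expect_length(sp$negative, 0)
  expect_length(sp$positive, 1)
  st <- split_tensors(sp)
  expect_equal(st$tensor, Reduce(`%o%`, factors), ignore_attr = TRUE)
})

test_that("one mixed-sign factor yields the two-term positive part", {
  factors <- list(S = c(0.5, -0.2), T = c(0.3, 0.4), C = c(0.1, 0.2))
  # relabel: x has mixed signs -> (x+ o y o z) splits over the sign of x
  sp <- patchentropy:::split_rank_one(factors)
  expect_length(sp$positive, 1)  # x+ o y+ o z+ (y, z fully positive)
  expect_length(sp$negative, 1)  # x- o y+ o z+
  st <- split_tensors(sp)
  expect_equal(st$tensor, Reduce(`%o%`, factors), ignore_attr = TRUE)
})

test_that("entropy ratios of a component behave as closed forms predict", {
  # uniform factors: ratio is log|mode| / sum of logs
  vecs <- list(S = rep(1 / 4, 4), T = rep(1 / 3, 3), C = rep(1 / 5, 5))
  er <- entropy_ratios(vecs)
  expect_equal(unname(er$ratio),
               log(c(4, 3, 5)) / sum(log(c(4, 3, 5))), tolerance = 1e-12)
  # degenerate mode contributes zero
  vecs2 <- list(S = c(1, 0, 0), T = rep(1 / 3, 3), C = rep(1 / 5, 5))
  expect_equal(unname(entropy_ratios(vecs2)$ratio[1]), 0)
  # numerator plus complement add to the joint entropy
  tb <- random_table(c(4, 3, 5), seed = 95)
  f <- decompose_fca(tb, n_components = 1, seed = 1)
  er3 <- entropy_ratios(f, 1)
  expect_equal(sum(er3$H_mode), er3$H_joint, tolerance = 1e-12)
})

test_that("signed scores are geometric means signed by the category weight", {
  tb <- random_table(c(3, 2, 4), seed = 97)
  f <- decompose_fca(tb, n_components = 1, seed = 1)
  ct <- ctr(f, 1)
  cp <- f$components[[2]]
  cells <- data.frame(cell_id = c("g1", "g2", "g3"),
                      S = c("a1", "a2", NA),
                      T = c("b1", "b2", "b1"),
                      C = c("c1", "c3", "c2"))
  sc <- signed_scores(f, 1, cells)
  w1 <- ct$by_mode$S["a1"] * ct$by_mode$T["b1"] * ct$by_mode$C["c1"]
  expect_equal(sc$score[1],
               unname(sign(cp$vectors$C["c1"]) * w1^(1 / 3)),
               tolerance = 1e-12)
  expect_true(is.na(sc$score[3]))
})

test_that("mwca results serialise with signed-CTR tables", {
  tb <- random_table(c(3, 4, 2), seed = 99)
  f <- decompose_fca(tb, n_components = 2, seed = 1)
  path <- tempfile(fileext = ".json")
  write_mwca(f, path)
  expect_true(file.exists(path))
  ctr_csv <- sprintf("%s_ctr_r1.csv", tools::file_path_sans_ext(path))
  expect_true(file.exists(ctr_csv))
  df <- read.csv(ctr_csv)
  expect_named(df, c("mode", "label", "signed_ctr_percent"))
  expect_equal(sum(abs(df$signed_ctr_percent[df$mode == "S"])), 100,
               tolerance = 1e-6)
  unlink(c(path, ctr_csv,
           sprintf("%s_ctr_r2.csv", tools::file_path_sans_ext(path))))
})
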