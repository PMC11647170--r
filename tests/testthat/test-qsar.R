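test_that("train/test splitting reproduces the study proportions", {
  ids <- sprintf("p%03d", 1:490)
  s <- split_train_test(ids, split_spec(1, 0.8))
  expect_length(s$train, 392)
  expect_length(s$test, 98)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), ids)

  s10 <- split_train_test(sprintf("q%02d", 1:10), split_spec(2, 0.8))
  expect_length(s10$train, 8)
  expect_identical(split_train_test(ids, split_spec(7)),
                   split_train_test(ids, split_spec(7)))
  expect_false(identical(split_train_test(ids, split_spec(7))$train,
                         split_train_test(ids, split_spec(8))$train))
  expect_error(split_train_test("only_one", split_spec(1)), "at least 2")
  expect_error(split_spec(1, 1.2), "train_fraction")
})

test_that("OLS fitting interpolates, degenerates and fails as specified", {
  ids <- sprintf("c%02d", 1:10)
  df <- data.frame(compound_id = ids, x1 = 1:10, stringsAsFactors = FALSE)
  attr(df, "response") <- stats::setNames(2 * df$x1 - 3, ids)
  class(df) <- c("descriptor_table", "data.frame")
  m <- fit_ols(df, "x1")
  expect_equal(m$intercept, -3, tolerance = 1e-10)
  expect_equal(unname(m$coefficients[["x1"]]), 2, tolerance = 1e-10)
  expect_equal(m$stats$r2, 1, tolerance = 1e-12)

  attr(df, "response") <- stats::setNames(rep(5, 10), ids)
  m0 <- fit_ols(df, "x1")
  expect_equal(unname(m0$coefficients[["x1"]]), 0)
  expect_equal(m0$stats$r2, 0)

  df$x2 <- 2 * df$x1
  attr(df, "response") <- stats::setNames(rnorm(10), ids)
  expect_error(fit_ols(df, c("x1", "x2")), "x2")
})

test_that("planted coefficients are recovered within 3 standard errors", {
  tab <- gen_descriptor_table(planted_model_spec(n = 490, pool_width = 10,
                                                 seed = 42))
  m <- fit_ols(tab, c("vsurf_S", "wienerPath"))
  X <- cbind(1, descriptor_matrix(tab)[, c("vsurf_S", "wienerPath")])
  y <- response_of(tab)
  lmfit <- lm(y ~ X - 1)
  se <- sqrt(diag(vcov(lmfit)))
  truth <- attr(tab, "truth")
  expect_lt(abs(m$intercept - truth$intercept), 3 * se[1])
  expect_lt(abs(m$coefficients[["vsurf_S"]] -
                  truth$coefficients[["vsurf_S"]]), 3 * se[2])
  expect_lt(abs(m$coefficients[["wienerPath"]] -
                  truth$coefficients[["wienerPath"]]), 3 * se[3])
})

test_that("R-squared has its fixed points and guards", {
  tab <- random_table(50, 2, seed = 3)
  perfect <- fit_ols(tab, c("d1", "d2"))
  yhat <- predict_qsar(perfect, tab)
  synth <- tab
  attr(synth, "response") <- yhat   # response the model predicts exactly
  expect_equal(r_squared(perfect, synth), 1, tolerance = 1e-12)

  ybar_model <- qsar_model(mean(response_of(tab)), c(d1 = 0))
  expect_equal(r_squared(ybar_model, tab), 0, tolerance = 1e-12)

  attr(synth, "response") <- stats::setNames(rep(1, 50), tab$compound_id)
  expect_error(r_squared(perfect, synth), "zero-variance")
})

test_that("hat-matrix LOO equals the explicit refit loop", {
  for (s in 1:20) {
    tab <- random_table(50, 2, seed = 100 + s)
    y <- response_of(tab)
    q2 <- loo_q2(tab, c("d1", "d2"))
    press <- 0
    for (i in 1:50) {
      sub <- tab[-i, , drop = FALSE]
      class(sub) <- class(tab)
      m_i <- fit_ols(sub, c("d1", "d2"), y[tab$compound_id[-i]])
      row_i <- tab[i, , drop = FALSE]
      class(row_i) <- class(tab)
      press <- press + (y[[i]] - predict_qsar(m_i, row_i))^2
    }
    q2_oracle <- 1 - press / sum((y - mean(y))^2)
    expect_equal(q2, unname(q2_oracle), tolerance = 1e-10)
  }
})

test_that("LOO q2 is bounded by R2 and collapses under y-scrambling", {
  qdiff <- numeric(10)
  q_scr <- numeric(10)
  for (s in 1:10) {
    tab <- random_table(60, 2, seed = 200 + s)
    m <- fit_ols(tab, c("d1", "d2"))
    q2 <- loo_q2(tab, c("d1", "d2"))
    expect_lte(q2, m$stats$r2)
    scr <- tab
    attr(scr, "response") <- with_seed(
      300 + s, stats::setNames(sample(response_of(tab)), tab$compound_id))
    q_scr[s] <- loo_q2(scr, c("d1", "d2"))
  }
  expect_lte(mean(q_scr), 0.1)
})

test_that("noiseless linear data gives q2 of 1", {
  tab <- random_table(40, 2, seed = 5)
  attr(tab, "response") <- stats::setNames(
    1.5 + 2 * tab$d1 - 0.7 * tab$d2, tab$compound_id)
  expect_equal(loo_q2(tab, c("d1", "d2")), 1, tolerance = 1e-12)
})

test_that("the frozen published model is pure arithmetic", {
  expect_identical(published_model_predict(0, 0), -1.26777)
  expect_equal(published_model_predict(100, 1000), -2.35877,
               tolerance = 1e-12)
  s_lo <- published_model_predict(200, 5000)
  s_hi <- published_model_predict(300, 5000)
  expect_lt(s_hi, s_lo)   # larger surface -> stronger (more negative)
  expect_gt(published_model_predict(200, 9000), s_lo)  # branching weakens
  pm <- published_model()
  expect_identical(pm$intercept, -1.26777)
  expect_identical(unname(pm$coefficients), c(-0.01161, 0.00007))
})

test_that("GA on a two-column pool reduces to the direct fit", {
  tab <- random_table(60, 2, seed = 9)
  direct <- fit_ols(tab, c("d1", "d2"))
  g <- ga_evolve(tab, ga_config(pop_size = 20, generations = 20,
                                max_descriptors = 2, seed = 4),
                 split_spec(4))
  expect_setequal(names(g$coefficients), c("d1", "d2"))
  g_all <- fit_ols(tab, names(g$coefficients))
  expect_equal(sort(g_all$coefficients), sort(direct$coefficients),
               tolerance = 1e-10)
})

test_that("GA runs are reproducible and monotone under elitism", {
  tab <- gen_descriptor_table(planted_model_spec(n = 120, pool_width = 40,
                                                 seed = 77))
  cfg <- ga_config(pop_size = 30, generations = 40, seed = 11)
  g1 <- ga_evolve(tab, cfg, split_spec(11))
  g2 <- ga_evolve(tab, cfg, split_spec(11))
  expect_identical(g1$coefficients, g2$coefficients)
  expect_identical(g1$stats, g2$stats)
  trace <- attr(g1, "fitness_trace")
  expect_true(all(diff(trace) >= 0))
  expect_error(
    ga_evolve(descriptor_table(list(a = c(x = 1), b = c(x = 1)),
                               c(a = 0, b = 1)),
              cfg, split_spec(1)),
    "constant")
})

test_that("predictions are invariant to affine descriptor rescaling", {
  tab <- random_table(50, 2, seed = 21)
  m <- fit_ols(tab, c("d1", "d2"))
  scaled <- tab
  scaled$d1 <- 10 * tab$d1 + 3
  class(scaled) <- class(tab)
  m_s <- fit_ols(scaled, c("d1", "d2"))
  expect_equal(predict_qsar(m_s, scaled), predict_qsar(m, tab),
               tolerance = 1e-8)
  # back-transformed coefficient identity
  expect_equal(m_s$coefficients[["d1"]] * 10, m$coefficients[["d1"]],
               tolerance = 1e-8)
})
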