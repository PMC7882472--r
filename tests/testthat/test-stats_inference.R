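# Standardization, fits, AICc, enumeration, candidate sets, averaging, VIF.

test_that("standardize01 maps min to 0, max to 1, linearly", {
  expect_equal(standardize01(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.3, 0.77, 1)
  expect_equal(standardize01(v), v)
  set.seed(3)
  x <- rnorm(20)
  expect_equal(standardize01(5 * x - 11), standardize01(x), tolerance = 1e-12)
  expect_error(standardize01(rep(4, 5)), "constant")
})

test_that("gaussian fit: exact line, aliased columns, normal-equation oracle", {
  x <- matrix(1:6, ncol = 1, dimnames = list(NULL, "x"))
  f <- suppressWarnings(fit_lm(2 * (1:6), x))  # perfect fit warns in summary
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x"], 2)
  expect_equal(sum(residuals(f$model)^2), 0, tolerance = 1e-20)

  xx <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(fit_lm(rnorm(6), xx), "aliased.*b")

  set.seed(8)
  n <- 40
  X <- cbind(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  y <- rnorm(n)
  f <- fit_lm(y, X)
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(f$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  # k counts intercept + slopes + residual variance
  expect_equal(f$k, ncol(X) + 2)
})

test_that("binomial fit: closed-form MLEs and separation flagging", {
  f <- fit_binom(29, 67)
  expect_equal(f$coefficients$estimate[1], log(29 / 38), tolerance = 1e-7)

  expect_warning(fs <- fit_binom(c(5, 7), c(5, 7)), "separation|flagged")
  expect_false(fs$converged)

  # two-group saturated model: group logits equal the sample log-odds
  g <- c(0, 0, 1, 1)
  succ <- c(3, 5, 9, 11); tri <- c(10, 10, 12, 14)
  f2 <- fit_binom(succ, tri, cbind(g = g))
  p0 <- sum(succ[g == 0]) / sum(tri[g == 0])
  p1 <- sum(succ[g == 1]) / sum(tri[g == 1])
  expect_equal(f2$coefficients$estimate[1], qlogis(p0), tolerance = 1e-6)
  expect_equal(sum(f2$coefficients$estimate), qlogis(p1), tolerance = 1e-6)
})

test_that("AICc formula, large-n limit, and AICc > AIC", {
  # AIC 20 with k = 2, n = 10: correction 2*2*3/7
  ll <- -(20 - 4) / 2
  expect_equal(aicc(ll, 2, 10), 20 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(ll, 2, 1e9), 20, tolerance = 1e-5)
  expect_error(aicc(-10, 5, 6), "undefined")
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(1:5, 1); n <- k + 1 + sample(1:30, 1); ll <- rnorm(1, -50, 10)
    expect_gt(aicc(ll, k, n), -2 * ll + 2 * k)
  }
})

test_that("submodel enumeration respects marginality and matches the oracle", {
  expect_length(enumerate_submodels("L", character(0), character(0)), 2)
  m18 <- enumerate_submodels(covariates = character(0))
  m36 <- enumerate_submodels()
  expect_length(m18, 18)
  expect_length(m36, 36)
  expect_equal(length(m18),
               oracle_enumerate(c("L", "S", "C"), c("L:C", "S:C", "L:S"),
                                character(0)))
  expect_equal(length(m36),
               oracle_enumerate(c("L", "S", "C"), c("L:C", "S:C", "L:S"), "R"))
  # null model present; no model carries an interaction without its parents
  expect_identical(m36[[1]], character(0))
  for (m in m36) for (ia in intersect(c("L:C", "S:C", "L:S"), m))
    expect_true(all(strsplit(ia, ":")[[1]] %in% m))
  expect_error(enumerate_submodels(c("L", "S"), "S:C"), "marginality")
})

test_that("candidate sets use strict Delta < 6 and renormalised weights", {
  fits <- list(fake_fit("L", 100), fake_fit("S", 102),
               fake_fit(c("L", "S"), 107))
  cs <- candidate_set(fits)
  expect_length(cs$fits, 2)  # Delta = 7 model excluded
  expect_equal(cs$weight, exp(-c(0, 2) / 2) / sum(exp(-c(0, 2) / 2)))
  expect_equal(cs$weight[1], 0.7311, tolerance = 1e-4)
  expect_equal(sum(cs$weight), 1)

  tie <- candidate_set(list(fake_fit("L", 50), fake_fit("S", 50)))
  expect_equal(tie$weight, c(0.5, 0.5))

  # a Delta of exactly 6 is outside the strict threshold
  edge <- candidate_set(list(fake_fit("L", 10), fake_fit("S", 16)))
  expect_length(edge$fits, 1)

  expect_warning(
    flagged <- candidate_set(list(fake_fit("L", 10),
                                  fake_fit("S", 10.5, converged = FALSE))),
    "flagged")
  expect_length(flagged$fits, 1)
})

test_that("conditional averaging: weighted means, SEs, importance, identity", {
  cand <- structure(list(
    fits = list(fake_fit("L", 0, est = 1.0, se = 0),
                fake_fit("L", 0, est = 2.0, se = 0)),
    delta = c(0, 0), weight = c(0.6, 0.4)), class = "fw_candidates")
  av <- conditional_average(cand)
  expect_equal(av$estimate[av$term == "L"], 1.4)
  expect_equal(av$importance[av$term == "L"], 2)

  # a term in exactly one candidate keeps that model's estimate and SE
  cand1 <- structure(list(
    fits = list(fake_fit("L", 0, est = 0.8, se = 0.3), fake_fit(character(0), 1)),
    delta = c(0, 1), weight = c(0.62, 0.38)), class = "fw_candidates")
  av1 <- conditional_average(cand1)
  expect_equal(av1$estimate, 0.8)
  expect_equal(av1$se, 0.3)
  expect_equal(av1$ci95, 1.96 * 0.3)
  expect_equal(av1$importance, 1)

  # 3-model toy against a hand-computed oracle including the SE formula
  w <- exp(-c(0, 1, 3) / 2); w <- w / sum(w)
  est <- c(1.2, 0.9, 2.0); se <- c(0.4, 0.5, 0.3)
  cand3 <- structure(list(
    fits = list(fake_fit("C", 0, est[1], se[1]),
                fake_fit("C", 1, est[2], se[2]),
                fake_fit("C", 3, est[3], se[3])),
    delta = c(0, 1, 3), weight = w), class = "fw_candidates")
  av3 <- conditional_average(cand3)
  bbar <- sum(w * est)
  se_avg <- sum(w * sqrt(se^2 + (est - bbar)^2))
  expect_equal(av3$estimate, bbar, tolerance = 1e-12)
  expect_equal(av3$se, se_avg, tolerance = 1e-12)
  expect_equal(av3$z, bbar / se_avg, tolerance = 1e-12)

  # degenerate single-candidate set: averaging returns that model
  cd <- structure(list(fits = list(fake_fit(c("L", "S"), 0,
                                            est = c(0.5, -1), se = c(0.1, 0.2))),
                       delta = 0, weight = 1), class = "fw_candidates")
  avd <- conditional_average(cd)
  expect_equal(avd$estimate[avd$term == "L"], 0.5)
  expect_equal(avd$se[avd$term == "S"], 0.2)
  expect_equal(avd$importance, c(1, 1))
})

test_that("averaging is invariant to model enumeration order", {
  fits <- list(fake_fit("L", 100, est = 1, se = 0.2),
               fake_fit(c("L", "S"), 101, est = c(1.5, -0.3),
                        se = c(0.25, 0.4)),
               fake_fit("S", 103, est = -0.6, se = 0.5))
  a1 <- conditional_average(candidate_set(fits))
  a2 <- conditional_average(candidate_set(rev(fits)))
  expect_equal(a1, a2)
})

test_that("VIF: orthogonal = 1, collinear = Inf, matches 1/(1-R2) oracle", {
  x_orth <- cbind(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(vif(x_orth)), c(1, 1), tolerance = 1e-12)

  x_dup <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  expect_true(all(is.infinite(vif(x_dup))))

  set.seed(77)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 2] + 0.6 * X[, 1]
  v <- vif(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("weights sum to one and conditional weights per term sum to one", {
  set.seed(55)
  d <- simulate_ratio_data(60, c(`(Intercept)` = -0.2, L = 0.3, S = -1,
                                 C = 0.4, `L:C` = 0, `S:C` = 1.5,
                                 `L:S` = 0), seed = 12)
  sel <- model_selection(d, list(kind = "binomial", successes = "successes",
                                 trials = "trials"))
  expect_equal(sum(sel$candidates$weight), 1, tolerance = 1e-12)
  expect_true(all(sel$averaged$importance >= 1))
  expect_true(all(sel$averaged$importance <= length(sel$candidates$fits)))
})
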