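test_that("implied moments follow the factor-model structure", {
  # Lambda = 0: Sigma = diag(Theta), mu = nu
  z <- implied_moments(list(Lambda = matrix(0, 2, 1), Theta = c(1, 2),
                            Phi = matrix(2), nu = c(3, 4), kappa = 0))
  expect_equal(z$Sigma, diag(c(1, 2)))
  expect_equal(z$mu, c(3, 4))
  # one factor, lambda = (1, 0.5), phi = 2, Theta = (1, 1)
  z <- implied_moments(list(Lambda = cbind(c(1, 0.5)), Theta = c(1, 1),
                            Phi = matrix(2), nu = c(0.2, 0.4),
                            kappa = 0.5))
  expect_equal(z$Sigma, matrix(c(3, 1, 1, 1.5), 2, 2))
  expect_equal(z$mu, c(0.2, 0.4) + c(1, 0.5) * 0.5)
  # kappa = 0 leaves mu = nu
  z0 <- implied_moments(list(Lambda = cbind(c(1, 0.5)), Theta = c(1, 1),
                             Phi = matrix(2), nu = c(0.2, 0.4), kappa = 0))
  expect_equal(z0$mu, c(0.2, 0.4))
  # second-order expansion Phi = Gamma phi2 Gamma' + diag(D)
  z2 <- implied_moments(list(Lambda = diag(2), Theta = c(0.1, 0.1),
                             Gamma = c(1, 2), phi2 = 1, D = c(0.5, 0.5)))
  expect_equal(z2$Sigma, matrix(c(1.5, 2, 2, 4.5), 2, 2) + diag(0.1, 2))
  expect_error(implied_moments(list(Lambda = diag(2), Theta = 1,
                                    Phi = diag(2))), "dimension")
})

test_that("the ML discrepancy has its closed-form values", {
  s <- group_summary(S = matrix(2), xbar = 1, n = 50)
  # perfect fit
  expect_equal(ml_discrepancy(s, matrix(2), 1), 0)
  # univariate: ln(1) + 2 - ln(2) - 1
  expect_equal(ml_discrepancy(s, matrix(1), 1), 1 - log(2))
  # mean misfit only: delta' S^-1 delta
  set.seed(9)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  mu <- rnorm(3); delta <- rnorm(3)
  s3 <- group_summary(S, xbar = mu + delta, n = 50)
  expect_equal(ml_discrepancy(s3, S, mu),
               drop(t(delta) %*% solve(S) %*% delta))
  expect_error(ml_discrepancy(s, matrix(-1), 1), "positive definite")
})

test_that("analytic gradients match central differences", {
  set.seed(21)
  d <- default_cesd_params()
  cfg <- generator_config(sizes = c(chinese = 300L, dutch = 300L),
                          missing_rate = 0)
  gs <- summarize_groups(generate_items(cfg, seed = 2))
  for (case in list(
    list(spec = builtin_spec("four_factor"),
         prof = constraint_profile("scalar", data.frame(
           class = "intercept", item = "Failure"))),
    list(spec = builtin_spec("second_order"),
         prof = constraint_profile("configural")))) {
    tpl <- mgcfa:::build_template(case$spec, names(gs), case$prof)
    env <- mgcfa:::fit_env(tpl, gs)
    obj <- mgcfa:::objective_fn(tpl, env)
    grad <- mgcfa:::gradient_fn(tpl, env)
    v0 <- mgcfa:::default_start(tpl, env)
    x <- v0; x[tpl$par$log] <- log(pmax(v0[tpl$par$log], 1e-5))
    x <- x + runif(length(x), -0.02, 0.02)
    g <- grad(x)
    num <- vapply(seq_along(x), function(i) {
      h <- 1e-6 * max(1, abs(x[i]))
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      (obj(xp) - obj(xm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - num)), 1e-6 * max(1, max(abs(g))))
  }
})

test_that("just-identified one-factor models match the tetrad closed form", {
  set.seed(5)
  for (rep in 1:5) {
    S <- tiny_factor_cov()
    sm <- group_summary(S, xbar = rnorm(3), n = 400)
    fit <- fit_mgcfa(tiny_spec(), sm)
    sol <- tetrad_solution(S)
    est <- fit$params[[1]]
    expect_lt(abs(est$Phi[1, 1] - sol$phi), 1e-5)
    expect_lt(max(abs(est$Lambda[, 1] - sol$lambda)), 1e-5)
    expect_lt(max(abs(est$Theta - sol$theta)), 1e-5)
    expect_equal(unname(est$nu), unname(sm$xbar), tolerance = 1e-6)
    # just identified: perfect fit
    expect_identical(fit$df, 0L)
    expect_lt(abs(fit$T), 1e-6)
  }
})

test_that("rescaling one item rescales its parameters and leaves T fixed", {
  set.seed(31)
  # over-identified 4-indicator factor covariance plus a PSD perturbation
  # (so T > 0 but S stays positive definite)
  lam <- c(1, 0.8, 1.2, 0.9)
  S4 <- 1.3 * tcrossprod(lam) + diag(c(0.5, 0.6, 0.7, 0.5)) +
    0.05 * crossprod(matrix(rnorm(16), 4))
  dimnames(S4) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  spec <- model_spec(item_battery(c("a", "b", "c", "d")),
                     list(F1 = c("a", "b", "c", "d")))
  xb <- c(1, 2, 1.5, 0.5)
  f0 <- fit_mgcfa(spec, group_summary(S4, xb, n = 500))
  cc <- 2.5  # rescale item d by c: loading, intercept x c; uniqueness x c^2
  D <- diag(c(1, 1, 1, cc))
  f1 <- fit_mgcfa(spec, group_summary(D %*% S4 %*% D, drop(D %*% xb),
                                      item_names = colnames(S4), n = 500))
  expect_equal(f1$T, f0$T, tolerance = 1e-6)
  expect_equal(f1$params[[1]]$Lambda["d", 1],
               cc * f0$params[[1]]$Lambda["d", 1], tolerance = 1e-5)
  expect_equal(unname(f1$params[[1]]$nu["d"]),
               cc * unname(f0$params[[1]]$nu["d"]), tolerance = 1e-5)
  expect_equal(unname(f1$params[[1]]$Theta["d"]),
               cc^2 * unname(f0$params[[1]]$Theta["d"]), tolerance = 1e-4)
})

test_that("standardization satisfies the unifactorial identity", {
  set.seed(13)
  # lambda* = lambda sqrt(phi) / sd; theta* = theta / var; lam*^2 + th* = 1
  for (rep in 1:5) {
    lam <- runif(3, 0.3, 2); phi <- runif(1, 0.3, 2)
    th <- runif(3, 0.2, 1.5)
    ps <- list(Lambda = cbind(lam), Theta = th, Phi = matrix(phi),
               nu = runif(3), kappa = 0)
    std <- standardize_params(ps)
    expect_equal(drop(std$Lambda)^2 + std$Theta, rep(1, 3))
  }
  # worked example: lambda = 1, phi = 0.25, Sigma_ii = 1 -> lambda* = 0.5
  std <- standardize_params(list(Lambda = cbind(1), Theta = 0.75,
                                 Phi = matrix(0.25)))
  expect_equal(drop(std$Lambda), 0.5)
  expect_equal(std$Theta, 0.75)
})

test_that("standard errors are well-behaved and roughly calibrated", {
  set.seed(17)
  # intercept of a near-saturated model: SE(nu) ~ sqrt(Sigma_ii / n)
  S <- tiny_factor_cov()
  n <- 900
  sm <- group_summary(S, xbar = c(0.5, 1, 1.5), n = n)
  fit <- standard_errors(fit_mgcfa(tiny_spec(), sm))
  pt <- parameter_table(fit)
  expect_true(all(is.finite(pt$se)) && all(pt$se > 0))
  se_nu <- pt$se[pt$class == "intercept" & pt$item == "a"]
  expect_equal(se_nu, sqrt(S[1, 1] / n), tolerance = 0.05)
})

test_that("Heywood-prone input is floored and flagged", {
  # a PD observed covariance whose tetrad solution wants phi > var(a),
  # i.e. a negative uniqueness on item a (0.9 * 0.8 / 0.5 = 1.44 > 1)
  S <- matrix(c(1, 0.9, 0.8, 0.9, 1, 0.5, 0.8, 0.5, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sm <- group_summary(S, xbar = c(0, 0, 0), n = 200)
  fit <- fit_mgcfa(tiny_spec(), sm)
  expect_true(all(fit$params[[1]]$Theta >= 1e-6 - 1e-12))
  expect_true(length(fit$heywood) > 0)
})
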