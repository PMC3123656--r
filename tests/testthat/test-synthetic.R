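test_that("default generating parameters encode the two-sample calibration", {
  d <- default_cesd_params()
  p1 <- d$params$chinese; p2 <- d$params$dutch
  expect_equal(unname(d$sizes), c(4903L, 1903L))
  # loadings equal across groups; markers at 1
  expect_equal(p1$Lambda, p2$Lambda)
  expect_equal(unname(p1$Lambda["Happy", "POS"]), 2.30)
  expect_equal(unname(p1$Lambda[cbind(c("Bothered", "Blues", "Good",
                                        "Unfriendly"),
                                      c("SOM", "DEP", "POS", "INT"))]),
               rep(1, 4))
  # group-specific intercepts: Failure and Good only
  diff_nu <- names(which(p1$nu != p2$nu))
  expect_setequal(diff_nu, c("Failure", "Good"))
  expect_equal(unname(c(p1$nu["Good"], p2$nu["Good"])), c(1.54, 0.68))
  # group-specific uniquenesses: the five non-invariant items
  diff_th <- names(which(p1$Theta != p2$Theta))
  expect_setequal(diff_th,
                  c("Depressed", "Failure", "Fearful", "Good", "Dislike"))
  expect_equal(unname(c(p1$Theta["Depressed"], p2$Theta["Depressed"])),
               c(0.30, 0.13))
  # latent means and SDs
  expect_equal(unname(p1$kappa), rep(0, 4))
  expect_equal(unname(p2$kappa), c(-0.261, -0.259, -0.125, -0.323))
  expect_equal(unname(sqrt(diag(p1$Phi))), c(0.482, 0.570, 0.354, 0.574),
               tolerance = 1e-12)
  expect_equal(unname(sqrt(diag(p2$Phi))), c(0.324, 0.318, 0.329, 0.184),
               tolerance = 1e-12)
})

test_that("generation is reproducible from the seed", {
  cfg <- generator_config(sizes = c(chinese = 80L, dutch = 80L))
  t1 <- generate_items(cfg, seed = 99)
  t2 <- generate_items(cfg, seed = 99)
  expect_identical(t1, t2)
  t3 <- generate_items(cfg, seed = 100)
  expect_false(identical(t1, t3))
})

test_that("large-sample moments converge to the implied moments", {
  d <- default_cesd_params()
  cfg <- generator_config(params = d$params["chinese"],
                          sizes = c(chinese = 200000L), missing_rate = 0)
  tab <- generate_items(cfg, seed = 12)
  s <- summarize_groups(tab, "chinese")
  imp <- implied_moments(d$params$chinese)
  expect_lt(max(abs(s$S - imp$Sigma)), 0.012)
  expect_lt(max(abs(s$xbar - imp$mu)), 0.012)
})

test_that("Likert output respects the scale, missingness and rank order", {
  cfg <- generator_config(sizes = c(chinese = 4000L, dutch = 1500L),
                          likert = TRUE, missing_rate = 0.01)
  tab <- generate_items(cfg, seed = 8)
  vals <- unlist(as.data.frame(tab)[, -1])
  expect_true(all(is.na(vals) | vals %in% 1:4))
  expect_equal(mean(is.na(vals)), 0.01, tolerance = 0.25)
  # discretization preserves the ordering of item intercorrelations
  d <- default_cesd_params()
  imp <- implied_moments(d$params$chinese)
  Rc <- cov2cor(imp$Sigma)
  Rl <- cov2cor(summarize_groups(tab, "chinese")$S)
  lower <- lower.tri(Rc)
  expect_gt(cor(Rc[lower], Rl[lower], method = "spearman"), 0.9)
})

test_that("planted edits change exactly the named parameter and are logged", {
  base <- null_genconfig(c(100L, 100L))
  expect_identical(planted_noninvariance(base, list())$params,
                   base$params)
  cfg <- planted_noninvariance(base, list(
    list(class = "intercept", item = "Mind", group = "g2", delta = 0.5)))
  expect_equal(cfg$params$g2$nu[["Mind"]],
               base$params$g2$nu[["Mind"]] + 0.5)
  expect_equal(cfg$params$g1, base$params$g1)
  other <- setdiff(names(cfg$params$g2$nu), "Mind")
  expect_equal(cfg$params$g2$nu[other], base$params$g2$nu[other])
  expect_equal(cfg$params$g2$Theta, base$params$g2$Theta)
  # loading and uniqueness edits
  cfg2 <- planted_noninvariance(base, list(
    list(class = "loading", item = "Happy", group = "g1", delta = -0.2),
    list(class = "uniqueness", item = "Sleep", group = "g1", delta = 0.3)))
  expect_equal(unname(cfg2$params$g1$Lambda["Happy", "POS"]), 2.30 - 0.2)
  expect_equal(cfg2$params$g1$Theta[["Sleep"]],
               base$params$g1$Theta[["Sleep"]] + 0.3)
  # the edit log records the planted truth and survives serialization
  expect_length(cfg2$edits, 2L)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg2$edits, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(lapply(back, function(e) e[c("class", "item", "group")]),
               lapply(cfg2$edits, function(e) e[c("class", "item",
                                                  "group")]))
  expect_equal(vapply(back, function(e) e$delta, numeric(1)), c(-0.2, 0.3))
  # invalid edits are rejected
  expect_error(planted_noninvariance(base, list(
    list(class = "uniqueness", item = "Sleep", group = "g1",
         delta = -10))), "non-positive")
  expect_error(planted_noninvariance(base, list(
    list(class = "intercept", item = "Nope", group = "g1", delta = 1))),
    "unknown item")
})

test_that("generator configuration is validated", {
  d <- default_cesd_params()
  expect_error(generator_config(missing_rate = 0.2), "missing_rate")
  expect_error(generator_config(params = d$params,
                                sizes = c(a = 10L, b = 10L)),
               "exceed the number of items")
  bad <- d$params
  bad$chinese$Phi <- matrix(1, 4, 4)  # singular
  expect_error(generator_config(params = bad, sizes = c(a = 100L,
                                                        b = 100L)),
               "positive definite")
})
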