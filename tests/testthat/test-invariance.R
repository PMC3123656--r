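test_that("nested-comparison deltas follow the convention", {
  set.seed(16)
  cfg <- null_genconfig(c(400L, 400L))
  gs <- summarize_groups(generate_items(cfg, seed = 16))
  spec <- builtin_spec("four_factor")
  f_conf <- fit_mgcfa(spec, gs, constraint_profile("configural"))
  f_metr <- fit_mgcfa(spec, gs, constraint_profile("metric"),
                      start = f_conf)
  cmp <- compare_nested(f_conf, f_metr)
  expect_identical(cmp$delta_df, 16L)        # 344 - 328
  expect_gte(cmp$delta_chisq, 0)
  # identical models: all deltas zero, accepted
  self <- compare_nested(f_conf, f_conf)
  expect_equal(self$delta_chisq, 0)
  expect_identical(self$delta_df, 0L)
  expect_equal(self$delta_cfi, 0)
  expect_true(self$accepted)
  # reversed nesting order is rejected
  expect_error(compare_nested(f_metr, f_conf), "not nested")
  # scalar vs metric: 20 intercepts equated - 4 means freed
  f_scal <- fit_mgcfa(spec, gs, constraint_profile("scalar"),
                      start = f_metr)
  expect_identical(compare_nested(f_metr, f_scal)$delta_df, 16L)
})

test_that("full-invariance data passes every rung of the ladder", {
  cfg <- null_genconfig(c(700L, 700L))
  rep <- run_invariance(builtin_spec("four_factor"),
                        summarize_groups(generate_items(cfg, seed = 23)))
  expect_identical(names(rep$steps),
                   c("configural", "metric", "scalar", "uniqueness"))
  expect_true(all(vapply(rep$steps, `[[`, "", "decision") == "accepted"))
  # with no releases to inherit, the full uniqueness model equates all 20
  # residual variances (df 380; the published 376 presupposes the two
  # scalar-level releases carried down)
  expect_identical(vapply(rep$steps, function(s) s$fit$df, integer(1)),
                   c(configural = 328L, metric = 344L, scalar = 360L,
                     uniqueness = 380L))
  # released lists stay empty on accepted full steps
  expect_true(all(vapply(rep$steps, function(s) nrow(s$released),
                         integer(1)) == 0L))
})

test_that("a planted intercept shift is localized by the partial search", {
  base <- null_genconfig(c(1000L, 1000L))
  cfg <- planted_noninvariance(base, list(
    list(class = "intercept", item = "Good", group = "g2", delta = 0.8)))
  rep <- run_invariance(builtin_spec("four_factor"),
                        summarize_groups(generate_items(cfg, seed = 77)))
  sc <- rep$steps$scalar
  expect_identical(sc$decision, "partial-accepted")
  expect_identical(sc$released$item, "Good")
  expect_identical(sc$released$class, "intercept")
  expect_identical(sc$fit$df, 359L)  # 360 - 1 release
  # the released item had the largest chi-square gain among all candidates
  gains <- sc$search_trail[[1]]
  expect_identical(gains$item[which.max(gains$gain)], "Good")
  # scalar exemptions are inherited by the uniqueness step
  un <- rep$steps$uniqueness
  ex <- un$fit$profile$exemptions
  expect_true(any(ex$class == "uniqueness" & ex$item == "Good"))
})

test_that("planted uniquenesses are released in magnitude order", {
  base <- null_genconfig(c(1000L, 1000L))
  # two non-invariant uniquenesses of clearly unequal misfit: Talk is
  # more than tripled (0.51 -> 1.71), Crying only mildly inflated
  # (0.27 -> 0.42); chi-square gain tracks the variance-ratio misfit
  cfg <- planted_noninvariance(base, list(
    list(class = "uniqueness", item = "Talk", group = "g2", delta = 1.2),
    list(class = "uniqueness", item = "Crying", group = "g2",
         delta = 0.15)))
  rep <- run_invariance(builtin_spec("four_factor"),
                        summarize_groups(generate_items(cfg, seed = 31)))
  un <- rep$steps$uniqueness
  expect_identical(un$decision, "partial-accepted")
  expect_identical(un$released$item[1], "Talk")  # larger misfit first
  expect_true(all(un$released$item %in% c("Talk", "Crying")))
  # brute-force check of the first pick: Talk's single-release refit gains
  # the most chi-square among all candidates
  gains <- un$search_trail[[1]]
  expect_identical(gains$item[which.max(gains$gain)], "Talk")
})

test_that("the ladder stops when a level cannot be made acceptable", {
  base <- null_genconfig(c(1000L, 1000L))
  cfg <- planted_noninvariance(base, list(
    list(class = "intercept", item = "Good", group = "g2", delta = 0.8)))
  rep <- run_invariance(builtin_spec("four_factor"),
                        summarize_groups(generate_items(cfg, seed = 77)),
                        allow_partial = FALSE)
  expect_identical(rep$steps$scalar$decision, "rejected")
  expect_false("uniqueness" %in% names(rep$steps))
})

test_that("cutoff configuration is validated and honored", {
  expect_error(cutoff_config(delta_cfi_max = 0), "cutoffs > 0")
  # the same misfit is rejected under the defaults but accepted under
  # permissive cutoffs
  cfg <- planted_noninvariance(null_genconfig(c(800L, 800L)), list(
    list(class = "intercept", item = "Sad", group = "g2", delta = 0.6)))
  gs <- summarize_groups(generate_items(cfg, seed = 41))
  strict <- run_invariance(builtin_spec("four_factor"), gs,
                           allow_partial = FALSE)
  expect_identical(strict$steps$scalar$decision, "rejected")
  loose <- run_invariance(builtin_spec("four_factor"), gs,
                          cutoffs = cutoff_config(0.5, 0.5),
                          allow_partial = FALSE)
  expect_identical(loose$steps$scalar$decision, "accepted")
})

test_that("the reference group is honored and validated", {
  cfg <- null_genconfig(c(300L, 300L))
  gs <- summarize_groups(generate_items(cfg, seed = 19))
  expect_error(run_invariance(builtin_spec("four_factor"), gs,
                              reference_group = "nope"), "reference group")
  rep <- run_invariance(builtin_spec("four_factor"), gs,
                        reference_group = "g2")
  expect_identical(rep$reference_group, "g2")
  # reference factor means fixed at zero
  expect_equal(unname(rep$steps$scalar$fit$params$g2$kappa), rep(0, 4))
})
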