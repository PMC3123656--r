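test_that("built-in CES-D structures have the documented shapes", {
  four <- builtin_spec("four_factor")
  expect_equal(unname(lengths(four$loadings)), c(7L, 7L, 4L, 2L))
  expect_equal(unname(unlist(four$markers)),
               c("Bothered", "Blues", "Good", "Unfriendly"))
  expect_equal(unname(lengths(builtin_spec("three_factor")$loadings)),
               c(14L, 4L, 2L))
  expect_equal(unname(lengths(builtin_spec("one_factor")$loadings)), 20L)
  so <- builtin_spec("second_order")
  expect_true(so$second_order)
  expect_length(so$factors, 4L)
  expect_error(builtin_spec("five_factor"))
})

test_that("validate_spec flags malformed structures without raising", {
  expect_identical(validate_spec(builtin_spec("four_factor")), character())
  b <- item_battery(c("a", "b", "c", "d"))
  partial <- model_spec(b, list(F1 = c("a", "b")))
  expect_length(validate_spec(partial), 1L)  # c, d unassigned
  single <- model_spec(b, list(F1 = c("a", "b", "c"), F2 = "d"))
  expect_match(validate_spec(single), "fewer than 2", all = FALSE)
  so2 <- model_spec(b, list(F1 = c("a", "b"), F2 = c("c", "d")),
                    second_order = TRUE)
  expect_match(validate_spec(so2), "under-identified", all = FALSE)
})

test_that("free-parameter counts match the moment arithmetic", {
  expect_identical(free_parameter_count(builtin_spec("four_factor")), 66L)
  expect_identical(free_parameter_count(builtin_spec("one_factor")), 60L)
  expect_identical(free_parameter_count(builtin_spec("three_factor")), 63L)
  # the count is invariant to the latent scaling choice
  for (nm in c("four_factor", "three_factor", "one_factor"))
    expect_identical(
      free_parameter_count(builtin_spec(nm), identification = "variance"),
      free_parameter_count(builtin_spec(nm), identification = "marker"))
})

test_that("single-group df reproduces the published ladder", {
  expect_identical(degrees_of_freedom(builtin_spec("four_factor")), 164L)
  expect_identical(degrees_of_freedom(builtin_spec("three_factor")), 167L)
  expect_identical(degrees_of_freedom(builtin_spec("one_factor")), 170L)
  # second-order under this package's identification (second-order variance
  # fixed to 1, four free second-order loadings, four disturbances)
  expect_identical(degrees_of_freedom(builtin_spec("second_order")), 166L)
})

test_that("each exemption restores (n_groups - 1) parameter copies", {
  spec <- builtin_spec("four_factor")
  cases <- list(
    list(level = "metric", class = "loading", item = "Happy"),
    list(level = "scalar", class = "intercept", item = "Failure"),
    list(level = "uniqueness", class = "uniqueness", item = "Sleep"))
  for (G in 2:3) {
    for (cs in cases) {
      base <- free_parameter_count(spec, G, constraint_profile(cs$level))
      ex <- data.frame(class = cs$class, item = cs$item)
      expect_identical(
        free_parameter_count(spec, G, constraint_profile(cs$level, ex)),
        base + (G - 1L))
    }
  }
})

test_that("anchor and identification rules are enforced", {
  spec <- builtin_spec("four_factor")
  # marker loadings are fixed, not releasable
  expect_error(
    free_parameter_count(spec, 2, constraint_profile(
      "metric", data.frame(class = "loading", item = "Blues"))),
    "marker")
  # a factor must keep at least one equated intercept for latent means
  expect_error(
    free_parameter_count(spec, 2, constraint_profile(
      "scalar", data.frame(class = "intercept",
                           item = c("Unfriendly", "Dislike")))),
    "unidentified")
  # exemptions must reference classes constrained at the level
  expect_error(
    constraint_profile("metric",
                       data.frame(class = "intercept", item = "Good")),
    "not constrained")
  # variance identification is a configural-only scaling
  expect_error(
    free_parameter_count(spec, 2, constraint_profile("metric"),
                         identification = "variance"),
    "configural")
})

test_that("model specs round-trip through YAML", {
  spec <- builtin_spec("four_factor")
  prof <- constraint_profile(
    "scalar", data.frame(class = "intercept", item = c("Failure", "Good")),
    reference_group = "chinese")
  path <- withr::local_tempfile(fileext = ".yaml")
  spec_to_yaml(spec, path, profile = prof)
  back <- spec_from_yaml(path)
  expect_equal(back$spec$loadings, spec$loadings)
  expect_equal(back$spec$markers, spec$markers)
  expect_identical(back$profile$level, "scalar")
  expect_setequal(back$profile$exemptions$item, c("Failure", "Good"))
  expect_identical(back$profile$reference_group, "chinese")
  # df bookkeeping survives the round trip
  expect_identical(degrees_of_freedom(back$spec, 2, back$profile), 358L)
})
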