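test_that("generation is deterministic given a seed and leaves the caller's
           RNG stream untouched", {
  d1 <- generate_preset("lacz_bone_marrow", seed = 5)
  d2 <- generate_preset("lacz_bone_marrow", seed = 5)
  d3 <- generate_preset("lacz_bone_marrow", seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1$records$count, d3$records$count))

  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_preset("mn_ret", seed = 1))
  expect_identical(runif(3), before)
})

test_that("the default design produces the study layout: 84 animals, 11 dose
           levels, 14 controls", {
  d <- generate_preset("piga_ret", seed = 1)
  expect_identical(nrow(d$records), 84L)
  expect_identical(length(unique(d$records$dose)), 11L)
  expect_identical(sum(d$records$dose == 0), 14L)
  expect_identical(sum(d$records$dose == 50), 7L)
})

test_that("noise-free continuous generation lies exactly on the true curve", {
  em <- endpoint_model("dna_adducts", model_id = "m4",
                       params = list(a = 2, b = 0.3, c = 6),
                       sigma = 0, biological_cv = 0)
  d <- generate_dataset(study_design(), em, seed = 1)
  expect_equal(d$records$response,
               exp_mean("m4", list(a = 2, b = 0.3, c = 6), d$records$dose),
               tolerance = 1e-12)
})

test_that("Poisson counts respect the law of large numbers: rate 1e-5 on a
           3e5 denominator averages about 3", {
  em <- endpoint_model("lacz_mf", model_id = "m1", params = list(a = 1),
                       denominator = 3e5) # 1 per 1e5 pfu = rate 1e-5
  des <- study_design(doses = c(0, 1, 2), n_per_dose = 400, n_control = 200)
  d <- generate_dataset(des, em, seed = 77)
  expect_identical(nrow(d$records), 1000L)
  expect_equal(mean(d$records$count), 3, tolerance = 0.1)
})

test_that("group geometric means converge to the generating curve", {
  em <- endpoint_model("dna_adducts", model_id = "m4",
                       params = list(a = 1, b = 0.4, c = 8),
                       sigma = 0.3, biological_cv = 0.2)
  des <- study_design(doses = c(0, 1, 5), n_per_dose = 5000, n_control = 5000)
  d <- generate_dataset(des, em, seed = 101)
  for (x in c(0, 1, 5)) {
    gm <- exp(mean(log(d$records$response[d$records$dose == x])))
    expect_equal(gm, exp_mean("m4", list(a = 1, b = 0.4, c = 8), x),
                 tolerance = 0.02)
  }
})

test_that("a binomial endpoint whose curve implies probability above one is
           rejected", {
  em <- endpoint_model("mn_ret", model_id = "m4",
                       params = list(a = 40, b = 0.5, c = 4)) # up to 160%
  expect_error(generate_dataset(study_design(), em, seed = 1),
               "probability > 1")
})

test_that("every preset generates valid datasets for seeds 1..10 and matches
           its anchors", {
  expect_identical(length(preset_names()), 19L)
  p <- bmd_preset("lacz_small_intestine")
  expect_equal(p$model$params$c, 208)
  expect_equal(exp_mean(p$model$model_id, p$model$params, p$true_bmd),
               2 * p$model$params$a, tolerance = 1e-10)
  p2 <- bmd_preset("mn_ret")
  expect_equal(p2$model$params$c, 4.5)
  expect_identical(p2$model$kind, "binomial_count")
  expect_error(bmd_preset("nope"), "unknown preset")

  for (pn in preset_names()) {
    for (s in 1:10) {
      d <- generate_preset(pn, seed = s)
      expect_s3_class(validate_dr_dataset(d), "dr_dataset")
    }
  }
})
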