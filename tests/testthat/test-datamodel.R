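test_that("a study-sized CSV reads into a validated dataset and a write/read
           round trip is lossless", {
  ds <- generate_preset("lacz_bone_marrow", seed = 3)
  expect_s3_class(ds, "dr_dataset")
  expect_identical(nrow(ds$records), 84L)
  expect_identical(length(unique(ds$records$dose)), 11L)
  expect_identical(sum(ds$records$dose == 0), 14L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_dr_csv(ds, path)
  back <- read_dr_csv(path)
  expect_identical(back$tissue, ds$tissue)
  expect_identical(back$endpoint, ds$endpoint)
  expect_identical(back$records$animal_id, ds$records$animal_id)
  expect_equal(back$records$dose, ds$records$dose, tolerance = 1e-12)
  expect_equal(back$records$count, ds$records$count, tolerance = 0)
  expect_equal(back$records$denominator, ds$records$denominator,
               tolerance = 1e-12)

  # continuous datasets round trip to full double precision
  ds2 <- generate_preset("adducts_liver", seed = 3)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dr_csv(ds2, path2)
  back2 <- read_dr_csv(path2)
  expect_equal(back2$records$response, ds2$records$response,
               tolerance = 1e-14)

  # several tissue x endpoint combinations in one file split into datasets
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_dr_csv(list(ds, generate_preset("lacz_spleen", seed = 4)), path3)
  both <- read_dr_csv(path3)
  expect_length(both, 2)
  expect_setequal(vapply(both, function(d) d$tissue, ""),
                  c("bone_marrow", "spleen"))
})

test_that("schema and validation errors name the problem and the rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("animal_id,foo\n1,2", path)
  expect_error(read_dr_csv(path, tissue = "liver", endpoint = "dna_adducts"),
               "schema error")

  base <- data.frame(animal_id = 1:6, dose = rep(c(0, 1, 2), 2))

  one_level <- data.frame(animal_id = 1:4, dose = 0, response = 1:4)
  expect_error(dr_dataset(one_level, "liver", "dna_adducts"),
               "3 distinct dose levels")

  bad_count <- base
  bad_count$count <- c(1, 2, 12, 0, 1, 2)
  bad_count$denominator <- 10
  expect_error(dr_dataset(bad_count, "bone_marrow", "lacz_mf"),
               "count exceeds denominator in rows: 3")

  neg_dose <- base
  neg_dose$dose[2] <- -1
  neg_dose$response <- 1
  expect_error(dr_dataset(neg_dose, "liver", "dna_adducts"),
               "negative or missing dose in rows: 2")

  nonpos <- base
  nonpos$response <- c(1, 0, 2, 3, 1, 2)
  expect_error(dr_dataset(nonpos, "liver", "dna_adducts"), "log-normal")

  no_ctrl <- data.frame(animal_id = 1:3, dose = c(1, 2, 3), response = 1:3)
  expect_error(dr_dataset(no_ctrl, "liver", "dna_adducts"), "dose 0")

  expect_error(dr_dataset(base, "liver", "weird_endpoint"),
               "unknown endpoint")
})

test_that("to_modelling_response converts counts to reporting units and
           applies the documented zero rules", {
  ds <- make_count_ds(dose = c(0, 0, 1, 1, 2, 2),
                      count = c(31, 5, 0, 8, 50, 60),
                      denominator = c(2.5e5, 2.5e5, 4e5, 4e5, 4e5, 4e5))
  y <- to_modelling_response(ds)
  expect_identical(nrow(y), 6L)            # half-minimum keeps every record
  expect_true(all(y$response > 0))
  expect_equal(y$response[1], 12.4)        # 31 / 2.5e5 pfu -> per 1e5 pfu
  # zero count -> half the smallest nonzero per-animal value (5/2.5e5 = 2.0)
  expect_equal(min(y$response), 1.0)

  # continuous responses pass through unchanged
  ds2 <- dr_dataset(data.frame(animal_id = 1:3, dose = c(0, 1, 2),
                               response = c(3.7, 5.1, 9.0)),
                    "liver", "dna_adducts")
  expect_equal(to_modelling_response(ds2)$response, c(3.7, 5.1, 9.0))

  # 'exclude' drops zero-count animals but refuses to empty a dose group
  y2 <- to_modelling_response(ds, zero_rule = "exclude")
  expect_identical(nrow(y2), 5L)
  ds3 <- make_count_ds(dose = c(0, 0, 1, 2), count = c(3, 2, 0, 5),
                       denominator = 1e5)
  expect_error(to_modelling_response(ds3, zero_rule = "exclude"),
               "half_minimum")
})
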