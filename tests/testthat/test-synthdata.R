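test_that("a simulated record has the acquisition geometry of the instrument", {
  env <- environment_config("storage")
  rec <- simulate_record("normal", env, seed = 3)
  expect_s3_class(rec, "enose_record")
  expect_identical(dim(rec$resistance), c(12L, 180L))
  expect_identical(dim(rec$preclean), c(12L, 60L))
  expect_true(all(rec$resistance > 0))
  expect_true(all(rec$preclean > 0))
  # determinism contract
  rec2 <- simulate_record("normal", env, seed = 3)
  expect_identical(rec, rec2)
  rec3 <- simulate_record("normal", env, seed = 4)
  expect_false(identical(rec$resistance, rec3$resistance))
})

test_that("noise-free laboratory records hit the anchored peak responses", {
  env <- environment_config("laboratory", noise_free = TRUE)
  profiles <- class_profiles("laboratory")
  for (cls in c("normal", "slight", "total")) {
    x <- baseline_correct(simulate_record(cls, env, seed = 1))$x
    expect_equal(max(x["S4", ]), profiles["S4", cls], tolerance = 0.01)
    expect_equal(max(x["S5", ]), profiles["S5", cls], tolerance = 0.01)
  }
  # storage anchor for the methane sensor
  env_s <- environment_config("storage", noise_free = TRUE)
  x <- baseline_correct(simulate_record("total", env_s, seed = 1))$x
  expect_equal(max(x["S8", ]), 3.03, tolerance = 0.01)
})

test_that("unit peak amplitudes give a flat unit response", {
  env <- environment_config("laboratory", noise_free = TRUE)
  flat <- matrix(1, 12, 3, dimnames = list(sensor_specs()$sensor_id,
                                           c("normal", "slight", "total")))
  x <- baseline_correct(simulate_record("slight", env, profiles = flat,
                                        seed = 1))$x
  expect_equal(max(abs(x - 1)), 0, tolerance = 1e-9)
})

test_that("noise-free peak responses increase strictly with rot degree", {
  env <- environment_config("laboratory", noise_free = TRUE)
  peaks <- sapply(c("normal", "slight", "total"), function(cls)
    apply(baseline_correct(simulate_record(cls, env, seed = 1))$x, 1, max))
  prof <- class_profiles("laboratory")
  increasing <- prof[, "normal"] < prof[, "slight"] &
    prof[, "slight"] < prof[, "total"]
  expect_true(all(peaks[increasing, "normal"] < peaks[increasing, "slight"]))
  expect_true(all(peaks[increasing, "slight"] < peaks[increasing, "total"]))
})

test_that("simulate_dataset returns balanced shuffled deterministic data", {
  env <- environment_config("laboratory")
  d1 <- simulate_dataset(1, env, seed = 5)
  expect_length(d1, 3L)
  expect_setequal(attr(d1, "labels"), c("normal", "slight", "total"))
  d5a <- simulate_dataset(5, env, seed = 9)
  d5b <- simulate_dataset(5, env, seed = 9)
  expect_length(d5a, 15L)
  expect_identical(table(attr(d5a, "labels")),
                   table(rep(c("normal", "slight", "total"), 5)))
  expect_identical(vapply(d5a, `[[`, "", "sample_id"),
                   vapply(d5b, `[[`, "", "sample_id"))
  expect_identical(d5a[[1]]$resistance, d5b[[1]]$resistance)
})

test_that("simulator rejects invalid inputs", {
  env <- environment_config("laboratory")
  expect_error(simulate_record("rotten", env), "unknown class label")
  expect_error(simulate_dataset(0, env), "n_per_class")
  expect_error(environment_config("laboratory", rise_tau = -1), "positive")
  bad <- class_profiles("laboratory"); bad[1, 1] <- 0.5
  expect_error(simulate_record("normal", env, profiles = bad), ">= 1")
})

test_that("storage mode widens inter-class feature-range overlap", {
  overlaps <- vapply(1:5, function(seed) {
    lab <- sim_feature_table("laboratory", 10, seed)
    sto <- sim_feature_table("storage", 10, seed)
    c(class_overlap_fraction(lab), class_overlap_fraction(sto))
  }, c(0, 0))
  expect_gt(mean(overlaps[2, ]), mean(overlaps[1, ]))
})
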