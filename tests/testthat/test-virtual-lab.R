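test_that("the design grid has 64 training, 8 cross-validation, 72 total points", {
  g <- design_grid(protocol("afh"))
  expect_identical(sum(g$tag == "training"), 64L)
  expect_identical(sum(g$tag == "cross_validation"), 8L)
  expect_identical(nrow(g), 72L)
  # training levels are the printed four, cross-validation the printed two
  expect_setequal(unique(g$F1[g$tag == "training"]),
                  c(1.25, 2.50, 3.75, 5.00))
  expect_setequal(unique(g$F2[g$tag == "cross_validation"]), c(1.9, 4.4))
})

test_that("protocol angles match the three experimental setups", {
  expect_equal(protocol("afh")$angles, c(-135, -90, -45))
  expect_equal(protocol("awr")$angles, c(-105, -90, -75))
  expect_equal(protocol("extensor")$angles, c(-115, -90, -75))
})

test_that("noise-free unquantized measurement equals the solver output", {
  target <- build_target_network("all_in_all")
  proto <- protocol("afh")
  rec <- measure(target, c(2.5, 1.25, 5.0), proto)
  sim <- simulate_loadset(target, c(2.5, 1.25, 5.0), proto$angles)
  expect_equal(as.numeric(rec[c("R1", "R2")]), sim$reactions)
  expect_equal(as.numeric(rec[c("d11", "d12", "d21", "d22", "d31", "d32")]),
               sim$distances)
})

test_that("quantization reports distances in whole millimetres and forces in dynamometer steps", {
  target <- build_target_network("all_in_all")
  proto <- protocol("afh", quantize = TRUE)
  rec <- measure(target, c(3.75, 2.5, 1.25), proto)
  d <- as.numeric(rec[c("d11", "d12", "d21", "d22", "d31", "d32")])
  expect_equal(d, round(d))
  R <- as.numeric(rec[c("R1", "R2")])
  expect_equal(R / proto$force_quantum, round(R / proto$force_quantum),
               tolerance = 1e-9)
})

test_that("noisy measurement is reproducible under a fixed seed", {
  target <- build_target_network("all_in_all")
  proto <- protocol("afh", noise_sd_force = 0.05, noise_sd_distance = 0.5,
                    quantize = TRUE)
  set.seed(99)
  r1 <- measure(target, c(2.5, 2.5, 2.5), proto)
  set.seed(99)
  r2 <- measure(target, c(2.5, 2.5, 2.5), proto)
  expect_identical(r1, r2)
})

test_that("the database is a pure function of target and protocol up to order", {
  target <- build_target_network("all_in_all")
  proto <- protocol("afh")
  set.seed(1); db1 <- build_database(target, proto)
  set.seed(1); db2 <- build_database(target, proto)
  expect_identical(db1$records, db2$records)
  set.seed(2); db3 <- build_database(target, proto)
  # same multiset of records, different order
  o1 <- db1$records[order(db1$records$set_id), ]
  o3 <- db3$records[order(db3$records$set_id), ]
  rownames(o1) <- rownames(o3) <- NULL
  expect_equal(o1, o3)
  expect_false(identical(db1$records$set_id, db3$records$set_id))
})

test_that("nearest-neighbor serving snaps to the training grid", {
  target <- build_target_network("all_in_all")
  set.seed(4)
  db <- build_database(target, protocol("afh"))
  hit <- nearest_available_test(c(1.3, 2.4, 5.0), db)
  expect_equal(as.numeric(hit$record[c("F1", "F2", "F3")]),
               c(1.25, 2.50, 5.00))
  # a request exactly on a grid point returns that point
  hit2 <- nearest_available_test(c(3.75, 3.75, 1.25), db)
  expect_equal(as.numeric(hit2$record[c("F1", "F2", "F3")]),
               c(3.75, 3.75, 1.25))
  # never a cross-validation record, even for a cv-grid request
  hit3 <- nearest_available_test(c(1.9, 1.9, 1.9), db)
  expect_identical(hit3$record$tag, "training")
  # equidistant tie resolves to the lexicographically smallest magnitudes
  mid <- c(1.875, 1.25, 1.25)     # halfway between F1 = 1.25 and 2.50
  hit4 <- nearest_available_test(mid, db)
  expect_equal(as.numeric(hit4$record[c("F1", "F2", "F3")]),
               c(1.25, 1.25, 1.25))
  hit5 <- nearest_available_test(mid, db)
  expect_identical(hit4$index, hit5$index)
})

test_that("seeding exposes one uniformly chosen training record", {
  target <- build_target_network("all_in_all")
  set.seed(8)
  db <- build_database(target, protocol("afh"))
  set.seed(21); s1 <- seed_database(db)
  set.seed(21); s2 <- seed_database(db)
  expect_identical(s1$exposed, s2$exposed)
  expect_identical(length(s1$exposed), 1L)
  expect_identical(db$records$tag[s1$exposed], "training")
  # uniformity over many draws: each of the 64 records within 3 sigma
  set.seed(1)
  draws <- replicate(10000, seed_database(db)$exposed)
  freq <- table(factor(draws, levels = which(db$records$tag == "training")))
  p <- 1 / 64
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(freq - 10000 * p) < 3.5 * sigma))
})

test_that("a model identical to the target scores within the quantization floor", {
  target <- build_target_network("all_in_all")
  set.seed(14)
  proto_q <- protocol("afh", quantize = TRUE)
  db_q <- build_database(target, proto_q)
  e_q <- training_error(target, db_q)$error
  # quantization of distances to 1 mm on ~100 mm scales: sub-percent error
  expect_lt(e_q, 1.5)
  expect_gt(e_q, 0)
  set.seed(14)
  db0 <- build_database(target, protocol("afh"))
  expect_lt(training_error(target, db0)$error, 1e-6)
})
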