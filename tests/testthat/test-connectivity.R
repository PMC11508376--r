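# The spatiotemporal kernel: scalar examples, truncation, invariants, and
# equivalence with a naive double-loop oracle.

trap0 <- data.frame(site_id = "t1", x_m = 0, y_m = 0, sampling_year = 2011)

test_that("parameter container enforces the optimization range", {
  p <- connectivity_params(1.7, 1.4)
  expect_s3_class(p, "connectivity_params")
  expect_equal(p$max_distance_km, 20)
  expect_error(connectivity_params(4.5, 1), "\\[0, 4\\]")
  expect_error(connectivity_params(1, -0.1), "\\[0, 4\\]")
  expect_silent(p2 <- connectivity_params(6, 1, allow_outside_range = TRUE))
  expect_equal(p2$alpha_s, 6)
})

test_that("distances are planar kilometres", {
  fires <- data.frame(x_m = c(3000, 0, 20000.001), y_m = c(4000, 0, 0))
  d <- pairwise_distance_km(trap0, fires)
  expect_equal(d[1, 1], 5)
  expect_equal(d[1, 2], 0)
  expect_gt(d[1, 3], 20)
  expect_error(pairwise_distance_km(trap0, data.frame(x_m = NA, y_m = 0)),
               "missing coordinates")
})

test_that("single- and two-fire sums match hand evaluation", {
  fire <- data.frame(fire_id = "f1", x_m = 2000, y_m = 0, area_m2 = 1e4,
                     year = 2010)
  res <- connectivity(trap0, fire, connectivity_params(1.7, 1.4))
  expect_equal(res$st_value, exp(-3.4) * log(1e4) * exp(-1.4),
               tolerance = 1e-12)
  expect_equal(res$n_contributing_fires, 1L)

  two <- data.frame(fire_id = c("f1", "f2"), x_m = c(5000, 15000), y_m = 0,
                    area_m2 = c(100, 1000), year = c(2010, 2005))
  res2 <- connectivity(trap0, two, connectivity_params(0, 0))
  expect_equal(res2$st_value, log(100) + log(1000), tolerance = 1e-12)
})

test_that("truncation is inclusive at the radius and total beyond it", {
  far <- data.frame(fire_id = "f", x_m = 25000, y_m = 0, area_m2 = 1e4,
                    year = 2010)
  res <- connectivity(trap0, far, connectivity_params(1, 1))
  expect_equal(res$st_value, 0)
  expect_equal(res$n_contributing_fires, 0L)

  at <- far; at$x_m <- 20000          # exactly on the boundary: contributes
  just_out <- far; just_out$x_m <- 20001
  expect_gt(connectivity(trap0, at, connectivity_params(1, 1))$st_value, 0)
  expect_equal(
    connectivity(trap0, just_out, connectivity_params(1, 1))$st_value, 0)
})

test_that("kernel guards its preconditions", {
  tiny <- data.frame(fire_id = "f", x_m = 0, y_m = 0, area_m2 = 0.5,
                     year = 2010)
  expect_error(connectivity(trap0, tiny, connectivity_params(1, 1)),
               "below 1 m2")
  late <- data.frame(fire_id = "f", x_m = 0, y_m = 0, area_m2 = 500,
                     year = 2011)
  expect_error(connectivity(trap0, late, connectivity_params(1, 1)),
               "prior to sampling")
  expect_warning(res <- connectivity(trap0, tiny[0, ],
                                     connectivity_params(1, 1)),
                 "empty fire register")
  expect_equal(res$st_value, 0)
})

test_that("weight curves are exponential decays anchored at 1", {
  expect_equal(weight_curve_spatial(0, c(0, 1, 7)), c(1, 1, 1))
  expect_equal(weight_curve_spatial(4, 2), exp(-8), tolerance = 1e-12)
  expect_equal(weight_curve_spatial(1.7, 0), 1)
  expect_equal(weight_curve_temporal(1.4, 3), exp(-4.2), tolerance = 1e-12)
  expect_equal(weight_curve_temporal(0, 0:12), rep(1, 13))
  expect_equal(weight_curve_temporal(1.4, 0), 1)
  w <- weight_curve_spatial(1.7, seq(0, 10, 0.5))
  expect_true(all(diff(w) < 0))
  expect_error(weight_curve_spatial(1, -1), "non-negative")
  expect_error(weight_curve_temporal(1, -1), "non-negative")
})

test_that("connectivity is additive over disjoint registers and monotone in the scales", {
  set.seed(21)
  traps <- random_traps(6)
  fires <- random_fires(40)
  p <- connectivity_params(1.2, 0.8)
  split <- fires[1:15, ]
  rest <- fires[16:40, ]
  expect_equal(connectivity(traps, fires, p)$st_value,
               connectivity(traps, split, p)$st_value +
                 connectivity(traps, rest, p)$st_value,
               tolerance = 1e-12)
  # adding one in-radius fire never decreases ST (areas >= 100 here)
  extra <- fires[1, ]
  extra$x_m <- traps$x_m[1] + 1000
  extra$y_m <- traps$y_m[1]
  expect_true(all(connectivity(traps, rbind(fires, extra), p)$st_value >=
                    connectivity(traps, fires, p)$st_value))
  # non-increasing in alpha_s and alpha_t
  for (a in c(0, 0.5, 2, 4)) {
    expect_true(all(
      connectivity(traps, fires, connectivity_params(a, 1))$st_value >=
        connectivity(traps, fires, connectivity_params(min(a + 1, 4), 1))$st_value))
    expect_true(all(
      connectivity(traps, fires, connectivity_params(1, a))$st_value >=
        connectivity(traps, fires, connectivity_params(1, min(a + 1, 4)))$st_value))
  }
})

test_that("vectorized kernel equals the naive double loop on random instances", {
  set.seed(31)
  for (rep in 1:5) {
    traps <- random_traps(sample(2:10, 1))
    fires <- random_fires(sample(5:100, 1))
    a_s <- runif(1, 0, 4)
    a_t <- runif(1, 0, 4)
    got <- connectivity(traps, fires,
                        connectivity_params(a_s, a_t))$st_value
    want <- naive_st(traps, fires, a_s, a_t)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the grid evaluator matches per-point connectivity, including mixed sampling years", {
  set.seed(41)
  traps <- random_traps(5)
  traps$sampling_year <- c(2011, 2011, 2012, 2011, 2012)
  fires <- random_fires(30)
  a_s <- c(0, 0.7, 2.1)
  a_t <- c(0.3, 1.4)
  st <- fireconn:::.st_grid(traps, fires, a_s, a_t)
  k <- 0
  for (i in seq_along(a_s)) {
    for (j in seq_along(a_t)) {
      k <- k + 1
      p <- connectivity_params(a_s[i], a_t[j])
      expect_equal(st[, k], connectivity(traps, fires, p)$st_value,
                   tolerance = 1e-12)
    }
  }
})
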