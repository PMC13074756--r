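# Evaluation statistics.

test_that("indirect_fraction is the defined ratio", {
  expect_equal(indirect_fraction(100, 100), 0)
  expect_equal(indirect_fraction(96, 100), 0.04)
  expect_equal(indirect_fraction(c(50, 0), c(100, 100)), c(0.5, 1))
  expect_error(indirect_fraction(1, 0), "positive")
  expect_error(indirect_fraction(-1, 10), "non-negative")
  # feeding the same run to both arguments is identically zero
  x <- runif(20)
  expect_equal(indirect_fraction(x, x), rep(0, 20))
})

test_that("mape matches hand arithmetic and a scalar oracle", {
  expect_equal(mape(tibble::tibble(phong = 1, diffuse = 1))$mape, 0)
  expect_equal(mape(tibble::tibble(phong = c(101, 99),
                                   diffuse = c(100, 100)))$mape, 1)
  set.seed(70)
  df <- tibble::tibble(g = rep(letters[1:3], each = 40),
                       phong = runif(120, 1, 2),
                       diffuse = runif(120, 1, 2))
  got <- mape(df, group_by = "g")
  for (gg in letters[1:3]) {
    sub <- df[df$g == gg, ]
    s <- 0
    for (i in seq_len(nrow(sub))) {
      s <- s + abs(sub$phong[i] - sub$diffuse[i]) / sub$diffuse[i]
    }
    expect_equal(got$mape[got$g == gg], 100 * s / nrow(sub),
                 tolerance = 1e-12)
  }
  # scale invariance and zero-denominator dropping
  expect_equal(mape(df |> dplyr::mutate(phong = phong * 7,
                                        diffuse = diffuse * 7))$mape,
               mape(df)$mape, tolerance = 1e-12)
  dz <- dplyr::bind_rows(df[1:10, ],
                         tibble::tibble(g = "a", phong = 1, diffuse = 0))
  expect_equal(mape(dz)$n_dropped, 1)
  expect_error(mape(df[0, ]), "empty")
})

test_that("band_fraction produces unit shares and drops empty records", {
  g <- spectral_grid()
  eq <- tibble::tibble(bin_center_nm = g$centers, value = 1)
  bf <- band_fraction(eq)
  expect_equal(bf$share, c(6, 10, 10, 4) / 30)
  set.seed(71)
  many <- tidyr::expand_grid(id = 1:50, bin_center_nm = g$centers) |>
    dplyr::mutate(value = runif(dplyr::n()))
  shares <- band_fraction(many, group_by = "id") |>
    dplyr::group_by(id) |>
    dplyr::summarise(s = sum(share))
  expect_equal(shares$s, rep(1, 50), tolerance = 1e-12)
  withz <- dplyr::bind_rows(many,
                            tidyr::expand_grid(id = 51L,
                                               bin_center_nm = g$centers) |>
                              dplyr::mutate(value = 0))
  out <- band_fraction(withz, group_by = "id")
  expect_false(51L %in% out$id)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_error(band_fraction(withz, group_by = "id", drop_zero = FALSE),
               "zero total")
})

test_that("quantiles use linear interpolation and order correctly", {
  expect_equal(tally_quantiles(1:5)[["Q50"]], 3)
  expect_equal(tally_quantiles(rep(4.2, 10)),
               c(Q25 = 4.2, Q50 = 4.2, Q90 = 4.2))
  set.seed(72)
  u <- runif(1e4)
  q <- tally_quantiles(u)
  expect_equal(q[["Q90"]], 0.9, tolerance = 0.02)
  expect_true(q[["Q25"]] <= q[["Q50"]] && q[["Q50"]] <= q[["Q90"]])
  expect_error(tally_quantiles(numeric(0)), "empty")
})

test_that("paired_t matches the closed-form textbook computation", {
  x <- c(12.1, 11.4, 13.2, 10.9, 12.8)
  y <- c(11.8, 11.0, 12.1, 11.2, 12.0)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  got <- paired_t(x, y)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero-variance")
  # consistent direction at tiny jitter
  set.seed(73)
  a <- rep(1, 40); b <- a - 1 + rnorm(40, 1, 1e-6)
  expect_lt(paired_t(a + 1, b)$p_value, 1e-4)
})

test_that("aggregate_metric equals an explicit groupwise loop", {
  set.seed(74)
  df <- tibble::tibble(plant = sample(1:9, 200, TRUE),
                       leaf_order = sample(1:5, 200, TRUE),
                       value = rnorm(200))
  got <- aggregate_metric(df, "leaf_order")
  for (k in 1:5) {
    v <- df$value[df$leaf_order == k]
    expect_equal(got$mean[got$leaf_order == k], mean(v), tolerance = 1e-12)
    expect_equal(got$se[got$leaf_order == k], sd(v) / sqrt(length(v)),
                 tolerance = 1e-12)
  }
  # constant grouping column: one row
  expect_equal(nrow(aggregate_metric(df |> dplyr::mutate(c = 1), "c")), 1)
  # central restriction equals the all-plant mean when all are central
  one <- aggregate_metric(df, "leaf_order", central_only = TRUE,
                          central = 1:9)
  expect_equal(one$mean, got$mean)
  expect_error(aggregate_metric(df, "nope"), "unknown dimension")
})

test_that("eta is invariant to rescaling the global irradiance", {
  set.seed(75)
  e_with <- runif(30, 1, 2)
  e_without <- e_with * runif(30, 0.9, 1)
  expect_equal(indirect_fraction(e_without * 3.7, e_with * 3.7),
               indirect_fraction(e_without, e_with), tolerance = 1e-12)
})

test_that("pair_tallies aligns runs record by record", {
  set.seed(76)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  fx <- fixture_optics()
  a <- trace(idx, one_scenario(0.5), fx$phong, n_rays = 2e4, seed = 3)
  b <- trace(idx, one_scenario(0.5), fx$diffuse, n_rays = 2e4, seed = 3)
  pr <- pair_tallies(a, b)
  expect_equal(nrow(pr), nrow(a$absorbed))
  expect_true(all(c("phong", "diffuse") %in% names(pr)))
})
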