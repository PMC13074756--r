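# Compiled tracer: indexing, traversal, radiometry, energy ledger.

test_that("build_index flattens and tags every triangle", {
  set.seed(60)
  sc <- assemble_canopy("grid3x3")
  idx <- build_index(sc)
  n_expected <- sum(vapply(sc$plants, function(p) {
    sum(vapply(p$architecture$leaves,
               function(l) nrow(l$mesh$faces), numeric(1))) +
      nrow(p$architecture$stem$faces)
  }, numeric(1)))
  expect_equal(nrow(idx$faces), n_expected)
  expect_equal(nrow(idx$tags), n_expected)
  expect_setequal(unique(idx$tags$plant), 1:9)
  sc_empty <- sc; sc_empty$plants <- list()
  expect_error(build_index(sc_empty), "empty")
})

test_that("BVH traversal equals brute-force intersection on random rays", {
  set.seed(61)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  n <- 1e4
  origins <- cbind(runif(n, -0.4, 0.4), runif(n, -0.4, 0.4),
                   runif(n, 0, 0.4))
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  bvh <- canopytrace:::intersect_rays_cpp(idx$vertices, idx$faces - 1L,
                                          origins, dirs, brute = FALSE)
  brute <- canopytrace:::intersect_rays_cpp(idx$vertices, idx$faces - 1L,
                                            origins, dirs, brute = TRUE)
  expect_identical(bvh$tri, brute$tri)
  expect_equal(bvh$t, brute$t, tolerance = 1e-12)
  expect_gt(sum(!is.na(bvh$tri)), 100)  # the ray set actually hits things
})

test_that("a horizontal unit leaf intercepts the closed-form flux", {
  idx <- slab_index(0.3)
  fx_kd <- 0.1; fx_tau <- 0.2
  op <- uniform_phong(fx_kd, 0, 1, fx_tau)
  a_b <- 1 - fx_kd - fx_tau  # absorptance, flat across bins
  w <- d65_photon_weights()

  tl <- trace(idx, one_scenario(1, alt = 90), op, n_rays = 4e5, seed = 7)
  got <- tl$absorbed$flux[tl$absorbed$leaf_order == 1]
  expected <- 1000 * w$weight * a_b
  # 3-sigma binomial band per bin from the tally's own ray weight
  w_ray <- sum(tl$ledger$emitted) / 4e5
  se <- sqrt(pmax(got, w_ray) * w_ray)
  expect_true(all(abs(got - expected) < 3 * se + 1e-9))
  expect_equal(sum(got), 1000 * a_b, tolerance = 0.01)

  # direct irradiance is specified on the horizontal plane (constant
  # global), so a horizontal leaf intercepts the same flux at any sun
  # altitude, while the normal-plane beam irradiance goes as 1/sin(alt)
  tl30 <- trace(idx, one_scenario(1, alt = 30), op, n_rays = 4e5, seed = 8)
  expect_equal(sum(tl30$absorbed$flux), 1000 * a_b, tolerance = 0.02)
  # sine law on a beam of fixed normal irradiance: the projected
  # interception of the horizontal leaf scales by sin(altitude)
  e_normal_30 <- 1000 / sin(30 * pi / 180)
  expect_equal(sum(tl30$absorbed$flux) / e_normal_30,
               a_b * sin(30 * pi / 180), tolerance = 0.02)
})

test_that("a fully shaded leaf gets nothing without scattering", {
  idx <- slab_index(c(0.3, 0.2), half = 0.5)
  op <- uniform_phong(0.2, 0, 1, 0.3)
  tl <- trace(idx, one_scenario(1, alt = 90), op, n_rays = 1e5,
              scattering = "none", seed = 9)
  tot <- total_by_leaf(tl)
  expect_gt(tot$flux[tot$leaf_order == 1], 0)
  expect_identical(tot$flux[tot$leaf_order == 2], 0)
  # with transmission active the lower leaf does absorb
  tl2 <- trace(idx, one_scenario(1, alt = 90), op, n_rays = 1e5,
               scattering = "no_reflection", seed = 9)
  tot2 <- total_by_leaf(tl2)
  expect_gt(tot2$flux[tot2$leaf_order == 2], 0)
})

test_that("sensors in an empty scene read the configured irradiance", {
  idx <- empty_index()
  op <- uniform_phong(0.1, 0, 1, 0)
  sens <- dplyr::bind_rows(horizontal_sensor(up = TRUE),
                           horizontal_sensor(up = FALSE)) |>
    dplyr::mutate(sensor_id = 1:2)
  # diffuse-only sky
  tl <- trace(idx, one_scenario(0), op, n_rays = 1e6, sensors = sens,
              seed = 10)
  up <- sum(tl$sensors$ppfd[tl$sensors$sensor_id == 1])
  expect_equal(up, 1000, tolerance = 0.02)
  # one-sidedness: down-facing sensor sees no downwelling light
  expect_identical(sum(tl$sensors$ppfd[tl$sensors$sensor_id == 2]), 0)
  # pure direct zenith sun
  tl2 <- trace(idx, one_scenario(1, alt = 90), op, n_rays = 2e5,
               sensors = sens, seed = 11)
  expect_equal(sum(tl2$sensors$ppfd[tl2$sensors$sensor_id == 1]), 1000,
               tolerance = 0.02)
  expect_identical(sum(tl2$sensors$ppfd[tl2$sensors$sensor_id == 2]), 0)
})

test_that("the per-bin energy ledger closes exactly in every mode", {
  set.seed(62)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  fx <- fixture_optics()
  for (mode in c("full", "single_reflection", "no_reflection", "none")) {
    tl <- trace(idx, one_scenario(0.5), fx$phong, n_rays = 1e5,
                scattering = mode, seed = 12)
    l <- tl$ledger
    gap <- abs(l$emitted - l$absorbed_leaf - l$absorbed_stem - l$ground -
                 l$escaped - l$truncated)
    expect_true(all(gap <= 1e-9 * pmax(l$emitted, 1e-300)))
  }
})

test_that("restricting scattering never increases absorbed flux", {
  set.seed(63)
  sc <- assemble_canopy("grid3x3")
  idx <- build_index(sc)
  fx <- fixture_optics()
  full <- trace(idx, one_scenario(0.7), fx$phong, n_rays = 5e5, seed = 13)
  single <- trace(idx, one_scenario(0.7), fx$phong, n_rays = 5e5, seed = 13,
                  scattering = "single_reflection")
  none <- trace(idx, one_scenario(0.7), fx$phong, n_rays = 5e5, seed = 13,
                scattering = "none")
  expect_lte(sum(none$absorbed$flux), sum(single$absorbed$flux))
  expect_lte(sum(single$absorbed$flux), sum(full$absorbed$flux))
  # per-leaf, allowing Monte-Carlo noise via common-random-number pairing
  d <- dplyr::inner_join(total_by_leaf(single), total_by_leaf(full),
                         by = c("plant", "leaf_order"),
                         suffix = c("_s", "_f"))
  d <- d[d$flux_f > 0, ]
  expect_true(all(d$flux_s <= d$flux_f * 1.02 + 1e-9))
})

test_that("Phong with ks = 0 is equivalent to its diffuse counterpart", {
  set.seed(64)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  kd <- 0.15; tau <- 0.15
  p <- trace(idx, one_scenario(0.6), uniform_phong(kd, 0, 1, tau),
             n_rays = 1e7, seed = 14)
  d <- trace(idx, one_scenario(0.6), uniform_diffuse(kd, tau),
             n_rays = 1e7, seed = 14)
  pr <- dplyr::inner_join(total_by_leaf(p), total_by_leaf(d),
                          by = c("plant", "leaf_order"),
                          suffix = c("_p", "_d"))
  m <- mape(dplyr::rename(pr, phong = flux_p, diffuse = flux_d))
  expect_lt(m$mape, 0.5)
})

test_that("replicate averaging behaves and converges like Monte Carlo", {
  set.seed(65)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  fx <- fixture_optics()
  s1 <- one_scenario(1, alt = 50)
  one <- run_replicates(idx, s1, fx$phong, n_reps = 1, seeds = 21,
                        n_rays = 5e4)
  lone <- trace(idx, s1, fx$phong, n_rays = 5e4, seed = 21)
  expect_equal(one$absorbed$flux, lone$absorbed$flux)

  r3 <- run_replicates(idx, s1, fx$phong, n_reps = 3, seeds = 22:24,
                       n_rays = 5e4)
  singles <- lapply(22:24, function(s) trace(idx, s1, fx$phong,
                                             n_rays = 5e4, seed = s))
  manual <- rowMeans(vapply(singles, function(x) x$absorbed$flux,
                            numeric(nrow(r3$absorbed))))
  expect_equal(r3$absorbed$flux, manual, tolerance = 1e-12)
  expect_true(all(r3$absorbed$se >= 0))

  # SE shrinks like 1/sqrt(n_rays): factor 2 between 1e5 and 4e5 rays
  se_at <- function(n_rays, seeds) {
    r <- run_replicates(idx, s1, fx$phong, n_reps = length(seeds),
                        seeds = seeds, n_rays = n_rays)
    tot <- r$absorbed |>
      dplyr::group_by(plant, leaf_order) |>
      dplyr::summarise(se = sqrt(sum(se^2)), f = sum(flux),
                       .groups = "drop")
    mean(tot$se[tot$f > 0])
  }
  ratio <- se_at(1e5, 31:38) / se_at(4e5, 41:48)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("tracing is deterministic for a fixed seed", {
  set.seed(66)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  fx <- fixture_optics()
  sens <- sensor_nodes(sc)
  a <- trace(idx, one_scenario(0.5), fx$phong, n_rays = 1e5, sensors = sens,
             seed = 99)
  b <- trace(idx, one_scenario(0.5), fx$phong, n_rays = 1e5, sensors = sens,
             seed = 99)
  expect_identical(a$absorbed$flux, b$absorbed$flux)
  expect_identical(a$sensors$ppfd, b$sensors$ppfd)
  c_ <- trace(idx, one_scenario(0.5), fx$phong, n_rays = 1e5,
              sensors = sens, seed = 100)
  expect_false(identical(a$absorbed$flux, c_$absorbed$flux))
})

test_that("tally results serialize to the long CSV layout", {
  set.seed(67)
  sc <- assemble_canopy("single")
  idx <- build_index(sc)
  fx <- fixture_optics()
  tl <- trace(idx, one_scenario(0.5), fx$phong, n_rays = 1e4 + 1,
              sensors = sensor_nodes(sc), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tally_csv(tl, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_setequal(unique(back$quantity), c("absorbed_flux", "sensor_ppfd"))
  expect_equal(nrow(back), nrow(tl$absorbed) + nrow(tl$sensors))
})
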