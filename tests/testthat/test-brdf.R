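# Modified-Phong BRDF: evaluation, integrals, sampling.

test_that("phong_eval reproduces closed-form cases", {
  wi <- dir_from_angles(35, 10)
  wo <- dir_from_angles(50, 200)
  expect_equal(phong_eval(0.3, 0, 10, wi, wo), 0.3 / pi, tolerance = 1e-12)

  # perfect mirror alignment: cos(alpha) = 1
  wi <- dir_from_angles(40, 180)
  wo <- dir_from_angles(40, 0)
  expect_equal(phong_eval(0, 0.2, 10, wi, wo), 0.2 * 12 / (2 * pi),
               tolerance = 1e-12)

  # independent scalar evaluation of the formula for an oblique case
  th_i <- 40; th_r <- 20
  cos_a <- sin(th_r * pi / 180) * sin(th_i * pi / 180) +
    cos(th_r * pi / 180) * cos(th_i * pi / 180)
  oracle <- 0.1 / pi + 0.1 * 6 / (2 * pi) * cos_a^4
  got <- phong_eval(0.1, 0.1, 4, dir_from_angles(th_i, 180),
                    dir_from_angles(th_r, 0))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(phong_eval(0.1, 0, 1, c(0, 0, -1), c(0, 0, 1)), "hemisphere")
})

test_that("phong_eval is reciprocal for random direction pairs", {
  set.seed(11)
  for (k in 1:1000) {
    wi <- dir_from_angles(runif(1, 0, 89), runif(1, 0, 360))
    wo <- dir_from_angles(runif(1, 0, 89), runif(1, 0, 360))
    expect_equal(phong_eval(0.07, 0.05, 12, wi, wo),
                 phong_eval(0.07, 0.05, 12, wo, wi), tolerance = 1e-14)
  }
})

test_that("radiant intensity peak shifts towards the normal", {
  # pure Lambertian: intensity maximal at the normal
  p0 <- radiant_intensity_profile(0.3, 0, 1, 40)
  expect_equal(p0$theta_r_deg[which.max(p0$intensity)], 0)

  # near-mirror limit: peak approaches the incidence angle
  p_inf <- radiant_intensity_profile(0.001, 0.3, 5000, 40,
                                     theta_r_deg = seq(0, 90, by = 0.1))
  expect_equal(p_inf$theta_r_deg[which.max(p_inf$intensity)], 40,
               tolerance = 0.05)

  # balanced case: dense grid-search argmax strictly inside (0, 40)
  p <- radiant_intensity_profile(0.1, 0.1, 10, 40,
                                 theta_r_deg = seq(-90, 90, by = 0.05))
  peak <- p$theta_r_deg[which.max(p$intensity)]
  expect_gt(peak, 0)
  expect_lt(peak, 40)
})

test_that("dhr matches Lambertian closure and normal-incidence lobe albedo", {
  lam <- phong_optics(tibble::tibble(bin_center_nm = 555, side = "adaxial",
                                     kd = 0.3, ks = 0, n_exp = 1, tau = 0))
  expect_equal(dhr(lam, c(0, 30, 60, 85))$dhr, rep(0.3, 4),
               tolerance = 1e-12)

  op <- phong_optics(tibble::tibble(bin_center_nm = 555, side = "adaxial",
                                    kd = 0.2, ks = 0.1, n_exp = 50,
                                    tau = 0))
  expect_equal(dhr(op, 0)$dhr, 0.3, tolerance = 1e-3)
  expect_error(dhr(op, 40, n_gl = 4), "order too low")
})

test_that("oblique dhr agrees with a Monte-Carlo integration oracle", {
  # kd = 0, ks = 0.3, n = 5 at 70 degrees: part of the lobe is clipped
  op <- phong_optics(tibble::tibble(bin_center_nm = 555, side = "adaxial",
                                    kd = 0, ks = 0.3, n_exp = 5, tau = 0),
                     check = FALSE)
  got <- dhr(op, 70)$dhr
  expect_lt(got, 0.3)

  # MC: sample the bare cos^n lobe around the mirror axis, weight by the
  # outgoing cosine (independent estimator of the same integral)
  set.seed(21)
  n <- 5; ti <- 70 * pi / 180; N <- 4e5
  ca <- runif(N)^(1 / (n + 1)); sa <- sqrt(1 - ca^2); ph <- 2 * pi * runif(N)
  dz <- ca * cos(ti) - sa * cos(ph) * sin(ti)
  vals <- (n + 2) / (n + 1) * pmax(0, dz)
  mc <- 0.3 * mean(vals)
  se <- 0.3 * sd(vals) / sqrt(N)
  expect_lt(abs(got - mc), 3 * se)
})

test_that("energy closure holds for random valid optics", {
  set.seed(31)
  for (k in 1:15) {
    tau <- runif(1, 0, 0.4)
    rho <- runif(1, 0, 0.9 - tau)
    n <- exp(runif(1, log(0.5), log(300)))
    a40 <- lobe_albedo(n, 40)
    # DHR peaks at normal incidence (kd + ks); bound ks so closure holds
    ks <- runif(1) * min(rho / a40, (1 - tau - rho) / max(1 - a40, 1e-9))
    kd <- rho - ks * a40
    op <- phong_optics(tibble::tibble(bin_center_nm = 555, side = "adaxial",
                                      kd = kd, ks = ks, n_exp = n,
                                      tau = tau))
    d <- dhr(op, seq(0, 85, by = 5))
    expect_true(all(d$dhr + tau <= 1 + 0.06))
    expect_true(all((d$dhr + tau)[d$theta_i_deg <= 40] <= 1 + 0.01))
  }
})

test_that("diffuse_equivalent anchors rho at DHR(40) and round-trips", {
  op <- phong_optics(tibble::tibble(
    bin_center_nm = c(445, 555), side = "adaxial",
    kd = c(0.05, 0.2), ks = c(0.04, 0), n_exp = c(8, 1),
    tau = c(0.05, 0.1)))
  de <- diffuse_equivalent(op)
  expect_equal(de$rho, dhr(op, 40)$dhr, tolerance = 1e-12)
  expect_equal(de$tau, op$tau)
  # ks = 0 row: rho equals kd exactly
  expect_equal(de$rho[2], 0.2, tolerance = 1e-9)
  # promoting a diffuse table to Phong (ks = 0) and back is the identity
  back <- diffuse_equivalent(phong_optics(
    de |> dplyr::mutate(kd = rho, ks = 0, n_exp = 1) |>
      dplyr::select(bin_center_nm, side, kd, ks, n_exp, tau)))
  expect_equal(back$rho, de$rho, tolerance = 1e-9)
})

test_that("sample_interaction events have the advertised distribution", {
  # all-absorbing surface
  op0 <- uniform_phong(0, 0, 1, 0)
  set.seed(41)
  evs <- replicate(50, sample_interaction(op0, 445, "adaxial",
                                          dir_from_angles(30))$event)
  expect_true(all(evs == "absorb"))

  # cosine-weighted reflection: mean outgoing cosine = 2/3
  opd <- uniform_diffuse(1, 0)
  set.seed(42)
  cz <- replicate(2e4, sample_interaction(opd, 445, "adaxial",
                                          dir_from_angles(40))$wo[3])
  expect_lt(abs(mean(cz) - 2 / 3), 3 * sd(cz) / sqrt(length(cz)))

  # event frequencies at 40 degrees match (kd, ks*A, tau, remainder)
  kd <- 0.05; ks <- 0.04; n <- 8; tau <- 0.2
  op <- uniform_phong(kd, ks, n, tau)
  p_expect <- c(diffuse = kd, specular = ks * lobe_albedo(n, 40),
                transmit = tau)
  p_expect <- c(p_expect, absorb = 1 - sum(p_expect))
  set.seed(43)
  N <- 2e4
  evs <- replicate(N, sample_interaction(op, 445, "adaxial",
                                         dir_from_angles(40))$event)
  for (e in names(p_expect)) {
    phat <- mean(evs == e)
    se <- sqrt(p_expect[[e]] * (1 - p_expect[[e]]) / N)
    expect_lt(abs(phat - p_expect[[e]]), 3 * se + 1e-9)
  }
  # transmitted directions exit the opposite hemisphere
  set.seed(44)
  repeat {
    s <- sample_interaction(op, 445, "adaxial", dir_from_angles(40))
    if (s$event == "transmit") break
  }
  expect_lt(s$wo[3], 0)
})
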