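FLAT_SYMMETRIC <- list(n330 = c(1, 0), u330 = c(1, 0),
                       n350 = c(0.70, 0), u350 = c(0.95, 0))

test_that("the two-state model is half unfolded exactly at Tm", {
  expect_equal(unfolded_fraction(67.8, tm = 67.8), 0.5)
  expect_equal(unfolded_fraction(70, tm = 70, dH_kJ = 800), 0.5)
  expect_lt(unfolded_fraction(60, tm = 70), 0.02)
  expect_gt(unfolded_fraction(80, tm = 70), 0.97)
})

test_that("a steeper enthalpy gives a strictly higher derivative peak", {
  peak <- vapply(c(200, 400, 800), function(dh) {
    m <- simulate_melt_curve(70, dH_kJ = dh, baselines = FLAT_SYMMETRIC)
    r <- m$f350 / m$f330
    max(diff(r) / diff(m$temperature_C))
  }, numeric(1))
  expect_true(all(diff(peak) > 0))
})

test_that("noise-free melt curves are reproducible regardless of seed", {
  a <- simulate_melt_curve(67.8, seed = 1)
  b <- simulate_melt_curve(67.8, seed = 999)
  expect_identical(a$f330, b$f330)
  expect_identical(a$f350, b$f350)
})

test_that("a symmetric transition is located within the 0.1 C grid resolution", {
  m <- simulate_melt_curve(70, baselines = FLAT_SYMMETRIC)
  tm <- tm_from_first_derivative(m)
  expect_lt(abs(tm$mean_tm - 70), 0.1)
})

test_that("triplicate extraction recovers a 67.8 C midpoint within 0.2 C at 0.2% noise", {
  reps <- lapply(1:3, function(i) {
    simulate_melt_curve(67.8, dH_kJ = 400, noise = 0.002, seed = 50 + i,
                        replicate = i)
  })
  res <- tm_from_first_derivative(reps)
  expect_length(res$tm, 3L)
  expect_lt(abs(res$mean_tm - 67.8), 0.2)
  expect_gte(res$sd_tm, 0)
  expect_true(all(res$tm > 25 & res$tm < 95))
})

test_that("degenerate melt curves raise extraction errors", {
  flat <- simulate_melt_curve(70, baselines = list(
    n330 = c(1, 0), u330 = c(1, 0), n350 = c(0.7, 0), u350 = c(0.7, 0)))
  expect_error(tm_from_first_derivative(flat),
               class = "ablineage_extraction_error")
  short <- simulate_melt_curve(70, step = 2)
  expect_error(tm_from_first_derivative(short),
               class = "ablineage_usage_error")
  expect_error(simulate_melt_curve(20), class = "ablineage_domain_error")
})

test_that("Tm extraction is equivariant under rescaling of both channels", {
  m <- simulate_melt_curve(67.8, noise = 0.002, seed = 3)
  tm1 <- tm_from_first_derivative(m)$mean_tm
  m$f330 <- 7.3 * m$f330
  m$f350 <- 0.41 * m$f350
  expect_equal(tm_from_first_derivative(m)$mean_tm, tm1, tolerance = 1e-10)
})

test_that("the taylorgram variance matches the hand-computed Taylor-Aris value", {
  # independent computation for Rh = 6.52 nm at 25 C in water
  eta <- 0.00089; TK <- 298.15; rc <- 37.5e-6; t_r <- 200
  D <- 1.380649e-23 * TK / (6 * pi * eta * 6.52e-9)
  s2_expected <- rc^2 * t_r / (24 * D)
  tg <- simulate_taylorgram(6.52, temperature_C = 25, viscosity = eta,
                            rc = rc, t_r = t_r)
  y <- tg$data$signal; t <- tg$data$time_s
  s2_empirical <- sum((t - sum(t * y) / sum(y))^2 * y) / sum(y)
  expect_equal(s2_empirical, s2_expected, tolerance = 0.01)
})

test_that("the radius round-trips through the dispersion model within 1% noise-free", {
  for (rh in c(1, 5, 6.52, 10, 20)) {
    tg <- simulate_taylorgram(rh, seed = 1)
    got <- rh_from_taylorgram(tg)
    expect_equal(got$n_species, 1L)
    expect_lt(abs(got$rh / rh - 1), 0.01)
  }
})

test_that("realistic noise keeps radius recovery within 2% and 0.05 nm at IgG size", {
  for (s in 1:3) {
    got <- rh_from_taylorgram(simulate_taylorgram(6.52, noise = 0.002,
                                                  seed = 60 + s))
    expect_lt(abs(got$rh / 6.52 - 1), 0.02)
    expect_lt(abs(got$rh - 6.52), 0.05)
  }
})

test_that("the radius is temperature-invariant between 25 C and 37 C runs", {
  r25 <- rh_from_taylorgram(simulate_taylorgram(6.52, temperature_C = 25,
                                                noise = 0.002, seed = 70))
  r37 <- rh_from_taylorgram(simulate_taylorgram(6.52, temperature_C = 37,
                                                noise = 0.002, seed = 71))
  expect_equal(r25$rh, r37$rh, tolerance = 0.01)
})

test_that("a two-species mixture selects the dual model and flags dispersity", {
  got <- rh_from_taylorgram(simulate_taylorgram(c(5.5, 9),
                                                fractions = c(0.8, 0.2),
                                                noise = 0.001, seed = 72))
  expect_equal(got$n_species, 2L)
  expect_true(got$dispersity)
  expect_length(got$rh_species, 2L)
  # dominant species listed first and smaller than the minor one here
  expect_lt(got$rh_species[1], got$rh_species[2])
})

test_that("water viscosity defaults reproduce the two run temperatures", {
  expect_equal(viscosity_water(25), 0.00089, tolerance = 0.005)
  expect_equal(viscosity_water(37), 0.000692, tolerance = 0.005)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration on random small groups", {
  set.seed(7)
  for (k in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    a <- round(stats::rnorm(na), 2)
    b <- round(stats::rnorm(nb, 0.5), 2)
    res <- mann_whitney_exact(a, b)
    expect_equal(res$p, mw_bruteforce_p(a, b), tolerance = 1e-12)
    expect_equal(res$U + res$U_other, na * nb)
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on untied samples", {
  set.seed(8)
  for (k in 1:10) {
    a <- stats::rnorm(5); b <- stats::rnorm(6, 1)
    res <- mann_whitney_exact(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$U, unname(ref$statistic))
  }
})

test_that("Mann-Whitney handles the canonical small cases", {
  res <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney_exact(numeric(0), 1),
               class = "ablineage_usage_error")
})

test_that("the reported 25 C radius groups give U = 33 and exact p = 8/792", {
  res <- mann_whitney_exact(RH25_T40, RH25_N40)
  expect_equal(res$U, 33)
  expect_equal(res$p, 8 / 792)
})

test_that("group summaries reproduce the reported residue-40 radius means and SDs", {
  vals <- c(RH25_N40, RH25_T40)
  grp <- c(rep("N40", 5), rep("T40", 7))
  gs <- group_summary(vals, grp)
  expect_equal(gs$mean[gs$group == "N40"], 6.16)
  expect_equal(gs$sd[gs$group == "N40"], 0.13)
  expect_equal(gs$mean[gs$group == "T40"], 6.46)
  expect_equal(gs$sd[gs$group == "T40"], 0.15)
  expect_equal(group_summary(c(5, 5, 5), rep("x", 3))[, c("mean", "sd")],
               data.frame(mean = 5, sd = 0), ignore_attr = TRUE)
  expect_error(group_summary(1:3, c("a", "b", "b")),
               class = "ablineage_usage_error")
})
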