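test_that("VPD follows the Magnus formula and its boundary behaviour", {
  expect_equal(vpd_from_t_rh(25, 100), 0)
  expect_equal(vpd_from_t_rh(25, 50), 1.584, tolerance = 1e-3)
  expect_equal(vpd_from_t_rh(0, 50), 0.3054, tolerance = 1e-3)
  # strictly decreasing in RH at fixed T, never negative
  rh <- seq(10, 100, by = 5)
  v <- vpd_from_t_rh(20, rh)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0))
  expect_error(vpd_from_t_rh(20, 0), "0, 100")
  expect_error(vpd_from_t_rh(20, 101), "0, 100")
})

test_that("Thornthwaite PET matches an independent textbook implementation", {
  clim <- make_climate(30, seed = 7)
  pet <- pet_thornthwaite(clim, latitude = 42)
  ref <- brute_thornthwaite(clim$tmean_c, clim$month, 42)
  expect_equal(pet, ref, tolerance = 1e-9)

  # all-freezing record evaporates nothing
  cold <- clim
  cold$tmean_c <- cold$tmean_c - 60
  expect_true(all(pet_thornthwaite(cold, 42) == 0))

  # equatorial constant temperature: equal PET across equal-length months
  eq <- clim
  eq$tmean_c <- 20
  pet_eq <- pet_thornthwaite(eq, 0)
  m30 <- pet_eq[eq$month %in% c(4, 6, 9, 11)]
  expect_lt(diff(range(m30)), 1e-9)

  expect_error(pet_thornthwaite(clim, 80), "66")
})

test_that("SPEI standardizes the climatic balance to N(0,1) per calendar month", {
  clim <- make_climate(200, seed = 11)
  s <- spei(clim, 1)
  v <- s$spei1
  ok <- !is.na(v)
  monthly_means <- tapply(v[ok], s$month[ok], mean)
  expect_lt(max(abs(monthly_means)), 0.05)
  expect_lt(abs(mean(v[ok] < -1) - pnorm(-1)), 0.03)

  # first k-1 months undefined at scale 12
  s12 <- spei(clim, 12)
  expect_true(all(is.na(s12$spei12[1:11])))
  expect_false(anyNA(s12$spei12[-(1:11)]))
})

test_that("SPEI is invariant to uniform location and unit changes of precipitation", {
  clim <- make_climate(120, seed = 3)
  base <- spei(clim, 1)$spei1
  shifted <- clim
  shifted$prcp_mm <- shifted$prcp_mm + 40
  s2 <- spei(shifted, 1)$spei1
  ok <- !is.na(base) & !is.na(s2)
  expect_lt(max(abs(base[ok] - s2[ok])), 0.02)

  # mm -> cm rescaling of the whole balance (P and PET together)
  clim_pet <- clim
  clim_pet$pet_mm <- pet_thornthwaite(clim, 42)
  cm <- clim_pet
  cm$prcp_mm <- cm$prcp_mm / 10
  cm$pet_mm <- cm$pet_mm / 10
  s3 <- spei(cm, 1)$spei1
  s1 <- spei(clim_pet, 1)$spei1
  ok <- !is.na(s1) & !is.na(s3)
  expect_lt(max(abs(s1[ok] - s3[ok])), 0.02)
})

test_that("degenerate calendar months are flagged undefined rather than standardized", {
  clim <- make_climate(40, seed = 5)
  clim$pet_mm <- 0
  clim$prcp_mm[clim$month == 6] <- 50  # constant balance every June
  s <- spei(clim, 1)
  expect_true(all(is.na(s$spei1[s$month == 6])))
  expect_false(anyNA(s$spei1[s$month != 6]))
})

test_that("growing-season SPEI uses exactly the April-October window of each year", {
  clim <- make_climate(60, seed = 9)
  gs <- growing_season_spei(clim, 42)
  expect_equal(nrow(gs), 60)
  expect_lt(abs(mean(gs$spei_gs)), 0.2)

  # perturbing a November leaves that year's value unchanged
  pert <- clim
  pert$prcp_mm[pert$year == 1930 & pert$month == 11] <- 500
  gs2 <- growing_season_spei(pert, 42)
  expect_equal(gs2$spei_gs[gs2$year == 1930], gs$spei_gs[gs$year == 1930],
               tolerance = 1e-12)
  # but an August perturbation does change it
  pert2 <- clim
  pert2$prcp_mm[pert2$year == 1930 & pert2$month == 8] <- 500
  gs3 <- growing_season_spei(pert2, 42)
  expect_false(isTRUE(all.equal(gs3$spei_gs[gs3$year == 1930],
                                gs$spei_gs[gs$year == 1930])))
})

test_that("Mann-Kendall statistic, antisymmetry and degenerate input", {
  mk <- mann_kendall(1:10)
  expect_equal(mk$s, 45)   # maximal n(n-1)/2
  expect_lt(mk$p, 0.05)
  expect_equal(mk$direction, "increasing")

  set.seed(4)
  x <- rnorm(25)
  expect_equal(mann_kendall(rev(x))$s, -mann_kendall(x)$s)

  flat <- mann_kendall(rep(3, 12))
  expect_equal(flat$s, 0)
  expect_equal(flat$p, 1)
})

test_that("Mann-Kendall p-values are uniform under the null", {
  set.seed(21)
  p <- replicate(1000, mann_kendall(rnorm(30))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("double-mass screen finds level shifts and respects its threshold", {
  set.seed(8)
  ref <- rgamma(40, 5, 0.1)
  prop <- 1.3 * ref + rnorm(40, 0, 0.5)
  dm <- double_mass(prop, ref)
  expect_false(dm$inhomogeneous)

  shifted <- ref
  shifted[21:40] <- 1.5 * shifted[21:40]
  dm2 <- double_mass(shifted, ref)
  expect_true(dm2$inhomogeneous)
  expect_lte(abs(dm2$break_index - 20), 2)

  expect_false(double_mass(shifted, ref, threshold = 1.0)$inhomogeneous)
  expect_error(double_mass(ref, rep(0, 40)), "zero")
})
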