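test_that("BAI conversion reproduces annulus areas and closure", {
  r <- data.frame(core_id = "a", tree_id = "t1", year = 2000:2001,
                  width_mm = c(10, 10))
  b <- bai_from_rings(r)
  expect_equal(b$bai_cm2, c(pi, 3 * pi))

  # two identical cores average to the single-core answer
  r2 <- rbind(r, transform(r, core_id = "b"))
  expect_equal(bai_from_rings(r2)$bai_cm2, b$bai_cm2)

  # random series against the brute-force annulus oracle
  set.seed(13)
  for (k in 1:20) {
    w <- runif(sample(5:60, 1), 0.1, 6)
    rr <- data.frame(core_id = "c", tree_id = "t", year = seq_along(w) + 1950,
                     width_mm = w)
    expect_equal(bai_from_rings(rr)$bai_cm2, brute_bai(w), tolerance = 1e-12)
    # closure: total area equals pi r_final^2
    expect_equal(sum(bai_from_rings(rr)$bai_cm2), pi * sum(w)^2 / 100,
                 tolerance = 1e-9)
  }

  bad <- data.frame(core_id = c("a", "b"), tree_id = "t",
                    year = c(2000, 2010), width_mm = 1)
  expect_error(bai_from_rings(bad), "non-overlapping")
})

test_that("RCS detrending is a ratio index: constants give 1, scaling cancels", {
  yrs <- 1970:2009
  rings <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(core_id = paste0("c", i), tree_id = paste0("t", i),
               year = yrs, width_mm = 2)
  }))
  idx <- rcs_detrend(rings, planting_year = 1970)
  expect_equal(idx$index, rep(1, nrow(idx)), tolerance = 1e-9)

  set.seed(2)
  rings$width_mm <- rep(3.5 * exp(-(1:40) / 12) + 0.5, 6) * exp(rnorm(240, 0, 0.2))
  i1 <- rcs_detrend(rings, 1970)
  doubled <- rings
  doubled$width_mm <- 2 * doubled$width_mm
  i2 <- rcs_detrend(doubled, 1970)
  expect_equal(i1$index, i2$index, tolerance = 1e-12)
})

test_that("RCS removes the negative-exponential age trend", {
  set.seed(31)
  ok <- 0
  for (rep in 1:10) {
    yrs <- 1960:2009
    rings <- do.call(rbind, lapply(1:12, function(i) {
      data.frame(core_id = paste0("c", i), tree_id = paste0("t", i), year = yrs,
                 width_mm = (4 * exp(-(1:50) / 15) + 0.6) * exp(rnorm(50, 0, 0.3)))
    }))
    idx <- rcs_detrend(rings, 1960)
    mean_by_age <- tapply(idx$index, idx$age, mean)
    if (mann_kendall(as.numeric(mean_by_age))$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("AR prewhitening selects sensible orders and whitens persistence", {
  set.seed(41)
  # white noise stays (order 0) most of the time
  kept <- sum(replicate(100, {
    x <- rnorm(80, 1, 0.2)
    identical(ar_prewhiten(x), x)
  }))
  # AIC keeps a known ~25 percent null overfit rate per candidate order,
  # so white noise stays untouched in roughly three quarters of series
  expect_gte(kept, 65)

  # an AR(1) with phi = 0.7 loses its lag-1 autocorrelation
  rho1 <- replicate(50, {
    x <- as.numeric(arima.sim(list(ar = 0.7), 120)) + 1
    r <- ar_prewhiten(x)
    r <- r[!is.na(r)]
    cor(r[-1], r[-length(r)])
  })
  expect_lt(median(abs(rho1)), 0.1)

  expect_equal(ar_prewhiten(rep(1, 30)), rep(1, 30))
})

test_that("chronology statistics obey the Wigley identities", {
  expect_equal(wigley_eps(20, 0.2), 0.8333, tolerance = 1e-4)
  expect_equal(wigley_snr(20, 0.2), 5.0)
  expect_equal(eps_from_snr(snr_from_eps(0.93)), 0.93, tolerance = 1e-12)

  # identical cores: rbar = 1, eps = 1
  yrs <- 1980:2019
  set.seed(6)
  w <- exp(rnorm(40, 0, 0.2))
  idx <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(core_id = paste0("c", i), year = yrs, index = w)
  }))
  ch <- build_chronology(idx)
  expect_equal(ch$rbar, 1)
  expect_equal(ch$eps, 1)

  # noisy cores: eps = snr/(1+snr) to numerical precision
  idx$index <- idx$index * exp(rnorm(200, 0, 0.3))
  ch2 <- build_chronology(idx)
  expect_equal(ch2$eps, ch2$snr / (1 + ch2$snr), tolerance = 1e-12)
  expect_equal(ch2$data$depth, rep(5L, 40), ignore_attr = TRUE)
})

test_that("chronology is invariant to scaling the input widths", {
  sim <- simulate_stand(sim_config(density = 300, n_years = 30, seed = 8))
  build <- function(rings) {
    idx <- rcs_detrend(rings, planting_year = 1975)
    for (id in unique(idx$core_id)) {
      sel <- idx$core_id == id
      idx$index[sel] <- ar_prewhiten(idx$index[sel])
    }
    build_chronology(idx[!is.na(idx$index), ])
  }
  ch1 <- build(sim$rings)
  scaled <- sim$rings
  scaled$width_mm <- scaled$width_mm * 3
  ch2 <- build(scaled)
  expect_equal(ch1$data$index, ch2$data$index, tolerance = 1e-10)
  expect_equal(ch1$rbar, ch2$rbar, tolerance = 1e-10)
})

test_that("same-time-span filter keeps cores covering the common period", {
  rings <- rbind(
    data.frame(core_id = "a", tree_id = "a", year = 1970:2009, width_mm = 1),
    data.frame(core_id = "b", tree_id = "b", year = 1970:2009, width_mm = 1),
    data.frame(core_id = "c", tree_id = "c", year = 1971:2009, width_mm = 1),
    data.frame(core_id = "d", tree_id = "d", year = 1995:2009, width_mm = 1)
  )
  kept <- unique(common_span_filter(rings)$core_id)
  expect_true(all(c("a", "b", "c") %in% kept))
  expect_false("d" %in% kept)
})

test_that("Tucson rwl files round-trip exactly at 0.01 mm precision", {
  set.seed(19)
  rings <- do.call(rbind, lapply(1:4, function(i) {
    first <- sample(1951:1997, 1)  # exercise ragged decade starts
    n <- sample(15:40, 1)
    data.frame(core_id = paste0("CORE", i), year = first:(first + n - 1),
               width_mm = round(runif(n, 0.1, 6), 2))
  }))
  path <- tempfile(fileext = ".rwl")
  write_rwl(rings, path)
  back <- read_rwl(path)
  expect_equal(back$width_mm, rings$width_mm)
  expect_equal(back$year, rings$year)
  expect_equal(as.character(back$core_id), as.character(rings$core_id))
})
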