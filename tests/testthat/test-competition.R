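test_that("Hegyi index on elementary configurations", {
  s <- data.frame(tree_id = c("a", "b"), x_m = c(0, 1), y_m = 0,
                  dbh_cm = c(20, 20))
  expect_equal(hegyi_ci(s)$ci, c(1, 1))

  s2 <- data.frame(tree_id = c("a", "b"), x_m = c(0, 2), y_m = 0,
                   dbh_cm = c(10, 20))
  expect_equal(hegyi_ci(s2)$ci[1], 1)  # 2x DBH at 2 m

  # beyond the radius: no competition
  s3 <- data.frame(tree_id = c("a", "b"), x_m = c(0, 9), y_m = 0,
                   dbh_cm = c(20, 20))
  expect_equal(hegyi_ci(s3)$ci, c(0, 0))

  dup <- data.frame(tree_id = c("a", "b"), x_m = 1, y_m = 1, dbh_cm = 10)
  expect_error(hegyi_ci(dup), "coincident")
})

test_that("Hegyi index matches the O(n^2) brute-force oracle on random stands", {
  for (k in 1:30) {
    s <- make_stand(sample(5:80, 1), seed = k)
    expect_equal(hegyi_ci(s)$ci, brute_hegyi(s), tolerance = 1e-12)
  }
})

test_that("shrinking the radius never increases the index; edge correction stays sane", {
  s <- make_stand(60, seed = 77)
  ci8 <- hegyi_ci(s, radius = 8)$ci
  ci4 <- hegyi_ci(s, radius = 4)$ci
  expect_true(all(ci4 <= ci8 + 1e-12))

  res <- hegyi_ci(s, radius = 8, edge_correct = TRUE)
  expect_true(all(res$ci >= 0))
  expect_true(all(res$ci >= ci8 - 1e-12))  # expansion only inflates
  # interior trees are not edge-flagged and not corrected
  interior <- s$x_m > 8 & s$x_m < 22 & s$y_m > 8 & s$y_m < 22
  expect_true(all(!res$edge[interior]))
  expect_equal(res$ci[interior], ci8[interior], tolerance = 1e-3)
})

test_that("CI classes use the printed half-open boundaries", {
  expect_equal(as.character(classify_ci(c(0.37, 1.0, 2.99, 3.0, 4.18))),
               c("low", "medium", "medium", "high", "high"))
  expect_error(classify_ci(-0.1), ">= 0")
})

test_that("growth-rate series normalizes increments", {
  expect_equal(growth_rate_series(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(growth_rate_series(c(3, 1)), c(0.75, 0.25))
  set.seed(3)
  w <- runif(50, 0.1, 5)
  expect_equal(sum(growth_rate_series(w)), 1, tolerance = 1e-12)
  expect_error(growth_rate_series(c(0, 0)), "zero total")
})

test_that("plot growth rate averages trees and renormalizes over the common span", {
  g1 <- data.frame(year = 2001:2002, gr = c(0.6, 0.4))
  g2 <- data.frame(year = 2001:2002, gr = c(0.4, 0.6))
  g3 <- data.frame(year = 2001:2002, gr = c(0.5, 0.5))
  pg <- plot_growth_rate(list(g1, g2, g3))
  expect_equal(pg$gr, c(0.5, 0.5))

  # ragged spans: trimmed to the intersection, still sums to one
  g4 <- data.frame(year = 2000:2002, gr = c(0.2, 0.5, 0.3))
  pg2 <- plot_growth_rate(list(g1, g2, g4))
  expect_equal(pg2$year, 2001:2002)
  expect_equal(sum(pg2$gr), 1, tolerance = 1e-12)

  expect_error(plot_growth_rate(list(g1, g2)), "at least 3")
})

test_that("DBH back-casting closes on the observation and stays monotone", {
  # uniform growth rate: half the years give half the diameter
  gr <- data.frame(year = 1:20, gr = rep(0.05, 20))
  bc <- backcast_dbh(20, 1:20, gr = gr)
  expect_equal(bc$dbh_cm[10], 10)
  expect_equal(bc$dbh_cm[20], 20)

  set.seed(9)
  w <- runif(30, 0.5, 4)
  bc2 <- backcast_dbh(25, 1:30, widths = w)
  expect_equal(bc2$dbh_cm[30], 25)
  expect_true(all(diff(bc2$dbh_cm) >= -1e-12))
  # cored-path closure is exact arithmetic
  expect_equal(bc2$dbh_cm[15], 25 - 2 * sum(w[16:30]) / 10)

  gr2 <- data.frame(year = 1:30, gr = growth_rate_series(w))
  bc3 <- backcast_dbh(25, 1:30, gr = gr2)
  expect_equal(bc3$dbh_cm[30], 25)
  expect_true(all(diff(bc3$dbh_cm) >= -1e-12))
})

test_that("annual CI reconstruction closes on the observed inventory", {
  sim <- simulate_stand(sim_config(density = 500, n_years = 25, seed = 4))
  rec <- reconstruct_ci(sim$stand, sim$rings)
  obs <- hegyi_ci(sim$stand)
  fin <- rec[rec$year == max(rec$year), ]
  expect_equal(fin$ci, obs$ci[match(fin$tree_id, obs$tree_id)],
               tolerance = 1e-9)
})

test_that("homogeneous plots have a constant reconstructed CI trajectory", {
  # identical trees on a grid with identical rings: ratios cancel
  n <- 16
  g <- expand.grid(x_m = seq(4, 26, length.out = 4),
                   y_m = seq(4, 26, length.out = 4))
  w <- 3 * exp(-(1:30) / 15) + 0.5
  # cores reach the pith: observed DBH is exactly the accumulated increment
  stand <- data.frame(tree_id = sprintf("T%02d", 1:n), x_m = g$x_m, y_m = g$y_m,
                      dbh_cm = 2 * sum(w) / 10, cored = rep(c(1, 0), each = 8))
  attr(stand, "plot_width") <- 30
  attr(stand, "plot_height") <- 30
  rings <- do.call(rbind, lapply(which(stand$cored == 1), function(i) {
    data.frame(core_id = paste0(stand$tree_id[i], "a"),
               tree_id = stand$tree_id[i], year = 1981:2010, width_mm = w)
  }))
  rec <- reconstruct_ci(stand, rings, min_dbh = 0.1)
  for (id in unique(rec$tree_id)) {
    tr <- rec$ci[rec$tree_id == id]
    expect_lt(diff(range(tr, na.rm = TRUE)), 1e-9)
  }
})

test_that("reconstructed annual CI tracks the simulator's true trajectory", {
  sim <- simulate_stand(sim_config(density = 600, n_years = 35, seed = 12))
  rec <- reconstruct_ci(sim$stand, sim$rings)
  m <- merge(rec, sim$true_ci, by = c("tree_id", "year"),
             suffixes = c("_rec", "_true"))
  m <- m[!is.na(m$ci_rec) & m$ci_true > 0.05, ]
  rel_err <- abs(m$ci_rec - m$ci_true) / m$ci_true
  expect_lt(median(rel_err), 0.10)
})
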