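spei_frame <- function(drought_years, span = 1980:2019, value = -1.4) {
  s <- data.frame(year = span, spei_gs = 0)
  s$spei_gs[s$year %in% drought_years] <- value
  s
}

test_that("drought events group by the 3-year separation rule", {
  ev <- select_drought_events(spei_frame(c(2008, 2009)))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$years, c(2008, 2009))

  # 6 years apart: two events
  ev2 <- select_drought_events(spei_frame(c(2008, 2014)))
  expect_length(ev2, 2)

  # 3 years apart (not > 3): merged into one
  ev3 <- select_drought_events(spei_frame(c(2008, 2011)))
  expect_length(ev3, 1)
  expect_equal(ev3[[1]]$years, c(2008, 2011))

  expect_length(select_drought_events(spei_frame(integer(0))), 0)
  all_dry <- spei_frame(1980:2019)
  expect_length(select_drought_events(all_dry), 1)
})

test_that("event selection matches the transitive-closure oracle on all length-12 patterns", {
  span <- 2001:2012
  for (mask in 0:(2^12 - 1)) {
    dry <- span[bitwAnd(mask, 2^(0:11)) > 0]
    ev <- select_drought_events(spei_frame(dry, span = span))
    ref <- brute_event_groups(dry)
    expect_equal(lapply(ev, `[[`, "years"), ref)
  }
})

test_that("moving-average BAI smooths interiors and flags partial endpoints", {
  b <- data.frame(year = 2001:2005, bai_cm2 = 1:5)
  sm <- moving_average_bai(b)
  expect_equal(sm$bai_smooth, c(1.5, 2, 3, 4, 4.5))
  expect_equal(sm$partial, c(TRUE, FALSE, FALSE, FALSE, TRUE))

  cst <- data.frame(year = 2001:2010, bai_cm2 = 4)
  expect_equal(moving_average_bai(cst)$bai_smooth, rep(4, 10))
})

test_that("Lloret indices: arithmetic, algebraic identities and degenerate case", {
  ev <- select_drought_events(spei_frame(2000, span = 1990:2010))[[1]]
  flat <- data.frame(year = 1990:2010, bai_cm2 = 6)
  r <- resilience_indices(flat, ev)
  expect_equal(c(r$rt, r$rc, r$rs, r$rrs), c(1, 1, 1, 0))

  # pre 10, during 5, post 8
  b <- data.frame(year = 1990:2010, bai_cm2 = 10)
  b$bai_cm2[b$year == 2000] <- 5
  b$bai_cm2[b$year %in% 2001:2003] <- 8
  r2 <- resilience_indices(b, ev)
  expect_equal(c(r2$rt, r2$rc, r2$rs, r2$rrs), c(0.5, 1.6, 0.8, 0.3))

  set.seed(15)
  for (k in 1:50) {
    bb <- data.frame(year = 1990:2010, bai_cm2 = rlnorm(21, 2, 0.5))
    rr <- resilience_indices(bb, ev)
    expect_equal(rr$rrs, rr$rs - rr$rt, tolerance = 1e-12)
    expect_equal(rr$rs, rr$rt * rr$rc, tolerance = 1e-12)
  }
})

test_that("windows shift away from neighbouring events or become undefined", {
  bai <- data.frame(year = 1990:2020, bai_cm2 = 10)
  e1 <- structure(list(years = 2000, min_spei = -1.5, index = 1),
                  class = "drought_event")
  e2 <- structure(list(years = 2002, min_spei = -1.2, index = 2),
                  class = "drought_event")
  # post window of e1 (2001-2003) is contaminated by e2: shifted to 2003-2005
  r <- resilience_indices(bai, e1, other_events = list(e2))
  expect_false(is.na(r$rc))

  # at the series edge the pre window cannot exist
  early <- structure(list(years = 1991, min_spei = -1.5, index = 1),
                     class = "drought_event")
  r2 <- resilience_indices(bai, early)
  expect_true(is.na(r2$rt))
  expect_false(is.na(r2$rc))
})

test_that("group comparison reports means and detects a planted shift", {
  set.seed(33)
  base <- data.frame(event = 1,
                     ci_class = rep(c("low", "high"), each = 20),
                     rt = rnorm(40, 1, 0.1), rc = rnorm(40, 1, 0.1),
                     rs = rnorm(40, 1, 0.1), rrs = rnorm(40, 0, 0.1))
  same <- group_compare(base)
  expect_equal(nrow(same$summary), 2 * 4)
  # identical populations: no tiny p-values expected
  expect_true(all(same$tests$p > 0.01))

  hits <- 0
  for (k in 1:100) {
    d <- base
    d$rc[d$ci_class == "high"] <- rnorm(20, 0.7, 0.1)  # -30 percent shift
    p <- group_compare(d)$tests
    if (p$p[p$index == "rc"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("CI-resilience correlations are affine-invariant and near zero under independence", {
  set.seed(44)
  ci <- data.frame(tree_id = sprintf("t%02d", 1:40), ci = runif(40, 0.3, 4))
  ind <- data.frame(tree_id = rep(ci$tree_id, 2), event = rep(1:2, each = 40),
                    rt = rnorm(80, 1, 0.2), rc = rnorm(80, 1, 0.2),
                    rs = rnorm(80, 1, 0.2), rrs = rnorm(80, 0, 0.2))
  tab <- ci_resilience_correlation(ci, ind)
  expect_equal(nrow(tab), 8)
  expect_lt(max(abs(tab$r)), 0.5)

  ci2 <- transform(ci, ci = 10 * ci + 3)
  tab2 <- ci_resilience_correlation(ci2, ind)
  expect_equal(tab2$r, tab$r, tolerance = 1e-12)
})

test_that("simulated dense stands recover less after drought than sparse ones", {
  d <- drought_density_experiment(1)
  expect_lt(d$pooled_rrs_cor, 0)
  late <- d$indices[d$indices$event >= 2 & !is.na(d$indices$rrs), ]
  cls <- tapply(late$rrs, as.character(late$ci_class), mean)
  expect_lt(cls[["high"]], cls[["low"]])
})
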