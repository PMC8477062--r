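#' Simulation configuration for synthetic stands, climates and growth
#'
#' The generator emulates the field design the pipeline targets: 30 x 30 m
#' even-aged plantation plots at densities between roughly 200 and 1000
#' trees/ha, a continental monsoon climate with a July-August precipitation
#' peak, and ring growth driven by a negative-exponential age trend, a
#' growing-season moisture signal and a Hegyi-competition penalty,
#' `width_t = A(age) * exp(beta_climate * z_t - gamma_competition * CI_t + eps)`.
#'
#' @param plot_width,plot_height Plot dimensions, m.
#' @param density Stand density, trees/ha, within `[100, 2000]`.
#' @param planting_year First growth year.
#' @param n_years Number of growth years (>= 10).
#' @param beta_climate Sensitivity of log ring width to the growing-season
#'   moisture z-score (unitless).
#' @param gamma_competition Log-growth penalty per Hegyi CI unit (unitless).
#' @param sigma_noise Lognormal standard deviation of ring width.
#' @param drought_years List of droughts, each `c(start_year, duration,
#'   severity)` with severity the fractional growing-year precipitation
#'   reduction in `(0, 1)`.
#' @param lambda_legacy Density-dependent drought legacy: extra log-growth
#'   penalty per CI unit applied during the `legacy_years` after each
#'   imposed drought year (recovery phase only, so resistance is unaffected
#'   while recovery, resilience and relative resilience become
#'   density-dependent).
#' @param legacy_years Duration of the post-drought legacy, years.
#' @param cored_fraction Fraction of trees flagged as cored.
#' @param latitude Site latitude, degrees (for PET/SPEI).
#' @param site_index Dominant height at base age 40, m (recorded covariate).
#' @param beta_site Log-growth sensitivity to relative site index
#'   (`(SI - 14)/14`); default 0 (site condition is a passive covariate).
#' @param climate_lead Years of climate generated before planting.
#' @param rw_max,rw_tau,rw_floor Parameters of the age trend
#'   `A(age) = rw_max * exp(-age/rw_tau) + rw_floor`, mm.
#' @param seed Integer seed; identical configurations give identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(plot_width = 30, plot_height = 30, density = 600,
                       planting_year = 1975, n_years = 40,
                       beta_climate = 0.25, gamma_competition = 0.05,
                       sigma_noise = 0.50, drought_years = list(),
                       lambda_legacy = 0.10, legacy_years = 2,
                       cored_fraction = 0.5, latitude = 42,
                       site_index = 14, beta_site = 0,
                       climate_lead = 10,
                       rw_max = 5.5, rw_tau = 15, rw_floor = 0.8,
                       seed = 1) {
  if (plot_width <= 0 || plot_height <= 0) stop("plot dimensions must be positive", call. = FALSE)
  if (density < 100 || density > 2000) stop("density must lie in [100, 2000] trees/ha", call. = FALSE)
  if (n_years < 10) stop("n_years must be >= 10", call. = FALSE)
  if (sigma_noise < 0) stop("sigma_noise must be >= 0", call. = FALSE)
  if (!is.list(drought_years)) drought_years <- list(drought_years)
  for (d in drought_years) {
    if (length(d) != 3) stop("each drought is c(start_year, duration, severity)", call. = FALSE)
    if (d[3] <= 0 || d[3] >= 1) stop("drought severity must lie in (0, 1)", call. = FALSE)
    if (d[2] < 1) stop("drought duration must be >= 1 year", call. = FALSE)
  }
  cfg <- list(plot_width = plot_width, plot_height = plot_height,
              density = density, planting_year = planting_year,
              n_years = n_years, beta_climate = beta_climate,
              gamma_competition = gamma_competition, sigma_noise = sigma_noise,
              drought_years = drought_years, lambda_legacy = lambda_legacy,
              legacy_years = legacy_years, cored_fraction = cored_fraction,
              latitude = latitude, site_index = site_index,
              beta_site = beta_site, climate_lead = climate_lead,
              rw_max = rw_max, rw_tau = rw_tau, rw_floor = rw_floor,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed for a named substage (and optional unit index),
# so adding trees or stages never perturbs existing random streams
substage_seed <- function(seed, stage, unit = 0L) {
  offs <- c(climate_t = 11L, climate_p = 23L, climate_rh = 37L,
            stand_pos = 53L, stand_cored = 67L, growth = 83L)
  base <- (as.double(seed) * 7919 + offs[[stage]] * 104729 + unit * 3571) %%
    2147483629
  as.integer(base)
}

#' Generate a monthly synthetic climate
#'
#' Temperature is a seasonal sinusoid plus optional linear trend and noise;
#' precipitation is gamma-distributed with a July-August peak; relative
#' humidity is a bounded seasonal base plus noise. Imposed droughts scale
#' down the precipitation of the affected years so that their growing-season
#' SPEI falls below -1 when computed by the climate module.
#'
#' @param config A [sim_config()].
#' @param t_trend Linear temperature trend, degrees C per year (default 0).
#' @param t_sd,rh_sd Noise standard deviations.
#' @return Monthly climate data frame (`year`, `month`, `tmean_c`, `prcp_mm`,
#'   `rh_pct`) with the latitude attached as an attribute. Covers
#'   `planting_year - climate_lead` through the last growth year.
#' @export
sim_climate <- function(config, t_trend = 0, t_sd = 0.7, rh_sd = 5) {
  stopifnot(inherits(config, "sim_config"))
  y0 <- config$planting_year - config$climate_lead
  y1 <- config$planting_year + config$n_years - 1
  years <- rep(y0:y1, each = 12)
  months <- rep(1:12, times = y1 - y0 + 1)
  n <- length(years)

  p_mean <- c(3, 4, 8, 15, 30, 55, 110, 100, 45, 20, 8, 4)  # ~400 mm/yr
  rh_base <- c(55, 52, 50, 48, 52, 60, 72, 74, 66, 60, 58, 56)

  set.seed(substage_seed(config$seed, "climate_t"))
  tmean <- 7 + 15 * cos(2 * pi * (months - 7) / 12) +
    t_trend * (years - y0) + stats::rnorm(n, 0, t_sd)
  set.seed(substage_seed(config$seed, "climate_p"))
  shape <- 4
  prcp <- stats::rgamma(n, shape = shape, scale = p_mean[months] / shape)
  set.seed(substage_seed(config$seed, "climate_rh"))
  rh <- pmin(100, pmax(5, rh_base[months] + stats::rnorm(n, 0, rh_sd)))

  for (d in config$drought_years) {
    dy <- seq(d[1], length.out = d[2])
    hit <- years %in% dy
    if (!any(hit)) next
    prcp[hit] <- prcp[hit] * (1 - d[3])
    rh[hit] <- pmax(5, rh[hit] - 15 * d[3])
  }

  clim <- data.frame(year = years, month = months, tmean_c = tmean,
                     prcp_mm = prcp, rh_pct = rh)
  attr(clim, "latitude") <- config$latitude
  clim
}

#' Generate a synthetic stand inventory
#'
#' Places `floor(area_ha * density)` trees on a jittered lattice inside the
#' plot rectangle; all trees share the planting year and a configurable
#' fraction is flagged as cored. DBH is seeded at 0.5 cm (seedling caliper)
#' and filled in by [sim_growth()].
#'
#' @param config A [sim_config()].
#' @return Stand inventory data frame (`plot_id`, `tree_id`, `x_m`, `y_m`,
#'   `dbh_cm`, `height_m`, `cored`, `planting_year`) with plot dimensions as
#'   attributes.
#' @export
sim_stand <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  area_ha <- config$plot_width * config$plot_height / 1e4
  n <- floor(area_ha * config$density)
  if (n < 2) stop("density infeasible for this plot size", call. = FALSE)

  ncol_g <- ceiling(sqrt(n * config$plot_width / config$plot_height))
  nrow_g <- ceiling(n / ncol_g)
  cw <- config$plot_width / ncol_g
  ch <- config$plot_height / nrow_g
  cells <- expand.grid(ix = seq_len(ncol_g), iy = seq_len(nrow_g))[seq_len(n), ]

  set.seed(substage_seed(config$seed, "stand_pos"))
  x <- (cells$ix - 0.5) * cw + stats::runif(n, -0.4, 0.4) * cw
  y <- (cells$iy - 0.5) * ch + stats::runif(n, -0.4, 0.4) * ch

  set.seed(substage_seed(config$seed, "stand_cored"))
  n_cored <- max(3, round(config$cored_fraction * n))
  cored <- integer(n)
  cored[sample.int(n, min(n_cored, n))] <- 1L

  stand <- data.frame(plot_id = "P1", tree_id = sprintf("T%03d", seq_len(n)),
                      x_m = x, y_m = y, dbh_cm = 0.5, height_m = NA_real_,
                      cored = cored, planting_year = config$planting_year)
  attr(stand, "plot_width") <- config$plot_width
  attr(stand, "plot_height") <- config$plot_height
  stand
}

#' Simulate ring growth with a known competition and climate ground truth
#'
#' Grows every tree year by year: the ring width is
#' `A(age) * exp(beta_climate * z_t - gamma_competition * CI_t + eps)`, where
#' `A(age) = rw_max * exp(-age/rw_tau) + rw_floor` (mm), `z_t` is the
#' growing-season (April-October) water-balance z-score computed from the
#' generated climate's own climatology, `CI_t` is the true Hegyi index
#' evaluated from the simulated DBHs at the start of year `t`, and the DBH
#' accumulates two radial widths per year. Noise streams are split per tree.
#'
#' A density-dependent drought legacy multiplies the exponent by
#' `-lambda_legacy * CI_t` during the `legacy_years` following each imposed
#' drought year: crowded trees recover more slowly after drought while their
#' resistance during the event is unaffected.
#'
#' @param stand A [sim_stand()] inventory.
#' @param climate A [sim_climate()] table covering the stand lifetime.
#' @param config The same [sim_config()].
#' @return List with `rings` (long core table for the cored trees), `stand`
#'   (inventory with final DBH and allometric height filled in), `true_ci`
#'   (long `tree_id`, `year`, `ci` with the true annual index of every tree)
#'   and `z` (data frame `year`, `z` of the moisture score used).
#' @export
sim_growth <- function(stand, climate, config) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$planting_year + seq_len(config$n_years) - 1
  if (!all(years %in% climate$year)) {
    stop("climate does not cover the stand lifetime", call. = FALSE)
  }
  pet <- pet_thornthwaite(climate, config$latitude)
  gs <- climate$month %in% 4:10
  d_gs <- tapply((climate$prcp_mm - pet)[gs], climate$year[gs], sum)
  z_all <- (d_gs - mean(d_gs)) / stats::sd(d_gs)
  z <- as.numeric(z_all[as.character(years)])

  n <- nrow(stand)
  age <- seq_len(config$n_years)
  A <- config$rw_max * exp(-age / config$rw_tau) + config$rw_floor
  site_term <- config$beta_site * (config$site_index - 14) / 14

  eps <- matrix(0, config$n_years, n)
  if (config$sigma_noise > 0) {
    for (i in seq_len(n)) {
      set.seed(substage_seed(config$seed, "growth", i))
      e <- stats::rnorm(config$n_years, 0, config$sigma_noise)
      # winsorize the lognormal tail: real rings do not span x20 jumps
      lim <- 2.5 * config$sigma_noise
      eps[, i] <- pmin(pmax(e, -lim), lim)
    }
  }

  # severe drought years: realized growing-season moisture below -1 (covers
  # both imposed and naturally occurring droughts); the legacy penalty acts
  # in the recovery years that follow, never during the drought itself
  drought_yrs <- years[z < -1]
  legacy <- years %in% unlist(lapply(drought_yrs, function(y) {
    y + seq_len(config$legacy_years)
  }))
  legacy <- legacy & !(years %in% drought_yrs)

  # positions are fixed: precompute the 8-m neighbourhood once
  dmat <- as.matrix(stats::dist(stand[, c("x_m", "y_m")]))
  if (any(dmat[upper.tri(dmat)] == 0)) {
    stop("coincident tree positions in stand", call. = FALSE)
  }
  nb <- lapply(seq_len(n), function(i) {
    j <- which(dmat[i, ] <= 8 & seq_len(n) != i)
    list(j = j, inv_d = 1 / dmat[i, j])
  })

  dbh <- rep(0.5, n)  # seedling caliper at planting, cm
  widths <- matrix(NA_real_, config$n_years, n)
  ci_true <- matrix(NA_real_, config$n_years, n)
  for (t in seq_len(config$n_years)) {
    ci <- vapply(seq_len(n), function(i) {
      sum(dbh[nb[[i]]$j] * nb[[i]]$inv_d) / dbh[i]
    }, numeric(1))
    ci_true[t, ] <- ci
    pen <- config$gamma_competition * ci +
      if (legacy[t]) config$lambda_legacy * ci else 0
    w <- A[t] * exp(config$beta_climate * z[t] - pen + site_term + eps[t, ])
    w <- pmin(w, 18)  # physical ceiling on a single ring, mm
    widths[t, ] <- w
    dbh <- dbh + 2 * w / 10
  }

  stand$dbh_cm <- dbh
  stand$height_m <- 1.3 + 1.1 * dbh^0.8

  cored_idx <- which(stand$cored == 1)
  rings <- do.call(rbind, lapply(cored_idx, function(i) {
    data.frame(core_id = paste0(stand$tree_id[i], "a"),
               tree_id = stand$tree_id[i], plot_id = stand$plot_id[i],
               year = years, width_mm = widths[, i])
  }))
  true_ci <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(tree_id = stand$tree_id[i], year = years, ci = ci_true[, i])
  }))
  list(rings = rings, stand = stand, true_ci = true_ci,
       z = data.frame(year = years, z = z),
       widths = data.frame(tree_id = rep(stand$tree_id, each = config$n_years),
                           year = rep(years, times = n),
                           width_mm = as.vector(widths)))
}

#' Simulate one stand end to end
#'
#' Convenience wrapper: climate, stand and growth from a single
#' configuration.
#'
#' @inheritParams sim_growth
#' @param ... Passed to [sim_climate()].
#' @return The [sim_growth()] list, plus `climate` and `config`.
#' @export
simulate_stand <- function(config, ...) {
  climate <- sim_climate(config, ...)
  stand <- sim_stand(config)
  out <- sim_growth(stand, climate, config)
  out$climate <- climate
  out$config <- config
  out
}

#' Write simulated data in the pipeline's input formats
#'
#' Writes the inventory CSV, climate CSV and a Tucson `.rwl` ring-width file
#' so simulated data can be re-read by the ingestion functions.
#'
#' @param sim A [simulate_stand()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$stand, file.path(dir, "inventory.csv"), row.names = FALSE)
  utils::write.csv(sim$climate, file.path(dir, "climate.csv"), row.names = FALSE)
  write_rwl(sim$rings[c("core_id", "year", "width_mm")],
            file.path(dir, "rings.rwl"))
  utils::write.csv(sim$rings, file.path(dir, "rings.csv"), row.names = FALSE)
  invisible(dir)
}
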