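#' Assemble the yearly stand-level modelling table for one simulated stand
#'
#' Runs the analysis pipeline on a simulated stand: basal area increments of
#' the cored trees, reconstructed annual competition indices and the
#' growing-season SPEI of the stand's climate, summarised per year.
#'
#' @param sim A [simulate_stand()] result (or the output of [sim_growth()]
#'   plus `climate` and `config` entries).
#' @param spei_gs Optional precomputed growing-season SPEI table (saves
#'   refitting when several stands share one climate).
#' @return Data frame `year`, `log_bai` (log mean BAI, cm^2), `ci`
#'   (mean reconstructed CI of cored trees), `spei_gs`, `site_index`.
#' @export
stand_model_table <- function(sim, spei_gs = NULL) {
  if (is.null(spei_gs)) {
    spei_gs <- growing_season_spei(sim$climate, sim$config$latitude)
  }
  rec <- reconstruct_ci(sim$stand, sim$rings)
  bai <- bai_from_rings(sim$rings)
  yrs <- sort(unique(bai$year))
  data.frame(
    year = yrs,
    log_bai = log(as.numeric(tapply(bai$bai_cm2, bai$year, mean))),
    ci = as.numeric(tapply(rec$ci, rec$year, mean, na.rm = TRUE)[as.character(yrs)]),
    spei_gs = spei_gs$spei_gs[match(yrs, spei_gs$year)],
    site_index = sim$config$site_index
  )
}

#' Recover known effect sizes from simulated stands
#'
#' The parameter-recovery experiment behind the attribution stage: simulates
#' a multi-site study (by default six sites, each with low/medium/high
#' density stands sharing the site's climate, mirroring a shelterbelt
#' sampling design), reconstructs annual competition indices, block-averages
#' log BAI, the growing-season SPEI and the modelled CI, fits the growth
#' model and decomposes its R^2 into climate, competition and site shares.
#' With the default effect sizes the climate sensitivity dominates the
#' competition penalty, so the decomposition should rank climate first.
#'
#' @param seed Integer seed for the whole experiment.
#' @param beta_climate,gamma_competition,lambda_legacy Effect sizes passed to
#'   [sim_config()]; the defaults satisfy the climate-dominance condition
#'   `beta_climate > gamma_competition * sd(CI)`.
#' @param densities Stand densities, trees/ha.
#' @param n_sites Number of sites (independent climates).
#' @param n_years Stand age, years.
#' @param droughts Imposed droughts (see [sim_config()]).
#' @return [lmg_importance()] result with the ranking stored in
#'   `attr(, "ranking")`.
#' @export
recover_known_effects <- function(seed, beta_climate = 0.30,
                                  gamma_competition = 0.02,
                                  lambda_legacy = 0.10,
                                  densities = c(250, 550, 900),
                                  n_sites = 6, n_years = 40,
                                  droughts = list(c(1996, 1, 0.65),
                                                  c(2008, 1, 0.70),
                                                  c(2014, 1, 0.60))) {
  site_indices <- seq(11, 17, length.out = n_sites)
  stands <- list()
  for (s in seq_len(n_sites)) {
    cfg_site <- sim_config(density = densities[1], n_years = n_years,
                           seed = (seed * 13 + s * 911) %% 2147483000,
                           beta_climate = beta_climate,
                           gamma_competition = gamma_competition,
                           lambda_legacy = lambda_legacy,
                           site_index = site_indices[s],
                           drought_years = droughts)
    climate <- sim_climate(cfg_site)
    gs <- growing_season_spei(climate, cfg_site$latitude)
    for (d in densities) {
      cfg <- sim_config(density = d, n_years = n_years,
                        seed = (seed * 13 + s * 911 + d) %% 2147483000,
                        beta_climate = beta_climate,
                        gamma_competition = gamma_competition,
                        lambda_legacy = lambda_legacy,
                        site_index = site_indices[s],
                        drought_years = droughts)
      stand <- sim_stand(cfg)
      g <- sim_growth(stand, climate, cfg)
      g$climate <- climate
      g$config <- cfg
      stands[[paste(s, d)]] <- stand_model_table(g, spei_gs = gs)
    }
  }
  res <- attribute_growth(stands, climate_vars = "spei_gs")
  attr(res, "ranking") <- res$group[order(-res$lmg)]
  res
}

#' Density-dependent drought vulnerability experiment
#'
#' Simulates stands of several densities under a shared climate with
#' repeated imposed droughts, computes per-tree Lloret indices for the
#' selected drought events, and correlates the observed competition index
#' with each index, pooling trees across density classes for the second and
#' later events (where the cumulative legacy is expected).
#'
#' @param seed Integer seed.
#' @param densities Stand densities, trees/ha.
#' @param n_sites Number of sites (independent climates).
#' @param n_years Stand age, years.
#' @param droughts Imposed droughts.
#' @param ... Further arguments to [sim_config()] (effect sizes).
#' @return List with `correlations` (the [ci_resilience_correlation()] table
#'   per index and event), `pooled_rrs_cor` (Pearson r of CI with RRs pooled
#'   over events 2+), and `indices` (the per-tree table).
#' @export
drought_density_experiment <- function(seed, densities = c(250, 550, 900),
                                       n_sites = 2, n_years = 40,
                                       droughts = list(c(1996, 1, 0.65),
                                                       c(2008, 1, 0.70),
                                                       c(2014, 1, 0.60)),
                                       ...) {
  inds <- list()
  for (s in seq_len(n_sites)) {
    cfg_site <- sim_config(density = densities[1], n_years = n_years,
                           seed = (seed * 17 + s * 733) %% 2147483000,
                           drought_years = droughts, ...)
    climate <- sim_climate(cfg_site)
    gs <- growing_season_spei(climate, cfg_site$latitude)
    events <- select_drought_events(gs)
    if (!length(events)) next
    for (d in densities) {
      cfg <- sim_config(density = d, n_years = n_years,
                        seed = (seed * 17 + s * 733 + d) %% 2147483000,
                        drought_years = droughts, ...)
      stand <- sim_stand(cfg)
      g <- sim_growth(stand, climate, cfg)
      bai <- bai_from_rings(g$rings)
      ind <- stand_resilience(bai, events)
      obs <- hegyi_ci(g$stand)
      ind$ci <- obs$ci[match(ind$tree_id, obs$tree_id)]
      ind$ci_class <- obs$class[match(ind$tree_id, obs$tree_id)]
      ind$site <- s
      ind$density <- d
      inds[[paste(s, d)]] <- ind
    }
  }
  ind_all <- do.call(rbind, inds)
  ci_tab <- unique(ind_all[c("tree_id", "site", "density", "ci")])
  ci_tab$tree_id <- paste(ci_tab$site, ci_tab$density, ci_tab$tree_id)
  ind_key <- ind_all
  ind_key$tree_id <- paste(ind_key$site, ind_key$density, ind_key$tree_id)
  cors <- ci_resilience_correlation(ci_tab, ind_key)
  late <- ind_all[ind_all$event >= 2 & !is.na(ind_all$rrs), ]
  pooled <- if (nrow(late) >= 10) stats::cor(late$ci, late$rrs) else NA_real_
  list(correlations = cors, pooled_rrs_cor = pooled, indices = ind_all)
}
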