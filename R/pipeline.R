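#' Read a stand inventory CSV
#'
#' Schema: `plot_id, tree_id, x_m, y_m, dbh_cm, height_m, cored,
#' planting_year`, plus optional columns. Plot dimensions may be supplied
#' and are attached as attributes.
#'
#' @param path CSV file path.
#' @param plot_width,plot_height Plot dimensions, m.
#' @return Stand inventory data frame.
#' @export
read_inventory <- function(path, plot_width = 30, plot_height = 30) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(inv, "plot_width") <- plot_width
  attr(inv, "plot_height") <- plot_height
  check_stand_frame(inv)
  inv
}

#' Read a monthly climate CSV
#'
#' Schema: `year, month, tmean_c, prcp_mm, rh_pct` (optional `wind_ms`,
#' `pres_hpa`). Missing values are rejected unless `allow_gaps = TRUE`, in
#' which case runs of at most two consecutive missing months are linearly
#' interpolated.
#'
#' @param path CSV file path.
#' @param latitude Site latitude, attached as an attribute.
#' @param allow_gaps Interpolate short gaps instead of rejecting them.
#' @return Climate data frame.
#' @export
read_climate_csv <- function(path, latitude = NULL, allow_gaps = FALSE) {
  clim <- utils::read.csv(path, stringsAsFactors = FALSE)
  vars <- intersect(c("tmean_c", "prcp_mm", "rh_pct", "wind_ms", "pres_hpa"),
                    names(clim))
  if (anyNA(clim[vars])) {
    if (!allow_gaps) {
      stop("missing climate values (use allow_gaps = TRUE to interpolate)",
           call. = FALSE)
    }
    for (v in vars) {
      miss <- is.na(clim[[v]])
      runs <- rle(miss)
      if (any(runs$lengths[runs$values] > 2)) {
        stop("gap longer than 2 consecutive months in ", v, call. = FALSE)
      }
      clim[[v]] <- stats::approx(which(!miss), clim[[v]][!miss],
                                 xout = seq_len(nrow(clim)), rule = 2)$y
    }
  }
  if (!is.null(latitude)) attr(clim, "latitude") <- latitude
  check_climate_frame(clim, c("year", "month", "tmean_c", "prcp_mm", "rh_pct"))
  clim
}

#' Read a long-format ring-width CSV
#'
#' Schema: `core_id, year, width_mm` plus optional `tree_id`, `plot_id`;
#' when `tree_id` is absent it defaults to the core id.
#'
#' @param path CSV file path.
#' @return Long ring-width data frame.
#' @export
read_rings_csv <- function(path) {
  rings <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"tree_id" %in% names(rings)) rings$tree_id <- rings$core_id
  check_rings_frame(rings)
  rings
}

#' Validate pipeline inputs
#'
#' Checks schemas, unit sanity (DBH 1-150 cm, ring widths 0.01-20 mm, RH in
#' (0,100]) and cross-file id consistency, collecting every violation
#' rather than stopping at the first.
#'
#' @param inventory,rings,climate Data frames (or `NULL` to skip a check).
#' @return Data frame `table`, `id`, `column`, `message`; zero rows when
#'   everything is well formed.
#' @export
validate_inputs <- function(inventory = NULL, rings = NULL, climate = NULL) {
  bad <- list()
  note <- function(table, id, column, message) {
    bad[[length(bad) + 1]] <<- data.frame(table = table, id = as.character(id),
                                          column = column, message = message)
  }
  if (!is.null(inventory)) {
    need <- c("plot_id", "tree_id", "x_m", "y_m", "dbh_cm", "cored")
    for (cc in setdiff(need, names(inventory))) {
      note("inventory", "-", cc, "missing column")
    }
    if ("dbh_cm" %in% names(inventory)) {
      out <- which(inventory$dbh_cm < 1 | inventory$dbh_cm > 150)
      for (i in out) note("inventory", inventory$tree_id[i], "dbh_cm",
                          sprintf("DBH %.2f cm outside [1, 150]", inventory$dbh_cm[i]))
    }
    if ("tree_id" %in% names(inventory) && anyDuplicated(inventory$tree_id)) {
      note("inventory", "-", "tree_id", "duplicate tree ids")
    }
  }
  if (!is.null(rings)) {
    for (cc in setdiff(c("core_id", "year", "width_mm"), names(rings))) {
      note("rings", "-", cc, "missing column")
    }
    if ("width_mm" %in% names(rings)) {
      out <- which(rings$width_mm < 0.01 | rings$width_mm > 20)
      for (i in out) note("rings", rings$core_id[i], "width_mm",
                          sprintf("width %.2f mm outside [0.01, 20] in year %s",
                                  rings$width_mm[i], rings$year[i]))
    }
    if (!is.null(inventory) && all(c("tree_id") %in% names(rings)) &&
        "tree_id" %in% names(inventory)) {
      orphan <- setdiff(unique(rings$tree_id), inventory$tree_id)
      for (id in orphan) note("rings", id, "tree_id",
                              "ring series without inventory record")
    }
  }
  if (!is.null(climate)) {
    for (cc in setdiff(c("year", "month", "tmean_c", "prcp_mm", "rh_pct"),
                       names(climate))) {
      note("climate", "-", cc, "missing column")
    }
    if ("rh_pct" %in% names(climate)) {
      out <- which(climate$rh_pct <= 0 | climate$rh_pct > 100)
      for (i in out) note("climate", paste0(climate$year[i], "-", climate$month[i]),
                          "rh_pct", "relative humidity outside (0, 100]")
    }
    if ("prcp_mm" %in% names(climate)) {
      out <- which(climate$prcp_mm < 0)
      for (i in out) note("climate", paste0(climate$year[i], "-", climate$month[i]),
                          "prcp_mm", "negative precipitation")
    }
  }
  if (!length(bad)) {
    return(data.frame(table = character(), id = character(),
                      column = character(), message = character()))
  }
  out <- do.call(rbind, bad)
  rownames(out) <- NULL
  out
}

#' Default pipeline parameters
#'
#' Every analysis parameter surfaced as a named key with its standard value:
#' 8 m competition radius, CI class cut-points 1 and 3, SPEI drought
#' threshold -1, 3-year event separation, 3-year resilience windows, 5-year
#' attribution blocks, April-October growing season, window end `C_Sep`.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(radius_m = 8, ci_breaks = c(1, 3), spei_threshold = -1,
       event_separation_yr = 3, resilience_window_yr = 3,
       block_width_yr = 5, growing_season_months = 4:10,
       window_end = "C_Sep", rcs_stiffness = 0.10, min_dbh_cm = 1,
       edge_correct = FALSE, smoothed_resilience = FALSE,
       spei_scales = c(1, 12), latitude = 42, seed = 1)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: climate derivation, BAI and
#' chronology building (per-plot RCS detrending, pooled chronology),
#' per-plot competition indices and annual CI reconstruction,
#' climate-growth correlation, attribution (when the inventory holds at
#' least two plots and a `site_index` column; otherwise recorded as
#' skipped) and drought resilience. Stage outputs are written as CSV under
#' `out_dir` together with a JSON manifest recording the package version,
#' parameter hash and seed; a stage failure halts the run with the failing
#' stage named, retaining earlier outputs.
#'
#' @param config List (or path to a YAML file) with `inventory`, `rings`,
#'   `climate` paths (or in-memory data frames under `data`), an `out_dir`,
#'   and any [pipeline_defaults()] overrides under `params`.
#' @return Named list of stage results, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  out_dir <- config$out_dir %||% stop("config$out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$data)) {
    inventory <- config$data$inventory
    rings <- config$data$rings
    climate <- config$data$climate
  } else {
    inventory <- read_inventory(config$inventory)
    rings <- if (grepl("\\.rwl$", config$rings)) {
      r <- read_rwl(config$rings); r$tree_id <- sub("a$", "", r$core_id); r
    } else read_rings_csv(config$rings)
    climate <- read_climate_csv(config$climate, latitude = params$latitude)
  }
  if (!"plot_id" %in% names(inventory)) inventory$plot_id <- "P1"
  report <- validate_inputs(inventory, rings, climate)
  if (nrow(report)) {
    utils::write.csv(report, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list(validation = report)

  results$climate <- stage("climate", {
    cl <- derive_climate(climate, latitude = params$latitude,
                         scales = params$spei_scales)
    gs <- growing_season_spei(cl, latitude = params$latitude,
                              months = params$growing_season_months)
    utils::write.csv(cl, file.path(out_dir, "climate_derived.csv"), row.names = FALSE)
    utils::write.csv(gs, file.path(out_dir, "spei_growing_season.csv"), row.names = FALSE)
    list(derived = cl, spei_gs = gs)
  })

  # per-plot views of the inventory (plot attributes preserved)
  plot_ids <- unique(inventory$plot_id)
  plot_of_tree <- inventory$plot_id[match(rings$tree_id, inventory$tree_id)]
  split_plot <- function(pid) {
    sub <- inventory[inventory$plot_id == pid, , drop = FALSE]
    attr(sub, "plot_width") <- attr(inventory, "plot_width")
    attr(sub, "plot_height") <- attr(inventory, "plot_height")
    sub
  }

  results$rings <- stage("rings", {
    bai <- bai_from_rings(rings)
    res <- list()
    for (pid in plot_ids) {
      pr <- rings[!is.na(plot_of_tree) & plot_of_tree == pid, , drop = FALSE]
      if (!nrow(pr)) next
      py <- split_plot(pid)$planting_year[1]
      idx <- rcs_detrend(pr, planting_year = py,
                         stiffness = params$rcs_stiffness)
      for (id in unique(idx$core_id)) {
        sel <- idx$core_id == id
        idx$index[sel] <- ar_prewhiten(idx$index[sel])
      }
      res[[pid]] <- idx[!is.na(idx$index), , drop = FALSE]
    }
    chron <- build_chronology(do.call(rbind, res))
    utils::write.csv(bai, file.path(out_dir, "bai.csv"), row.names = FALSE)
    utils::write.csv(chron$data, file.path(out_dir, "chronology.csv"), row.names = FALSE)
    list(bai = bai, chronology = chron)
  })

  results$competition <- stage("competition", {
    ci_now <- list(); ci_annual <- list()
    for (pid in plot_ids) {
      pinv <- split_plot(pid)
      pr <- rings[!is.na(plot_of_tree) & plot_of_tree == pid, , drop = FALSE]
      ci_now[[pid]] <- cbind(plot_id = pid,
                             hegyi_ci(pinv, radius = params$radius_m,
                                      edge_correct = params$edge_correct))
      ci_annual[[pid]] <- cbind(plot_id = pid,
                                reconstruct_ci(pinv, pr,
                                               radius = params$radius_m,
                                               min_dbh = params$min_dbh_cm))
    }
    ci_now <- do.call(rbind, ci_now)
    ci_annual <- do.call(rbind, ci_annual)
    rownames(ci_now) <- rownames(ci_annual) <- NULL
    utils::write.csv(ci_now, file.path(out_dir, "ci_observed.csv"), row.names = FALSE)
    utils::write.csv(ci_annual, file.path(out_dir, "ci_annual.csv"), row.names = FALSE)
    list(observed = ci_now, annual = ci_annual)
  })

  results$correlation <- stage("correlation", {
    chron <- results$rings$chronology
    design <- lag_align(results$climate$derived, chron$data$year,
                        window_end = params$window_end)
    tab <- correlate_climate_growth(chron, design)
    utils::write.csv(tab, file.path(out_dir, "climate_growth.csv"), row.names = FALSE)
    list(table = tab, top = select_significant(tab))
  })

  # attribution needs contrast in site condition: several plots with a
  # site_index column; otherwise the stage is recorded as skipped
  results$attribution <- stage("attribution", {
    if (length(plot_ids) < 2 || !"site_index" %in% names(inventory)) {
      list(skipped = "needs >= 2 plots and a site_index inventory column")
    } else {
      gs <- results$climate$spei_gs
      tabs <- lapply(plot_ids, function(pid) {
        trees <- inventory$tree_id[inventory$plot_id == pid]
        bai <- results$rings$bai
        bai <- bai[bai$tree_id %in% trees, , drop = FALSE]
        ann <- results$competition$annual
        ann <- ann[ann$plot_id == pid, , drop = FALSE]
        yrs <- sort(unique(bai$year))
        data.frame(
          year = yrs,
          log_bai = log(as.numeric(tapply(bai$bai_cm2, bai$year, mean))),
          ci = as.numeric(tapply(ann$ci, ann$year, mean,
                                 na.rm = TRUE)[as.character(yrs)]),
          spei_gs = gs$spei_gs[match(yrs, gs$year)],
          site_index = inventory$site_index[inventory$plot_id == pid][1]
        )
      })
      att <- attribute_growth(tabs, climate_vars = "spei_gs",
                              width = params$block_width_yr)
      utils::write.csv(as.data.frame(att), file.path(out_dir, "attribution.csv"),
                       row.names = FALSE)
      att
    }
  })

  results$resilience <- stage("resilience", {
    events <- select_drought_events(results$climate$spei_gs,
                                    threshold = params$spei_threshold,
                                    separation = params$event_separation_yr)
    ind <- if (length(events)) {
      stand_resilience(results$rings$bai, events,
                       window = params$resilience_window_yr,
                       smoothed = params$smoothed_resilience)
    } else NULL
    if (!is.null(ind)) {
      obs <- results$competition$observed
      ind$ci <- obs$ci[match(ind$tree_id, obs$tree_id)]
      ind$ci_class <- obs$class[match(ind$tree_id, obs$tree_id)]
      utils::write.csv(ind, file.path(out_dir, "resilience.csv"), row.names = FALSE)
    }
    list(events = events, indices = ind)
  })

  manifest <- list(
    package = "dendrocomp",
    version = as.character(utils::packageVersion("dendrocomp")),
    seed = params$seed,
    params = params[order(names(params))],
    n_trees = nrow(inventory), n_cores = length(unique(rings$core_id)),
    n_climate_months = nrow(climate)
  )
  pfile <- file.path(out_dir, "params.yaml")
  yaml::write_yaml(manifest$params, pfile)
  manifest$config_hash <- unname(tools::md5sum(pfile))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
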