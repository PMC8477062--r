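#' Select severe drought events from growing-season SPEI
#'
#' Years whose growing-season SPEI falls below `threshold` are severe
#' drought years; consecutive drought years form runs, and runs whose
#' endpoints are separated by `separation` or fewer calendar years are
#' merged into one multi-year event (a short recovery gap does not split a
#' drought spell). Events are returned in chronological order.
#'
#' @param spei_gs Data frame `year`, `spei_gs` (see
#'   [growing_season_spei()]).
#' @param threshold Severity threshold (default -1).
#' @param separation Maximum calendar-year separation that still merges two
#'   runs (default 3; events must be separated by more than 3 years).
#' @return List of `drought_event` objects, each with `years` (the drought
#'   years of the event), `min_spei` and `index` (ordinal).
#' @examples
#' s <- data.frame(year = 2000:2015, spei_gs = 0)
#' s$spei_gs[s$year %in% c(2008, 2014)] <- -1.4
#' length(select_drought_events(s))  # 2: separated by 6 > 3 years
#' @export
select_drought_events <- function(spei_gs, threshold = -1, separation = 3) {
  stopifnot(all(c("year", "spei_gs") %in% names(spei_gs)))
  dy <- sort(spei_gs$year[!is.na(spei_gs$spei_gs) & spei_gs$spei_gs < threshold])
  if (!length(dy)) return(list())
  grp <- cumsum(c(1, diff(dy) > separation))
  events <- lapply(unique(grp), function(g) {
    yrs <- dy[grp == g]
    ev <- list(years = yrs,
               min_spei = min(spei_gs$spei_gs[spei_gs$year %in% yrs]),
               index = g)
    class(ev) <- "drought_event"
    ev
  })
  events
}

#' @export
print.drought_event <- function(x, ...) {
  cat(sprintf("Drought event %d: years %s (min growing-season SPEI %.2f)\n",
              x$index, paste(x$years, collapse = ", "), x$min_spei))
  invisible(x)
}

#' Three-year moving average of a BAI series
#'
#' Centred moving mean; the endpoints use the available two-year means and
#' are flagged.
#'
#' @param bai Data frame `year`, `bai_cm2` (single tree or stand mean).
#' @param window Window width, odd (default 3).
#' @return The input with `bai_smooth` and `partial` columns added.
#' @export
moving_average_bai <- function(bai, window = 3) {
  stopifnot(all(c("year", "bai_cm2") %in% names(bai)))
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  x <- bai$bai_cm2[order(bai$year)]
  bai <- bai[order(bai$year), , drop = FALSE]
  n <- length(x)
  if (n < window) stop("series shorter than the window", call. = FALSE)
  half <- (window - 1) / 2
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  partial <- is.na(sm)
  for (i in which(partial)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  bai$bai_smooth <- sm
  bai$partial <- partial
  rownames(bai) <- NULL
  bai
}

# find a clean window of `width` consecutive years adjacent to the event,
# shifting away from it by at most `max_shift` years when other events intrude
clean_window <- function(anchor, direction, width, series_years, blocked,
                         max_shift = 5) {
  for (shift in 0:max_shift) {
    if (direction < 0) {
      win <- seq(anchor - shift - width + 1, anchor - shift)
    } else {
      win <- seq(anchor + shift, anchor + shift + width - 1)
    }
    if (all(win %in% series_years) && !any(win %in% blocked)) return(win)
  }
  NULL
}

#' Lloret resistance, recovery, resilience and relative resilience
#'
#' For a drought event, `BAI_D` is the mean BAI over the event years and
#' `BAI_pre` / `BAI_post` the mean BAIs over the `window` years immediately
#' before / after the event. The indices are
#' `Rt = BAI_D / BAI_pre`, `Rc = BAI_post / BAI_D`,
#' `Rs = BAI_post / BAI_pre`, `RRs = (BAI_post - BAI_D) / BAI_pre`, linked
#' by `RRs = Rs - Rt` and `Rs = Rt * Rc`. When another event's years
#' intrude into a window, the window is shifted to the nearest clean span
#' within 5 years; otherwise the indices are `NA` (reported, not dropped).
#'
#' @param bai Data frame `year`, `bai_cm2` for one tree (raw BAI by default;
#'   set `smoothed = TRUE` to use the 3-year moving average).
#' @param event A `drought_event`.
#' @param window Pre/post window width, years (default 3).
#' @param other_events Optional list of the other events at the site, whose
#'   years must not contaminate the windows.
#' @param smoothed Use smoothed BAI inside the windows (default `FALSE`).
#' @return One-row data frame `event`, `rt`, `rc`, `rs`, `rrs`, `bai_pre`,
#'   `bai_d`, `bai_post`.
#' @export
resilience_indices <- function(bai, event, window = 3, other_events = list(),
                               smoothed = FALSE) {
  stopifnot(inherits(event, "drought_event"))
  if (smoothed) {
    bai <- moving_average_bai(bai, window)
    val <- bai$bai_smooth
  } else {
    val <- bai$bai_cm2
  }
  yrs <- bai$year
  blocked <- unique(unlist(lapply(other_events, function(e) e$years)))

  ev_years <- event$years
  if (!all(ev_years %in% yrs)) {
    return(data.frame(event = event$index, rt = NA_real_, rc = NA_real_,
                      rs = NA_real_, rrs = NA_real_, bai_pre = NA_real_,
                      bai_d = NA_real_, bai_post = NA_real_))
  }
  pre <- clean_window(min(ev_years) - 1, -1, window, yrs, c(blocked, ev_years))
  post <- clean_window(max(ev_years) + 1, +1, window, yrs, c(blocked, ev_years))
  bai_d <- mean(val[yrs %in% ev_years])
  bai_pre <- if (is.null(pre)) NA_real_ else mean(val[yrs %in% pre])
  bai_post <- if (is.null(post)) NA_real_ else mean(val[yrs %in% post])

  rt <- bai_d / bai_pre
  rc <- bai_post / bai_d
  rs <- bai_post / bai_pre
  data.frame(event = event$index, rt = rt, rc = rc, rs = rs, rrs = rs - rt,
             bai_pre = bai_pre, bai_d = bai_d, bai_post = bai_post)
}

#' Per-tree resilience indices for all events of a site
#'
#' @param bai Long data frame `tree_id`, `year`, `bai_cm2`.
#' @param events List of `drought_event`s (see [select_drought_events()]).
#' @inheritParams resilience_indices
#' @return Long data frame with one row per tree and event.
#' @export
stand_resilience <- function(bai, events, window = 3, smoothed = FALSE) {
  stopifnot(all(c("tree_id", "year", "bai_cm2") %in% names(bai)))
  out <- list()
  for (id in unique(bai$tree_id)) {
    tb <- bai[bai$tree_id == id, c("year", "bai_cm2")]
    for (k in seq_along(events)) {
      r <- resilience_indices(tb, events[[k]], window = window,
                              other_events = events[-k], smoothed = smoothed)
      r <- cbind(tree_id = id, r)
      out[[length(out) + 1]] <- r
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare resilience indices between groups
#'
#' Group means, standard deviations and sizes per (grouping, event), with
#' pairwise Welch t-tests between groups. Welch tests stand in for
#' ANOVA-based post-hoc comparisons and are labelled as such in the output
#' metadata.
#'
#' @param indices Long data frame of per-tree indices with an `event` column
#'   and the grouping column.
#' @param group Name of the grouping column (e.g. `"ci_class"`).
#' @param vars Index columns to compare.
#' @param min_n Minimum group size; smaller groups are dropped with a
#'   warning.
#' @return List with `summary` (mean/sd/n per group, event and index) and
#'   `tests` (pairwise Welch p-values); `attr(, "method")` records the test.
#' @export
group_compare <- function(indices, group = "ci_class",
                          vars = c("rt", "rc", "rs", "rrs"), min_n = 3) {
  stopifnot(group %in% names(indices), "event" %in% names(indices))
  sums <- list(); tests <- list()
  for (ev in sort(unique(indices$event))) {
    sub <- indices[indices$event == ev, , drop = FALSE]
    tab <- table(sub[[group]])
    small <- names(tab)[tab < min_n & tab > 0]
    if (length(small)) {
      warning("dropping group(s) with n < ", min_n, ": ",
              paste(small, collapse = ", "), call. = FALSE)
      sub <- sub[!(sub[[group]] %in% small), , drop = FALSE]
    }
    glev <- unique(as.character(sub[[group]]))
    for (v in vars) {
      for (g in glev) {
        x <- sub[[v]][sub[[group]] == g & !is.na(sub[[v]])]
        sums[[length(sums) + 1]] <- data.frame(
          event = ev, index = v, group = g, mean = mean(x),
          sd = stats::sd(x), n = length(x))
      }
      if (length(glev) >= 2) {
        pairs <- utils::combn(glev, 2, simplify = FALSE)
        for (pr in pairs) {
          x1 <- sub[[v]][sub[[group]] == pr[1] & !is.na(sub[[v]])]
          x2 <- sub[[v]][sub[[group]] == pr[2] & !is.na(sub[[v]])]
          p <- if (length(x1) >= 2 && length(x2) >= 2 &&
                   (stats::sd(x1) > 0 || stats::sd(x2) > 0)) {
            stats::t.test(x1, x2)$p.value
          } else NA_real_
          tests[[length(tests) + 1]] <- data.frame(
            event = ev, index = v, group1 = pr[1], group2 = pr[2], p = p)
        }
      }
    }
  }
  out <- list(summary = do.call(rbind, sums), tests = do.call(rbind, tests))
  attr(out, "method") <- "pairwise Welch t-tests (stand-in for ANOVA post-hoc)"
  out
}

#' Correlation of competition index with resilience indices
#'
#' Pearson correlation (with two-sided p) between the per-tree modelled CI
#' and each resilience index, per event, pooling trees across density
#' classes.
#'
#' @param ci Data frame `tree_id`, `ci` (modelled/reconstructed CI per tree).
#' @param indices Long per-tree index table (see [stand_resilience()]).
#' @param vars Index columns (default all four).
#' @param min_n Minimum pooled trees (default 10).
#' @return Data frame `event`, `index`, `r`, `p`, `n`.
#' @export
ci_resilience_correlation <- function(ci, indices,
                                      vars = c("rt", "rc", "rs", "rrs"),
                                      min_n = 10) {
  stopifnot(all(c("tree_id", "ci") %in% names(ci)))
  out <- list()
  for (ev in sort(unique(indices$event))) {
    sub <- indices[indices$event == ev, , drop = FALSE]
    cc <- ci$ci[match(sub$tree_id, ci$tree_id)]
    for (v in vars) {
      ok <- !is.na(cc) & !is.na(sub[[v]])
      if (sum(ok) < min_n) next
      if (stats::sd(cc[ok]) == 0) stop("zero variance in CI", call. = FALSE)
      ct <- stats::cor.test(cc[ok], sub[[v]][ok], method = "pearson")
      out[[length(out) + 1]] <- data.frame(event = ev, index = v,
                                           r = unname(ct$estimate),
                                           p = ct$p.value, n = sum(ok))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
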