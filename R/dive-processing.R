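# Dive detection and summary, replicating standard time-depth-recorder
# processing: zero-offset correction of transducer drift, wet submergence
# runs as dives, trapezoid-style phase segmentation at 80% of maximum depth,
# and plausibility filters on rates and durations.

#' Zero-offset correct a depth series
#'
#' Pressure transducers drift, so raw "surface" readings wander away from
#' 0 m. Within rolling windows the baseline is taken as a low quantile of
#' near-surface readings (< 10 m), linearly interpolated between window
#' centres, subtracted, and corrected depths clamped at 0. Windows without
#' surface readings carry the previous baseline forward with a warning.
#'
#' @param records tag records tibble (time-sorted within seal).
#' @param window_hours rolling window width (hours).
#' @param surface_quantile quantile of near-surface readings used as the
#'   baseline.
#' @param near_surface_m readings shallower than this (m) are considered
#'   surface candidates.
#' @return `records` with `depth_m` corrected.
#' @export
zero_offset_correct <- function(records, window_hours = 6,
                                surface_quantile = 0.05,
                                near_surface_m = 10) {
  assert_cols(records, c("seal_id", "timestamp", "depth_m"), "records")
  correct_one <- function(df, ...) {
    tt <- as.numeric(df$timestamp)
    win <- window_hours * 3600
    idx <- floor((tt - tt[1]) / win)
    # per window: the surface baseline and the time where it is attained.
    # Anchoring at the attainment time (rather than the window centre) keeps
    # the interpolated baseline in phase with a slowly drifting transducer.
    wstats <- tapply(seq_along(tt), idx, function(i) {
      surf <- df$depth_m[i] < near_surface_m
      if (!any(surf)) return(c(NA_real_, mean(tt[i])))
      q <- quantile(df$depth_m[i][surf], surface_quantile, names = FALSE)
      at <- i[surf][df$depth_m[i][surf] <= q + 0.05]
      c(q, mean(tt[at]))
    })
    base <- vapply(wstats, `[`, numeric(1), 1)
    anchor <- vapply(wstats, `[`, numeric(1), 2)
    if (anyNA(base)) {
      warn("window(s) with no surface readings; carrying previous baseline")
      for (k in seq_along(base)) {
        if (is.na(base[k])) base[k] <- if (k == 1) 0 else base[k - 1]
      }
    }
    offset <- if (length(base) == 1) rep(base, length(tt)) else {
      o <- approx(anchor, base, xout = tt, rule = 2)$y
      # extend the trend past the outermost anchors so a steady drift is
      # tracked to the ends of the record
      k <- length(base)
      lo <- tt < anchor[1]
      hi <- tt > anchor[k]
      s1 <- (base[2] - base[1]) / (anchor[2] - anchor[1])
      sk <- (base[k] - base[k - 1]) / (anchor[k] - anchor[k - 1])
      o[lo] <- base[1] + s1 * (tt[lo] - anchor[1])
      o[hi] <- base[k] + sk * (tt[hi] - anchor[k])
      o
    }
    df$depth_m <- pmax(0, df$depth_m - offset)
    df
  }
  records |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(correct_one) |>
    dplyr::ungroup()
}

#' Detect dives in corrected tag records
#'
#' A dive is a maximal run of wet samples with depth greater than 0, bounded
#' by surface readings. Dives whose maximum depth is shallower than
#' `min_depth` (surface behaviour, wave action) or whose duration exceeds
#' `max_duration_min` (merged-dive artifacts) are discarded.
#'
#' @param records corrected tag records.
#' @param min_depth minimum dive depth (m); strictly shallower dives are
#'   removed.
#' @param max_duration_min maximum duration (min); strictly longer dives are
#'   removed.
#' @param cadence_s nominal sampling cadence (s), used for duration
#'   accounting (`duration = n_samples * cadence`).
#' @return tibble with one row per dive: `seal_id`, `dive_id`, `start`,
#'   `end`, `duration_s`, `max_depth_m` and a `samples` list-column holding
#'   the dive's records.
#' @export
detect_dives <- function(records, min_depth = 5, max_duration_min = 30,
                         cadence_s = 10) {
  assert_cols(records, c("seal_id", "timestamp", "depth_m"), "records")
  if (!"wet" %in% names(records)) records$wet <- TRUE
  one_seal <- function(df, key) {
    sub <- df$wet & df$depth_m > 0
    # break runs across large time gaps as well as surface samples
    gap <- c(FALSE, diff(as.numeric(df$timestamp)) > 5 * cadence_s)
    run_id <- cumsum(!sub | gap)
    idx <- which(sub)
    if (!length(idx)) return(tibble::tibble())
    dives <- split(idx, run_id[idx])
    purrr::map(dives, function(i) {
      smp <- df[i, ]
      tibble::tibble(
        start = smp$timestamp[1],
        end = smp$timestamp[nrow(smp)],
        duration_s = nrow(smp) * cadence_s,
        max_depth_m = max(smp$depth_m),
        n_samples = nrow(smp),
        samples = list(smp)
      )
    }) |> dplyr::bind_rows()
  }
  out <- records |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(one_seal) |>
    dplyr::ungroup()
  if (!nrow(out)) return(out)
  out <- out |>
    dplyr::filter(.data$max_depth_m >= min_depth,
                  .data$duration_s <= max_duration_min * 60) |>
    dplyr::mutate(dive_id = dplyr::row_number(), .after = "seal_id")
  out
}

#' Split dives into descent, bottom and ascent phases
#'
#' The bottom phase is the contiguous span from the first to the last sample
#' at depths at or beyond 80% of the dive's maximum depth (wiggles above the
#' threshold inside that envelope stay in the bottom phase); descent is
#' everything before, ascent everything after. Phase durations are counted
#' as samples times the cadence so the three phases partition the dive
#' exactly. Vertical rates are the maximum depth divided by the phase
#' duration.
#'
#' @param dives output of [detect_dives()].
#' @param bottom_threshold fraction of maximum depth defining the bottom
#'   phase.
#' @param cadence_s sampling cadence (s).
#' @return `dives` with added columns `descent_s`, `bottom_s`, `ascent_s`,
#'   `descent_rate`, `ascent_rate`, `bottom_duration_s` (= `bottom_s`) and a
#'   `phase` column inside each `samples` tibble.
#' @export
split_phases <- function(dives, bottom_threshold = 0.8, cadence_s = 10) {
  if (!nrow(dives)) return(dives)
  res <- purrr::map(dives$samples, function(smp) {
    n <- nrow(smp)
    if (n < 3) {
      return(list(smp = smp, descent = 0L, bottom = n, ascent = 0L))
    }
    thr <- bottom_threshold * max(smp$depth_m)
    at_bottom <- which(smp$depth_m >= thr)
    b0 <- min(at_bottom); b1 <- max(at_bottom)
    phase <- rep("bottom", n)
    if (b0 > 1) phase[1:(b0 - 1)] <- "descent"
    if (b1 < n) phase[(b1 + 1):n] <- "ascent"
    smp$phase <- phase
    list(smp = smp, descent = b0 - 1L, bottom = b1 - b0 + 1L, ascent = n - b1)
  })
  dives$samples <- purrr::map(res, "smp")
  dives$descent_s <- purrr::map_int(res, "descent") * cadence_s
  dives$bottom_s <- purrr::map_int(res, "bottom") * cadence_s
  dives$ascent_s <- purrr::map_int(res, "ascent") * cadence_s
  dives$bottom_duration_s <- dives$bottom_s
  dives$descent_rate <- ifelse(dives$descent_s > 0,
                               dives$max_depth_m / dives$descent_s, 0)
  dives$ascent_rate <- ifelse(dives$ascent_s > 0,
                              dives$max_depth_m / dives$ascent_s, 0)
  dives
}

#' Plausibility-filter dives on rates and duration
#'
#' Removes dives with descent or ascent rates at or above `max_rate` or
#' exactly 0 (biologically impossible or mis-segmented), and dives lasting
#' `min_duration_s` or less (misidentified surface behaviour).
#'
#' @param dives output of [split_phases()].
#' @param max_rate rate cut-off (m s^-1); `>=` is removed.
#' @param min_duration_s duration cut-off (s); `<=` is removed.
#' @return filtered dive tibble.
#' @export
filter_dives <- function(dives, max_rate = 6, min_duration_s = 20) {
  if (!nrow(dives)) return(dives)
  dplyr::filter(
    dives,
    .data$descent_rate < max_rate, .data$descent_rate > 0,
    .data$ascent_rate < max_rate, .data$ascent_rate > 0,
    .data$duration_s > min_duration_s
  )
}

#' Full dive-processing pipeline
#'
#' Convenience chain: [zero_offset_correct()] |> [detect_dives()] |>
#' [split_phases()] |> [filter_dives()].
#'
#' @param records raw tag records.
#' @param ... passed to the individual steps by name (`window_hours`,
#'   `min_depth`, `max_duration_min`, `bottom_threshold`, `max_rate`,
#'   `min_duration_s`, `cadence_s`).
#' @return filtered, phase-annotated dive tibble.
#' @export
process_dives <- function(records, window_hours = 6, min_depth = 5,
                          max_duration_min = 30, bottom_threshold = 0.8,
                          max_rate = 6, min_duration_s = 20, cadence_s = 10) {
  records |>
    zero_offset_correct(window_hours = window_hours) |>
    detect_dives(min_depth = min_depth, max_duration_min = max_duration_min,
                 cadence_s = cadence_s) |>
    split_phases(cadence_s = cadence_s) |>
    filter_dives(max_rate = max_rate, min_duration_s = min_duration_s)
}
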