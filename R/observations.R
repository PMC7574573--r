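#' Assemble the state-by-environment observation table
#'
#' Joins decoded behavioural states with per-dive environmental covariates:
#' for each decoded step at time `t`, covariates are medians over the dives
#' of that seal whose end time falls in `(t - step, t]`, taken as
#' representative of conditions encountered in the lead-up to the behavioural
#' decision. Season comes from the calendar month (summer June-August, fall
#' September-December); January steps are excluded. The water-column model
#' requires a defined chlorophyll-a (noon window, dives of at least 50 m)
#' and T50; the bottom-conditions model requires bottom covariates. Rows
#' missing a required covariate are dropped and counted. Bottom depth enters
#' the model as its natural logarithm.
#'
#' @param states decoded states from [decode_states()] (or a [fit_hmm()]
#'   object's `states`).
#' @param env per-dive covariates from [dive_environment()].
#' @param metadata tibble with `seal_id` and `sex` (`"F"`/`"M"`); an unknown
#'   sex is an error.
#' @param model `"water_column"` or `"bottom_conditions"`.
#' @param step_h covariate look-back window (hours); defaults to the track
#'   step.
#' @return observation tibble ready for [fit_pql_glmm()]: `seal_id`, `time`,
#'   `t_hours` (hours since each seal's first step), `y` (1 = apparent
#'   foraging), covariates, `sex`, `season`. Dropped-row counts are in
#'   attribute `"n_dropped"`.
#' @export
assemble_observations <- function(states, env, metadata,
                                  model = c("water_column", "bottom_conditions"),
                                  step_h = 3) {
  model <- match.arg(model)
  assert_cols(states, c("seal_id", "timestamp", "state"), "states")
  assert_cols(env, c("seal_id", "dive_end", "T50", "chla_mg_m3",
                     "bot_depth_m", "bot_temp_c", "bot_dur_s"), "env")
  assert_cols(metadata, c("seal_id", "sex"), "metadata")
  if (!all(metadata$sex %in% c("F", "M"))) {
    abort("metadata$sex must be 'F' or 'M'")
  }

  win_s <- step_h * 3600
  med <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)

  obs <- states |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(function(st, key) {
      ev <- env[env$seal_id == key$seal_id, ]
      ends <- as.numeric(ev$dive_end)
      purrr::map(seq_len(nrow(st)), function(i) {
        t1 <- as.numeric(st$timestamp[i])
        in_win <- which(ends > t1 - win_s & ends <= t1)
        tibble::tibble(
          time = st$timestamp[i],
          y = as.integer(st$state[i] == "foraging"),
          chl = med(ev$chla_mg_m3[in_win]),
          T50 = med(ev$T50[in_win]),
          bot_dur = med(ev$bot_dur_s[in_win]),
          bot_temp = med(ev$bot_temp_c[in_win]),
          bot_depth = med(ev$bot_depth_m[in_win]),
          n_dives = length(in_win)
        )
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::ungroup()

  obs$season <- season_of(obs$time)
  obs <- dplyr::left_join(obs, metadata[c("seal_id", "sex")], by = "seal_id")
  if (anyNA(obs$sex)) abort("seal(s) missing from metadata")
  obs$sex <- factor(obs$sex, levels = c("M", "F"))
  obs$log_bot_depth <- ifelse(!is.na(obs$bot_depth) & obs$bot_depth > 0,
                              log(obs$bot_depth), NA_real_)

  required <- if (model == "water_column") c("chl", "T50") else {
    c("bot_dur", "bot_temp", "log_bot_depth")
  }
  obs <- obs |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::mutate(t_hours = as.numeric(.data$time - min(.data$time), units = "hours")) |>
    dplyr::ungroup()
  complete <- !is.na(obs$season) &
    rowSums(is.na(obs[required])) == 0
  n_dropped <- sum(!complete)
  out <- obs[complete, ]
  attr(out, "n_dropped") <- n_dropped
  out
}
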