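#' Convert session RPE to estimated exercise intensity
#'
#' Maps a Borg CR-10 session rating of perceived exertion to an estimated
#' exercise intensity as a percentage of maximal oxygen uptake. The default
#' mapping is linear (`srpe * 10`), so an sRPE of 6-7 corresponds to the
#' 60-70% VO2max band typical of moderate continuous running. A custom
#' mapping function can be supplied for other calibrations.
#'
#' @param srpe Numeric vector of CR-10 ratings in \[0, 10\].
#' @param mapping Optional function `srpe -> intensity_pct` replacing the
#'   default linear mapping.
#' @return Intensity as a percentage of VO2max.
#' @export
#' @examples
#' srpe_to_intensity(6.5) # 65
srpe_to_intensity <- function(srpe, mapping = NULL) {
  if (any(is.na(srpe)) || any(srpe < 0 | srpe > 10)) {
    stop("sRPE must lie in [0, 10]", call. = FALSE)
  }
  if (is.null(mapping)) srpe * 10 else mapping(srpe)
}

#' Session training load
#'
#' Session training load in arbitrary units (A.U.): running duration in
#' minutes multiplied by session intensity in percent.
#'
#' @param duration_min Session duration, minutes (> 0).
#' @param intensity_pct Session intensity, %VO2max (> 0).
#' @return Session load, A.U.
#' @export
#' @examples
#' session_load(25, 65) # 1625
session_load <- function(duration_min, intensity_pct) {
  if (any(is.na(duration_min)) || any(duration_min <= 0)) {
    stop("duration_min must be positive", call. = FALSE)
  }
  if (any(is.na(intensity_pct)) || any(intensity_pct <= 0)) {
    stop("intensity_pct must be positive", call. = FALSE)
  }
  duration_min * intensity_pct
}

#' Weekly training load
#'
#' Weekly load is the mean session load within the week multiplied by the
#' number of sessions performed; when all sessions are identical this equals
#' the product form session load x sessions per week.
#'
#' @param session_loads Numeric vector of session loads within one week.
#' @param sessions_per_week Number of sessions; defaults to
#'   `length(session_loads)`.
#' @return Weekly load, A.U.
#' @export
weekly_load <- function(session_loads, sessions_per_week = length(session_loads)) {
  if (length(session_loads) < 1) stop("empty training week", call. = FALSE)
  mean(session_loads) * sessions_per_week
}

#' Total training load
#'
#' Total load over the programme. With one weekly load and an explicit
#' number of weeks the product form weekly load x weeks is used; with a
#' vector of per-week loads they are summed, which accommodates taper and
#' test weeks where the weekly load differs.
#'
#' @param weekly_loads Numeric vector of weekly loads.
#' @param weeks Number of weeks (only used when a single weekly load is
#'   given; defaults to `length(weekly_loads)`).
#' @return Total load, A.U.
#' @export
total_load <- function(weekly_loads, weeks = length(weekly_loads)) {
  if (length(weekly_loads) < 1) stop("empty training diary", call. = FALSE)
  if (length(weekly_loads) == 1) weekly_loads * weeks else sum(weekly_loads)
}

#' Summarise training loads from a diary
#'
#' Computes per-participant session, weekly and total training loads from a
#' training diary. Intensity is derived from sRPE via
#' [srpe_to_intensity()].
#'
#' @param diary Tibble with columns `participant_id`, `week`,
#'   `duration_min`, `srpe` (one row per session).
#' @param mapping Optional sRPE-to-intensity mapping passed to
#'   [srpe_to_intensity()].
#' @return Tibble with one row per participant: `participant_id`,
#'   `sTL` (mean session load), `wTL` (mean weekly load), `tTL` (total
#'   load), `sessions`, `weeks`.
#' @export
training_load_summary <- function(diary, mapping = NULL) {
  diary <- tibble::as_tibble(diary)
  if (nrow(diary) == 0) stop("empty training diary", call. = FALSE)
  diary$sTL <- session_load(diary$duration_min,
                            srpe_to_intensity(diary$srpe, mapping))
  weekly <- diary |>
    dplyr::group_by(.data$participant_id, .data$week) |>
    dplyr::summarise(wTL = weekly_load(.data$sTL), .groups = "drop")
  per_part <- diary |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(sTL = mean(.data$sTL), sessions = dplyr::n(),
                     .groups = "drop")
  agg <- weekly |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(wTL = mean(.data$wTL), tTL = total_load(.data$wTL),
                     weeks = dplyr::n(), .groups = "drop")
  dplyr::left_join(per_part, agg, by = "participant_id")
}

#' Percentage change
#'
#' Relative change from baseline, in percent:
#' `100 * (followup - baseline) / baseline`.
#'
#' @param baseline,followup Numeric vectors; `baseline` must be positive.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(2.00, 2.23) # 11.5
percent_change <- function(baseline, followup) {
  if (any(is.na(baseline)) || any(baseline <= 0)) {
    stop("baseline must be positive", call. = FALSE)
  }
  100 * (followup - baseline) / baseline
}

#' Cooper-test response records
#'
#' Builds per-participant response records from long Cooper-test data:
#' baseline distance, absolute change (final week minus baseline) and the
#' individual percentage change. Group-level summaries should average the
#' individual percentages (mean of individual percent changes), not take
#' the percent change of group means.
#'
#' @param cooper Tibble with columns `participant_id`, `group` (`"EG"`
#'   training arm / `"CG"` control), `week`, `distance_km` (and optionally
#'   `srpe`).
#' @param baseline_week,final_week Weeks used as baseline and endpoint
#'   (defaults 0 and 8).
#' @return Tibble `participant_id`, `group`, `baseline_km`, `final_km`,
#'   `delta_km`, `pct_change`, one row per participant with both records
#'   present.
#' @export
cooper_responses <- function(cooper, baseline_week = 0, final_week = 8) {
  cooper <- tibble::as_tibble(cooper)
  if (anyDuplicated(cooper[, c("participant_id", "week")]) > 0) {
    stop("More than one Cooper record per participant-week", call. = FALSE)
  }
  base <- cooper[cooper$week == baseline_week,
                 c("participant_id", "group", "distance_km")]
  names(base)[3] <- "baseline_km"
  fin <- cooper[cooper$week == final_week, c("participant_id", "distance_km")]
  names(fin)[2] <- "final_km"
  out <- dplyr::inner_join(base, fin, by = "participant_id")
  out$delta_km <- out$final_km - out$baseline_km
  out$pct_change <- percent_change(out$baseline_km, out$final_km)
  tibble::as_tibble(out)
}

#' Classify training responders
#'
#' Training-arm participants whose individual percentage improvement is
#' strictly greater than the training-arm mean percentage improvement are
#' responders; ties at the mean (within floating-point tolerance, so the
#' tie rule is well defined on computed percentages) and all others are
#' non-responders. Control participants are never classified (`NA`).
#'
#' @param responses Tibble from [cooper_responses()] (columns
#'   `participant_id`, `group`, `pct_change`).
#' @return The input with a logical `responder` column added.
#' @export
#' @examples
#' r <- tibble::tibble(participant_id = c("a", "b", "c"), group = "EG",
#'                     pct_change = c(5, 10, 15))
#' dichotomize_responders(r)$responder # FALSE FALSE TRUE
dichotomize_responders <- function(responses) {
  responses <- tibble::as_tibble(responses)
  eg <- responses$group == "EG"
  if (sum(eg & !is.na(responses$pct_change)) < 2) {
    stop("Need at least 2 training-arm percent changes to classify",
         call. = FALSE)
  }
  eg_mean <- mean(responses$pct_change[eg], na.rm = TRUE)
  if (isTRUE(all.equal(stats::var(responses$pct_change[eg]), 0))) {
    warning("All training-arm changes identical; no responders", call. = FALSE)
  }
  tol <- sqrt(.Machine$double.eps) * max(1, abs(eg_mean))
  responses$responder <- ifelse(eg, responses$pct_change > eg_mean + tol, NA)
  responses
}
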