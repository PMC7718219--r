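#' DVARS censoring threshold for a run
#'
#' The outlier threshold applied to a run's DVARS trace: 150% of the
#' inter-quartile range above the 75th percentile, i.e.
#' `Q75 + 1.5 * (Q75 - Q25)`. Quantiles use linear interpolation between order
#' statistics (R's default type 7), so the rule is bit-reproducible.
#'
#' @param dvars Numeric vector of per-frame DVARS values for one run.
#' @return The scalar threshold.
#' @examples
#' dvars_threshold(c(1, 2, 3, 4)) # 3.25 + 1.5 * 1.5 = 5.5
#' @export
dvars_threshold <- function(dvars) {
  if (length(dvars) < 4) stop("need at least 4 frames to estimate DVARS quartiles")
  q <- stats::quantile(dvars, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Frame censoring mask for one run
#'
#' Applies the three censoring rules in sequence:
#' 1. flag every frame with FD strictly above `fd_thresh_um` (50 um) or DVARS
#'    strictly above the run's [dvars_threshold()];
#' 2. augment the mask by additionally dropping the one frame immediately
#'    after each flagged frame (a flag on the final frame augments nothing);
#' 3. drop entirely any maximal contiguous block of kept frames shorter than
#'    `min_segment` frames.
#'
#' @param trace A tibble with per-frame columns `fd_um` and `dvars`
#'   (and optionally `frame`), as produced by [sample_motion()].
#' @param fd_thresh_um Framewise-displacement threshold in micrometres.
#' @param min_segment Minimum surviving contiguous segment length, in frames.
#' @param dvars_thresh Optional fixed DVARS threshold; by default it is
#'   recomputed from this run's trace.
#' @return The input tibble with logical column `keep` added, plus attribute
#'   `n_kept`.
#' @export
censor_mask <- function(trace, fd_thresh_um = 50, min_segment = 5,
                        dvars_thresh = NULL) {
  stopifnot(is.data.frame(trace), all(c("fd_um", "dvars") %in% names(trace)))
  n <- nrow(trace)
  if (n == 0) stop("empty motion trace")
  if (is.null(dvars_thresh)) dvars_thresh <- dvars_threshold(trace$dvars)

  flagged <- trace$fd_um > fd_thresh_um | trace$dvars > dvars_thresh
  # augmented mask: the frame after each movement is also dropped
  aug <- flagged
  if (n > 1) aug[2:n] <- aug[2:n] | flagged[1:(n - 1)]
  keep <- !aug

  # censor kept segments shorter than min_segment
  r <- rle(keep)
  r$values[r$values & r$lengths < min_segment] <- FALSE
  keep <- inverse.rle(r)

  out <- dplyr::mutate(trace, keep = keep)
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Run and session inclusion verdicts after censoring
#'
#' Runs retaining fewer than `min_run_frames` frames are excluded; a session's
#' frame count is the sum over its surviving runs, and sessions below
#' `min_session_frames` (192 frames = 8 min at TR 2.5 s) are excluded.
#' Comparisons are strict ("less than"), so a run with exactly 50 kept frames
#' and a session with exactly 192 survive.
#'
#' @param run_summary Tibble with one row per run: columns `session`, `run`,
#'   `n_kept` (and optionally `mouse`).
#' @param min_run_frames Minimum kept frames per run.
#' @param min_session_frames Minimum total kept frames per session.
#' @return A list with tibbles `runs` (columns `session`, `run`, `n_kept`,
#'   `included`, `reason`) and `sessions` (`session`, `n_frames`, `n_runs_kept`,
#'   `included`, `reason`).
#' @export
apply_exclusions <- function(run_summary, min_run_frames = 50,
                             min_session_frames = 192) {
  stopifnot(is.data.frame(run_summary),
            all(c("session", "run", "n_kept") %in% names(run_summary)))
  if (nrow(run_summary) == 0) stop("empty run summary: no sessions to assess")
  extra <- intersect("mouse", names(run_summary))

  runs <- run_summary |>
    dplyr::mutate(
      included = .data$n_kept >= min_run_frames,
      reason = dplyr::if_else(.data$included, NA_character_,
        sprintf("run kept %d frames (< %d)", .data$n_kept, as.integer(min_run_frames))
      )
    )
  sessions <- runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(extra, "session")))) |>
    dplyr::summarise(
      n_frames = sum(.data$n_kept[.data$included]),
      n_runs_kept = sum(.data$included),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      included = .data$n_frames >= min_session_frames,
      reason = dplyr::if_else(.data$included, NA_character_,
        sprintf("session kept %d frames (< %d)", .data$n_frames,
                as.integer(min_session_frames))
      )
    )
  list(runs = runs, sessions = sessions)
}

#' Censor a cohort's motion traces and summarise inclusion
#'
#' Convenience wrapper: applies [censor_mask()] per run of a long motion table
#' and [apply_exclusions()] to the result.
#'
#' @param motion Long tibble with columns `mouse`, `session`, `run`, `frame`,
#'   `fd_um`, `dvars`.
#' @inheritParams censor_mask
#' @inheritParams apply_exclusions
#' @return A list with `masks` (the motion table plus `keep`) and the
#'   `runs`/`sessions` report from [apply_exclusions()].
#' @export
scrub_cohort <- function(motion, fd_thresh_um = 50, min_segment = 5,
                         min_run_frames = 50, min_session_frames = 192) {
  masks <- motion |>
    dplyr::group_by(.data$mouse, .data$session, .data$run) |>
    dplyr::group_modify(~ censor_mask(.x, fd_thresh_um, min_segment)) |>
    dplyr::ungroup()
  run_summary <- masks |>
    dplyr::group_by(.data$mouse, .data$session, .data$run) |>
    dplyr::summarise(n_kept = sum(.data$keep),
                     mean_fd = mean(.data$fd_um), .groups = "drop")
  rep <- apply_exclusions(run_summary, min_run_frames, min_session_frames)
  c(list(masks = masks), rep)
}
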