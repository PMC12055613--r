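# broom-style tidiers for the package's result objects.

#' Tidy an IoEE result
#'
#' @param x An `ioee_result` from [compute_ioee()].
#' @param ... Unused.
#' @return One row per component distance plus the index itself.
#' @export
tidy.ioee_result <- function(x, ...) {
  tibble(
    quantity = c("ioee", "max_shoulder_wrist", "max_shoulder_elbow",
                 "max_elbow_wrist"),
    value = c(x$ioee, x$max_shoulder_wrist, x$max_shoulder_elbow,
              x$max_elbow_wrist),
    unit = c("dimensionless", "px", "px", "px")
  )
}

#' @rdname tidy.ioee_result
#' @export
glance.ioee_result <- function(x, ...) {
  tibble(ioee = x$ioee, n_valid_frames = x$n_valid_frames,
         exceeds_unity = x$exceeds_unity_flag)
}

#' Tidy an elbow-angle result
#'
#' @param x An `elbow_angle_result` from [max_elbow_angle()].
#' @param ... Unused.
#' @return The per-frame angle series.
#' @export
tidy.elbow_angle_result <- function(x, ...) x$angles

#' @rdname tidy.elbow_angle_result
#' @export
glance.elbow_angle_result <- function(x, ...) {
  tibble(max_angle_deg = x$max_angle, frame_of_max = x$frame_of_max,
         n_degenerate_frames = x$n_degenerate_frames)
}

#' Tidy a reaction-time summary
#'
#' @param x A `reaction_time_summary` from [summarize_conditions()].
#' @param ... Unused.
#' @return Per-condition latency statistics.
#' @export
tidy.reaction_time_summary <- function(x, ...) x$conditions

#' @rdname tidy.reaction_time_summary
#' @export
glance.reaction_time_summary <- function(x, ...) {
  wide <- x$conditions |>
    dplyr::select("condition", "mean_ms") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_ms")
  tibble(vrt_mean = wide$VRT, vart_mean = wide$VART, vsrt_mean = wide$VSRT,
         startreact_ms = x$startreact_ms,
         n_valid = sum(x$conditions$n_valid),
         n_excluded = sum(x$conditions$n_excluded))
}

#' Tidy a correlation test
#'
#' @param x A `reach_cor` from [cor_spearman()] or [cor_pearson()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `p.value`, `method`, `n`.
#' @export
tidy.reach_cor <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value, method = x$method,
         n = x$n, exact = x$exact)
}

#' @rdname tidy.reach_cor
#' @export
glance.reach_cor <- function(x, ...) tidy.reach_cor(x)
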