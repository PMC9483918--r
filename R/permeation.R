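#' Detect membrane permeation events
#'
#' Classifies each marker atom's z coordinate (optionally centered on the
#' lipid center of mass) into three regions — bulk above (z > +h), membrane
#' (|z| <= h), bulk below (z < -h) — and counts full traversals: an event
#' is recorded when a marker goes from one bulk region through the membrane
#' to the opposite bulk region; returning to the entry-side bulk resets the
#' state, and hopping between the bulk regions through the periodic
#' boundary (no membrane visit) is not an event. Events still in progress
#' at the end of the trajectory are not counted.
#'
#' Successive-frame z displacements are minimized over periodic images
#' before classification; a step of half the box height or more is
#' ambiguous and triggers a warning naming the frame.
#'
#' @param traj an `md_trajectory`.
#' @param markers integer atom ids of the permeation markers (e.g. the
#'   amine nitrogen of an anesthetic, the phosphorus of TPP).
#' @param membrane_halfwidth region half-thickness h, nm; default `NULL`
#'   estimates it from the lipid density via
#'   [estimate_membrane_halfwidth()].
#' @param frame_range frames to analyze.
#' @param center_selection atom ids for per-frame centering (`NULL` for
#'   trajectories already centered on the membrane).
#' @return Tibble of class `permeation_result` with one row per event:
#'   marker, entry_frame, exit_frame, direction (`"+z->-z"` or
#'   `"-z->+z"`); attributes membrane_halfwidth, n_frames.
#' @export
detect_permeations <- function(traj, markers, membrane_halfwidth = NULL,
                               frame_range = NULL, center_selection = NULL) {
  validate_trajectory(traj)
  if (length(markers) == 0) abort("marker selection is empty")
  frames <- resolve_frames(traj, frame_range)
  if (!is.null(center_selection)) {
    sub <- traj
    sub$coords <- traj$coords[frames]
    sub$box <- traj$box[frames, , drop = FALSE]
    sub$times <- traj$times[frames]
    traj <- center_coordinates(sub, center_selection, axis = "z")
    frames <- seq_along(traj$coords)
  }
  if (is.null(membrane_halfwidth)) {
    membrane_halfwidth <- estimate_membrane_halfwidth(traj,
                                                      frame_range = frames)
  }
  h <- membrane_halfwidth
  box_z <- traj$box[frames, 3]
  if (any(h >= box_z / 2)) {
    abort("membrane_halfwidth must be < box_z/2 at all frames")
  }
  events <- list()
  for (m in markers) {
    z_raw <- vapply(frames, function(f) traj$coords[[f]][m, 3], numeric(1))
    # unwrap successive displacements over periodic images, then re-wrap
    dz <- min_image_diff(diff(z_raw), box_z[-1])
    if (any(abs(dz) >= box_z[-1] / 2 - 1e-9)) {
      bad <- which(abs(dz) >= box_z[-1] / 2 - 1e-9)[1]
      warn(sprintf(
        "marker %d: ambiguous half-box z step at frame %d (possible undetected wrap)",
        m, frames[bad + 1]))
    }
    z <- wrap_centered(cumsum(c(z_raw[1], dz)), box_z)
    region <- ifelse(z > h, 1L, ifelse(z < -h, -1L, 0L))
    side <- 0L       # last bulk region visited
    came_from <- 0L  # bulk side from which the membrane was entered
    for (k in seq_along(region)) {
      r <- region[k]
      if (r == 0L) {
        if (came_from == 0L && side != 0L) {
          came_from <- side
          entry <- k
        }
      } else {
        if (came_from != 0L && r == -came_from) {
          events[[length(events) + 1]] <- tibble(
            marker = m, entry_frame = frames[entry], exit_frame = frames[k],
            direction = if (came_from == 1L) "+z->-z" else "-z->+z")
        }
        side <- r
        came_from <- 0L
      }
    }
  }
  out <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble(marker = integer(), entry_frame = integer(),
           exit_frame = integer(), direction = character())
  attr(out, "membrane_halfwidth") <- h
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("permeation_result", class(out))
  out
}
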