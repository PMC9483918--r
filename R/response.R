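#' Construct a response curve
#'
#' A response curve records the order-parameter change dS of one head-group
#' segment against a binding x-axis: bound solutes per lipid or bulk
#' concentration. The no-solute origin (0, 0) is implied in fits and
#' comparisons.
#'
#' @param points data frame with columns `x`, `delta_s` and optionally
#'   `stderr`.
#' @param label segment label (`"alpha"`, `"beta"`, ...).
#' @param x_kind `"bound_per_lipid"` or `"concentration_mM"`.
#' @param source `"simulation"` or `"experiment"`.
#' @return Tibble of class `response_curve`, sorted by x, with columns
#'   label, x_kind, x, delta_s, stderr, source.
#' @export
response_curve <- function(points, label, x_kind = c("bound_per_lipid",
                                                     "concentration_mM"),
                           source = c("simulation", "experiment")) {
  x_kind <- match.arg(x_kind)
  source <- match.arg(source)
  points <- as_tibble(points)
  if (!all(c("x", "delta_s") %in% names(points))) {
    abort("points needs columns x and delta_s")
  }
  if (any(points$x < 0)) abort("x must be >= 0")
  if (!"stderr" %in% names(points)) points$stderr <- NA_real_
  out <- tibble(label = label, x_kind = x_kind, x = points$x,
                delta_s = points$delta_s, stderr = points$stderr,
                source = source)
  out <- out[order(out$x), ]
  class(out) <- c("response_curve", class(out))
  out
}

#' Build an order-parameter response curve from trajectories
#'
#' For each system, computes the order parameter of the labelled C-H bonds,
#' its change against the solute-free reference system, and the binding
#' x-value (bound per lipid or bulk concentration) from the bound-count
#' time series.
#'
#' @param systems list of lists, each with elements `traj`
#'   (an `md_trajectory`), `solutes`, `lipids`, `bonds`, and optionally
#'   `frame_range`; selections default to the trajectory's named selections
#'   and `bonds` to the ground-truth bond table if present.
#' @param reference a solute-free `md_trajectory` (or list with `traj`,
#'   `bonds`, `frame_range`) providing the dS = 0 baseline.
#' @param criterion a [binding_criterion()].
#' @param label bond label to extract.
#' @param x_kind x-axis: `"bound_per_lipid"` or `"concentration_mM"`.
#' @return A `response_curve` (source `"simulation"`).
#' @export
build_response_curve <- function(systems, reference, criterion,
                                 label = "ch",
                                 x_kind = c("bound_per_lipid",
                                            "concentration_mM")) {
  x_kind <- match.arg(x_kind)
  if (length(systems) < 1) abort("need at least one system")
  norm_sys <- function(s) {
    if (inherits(s, "md_trajectory")) s <- list(traj = s)
    sel <- attr(s$traj$topology, "selections")
    if (is.null(s$solutes)) {
      s$solutes <- if (!is.null(sel$solutes) && length(sel$solutes) > 0) {
        split(sel$solutes,
              s$traj$topology$molecule_id[match(sel$solutes,
                                                s$traj$topology$atom_id)])
      } else list()
    }
    if (is.null(s$lipids)) s$lipids <- sel$lipids
    if (is.null(s$bonds)) s$bonds <- as_tibble(s$traj$ground_truth$bonds)
    if (is.null(s$frame_range)) s$frame_range <- NULL
    s
  }
  ref <- norm_sys(reference)
  if (length(ref$solutes) > 0) {
    abort("reference system must be solute-free")
  }
  s_ref <- compute_order_parameters(ref$traj, ref$bonds, ref$frame_range)
  s_ref <- s_ref[s_ref$label == label, ]
  pts <- purrr::map_dfr(systems, function(s) {
    s <- norm_sys(s)
    resolve_frames(s$traj, s$frame_range)  # validates non-empty range
    res <- compute_order_parameters(s$traj, s$bonds, s$frame_range)
    res <- res[res$label == label, ]
    d <- delta_order_parameter(res, s_ref)
    series <- bound_timeseries(s$traj, s$solutes, s$lipids, criterion,
                               frame_range = s$frame_range)
    x <- if (x_kind == "bound_per_lipid") bound_per_lipid(series) else
      bulk_concentration(series)
    tibble(x = x, delta_s = d$delta_S, stderr = d$stderr)
  })
  response_curve(pts, label = label, x_kind = x_kind, source = "simulation")
}

#' Read an experimental response curve from CSV
#'
#' Expected header: `x_kind,label,x,delta_s[,stderr]`.
#'
#' @param path CSV file.
#' @return A `response_curve` (source `"experiment"`); multiple
#'   (x_kind, label) combinations yield a list of curves keyed by
#'   `label.x_kind` when the file mixes them.
#' @export
read_response_curve <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_kind", "label", "x", "delta_s") %in% names(df))) {
    abort("response CSV needs columns x_kind, label, x, delta_s")
  }
  groups <- split(df, paste(df$label, df$x_kind, sep = "."))
  curves <- lapply(groups, function(g) {
    response_curve(g[, intersect(c("x", "delta_s", "stderr"), names(g))],
                   label = g$label[1], x_kind = g$x_kind[1],
                   source = "experiment")
  })
  if (length(curves) == 1) curves[[1]] else curves
}

#' Fit the response slope through the origin
#'
#' Weighted least squares of dS on x with no intercept (dS must vanish with
#' no bound solute); weights 1/stderr^2 when stderrs are available, unit
#' weights otherwise. The implied origin (0, 0) carries no information in a
#' through-origin fit and is not added as a data point. A free-intercept
#' fit is available via `intercept = TRUE`.
#'
#' @param curve a `response_curve`.
#' @param intercept fit a free intercept instead of forcing the origin.
#' @return An object of class `response_fit`; see [tidy.response_fit()] and
#'   [glance.response_fit()].
#' @export
fit_response_slope <- function(curve, intercept = FALSE) {
  stopifnot(inherits(curve, "response_curve"))
  if (nrow(curve) < 1) abort("curve has no points")
  if (all(curve$x == 0)) abort("all x are zero; slope is undefined")
  w <- if (all(is.finite(curve$stderr)) && all(curve$stderr > 0)) {
    1 / curve$stderr^2
  } else rep(1, nrow(curve))
  dat <- data.frame(x = curve$x, y = curve$delta_s, w = w)
  min_pts <- if (intercept) 2 else 1
  if (nrow(dat) < min_pts) abort("not enough points for this fit")
  fml <- if (intercept) y ~ x else y ~ 0 + x
  fit <- lm(fml, data = dat, weights = w)
  # noiseless fixtures legitimately produce perfect fits
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[["x"]])
  slope_stderr <- if (nrow(dat) > min_pts) {
    unname(sm$coefficients["x", "Std. Error"])
  } else NA_real_
  structure(list(slope = slope, slope_stderr = slope_stderr,
                 intercept = if (intercept) unname(coef(fit)[1]) else 0,
                 lm = fit, curve = curve, through_origin = !intercept),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("<response_fit: slope %.4g +/- %.3g per %s (%s)>\n",
              x$slope, x$slope_stderr, x$curve$x_kind[1],
              if (x$through_origin) "through origin" else "free intercept"))
  invisible(x)
}

#' Tidy a response-slope fit
#'
#' @param x a `response_fit`.
#' @param ... unused.
#' @return One row per coefficient: term, estimate, std.error.
#' @method tidy response_fit
#' @export
tidy.response_fit <- function(x, ...) {
  tibble(term = if (x$through_origin) "slope" else c("intercept", "slope"),
         estimate = if (x$through_origin) x$slope else
           c(x$intercept, x$slope),
         std.error = if (x$through_origin) x$slope_stderr else
           unname(suppressWarnings(summary(x$lm))$coefficients[, "Std. Error"]))
}

#' Glance at a response-slope fit
#'
#' @param x a `response_fit`.
#' @param ... unused.
#' @return One-row tibble: slope, slope_stderr, n_points, r.squared.
#' @method glance response_fit
#' @export
glance.response_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_stderr = x$slope_stderr,
         n_points = nrow(x$curve),
         r.squared = suppressWarnings(summary(x$lm))$r.squared)
}

#' Compare simulated and experimental response curves
#'
#' Fits both curves through the origin and reports the slope ratio
#' (simulation / experiment) together with the root-mean-square deviation
#' of dS over the overlapping x range, evaluated at the experimental x
#' positions by linear interpolation of the simulated curve (with the
#' implied origin included; no extrapolation).
#'
#' @param sim,exp `response_curve`s with matching label and x_kind.
#' @return One-row tibble: slope_ratio, rms_deviation, n_overlap.
#' @export
compare_curves <- function(sim, exp) {
  stopifnot(inherits(sim, "response_curve"), inherits(exp, "response_curve"))
  if (sim$label[1] != exp$label[1] || sim$x_kind[1] != exp$x_kind[1]) {
    abort("curves must share label and x_kind")
  }
  sim_x <- c(0, sim$x); sim_y <- c(0, sim$delta_s)
  exp_x <- c(0, exp$x); exp_y <- c(0, exp$delta_s)
  overlap <- exp$x >= min(sim_x) & exp$x <= max(sim_x)
  if (!any(overlap)) abort("curves have disjoint x ranges")
  pred <- approx(sim_x, sim_y, xout = exp$x[overlap], ties = "ordered")$y
  rms <- sqrt(mean((pred - exp$delta_s[overlap])^2))
  ratio <- fit_response_slope(sim)$slope / fit_response_slope(exp)$slope
  tibble(slope_ratio = ratio, rms_deviation = rms,
         n_overlap = sum(overlap))
}
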