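#' Read a pipeline configuration
#'
#' The configuration is YAML with three blocks:
#' * `paths`: `topology`, optional `trajectories` (list), optional
#'   `charge_map`, optional `experimental_csv`;
#' * `selections`: for each of `lipids`, `phosphate_oxygens`, `solutes`,
#'   `waters`, `markers` either a named-selection label (string) or a list
#'   with `residue_name` / `atom_name` filters; `ch_bonds` as a list of
#'   `{label, residue_name, carbon_name, hydrogen_names}`;
#' * `parameters`: `criterion: {distance_cutoff, bound_fraction}` or
#'   `scan: {distance_grid, fraction_grid}`, and optional `bin_width`,
#'   `contact_cutoff`, `temperature`, `membrane_halfwidth`, `frame_range`,
#'   `seed`.
#'
#' @param path YAML file.
#' @return The configuration list (class `membindr_config`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read config: ", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "membindr_config")
}

resolve_selection <- function(topology, spec) {
  if (is.null(spec)) return(NULL)
  sel <- attr(topology, "selections")
  if (is.character(spec) && length(spec) == 1) {
    if (!is.null(sel[[spec]])) return(sel[[spec]])
    return(select_atoms(topology, residue_name = spec))
  }
  select_atoms(topology,
               residue_name = spec$residue_name,
               atom_name = spec$atom_name,
               element = spec$element)
}

# Defaults standing in for unstated analysis conventions; always echoed
# into the manifest so no silent convention exists.
pipeline_defaults <- function() {
  list(bin_width = 1 / 30, contact_cutoff = 0.325, temperature = 298,
       n_blocks = 5, water_molarity_mM = .WATER_MOLARITY_MM,
       distance_grid = seq(0.1, 1, by = 0.1),
       fraction_grid = seq(0.1, 1, by = 0.1))
}

#' Run the full analysis pipeline
#'
#' Orchestrates one system end to end: load trajectory, equilibration
#' diagnostic, binding-criterion scan and selection (or a fixed criterion),
#' bound-count series with bound-per-lipid and bulk-concentration
#' normalizations, order parameters, density and PMF profiles, contact
#' statistics, and permeation counting. Results are written as TSV/JSON
#' under `out_dir` together with a provenance manifest (package version,
#' parameters including every defaulted convention, input checksums,
#' per-stage status). Identical config and inputs give identical outputs.
#'
#' @param config a `membindr_config` (see [read_analysis_config()]) or an
#'   equivalent list.
#' @param out_dir output directory (created).
#' @param traj optionally, an already-loaded `md_trajectory` (overrides
#'   `config$paths`).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, traj = NULL) {
  par <- utils::modifyList(pipeline_defaults(),
                           config$parameters %||% list())
  if (!is.null(par$seed)) set.seed(as.integer(par$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "membindr",
                   version = as.character(utils::packageVersion("membindr")),
                   parameters = par, stages = list(), inputs = list())
  if (is.null(traj)) {
    if (is.null(config$paths$topology)) {
      abort("config$paths$topology is required when no trajectory is given")
    }
    paths <- c(config$paths$topology, unlist(config$paths$trajectories))
    manifest$inputs <- as.list(tools::md5sum(paths))
    traj <- load_trajectory(config$paths$topology,
                            unlist(config$paths$trajectories) %||% character())
  }
  top <- traj$topology
  scfg <- config$selections %||% list()
  need <- c("lipids", "solutes", "waters")
  sels <- lapply(setNames(nm = c(need, "phosphate_oxygens", "markers")),
                 function(k) resolve_selection(top, scfg[[k]]))
  for (k in need) {
    if (is.null(sels[[k]])) {
      abort(paste0("config selections must resolve '", k, "'"))
    }
  }
  if (!is.null(config$paths$charge_map)) {
    traj$topology <- apply_charge_map(top, read_charge_map(config$paths$charge_map))
    top <- traj$topology
  }
  solutes <- split(sels$solutes,
                   top$molecule_id[match(sels$solutes, top$atom_id)])
  frame_range <- par$frame_range %||% NULL
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "error",
      message = if (ok) "" else conditionMessage(res))
    if (!ok) warn(paste0("stage '", name, "' failed: ",
                         conditionMessage(res)))
    if (ok) res else NULL
  }

  # binding criterion: fixed or scanned
  if (!is.null(par$criterion)) {
    criterion <- binding_criterion(par$criterion$distance_cutoff,
                                   par$criterion$bound_fraction)
    results$criterion_surface <- NULL
  } else {
    results$criterion_surface <- stage("criterion_scan", {
      criterion_scan(traj, solutes, sels$lipids,
                     distance_grid = unlist(par$distance_grid),
                     fraction_grid = unlist(par$fraction_grid),
                     frame_range = frame_range)
    })
    criterion <- select_criterion(results$criterion_surface)
  }
  results$criterion <- criterion

  results$bound_series <- stage("bound_timeseries", {
    bound_timeseries(traj, solutes, sels$lipids, criterion,
                     frame_range = frame_range)
  })
  if (!is.null(results$bound_series)) {
    results$equilibration <- stage("equilibration", {
      equilibration_split(results$bound_series, n_blocks = par$n_blocks)
    })
    results$bound_per_lipid <- stage("bound_per_lipid", {
      bound_per_lipid(results$bound_series)
    })
    results$bulk_concentration_mM <- stage("bulk_concentration", {
      bulk_concentration(results$bound_series)
    })
  }

  if (!is.null(scfg$ch_bonds)) {
    results$order_parameters <- stage("order_parameters", {
      bonds <- purrr::map_dfr(scfg$ch_bonds, function(b) {
        ch_bonds_from_names(top, b$label, b$residue_name, b$carbon_name,
                            unlist(b$hydrogen_names))
      })
      compute_order_parameters(traj, bonds, frame_range,
                               n_blocks = par$n_blocks)
    })
  }

  results$density <- stage("density_profile", {
    density_profile(traj, sels$solutes, bin_width = par$bin_width,
                    center_selection = sels$lipids,
                    frame_range = frame_range, selection_label = "solutes")
  })
  if (!is.null(results$density)) {
    results$pmf <- stage("pmf", {
      pmf_from_density(results$density, temperature = par$temperature)
    })
  }

  results$contacts <- stage("contacts", {
    contact_stats(traj, solutes, sels$lipids,
                  sels$phosphate_oxygens %||% integer(),
                  criterion, cutoff = par$contact_cutoff,
                  frame_range = frame_range)
  })

  if (!is.null(sels$markers) && length(sels$markers) > 0) {
    results$permeation <- stage("permeation", {
      detect_permeations(traj, sels$markers,
                         membrane_halfwidth = par$membrane_halfwidth,
                         frame_range = frame_range)
    })
  }

  # serialize
  wtsv <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(out_dir, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(results$bound_series)) wtsv(results$bound_series, "bound_series.tsv")
  if (!is.null(results$criterion_surface)) {
    wtsv(as_tibble(results$criterion_surface), "criterion_surface.tsv")
  }
  if (!is.null(results$order_parameters)) {
    wtsv(results$order_parameters, "order_parameters.tsv")
  }
  if (!is.null(results$density)) wtsv(results$density, "density.tsv")
  if (!is.null(results$pmf)) wtsv(results$pmf, "pmf.tsv")
  if (!is.null(results$permeation)) wtsv(results$permeation, "permeation.tsv")
  summary <- list(
    criterion = unclass(criterion)[c("distance_cutoff", "bound_fraction")],
    equilibration = results$equilibration,
    bound_per_lipid = results$bound_per_lipid,
    bulk_concentration_mM = results$bulk_concentration_mM,
    contacts = if (!is.null(results$contacts)) {
      as.list(as.data.frame(results$contacts))
    },
    permeation_events = if (!is.null(results$permeation)) {
      nrow(results$permeation)
    })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  manifest$complete <- all(vapply(manifest$stages,
                                  function(s) s$status == "ok", logical(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
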