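#' Read a campaign/family configuration from YAML
#'
#' Recognized top-level keys: `mild`, `severe`, `cco`, `n_per_source`,
#' `base_seed`, `policy` (fields of [run_policy()]), `waveform` (fields of
#' [cardiac_waveform()]), `fluid`, `embolus`, `targets` (`desc_fraction`,
#' `cerebral`), and `network` (fields of [network_template()]). Missing keys
#' fall back to package defaults.
#'
#' @param path YAML file path.
#' @return config list with the fully resolved component objects.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_args <- function(f, over) do.call(f, as.list(over %||% list()))
  `%||%` <- function(a, b) if (is.null(a)) b else a
  template <- merge_args(network_template, cfg$network)
  network <- build_baseline_network(template)
  list(
    raw = cfg,
    network = network,
    models = enumerate_models(mild = cfg$mild %||% c(10, 25, 40),
                              severe = cfg$severe %||% c(50, 70, 85),
                              cco = cfg$cco %||% TRUE),
    policy = merge_args(run_policy, cfg$policy),
    waveform = merge_args(cardiac_waveform, cfg$waveform),
    fluid = merge_args(fluid_properties, cfg$fluid),
    props = merge_args(embolus_properties, cfg$embolus),
    targets = do.call(target_flow_splits,
                      c(list(network = network), as.list(cfg$targets))),
    n_per_source = cfg$n_per_source %||% 5500,
    base_seed = cfg$base_seed %||% 1)
}

#' Write a campaign summary table to CSV
#' @param summary a [summarize_campaign()] frame.
#' @param path output CSV path.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write communicator flow maps for a model family to CSV
#'
#' One row per model label, columns = signed cycle-mean communicating-segment
#' flows (mL/min) plus cervical fractions of total cerebral blood flow.
#'
#' @param flow_maps named list of [communicator_flow_map()] results (names =
#'   model labels).
#' @param path output CSV path.
#' @export
write_flow_map_csv <- function(flow_maps, path) {
  rows <- lapply(names(flow_maps), function(lb) {
    fm <- flow_maps[[lb]]
    data.frame(label = lb, t(fm$flows_ml_min),
               lica_frac = fm$cervical_fractions[["lica"]],
               rica_frac = fm$cervical_fractions[["rica"]],
               ba_frac = fm$cervical_fractions[["ba"]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export trajectories as VTP polylines
#'
#' Writes recorded embolus trajectories (from [integrate_batch()] with
#' `record_every > 0`) as an ASCII VTK PolyData file, one polyline per
#' embolus with time as point data.
#'
#' @param trajectory_set a `trajectory_set` with recorded trajectories.
#' @param path output `.vtp` path.
#' @export
write_trajectories_vtp <- function(trajectory_set, path) {
  tr <- trajectory_set$trajectory
  if (is.null(tr)) stop("no recorded trajectories; rerun with record_every > 0")
  tr <- tr[vapply(tr, function(m) nrow(m) > 1, logical(1))]
  npts <- vapply(tr, nrow, integer(1))
  total <- sum(npts)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('  <PolyData>')
  w('    <Piece NumberOfPoints="%d" NumberOfLines="%d">', total, length(tr))
  w('      <PointData Scalars="time">')
  w('        <DataArray type="Float64" Name="time" format="ascii">')
  for (m in tr) w('          %s', paste(format(m[, 1], digits = 8),
                                        collapse = " "))
  w('        </DataArray>')
  w('      </PointData>')
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  for (m in tr) w('          %s', paste(format(t(m[, 2:4]), digits = 8),
                                        collapse = " "))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Lines>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w('          %s', paste(seq_len(total) - 1, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w('          %s', paste(cumsum(npts), collapse = " "))
  w('        </DataArray>')
  w('      </Lines>')
  w('    </Piece>')
  w('  </PolyData>')
  w('</VTKFile>')
  invisible(path)
}

#' Export network centerlines as VTP polylines with radius point data
#'
#' @param net a `vessel_network`.
#' @param path output `.vtp` path.
#' @param points_per_segment centerline discretization.
#' @export
write_network_vtp <- function(net, path, points_per_segment = 25) {
  cls <- lapply(net$segments$name, function(nm)
    segment_centerline(net, nm, points_per_segment))
  npts <- vapply(cls, nrow, integer(1))
  total <- sum(npts)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('  <PolyData>')
  w('    <Piece NumberOfPoints="%d" NumberOfLines="%d">', total, length(cls))
  w('      <PointData Scalars="radius">')
  w('        <DataArray type="Float64" Name="radius" format="ascii">')
  for (m in cls) w('          %s', paste(format(m$radius, digits = 8),
                                         collapse = " "))
  w('        </DataArray>')
  w('      </PointData>')
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  for (m in cls) w('          %s',
                   paste(format(t(as.matrix(m[, c("x", "y", "z")])),
                                digits = 8), collapse = " "))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Lines>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w('          %s', paste(seq_len(total) - 1, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w('          %s', paste(cumsum(npts), collapse = " "))
  w('        </DataArray>')
  w('      </Lines>')
  w('    </Piece>')
  w('  </PolyData>')
  w('</VTKFile>')
  invisible(path)
}
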