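#' Monte Carlo run policy
#'
#' Sampling and stitching policy for an embolus transport experiment: number
#' of emboli per source, the 10-cycle base horizon, the single 10-cycle
#' extension applied when more than the unresolved-fraction threshold of
#' emboli are still recirculating, and the particle time step.
#'
#' @param n_per_source emboli per release source.
#' @param base_cycles cardiac cycles in the stitched base horizon.
#' @param extension_cycles cycles added (once) when the unresolved fraction
#'   exceeds the threshold.
#' @param unresolved_threshold maximum tolerated unresolved fraction.
#' @param dt particle time step, s.
#' @param seed integer seed.
#' @return object of class `run_policy`.
#' @export
run_policy <- function(n_per_source = 5500, base_cycles = 10,
                       extension_cycles = 10, unresolved_threshold = 0.1,
                       dt = 5e-5, seed = 1) {
  stopifnot(n_per_source > 0, base_cycles >= 1, extension_cycles >= 0,
            unresolved_threshold > 0, unresolved_threshold < 1, dt > 0)
  structure(list(n_per_source = n_per_source, base_cycles = base_cycles,
                 extension_cycles = extension_cycles,
                 unresolved_threshold = unresolved_threshold,
                 dt = dt, seed = seed),
            class = "run_policy")
}

#' Extend the periodic flow field over stitched cardiac cycles
#'
#' The periodic cycle solution is stitched end-to-end with no cycle-to-cycle
#' variation: `u(x, t + T) = u(x, t)` over the whole horizon
#' `n_cycles * T`.
#'
#' @param field a [segment_velocity_field()].
#' @param n_cycles number of cycles in the horizon.
#' @return the field with its time horizon extended.
#' @export
stitch_cycles <- function(field, n_cycles) {
  stopifnot(inherits(field, "velocity_field"), n_cycles >= 1)
  field$horizon <- n_cycles * field$period
  field
}

#' Sample embolus release states
#'
#' Carotid sources: positions uniform over the stenosis-length wall patch of
#' the release carotid, offset inward from the wall by the embolus radius
#' (uniform in arc length and azimuth). Cardiogenic source: positions uniform
#' over the aortic-root inlet disc of radius `R_inlet - a`. Release times are
#' uniform over one cardiac cycle. Reproducible per seed.
#'
#' @param source `"left_carotid"`, `"right_carotid"` or `"cardiogenic"`.
#' @param network the (stenosed) `vessel_network` of the model.
#' @param n number of emboli.
#' @param radius embolus radius, mm.
#' @param seed integer seed.
#' @param period cardiac cycle duration, s.
#' @return data.frame with `x`, `y`, `z` (mm), `t0` (s), `segment`, `source`.
#' @export
sample_release <- function(source = c("left_carotid", "right_carotid",
                                      "cardiogenic"),
                           network, n, radius = 0.25, seed = 1,
                           period = 0.83) {
  source <- match.arg(source)
  stopifnot(n > 0)
  seg_name <- switch(source, left_carotid = "ica_L", right_carotid = "ica_R",
                     cardiogenic = "asc_aorta")
  i <- match(seg_name, network$segments$name)
  sg <- network$segments[i, ]
  if (sg$occluded)
    stop("cannot release emboli from an occluded carotid (", seg_name, ")")
  fr <- .seg_frame(network, seg_name)
  local_seed(seed, {
    if (source == "cardiogenic") {
      s0 <- 0.5
      Rin <- segment_radius(network, seg_name, s0)
      rho <- (Rin - radius) * sqrt(runif(n))
      phi <- runif(n, 0, 2 * pi)
      s <- rep(s0, n)
    } else {
      if (sg$severity > 0) {
        lo <- sg$sten_center - sg$sten_length / 2
        hi <- sg$sten_center + sg$sten_length / 2
      } else {  # no stenosis: central third of the carotid
        lo <- sg$L / 3; hi <- 2 * sg$L / 3
      }
      s <- runif(n, lo, hi)
      phi <- runif(n, 0, 2 * pi)
      rho <- segment_radius(network, seg_name, s) - radius
    }
    t0 <- runif(n, 0, period)
    pts <- t(vapply(seq_len(n), function(k) {
      fr$p0 + s[k] * fr$ez + rho[k] * (cos(phi[k]) * fr$e1 +
                                         sin(phi[k]) * fr$e2)
    }, numeric(3)))
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], t0 = t0,
               segment = seg_name, source = source, stringsAsFactors = FALSE)
  })
}

#' Run one embolus transport experiment
#'
#' One (model, release source) simulation unit: applies the model's bilateral
#' stenoses, solves the pulsatile network flow with the held-fixed tuned
#' outlet resistances, reconstructs the velocity field, releases the Monte
#' Carlo embolus batch and integrates it over the stitched base horizon.
#' If more than the policy threshold of emboli remain unresolved, all
#' unresolved trajectories are extended once by the extension cycles.
#' Deterministic for a given seed.
#'
#' @param spec a list or one-row data.frame with `label`, `left`, `right`,
#'   `source`, `n`, `seed` (see [enumerate_experiments()]).
#' @param network baseline `vessel_network`.
#' @param resistances tuned [tune_outlet_resistances()] set (held fixed
#'   across models).
#' @param waveform a [cardiac_waveform()].
#' @param fluid a [fluid_properties()].
#' @param props an [embolus_properties()].
#' @param policy a [run_policy()]; `spec$n`/`spec$seed` override its counts.
#' @param solution optional precomputed `flow_solution` for the model.
#' @param keep_trajectories keep the full `trajectory_set` in the result.
#' @return object of class `experiment_result`: the `distribution_record`
#'   (outlet counts, unresolved count, flags) plus per-trajectory fates and
#'   visited-segment lists.
#' @export
run_experiment <- function(spec, network, resistances,
                           waveform = cardiac_waveform(),
                           fluid = fluid_properties(),
                           props = embolus_properties(),
                           policy = run_policy(), solution = NULL,
                           keep_trajectories = FALSE) {
  n <- if (!is.null(spec$n)) spec$n else policy$n_per_source
  seed <- if (!is.null(spec$seed)) spec$seed else policy$seed
  net_m <- apply_model(network, spec)
  if (is.null(solution))
    solution <- solve_unsteady(net_m, waveform, resistances, fluid)
  field <- segment_velocity_field(solution, net_m, fluid)
  field <- stitch_cycles(field, policy$base_cycles)
  rel <- sample_release(spec$source, net_m, n,
                        radius = props$diameter_um * 5e-4, seed = seed,
                        period = waveform$period)
  ts <- integrate_batch(field, rel, props, fluid, dt = policy$dt)
  unresolved <- which(ts$fates$status == "unresolved")
  extended <- FALSE
  if (length(unresolved) / n > policy$unresolved_threshold &&
      policy$extension_cycles > 0) {
    extended <- TRUE
    horizon2 <- (policy$base_cycles + policy$extension_cycles) *
      waveform$period
    rel2 <- rel[unresolved, , drop = FALSE]
    rel2$x <- ts$position[unresolved, 1]
    rel2$y <- ts$position[unresolved, 2]
    rel2$z <- ts$position[unresolved, 3]
    rel2$t0 <- ts$fates$t_final[unresolved]
    rel2$segment <- vapply(ts$visited[unresolved],
                           function(v) v[length(v)], character(1))
    ts2 <- integrate_batch(field, rel2, props, fluid, dt = policy$dt,
                           horizon = horizon2,
                           v0 = ts$velocity[unresolved, , drop = FALSE])
    ts$fates[unresolved, c("status", "outlet", "exit_time", "t_final",
                           "collisions")] <-
      data.frame(ts2$fates$status, ts2$fates$outlet, ts2$fates$exit_time,
                 ts2$fates$t_final,
                 ts$fates$collisions[unresolved] + ts2$fates$collisions)
    ts$position[unresolved, ] <- ts2$position
    ts$visited[unresolved] <- Map(function(a, b) c(a, b[-1]),
                                  ts$visited[unresolved], ts2$visited)
  }
  counts <- table(factor(ts$fates$outlet, levels = network$outlets))
  n_unres <- sum(ts$fates$status == "unresolved")
  record <- structure(list(
    label = spec$label, source = spec$source, seed = seed, n = n,
    counts = stats::setNames(as.integer(counts), names(counts)),
    unresolved = n_unres, extended = extended,
    above_threshold = n_unres / n > policy$unresolved_threshold,
    cycles = policy$base_cycles +
      if (extended) policy$extension_cycles else 0),
    class = "distribution_record")
  structure(list(record = record, fates = ts$fates, visited = ts$visited,
                 trajectories = if (keep_trajectories) ts else NULL),
            class = "experiment_result")
}

#' @export
print.distribution_record <- function(x, ...) {
  cat(sprintf("<distribution_record> %s / %s (n = %d, seed %d)\n",
              x$label, x$source, x$n, x$seed))
  print(x$counts)
  cat(sprintf("  unresolved %d (%.2f%%)%s%s\n", x$unresolved,
              100 * x$unresolved / x$n,
              if (x$extended) ", extended" else "",
              if (x$above_threshold) ", ABOVE THRESHOLD" else ""))
  invisible(x)
}

#' Run the full in silico experiment campaign
#'
#' Tunes outlet resistances once on the baseline network, then executes every
#' experiment of the family (78 at defaults), reusing the held-fixed
#' resistances across all models. Per-experiment failures are isolated and
#' reported; completed experiments found in `out_dir` with a matching
#' configuration hash are skipped (resumable).
#'
#' @param experiments an [enumerate_experiments()] frame.
#' @param network baseline `vessel_network`.
#' @param policy a [run_policy()].
#' @param waveform,fluid,props model conditions.
#' @param targets a [target_flow_splits()] object (default baseline targets).
#' @param resistances optional pre-tuned resistances (skips tuning).
#' @param out_dir optional directory for per-experiment JSON records and the
#'   campaign manifest.
#' @param progress print progress lines.
#' @return object of class `campaign_result`: `records` (list of
#'   `distribution_record`), `failures`, `manifest`, and the per-experiment
#'   CCA recruitment bookkeeping for cardiogenic sources.
#' @export
run_campaign <- function(experiments, network, policy = run_policy(),
                         waveform = cardiac_waveform(),
                         fluid = fluid_properties(),
                         props = embolus_properties(),
                         targets = target_flow_splits(network),
                         resistances = NULL, out_dir = NULL,
                         progress = FALSE) {
  stopifnot(inherits(experiments, "experiment_set"))
  if (is.null(resistances))
    resistances <- tune_outlet_resistances(network, targets, waveform, fluid)
  manifest <- list(
    package_version = as.character(utils::packageVersion("emboflow")),
    n_experiments = nrow(experiments),
    policy = unclass(policy),
    waveform = list(period = waveform$period, mean_flow = waveform$mean_flow),
    fluid = unclass(fluid), props = unclass(props),
    resistances = as.list(resistances$resistances),
    seeds = experiments$seed)
  hash <- .content_hash(manifest)
  manifest$hash <- hash
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  records <- list()
  failures <- list()
  cca <- list()
  sol_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(experiments))) {
    sp <- as.list(experiments[i, ])
    key <- paste0(sp$label, "_", sp$source)
    rec_path <- if (!is.null(out_dir)) file.path(out_dir, paste0(key, ".json"))
    if (!is.null(out_dir) && file.exists(rec_path)) {
      prev <- jsonlite::read_json(rec_path, simplifyVector = TRUE)
      if (identical(prev$hash, hash)) {
        cc <- unlist(prev$record$counts)
        prev$record$counts <- stats::setNames(as.integer(cc), names(cc))
        records[[key]] <- structure(prev$record, class = "distribution_record")
        if (progress) message("skip (cached): ", key)
        next
      }
    }
    res <- tryCatch({
      if (!exists(sp$label, envir = sol_cache)) {
        net_m <- apply_model(network, sp)
        assign(sp$label, solve_unsteady(net_m, waveform, resistances, fluid),
               envir = sol_cache)
      }
      run_experiment(sp, network, resistances, waveform, fluid, props,
                     policy, solution = get(sp$label, envir = sol_cache))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      if (progress) message("FAILED: ", key, " - ", conditionMessage(res))
      next
    }
    records[[key]] <- res$record
    if (sp$source == "cardiogenic")
      cca[[key]] <- cca_recruitment_split(res$visited)
    if (!is.null(out_dir)) {
      rec_out <- unclass(res$record)
      rec_out$counts <- as.list(rec_out$counts)
      jsonlite::write_json(list(hash = hash, record = rec_out),
                           rec_path, auto_unbox = TRUE, digits = NA)
    }
    if (progress)
      message(sprintf("[%d/%d] %s: unresolved %.1f%%", i, nrow(experiments),
                      key, 100 * res$record$unresolved / res$record$n))
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  structure(list(records = records, failures = failures, manifest = manifest,
                 cca_splits = cca, resistances = resistances),
            class = "campaign_result")
}

# stable content hash of a config list (via canonical JSON + md5)
.content_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
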