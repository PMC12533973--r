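#' Enumerate the bilateral-stenosis model family
#'
#' Builds the parametric model set: every pairing of one mild and one
#' moderate/severe severity assigned to each side (`2 * |mild| * |severe|`
#' bilateral models), plus, when `cco = TRUE`, the contralateral carotid
#' occlusion set: one carotid fully occluded (100%) paired with every mild and
#' moderate/severe severity on the other side (`2 * (|mild| + |severe|)`
#' models). Defaults give the 18 + 12 = 30 model family. Labels follow the
#' `"<left>L<right>R"` convention (e.g. `10L50R` = 10% left, 50% right).
#'
#' @param mild mild NASCET severities, percent.
#' @param severe moderate/severe NASCET severities, percent.
#' @param cco include the 100%-occlusion (CCO) set.
#' @return data.frame of class `model_family` with columns `label`,
#'   `left`, `right`, `is_cco`.
#' @export
enumerate_models <- function(mild = c(10, 25, 40), severe = c(50, 70, 85),
                             cco = TRUE) {
  if (length(intersect(mild, severe)) > 0)
    stop("mild and moderate/severe severity sets must not overlap")
  stopifnot(all(mild > 0 & mild < 100), all(severe > 0 & severe < 100))
  rows <- list()
  for (m in mild) for (s in severe) {
    rows[[length(rows) + 1]] <- data.frame(left = m, right = s)
    rows[[length(rows) + 1]] <- data.frame(left = s, right = m)
  }
  bilateral <- if (length(rows)) do.call(rbind, rows) else
    data.frame(left = numeric(0), right = numeric(0))
  bilateral$is_cco <- rep(FALSE, nrow(bilateral))
  if (cco) {
    other <- c(mild, severe)
    if (length(other) > 0) {
      ccoset <- rbind(data.frame(left = 100, right = other),
                      data.frame(left = other, right = 100))
      ccoset$is_cco <- TRUE
      bilateral <- rbind(bilateral, ccoset)
    }
  }
  if (nrow(bilateral) == 0)
    return(structure(data.frame(label = character(0), left = numeric(0),
                                right = numeric(0), is_cco = logical(0)),
                     class = c("model_family", "data.frame")))
  bilateral$label <- sprintf("%gL%gR", bilateral$left, bilateral$right)
  if (anyDuplicated(bilateral$label)) stop("duplicate model labels")
  rownames(bilateral) <- NULL
  structure(bilateral[, c("label", "left", "right", "is_cco")],
            class = c("model_family", "data.frame"))
}

#' Enumerate the embolus release experiments for a model family
#'
#' Non-CCO models admit three release sources (left carotid, right carotid,
#' cardiogenic); CCO models admit two (the patent carotid and cardiogenic) —
#' emboli are never released from a fully occluded carotid. Experiment seeds
#' are derived deterministically and distinctly from `base_seed`.
#'
#' @param models a `model_family` from [enumerate_models()].
#' @param n_per_source emboli released per experiment.
#' @param base_seed integer seed root.
#' @return data.frame of class `experiment_set` with one row per experiment:
#'   `label`, `left`, `right`, `is_cco`, `source`, `n`, `seed`.
#' @export
enumerate_experiments <- function(models, n_per_source = 5500, base_seed = 1) {
  stopifnot(inherits(models, "model_family"), n_per_source > 0)
  rows <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    sources <- if (!m$is_cco) c("left_carotid", "right_carotid", "cardiogenic")
               else if (m$left >= 100) c("right_carotid", "cardiogenic")
               else c("left_carotid", "cardiogenic")
    for (src in sources)
      rows[[length(rows) + 1]] <- data.frame(
        label = m$label, left = m$left, right = m$right, is_cco = m$is_cco,
        source = src, n = n_per_source, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(structure(data.frame(label = character(0), left = numeric(0),
                                right = numeric(0), is_cco = logical(0),
                                source = character(0), n = integer(0),
                                seed = integer(0)),
                     class = c("experiment_set", "data.frame")))
  out <- do.call(rbind, rows)
  out$seed <- as.integer((base_seed + 7919 * seq_len(nrow(out))) %% 2147483647L)
  rownames(out) <- NULL
  structure(out, class = c("experiment_set", "data.frame"))
}

#' Apply a model's bilateral stenoses to the baseline network
#'
#' @param network baseline `vessel_network`.
#' @param model one row of a `model_family` (or a list with `left`, `right`).
#' @return stenosed `vessel_network`.
#' @export
apply_model <- function(network, model) {
  net <- apply_stenosis(network, stenosis_spec("left", model$left))
  apply_stenosis(net, stenosis_spec("right", model$right))
}

#' Serialize a network to JSON
#'
#' Writes segments (with discretized centerlines and radius profiles), nodes
#' and outlet bookkeeping. Byte-stable for identical networks.
#'
#' @param net a `vessel_network`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @param centerline_points points per segment centerline.
#' @return JSON string (invisibly if written to `path`).
#' @export
network_to_json <- function(net, path = NULL, centerline_points = 25) {
  segs <- lapply(seq_len(nrow(net$segments)), function(i) {
    sg <- net$segments[i, ]
    cl <- segment_centerline(net, sg$name, centerline_points)
    list(name = sg$name, prox = sg$prox, dist = sg$dist,
         r0 = sg$r0, r1 = sg$r1, L = sg$L, severity = sg$severity,
         occluded = sg$occluded, outlet = sg$outlet,
         centerline = unname(as.matrix(cl[, c("x", "y", "z")])),
         radius_profile = cl$radius)
  })
  obj <- list(nodes = net$nodes, inlet = net$inlet, outlets = net$outlets,
              hemisphere_map = as.list(net$hemisphere_map), segments = segs)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
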