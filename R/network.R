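#' Baseline heart-to-brain network template
#'
#' Returns the configuration for the synthetic single-inlet, eleven-outlet
#' arterial tree: aortic root inlet; descending aorta, left/right subclavian,
#' left/right external carotid, and the six cerebral outlets (M1, A1->A2, P2),
#' joined by a complete Circle of Willis (AcoA, both posterior communicators,
#' both P1 segments). Geometry is left-right symmetric in segment lengths and
#' radii; in the default layout the brachiocephalic trunk branches off the
#' aortic arch first (right cervical vessels originate proximal to the left),
#' the one deliberate asymmetry of the template. Coordinates are mm,
#' right-handed, patient-left = +x, anterior = +y, superior = +z.
#'
#' @param symmetric_arch if `TRUE`, build a perfectly mirror-symmetric arch
#'   (both cervical trunks branch from the same arch node); used for symmetry
#'   oracles rather than physiologic realism.
#' @param stenosis_site_fraction arc-length fraction of the internal carotid
#'   at which a stenosis throat is centred (proximal ICA default).
#' @param stenosis_length_k proportionality constant of the stenosis-length
#'   rule (see [stenosis_length()]).
#' @return a config list with `nodes`, `segments` data frames and options.
#' @export
network_template <- function(symmetric_arch = FALSE,
                             stenosis_site_fraction = 0.3,
                             stenosis_length_k = 0.5) {
  node <- function(id, x, y, z, kind = "junction", hemisphere = "none")
    data.frame(id = id, x = x, y = y, z = z, kind = kind,
               hemisphere = hemisphere, stringsAsFactors = FALSE)
  seg <- function(name, prox, dist, r0, r1, outlet = NA_character_)
    data.frame(name = name, prox = prox, dist = dist, r0 = r0, r1 = r1,
               outlet = outlet, stringsAsFactors = FALSE)

  nodes <- rbind(
    node("root", 0, 0, 0, kind = "inlet"),
    node("arch1", 0, 0, 45),
    node("desc_out", if (symmetric_arch) 0 else 24, 0, -55, kind = "outlet"),
    node("vert_R", -40, 0, 60), node("vert_L", 40, 0, 60),
    node("sub_out_R", -70, 0, 52, kind = "outlet"),
    node("sub_out_L", 70, 0, 52, kind = "outlet"),
    node("bif_R", -18, 0, 120), node("bif_L", 18, 0, 120),
    node("eca_out_R", -22, 10, 170, kind = "outlet"),
    node("eca_out_L", 22, 10, 170, kind = "outlet"),
    node("ica_t_R", -12, 0, 165), node("ica_t_L", 12, 0, 165),
    node("vb", 0, -12, 140), node("ba_top", 0, -8, 158),
    node("p_R", -7, -5, 162), node("p_L", 7, -5, 162),
    node("pca_out_R", -24, -14, 172, kind = "outlet", hemisphere = "right"),
    node("pca_out_L", 24, -14, 172, kind = "outlet", hemisphere = "left"),
    node("mca_out_R", -38, 2, 166, kind = "outlet", hemisphere = "right"),
    node("mca_out_L", 38, 2, 166, kind = "outlet", hemisphere = "left"),
    node("acoa_R", -3, 8, 168), node("acoa_L", 3, 8, 168),
    node("aca_out_R", -4, 16, 192, kind = "outlet", hemisphere = "right"),
    node("aca_out_L", 4, 16, 192, kind = "outlet", hemisphere = "left"))

  if (symmetric_arch) {
    nodes <- rbind(nodes,
                   node("bct_R", -14, 0, 75), node("bct_L", 14, 0, 75))
    arch <- rbind(
      seg("asc_aorta", "root", "arch1", 12.5, 11.5),
      seg("desc_aorta", "arch1", "desc_out", 11.0, 9.5, outlet = "desc_aorta"),
      seg("trunk_R", "arch1", "bct_R", 6.0, 5.5),
      seg("trunk_L", "arch1", "bct_L", 6.0, 5.5),
      seg("cca_R", "bct_R", "bif_R", 3.5, 3.2),
      seg("cca_L", "bct_L", "bif_L", 3.5, 3.2),
      seg("sub_R1", "bct_R", "vert_R", 4.5, 4.3),
      seg("sub_L1", "bct_L", "vert_L", 4.5, 4.3))
  } else {
    # the arch curves smoothly over its apex into the descending aorta;
    # the brachiocephalic trunk takes off first (most proximal) and rises
    nodes <- rbind(nodes,
                   node("arch2", 3, 0, 52), node("arch3", 9, 0, 55),
                   node("arch4", 16, 0, 52), node("arch5", 22, 0, 40),
                   node("bct", -14, 0, 75))
    arch <- rbind(
      seg("asc_aorta", "root", "arch1", 12.5, 11.5),
      seg("arch_a", "arch1", "arch2", 11.5, 11.2),
      seg("arch_b", "arch2", "arch3", 11.2, 11.0),
      seg("arch_c", "arch3", "arch4", 11.0, 10.8),
      seg("arch_d", "arch4", "arch5", 10.8, 10.5),
      seg("desc_aorta", "arch5", "desc_out", 10.5, 9.5, outlet = "desc_aorta"),
      seg("brachiocephalic", "arch2", "bct", 6.0, 5.5),
      seg("cca_R", "bct", "bif_R", 3.5, 3.2),
      seg("cca_L", "arch3", "bif_L", 3.5, 3.2),
      seg("sub_R1", "bct", "vert_R", 4.5, 4.3),
      seg("sub_L1", "arch4", "vert_L", 4.5, 4.3))
  }

  segments <- rbind(
    arch,
    seg("sub_R2", "vert_R", "sub_out_R", 4.3, 4.0, outlet = "sub_R"),
    seg("sub_L2", "vert_L", "sub_out_L", 4.3, 4.0, outlet = "sub_L"),
    seg("ica_R", "bif_R", "ica_t_R", 3.0, 3.0),
    seg("ica_L", "bif_L", "ica_t_L", 3.0, 3.0),
    seg("eca_R", "bif_R", "eca_out_R", 2.0, 1.8, outlet = "eca_R"),
    seg("eca_L", "bif_L", "eca_out_L", 2.0, 1.8, outlet = "eca_L"),
    seg("vert_R", "vert_R", "vb", 1.9, 1.8),
    seg("vert_L", "vert_L", "vb", 1.9, 1.8),
    seg("basilar", "vb", "ba_top", 1.8, 1.7),
    # CoW communicating segments; sign conventions are fixed by orientation:
    # AcoA positive = right -> left, PcoA positive = posterior -> anterior,
    # P1 positive = basilar -> posterior cerebral.
    seg("p1_R", "ba_top", "p_R", 1.1, 1.1),
    seg("p1_L", "ba_top", "p_L", 1.1, 1.1),
    seg("pcoa_R", "p_R", "ica_t_R", 0.6, 0.6),
    seg("pcoa_L", "p_L", "ica_t_L", 0.6, 0.6),
    seg("acoa", "acoa_R", "acoa_L", 0.7, 0.7),
    seg("pca_R", "p_R", "pca_out_R", 1.1, 1.0, outlet = "pca_R"),
    seg("pca_L", "p_L", "pca_out_L", 1.1, 1.0, outlet = "pca_L"),
    seg("mca_R", "ica_t_R", "mca_out_R", 1.5, 1.4, outlet = "mca_R"),
    seg("mca_L", "ica_t_L", "mca_out_L", 1.5, 1.4, outlet = "mca_L"),
    seg("a1_R", "ica_t_R", "acoa_R", 1.2, 1.2),
    seg("a1_L", "ica_t_L", "acoa_L", 1.2, 1.2),
    seg("aca_R", "acoa_R", "aca_out_R", 1.2, 1.1, outlet = "aca_R"),
    seg("aca_L", "acoa_L", "aca_out_L", 1.2, 1.1, outlet = "aca_L"))

  list(nodes = nodes, segments = segments,
       symmetric_arch = symmetric_arch,
       stenosis_site_fraction = stenosis_site_fraction,
       stenosis_length_k = stenosis_length_k)
}

.required_segments <- c(
  "asc_aorta", "desc_aorta", "cca_L", "cca_R", "ica_L", "ica_R",
  "eca_L", "eca_R", "sub_R2", "sub_L2", "vert_L", "vert_R", "basilar",
  "p1_L", "p1_R", "pcoa_L", "pcoa_R", "acoa", "a1_L", "a1_R",
  "mca_L", "mca_R", "aca_L", "aca_R", "pca_L", "pca_R")

#' Build the baseline (no-stenosis) vessel network
#'
#' Validates the template and assembles a `vessel_network`: segment table with
#' computed lengths, inlet/outlet bookkeeping, and the outlet hemisphere map.
#' Deterministic for a given configuration.
#'
#' @param config a template from [network_template()] (possibly modified).
#' @return object of class `vessel_network`.
#' @export
build_baseline_network <- function(config = network_template()) {
  nodes <- config$nodes
  segs <- config$segments
  missing <- setdiff(.required_segments, segs$name)
  if (length(missing) > 0) {
    stop("baseline network configuration is missing required segment(s): ",
         paste(missing, collapse = ", "),
         " (a complete Circle of Willis and all cervical vessels are required)")
  }
  if (anyDuplicated(segs$name)) stop("duplicate segment names in configuration")
  bad <- setdiff(c(segs$prox, segs$dist), nodes$id)
  if (length(bad) > 0) stop("segment endpoint references unknown node: ",
                            paste(unique(bad), collapse = ", "))
  if (any(segs$prox == segs$dist)) stop("segment must connect two distinct nodes")
  if (any(segs$r0 <= 0 | segs$r1 <= 0)) stop("all radii must be positive")

  xyz <- function(id) unlist(nodes[match(id, nodes$id), c("x", "y", "z")])
  g0 <- t(vapply(segs$prox, xyz, numeric(3)))
  g1 <- t(vapply(segs$dist, xyz, numeric(3)))

  # Ostium placement: a side branch joining a through-vessel attaches on the
  # through-vessel wall, not its centerline. For each segment end, if the
  # node hosts a pair of roughly collinear segments both substantially wider
  # than this one, the geometric endpoint is moved radially to that pair's
  # wall (the hydraulic topology is unchanged).
  end_dir <- function(i, at_prox) {
    d <- g1[i, ] - g0[i, ]
    d <- d / sqrt(sum(d^2))
    if (at_prox) d else -d  # away from the node into the segment
  }
  end_radius <- function(i, at_prox) if (at_prox) segs$r0[i] else segs$r1[i]
  for (i in seq_len(nrow(segs))) {
    for (at_prox in c(TRUE, FALSE)) {
      nd <- if (at_prox) segs$prox[i] else segs$dist[i]
      others <- setdiff(which(segs$prox == nd | segs$dist == nd), i)
      big <- others[vapply(others, function(j)
        end_radius(j, segs$prox[j] == nd), numeric(1)) >=
          1.5 * end_radius(i, at_prox)]
      if (length(big) < 2) next
      rr <- vapply(big, function(j) end_radius(j, segs$prox[j] == nd),
                   numeric(1))
      big <- big[order(-rr)][1:2]
      a1 <- end_dir(big[1], segs$prox[big[1]] == nd)
      a2 <- end_dir(big[2], segs$prox[big[2]] == nd)
      if (sum(a1 * a2) > -0.4) next  # not a through-vessel passage
      axis <- a2  # through direction
      Rp <- min(vapply(big, function(j) end_radius(j, segs$prox[j] == nd),
                       numeric(1)))
      d <- end_dir(i, at_prox)
      dr <- d - sum(d * axis) * axis
      ndr <- sqrt(sum(dr^2))
      if (ndr < 0.2) next  # branch collinear with parent: keep centerline
      off <- 0.9 * Rp * dr / ndr
      if (at_prox) g0[i, ] <- g0[i, ] + off else g1[i, ] <- g1[i, ] + off
    }
  }
  L <- sqrt(rowSums((g1 - g0)^2))
  if (any(L <= 0)) stop("zero-length segment in configuration")
  segs$L <- L
  segs$gx0 <- g0[, 1]; segs$gy0 <- g0[, 2]; segs$gz0 <- g0[, 3]
  segs$gx1 <- g1[, 1]; segs$gy1 <- g1[, 2]; segs$gz1 <- g1[, 3]
  segs$severity <- 0
  segs$sten_center <- NA_real_
  segs$sten_length <- NA_real_
  segs$r_ref <- NA_real_
  segs$occluded <- FALSE
  segs$id <- seq_len(nrow(segs))

  outlets <- segs$outlet[!is.na(segs$outlet)]
  if (length(outlets) != 11) stop("network must expose exactly 11 outlets, got ",
                                  length(outlets))
  inlet <- nodes$id[nodes$kind == "inlet"]
  if (length(inlet) != 1) stop("network must have exactly one inlet node")
  hemi <- nodes$hemisphere[match(segs$dist[!is.na(segs$outlet)], nodes$id)]
  hemisphere_map <- stats::setNames(hemi, outlets)

  net <- structure(list(nodes = nodes, segments = segs, inlet = inlet,
                        outlets = sort(outlets), hemisphere_map = hemisphere_map,
                        options = config[c("symmetric_arch",
                                           "stenosis_site_fraction",
                                           "stenosis_length_k")]),
                   class = "vessel_network")
  .check_connected(net)
  net
}

.check_connected <- function(net) {
  segs <- net$segments
  live <- segs[!segs$occluded, ]
  reach <- net$inlet
  repeat {
    nxt <- unique(c(live$dist[live$prox %in% reach],
                    live$prox[live$dist %in% reach]))
    add <- setdiff(nxt, reach)
    if (length(add) == 0) break
    reach <- c(reach, add)
  }
  out_nodes <- net$nodes$id[net$nodes$kind == "outlet"]
  lost <- setdiff(out_nodes, reach)
  if (length(lost) > 0)
    stop("outlet node(s) disconnected from inlet: ", paste(lost, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network> ", nrow(x$segments), " segments, ",
      nrow(x$nodes), " nodes, inlet '", x$inlet, "', ",
      length(x$outlets), " outlets\n", sep = "")
  sten <- x$segments[x$segments$severity > 0, ]
  if (nrow(sten) > 0) {
    for (i in seq_len(nrow(sten)))
      cat(sprintf("  stenosis: %s %g%% (throat %.3g mm, length %.3g mm)%s\n",
                  sten$name[i], sten$severity[i],
                  sten$r_ref[i] * (1 - sten$severity[i] / 100),
                  sten$sten_length[i],
                  if (sten$occluded[i]) " [occluded]" else ""))
  } else cat("  no stenosis (baseline)\n")
  invisible(x)
}

#' NASCET stenosis severity from radii
#'
#' Diameter-ratio criterion: `(1 - d_min/d_ref) * 100`, equal to the radius
#' ratio for a circular lumen.
#'
#' @param r_min minimum (throat) radius, mm.
#' @param r_ref reference healthy lumen radius, mm.
#' @return severity in percent, in `[0, 100]`.
#' @export
nascet_severity <- function(r_min, r_ref) {
  stopifnot(r_ref > 0, r_min >= 0)
  if (any(r_min > r_ref)) stop("r_min exceeds r_ref: negative severity not allowed")
  (1 - r_min / r_ref) * 100
}

#' Stenosis length rule
#'
#' Stenosis axial extent grows in proportion to severity:
#' `L = k * (severity/100) * L_ref`, zero at zero severity and strictly
#' increasing in severity.
#'
#' @param severity NASCET percent in `[0, 100]`.
#' @param L_ref reference length, mm (the host carotid segment length).
#' @param k dimensionless proportionality constant.
#' @return stenosis length, mm.
#' @export
stenosis_length <- function(severity, L_ref, k = 0.5) {
  stopifnot(all(severity >= 0 & severity <= 100), L_ref > 0, k > 0)
  k * (severity / 100) * L_ref
}

#' Stenosis specification for one carotid
#'
#' @param side `"left"` or `"right"`.
#' @param severity NASCET percent in `{0..100}`; 100 marks complete occlusion.
#' @param site_segment segment name carrying the stenosis (proximal ICA default).
#' @return object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(side = c("left", "right"), severity,
                          site_segment = NULL) {
  side <- match.arg(side)
  stopifnot(is.numeric(severity), severity >= 0, severity <= 100)
  if (is.null(site_segment))
    site_segment <- if (side == "left") "ica_L" else "ica_R"
  structure(list(side = side, severity = severity, site_segment = site_segment),
            class = "stenosis_spec")
}

#' Apply a NASCET stenosis to a carotid segment
#'
#' Imposes a smooth cosine taper on the radius profile over the stenosis
#' length, reaching throat radius `r_ref * (1 - severity/100)` at the throat.
#' Severity 0 returns the network unchanged; severity 100 flags the segment
#' occluded (zero lumen, no flow, no release), leaving downstream vessels
#' reachable via the Circle of Willis.
#'
#' @param network a `vessel_network`.
#' @param spec a [stenosis_spec()].
#' @return modified `vessel_network`.
#' @export
apply_stenosis <- function(network, spec) {
  stopifnot(inherits(network, "vessel_network"), inherits(spec, "stenosis_spec"))
  if (spec$severity == 0) return(network)
  segs <- network$segments
  i <- match(spec$site_segment, segs$name)
  if (is.na(i)) stop("unknown segment: ", spec$site_segment)
  if (!grepl("^ica_", segs$name[i]))
    stop("stenosis can only be applied to a carotid (ICA) segment, not ",
         segs$name[i])
  L <- segs$L[i]
  frac <- network$options$stenosis_site_fraction
  slen <- stenosis_length(spec$severity, L, network$options$stenosis_length_k)
  sc <- min(max(frac * L, slen / 2), L - slen / 2)
  segs$severity[i] <- spec$severity
  segs$sten_center[i] <- sc
  segs$sten_length[i] <- slen
  # reference radius = undiseased lumen radius at the throat location
  segs$r_ref[i] <- segs$r0[i] + (segs$r1[i] - segs$r0[i]) * sc / L
  segs$occluded[i] <- spec$severity >= 100
  network$segments <- segs
  if (!segs$occluded[i]) return(network)
  .check_connected(network)
  network
}

#' Radius profile of a segment
#'
#' Lumen radius (and its axial derivatives) at arc length `s` from the
#' proximal node: linear base taper modulated by the cosine stenosis taper.
#' This is the single radius law shared by the resistance integrals, release
#' sampling and (mirrored in compiled code) the velocity field.
#'
#' @param net a `vessel_network`.
#' @param segment segment name.
#' @param s arc length(s) from proximal node, mm.
#' @return radius, mm (vectorized over `s`).
#' @export
segment_radius <- function(net, segment, s) {
  i <- match(segment, net$segments$name)
  if (is.na(i)) stop("unknown segment: ", segment)
  sg <- net$segments[i, ]
  r <- sg$r0 + (sg$r1 - sg$r0) * s / sg$L
  if (sg$severity > 0 && !sg$occluded) {
    h <- sg$sten_length / 2
    u <- (s - sg$sten_center) / h
    f <- 1 - sg$severity / 100
    m <- ifelse(abs(u) < 1, 1 - (1 - f) * 0.5 * (1 + cos(pi * u)), 1)
    r <- r * m
  }
  if (sg$occluded) r[] <- 0
  r
}

#' Discretized centerline of a segment
#'
#' @param net a `vessel_network`.
#' @param segment segment name.
#' @param n number of points.
#' @return data.frame with columns `s`, `x`, `y`, `z`, `radius`.
#' @export
segment_centerline <- function(net, segment, n = 50) {
  i <- match(segment, net$segments$name)
  if (is.na(i)) stop("unknown segment: ", segment)
  sg <- net$segments[i, ]
  p0 <- c(sg$gx0, sg$gy0, sg$gz0)
  p1 <- c(sg$gx1, sg$gy1, sg$gz1)
  s <- seq(0, sg$L, length.out = n)
  f <- s / sg$L
  data.frame(s = s,
             x = p0[1] + (p1[1] - p0[1]) * f,
             y = p0[2] + (p1[2] - p0[2]) * f,
             z = p0[3] + (p1[3] - p0[3]) * f,
             radius = segment_radius(net, segment, s))
}

#' Mirror a network left-right
#'
#' Reflects all coordinates through the midsagittal plane (x -> -x) and swaps
#' left/right labels, producing the mirror-image network. Useful for
#' symmetry checks: applying a stenosis on the left of a symmetric baseline
#' must equal the mirror of applying it on the right.
#'
#' @param net a `vessel_network`.
#' @return mirrored `vessel_network`.
#' @export
mirror_network <- function(net) {
  swap <- function(x) {
    y <- sub("_L([0-9]*)$", "_@\\1", x)
    y <- sub("_R([0-9]*)$", "_L\\1", y)
    sub("_@([0-9]*)$", "_R\\1", y)
  }
  net$nodes$x <- -net$nodes$x
  net$nodes$id <- swap(net$nodes$id)
  net$nodes$hemisphere <- c(left = "right", right = "left",
                            none = "none")[net$nodes$hemisphere]
  sg <- net$segments
  sg$name <- swap(sg$name); sg$prox <- swap(sg$prox); sg$dist <- swap(sg$dist)
  sg$outlet <- ifelse(is.na(sg$outlet), sg$outlet, swap(sg$outlet))
  sg$gx0 <- -sg$gx0; sg$gx1 <- -sg$gx1
  net$segments <- sg
  net$inlet <- swap(net$inlet)
  hm <- stats::setNames(c(left = "right", right = "left",
                          none = "none")[net$hemisphere_map],
                        swap(names(net$hemisphere_map)))
  net$hemisphere_map <- hm
  net$outlets <- sort(swap(net$outlets))
  net
}
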