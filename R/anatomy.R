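#' Maximum isometric muscle force from PCSA
#'
#' The upper bound on each muscle force is its physiological cross-sectional
#' area times a maximum isometric stress.
#'
#' @param pcsa physiological cross-sectional area, cm^2 (> 0)
#' @param sigma_max maximum isometric stress, N/cm^2 (> 0; default 31.39)
#' @return force bound in N
#' @export
f_max_from_pcsa <- function(pcsa, sigma_max = 31.39) {
  if (any(pcsa <= 0)) stop("pcsa must be positive")
  if (any(sigma_max <= 0)) stop("sigma_max must be positive")
  pcsa * sigma_max
}

#' Path to the packaged default musculoskeletal geometry
#'
#' A reduced, file-configurable geometry: 16 muscle elements (three vasti,
#' rectus femoris, three hamstrings, biceps femoris short head, both
#' gastrocnemii, soleus, tibialis anterior, peroneus longus, gluteus maximus
#' and medius, iliopsoas), the patellar tendon, four knee ligaments
#' (ACL/PCL/MCL/LCL), and medial/lateral tibiofemoral plus patellofemoral
#' contact points. Attachment coordinates and PCSA values are plausible
#' synthetic placeholders for a reference limb (0.42 m thigh and shank),
#' not measurements; the loader is count-agnostic so a richer file drops in.
#'
#' @return file path
#' @export
default_geometry_path <- function() {
  system.file("extdata", "geometry_default.yaml", package = "kneeload",
              mustWork = TRUE)
}

#' Load and validate a musculoskeletal geometry file
#'
#' @param path YAML geometry file; see `default_geometry_path()` for the
#'   schema (segments with inertia ratios, muscles with per-segment
#'   attachments and PCSA or f_max, ligaments with l_max, contact points,
#'   a patellar tendon path, and a quadriceps rho lookup).
#' @return validated geometry list with class `msk_geometry`; muscles gain
#'   an `f_max` (from PCSA where not given explicitly)
#' @export
load_geometry <- function(path = default_geometry_path()) {
  g <- yaml::read_yaml(path)
  segs <- names(g$segments)
  if (is.null(segs) || !all(c("foot", "shank", "thigh", "patella") %in% segs)) {
    stop("geometry must define at least foot, shank, thigh and patella segments")
  }
  sigma <- g$sigma_max %||% 31.39
  check_attach <- function(att, what) {
    if (!is.list(att) || length(att) < 2) {
      stop(what, ": a path needs at least two attachment points")
    }
    for (a in att) {
      if (is.null(a$segment) || !(a$segment %in% segs)) {
        stop(what, ": attachment references undefined segment '",
             a$segment %||% "<missing>", "'")
      }
      if (length(unlist(a$xyz)) != 3) stop(what, ": attachment xyz must be length 3")
    }
  }
  for (i in seq_along(g$muscles)) {
    m <- g$muscles[[i]]
    check_attach(m$attachments, m$name %||% paste("muscle", i))
    if (is.null(m$f_max)) {
      if (is.null(m$pcsa)) stop(m$name, ": needs pcsa or f_max")
      g$muscles[[i]]$f_max <- f_max_from_pcsa(m$pcsa, sigma)
    }
    if (g$muscles[[i]]$f_max <= 0) stop(m$name, ": f_max must be positive")
    g$muscles[[i]]$group <- m$group %||% "other"
  }
  for (l in g$ligaments) {
    check_attach(l$attachments, l$name %||% "ligament")
    if (is.null(l$l_max) || l$l_max <= 0) stop(l$name, ": l_max must be positive")
  }
  check_attach(g$patellar_tendon$attachments, "patellar_tendon")
  for (cp in c("medial", "lateral", "patellofemoral")) {
    p <- g$contacts[[cp]]
    if (is.null(p) || !(p$segment %in% segs) || length(unlist(p$xyz)) != 3) {
      stop("contact point '", cp, "' missing or malformed")
    }
  }
  if (unlist(g$contacts$medial$xyz)[3] >= unlist(g$contacts$lateral$xyz)[3]) {
    stop("medial contact must have a smaller mediolateral coordinate than lateral (right limb)")
  }
  if (is.null(g$rho_lookup) ||
      is.null(g$rho_lookup$flexion_deg) || is.null(g$rho_lookup$ratio) ||
      length(g$rho_lookup$flexion_deg) != length(g$rho_lookup$ratio)) {
    stop("rho_lookup must give parallel flexion_deg and ratio vectors")
  }
  if (is.unsorted(g$rho_lookup$flexion_deg, strictly = TRUE)) {
    stop("rho_lookup flexion_deg must be strictly increasing")
  }
  structure(g, class = "msk_geometry")
}

#' @export
print.msk_geometry <- function(x, ...) {
  cat("<msk_geometry>", length(x$muscles), "muscle elements,",
      length(x$ligaments), "ligaments,",
      length(x$contacts), "contact points\n")
  per_seg <- table(unlist(lapply(x$muscles, function(m) {
    vapply(m$attachments, `[[`, character(1), "segment")
  })))
  cat("  muscle attachments per segment:",
      paste(names(per_seg), per_seg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a geometry list back to YAML
#' @param geometry an `msk_geometry`
#' @param path output file
#' @export
write_geometry <- function(geometry, path) {
  g <- unclass(geometry)
  yaml::write_yaml(g, path, precision = 12)
  invisible(path)
}

#' Scale geometry to subject segment lengths and strength
#'
#' Attachment and contact coordinates are stored for a reference limb; this
#' scales every segment-local coordinate isotropically by the ratio of the
#' subject's segment length to the reference length. Muscle and ligament
#' force bounds are scaled by \eqn{(mass / 70)^{2/3}} (cross-sectional area
#' scaling) when a body mass is supplied.
#'
#' @param geometry an `msk_geometry`
#' @param lengths named list/vector of subject segment lengths (m) for any
#'   of the segments in the file
#' @param mass optional body mass (kg) for strength scaling (reference
#'   70 kg)
#' @return scaled geometry
#' @export
scale_geometry <- function(geometry, lengths, mass = NULL) {
  ratio <- vapply(names(geometry$segments), function(s) {
    ref <- geometry$segments[[s]]$reference_length
    if (is.null(ref) || is.null(lengths[[s]])) 1 else lengths[[s]] / ref
  }, numeric(1))
  sc <- function(att) {
    lapply(att, function(a) {
      a$xyz <- unlist(a$xyz) * ratio[[a$segment]]
      a
    })
  }
  for (i in seq_along(geometry$muscles)) {
    geometry$muscles[[i]]$attachments <- sc(geometry$muscles[[i]]$attachments)
  }
  for (i in seq_along(geometry$ligaments)) {
    geometry$ligaments[[i]]$attachments <- sc(geometry$ligaments[[i]]$attachments)
  }
  geometry$patellar_tendon$attachments <- sc(geometry$patellar_tendon$attachments)
  for (cp in names(geometry$contacts)) {
    p <- geometry$contacts[[cp]]
    geometry$contacts[[cp]]$xyz <- unlist(p$xyz) * ratio[[p$segment]]
  }
  if (!is.null(mass)) {
    ss <- (mass / 70)^(2 / 3)
    for (i in seq_along(geometry$muscles)) {
      geometry$muscles[[i]]$f_max <- geometry$muscles[[i]]$f_max * ss
    }
    for (i in seq_along(geometry$ligaments)) {
      geometry$ligaments[[i]]$l_max <- geometry$ligaments[[i]]$l_max * ss
    }
  }
  geometry
}

#' Quadriceps rho ratio at a knee flexion angle
#'
#' rho is the ratio of patellar tendon force to quadriceps tendon force,
#' interpolated linearly in the geometry's lookup; it is zero for muscles
#' outside the quadriceps group.
#'
#' @param geometry an `msk_geometry`
#' @param flexion_deg knee flexion angle (degrees)
#' @return scalar ratio
#' @export
rho_at <- function(geometry, flexion_deg) {
  lk <- geometry$rho_lookup
  stats::approx(lk$flexion_deg, lk$ratio, xout = flexion_deg, rule = 2)$y
}

#' Lines of action and lever vectors for a muscle or ligament path
#'
#' For every path point whose segment is posed, returns the unit force
#' direction acting on that segment at that point (toward the neighbouring
#' path point; for an interior via point, the sum of the unit directions
#' toward both neighbours, i.e. a frictionless pulley), and the lever vector
#' from the segment's proximal joint centre to the point, both in the
#' global frame.
#'
#' @param attachments list of `{segment, xyz}` path points (ordered origin
#'   to insertion)
#' @param poses named list of [segment_pose()] objects
#' @return list of contributions: `segment`, `point` (global m), `p_hat`
#'   (force direction on that segment; unit for endpoints), `r_vec` (lever, m)
#' @export
line_of_action <- function(attachments, poses) {
  pts <- lapply(attachments, function(a) {
    seg <- a$segment
    if (is.null(poses[[seg]])) return(NULL)
    pose_transform(poses[[seg]], unlist(a$xyz))
  })
  # global positions for all points are needed for directions even when a
  # point's own segment is not posed
  all_global <- lapply(seq_along(attachments), function(i) {
    a <- attachments[[i]]
    if (!is.null(pts[[i]])) return(pts[[i]])
    stop("segment '", a$segment, "' in path is not posed")
  })
  np <- length(all_global)
  out <- list()
  for (i in seq_len(np)) {
    seg <- attachments[[i]]$segment
    pt <- all_global[[i]]
    dir <- c(0, 0, 0)
    if (i > 1) {
      d <- all_global[[i - 1]] - pt
      if (sqrt(sum(d^2)) < 1e-9) stop("coincident path points: direction undefined")
      dir <- dir + unitize(d)
    }
    if (i < np) {
      d <- all_global[[i + 1]] - pt
      if (sqrt(sum(d^2)) < 1e-9) stop("coincident path points: direction undefined")
      dir <- dir + unitize(d)
    }
    out[[length(out) + 1]] <- list(
      segment = seg, point = pt, p_hat = dir,
      r_vec = pt - poses[[seg]]$origin
    )
  }
  out
}
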