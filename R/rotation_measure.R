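#' Occlusal reference plane
#'
#' Plane through three landmark points on T0 (the two first-molar cusp
#' tips used for the initial alignment and the mesial incisal point of
#' the right central incisor). The normal is unit length; when `toward`
#' is supplied (e.g. the crown landmark positions), the normal is flipped
#' so that the mean of those points lies on the positive (occlusal) side.
#'
#' @param p1,p2,p3 Length-3 points (mm), non-collinear.
#' @param toward Optional matrix of points whose mean must fall on the
#'   positive side of the plane.
#' @return An object of class `occlusal_plane` with `origin` and unit
#'   `normal`.
#' @export
occlusal_plane <- function(p1, p2, p3, toward = NULL) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  nrm <- cross3(p2 - p1, p3 - p1)
  len <- sqrt(sum(nrm^2))
  scale <- max(sqrt(sum((p2 - p1)^2)), sqrt(sum((p3 - p1)^2)), 1)
  if (len < 1e-9 * scale^2) {
    abort("occlusal plane points are collinear", "rotometry_degenerate")
  }
  nrm <- nrm / len
  if (!is.null(toward)) {
    toward <- matrix(as.numeric(toward), ncol = 3L)
    side <- sum((colMeans(toward) - p1) * nrm)
    if (abs(side) < 1e-9) {
      abort("orientation reference lies in the occlusal plane",
            "rotometry_degenerate")
    }
    if (side < 0) nrm <- -nrm
  }
  structure(list(origin = p1, normal = nrm), class = "occlusal_plane")
}

#' @export
print.occlusal_plane <- function(x, ...) {
  cat(sprintf("<occlusal_plane: normal (%.3f, %.3f, %.3f)>\n",
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Project a vector onto the occlusal plane
#'
#' Removes the component along the plane normal. A vector (numerically)
#' perpendicular to the plane has no in-plane direction and raises a
#' degenerate-vector error.
#'
#' @param v Length-3 vector.
#' @param plane An `occlusal_plane`.
#' @return The in-plane component of `v`.
#' @export
project_vector <- function(v, plane) {
  v <- as.numeric(v)
  if (!all(is.finite(v))) {
    abort("non-finite vector", "rotometry_invalid_input")
  }
  p <- v - sum(v * plane$normal) * plane$normal
  if (sqrt(sum(p^2)) < 1e-9) {
    abort("vector is perpendicular to the occlusal plane",
          "rotometry_degenerate")
  }
  p
}

#' Signed in-plane rotation angle
#'
#' Angle from the projection of `v_ref` to the projection of `v_obs`,
#' about the occlusal normal, in degrees in (-180, 180]. Positive is
#' counter-clockwise viewed from the occlusal side (right-hand rule about
#' the normal).
#'
#' @param v_ref,v_obs Length-3 vectors (typically the T0 landmark vector
#'   and its transferred T1/T2 counterpart).
#' @param plane An `occlusal_plane`.
#' @return Signed angle in degrees.
#' @export
signed_rotation_angle <- function(v_ref, v_obs, plane) {
  a <- project_vector(v_ref, plane)
  b <- project_vector(v_obs, plane)
  s <- sum(plane$normal * cross3(a, b))
  ang <- atan2(s, sum(a * b)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Landmark vector (tail -> head) for one tooth, from a landmark table.
tooth_vector <- function(landmarks, tooth, tooth_type) {
  roles <- landmark_roles(tooth_type)
  rows <- landmarks[landmarks$tooth == tooth, , drop = FALSE]
  tail_r <- rows[rows$role == roles[1L], , drop = FALSE]
  head_r <- rows[rows$role == roles[2L], , drop = FALSE]
  if (nrow(tail_r) != 1L || nrow(head_r) != 1L) {
    abort(sprintf("tooth %d lacks its two landmarks", tooth),
          "rotometry_not_found")
  }
  c(head_r$x - tail_r$x, head_r$y - tail_r$y, head_r$z - tail_r$z)
}

# The three alignment points on one timepoint of an arch case: the
# disto-vestibular cusps of the right and left first molars and the
# mesial incisal point of the right central incisor. For T1/T2 the
# operator's re-picking of the same anatomical points is emulated via the
# shared mesh topology: the T0 landmark's nearest vertex index is looked
# up on the other timepoint.
alignment_points <- function(case, frame = "T0") {
  quads <- if (case$arch == "mandibular") c(right = 4L, left = 3L) else
    c(right = 1L, left = 2L)
  spec <- list(
    c(tooth = quads[["right"]] * 10L + 6L, role = "disto-vestibular-cusp"),
    c(tooth = quads[["left"]] * 10L + 6L, role = "disto-vestibular-cusp"),
    c(tooth = quads[["right"]] * 10L + 1L, role = "mesial-point"))
  lm <- case$landmarks_T0
  pts <- matrix(NA_real_, 3L, 3L)
  for (i in seq_along(spec)) {
    row <- lm[lm$tooth == as.integer(spec[[i]][["tooth"]]) &
                lm$role == spec[[i]][["role"]], , drop = FALSE]
    if (nrow(row) != 1L) {
      abort(sprintf("alignment landmark missing: tooth %s role %s",
                    spec[[i]][["tooth"]], spec[[i]][["role"]]),
            "rotometry_not_found")
    }
    p0 <- c(row$x, row$y, row$z)
    if (frame == "T0") {
      pts[i, ] <- p0
    } else {
      v0 <- case$meshes$T0$vertices
      d2 <- (v0[, 1] - p0[1])^2 + (v0[, 2] - p0[2])^2 +
        (v0[, 3] - p0[3])^2
      pts[i, ] <- case$meshes[[frame]]$vertices[which.min(d2), ]
    }
  }
  pts
}

# Measure one comparison (T0 vs T1 or T0 vs T2) for every labelled tooth.
measure_comparison <- function(case, frame, plane, max_iterations,
                               sample_size, tol, trim_fraction,
                               tooth_max_iterations, tooth_tol) {
  t0 <- case$meshes$T0
  other <- case$meshes[[frame]]
  init <- three_point_align(alignment_points(case, frame),
                            alignment_points(case, "T0"))
  gfit <- global_best_fit(other, t0, init,
                          max_iterations = max_iterations, tol = tol,
                          sample_size = sample_size,
                          trim_fraction = trim_fraction)
  aligned <- tri_mesh(rt_apply(gfit$transform, other$vertices),
                      other$faces)
  teeth <- labelled_teeth(case$labels)
  angles <- rep(NA_real_, length(teeth))
  errors <- character(0L)
  for (i in seq_along(teeth)) {
    fdi <- teeth[i]
    ttype <- case$labels$tooth_types[[as.character(fdi)]]
    res <- tryCatch({
      tfit <- tooth_best_fit(fdi, t0, case$labels, aligned,
                             max_iterations = tooth_max_iterations,
                             tol = tooth_tol,
                             trim_fraction = trim_fraction)
      moved <- transfer_landmarks(
        case$landmarks_T0[case$landmarks_T0$tooth == fdi, , drop = FALSE],
        tfit, frame = frame)
      v0 <- tooth_vector(case$landmarks_T0, fdi, ttype)
      v1 <- tooth_vector(moved, fdi, ttype)
      signed_rotation_angle(v0, v1, plane)
    }, rotometry_error = function(e) e)
    if (inherits(res, "condition")) {
      errors <- c(errors, sprintf("tooth %d (%s): %s", fdi, frame,
                                  conditionMessage(res)))
    } else {
      angles[i] <- res
    }
  }
  list(teeth = teeth, angles = angles, errors = errors,
       global_fit = gfit)
}

#' Measure prescribed and achieved rotations for an arch case
#'
#' Full measurement workflow for one arch: three-point initial alignment
#' and global best fit of T1 (and T2) onto T0, per-tooth surface best fit
#' for landmark transfer, projection of the landmark vectors onto the T0
#' occlusal plane, and signed angle extraction. Both angles are then
#' re-signed by the sign of the raw prescribed angle so that prescribed
#' is non-negative and achieved carries sign relative to the prescribed
#' direction (negative achieved = rotation opposite to plan).
#'
#' Teeth whose measurement fails (missing landmark, degenerate
#' projection, too-small submesh) are skipped and reported in the
#' `errors` attribute; the case continues.
#'
#' @param case An `arch_case` (see [generate_arch()]).
#' @param max_iterations Iteration cap of the whole-arch global best fit
#'   (default 50, the cap the measurement protocol fixes).
#' @param sample_size Moving-vertex subsample bound for the global fit.
#' @param tol Global-fit early-stop tolerance (mm).
#' @param trim_fraction ICP trimming fraction.
#' @param tooth_max_iterations,tooth_tol Convergence settings of the
#'   per-tooth fits. Round (nearly rotation-symmetric) crowns converge
#'   slowly under point-to-point ICP, so tooth fits run to convergence
#'   rather than stopping at the global fit's 50-iteration cap.
#' @return Data frame with columns `case_id`, `arch`, `fdi`,
#'   `tooth_type`, `prescribed_deg`, `achieved_deg`, plus attributes
#'   `errors` (character) and `global_rms` (named numeric, mm).
#' @export
measure_case <- function(case, max_iterations = 50L, sample_size = 5000L,
                         tol = 1e-7, trim_fraction = 0,
                         tooth_max_iterations = 1000L, tooth_tol = 1e-9) {
  ap <- alignment_points(case, "T0")
  crown <- as.matrix(case$landmarks_T0[, c("x", "y", "z")])
  plane <- occlusal_plane(ap[1L, ], ap[2L, ], ap[3L, ], toward = crown)
  m1 <- measure_comparison(case, "T1", plane, max_iterations,
                           sample_size, tol, trim_fraction,
                           tooth_max_iterations, tooth_tol)
  m2 <- measure_comparison(case, "T2", plane, max_iterations,
                           sample_size, tol, trim_fraction,
                           tooth_max_iterations, tooth_tol)
  sgn <- ifelse(is.na(m1$angles) | m1$angles == 0, 1,
                sign(m1$angles))
  out <- data.frame(
    case_id = case$case_id,
    arch = case$arch,
    fdi = m1$teeth,
    tooth_type = unname(vapply(as.character(m1$teeth), function(k)
      case$labels$tooth_types[[k]], character(1L))),
    prescribed_deg = sgn * m1$angles,
    achieved_deg = sgn * m2$angles)
  keep <- !is.na(out$prescribed_deg) & !is.na(out$achieved_deg)
  skipped <- out$fdi[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- c(m1$errors, m2$errors)
  attr(out, "skipped") <- skipped
  attr(out, "global_rms") <- c(T1 = m1$global_fit$rms_mm,
                               T2 = m2$global_fit$rms_mm)
  out
}
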