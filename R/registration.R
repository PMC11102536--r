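#' Rigid transforms
#'
#' A rigid (proper orthogonal) transform `x -> R x + t` in mm. Rotation
#' matrices are validated to be orthonormal with determinant +1 within
#' 1e-9; composition and inversion stay within the class.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)) ||
      !all(is.finite(rotation))) {
    abort("non-finite rigid transform", "rotometry_invalid_input")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be orthonormal with determinant +1",
          "rotometry_invalid_input")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @rdname rigid_transform
#' @param a,b `rigid_transform`s; `rt_compose(a, b)` applies `b` first.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @export
rt_inverse <- function(tf) {
  rigid_transform(t(tf$rotation),
                  -as.vector(t(tf$rotation) %*% tf$translation))
}

#' @rdname rigid_transform
#' @param points Numeric matrix `n x 3` (or length-3 vector).
#' @export
rt_apply <- function(tf, points) {
  if (is.null(dim(points))) {
    return(as.vector(tf$rotation %*% points) + tf$translation)
  }
  sweep(points %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' @rdname rigid_transform
#' @export
rt_rotation_angle <- function(tf) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(tf$rotation)) - 1) / 2)))
  ang * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: %.3f deg rotation, |t| = %.3f mm>\n",
              rt_rotation_angle(x), sqrt(sum(x$translation^2))))
  invisible(x)
}

# Orthogonal-Procrustes (Kabsch) least-squares rigid fit mapping the rows
# of P onto the rows of Q. Reflections are excluded by construction.
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cq - as.vector(R %*% cp))
}

#' Three-point initial alignment
#'
#' Least-squares rigid transform (no scaling, no reflection) mapping an
#' ordered triple of source landmarks onto the corresponding target
#' triple; exact when the triples are congruent. In the arch workflow the
#' three points are the mesio-buccal (here disto-vestibular) cusp tips of
#' the right and left first molars and the most mesial incisal point of
#' the right central incisor.
#'
#' @param source_points,target_points 3 x 3 matrices, one landmark per
#'   row, in corresponding order.
#' @return A `rigid_transform` mapping source onto target.
#' @export
three_point_align <- function(source_points, target_points) {
  source_points <- matrix(as.numeric(source_points), ncol = 3L)
  target_points <- matrix(as.numeric(target_points), ncol = 3L)
  if (nrow(source_points) != 3L || nrow(target_points) != 3L) {
    abort("three_point_align needs exactly 3 source and 3 target points",
          "rotometry_invalid_input")
  }
  for (m in list(source_points, target_points)) {
    v1 <- m[2L, ] - m[1L, ]
    v2 <- m[3L, ] - m[1L, ]
    cr <- cross3(v1, v2)
    scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)), 1)
    if (sqrt(sum(cr^2)) < 1e-9 * scale^2) {
      abort("collinear landmark triple", "rotometry_degenerate")
    }
  }
  kabsch(source_points, target_points)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Shared ICP core: moving points against a fixed surface.
icp_core <- function(points, fixed, init, max_iterations, tol,
                     trim_fraction) {
  cur <- init
  rms <- Inf
  history <- numeric(0L)
  iterations <- 0L
  n_used <- nrow(points)
  for (it in seq_len(max_iterations)) {
    moved <- rt_apply(cur, points)
    cc <- closest_points_on_mesh(moved, fixed$vertices, fixed$faces)
    ord <- seq_len(nrow(points))
    if (trim_fraction > 0) {
      keep <- ceiling((1 - trim_fraction) * nrow(points))
      ord <- order(cc$dist2)[seq_len(max(3L, keep))]
    }
    n_used <- length(ord)
    new_rms <- sqrt(mean(cc$dist2[ord]))
    history <- c(history, new_rms)
    if (it > 1L && rms - new_rms < tol) {
      rms <- new_rms
      break
    }
    rms <- new_rms
    upd <- kabsch(moved[ord, , drop = FALSE],
                  cc$points[ord, , drop = FALSE])
    cur <- rt_compose(upd, cur)
    iterations <- it
  }
  if (iterations == max_iterations) {
    # Budget exhausted: evaluate the RMS at the final transform.
    moved <- rt_apply(cur, points)
    cc <- closest_points_on_mesh(moved, fixed$vertices, fixed$faces)
    d2 <- sort(cc$dist2)[seq_len(n_used)]
    rms <- sqrt(mean(d2))
    history <- c(history, rms)
  }
  structure(list(transform = cur, iterations = iterations,
                 rms_mm = rms, n_correspondences = n_used,
                 rms_history = history),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result: %d iterations, RMS %.5f mm, %d correspondences>\n",
    x$iterations, x$rms_mm, x$n_correspondences))
  invisible(x)
}

#' Global best-fit surface registration (ICP)
#'
#' Iterative-closest-point refinement of an initial rigid transform:
#' each iteration pairs the (subsampled) moving vertices with their
#' nearest points on the fixed surface (point-to-triangle, ties broken by
#' lowest face index), solves the least-squares rigid update in closed
#' form, and applies it. Iterations are capped at 50 by default; an early
#' stop triggers when the RMS improvement falls below `tol`. The RMS over
#' iterations is non-increasing, so the returned RMS never exceeds the RMS
#' at `init`.
#'
#' @param moving,fixed `tri_mesh` objects; `moving` is registered onto
#'   `fixed`.
#' @param init Initial `rigid_transform` (e.g. from
#'   [three_point_align()]).
#' @param max_iterations Iteration cap (default 50).
#' @param tol RMS-improvement early-stop threshold in mm; set to 0 to
#'   always run the full iteration budget.
#' @param sample_size Upper bound on moving vertices used per iteration;
#'   subsampling is a deterministic evenly-spaced selection.
#' @param trim_fraction Fraction of worst correspondences discarded each
#'   iteration (0 = none; clean synthetic surfaces need no trimming).
#' @return An `alignment_result`: `transform`, `iterations`, `rms_mm`,
#'   `n_correspondences`, `rms_history`.
#' @export
global_best_fit <- function(moving, fixed, init = rt_identity(),
                            max_iterations = 50L, tol = 1e-7,
                            sample_size = 5000L, trim_fraction = 0) {
  validate_mesh(moving)
  validate_mesh(fixed)
  if (!inherits(init, "rigid_transform")) {
    abort("init must be a rigid_transform", "rotometry_invalid_input")
  }
  stopifnot_scalar_number(max_iterations, "max_iterations", lower = 1)
  stopifnot_scalar_number(trim_fraction, "trim_fraction", 0, 0.9)
  pts <- moving$vertices
  if (nrow(pts) > sample_size) {
    pts <- pts[unique(round(seq(1L, nrow(pts), length.out = sample_size))),
               , drop = FALSE]
  }
  icp_core(pts, fixed, init, as.integer(max_iterations), tol,
           trim_fraction)
}

#' Per-tooth surface best fit
#'
#' Runs ICP with one tooth's submesh as the moving point set against the
#' full target mesh, capturing that tooth's individual rigid motion
#' between timepoints. The target is the whole opposing model (no
#' segmentation of the target timepoint is assumed).
#'
#' @param tooth FDI code.
#' @param source_mesh Labelled source `tri_mesh` (typically T0).
#' @param source_labels `tooth_label_map` for `source_mesh`.
#' @param target_mesh Target `tri_mesh`, already in (or initialised into)
#'   the source frame.
#' @param init Initial `rigid_transform`; pass the global alignment when
#'   the target has not been pre-transformed.
#' @param supersample When `TRUE` (default) the moving point set is the
#'   submesh vertices plus the face centroids. The denser surface
#'   sampling interrogates more of the target surface, averaging out
#'   target-side scan noise in the rotation estimate; with noisy meshes
#'   it roughly quarters the angular bias relative to vertices alone.
#' @inheritParams global_best_fit
#' @return An `alignment_result` with a `tooth` element.
#' @export
tooth_best_fit <- function(tooth, source_mesh, source_labels, target_mesh,
                           init = rt_identity(), max_iterations = 50L,
                           tol = 1e-7, trim_fraction = 0,
                           supersample = TRUE, sample_size = 5000L) {
  sub <- extract_tooth_submesh(source_mesh, source_labels, tooth)
  if (n_vertices(sub) < 10L) {
    abort(sprintf("tooth %s submesh has fewer than 10 vertices", tooth),
          "rotometry_invalid_segmentation")
  }
  validate_mesh(target_mesh)
  pts <- sub$vertices
  if (supersample) {
    f <- sub$faces
    pts <- rbind(pts, (pts[f[, 1L], ] + pts[f[, 2L], ] +
                         pts[f[, 3L], ]) / 3)
  }
  if (nrow(pts) > sample_size) {
    pts <- pts[unique(round(seq(1L, nrow(pts), length.out = sample_size))),
               , drop = FALSE]
  }
  res <- icp_core(pts, target_mesh, init,
                  as.integer(max_iterations), tol, trim_fraction)
  res$tooth <- as.integer(tooth)
  res
}

#' Transfer landmarks by a per-tooth fit
#'
#' Maps landmarks placed on the source timepoint into the target frame by
#' the tooth's rigid fit, preserving tooth id and role and updating the
#' frame tag. This reproduces landmark re-creation "in the same position"
#' on the other model: the transferred point is the same anatomical
#' location carried by the tooth's own rigid motion.
#'
#' @param landmarks Landmark data frame (one tooth).
#' @param tooth_fit `alignment_result` from [tooth_best_fit()] for the
#'   same tooth.
#' @param frame Frame tag for the transferred landmarks.
#' @return Landmark data frame in the target frame.
#' @export
transfer_landmarks <- function(landmarks, tooth_fit, frame = "T1") {
  if (!is.null(tooth_fit$tooth) &&
      !all(landmarks$tooth == tooth_fit$tooth)) {
    abort("landmark tooth ids do not match the tooth fit",
          "rotometry_invalid_input")
  }
  pos <- rt_apply(tooth_fit$transform,
                  as.matrix(landmarks[, c("x", "y", "z")]))
  out <- landmarks
  out$x <- pos[, 1L]
  out$y <- pos[, 2L]
  out$z <- pos[, 3L]
  out$frame <- frame
  out
}

#' Transform JSON sidecar
#'
#' @param result An `alignment_result`.
#' @param path File path.
#' @export
write_transform <- function(result, path) {
  jsonlite::write_json(
    list(rotation = result$transform$rotation,
         translation = result$transform$translation,
         rms_mm = result$rms_mm, iterations = result$iterations),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
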