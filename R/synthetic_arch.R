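# Synthetic dental arches with known ground-truth rotations.
#
# The generator emulates the statistical structure of a clear-aligner
# rotation study: parabolic arches of 14 teeth (7 types per quadrant),
# per-tooth prescribed rotations about the crown-vertical axis drawn from
# tooth-type truncated normals (floor 2 deg), achieved rotations equal to
# prescribed times a tooth-type accuracy factor plus angular noise,
# whole-arch rigid pose perturbations of T1/T2, and Gaussian vertex
# jitter standing in for scanner noise.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Stable sub-seed derivation
#'
#' Fans a single global seed out to per-stage, per-case sub-seeds by a
#' stable polynomial string hash, so adding cases never reshuffles the
#' randomness of existing ones. Result is in `[0, 2^31 - 2]`.
#'
#' @param ... Seed components (coerced to character).
#' @return Integer sub-seed.
#' @export
stable_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1L)),
             collapse = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Truncated-normal draw by rejection; sd = 0 collapses to the clamped
# mean (used by the deterministic null-rotation configuration).
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  for (tries in 1:10000) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (length(need) == 0L) return(out)
  }
  abort("truncated-normal rejection sampling failed; bounds too tight",
        "rotometry_invalid_input")
}

# Mean of a normal(mean, sd) truncated to [lower, upper] -- used by tests
# as the reference value for distribution-emulation checks.
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# ---- crown templates --------------------------------------------------

template_params <- function(tooth_type) {
  # half-widths (mm): a mesio-distal, b bucco-lingual; h crown height;
  # cusp bump height. Values are typical adult crown dimensions.
  p <- switch(tooth_type,
    central_incisor = list(a = 2.75, b = 1.60, h = 8.0, cusp = 0.5),
    lateral_incisor = list(a = 3.00, b = 1.70, h = 7.8, cusp = 0.5),
    canine          = list(a = 3.50, b = 2.20, h = 8.5, cusp = 0.6),
    first_premolar  = list(a = 3.50, b = 3.00, h = 7.5, cusp = 0.8),
    second_premolar = list(a = 3.50, b = 3.10, h = 7.3, cusp = 0.8),
    first_molar     = list(a = 5.00, b = 5.50, h = 6.5, cusp = 0.8),
    second_molar    = list(a = 4.80, b = 5.20, h = 6.3, cusp = 0.8),
    abort(sprintf("unknown tooth type: %s", tooth_type),
          "rotometry_invalid_input"))
  p
}

#' Crown-like tooth template mesh
#'
#' Builds a closed, crown-like mesh in a canonical frame (+x mesial,
#' +y buccal/vestibular, +z occlusal; base at z = 0): a tapered
#' superellipse prism with raised rim vertices at the cusp or incisal
#' positions that carry the tooth type's two landmarks. Cusp heights are
#' deliberately asymmetric (buccal taller than lingual, mesial taller
#' than distal) so no crown is invariant under a 180-degree rotation.
#'
#' @param tooth_type One of [tooth_types()].
#' @param size Optional overrides for the template parameters `a`, `b`,
#'   `h`, `cusp` (mm).
#' @return List with `mesh` (a watertight `tri_mesh`), `landmarks`
#'   (2 x 3 matrix in template frame, tail row first), `roles`
#'   (character 2), and `landmark_vertices` (indices into the mesh).
#' @export
make_tooth_template <- function(tooth_type, size = list()) {
  p <- utils::modifyList(template_params(tooth_type), size)
  n <- 24L
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  pexp <- 2.5
  r <- (abs(cos(theta) / p$a)^pexp +
          abs(sin(theta) / p$b)^pexp)^(-1 / pexp)

  # rim-vertex bump profile; at() maps a rim angle (deg) to its vertex
  # index (+x mesial = 0, +y buccal = 90)
  at <- function(deg) as.integer(deg / (360 / n)) + 1L
  bump <- numeric(n)
  if (grepl("premolar", tooth_type)) {
    bump[at(90)] <- p$cusp           # buccal
    bump[at(270)] <- p$cusp * 0.70   # lingual
    lm_idx <- c(at(90), at(270))
  } else if (grepl("molar", tooth_type)) {
    bump[at(135)] <- p$cusp          # disto-vestibular
    bump[at(315)] <- p$cusp * 0.95   # mesio-lingual
    bump[at(45)] <- p$cusp * 0.80    # mesio-vestibular
    bump[at(225)] <- p$cusp * 0.55   # disto-lingual
    lm_idx <- c(at(135), at(315))
  } else {
    bump[at(0)] <- p$cusp            # mesial incisal corner
    bump[at(180)] <- p$cusp * 0.75   # distal incisal corner
    lm_idx <- c(at(0), at(180))
  }

  zs <- c(0, p$h / 3, 2 * p$h / 3, p$h)
  taper <- 0.75 + 0.25 * zs / p$h
  rings <- lapply(seq_along(zs), function(j) {
    z <- if (j == length(zs)) zs[j] + bump else rep(zs[j], n)
    cbind(taper[j] * r * cos(theta), taper[j] * r * sin(theta), z)
  })
  verts <- do.call(rbind, rings)
  bottom_center <- nrow(verts) + 1L
  top_center <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, p$h + p$cusp * 0.5))

  faces <- matrix(0L, 0L, 3L)
  for (j in seq_len(length(zs) - 1L)) {
    lo <- (j - 1L) * n
    hi <- j * n
    k2 <- c(seq_len(n - 1L) + 1L, 1L)
    faces <- rbind(faces,
                   cbind(lo + seq_len(n), lo + k2, hi + k2),
                   cbind(lo + seq_len(n), hi + k2, hi + seq_len(n)))
  }
  k2 <- c(seq_len(n - 1L) + 1L, 1L)
  faces <- rbind(faces,
                 cbind(bottom_center, k2, seq_len(n)),          # bottom cap
                 cbind(top_center, 3L * n + seq_len(n), 3L * n + k2))
  mesh <- tri_mesh(verts, faces)
  lm_verts <- 3L * n + lm_idx
  list(mesh = mesh,
       landmarks = unname(verts[lm_verts, , drop = FALSE]),
       roles = landmark_roles(tooth_type),
       landmark_vertices = lm_verts)
}

# ---- generator configuration ------------------------------------------

# Tooth-type prescription distributions (deg) and accuracy-factor means
# emulating a published clear-aligner rotation cohort, per arch.
default_prescription_table <- function(arch) {
  tt <- tooth_types()
  if (arch == "mandibular") {
    data.frame(tooth_type = tt,
               mean = c(8.79, 10.77, 11.03, 11.48, 10.18, 5.55, 6.12),
               sd = c(5.84, 9.50, 6.94, 7.02, 11.25, 2.99, 3.58))
  } else {
    data.frame(tooth_type = tt,
               mean = c(7.52, 7.62, 8.32, 6.92, 7.85, 10.35, 10.14),
               sd = c(4.05, 4.84, 6.21, 3.56, 5.84, 5.50, 6.88))
  }
}

default_accuracy_table <- function(arch) {
  tt <- tooth_types()
  if (arch == "mandibular") {
    data.frame(tooth_type = tt,
               mean = c(0.8834, 0.8961, 0.7813, 0.7114, 0.7339,
                        0.7468, 0.7094))
  } else {
    data.frame(tooth_type = tt,
               mean = c(0.7555, 0.7390, 0.7359, 0.7921, 0.8203,
                        0.7839, 0.6070))
  }
}

#' Generator configuration
#'
#' Collects every tunable of the synthetic-arch generator. Defaults state
#' the emulated world: prescription distributions and accuracy-factor
#' means follow the published per-tooth-type cohort statistics, the
#' prescription floor is the study's 2-degree exclusion cutoff, the
#' accuracy-factor SD is 0.3 truncated to (-0.5, 1.5) so under-, over-
#' and wrong-direction performance all occur, vertex jitter SD is
#' 0.05 mm (typical intraoral-scanner noise), and whole-arch pose
#' perturbations are bounded by 5 degrees / 5 mm.
#'
#' @param arch `"mandibular"` or `"maxillary"`.
#' @param seed Integer RNG seed; same config implies identical output.
#' @param prescription Data frame `tooth_type`, `mean`, `sd` (deg).
#' @param accuracy Data frame `tooth_type`, `mean` (fraction of
#'   prescribed achieved).
#' @param accuracy_sd SD of the accuracy factor.
#' @param accuracy_bounds Truncation bounds of the accuracy factor.
#' @param floor_deg Prescription truncation floor (deg).
#' @param angle_noise_sd Achieved-angle Gaussian noise SD (deg).
#' @param jitter_sd Per-vertex Gaussian jitter SD (mm), per timepoint.
#' @param pose_max_deg,pose_max_mm Bounds of the uniform whole-arch
#'   rigid perturbation applied independently to T1 and T2.
#' @param arch_halfwidth,arch_depth Parabolic arch form (mm).
#' @param gap_mm Interproximal clearance between adjacent crowns.
#' @return A `generator_config` list.
#' @export
generator_config <- function(arch = c("mandibular", "maxillary"),
                             seed = 1L,
                             prescription = NULL,
                             accuracy = NULL,
                             accuracy_sd = 0.3,
                             accuracy_bounds = c(-0.5, 1.5),
                             floor_deg = 2,
                             angle_noise_sd = 0.5,
                             jitter_sd = 0.05,
                             pose_max_deg = 5,
                             pose_max_mm = 5,
                             arch_halfwidth = NULL,
                             arch_depth = NULL,
                             gap_mm = 0.6) {
  arch <- match.arg(arch)
  if (is.null(prescription)) prescription <- default_prescription_table(arch)
  if (is.null(accuracy)) accuracy <- default_accuracy_table(arch)
  if (is.null(arch_halfwidth)) {
    arch_halfwidth <- if (arch == "mandibular") 27 else 28
  }
  if (is.null(arch_depth)) {
    arch_depth <- if (arch == "mandibular") 38 else 40
  }
  for (nm in c("accuracy_sd", "floor_deg", "angle_noise_sd", "jitter_sd",
               "pose_max_deg", "pose_max_mm", "gap_mm")) {
    stopifnot_scalar_number(get(nm), nm, lower = 0)
  }
  if (any(prescription$sd < 0)) {
    abort("prescription SDs must be non-negative",
          "rotometry_invalid_input")
  }
  structure(list(arch = arch, seed = as.integer(seed),
                 prescription = prescription, accuracy = accuracy,
                 accuracy_sd = accuracy_sd,
                 accuracy_bounds = accuracy_bounds,
                 floor_deg = floor_deg, angle_noise_sd = angle_noise_sd,
                 jitter_sd = jitter_sd, pose_max_deg = pose_max_deg,
                 pose_max_mm = pose_max_mm,
                 arch_halfwidth = arch_halfwidth,
                 arch_depth = arch_depth, gap_mm = gap_mm),
            class = "generator_config")
}

# FDI sequence right second molar -> left second molar for one arch.
arch_fdi_sequence <- function(arch) {
  quads <- if (arch == "mandibular") c(4L, 3L) else c(1L, 2L)
  c(quads[1L] * 10L + 7:1, quads[2L] * 10L + 1:7)
}

# Tooth centre positions and local frames along the parabolic curve
# y = D (1 - (x / halfW)^2), teeth spaced by their mesio-distal widths.
arch_layout <- function(config) {
  halfW <- config$arch_halfwidth
  D <- config$arch_depth
  fdi <- arch_fdi_sequence(config$arch)
  types <- fdi_tooth_type(fdi)
  a <- vapply(types, function(t) template_params(t)$a, numeric(1L))

  # arc-length positions from the midline, right side mirrored
  half <- length(fdi) / 2L
  s <- numeric(length(fdi))
  right <- rev(seq_len(half))           # 41 .. 47 order for cumulation
  left <- half + seq_len(half)
  for (side in list(right, left)) {
    acc <- config$gap_mm / 2
    prev_a <- NA_real_
    for (i in side) {
      acc <- acc + (if (is.na(prev_a)) 0 else prev_a + config$gap_mm) +
        a[i]
      s[i] <- acc
      prev_a <- a[i]
    }
  }

  # invert arc length numerically on a fine grid
  xg <- seq(0, 2.2 * halfW, length.out = 4000L)
  dy <- -2 * D * xg / halfW^2
  seg <- sqrt(1 + dy^2) * c(0, diff(xg))
  sg <- cumsum(seg)
  if (max(s) > max(sg)) {
    abort("arch form too small for the tooth row", "rotometry_generation")
  }
  xs <- stats::approx(sg, xg, xout = s)$y
  side_sign <- rep(c(1, -1), each = half)  # right = +x, left = -x
  centers <- cbind(side_sign * xs, D * (1 - (xs / halfW)^2), 0)

  frames <- vector("list", length(fdi))
  interior <- c(0, 0.45 * D)
  for (i in seq_along(fdi)) {
    x <- centers[i, 1L]
    yp <- -2 * D * x / halfW^2
    tangent <- c(1, yp) / sqrt(1 + yp^2)
    mesial <- if (x >= 0) -tangent else tangent
    normal <- c(tangent[2L], -tangent[1L])
    if (sum(normal * (centers[i, 1:2] - interior)) < 0) normal <- -normal
    frames[[i]] <- list(mesial = c(mesial, 0), buccal = c(normal, 0))
  }

  # overlap guard: adjacent centres must clear the summed half-widths
  d <- sqrt(rowSums((centers[-1L, , drop = FALSE] -
                       centers[-nrow(centers), , drop = FALSE])^2))
  need <- a[-1L] + a[-length(a)]
  if (any(d < need)) {
    abort("teeth overlap; increase arch size or gap",
          "rotometry_generation")
  }
  list(fdi = fdi, types = types, centers = centers, frames = frames)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

random_pose <- function(max_deg, max_mm) {
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1L, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L],
                ax[2L], -ax[1L], 0), 3L, 3L)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  t <- stats::rnorm(3L)
  t <- t / sqrt(sum(t^2)) * stats::runif(1L, 0, max_mm)
  rigid_transform(R, t)
}

#' Generate a synthetic arch case with ground truth
#'
#' Builds the T0 arch from crown templates placed along the parabolic
#' curve, draws per-tooth prescribed angles (tooth-type truncated normal,
#' random sign) and accuracy factors, rotates each tooth about the
#' crown-vertical axis through its centroid to produce T1 (prescribed)
#' and T2 (achieved = prescribed x factor + noise), applies independent
#' whole-arch rigid perturbations to T1 and T2, and adds per-timepoint
#' vertex jitter. The three meshes share vertex count and face list.
#' Landmarks are read off the final (jittered) T0 surface.
#'
#' @param config A [generator_config()].
#' @param case_id Case identifier string.
#' @return List with `case` (an `arch_case`: `case_id`, `arch`, `meshes`
#'   `$T0/$T1/$T2`, `labels`, `landmarks_T0`) and `truth` (a
#'   `synthetic_ground_truth`: per-tooth table, global poses, seed).
#' @export
generate_arch <- function(config, case_id = "case01") {
  if (!inherits(config, "generator_config")) {
    abort("config must be a generator_config", "rotometry_invalid_input")
  }
  with_seed(config$seed, generate_arch_impl(config, case_id))
}

generate_arch_impl <- function(config, case_id) {
  layout <- arch_layout(config)
  ntooth <- length(layout$fdi)

  verts0 <- NULL
  faces <- NULL
  assignments <- list()
  lm_tooth <- integer(0L)
  lm_role <- character(0L)
  lm_vertex <- integer(0L)
  offset <- 0L
  for (i in seq_len(ntooth)) {
    tpl <- make_tooth_template(layout$types[i])
    fr <- layout$frames[[i]]
    M <- cbind(fr$mesial, fr$buccal, c(0, 0, 1))
    v <- tpl$mesh$vertices %*% t(M)
    v <- sweep(v, 2L, layout$centers[i, ], "+")
    f <- tpl$mesh$faces
    if (det(M) < 0) f <- f[, c(1L, 3L, 2L)]  # mirrored side: fix winding
    verts0 <- rbind(verts0, v)
    faces <- rbind(faces, f + offset)
    assignments[[as.character(layout$fdi[i])]] <-
      offset + seq_len(n_vertices(tpl$mesh))
    lm_tooth <- c(lm_tooth, rep(layout$fdi[i], 2L))
    lm_role <- c(lm_role, tpl$roles)
    lm_vertex <- c(lm_vertex, offset + tpl$landmark_vertices)
    offset <- offset + n_vertices(tpl$mesh)
  }

  # per-tooth prescribed and achieved angles
  presc <- ach <- fac <- numeric(ntooth)
  pt <- config$prescription
  at <- config$accuracy
  for (i in seq_len(ntooth)) {
    row <- pt[pt$tooth_type == layout$types[i], , drop = FALSE]
    arow <- at[at$tooth_type == layout$types[i], , drop = FALSE]
    mag <- rtruncnorm1(1L, row$mean, row$sd, lower = config$floor_deg)
    sgn <- sample(c(-1, 1), 1L)
    presc[i] <- sgn * mag
    fac[i] <- rtruncnorm1(1L, arow$mean, config$accuracy_sd,
                          config$accuracy_bounds[1L],
                          config$accuracy_bounds[2L])
    ach[i] <- presc[i] * fac[i] +
      stats::rnorm(1L, 0, config$angle_noise_sd)
  }

  pivots <- matrix(0, ntooth, 3L)
  verts1 <- verts0
  verts2 <- verts0
  for (i in seq_len(ntooth)) {
    idx <- assignments[[as.character(layout$fdi[i])]]
    pivot <- colMeans(verts0[idx, , drop = FALSE])
    pivots[i, ] <- pivot
    for (tp in 1:2) {
      ang <- if (tp == 1L) presc[i] else ach[i]
      R <- rotation_about_z(ang)
      rotated <- sweep(sweep(verts0[idx, , drop = FALSE], 2L, pivot) %*%
                         t(R), 2L, pivot, "+")
      if (tp == 1L) verts1[idx, ] <- rotated else verts2[idx, ] <- rotated
    }
  }

  g1 <- random_pose(config$pose_max_deg, config$pose_max_mm)
  g2 <- random_pose(config$pose_max_deg, config$pose_max_mm)
  verts1 <- rt_apply(g1, verts1)
  verts2 <- rt_apply(g2, verts2)

  jit <- function(v) {
    if (config$jitter_sd == 0) return(v)
    v + matrix(stats::rnorm(length(v), 0, config$jitter_sd), ncol = 3L)
  }
  verts0 <- jit(verts0)
  verts1 <- jit(verts1)
  verts2 <- jit(verts2)

  labels <- tooth_label_map(assignments, nrow(verts0))
  landmarks <- landmark_table(lm_tooth, lm_role,
                              verts0[lm_vertex, , drop = FALSE],
                              frame = "T0")
  case <- structure(
    list(case_id = case_id, arch = config$arch,
         meshes = list(T0 = tri_mesh(verts0, faces),
                       T1 = tri_mesh(verts1, faces),
                       T2 = tri_mesh(verts2, faces)),
         labels = labels, landmarks_T0 = landmarks,
         landmark_vertices = lm_vertex),
    class = "arch_case")
  truth <- structure(
    list(teeth = data.frame(
           fdi = layout$fdi, tooth_type = layout$types,
           prescribed_deg = presc, achieved_deg = ach,
           accuracy_factor = fac,
           axis_x = 0, axis_y = 0, axis_z = 1,
           pivot_x = pivots[, 1L], pivot_y = pivots[, 2L],
           pivot_z = pivots[, 3L], row.names = NULL),
         global_T1 = g1, global_T2 = g2,
         seed = config$seed, jitter_sd = config$jitter_sd),
    class = "synthetic_ground_truth")
  list(case = case, truth = truth)
}

#' @export
print.arch_case <- function(x, ...) {
  cat(sprintf("<arch_case %s: %s, %d teeth, %d vertices per timepoint>\n",
              x$case_id, x$arch, length(x$labels$assignments),
              n_vertices(x$meshes$T0)))
  invisible(x)
}

#' Write / read a case directory
#'
#' `emit_case` writes T0/T1/T2 binary STL, the labels and landmarks JSON
#' sidecars, and the ground-truth JSON. `read_case` reloads them.
#'
#' @param case An `arch_case`.
#' @param truth Matching `synthetic_ground_truth` (or `NULL`).
#' @param dir Output directory (created if missing).
#' @export
emit_case <- function(case, truth, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) {
    abort(sprintf("cannot write case directory: %s", dir),
          "rotometry_io_error")
  }
  for (tp in c("T0", "T1", "T2")) {
    write_stl(case$meshes[[tp]], file.path(dir, paste0(tp, ".stl")),
              mode = "binary")
  }
  # STL stores vertices per facet; read_stl rebuilds them in face-stream
  # first-appearance order. Remap the label indices to that ordering so
  # the sidecar matches the reloaded mesh.
  stream <- as.vector(t(case$meshes$T0$faces))
  new_order <- unique(stream)
  remap <- integer(length(new_order))
  remap[new_order] <- seq_along(new_order)
  relabelled <- tooth_label_map(
    lapply(case$labels$assignments, function(ix) sort(remap[ix])),
    length(new_order))
  write_tooth_labels(relabelled, file.path(dir, "labels.json"))
  write_landmarks(case$landmarks_T0, file.path(dir, "landmarks.json"))
  if (!is.null(truth)) {
    tf <- function(g) list(rotation = g$rotation,
                           translation = g$translation)
    jsonlite::write_json(
      list(teeth = truth$teeth, global_T1 = tf(truth$global_T1),
           global_T2 = tf(truth$global_T2), seed = truth$seed,
           jitter_sd = truth$jitter_sd,
           case_id = case$case_id, arch = case$arch),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows",
      matrix = "rowmajor")
  }
  invisible(dir)
}

#' @rdname emit_case
#' @export
read_case <- function(dir) {
  meshes <- lapply(c(T0 = "T0", T1 = "T1", T2 = "T2"), function(tp)
    read_stl(file.path(dir, paste0(tp, ".stl"))))
  labels <- read_tooth_labels(file.path(dir, "labels.json"),
                              n_vertices(meshes$T0))
  landmarks <- read_landmarks(file.path(dir, "landmarks.json"))
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    obj <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- structure(
      list(teeth = obj$teeth,
           global_T1 = rigid_transform(obj$global_T1$rotation,
                                       obj$global_T1$translation),
           global_T2 = rigid_transform(obj$global_T2$rotation,
                                       obj$global_T2$translation),
           seed = obj$seed, jitter_sd = obj$jitter_sd),
      class = "synthetic_ground_truth")
  }
  arch <- fdi_arch(labelled_teeth(labels)[1L])
  case <- structure(
    list(case_id = basename(dir), arch = arch, meshes = meshes,
         labels = labels, landmarks_T0 = landmarks),
    class = "arch_case")
  list(case = case, truth = truth)
}
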