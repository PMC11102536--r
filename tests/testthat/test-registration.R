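test_that("rigid transforms compose, invert and reject invalid input", {
  R <- rotometry:::rotation_about_z(33)
  tf <- rigid_transform(R, c(1, -2, 3))
  inv <- rt_inverse(tf)
  id <- rt_compose(inv, tf)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)
  p <- c(4, 5, 6)
  expect_equal(rt_apply(inv, rt_apply(tf, p)), p, tolerance = 1e-12)
  expect_error(rigid_transform(diag(3) * 2),
               class = "rotometry_invalid_input")
  expect_error(rigid_transform(diag(c(1, 1, -1))),
               class = "rotometry_invalid_input")
})

test_that("three_point_align recovers congruent transforms exactly", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 8, 0))
  expect_equal(three_point_align(src, src)$rotation, diag(3),
               tolerance = 1e-12)
  tf <- rigid_transform(rotometry:::rotation_about_z(30), c(1, 2, 3))
  tgt <- rt_apply(tf, src)
  got <- three_point_align(src, tgt)
  expect_equal(got$rotation, tf$rotation, tolerance = 1e-9)
  expect_equal(got$translation, tf$translation, tolerance = 1e-9)
  # exact inverse property
  fwd <- three_point_align(src, tgt)
  bwd <- three_point_align(tgt, src)
  comp <- rt_compose(bwd, fwd)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_error(three_point_align(rbind(c(0, 0, 0), c(1, 0, 0),
                                       c(2, 0, 0)), src),
               class = "rotometry_degenerate")
})

test_that("three_point_align residual matches a brute-force optimum", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 8, 0))
  tgt <- rt_apply(rigid_transform(rotometry:::rotation_about_z(20),
                                  c(0.5, -1, 2)), src)
  tgt[2L, ] <- tgt[2L, ] + c(0.3, -0.4, 0.2)  # break congruence
  fit <- three_point_align(src, tgt)
  res_fit <- sum((rt_apply(fit, src) - tgt)^2)

  # independent numeric minimiser over axis-angle + translation
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    R <- if (th < 1e-12) diag(3) else {
      ax <- par[1:3] / th
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1],
                    ax[2], -ax[1], 0), 3, 3)
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    moved <- sweep(src %*% t(R), 2L, par[4:6], "+")
    sum((moved - tgt)^2)
  }
  best <- Inf
  set.seed(11)
  for (k in 1:20) {
    st <- c(rnorm(3, 0, 0.5), rnorm(3, 0, 2))
    o <- optim(st, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_lt(res_fit, best + 1e-6)
  expect_equal(res_fit, best, tolerance = 1e-4)
})

test_that("global_best_fit aligns identical and transformed meshes", {
  mesh <- get_sim("mandibular", seed = 2, jitter_sd = 0)$case$meshes$T0
  selfres <- global_best_fit(mesh, mesh)
  expect_equal(selfres$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(selfres$rms_mm, 1e-9)

  tf <- rigid_transform(rotometry:::rotation_about_z(8), c(2, -1, 0.5))
  moved <- tri_mesh(rt_apply(tf, mesh$vertices), mesh$faces)
  # init from three exact landmark pairs
  pts <- mesh$vertices[c(1L, 200L, 900L), ]
  init <- three_point_align(pts, rt_apply(tf, pts))
  res <- global_best_fit(mesh, moved, init)
  err <- rt_compose(rt_inverse(tf), res$transform)
  expect_lt(rt_rotation_angle(err), 0.1)
  expect_lt(sqrt(sum(err$translation^2)), 0.01)
  expect_lte(res$iterations, 50L)

  expect_error(global_best_fit(mesh, mesh, init = "no"),
               class = "rotometry_invalid_input")
})

test_that("registration RMS settles near the noise floor under jitter", {
  mesh <- get_template_mesh("first_molar")
  set.seed(42)
  sigma <- 0.05
  noisy <- mesh$vertices +
    matrix(rnorm(length(mesh$vertices), 0, sigma), ncol = 3L)
  res <- global_best_fit(tri_mesh(noisy, mesh$faces), mesh)
  expect_lt(res$rms_mm, 2 * sigma)
  expect_gt(res$rms_mm, sigma / 4)
})

test_that("ICP RMS history is non-increasing", {
  sim <- get_sim("mandibular", seed = 3, jitter_sd = 0.05)
  t1 <- sim$case$meshes$T1
  res <- global_best_fit(t1, sim$case$meshes$T0,
                         three_point_align(
                           t1$vertices[c(1L, 300L, 800L), ],
                           sim$case$meshes$T0$vertices[c(1L, 300L, 800L), ]),
                         tol = 0)
  expect_true(all(diff(res$rms_history) <= 1e-12))
})

test_that("tooth_best_fit recovers per-tooth motion and flags trouble", {
  sim <- get_sim("mandibular", seed = 3, jitter_sd = 0)
  t0 <- sim$case$meshes$T0
  t1 <- tri_mesh(rt_apply(rt_inverse(sim$truth$global_T1),
                          sim$case$meshes$T1$vertices),
                 sim$case$meshes$T1$faces)
  tr <- sim$truth$teeth
  for (i in c(2L, 8L, 13L)) {
    fit <- tooth_best_fit(tr$fdi[i], t0, sim$case$labels, t1,
                          max_iterations = 300L, tol = 1e-9)
    expect_lt(abs(z_angle(fit$transform$rotation) - tr$prescribed_deg[i]),
              0.1)
  }

  # a tooth that did not move while its neighbours did
  fixed_t1 <- t1
  idx <- sim$case$labels$assignments[["33"]]
  fixed_t1$vertices[idx, ] <- t0$vertices[idx, ]
  fit0 <- tooth_best_fit(33L, t0, sim$case$labels, fixed_t1,
                         max_iterations = 300L, tol = 1e-9)
  expect_lt(abs(z_angle(fit0$transform$rotation)), 0.1)

  # grossly wrong init on a near-round molar: wrong optimum, large RMS
  bad_init <- rigid_transform(rotometry:::rotation_about_z(90))
  pivot <- colMeans(t0$vertices[sim$case$labels$assignments[["36"]], ])
  bad_init <- rigid_transform(
    bad_init$rotation, pivot - as.vector(bad_init$rotation %*% pivot))
  fit_bad <- tooth_best_fit(36L, t0, sim$case$labels, t1,
                            init = bad_init, max_iterations = 100L)
  ok <- abs(z_angle(fit_bad$transform$rotation) -
              tr$prescribed_deg[tr$fdi == 36L]) < 0.5
  expect_true(ok || fit_bad$rms_mm > 0.02)

  expect_error(tooth_best_fit(19L, t0, sim$case$labels, t1),
               class = "rotometry_not_found")
})

test_that("landmark transfer is the rigid map of the points", {
  sim <- get_sim("mandibular", seed = 2, jitter_sd = 0)
  lm <- sim$case$landmarks_T0[sim$case$landmarks_T0$tooth == 34L, ]
  idfit <- structure(list(transform = rt_identity(), tooth = 34L),
                     class = "alignment_result")
  same <- transfer_landmarks(lm, idfit, frame = "T1")
  expect_equal(same[, c("x", "y", "z")], lm[, c("x", "y", "z")])
  expect_true(all(same$frame == "T1"))

  shift <- structure(list(transform = rigid_transform(diag(3), c(1, 2, 3)),
                          tooth = 34L), class = "alignment_result")
  moved <- transfer_landmarks(lm, shift)
  expect_equal(as.matrix(moved[, c("x", "y", "z")]) -
                 as.matrix(lm[, c("x", "y", "z")]),
               matrix(rep(c(1, 2, 3), each = 2L), ncol = 3L),
               ignore_attr = TRUE)

  wrong <- structure(list(transform = rt_identity(), tooth = 35L),
                     class = "alignment_result")
  expect_error(transfer_landmarks(lm, wrong),
               class = "rotometry_invalid_input")

  # transferred landmark lands on the generator's true rotated position
  t1 <- tri_mesh(rt_apply(rt_inverse(sim$truth$global_T1),
                          sim$case$meshes$T1$vertices),
                 sim$case$meshes$T1$faces)
  fit <- tooth_best_fit(34L, sim$case$meshes$T0, sim$case$labels, t1,
                        max_iterations = 300L, tol = 1e-9)
  got <- transfer_landmarks(lm, fit)
  lmv <- sim$case$landmark_vertices[sim$case$landmarks_T0$tooth == 34L]
  truth_pos <- t1$vertices[lmv, ]
  expect_lt(max(abs(as.matrix(got[, c("x", "y", "z")]) - truth_pos)),
            0.05)
})
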