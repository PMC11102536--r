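test_that("templates expose the landmark scheme of each tooth type", {
  pm <- make_tooth_template("second_premolar")
  expect_setequal(pm$roles, c("buccal-cusp", "lingual-cusp"))
  sep <- sqrt(sum((pm$landmarks[1L, ] - pm$landmarks[2L, ])^2))
  expect_gt(sep, 2)

  inc <- make_tooth_template("central_incisor")
  expect_setequal(inc$roles, c("mesial-point", "distal-point"))

  # molar landmark vector is diagonal, not along the mesio-distal axis
  mo <- make_tooth_template("first_molar")
  v <- mo$landmarks[2L, ] - mo$landmarks[1L, ]
  v <- v / sqrt(sum(v^2))
  expect_lt(abs(v[1L]), 0.95)  # not parallel to +x (mesial)
  expect_gt(abs(v[2L]), 0.3)

  expect_error(make_tooth_template("wisdom_tooth"),
               class = "rotometry_invalid_input")
})

test_that("every template is watertight with enough faces", {
  for (tt in tooth_types()) {
    tpl <- make_tooth_template(tt)
    f <- tpl$mesh$faces
    expect_gt(nrow(f), 50)
    edges <- rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                   cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                   cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3])))
    counts <- table(paste(edges[, 1], edges[, 2]))
    expect_true(all(counts == 2L), label = paste(tt, "edge manifold"))
    # landmarks sit exactly on mesh vertices
    expect_equal(tpl$mesh$vertices[tpl$landmark_vertices, ],
                 tpl$landmarks)
  }
})

test_that("generation is deterministic and emit is byte-stable", {
  cfg <- generator_config("maxillary", seed = 77)
  a <- generate_arch(cfg, "det")
  b <- generate_arch(cfg, "det")
  expect_identical(a$case$meshes$T0$vertices, b$case$meshes$T0$vertices)
  expect_identical(a$truth$teeth, b$truth$teeth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_case(a$case, a$truth, d1)
  emit_case(b$case, b$truth, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("byte-identical", f))
  }
})

test_that("null-rotation config leaves timepoints rigid copies of T0", {
  tt <- tooth_types()
  null_presc <- data.frame(tooth_type = tt, mean = 0, sd = 0)
  cfg <- generator_config("mandibular", seed = 5,
                          prescription = null_presc, floor_deg = 0,
                          angle_noise_sd = 0, accuracy_sd = 0,
                          jitter_sd = 0)
  sim <- generate_arch(cfg, "null")
  expect_true(all(sim$truth$teeth$prescribed_deg == 0))
  undone <- rt_apply(rt_inverse(sim$truth$global_T1),
                     sim$case$meshes$T1$vertices)
  expect_equal(undone, sim$case$meshes$T0$vertices, tolerance = 1e-9)
})

test_that("perfect-aligner config makes achieved equal prescribed", {
  acc1 <- data.frame(tooth_type = tooth_types(), mean = 1)
  cfg <- generator_config("mandibular", seed = 6, accuracy = acc1,
                          accuracy_sd = 0, angle_noise_sd = 0,
                          jitter_sd = 0)
  sim <- generate_arch(cfg, "perfect")
  expect_equal(sim$truth$teeth$achieved_deg,
               sim$truth$teeth$prescribed_deg, tolerance = 1e-12)
})

test_that("rigid consistency: T1 tooth equals transformed T0 tooth", {
  sim <- get_sim("mandibular", seed = 3, jitter_sd = 0)
  tr <- sim$truth$teeth
  for (i in c(1L, 6L, 10L)) {
    idx <- sim$case$labels$assignments[[as.character(tr$fdi[i])]]
    v0 <- sim$case$meshes$T0$vertices[idx, ]
    pivot <- c(tr$pivot_x[i], tr$pivot_y[i], tr$pivot_z[i])
    th <- tr$prescribed_deg[i] * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                3L, 3L)
    rot <- sweep(sweep(v0, 2L, pivot) %*% t(R), 2L, pivot, "+")
    expected <- rt_apply(sim$truth$global_T1, rot)
    expect_equal(sim$case$meshes$T1$vertices[idx, ], expected,
                 tolerance = 1e-6)
  }
})

test_that("landmark vectors have usable occlusal-plane projections", {
  for (arch in c("mandibular", "maxillary")) {
    sim <- get_sim(arch, seed = 4, jitter_sd = 0.05)
    lm <- sim$case$landmarks_T0
    for (fdi in labelled_teeth(sim$case$labels)) {
      rows <- lm[lm$tooth == fdi, ]
      v <- as.numeric(rows[2L, c("x", "y", "z")] -
                        rows[1L, c("x", "y", "z")])
      expect_gt(sqrt(v[1L]^2 + v[2L]^2), 0.5)  # in-plane component, mm
    }
  }
})

test_that("pooled prescribed angles match the truncated-normal mean", {
  # 100 cases; each arch case carries 2 teeth per type
  cfg0 <- generator_config("mandibular")
  mags <- vector("list", 100L)
  for (k in seq_len(100L)) {
    cfg <- generator_config("mandibular", seed = 9000 + k)
    sim <- generate_arch(cfg, "pool")
    mags[[k]] <- data.frame(tooth_type = sim$truth$teeth$tooth_type,
                            mag = abs(sim$truth$teeth$prescribed_deg))
  }
  pooled <- do.call(rbind, mags)
  for (tt in tooth_types()) {
    x <- pooled$mag[pooled$tooth_type == tt]
    row <- cfg0$prescription[cfg0$prescription$tooth_type == tt, ]
    # closed-form truncated-normal mean as the oracle
    a <- (cfg0$floor_deg - row$mean) / row$sd
    expected <- row$mean + row$sd * dnorm(a) / (1 - pnorm(a))
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected), 3 * se + 1e-9,
              label = paste("pooled mean for", tt))
  }
})

test_that("cases survive the emit/read round trip", {
  sim <- get_sim("mandibular", seed = 2, jitter_sd = 0)
  dir <- withr::local_tempdir()
  emit_case(sim$case, sim$truth, dir)
  back <- read_case(dir)
  key <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
  expect_equal(key(back$case$meshes$T0$vertices),
               key(sim$case$meshes$T0$vertices), tolerance = 2e-5)
  expect_equal(back$truth$teeth$prescribed_deg,
               sim$truth$teeth$prescribed_deg)
  expect_equal(back$truth$teeth$achieved_deg,
               sim$truth$teeth$achieved_deg)
  expect_equal(back$case$arch, "mandibular")
  # labels remain consistent: every tooth submesh extractable
  for (fdi in labelled_teeth(back$case$labels)) {
    sub <- extract_tooth_submesh(back$case$meshes$T0, back$case$labels,
                                 fdi)
    expect_gte(n_vertices(sub), 10L)
  }
})

test_that("degenerate arch parameters are rejected", {
  expect_error(
    generate_arch(generator_config("mandibular", arch_halfwidth = 6,
                                   arch_depth = 6)),
    class = "rotometry_generation")
})
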