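# Shared fixtures: built in code at test time, cached per session.

fixture_env <- new.env(parent = emptyenv())

# One generated arch case, memoised on (arch, seed, jitter).
get_sim <- function(arch = "mandibular", seed = 1L, jitter_sd = 0,
                    ...) {
  key <- paste(arch, seed, jitter_sd, ...)
  if (is.null(fixture_env[[key]])) {
    cfg <- generator_config(arch, seed = seed, jitter_sd = jitter_sd,
                            ...)
    fixture_env[[key]] <- generate_arch(cfg, paste0("fix_", seed))
  }
  fixture_env[[key]]
}

# A small standalone mesh: one tooth template.
get_template_mesh <- function(type = "first_premolar") {
  make_tooth_template(type)$mesh
}

# z-rotation angle (deg) of a rotation matrix
z_angle <- function(R) atan2(R[2, 1], R[1, 1]) * 180 / pi

# Signed-truth comparison of measure_case output against ground truth:
# returns per-tooth absolute errors for prescribed and achieved angles.
recovery_errors <- function(measured, truth) {
  cmp <- merge(measured, truth$teeth, by = "fdi",
               suffixes = c("_m", "_t"))
  sgn <- sign(cmp$prescribed_deg_t)
  c(abs(cmp$prescribed_deg_m - abs(cmp$prescribed_deg_t)),
    abs(cmp$achieved_deg_m - sgn * cmp$achieved_deg_t))
}

# Rotation records with prescribed per-tooth performance values, for
# count/percentage checks.
records_with_performance <- function(perf, prescribed = 10) {
  build_records(data.frame(
    case_id = "x", arch = "mandibular",
    fdi = rep(31L, length(perf)),
    tooth_type = "central_incisor",
    prescribed_deg = rep(prescribed, length(perf)),
    achieved_deg = prescribed + perf))
}

# Minimal ASCII STL text for a unit right triangle.
ascii_stl_lines <- function() {
  c("solid tri",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid tri")
}
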