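# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# 128 x 128, 2 mm phantom (the default study scale)
phantom128 <- function() memo("ph128", make_digital_phantom(c(128, 128), 2))

# 64 x 64, 3 mm phantom (desk-scale dynamic studies)
phantom64 <- function() memo("ph64", make_digital_phantom(c(64, 64), 3))

head_roles <- function(ph) {
  setdiff(names(ph$labels$dict), c("background", "head_holder"))
}

# mask (plain logical vector) of a set of roles
role_idx <- function(ph, roles) {
  as.integer(ph$labels$vol) %in% ph$labels$dict[roles]
}

role_mask_vol <- function(ph, roles) {
  region_mask(ph$labels, roles)
}

# smooth two-level activity image painted from the labels (gray 4 : white 1)
phantom_activity <- function(ph, fwhm = 6) {
  dict <- ph$labels$dict
  act <- array(0, dim(ph$labels$vol))
  gray_roles <- c("gray", "cerebellum", "frontal", "parietal",
                  "lateral_temporal", "medial_temporal", "posterior_cingulate")
  act[role_idx(ph, gray_roles)] <- 4
  act[role_idx(ph, "white")] <- 1
  gaussian_smooth(image_volume(act, vol_spacing(ph$ct), "PET-activity"), fwhm)
}

# small fast geometry for unit tests
tiny_geom <- function(n_rad = 56, n_ang = 32, fwhm = 0) {
  scan_geometry(n_rad = n_rad, dr_mm = 4, n_ang = n_ang, fwhm_mm = fwhm)
}

# uniform disc volume (nx x nx, spacing sp), radius r mm, value a
disc_volume <- function(nx = 64, sp = 2, r = 50, a = 2) {
  x <- axis_coords(nx, sp)
  X <- matrix(x, nx, nx)
  Y <- matrix(x, nx, nx, byrow = TRUE)
  image_volume((X^2 + Y^2 < r^2) * a, sp, "PET-activity")
}

expect_transform_close <- function(est, true, tol_mm = 0.5, tol_deg = 0.5) {
  expect_lt(max(abs(est$t - true$t)), tol_mm)
  expect_lt(max(abs(est$r - true$r)), tol_deg)
}
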