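test_that("polymerization force follows the force-velocity relation", {
  expect_equal(polymerization_force(kinetic_params(v_contact = 0.05)), 0)
  expect_equal(polymerization_force(
    kinetic_params(v_grow = 0.05, v_contact = 0.01, stall_force = 5)), 4)
  expect_equal(polymerization_force(
    kinetic_params(v_contact = 1e-12, stall_force = 5)), 5, tolerance = 1e-9)
})

test_that("buckling force has the closed form and the reference-length floor", {
  expect_equal(buckling_force(5, 5, 1.25), 1.25 * pi^2 / 25)
  expect_equal(buckling_force(5, 8, 1.25), 1.25 * pi^2 / 25) # max of the two
  expect_equal(buckling_force(1e6, 4, 1.25), 1.25 * pi^2 / 16)
  l <- seq(2, 6, by = 0.5)
  f <- buckling_force(l, 10, 1.25)
  expect_true(all(diff(f) < 0)) # decays until the floor takes over
})

test_that("anchors co-rotate with the nucleus at fixed radius", {
  n0 <- nucleus_state(c(0, 0), 0)
  expect_equal(anchor_world_position(n0, 0, 1.4), c(1.4, 0))
  npi <- nucleus_state(c(0, 0), pi)
  expect_equal(anchor_world_position(npi, 0, 1.4), c(-1.4, 0),
               tolerance = 1e-12)
  n2 <- nucleus_state(c(1, -2), 0.7)
  p <- anchor_world_position(n2, 1.1, 1.4)
  expect_equal(sqrt(sum((p - c(1, -2))^2)), 1.4)
})

test_that("contact force obeys the Heaviside condition and the min(fp, fe) cap", {
  kin <- kinetic_params()
  geom <- cell_geometry(7, 1.75)
  nuc <- nucleus_state(c(0, 0), 0)
  inside <- microtubule_state(length = 3, drawn_tau = 100)
  expect_identical(contact_force(inside, nuc, geom, kin)$contact, FALSE)
  expect_equal(contact_force(inside, nuc, geom, kin)$force, c(0, 0))

  # collinear polymerization-limited contact (short cell so fe > fp)
  g2 <- cell_geometry(3, 1.75)
  mt <- microtubule_state(length = 1.7, drawn_tau = 100)
  fr <- contact_force(mt, nuc, g2, kin)
  fp <- polymerization_force(kin)
  fe <- buckling_force(1.7, 1.7, kin$flexural_rigidity)
  expect_true(fr$contact)
  expect_gt(fe, fp)
  expect_equal(fr$force, c(-fp, 0))
  expect_equal(fr$torque, 0)

  # buckling-limited contact in a long cell
  mtl <- microtubule_state(length = 6, drawn_tau = 100,
                           buckling_ref_length = 5.6)
  frl <- contact_force(mtl, nuc, geom, kin)
  expect_true(frl$contact)
  expect_equal(sqrt(sum(frl$force^2)),
               buckling_force(6, 5.6, kin$flexural_rigidity))
  expect_lt(sqrt(sum(frl$force^2)), fp)

  # shrinking filaments never push
  shr <- microtubule_state(length = 8, phase = "shrinking", drawn_tau = 100)
  expect_equal(contact_force(shr, nuc, geom, kin)$force, c(0, 0))

  # force magnitude never exceeds the stall force
  set.seed(2)
  for (i in 1:50) {
    m <- microtubule_state(anchor_angle = runif(1, -pi, pi),
                           axis_angle = runif(1, -1.2, 1.2),
                           length = runif(1, 0.5, 12), drawn_tau = 100,
                           side = sample(c("right", "left"), 1))
    f <- contact_force(m, nuc, geom, kin)
    expect_lte(sqrt(sum(f$force^2)), kin$stall_force + 1e-12)
  }
})

test_that("mirror-symmetric contacts cancel exactly", {
  kin <- kinetic_params()
  geom <- cell_geometry(7, 1.75)
  nuc <- nucleus_state(c(0, 0), 0)
  r <- microtubule_state(anchor_angle = 0, axis_angle = 0, length = 6,
                         drawn_tau = 100, side = "right",
                         buckling_ref_length = 5.6)
  l <- microtubule_state(anchor_angle = pi, axis_angle = 0, length = 6,
                         drawn_tau = 100, side = "left",
                         buckling_ref_length = 5.6)
  fr <- contact_force(r, nuc, geom, kin)
  fl <- contact_force(l, nuc, geom, kin)
  expect_true(fr$contact && fl$contact)
  expect_equal(fr$force[1] + fl$force[1], 0)
})

test_that("nucleus drags are the Stokes sphere expressions", {
  d <- nucleus_drags(drag_environment(1, 1, 1e-3))
  expect_equal(unname(d), c(6 * pi, 8 * pi))
  d2 <- nucleus_drags(drag_environment(1, 2, 1e-3))
  expect_equal(unname(d2["rotational"] / d["rotational"]), 8)
  d14 <- nucleus_drags(drag_environment(1, 1.4, 0.0125))
  expect_equal(unname(d14["translational"]), 6 * pi * 1.4, tolerance = 1e-9)
})

test_that("slender-body MT drag sums the longest filament per anchor anisotropically", {
  env <- drag_environment(1, 1.4, 0.0125)
  expect_equal(unname(mt_drag_components(numeric(0), numeric(0), env)),
               c(0, 0))
  d <- mt_drag_components(5, 0, env)
  expect_equal(unname(d["parallel"]), 2 * pi * 5 / (log(5 / 0.025) - 0.2))
  expect_equal(unname(d["perpendicular"]), 0) # zero projected length skipped
  # parallel drag increases with length for axial filaments
  par <- vapply(seq(1, 10, by = 0.5), function(l)
    mt_drag_components(l, 0, env)["parallel"], numeric(1))
  expect_true(all(diff(par) > 0))
  # orientation-sign independence
  expect_equal(mt_drag_components(5, 0.4, env),
               mt_drag_components(5, -0.4, env))
  # sub-slender projected lengths are dropped, never negative
  tiny <- mt_drag_components(0.02, 0, env)
  expect_gte(tiny["parallel"], 0)
})

test_that("series drag combination reduces correctly in its limits", {
  expect_equal(effective_translational_drag(26.39, 1e12), 26.39,
               tolerance = 1e-9)
  expect_equal(effective_translational_drag(10, 10), 5)
  expect_equal(effective_translational_drag(26.39, 100),
               1 / (1 / 26.39 + 1 / 100))
  expect_equal(effective_translational_drag(26.39, 0), 26.39)
  z <- effective_translational_drag(26.39, 17)
  expect_true(z > 0 && z <= min(26.39, 17))
})
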