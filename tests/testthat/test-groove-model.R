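test_that("bur profile radius widens linearly above the tip", {
  bur <- fissure_bur()
  expect_equal(groove_profile_radius(bur, 0), 0.59)
  expect_equal(groove_profile_radius(bur, 3), 0.747223, tolerance = 1e-6)
  # untapered bur keeps its tip radius at any height
  straight <- fissure_bur(tip_radius = 0.59, half_angle = 0)
  expect_equal(groove_profile_radius(straight, c(0, 2, 7)), rep(0.59, 3))
  expect_true(all(diff(groove_profile_radius(bur, seq(0, 5, 0.5))) > 0))
  expect_error(groove_profile_radius(bur, -1), "non-negative")
  expect_error(fissure_bur(tip_radius = 0), "positive")
  expect_error(fissure_bur(half_angle = 25), "\\[0, 20\\)")
})

test_that("the groove's resisting wall sits half the base minus the tip radius from the axis", {
  expect_equal(groove_resisting_wall_distance(8, fissure_bur()), 3.41)
  expect_equal(groove_resisting_wall_distance(10, fissure_bur(tip_radius = 0.5)), 4.5)
  # a vanishing bur leaves the wall at the midpoint
  expect_equal(
    groove_resisting_wall_distance(8, fissure_bur(tip_radius = 1e-9)), 4,
    tolerance = 1e-6
  )
  expect_error(
    groove_resisting_wall_distance(8, fissure_bur(tip_radius = 4)),
    "half the buccolingual base"
  )
})

test_that("groove augmentation matches analytic forms on an untapered wall", {
  # with a vertical wall the channel is exactly a half cone-frustum:
  # groove = pi*(r0*H + tan(phi)*H^2/2)/cos(phi), strip = 2*(r0*H + tan(phi)*H^2/2)
  H <- 4; r0 <- 0.59; phi <- 3 * pi / 180
  core <- r0 * H + tan(phi) * H^2 / 2
  rH <- r0 + H * tan(phi)
  gg <- prep_grid(height = H, taper = 0) |>
    groove_augmentation(n_grooves = 1)
  expect_equal(gg$groove_area, pi * core / cos(phi), tolerance = 1e-8)
  expect_equal(gg$removed_area, 2 * core + pi * rH^2 / 2, tolerance = 1e-8)
  expect_equal(gg$net_gain, gg$groove_area - gg$removed_area)
})

test_that("two grooves on symmetric walls give exactly twice one groove", {
  g <- prep_grid(height = c(3, 5), taper = c(2, 18))
  one <- groove_augmentation(g, n_grooves = 1)
  two <- groove_augmentation(g, n_grooves = 2)
  expect_equal(two$removed_area, 2 * one$removed_area, tolerance = 1e-12)
  expect_equal(two$groove_area, 2 * one$groove_area, tolerance = 1e-12)
  expect_equal(two$net_gain, 2 * one$net_gain, tolerance = 1e-12)
})

test_that("a vanishing bur contributes nothing", {
  tiny <- fissure_bur(tip_radius = 1e-8, half_angle = 0)
  gg <- prep_grid(height = 3, taper = 6) |> groove_augmentation(bur = tiny)
  expect_lt(gg$removed_area, 1e-6)
  expect_lt(gg$groove_area, 1e-6)
  expect_lt(abs(gg$net_gain), 1e-6)
})

test_that("net gain is positive and grows with taper and with height", {
  gg <- premolar_grid() |> groove_augmentation()
  expect_true(all(gg$net_gain > 0))
  by_h <- split(gg, gg$height)
  for (sub in by_h) {
    sub <- sub[order(sub$taper), ]
    expect_true(all(diff(sub$net_gain) > 0))
  }
  by_t <- split(gg, gg$taper)
  for (sub in by_t) {
    sub <- sub[order(sub$height), ]
    expect_true(all(diff(sub$net_gain) > 0))
  }
})

test_that("frozen two-groove values for the 3 mm / 2 degree cell", {
  # frozen from the implemented model, verified against the triangulation
  # oracle in test-arc-oracle.R
  gg <- prep_grid(height = 3, taper = 2) |> groove_augmentation()
  expect_equal(gg$removed_area, 9.74717835, tolerance = 1e-7)
  expect_equal(gg$groove_area, 13.25127694, tolerance = 1e-7)
  expect_equal(gg$net_gain, 3.50409859, tolerance = 1e-7)
})

test_that("oversized burs and bad groove counts are rejected", {
  wide <- fissure_bur(tip_radius = 3, half_angle = 3)
  expect_error(
    prep_grid(height = 5, taper = 12) |> groove_augmentation(bur = wide),
    "groove too wide"
  )
  expect_error(
    premolar_grid() |> groove_augmentation(n_grooves = 3),
    "1 or 2"
  )
  expect_error(groove_augmentation(premolar_grid(), bur = list()), "bur_spec")
})
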