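test_that("half-arcsine limits reproduce the published per-height values", {
  lim <- max_resistance_angle(c(3, 4, 5), 8)
  expect_equal(round(lim$theta_max, 1), c(11.0, 15.0, 19.3))
  # H/B = 1/2 is analytically exact: asin(1/2)/2 = 15 degrees
  expect_equal(max_resistance_angle(4, 8)$theta_max, 15)
  expect_false(any(lim$capped))
  # zero wall height resists nothing
  expect_equal(max_resistance_angle(0, 8)$theta_max, 0)
})

test_that("the limit saturates when the wall is taller than the base", {
  # arc re-entry height B*sin(2*theta) <= B <= H, so every taper < 45 resists
  lim <- max_resistance_angle(4, 3.41)
  expect_true(lim$capped)
  expect_equal(lim$theta_max, 45)
  for (th in c(1, 20, 44.9)) {
    expect_true(resists(th, height = 4, base_length = 3.41))
    expect_true(sweep_resists(th, 4, 3.41)$resists)
  }
})

test_that("critical contact height is the arc re-entry height B*sin(2*theta)", {
  expect_equal(critical_contact_height(0, 8), 0)
  expect_equal(critical_contact_height(15, 8), 4)
  # inverse of the limit: at theta_max for H = 3, the arc re-enters at 3 mm
  th3 <- max_resistance_angle(3, 8)$theta_max
  expect_equal(critical_contact_height(th3, 8), 3, tolerance = 1e-9)
  expect_error(critical_contact_height(45, 8), "\\[0, 45\\)")
  expect_error(critical_contact_height(5, 0), "positive")
})

test_that("resists() encodes wall-intercepts-arc and honours published cases", {
  expect_false(resists(12, height = 3, base_length = 8)) # above the 11.0 limit
  expect_true(resists(19, height = 5, base_length = 8)) # below 19.3
  expect_true(resists(3, height = 3, base_length = 3.41))
  expect_true(resists(0.01, height = 5, base_length = 8))

  # boundary consistency just around the limit
  for (h in c(3, 4, 5)) {
    tm <- max_resistance_angle(h, 8)$theta_max
    expect_true(resists(tm - 0.01, h, 8))
    expect_false(resists(tm + 0.01, h, 8))
  }
})

test_that("the limit is monotone in height and base length", {
  hs <- seq(0.5, 7.5, by = 0.5)
  expect_true(all(diff(max_resistance_angle(hs, 8)$theta_max) >= 0))
  bs <- seq(5, 12, by = 0.5)
  expect_true(all(diff(max_resistance_angle(3, bs)$theta_max) <= 0))
})

test_that("grid-level resistance columns agree with the scalar rules", {
  rl <- premolar_grid() |> resistance_limit()
  expect_equal(rl$theta_max, max_resistance_angle(rl$height, rl$bl_length)$theta_max)
  expect_equal(rl$resists, rl$taper_b < rl$theta_max)
  # low-taper cells resist; at 18 degrees only the 5 mm wall (limit 19.3) does
  expect_true(all(rl$resists[rl$taper == 2]))
  expect_equal(rl$resists[rl$taper == 18], c(3, 4, 5) >= 5)
})

test_that("grooves rescue over-tapered preparations at every study height", {
  gr <- premolar_grid() |> groove_resistance()
  expect_equal(unique(gr$groove_base_length), 3.41)
  expect_true(all(gr$groove_resists))
  # heights 4 and 5 exceed the 3.41 mm base, so their limits saturate
  expect_equal(gr$groove_capped, gr$height >= 3.41)
  # while the plain 12-degree, 3 mm preparation rotates free
  expect_false(resists(12, height = 3, base_length = 8))

  expect_error(
    premolar_grid() |> groove_resistance(bur = fissure_bur(tip_radius = 4)),
    "half the buccolingual base"
  )
})
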