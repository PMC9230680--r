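# Screw-theory primitives: hat/vee, exponential maps, PoE posture, wrench
# rotation.

test_that("hat_twist builds the Lie-algebra matrix and vee inverts it", {
  zero <- twist(c(0, 0, 0), c(0, 0, 0))
  expect_equal(hat_twist(zero), matrix(0, 4, 4))

  xi <- twist(c(1, 0, 0), c(0, 0, 0))
  m <- hat_twist(xi)
  expect_equal(m[1:3, 1:3],
               matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE))
  expect_equal(m[1:3, 4], c(0, 0, 0))
  expect_equal(m[4, ], rep(0, 4))

  set.seed(11)
  for (i in 1:20) {
    xi <- random_unit_twist()
    back <- vee_twist(hat_twist(xi))
    expect_equal(back$omega, xi$omega)
    expect_equal(back$v, xi$v)
  }
})

test_that("exp_twist reproduces the prismatic and revolute closed forms", {
  # any twist at zero angle is the identity
  expect_equal(pose_diff(exp_twist(random_unit_twist(), 0), hom_transform()),
               0, tolerance = 1e-12)

  # prismatic: pure translation delta_l along z
  dl <- 3.7
  g1 <- exp_twist(prismatic_twist(c(0, 0, 1)), dl)
  expect_equal(g1$R, diag(3))
  expect_equal(g1$t, c(0, 0, dl))

  # revolute about x through (0, 0, l): rotation Rx with translation
  # (0, l sin, l (1 - cos))
  l <- 150; th <- 0.31
  g2 <- exp_twist(revolute_twist(c(1, 0, 0), c(0, 0, l)), th)
  expect_equal(g2$R, rot_x(th), tolerance = 1e-12)
  expect_equal(g2$t, c(0, l * sin(th), l * (1 - cos(th))), tolerance = 1e-12)
})

test_that("exp_twist matches the 30-term series oracle on random twists", {
  set.seed(42)
  for (i in 1:100) {
    xi <- random_unit_twist()
    th <- stats::runif(1, -pi, pi)
    closed <- as_matrix4(exp_twist(xi, th))
    series <- expm_series(th * hat_twist(xi), 30)
    expect_lt(max(abs(closed - series)), 1e-9)
  }
  # prismatic twists too
  for (i in 1:20) {
    xi <- prismatic_twist(stats::rnorm(3))
    th <- stats::runif(1, -5, 5)
    expect_lt(max(abs(as_matrix4(exp_twist(xi, th)) -
                        expm_series(th * hat_twist(xi), 30))), 1e-9)
  }
})

test_that("exp_twist is a one-parameter subgroup along a fixed screw", {
  set.seed(7)
  for (i in 1:25) {
    xi <- random_unit_twist()
    a <- stats::runif(1, -pi, pi); b <- stats::runif(1, -pi, pi)
    expect_lt(pose_diff(exp_twist(xi, a) %g% exp_twist(xi, b),
                        exp_twist(xi, a + b)), 1e-9)
  }
})

test_that("exp_twist rejects non-unit nonzero omega", {
  expect_error(exp_twist(twist(c(2, 0, 0), c(0, 0, 0)), 0.5),
               "normalization")
})

test_that("returned transforms satisfy rotation validity invariants", {
  set.seed(5)
  for (i in 1:30) {
    g <- exp_twist(random_unit_twist(), stats::runif(1, -pi, pi))
    expect_lt(max(abs(crossprod(g$R) - diag(3))), 1e-10)
    expect_lt(abs(det(g$R) - 1), 1e-10)
  }
})

test_that("pose_poe composes the rod and hinge exponentials", {
  l <- 150
  # zero motion: raw product is the identity, full product is p(0)
  expect_equal(pose_diff(pose_poe(0, 0, l), hom_transform()), 0)
  expect_equal(pose_poe(0, 0, l, include_p0 = TRUE)$t, c(0, l, 0))

  # raw product reproduces the printed two-exponential matrix
  dl <- 2.4; th <- 0.2
  g <- pose_poe(dl, th, l)
  expect_equal(g$R, rot_x(th), tolerance = 1e-12)
  expect_equal(g$t, c(0, l * sin(th), dl + l * (1 - cos(th))),
               tolerance = 1e-12)

  # arbitrary parameters: equals chaining exp_twist via %g%
  set.seed(3)
  for (i in 1:10) {
    dl <- stats::runif(1, -3, 3); th <- stats::runif(1, -0.5, 0.5)
    chain <- exp_twist(prismatic_twist(c(0, 0, 1)), dl) %g%
      exp_twist(revolute_twist(c(1, 0, 0), c(0, 0, l)), th)
    expect_lt(pose_diff(pose_poe(dl, th, l), chain), 1e-12)
    full <- chain %g% hom_transform(diag(3), c(0, l, 0))
    expect_lt(pose_diff(pose_poe(dl, th, l, include_p0 = TRUE), full), 1e-12)
  }
  expect_error(pose_poe(1, 0.1, -5), "l")
})

test_that("rotate_wrench applies Rx, preserves norms, and inverts", {
  F0 <- wrench(c(3, -4, 12), c(10, 0, -7))
  expect_equal(rotate_wrench(F0, 0), F0)

  # f = (0,0,1) through a quarter turn lands on (0,-1,0)
  Fq <- rotate_wrench(wrench(c(0, 0, 1)), pi / 2)
  expect_equal(Fq$f, c(0, -1, 0), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:30) {
    F <- random_wrench()
    th <- stats::runif(1, -2 * pi, 2 * pi)
    Fr <- rotate_wrench(F, th)
    expect_equal(sqrt(sum(Fr$f^2)), sqrt(sum(F$f^2)), tolerance = 1e-12)
    expect_equal(sqrt(sum(Fr$tau^2)), sqrt(sum(F$tau^2)), tolerance = 1e-12)
    back <- rotate_wrench(Fr, -th)
    expect_lt(max(abs(back$f - F$f), abs(back$tau - F$tau)), 1e-12)
  }
})

test_that("twist pitch is (omega.v)/|omega|^2 and infinite for prismatic", {
  expect_equal(twist_pitch(prismatic_twist(c(0, 0, 1))), Inf)
  # revolute through a point: v perpendicular to omega, zero pitch
  expect_equal(twist_pitch(revolute_twist(c(1, 0, 0), c(0, 0, 150))), 0)
  expect_equal(twist_pitch(twist(c(0, 0, 1), c(1, 2, 3))), 3)
})
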