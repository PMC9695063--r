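test_that("moved-bead count range follows the 3N/4 rule", {
  expect_equal(knotgo:::max_moved_beads(8), 5)    # largest integer < 6
  expect_equal(knotgo:::max_moved_beads(10), 7)   # largest integer < 7.5
  expect_equal(knotgo:::max_moved_beads(4), 2)
  set.seed(1)
  x <- random_clashfree_chain(8, 3)
  ms <- replicate(2000, select_move(x)$m)
  expect_setequal(sort(unique(ms)), 1:5)
})

test_that("move kinds are drawn with probability one half each", {
  set.seed(2)
  x <- random_clashfree_chain(12, 4)
  kinds <- replicate(1e4, select_move(x)$kind)
  expect_lt(abs(mean(kinds == "crankshaft") - 0.5), 0.02)
})

test_that("the smallest pivot rotates only the terminal bead", {
  set.seed(3)
  x <- random_clashfree_chain(8, 5)
  repeat {
    mv <- select_move(x)
    if (mv$kind == "pivot" && mv$m == 1) break
  }
  expect_true(identical(mv$moving_set, 1L:1L) ||
              identical(mv$moving_set, 8L:8L))
  mv$angle <- 1.2
  mv$ltyp <- FALSE
  trial <- apply_and_screen(x, mv, go_params())
  if (!is.null(trial)) {
    moved <- which(rowSums(abs(trial - x)) > 1e-12)
    expect_true(all(moved %in% mv$moving_set))
  }
})

test_that("free interval is the full circle when no collision is reachable", {
  # terminal bead orbits on a small circle; every fixed bead is far
  # outside the orbit's reach
  x <- rbind(c(0, 0, 3), c(0, 0, 0), c(30, 0, 0), c(60, 0, 0), c(90, 0, 0))
  mv <- structure(list(kind = "pivot", m = 1L, moving_set = 1L,
                       axis_point = x[2, ], axis_dir = c(0, 1, 0),
                       ltyp = TRUE, free_interval = NULL, angle = NULL),
                  class = "move_proposal")
  mv <- free_rotation_interval(x, mv, go_params())
  expect_equal(mv$free_interval, c(-pi, pi))
})

test_that("contact angles match the law of cosines on a planar construction", {
  # moving bead on a circle of radius R about the z-axis, one coplanar fixed
  # bead at distance D on the opposite azimuth: contact at +-(pi - alpha),
  # cos(alpha) = (R^2 + D^2 - c^2) / (2 R D)
  R <- 4; D <- 5; r <- 1.7; c2 <- 2 * r
  x <- rbind(c(R, 0, 0),        # moving bead 1
             c(0, 0, 0),        # axis bead 2
             c(-D, 0, 0),       # fixed bead 3 at azimuth pi
             c(-D - 3.8, 0, 0)) # spacer
  mv <- structure(list(kind = "pivot", m = 1L, moving_set = 1L,
                       axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                       ltyp = TRUE, free_interval = NULL, angle = NULL),
                  class = "move_proposal")
  got <- free_rotation_interval(x, mv, go_params())$free_interval
  alpha <- acos((R^2 + D^2 - c2^2) / (2 * R * D))
  expect_equal(got, c(-(pi - alpha), pi - alpha), tolerance = 1e-9)
})

test_that("analytic free intervals agree with the dense-scan oracle", {
  set.seed(11)
  p <- go_params()
  for (rep in 1:30) {
    x <- random_clashfree_chain(12, 400 + rep)
    mv <- select_move(x)
    mv <- free_rotation_interval(x, mv, p)
    sc <- free_interval_scan(x, mv, p, step = 1e-3)
    expect_lt(max(abs(mv$free_interval - sc)), 2.5e-3)
  }
})

test_that("LTyP angles stay inside the free interval and trials never clash", {
  set.seed(12)
  p <- go_params()
  x <- random_clashfree_chain(10, 21)
  for (rep in 1:500) {
    mv <- select_move(x)
    mv <- free_rotation_interval(x, mv, p)
    mv <- propose_angle(mv)
    expect_gte(mv$angle, mv$free_interval[1])
    expect_lte(mv$angle, mv$free_interval[2])
    trial <- apply_and_screen(x, mv, p)   # errors on any LTyP clash
    x <- trial
  }
  expect_false(knotgo:::cpp_has_clash(x, p$bead_radius))
})

test_that("zero angle is the identity and rotations are rigid", {
  set.seed(13)
  p <- go_params()
  x <- random_clashfree_chain(10, 31)
  mv <- select_move(x, ltyp = FALSE)
  mv$angle <- 0
  expect_equal(apply_and_screen(x, mv, p), x, tolerance = 1e-15)
  mv$angle <- 2.1
  trial <- apply_and_screen(x, mv, p)
  if (!is.null(trial)) {
    b0 <- sqrt(rowSums(diff(x)^2)); b1 <- sqrt(rowSums(diff(trial)^2))
    expect_equal(b1, b0, tolerance = 1e-9)
    set <- mv$moving_set
    expect_equal(as.matrix(dist(trial[set, , drop = FALSE])),
                 as.matrix(dist(x[set, , drop = FALSE])), tolerance = 1e-9)
  }
})

test_that("the free interval is symmetric between a state and its trial", {
  set.seed(14)
  p <- go_params()
  for (rep in 1:20) {
    x <- random_clashfree_chain(10, 600 + rep)
    mv <- select_move(x)
    mv <- free_rotation_interval(x, mv, p)
    iv <- mv$free_interval
    if (diff(iv) >= 2 * pi - 1e-9) next
    th <- runif(1, iv[1], iv[2])
    mv$angle <- th
    trial <- apply_and_screen(x, mv, p)
    iv2 <- free_rotation_interval(trial, mv, p)$free_interval
    # same clash-free arc seen from the rotated state: shifted by -theta
    expect_equal(diff(iv2), diff(iv), tolerance = 1e-6)
    expect_equal(iv2[1], iv[1] - th, tolerance = 1e-6)
  }
})

test_that("bead radius 1.38 A is the crossing-safety threshold at 3.9 A bonds", {
  r <- min_crossing_safe_radius(3.9)
  expect_equal(r, (3.9 / 2) * sqrt(2) / 2, tolerance = 1e-4)
})

test_that("non-LTyP trials with steric clashes are rejected before Metropolis", {
  # force a clash: two parallel strands 3.5 A apart, rotate one into the other
  x <- rbind(cbind(3.8 * (0:3), 0, 0), cbind(3.8 * (3:0), 3.5, 0.5))
  p <- go_params()
  expect_false(knotgo:::cpp_has_clash(x, p$bead_radius))
  mv <- structure(list(kind = "pivot", m = 2L, moving_set = 1:2,
                       axis_point = x[3, ], axis_dir = c(0, 0, 1),
                       ltyp = FALSE, free_interval = NULL, angle = pi),
                  class = "move_proposal")
  expect_null(apply_and_screen(x, mv, p))
})
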