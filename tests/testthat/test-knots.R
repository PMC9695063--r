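test_that("closed benchmark curves are typed by their Alexander invariants", {
  # expected invariants from the textbook Alexander polynomials:
  # 3_1: t^2-t+1 -> |D(-1)|=3, |D(-2)|=7; 4_1: t^2-3t+1 -> 5, 11;
  # 5_1: t^4-t^3+t^2-t+1 -> 5, 31 (odd parts shown)
  cases <- list(trefoil = c("3_1", 3, 7), figure8 = c("4_1", 5, 11),
                torus51 = c("5_1", 5, 31), circle = c("unknot", 1, 1))
  for (nm in names(cases)) {
    ty <- knot_type(closed_curve(nm), closed = TRUE)
    inv <- attr(ty, "invariants")
    expect_identical(as.character(ty), cases[[nm]][1])
    expect_equal(inv$det1, as.numeric(cases[[nm]][2]))
    expect_equal(inv$det2_odd, as.numeric(cases[[nm]][3]))
  }
})

test_that("the invariant lookup separates all labelled knots", {
  # 5_2 (2t^2-3t+2) and 6_1 (2t^2-5t+2) evaluated by direct arithmetic:
  # |D(-1)| = 7 and 9; |D(-2)| = 16 and 20, with odd parts 1 and 5
  p52 <- function(t) 2 * t^2 - 3 * t + 2
  p61 <- function(t) 2 * t^2 - 5 * t + 2
  odd <- function(v) { while (v %% 2 == 0) v <- v / 2; v }
  expect_equal(abs(p52(-1)), 7); expect_equal(odd(abs(p52(-2))), 1)
  expect_equal(abs(p61(-1)), 9); expect_equal(odd(abs(p61(-2))), 5)
  expect_identical(knotgo:::knot_label_from_invariants(7, 1), "5_2")
  expect_identical(knotgo:::knot_label_from_invariants(9, 5), "6_1")
  # a granny-knot composite (det 9, odd part of D(-2) = 49) is "other"
  expect_identical(knotgo:::knot_label_from_invariants(9, 49), "other")
})

test_that("open-chain typing handles the parametric trefoil and its mirror", {
  arc <- trefoil_curve(60)
  expect_identical(as.character(knot_type(arc)), "3_1")
  expect_identical(as.character(knot_type(arc %*% diag(c(1, 1, -1)))), "3_1")
  expect_true(is_knotted(arc))
  hairpin <- rbind(cbind(3.8 * (0:5), 0, 0), cbind(3.8 * (5:0), 3.5, 0.7))
  expect_identical(as.character(knot_type(hairpin)), "unknot")
  expect_false(is_knotted(hairpin))
})

test_that("typing is invariant under rigid motion, scaling and refinement", {
  set.seed(31)
  x <- trefoil_curve(50)
  for (rep in 1:5)
    expect_identical(as.character(knot_type(random_rigid_motion(x))), "3_1")
  expect_identical(as.character(knot_type(x * 37.5)), "3_1")
  expect_identical(as.character(knot_type(trefoil_curve(200))), "3_1")
})

test_that("KMT reduction collapses convex chains and preserves endpoints", {
  straight <- cbind(0:9, 0, 0)
  r <- kmt_reduce(straight)
  expect_lte(nrow(r), 3)
  expect_equal(r[1, ], straight[1, ])
  expect_equal(r[nrow(r), ], straight[10, ])
  # convex planar arc
  t <- seq(0, pi, length.out = 20)
  arc <- cbind(cos(t), sin(t), 0)
  expect_lte(nrow(kmt_reduce(arc)), 3)
})

test_that("KMT reduction never changes the knot state of sampled conformations", {
  p <- go_params(w = 0.5)
  topo <- make_knotted_topology(35)
  run <- quick_run(topo, p, temperature_ladder(0.15, 0.6, 4), total = 4e4,
                   seed = 8, sample_period = 2e3)
  # final replica conformations span folded (knotted) and unfolded states
  for (x in run$final$coords) {
    red <- kmt_reduce(x)
    expect_identical(is_knotted(red), is_knotted(x))
  }
})

test_that("radial closure yields a single loop containing all input vertices", {
  x <- trefoil_curve(40)
  loop <- close_chain(x, arc_points = 12)
  expect_equal(nrow(loop), 40 + 2 + 12)
  expect_equal(loop[seq_len(40), ], x)
  # closure points lie far outside the chain
  cen <- colMeans(x)
  rmax <- max(sqrt(rowSums(sweep(x, 2, cen)^2)))
  rclose <- sqrt(rowSums(sweep(loop[41:54, , drop = FALSE], 2, cen)^2))
  expect_true(all(rclose > 5 * rmax))
  # closing an unknotted hairpin gives the unknot
  hp <- rbind(cbind(3.8 * (0:5), 0, 0), cbind(3.8 * (5:0), 3.5, 0.7))
  expect_identical(as.character(knot_type(close_chain(hp), closed = TRUE)),
                   "unknot")
})

test_that("knotted core is minimal and stable under straight tail extension", {
  topo <- make_knotted_topology(35)
  x <- topo$coords
  core <- knotted_core(x)
  a <- core[["core_start"]]; b <- core[["core_end"]]
  expect_true(is_knotted(x[a:b, , drop = FALSE]))
  expect_false(is_knotted(x[(a + 1):b, , drop = FALSE]))
  expect_false(is_knotted(x[a:(b - 1), , drop = FALSE]))
  expect_error(knotted_core(cbind(0:9, 0, 0)), "not knotted")
  # appended collinear tail: core fixed, tail grows by the appended count
  dirC <- x[35, ] - x[34, ]; dirC <- dirC / sqrt(sum(dirC^2))
  tail20 <- t(vapply(1:20, function(s) x[35, ] + 3.8 * s * dirC, numeric(3)))
  xt <- rbind(x, tail20)
  core_t <- knotted_core(xt)
  expect_equal(core_t[["core_start"]], a)
  expect_equal(core_t[["core_end"]], b)
})

test_that("knot reports classify depth from tail lengths", {
  deep <- knot_report(synthetic_protein_trace("rds3p_like"))
  expect_identical(deep$knot_type, "3_1")
  expect_identical(deep$depth_class, "deep")
  expect_equal(c(deep$core_start, deep$core_end), c(21, 74))
  expect_equal(c(deep$n_tail_len, deep$c_tail_len), c(20, 35))
  shallow <- knot_report(synthetic_protein_trace("mj0366_like"))
  expect_identical(shallow$depth_class, "shallow")
  expect_equal(c(shallow$core_start, shallow$core_end), c(11, 82))
  unk <- knot_report(synthetic_protein_trace("fn3_like"))
  expect_false(unk$knotted)
  expect_true(is.na(unk$core_start))
})
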