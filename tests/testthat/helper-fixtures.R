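# shared helpers for the test suite; all fixtures are built in code

# freely jointed clash-free chain (retry streams until clash-free)
random_clashfree_chain <- function(n, seed, radius = 1.7, bond = 3.8) {
  att <- 0
  repeat {
    att <- att + 1
    x <- knotgo:::cpp_random_chain(rep(bond, n - 1), seed, att)
    if (!knotgo:::cpp_has_clash(x, radius)) return(x)
    if (att > 1000) stop("could not build a clash-free chain")
  }
}

# topology on the knotted fixture geometry restricted to contacts whose
# chirality is defined in both pair orders and whose triple products are
# comfortably nonzero: on such contacts the mirror image scores exactly zero
mirror_test_topology <- function() {
  base <- make_knotted_topology(35)
  x <- base$coords
  n <- nrow(x)
  trip <- function(i, j) {
    abs(sum((x[i, ] - x[j, ]) *
            crossprod_vec(x[j + 1, ] - x[j, ], x[j - 1, ] - x[j, ])))
  }
  ct <- base$contacts
  interior <- !(ct$i %in% c(1, n)) & !(ct$j %in% c(1, n))
  ct <- ct[interior, , drop = FALSE]
  keep <- mapply(trip, ct$i, ct$j) > 1e-6 & mapply(trip, ct$j, ct$i) > 1e-6
  native_topology(x, cbind(ct$i[keep], ct$j[keep]),
                  contact_rule = base$contact_rule)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random proper rigid motion (rotation + translation)
random_rigid_motion <- function(x) {
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0),
              c(0, 0, 1))
  sweep(x %*% (Rx %*% Rz), 2, runif(3, -20, 20), "+")
}

# closed parametric benchmark loops
closed_curve <- function(kind, n = 120) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  switch(kind,
    trefoil = cbind(sin(tt) + 2 * sin(2 * tt), cos(tt) - 2 * cos(2 * tt),
                    -sin(3 * tt)),
    figure8 = cbind((2 + cos(2 * tt)) * cos(3 * tt),
                    (2 + cos(2 * tt)) * sin(3 * tt), sin(4 * tt)),
    torus51 = cbind((2 + cos(5 * tt)) * cos(2 * tt),
                    (2 + cos(5 * tt)) * sin(2 * tt), sin(5 * tt)),
    circle = cbind(cos(tt), sin(tt), 0 * tt))
}

# short REMC run on a given topology (shared by several tests)
quick_run <- function(topo, params, temps, total = 1e5, seed = 1,
                      ltyp = FALSE, start = "native", den = NULL,
                      sample_period = 1e3, record_knots = FALSE, ...) {
  cfg <- run_config(temps, total, exchange_period = 1e3,
                    sample_period = sample_period, ltyp = ltyp,
                    start = start, seed = seed, start_conformation = den,
                    record_knots = record_knots, ...)
  run_remc(topo, params, cfg)
}
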