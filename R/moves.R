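#' Draw a random crankshaft or pivot proposal
#'
#' The move kind is chosen with probability 1/2 each; the number of moved
#' beads m is uniform on {1, ..., m_max} with m_max the largest integer
#' strictly smaller than 3N/4. A crankshaft rotates a uniformly random
#' contiguous internal window of m beads about the axis through its two
#' flanking beads; a pivot rotates the m beads adjacent to a uniformly
#' random terminus about an isotropically random axis through the bead at
#' distance m from that terminus. Draws infeasible for the chain length
#' (a crankshaft window with no flanks) are redrawn. Uses R's RNG; seed
#' with [set.seed()].
#'
#' @param conf conformation coordinates (N x 3 matrix or `go_conformation`).
#' @param ltyp logical: will the move be used in topology-preserving mode?
#'   (recorded on the proposal; the free interval is computed separately).
#' @return An object of class `move_proposal`: kind, moving-bead index
#'   range (1-based), axis point and unit direction.
#' @export
select_move <- function(conf, ltyp = TRUE) {
  x <- conf_coords(conf)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 beads")
  mmax <- max_moved_beads(n)
  repeat {
    crank <- runif(1) < 0.5
    m <- 1L + as.integer(floor(runif(1) * mmax)) %% mmax
    if (crank) {
      if (m > n - 2) next
      a <- 1L + as.integer(floor(runif(1) * (n - m - 1))) %% (n - m - 1L)
      a <- a + 1L                       # window start in [2, n-m] (1-based)
      b <- a + m - 1L
      d <- x[b + 1L, ] - x[a - 1L, ]
      return(structure(list(kind = "crankshaft", m = m,
                            moving_set = a:b,
                            axis_point = x[a - 1L, ],
                            axis_dir = d / sqrt(sum(d^2)),
                            ltyp = ltyp, free_interval = NULL, angle = NULL),
                       class = "move_proposal"))
    } else {
      if (m > n - 1) next
      nterm <- runif(1) < 0.5
      if (nterm) {
        axis <- m + 1L; set <- 1:m
      } else {
        axis <- n - m; set <- (n - m + 1L):n
      }
      u <- random_unit_vector()
      return(structure(list(kind = "pivot", m = m, moving_set = set,
                            axis_point = x[axis, ], axis_dir = u,
                            ltyp = ltyp, free_interval = NULL, angle = NULL),
                       class = "move_proposal"))
    }
  }
}

# largest integer strictly smaller than 3N/4
max_moved_beads <- function(n) {
  m <- floor(3 * n / 4)
  if (4 * m == 3 * n) m <- m - 1
  max(1L, as.integer(m))
}

random_unit_vector <- function() {
  repeat {
    v <- runif(3, -1, 1)
    s <- sum(v^2)
    if (s > 0 && s <= 1) return(v / sqrt(s))
  }
}

#' Free rotation interval of a proposal (LTyP)
#'
#' For every (moving bead, fixed bead) pair that can come within contact
#' distance under the rotation, the clockwise and counter-clockwise contact
#' angles are solved in closed form; the free interval of the whole moving
#' block is the intersection of all pairwise clash-free arcs containing
#' angle 0. Rotating to either endpoint brings some pair exactly into
#' grazing contact (contact without overlap), which is allowed.
#'
#' @param conf conformation coordinates; must be clash-free.
#' @param proposal a `move_proposal` from [select_move()].
#' @param params a [go_params()] object (bead radius).
#' @return The proposal with `free_interval = c(lo, hi)` filled in
#'   (`lo <= 0 <= hi`, radians; `c(-pi, pi)` when unrestricted).
#' @export
free_rotation_interval <- function(conf, proposal, params = go_params()) {
  x <- conf_coords(conf)
  set <- proposal$moving_set
  iv <- cpp_free_interval(x, proposal$kind == "crankshaft",
                          min(set) - 1L, max(set) - 1L,
                          proposal$axis_point, proposal$axis_dir,
                          params$bead_radius)
  proposal$free_interval <- iv
  proposal
}

#' Draw the rotation angle of a proposal
#'
#' Non-LTyP proposals draw uniformly on (-pi, pi]; LTyP proposals draw
#' uniformly on their free rotation interval (which must have been computed
#' with [free_rotation_interval()]). Uses R's RNG.
#'
#' @param proposal a `move_proposal`.
#' @return The proposal with `angle` filled in.
#' @export
propose_angle <- function(proposal) {
  if (proposal$ltyp) {
    iv <- proposal$free_interval
    if (is.null(iv)) stop("LTyP proposal lacks a free rotation interval")
    proposal$angle <- runif(1, iv[1], iv[2])
  } else {
    proposal$angle <- runif(1, -pi, pi)
  }
  proposal
}

#' Apply a proposal and screen the trial conformation
#'
#' Rigidly rotates the moving block about the proposal axis. LTyP trials
#' are clash-free by construction and are asserted to be so; non-LTyP
#' trials with any non-bonded pair closer than twice the bead radius are
#' rejected (returned as `NULL`) before any Metropolis test.
#'
#' @param conf conformation coordinates.
#' @param proposal a `move_proposal` with `angle` set.
#' @param params a [go_params()] object.
#' @return The trial coordinate matrix, or `NULL` for a steric rejection.
#' @export
apply_and_screen <- function(conf, proposal, params = go_params()) {
  x <- conf_coords(conf)
  if (is.null(proposal$angle)) stop("proposal has no angle")
  set <- proposal$moving_set
  trial <- cpp_rotate_block(x, min(set) - 1L, max(set) - 1L,
                            proposal$axis_point, proposal$axis_dir,
                            proposal$angle)
  clash <- cpp_block_clashes(trial, min(set) - 1L, max(set) - 1L,
                             params$bead_radius)
  if (clash) {
    if (proposal$ltyp)
      stop("LTyP violation: clash in a topology-preserving trial")
    return(NULL)
  }
  trial
}

#' One Metropolis Monte Carlo step at fixed temperature
#'
#' Reference single-step implementation chaining [select_move()],
#' [free_rotation_interval()], [propose_angle()] and [apply_and_screen()],
#' then accepting with probability `min(1, exp(-dE / T))` (kB = 1). A
#' steric rejection or Metropolis rejection retains the current
#' conformation; either way the call counts as one Monte Carlo step. The
#' production sampler ([run_remc()]) uses an equivalent compiled path.
#'
#' @param conf current coordinates.
#' @param topo the [native_topology()].
#' @param params a [go_params()] object.
#' @param temperature reduced temperature (> 0).
#' @param ltyp use the topology-preserving move variant.
#' @return List with `coords`, `energy`, `accepted`.
#' @export
metropolis_step <- function(conf, topo, params, temperature, ltyp = TRUE) {
  x <- conf_coords(conf)
  mv <- select_move(x, ltyp = ltyp)
  if (ltyp) mv <- free_rotation_interval(x, mv, params)
  mv <- propose_angle(mv)
  trial <- apply_and_screen(x, mv, params)
  e0 <- total_energy(x, topo, params)
  if (is.null(trial))
    return(list(coords = x, energy = e0, accepted = FALSE))
  e1 <- total_energy(trial, topo, params)
  de <- e1 - e0
  if (de <= 0 || runif(1) < exp(-de / temperature))
    list(coords = trial, energy = e1, accepted = TRUE)
  else
    list(coords = x, energy = e0, accepted = FALSE)
}

#' Dense-scan oracle for the free rotation interval
#'
#' Brute-force check of the analytic interval: rotates the moving block
#' over a uniform angular grid and reports the maximal clash-free run of
#' angles containing 0. Intended for validation; independent of the
#' closed-form computation.
#'
#' @param conf conformation coordinates.
#' @param proposal a `move_proposal`.
#' @param params a [go_params()] object.
#' @param step angular grid resolution in radians.
#' @return `c(lo, hi)` in radians.
#' @export
free_interval_scan <- function(conf, proposal, params = go_params(),
                               step = 1e-3) {
  x <- conf_coords(conf)
  set <- proposal$moving_set
  cpp_free_interval_scan(x, proposal$kind == "crankshaft",
                         min(set) - 1L, max(set) - 1L,
                         proposal$axis_point, proposal$axis_dir,
                         params$bead_radius, step)
}
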