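#' Model parameters for the Go potential
#'
#' Bundles the parameters of the coarse-grained interaction model: the
#' uniform contact energy `epsilon` (reduced units), the potential-well
#' half-width `w` (Angstrom), the hard bead radius (Angstrom; the van der
#' Waals radius of a C-alpha atom), and the heavy-atom native-contact
#' cutoff (Angstrom).
#'
#' The half-width `w` sets the cooperativity of the folding transition: it
#' is the knob one tunes until the simulated FWHM/Tm ratio of the heat
#' capacity peak falls between 4 and 5 percent. The bead radius must be at
#' least 1.38 Angstrom for bead-bead exclusion alone to forbid chain
#' crossing at 3.9 Angstrom bonds (see [min_crossing_safe_radius()]);
#' the 1.7 Angstrom default satisfies this.
#'
#' @param epsilon contact energy, must be negative (default -1).
#' @param w potential-well half-width in Angstrom (default 1).
#' @param bead_radius hard-sphere bead radius in Angstrom (default 1.7).
#' @param contact_cutoff heavy-atom distance cutoff defining native
#'   contacts, in Angstrom (default 4.5).
#' @return An object of class `go_params`.
#' @examples
#' p <- go_params(w = 0.8)
#' p$w
#' @export
go_params <- function(epsilon = -1, w = 1, bead_radius = 1.7,
                      contact_cutoff = 4.5) {
  if (!is.numeric(epsilon) || epsilon >= 0) stop("epsilon must be negative")
  if (!is.numeric(w) || w <= 0) stop("w must be positive")
  if (!is.numeric(bead_radius) || bead_radius <= 0)
    stop("bead_radius must be positive")
  if (!is.numeric(contact_cutoff) || contact_cutoff <= 0)
    stop("contact_cutoff must be positive")
  structure(list(epsilon = epsilon, w = w, bead_radius = bead_radius,
                 contact_cutoff = contact_cutoff),
            class = "go_params")
}

#' @export
print.go_params <- function(x, ...) {
  cat("Go-model parameters:\n")
  cat(sprintf("  epsilon        %g (reduced)\n", x$epsilon))
  cat(sprintf("  w              %g A (well half-width)\n", x$w))
  cat(sprintf("  bead radius    %g A\n", x$bead_radius))
  cat(sprintf("  contact cutoff %g A (heavy-atom)\n", x$contact_cutoff))
  invisible(x)
}

#' Minimal bead radius that makes bead-bead exclusion forbid chain crossing
#'
#' For two rigid sticks of length at most `max_bond` whose interiors cross,
#' the four joint beads cannot all stay farther apart than some limiting
#' separation; if the bead radius is at least half the worst-case minimal
#' separation, any crossing would force two beads to overlap, so screening
#' bead pairs alone preserves the linear topology of the chain.
#'
#' The worst case is found numerically by maximising, over the crossing
#' point position along each stick and the angle between the sticks, the
#' minimal distance among the four (endpoint, endpoint) pairs. The maximum
#' is attained for perpendicular sticks crossing at their midpoints, giving
#' `(max_bond / 2) * sqrt(2) / 2`, which is 1.379 A for 3.9 A bonds.
#'
#' @param max_bond maximal bond (stick) length in Angstrom (default 3.9).
#' @return Minimal crossing-safe bead radius in Angstrom.
#' @examples
#' round(min_crossing_safe_radius(3.9), 2)  # 1.38
#' @export
min_crossing_safe_radius <- function(max_bond = 3.9) {
  L <- max_bond
  # sticks cross at the origin; endpoints at distances (s, L-s) and (t, L-t)
  # along unit directions separated by angle theta
  minpair <- function(par) {
    s <- par[1]; t <- par[2]; th <- par[3]
    a <- c(1, 0)
    b <- c(cos(th), sin(th))
    ends_a <- rbind(-s * a, (L - s) * a)
    ends_b <- rbind(-t * b, (L - t) * b)
    d <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j)
      sqrt(sum((ends_a[i, ] - ends_b[j, ])^2))))
    min(d)
  }
  # coarse grid, then local refinement of the maximin
  grid <- expand.grid(s = seq(0.05, L - 0.05, length.out = 9),
                      t = seq(0.05, L - 0.05, length.out = 9),
                      th = seq(0.1, pi / 2, length.out = 9))
  vals <- apply(grid, 1, minpair)
  best <- as.numeric(grid[which.max(vals), ])
  opt <- optim(best, function(p) {
    if (p[1] < 0 || p[1] > L || p[2] < 0 || p[2] > L) return(Inf)
    -minpair(p)
  }, method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 5000))
  -opt$value / 2
}
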