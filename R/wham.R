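# log(sum(exp(x))) with the usual max shift
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' WHAM density-of-states estimate from multi-temperature samples
#'
#' Combines the energy histograms of all ladder temperatures into a
#' maximum-likelihood density of states over joint (E, Q, knotted) bins by
#' iterating the standard self-consistency equations
#' `g(m) = sum_k H_k(m) / sum_k n_k exp(f_k - E_m / T_k)` and
#' `exp(-f_k) = sum_m g(m) exp(-E_m / T_k)` (kB = 1) until the
#' per-temperature free energies change by less than `tol`.
#'
#' Energy bins default to width `max(0.05, range/400)` reduced units; Q
#' bins to one per native-contact count (Q is naturally discrete).
#'
#' @param samples sample table of an [run_remc()] run (or the run itself):
#'   columns `temperature`, `E`, `Q`, optionally `knotted`.
#' @param temperatures the ladder; defaults to the sorted unique sampled
#'   temperatures.
#' @param nc number of native contacts (sets the Q bin width `1/nc`);
#'   inferred from the run object when available.
#' @param e_binwidth energy bin width override.
#' @param tol convergence tolerance on the free energies.
#' @param max_iter iteration cap.
#' @param min_overlap warn when any adjacent-temperature pair of energy
#'   histograms shares less than this fraction of samples.
#' @return An object of class `wham_dos` with the occupied bins
#'   (`E`, `Q`, `knotted`, `log_g`) and per-temperature log normalizers
#'   `f`.
#' @export
wham_fit <- function(samples, temperatures = NULL, nc = NULL,
                     e_binwidth = NULL, tol = 1e-8, max_iter = 1e5,
                     min_overlap = 0.01) {
  if (inherits(samples, "remc_run")) {
    if (is.null(nc)) nc <- samples$topo_nc
    samples <- samples$samples
  }
  if (is.null(temperatures))
    temperatures <- sort(unique(samples$temperature))
  K <- length(temperatures)
  if (!all(samples$temperature %in% temperatures))
    stop("samples contain temperatures outside the ladder")

  er <- range(samples$E)
  h <- if (is.null(e_binwidth)) max(0.05, diff(er) / 400) else e_binwidth
  e_bin <- round((samples$E - er[1]) / h)
  q_res <- if (!is.null(nc) && nc > 0) 1 / nc else {
    uq <- sort(unique(round(samples$Q, 10)))
    if (length(uq) > 1) max(min(diff(uq)), 1e-3) else 1
  }
  q_bin <- round(samples$Q / q_res)
  k_bin <- if ("knotted" %in% names(samples) && !all(is.na(samples$knotted)))
    as.integer(samples$knotted) else rep(0L, nrow(samples))

  key <- paste(e_bin, q_bin, k_bin)
  bins <- !duplicated(key)
  bin_id <- match(key, key[bins])
  M <- sum(bins)
  E_m <- er[1] + e_bin[bins] * h
  Q_m <- q_bin[bins] * q_res
  K_m <- k_bin[bins]

  t_idx <- match(samples$temperature, temperatures)
  H <- matrix(0, K, M)
  tab <- table(factor(t_idx, levels = seq_len(K)),
               factor(bin_id, levels = seq_len(M)))
  H[] <- as.numeric(tab)
  n_k <- rowSums(H)
  if (any(n_k == 0)) stop("a ladder temperature has no samples")

  # adjacent-histogram overlap check on the energy axis
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      ek <- unique(e_bin[t_idx == k])
      ek1 <- unique(e_bin[t_idx == k + 1])
      ov <- sum(e_bin[t_idx == k] %in% ek1) / n_k[k]
      if (length(intersect(ek, ek1)) == 0)
        stop(sprintf(
          "no energy-histogram overlap between T=%.4g and T=%.4g",
          temperatures[k], temperatures[k + 1]))
      if (ov < min_overlap)
        warning(sprintf(
          "adjacent overlap below %.1f%% between T=%.4g and T=%.4g",
          100 * min_overlap, temperatures[k], temperatures[k + 1]))
    }
  }

  beta <- 1 / temperatures
  logH_tot <- log(colSums(H))
  log_nk <- log(n_k)
  f <- numeric(K)
  BE <- -outer(beta, E_m)          # K x M matrix of -E_m / T_k
  for (iter in seq_len(max_iter)) {
    # log denominator per bin: logsumexp_k (log n_k + f_k - beta_k E_m)
    A <- BE + f + log_nk           # column-recycled: rows are k
    amax <- apply(A, 2, max)
    log_den <- amax + log(colSums(exp(sweep(A, 2, amax))))
    log_g <- logH_tot - log_den
    fnew <- vapply(seq_len(K), function(k) -logsumexp(log_g + BE[k, ]),
                   numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("WHAM did not reach tolerance in ", max_iter, " iterations")

  structure(list(E = E_m, Q = Q_m, knotted = K_m, log_g = log_g,
                 f = f, temperatures = temperatures,
                 e_binwidth = h, q_binwidth = q_res,
                 iterations = iter, delta = delta),
            class = "wham_dos")
}

#' @export
print.wham_dos <- function(x, ...) {
  cat(sprintf(
    "WHAM density of states: %d occupied (E,Q,k) bins, %d temperatures\n",
    length(x$E), length(x$temperatures)))
  cat(sprintf("  converged to %.2g in %d iterations\n", x$delta,
              x$iterations))
  invisible(x)
}

#' Canonical thermodynamic curves from a density of states
#'
#' Internal energy `U(T)` and heat capacity
#' `CV(T) = (<E^2> - <E>^2) / T^2` (reduced units) as canonical averages
#' over the estimated density of states.
#'
#' @param dos a [wham_fit()] result.
#' @param T_grid temperatures at which to evaluate the curves.
#' @return A data.frame with columns `temperature`, `U`, `CV`.
#' @export
thermo_curves <- function(dos, T_grid) {
  out <- vapply(T_grid, function(Tv) {
    lw <- dos$log_g - dos$E / Tv
    z <- logsumexp(lw)
    p <- exp(lw - z)
    U <- sum(p * dos$E)
    E2 <- sum(p * dos$E^2)
    c(U, (E2 - U^2) / Tv^2)
  }, numeric(2))
  data.frame(temperature = T_grid, U = out[1, ], CV = out[2, ])
}

#' Melting temperature and cooperativity of a heat-capacity peak
#'
#' Tm is the temperature of maximal CV; the full width at half maximum is
#' obtained by linear interpolation of the two half-maximum crossings, and
#' the cooperativity measure is the FWHM/Tm ratio (around 4-5% for a
#' well-tuned two-state transition).
#'
#' @param T_grid temperatures (dense grid spanning the peak).
#' @param cv heat-capacity values on `T_grid` (or a [thermo_curves()]
#'   data.frame as the first argument, with `cv` missing).
#' @return List with `Tm`, `FWHM`, `ratio`.
#' @export
melting_and_width <- function(T_grid, cv) {
  if (missing(cv) && is.data.frame(T_grid)) {
    cv <- T_grid$CV; T_grid <- T_grid$temperature
  }
  i <- which.max(cv)
  if (i == 1 || i == length(cv))
    stop("CV peak at the grid boundary: temperature grid too narrow")
  tm <- T_grid[i]
  half <- cv[i] / 2
  cross <- function(idx) {
    # linear interpolation between the bracketing grid points
    j <- idx[1]; k <- idx[2]
    T_grid[j] + (half - cv[j]) * (T_grid[k] - T_grid[j]) / (cv[k] - cv[j])
  }
  lo_idx <- which(cv[seq_len(i)] < half)
  hi_idx <- which(cv[seq(i, length(cv))] < half)
  if (length(lo_idx) == 0 || length(hi_idx) == 0)
    stop("half-maximum crossing outside the temperature grid")
  jl <- max(lo_idx)
  t_lo <- cross(c(jl, jl + 1))
  jh <- i - 1 + min(hi_idx)
  t_hi <- cross(c(jh - 1, jh))
  list(Tm = tm, FWHM = t_hi - t_lo, ratio = (t_hi - t_lo) / tm)
}

#' Knotting probability profiles along temperature and Q
#'
#' `pk(T)` is the canonical average of the knot indicator at each
#' temperature; `pk(Q)` is the knotted fraction per Q bin of the density
#' reweighted to a reference temperature (default: the CV-peak temperature
#' on the supplied grid). Empty Q bins are reported as `NA`, not zero.
#'
#' @param dos a [wham_fit()] result carrying the knot axis.
#' @param T_grid temperatures for the `pk(T)` profile.
#' @param t_ref reference temperature for `pk(Q)`; default Tm.
#' @return List with data.frames `pk_T` (`temperature`, `pk`) and `pk_Q`
#'   (`Q`, `pk`), plus `t_ref`.
#' @export
knotting_profiles <- function(dos, T_grid, t_ref = NULL) {
  pk_T <- vapply(T_grid, function(Tv) {
    lw <- dos$log_g - dos$E / Tv
    z <- logsumexp(lw)
    sum(exp(lw - z) * dos$knotted)
  }, numeric(1))
  if (is.null(t_ref)) {
    cv <- thermo_curves(dos, T_grid)
    t_ref <- cv$temperature[which.max(cv$CV)]
  }
  lw <- dos$log_g - dos$E / t_ref
  w <- exp(lw - logsumexp(lw))
  qs <- sort(unique(dos$Q))
  pk_Q <- vapply(qs, function(q) {
    sel <- dos$Q == q
    tot <- sum(w[sel])
    if (tot <= 0) return(NA_real_)
    sum(w[sel] * dos$knotted[sel]) / tot
  }, numeric(1))
  list(pk_T = data.frame(temperature = T_grid, pk = pk_T),
       pk_Q = data.frame(Q = qs, pk = pk_Q),
       t_ref = t_ref)
}

#' Direct per-temperature estimates with block-bootstrap errors
#'
#' Sample-average estimates of U and CV at each ladder temperature, with
#' standard errors from a moving-block bootstrap over the (autocorrelated)
#' sample series.
#'
#' @param samples sample table of an [run_remc()] run (or the run).
#' @param n_blocks number of contiguous blocks per temperature series; the
#'   default `NULL` uses `min(50, n/10)` so that blocks hold at least ten
#'   samples — blocks must be long compared to the correlation time of the
#'   series for the bootstrap errors to be honest, and the fixed
#'   production-scale choice of 50 blocks makes blocks far too short when
#'   a desk-scale run has only a few hundred samples per temperature.
#' @param n_boot bootstrap resamples.
#' @param boot_seed RNG sub-seed for the bootstrap.
#' @return A data.frame: `temperature`, `U`, `U_se`, `CV`, `CV_se`, `n`.
#' @export
thermo_direct <- function(samples, n_blocks = NULL, n_boot = 200,
                          boot_seed = 1234) {
  if (inherits(samples, "remc_run")) samples <- samples$samples
  temps <- sort(unique(samples$temperature))
  if (is.null(n_blocks)) {
    n0 <- sum(samples$temperature == temps[1])
    n_blocks <- max(5, min(50, floor(n0 / 10)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(boot_seed)
  rows <- lapply(temps, function(Tv) {
    e <- samples$E[samples$temperature == Tv][order(
      samples$mcs[samples$temperature == Tv])]
    n <- length(e)
    U <- mean(e)
    CV <- (mean(e^2) - U^2) / Tv^2
    nb <- min(n_blocks, n)
    starts <- floor(seq(1, n + 1, length.out = nb + 1))
    blocks <- lapply(seq_len(nb), function(b) e[starts[b]:(starts[b + 1] - 1)])
    stat <- vapply(seq_len(n_boot), function(r) {
      eb <- unlist(blocks[sample.int(nb, nb, replace = TRUE)])
      m <- mean(eb)
      c(m, (mean(eb^2) - m^2) / Tv^2)
    }, numeric(2))
    data.frame(temperature = Tv, U = U, U_se = sd(stat[1, ]),
               CV = CV, CV_se = sd(stat[2, ]), n = n)
  })
  do.call(rbind, rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Equilibration cross-check over the four start/move-set combinations
#'
#' Thermal equilibrium at every ladder temperature implies that runs
#' started from the native and from a denatured conformation, with either
#' the LTyP or the non-LTyP move set, must coincide. The check passes when
#' the largest deviation in U and CV between any pair of runs, at any
#' ladder temperature, stays within `n_se` combined standard errors
#' (block bootstrap).
#'
#' @param runs a list of >= 2 `remc_run` objects (or sample tables) with
#'   identical temperature ladders.
#' @param n_se allowed deviation in combined standard errors (default 3).
#' @param ... passed to [thermo_direct()].
#' @return List with `pass`, `max_dev_U`, `max_dev_CV` (in SE units) and
#'   the per-run estimate table.
#' @export
check_equilibration <- function(runs, n_se = 3, ...) {
  est <- lapply(runs, thermo_direct, ...)
  ladders <- lapply(est, function(e) round(e$temperature, 12))
  if (!all(vapply(ladders, identical, logical(1), ladders[[1]])))
    stop("runs have mismatched temperature ladders")
  nT <- nrow(est[[1]])
  max_u <- 0; max_cv <- 0
  for (a in seq_along(est)) for (b in seq_along(est)) {
    if (b <= a) next
    # a floor on the combined SE keeps exact agreement (e.g. degenerate
    # zero-variance series) at deviation 0 instead of 0/0
    du <- abs(est[[a]]$U - est[[b]]$U) /
      pmax(sqrt(est[[a]]$U_se^2 + est[[b]]$U_se^2), 1e-12)
    dc <- abs(est[[a]]$CV - est[[b]]$CV) /
      pmax(sqrt(est[[a]]$CV_se^2 + est[[b]]$CV_se^2), 1e-12)
    max_u <- max(max_u, du)
    max_cv <- max(max_cv, dc)
  }
  list(pass = max_u <= n_se && max_cv <= n_se,
       max_dev_U = max_u, max_dev_CV = max_cv,
       estimates = est)
}
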