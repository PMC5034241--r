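#' Dissociation simulation parameters
#'
#' Reduced units throughout: the bead diameter sigma is the length unit, the
#' thermal energy epsilon = kT the energy unit, and tau_sim = sigma^2 gamma /
#' epsilon the time unit. The harmonic bond rest length is tied to
#' 1.5 sigma, the mean Calpha-Calpha spacing of the bead model, so mapping a
#' 3.8 Angstrom virtual bond onto 1.5 sigma gives sigma of about 2.5
#' Angstrom.
#'
#' @param sigma bead diameter (length unit; default 1).
#' @param epsilon energy unit, equal to kT (default 1).
#' @param spring_k harmonic bond stiffness in epsilon/sigma^2 (default 300,
#'   holding instantaneous bond lengths within 20% of rest at dt = 0.001).
#' @param gamma friction coefficient (default 1).
#' @param dt integration step in tau_sim (default 0.001; the WCA core makes
#'   the Euler-Maruyama step diverge for dt much beyond 0.005 at these
#'   parameters).
#' @param t_max total simulated time in tau_sim.
#' @param record_every steps between successive G' evaluations (the O(N^2)
#'   cost of G' dominates, so recording is throttled).
#' @param n_traj number of independent trajectories in the ensemble
#'   (default 100).
#' @param seed master seed; trajectory k uses seed + k - 1.
#' @return An object of class `sim_config`; `bond_rest` is always
#'   `1.5 * sigma`.
#' @export
sim_config <- function(sigma = 1, epsilon = 1, spring_k = 300, gamma = 1,
                       dt = 0.001, t_max = 1e4, record_every = 1000,
                       n_traj = 100, seed = 1) {
  stopifnot(sigma > 0, epsilon > 0, spring_k > 0, gamma > 0, dt > 0,
            record_every >= 1, n_traj >= 1)
  if (t_max <= 100 * record_every * dt)
    stop("t_max must exceed 100 recorded intervals, or no fit window remains")
  structure(list(sigma = sigma, epsilon = epsilon,
                 bond_rest = 1.5 * sigma, spring_k = spring_k,
                 gamma = gamma, dt = dt, t_max = t_max,
                 record_every = as.integer(record_every),
                 n_traj = as.integer(n_traj), seed = as.integer(seed)),
            class = "sim_config")
}

#' WCA excluded-volume potential and force
#'
#' Truncated-and-shifted Lennard-Jones potential cut at its minimum
#' \eqn{2^{1/6}\sigma}: \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} -
#' (\sigma/r)^6] + \epsilon} for \eqn{r < 2^{1/6}\sigma} and zero beyond —
#' purely repulsive, continuous at the cutoff. `wca_force` returns the force
#' on the first particle of a pair separated by `r_vec` (first minus second
#' position): repulsive, pointing along `+r_vec`.
#'
#' @param r distance (for the potential) in units of sigma's units.
#' @param r_vec 3D displacement vector between the two particles.
#' @param sigma bead diameter.
#' @param epsilon energy scale.
#' @return `wca_potential`: numeric energy. `wca_force`: 3D force vector.
#' @export
wca_potential <- function(r, sigma = 1, epsilon = 1) {
  stopifnot(all(r > 0))
  u <- 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6) + epsilon
  ifelse(r < 2^(1 / 6) * sigma, u, 0)
}

#' @rdname wca_potential
#' @export
wca_force <- function(r_vec, sigma = 1, epsilon = 1) {
  r_vec <- as.numeric(r_vec)
  stopifnot(length(r_vec) == 3L)
  r2 <- sum(r_vec^2)
  if (r2 == 0) stop("zero separation")
  rmin <- 0.05 * sigma
  clamped <- FALSE
  if (r2 < rmin^2) {
    r2 <- rmin^2
    clamped <- TRUE
    warning("overlapping beads: WCA force clamped at r = 0.05 sigma")
  }
  if (r2 >= 2^(1 / 3) * sigma^2) return(c(0, 0, 0))
  sr6 <- (sigma^2 / r2)^3
  fac <- 24 * epsilon * (2 * sr6^2 - sr6) / r2
  if (clamped) r_vec <- r_vec / sqrt(sum(r_vec^2)) * rmin
  fac * r_vec
}

#' Simulate dimer dissociation and record G'(t)
#'
#' Each chain becomes a bead-spring polymer: beads at the Calpha positions
#' (coordinates rescaled uniformly so the mean bond length equals
#' `bond_rest` = 1.5 sigma; G' is scale-free, so the starting value is
#' untouched), harmonic bonds between adjacent beads of a chain, and WCA
#' excluded volume between every other bead pair, inter- and intra-chain.
#' With no attractive interactions the crystal arrangement dissolves as in
#' unfolding at high temperature, and the mutual entanglement decays. The
#' overdamped Langevin equation is integrated with Gaussian noise satisfying
#' fluctuation-dissipation; G' over the two open chains is recorded every
#' `record_every` steps and averaged over `n_traj` independent trajectories
#' (seeds `seed`, `seed + 1`, ...).
#'
#' A trajectory whose coordinates blow up (non-finite) is dropped from the
#' ensemble and counted in `n_failed`.
#'
#' @param dimer a [dimer_structure].
#' @param config a [sim_config].
#' @param interactions set `FALSE` to switch off all forces (free diffusion;
#'   used for integrator checks).
#' @return An object of class `entanglement_trace`: `times`, `g_prime_mean`,
#'   `g_prime_sem`, the per-trajectory matrix `g_traj` (records x
#'   trajectories), `msd` (bead-averaged mean-square displacement, ensemble
#'   mean), `n_traj`, `n_failed`, `config`.
#' @export
run_unbinding <- function(dimer, config = sim_config(), interactions = TRUE) {
  stopifnot(inherits(dimer, "dimer_structure"), inherits(config, "sim_config"))
  if (dimer$rejected)
    warning("dimer ", dimer$pdb_id, " fails the gap filter")
  xa <- dimer$chain_a$coords
  xb <- dimer$chain_b$coords
  n1 <- nrow(xa)
  all_bonds <- c(bond_lengths(xa), bond_lengths(xb))
  scale <- config$bond_rest / mean(all_bonds)
  x0 <- rbind(xa, xb) * scale
  n_steps <- as.integer(round(config$t_max / config$dt))
  n_steps <- (n_steps %/% config$record_every) * config$record_every
  g_list <- vector("list", config$n_traj)
  msd_acc <- NULL
  times <- NULL
  final_coords <- NULL
  n_failed <- 0L
  for (k in seq_len(config$n_traj)) {
    tr <- cpp_run_trajectory(x0, n1, config$spring_k, config$bond_rest,
                             config$sigma, config$epsilon, config$gamma,
                             config$epsilon, # kT = epsilon
                             config$dt, n_steps, config$record_every,
                             config$seed + k - 1L, interactions)
    if (!tr$ok) {
      n_failed <- n_failed + 1L
      next
    }
    g_list[[k]] <- tr$g_prime
    times <- tr$times
    msd_acc <- if (is.null(msd_acc)) tr$msd else msd_acc + tr$msd
    if (is.null(final_coords)) final_coords <- tr$final_coords
  }
  g_list <- g_list[!vapply(g_list, is.null, logical(1))]
  if (!length(g_list))
    stop("all trajectories diverged; reduce dt or spring_k")
  if (n_failed > 0)
    warning(n_failed, " trajectories diverged and were excluded")
  g_traj <- do.call(cbind, g_list)
  structure(list(times = times,
                 g_prime_mean = rowMeans(g_traj),
                 g_prime_sem = apply(g_traj, 1, sd) / sqrt(ncol(g_traj)),
                 g_traj = g_traj,
                 msd = msd_acc / length(g_list),
                 final_coords = final_coords, n_beads_a = n1,
                 n_traj = ncol(g_traj), n_failed = n_failed,
                 config = config),
            class = "entanglement_trace")
}

#' @export
print.entanglement_trace <- function(x, ...) {
  cat(sprintf(
    "<entanglement_trace> %d records x %d trajectories, t in [0, %g]\n",
    length(x$times), x$n_traj, max(x$times)))
  cat(sprintf("  G'(0) = %.3f, G'(t_max) = %.3f +/- %.3f\n",
              x$g_prime_mean[1], x$g_prime_mean[length(x$times)],
              x$g_prime_sem[length(x$times)]))
  invisible(x)
}

#' Exponential fit of the entanglement decay
#'
#' Fits \eqn{G'(t) = G^* e^{-t/\tau}} to the ensemble-averaged trace by
#' nonlinear least squares, discarding the first `skip` recorded points so
#' the fit captures the long-time decay rather than the initial transient.
#' G* extrapolates the decay back to t = 0 and acts as a dynamical
#' entanglement estimate (it need not match the static G' of the crystal);
#' tau is the disentanglement timescale in tau_sim. Uncertainties come from
#' bootstrap resampling of whole trajectories.
#'
#' @param trace an `entanglement_trace`.
#' @param skip number of leading recorded points excluded from the fit
#'   (default 100).
#' @param n_boot bootstrap resamples over trajectories (default 200).
#' @return An object of class `decay_fit`: `g_star`, `tau`, `g_star_err`,
#'   `tau_err`, `fit_start_index`, `n_boot`.
#' @export
fit_decay <- function(trace, skip = 100, n_boot = 200) {
  stopifnot(inherits(trace, "entanglement_trace"))
  n <- length(trace$times)
  if (n <= skip + 10)
    stop("trace too short: need more than skip + 10 recorded points")
  idx <- (skip + 1L):n
  fit_one <- function(g) {
    t <- trace$times[idx]
    y <- g[idx]
    span <- t[length(t)] - t[1]
    a0 <- y[1]
    if (!is.finite(a0) || abs(a0) < 1e-6)
      a0 <- sign(mean(y) + 1e-300) * max(abs(y), 1e-3)
    # timescale starts: log-linear regression on the smoothed |y|, plus a
    # spread of fractions of the window in case the signal is noise-dominated
    tau_starts <- span * c(1 / 3, 1 / 10, 1, 1 / 30)
    w <- max(5L, length(y) %/% 50L)
    ys <- stats::filter(y, rep(1 / w, w), sides = 2)
    pos <- which(is.finite(ys) & abs(ys) > 1e-8)
    if (length(pos) > 10) {
      slope <- coef(stats::lm(log(abs(ys[pos])) ~ t[pos]))[2]
      if (is.finite(slope) && slope < 0)
        tau_starts <- c(-1 / slope, tau_starts)
    }
    for (tau0 in pmax(tau_starts, 1e-6)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-t / tau),
                          start = list(a = a0, tau = tau0),
                          lower = c(-Inf, 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) return(coef(fit))
    }
    stop("no starting point led to convergence")
  }
  est <- tryCatch(fit_one(trace$g_prime_mean), error = function(e)
    stop("decay fit did not converge: ", conditionMessage(e)))
  if (!is.finite(est["tau"]) || est["tau"] <= 0)
    stop("decay fit did not converge: non-positive timescale")
  if (abs(est["a"]) < 1e-8)
    stop("decay fit did not converge: amplitude indistinguishable from ",
         "zero, timescale unidentifiable")
  boots <- matrix(NA_real_, n_boot, 2)
  if (n_boot > 0) {
    nt <- ncol(trace$g_traj)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(nt, nt, replace = TRUE)
      gb <- rowMeans(trace$g_traj[, cols, drop = FALSE])
      boots[b, ] <- tryCatch(fit_one(gb), error = function(e) c(NA, NA))
    }
  }
  structure(list(g_star = unname(est["a"]), tau = unname(est["tau"]),
                 g_star_err = sd(boots[, 1], na.rm = TRUE),
                 tau_err = sd(boots[, 2], na.rm = TRUE),
                 fit_start_index = skip + 1L, n_boot = n_boot),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> G* = %.3f +/- %.3f, tau = %.1f +/- %.1f tau_sim\n",
              x$g_star, x$g_star_err, x$tau, x$tau_err))
  invisible(x)
}
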