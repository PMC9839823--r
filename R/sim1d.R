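#' Lagrangian state for the 1D solver
#'
#' Bundles the Lagrangian grid `X`, the concentration fields `u`, the local
#' dilation field `mu` and the current time. The Eulerian image of the grid
#' is the cumulative integral of `mu` (see [eulerian_positions()]); `mu` is
#' reset to one at every remesh.
#'
#' @param X strictly increasing numeric grid on `[0, L]`.
#' @param u numeric matrix (`length(X)` rows, `m` columns) or a vector for
#'   `m = 1`.
#' @param mu positive numeric vector of local dilation factors, same length
#'   as `X` (default all ones).
#' @param t current time.
#' @return an object of class `lagrangian_state_1d`.
#' @export
lagrangian_state_1d <- function(X, u, mu = rep(1, length(X)), t = 0) {
  X <- as.numeric(X)
  if (length(X) < 3) stop("need at least 3 grid nodes")
  if (any(diff(X) <= 0)) stop("X must be strictly increasing")
  u <- if (is.matrix(u)) u else matrix(as.numeric(u), ncol = 1)
  if (nrow(u) != length(X)) stop("u must have one row per grid node")
  mu <- as.numeric(mu)
  if (length(mu) != length(X)) stop("mu must match the grid")
  if (any(mu <= 0)) stop("mu must be positive everywhere")
  structure(list(X = X, u = u, mu = mu, t = t),
            class = "lagrangian_state_1d")
}

#' @export
print.lagrangian_state_1d <- function(x, ...) {
  cat("<lagrangian_state_1d> t = ", signif(x$t, 6),
      ", N = ", length(x$X),
      ", m = ", ncol(x$u),
      ", L(t) = ", signif(domain_length(x), 6), "\n", sep = "")
  invisible(x)
}

#' Eulerian node positions
#'
#' Maps the Lagrangian grid to Eulerian positions by cumulative trapezoidal
#' integration of `mu`, anchored at `x(t, 0) = 0`.
#'
#' @param state a [lagrangian_state_1d()].
#' @return numeric vector of strictly increasing positions with `x[1] = 0`.
#' @export
eulerian_positions <- function(state) {
  stopifnot(inherits(state, "lagrangian_state_1d"))
  if (any(state$mu <= 0)) stop("mu <= 0: Eulerian map degenerate")
  dX <- diff(state$X)
  x <- c(0, cumsum(dX * (state$mu[-length(state$mu)] + state$mu[-1]) / 2))
  if (any(diff(x) <= 0)) stop("Eulerian map not strictly increasing")
  x
}

#' Current domain length
#' @param state a [lagrangian_state_1d()].
#' @return `x(t, L_ref) - x(t, 0)`.
#' @export
domain_length <- function(state) {
  x <- eulerian_positions(state)
  x[length(x)] - x[1]
}

#' Metric-weighted diffusion stencil
#'
#' Discretizes `(1/mu) d/dX ((1/mu) du/dX)` on a uniform Lagrangian grid:
#' the three-point stencil
#' `(1/(2 mu_i)) [ (1/mu_i)(u_{i+1}+u_{i-1}-2u_i) + (1/mu_{i+1})(u_{i+1}-u_i)
#' + (1/mu_{i-1})(u_{i-1}-u_i) ]` divided by `dX^2`, with Neumann boundaries
#' imposed by ghost-node reflection (`u_{-1} = u_1`, `mu_{-1} = mu_1`).
#' The stencil is in flux form, so the semi-discrete system conserves the
#' trapezoidal mass `sum(w u mu) dX` exactly when the kinetics vanish.
#'
#' @param state a [lagrangian_state_1d()] on a uniform grid.
#' @param species column index of the species to difference.
#' @return numeric vector, the discrete diffusion operator applied to the
#'   species field (without the diffusivity factor).
#' @export
discretize_diffusion <- function(state, species = 1) {
  stopifnot(inherits(state, "lagrangian_state_1d"))
  N <- length(state$X)
  if (N < 3) stop("need at least 3 grid nodes")
  dX <- diff(state$X)
  if (max(abs(dX - dX[1])) > 1e-10 * dX[1])
    stop("grid must be uniform within an epoch; remesh first")
  u <- state$u[, species]
  mu <- state$mu
  im <- c(2, seq_len(N - 1))        # ghost reflection at the left
  ip <- c(seq(2, N), N - 1)         # and right boundary
  up <- u[ip]; um <- u[im]; mup <- mu[ip]; mum <- mu[im]
  (1 / (2 * mu)) * ((up + um - 2 * u) / mu + (up - u) / mup +
                      (um - u) / mum) / dX[1]^2
}

#' Right-hand side of the closed 1D Lagrangian system
#'
#' Evaluates `du/dt = (D/mu) d/dX((1/mu) du/dX) - u S(t,u) + f(u)` and
#' `dmu/dt = mu S(t,u)` pointwise on the grid. This is the reference R
#' implementation; the adaptive integrator uses an equivalent compiled one
#' (the two are cross-checked in the test suite).
#'
#' @param t time.
#' @param state a [lagrangian_state_1d()].
#' @param spec a [kinetics_spec()].
#' @param law a [growth_law()].
#' @param D numeric vector of diffusivities, one per species.
#' @return list with `du` (matrix) and `dmu` (vector).
#' @export
rhs_1d <- function(t, state, spec, law, D) {
  stopifnot(inherits(state, "lagrangian_state_1d"),
            inherits(spec, "kinetics_spec"), inherits(law, "growth_law"))
  m <- ncol(state$u)
  if (m != spec$n_species) stop("state has ", m, " species, kinetics ",
                                spec$n_species)
  if (length(D) != m) stop("need one diffusivity per species")
  N <- length(state$X)
  S <- vapply(seq_len(N), function(i) evaluate_growth(law, t, state$u[i, ]),
              numeric(1))
  f <- t(vapply(seq_len(N), function(i) {
    fr <- evaluate_kinetics(spec, state$u[i, ])
    if (length(fr) == 1) c(fr, numeric(0)) else fr
  }, numeric(m)))
  f <- matrix(f, nrow = N)
  du <- matrix(0, N, m)
  for (s in seq_len(m))
    du[, s] <- D[s] * discretize_diffusion(state, s) - state$u[, s] * S +
      f[, s]
  dmu <- state$mu * S
  if (any(!is.finite(du)) || any(!is.finite(dmu)))
    stop("rhs_1d: non-finite derivative at t = ", t)
  list(du = du, dmu = dmu)
}

# map R-side specs to the compiled integrator's codes/parameters
kinetics_codes <- function(spec) {
  p <- spec$params
  switch(spec$name,
    schnakenberg = list(code = 1L, par = c(p$a, p$b), fn = NULL),
    gierer_meinhardt = list(code = 2L, par = c(p$a, p$b, p$c), fn = NULL),
    fitzhugh_nagumo = list(code = 3L, par = c(p$a, p$b, p$c, p$i0), fn = NULL),
    logistic = list(code = 4L, par = numeric(), fn = NULL),
    bistable = list(code = 5L, par = numeric(), fn = NULL),
    custom = {
      m <- spec$n_species
      fn <- if (isTRUE(spec$vectorized)) {
        function(t, U) {
          out <- spec$f(U)
          matrix(out, nrow = m)
        }
      } else {
        function(t, U) {
          out <- vapply(seq_len(ncol(U)), function(i) spec$f(U[, i]),
                        numeric(m))
          matrix(out, nrow = m)
        }
      }
      list(code = 0L, par = numeric(), fn = fn)
    })
}

growth_codes <- function(law) {
  p <- law$params
  switch(law$form,
    constant = list(code = 1L, par = c(p$s0), fn = NULL),
    prescribed_time = list(code = 2L, par = numeric(),
                           fn = function(t, U) rep(law$fn(t), ncol(U))),
    linear = list(code = 3L, par = c(p$s0, p$sigma), fn = NULL),
    thresholded_tanh = list(code = 4L, par = c(p$s0, p$u_th, p$k_th),
                            fn = NULL),
    quadratic_ratio = list(code = 5L, par = c(p$s0, p$u_ref), fn = NULL),
    difference = list(code = 6L, par = c(p$r, p$alpha), fn = NULL),
    custom = {
      fn <- if (isTRUE(law$vectorized)) {
        function(t, U) as.numeric(law$fn(t, U))
      } else {
        function(t, U) vapply(seq_len(ncol(U)),
                              function(i) evaluate_growth(law, t, U[, i]),
                              numeric(1))
      }
      list(code = 0L, par = numeric(), fn = fn)
    })
}

pack_state <- function(state) as.numeric(t(cbind(state$u, state$mu)))

unpack_state <- function(y, X, m, t) {
  M <- matrix(y, nrow = m + 1)
  lagrangian_state_1d(X, t(M[seq_len(m), , drop = FALSE]), M[m + 1, ], t)
}

#' Advance one epoch with the stiff integrator
#'
#' Integrates the semi-discrete 1D system from `state$t` to `until` with an
#' adaptive L-stable SDIRK method (banded Jacobian, per-step error control).
#' Default tolerances are `rtol = atol = 1e-11`.
#'
#' @inheritParams rhs_1d
#' @param until target time (`> state$t`).
#' @param tolerances list with elements `rtol`, `atol`.
#' @param hmax optional maximum step size.
#' @param stats if `TRUE`, attach integrator statistics as an attribute.
#' @return the advanced [lagrangian_state_1d()].
#' @export
advance_epoch <- function(state, spec, law, D, until,
                          tolerances = list(rtol = 1e-11, atol = 1e-11),
                          hmax = 0, stats = FALSE) {
  stopifnot(inherits(state, "lagrangian_state_1d"))
  if (until <= state$t) stop("'until' must exceed the current time")
  dX <- diff(state$X)
  if (max(abs(dX - dX[1])) > 1e-10 * dX[1])
    stop("grid must be uniform within an epoch; remesh first")
  kc <- kinetics_codes(spec)
  gc <- growth_codes(law)
  res <- rd1d_integrate_cpp(pack_state(state), state$t, until,
                            spec$n_species, dX[1], as.numeric(D),
                            kc$code, kc$par, gc$code, gc$par,
                            kc$fn, gc$fn,
                            tolerances$rtol, tolerances$atol,
                            0, hmax, 20000000L)
  out <- unpack_state(res$y, state$X, spec$n_species, res$t)
  if (stats)
    attr(out, "stats") <- res[c("nsteps", "nreject", "nfeval", "njac")]
  out
}

#' Epoch / remeshing schedule
#'
#' @param epoch_length fixed remesh interval in time units (`Inf` to rely
#'   on the trigger only).
#' @param trigger_ratio remesh as soon as `max(mu)/min(mu)` exceeds this
#'   (default 2; must be `> 1`).
#' @param interpolation `"pchip"` (monotone cubic, default), `"cubic"`, or
#'   `"linear"` for the field transfer at remesh.
#' @return an object of class `epoch_schedule`.
#' @export
epoch_schedule <- function(epoch_length = Inf, trigger_ratio = 2,
                           interpolation = c("pchip", "cubic", "linear")) {
  if (epoch_length <= 0) stop("epoch_length must be positive")
  if (trigger_ratio <= 1) stop("trigger_ratio must exceed 1")
  structure(list(epoch_length = epoch_length, trigger_ratio = trigger_ratio,
                 interpolation = match.arg(interpolation)),
            class = "epoch_schedule")
}

#' Remesh: adopt the Eulerian domain as the new Lagrangian reference
#'
#' The current Eulerian image `[0, L(t)]` becomes the new uniformly spaced
#' computational grid, `mu` is reset to one, and the concentration fields
#' are interpolated onto the new grid (monotone piecewise cubic by
#' default). Domain length is preserved exactly.
#'
#' @param state a [lagrangian_state_1d()].
#' @param schedule an [epoch_schedule()] (only the interpolation choice is
#'   used here).
#' @return the remeshed [lagrangian_state_1d()].
#' @export
remesh <- function(state, schedule = epoch_schedule()) {
  stopifnot(inherits(state, "lagrangian_state_1d"))
  x <- eulerian_positions(state)           # aborts if non-monotone
  N <- length(x)
  L <- x[N]
  Xnew <- seq(0, L, length.out = N)
  m <- ncol(state$u)
  unew <- matrix(0, N, m)
  for (s in seq_len(m)) {
    unew[, s] <- switch(schedule$interpolation,
      pchip = stats::splinefun(x, state$u[, s], method = "monoH.FC")(Xnew),
      cubic = stats::splinefun(x, state$u[, s], method = "natural")(Xnew),
      linear = stats::approx(x, state$u[, s], xout = Xnew)$y)
  }
  # endpoints are shared, so interpolation cannot move them
  unew[1, ] <- state$u[1, ]
  unew[N, ] <- state$u[N, ]
  lagrangian_state_1d(Xnew, unew, rep(1, N), state$t)
}

#' Initial-condition specifications for the 1D solver
#'
#' * `noisy_equilibrium`: `u(0, x) = u* (1 + eta(x))` per species, with
#'   `eta` i.i.d. normal, zero mean, variance `noise_variance` (default
#'   `1e-2`), drawn from a counter-based generator keyed by `(seed, species,
#'   node index)` so runs are bit-reproducible and the per-node law does not
#'   depend on resolution.
#' * `tanh_front`: `u(0, x) = (1 + tanh(L/5 - x))/2` (scalar kinetics).
#' * `custom`: `fn(x)` returning a matrix of concentrations.
#'
#' @param mode one of `"noisy_equilibrium"`, `"tanh_front"`, `"custom"`.
#' @param noise_variance nonnegative noise variance.
#' @param seed integer seed (mandatory for `noisy_equilibrium`).
#' @param fn function of the position vector for `custom`.
#' @return an object of class `ic_spec`.
#' @export
ic_spec <- function(mode = c("noisy_equilibrium", "tanh_front", "custom"),
                    noise_variance = 1e-2, seed = NULL, fn = NULL) {
  mode <- match.arg(mode)
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  if (mode == "noisy_equilibrium" && is.null(seed))
    stop("noisy_equilibrium initial conditions require a seed")
  if (mode == "custom" && !is.function(fn))
    stop("custom initial conditions require fn(x)")
  structure(list(mode = mode, noise_variance = noise_variance,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 fn = fn),
            class = "ic_spec")
}

#' Build the initial Lagrangian state
#'
#' @param spec a [kinetics_spec()].
#' @param L initial domain length.
#' @param N_s number of equispaced grid nodes.
#' @param ic an [ic_spec()].
#' @param equilibrium optionally, the equilibrium to perturb (defaults to
#'   the first one returned by [find_equilibria()]).
#' @return a [lagrangian_state_1d()] at `t = 0` with `mu == 1`.
#' @export
initial_state_1d <- function(spec, L, N_s, ic, equilibrium = NULL) {
  stopifnot(inherits(ic, "ic_spec"), N_s >= 3, L > 0)
  X <- seq(0, L, length.out = N_s)
  m <- spec$n_species
  u <- switch(ic$mode,
    noisy_equilibrium = {
      ustar <- if (!is.null(equilibrium)) equilibrium
               else find_equilibria(spec)[[1]]$u_star
      out <- matrix(0, N_s, m)
      for (s in seq_len(m)) {
        eta <- sqrt(ic$noise_variance) *
          counter_normals_cpp(ic$seed, s, N_s)
        out[, s] <- ustar[s] * (1 + eta)
      }
      out
    },
    tanh_front = matrix((1 + tanh(L / 5 - X)) / 2, ncol = 1)[, rep(1, m),
                                                             drop = FALSE],
    custom = {
      out <- ic$fn(X)
      if (is.null(dim(out))) out <- matrix(out, ncol = m)
      out
    })
  lagrangian_state_1d(X, u, rep(1, N_s), 0)
}

#' Run a full 1D simulation
#'
#' Drives the epoch loop: integrate with [advance_epoch()], remesh with
#' [remesh()] whenever the fixed epoch length elapses or the mesh-quality
#' trigger `max(mu)/min(mu) > trigger_ratio` fires, record snapshots and the
#' domain-length series, and stop at the final time or when an optional
#' target length is reached.
#'
#' @param config a list (or `simulation_config`) with fields `kinetics`,
#'   `growth`, `D`, `L`, `N_s`, `ic`, `t_final`, and optionally
#'   `target_length`, `epoch` ([epoch_schedule()]), `snapshot_times`,
#'   `tolerances`, `hmax`, `n_length_samples`.
#' @return an object of class `sim_result_1d` with fields `times`,
#'   `snapshots` (each `(t, X, x, u, mu)`), `L` (data.frame `t`, `L`),
#'   `config`, and `seed`.
#' @export
run_simulation_1d <- function(config) {
  cfg <- config
  for (f in c("kinetics", "growth", "D", "L", "N_s", "ic", "t_final"))
    if (is.null(cfg[[f]])) stop("config is missing field '", f, "'")
  epoch <- cfg$epoch %||% epoch_schedule()
  tol <- cfg$tolerances %||% list(rtol = 1e-11, atol = 1e-11)
  hmax <- cfg$hmax %||% 0
  nls <- cfg$n_length_samples %||% 200L
  snaps_req <- sort(unique(c(cfg$snapshot_times %||% numeric(), cfg$t_final)))
  snaps_req <- snaps_req[snaps_req > 0 & snaps_req <= cfg$t_final]
  lsample <- seq(0, cfg$t_final, length.out = nls + 1)[-1]
  epochs <- if (is.finite(epoch$epoch_length))
    seq(epoch$epoch_length, cfg$t_final, by = epoch$epoch_length)
  else numeric()
  events <- sort(unique(c(snaps_req, lsample, epochs, cfg$t_final)))

  state <- initial_state_1d(cfg$kinetics, cfg$L, cfg$N_s, cfg$ic,
                            cfg$equilibrium %||% NULL)
  snapshots <- list()
  take_snap <- function(st) list(t = st$t, X = st$X,
                                 x = eulerian_positions(st),
                                 u = st$u, mu = st$mu)
  snapshots[[1]] <- take_snap(state)
  Lt <- data.frame(t = 0, L = domain_length(state))

  for (te in events) {
    state <- advance_epoch(state, cfg$kinetics, cfg$growth, cfg$D, te,
                           tolerances = tol, hmax = hmax)
    Lnow <- domain_length(state)
    Lt <- rbind(Lt, data.frame(t = state$t, L = Lnow))
    if (any(abs(snaps_req - te) < 1e-9))
      snapshots[[length(snapshots) + 1]] <- take_snap(state)
    hit_target <- !is.null(cfg$target_length) && Lnow >= cfg$target_length
    if (hit_target) {
      if (!any(abs(snaps_req - te) < 1e-9))
        snapshots[[length(snapshots) + 1]] <- take_snap(state)
      break
    }
    ratio <- max(state$mu) / min(state$mu)
    if (te %in% epochs || ratio > epoch$trigger_ratio)
      state <- remesh(state, epoch)
  }

  structure(list(times = vapply(snapshots, `[[`, numeric(1), "t"),
                 snapshots = snapshots, L = Lt, config = cfg,
                 seed = cfg$ic$seed, final_state = state),
            class = "sim_result_1d")
}

#' @export
print.sim_result_1d <- function(x, ...) {
  cat("<sim_result_1d> ", length(x$snapshots), " snapshots, t in [0, ",
      signif(max(x$L$t), 6), "], L: ", signif(x$L$L[1], 6), " -> ",
      signif(x$L$L[nrow(x$L)], 6), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count pattern peaks in a 1D profile
#'
#' Local maxima whose topographic prominence exceeds `prominence` times the
#' field range. Boundary nodes are excluded by default (a half-peak pinned
#' at a Neumann boundary); set `include_boundary = TRUE` to count them.
#'
#' @param profile numeric field sampled on the grid.
#' @param prominence relative prominence threshold in (0, 1); default 0.1.
#' @param include_boundary count boundary maxima as peaks.
#' @return integer peak count (0 for a constant field).
#' @export
count_peaks <- function(profile, prominence = 0.1,
                        include_boundary = FALSE) {
  u <- as.numeric(profile)
  n <- length(u)
  if (n < 3) stop("profile must have length >= 3")
  rng <- diff(range(u))
  if (rng == 0) return(0L)
  thresh <- prominence * rng
  # candidate maxima (plateau-aware: first node of a plateau)
  cand <- integer()
  i <- 2
  while (i <= n - 1) {
    if (u[i] > u[i - 1]) {
      j <- i
      while (j < n && u[j + 1] == u[j]) j <- j + 1
      if (j <= n - 1 && u[j + 1] < u[j]) cand <- c(cand, i)
      i <- j + 1
    } else i <- i + 1
  }
  if (include_boundary) {
    if (u[1] > u[2]) cand <- c(1L, cand)
    if (u[n] > u[n - 1]) cand <- c(cand, n)
  }
  count <- 0L
  for (p in cand) {
    h <- u[p]
    # lowest point until higher terrain (or the end) on each side
    left_min <- if (p == 1) -Inf else h
    k <- p
    while (k > 1) {
      k <- k - 1
      if (u[k] > h) break
      left_min <- min(left_min, u[k])
    }
    right_min <- if (p == n) -Inf else h
    k <- p
    while (k < n) {
      k <- k + 1
      if (u[k] > h) break
      right_min <- min(right_min, u[k])
    }
    if (h - max(left_min, right_min) >= thresh) count <- count + 1L
  }
  count
}

#' Classify the long-time behaviour of the domain length
#'
#' Operational classification of an `L(t)` series: the trend is the least
#' squares slope of `log L` over the final window (thresholds `+-slope_tol`
#' per unit time); when the trend is flat, oscillation is declared if the
#' residual about the windowed trend has relative amplitude above
#' `amp_tol` (a clear trend wins over transient wiggles). The same
#' classification is computed on the penultimate window; if the two windows
#' disagree the result is `"undetermined"`.
#'
#' @param t,L numeric time and length series (same length).
#' @param window window width in time units; the series must span at least
#'   two windows.
#' @param slope_tol trend threshold on `d log L / dt` (default `1e-4`).
#' @param amp_tol relative oscillation amplitude threshold (default 0.01).
#' @return one of `"growing"`, `"shrinking"`, `"fixed"`, `"oscillating"`,
#'   `"undetermined"`.
#' @export
classify_long_time_behaviour <- function(t, L, window,
                                         slope_tol = 1e-4,
                                         amp_tol = 0.01) {
  stopifnot(length(t) == length(L), all(L > 0))
  tmax <- max(t)
  if (tmax - min(t) < 2 * window)
    stop("series must span at least two windows")
  classify_window <- function(lo, hi) {
    sel <- t >= lo & t <= hi
    if (sum(sel) < 4) stop("too few samples in window [", lo, ", ", hi, "]")
    tw <- t[sel]; lw <- log(L[sel])
    fit <- stats::lm.fit(cbind(1, tw), lw)
    slope <- fit$coefficients[2]
    amp <- (max(fit$residuals) - min(fit$residuals)) / 2
    # a clear trend wins; sustained oscillation is the terminal class only
    # about a flat trend (transient wiggles on growth stay "growing")
    if (slope > slope_tol) "growing"
    else if (slope < -slope_tol) "shrinking"
    else if (amp > amp_tol) "oscillating"
    else "fixed"
  }
  c1 <- classify_window(tmax - window, tmax)
  c2 <- classify_window(tmax - 2 * window, tmax - window)
  if (identical(c1, c2)) c1 else "undetermined"
}
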