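#' Integrate the spatially homogeneous base state
#'
#' The base state about which stability is assessed evolves as
#' `du*/dt = -S(t, u*) u* + f(u*)` with `u*(0)` a homogeneous equilibrium
#' (`f(u*(0)) = 0`), and `mu*(t) = exp( integral of S(s, u*(s)) ds )` with
#' `mu*(0) = 1`. `u*` is integrated autonomously (it does not involve
#' `mu*`); `mu*` then follows by trapezoidal quadrature of `S` along the
#' stored trajectory.
#'
#' @param spec a [kinetics_spec()] (any `m`).
#' @param law a [growth_law()].
#' @param t_span length-2 numeric `c(t0 = 0, t1)`.
#' @param which_equilibrium index into [find_equilibria()] (default 1), or
#'   a numeric vector giving `u*(0)` directly.
#' @param n_grid number of stored grid times (default 801; the grid is also
#'   the finite-difference grid for Theorem-1 derivatives).
#' @param rtol,atol integration tolerances (default `1e-10`).
#' @return an object of class `base_state` with fields `t`, `u_star`
#'   (matrix, one row per time), `S` (vector), `mu_star` (vector), `spec`,
#'   `law`.
#' @export
integrate_base_state <- function(spec, law, t_span, which_equilibrium = 1,
                                 n_grid = 801, rtol = 1e-10, atol = 1e-12) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1], t_span[1] == 0)
  u0 <- if (is.numeric(which_equilibrium) && length(which_equilibrium) ==
            spec$n_species && spec$n_species > 1)
    which_equilibrium
  else if (length(which_equilibrium) == 1 && which_equilibrium ==
           round(which_equilibrium) && which_equilibrium >= 1)
    find_equilibria(spec)[[which_equilibrium]]$u_star
  else as.numeric(which_equilibrium)
  if (max(abs(evaluate_kinetics(spec, u0))) > 1e-8)
    stop("u*(0) is not an equilibrium of the kinetics")
  tg <- seq(t_span[1], t_span[2], length.out = n_grid)
  rhs <- function(t, y) -evaluate_growth(law, t, y) * y +
    evaluate_kinetics(spec, y)
  traj <- ode_dp45(rhs, u0, tg, rtol = rtol, atol = atol)
  if (any(!is.finite(traj)))
    stop("base state blew up before t = ", t_span[2])
  Ss <- vapply(seq_along(tg),
               function(i) evaluate_growth(law, tg[i], traj[i, ]),
               numeric(1))
  # composite Simpson per interval, midpoints from the u* spline
  m <- ncol(traj)
  ufun <- lapply(seq_len(m), function(s)
    stats::splinefun(tg, traj[, s], method = "natural"))
  tm <- (tg[-1] + tg[-n_grid]) / 2
  Smid <- vapply(seq_along(tm), function(i)
    evaluate_growth(law, tm[i],
                    vapply(ufun, function(f) f(tm[i]), numeric(1))),
    numeric(1))
  dt <- diff(tg)
  logmu <- c(0, cumsum(dt / 6 * (Ss[-n_grid] + 4 * Smid + Ss[-1])))
  out <- structure(list(t = tg, u_star = traj, S = Ss,
                        mu_star = exp(logmu), spec = spec, law = law),
                   class = "base_state")
  out$interp <- build_base_interp(out)
  out
}

#' @export
print.base_state <- function(x, ...) {
  n <- length(x$t)
  cat("<base_state> t in [0, ", signif(x$t[n], 6), "], u*(0) = (",
      paste(signif(x$u_star[1, ], 6), collapse = ", "),
      "), mu*(end) = ", signif(x$mu_star[n], 6), "\n", sep = "")
  invisible(x)
}

# spline interpolators over the base-state grid (cached on the object)
build_base_interp <- function(base) {
  m <- ncol(base$u_star)
  ufun <- lapply(seq_len(m), function(s)
    stats::splinefun(base$t, base$u_star[, s], method = "natural"))
  mufun <- stats::splinefun(base$t, base$mu_star, method = "natural")
  list(u = function(t) vapply(ufun, function(f) f(t), numeric(1)),
       mu = mufun)
}

base_state_interp <- function(base) {
  base$interp %||% build_base_interp(base)
}

#' Linearization matrices about the base state
#'
#' Assembles, at time `t`, the kinetics Jacobian `J`, the
#' concentration-dependence matrix `K` with
#' `K[i, j] = dS/du_j(t, u*) * u*_i` (a rank-one outer product), the growth
#' gradient, and the linearized kinetics `M = J - K - S(t, u*) I`.
#'
#' @param spec,law as in [integrate_base_state()].
#' @param base a `base_state`.
#' @param t time within the base-state span.
#' @return a list of class `linearization_matrices` with fields `J`, `K`,
#'   `gradS`, `S`, `M`, `mu_star`, `t`.
#' @export
linearization_matrices <- function(spec, law, base, t) {
  stopifnot(inherits(base, "base_state"))
  if (t < base$t[1] - 1e-12 || t > base$t[length(base$t)] + 1e-12)
    stop("t outside the base-state span")
  itp <- base_state_interp(base)
  ustar <- itp$u(t)
  J <- kinetics_jacobian(spec, ustar)
  gradS <- growth_gradient(law, t, ustar)
  K <- outer(ustar, gradS)
  S <- evaluate_growth(law, t, ustar)
  m <- length(ustar)
  structure(list(J = J, K = K, gradS = gradS, S = S,
                 M = J - K - S * diag(m), mu_star = itp$mu(t), t = t),
            class = "linearization_matrices")
}

#' Spatial mode specification on the initial interval
#'
#' Mode `k` has Lagrangian eigenfunction `cos(k pi X / L)` and eigenvalue
#' `rho_k = (k pi / L)^2` of the (negated) Laplacian on `[0, L]` with
#' Neumann conditions.
#'
#' @param k nonnegative integer mode index.
#' @param L initial interval length.
#' @return list of class `mode_spec` with `k`, `L`, `rho_k`.
#' @export
mode_spec <- function(k, L) {
  stopifnot(k >= 0, k == round(k), L > 0)
  structure(list(k = as.integer(k), L = L, rho_k = (k * pi / L)^2),
            class = "mode_spec")
}

# the two bracketed quantities whose time derivative enters the criterion;
# returns NA for a branch whose off-diagonal denominator is (near) zero
theorem1_brackets <- function(spec, law, base, D, rho, t, diag_tol) {
  lm <- linearization_matrices(spec, law, base, t)
  M <- lm$M; mu2 <- lm$mu_star^2
  b1 <- if (abs(M[1, 2]) > diag_tol)
    (M[1, 1] - D[1] * rho / mu2) / M[1, 2] else NA_real_
  b2 <- if (abs(M[2, 1]) > diag_tol)
    (M[2, 2] - D[2] * rho / mu2) / M[2, 1] else NA_real_
  c(b1, b2)
}

#' Instability flag for one mode at one time
#'
#' Evaluates the differential criterion for exponential growth of mode `k`
#' about the evolving base state: with `M(t) = J - K - S I` and
#' `rho_t = rho_k / mu*(t)^2`, the mode grows exponentially at `t` if
#'
#' `det M - (D2 M11 + D1 M22) rho_t + D1 D2 rho_t^2 <
#'   max{ M12 d/dt[(M11 - D1 rho_t)/M12], M21 d/dt[(M22 - D2 rho_t)/M21] }`
#'
#' (The printed source of this criterion pairs the diffusivities with the
#' opposite diagonal entries on the left side; that pairing contradicts the
#' bracketed right-hand terms and the constant-coefficient dispersion
#' relation, so the standard pairing is used; see the methods vignette.)
#' The criterion requires `M` off-diagonal entries to be nonzero; when both
#' are below `diag_tol` the result is `NA` ("criterion inapplicable"), and
#' a branch with a vanishing denominator is dropped with a note in the
#' `"dropped_branch"` attribute.
#'
#' @param spec,law,base as in [linearization_matrices()].
#' @param D length-2 diffusivities.
#' @param mode a [mode_spec()].
#' @param t evaluation time.
#' @param deriv_step centered-difference half-step for the right-hand-side
#'   time derivatives (default `1e-3`).
#' @param diag_tol threshold below which an off-diagonal entry of `M`
#'   counts as zero (default `1e-12`).
#' @return `TRUE`, `FALSE`, or `NA` (criterion inapplicable).
#' @export
theorem1_flag <- function(spec, law, base, D, mode, t,
                          deriv_step = 1e-3, diag_tol = 1e-12) {
  stopifnot(inherits(mode, "mode_spec"), length(D) == 2,
            spec$n_species == 2)
  lm <- linearization_matrices(spec, law, base, t)
  M <- lm$M
  if (abs(M[1, 2]) < diag_tol && abs(M[2, 1]) < diag_tol)
    return(NA)
  rho <- mode$rho_k
  mu2 <- lm$mu_star^2
  lhs <- det(M) - (D[2] * M[1, 1] + D[1] * M[2, 2]) * rho / mu2 +
    D[1] * D[2] * rho^2 / mu2^2
  # centered differences of the brackets, clamped to the base-state span
  tmax <- base$t[length(base$t)]
  h <- min(deriv_step, t - base$t[1], tmax - t)
  if (h <= 0) h <- min(deriv_step, tmax - base$t[1]) / 2
  tm <- max(base$t[1], t - h); tp <- min(tmax, t + h)
  bp <- theorem1_brackets(spec, law, base, D, rho, tp, diag_tol)
  bm <- theorem1_brackets(spec, law, base, D, rho, tm, diag_tol)
  db <- (bp - bm) / (tp - tm)
  terms <- c(if (abs(M[1, 2]) > diag_tol) M[1, 2] * db[1] else NA_real_,
             if (abs(M[2, 1]) > diag_tol) M[2, 1] * db[2] else NA_real_)
  dropped <- which(is.na(terms))
  if (all(is.na(terms))) return(NA)
  out <- lhs < max(terms, na.rm = TRUE)
  if (length(dropped)) attr(out, "dropped_branch") <- dropped
  out
}

#' Constant-coefficient dispersion band
#'
#' For the frozen linearization at time `t`, the band of spatial
#' eigenvalues `rho` for which `det(M - rho/mu*^2 D) < 0` (one positive
#' growth rate when `tr < 0`): the real roots of the quadratic
#' `D1 D2 (rho/mu*^2)^2 - (D2 M11 + D1 M22)(rho/mu*^2) + det M`.
#'
#' @inheritParams theorem1_flag
#' @param t evaluation time (default 0).
#' @return numeric vector of 0 or 2 band endpoints in `rho` (ascending).
#' @export
turing_band <- function(spec, law, base, D, t = 0) {
  lm <- linearization_matrices(spec, law, base, t)
  M <- lm$M; mu2 <- lm$mu_star^2
  a <- D[1] * D[2]
  b <- -(D[2] * M[1, 1] + D[1] * M[2, 2])
  cc <- det(M)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(numeric())
  r <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  r * mu2
}

#' Per-mode instability intervals over time
#'
#' Applies [theorem1_flag()] to modes `k = 0, ..., k_max` on a time grid
#' and assembles, for each mode, the maximal intervals of consecutive
#' flagged grid times.
#'
#' @inheritParams theorem1_flag
#' @param L initial interval length.
#' @param k_max largest mode index.
#' @param t_grid evaluation times (within the base-state span).
#' @param ... passed to [theorem1_flag()].
#' @return object of class `mode_stability_report`: list with `k`, `rho_k`,
#'   `t_grid`, `flags` (logical matrix, modes x times, `NA` where
#'   inapplicable) and `intervals` (list of 2-column matrices
#'   `t_start`, `t_end`).
#' @export
unstable_modes <- function(spec, law, base, D, L, k_max, t_grid, ...) {
  stopifnot(k_max >= 0)
  ks <- 0:k_max
  flags <- matrix(NA, length(ks), length(t_grid),
                  dimnames = list(paste0("k", ks), NULL))
  for (i in seq_along(ks)) {
    md <- mode_spec(ks[i], L)
    flags[i, ] <- vapply(t_grid, function(t)
      as.logical(theorem1_flag(spec, law, base, D, md, t, ...)),
      logical(1))
  }
  intervals <- lapply(seq_along(ks), function(i) {
    fl <- flags[i, ] %in% TRUE
    r <- rle(fl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sel <- which(r$values)
    if (!length(sel)) return(matrix(numeric(), 0, 2,
                                    dimnames = list(NULL,
                                                    c("t_start", "t_end"))))
    cbind(t_start = t_grid[starts[sel]], t_end = t_grid[ends[sel]])
  })
  structure(list(k = ks, rho_k = (ks * pi / L)^2, L = L,
                 t_grid = t_grid, flags = flags, intervals = intervals),
            class = "mode_stability_report")
}

#' @export
print.mode_stability_report <- function(x, ...) {
  nflag <- vapply(x$intervals, nrow, integer(1))
  cat("<mode_stability_report> k = 0..", max(x$k), ", ",
      sum(nflag > 0), " mode(s) with nonempty instability intervals\n",
      sep = "")
  invisible(x)
}

#' Export instability intervals as a data frame
#' @param report a `mode_stability_report`.
#' @return data.frame with columns `k`, `t_start`, `t_end`.
#' @export
intervals_frame <- function(report) {
  stopifnot(inherits(report, "mode_stability_report"))
  do.call(rbind, lapply(seq_along(report$k), function(i) {
    iv <- report$intervals[[i]]
    if (!nrow(iv)) return(NULL)
    data.frame(k = report$k[i], t_start = iv[, 1], t_end = iv[, 2])
  })) %||% data.frame(k = integer(), t_start = numeric(),
                      t_end = numeric())
}

#' Directly integrate the linear mode amplitudes
#'
#' Integrates `dV_k/dt = -rho_k mu*(t)^{-2} D V_k + M(t) V_k`, the exact
#' linear evolution whose sign structure Theorem-style flags predict; used
#' as the empirical check on the criterion.
#'
#' @inheritParams theorem1_flag
#' @param t_span length-2 time interval within the base-state span.
#' @param V0 nonzero initial amplitude vector.
#' @param n_out number of output times.
#' @param rtol,atol tolerances (default `1e-10`).
#' @return matrix with columns `t`, one column per component of `V`, and
#'   `norm`.
#' @export
integrate_mode_amplitudes <- function(spec, law, base, D, mode, t_span, V0,
                                      n_out = 101, rtol = 1e-10,
                                      atol = 1e-12) {
  stopifnot(inherits(mode, "mode_spec"), any(V0 != 0))
  itp <- base_state_interp(base)
  rho <- mode$rho_k
  m <- length(V0)
  rhs <- function(t, V) {
    lmM <- linearization_matrices(spec, law, base, t)$M
    -rho / itp$mu(t)^2 * (D * V) + as.numeric(lmM %*% V)
  }
  tg <- seq(t_span[1], t_span[2], length.out = n_out)
  traj <- ode_dp45(rhs, V0, tg, rtol = rtol, atol = atol)
  cbind(t = tg, traj, norm = sqrt(rowSums(traj^2)))
}
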