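#' Reaction kinetics specifications
#'
#' Construct a kinetics specification for one of the built-in reaction terms
#' or a user-supplied (`custom`) one. The built-ins are the classical
#' dimensionless forms used throughout the package:
#'
#' * `schnakenberg`: `f(u,v) = a - u + u^2 v`, `g(u,v) = b - u^2 v`
#' * `gierer_meinhardt`: `f(u,v) = a + u^2/v - b u`, `g(u,v) = u^2 - c v`
#'   (classical activator sign; the activator equilibrium is
#'   `u* = (a + c)/b`, `v* = u*^2/c`)
#' * `fitzhugh_nagumo`: `f(u,v) = c (u - u^3/3 + v - i0)`,
#'   `g(u,v) = (a - u - b v)/c`
#' * `logistic`: `f(u) = u (1 - u)`
#' * `bistable`: `f(u) = u (1 - u^2)`
#'
#' All built-in parameters are positive dimensionless rates.
#'
#' @param name one of `"schnakenberg"`, `"gierer_meinhardt"`,
#'   `"fitzhugh_nagumo"`, `"logistic"`, `"bistable"`, `"custom"`.
#' @param params named list/vector of real parameters (`a`, `b`, `c`, `i0`
#'   as applicable). Ignored for the scalar built-ins.
#' @param f for `custom`: a function `f(u)` returning a length-`m` numeric.
#' @param jac for `custom`: optional analytic Jacobian function `jac(u)`
#'   returning an `m x m` matrix; if omitted, central finite differences are
#'   used (with a one-time warning).
#' @param n_species number of species `m` (1 or 2); required for `custom`,
#'   inferred for built-ins.
#' @param vectorized for `custom`: if `TRUE`, `f` accepts an `m x N` matrix
#'   of states (one column per grid node) and returns an `m x N` matrix;
#'   this avoids per-node R callbacks inside the compiled solver.
#' @return an object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(name, params = list(), f = NULL, jac = NULL,
                          n_species = NULL, vectorized = FALSE) {
  name <- match.arg(name, c("schnakenberg", "gierer_meinhardt",
                            "fitzhugh_nagumo", "logistic", "bistable",
                            "custom"))
  params <- as.list(params)
  required <- switch(name,
    schnakenberg = c("a", "b"),
    gierer_meinhardt = c("a", "b", "c"),
    fitzhugh_nagumo = c("a", "b", "c", "i0"),
    logistic = character(), bistable = character(), custom = character())
  missing_p <- setdiff(required, names(params))
  if (length(missing_p))
    stop("kinetics '", name, "' requires parameter(s): ",
         paste(missing_p, collapse = ", "))
  for (p in required) {
    if (!is.finite(params[[p]]))
      stop("parameter '", p, "' must be finite")
    if (params[[p]] <= 0)
      stop("parameter '", p, "' must be positive for '", name, "' kinetics")
  }
  m <- switch(name,
    schnakenberg = 2L, gierer_meinhardt = 2L, fitzhugh_nagumo = 2L,
    logistic = 1L, bistable = 1L,
    custom = {
      if (is.null(n_species)) stop("custom kinetics require n_species")
      as.integer(n_species)
    })
  if (!m %in% 1:2) stop("n_species must be 1 or 2")
  if (name == "custom" && !is.function(f))
    stop("custom kinetics require a function f(u)")
  structure(list(name = name, params = params, n_species = m,
                 f = f, jac = jac, vectorized = isTRUE(vectorized)),
            class = "kinetics_spec")
}

#' @export
print.kinetics_spec <- function(x, ...) {
  cat("<kinetics_spec> ", x$name, " (m = ", x$n_species, ")\n", sep = "")
  if (length(x$params))
    cat("  params: ",
        paste(names(x$params), unlist(x$params), sep = " = ",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate reaction kinetics
#'
#' @param spec a [kinetics_spec()].
#' @param u numeric state vector of length `spec$n_species`.
#' @return numeric vector `f(u)` of the same length.
#' @export
evaluate_kinetics <- function(spec, u) {
  stopifnot(inherits(spec, "kinetics_spec"))
  if (length(u) != spec$n_species)
    stop("u has length ", length(u), " but kinetics has m = ",
         spec$n_species)
  p <- spec$params
  switch(spec$name,
    schnakenberg = c(p$a - u[1] + u[1]^2 * u[2],
                     p$b - u[1]^2 * u[2]),
    gierer_meinhardt = c(p$a + u[1]^2 / u[2] - p$b * u[1],
                         u[1]^2 - p$c * u[2]),
    fitzhugh_nagumo = c(p$c * (u[1] - u[1]^3 / 3 + u[2] - p$i0),
                        (p$a - u[1] - p$b * u[2]) / p$c),
    logistic = u[1] * (1 - u[1]),
    bistable = u[1] * (1 - u[1]^2),
    custom = {
      out <- if (spec$vectorized) spec$f(matrix(u, ncol = 1)) else spec$f(u)
      if (length(out) != spec$n_species)
        stop("custom f(u) returned length ", length(out))
      as.numeric(out)
    })
}

#' Analytic Jacobian of the reaction kinetics
#'
#' @inheritParams evaluate_kinetics
#' @return an `m x m` numeric matrix with entries `J[i, j] = d f_i / d u_j`.
#' @export
kinetics_jacobian <- function(spec, u) {
  stopifnot(inherits(spec, "kinetics_spec"))
  if (length(u) != spec$n_species)
    stop("u has length ", length(u), " but kinetics has m = ",
         spec$n_species)
  p <- spec$params
  switch(spec$name,
    schnakenberg = matrix(c(-1 + 2 * u[1] * u[2], -2 * u[1] * u[2],
                            u[1]^2, -u[1]^2), 2, 2),
    gierer_meinhardt = matrix(c(2 * u[1] / u[2] - p$b, 2 * u[1],
                                -u[1]^2 / u[2]^2, -p$c), 2, 2),
    fitzhugh_nagumo = matrix(c(p$c * (1 - u[1]^2), -1 / p$c,
                               p$c, -p$b / p$c), 2, 2),
    logistic = matrix(1 - 2 * u[1], 1, 1),
    bistable = matrix(1 - 3 * u[1]^2, 1, 1),
    custom = {
      if (is.function(spec$jac)) {
        J <- spec$jac(u)
        matrix(as.numeric(J), spec$n_species, spec$n_species)
      } else {
        warn_fd_once("kinetics")
        fd_jacobian(function(z) evaluate_kinetics(spec, z), u)
      }
    })
}

# one-shot warning registry for finite-difference fallbacks
.rdgrow_fd_warned <- new.env(parent = emptyenv())
warn_fd_once <- function(what) {
  if (is.null(.rdgrow_fd_warned[[what]])) {
    .rdgrow_fd_warned[[what]] <- TRUE
    warning("custom ", what,
            ": no analytic Jacobian/gradient supplied; ",
            "falling back to central finite differences", call. = FALSE)
  }
}

# central finite-difference Jacobian, h scaled to the state
fd_jacobian <- function(fn, u, h = 1e-6) {
  m <- length(fn(u))
  J <- matrix(0, m, length(u))
  for (j in seq_along(u)) {
    hj <- h * max(1, abs(u[j]))
    up <- u; up[j] <- u[j] + hj
    um <- u; um[j] <- u[j] - hj
    J[, j] <- (fn(up) - fn(um)) / (2 * hj)
  }
  J
}

#' Homogeneous equilibria of the kinetics
#'
#' Finds all real solutions of `f(u) = 0` and classifies each by the
#' eigenvalues of the kinetics Jacobian. For the built-in kinetics the
#' problem reduces (after clearing denominators) to polynomial root finding,
#' done via the companion matrix (`polyroot`); Gierer-Meinhardt roots with
#' non-positive activator are discarded since `u^2/v` requires `v > 0`.
#' Custom kinetics use damped multi-start Newton iteration.
#'
#' @param spec a [kinetics_spec()].
#' @param tol residual tolerance for accepting a root (default `1e-12`).
#' @param class_tol eigenvalue threshold below which a root is classified
#'   `degenerate`.
#' @return a list of `equilibrium` objects, each with fields `u_star`
#'   (length-`m` numeric) and `stability_class` (one of `node_stable`,
#'   `node_unstable`, `spiral_stable`, `spiral_unstable`, `saddle`,
#'   `degenerate`), ordered by ascending first component.
#' @export
find_equilibria <- function(spec, tol = 1e-12, class_tol = 1e-8) {
  stopifnot(inherits(spec, "kinetics_spec"))
  p <- spec$params
  roots <- switch(spec$name,
    logistic = list(0, 1),
    bistable = list(-1, 0, 1),
    schnakenberg = {
      u <- p$a + p$b
      if (abs(u) < .Machine$double.eps)
        stop("Schnakenberg equilibrium degenerate: a + b = 0")
      list(c(u, p$b / u^2))
    },
    gierer_meinhardt = {
      u <- (p$a + p$c) / p$b
      if (u <= 0) stop("Gierer-Meinhardt equilibrium non-positive")
      list(c(u, u^2 / p$c))
    },
    fitzhugh_nagumo = {
      # f = g = 0 with v = (a - u)/b reduces to the cubic
      #   -u^3/3 + (1 - 1/b) u + a/b - i0 = 0
      z <- polyroot(c(p$a / p$b - p$i0, 1 - 1 / p$b, 0, -1 / 3))
      re <- Re(z[abs(Im(z)) < 1e-8])
      lapply(sort(re), function(u) c(u, (p$a - u) / p$b))
    },
    custom = newton_equilibria(spec, tol = tol))
  roots <- Filter(function(r) {
    res <- max(abs(evaluate_kinetics(spec, r)))
    is.finite(res) && res < max(tol, 1e-10)
  }, roots)
  if (!length(roots))
    stop("no real equilibrium found for kinetics '", spec$name, "'")
  ord <- order(vapply(roots, `[`, numeric(1), 1))
  lapply(roots[ord], function(r) {
    ev <- eigen(kinetics_jacobian(spec, r), only.values = TRUE)$values
    structure(list(u_star = r,
                   stability_class = classify_eigenvalues(ev, class_tol)),
              class = "equilibrium")
  })
}

classify_eigenvalues <- function(ev, tol = 1e-8) {
  re <- Re(ev); im <- Im(ev)
  if (any(abs(re) < tol)) return("degenerate")
  if (any(abs(im) > tol)) {
    if (all(re < 0)) "spiral_stable" else "spiral_unstable"
  } else {
    if (all(re < 0)) "node_stable"
    else if (all(re > 0)) "node_unstable"
    else "saddle"
  }
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium> u* = (",
      paste(signif(x$u_star, 8), collapse = ", "),
      ")  [", x$stability_class, "]\n", sep = "")
  invisible(x)
}

# damped multi-start Newton for custom kinetics
newton_equilibria <- function(spec, tol = 1e-12, starts = NULL) {
  m <- spec$n_species
  if (is.null(starts)) {
    g <- c(-3, -1, -0.3, 0, 0.3, 1, 3, 10)
    starts <- if (m == 1) lapply(g, identity)
              else unlist(lapply(g, function(a) lapply(g, function(b) c(a, b))),
                          recursive = FALSE)
  }
  found <- list()
  for (s in starts) {
    u <- as.numeric(s)
    ok <- FALSE
    for (it in 1:100) {
      fu <- tryCatch(evaluate_kinetics(spec, u), error = function(e) NULL)
      if (is.null(fu) || any(!is.finite(fu))) break
      if (max(abs(fu)) < tol) { ok <- TRUE; break }
      J <- tryCatch(kinetics_jacobian(spec, u), error = function(e) NULL)
      if (is.null(J) || any(!is.finite(J))) break
      du <- tryCatch(solve(J, fu), error = function(e) NULL)
      if (is.null(du)) break
      lam <- 1
      repeat {
        un <- u - lam * du
        fn <- tryCatch(evaluate_kinetics(spec, un), error = function(e) NULL)
        if (!is.null(fn) && all(is.finite(fn)) &&
            max(abs(fn)) < max(abs(fu))) break
        lam <- lam / 2
        if (lam < 1e-6) { un <- u - du; break }
      }
      u <- un
    }
    if (ok && !any(vapply(found, function(r) max(abs(r - u)) < 1e-6,
                          logical(1))))
      found <- c(found, list(u))
  }
  found
}

#' Growth-law specifications
#'
#' Construct the local dilation-rate law `S(t, u)` that closes the model:
#' the local volume element dilates at rate `S`, i.e.
#' `d log(mu) / dt = S(t, u)`. Available forms:
#'
#' * `constant`: `S = s0`
#' * `prescribed_time`: `S = fn(t)` for a user function of time only
#' * `linear`: `S = s0 + sigma * u1`
#' * `thresholded_tanh`: `S = s0 * (1 + tanh(k_th * (u1 - u_th)))`
#' * `quadratic_ratio`: `S = s0 * ((u1 / u_ref)^2 - 1)`
#' * `difference`: `S = r * (u1 - alpha * u2)`
#' * `custom`: `S = fn(t, u)` with optional analytic gradient `grad(t, u)`
#'
#' @param form one of the forms above.
#' @param s0,sigma,k_th,u_th,u_ref,r,alpha real coefficients as applicable.
#'   `s0` and `r` are rates (inverse time); `u_th`, `u_ref` are
#'   concentrations; `k_th` is a threshold steepness; `alpha` the weight of
#'   the second species; `sigma` a linear sensitivity.
#' @param fn,grad functions for `prescribed_time` / `custom` forms; `grad`
#'   must return the length-`m` gradient of `S` in `u`.
#' @param time_dependent logical; `TRUE` only for laws depending explicitly
#'   on time.
#' @param vectorized for `custom`: if `TRUE`, `fn(t, U)` accepts an
#'   `m x N` state matrix and returns a length-`N` vector of rates.
#' @return an object of class `growth_law`.
#' @export
growth_law <- function(form, s0 = NULL, sigma = NULL, k_th = NULL,
                       u_th = NULL, u_ref = NULL, r = NULL, alpha = NULL,
                       fn = NULL, grad = NULL, time_dependent = NULL,
                       vectorized = FALSE) {
  form <- match.arg(form, c("constant", "prescribed_time", "linear",
                            "thresholded_tanh", "quadratic_ratio",
                            "difference", "custom"))
  need <- function(val, nm) {
    if (is.null(val) || !is.finite(val))
      stop("growth law '", form, "' requires parameter '", nm, "'")
    val
  }
  params <- switch(form,
    constant = list(s0 = need(s0, "s0")),
    prescribed_time = {
      if (!is.function(fn)) stop("prescribed_time requires fn(t)")
      list()
    },
    linear = list(s0 = need(s0, "s0"), sigma = need(sigma, "sigma")),
    thresholded_tanh = list(s0 = need(s0, "s0"), u_th = need(u_th, "u_th"),
                            k_th = need(k_th, "k_th")),
    quadratic_ratio = {
      u_ref <- need(u_ref, "u_ref")
      if (u_ref == 0) stop("u_ref must be nonzero")
      list(s0 = need(s0, "s0"), u_ref = u_ref)
    },
    difference = list(r = need(r, "r"), alpha = need(alpha, "alpha")),
    custom = {
      if (!is.function(fn)) stop("custom growth law requires fn(t, u)")
      list()
    })
  td <- if (!is.null(time_dependent)) isTRUE(time_dependent)
        else form == "prescribed_time" ||
             (form == "custom" && is.null(time_dependent))
  structure(list(form = form, params = params, fn = fn, grad = grad,
                 time_dependent = td, vectorized = isTRUE(vectorized)),
            class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat("<growth_law> ", x$form,
      if (x$time_dependent) " (time-dependent)" else "", "\n", sep = "")
  if (length(x$params))
    cat("  params: ",
        paste(names(x$params), unlist(x$params), sep = " = ",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the local dilation rate `S(t, u)`
#'
#' @param law a [growth_law()].
#' @param t time.
#' @param u numeric state vector (first species first).
#' @return scalar dilation rate.
#' @export
evaluate_growth <- function(law, t, u) {
  stopifnot(inherits(law, "growth_law"))
  p <- law$params
  switch(law$form,
    constant = p$s0,
    prescribed_time = as.numeric(law$fn(t)),
    linear = p$s0 + p$sigma * u[1],
    thresholded_tanh = p$s0 * (1 + tanh(p$k_th * (u[1] - p$u_th))),
    quadratic_ratio = p$s0 * ((u[1] / p$u_ref)^2 - 1),
    difference = p$r * (u[1] - p$alpha * u[2]),
    custom = {
      if (law$vectorized) as.numeric(law$fn(t, matrix(u, ncol = 1)))
      else as.numeric(law$fn(t, u))
    })
}

#' Gradient of the dilation rate in the concentrations
#'
#' Returns `dS/du_j` at `(t, u)`; analytic for all built-in forms, finite
#' differences (with a one-time warning) for `custom` laws without `grad`.
#'
#' @inheritParams evaluate_growth
#' @return numeric vector of length `length(u)`.
#' @export
growth_gradient <- function(law, t, u) {
  stopifnot(inherits(law, "growth_law"))
  p <- law$params
  m <- length(u)
  g <- numeric(m)
  switch(law$form,
    constant = g,
    prescribed_time = g,
    linear = { g[1] <- p$sigma; g },
    thresholded_tanh = {
      g[1] <- p$s0 * p$k_th / cosh(p$k_th * (u[1] - p$u_th))^2
      g
    },
    quadratic_ratio = { g[1] <- 2 * p$s0 * u[1] / p$u_ref^2; g },
    difference = { g[1] <- p$r; g[2] <- -p$r * p$alpha; g },
    custom = {
      if (is.function(law$grad)) as.numeric(law$grad(t, u))
      else {
        warn_fd_once("growth law")
        vapply(seq_len(m), function(j) {
          hj <- 1e-6 * max(1, abs(u[j]))
          up <- u; up[j] <- u[j] + hj
          um <- u; um[j] <- u[j] - hj
          (evaluate_growth(law, t, up) - evaluate_growth(law, t, um)) /
            (2 * hj)
        }, numeric(1))
      }
    })
}
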