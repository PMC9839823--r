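# shared fixtures: built in code, no stored data

schnak_spec <- function() kinetics_spec("schnakenberg",
                                        list(a = 0.01, b = 1.1))
gm_spec <- function() kinetics_spec("gierer_meinhardt",
                                    list(a = 0.01, b = 0.5, c = 5.5))
fhn_spec <- function() kinetics_spec("fitzhugh_nagumo",
                                     list(a = 1.01, b = 1, c = 1, i0 = 1))

# pure-decay kinetics (f == 0), vectorized for the compiled solver
zero_kinetics <- function(m = 1)
  kinetics_spec("custom", f = function(U) 0 * U, n_species = m,
                vectorized = TRUE)

# trapezoidal mass of species s over the Lagrangian grid
trapz_mass <- function(state, s = 1) {
  dX <- diff(state$X)[1]
  w <- c(dX / 2, rep(dX, length(state$X) - 2), dX / 2)
  sum(w * state$u[, s] * state$mu)
}

# closed-form Schnakenberg equilibrium and Jacobian (independent of the
# package's kinetics code paths)
schnak_closed <- function(a = 0.01, b = 1.1) {
  u <- a + b; v <- b / u^2
  J <- matrix(c(-1 + 2 * u * v, -2 * u * v, u^2, -u^2), 2, 2)
  list(u_star = c(u, v), J = J)
}

# frozen base-state object for constant coefficients (S == 0, mu* == 1)
frozen_base <- function(spec, u_star, tmax = 1) {
  out <- structure(list(t = c(0, tmax),
                        u_star = rbind(u_star, u_star),
                        S = c(0, 0), mu_star = c(1, 1),
                        spec = spec, law = growth_law("constant", s0 = 0)),
                   class = "base_state")
  out$interp <- rdgrow:::build_base_interp(out)
  out
}

# wrap a constant 2x2 matrix as custom kinetics with equilibrium at 0
matrix_kinetics <- function(M)
  kinetics_spec("custom", f = function(u) as.numeric(M %*% u),
                jac = function(u) M, n_species = 2)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
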