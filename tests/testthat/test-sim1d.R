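test_that("diffusion stencil reduces to known values and conserves flux form", {
  # mu == 1 recovers the standard second difference
  st <- lagrangian_state_1d(0:2, c(0, 1, 0), rep(1, 3))
  expect_equal(discretize_diffusion(st)[2], -2)
  # mu == 2: each 1/mu factor contributes 1/2, interior value -0.5
  st2 <- lagrangian_state_1d(0:2, c(0, 1, 0), rep(2, 3))
  expect_equal(discretize_diffusion(st2)[2], -0.5)
  # constant field: zero for any mu
  set.seed(2)
  st3 <- lagrangian_state_1d(seq(0, 5, length.out = 20), rep(0.7, 20),
                             runif(20, 0.5, 2))
  expect_equal(max(abs(discretize_diffusion(st3))), 0)
  # non-uniform grid rejected
  st4 <- lagrangian_state_1d(c(0, 1, 3), c(0, 1, 0))
  expect_error(discretize_diffusion(st4), "uniform")
})

test_that("R and compiled right-hand sides agree on random states", {
  sp <- schnak_spec()
  law <- growth_law("difference", r = 0.162, alpha = 1.3)
  set.seed(7)
  for (rep in 1:5) {
    N <- sample(10:60, 1)
    st <- lagrangian_state_1d(seq(0, 5, length.out = N),
                              cbind(runif(N, 0.5, 1.5), runif(N, 0.5, 1.5)),
                              runif(N, 0.8, 1.4))
    r1 <- rhs_1d(0, st, sp, law, c(1, 40))
    kc <- rdgrow:::kinetics_codes(sp)
    gc <- rdgrow:::growth_codes(law)
    r2 <- matrix(rdgrow:::rd1d_rhs_cpp(0, rdgrow:::pack_state(st), 2,
                                       diff(st$X)[1], c(1, 40),
                                       kc$code, kc$par, gc$code, gc$par,
                                       NULL, NULL), nrow = 3)
    expect_lt(max(abs(t(r2[1:2, ]) - r1$du)), 1e-11)
    expect_lt(max(abs(r2[3, ] - r1$dmu)), 1e-11)
  }
})

test_that("rhs_1d: homogeneous states and pointwise dilution", {
  sp <- schnak_spec()
  eq <- schnak_closed()$u_star
  st <- initial_state_1d(sp, 5, 21,
                         ic_spec("custom",
                                 fn = function(x)
                                   cbind(rep(eq[1], length(x)),
                                         rep(eq[2], length(x)))))
  lawc <- growth_law("constant", s0 = 0.01)
  r <- rhs_1d(0, st, sp, lawc, c(1, 40))
  # f(u*) = 0 so du = -s0 u*, dmu = s0 mu
  expect_equal(r$du[5, ], -0.01 * eq, tolerance = 1e-10)
  expect_equal(r$dmu, 0.01 * st$mu, tolerance = 1e-12)
  # S = r(u - 1.3 v) at equilibrium: mudot/mu from the closed form
  lawd <- growth_law("difference", r = 0.162, alpha = 1.3)
  r2 <- rhs_1d(0, st, sp, lawd, c(1, 40))
  expect_equal(r2$dmu / st$mu,
               rep(0.162 * (eq[1] - 1.3 * eq[2]), 21), tolerance = 1e-12)
})

test_that("eulerian map: cumulative integral of mu, anchored at zero", {
  st <- lagrangian_state_1d(seq(0, 5, length.out = 11), rep(1, 11),
                            rep(2, 11))
  x <- eulerian_positions(st)
  expect_equal(x[1], 0)
  expect_equal(x[11], 10)
  # mu = 1 + X on [0, 1]: x(1) = 3/2 to quadrature accuracy
  X <- seq(0, 1, length.out = 201)
  st2 <- lagrangian_state_1d(X, rep(0, 201), 1 + X)
  expect_equal(tail(eulerian_positions(st2), 1), 1.5, tolerance = 1e-4)
  st$mu[4] <- -1
  expect_error(eulerian_positions(st), "mu")
})

test_that("advance_epoch: exponential length law and equilibria fixed", {
  # constant S: L(t) = L0 e^{S t} (here to machine-level accuracy at the
  # default tolerances 1e-11)
  z <- zero_kinetics()
  law <- growth_law("constant", s0 = 0.01)
  st <- initial_state_1d(z, 5, 51,
                         ic_spec("custom",
                                 fn = function(x) matrix(1, length(x), 1)))
  st2 <- advance_epoch(st, z, law, 1, until = 100)
  expect_rel_equal(domain_length(st2) / domain_length(st), exp(1), 1e-6)
  # logistic at u = 1 with S = 0 stays put
  lg <- kinetics_spec("logistic")
  st3 <- initial_state_1d(lg, 5, 31,
                          ic_spec("custom",
                                  fn = function(x) matrix(1, length(x), 1)))
  st4 <- advance_epoch(st3, lg, growth_law("constant", s0 = 0), 1,
                       until = 10)
  expect_lt(max(abs(st4$u - 1)), 1e-9)
  expect_lt(max(abs(st4$mu - 1)), 1e-12)
})

test_that("heat-kernel decay fixes the stencil's grid-spacing scale", {
  # on a fixed domain (S = 0, f = 0) the cosine mode decays at exactly
  # D (pi/L)^2 -- this pins the 1/dX^2 divisor of the diffusion stencil
  z <- zero_kinetics()
  L <- 5; tend <- 5
  amp_err <- vapply(c(100, 200), function(N) {
    st <- initial_state_1d(z, L, N,
                           ic_spec("custom",
                                   fn = function(x)
                                     matrix(1 + 0.1 * cos(pi * x / L),
                                            ncol = 1)))
    st2 <- advance_epoch(st, z, growth_law("constant", s0 = 0), 1, tend)
    amp <- (max(st2$u) - min(st2$u)) / 2
    abs(amp / (0.1 * exp(-(pi / L)^2 * tend)) - 1)
  }, numeric(1))
  expect_lt(amp_err[1], 1e-3)
  expect_lt(amp_err[2], amp_err[1] / 2)  # second-order continuum limit
})

test_that("mass conservation for f == 0 under concentration-dependent growth", {
  z <- zero_kinetics()
  law <- growth_law("thresholded_tanh", s0 = 0.002, u_th = 0.5, k_th = 10)
  st <- initial_state_1d(z, 5, 200,
                         ic_spec("custom",
                                 fn = function(x)
                                   matrix(0.5 + 0.4 * sin(2 * pi * x / 5),
                                          ncol = 1)))
  st2 <- advance_epoch(st, z, law, 1, until = 20)
  expect_rel_equal(trapz_mass(st2), trapz_mass(st), 1e-9)
  expect_true(all(st2$mu > 0))
  expect_true(all(diff(eulerian_positions(st2)) > 0))
})

test_that("remesh preserves length exactly and fields to interpolation error", {
  z <- zero_kinetics()
  # mu == 2 uniform: new domain [0, 10], mu reset to one
  st <- initial_state_1d(z, 5, 101,
                         ic_spec("custom",
                                 fn = function(x)
                                   matrix(sin(pi * x / 5), ncol = 1)))
  st$mu <- rep(2, 101)
  r <- remesh(st)
  expect_equal(tail(r$X, 1), 10)
  expect_equal(r$mu, rep(1, 101))
  # mu == 1: identity to round-off
  st2 <- initial_state_1d(z, 5, 101,
                          ic_spec("custom",
                                  fn = function(x)
                                    matrix(sin(pi * x / 5), ncol = 1)))
  r2 <- remesh(st2)
  expect_lt(max(abs(r2$u - st2$u)), 1e-12)
  # smooth field through a non-uniform map: pchip error < 1e-6 at N = 1e3
  st3 <- initial_state_1d(z, 5, 1000,
                          ic_spec("custom",
                                  fn = function(x) matrix(0, length(x), 1)))
  st3$mu <- 1 + 0.3 * sin(2 * pi * st3$X / 5)
  x <- eulerian_positions(st3)
  L <- tail(x, 1)
  st3$u <- matrix(sin(pi * x / L), ncol = 1)
  r3 <- remesh(st3)
  expect_lt(max(abs(r3$u - sin(pi * r3$X / L))), 1e-6)
  # mass preserved through remesh to interpolation error
  expect_rel_equal(trapz_mass(r3), trapz_mass(st3), 1e-6)
})

test_that("run_simulation_1d is remesh-invariant and resolution-robust", {
  sp <- schnak_spec()
  law <- growth_law("constant", s0 = 0.005)
  mk <- function(N_s, epoch_length) {
    simulation_config(1, sp, law, D = c(1, 40), L = 5, N_s = N_s,
                      ic = ic_spec("noisy_equilibrium", 1e-2, seed = 11),
                      t_final = 150, epoch = epoch_schedule(epoch_length),
                      tolerances = list(rtol = 1e-9, atol = 1e-9),
                      n_length_samples = 20)
  }
  L_end <- function(cfg) tail(run_simulation_1d(cfg)$L$L, 1)
  base <- L_end(mk(200, Inf))          # single epoch, no remesh
  more_epochs <- L_end(mk(200, 30))
  finer <- L_end(mk(400, 30))
  expect_rel_equal(more_epochs, base, 1e-3)
  expect_rel_equal(finer, more_epochs, 1e-3)
})

test_that("homogeneous run reproduces the base-state ODE oracle", {
  sp <- schnak_spec()
  law <- growth_law("difference", r = 0.162, alpha = 1.3)
  eq <- schnak_closed()$u_star
  st <- initial_state_1d(sp, 5, 41,
                         ic_spec("custom",
                                 fn = function(x)
                                   cbind(rep(eq[1], length(x)),
                                         rep(eq[2], length(x)))))
  st2 <- advance_epoch(st, sp, law, c(1, 40), until = 50)
  # independent oracle: the homogeneous base-state ODE via the explicit
  # RK45 integrator (different method, different code path)
  traj <- ode_dp45(function(t, y)
    -evaluate_growth(law, t, y) * y + evaluate_kinetics(sp, y),
    eq, c(0, 50), rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(st2$u[10, ] - traj[2, ])), 1e-6)
  # fields stay spatially uniform
  expect_lt(max(apply(st2$u, 2, function(z) diff(range(z)))), 1e-9)
})

test_that("initial conditions: seeded noise is reproducible and resolution-consistent", {
  sp <- schnak_spec()
  ic <- ic_spec("noisy_equilibrium", 1e-2, seed = 99)
  a <- initial_state_1d(sp, 5, 100, ic)
  b <- initial_state_1d(sp, 5, 100, ic)
  expect_identical(a$u, b$u)
  # counter-based generator: node i's draw does not depend on N_s
  cN <- counter_normals_cpp(99, 1, 100)
  c2N <- counter_normals_cpp(99, 1, 200)
  expect_identical(cN, c2N[1:100])
  # noise statistics in the right ballpark (variance 1e-2)
  big <- counter_normals_cpp(1, 1, 20000)
  expect_lt(abs(mean(big)), 0.03)
  expect_lt(abs(sd(big) - 1), 0.03)
  # tanh front matches its closed form
  st <- initial_state_1d(kinetics_spec("logistic"), 30, 50,
                         ic_spec("tanh_front"))
  expect_equal(st$u[, 1], (1 + tanh(30 / 5 - st$X)) / 2)
})

test_that("count_peaks handles the standard cases", {
  X <- seq(0, 1, length.out = 401)
  expect_equal(count_peaks(sin(4 * pi * X)), 2)   # two interior peaks
  expect_equal(count_peaks(rep(3, 10)), 0)
  two_gauss <- exp(-((X - 0.3) / 0.05)^2) + exp(-((X - 0.7) / 0.05)^2)
  expect_equal(count_peaks(two_gauss, prominence = 0.4), 2)
  expect_equal(count_peaks(two_gauss, prominence = 0.05), 2)
  # boundary maximum excluded by default, counted on request
  ramp <- c(5, 1, 2, 1, 0)
  expect_equal(count_peaks(ramp, prominence = 0.1), 1)
  expect_equal(count_peaks(ramp, prominence = 0.1,
                           include_boundary = TRUE), 2)
})

test_that("long-time classification separates the canonical series", {
  t <- seq(0, 400, by = 0.5)
  expect_identical(
    classify_long_time_behaviour(t, 10 * exp(0.01 * t), window = 100),
    "growing")
  expect_identical(
    classify_long_time_behaviour(t, rep(10, length(t)), window = 100),
    "fixed")
  expect_identical(
    classify_long_time_behaviour(t, 10 + 0.5 * sin(t), window = 100),
    "oscillating")
  expect_identical(
    classify_long_time_behaviour(t, 10 * exp(-0.01 * t), window = 100),
    "shrinking")
  expect_error(classify_long_time_behaviour(t, rep(10, length(t)),
                                            window = 300), "two windows")
})
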