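#' 2D domain specifications
#'
#' Initial planar domains: a disk, the dumbbell-shaped region
#' `|y| <= (x^8 + 0.01) sqrt(1 - x^8)` for `x` in `[-0.995, 0.995]`
#' (thin central channel of half-width 0.01, two lobes; the printed
#' parametric form is degenerate and is reinterpreted as this region — see
#' the methods vignette), a generic star-shaped domain
#' `r(theta) = radius (1 + amplitude cos(lobes theta))`, or an arbitrary
#' simple polygon.
#'
#' @param shape `"disk"`, `"dumbbell"`, `"star"`, or `"polygon"`.
#' @param radius disk/star base radius.
#' @param lobes,amplitude star lobe count and relative amplitude.
#' @param vertices 2-column matrix of polygon vertices (counter-clockwise).
#' @param h target mesh edge length.
#' @return an object of class `domain_spec_2d`.
#' @export
domain_spec_2d <- function(shape = c("disk", "dumbbell", "star", "polygon"),
                           radius = 3, lobes = 5, amplitude = 0.3,
                           vertices = NULL, h = 0.2) {
  shape <- match.arg(shape)
  if (h <= 0) stop("h must be positive")
  if (shape == "polygon") {
    if (is.null(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
      stop("polygon requires a 2-column vertex matrix")
  }
  structure(list(shape = shape, radius = radius, lobes = lobes,
                 amplitude = amplitude, vertices = vertices, h = h),
            class = "domain_spec_2d")
}

# --- small planar geometry helpers -------------------------------------

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, 1:(n - 1))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

dist_to_polyline <- function(px, py, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j[i], 1]; by <- poly[j[i], 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 == 0) rep(0, length(px))
          else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + tt * vx); dy <- py - (ay + tt * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

boundary_self_intersects <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    for (k in (i + 1):n) {
      if (k == i || j[k] == i || k == j[i]) next
      if (segments_intersect(poly[i, ], poly[j[i], ],
                             poly[k, ], poly[j[k], ])) return(TRUE)
    }
  }
  FALSE
}

# --- boundary polylines for the built-in shapes ------------------------

dumbbell_halfwidth <- function(x) (x^8 + 0.01) * sqrt(pmax(0, 1 - x^8))

boundary_polyline <- function(spec) {
  h <- spec$h
  switch(spec$shape,
    disk = {
      R <- spec$radius
      n <- max(16L, ceiling(2 * pi * R / h))
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      cbind(R * cos(th), R * sin(th))
    },
    star = {
      R <- spec$radius; A <- spec$amplitude; p <- spec$lobes
      # crude perimeter estimate for arc-length-ish sampling
      thf <- seq(0, 2 * pi, length.out = 2000)
      rf <- R * (1 + A * cos(p * thf))
      per <- sum(sqrt(diff(rf * cos(thf))^2 + diff(rf * sin(thf))^2))
      n <- max(32L, ceiling(per / h))
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      r <- R * (1 + A * cos(p * th))
      if (any(r <= 0)) stop("star amplitude too large: boundary reaches r <= 0")
      cbind(r * cos(th), r * sin(th))
    },
    dumbbell = {
      xc <- 0.995
      # local spacing follows the channel half-width so thin parts stay
      # resolved; march along x accumulating points
      xs <- xc
      x <- -xc
      pts_x <- x
      while (x < xc) {
        w <- dumbbell_halfwidth(x)
        step <- max(0.004, min(h, 1.5 * w))
        x <- min(xc, x + step)
        pts_x <- c(pts_x, x)
      }
      top <- cbind(pts_x, dumbbell_halfwidth(pts_x))
      wc <- dumbbell_halfwidth(xc)
      # right cap (vertical edge from +w to -w), subdivided
      ncap <- max(2L, ceiling(2 * wc / min(h, 0.05)))
      capy <- seq(wc, -wc, length.out = ncap + 1)[-c(1, ncap + 1)]
      right_cap <- cbind(rep(xc, length(capy)), capy)
      bot <- cbind(rev(pts_x), -dumbbell_halfwidth(rev(pts_x)))
      capy2 <- seq(-wc, wc, length.out = ncap + 1)[-c(1, ncap + 1)]
      left_cap <- cbind(rep(-xc, length(capy2)), capy2)
      poly <- rbind(top, right_cap, bot, left_cap)
      poly[!duplicated(round(poly, 12)), ]
    },
    polygon = {
      v <- spec$vertices
      if (polygon_area(v) < 0) v <- v[rev(seq_len(nrow(v))), ]
      out <- NULL
      n <- nrow(v)
      for (i in seq_len(n)) {
        a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
        len <- sqrt(sum((b - a)^2))
        k <- max(1L, ceiling(len / h))
        tt <- seq(0, 1, length.out = k + 1)[-(k + 1)]
        out <- rbind(out, cbind(a[1] + tt * (b[1] - a[1]),
                                a[2] + tt * (b[2] - a[2])))
      }
      out
    })
}

# --- mesh construction --------------------------------------------------

#' Planar Lagrangian mesh
#'
#' @param X reference node coordinates (N x 2).
#' @param tri triangle connectivity (T x 3, 1-based); reoriented so all
#'   reference triangles are counter-clockwise.
#' @param boundary integer vector of node indices forming the closed
#'   boundary loop, in order.
#' @param h target edge length.
#' @param x current Eulerian coordinates (defaults to `X`).
#' @return an object of class `planar_mesh`.
#' @export
planar_mesh <- function(X, tri, boundary, h, x = X) {
  X <- as.matrix(X); x <- as.matrix(x); tri <- as.matrix(tri)
  stopifnot(ncol(X) == 2, ncol(tri) == 3, nrow(x) == nrow(X))
  # orient reference triangles CCW
  a <- X[tri[, 1], ]; b <- X[tri[, 2], ]; cc <- X[tri[, 3], ]
  det2 <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  flip <- det2 < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  structure(list(X = X, x = x, tri = tri,
                 boundary = as.integer(boundary), h = h),
            class = "planar_mesh")
}

#' @export
print.planar_mesh <- function(x, ...) {
  cat("<planar_mesh> ", nrow(x$X), " nodes, ", nrow(x$tri),
      " triangles, ", length(x$boundary), " boundary nodes, area = ",
      signif(mesh_area(x), 6), "\n", sep = "")
  invisible(x)
}

#' Total mesh area (current configuration)
#' @param mesh a [planar_mesh()].
#' @return sum of (signed) triangle areas.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$x, mesh$tri))

triangle_areas <- function(coords, tri) {
  a <- coords[tri[, 1], , drop = FALSE]
  b <- coords[tri[, 2], , drop = FALSE]
  cc <- coords[tri[, 3], , drop = FALSE]
  ((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
     (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])) / 2
}

mesh_from_boundary <- function(poly, h) {
  nb <- nrow(poly)
  # hexagonal interior lattice clipped to the polygon
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  dy <- h * sqrt(3) / 2
  ys <- seq(yr[1] + dy / 2, yr[2], by = dy)
  pts <- NULL
  for (k in seq_along(ys)) {
    off <- if (k %% 2 == 0) h / 2 else 0
    xs <- seq(xr[1] + h / 2 + off, xr[2], by = h)
    if (length(xs)) pts <- rbind(pts, cbind(xs, ys[k]))
  }
  if (!is.null(pts) && nrow(pts)) {
    keep <- point_in_polygon(pts[, 1], pts[, 2], poly) &
      dist_to_polyline(pts[, 1], pts[, 2], poly) > 0.6 * h
    pts <- pts[keep, , drop = FALSE]
  }
  allpts <- rbind(poly, pts)
  tri <- delaunay_cpp(allpts[, 1], allpts[, 2])
  # drop triangles whose centroid lies outside the (possibly non-convex)
  # polygon
  cx <- (allpts[tri[, 1], 1] + allpts[tri[, 2], 1] + allpts[tri[, 3], 1]) / 3
  cy <- (allpts[tri[, 1], 2] + allpts[tri[, 2], 2] + allpts[tri[, 3], 2]) / 3
  keep <- point_in_polygon(cx, cy, poly)
  tri <- tri[keep, , drop = FALSE]
  # drop unreferenced points (rare: lattice points stranded outside)
  used <- sort(unique(as.integer(tri)))
  if (!all(seq_len(nb) %in% used))
    stop("mesh generation failed: boundary node dropped (h too coarse ",
         "for this shape)")
  remap <- integer(nrow(allpts)); remap[used] <- seq_along(used)
  planar_mesh(X = allpts[used, , drop = FALSE],
              tri = matrix(remap[tri], ncol = 3),
              boundary = seq_len(nb), h = h)
}

#' Generate a conforming triangulation of an initial domain
#'
#' Boundary polylines are sampled at the target edge length (adaptively for
#' the dumbbell so its 0.02-wide channel stays resolved), interior nodes
#' come from a hexagonal lattice, and the triangulation is Delaunay with
#' outside-centroid filtering for non-convex shapes. The current
#' configuration is initialized to the reference one (`x = X`, `mu = 1`).
#'
#' @param spec a [domain_spec_2d()].
#' @return a [planar_mesh()].
#' @export
generate_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec_2d"))
  poly <- boundary_polyline(spec)
  if (boundary_self_intersects(poly))
    stop("generated boundary polyline self-intersects")
  mesh_from_boundary(poly, spec$h)
}

#' Per-element metric of the Lagrangian-to-Eulerian map
#'
#' For each triangle the affine map from reference to current coordinates
#' gives `dx/dX`; the volume-form coefficient is
#' `mu = sqrt(|dx/dX1|^2 |dx/dX2|^2 - (dx/dX1 . dx/dX2)^2)` (the local area
#' ratio) and the inverse metric `H` follows from the same derivatives.
#'
#' @param mesh a [planar_mesh()].
#' @return list of class `metric_field` with per-element vectors `mu`,
#'   `H11`, `H12`, `H22`.
#' @export
compute_metric <- function(mesh) {
  stopifnot(inherits(mesh, "planar_mesh"))
  tri <- mesh$tri
  E1 <- mesh$X[tri[, 2], ] - mesh$X[tri[, 1], ]
  E2 <- mesh$X[tri[, 3], ] - mesh$X[tri[, 1], ]
  e1 <- mesh$x[tri[, 2], ] - mesh$x[tri[, 1], ]
  e2 <- mesh$x[tri[, 3], ] - mesh$x[tri[, 1], ]
  detE <- E1[, 1] * E2[, 2] - E1[, 2] * E2[, 1]
  # columns of F = dx/dX from e = F E
  c1x <- (e1[, 1] * E2[, 2] - e2[, 1] * E1[, 2]) / detE
  c1y <- (e1[, 2] * E2[, 2] - e2[, 2] * E1[, 2]) / detE
  c2x <- (-e1[, 1] * E2[, 1] + e2[, 1] * E1[, 1]) / detE
  c2y <- (-e1[, 2] * E2[, 1] + e2[, 2] * E1[, 1]) / detE
  detF <- c1x * c2y - c1y * c2x
  if (any(detF <= 0))
    stop("inverted element(s): ", paste(which(detF <= 0)[1:min(3, sum(detF <= 0))],
                                        collapse = ", "),
         " (mu <= 0)")
  g11 <- c1x^2 + c1y^2
  g22 <- c2x^2 + c2y^2
  g12 <- c1x * c2x + c1y * c2y
  mu <- sqrt(pmax(0, g11 * g22 - g12^2))
  structure(list(mu = mu, H11 = g22 / mu^2, H12 = -g12 / mu^2,
                 H22 = g11 / mu^2),
            class = "metric_field")
}

# --- P1 finite elements -------------------------------------------------

fem_assemble <- function(coords, tri) {
  A <- triangle_areas(coords, tri)
  if (any(A <= 0)) stop("inverted element in FEM assembly: ",
                        which(A <= 0)[1])
  x1 <- coords[tri[, 1], 1]; y1 <- coords[tri[, 1], 2]
  x2 <- coords[tri[, 2], 1]; y2 <- coords[tri[, 2], 2]
  x3 <- coords[tri[, 3], 1]; y3 <- coords[tri[, 3], 2]
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  B <- cbind(b1, b2, b3); C <- cbind(c1, c2, c3)
  n <- nrow(coords); nt <- nrow(tri)
  ii <- jj <- vv <- vm <- numeric(9 * nt)
  idx <- 0
  for (a in 1:3) for (b in 1:3) {
    sel <- idx * nt + seq_len(nt)
    ii[sel] <- tri[, a]; jj[sel] <- tri[, b]
    vv[sel] <- (B[, a] * B[, b] + C[, a] * C[, b]) / (4 * A)
    vm[sel] <- A / 12 * (1 + (a == b))
    idx <- idx + 1
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = vm, dims = c(n, n))
  ml <- as.numeric(M %*% rep(1, n))   # lumped mass (row sums)
  list(K = K, M = M, ml = ml, area = A, B = B, C = C)
}

# area-weighted node recovery of per-element P1 gradients of nodal field f
recover_gradient <- function(coords, tri, fem, f) {
  A <- fem$area
  fe <- cbind(f[tri[, 1]], f[tri[, 2]], f[tri[, 3]])
  gx <- rowSums(fe * fem$B) / (2 * A)
  gy <- rowSums(fe * fem$C) / (2 * A)
  n <- nrow(coords)
  wx <- wy <- ww <- numeric(n)
  for (a in 1:3) {
    idx <- tri[, a]
    wx <- wx + unname(tapply_add(gx * A, idx, n))
    wy <- wy + unname(tapply_add(gy * A, idx, n))
    ww <- ww + unname(tapply_add(A, idx, n))
  }
  cbind(wx / ww, wy / ww)
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Solve the potential-flow Poisson problem
#'
#' Finite-element solve of `laplacian(phi) = S` on the current Eulerian
#' geometry with `phi = 0` on the boundary; the flow velocity `a =
#' grad(phi)` is recovered at nodes by area-weighted averaging of element
#' gradients.
#'
#' @param mesh a [planar_mesh()].
#' @param S_field nodal values of the dilation rate.
#' @return list of class `potential_field` with `phi` (nodal) and `a`
#'   (N x 2 nodal velocity).
#' @export
solve_potential <- function(mesh, S_field) {
  stopifnot(inherits(mesh, "planar_mesh"),
            length(S_field) == nrow(mesh$x))
  fem <- fem_assemble(mesh$x, mesh$tri)
  n <- nrow(mesh$x)
  bnd <- mesh$boundary
  int <- setdiff(seq_len(n), bnd)
  phi <- numeric(n)
  if (length(int)) {
    rhs <- -as.numeric(fem$M %*% S_field)
    phi[int] <- as.numeric(Matrix::solve(fem$K[int, int, drop = FALSE],
                                         rhs[int]))
  }
  a <- recover_gradient(mesh$x, mesh$tri, fem, phi)
  structure(list(phi = phi, a = a), class = "potential_field")
}

# outward unit normals at boundary nodes (angle-bisector of adjacent edges)
boundary_normals <- function(mesh) {
  bnd <- mesh$boundary
  P <- mesh$x[bnd, , drop = FALSE]
  nb <- nrow(P)
  nxt <- c(2:nb, 1); prv <- c(nb, 1:(nb - 1))
  # edge tangents; boundary loop is CCW, outward normal is (ty, -tx)
  t1 <- P - P[prv, , drop = FALSE]
  t2 <- P[nxt, , drop = FALSE] - P
  n1 <- cbind(t1[, 2], -t1[, 1])
  n2 <- cbind(t2[, 2], -t2[, 1])
  nrm <- n1 / sqrt(rowSums(n1^2)) + n2 / sqrt(rowSums(n2^2))
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

# vectorized growth / kinetics over an N x m state matrix
growth_rate_field <- function(law, t, U) {
  p <- law$params
  switch(law$form,
    constant = rep(p$s0, nrow(U)),
    prescribed_time = rep(as.numeric(law$fn(t)), nrow(U)),
    linear = p$s0 + p$sigma * U[, 1],
    thresholded_tanh = p$s0 * (1 + tanh(p$k_th * (U[, 1] - p$u_th))),
    quadratic_ratio = p$s0 * ((U[, 1] / p$u_ref)^2 - 1),
    difference = p$r * (U[, 1] - p$alpha * U[, 2]),
    custom = {
      if (isTRUE(law$vectorized)) as.numeric(law$fn(t, t(U)))
      else vapply(seq_len(nrow(U)),
                  function(i) evaluate_growth(law, t, U[i, ]), numeric(1))
    })
}

kinetics_field <- function(spec, U) {
  p <- spec$params
  switch(spec$name,
    schnakenberg = cbind(p$a - U[, 1] + U[, 1]^2 * U[, 2],
                         p$b - U[, 1]^2 * U[, 2]),
    gierer_meinhardt = cbind(p$a + U[, 1]^2 / U[, 2] - p$b * U[, 1],
                             U[, 1]^2 - p$c * U[, 2]),
    fitzhugh_nagumo = cbind(p$c * (U[, 1] - U[, 1]^3 / 3 + U[, 2] - p$i0),
                            (p$a - U[, 1] - p$b * U[, 2]) / p$c),
    logistic = cbind(U[, 1] * (1 - U[, 1])),
    bistable = cbind(U[, 1] * (1 - U[, 1]^2)),
    custom = {
      if (isTRUE(spec$vectorized)) t(spec$f(t(U)))
      else matrix(t(vapply(seq_len(nrow(U)),
                           function(i) evaluate_kinetics(spec, U[i, ]),
                           numeric(spec$n_species))),
                  nrow = nrow(U))
    })
}

#' One step of the 2D moving-mesh splitting
#'
#' Operator splitting: (i) solve the potential-flow Poisson problem for
#' `phi` and `a = grad(phi)` on the current geometry; (ii) advect the
#' mesh, with boundary-node velocities projected onto the outward normal
#' (the continuous flow is normal at the boundary; projection suppresses
#' discrete tangential drift), halving `dt` if any element would invert;
#' (iii) apply dilution conservatively by rescaling nodal values with the
#' lumped-mass ratio (exactly mass-conserving for vanishing kinetics);
#' (iv) a Strang sandwich of pointwise reaction (RK4 substeps, `dt/2`),
#' theta-method diffusion on the moved mesh with natural Neumann data
#' (`dt`), and reaction again (`dt/2`). The mesh motion couples at first
#' order; on a static domain with `theta = 0.5` the scheme is second
#' order in `dt`, and factorizations are cached across steps.
#'
#' @param mesh a [planar_mesh()].
#' @param u N x m matrix of nodal concentrations.
#' @param spec a [kinetics_spec()].
#' @param law a [growth_law()].
#' @param D diffusivities (length m).
#' @param dt requested time step; the step actually taken (possibly
#'   halved, and capped at `cfl * h / max|a|`) is returned.
#' @param t current time.
#' @param cfl mesh-motion CFL factor (default 0.2).
#' @param reaction_dt_max substep cap for the RK4 reaction update.
#' @param max_halvings element-inversion retries before aborting.
#' @param theta implicitness of the diffusion solve: 1 (default) is
#'   backward Euler (robustly damped, like the stiff BDF the problem
#'   calls for), 0.5 is Crank-Nicolson (second order on a static domain,
#'   but undamped for sharp transients at large `dt`).
#' @return list with `mesh`, `u`, `dt_used`, `phi`, `a`.
#' @export
advance_2d <- function(mesh, u, spec, law, D, dt, t = 0, cfl = 0.2,
                       reaction_dt_max = 0.25, max_halvings = 20,
                       theta = 1) {
  stopifnot(inherits(mesh, "planar_mesh"))
  u <- as.matrix(u)
  m <- ncol(u)
  stopifnot(length(D) == m, nrow(u) == nrow(mesh$x))
  S <- growth_rate_field(law, t, u)
  n <- nrow(mesh$x)
  if (all(S == 0)) {
    pot <- structure(list(phi = numeric(n), a = matrix(0, n, 2)),
                     class = "potential_field")
    a <- pot$a
    moved <- FALSE
  } else {
    pot <- solve_potential(mesh, S)
    a <- pot$a
    bnd <- mesh$boundary
    nrm <- boundary_normals(mesh)
    an <- rowSums(a[bnd, , drop = FALSE] * nrm)
    a[bnd, ] <- nrm * an
    amax <- max(sqrt(rowSums(a^2)))
    if (amax > 0) dt <- min(dt, cfl * mesh$h / amax)
    moved <- amax > 0
  }

  if (moved) {
    fem_old <- fem_assemble(mesh$x, mesh$tri)
    for (halv in 0:max_halvings) {
      xnew <- mesh$x + dt * a
      if (all(triangle_areas(xnew, mesh$tri) > 0)) break
      if (halv == max_halvings)
        stop("advance_2d: element inversion persists after ", max_halvings,
             " halvings at t = ", t)
      dt <- dt / 2
    }
    mesh$x <- xnew
    fem <- fem_assemble(mesh$x, mesh$tri)
    # conservative dilution: nodal mass is preserved under the mesh motion
    u <- u * (fem_old$ml / fem$ml)
  } else {
    fem <- fem_assemble(mesh$x, mesh$tri)
  }

  react <- function(u, tau) {
    nsub <- max(1L, ceiling(tau / reaction_dt_max))
    hdt <- tau / nsub
    for (k in seq_len(nsub)) {
      k1 <- kinetics_field(spec, u)
      k2 <- kinetics_field(spec, u + hdt / 2 * k1)
      k3 <- kinetics_field(spec, u + hdt / 2 * k2)
      k4 <- kinetics_field(spec, u + hdt * k3)
      u <- u + hdt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    u
  }

  # Strang sandwich: reaction / theta-method diffusion / reaction
  u <- react(u, dt / 2)
  for (s in seq_len(m)) {
    if (D[s] == 0) next
    rhs <- fem$ml * u[, s] / dt -
      (1 - theta) * D[s] * as.numeric(fem$K %*% u[, s])
    u[, s] <- solve_diffusion_cached(fem, theta * D[s], dt, rhs, mesh,
                                     moved)
  }
  u <- react(u, dt / 2)
  if (any(!is.finite(u)))
    stop("advance_2d: non-finite concentrations at t = ", t + dt)
  list(mesh = mesh, u = u, dt_used = dt, phi = pot$phi, a = a)
}

# Cholesky factors of (M/dt + D/2 K) are reused while the mesh is static
.diff_cache <- new.env(parent = emptyenv())
solve_diffusion_cached <- function(fem, Ds, dt, rhs, mesh, moved) {
  key <- paste(nrow(mesh$x), signif(dt, 15), signif(Ds, 15),
               signif(sum(mesh$x), 15), sep = "|")
  fac <- if (!moved) .diff_cache[[key]] else NULL
  if (is.null(fac)) {
    A <- Matrix::Diagonal(x = fem$ml / dt) + Ds * fem$K
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(A))
    if (!moved) {
      rm(list = ls(.diff_cache), envir = .diff_cache)  # keep it tiny
      .diff_cache[[key]] <- fac
    }
  }
  as.numeric(Matrix::solve(fac, rhs))
}

# minimum element quality 2 * inradius / circumradius (1 for equilateral)
mesh_quality <- function(mesh) {
  tri <- mesh$tri; x <- mesh$x
  a <- sqrt(rowSums((x[tri[, 2], ] - x[tri[, 3], ])^2))
  b <- sqrt(rowSums((x[tri[, 1], ] - x[tri[, 3], ])^2))
  cc <- sqrt(rowSums((x[tri[, 1], ] - x[tri[, 2], ])^2))
  s <- (a + b + cc) / 2
  A <- pmax(triangle_areas(x, tri), 0)
  inr <- A / s
  circ <- a * b * cc / (4 * pmax(A, .Machine$double.xmin))
  min(2 * inr / circ)
}

#' Re-triangulate the current domain
#'
#' The current Eulerian boundary polyline is refined (midpoint insertion on
#' edges longer than `1.5 h`) and coarsened (removal of nearly collinear
#' vertices on edges shorter than `0.45 h`), re-triangulated at the target
#' `h`, and the fields transferred by barycentric interpolation. The new
#' mesh's reference configuration is the current geometry (`mu` resets
#' to 1). A self-intersecting boundary (possible under strong contraction)
#' is reported as an error, not repaired.
#'
#' @param mesh a [planar_mesh()].
#' @param u N x m matrix of nodal fields.
#' @return list with the new `mesh` and interpolated `u`.
#' @export
remesh_2d <- function(mesh, u) {
  stopifnot(inherits(mesh, "planar_mesh"))
  u <- as.matrix(u)
  h <- mesh$h
  poly <- mesh$x[mesh$boundary, , drop = FALSE]
  if (boundary_self_intersects(poly))
    stop("remesh_2d: boundary polyline self-intersects (domain contact)")
  poly <- resample_boundary(poly, h)
  newmesh <- mesh_from_boundary(poly, h)
  unew <- interp_p1(mesh, u, newmesh$X)
  list(mesh = newmesh, u = unew)
}

# Arc-length resampling of a closed boundary polyline with a local-
# feature-size-aware target spacing: near-touching boundary parts (e.g.
# the dumbbell channel walls) keep a spacing tied to their separation so
# thin features stay resolved, everywhere else the spacing is the target
# h. New vertices lie on the old polyline, so the enclosed area changes
# only by corner-cut terms of order (spacing^2 * turning angle).
resample_boundary <- function(poly, h) {
  nb <- nrow(poly)
  nxt <- c(2:nb, 1)
  seglen <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2))
  # local feature size at each vertex: distance to boundary parts that are
  # far away *along* the boundary (arc-length exclusion, so fine local
  # spacing does not masquerade as a nearby opposite wall)
  P <- sum(seglen)
  arc <- c(0, cumsum(seglen))[seq_len(nb)]
  lfs <- rep(Inf, nb)
  for (i in seq_len(nb)) {
    darc <- abs(arc - arc[i])
    darc <- pmin(darc, P - darc)
    far <- darc > max(1.5 * h, 3 * seglen[i])
    if (!any(far)) next
    lfs[i] <- sqrt(min((poly[far, 1] - poly[i, 1])^2 +
                         (poly[far, 2] - poly[i, 2])^2))
  }
  target <- pmin(h, pmax(0.8 * lfs, 0.15 * h))
  # walk the polyline accumulating arc length in units of the local target
  cum <- c(0, cumsum(seglen))
  total_units <- sum(seglen / target)
  n_new <- max(16L, round(total_units))
  unit_pos <- cumsum(c(0, seglen / target))
  want <- seq(0, total_units, length.out = n_new + 1)[-(n_new + 1)]
  out <- matrix(0, n_new, 2)
  for (k in seq_len(n_new)) {
    i <- findInterval(want[k], unit_pos, rightmost.closed = TRUE)
    i <- min(i, nb)
    frac <- (want[k] - unit_pos[i]) / (seglen[i] / target[i])
    out[k, ] <- poly[i, ] + frac * (poly[nxt[i], ] - poly[i, ])
  }
  out[!duplicated(round(out, 12)), , drop = FALSE]
}

# barycentric interpolation from (mesh$x, u) onto query points, with a
# background grid for point location and nearest-node fallback
interp_p1 <- function(mesh, u, pts) {
  tri <- mesh$tri; x <- mesh$x
  nt <- nrow(tri)
  p1 <- x[tri[, 1], , drop = FALSE]
  p2 <- x[tri[, 2], , drop = FALSE]
  p3 <- x[tri[, 3], , drop = FALSE]
  xmin <- pmin(p1[, 1], p2[, 1], p3[, 1]); xmax <- pmax(p1[, 1], p2[, 1], p3[, 1])
  ymin <- pmin(p1[, 2], p2[, 2], p3[, 2]); ymax <- pmax(p1[, 2], p2[, 2], p3[, 2])
  cell <- max(xmax - xmin, ymax - ymin, 1e-12)
  ox <- min(xmin); oy <- min(ymin)
  keyf <- function(cx, cy) paste(cx, cy, sep = ",")
  buckets <- new.env(parent = emptyenv())
  for (t in seq_len(nt)) {
    for (cx in floor((xmin[t] - ox) / cell):floor((xmax[t] - ox) / cell))
      for (cy in floor((ymin[t] - oy) / cell):floor((ymax[t] - oy) / cell)) {
        k <- keyf(cx, cy)
        buckets[[k]] <- c(buckets[[k]], t)
      }
  }
  npt <- nrow(pts)
  out <- matrix(NA_real_, npt, ncol(u))
  detT <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  for (i in seq_len(npt)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    cand <- buckets[[keyf(floor((px - ox) / cell), floor((py - oy) / cell))]]
    hit <- FALSE
    for (t in cand) {
      l1 <- ((p2[t, 1] - px) * (p3[t, 2] - py) -
               (p2[t, 2] - py) * (p3[t, 1] - px)) / detT[t]
      l2 <- ((p3[t, 1] - px) * (p1[t, 2] - py) -
               (p3[t, 2] - py) * (p1[t, 1] - px)) / detT[t]
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        out[i, ] <- l1 * u[tri[t, 1], ] + l2 * u[tri[t, 2], ] +
          l3 * u[tri[t, 3], ]
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      j <- which.min((x[, 1] - px)^2 + (x[, 2] - py)^2)
      out[i, ] <- u[j, ]
    }
  }
  out
}

#' Discrete boundary-shape summary
#'
#' Discrete curvature at each boundary vertex is the exterior turning angle
#' divided by the average of the adjacent edge lengths; also reports
#' perimeter, enclosed area and the isoperimetric ratio `P^2 / (4 pi A)`
#' (1 for a circle, `>= 1` always).
#'
#' @param mesh a [planar_mesh()] (or a 2-column matrix taken as the
#'   boundary polyline).
#' @param resample if `TRUE` (default), resample the polyline to uniform
#'   arc-length spacing (same vertex count) before measuring turning
#'   angles: between remeshes the Lagrangian boundary vertices cluster
#'   tangentially, which inflates the raw vertex-wise curvature spread
#'   with discretization noise. Perimeter and area always use the raw
#'   polyline.
#' @return list with `mean_curvature`, `sd_curvature`, `perimeter`,
#'   `area`, `isoperimetric_ratio`.
#' @export
boundary_curvature_stats <- function(mesh, resample = TRUE) {
  poly_raw <- if (inherits(mesh, "planar_mesh"))
    mesh$x[mesh$boundary, , drop = FALSE] else as.matrix(mesh)
  nb0 <- nrow(poly_raw)
  if (nb0 < 4) stop("need at least 4 boundary vertices")
  poly <- if (resample) uniform_arc_resample(poly_raw) else poly_raw
  nb <- nrow(poly)
  nxt <- c(2:nb, 1); prv <- c(nb, 1:(nb - 1))
  e1 <- poly - poly[prv, , drop = FALSE]
  e2 <- poly[nxt, , drop = FALSE] - poly
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  ang <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1],
               rowSums(e1 * e2))
  kappa <- ang / ((l1 + l2) / 2)
  nxt0 <- c(2:nb0, 1)
  P <- sum(sqrt(rowSums((poly_raw[nxt0, , drop = FALSE] - poly_raw)^2)))
  A <- abs(polygon_area(poly_raw))
  list(mean_curvature = mean(kappa), sd_curvature = stats::sd(kappa),
       perimeter = P, area = A,
       isoperimetric_ratio = P^2 / (4 * pi * A))
}

# same-count uniform arc-length resampling of a closed polyline, anchored
# at the first vertex
uniform_arc_resample <- function(poly) {
  nb <- nrow(poly)
  nxt <- c(2:nb, 1)
  seglen <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2))
  P <- sum(seglen)
  cum <- c(0, cumsum(seglen))
  want <- seq(0, P, length.out = nb + 1)[-(nb + 1)]
  out <- matrix(0, nb, 2)
  for (k in seq_len(nb)) {
    i <- findInterval(want[k], cum, rightmost.closed = TRUE)
    i <- min(i, nb)
    frac <- if (seglen[i] > 0) (want[k] - cum[i]) / seglen[i] else 0
    out[k, ] <- poly[i, ] + frac * (poly[nxt[i], ] - poly[i, ])
  }
  out
}

#' Run a full 2D moving-mesh simulation
#'
#' Epoch loop of [advance_2d()] with quality-triggered [remesh_2d()]
#' (minimum element quality below `quality_min`, or mean boundary-edge
#' drift beyond twice the target `h`). Snapshots (mesh, fields, boundary
#' polyline, area) are recorded at the sampled times.
#'
#' @param config list with fields `kinetics`, `growth`, `D`, `domain`
#'   (a [domain_spec_2d()]), `ic` (an [ic_spec()] or a function
#'   `f(x, y)` returning the initial fields), `t_final`, `dt`, and
#'   optionally `snapshot_times`, `quality_min` (default 0.3), `cfl`,
#'   `seed`.
#' @return object of class `sim_result_2d` with `times`, `snapshots`
#'   (each `(t, mesh, u, boundary, area)`), `area` (data.frame `t`,
#'   `area`), `config`.
#' @export
run_simulation_2d <- function(config) {
  cfg <- config
  for (f in c("kinetics", "growth", "D", "domain", "ic", "t_final", "dt"))
    if (is.null(cfg[[f]])) stop("config is missing field '", f, "'")
  qmin <- cfg$quality_min %||% 0.3
  cfl <- cfg$cfl %||% 0.2
  mesh <- generate_domain(cfg$domain)
  m <- cfg$kinetics$n_species
  u <- init_fields_2d(cfg, mesh, m)
  snaps_req <- sort(unique(c(cfg$snapshot_times %||% numeric(),
                             cfg$t_final)))
  snaps_req <- snaps_req[snaps_req > 0]
  take_snap <- function(t, mesh, u) list(
    t = t, mesh = mesh, u = u,
    boundary = mesh$x[mesh$boundary, , drop = FALSE],
    area = mesh_area(mesh))
  snapshots <- list(take_snap(0, mesh, u))
  area_t <- c(0); area_v <- c(mesh_area(mesh))
  t <- 0
  isnap <- 1
  while (t < cfg$t_final - 1e-12) {
    dt <- min(cfg$dt, cfg$t_final - t)
    if (isnap <= length(snaps_req)) dt <- min(dt, snaps_req[isnap] - t)
    step <- advance_2d(mesh, u, cfg$kinetics, cfg$growth, cfg$D, dt,
                       t = t, cfl = cfl, theta = cfg$theta %||% 1)
    mesh <- step$mesh; u <- step$u; t <- t + step$dt_used
    area_t <- c(area_t, t); area_v <- c(area_v, mesh_area(mesh))
    while (isnap <= length(snaps_req) && t >= snaps_req[isnap] - 1e-9) {
      snapshots[[length(snapshots) + 1]] <- take_snap(t, mesh, u)
      isnap <- isnap + 1
    }
    bedges <- diff(rbind(mesh$x[mesh$boundary, , drop = FALSE],
                         mesh$x[mesh$boundary[1], , drop = FALSE]))
    elen <- sqrt(rowSums(bedges^2))
    if (mesh_quality(mesh) < qmin || mean(elen) > 2 * mesh$h) {
      rm2 <- remesh_2d(mesh, u)
      mesh <- rm2$mesh; u <- rm2$u
    }
  }
  structure(list(times = vapply(snapshots, `[[`, numeric(1), "t"),
                 snapshots = snapshots,
                 area = data.frame(t = area_t, area = area_v),
                 config = cfg),
            class = "sim_result_2d")
}

#' @export
print.sim_result_2d <- function(x, ...) {
  n <- nrow(x$area)
  cat("<sim_result_2d> ", length(x$snapshots), " snapshots, t in [0, ",
      signif(x$area$t[n], 6), "], area: ", signif(x$area$area[1], 6),
      " -> ", signif(x$area$area[n], 6), "\n", sep = "")
  invisible(x)
}

init_fields_2d <- function(cfg, mesh, m) {
  ic <- cfg$ic
  n <- nrow(mesh$X)
  if (is.function(ic)) {
    u <- ic(mesh$X[, 1], mesh$X[, 2])
    if (is.null(dim(u))) u <- matrix(u, ncol = 1)
    return(as.matrix(u))
  }
  stopifnot(inherits(ic, "ic_spec"))
  if (ic$mode != "noisy_equilibrium")
    stop("2D initial conditions: use a function ic(x, y) or ",
         "noisy_equilibrium")
  ustar <- cfg$equilibrium %||% find_equilibria(cfg$kinetics)[[1]]$u_star
  u <- matrix(0, n, m)
  for (s in seq_len(m)) {
    eta <- sqrt(ic$noise_variance) * counter_normals_cpp(ic$seed, s, n)
    u[, s] <- ustar[s] * (1 + eta)
  }
  u
}
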