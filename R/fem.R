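# Finite-element acoustics: scattering of a plane wave by a thin-shelled ear
# cavity inside a spherical air domain.
#
# Frequency domain: Helmholtz equation (1/rho)(Lap p + k^2 p) = 0 with a
# second-order spherical radiation condition on the outer sphere,
#   n.grad p + (ik + 1/R) p - R/(2(ikR+1)) Lap_t p  =  (same applied to p_inc),
# so the incident plane wave enters through the boundary data and the
# scattered field leaves without reflection. Cavity walls are either rigid
# (natural boundary condition across duplicated nodes) or locally-reacting
# thin shells with per-area mass rho_s*t and a bending-derived stiffness,
# eliminated analytically: (s - w^2 m) U = p_in - p_out.
#
# Time domain: wave equation with the first-order spherical condition and
# generalized-alpha time stepping.

# ---- reference elements ------------------------------------------------------

TET_EDGES <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
TRI_EDGES <- rbind(c(1, 2), c(1, 3), c(2, 3))
DL3 <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
DL2 <- rbind(c(-1, -1), c(1, 0), c(0, 1))

tet_shape <- function(lam, order) {
  if (order == 1) return(lam)
  v <- lam * (2 * lam - 1)
  e <- 4 * lam[TET_EDGES[, 1]] * lam[TET_EDGES[, 2]]
  c(v, e)
}

tet_shape_grad <- function(lam, order) {
  if (order == 1) return(DL3)
  g <- matrix(0, 10, 3)
  for (i in 1:4) g[i, ] <- (4 * lam[i] - 1) * DL3[i, ]
  for (k in 1:6) {
    a <- TET_EDGES[k, 1]; b <- TET_EDGES[k, 2]
    g[4 + k, ] <- 4 * (lam[a] * DL3[b, ] + lam[b] * DL3[a, ])
  }
  g
}

tri_shape <- function(lam, order) {
  if (order == 1) return(lam)
  v <- lam * (2 * lam - 1)
  e <- 4 * lam[TRI_EDGES[, 1]] * lam[TRI_EDGES[, 2]]
  c(v, e)
}

tri_shape_grad <- function(lam, order) {
  if (order == 1) return(DL2)
  g <- matrix(0, 6, 2)
  for (i in 1:3) g[i, ] <- (4 * lam[i] - 1) * DL2[i, ]
  for (k in 1:3) {
    a <- TRI_EDGES[k, 1]; b <- TRI_EDGES[k, 2]
    g[3 + k, ] <- 4 * (lam[a] * DL2[b, ] + lam[b] * DL2[a, ])
  }
  g
}

lam_from_xi3 <- function(xi) c(1 - sum(xi), xi)
lam_from_xi2 <- function(xi) c(1 - sum(xi), xi)

# reference mass matrices (exact via degree-5 conical quadrature)
ref_mass_tet <- function(order) {
  q <- tet_quadrature(3)
  nb <- if (order == 1) 4 else 10
  M <- matrix(0, nb, nb)
  for (i in seq_along(q$weights)) {
    N <- tet_shape(lam_from_xi3(q$points[i, ]), order)
    M <- M + q$weights[i] * tcrossprod(N)
  }
  M   # integrates to reference volume 1/6 for sum of all entries
}

ref_mass_tri <- function(order) {
  q <- tri_quadrature(3)
  nb <- if (order == 1) 3 else 6
  M <- matrix(0, nb, nb)
  for (i in seq_along(q$weights)) {
    N <- tri_shape(lam_from_xi2(q$points[i, ]), order)
    M <- M + q$weights[i] * tcrossprod(N)
  }
  M
}

# ---- dof numbering -----------------------------------------------------------

# P2 dofs = vertex nodes followed by unique-edge midpoints
fem_dofs <- function(mesh, order) {
  nv <- nrow(mesh$nodes)
  if (order == 1) {
    return(list(order = 1, n = nv, coords = mesh$nodes, tet = mesh$tets,
                edge_of = NULL))
  }
  tets <- mesh$tets
  e_all <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  lo <- pmin(e_all[, 1], e_all[, 2]); hi <- pmax(e_all[, 1], e_all[, 2])
  key <- (lo - 1) * nv + hi
  uk <- !duplicated(key)
  edge_id <- match(key, key[uk])
  n_edge <- sum(uk)
  mids <- (mesh$nodes[lo[uk], , drop = FALSE] + mesh$nodes[hi[uk], , drop = FALSE]) / 2
  m <- nrow(tets)
  tet10 <- cbind(tets, matrix(nv + edge_id, m, 6))
  edge_env <- list(key = key[uk], id = seq_len(n_edge))
  list(order = 2, n = nv + n_edge, coords = rbind(mesh$nodes, mids),
       tet = tet10, edge_key = key[uk], nv = nv)
}

edge_dof_lookup <- function(dofs, a, b) {
  key <- (pmin(a, b) - 1) * dofs$nv + pmax(a, b)
  dofs$nv + match(key, dofs$edge_key)
}

tri_dof_rows <- function(dofs, tris) {
  if (dofs$order == 1) return(tris)
  cbind(tris,
        edge_dof_lookup(dofs, tris[, 1], tris[, 2]),
        edge_dof_lookup(dofs, tris[, 1], tris[, 3]),
        edge_dof_lookup(dofs, tris[, 2], tris[, 3]))
}

# vectorised 3x3 inverses; input columns e1,e2,e3 as m x 9 (column-major J)
inv3 <- function(J) {
  a <- J[, 1]; b <- J[, 4]; cc <- J[, 7]
  d <- J[, 2]; e <- J[, 5]; f <- J[, 8]
  g <- J[, 3]; h <- J[, 6]; i <- J[, 9]
  det <- a * (e * i - f * h) - b * (d * i - f * g) + cc * (d * h - e * g)
  inv <- cbind(
    (e * i - f * h), -(d * i - f * g), (d * h - e * g),
    -(b * i - cc * h), (a * i - cc * g), -(a * h - b * g),
    (b * f - cc * e), -(a * f - cc * d), (a * e - b * d)
  )
  # inv is the classical adjugate transposed layout: entries of J^-1 in
  # row-major order (r11, r21, r31, r12, ...) after division
  inv <- inv / det
  list(inv = inv, det = det)
}

# ---- assembly ----------------------------------------------------------------

assemble_volume <- function(mesh, dofs) {
  order <- dofs$order
  nb <- if (order == 1) 4 else 10
  tets <- mesh$tets
  m <- nrow(tets)
  p1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  # J stored as m x 9, columns (e1x,e1y,e1z, e2x,..., e3z): column-major J
  J <- cbind(mesh$nodes[tets[, 2], , drop = FALSE] - p1,
             mesh$nodes[tets[, 3], , drop = FALSE] - p1,
             mesh$nodes[tets[, 4], , drop = FALSE] - p1)
  inv <- inv3(J)
  detJ <- abs(inv$det)
  IJ <- inv$inv   # entries r_{ij} = (J^-1)_{ij}, layout r11,r21,r31,r12,...

  Mref <- ref_mass_tet(order)
  rows <- dofs$tet[, rep(seq_len(nb), times = nb)]
  cols <- dofs$tet[, rep(seq_len(nb), each = nb)]
  Mvals <- outer(detJ, as.vector(Mref))
  Mmat <- Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                               x = as.vector(Mvals), dims = c(dofs$n, dofs$n))

  q <- tet_quadrature(if (order == 1) 1 else 2)
  Kacc <- matrix(0, m, nb * nb)
  for (iq in seq_along(q$weights)) {
    lam <- lam_from_xi3(q$points[iq, ])
    G <- tet_shape_grad(lam, order)      # nb x 3 (ref gradients)
    # physical gradients: B[a, i] = sum_r IJ[r,i] * G[a,r]
    B <- vector("list", nb)
    for (a in seq_len(nb)) {
      B[[a]] <- cbind(
        IJ[, 1] * G[a, 1] + IJ[, 2] * G[a, 2] + IJ[, 3] * G[a, 3],
        IJ[, 4] * G[a, 1] + IJ[, 5] * G[a, 2] + IJ[, 6] * G[a, 3],
        IJ[, 7] * G[a, 1] + IJ[, 8] * G[a, 2] + IJ[, 9] * G[a, 3]
      )
    }
    w <- q$weights[iq] * detJ
    for (a in seq_len(nb)) {
      for (b in seq_len(a)) {
        v <- w * rowSums(B[[a]] * B[[b]])
        Kacc[, (b - 1) * nb + a] <- Kacc[, (b - 1) * nb + a] + v
        if (a != b) Kacc[, (a - 1) * nb + b] <- Kacc[, (a - 1) * nb + b] + v
      }
    }
  }
  Kmat <- Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                               x = as.vector(Kacc), dims = c(dofs$n, dofs$n))
  list(M = Mmat, K = Kmat, detJ = detJ, IJ = IJ)
}

assemble_surface <- function(mesh, dofs, tris, stiffness = TRUE) {
  order <- dofs$order
  nb <- if (order == 1) 3 else 6
  m <- nrow(tris)
  p1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tris[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[tris[, 3], , drop = FALSE] - p1
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  detG <- g11 * g22 - g12^2
  sq <- sqrt(pmax(detG, 0))
  trows <- tri_dof_rows(dofs, tris)
  rows <- trows[, rep(seq_len(nb), times = nb)]
  cols <- trows[, rep(seq_len(nb), each = nb)]
  Mref <- ref_mass_tri(order)
  Mvals <- outer(sq, as.vector(Mref))
  Ms <- Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                             x = as.vector(Mvals), dims = c(dofs$n, dofs$n))
  if (!stiffness) return(list(M = Ms, S = NULL, dof_rows = trows))
  # inverse metric
  i11 <- g22 / detG; i12 <- -g12 / detG; i22 <- g11 / detG
  q <- tri_quadrature(if (order == 1) 1 else 2)
  Sacc <- matrix(0, m, nb * nb)
  for (iq in seq_along(q$weights)) {
    lam <- lam_from_xi2(q$points[iq, ])
    G <- tri_shape_grad(lam, order)    # nb x 2
    w <- q$weights[iq] * sq            # reference weights sum to 1/2
    for (a in seq_len(nb)) {
      for (b in seq_len(a)) {
        v <- w * (G[a, 1] * (i11 * G[b, 1] + i12 * G[b, 2]) +
                    G[a, 2] * (i12 * G[b, 1] + i22 * G[b, 2]))
        Sacc[, (b - 1) * nb + a] <- Sacc[, (b - 1) * nb + a] + v
        if (a != b) Sacc[, (a - 1) * nb + b] <- Sacc[, (a - 1) * nb + b] + v
      }
    }
  }
  Ss <- Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                             x = as.vector(Sacc), dims = c(dofs$n, dofs$n))
  list(M = Ms, S = Ss, dof_rows = trows)
}

# ---- model descriptors -------------------------------------------------------

#' Air medium properties
#' @param sound_speed Speed of sound, m/s (default 343).
#' @param density Air density, kg/m^3 (default 1.21; enters only the
#'   shell-coupling terms since pressure ratios are density-invariant).
#' @return List of class `"air_medium"`.
#' @export
air_medium <- function(sound_speed = 343, density = 1.21) {
  stopifnot(sound_speed > 0, density > 0)
  structure(list(sound_speed = sound_speed, density = density),
            class = "air_medium")
}

#' Isotropic thin-shell material
#'
#' Shell properties of the ear cuticle/tympana. The frequency-domain solver
#' uses a locally-reacting impedance: per-area mass `density * thickness` and
#' per-area stiffness derived from the fundamental bending mode of a clamped
#' circular plate of radius `effective_radius`.
#'
#' @param youngs_modulus Pa (default 2e9).
#' @param density kg/m^3 (default 1300).
#' @param poisson_ratio Dimensionless in (0, 0.5) (default 0.3).
#' @param thickness m (default 5e-6, tympanal membrane; the rest of the ear
#'   shell uses 175e-6).
#' @param effective_radius Plate radius for the bending stiffness, m
#'   (default 1.5e-4).
#' @param stiffness_override Per-area stiffness in Pa/m; overrides the
#'   bending-derived value when given (use `Inf` for a rigid wall).
#' @return List of class `"shell_material"` with derived `mass_per_area` and
#'   `stiffness_per_area`.
#' @export
shell_material <- function(youngs_modulus = 2e9, density = 1300,
                           poisson_ratio = 0.3, thickness = 5e-6,
                           effective_radius = 1.5e-4,
                           stiffness_override = NULL) {
  stopifnot(youngs_modulus > 0, density > 0, thickness > 0,
            poisson_ratio > 0, poisson_ratio < 0.5)
  m_a <- density * thickness
  D <- youngs_modulus * thickness^3 / (12 * (1 - poisson_ratio^2))
  w1 <- 10.2158 / effective_radius^2 * sqrt(D / m_a)
  s_a <- if (is.null(stiffness_override)) m_a * w1^2 else stiffness_override
  structure(list(youngs_modulus = youngs_modulus, density = density,
                 poisson_ratio = poisson_ratio, thickness = thickness,
                 effective_radius = effective_radius,
                 mass_per_area = m_a, stiffness_per_area = s_a,
                 f_plate_hz = w1 / (2 * pi)),
            class = "shell_material")
}

#' Incident plane wave
#'
#' Unit-amplitude plane wave travelling along `direction`. By default the
#' wave travels in -z, i.e. onto the slit of a parametric ear (slit at the +z
#' pole), which corresponds to point zero; `incidence_angle` tilts the
#' direction in the x-z plane (degrees, -10..10 in the emulated protocol).
#'
#' @param amplitude Pa (default 1).
#' @param incidence_angle Degrees on the fixed plane; 0 = point zero.
#' @param direction Optional explicit unit vector (overrides the angle).
#' @return List of class `"plane_wave"`.
#' @export
plane_wave <- function(amplitude = 1, incidence_angle = 0, direction = NULL) {
  stopifnot(amplitude >= 0)
  if (is.null(direction)) {
    th <- incidence_angle * pi / 180
    direction <- c(sin(th), 0, -cos(th))
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("`direction` must be a non-zero vector.")
  structure(list(amplitude = amplitude, direction = direction / nrm,
                 incidence_angle = incidence_angle),
            class = "plane_wave")
}

# shared precomputation for both solvers
fem_setup <- function(mesh, dofs, rigid_walls) {
  if (is.null(mesh$tri$outer_sphere)) {
    abort("Mesh has no outer radiation sphere; build it with the ball/annulus/parametric constructors.")
  }
  vol <- assemble_volume(mesh, dofs)
  outer <- assemble_surface(mesh, dofs, mesh$tri$outer_sphere, stiffness = TRUE)
  outer_dofs <- sort(unique(as.integer(outer$dof_rows)))
  wall <- NULL
  pair_map <- NULL
  if (!is.null(mesh$node_pairs) && !rigid_walls) {
    wallm <- assemble_surface(mesh, dofs, mesh$tri$shell_wall_in, stiffness = FALSE)
    # in -> out dof map (vertices from node_pairs; P2 midpoints via edges)
    pair <- seq_len(dofs$n)
    pair[mesh$node_pairs[, "inside"]] <- mesh$node_pairs[, "outside"]
    if (dofs$order == 2) {
      tin <- mesh$tri$shell_wall_in
      tout <- mesh$tri$shell_wall_out
      for (ecol in seq_len(3)) {
        a_in <- tin[, TRI_EDGES[ecol, 1]]; b_in <- tin[, TRI_EDGES[ecol, 2]]
        a_out <- tout[, TRI_EDGES[ecol, 1]]; b_out <- tout[, TRI_EDGES[ecol, 2]]
        mid_in <- edge_dof_lookup(dofs, a_in, b_in)
        mid_out <- edge_dof_lookup(dofs, a_out, b_out)
        pair[mid_in] <- mid_out
      }
    }
    Mw <- wallm$M
    Tm <- Matrix::sparseMatrix(i = seq_len(dofs$n), j = pair, x = 1,
                               dims = c(dofs$n, dofs$n))
    # coupling pattern: rows in get -(Mw p_in - Mw p_out); rows out the
    # opposite, with out rows/cols reached through the pair map
    W <- -Mw + Mw %*% Matrix::t(Tm) + Tm %*% Mw - Tm %*% Mw %*% Matrix::t(Tm)
    wall <- list(W = W, pair = pair)
  }
  list(vol = vol, outer = outer, outer_dofs = outer_dofs, wall = wall)
}

# ---- linear solver -----------------------------------------------------------

# y = S %*% x for real sparse S and complex x
cmv <- function(S, x) {
  as.numeric(S %*% Re(x)) + 1i * as.numeric(S %*% Im(x))
}

# Complex sparse Helmholtz solve: BiCGSTAB preconditioned by a CHOLMOD
# Cholesky factorisation of the definite shifted operator K + k^2 M + Ms/R
# (the classic positive-shift preconditioner; the domains here span at most a
# few wavelengths, so Krylov convergence is fast). Falls back to a direct
# sparse LU of the real 2n-interleaved system if the iteration stalls.
solve_helmholtz_complex <- function(Amul, P, b, tol = 1e-8, maxit = 800) {
  n <- length(b)
  Ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(P), "CsparseMatrix"),
                         LDL = FALSE, super = TRUE)
  Pinv <- function(x) {
    as.numeric(Matrix::solve(Ch, Re(x))) + 1i * as.numeric(Matrix::solve(Ch, Im(x)))
  }
  x <- complex(length.out = n)
  r <- b - Amul(x)
  r0 <- r
  rho <- alpha <- om <- 1 + 0i
  v <- p <- complex(length.out = n)
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) return(x)
  ok <- FALSE
  for (i in seq_len(maxit)) {
    rho1 <- sum(Conj(r0) * r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / om)
    rho <- rho1
    p <- r + beta * (p - om * v)
    ph <- Pinv(p); v <- Amul(ph)
    alpha <- rho / sum(Conj(r0) * v)
    s <- r - alpha * v
    sh <- Pinv(s); t <- Amul(sh)
    om <- sum(Conj(t) * s) / sum(Conj(t) * t)
    x <- x + alpha * ph + om * sh
    r <- s - om * t
    if (sqrt(sum(Mod(r)^2)) < tol * nb) { ok <- TRUE; break }
  }
  if (!ok && sqrt(sum(Mod(b - Amul(x))^2)) > 10 * tol * nb) {
    return(NULL)   # caller falls back to direct solve
  }
  x
}

# ---- frequency domain --------------------------------------------------------

#' Solve the frequency-domain scattering problem
#'
#' Assembles and solves the Helmholtz system with the second-order spherical
#' radiation boundary condition and plane-wave incidence for each requested
#' frequency, returning the complex total pressure at every degree of
#' freedom.
#'
#' @param mesh An `ear_mesh` (e.g. [build_parametric_ear()],
#'   [build_ball_mesh()], [build_annulus_mesh()]).
#' @param air An [air_medium()].
#' @param shells `"rigid"` for immobile walls, or a [shell_material()] for the
#'   locally-reacting elastic wall model. Ignored when the mesh has no wall.
#' @param wave A [plane_wave()].
#' @param frequencies Numeric vector of frequencies, Hz.
#' @param order Element order: 2 (quadratic Lagrange, default) or 1.
#' @param check_resolution `"warn"` (default), `"error"` or `"none"`: action
#'   when the mesh violates the six-elements-per-wavelength rule at the
#'   highest frequency.
#' @return A list of class `"harmonic_sweep"`; each element is a
#'   `harmonic_solution` with the complex nodal pressure, the shell
#'   displacement (elastic walls), and solver metadata.
#' @export
solve_frequency_domain <- function(mesh, air = air_medium(), shells = "rigid",
                                   wave = plane_wave(), frequencies,
                                   order = 2,
                                   check_resolution = c("warn", "error", "none")) {
  stopifnot(inherits(mesh, "ear_mesh"), inherits(air, "air_medium"),
            inherits(wave, "plane_wave"), all(frequencies > 0))
  check_resolution <- match.arg(check_resolution)
  rigid <- identical(shells, "rigid")
  if (!rigid && !inherits(shells, "shell_material")) {
    abort('`shells` must be "rigid" or a shell_material().')
  }
  c0 <- air$sound_speed
  hx <- hmax_rule(c0, max(frequencies))
  if (mesh$h_max > hx * (1 + 1e-9) && check_resolution != "none") {
    msg <- sprintf("Mesh h_max %.3g m exceeds the six-per-wavelength limit %.3g m at %.3g kHz.",
                   mesh$h_max, hx, max(frequencies) / 1000)
    if (check_resolution == "error") abort(msg) else warn(msg)
  }
  dofs <- fem_dofs(mesh, order)
  setup <- fem_setup(mesh, dofs, rigid)
  R <- mesh$sphere_radius
  xo <- dofs$coords
  r_dof <- sqrt(rowSums(xo^2))
  ndotE <- (xo %*% wave$direction)[, 1] / pmax(r_dof, 1e-300)
  xdotE <- (xo %*% wave$direction)[, 1]
  K <- setup$vol$K; M <- setup$vol$M
  Ms <- setup$outer$M; Ss <- setup$outer$S
  sols <- lapply(frequencies, function(f) {
    k <- 2 * pi * f / c0
    c1 <- 1i * k + 1 / R
    c2 <- R / (2 * (1i * k * R + 1))
    # incident plane wave at dof locations (zero weight off the outer surface)
    pin <- wave$amplitude * exp(-1i * k * xdotE)
    v <- (c1 - 1i * k * ndotE) * pin
    b <- cmv(Ms, v) + c2 * cmv(Ss, pin)
    d_shell <- NA_complex_
    cd <- 0 + 0i
    if (!rigid && !is.null(setup$wall)) {
      w <- 2 * pi * f
      d_shell <- shells$stiffness_per_area - w^2 * shells$mass_per_area
      cd <- air$density * w^2 / d_shell
    }
    W <- if (!rigid && !is.null(setup$wall)) setup$wall$W else NULL
    Amul <- function(x) {
      out <- cmv(K, x) - k^2 * cmv(M, x) + c1 * cmv(Ms, x) + c2 * cmv(Ss, x)
      if (!is.null(W)) out <- out + cd * cmv(W, x)
      out
    }
    P <- K + k^2 * M + (1 / R) * Ms
    p <- solve_helmholtz_complex(Amul, P, b)
    if (is.null(p)) {
      # direct fallback on the interleaved real system
      Ar <- K - k^2 * M + Re(c1) * Ms + Re(c2) * Ss
      Ai <- Im(c1) * Ms + Im(c2) * Ss
      if (!is.null(W)) {
        Ar <- Ar + Re(cd) * W
        Ai <- Ai + Im(cd) * W
      }
      I2 <- Matrix::Matrix(diag(2), sparse = TRUE)
      J2 <- Matrix::Matrix(matrix(c(0, 1, -1, 0), 2), sparse = TRUE)
      Z <- methods::as(kronecker(Ar, I2) + kronecker(Ai, J2), "CsparseMatrix")
      xz <- as.numeric(Matrix::solve(Z, as.numeric(rbind(Re(b), Im(b)))))
      p <- complex(real = xz[c(TRUE, FALSE)], imaginary = xz[c(FALSE, TRUE)])
    }
    U <- NULL
    if (!rigid && !is.null(setup$wall)) {
      ins <- mesh$node_pairs[, "inside"]
      U <- (p[ins] - p[setup$wall$pair[ins]]) / d_shell
    }
    structure(list(frequency = f, pressure = p, shell_displacement = U,
                   dof_coords = dofs$coords, order = order, mesh = mesh,
                   wave = wave, air = air),
              class = "harmonic_solution")
  })
  structure(sols, class = "harmonic_sweep")
}

#' @export
print.harmonic_solution <- function(x, ...) {
  cat(sprintf("<harmonic_solution: f = %.4g kHz, %d dofs, max |p| = %.4g Pa>\n",
              x$frequency / 1000, length(x$pressure), max(Mod(x$pressure))))
  invisible(x)
}

#' @export
print.harmonic_sweep <- function(x, ...) {
  cat(sprintf("<harmonic_sweep: %d frequencies, %.4g - %.4g kHz>\n",
              length(x), x[[1]]$frequency / 1000, x[[length(x)]]$frequency / 1000))
  invisible(x)
}

# ---- probing -----------------------------------------------------------------

locate_point <- function(mesh, dofs, point) {
  tets <- mesh$tets
  p1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  J <- cbind(mesh$nodes[tets[, 2], , drop = FALSE] - p1,
             mesh$nodes[tets[, 3], , drop = FALSE] - p1,
             mesh$nodes[tets[, 4], , drop = FALSE] - p1)
  inv <- inv3(J)
  IJ <- inv$inv
  dx <- -sweep(p1, 2, point)   # point - p1
  l2 <- IJ[, 1] * dx[, 1] + IJ[, 4] * dx[, 2] + IJ[, 7] * dx[, 3]
  l3 <- IJ[, 2] * dx[, 1] + IJ[, 5] * dx[, 2] + IJ[, 8] * dx[, 3]
  l4 <- IJ[, 3] * dx[, 1] + IJ[, 6] * dx[, 2] + IJ[, 9] * dx[, 3]
  l1 <- 1 - l2 - l3 - l4
  minl <- pmin(l1, l2, l3, l4)
  i <- which.max(minl)
  if (minl[i] < -1e-6) abort("Probe point lies outside the mesh.")
  lam <- c(l1[i], l2[i], l3[i], l4[i])
  N <- tet_shape(lam, dofs$order)
  list(tet = i, lambda = lam, dof_ids = dofs$tet[i, ], shape = N)
}

#' Interpolate pressure at a probe point
#'
#' Element-interpolated pressure at an interior point: a complex amplitude per
#' frequency for harmonic solutions/sweeps, or a [trace()] for time-domain
#' solutions (where the point must be one of the probes requested at solve
#' time).
#'
#' @param solution A `harmonic_solution`, `harmonic_sweep` or `time_solution`.
#' @param point Numeric xyz coordinates, m.
#' @return Complex scalar, a tibble (`frequency`, `pressure`, `magnitude`) for
#'   sweeps, or a [trace()] for time solutions.
#' @export
probe_pressure <- function(solution, point) {
  if (inherits(solution, "harmonic_sweep")) {
    s1 <- solution[[1]]
    dofs <- fem_dofs(s1$mesh, s1$order)
    loc <- locate_point(s1$mesh, dofs, point)
    vals <- vapply(solution, function(s) {
      sum(s$pressure[loc$dof_ids] * loc$shape)
    }, complex(1))
    return(tibble(frequency = vapply(solution, function(s) s$frequency, numeric(1)),
                  pressure = vals, magnitude = Mod(vals)))
  }
  if (inherits(solution, "harmonic_solution")) {
    dofs <- fem_dofs(solution$mesh, solution$order)
    loc <- locate_point(solution$mesh, dofs, point)
    return(sum(solution$pressure[loc$dof_ids] * loc$shape))
  }
  if (inherits(solution, "time_solution")) {
    d2 <- colSums((t(solution$probe_points) - point)^2)
    i <- which.min(d2)
    if (d2[i] > (1e-6)^2) {
      abort("Point was not among the probes requested from solve_time_domain().")
    }
    return(trace(solution$probe_pressure[i, ], 1 / solution$dt, unit = "Pa"))
  }
  abort("Unsupported solution object.")
}

#' Cavity gain in decibels
#'
#' Gain of the cavity interior over the exterior reference:
#' `20 log10(|p_inside| / |p_outside|)`.
#'
#' @param p_inside,p_outside Pressures (complex or magnitudes); `p_outside`
#'   must be non-zero.
#' @return Gain in dB.
#' @export
cavity_gain_db <- function(p_inside, p_outside) {
  if (any(Mod(p_outside) == 0)) abort("`p_outside` must be non-zero.")
  20 * log10(Mod(p_inside) / Mod(p_outside))
}

# ---- time domain -------------------------------------------------------------

#' Solve the time-domain scattering problem
#'
#' Integrates the acoustic wave equation with a first-order spherical
#' radiation condition and a gated sinusoidal incident plane wave, using the
#' generalized-alpha method (spectral radius `rho_inf`) with a constant time
#' step. Cavity walls are treated as rigid.
#'
#' @param mesh An `ear_mesh`.
#' @param air An [air_medium()].
#' @param wave A [plane_wave()].
#' @param f0 Incident tone frequency, Hz.
#' @param duration Simulated time, s.
#' @param dt Time step, s; default `1/(60 * 150e3)` which gives CFL = 0.1
#'   under the six-per-wavelength mesh rule at 150 kHz.
#' @param order Element order (default 1; quadratic also supported).
#' @param probe_points Matrix (n x 3) of probe coordinates whose pressure time
#'   series are recorded.
#' @param rho_inf Generalized-alpha spectral radius (default 0.75).
#' @param ramp_cycles Smooth turn-on ramp of the incident tone, in cycles
#'   (default 1).
#' @return A list of class `"time_solution"`: `times`, `probe_pressure`
#'   (probes x steps), `probe_points`, `dt`, `f0`, and the final pressure
#'   field `final_field`.
#' @export
solve_time_domain <- function(mesh, air = air_medium(), wave = plane_wave(),
                              f0, duration, dt = 1 / (60 * 150e3), order = 1,
                              probe_points, rho_inf = 0.75, ramp_cycles = 1) {
  stopifnot(inherits(mesh, "ear_mesh"), f0 > 0, duration > 0, dt > 0)
  if (is.null(dim(probe_points))) probe_points <- matrix(probe_points, nrow = 1)
  c0 <- air$sound_speed
  cfl <- cfl_number(c0, dt, mesh$h_max)
  if (cfl > 0.1 + 1e-6) {
    warn(sprintf("CFL = %.3g exceeds the 0.1 accuracy target.", cfl))
  }
  dofs <- fem_dofs(mesh, order)
  setup <- fem_setup(mesh, dofs, rigid_walls = TRUE)
  R <- mesh$sphere_radius
  Mbar <- setup$vol$M / c0^2
  C <- setup$outer$M / c0
  Ktot <- setup$vol$K + setup$outer$M / R
  # generalized-alpha (second-order systems)
  am <- (2 * rho_inf - 1) / (rho_inf + 1)
  af <- rho_inf / (rho_inf + 1)
  gam <- 0.5 - am + af
  bet <- 0.25 * (1 - am + af)^2
  Aeff <- (1 - am) * Mbar + (1 - af) * gam * dt * C + (1 - af) * bet * dt^2 * Ktot
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Aeff), "CsparseMatrix"),
                          LDL = FALSE, super = TRUE)
  n <- dofs$n
  nt <- floor(duration / dt)
  xo <- dofs$coords
  xdotE <- (xo %*% wave$direction)[, 1]
  r_dof <- sqrt(rowSums(xo^2))
  ndotE <- xdotE / pmax(r_dof, 1e-300)
  outer_d <- setup$outer_dofs
  tau <- (xdotE - min(xdotE[outer_d])) / c0
  w0 <- 2 * pi * f0
  ramp <- ramp_cycles / f0
  bc_rhs <- function(t) {
    u <- t - tau
    E <- pmin(pmax(u / ramp, 0), 1)
    Ep <- as.numeric(u > 0 & u < ramp) / ramp
    s <- sin(w0 * u); cs <- cos(w0 * u)
    pi_t <- wave$amplitude * E * s
    D <- wave$amplitude * (Ep * s + E * w0 * cs)
    v <- D * (1 - ndotE) / c0 + pi_t / R
    as.numeric(C %*% (v * c0))   # C = Ms/c, so Ms %*% v = c * C %*% v
  }
  probes <- lapply(seq_len(nrow(probe_points)), function(i) {
    locate_point(mesh, dofs, probe_points[i, ])
  })
  P <- matrix(0, nrow(probe_points), nt)
  p <- numeric(n); vvec <- numeric(n); a <- numeric(n)
  times <- dt * seq_len(nt)
  for (it in seq_len(nt)) {
    t1 <- times[it]
    tmid <- (1 - af) * t1 + af * (t1 - dt)
    f_mid <- bc_rhs(tmid)
    p_pred <- p + dt * vvec + dt^2 * (0.5 - bet) * a
    v_pred <- vvec + dt * (1 - gam) * a
    rhs <- f_mid -
      as.numeric(Mbar %*% (am * a)) -
      as.numeric(C %*% ((1 - af) * v_pred + af * vvec)) -
      as.numeric(Ktot %*% ((1 - af) * p_pred + af * p))
    a_new <- as.numeric(Matrix::solve(fac, rhs))
    p <- p_pred + bet * dt^2 * a_new
    vvec <- v_pred + gam * dt * a_new
    a <- a_new
    for (ip in seq_along(probes)) {
      P[ip, it] <- sum(p[probes[[ip]]$dof_ids] * probes[[ip]]$shape)
    }
    if (it %% 200 == 0 && max(abs(p)) > 1e6 * max(wave$amplitude, 1e-12)) {
      abort(sprintf("Time integration diverged at step %d (energy blow-up).", it))
    }
  }
  structure(list(times = times, probe_pressure = P,
                 probe_points = probe_points, dt = dt, f0 = f0,
                 final_field = p, order = order, cfl = cfl),
            class = "time_solution")
}

#' @export
print.time_solution <- function(x, ...) {
  cat(sprintf("<time_solution: f0 = %.4g kHz, %d steps of %.3g us, CFL = %.3g>\n",
              x$f0 / 1000, length(x$times), x$dt * 1e6, x$cfl))
  invisible(x)
}

#' Steady-state amplitude of a time-domain probe signal
#'
#' Amplitude of the settled oscillation: half the peak-to-peak excursion over
#' the last `cycles` cycles of the probe series.
#'
#' @param solution A `time_solution`.
#' @param probe_index Which probe (default 1).
#' @param cycles Number of trailing cycles to use (default 3).
#' @return Amplitude in Pa.
#' @export
steady_state_amplitude <- function(solution, probe_index = 1, cycles = 3) {
  stopifnot(inherits(solution, "time_solution"))
  y <- solution$probe_pressure[probe_index, ]
  nwin <- max(8L, round(cycles / solution$f0 / solution$dt))
  yy <- tail(y, nwin)
  (max(yy) - min(yy)) / 2
}
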