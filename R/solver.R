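#' Saliva fluid properties
#'
#' Saliva is treated as an incompressible Newtonian fluid with the density
#' of water (1 g/cm^3 = 1000 kg/m^3).  The dynamic viscosity defaults to
#' the water-like 1.0 mPa s.  `eddy_factor` multiplies the molecular
#' viscosity to emulate enhanced (turbulent) momentum diffusion in
#' sensitivity runs; the default 1 runs the solver laminar, appropriate at
#' the bracket Reynolds number (~4e2).
#'
#' @param density kg/m^3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param eddy_factor Dimensionless multiplier on the viscosity.
#' @return A `fluid_props` object.
#' @export
fluid_props <- function(density = 1000, viscosity = 1.0e-3, eddy_factor = 1) {
  if (density <= 0 || viscosity <= 0 || eddy_factor <= 0)
    stop("density, viscosity and eddy_factor must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity,
                 eddy_factor = eddy_factor), class = "fluid_props")
}

#' Swallow-cycle inflow forcing
#'
#' One swallow drives the saliva film across the tooth as a single
#' unidirectional pulse: inflow speed follows a half-sine,
#' `peak_speed * sin(pi t / T)`, zero at `t = 0` and `t = T` and maximal at
#' mid-cycle.  The defaults are a 0.25 s movement with a 0.172 m/s peak.
#'
#' @param direction `"gingival"` (flow toward -y, entering the occlusal
#'   face) or `"occlusal"` (toward +y, entering the gingival face).
#' @param duration Cycle duration T, s.
#' @param peak_speed Peak inflow speed, m/s.
#' @return A `swallow_cycle` object.
#' @export
swallow_cycle <- function(direction = c("gingival", "occlusal"),
                          duration = 0.25, peak_speed = 0.172) {
  direction <- match.arg(direction)
  if (duration <= 0 || peak_speed <= 0)
    stop("duration and peak_speed must be positive", call. = FALSE)
  structure(list(direction = direction, duration = duration,
                 peak_speed = peak_speed), class = "swallow_cycle")
}

#' Instantaneous inflow speed of a swallow cycle
#'
#' @param t Time, s; must lie in `[0, T]`.
#' @param cycle A [swallow_cycle()].
#' @return Inflow speed, m/s: `peak_speed * sin(pi t / T)`.
#' @export
#' @examples
#' inflow_speed(0.125, swallow_cycle())  # peak, 0.172 m/s
inflow_speed <- function(t, cycle) {
  stopifnot(inherits(cycle, "swallow_cycle"))
  if (any(t < -1e-12 | t > cycle$duration + 1e-12))
    stop("t outside the swallow cycle [0, ", cycle$duration, "] s",
         call. = FALSE)
  cycle$peak_speed * sin(pi * pmin(pmax(t, 0), cycle$duration) / cycle$duration)
}

# ---------------------------------------------------------------------------
# Boundary-condition specification (internal).
#   x: "slip" | "periodic"
#   y: "slip" | "inout"    (inout: prescribed normal inflow + balanced outflow)
#   z: "slip" | "noslip"   (both z walls; z = 0 is the tooth surface)
#   inflow: list(side = "hi"|"lo", speed = function(t) m/s) when y == "inout"
bc_spec <- function(x = "slip", y = "slip", z = "slip", inflow = NULL) {
  x <- match.arg(x, c("slip", "periodic"))
  y <- match.arg(y, c("slip", "inout"))
  z <- match.arg(z, c("slip", "noslip"))
  if (y == "inout" && is.null(inflow))
    stop("inout boundary needs an inflow spec", call. = FALSE)
  structure(list(x = x, y = y, z = z, inflow = inflow), class = "bc_spec")
}

bc_for_cycle <- function(cycle, z = "slip") {
  side <- if (cycle$direction == "gingival") "hi" else "lo"
  bc_spec(x = "slip", y = "inout", z = z,
          inflow = list(side = side, speed = function(t) inflow_speed(t, cycle),
                        sign = if (cycle$direction == "gingival") -1 else 1))
}

# ---------------------------------------------------------------------------
# Ghost-cell padding.  mode in {"mirror","negate","wrap","wrapdup","zero"}:
# mirror = zero-gradient; negate = zero value at the wall (no-slip /
# zero-tangential); wrap = periodic over an n-sized axis; wrapdup = periodic
# over an (n+1)-sized staggered axis whose end faces coincide.
ghost_slab <- function(a, axis, side, mode) {
  d <- dim(a)[axis]
  k <- switch(mode,
              mirror = ,
              negate = if (side == "lo") 1L else d,
              wrap = if (side == "lo") d else 1L,
              wrapdup = if (side == "lo") d - 1L else 2L,
              zero = NA_integer_)
  sl <- switch(axis,
               `1` = a[k, , , drop = FALSE],
               `2` = a[, k, , drop = FALSE],
               `3` = a[, , k, drop = FALSE])
  if (mode == "zero") sl[] <- 0
  if (mode == "negate") sl <- -sl
  sl
}

# Pad by one ghost layer along a single axis.
pad1 <- function(a, axis, modes) {
  d <- dim(a)
  dd <- d; dd[axis] <- d[axis] + 2L
  res <- array(0, dd)
  lo <- ghost_slab(a, axis, "lo", modes[1])
  hi <- ghost_slab(a, axis, "hi", modes[2])
  if (axis == 1) {
    res[2:(d[1] + 1), , ] <- a; res[1, , ] <- lo; res[d[1] + 2, , ] <- hi
  } else if (axis == 2) {
    res[, 2:(d[2] + 1), ] <- a; res[, 1, ] <- lo; res[, d[2] + 2, ] <- hi
  } else {
    res[, , 2:(d[3] + 1)] <- a; res[, , 1] <- lo; res[, , d[3] + 2] <- hi
  }
  res
}

# Pad along all three axes (corner ghosts are never read).
pad3 <- function(a, mx, my, mz) pad1(pad1(pad1(a, 1, mx), 2, my), 3, mz)

# Upwind advective term adv * df/ds for collocated arrays.
upw <- function(adv, fm, fc, fp, h) {
  (pmax(adv, 0) * (fc - fm) + pmin(adv, 0) * (fp - fc)) / h
}

# Ghost modes per component/axis for a bc_spec.  For the inout y boundary,
# tangential velocity is forced to zero on the inflow side (plug inflow)
# and zero-gradient on the outflow side.
bc_modes <- function(bc) {
  ymode_tan <- if (bc$y == "inout") {
    if (bc$inflow$side == "lo") c("negate", "mirror") else c("mirror", "negate")
  } else c("mirror", "mirror")
  list(
    x_tan = if (bc$x == "periodic") c("wrap", "wrap") else c("mirror", "mirror"),
    x_own = if (bc$x == "periodic") c("wrapdup", "wrapdup") else c("mirror", "mirror"),
    y_tan = ymode_tan,
    y_own = c("mirror", "mirror"),
    z_tan = if (bc$z == "noslip") c("negate", "negate") else c("mirror", "mirror"),
    z_own = c("mirror", "mirror"))
}

# Explicit upwind advection + diffusion + body force: returns star velocities.
# The immersed appliance is frictionless: where a tangential-direction
# neighbour falls on a solid-masked face (held at zero), the stencil uses
# the centre value instead (zero-gradient mirror), so the mask exerts no
# artificial shear; normal-direction neighbours keep their zero
# (impermeability).
adv_diff <- function(field, model, bc, nu, dt, body_force = c(0, 0, 0),
                     sf = solid_face_masks(model)) {
  u <- field$u; v <- field$v; w <- field$w
  h <- field$h_m
  n <- dim(field$p); nx <- n[1]; ny <- n[2]; nz <- n[3]
  m <- bc_modes(bc)
  zz <- c("zero", "zero")
  # tangential-neighbour mirror: neighbour value where free, centre where
  # the neighbour face is solid-masked
  mirror_tan <- function(nb, msk_nb, C) nb * (1 - msk_nb) + C * msk_nb

  # --- u (x-faces) ---
  ue <- pad3(u, m$x_own, m$y_tan, m$z_tan)
  mue <- pad3(sf$u * 1, zz, zz, zz)
  Cu <- ue[2:(nx + 2), 2:(ny + 1), 2:(nz + 1)]
  Xm <- ue[1:(nx + 1), 2:(ny + 1), 2:(nz + 1)]
  Xp <- ue[3:(nx + 3), 2:(ny + 1), 2:(nz + 1)]
  Ym <- mirror_tan(ue[2:(nx + 2), 1:ny, 2:(nz + 1)],
                   mue[2:(nx + 2), 1:ny, 2:(nz + 1)], Cu)
  Yp <- mirror_tan(ue[2:(nx + 2), 3:(ny + 2), 2:(nz + 1)],
                   mue[2:(nx + 2), 3:(ny + 2), 2:(nz + 1)], Cu)
  Zm <- mirror_tan(ue[2:(nx + 2), 2:(ny + 1), 1:nz],
                   mue[2:(nx + 2), 2:(ny + 1), 1:nz], Cu)
  Zp <- mirror_tan(ue[2:(nx + 2), 2:(ny + 1), 3:(nz + 2)],
                   mue[2:(nx + 2), 2:(ny + 1), 3:(nz + 2)], Cu)
  vpx <- pad1(v, 1, m$x_tan)
  vbar <- 0.25 * (vpx[1:(nx + 1), 1:ny, ] + vpx[2:(nx + 2), 1:ny, ] +
                  vpx[1:(nx + 1), 2:(ny + 1), ] + vpx[2:(nx + 2), 2:(ny + 1), ])
  wpx <- pad1(w, 1, m$x_tan)
  wbar <- 0.25 * (wpx[1:(nx + 1), , 1:nz] + wpx[2:(nx + 2), , 1:nz] +
                  wpx[1:(nx + 1), , 2:(nz + 1)] + wpx[2:(nx + 2), , 2:(nz + 1)])
  lap <- (Xm + Xp + Ym + Yp + Zm + Zp - 6 * Cu) / h^2
  ustar <- u + dt * (-upw(Cu, Xm, Cu, Xp, h) - upw(vbar, Ym, Cu, Yp, h) -
                     upw(wbar, Zm, Cu, Zp, h) + nu * lap + body_force[1])

  # --- v (y-faces) ---
  ve <- pad3(v, m$x_tan, m$y_own, m$z_tan)
  mve <- pad3(sf$v * 1, zz, zz, zz)
  Cv <- ve[2:(nx + 1), 2:(ny + 2), 2:(nz + 1)]
  Xm <- mirror_tan(ve[1:nx, 2:(ny + 2), 2:(nz + 1)],
                   mve[1:nx, 2:(ny + 2), 2:(nz + 1)], Cv)
  Xp <- mirror_tan(ve[3:(nx + 2), 2:(ny + 2), 2:(nz + 1)],
                   mve[3:(nx + 2), 2:(ny + 2), 2:(nz + 1)], Cv)
  Ym <- ve[2:(nx + 1), 1:(ny + 1), 2:(nz + 1)]
  Yp <- ve[2:(nx + 1), 3:(ny + 3), 2:(nz + 1)]
  Zm <- mirror_tan(ve[2:(nx + 1), 2:(ny + 2), 1:nz],
                   mve[2:(nx + 1), 2:(ny + 2), 1:nz], Cv)
  Zp <- mirror_tan(ve[2:(nx + 1), 2:(ny + 2), 3:(nz + 2)],
                   mve[2:(nx + 1), 2:(ny + 2), 3:(nz + 2)], Cv)
  upy <- pad1(u, 2, m$y_tan)
  ubar <- 0.25 * (upy[1:nx, 1:(ny + 1), ] + upy[2:(nx + 1), 1:(ny + 1), ] +
                  upy[1:nx, 2:(ny + 2), ] + upy[2:(nx + 1), 2:(ny + 2), ])
  wpy <- pad1(w, 2, m$y_tan)
  wbar <- 0.25 * (wpy[, 1:(ny + 1), 1:nz] + wpy[, 2:(ny + 2), 1:nz] +
                  wpy[, 1:(ny + 1), 2:(nz + 1)] + wpy[, 2:(ny + 2), 2:(nz + 1)])
  lap <- (Xm + Xp + Ym + Yp + Zm + Zp - 6 * Cv) / h^2
  vstar <- v + dt * (-upw(ubar, Xm, Cv, Xp, h) - upw(Cv, Ym, Cv, Yp, h) -
                     upw(wbar, Zm, Cv, Zp, h) + nu * lap + body_force[2])

  # --- w (z-faces) ---
  we <- pad3(w, m$x_tan, m$y_tan, m$z_own)
  mwe <- pad3(sf$w * 1, zz, zz, zz)
  Cw <- we[2:(nx + 1), 2:(ny + 1), 2:(nz + 2)]
  Xm <- mirror_tan(we[1:nx, 2:(ny + 1), 2:(nz + 2)],
                   mwe[1:nx, 2:(ny + 1), 2:(nz + 2)], Cw)
  Xp <- mirror_tan(we[3:(nx + 2), 2:(ny + 1), 2:(nz + 2)],
                   mwe[3:(nx + 2), 2:(ny + 1), 2:(nz + 2)], Cw)
  Ym <- mirror_tan(we[2:(nx + 1), 1:ny, 2:(nz + 2)],
                   mwe[2:(nx + 1), 1:ny, 2:(nz + 2)], Cw)
  Yp <- mirror_tan(we[2:(nx + 1), 3:(ny + 2), 2:(nz + 2)],
                   mwe[2:(nx + 1), 3:(ny + 2), 2:(nz + 2)], Cw)
  Zm <- we[2:(nx + 1), 2:(ny + 1), 1:(nz + 1)]
  Zp <- we[2:(nx + 1), 2:(ny + 1), 3:(nz + 3)]
  upz <- pad1(u, 3, m$z_tan)
  ubar <- 0.25 * (upz[1:nx, , 1:(nz + 1)] + upz[2:(nx + 1), , 1:(nz + 1)] +
                  upz[1:nx, , 2:(nz + 2)] + upz[2:(nx + 1), , 2:(nz + 2)])
  vpz <- pad1(v, 3, m$z_tan)
  vbar <- 0.25 * (vpz[, 1:ny, 1:(nz + 1)] + vpz[, 2:(ny + 1), 1:(nz + 1)] +
                  vpz[, 1:ny, 2:(nz + 2)] + vpz[, 2:(ny + 1), 2:(nz + 2)])
  lap <- (Xm + Xp + Ym + Yp + Zm + Zp - 6 * Cw) / h^2
  wstar <- w + dt * (-upw(ubar, Xm, Cw, Xp, h) - upw(vbar, Ym, Cw, Yp, h) -
                     upw(Cw, Zm, Cw, Zp, h) + nu * lap + body_force[3])

  field$u <- ustar; field$v <- vstar; field$w <- wstar
  field
}

# Logical masks of faces adjacent to at least one solid cell.
solid_face_masks <- function(model) {
  s <- model$solid
  n <- dim(s)
  us <- array(FALSE, c(n[1] + 1, n[2], n[3]))
  us[2:(n[1] + 1), , ] <- s
  us[1:n[1], , ] <- us[1:n[1], , ] | s
  vs <- array(FALSE, c(n[1], n[2] + 1, n[3]))
  vs[, 2:(n[2] + 1), ] <- s
  vs[, 1:n[2], ] <- vs[, 1:n[2], ] | s
  ws <- array(FALSE, c(n[1], n[2], n[3] + 1))
  ws[, , 2:(n[3] + 1)] <- s
  ws[, , 1:n[3]] <- ws[, , 1:n[3]] | s
  list(u = us, v = vs, w = ws)
}

# Enforce wall, inflow/outflow and solid-face conditions at time t.
# Returns the field plus the instantaneous inflow flux (m^3/s).
apply_bcs <- function(field, model, bc, t, sf = solid_face_masks(model)) {
  n <- dim(field$p); nx <- n[1]; ny <- n[2]; nz <- n[3]
  flux_in <- 0
  if (bc$x == "slip") {
    field$u[1, , ] <- 0
    field$u[nx + 1, , ] <- 0
  } else {
    field$u[nx + 1, , ] <- field$u[1, , ]
  }
  if (bc$y == "slip") {
    field$v[, 1, ] <- 0
    field$v[, ny + 1, ] <- 0
  } else {
    s <- bc$inflow$speed(t)
    sgn <- bc$inflow$sign
    open_lo <- !model$solid[, 1, ]   # nx x nz
    open_hi <- !model$solid[, ny, ]
    h <- field$h_m
    if (bc$inflow$side == "hi") {
      field$v[, ny + 1, ] <- sgn * s * open_hi
      flux_in <- s * h^2 * sum(open_hi)
      vout <- flux_in / (h^2 * sum(open_lo))
      field$v[, 1, ] <- sgn * vout * open_lo
    } else {
      field$v[, 1, ] <- sgn * s * open_lo
      flux_in <- s * h^2 * sum(open_lo)
      vout <- flux_in / (h^2 * sum(open_hi))
      field$v[, ny + 1, ] <- sgn * vout * open_hi
    }
  }
  field$w[, , 1] <- 0
  field$w[, , nz + 1] <- 0
  field$u[sf$u] <- 0
  field$v[sf$v] <- 0
  field$w[sf$w] <- 0
  attr(field, "flux_in") <- flux_in
  field
}

# ---------------------------------------------------------------------------
# Pressure projection.

# Build the fluid-cell Poisson operator (7-point, Neumann at walls/solids,
# periodic wrap in x when requested), factorise it once, and precompute the
# face lists used for the velocity correction.
make_projector <- function(model, bc = bc_spec()) {
  s <- model$solid
  n <- dim(s); nx <- n[1]; ny <- n[2]; nz <- n[3]
  fluid <- !s
  nf <- sum(fluid)
  comp <- array(0L, n)
  comp[fluid] <- seq_len(nf)
  h <- model$h * 1e-3

  lin3 <- function(i, j, k, d) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  edges_L <- integer(0); edges_R <- integer(0)
  face_comp <- character(0); face_idx <- integer(0)

  add_faces <- function(mask, Lc, Rc, fidx, compname) {
    keep <- which(mask)
    list(L = comp[Lc[keep]], R = comp[Rc[keep]], f = fidx[keep],
         comp = rep(compname, length(keep)))
  }

  # x-direction interior faces: cells (i,j,k)-(i+1,j,k), u face (i+1,j,k)
  I <- as.matrix(expand.grid(i = 1:(nx - 1), j = 1:ny, k = 1:nz))
  mask <- fluid[lin3(I[, 1], I[, 2], I[, 3], n)] &
          fluid[lin3(I[, 1] + 1L, I[, 2], I[, 3], n)]
  fx <- add_faces(mask, lin3(I[, 1], I[, 2], I[, 3], n),
                  lin3(I[, 1] + 1L, I[, 2], I[, 3], n),
                  lin3(I[, 1] + 1L, I[, 2], I[, 3], c(nx + 1L, ny, nz)), "u")
  # periodic x wrap: cells (nx,j,k)-(1,j,k), u face (1,j,k); normal +x from
  # cell nx into cell 1
  if (bc$x == "periodic") {
    J <- as.matrix(expand.grid(j = 1:ny, k = 1:nz))
    mask <- fluid[lin3(rep(nx, nrow(J)), J[, 1], J[, 2], n)] &
            fluid[lin3(rep(1L, nrow(J)), J[, 1], J[, 2], n)]
    fw <- add_faces(mask, lin3(rep(nx, nrow(J)), J[, 1], J[, 2], n),
                    lin3(rep(1L, nrow(J)), J[, 1], J[, 2], n),
                    lin3(rep(1L, nrow(J)), J[, 1], J[, 2], c(nx + 1L, ny, nz)),
                    "u")
    fx <- list(L = c(fx$L, fw$L), R = c(fx$R, fw$R), f = c(fx$f, fw$f),
               comp = c(fx$comp, fw$comp))
  }
  # y-direction: cells (i,j,k)-(i,j+1,k), v face (i,j+1,k)
  I <- as.matrix(expand.grid(i = 1:nx, j = 1:(ny - 1), k = 1:nz))
  mask <- fluid[lin3(I[, 1], I[, 2], I[, 3], n)] &
          fluid[lin3(I[, 1], I[, 2] + 1L, I[, 3], n)]
  fy <- add_faces(mask, lin3(I[, 1], I[, 2], I[, 3], n),
                  lin3(I[, 1], I[, 2] + 1L, I[, 3], n),
                  lin3(I[, 1], I[, 2] + 1L, I[, 3], c(nx, ny + 1L, nz)), "v")
  # z-direction: cells (i,j,k)-(i,j,k+1), w face (i,j,k+1)
  I <- as.matrix(expand.grid(i = 1:nx, j = 1:ny, k = 1:(nz - 1)))
  mask <- fluid[lin3(I[, 1], I[, 2], I[, 3], n)] &
          fluid[lin3(I[, 1], I[, 2], I[, 3] + 1L, n)]
  fz <- add_faces(mask, lin3(I[, 1], I[, 2], I[, 3], n),
                  lin3(I[, 1], I[, 2], I[, 3] + 1L, n),
                  lin3(I[, 1], I[, 2], I[, 3] + 1L, c(nx, ny, nz + 1L)), "w")

  L <- c(fx$L, fy$L, fz$L)
  R <- c(fx$R, fy$R, fz$R)

  # negative Laplacian over fluid cells (SPD after pinning)
  ii <- c(L, R, L, R)
  jj <- c(R, L, L, R)
  xx <- c(rep(-1, 2 * length(L)), rep(1, 2 * length(L)))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / h^2, dims = c(nf, nf))

  # connected components of the fluid graph (frontier propagation)
  Adj <- Matrix::sparseMatrix(i = c(L, R), j = c(R, L), x = 1,
                              dims = c(nf, nf))
  label <- integer(nf)
  ncomp <- 0L
  while (any(label == 0L)) {
    ncomp <- ncomp + 1L
    seed <- which(label == 0L)[1]
    memb <- logical(nf); memb[seed] <- TRUE
    repeat {
      grown <- as.logical(Adj %*% memb > 0) | memb
      if (identical(grown, memb)) break
      memb <- grown
    }
    label[memb] <- ncomp
  }
  pins <- vapply(seq_len(ncomp), function(cc) which(label == cc)[1], 1L)
  keep <- setdiff(seq_len(nf), pins)
  Ared <- A[keep, keep, drop = FALSE]
  chol <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Ared), "CsparseMatrix"),
                           LDL = FALSE, perm = TRUE)

  structure(list(comp = comp, fluid = fluid, nf = nf, keep = keep, pins = pins,
                 chol = chol, h = h, dims = n, periodic_x = bc$x == "periodic",
                 faces = list(u = fx, v = fy, w = fz),
                 sf = solid_face_masks(model)),
            class = "projector")
}

#' Project a velocity field onto the divergence-free subspace
#'
#' Solves the pressure-Poisson equation over the fluid cells (Neumann at
#' walls and solid surfaces) with a direct sparse Cholesky factorisation
#' and subtracts the pressure gradient from the interior face velocities.
#' Prescribed faces (domain boundaries, solid-adjacent faces) are not
#' touched, so the input must carry zero (or globally balanced) net flux
#' across them.
#'
#' @param field A `flow_field`.
#' @param model The `geometry_model` the field lives on.
#' @param tol Relative tolerance; the post-projection divergence must
#'   satisfy `max |div| <= 10 * tol * v_scale / h` or an error is raised.
#' @param projector Optional cached projector from an earlier call (rebuilt
#'   from the model otherwise).
#' @param rho_over_dt If supplied, the pressure field is stored in Pa as
#'   `phi * rho / dt`; otherwise the raw projection potential (m^2/s) is
#'   stored.
#' @param bc Boundary-condition spec used when building a projector.
#' @return The projected `flow_field`.
#' @export
project <- function(field, model, tol = 1e-8, projector = NULL,
                    rho_over_dt = NULL, bc = bc_spec()) {
  if (is.null(projector)) projector <- make_projector(model, bc)
  pr <- projector
  D <- divergence(field)[pr$fluid]
  b <- -D
  phi <- numeric(pr$nf)
  phi[pr$keep] <- as.numeric(Matrix::solve(pr$chol, b[pr$keep]))

  for (cn in c("u", "v", "w")) {
    fl <- pr$faces[[cn]]
    if (length(fl$f) == 0) next
    dphi <- (phi[fl$R] - phi[fl$L]) / pr$h
    field[[cn]][fl$f] <- field[[cn]][fl$f] - dphi
  }
  if (pr$periodic_x) {
    nx <- pr$dims[1]
    field$u[nx + 1, , ] <- field$u[1, , ]
  }
  field$p[] <- 0
  field$p[pr$fluid] <- if (is.null(rho_over_dt)) phi else phi * rho_over_dt

  vscale <- max(abs(field$u), abs(field$v), abs(field$w), 1e-6)
  maxdiv <- max(abs(divergence(field)[pr$fluid]))
  if (maxdiv > max(10 * tol * vscale / pr$h, 1e-10))
    stop("pressure projection did not reach tolerance: max |div| = ",
         format(maxdiv), " 1/s (threshold ",
         format(max(10 * tol * vscale / pr$h, 1e-10)), ")", call. = FALSE)
  field
}

#' Advance the flow one time step
#'
#' One explicit step of the incompressible momentum equation
#' `rho (dv/dt + v . grad v) = -grad p + mu lap v` (gravity neglected):
#' upwind advection and central diffusion form a provisional velocity,
#' boundary conditions are applied at the new time, and a pressure
#' projection restores `div v = 0`.
#'
#' @param field A `flow_field`.
#' @param model The `geometry_model`.
#' @param props [fluid_props()].
#' @param dt Time step, s; must satisfy the advective CFL bound
#'   `dt <= 0.4 h / max|v|` and the diffusive bound `dt <= 0.25 h^2 / nu`.
#' @param bc Boundary conditions (internal spec; defaults to slip walls).
#' @param projector Cached projector (built if missing).
#' @param body_force Acceleration vector, m/s^2 (e.g. a driving force for
#'   channel-flow verification).
#' @param tol Projection tolerance.
#' @return The updated `flow_field` at `time + dt`.
#' @export
advance <- function(field, model, props, dt, bc = bc_spec(),
                    projector = NULL, body_force = c(0, 0, 0), tol = 1e-8) {
  stopifnot(inherits(field, "flow_field"), inherits(props, "fluid_props"))
  h <- field$h_m
  nu <- props$viscosity * props$eddy_factor / props$density
  maxv <- max(abs(field$u), abs(field$v), abs(field$w))
  if (maxv > 0 && dt > 0.4 * h / maxv + 1e-15)
    stop("advective CFL violation: dt = ", format(dt), " s exceeds required ",
         format(0.4 * h / maxv), " s", call. = FALSE)
  if (dt > 0.25 * h^2 / nu + 1e-15)
    stop("diffusive stability violation: dt = ", format(dt),
         " s exceeds required ", format(0.25 * h^2 / nu), " s", call. = FALSE)
  if (is.null(projector)) projector <- make_projector(model, bc)

  t_new <- field$time + dt
  field <- adv_diff(field, model, bc, nu, dt, body_force, sf = projector$sf)
  field <- apply_bcs(field, model, bc, t_new, projector$sf)
  flux_in <- attr(field, "flux_in")
  field <- project(field, model, tol = tol, projector = projector,
                   rho_over_dt = props$density / dt, bc = bc)
  if (anyNA(field$u) || anyNA(field$v) || anyNA(field$w))
    stop("solver diverged: NaN in velocity field at t = ", format(t_new),
         call. = FALSE)
  field$time <- t_new
  attr(field, "flux_in") <- flux_in
  field
}

#' Simulate one swallow cycle over the appliance
#'
#' Integrates the transient flow for `t` in `[0, T]` under the sinusoidal
#' swallow inflow.  Saliva enters through the upstream occluso-gingival
#' face (the occlusal face for gingival-directed flow and vice versa),
#' leaves through the opposite face with the flux balanced exactly, and
#' sees free-slip (frictionless), impermeable tooth, appliance and lateral
#' boundaries (a no-slip film option is exposed via `slip`).
#'
#' @param model A `geometry_model`.
#' @param cycle A [swallow_cycle()].
#' @param props [fluid_props()].
#' @param snapshot_times Times (s) at which to keep full field snapshots;
#'   defaults to mid-cycle and the nearest step to the end.
#' @param slip `"free"` or `"no"` for the z walls (tooth surface / labial
#'   boundary).
#' @param max_steps Safety cap on the number of time steps.
#' @param verbose Print progress to stderr.
#' @return A `swallow_result` list: `fields` (named list of snapshots),
#'   `max_speed` (nx x ny matrix, cycle-maximum near-wall speed, m/s;
#'   NA under the appliance), `inflow_volume_ml`, `outflow_volume_ml`,
#'   `dt`, `n_steps`, plus the model and cycle.
#' @export
simulate_swallow <- function(model, cycle, props = fluid_props(),
                             snapshot_times = NULL, slip = c("free", "no"),
                             max_steps = 100000, verbose = FALSE) {
  stopifnot(inherits(model, "geometry_model"), inherits(cycle, "swallow_cycle"))
  slip <- match.arg(slip)
  bc <- bc_for_cycle(cycle, z = if (slip == "free") "slip" else "noslip")
  h <- model$h * 1e-3
  nu <- props$viscosity * props$eddy_factor / props$density
  dt_diff <- 0.25 * h^2 / nu
  if (is.null(snapshot_times))
    snapshot_times <- c(cycle$duration / 2, cycle$duration)
  snapshot_times <- sort(snapshot_times)

  projector <- make_projector(model, bc)
  field <- flow_field(model)
  nx <- length(model$x); ny <- length(model$y)
  max_speed <- matrix(0, nx, ny)
  vol_in <- 0; vol_out <- 0
  fields <- list()
  n_steps <- 0L
  snap_i <- 1L
  # adaptive time step: the CFL speed scale is the larger of the current
  # field maximum and the imposed inflow, with 10% headroom for the
  # within-step speed-up through the appliance constriction
  while (field$time < cycle$duration - 1e-12) {
    maxv <- max(abs(field$u), abs(field$v), abs(field$w),
                inflow_speed(min(field$time + dt_diff, cycle$duration), cycle),
                1e-4)
    dt <- min(0.4 * h / (1.1 * maxv), dt_diff,
              cycle$duration - field$time, cycle$duration / 100)
    field <- advance(field, model, props, dt, bc = bc, projector = projector)
    n_steps <- n_steps + 1L
    if (n_steps > max_steps)
      stop("time-step count exceeds max_steps", call. = FALSE)
    sp <- surface_speed_matrix(field, model)
    max_speed <- pmax(max_speed, sp, na.rm = FALSE)
    max_speed[is.na(sp)] <- NA
    flux <- attr(field, "flux_in")
    vol_in <- vol_in + flux * dt
    # outflow measured on the downstream boundary face
    n3 <- dim(field$p)
    vout <- if (bc$inflow$side == "hi") field$v[, 1, ] else field$v[, n3[2] + 1, ]
    vol_out <- vol_out + sum(abs(vout)) * h^2 * dt
    while (snap_i <= length(snapshot_times) &&
           field$time >= snapshot_times[snap_i] - 1e-12) {
      fields[[sprintf("t%04.0fms", field$time * 1000)]] <- field
      snap_i <- snap_i + 1L
    }
    if (verbose && n_steps %% 50 == 0)
      message(sprintf("  step %d t=%.4f s max|v|=%.4f m/s",
                      n_steps, field$time, max(abs(field$v))))
  }
  structure(list(fields = fields, max_speed = max_speed,
                 inflow_volume_ml = vol_in * 1e6,
                 outflow_volume_ml = vol_out * 1e6,
                 dt = cycle$duration / n_steps, n_steps = n_steps,
                 model = model, cycle = cycle, props = props),
            class = "swallow_result")
}

#' @export
print.swallow_result <- function(x, ...) {
  cat("<swallow_result> ", x$cycle$direction, " swallow, ", x$n_steps,
      " steps of ", format(x$dt, digits = 3), " s\n", sep = "")
  cat("  inflow ", format(x$inflow_volume_ml, digits = 4), " ml, outflow ",
      format(x$outflow_volume_ml, digits = 4), " ml\n", sep = "")
  cat("  peak near-wall speed ", format(max(x$max_speed, na.rm = TRUE),
                                        digits = 4), " m/s\n", sep = "")
  invisible(x)
}

# Near-wall speed magnitude at the first fluid cell layer (internal matrix
# form; the tidy interface is near_wall_speed()).
surface_speed_matrix <- function(field, model, layer = 1) {
  n <- dim(field$p)
  uc <- 0.5 * (field$u[1:n[1], , layer] + field$u[2:(n[1] + 1), , layer])
  vc <- 0.5 * (field$v[, 1:n[2], layer] + field$v[, 2:(n[2] + 1), layer])
  wc <- 0.5 * (field$w[, , layer] + field$w[, , layer + 1])
  sp <- sqrt(uc^2 + vc^2 + wc^2)
  sp[model$solid[, , layer]] <- NA
  sp
}
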