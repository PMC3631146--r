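#' Construct an empty flow field on a geometry model
#'
#' Velocity lives on a staggered (MAC) grid: `u` on x-faces
#' (`(nx+1) x ny x nz`), `v` on y-faces, `w` on z-faces; pressure `p` at
#' cell centres.  Velocities are in m/s, pressure in Pa, geometry in mm.
#'
#' @param model A `geometry_model`.
#' @param time Time stamp, s.
#' @return A `flow_field` object.
#' @export
flow_field <- function(model, time = 0) {
  n <- dim(model$solid)
  structure(list(u = array(0, c(n[1] + 1, n[2], n[3])),
                 v = array(0, c(n[1], n[2] + 1, n[3])),
                 w = array(0, c(n[1], n[2], n[3] + 1)),
                 p = array(0, n),
                 time = time,
                 h_m = model$h * 1e-3),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> t = ", format(x$time), " s, grid ",
      paste(dim(x$p), collapse = "x"), ", max speed ",
      format(max(abs(x$u), abs(x$v), abs(x$w)), digits = 4), " m/s\n",
      sep = "")
  invisible(x)
}

# Staggered coordinates (mm) for each component.
face_coords <- function(model, comp = c("u", "v", "w")) {
  comp <- match.arg(comp)
  h <- model$h
  n <- dim(model$solid)
  xc <- model$x; yc <- model$y; zc <- model$z
  switch(comp,
         u = list(x = (0:n[1]) * h, y = yc, z = zc),
         v = list(x = xc, y = (0:n[2]) * h, z = zc),
         w = list(x = xc, y = yc, z = (0:n[3]) * h))
}

# Evaluate f(x, y, z) (mm args) on the staggered locations of `comp`.
eval_staggered <- function(model, comp, f) {
  co <- face_coords(model, comp)
  nx <- length(co$x); ny <- length(co$y); nz <- length(co$z)
  X <- array(rep(co$x, ny * nz), c(nx, ny, nz))
  Y <- aperm(array(rep(co$y, nx * nz), c(ny, nx, nz)), c(2, 1, 3))
  Z <- aperm(array(rep(co$z, nx * ny), c(nz, nx, ny)), c(2, 3, 1))
  f(X, Y, Z)
}

#' Discrete divergence of a flow field
#'
#' @param field A `flow_field`.
#' @return An `nx x ny x nz` array of per-cell divergences, 1/s.
#' @export
divergence <- function(field) {
  h <- field$h_m
  n <- dim(field$p)
  (field$u[-1, , , drop = FALSE] - field$u[-(n[1] + 1), , , drop = FALSE] +
   field$v[, -1, , drop = FALSE] - field$v[, -(n[2] + 1), , drop = FALSE] +
   field$w[, , -1, drop = FALSE] - field$w[, , -(n[3] + 1), drop = FALSE]) / h
}

#' Analytic reference flow fields
#'
#' Closed-form velocity fields evaluated exactly at the staggered grid
#' locations, used as oracles for the solver and for the flow metrics.
#'
#' Kinds:
#' \describe{
#'   \item{`uniform`}{`params$velocity = c(ux, uy, uz)` m/s everywhere.}
#'   \item{`shear`}{`u = alpha * z`; `params$alpha` in 1/s (z in m).}
#'   \item{`poiseuille`}{plane channel profile across the film,
#'     `u(z) = u_max * (1 - (2 z / H - 1)^2)` with `H` the domain depth;
#'     `params$u_max` m/s.}
#'   \item{`lamb_oseen`}{a Lamb--Oseen vortex normal to the tooth surface:
#'     tangential speed `v_theta(r) = Gamma / (2 pi r) * (1 - exp(-r^2 /
#'     r_c^2))`; `params$gamma` m^2/s, `params$r_c` mm, `params$center =
#'     c(x, y)` mm.  Independent of z.}
#' }
#'
#' @param kind One of `"uniform"`, `"shear"`, `"poiseuille"`, `"lamb_oseen"`.
#' @param params Named list of parameters for the chosen kind.
#' @param model A `geometry_model` supplying the grid.
#' @return A `flow_field`.
#' @export
analytic_field <- function(kind, params, model) {
  fld <- flow_field(model)
  mm <- 1e-3
  if (kind == "uniform") {
    vel <- params$velocity %||% c(params$speed %||% 0.05, 0, 0)
    fld$u[] <- vel[1]; fld$v[] <- vel[2]; fld$w[] <- vel[3]
  } else if (kind == "shear") {
    alpha <- params$alpha
    fld$u <- eval_staggered(model, "u", function(x, y, z) alpha * z * mm)
  } else if (kind == "poiseuille") {
    u_max <- params$u_max
    H <- model$spec$depth
    fld$u <- eval_staggered(model, "u",
                            function(x, y, z) u_max * (1 - (2 * z / H - 1)^2))
  } else if (kind == "lamb_oseen") {
    gamma <- params$gamma
    rc <- params$r_c * mm
    ctr <- params$center %||% c(model$spec$length_md / 2,
                                model$spec$length_og / 2)
    vtheta <- function(r) ifelse(r < 1e-12, 0,
                                 gamma / (2 * pi * r) * (1 - exp(-r^2 / rc^2)))
    fld$u <- eval_staggered(model, "u", function(x, y, z) {
      rx <- (x - ctr[1]) * mm; ry <- (y - ctr[2]) * mm
      r <- sqrt(rx^2 + ry^2)
      -vtheta(r) * ifelse(r < 1e-12, 0, ry / r)
    })
    fld$v <- eval_staggered(model, "v", function(x, y, z) {
      rx <- (x - ctr[1]) * mm; ry <- (y - ctr[2]) * mm
      r <- sqrt(rx^2 + ry^2)
      vtheta(r) * ifelse(r < 1e-12, 0, rx / r)
    })
  } else {
    stop("unknown analytic field kind: ", kind, call. = FALSE)
  }
  fld
}

#' Tangential speed of a Lamb--Oseen vortex
#'
#' @param r Radius from the core centre, m.
#' @param gamma Circulation, m^2/s.
#' @param r_c Core radius, m.
#' @return Tangential speed, m/s.
#' @export
lamb_oseen_vtheta <- function(r, gamma, r_c) {
  ifelse(r < 1e-12, 0, gamma / (2 * pi * r) * (1 - exp(-r^2 / r_c^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
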