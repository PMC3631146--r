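test_that("swallow inflow follows the half-sine pulse", {
  cyc <- swallow_cycle("gingival")
  expect_equal(inflow_speed(0, cyc), 0)
  expect_equal(inflow_speed(0.125, cyc), 0.172)  # peak at mid-cycle
  expect_equal(inflow_speed(0.25, cyc), 0, tolerance = 1e-12)
  expect_error(inflow_speed(0.3, cyc), "outside")
  expect_error(swallow_cycle(duration = -1), "positive")
})

test_that("zero field under zero forcing is a fixed point of advance", {
  geo <- channel_model()
  f <- flow_field(geo)
  f2 <- advance(f, geo, fluid_props(), 1e-3)
  expect_equal(max(abs(f2$u), abs(f2$v), abs(f2$w)), 0)
  expect_equal(f2$time, 1e-3)
})

test_that("uniform flow in an obstacle-free periodic channel is unchanged", {
  geo <- channel_model()
  bc <- periflow:::bc_spec(x = "periodic", y = "slip", z = "slip")
  f <- analytic_field("uniform", list(velocity = c(0.05, 0, 0)), geo)
  f2 <- advance(f, geo, fluid_props(), 5e-4, bc = bc)
  expect_lt(max(abs(f2$u - 0.05)), 1e-12)
  expect_lt(max(abs(f2$v)), 1e-12)
  expect_lt(max(abs(f2$w)), 1e-12)
})

test_that("advance enforces the CFL and stability bounds", {
  geo <- channel_model()
  f <- analytic_field("uniform", list(velocity = c(0.1, 0, 0)), geo)
  h <- geo$h * 1e-3
  expect_error(advance(f, geo, fluid_props(), 2 * 0.4 * h / 0.1,
                       bc = periflow:::bc_spec(x = "periodic")),
               "CFL")
  f0 <- flow_field(geo)
  expect_error(advance(f0, geo, fluid_props(), 1, bc = periflow:::bc_spec()),
               "diffusive")
})

test_that("projection leaves divergence-free and constant fields unchanged", {
  geo <- channel_model()
  f <- analytic_field("uniform", list(velocity = c(0.03, 0, 0)), geo)
  f <- periflow:::apply_bcs(f, geo, periflow:::bc_spec(x = "periodic"), 0)
  f2 <- project(f, geo, bc = periflow:::bc_spec(x = "periodic"))
  expect_equal(f2$u, f$u, tolerance = 1e-10)
  expect_equal(f2$v, f$v, tolerance = 1e-10)
})

test_that("projection drives a random field divergence-free and matches a dense solve", {
  spec <- domain_spec(length_md = 0.6, length_og = 0.6, depth = 0.6,
                      cell_size = 0.1)
  geo <- build_domain(spec)   # 6^3 grid, no solids
  set.seed(42)
  f <- flow_field(geo)
  f$u[] <- rnorm(length(f$u), 0, 0.01)
  f$v[] <- rnorm(length(f$v), 0, 0.01)
  f$w[] <- rnorm(length(f$w), 0, 0.01)
  f <- periflow:::apply_bcs(f, geo, periflow:::bc_spec(), 0)
  div0 <- divergence(f)
  f2 <- project(f, geo)
  h <- geo$h * 1e-3
  vscale <- max(abs(f2$u), abs(f2$v), abs(f2$w))
  expect_lt(max(abs(divergence(f2))), 10 * 1e-8 * vscale / h)

  # independent dense oracle: assemble the Neumann Laplacian by explicit
  # cell loops and solve with base R linear algebra
  n <- dim(geo$solid)
  N <- prod(n)
  idx <- function(i, j, k) i + (j - 1) * n[1] + (k - 1) * n[1] * n[2]
  A <- matrix(0, N, N)
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    me <- idx(i, j, k)
    nbrs <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                 c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (nb in nbrs) {
      if (nb[1] < 1 || nb[1] > n[1] || nb[2] < 1 || nb[2] > n[2] ||
          nb[3] < 1 || nb[3] > n[3]) next
      other <- idx(nb[1], nb[2], nb[3])
      A[me, me] <- A[me, me] + 1 / h^2
      A[me, other] <- A[me, other] - 1 / h^2
    }
  }
  b <- -as.vector(div0)
  # pin the first cell to fix the Neumann nullspace
  Ar <- A[-1, -1]; br <- b[-1]
  phi <- c(0, solve(Ar, br))
  # compare potentials up to an additive constant
  phi_pkg <- as.vector(f2$p)
  expect_equal(phi - mean(phi), phi_pkg - mean(phi_pkg), tolerance = 1e-6)
})

test_that("steady channel flow reproduces the Poiseuille profile within 2% of peak", {
  geo <- channel_model(cell_size = 0.1)
  props <- fluid_props()
  nu <- props$viscosity / props$density
  H <- geo$spec$depth * 1e-3
  u_max <- 0.01
  g <- 8 * nu * u_max / H^2
  bc <- periflow:::bc_spec(x = "periodic", y = "slip", z = "noslip")
  pr <- periflow:::make_projector(geo, bc)
  f <- flow_field(geo)
  dt <- 0.25 * (geo$h * 1e-3)^2 / nu
  for (s in 1:500)
    f <- advance(f, geo, props, dt, bc = bc, projector = pr,
                 body_force = c(g, 0, 0))
  z <- geo$z * 1e-3
  analytic <- g / (2 * nu) * z * (H - z)
  numeric <- f$u[3, 3, ]
  expect_lt(max(abs(numeric - analytic)) / u_max, 0.02)
  # max of the parabola sits at mid-gap
  expect_equal(which.max(numeric), which.max(analytic))
})

test_that("an obstacle-free swallow produces a uniform near-wall field at mid-cycle", {
  geo <- build_domain(domain_spec(cell_size = 0.4))
  sim <- simulate_swallow(geo, swallow_cycle("gingival"),
                          snapshot_times = 0.125)
  sp <- periflow:::surface_speed_matrix(sim$fields[[1]], geo)
  expect_lt((max(sp) - min(sp)) / mean(sp), 0.02)
  # and the speed is the imposed peak inflow
  expect_equal(mean(sp), 0.172, tolerance = 0.01)
})

test_that("swallow simulation conserves mass and stays divergence-free", {
  sim <- cached_sim("gingival_04", cell_size = 0.4)
  expect_lt(abs(sim$inflow_volume_ml - sim$outflow_volume_ml) /
              sim$inflow_volume_ml, 0.001)
  mid <- sim$fields[[1]]
  geo <- sim$model
  h <- geo$h * 1e-3
  vscale <- max(abs(mid$u), abs(mid$v), abs(mid$w))
  expect_lt(max(abs(divergence(mid)[!geo$solid])), 10 * 1e-8 * vscale / h)
})

test_that("mirror-symmetric geometry yields mirror-symmetric fields", {
  sim <- cached_sim("gingival_04", cell_size = 0.4)
  mid <- sim$fields[[1]]
  nx <- length(sim$model$x)
  # v and w even under x-mirror; u odd (face-centred: face i <-> nx+2-i)
  vflip <- mid$v[nx:1, , ]
  expect_equal(mid$v, vflip, tolerance = 1e-6)
  uflip <- -mid$u[(nx + 1):1, , ]
  expect_equal(mid$u, uflip, tolerance = 1e-6)
})

test_that("lateral sites see faster near-wall flow than occlusal/gingival sites", {
  sim <- cached_sim("gingival_04", cell_size = 0.4)
  map <- near_wall_speed(sim$fields[[1]], sim$model, direction = "gingival")
  rav <- regional_average_velocity(map)
  sp <- setNames(rav$avg_speed_m_s, rav$site)
  expect_gt(min(sp["BL"], sp["BR"]), max(sp["BO"], sp["BG"]))
})

test_that("halving the cell size changes regional averages moderately", {
  coarse <- cached_sim("gingival_04", cell_size = 0.4)
  fine <- cached_sim("gingival_02", cell_size = 0.2)
  get_speeds <- function(sim) {
    map <- near_wall_speed(sim$fields[[1]], sim$model)
    setNames(regional_average_velocity(map)$avg_speed_m_s,
             regional_average_velocity(map)$site)
  }
  sc <- get_speeds(coarse); sf <- get_speeds(fine)
  expect_lt(max(abs(sf - sc) / sc), 0.10)
})
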