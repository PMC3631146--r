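test_that("near-wall sampling reproduces closed-form fields", {
  geo <- default_model()
  # uniform
  f <- analytic_field("uniform", list(velocity = c(0.05, 0, 0)), geo)
  map <- near_wall_speed(f, geo)
  expect_true(all(abs(map$speed_m_s - 0.05) < 1e-12))
  # zero
  expect_true(all(near_wall_speed(flow_field(geo), geo)$speed_m_s == 0))
  # linear shear u = alpha z sampled at the first cell-centre height h/2
  alpha <- 100
  fs <- analytic_field("shear", list(alpha = alpha), geo)
  ms <- near_wall_speed(fs, geo)
  expect_equal(unique(round(ms$speed_m_s, 12)),
               alpha * (geo$h / 2) * 1e-3)
  # appliance-covered cells are excluded
  expect_equal(nrow(map), sum(!geo$solid[, , 1]))
})

test_that("regional averages equal a brute-force area-weighted mean", {
  geo <- default_model()
  f <- flow_field(geo)
  set.seed(7)
  f$u[] <- runif(length(f$u), 0, 0.1)
  f$v[] <- runif(length(f$v), 0, 0.1)
  map <- near_wall_speed(f, geo)
  rav <- regional_average_velocity(map)
  for (s in c("BO", "BG", "BL", "BR")) {
    acc <- 0; area <- 0
    for (r in seq_len(nrow(map))) {
      if (!is.na(map$site[r]) && map$site[r] == s) {
        acc <- acc + map$speed_m_s[r] * map$area_mm2[r]
        area <- area + map$area_mm2[r]
      }
    }
    expect_equal(rav$avg_speed_m_s[rav$site == s], acc / area)
  }
  # uniform map: every site mean equals the uniform speed
  mu <- near_wall_speed(analytic_field("uniform",
                                       list(velocity = c(0.05, 0, 0)), geo),
                        geo)
  expect_true(all(abs(regional_average_velocity(mu)$avg_speed_m_s - 0.05) <
                    1e-12))
  # mirror-symmetric map: BL equals BR exactly
  sym <- setNames(rav$avg_speed_m_s, rav$site)
  msym <- map
  msym$speed_m_s <- sqrt((map$x_mm - 5)^2 + (map$y_mm - 5)^2)
  rs <- regional_average_velocity(msym)
  expect_equal(rs$avg_speed_m_s[rs$site == "BL"],
               rs$avg_speed_m_s[rs$site == "BR"], tolerance = 1e-14)
})

test_that("empty regions raise an error", {
  geo <- default_model()
  map <- near_wall_speed(flow_field(geo), geo)
  map$site[map$site == "BO"] <- NA
  expect_error(regional_average_velocity(map), "BO")
})

test_that("low-velocity area is threshold-monotone and exact on uniform fields", {
  geo <- default_model()
  u1 <- near_wall_speed(analytic_field("uniform",
                                       list(velocity = c(0.01, 0, 0)), geo),
                        geo)
  expect_equal(low_velocity_area(u1), 0)
  u2 <- near_wall_speed(analytic_field("uniform",
                                       list(velocity = c(0.001, 0, 0)), geo),
                        geo)
  expect_equal(low_velocity_area(u2, region = "BG"),
               region_areas(geo)$area_mm2[2])
  expect_error(low_velocity_area(u2, threshold = -1), "positive")
  # monotonicity over random maps
  set.seed(11)
  f <- flow_field(geo)
  f$u[] <- runif(length(f$u), 0, 0.02)
  m <- near_wall_speed(f, geo)
  thresholds <- sort(runif(10, 0, 0.02))
  areas <- vapply(thresholds, function(t)
    low_velocity_area(m, threshold = t), 1.0)
  expect_true(all(diff(areas) >= 0))
  # partition property: site areas sum to at most the whole-band area
  expect_lte(sum(vapply(c("BO", "BG", "BL", "BR"), function(s)
    low_velocity_area(m, region = s), 1.0)),
    low_velocity_area(m, region = "band") + 1e-9)
})

test_that("Lamb-Oseen slow core area matches the analytic disc within 2 cell-areas", {
  geo <- build_domain(domain_spec(cell_size = 0.05))
  vt <- function(r) lamb_oseen_vtheta(r, 3e-4, 2e-3)
  r1 <- uniroot(function(r) vt(r) - 0.005, c(1e-6, 1.12 * 2e-3),
                tol = 1e-12)$root
  disc <- pi * (r1 * 1000)^2
  for (ctr in list(c(5, 5), c(5.03, 4.97))) {
    fld <- analytic_field("lamb_oseen",
                          list(gamma = 3e-4, r_c = 2, center = ctr), geo)
    lva <- low_velocity_area(near_wall_speed(fld, geo))
    expect_lt(abs(lva - disc), 2 * geo$h^2)
  }
})

test_that("vortex detection is empty for uniform flow and locates analytic vortices", {
  geo <- default_model()
  f <- analytic_field("uniform", list(velocity = c(0.05, 0, 0)), geo)
  expect_equal(nrow(detect_vortices(f, geo)), 0)

  # single Lamb-Oseen vortex centred in BG
  ctr <- c(5, 2.5)
  f1 <- analytic_field("lamb_oseen",
                       list(gamma = 1e-4, r_c = 0.5, center = ctr), geo)
  vx <- detect_vortices(f1, geo, region = "BG")
  expect_equal(nrow(vx), 1)
  expect_lt(abs(vx$x_mm - ctr[1]), geo$h)
  expect_lt(abs(vx$y_mm - ctr[2]), geo$h)

  # two well-separated vortices
  f2 <- analytic_field("lamb_oseen",
                       list(gamma = 1e-4, r_c = 0.4, center = c(2, 2)),
                       build_domain(domain_spec()))
  f3 <- analytic_field("lamb_oseen",
                       list(gamma = 1e-4, r_c = 0.4, center = c(8, 8)),
                       build_domain(domain_spec()))
  f2$u <- f2$u + f3$u
  f2$v <- f2$v + f3$v
  open <- build_domain(domain_spec())
  vx2 <- detect_vortices(f2, open)
  expect_equal(nrow(vx2), 2)
  cents <- vx2[order(vx2$x_mm), ]
  expect_lt(max(abs(cents$x_mm - c(2, 8))), open$h)
  expect_lt(max(abs(cents$y_mm - c(2, 8))), open$h)
})

test_that("vortex detection commutes with 90-degree rotation and mirror reflection", {
  open <- build_domain(domain_spec())
  base <- c(4, 4)
  f <- analytic_field("lamb_oseen",
                      list(gamma = 1e-4, r_c = 0.5, center = base), open)
  v0 <- detect_vortices(f, open)
  # rotating the flow field by 90 degrees about the domain centre moves the
  # (rotationally symmetric) vortex to the rotated centre
  rot <- c(5 - (base[2] - 5), 5 + (base[1] - 5))
  fr <- analytic_field("lamb_oseen",
                       list(gamma = 1e-4, r_c = 0.5, center = rot), open)
  vr <- detect_vortices(fr, open)
  expect_equal(nrow(v0), nrow(vr))
  expect_equal(vr$area_mm2, v0$area_mm2)
  expect_equal(c(vr$x_mm, vr$y_mm), c(rot[1] + (v0$x_mm - base[1]),
                                      rot[2] + (v0$y_mm - base[2])),
               tolerance = 1e-9)
  # mirror reflection of the velocity arrays
  nx <- length(open$x)
  fm <- f
  fm$u <- -f$u[(nx + 1):1, , , drop = FALSE]
  fm$v <- f$v[nx:1, , , drop = FALSE]
  fm$w <- f$w[nx:1, , , drop = FALSE]
  vm <- detect_vortices(fm, open)
  expect_equal(nrow(vm), nrow(v0))
  expect_equal(vm$x_mm, 10 - v0$x_mm, tolerance = 1e-9)
  expect_equal(vm$y_mm, v0$y_mm, tolerance = 1e-9)
  expect_equal(vm$area_mm2, v0$area_mm2)
})

test_that("direction combination averages areas and speeds and keeps site pairing", {
  g <- tibble::tibble(site = c("BO", "BG", "BL", "BR"), direction = "gingival",
                      avg_speed_m_s = c(0.1, 0.08, 0.15, 0.15),
                      low_velocity_area_mm2 = c(2, 3, 0, 0),
                      vortex_area_mm2 = c(0, 1.9, 0, 0))
  o <- g
  o$direction <- "occlusal"
  o$low_velocity_area_mm2 <- c(3, 2, 0, 0)
  o$vortex_area_mm2 <- 0
  cmb <- combine_directions(g, o)
  expect_equal(cmb$low_velocity_area_mm2[cmb$site == "BO"], 2.5)
  expect_equal(cmb$vortex_area_mm2[cmb$site == "BG"], 1.9)
  expect_equal(cmb$avg_speed_m_s, g$avg_speed_m_s)
  same <- combine_directions(g, dplyr::mutate(g, direction = "occlusal"))
  expect_equal(same$low_velocity_area_mm2, g$low_velocity_area_mm2)
  bad <- o
  bad$site <- c("BO", "BG", "BL", "XX")
  expect_error(combine_directions(g, bad), "site mismatch")
})
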