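#' Near-wall speed map over the tooth surface
#'
#' Samples the speed magnitude in the first fluid cell layer above the
#' tooth surface (`z = 0`), the layer whose clearance action governs
#' plaque retention.  Cells covered by the appliance are excluded.
#'
#' @param field A `flow_field`, or an `nx x ny` matrix of speeds (m/s,
#'   e.g. the cycle-maximum map from [simulate_swallow()]).
#' @param model The `geometry_model`.
#' @param layer_height Sampling layer index (cells above the surface).
#' @param direction Optional direction tag stored with the map.
#' @return A `surface_speed_map` tibble: `i`, `j`, `x_mm`, `y_mm`, `site`,
#'   `speed_m_s`, `area_mm2`.
#' @export
near_wall_speed <- function(field, model, layer_height = 1, direction = NA) {
  sp <- if (is.matrix(field)) {
    m <- field
    m[model$solid[, , layer_height]] <- NA
    m
  } else {
    surface_speed_matrix(field, model, layer = layer_height)
  }
  out <- surface_cells(model)
  out$speed_m_s <- as.vector(sp)
  out$area_mm2 <- model$h^2
  out$direction <- direction
  out <- dplyr::filter(out, !.data$covered)
  out$covered <- NULL
  class(out) <- c("surface_speed_map", class(out))
  out
}

#' Area-weighted mean near-wall speed per peri-bracket site
#'
#' @param map A `surface_speed_map` (see [near_wall_speed()]).
#' @param model Unused placeholder kept for a uniform metric signature.
#' @return A tibble `site`, `avg_speed_m_s`, `area_mm2` for BO, BG, BL, BR.
#' @export
regional_average_velocity <- function(map, model = NULL) {
  sites <- c("BO", "BG", "BL", "BR")
  banded <- dplyr::filter(map, !is.na(.data$site))
  out <- banded |>
    dplyr::group_by(site = factor(.data$site, levels = sites)) |>
    dplyr::summarise(
      avg_speed_m_s = sum(.data$speed_m_s * .data$area_mm2) / sum(.data$area_mm2),
      area_mm2 = sum(.data$area_mm2), .groups = "drop") |>
    tidyr::complete(site = factor(sites, levels = sites))
  if (anyNA(out$avg_speed_m_s))
    stop("empty peri-bracket region(s): ",
         paste(out$site[is.na(out$avg_speed_m_s)], collapse = ", "),
         call. = FALSE)
  out$site <- as.character(out$site)
  out
}

#' Low-velocity area
#'
#' Total tooth-surface area where the near-wall speed does not exceed the
#' threshold (default 0.005 m/s = 5 mm/s, the plaque-retention proxy).
#'
#' @param map A `surface_speed_map`.
#' @param model Unused placeholder kept for a uniform metric signature.
#' @param threshold Speed threshold, m/s.
#' @param region Optional site label (`"BO"`, `"BG"`, `"BL"`, `"BR"`) or
#'   `"band"` for the whole 2-mm band; `NULL` = whole surface.
#' @return Area, mm^2.
#' @export
low_velocity_area <- function(map, model = NULL, threshold = 0.005,
                              region = NULL) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  sel <- map
  if (!is.null(region)) {
    sel <- if (identical(region, "band")) {
      dplyr::filter(map, !is.na(.data$site))
    } else {
      dplyr::filter(map, .data$site %in% region)
    }
  }
  sum(sel$area_mm2[!is.na(sel$speed_m_s) & sel$speed_m_s <= threshold])
}

# Mask-aware gradients of a surface matrix: central differences where both
# neighbours are fluid, one-sided next to solid cells or domain edges
# (differencing across the solid mask would manufacture spurious shear).
grad_surface <- function(M, h, fluid = NULL) {
  nx <- nrow(M); ny <- ncol(M)
  if (is.null(fluid)) fluid <- matrix(TRUE, nx, ny)
  one_axis <- function(val_m, val_p, ok_m, ok_p) {
    g <- matrix(0, nx, ny)
    both <- ok_m & ok_p
    g[both] <- (val_p[both] - val_m[both]) / (2 * h)
    fwd <- !ok_m & ok_p
    g[fwd] <- (val_p[fwd] - M[fwd]) / h
    bwd <- ok_m & !ok_p
    g[bwd] <- (M[bwd] - val_m[bwd]) / h
    g
  }
  gx <- one_axis(rbind(0, M[-nx, ]), rbind(M[-1, ], 0),
                 rbind(FALSE, fluid[-nx, ]), rbind(fluid[-1, ], FALSE))
  gy <- one_axis(cbind(0, M[, -ny]), cbind(M[, -1], 0),
                 cbind(FALSE, fluid[, -ny]), cbind(fluid[, -1], FALSE))
  list(gx = gx, gy = gy)
}

# 2D Q-criterion of the near-wall tangential field (1/s^2).
surface_q <- function(field, model, layer = 1) {
  n <- dim(field$p)
  uc <- 0.5 * (field$u[1:n[1], , layer] + field$u[2:(n[1] + 1), , layer])
  vc <- 0.5 * (field$v[, 1:n[2], layer] + field$v[, 2:(n[2] + 1), layer])
  solid <- model$solid[, , layer]
  uc[solid] <- 0; vc[solid] <- 0
  h <- model$h * 1e-3
  gu <- grad_surface(uc, h, fluid = !solid)
  gv <- grad_surface(vc, h, fluid = !solid)
  S11 <- gu$gx; S22 <- gv$gy
  S12 <- 0.5 * (gu$gy + gv$gx)
  O12 <- 0.5 * (gu$gy - gv$gx)
  Q <- 0.5 * (2 * O12^2 - (S11^2 + S22^2 + 2 * S12^2))
  Q[solid] <- NA
  Q
}

# 4-connected component labelling of a logical matrix (NA = excluded).
label_components <- function(mask) {
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo) > 0) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    nx <- nrow(mask)
    while (length(queue) > 0) {
      cell <- queue[1]; queue <- queue[-1]
      i <- (cell - 1L) %% nx + 1L
      j <- (cell - 1L) %/% nx + 1L
      nb <- c(if (i > 1) cell - 1L, if (i < nx) cell + 1L,
              if (j > 1) cell - nx, if (j < ncol(mask)) cell + nx)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Detect near-wall vortices
#'
#' Identifies closed-recirculation regions on the tooth surface as
#' connected components of cells whose 2D Q-criterion (second invariant of
#' the tangential velocity-gradient tensor) exceeds `eps_q`.  Components
#' are reported with their area-weighted centroid and area, ordered by
#' area descending then by centroid coordinates.
#'
#' @param field A `flow_field`.
#' @param model The `geometry_model`.
#' @param region Optional site label; only components intersecting that
#'   peri-bracket region are returned.
#' @param eps_q Q threshold, 1/s^2.
#' @param layer_height Sampling layer (cells above the surface).
#' @return A tibble: `vortex`, `x_mm`, `y_mm` (centroid), `area_mm2`,
#'   `sites` (comma-joined region labels the component touches).
#' @export
detect_vortices <- function(field, model, region = NULL, eps_q = 1e-6,
                            layer_height = 1) {
  Q <- surface_q(field, model, layer = layer_height)
  lab <- label_components(Q > eps_q)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0)
    return(tibble::tibble(vortex = integer(), x_mm = numeric(),
                          y_mm = numeric(), area_mm2 = numeric(),
                          sites = character()))
  nx <- nrow(lab)
  out <- purrr::map_dfr(ids, function(id) {
    cells <- which(lab == id)
    i <- (cells - 1L) %% nx + 1L
    j <- (cells - 1L) %/% nx + 1L
    touched <- sort(unique(stats::na.omit(model$region[cells])))
    tibble::tibble(x_mm = mean(model$x[i]), y_mm = mean(model$y[j]),
                   area_mm2 = length(cells) * model$h^2,
                   sites = paste(touched, collapse = ","),
                   .cells = list(cells))
  })
  if (!is.null(region)) {
    hit <- purrr::map_lgl(out$.cells, function(cells)
      any(model$region[cells] %in% region, na.rm = TRUE))
    out <- out[hit, , drop = FALSE]
  }
  out <- out[order(-out$area_mm2, out$x_mm, out$y_mm), , drop = FALSE]
  out$.cells <- NULL
  out$vortex <- seq_len(nrow(out))
  dplyr::relocate(out, "vortex")
}

#' Per-site vortex area
#'
#' Area of Q-positive (recirculating) cells inside each peri-bracket
#' region.
#'
#' @inheritParams detect_vortices
#' @return A tibble `site`, `vortex_area_mm2`.
#' @export
vortex_area_by_site <- function(field, model, eps_q = 1e-6, layer_height = 1) {
  Q <- surface_q(field, model, layer = layer_height)
  sites <- c("BO", "BG", "BL", "BR")
  pos <- !is.na(Q) & Q > eps_q
  area <- vapply(sites, function(s)
    sum(pos & !is.na(model$region) & model$region == s) * model$h^2, 1.0)
  tibble::tibble(site = sites, vortex_area_mm2 = unname(area))
}

#' Assemble the per-site flow metrics for one direction
#'
#' @param map A `surface_speed_map` (typically the cycle-maximum map).
#' @param model The `geometry_model`.
#' @param field Optional `flow_field` snapshot for vortex identification
#'   (e.g. the mid-cycle field); vortex areas are 0 when absent.
#' @param direction Direction tag (`"gingival"`, `"occlusal"`).
#' @param threshold Low-velocity threshold, m/s.
#' @param eps_q Q-criterion threshold, 1/s^2.
#' @return A `region_metrics` tibble: `site`, `direction`,
#'   `avg_speed_m_s`, `low_velocity_area_mm2`, `vortex_area_mm2`.
#' @export
region_metrics <- function(map, model, field = NULL, direction = NA,
                           threshold = 0.005, eps_q = 1e-6) {
  out <- regional_average_velocity(map, model)
  out$low_velocity_area_mm2 <- vapply(out$site, function(s)
    low_velocity_area(map, model, threshold = threshold, region = s), 1.0)
  va <- if (is.null(field)) {
    tibble::tibble(site = out$site, vortex_area_mm2 = 0)
  } else {
    vortex_area_by_site(field, model, eps_q = eps_q)
  }
  out <- dplyr::left_join(out, va, by = "site")
  out$direction <- direction
  out$area_mm2 <- NULL
  out <- dplyr::relocate(out, "site", "direction")
  class(out) <- c("region_metrics", class(out))
  out
}

#' Combine gingival- and occlusal-direction metrics
#'
#' A tooth experiences swallows in both directions; the combined
#' plaque-retention picture averages the directional mean speeds and
#' low-velocity areas and takes the larger of the two directional vortex
#' areas (vortices form under one direction only).
#'
#' @param gingival,occlusal `region_metrics` tibbles for the two
#'   directions, same sites.
#' @return A `region_metrics` tibble with `direction = "combined"`.
#' @export
combine_directions <- function(gingival, occlusal) {
  sites <- c("BO", "BG", "BL", "BR")
  g <- dplyr::arrange(gingival, factor(.data$site, sites))
  o <- dplyr::arrange(occlusal, factor(.data$site, sites))
  if (!identical(g$site, o$site))
    stop("site mismatch between the two directions", call. = FALSE)
  out <- tibble::tibble(
    site = g$site,
    direction = "combined",
    avg_speed_m_s = (g$avg_speed_m_s + o$avg_speed_m_s) / 2,
    low_velocity_area_mm2 = (g$low_velocity_area_mm2 + o$low_velocity_area_mm2) / 2,
    vortex_area_mm2 = pmax(g$vortex_area_mm2, o$vortex_area_mm2))
  class(out) <- c("region_metrics", class(out))
  out
}
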