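#' Specify the vestibular fluid domain
#'
#' The computational domain is the thin film of saliva held in the labial
#' vestibule against the tooth surface: a rectangular box whose `z = 0` face
#' is the (flattened) labial tooth surface.  Axes follow the clinical
#' convention used throughout the package: `x` is mesio-distal (viewer's
#' left/right when facing the tooth), `y` is occluso-gingival with occlusal
#' = +y, and `z` is the labio-lingual protrusion away from the tooth.
#'
#' The defaults (10 x 10 x 1.4 mm) give a saliva volume of 140 mm^3 =
#' 0.14 ml, the volume of the film driven by one swallow.
#'
#' @param length_md Mesio-distal extent (x), mm.
#' @param length_og Occluso-gingival extent (y), mm.
#' @param depth Labio-lingual extent (z), mm -- the saliva film thickness.
#' @param cell_size Uniform Cartesian cell edge, mm.
#' @return A `domain_spec` object (list).
#' @export
#' @examples
#' d <- domain_spec()
#' d$length_md * d$length_og * d$depth  # 140 mm^3 = 0.14 ml
domain_spec <- function(length_md = 10, length_og = 10, depth = 1.4,
                        cell_size = 0.2) {
  stopifnot(is.numeric(length_md), is.numeric(length_og), is.numeric(depth),
            is.numeric(cell_size))
  if (length_md <= 0 || length_og <= 0 || depth <= 0)
    stop("domain extents must be positive", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  dims <- c(nx = round(length_md / cell_size + 1e-6),
            ny = round(length_og / cell_size + 1e-6),
            nz = round(depth / cell_size + 1e-6))
  if (any(dims < 4))
    stop("grid must have at least 4 cells per axis; reduce cell_size",
         call. = FALSE)
  structure(list(length_md = length_md, length_og = length_og, depth = depth,
                 cell_size = cell_size, dims = dims,
                 origin = "tooth-surface corner (x=0, y=0 gingival edge, z=0)"),
            class = "domain_spec")
}

#' Specify the orthodontic appliance
#'
#' The bracket is modelled as a rectangular prism bonded to the tooth
#' surface (base on the `z = 0` plane); the archwire, when present, is a
#' horizontal cylinder running mesio-distally across the whole domain,
#' resting labial to the bracket at the slot height
#' `z = bracket_thickness + wire_diameter / 2`.
#'
#' The default bracket width of 2.4 mm is the clinical width scale of the
#' twin bracket on a lower central incisor; 0.014 inch = 0.3556 mm is the
#' initial-levelling nitinol archwire.  Height and labial thickness are not
#' clinically standardised at this abstraction and are exposed as
#' parameters; the default thickness (1.0 mm) leaves room inside the 1.4 mm
#' saliva film for the wire.
#'
#' @param bracket_width Mesio-distal bracket extent, mm.
#' @param bracket_height Occluso-gingival bracket extent, mm.
#' @param bracket_thickness Labial protrusion of the bracket from the tooth
#'   surface, mm.
#' @param wire_diameter Archwire diameter, mm (0.014 inch default).
#' @param wire_present Logical; `TRUE` models the post-wire-placement (T2)
#'   configuration, `FALSE` the bracket-only (T1) configuration.
#' @param bracket_center `(x, y)` of the bracket centre on the tooth plane,
#'   mm; defaults to the domain centre when used with [build_domain()]'s
#'   default domain.
#' @return An `appliance_spec` object (list).
#' @export
appliance_spec <- function(bracket_width = 2.4, bracket_height = 3.0,
                           bracket_thickness = 1.0,
                           wire_diameter = 0.3556, wire_present = FALSE,
                           bracket_center = c(5, 5)) {
  if (bracket_width <= 0 || bracket_height <= 0 || bracket_thickness <= 0)
    stop("bracket dimensions must be positive (degenerate appliance)",
         call. = FALSE)
  if (wire_present && wire_diameter <= 0)
    stop("wire_diameter must be positive when wire_present", call. = FALSE)
  stopifnot(length(bracket_center) == 2)
  structure(list(bracket_width = bracket_width,
                 bracket_height = bracket_height,
                 bracket_thickness = bracket_thickness,
                 wire_diameter = wire_diameter,
                 wire_present = isTRUE(wire_present),
                 bracket_center = as.numeric(bracket_center)),
            class = "appliance_spec")
}

# Tolerance for point-in-solid comparisons (mm): cell centres that land
# exactly on an appliance boundary must rasterise symmetrically.
geom_eps <- 1e-9

# Cell-centre coordinates (mm) along one axis: half-integer offsets.
cell_centers <- function(n, h) (seq_len(n) - 0.5) * h

#' Build the discretised geometry model
#'
#' Rasterises the appliance onto the uniform Cartesian grid: a cell is
#' solid when its centre lies inside the bracket prism or the wire
#' cylinder.  Also labels the four peri-bracket regions on the tooth
#' surface via [partition_peri_bracket()].
#'
#' @param spec A [domain_spec()].
#' @param appliance An [appliance_spec()].
#' @param band_width Width of the peri-bracket sampling band, mm.
#' @return A `geometry_model` object: the two specs plus `solid` (logical
#'   `nx x ny x nz` array), `region` (character `nx x ny` matrix with
#'   values `BO`, `BG`, `BL`, `BR` or `NA`), cell-centre coordinate
#'   vectors `x`, `y`, `z` (mm) and `h` (cell size, mm).
#' @export
#' @examples
#' geo <- build_domain(domain_spec(), appliance_spec())
#' table(geo$region)
build_domain <- function(spec, appliance = NULL, band_width = 2.0) {
  stopifnot(inherits(spec, "domain_spec"))
  if (is.null(appliance)) {
    # appliance-free film (validation/channel configurations)
    h <- spec$cell_size
    n <- spec$dims
    return(structure(list(spec = spec, appliance = NULL,
                          solid = array(FALSE, dim = unname(n)),
                          region = NULL,
                          x = cell_centers(n["nx"], h),
                          y = cell_centers(n["ny"], h),
                          z = cell_centers(n["nz"], h),
                          h = h, band_width = band_width),
                     class = "geometry_model"))
  }
  stopifnot(inherits(appliance, "appliance_spec"))
  cx <- appliance$bracket_center[1]
  cy <- appliance$bracket_center[2]
  hw <- appliance$bracket_width / 2
  hh <- appliance$bracket_height / 2
  margins <- c(left = cx - hw, right = spec$length_md - (cx + hw),
               gingival = cy - hh, occlusal = spec$length_og - (cy + hh))
  bad <- margins < band_width - 1e-9
  if (any(bad))
    stop("bracket footprint violates the ", band_width,
         " mm margin on the ", paste(names(margins)[bad], collapse = ", "),
         " side(s) of the domain", call. = FALSE)
  if (appliance$bracket_thickness > spec$depth)
    stop("bracket_thickness exceeds domain depth", call. = FALSE)

  h <- spec$cell_size
  n <- spec$dims
  x <- cell_centers(n["nx"], h)
  y <- cell_centers(n["ny"], h)
  z <- cell_centers(n["nz"], h)

  solid <- array(FALSE, dim = unname(n))
  in_x <- abs(x - cx) <= hw + geom_eps
  in_y <- abs(y - cy) <= hh + geom_eps
  in_z <- z <= appliance$bracket_thickness + geom_eps
  solid[in_x, in_y, in_z] <- TRUE

  model <- structure(list(spec = spec, appliance = appliance,
                          solid = solid, region = NULL,
                          x = x, y = y, z = z, h = h,
                          band_width = band_width),
                     class = "geometry_model")
  if (appliance$wire_present) model <- toggle_archwire(model, TRUE)
  partition_peri_bracket(model, band_width)
}

# Logical nx x ny x nz array of cells whose centre lies inside the wire
# cylinder (axis along x at y = cy, z = thickness + r).
wire_mask <- function(model) {
  ap <- model$appliance
  r <- ap$wire_diameter / 2
  zc <- ap$bracket_thickness + r
  yc <- ap$bracket_center[2]
  in_circ <- outer(model$y, model$z,
                   function(yy, zz) (yy - yc)^2 + (zz - zc)^2 <= r^2 + geom_eps)
  n <- dim(model$solid)
  aperm(array(rep(in_circ, n[1]), dim = c(n[2], n[3], n[1])), c(3, 1, 2))
}

#' Add or remove the archwire from the solid mask
#'
#' @param model A `geometry_model`.
#' @param present Logical; desired wire state.
#' @return The model with the wire cylinder added to or removed from the
#'   solid mask; all other fields unchanged.
#' @export
toggle_archwire <- function(model, present) {
  stopifnot(inherits(model, "geometry_model"))
  if (is.null(model$appliance))
    stop("model has no appliance to carry a wire", call. = FALSE)
  if (present == model$appliance$wire_present && !is.null(model$region))
    return(model)
  wm <- wire_mask(model)
  if (present) {
    model$solid <- model$solid | wm
  } else {
    # remove wire cells not shared with the bracket prism
    bracket <- rebuild_bracket_mask(model)
    model$solid <- model$solid & !(wm & !bracket)
  }
  model$appliance$wire_present <- present
  if (!is.null(model$region)) model <- partition_peri_bracket(model, model$band_width)
  model
}

rebuild_bracket_mask <- function(model) {
  ap <- model$appliance
  cx <- ap$bracket_center[1]; cy <- ap$bracket_center[2]
  solid <- array(FALSE, dim = dim(model$solid))
  solid[abs(model$x - cx) <= ap$bracket_width / 2 + geom_eps,
        abs(model$y - cy) <= ap$bracket_height / 2 + geom_eps,
        model$z <= ap$bracket_thickness + geom_eps] <- TRUE
  solid
}

#' Label the four peri-bracket regions on the tooth surface
#'
#' The sampling band extends `band_width` (default 2 mm) beyond the bracket
#' footprint in each lateral direction (rectangular expansion, so its area
#' is `(W + 2b)(H + 2b) - W*H`).  Each band cell is assigned to the side of
#' the nearest bracket edge: `BO` occlusal (+y), `BG` gingival (-y), `BL` /
#' `BR` the viewer's-left / viewer's-right lateral sides.  Corner cells,
#' equidistant from two edges, go to the lateral region (deterministic
#' tie-break).
#'
#' @param model A `geometry_model`.
#' @param band_width Band width, mm.
#' @return The model with its `region` matrix (re)computed.
#' @export
partition_peri_bracket <- function(model, band_width = 2.0) {
  stopifnot(inherits(model, "geometry_model"))
  if (is.null(model$appliance))
    stop("model has no appliance; no peri-bracket band to label", call. = FALSE)
  ap <- model$appliance
  cx <- ap$bracket_center[1]; cy <- ap$bracket_center[2]
  hw <- ap$bracket_width / 2; hh <- ap$bracket_height / 2
  if (cx - hw - band_width < -1e-9 ||
      cx + hw + band_width > model$spec$length_md + 1e-9 ||
      cy - hh - band_width < -1e-9 ||
      cy + hh + band_width > model$spec$length_og + 1e-9)
    stop("peri-bracket band of width ", band_width,
         " mm exceeds the domain", call. = FALSE)

  nx <- length(model$x); ny <- length(model$y)
  X <- matrix(model$x, nx, ny)
  Y <- matrix(model$y, nx, ny, byrow = TRUE)
  # signed excess distance past the footprint edges (<= 0 means inside span)
  dx <- abs(X - cx) - hw
  dy <- abs(Y - cy) - hh
  in_band <- dx <= band_width + geom_eps & dy <= band_width + geom_eps &
    (dx > geom_eps | dy > geom_eps)
  region <- matrix(NA_character_, nx, ny)
  # nearest-edge ownership: perpendicular distance to the lateral edge line
  # is dx, to the occlusal/gingival line dy; tie -> lateral
  lateral <- in_band & dx > geom_eps & (dy <= geom_eps | dx <= dy + geom_eps)
  og <- in_band & !lateral
  region[lateral & X < cx] <- "BL"
  region[lateral & X >= cx] <- "BR"
  region[og & Y > cy] <- "BO"
  region[og & Y <= cy] <- "BG"
  model$region <- region
  model$band_width <- band_width
  model
}

#' @export
print.geometry_model <- function(x, ...) {
  n <- dim(x$solid)
  cat("<geometry_model> ", x$spec$length_md, "x", x$spec$length_og, "x",
      x$spec$depth, " mm, h = ", x$h, " mm (", n[1], "x", n[2], "x", n[3],
      " cells)\n", sep = "")
  if (is.null(x$appliance)) {
    cat("  appliance-free film; solid cells: 0\n")
    return(invisible(x))
  }
  cat("  bracket ", x$appliance$bracket_width, "x",
      x$appliance$bracket_height, "x", x$appliance$bracket_thickness,
      " mm; archwire ", if (x$appliance$wire_present) "present" else "absent",
      "\n", sep = "")
  cat("  solid cells: ", sum(x$solid), "; band cells: ",
      sum(!is.na(x$region)), "\n", sep = "")
  invisible(x)
}

#' Peri-bracket region areas
#'
#' @param model A `geometry_model`.
#' @return A tibble with one row per site (`BO`, `BG`, `BL`, `BR`) and its
#'   area in mm^2.
#' @export
region_areas <- function(model) {
  stopifnot(inherits(model, "geometry_model"), !is.null(model$region))
  tab <- table(factor(model$region, levels = c("BO", "BG", "BL", "BR")))
  tibble::tibble(site = names(tab),
                 area_mm2 = as.numeric(tab) * model$h^2)
}

#' Tooth-surface cells as a tibble
#'
#' One row per tooth-surface grid cell with its centre coordinates, region
#' label and whether the appliance covers it (solid at the first cell
#' layer).
#'
#' @param model A `geometry_model`.
#' @return A tibble: `i`, `j`, `x_mm`, `y_mm`, `site`, `covered`.
#' @export
surface_cells <- function(model) {
  nx <- length(model$x); ny <- length(model$y)
  tibble::tibble(
    i = rep(seq_len(nx), times = ny),
    j = rep(seq_len(ny), each = nx),
    x_mm = rep(model$x, times = ny),
    y_mm = rep(model$y, each = nx),
    site = as.vector(model$region),
    covered = as.vector(model$solid[, , 1]))
}
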