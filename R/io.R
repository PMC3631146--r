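record_cols <- c("patient_id", "timepoint", "site", "log10_cfu", "gi", "pd")

#' Read a clinical-record CSV
#'
#' Validates the schema: required columns, timepoints in T0/T1/T2, known
#' site labels, positive log10 CFU and non-negative pocket depth.
#' Violations raise an error naming the offending row and column.
#'
#' @param path CSV path.
#' @return A tibble of clinical records.
#' @export
read_records <- function(path) {
  recs <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(record_cols, names(recs))
  if (length(miss) > 0)
    stop("record CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!recs$timepoint %in% timepoint_levels)
  if (length(bad) > 0)
    stop("invalid timepoint ", shQuote(recs$timepoint[bad[1]]),
         " in column 'timepoint', row ", bad[1], call. = FALSE)
  bad <- which(!recs$site %in% site_levels)
  if (length(bad) > 0)
    stop("invalid site ", shQuote(recs$site[bad[1]]),
         " in column 'site', row ", bad[1], call. = FALSE)
  bad <- which(!is.na(recs$log10_cfu) & recs$log10_cfu <= 0)
  if (length(bad) > 0)
    stop("non-positive log10_cfu in row ", bad[1], call. = FALSE)
  bad <- which(!is.na(recs$pd) & recs$pd < 0)
  if (length(bad) > 0)
    stop("negative pd in row ", bad[1], call. = FALSE)
  recs[record_cols]
}

#' Write a clinical-record CSV
#'
#' @param records A tibble of clinical records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records[record_cols], path)
  invisible(path)
}

fmt4 <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))

#' Microbial summary tables (averages and site differences)
#'
#' Builds the two blocks of the per-site bacterial table from
#' patient-level records: per-site mean +/- SD of log10 CFU at T1 and T2,
#' and the six pairwise site differences with paired-t p-values.
#'
#' @param records Patient-level clinical records.
#' @return A list of tibbles `averages` and `differences`.
#' @export
microbial_tables <- function(records) {
  sm <- summarize_sites(records, "log10_cfu")
  avg <- sm |>
    dplyr::filter(.data$timepoint %in% c("T1", "T2")) |>
    tidyr::pivot_wider(id_cols = "site", names_from = "timepoint",
                       values_from = c("mean", "sd"))
  d1 <- site_differences(records, "T1")
  d2 <- site_differences(records, "T2")
  diffs <- dplyr::full_join(d1, d2, by = "pair", suffix = c("_T1", "_T2"))
  list(averages = avg, differences = diffs)
}

#' Write the report tables as CSV
#'
#' Emits the per-site averages, the pairwise site differences and the
#' longitudinal periodontal table, all with 4-decimal formatting.
#'
#' @param records Patient-level clinical records.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mt <- microbial_tables(records)
  lr <- longitudinal_report(records)
  fmt_tbl <- function(tb) {
    tb[] <- lapply(tb, function(col) if (is.numeric(col)) fmt4(col) else col)
    tb
  }
  paths <- file.path(dir, c("table1_averages.csv", "table1_differences.csv",
                            "table2_longitudinal.csv"))
  readr::write_csv(fmt_tbl(mt$averages), paths[1])
  readr::write_csv(fmt_tbl(mt$differences), paths[2])
  readr::write_csv(fmt_tbl(lr), paths[3])
  invisible(paths)
}

#' Write region labels as CSV
#'
#' @param model A `geometry_model`.
#' @param path Output CSV path (`x_mm`, `y_mm`, `label`).
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(model, path) {
  sc <- surface_cells(model)
  out <- tibble::tibble(x_mm = sc$x_mm, y_mm = sc$y_mm,
                        label = ifelse(is.na(sc$site), "NONE", sc$site))
  readr::write_csv(out, path)
  invisible(path)
}

vtk_header <- function(title, dims, origin, spacing) {
  c("# vtk DataFile Version 3.0", title, "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", dims[1], dims[2], dims[3]),
    paste("ORIGIN", origin[1], origin[2], origin[3]),
    paste("SPACING", spacing[1], spacing[2], spacing[3]))
}

#' Write the geometry mask and region labels as legacy VTK
#'
#' Cell-centred structured-points file with the solid mask (0/1) and the
#' peri-bracket region code (0 none, 1 BO, 2 BG, 3 BL, 4 BR; -1 solid).
#'
#' @param model A `geometry_model`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_geometry <- function(model, path) {
  n <- dim(model$solid)
  h <- model$h
  codes <- c(BO = 1, BG = 2, BL = 3, BR = 4)
  reg2d <- matrix(0, n[1], n[2])
  known <- !is.na(model$region)
  reg2d[known] <- codes[model$region[known]]
  reg <- array(0, n)
  reg[, , 1] <- reg2d
  reg[model$solid] <- -1
  lines <- c(vtk_header("periflow geometry", n, rep(h / 2, 3), rep(h, 3)),
             paste("POINT_DATA", prod(n)),
             "SCALARS solid int 1", "LOOKUP_TABLE default",
             paste(as.integer(model$solid), collapse = " "),
             "SCALARS region int 1", "LOOKUP_TABLE default",
             paste(as.integer(reg), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a flow-field snapshot as legacy VTK
#'
#' Velocities are averaged to cell centres and written as a vector field
#' with the pressure scalar.
#'
#' @param field A `flow_field`.
#' @param model The `geometry_model`.
#' @param path Output `.vtk` path (conventionally stamped with the time
#'   in ms, e.g. `field_t0125ms.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, model, path) {
  n <- dim(field$p)
  h <- model$h
  uc <- 0.5 * (field$u[1:n[1], , , drop = FALSE] +
               field$u[2:(n[1] + 1), , , drop = FALSE])
  vc <- 0.5 * (field$v[, 1:n[2], , drop = FALSE] +
               field$v[, 2:(n[2] + 1), , drop = FALSE])
  wc <- 0.5 * (field$w[, , 1:n[3], drop = FALSE] +
               field$w[, , 2:(n[3] + 1), drop = FALSE])
  vec <- cbind(as.vector(uc), as.vector(vc), as.vector(wc))
  lines <- c(vtk_header(sprintf("periflow field t=%.6f s", field$time),
                        n, rep(h / 2, 3), rep(h, 3)),
             paste("POINT_DATA", prod(n)),
             "VECTORS velocity float",
             paste(apply(format(vec, scientific = TRUE, digits = 7), 1, paste,
                         collapse = " "),
                   collapse = "\n"),
             "SCALARS pressure float 1", "LOOKUP_TABLE default",
             paste(format(as.vector(field$p), scientific = TRUE, digits = 7),
                   collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read geometry configuration
#'
#' YAML round-trip of the domain and appliance specification, all in mm.
#'
#' @param spec A [domain_spec()].
#' @param appliance An [appliance_spec()].
#' @param path YAML path.
#' @return `write_geometry_config()`: `path` invisibly;
#'   `read_geometry_config()`: a list with `spec` and `appliance`.
#' @export
write_geometry_config <- function(spec, appliance, path) {
  yaml::write_yaml(list(
    domain = list(length_md = spec$length_md, length_og = spec$length_og,
                  depth = spec$depth, cell_size = spec$cell_size),
    appliance = list(bracket_width = appliance$bracket_width,
                     bracket_height = appliance$bracket_height,
                     bracket_thickness = appliance$bracket_thickness,
                     wire_diameter = appliance$wire_diameter,
                     wire_present = appliance$wire_present,
                     bracket_center = appliance$bracket_center)), path)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path))
    stop("geometry config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  list(spec = do.call(domain_spec, cfg$domain),
       appliance = do.call(appliance_spec, cfg$appliance))
}
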