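#' Export a cell mesh as an OFF file
#'
#' @param cell a `polyhedral_cell`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_off <- function(cell, path) {
  stopifnot(inherits(cell, "polyhedral_cell"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nrow(cell$vertices), length(cell$faces),
                     nrow(cell$edges)), con)
  writeLines(apply(cell$vertices, 1, function(v)
    sprintf("%.12g %.12g %.12g", v[1], v[2], v[3])), con)
  writeLines(vapply(cell$faces, function(f)
    paste(c(length(f), f - 1L), collapse = " "), character(1)), con)
  invisible(path)
}

#' Export a cell mesh as legacy VTK polydata
#'
#' @param cell a `polyhedral_cell`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(cell, path) {
  stopifnot(inherits(cell, "polyhedral_cell"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("network cell g=%d (%s), lengths in a_x",
                       cell$g_label, cell$name),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(cell$vertices))), con)
  writeLines(apply(cell$vertices, 1, function(v)
    sprintf("%.12g %.12g %.12g", v[1], v[2], v[3])), con)
  sizes <- vapply(cell$faces, length, integer(1))
  writeLines(sprintf("POLYGONS %d %d", length(cell$faces),
                     sum(sizes) + length(sizes)), con)
  writeLines(vapply(cell$faces, function(f)
    paste(c(length(f), f - 1L), collapse = " "), character(1)), con)
  invisible(path)
}

#' Export a free-energy field as a VTK structured grid
#'
#' @param field a `free_energy_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, path) {
  stopifnot(inherits(field, "free_energy_field"))
  con <- file(path, "w")
  on.exit(close(con))
  nx <- length(field$x); ny <- length(field$y); nz <- length(field$z)
  writeLines(c("# vtk DataFile Version 3.0",
               "free energy change dF in k_BT on a grid in a_x",
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("X_COORDINATES %d double", nx),
               paste(sprintf("%.10g", field$x), collapse = " "),
               sprintf("Y_COORDINATES %d double", ny),
               paste(sprintf("%.10g", field$y), collapse = " "),
               sprintf("Z_COORDINATES %d double", nz),
               paste(sprintf("%.10g", field$z), collapse = " "),
               sprintf("POINT_DATA %d", nx * ny * nz),
               "SCALARS dF double 1", "LOOKUP_TABLE default"), con)
  vals <- as.numeric(aperm(field$values, c(1, 2, 3)))
  writeLines(paste(sprintf("%.8g", vals), collapse = " "), con)
  invisible(path)
}

#' Export bead-network coordinates as XYZ plus a JSON adjacency sidecar
#'
#' @param network a `bead_network`.
#' @param path XYZ output file; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(network, path) {
  stopifnot(inherits(network, "bead_network"))
  con <- file(path, "w")
  writeLines(as.character(nrow(network$sites)), con)
  writeLines("bead-spring network, coordinates in a_x", con)
  kind <- ifelse(seq_len(nrow(network$sites)) <= nrow(network$crosslinks),
                 "X", "B")
  writeLines(sprintf("%s %.12g %.12g %.12g", kind, network$sites[, 1],
                     network$sites[, 2], network$sites[, 3]), con)
  close(con)
  jsonlite::write_json(
    list(springs = network$springs, pinned = which(network$pinned),
         N = network$N, b = network$b, a_x = network$a_x),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a curve or table as CSV with a unit-bearing header comment
#'
#' @param df data frame.
#' @param path output file.
#' @param units character comment naming the units (a_x, tau, k_BT).
#' @return `path`, invisibly.
#' @export
write_units_csv <- function(df, path, units) {
  con <- file(path, "w")
  writeLines(paste0("# units: ", units), con)
  close(con)
  suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                               append = TRUE, quote = FALSE))
  invisible(path)
}

#' Export an MEP profile as CSV
#'
#' @param profile an `mep_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write_units_csv(data.frame(z = profile$z, dF = profile$dF), path,
                  "z in a_x, dF in k_BT")
}

#' Generate the desk-scale fixture suite
#'
#' Writes the small deterministic inputs used by the tests and examples:
#' tetrahedron and cube meshes, a low-resolution cube landscape profile at
#' the reference diameter `d/a_x = 1.4`, a flat-potential free-diffusion NLE
#' configuration, and an exact power-law series for exponent-fit checks.
#' Idempotent.
#'
#' @param out_dir writable directory.
#' @return Named list of file paths, invisibly.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (g in c(4, 6)) {
    cell <- build_cell(g)
    paths[[paste0("cell_g", g)]] <-
      write_off(cell, file.path(out_dir, sprintf("cell_g%d.off", g)))
  }
  prof <- mep_profile(build_cell(6), 1.4, n_z = 16)
  paths$cube_d1.4 <- write_profile_csv(prof,
                                       file.path(out_dir, "cube_d1.4_profile.csv"))
  cfg <- nle_config(t_total = 1e4, n_replicas = 64L, seed = 20L)
  paths$free_diffusion <- file.path(out_dir, "free_diffusion_config.json")
  jsonlite::write_json(unclass(cfg), paths$free_diffusion, auto_unbox = TRUE)
  x <- 10^seq(0, 1, length.out = 20)
  paths$power_law <- write_units_csv(data.frame(x = x, y = 3 * x^2),
                                     file.path(out_dir, "power_law_series.csv"),
                                     "dimensionless")
  invisible(paths)
}
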