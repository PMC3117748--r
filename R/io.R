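## Scalar-field export / import.
##
## Three formats, all round-tripping values bit-identically:
##  * "vtk"   — legacy ASCII structured-points (spacing/origin in the header);
##  * "nifti" — NIfTI-1 via RNifti, stored as float64 with pixdim = spacing;
##  * "csv"   — one node per row (x_mm, y_mm, z_mm, value) plus a comment
##              header carrying the unit and spacing.
## Doubles are written with 17 significant digits ("%.17g"), which is
## sufficient to reproduce an IEEE double exactly.

field_format_from_path <- function(path) {
  low <- tolower(path)
  if (grepl("\\.vtk$", low)) "vtk"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.csv$", low)) "csv"
  else stop_validation(sprintf(
    "cannot guess a field format from `%s`; pass `format` explicitly.", path))
}

#' Export a scalar field to VTK, NIfTI, or CSV
#'
#' @param field a `scalar_field`.
#' @param path output path; the extension is used to guess `format` when it
#'   is not given.
#' @param format `"vtk"` (legacy ASCII structured points), `"nifti"`, or
#'   `"csv"`.
#' @return the path, invisibly.
#' @seealso [read_field()] for the inverse.
#' @export
export_field <- function(field, path, format = NULL) {
  stopifnot(inherits(field, "scalar_field"))
  format <- format %||% field_format_from_path(path)
  if (!format %in% c("vtk", "nifti", "csv")) {
    stop_validation(sprintf(
      "unknown field format `%s` (supported: vtk, nifti, csv).", format))
  }
  grid <- field$grid
  if (format == "vtk") {
    con <- file(path, "wb")  # binary mode: deterministic \n line endings
    on.exit(close(con))
    writeLines(c(
      "# vtk DataFile Version 3.0",
      sprintf("littsim scalar field; unit=%s", field$unit),
      "ASCII",
      "DATASET STRUCTURED_POINTS",
      sprintf("DIMENSIONS %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3]),
      sprintf("ORIGIN %.17g %.17g %.17g", grid$origin[1], grid$origin[2], grid$origin[3]),
      sprintf("SPACING %.17g %.17g %.17g", grid$spacing, grid$spacing, grid$spacing),
      sprintf("POINT_DATA %d", n_nodes(grid)),
      "SCALARS value double 1",
      "LOOKUP_TABLE default",
      ## VTK point order is x-fastest, matching R array storage order
      sprintf("%.17g", as.vector(field$values))
    ), con = con)
  } else if (format == "nifti") {
    img <- RNifti::asNifti(field$values)
    RNifti::pixdim(img) <- rep(grid$spacing, 3)
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    coords <- node_coordinates(grid)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(
      sprintf("# littsim scalar field; unit=%s; spacing=%.17g; origin=%.17g %.17g %.17g",
              field$unit, grid$spacing, grid$origin[1], grid$origin[2], grid$origin[3]),
      "x_mm,y_mm,z_mm,value",
      sprintf("%.17g,%.17g,%.17g,%.17g",
              coords[, 1], coords[, 2], coords[, 3], as.vector(field$values))
    ), con = con)
  }
  invisible(path)
}

#' Read a scalar field written by [export_field()]
#'
#' @param path input path.
#' @param format `"vtk"`, `"nifti"`, or `"csv"`; guessed from the extension
#'   when omitted.
#' @param unit unit tag to attach when the file does not carry one
#'   (NIfTI). Defaults to `"kelvin"`.
#' @return a `scalar_field`.
#' @export
read_field <- function(path, format = NULL, unit = "kelvin") {
  if (!file.exists(path)) {
    stop_validation(sprintf("field file not found: %s", path))
  }
  format <- format %||% field_format_from_path(path)
  if (format == "vtk") {
    lines <- readLines(path, n = 10L)
    unit_line <- grep("unit=", lines, value = TRUE)
    if (length(unit_line)) unit <- sub(".*unit=", "", unit_line[1])
    dims <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE), " ")[[1]][-1])
    origin <- as.numeric(strsplit(grep("^ORIGIN", lines, value = TRUE), " ")[[1]][-1])
    spacing <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE), " ")[[1]][-1])[1]
    skip <- grep("^LOOKUP_TABLE", lines)
    values <- scan(path, skip = skip, quiet = TRUE)
    grid <- build_grid((dims - 1L) * spacing, spacing)
    grid$origin <- origin
    scalar_field(grid, values, unit = unit)
  } else if (format == "nifti") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1]
    dims <- dim(img)
    grid <- build_grid((dims - 1L) * spacing, spacing)
    scalar_field(grid, as.vector(img), unit = unit)
  } else if (format == "csv") {
    header <- readLines(path, n = 1L)
    if (grepl("unit=", header)) {
      unit <- sub(";.*", "", sub(".*unit=", "", header))
    }
    spacing <- if (grepl("spacing=", header)) {
      as.numeric(sub(";.*", "", sub(".*spacing=", "", header)))
    } else NA_real_
    tab <- read.csv(path, comment.char = "#")
    if (!all(c("x_mm", "y_mm", "z_mm", "value") %in% names(tab))) {
      stop_validation("CSV field files need columns x_mm, y_mm, z_mm, value.")
    }
    if (is.na(spacing)) {
      ux <- sort(unique(tab$x_mm))
      spacing <- if (length(ux) > 1) ux[2] - ux[1] else 1
    }
    dims <- vapply(tab[c("x_mm", "y_mm", "z_mm")],
                   function(v) length(unique(v)), integer(1))
    grid <- build_grid((dims - 1L) * spacing, spacing)
    ## rows were written in node order (x fastest)
    scalar_field(grid, tab$value, unit = unit)
  } else {
    stop_validation(sprintf(
      "unknown field format `%s` (supported: vtk, nifti, csv).", format))
  }
}
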