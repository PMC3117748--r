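#' Build a regular node-centred simulation grid
#'
#' The computational domain is a rectangular block discretised by a regular
#' node-centred lattice: nodes sit at coordinates `(i*h, j*h, k*h)` (0-based
#' indices, mm, measured from the domain corner at `origin`), so a block of
#' extent `E` at spacing `h` carries `E/h + 1` nodes per axis and the node
#' coordinates cover the extent exactly. `spacing` must divide each extent
#' component evenly.
#'
#' When a [fiber_source()] is supplied, its (possibly domain-centred) axis is
#' resolved against the extent and the diffuser segment is required to lie
#' strictly inside the domain.
#'
#' @param extent domain size (mm, 3-vector). Default `c(70, 70, 20)`.
#' @param spacing node spacing (mm, scalar > 0). Default 0.5.
#' @param source optional [fiber_source()] whose placement is validated.
#' @return an object of class `sim_grid` with fields `extent`, `spacing`,
#'   `shape` (node counts), and `origin`.
#' @examples
#' build_grid(c(70, 70, 20), 0.5)$shape   # 141 141 41
#' build_grid(c(70, 70, 20), 1.0)$shape   # 71 71 21
#' @export
build_grid <- function(extent = c(70, 70, 20), spacing = 0.5, source = NULL) {
  extent <- check_vector3(extent, "extent")
  check_number(spacing, "spacing", lower = 0, strict_lower = TRUE)
  if (any(extent < spacing)) {
    stop_validation("each `extent` component must be at least one `spacing`.")
  }
  ratio <- extent / spacing
  if (any(abs(ratio - round(ratio)) > 1e-8 * pmax(1, ratio))) {
    stop_validation(sprintf(
      "`spacing` (%g) must evenly divide every `extent` component (%s).",
      spacing, paste(extent, collapse = " x ")))
  }
  grid <- structure(
    list(
      extent = extent,
      spacing = spacing,
      shape = as.integer(round(ratio)) + 1L,
      origin = c(0, 0, 0)
    ),
    class = "sim_grid"
  )
  if (!is.null(source)) {
    stopifnot(inherits(source, "fiber_source"))
    source <- resolve_fiber(source, extent)
    ends <- fiber_endpoints(source)
    inside <- ends > rep(grid$origin, each = 2) + 1e-9 &
      ends < rep(grid$origin + extent, each = 2) - 1e-9
    if (!all(inside)) {
      stop_geometry(sprintf(
        "fiber segment [(%s) -> (%s)] does not lie strictly inside the %s mm domain.",
        paste(format(ends[1, ]), collapse = ", "),
        paste(format(ends[2, ]), collapse = ", "),
        paste(extent, collapse = " x ")))
    }
  }
  grid
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %s mm at %g mm spacing: %s nodes (%s total)\n",
              paste(x$extent, collapse = " x "), x$spacing,
              paste(x$shape, collapse = " x "),
              format(n_nodes(x), big.mark = ",")))
  invisible(x)
}

#' Grid helpers
#'
#' `n_nodes()` gives the total node count, `grid_axes()` the per-axis node
#' coordinate vectors, `node_coordinates()` the full `n x 3` coordinate matrix
#' (first array index varies fastest, matching the storage order of field
#' values), and `node_weights()` the finite-volume integration weight of every
#' node (mm^3): `spacing^3`, halved once per domain face the node lies on, so
#' that the weights sum exactly to the domain volume.
#'
#' @param grid a `sim_grid`.
#' @return see above.
#' @examples
#' g <- build_grid(c(10, 10, 10), 1)
#' sum(node_weights(g)) == prod(g$extent)
#' @export
n_nodes <- function(grid) prod(grid$shape)

#' @rdname n_nodes
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + grid$spacing * (seq_len(grid$shape[a]) - 1))
}

#' @rdname n_nodes
#' @export
node_coordinates <- function(grid) {
  ax <- grid_axes(grid)
  s <- grid$shape
  cbind(
    x = rep(ax[[1]], times = s[2] * s[3]),
    y = rep(rep(ax[[2]], each = s[1]), times = s[3]),
    z = rep(ax[[3]], each = s[1] * s[2])
  )
}

#' @rdname n_nodes
#' @export
node_weights <- function(grid) {
  s <- grid$shape
  w1 <- function(n) {
    w <- rep(1, n)
    w[c(1, n)] <- 0.5
    w
  }
  wx <- w1(s[1]); wy <- w1(s[2]); wz <- w1(s[3])
  w <- outer(outer(wx, wy), wz)
  array(w * grid$spacing^3, dim = s)
}

#' Scalar field on a simulation grid
#'
#' A node-wise scalar quantity stored as a 3-d array in grid index order.
#' Temperature fields (`unit = "kelvin"`) must be strictly positive.
#'
#' @param grid a `sim_grid`.
#' @param values numeric vector or array with one value per node.
#' @param unit one of `"kelvin"`, `"watt_per_mm3"`, `"dimensionless"`,
#'   `"minutes"`.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values,
                         unit = c("kelvin", "watt_per_mm3", "dimensionless",
                                  "minutes")) {
  stopifnot(inherits(grid, "sim_grid"))
  unit <- match.arg(unit)
  if (length(values) != n_nodes(grid)) {
    stop_validation(sprintf(
      "field has %d values but the grid has %d nodes.",
      length(values), n_nodes(grid)))
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_validation("field values must be finite numbers.")
  }
  if (unit == "kelvin" && any(values <= 0)) {
    stop_validation("temperature fields must be strictly positive (kelvin).")
  }
  structure(
    list(grid = grid, values = array(as.numeric(values), dim = grid$shape),
         unit = unit),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  rng <- range(x$values)
  if (x$unit == "kelvin") {
    cat(sprintf("<scalar_field> kelvin, %s nodes, range %.3f .. %.3f C\n",
                format(n_nodes(x$grid), big.mark = ","),
                kelvin_to_celsius(rng[1]), kelvin_to_celsius(rng[2])))
  } else {
    cat(sprintf("<scalar_field> %s, %s nodes, range %.4g .. %.4g\n",
                x$unit, format(n_nodes(x$grid), big.mark = ","), rng[1], rng[2]))
  }
  invisible(x)
}

#' Distance from points to the diffuser axis segment
#'
#' Euclidean distance to the *finite* diffuser segment (not the infinite
#' line): beyond the segment ends the distance is measured to the end point.
#'
#' @param points a length-3 vector or an `n x 3` matrix of coordinates (mm).
#' @param source a [fiber_source()] with resolved `axis_origin`.
#' @return numeric vector of distances (mm).
#' @examples
#' src <- resolve_fiber(fiber_source(), c(70, 70, 20))
#' distance_to_fiber(c(35, 38, 10), src)  # 3
#' @export
distance_to_fiber <- function(points, source) {
  stopifnot(inherits(source, "fiber_source"))
  if (is.null(dim(points))) {
    points <- matrix(check_vector3(points, "points"), nrow = 1)
  }
  if (ncol(points) != 3L) {
    stop_validation("`points` must have three columns (x, y, z in mm).")
  }
  p0 <- source$axis_origin
  if (is.null(p0)) {
    stop_validation("fiber axis_origin is unresolved; see `resolve_fiber()`.")
  }
  e <- source$axis_direction
  L <- source$diffuser_length
  rel <- sweep(points, 2, p0)
  s <- pmin(pmax(rel %*% e, 0), L)
  d2 <- rowSums(rel^2) - 2 * s * (rel %*% e) + s^2
  sqrt(pmax(as.numeric(d2), 0))
}

#' Binary capsule mask around the diffuser
#'
#' Marks every node within `radius` of the diffuser axis segment (a capsule:
#' cylinder of length `diffuser_length` with hemispherical caps). The mask
#' volume (weights of marked nodes) converges to the closed-form capsule
#' volume `pi r^2 L + 4/3 pi r^3` as the grid is refined.
#'
#' @param grid a `sim_grid`.
#' @param source a [fiber_source()]; a `NULL` `axis_origin` is resolved
#'   against the grid extent.
#' @param radius capsule radius (mm, >= 0). Defaults to the source's
#'   `capsule_radius`.
#' @return a `scalar_field` of 0/1 values (`"dimensionless"`).
#' @examples
#' g <- build_grid(c(30, 20, 20), 1)
#' m <- capsule_mask(g, fiber_source())
#' sum(node_weights(g)[m$values == 1])  # close to pi*4.4^2*10 + 4/3*pi*4.4^3
#' @export
capsule_mask <- function(grid, source, radius = source$capsule_radius) {
  stopifnot(inherits(grid, "sim_grid"))
  check_number(radius, "radius", lower = 0)
  source <- resolve_fiber(source, grid$extent)
  d <- distance_to_fiber(node_coordinates(grid), source)
  scalar_field(grid, as.numeric(d <= radius), unit = "dimensionless")
}

## Closed-form capsule volume (mm^3): cylinder + two hemispherical caps.
capsule_volume <- function(radius, length) {
  pi * radius^2 * length + 4 / 3 * pi * radius^3
}
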