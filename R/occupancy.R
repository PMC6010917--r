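#' Tile a pasture into equal patches
#'
#' Two levels are used: `quarter_16ha` splits the pasture bounding box into
#' four equal quadrants (16 ha each for the nominal 800 x 800 m pasture) and
#' `grid_1ha` tiles it with 100 x 100 m cells. Cells are anchored at the
#' bounding-box minimum corner, ordered row-major from the south-west, and
#' clipped to the pasture boundary; clipped-out cells are dropped.
#'
#' @param pasture A [pasture()] object.
#' @param level `"quarter_16ha"` or `"grid_1ha"`.
#' @param cell_m Cell side for the 1-ha level, metres (default 100).
#' @return A `patch_grid`: data.frame with columns `cell_id`, `x0`, `y0`,
#'   `width`, `height`, `area_m2`, and attributes `level`, `pasture_id`,
#'   `anchor` (c(x, y)), `cell_w`, `cell_h`, `nx`, `ny`.
#' @export
build_grid <- function(pasture, level = c("grid_1ha", "quarter_16ha"),
                       cell_m = 100) {
  level <- match.arg(level)
  b <- pasture$boundary
  xr <- range(b[, 1]); yr <- range(b[, 2])
  if (diff(xr) <= 0 || diff(yr) <= 0) stop("degenerate pasture polygon")
  if (level == "quarter_16ha") {
    w <- diff(xr) / 2; h <- diff(yr) / 2
    nx <- 2L; ny <- 2L
  } else {
    w <- cell_m; h <- cell_m
    nx <- as.integer(ceiling(diff(xr) / w - 1e-9))
    ny <- as.integer(ceiling(diff(yr) / h - 1e-9))
  }
  cells <- expand.grid(col = seq_len(nx) - 1L, row = seq_len(ny) - 1L)
  cells <- cells[order(cells$row, cells$col), ]
  x0 <- xr[1] + cells$col * w
  y0 <- yr[1] + cells$row * h
  area <- vapply(seq_along(x0), function(i) {
    polygon_area_m2(.clip_rect(b, x0[i], x0[i] + w, y0[i], y0[i] + h))
  }, numeric(1))
  keep <- area > 1e-6
  out <- data.frame(cell_id = paste0("r", cells$row, "c", cells$col),
                    x0 = x0, y0 = y0, width = w, height = h,
                    area_m2 = area)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, level = level, pasture_id = pasture$id,
            anchor = c(xr[1], yr[1]), cell_w = w, cell_h = h,
            nx = nx, ny = ny, class = c("patch_grid", "data.frame"))
}

# map fixes to the cell_id of the grid cell containing them; cells are
# half-open [x0, x0+w) x [y0, y0+h), except that points exactly on the
# bounding-box maximum edge fold into the last cell, so assignment is unique
.grid_cell_of <- function(fixes, grid) {
  a <- attr(grid, "anchor")
  w <- attr(grid, "cell_w"); h <- attr(grid, "cell_h")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  col <- pmin(floor((fixes$easting_m - a[1]) / w), nx - 1L)
  row <- pmin(floor((fixes$northing_m - a[2]) / h), ny - 1L)
  paste0("r", row, "c", col)
}

#' Proportional patch occupancy of a set of fixes
#'
#' Fraction of fixes falling in each grid cell. All grid cells are reported
#' (zeros included) and fractions sum to 1.
#'
#' @param fixes Fix data.frame (inside the pasture) with UTM coordinates.
#' @param grid A [build_grid()] patch grid.
#' @return Data.frame with columns `cell_id`, `n`, `prop`.
#' @export
occupancy_proportions <- function(fixes, grid) {
  if (nrow(fixes) == 0L) stop("cannot compute occupancy of zero fixes")
  id <- .grid_cell_of(fixes, grid)
  stray <- !id %in% grid$cell_id
  if (any(stray))
    stop(sum(stray), " fix(es) fall outside the patch grid; crop to the ",
         "pasture first")
  n <- table(factor(id, levels = grid$cell_id))
  data.frame(cell_id = grid$cell_id, n = as.integer(n),
             prop = as.integer(n) / nrow(fixes))
}

#' Occupancy difference between a logging scheme and constant logging
#'
#' Per-cell absolute difference in proportional occupancy between a scheme's
#' subsample and the constant-logging reference, summarised conservatively
#' by the maximum across patches (and, for context, the mean).
#'
#' @param constant_props,scheme_props Data.frames from
#'   [occupancy_proportions()] computed on the *same* grid.
#' @return List with `per_cell` (cell_id, abs_diff), `max_abs_diff`,
#'   `mean_abs_diff` (fractions in \[0, 1\]; multiply by 100 for the
#'   percentage scale used in reports).
#' @export
occupancy_difference <- function(constant_props, scheme_props) {
  if (!identical(constant_props$cell_id, scheme_props$cell_id))
    stop("occupancy proportions were computed on different grids")
  d <- abs(constant_props$prop - scheme_props$prop)
  list(per_cell = data.frame(cell_id = constant_props$cell_id, abs_diff = d),
       max_abs_diff = max(d), mean_abs_diff = mean(d))
}

#' Compare patch occupancy across logging schemes
#'
#' Convenience wrapper: applies each scheme to one deployment's
#' constant-logging fixes and scores it by absolute occupancy difference on
#' a grid.
#'
#' @param fixes Daytime-filtered constant-logging fixes of one deployment.
#' @param grid A [build_grid()] patch grid.
#' @param schemes List of [logging_scheme()]s (default the four reduced
#'   schemes).
#' @return Data.frame with `scheme`, `level`, `max_abs_diff`,
#'   `mean_abs_diff` (fractions).
#' @export
compare_schemes_occupancy <- function(fixes, grid,
                                      schemes = standard_schemes(FALSE)) {
  ref <- occupancy_proportions(fixes, grid)
  rows <- lapply(schemes, function(s) {
    sub <- apply_scheme(fixes, s)
    d <- occupancy_difference(ref, occupancy_proportions(sub, grid))
    data.frame(scheme = scheme_label(s), level = attr(grid, "level"),
               max_abs_diff = d$max_abs_diff, mean_abs_diff = d$mean_abs_diff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
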