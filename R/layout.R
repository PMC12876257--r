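#' Sensor layout: 128 channels on a 12 x 12 scalp grid
#'
#' A dense-array net of 128 electrodes is arranged on a 12 x 12 matrix whose
#' rows run front (row 1) to back (row 12) and whose columns split into left
#' (1-6) and right (7-12) hemispheres. Cells (1,3) and (1,10) are left empty
#' as prefrontal reference markers, leaving 142 cells; 14 electrodes are
#' doubled (each written into two mirror-related cells) to fill the grid.
#'
#' The exact channel-to-cell assignment is hardware- and montage-specific, so
#' it is data, not code: the package ships a documented default table
#' (constructed to respect the region colouring and left/right symmetry of
#' the montage) and accepts user-supplied tables in the same format.
#'
#' @param entries data frame with columns `channel_id`, `row`, `col`,
#'   `region` (one row per grid cell occupied by the channel; doubled
#'   channels appear twice).
#' @param n_channels number of distinct channels expected (default 128).
#' @param grid_shape grid dimensions, default `c(12, 12)`.
#' @param empty_cells two-column matrix of (row, col) reference cells that
#'   must stay unassigned.
#' @return a validated `sensor_layout` object.
#' @seealso [load_layout()], [map_to_grid()]
#' @export
sensor_layout <- function(entries,
                          n_channels = 128L,
                          grid_shape = c(12L, 12L),
                          empty_cells = rbind(c(1L, 3L), c(1L, 10L))) {
  req <- c("channel_id", "row", "col", "region")
  if (!all(req %in% names(entries))) {
    stop("layout entries need columns: ", paste(req, collapse = ", "))
  }
  entries <- as.data.frame(entries)[, req]
  entries$channel_id <- as.integer(entries$channel_id)
  entries$row <- as.integer(entries$row)
  entries$col <- as.integer(entries$col)
  entries$region <- as.character(entries$region)

  bad <- which(entries$row < 1 | entries$row > grid_shape[1] |
               entries$col < 1 | entries$col > grid_shape[2])
  if (length(bad)) {
    stop("grid indices out of range at table row(s) ",
         paste(bad, collapse = ", "))
  }
  bad <- which(entries$channel_id < 1 | entries$channel_id > n_channels)
  if (length(bad)) {
    stop("channel_id out of 1..", n_channels, " at table row(s) ",
         paste(bad, collapse = ", "))
  }

  cell_key <- paste(entries$row, entries$col)
  empty_key <- paste(empty_cells[, 1], empty_cells[, 2])
  hit <- which(cell_key %in% empty_key)
  if (length(hit)) {
    stop("channel ", entries$channel_id[hit[1]],
         " assigned to reserved empty cell (",
         entries$row[hit[1]], ",", entries$col[hit[1]],
         ") at table row ", hit[1])
  }
  dup <- which(duplicated(cell_key))
  if (length(dup)) {
    stop("cell (", entries$row[dup[1]], ",", entries$col[dup[1]],
         ") assigned more than once (table row ", dup[1], ")")
  }

  missing <- setdiff(seq_len(n_channels), entries$channel_id)
  if (length(missing)) {
    stop("channel ", paste(missing, collapse = ", "), " unassigned")
  }
  tab <- table(entries$channel_id)
  if (any(tab > 2)) {
    stop("channel ", names(tab)[which(tab > 2)[1]],
         " assigned to more than two cells")
  }

  n_cells <- prod(grid_shape) - nrow(empty_cells)
  if (nrow(entries) != n_cells) {
    stop("expected ", n_cells, " filled cells, got ", nrow(entries))
  }

  structure(
    list(entries = entries,
         n_channels = as.integer(n_channels),
         grid_shape = as.integer(grid_shape),
         empty_cells = empty_cells),
    class = "sensor_layout"
  )
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("sensor_layout:", x$n_channels, "channels on a",
      x$grid_shape[1], "x", x$grid_shape[2], "grid\n")
  cat("  filled cells:", nrow(x$entries),
      " doubled channels:", length(doubled_channels(x)),
      " empty cells:", nrow(x$empty_cells), "\n")
  invisible(x)
}

#' Channels assigned to two grid cells
#'
#' @param layout a `sensor_layout`.
#' @return integer vector of doubled channel ids.
#' @export
doubled_channels <- function(layout) {
  tab <- table(layout$entries$channel_id)
  sort(as.integer(names(tab)[tab == 2L]))
}

#' Load a sensor layout table
#'
#' Reads a comma-separated table with columns `channel_id,row,col,region`
#' (1-based indices, row 1 = front). Lines starting with `#` are comments.
#' With `path = NULL` the bundled default layout is loaded.
#'
#' @param path path to a layout file, or `NULL` for the package default.
#' @return a validated `sensor_layout`.
#' @export
load_layout <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_layout.csv", package = "eegstates")
  }
  if (!file.exists(path)) stop("layout file not found: ", path)
  entries <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  sensor_layout(entries)
}

#' Write a sensor layout table
#'
#' @param layout a `sensor_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# Sensor layout: channel -> 12x12 grid cell (1-based; row 1 = front,",
    "# cols 1-6 left hemisphere, 7-12 right). Cells (1,3) and (1,10) are",
    "# reserved empty prefrontal reference positions."
  ), con)
  utils::write.csv(layout$entries, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map per-channel values onto the scalp grid
#'
#' Doubled channels write the same value into both of their cells; the two
#' empty reference cells carry `NA` as a sentinel.
#'
#' @param values numeric vector of per-channel values, either named by
#'   channel id or unnamed with length equal to the channel count (position
#'   = channel id).
#' @param layout a `sensor_layout`.
#' @return numeric matrix of dimension `layout$grid_shape` with `NA` at the
#'   empty reference cells.
#' @examples
#' lay <- load_layout()
#' g <- map_to_grid(rep(1, 128), lay)
#' sum(is.na(g))  # 2 sentinel cells
#' @export
map_to_grid <- function(values, layout) {
  ids <- layout$entries$channel_id
  if (is.null(names(values))) {
    if (length(values) != layout$n_channels) {
      stop("expected ", layout$n_channels, " channel values, got ",
           length(values))
    }
    v <- values[ids]
  } else {
    missing <- setdiff(as.character(unique(ids)), names(values))
    if (length(missing)) {
      stop("missing value for channel(s): ", paste(missing, collapse = ", "))
    }
    v <- unname(values[as.character(ids)])
  }
  grid <- matrix(NA_real_, layout$grid_shape[1], layout$grid_shape[2])
  grid[cbind(layout$entries$row, layout$entries$col)] <- v
  grid
}

#' Region of each channel
#'
#' @param layout a `sensor_layout`.
#' @return character vector of length `n_channels`; for doubled channels the
#'   region of their first listed cell.
#' @keywords internal
channel_regions <- function(layout) {
  e <- layout$entries[!duplicated(layout$entries$channel_id), ]
  e <- e[order(e$channel_id), ]
  e$region
}
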