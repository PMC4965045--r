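# Optode montage: checkerboard emitter/detector grids and the channels
# (adjacent emitter-detector pairs) they define.

#' Build a checkerboard optode layout
#'
#' Constructs the channel table for one or two rectangular optode grids in
#' which emitter and detector roles alternate in both directions
#' (checkerboard).  Every horizontally or vertically adjacent
#' emitter-detector pair forms one measurement channel, so an
#' `r` x `c` grid yields `r*(c-1) + c*(r-1)` channels.  With the default
#' two 4x4 grids (left grid centered on C3, right grid on C4) this gives
#' the standard 48-channel montage over the bilateral motor cortices.
#'
#' Channel indices are assigned grid-major, then by emitter position
#' (row-major), then by detector position, so channels 1..24 lie in the
#' left hemisphere and 25..48 in the right for the default montage.
#'
#' @param grid_rows,grid_cols grid dimensions (optodes per side), >= 1.
#' @param n_grids 1 (single grid, left hemisphere) or 2 (bilateral).
#' @param spacing_mm emitter-detector separation in millimetres (> 0).
#' @return An object of class `channel_layout`: a list with `channels`
#'   (data frame: `channel`, emitter/detector grid coordinates and
#'   positions in mm, `hemisphere`), `n_channels`, grid geometry fields
#'   and `center_labels` (scalp landmarks, C3/C4).
#' @examples
#' lay <- build_checkerboard_layout()
#' lay$n_channels          # 48
#' table(lay$channels$hemisphere)
#' @export
build_checkerboard_layout <- function(grid_rows = 4L, grid_cols = 4L,
                                      n_grids = 2L, spacing_mm = 25) {
  if (!is_count(grid_rows) || !is_count(grid_cols)) {
    stop_invalid("`grid_rows` and `grid_cols` must be counts >= 1")
  }
  if (!is_count(n_grids) || !(n_grids %in% c(1L, 2L))) {
    stop_invalid("`n_grids` must be 1 or 2")
  }
  if (!is_number(spacing_mm) || spacing_mm <= 0) {
    stop_invalid("`spacing_mm` must be a positive length")
  }
  hemis <- c("left", "right")[seq_len(n_grids)]
  labels <- c("C3", "C4")[seq_len(n_grids)]
  # grids laid out side by side with a gap of 3 spacings between them
  grid_offset_x <- (grid_cols + 2) * spacing_mm

  all_ch <- vector("list", n_grids)
  for (g in seq_len(n_grids)) {
    pairs <- enumerate_channel_pairs(grid_rows, grid_cols)
    pairs$hemisphere <- rep(hemis[[g]], nrow(pairs))
    pairs$emitter_x_mm <- (pairs$emitter_col - 1) * spacing_mm +
      (g - 1) * grid_offset_x
    pairs$emitter_y_mm <- (pairs$emitter_row - 1) * spacing_mm
    pairs$detector_x_mm <- (pairs$detector_col - 1) * spacing_mm +
      (g - 1) * grid_offset_x
    pairs$detector_y_mm <- (pairs$detector_row - 1) * spacing_mm
    all_ch[[g]] <- pairs
  }
  channels <- do.call(rbind, all_ch)
  channels <- cbind(channel = seq_len(nrow(channels)), channels)
  rownames(channels) <- NULL

  layout <- structure(
    list(channels = channels,
         n_channels = nrow(channels),
         grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols),
         n_grids = as.integer(n_grids),
         spacing_mm = spacing_mm,
         center_labels = labels),
    class = "channel_layout")
  layout
}

# All adjacent emitter-detector pairs of an r x c checkerboard.  Role at
# (row, col) is emitter when (row + col) is even (1-based indexing puts
# an emitter at the (1, 1) corner, fixing the checkerboard phase).
# Ordered by emitter position (row-major), then detector position.
enumerate_channel_pairs <- function(r, c) {
  is_emitter <- function(row, col) ((row + col) %% 2L) == 0L
  out <- list()
  for (row in seq_len(r)) {
    for (col in seq_len(c)) {
      if (!is_emitter(row, col)) next
      # neighbours in row-major order relative to the emitter
      nb <- rbind(c(row - 1L, col), c(row, col - 1L),
                  c(row, col + 1L), c(row + 1L, col))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= r & nb[, 2] >= 1 & nb[, 2] <= c, ,
               drop = FALSE]
      for (i in seq_len(nrow(nb))) {
        out[[length(out) + 1L]] <- data.frame(
          emitter_row = row, emitter_col = col,
          detector_row = nb[i, 1], detector_col = nb[i, 2])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(emitter_row = integer(), emitter_col = integer(),
                      detector_row = integer(), detector_col = integer()))
  }
  do.call(rbind, out)
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %d channel(s): %d grid(s) of %dx%d optodes, %g mm spacing\n",
              x$n_channels, x$n_grids, x$grid_rows, x$grid_cols, x$spacing_mm))
  counts <- table(x$channels$hemisphere)
  cat("  hemispheres:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.channel_layout <- function(x, ...) x$channels

#' Channel indices belonging to one hemisphere
#'
#' @param layout a `channel_layout`.
#' @param hemisphere `"left"` or `"right"`.
#' @return integer vector of channel indices.
#' @export
hemisphere_channels <- function(layout, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  layout$channels$channel[layout$channels$hemisphere == hemisphere]
}

# Stable fingerprint of the layout geometry, stored in run sidecars so a
# reader can verify channel compatibility.
layout_hash <- function(layout) {
  key <- paste(layout$grid_rows, layout$grid_cols, layout$n_grids,
               format(layout$spacing_mm, digits = 12),
               paste(layout$center_labels, collapse = ","), sep = "|")
  fnv1a_hash(key)
}

#' Export the channel table as TSV
#'
#' Writes one row per channel: index, emitter and detector positions in
#' mm, and hemisphere membership.
#'
#' @param layout a `channel_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  cols <- c("channel", "emitter_x_mm", "emitter_y_mm",
            "detector_x_mm", "detector_y_mm", "hemisphere")
  utils::write.table(layout$channels[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
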