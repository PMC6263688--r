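#' Write a respiratory-rate trace to CSV
#'
#' One row per analysis window with header
#' `time_s,rr_bpm,rr_bpm_median,periodicity,pc_index`. Values are written
#' with 6 significant digits and round-trip losslessly at that precision.
#'
#' @param trace an [rr_trace()] (or data frame with those columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr_trace <- function(trace, path) {
  if (nrow(trace) == 0L) stop("empty trace")
  cols <- c("time_s", "rr_bpm", "rr_bpm_median", "periodicity", "pc_index")
  df <- as.data.frame(trace)[, cols]
  for (j in c("time_s", "rr_bpm", "rr_bpm_median", "periodicity"))
    df[[j]] <- signif(df[[j]], 6)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a respiratory-rate trace CSV
#'
#' @param path file written by [write_rr_trace()].
#' @return Data frame with the trace columns.
#' @export
read_rr_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "rr_bpm", "rr_bpm_median", "periodicity", "pc_index")
  if (!all(need %in% names(df))) stop("not an rr trace file: ", path)
  df
}

# blue -> yellow colormap on [0, 1]
heat_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#00204D", "#2C728E", "#95D840", "#FDE725"))
  rgb <- ramp(pmin(pmax(v, 0), 1)) / 255
  array(rgb, dim = c(dim(v), 3L))
}

#' Write an occupancy heat map
#'
#' The CSV holds the raw dwell-time grid in seconds. The PNG renders the
#' grid with a blue (little or no time) to yellow (much time) colormap; with
#' `log = TRUE` the rendered grid is the `log1p`-transformed map, which
#' reveals rarely visited paths.
#'
#' @param map an [occupancy_heatmap()] result (finite, non-negative).
#' @param path_png PNG output path (`NULL` to skip).
#' @param path_csv CSV output path (`NULL` to skip).
#' @param log render the logarithmic variant of the PNG.
#' @param upscale integer pixel replication factor for the PNG.
#' @return Invisibly, the paths written.
#' @export
write_heatmap <- function(map, path_png = NULL, path_csv = NULL, log = FALSE,
                          upscale = 8L) {
  m <- unclass(map)
  if (any(!is.finite(m)) || any(m < 0)) stop("heat map must be finite and non-negative")
  if (!is.null(path_csv))
    utils::write.table(m, path_csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(path_png)) {
    r <- if (log) log1p(m) else m
    mx <- max(r)
    v <- if (mx > 0) r / mx else r
    v <- v[rep(seq_len(nrow(v)), each = upscale),
           rep(seq_len(ncol(v)), each = upscale)]
    png::writePNG(heat_colors(v), path_png)
  }
  invisible(c(png = path_png, csv = path_csv))
}

#' Read an occupancy heat-map CSV
#'
#' @param path file written by [write_heatmap()].
#' @return Numeric matrix of seconds.
#' @export
read_heatmap_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
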