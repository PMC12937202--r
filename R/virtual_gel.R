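# Virtual agarose gel: log-linear migration model, band resolvability,
# deterministic lane tables and an optional base-graphics rendering.

#' Gel migration model
#'
#' Standard log-linear mobility: distance = a - b * log10(size), floored
#' at 0. The defaults describe a 2.75% agarose gel sized so a 600 bp
#' ladder spans the lane; the smallest distinguishable size difference is
#' `max(10, 0.06 * size)` bp, which makes a {162, 227, 275, 307, 527}
#' ladder comfortably resolvable while 307 vs 312 is not — ordinary gel
#' practice. No published mobility data underlie these constants; they
#' are illustrative and nothing downstream depends on them.
#'
#' @param gel_pct Agarose percentage (documentation only).
#' @param a Intercept, mm.
#' @param b Slope, mm per log10(bp); must be > 0.
#' @param min_resolvable_delta Function of size (bp) returning the
#'   smallest distinguishable size difference at that size.
#' @return Object of class `gel_model`.
#' @export
gel_model <- function(gel_pct = 2.75, a = 140, b = 55,
                      min_resolvable_delta = function(size) {
                        pmax(10, 0.06 * size)
                      }) {
  stopifnot(b > 0, is.function(min_resolvable_delta))
  structure(list(gel_pct = gel_pct, a = a, b = b,
                 min_resolvable_delta = min_resolvable_delta),
            class = "gel_model")
}

#' Migration distance of a fragment
#'
#' @param size Fragment size in bp, >= 1. Vectorised.
#' @param model A [gel_model()].
#' @return Distance in mm (>= 0), strictly decreasing in size until the
#'   floor at 0.
#' @export
migration_distance <- function(size, model = gel_model()) {
  if (any(size < 1)) stop("fragment size must be >= 1 bp")
  pmax(0, model$a - model$b * log10(size))
}

#' Can a set of band sizes be distinguished on the gel?
#'
#' @param sizes Band sizes in bp (any order).
#' @param model A [gel_model()].
#' @return List with `resolvable` (logical) and, when `FALSE`,
#'   `offending_pair` (the first adjacent pair closer than the model's
#'   minimum resolvable difference at the smaller size).
#' @export
resolvable <- function(sizes, model = gel_model()) {
  stopifnot(length(sizes) >= 1L)
  s <- sort(sizes)
  if (length(s) > 1L) {
    for (i in seq_len(length(s) - 1L)) {
      if (s[i + 1L] - s[i] < model$min_resolvable_delta(s[i])) {
        return(list(resolvable = FALSE,
                    offending_pair = c(s[i], s[i + 1L])))
      }
    }
  }
  list(resolvable = TRUE, offending_pair = NULL)
}

#' Build a gel lane from band sizes
#'
#' @param label Lane label.
#' @param sizes Band sizes, bp.
#' @param model A [gel_model()].
#' @return Object of class `gel_lane`: label plus a `bands` data.frame
#'   (`size`, `distance`) sorted by size.
#' @export
gel_lane <- function(label, sizes, model = gel_model()) {
  sizes <- sort(as.numeric(sizes))
  bands <- data.frame(size = sizes,
                      distance = migration_distance(sizes, model))
  structure(list(label = label, bands = bands), class = "gel_lane")
}

#' Render a virtual gel as a deterministic table
#'
#' One row per band, ladder lane first; output is byte-stable for fixed
#' input, suitable for regression testing and plain-text reports.
#'
#' @param lanes List of [gel_lane()] objects.
#' @param ladder Ladder rung sizes in bp (default a 600 bp ladder in
#'   100 bp steps).
#' @param model A [gel_model()].
#' @return Data.frame: `lane`, `label`, `kind` (`"ladder"`/`"band"`),
#'   `size`, `distance`.
#' @export
render_gel <- function(lanes, ladder = seq(100, 600, by = 100),
                       model = gel_model()) {
  ladder_lane <- gel_lane("M", ladder, model)
  all_lanes <- c(list(ladder_lane), lanes)
  kinds <- c("ladder", rep("band", length(lanes)))
  rows <- lapply(seq_along(all_lanes), function(i) {
    ln <- all_lanes[[i]]
    if (!nrow(ln$bands)) {
      return(data.frame(lane = i, label = ln$label, kind = kinds[i],
                        size = NA_real_, distance = NA_real_))
    }
    data.frame(lane = i, label = ln$label, kind = kinds[i],
               size = ln$bands$size, distance = ln$bands$distance)
  })
  do.call(rbind, rows)
}

#' Plot a virtual gel
#'
#' Base-graphics rendering of [render_gel()] output: lanes as columns,
#' bands as horizontal segments at their migration distance.
#'
#' @param gel Data.frame from [render_gel()].
#' @param main Plot title.
#' @return `NULL`, invisibly; draws on the active device.
#' @export
plot_gel <- function(gel, main = "virtual gel") {
  lanes <- unique(gel[, c("lane", "label")])
  dmax <- max(gel$distance, na.rm = TRUE)
  graphics::plot(NULL, xlim = c(0.5, nrow(lanes) + 0.5),
                 ylim = c(dmax * 1.05, 0), xaxt = "n",
                 xlab = "lane", ylab = "migration (mm)", main = main)
  graphics::axis(1, at = lanes$lane, labels = lanes$label)
  with_bands <- gel[!is.na(gel$size), , drop = FALSE]
  graphics::segments(with_bands$lane - 0.3, with_bands$distance,
                     with_bands$lane + 0.3, with_bands$distance,
                     lwd = ifelse(with_bands$kind == "ladder", 1, 3))
  invisible(NULL)
}
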