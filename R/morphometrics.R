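#' Spore volume as a rotation ellipsoid
#'
#' Approximates the spore by an ellipsoid of revolution about its long axis:
#' `V = pi * L * W^2 / 6` (cubic micrometres when L and W are in micrometres).
#'
#' @param length,width spore length and width (micrometres); vectorised.
#' @return volume(s) in cubic micrometres.
#' @examples
#' spore_volume(12, 6)       # 72 * pi
#' spore_volume(11.6, 5.0)   # 151.8
#' @export
spore_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  pi * length * width^2 / 6
}

#' Construct a measurement set
#'
#' Length/width observations of one structure type (basidiospores, pileipellis
#' terminal elements, ...), grouped by collection and basidiome.  The [n/m/p]
#' bookkeeping reads: n structures measured from m basidiomes of p
#' collections.
#'
#' @param data data frame with columns `collection`, `basidiome`, `length_um`,
#'   `width_um` (a `structure` column is optional and filled from the
#'   `structure` argument otherwise).
#' @param structure structure label.
#' @return a `measurement_set` data frame.
#' @export
measurement_set <- function(data, structure = "basidiospores") {
  data <- as.data.frame(data)
  need <- c("collection", "basidiome", "length_um", "width_um")
  if (!all(need %in% names(data)))
    stop("measurement data needs columns ", paste(need, collapse = ", "))
  if (nrow(data) == 0L) stop("empty measurement set")
  if (any(!is.finite(data$length_um)) || any(!is.finite(data$width_um)) ||
      any(data$length_um <= 0) || any(data$width_um <= 0))
    stop("lengths and widths must be positive")
  if (!"structure" %in% names(data)) data$structure <- structure
  structure(data[, c("collection", "basidiome", "structure",
                     "length_um", "width_um")],
            class = c("measurement_set", "data.frame"))
}

block_stats <- function(collection_means) {
  s <- if (length(collection_means) > 1L) stats::sd(collection_means) else 0
  c(min = min(collection_means), mean = mean(collection_means),
    sd = s, max = max(collection_means))
}

#' Summarise spore or pileipellis measurements
#'
#' Computes the description-style statistics: per collection, the mean length,
#' width, length/width quotient Q and rotation-ellipsoid volume Vm (Q and Vm
#' averaged per spore, then per collection); across collections, the
#' (minimum of the averages) average +/- standard deviation of the averages
#' (maximum of the averages) convention, with the grand value the unweighted
#' mean of collection means and the sd taken across collection means (n-1).
#' With a single collection the sd is reported as 0 and flagged.
#'
#' @param ms a [measurement_set()] (or a data frame acceptable to it).
#' @return an object of class `structure_summary` with counts `n`, `m`, `p`
#'   and blocks `length`, `width`, `Q`, `Vm`, each `c(min, mean, sd, max)`
#'   over collection means.  `format()` renders the description string, e.g.
#'   `"[561/19/19] (10.3\u2013)11.6 \u00b1 0.6(\u201312.8) \u00d7 (4.7\u2013)5.0 \u00b1 0.2(\u20135.5) \u00b5m, ..."`.
#' @export
summarize_structure <- function(ms) {
  ms <- measurement_set(ms, structure = if (is.data.frame(ms) &&
                                            "structure" %in% names(ms))
    ms$structure[1] else "basidiospores")
  per_obs_q <- ms$length_um / ms$width_um
  per_obs_v <- spore_volume(ms$length_um, ms$width_um)
  coll <- as.character(ms$collection)
  cm <- function(x) as.numeric(tapply(x, coll, mean))
  out <- list(
    structure = ms$structure[1],
    n = nrow(ms),
    m = length(unique(paste(ms$collection, ms$basidiome, sep = "\x1f"))),
    p = length(unique(coll)),
    length = block_stats(cm(ms$length_um)),
    width = block_stats(cm(ms$width_um)),
    Q = block_stats(cm(per_obs_q)),
    Vm = block_stats(cm(per_obs_v))
  )
  out$single_collection <- out$p == 1L
  class(out) <- "structure_summary"
  out
}

#' @export
format.structure_summary <- function(x, ...) {
  dim1 <- function(v) sprintf("(%.1f\u2013)%.1f \u00b1 %.1f(\u2013%.1f)",
                              v["min"], v["mean"], v["sd"], v["max"])
  q <- sprintf("(%.2f\u2013)%.2f \u00b1 %.2f(\u2013%.2f)",
               x$Q["min"], x$Q["mean"], x$Q["sd"], x$Q["max"])
  vm <- sprintf("%.0f \u00b1 %.0f", x$Vm["mean"], x$Vm["sd"])
  sprintf("[%d/%d/%d] %s \u00d7 %s \u00b5m, Q = %s, Vm = %s \u00b5m\u00b3",
          x$n, x$m, x$p, dim1(x$length), dim1(x$width), q, vm)
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(x$structure, format(x), "\n")
  if (x$single_collection)
    cat("  (single collection: sd across collection means reported as 0)\n")
  invisible(x)
}
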