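#' Load an electrode montage
#'
#' A montage holds 2-D projected electrode positions and the unweighted
#' adjacency graph used for topological channel distances. Two schematic
#' layouts ship with the package: `"standard_1020_32"` (the 32-channel
#' 10-20/10-10 set used by consumer-grade affect benchmarks) and
#' `"emotiv_epoc_14"` (the 14-channel Emotiv EPOC set). A custom montage is
#' read from a `name,x,y` CSV file.
#'
#' Two electrodes are adjacent when their Euclidean distance does not exceed
#' `spacing_factor` times the minimal inter-electrode spacing of the montage.
#'
#' @param name `"standard_1020_32"`, `"emotiv_epoc_14"`, or a path to a CSV.
#' @param spacing_factor adjacency threshold multiplier (default 1.1).
#' @return An object of class `eeg_montage` with elements `positions`
#'   (data.frame name/x/y), `adjacency` (binary symmetric matrix) and
#'   `channel_names`.
#' @export
load_montage <- function(name = "standard_1020_32", spacing_factor = 1.1) {
  builtin <- c(standard_1020_32 = "montage_standard_1020_32.csv",
               emotiv_epoc_14 = "montage_emotiv_epoc_14.csv")
  path <- if (name %in% names(builtin)) {
    system.file("extdata", builtin[[name]], package = "eegsel", mustWork = TRUE)
  } else {
    stop_if(!file.exists(name), sprintf("unknown montage '%s' (not a builtin name or file)", name))
    name
  }
  pos <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("name", "x", "y") %in% names(pos)),
          "montage file must have columns name,x,y")
  dup <- pos$name[duplicated(pos$name)]
  stop_if(length(dup) > 0,
          "duplicate channel names in montage: ", paste(unique(dup), collapse = ", "))
  montage_from_positions(pos, spacing_factor = spacing_factor,
                         name = if (name %in% names(builtin)) name else basename(name))
}

#' Build a montage object from an electrode position table
#'
#' @param positions data.frame with columns `name`, `x`, `y`.
#' @param spacing_factor adjacency threshold multiplier.
#' @param name label for printing.
#' @return `eeg_montage` object.
#' @export
montage_from_positions <- function(positions, spacing_factor = 1.1,
                                   name = "custom") {
  xy <- as.matrix(positions[, c("x", "y")])
  rownames(xy) <- positions$name
  d <- as.matrix(stats::dist(xy))
  off <- d[upper.tri(d)]
  stop_if(length(off) == 0, "montage needs at least two electrodes")
  thr <- spacing_factor * min(off)
  adj <- (d <= thr) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- list(positions$name, positions$name)
  structure(list(name = name, positions = positions, adjacency = adj,
                 channel_names = positions$name,
                 spacing_factor = spacing_factor),
            class = "eeg_montage")
}

#' Restrict a montage to a subset of channels
#' @param montage an `eeg_montage`.
#' @param channels channel names to keep (order preserved as given).
#' @return `eeg_montage` restricted to `channels`.
#' @export
montage_subset <- function(montage, channels) {
  missing <- setdiff(channels, montage$channel_names)
  stop_if(length(missing) > 0,
          "channels not present in montage: ", paste(missing, collapse = ", "))
  pos <- montage$positions[match(channels, montage$positions$name), , drop = FALSE]
  montage_from_positions(pos, spacing_factor = montage$spacing_factor,
                         name = paste0(montage$name, "-subset"))
}

#' @export
print.eeg_montage <- function(x, ...) {
  deg <- rowSums(x$adjacency)
  cat(sprintf("<eeg_montage> '%s': %d electrodes, %d adjacency edges (degree %d-%d)\n",
              x$name, length(x$channel_names), sum(x$adjacency) / 2,
              min(deg), max(deg)))
  invisible(x)
}

#' @export
plot.eeg_montage <- function(x, ...) {
  p <- x$positions
  graphics::plot(p$x, p$y, asp = 1, pch = 21, bg = "grey85", cex = 2.5,
                 xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("montage %s", x$name), ...)
  idx <- which(x$adjacency == 1, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  graphics::segments(p$x[idx[, 1]], p$y[idx[, 1]], p$x[idx[, 2]], p$y[idx[, 2]],
                     col = "grey70")
  graphics::points(p$x, p$y, pch = 21, bg = "grey85", cex = 2.5)
  graphics::text(p$x, p$y, p$name, cex = 0.55)
  invisible(x)
}

#' Topological channel-distance (neighboring) matrix
#'
#' Entry (p, q) is the shortest-path hop count kappa between electrodes p and
#' q on the montage adjacency graph when `0 < kappa <= kappa_max`, and 0
#' otherwise (including the diagonal and pairs farther apart than
#' `kappa_max`). Spatially close channel pairs therefore carry a small
#' positive entry which downstream code uses to discount their co-activation.
#'
#' @param montage an `eeg_montage`.
#' @param kappa_max hop-count cap (default 2).
#' @return integer matrix of class `delta_matrix` with attribute `kappa_max`.
#' @export
neighboring_matrix <- function(montage, kappa_max = 2) {
  stop_if(!is_count(kappa_max), "kappa_max must be a positive integer")
  g <- igraph::graph_from_adjacency_matrix(montage$adjacency, mode = "undirected")
  hops <- igraph::distances(g)
  if (any(is.infinite(hops))) {
    comp <- igraph::components(g)
    main <- which.max(comp$csize)
    isolated <- montage$channel_names[comp$membership != main]
    stop("montage graph is disconnected; unreachable channels: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  }
  delta <- hops
  delta[delta > kappa_max] <- 0
  diag(delta) <- 0
  storage.mode(delta) <- "integer"
  structure(delta, kappa_max = kappa_max, class = c("delta_matrix", "matrix", "array"))
}
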