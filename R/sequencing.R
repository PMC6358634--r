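#' Quantize a fluence map
#'
#' Bins a nonnegative 2D fluence map to integer levels 0..L by rounding
#' v * L / max(v); an all-zero map stays zero. The physical fluence of one
#' level is max(v) / L, returned as attribute `unit`.
#'
#' @param map nonnegative numeric matrix (rows x leaf-travel columns).
#' @param levels number of levels L >= 1.
#' @return Integer matrix with attribute `unit`.
#' @export
quantize_fluence <- function(map, levels) {
  if (levels < 1) stopf("levels must be >= 1")
  if (any(map < 0)) stopf("fluence map must be nonnegative")
  m <- max(map)
  if (m <= 0) {
    out <- matrix(0L, nrow(map), ncol(map))
    attr(out, "unit") <- 0
    return(out)
  }
  out <- matrix(as.integer(round(map * levels / m)), nrow(map), ncol(map))
  attr(out, "unit") <- m / levels
  out
}

# Per-row interval queues of the unidirectional level decomposition:
# level t opens the maximal runs of columns with intmap >= t.
row_interval_queue <- function(row) {
  out <- list()
  if (!any(row > 0)) return(out)
  for (t in seq_len(max(row))) {
    open <- row >= t
    r <- rle(open)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) out[[length(out) + 1L]] <- c(starts[k], ends[k] + 1L)
  }
  out
}

#' Sweep-sequence an integer fluence map into MLC apertures
#'
#' Unidirectional level decomposition: for each row, level t in 1..L opens
#' the columns where the map is >= t; one unit-weight aperture is formed per
#' pass by taking each row's next pending interval, and identical
#' consecutive shapes are merged with summed weight. With an uncapped
#' segment count the weighted sum of aperture masks reconstructs the map
#' integer-exactly. If the segment count exceeds `max_apertures`, the
#' segments of largest weight x open-area are kept and the result is marked
#' approximate.
#'
#' @param intmap nonnegative integer matrix (one row per leaf-pair track).
#' @param max_apertures cap on the number of segments (Inf = uncapped).
#' @return List of apertures, each `list(shape, weight)` where `shape` is an
#'   (nrow x 2) matrix of half-open column intervals (NA rows closed);
#'   attribute `approximate` marks a capped decomposition. Empty list for an
#'   all-zero map.
#' @export
sweep_sequence <- function(intmap, max_apertures = Inf) {
  if (any(intmap < 0) || any(intmap != round(intmap))) stopf("intmap must be nonnegative integers")
  nr <- nrow(intmap)
  queues <- lapply(seq_len(nr), function(r) row_interval_queue(intmap[r, ]))
  heads <- rep(1L, nr)
  apertures <- list()
  repeat {
    pending <- which(heads <= lengths(queues))
    if (!length(pending)) break
    shape <- matrix(NA_real_, nr, 2, dimnames = list(NULL, c("left", "right")))
    for (r in pending) {
      shape[r, ] <- queues[[r]][[heads[r]]]
      heads[r] <- heads[r] + 1L
    }
    last <- if (length(apertures)) apertures[[length(apertures)]] else NULL
    if (!is.null(last) && identical(last$shape, shape)) {
      apertures[[length(apertures)]]$weight <- last$weight + 1
    } else {
      apertures[[length(apertures) + 1L]] <- list(shape = shape, weight = 1)
    }
  }
  approximate <- FALSE
  if (length(apertures) > max_apertures) {
    score <- vapply(apertures, function(a) a$weight * aperture_area(a$shape), 1)
    keep <- sort(order(score, decreasing = TRUE)[seq_len(max_apertures)])
    apertures <- apertures[keep]
    approximate <- TRUE
  }
  attr(apertures, "approximate") <- approximate
  apertures
}

aperture_area <- function(shape) sum(shape[, 2] - shape[, 1], na.rm = TRUE)

# 0/1 bixel mask (length nrow*ncol, row-fastest) of an aperture shape.
aperture_mask <- function(shape, nrow, ncol) {
  m <- matrix(0, nrow, ncol)
  for (r in seq_len(nrow)) {
    if (is.na(shape[r, 1])) next
    m[r, shape[r, 1]:(shape[r, 2] - 1L)] <- 1
  }
  as.numeric(m)
}

# Reconstruction sum_a weight_a * mask_a as a matrix.
apertures_fluence <- function(apertures, nrow, ncol) {
  out <- matrix(0, nrow, ncol)
  for (a in apertures) out <- out + a$weight * matrix(aperture_mask(a$shape, nrow, ncol), nrow, ncol)
  out
}

#' Sequence one beam's fluence map
#'
#' Quantizes the continuous fluence to `levels` (default max_apertures + 2)
#' and sweep-sequences it; aperture weights are returned in physical
#' fluence units (level unit x integer weight).
#'
#' @param wmap nonnegative fluence matrix of one beam.
#' @param max_apertures per-beam segment cap.
#' @param levels quantization levels.
#' @return List of apertures with fluence-unit weights.
#' @export
sequence_beam <- function(wmap, max_apertures = 5, levels = NULL) {
  if (is.null(levels)) levels <- if (is.finite(max_apertures)) max_apertures + 2 else 10
  q <- quantize_fluence(wmap, levels)
  aps <- sweep_sequence(q, max_apertures)
  for (k in seq_along(aps)) aps[[k]]$weight <- aps[[k]]$weight * attr(q, "unit")
  aps
}

#' Optimise aperture weights
#'
#' Converts the aperture-weight problem back into a fluence optimisation:
#' each aperture contributes one dose column D_a = sum of its open bixels'
#' d_ij columns, and the same projected L-BFGS optimiser is run over the
#' aperture weights with the plan objective. Shapes are fixed; only weights
#' move, and the objective never increases relative to the starting weights.
#'
#' @param apertures list of apertures, each carrying `beam` (1-based position
#'   in `dij`), `shape` and starting `weight`.
#' @param dij a `dose_influence`.
#' @param obj a [plan_objective].
#' @param cfg an [optimizer_config].
#' @return list(weights, trace, columns) where `columns` is the dense
#'   (voxels x apertures) dose matrix used.
#' @export
optimize_aperture_weights <- function(apertures, dij, obj, cfg = optimizer_config()) {
  if (!length(apertures)) stopf("no apertures to optimise")
  cols <- matrix(vapply(apertures, function(a) {
    g <- dij$grids[[a$beam]]
    as.numeric(dij$blocks[[a$beam]] %*% aperture_mask(a$shape, g$nrow, g$ncol))
  }, numeric(dij$nvox)), nrow = dij$nvox)
  w0 <- vapply(apertures, `[[`, 1, "weight")
  res <- optimize_fluence(cols, obj, w0, cfg)
  list(weights = res$w, trace = res$trace, columns = cols)
}
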