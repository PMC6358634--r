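#' Plan objective
#'
#' Resolves the per-structure importance factors and dose bounds of a
#' phantom into per-voxel vectors for the quadratic penalty objective
#' \deqn{F = \sum_i a_i \left([d_i^{min} - d_i]_+^2 + [d_i - d_i^{max}]_+^2\right)}
#' summed over every voxel of every structure that carries an objective.
#' Each voxel counts once (no volume weighting); air and objective-free
#' structures are excluded.
#'
#' @param phantom a `voxel_phantom`.
#' @param table optional data.frame (structure, a, d_min, d_max) overriding
#'   the objectives stored in the phantom's structures.
#' @return A `plan_objective`: voxel index vector `idx` plus aligned
#'   vectors `a`, `d_min` (-Inf where absent) and `d_max` (Inf).
#' @export
plan_objective <- function(phantom, table = NULL) {
  structs <- phantom$structures
  if (!is.null(table)) {
    for (r in seq_len(nrow(table))) {
      nm <- table$structure[r]
      if (!nm %in% names(structs)) stopf("objective table names unknown structure '%s'", nm)
      if (table$a[r] < 0) stopf("importance factor a must be >= 0 (structure '%s')", nm)
      structs[[nm]]$a <- table$a[r]
      structs[[nm]]$d_min <- if (is.finite(table$d_min[r] %||% NA)) table$d_min[r] else NULL
      structs[[nm]]$d_max <- if (is.finite(table$d_max[r] %||% NA)) table$d_max[r] else NULL
      if (!is.null(structs[[nm]]$d_min) && is.null(structs[[nm]]$d_max))
        stopf("structure '%s': d_min requires d_max (targets carry both bounds)", nm)
    }
  }
  idx <- integer(0); a <- numeric(0); dmin <- numeric(0); dmax <- numeric(0)
  rows <- list()
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    if (is.null(s$a)) next
    v <- which(phantom$labels == k)
    if (!length(v)) next
    idx <- c(idx, v)
    a <- c(a, rep(s$a, length(v)))
    dmin <- c(dmin, rep(s$d_min %||% -Inf, length(v)))
    dmax <- c(dmax, rep(s$d_max %||% Inf, length(v)))
    rows[[s$name]] <- list(a = s$a, d_min = s$d_min, d_max = s$d_max,
                           n_vox = length(v))
  }
  structure(list(idx = idx, a = a, d_min = dmin, d_max = dmax,
                 structures = rows, nvox = n_voxels(phantom$grid)),
            class = "plan_objective")
}

# Bare objective over already-subset dose values (length(d) == length(obj$idx)).
objective_terms <- function(d, obj) {
  under <- pmax(obj$d_min - d, 0)
  over <- pmax(d - obj$d_max, 0)
  list(value = sum(obj$a * (under^2 + over^2)),
       dgrad = 2 * obj$a * (over - under))
}

#' Total dose from fluence
#'
#' Linear dose model: d_i = sum_j d_ij w_j over the active beams.
#'
#' @param dij a `dose_influence`.
#' @param w fluence vector, concatenated over the active beams in order.
#' @param beams 1-based positions of the active beams in `dij`.
#' @return Dose per voxel (Gy), length = number of phantom voxels.
#' @export
compute_dose <- function(dij, w, beams = seq_along(dij$blocks)) {
  sub <- dij_submatrix(dij, beams)
  if (length(w) != ncol(sub$A))
    stopf("fluence vector length %d does not match %d bixels of the active beams",
          length(w), ncol(sub$A))
  as.numeric(sub$A %*% w)
}

#' Objective value of a dose distribution
#'
#' @param d dose per voxel (full phantom length, or already restricted to
#'   `obj$idx` when `restricted = TRUE`).
#' @param obj a [plan_objective].
#' @param restricted whether `d` is already subset to the objective voxels.
#' @return Nonnegative scalar F.
#' @export
objective_value <- function(d, obj, restricted = FALSE) {
  dv <- if (restricted) d else d[obj$idx]
  objective_terms(dv, obj)$value
}

#' Objective gradient with respect to fluence
#'
#' dF/dw_j = sum_i 2 a_i ([d_i - d_max]_+ - [d_min - d_i]_+) d_ij.
#'
#' @param w fluence vector over the active beams.
#' @param dij a `dose_influence`.
#' @param obj a [plan_objective].
#' @param beams active beam positions.
#' @return Gradient vector over bixels.
#' @export
objective_gradient <- function(w, dij, obj, beams = seq_along(dij$blocks)) {
  sub <- dij_submatrix(dij, beams)
  d <- as.numeric(sub$A %*% w)
  g_d <- numeric(dij$nvox)
  g_d[obj$idx] <- objective_terms(d[obj$idx], obj)$dgrad
  as.numeric(Matrix::crossprod(sub$A, g_d))
}
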