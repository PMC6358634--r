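#' Candidate beam node sets
#'
#' Nodes are discrete source positions on a sphere of radius SAD (default
#' 800 mm) centred on the phantom's target point, mimicking the workspace of
#' a robotic delivery system. Placement is a deterministic Fibonacci spiral
#' over a superior polar cap, with a posterior exclusion cone standing in
#' for the couch; the seed rotates the spiral azimuthally so independent
#' node sets can be generated reproducibly.
#'
#' @param n number of nodes (>= 1).
#' @param target aim point (mm triple), typically the PTV centroid.
#' @param sad source-axis distance in mm.
#' @param cap_deg polar half-angle of the cap about +z (degrees).
#' @param exclusion_deg half-angle of the posterior (-y) exclusion cone.
#' @param min_sep_deg minimum allowed pairwise angular separation; node
#'   generation fails if `n` nodes cannot be placed this far apart.
#' @param seed integer; deterministic azimuthal offset of the spiral.
#' @param name node set name.
#' @return A `node_set`: data.frame with columns index (0-based), x, y, z
#'   (source positions, mm), with attributes `target`, `sad`, `name`.
#' @export
generate_nodeset <- function(n, target = c(0, 0, 0), sad = 800,
                             cap_deg = 110, exclusion_deg = 30,
                             min_sep_deg = 5, seed = 0, name = "body") {
  if (n < 1) stopf("n must be >= 1")
  phi0 <- (seed %% 1000) * 2.39996322972865332  # golden angle offset per seed
  dirs <- if (n == 1) {
    matrix(c(0, 0, 1), 1, 3)
  } else {
    m <- n
    repeat {
      d <- fibonacci_cap(m, cap_deg, phi0)
      keep <- angle_between(d, c(0, -1, 0)) > exclusion_deg * pi / 180
      if (sum(keep) >= n) { d <- d[keep, , drop = FALSE][seq_len(n), , drop = FALSE]; break }
      m <- m + (n - sum(keep))
    }
    d
  }
  if (n > 1) {
    min_sep <- min_pairwise_sep(dirs)
    if (min_sep < min_sep_deg * pi / 180)
      stopf("cannot place %d nodes with pairwise separation >= %g deg (achieved %.2f deg)",
            n, min_sep_deg, min_sep * 180 / pi)
  }
  src <- sweep(dirs * sad, 2, target, `+`)
  ns <- data.frame(index = 0:(n - 1), x = src[, 1], y = src[, 2], z = src[, 3])
  attr(ns, "target") <- as.numeric(target)
  attr(ns, "sad") <- sad
  attr(ns, "name") <- name
  class(ns) <- c("node_set", "data.frame")
  ns
}

# Fibonacci spiral over the polar cap theta in [0, cap_deg] about +z.
fibonacci_cap <- function(m, cap_deg, phi0) {
  i <- seq_len(m)
  z <- 1 - (i - 0.5) / m * (1 - cos(cap_deg * pi / 180))
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- phi0 + i * 2.39996322972865332
  cbind(r * cos(phi), r * sin(phi), z)
}

min_pairwise_sep <- function(dirs) {
  g <- matrix(pmin(1, pmax(-1, tcrossprod(dirs))), nrow(dirs))
  diag(g) <- -1
  acos(max(g))
}

node_directions <- function(ns) {
  target <- attr(ns, "target")
  src <- as.matrix(ns[, c("x", "y", "z")])
  d <- sweep(-src, 2, target, `+`)  # from source toward target
  d / sqrt(rowSums(d^2))
}

#' Evenly spaced subset of a node set
#'
#' Greedy farthest-point subsampling by angular separation: the first two
#' nodes are the pair at maximal separation, then each added node maximises
#' its minimum separation from those already chosen (ties broken by lowest
#' index). Deterministic; the subset is re-indexed 0..n-1 and keeps the
#' original index in column `source_index`.
#'
#' @param full a `node_set`.
#' @param n subset size (<= number of nodes in `full`).
#' @return A `node_set` of `n` nodes.
#' @export
subset_nodeset <- function(full, n) {
  nf <- nrow(full)
  if (n > nf) stopf("subset size %d exceeds node set size %d", n, nf)
  sel <- if (n == nf) {
    seq_len(nf)
  } else {
    dirs <- node_directions(full)
    ang <- acos(matrix(pmin(1, pmax(-1, tcrossprod(dirs))), nrow(dirs)))
    pair <- which(ang == max(ang), arr.ind = TRUE)[1, ]
    chosen <- sort(as.integer(pair))
    if (n == 1) chosen <- chosen[1]
    while (length(chosen) < n) {
      dmin <- apply(ang[, chosen, drop = FALSE], 1, min)
      dmin[chosen] <- -1
      chosen <- c(chosen, which.max(dmin))
    }
    sort(chosen)
  }
  out <- full[sel, , drop = FALSE]
  out$source_index <- out$index
  out$index <- 0:(n - 1)
  rownames(out) <- NULL
  attr(out, "target") <- attr(full, "target")
  attr(out, "sad") <- attr(full, "sad")
  attr(out, "name") <- paste0(attr(full, "name"), "-subset", n)
  class(out) <- c("node_set", "data.frame")
  out
}

#' Read/write node sets as tab-separated text
#'
#' Format: comment header lines starting with '#' carrying name, sad and
#' target, a '# index\tx\ty\tz' column line, then one node per line.
#'
#' @param ns a `node_set`.
#' @param path file path.
#' @return `read_nodeset` returns a `node_set`; `write_nodeset` returns
#'   `path` invisibly.
#' @export
write_nodeset <- function(ns, path) {
  target <- attr(ns, "target")
  lines <- c(
    sprintf("# nodeset: %s", attr(ns, "name") %||% "unnamed"),
    sprintf("# sad_mm: %.6g", attr(ns, "sad")),
    sprintf("# target_mm: %.6g %.6g %.6g", target[1], target[2], target[3]),
    "# index\tx\ty\tz",
    sprintf("%d\t%.9g\t%.9g\t%.9g", ns$index, ns$x, ns$y, ns$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_nodeset
#' @export
read_nodeset <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  grab <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  d <- read.table(text = body, col.names = c("index", "x", "y", "z"))
  ns <- data.frame(index = as.integer(d$index), x = d$x, y = d$y, z = d$z)
  attr(ns, "sad") <- as.numeric(grab("sad_mm") %||% 800)
  tgt <- grab("target_mm")
  attr(ns, "target") <- if (is.null(tgt)) c(0, 0, 0) else as.numeric(strsplit(tgt, "\\s+")[[1]])
  attr(ns, "name") <- grab("nodeset") %||% "unnamed"
  class(ns) <- c("node_set", "data.frame")
  ns
}
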