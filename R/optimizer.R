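#' Optimiser configuration
#'
#' Settings for the projected L-BFGS fluence optimiser. The update is
#' \deqn{w^{x+1} = [w^x - \alpha p^x]_+}
#' where p is the L-BFGS direction from the two-loop recursion and the
#' relaxation parameter alpha comes from a backtracking Armijo line search
#' (start 1, halve, c = 1e-4), so every accepted step decreases F. Standalone
#' plans use 40 iterations and beam-selection inner plans 20 by convention;
#' an early exit triggers when the relative change in F falls below `tol`.
#'
#' @param max_iter iteration budget (>= 1).
#' @param memory number of stored curvature pairs (>= 1).
#' @param armijo_c sufficient-decrease constant.
#' @param max_backtrack maximum halvings of the step length.
#' @param tol relative-change early-exit tolerance.
#' @return An `optimizer_config` object.
#' @export
optimizer_config <- function(max_iter = 40, memory = 10, armijo_c = 1e-4,
                             max_backtrack = 40, tol = 1e-10) {
  if (max_iter < 1 || memory < 1) stopf("max_iter and memory must be >= 1")
  structure(list(max_iter = as.integer(max_iter), memory = as.integer(memory),
                 armijo_c = armijo_c, max_backtrack = as.integer(max_backtrack),
                 tol = tol),
            class = "optimizer_config")
}

#' Projected L-BFGS fluence optimisation
#'
#' Minimises the quadratic min/max-dose penalty F over nonnegative fluence.
#' The search direction is built by the L-BFGS two-loop recursion over
#' curvature pairs of projected iterates (pairs with s.y <= 1e-12 are
#' discarded); the first iteration, with empty memory, reduces to projected
#' steepest descent. If the quasi-Newton step yields no sufficient decrease
#' the gradient direction is tried before giving up, so the objective trace
#' is non-increasing by construction.
#'
#' @param A dose operator: matrix or dgCMatrix, (voxels x bixels). Rows not
#'   listed in `obj$idx` are ignored.
#' @param obj a [plan_objective] (its `idx` indexes rows of `A`).
#' @param w0 nonnegative starting fluence.
#' @param cfg an [optimizer_config].
#' @return list(w, trace, n_iter, converged); `trace` holds F at w0 and
#'   after every accepted iteration.
#' @export
optimize_fluence <- function(A, obj, w0, cfg = optimizer_config()) {
  if (any(w0 < 0)) stopf("starting fluence must be nonnegative")
  nb <- ncol(A)
  if (length(w0) != nb) stopf("w0 length %d does not match %d bixels", length(w0), nb)
  if (nb == 0L) return(list(w = w0, trace = numeric(0), n_iter = 0L, converged = TRUE))
  Ao <- A[obj$idx, , drop = FALSE]
  fg <- function(w) {
    d <- as.numeric(Ao %*% w)
    tr <- objective_terms(d, obj)
    if (!is.finite(tr$value)) stopf("non-finite objective encountered")
    g <- as.numeric(Matrix::crossprod(Ao, tr$dgrad))
    if (any(!is.finite(g))) stopf("non-finite gradient encountered")
    list(f = tr$value, g = g)
  }
  w <- w0
  cur <- fg(w)
  trace <- cur$f
  S <- list(); Y <- list(); rho <- numeric(0)
  converged <- FALSE
  it <- 0L
  stalled <- FALSE
  while (it < cfg$max_iter) {
    # optimality on the nonnegativity bound: zero the gradient on active
    # coordinates being pushed outward
    active <- w <= 0 & cur$g > 0
    pg <- ifelse(active, 0, cur$g)
    if (cur$f == 0 || max(abs(pg)) <= 1e-12 * max(1, cur$f)) { converged <- TRUE; break }
    it <- it + 1L
    p <- lbfgs_direction(cur$g, S, Y, rho)
    # active coordinates take the raw gradient so the projection pins them
    p[active] <- cur$g[active]
    step <- line_search_projected(fg, w, cur, p, cfg)
    if (is.null(step) && length(S)) {
      # quasi-Newton direction failed; retry with plain projected gradient
      S <- list(); Y <- list(); rho <- numeric(0)
      step <- line_search_projected(fg, w, cur, cur$g, cfg)
    }
    if (is.null(step)) { it <- it - 1L; break }
    s <- step$w - w
    y <- step$new$g - cur$g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      S <- c(S, list(s)); Y <- c(Y, list(y)); rho <- c(rho, 1 / sy)
      if (length(S) > cfg$memory) { S <- S[-1]; Y <- Y[-1]; rho <- rho[-1] }
    }
    relchange <- (cur$f - step$new$f) / max(cur$f, .Machine$double.xmin)
    w <- step$w
    cur <- step$new
    trace <- c(trace, cur$f)
    if (relchange < cfg$tol) {
      # stagnated twice in a row with a fresh memory: accept as converged
      if (stalled && !length(S)) { converged <- TRUE; break }
      stalled <- TRUE
      S <- list(); Y <- list(); rho <- numeric(0)
    } else stalled <- FALSE
  }
  list(w = w, trace = trace, n_iter = it, converged = converged)
}

# Two-loop recursion; with empty memory returns the gradient itself
# (projected steepest descent on the first iteration).
lbfgs_direction <- function(g, S, Y, rho) {
  m <- length(S)
  if (m == 0L) return(g)
  q <- g
  alpha <- numeric(m)
  for (i in m:1) {
    alpha[i] <- rho[i] * sum(S[[i]] * q)
    q <- q - alpha[i] * Y[[i]]
  }
  gamma <- sum(S[[m]] * Y[[m]]) / sum(Y[[m]] * Y[[m]])
  r <- gamma * q
  for (i in 1:m) {
    beta <- rho[i] * sum(Y[[i]] * r)
    r <- r + (alpha[i] - beta) * S[[i]]
  }
  r
}

# Backtracking Armijo search along the projected arc w(alpha) = [w - alpha p]+.
line_search_projected <- function(fg, w, cur, p, cfg) {
  sp <- max(abs(p))
  if (sp == 0) return(NULL)
  alpha <- 1
  for (k in seq_len(cfg$max_backtrack)) {
    wn <- pmax(w - alpha * p, 0)
    dw <- wn - w
    if (all(dw == 0)) return(NULL)
    new <- fg(wn)
    if (new$f <= cur$f + cfg$armijo_c * sum(cur$g * dw) && new$f < cur$f)
      return(list(w = wn, new = new, alpha = alpha))
    alpha <- alpha / 2
  }
  NULL
}

#' Initial fluence
#'
#' Uniform mode scales a flat fluence so the mean PTV dose equals the
#' prescription; zeros mode returns the zero vector.
#'
#' @param A dose operator (voxels x bixels).
#' @param ptv_idx row indices of the PTV voxels.
#' @param prescription prescription dose, Gy.
#' @param mode "uniform" or "zeros".
#' @return Nonnegative fluence vector of length ncol(A).
#' @export
initial_fluence <- function(A, ptv_idx, prescription, mode = c("uniform", "zeros")) {
  mode <- match.arg(mode)
  nb <- ncol(A)
  if (nb == 0L) return(numeric(0))
  if (mode == "zeros") return(numeric(nb))
  ones <- rep(1, nb)
  mean_ptv <- mean(as.numeric(A[ptv_idx, , drop = FALSE] %*% ones))
  if (mean_ptv <= 0) stopf("uniform fluence delivers no PTV dose; beams miss the target")
  rep(prescription / mean_ptv, nb)
}
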