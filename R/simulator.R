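#' Two-master stochastic GRN model for binary fate decisions
#'
#' The canonical mutual-inhibition / self-activation motif of binary
#' lineage choice (the GATA1-PU.1 class of circuits): two master
#' regulators x and y, each activating itself and repressing the other
#' through Hill kinetics, plus a set of downstream genes that read the
#' masters out linearly with additive noise. The deterministic master
#' dynamics are
#'
#' \deqn{\dot x = \mu\, a\, x^h/(S^h + x^h) + b\, S^h/(S^h + y^h) - k x +
#'   \mathrm{bias}_x}
#' \deqn{\dot y = \mu\, a\, y^h/(S^h + y^h) + b\, S^h/(S^h + x^h) - k y +
#'   \mathrm{bias}_y}
#'
#' where a positive `bias` enters x's production and a negative one
#' enters y's (so production never turns negative and the sign of `bias`
#' picks the favored branch).
#'
#' For strong self-activation (\eqn{\mu} near 1 with the default rates)
#' the system is tristable: a central co-expression attractor (the
#' multipotent progenitor) flanked by two asymmetric attractors (the two
#' committed lineages). Lowering \eqn{\mu} weakens self-activation until
#' the central attractor vanishes in a pitchfork-like bifurcation and
#' every cell must commit. A nonzero `bias` (an extra production term on
#' x, the instructive differentiation signal) breaks the symmetry into an
#' imperfect pitchfork: the x-branch becomes the intended fate and the
#' y-branch is reachable only when noise overcomes the bias — cells that
#' land there are "rebellious".
#'
#' @param a self-activation strength (default 1).
#' @param b cross-inhibition basal production strength (default 1).
#' @param k first-order decay rate (default 1).
#' @param S Hill threshold (default 0.5).
#' @param h Hill exponent (>= 1; default 4).
#' @param mu bifurcation parameter scaling the self-activation/decay
#'   balance (default 1).
#' @param bias instructive imperfection term added to x's production
#'   (default 0).
#' @param noise_sigma additive noise scale of the Euler-Maruyama
#'   integration (default 0.08).
#' @param w_x,w_y downstream linear coupling weights to x and y (equal
#'   length vectors; defaults give 5 x-driven and 5 y-driven readout
#'   genes with varied gains).
#' @param basal downstream basal production (scalar or vector).
#' @param k_down downstream decay rate (default 1).
#' @return an object of class `grn_model`.
#' @export
grn_model <- function(a = 1, b = 1, k = 1, S = 0.5, h = 4,
                      mu = 1, bias = 0, noise_sigma = 0.08,
                      w_x = c(1.0, 0.8, 0.6, 0.45, 0.3,
                              0.05, 0.1, 0.15, 0.1, 0.05),
                      w_y = c(0.05, 0.1, 0.15, 0.1, 0.05,
                              1.0, 0.8, 0.6, 0.45, 0.3),
                      basal = 0.1, k_down = 1) {
  if (length(w_x) != length(w_y))
    stop("w_x and w_y must have equal length")
  if (any(c(a, b, k, S, k_down) <= 0)) stop("rates must be > 0")
  if (h < 1) stop("Hill exponent must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  nd <- length(w_x)
  basal <- rep_len(basal, nd)
  structure(list(a = a, b = b, k = k, S = S, h = h, mu = mu, bias = bias,
                 noise_sigma = noise_sigma, w_x = w_x, w_y = w_y,
                 basal = basal, k_down = rep_len(k_down, nd),
                 n_genes = nd + 2L),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat(sprintf(paste0("grn_model: 2 masters + %d downstream genes\n",
                     "  mu = %.3f, bias = %.3f, noise_sigma = %.3f, ",
                     "h = %g, S = %g\n"),
              length(x$w_x), x$mu, x$bias, x$noise_sigma, x$h, x$S))
  invisible(x)
}

# Deterministic drift of the master pair; st is an n x 2 matrix.
.master_drift <- function(st, model, mu) {
  x <- st[, 1L]; y <- st[, 2L]
  Sh <- model$S^model$h
  xh <- x^model$h; yh <- y^model$h
  cbind(mu * model$a * xh / (Sh + xh) + model$b * Sh / (Sh + yh) -
          model$k * x + max(model$bias, 0),
        mu * model$a * yh / (Sh + yh) + model$b * Sh / (Sh + xh) -
          model$k * y + max(-model$bias, 0))
}

#' Fixed points of the master subsystem
#'
#' Multi-start Newton root finding on the deterministic two-master drift
#' at a given value of the bifurcation parameter, with stability from the
#' eigenvalues of the finite-difference Jacobian.
#'
#' @param model a [grn_model()].
#' @param mu bifurcation parameter value (default the model's).
#' @param grid_n starting points per axis on \[0, 3\] (default 8).
#' @param tol root tolerance on the drift norm.
#' @return data.frame with columns `x`, `y`, `stable`, `lambda_max` (the
#'   largest real part of the Jacobian eigenvalues), one row per distinct
#'   fixed point.
#' @export
find_fixed_points <- function(model, mu = model$mu, grid_n = 8,
                              tol = 1e-10) {
  stopifnot(inherits(model, "grn_model"))
  f <- function(p) drop(.master_drift(rbind(p), model, mu))
  jac <- function(p, eps = 1e-6) {
    cbind((f(p + c(eps, 0)) - f(p - c(eps, 0))) / (2 * eps),
          (f(p + c(0, eps)) - f(p - c(0, eps))) / (2 * eps))
  }
  starts <- as.matrix(expand.grid(seq(0, 3, length.out = grid_n),
                                  seq(0, 3, length.out = grid_n)))
  roots <- list()
  for (s in seq_len(nrow(starts))) {
    p <- starts[s, ]
    ok <- FALSE
    for (it in 1:100) {
      fv <- f(p)
      if (!all(is.finite(fv))) break
      if (sqrt(sum(fv^2)) < tol) { ok <- TRUE; break }
      step <- tryCatch(solve(jac(p), fv), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      # damped Newton keeps iterates in the positive quadrant's vicinity
      lam <- 1
      repeat {
        q <- p - lam * step
        if (all(is.finite(q)) && max(abs(q)) < 50) break
        lam <- lam / 2
        if (lam < 1e-6) break
      }
      p <- q
    }
    if (ok && all(p > -1e-8)) roots[[length(roots) + 1L]] <- pmax(p, 0)
  }
  if (!length(roots)) stop("no fixed point found: invalid model/mu")
  pts <- unique(do.call(rbind, lapply(roots, round, digits = 6)))
  out <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    ev <- eigen(jac(pts[i, ]), only.values = TRUE)$values
    data.frame(x = pts[i, 1L], y = pts[i, 2L],
               stable = max(Re(ev)) < 0, lambda_max = max(Re(ev)))
  }))
  rownames(out) <- NULL
  out
}

#' Critical value of the bifurcation parameter
#'
#' Bisects on `mu` for the disappearance of the progenitor (central,
#' near-diagonal) stable fixed point of the master subsystem.
#'
#' @param model a [grn_model()].
#' @param lower,upper bracketing interval for `mu`.
#' @param tol bisection tolerance on `mu`.
#' @return the critical `mu` below which no progenitor attractor exists.
#' @export
critical_mu <- function(model, lower = 0.2, upper = 1.5, tol = 1e-4) {
  has_prog <- function(mu) {
    fps <- tryCatch(find_fixed_points(model, mu = mu),
                    error = function(e) NULL)
    !is.null(fps) && nrow(.label_fixed_points(fps)[
      .label_fixed_points(fps)$label == "progenitor", , drop = FALSE]) > 0
  }
  if (!has_prog(upper)) stop("no progenitor attractor at upper mu")
  if (has_prog(lower)) stop("progenitor attractor persists at lower mu")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_prog(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Label stable fixed points: the one nearest the diagonal x = y is the
# progenitor (if close enough relative to the attractor spread); of the
# others, larger x - y is the x-branch, smaller the y-branch.
.label_fixed_points <- function(fps) {
  st <- fps[fps$stable, , drop = FALSE]
  if (!nrow(st)) stop("no stable fixed point found: invalid model/mu")
  st$label <- NA_character_
  asym <- abs(st$x - st$y)
  if (nrow(st) == 1L) {
    st$label <- if (asym < 0.5 * (st$x + st$y)) "progenitor" else "x-branch"
    if (st$label == "x-branch" && st$y > st$x) st$label <- "y-branch"
    return(st)
  }
  spread <- max(1e-8, max(stats::dist(st[, c("x", "y")])))
  prog <- which.min(asym)
  if (asym[prog] < 0.25 * spread) st$label[prog] <- "progenitor"
  rest <- which(is.na(st$label))
  if (length(rest)) {
    d <- st$x[rest] - st$y[rest]
    st$label[rest] <- ifelse(d >= 0, "x-branch", "y-branch")
  }
  st
}

#' Classify cell states by attractor basin
#'
#' Assigns each cell to the nearest stable fixed point of the master
#' subsystem in the (x, y) plane, within a capture radius of 25% of the
#' smallest inter-attractor distance; states outside every radius are
#' `"undecided"`. The near-diagonal attractor is the `"progenitor"`; of
#' the committed attractors, the one favored by the sign of the model's
#' bias is `"intended"` and the other is `"rebellious"` (with zero bias
#' the x-branch is reported as intended by convention).
#'
#' @param state numeric vector (first two entries = master concentrations,
#'   linear scale) or an n x >=2 matrix of states, one row per cell.
#' @param model a [grn_model()].
#' @param mu bifurcation parameter at which basins are evaluated.
#' @param capture_frac capture radius as a fraction of the smallest
#'   inter-attractor distance (default 0.25); with a single attractor the
#'   radius is `capture_frac * 4`.
#' @param fps optional precomputed [find_fixed_points()] table.
#' @return character vector of labels in `progenitor`, `intended`,
#'   `rebellious`, `undecided`.
#' @export
classify_attractor <- function(state, model, mu = model$mu,
                               capture_frac = 0.25, fps = NULL) {
  if (is.null(dim(state))) state <- rbind(state)
  xy <- state[, 1:2, drop = FALSE]
  if (is.null(fps)) fps <- find_fixed_points(model, mu = mu)
  st <- .label_fixed_points(fps)
  intended_branch <- if (model$bias >= 0) "x-branch" else "y-branch"
  st$out_label <- ifelse(st$label == "progenitor", "progenitor",
                         ifelse(st$label == intended_branch,
                                "intended", "rebellious"))
  centers <- as.matrix(st[, c("x", "y")])
  radius <- if (nrow(centers) > 1L)
    capture_frac * min(stats::dist(centers)) else capture_frac * 4
  d <- sqrt(outer(xy[, 1L], centers[, 1L], "-")^2 +
            outer(xy[, 2L], centers[, 2L], "-")^2)
  nearest <- max.col(-d, ties.method = "first")
  lab <- st$out_label[nearest]
  lab[d[cbind(seq_len(nrow(xy)), nearest)] > radius] <- "undecided"
  lab
}

# Per-(cell, stage) reproducible sub-seed; keeps each cell's noise stream
# independent of how many other cells are simulated.
.cell_seed <- function(seed, cell, stage) {
  as.integer((as.numeric(seed) * 7919 + cell * 104729 + stage * 15485863)
             %% 2147483629)
}

# One Euler-Maruyama stage at fixed mu. st: n x (2 + nd) state matrix on
# the linear concentration scale. Reflecting boundary at 0.
.integrate_stage <- function(st, model, mu, time, dt, seed, stage) {
  n <- nrow(st)
  nd <- length(model$w_x)
  g <- 2L + nd
  steps <- max(1L, round(time / dt))
  sig <- model$noise_sigma * sqrt(dt)
  # per-cell noise streams (one column per cell) so trajectories are
  # invariant to n_cells; within a cell, g draws are consumed per step
  noise <- if (sig > 0) vapply(seq_len(n), function(i) {
    set.seed(.cell_seed(seed, i, stage))
    stats::rnorm(steps * g)
  }, numeric(steps * g)) else NULL
  basal_m <- matrix(model$basal, n, nd, byrow = TRUE)
  kd <- matrix(model$k_down, n, nd, byrow = TRUE)
  for (s in seq_len(steps)) {
    drift_m <- .master_drift(st[, 1:2, drop = FALSE], model, mu)
    z <- st[, -(1:2), drop = FALSE]
    drift_d <- basal_m + tcrossprod(st[, 1L], model$w_x) +
      tcrossprod(st[, 2L], model$w_y) - z * kd
    st <- st + dt * cbind(drift_m, drift_d)
    if (sig > 0)
      st <- st + sig * t(noise[((s - 1L) * g + 1L):(s * g), , drop = FALSE])
    st <- abs(st)                                  # reflect at 0
  }
  if (!all(is.finite(st)))
    stop("non-finite state during integration: reduce dt")
  st
}

#' Simulate a snapshot ensemble through a bifurcation schedule
#'
#' Integrates `n_cells` independent cells of the stochastic GRN by
#' Euler-Maruyama while the bifurcation parameter is stepped
#' piecewise-constant through `mu_schedule`. All cells start at the
#' progenitor fixed point of the first `mu` and equilibrate for
#' `burn_in` time units before the first snapshot; each subsequent stage
#' integrates `stage_time` units at its `mu` and then records a snapshot.
#' Snapshots are [expression_matrix()] objects on the log2(value + 1)
#' scale with per-cell attractor labels in the `fraction` metadata
#' column, so every analysis function consumes them directly.
#'
#' @param model a [grn_model()].
#' @param n_cells ensemble size (>= 10).
#' @param mu_schedule data.frame with columns `time_label` and `mu`
#'   (monotone in `mu`).
#' @param seed integer seed; the same seed reproduces the ensemble
#'   bit-identically, and each cell's noise stream is independent of
#'   `n_cells`.
#' @param dt Euler-Maruyama step (default 0.01).
#' @param stage_time integration time per schedule stage (default 15).
#' @param burn_in equilibration time before the first snapshot
#'   (default `stage_time`).
#' @return an object of class `simulation_ensemble`: list with
#'   `snapshots` (named list of `ExpressionMatrix`), `labels` (per-cell
#'   attractor label per snapshot), `schedule`, `model`, `seed`, `dt`,
#'   `stage_time`, `states` (final linear-scale state per snapshot).
#' @export
simulate_ensemble <- function(model, n_cells, mu_schedule, seed = 1,
                              dt = 0.01, stage_time = 15,
                              burn_in = stage_time) {
  stopifnot(inherits(model, "grn_model"))
  if (n_cells < 10) stop("n_cells must be >= 10")
  mu_schedule <- as.data.frame(mu_schedule)
  if (!all(c("time_label", "mu") %in% names(mu_schedule)))
    stop("mu_schedule needs columns time_label, mu")
  dmu <- diff(mu_schedule$mu)
  if (!(all(dmu <= 0) || all(dmu >= 0)))
    stop("mu_schedule must be monotone in mu")

  nd <- length(model$w_x)
  fps0 <- .label_fixed_points(find_fixed_points(model,
                                                mu = mu_schedule$mu[1L]))
  prog <- fps0[fps0$label == "progenitor", , drop = FALSE]
  start <- if (nrow(prog)) c(prog$x[1L], prog$y[1L])
           else c(fps0$x[1L], fps0$y[1L])
  z0 <- (model$basal + model$w_x * start[1L] + model$w_y * start[2L]) /
    model$k_down
  st <- matrix(rep(c(start, z0), each = n_cells), nrow = n_cells)

  gene_names <- c("M1", "M2", sprintf("G%02d", seq_len(nd)))
  cell_names <- sprintf("c%04d", seq_len(n_cells))
  snapshots <- list(); labels <- list(); states <- list()
  for (k in seq_len(nrow(mu_schedule))) {
    mu_k <- mu_schedule$mu[k]
    lab_k <- as.character(mu_schedule$time_label[k])
    time_k <- if (k == 1L) burn_in else stage_time
    st <- .integrate_stage(st, model, mu_k, time_k, dt, seed, stage = k)
    att <- classify_attractor(st, model, mu = mu_k)
    expr <- log2(st + 1)
    dimnames(expr) <- list(cell_names, gene_names)
    meta <- data.frame(cell_id = cell_names, time_point = lab_k,
                       treatment = "sim", fraction = att)
    snapshots[[lab_k]] <- expression_matrix(expr, cell_meta = meta)
    labels[[lab_k]] <- att
    states[[lab_k]] <- st
  }
  structure(list(snapshots = snapshots, labels = labels,
                 schedule = mu_schedule, model = model, seed = seed,
                 dt = dt, stage_time = stage_time, states = states),
            class = "simulation_ensemble")
}

#' @export
print.simulation_ensemble <- function(x, ...) {
  cat(sprintf("simulation_ensemble: %d snapshots x %d cells x %d genes\n",
              length(x$snapshots), nrow(x$snapshots[[1L]]$values),
              x$model$n_genes))
  for (k in seq_len(nrow(x$schedule))) {
    lab <- as.character(x$schedule$time_label[k])
    tab <- table(x$labels[[lab]])
    cat(sprintf("  %s (mu = %.3f): %s\n", lab, x$schedule$mu[k],
                paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Concatenate ensemble snapshots into one ExpressionMatrix
#'
#' Stacks all snapshots, prefixing cell ids with their time label, so the
#' combined matrix can be analyzed with [ic_timecourse()] or
#' [pca_project()] (which expects all time points concatenated).
#'
#' @param ensemble a [simulate_ensemble()] result.
#' @return an [expression_matrix()] with `time_point` metadata.
#' @export
as_expression_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "simulation_ensemble"))
  vals <- list(); metas <- list()
  for (lab in names(ensemble$snapshots)) {
    sn <- ensemble$snapshots[[lab]]
    v <- sn$values
    rownames(v) <- paste(lab, rownames(v), sep = "_")
    m <- sn$cell_meta
    m$cell_id <- rownames(v)
    vals[[lab]] <- v
    metas[[lab]] <- m
  }
  expression_matrix(do.call(rbind, vals),
                    cell_meta = do.call(rbind, metas),
                    gene_roles = ensemble$snapshots[[1L]]$gene_roles)
}

#' Ensemble relaxation time after a sorting-like perturbation
#'
#' Places all cells at the progenitor fixed point displaced by
#' `perturbation`, integrates at fixed `mu`, and reports the time at
#' which the ensemble median displacement from the fixed point (in the
#' master plane) first falls below `threshold` times the initial
#' displacement. Near a bifurcation the attracting force weakens and
#' this time diverges — critical slowing down. For the noise-free system
#' the linearized prediction is `log(1/threshold) / |Re lambda_max|`
#' with `lambda_max` the slowest Jacobian eigenvalue at the fixed point
#' (see [predicted_relaxation_time()]).
#'
#' @param model a [grn_model()].
#' @param mu bifurcation parameter (progenitor attractor must exist).
#' @param perturbation displacement of the starting cloud in the master
#'   plane (length 2, or length `n_genes` of which the first two entries
#'   are used). Default: 0.05 along the slowest eigenvector.
#' @param threshold fraction of the initial displacement defining arrival
#'   (in (0, 1]; default `exp(-1)`).
#' @param n_cells ensemble size (default 1; noise-free runs need only 1).
#' @param noise_sigma noise scale override (default the model's; set 0
#'   for the deterministic variant).
#' @param seed integer seed for the noisy variant.
#' @param dt integration step (default 0.005).
#' @param max_time give-up horizon; non-convergence returns `Inf` with
#'   attribute `censored = TRUE` rather than an error.
#' @return relaxation time in model time units, with attributes
#'   `censored`, `fixed_point`, `lambda_max`.
#' @export
relaxation_time <- function(model, mu = model$mu, perturbation = NULL,
                            threshold = exp(-1), n_cells = 1,
                            noise_sigma = model$noise_sigma, seed = 1,
                            dt = 0.005, max_time = 500) {
  stopifnot(inherits(model, "grn_model"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  fps <- .label_fixed_points(find_fixed_points(model, mu = mu))
  prog <- fps[fps$label == "progenitor", , drop = FALSE]
  if (!nrow(prog))
    stop("no progenitor attractor at mu = ", mu,
         ": already past the bifurcation")
  fp <- c(prog$x[1L], prog$y[1L])
  lam <- .slowest_eigen(model, mu, fp)
  if (is.null(perturbation))
    perturbation <- 0.05 * lam$vector
  pert <- perturbation[1:2]
  if (threshold == 1) {
    out <- 0
    attr(out, "censored") <- FALSE
    attr(out, "fixed_point") <- fp
    attr(out, "lambda_max") <- lam$value
    return(out)
  }

  m2 <- model
  m2$noise_sigma <- noise_sigma
  nd <- length(model$w_x)
  z0 <- (model$basal + model$w_x * fp[1L] + model$w_y * fp[2L]) /
    model$k_down
  st <- matrix(rep(c(fp + pert, z0), each = n_cells), nrow = n_cells)
  d0 <- sqrt(sum(pert^2))
  steps_chunk <- 50L
  t_now <- 0
  out <- Inf; censored <- TRUE
  stage <- 0L
  while (t_now < max_time) {
    stage <- stage + 1L
    st <- .integrate_stage(st, m2, mu, steps_chunk * dt, dt, seed, stage)
    t_now <- t_now + steps_chunk * dt
    disp <- sqrt((st[, 1L] - fp[1L])^2 + (st[, 2L] - fp[2L])^2)
    if (stats::median(disp) < threshold * d0) {
      out <- t_now; censored <- FALSE
      break
    }
  }
  attr(out, "censored") <- censored
  attr(out, "fixed_point") <- fp
  attr(out, "lambda_max") <- lam$value
  out
}

# Slowest eigenvalue/eigenvector of the finite-difference Jacobian of the
# master drift at a point.
.slowest_eigen <- function(model, mu, p, eps = 1e-6) {
  f <- function(q) drop(.master_drift(rbind(q), model, mu))
  J <- cbind((f(p + c(eps, 0)) - f(p - c(eps, 0))) / (2 * eps),
             (f(p + c(0, eps)) - f(p - c(0, eps))) / (2 * eps))
  ev <- eigen(J)
  i <- which.max(Re(ev$values))
  vec <- Re(ev$vectors[, i])
  vec <- vec / sqrt(sum(vec^2))
  list(value = Re(ev$values[i]), vector = vec)
}

#' @rdname relaxation_time
#' @export
predicted_relaxation_time <- function(model, mu = model$mu,
                                      threshold = exp(-1)) {
  fps <- .label_fixed_points(find_fixed_points(model, mu = mu))
  prog <- fps[fps$label == "progenitor", , drop = FALSE]
  if (!nrow(prog)) stop("no progenitor attractor at mu = ", mu)
  lam <- .slowest_eigen(model, mu, c(prog$x[1L], prog$y[1L]))
  if (lam$value >= 0) stop("fixed point not attracting")
  log(1 / threshold) / abs(lam$value)
}

#' Pinned benchmark scenario: an ensemble driven through the bifurcation
#'
#' A fixed configuration emulating a differentiation time-course
#' experiment at desk scale: 12 genes (2 masters + 10 downstream
#' readouts), 500 cells, and four sampling times t0-t3 whose bifurcation
#' parameter ramps from deep inside the progenitor regime to past the
#' tipping point, with a mild instructive bias toward the x-branch.
#' Analyzing it with [ic_timecourse()] reproduces the early-warning
#' phenomenology: mean cell-cell correlation falls, mean absolute
#' gene-gene correlation rises, I_C peaks at the snapshot nearest the
#' tipping point, and a minority of rebellious cells commits to the
#' non-intended branch.
#'
#' @param seed integer seed (default 1).
#' @param n_cells ensemble size (default 500).
#' @return a [simulate_ensemble()] result; the critical `mu` is attached
#'   as attribute `"mu_critical"`.
#' @export
default_scenario <- function(seed = 1, n_cells = 500) {
  model <- grn_model(bias = 0.04, noise_sigma = 0.08)
  schedule <- data.frame(
    time_label = c("t0", "t1", "t2", "t3"),
    mu = c(1.00, 0.88, 0.82, 0.70))
  ens <- simulate_ensemble(model, n_cells = n_cells,
                           mu_schedule = schedule, seed = seed,
                           dt = 0.01, stage_time = 15, burn_in = 25)
  # critical mu of this model, from critical_mu(grn_model(bias = 0.04))
  attr(ens, "mu_critical") <- 0.8115
  ens
}

#' Fraction of committed cells in the non-intended attractor
#'
#' @param ensemble a [simulate_ensemble()] result.
#' @param snapshot time label (default the last snapshot).
#' @return fraction of cells labeled `rebellious` among all cells.
#' @export
rebellious_fraction <- function(ensemble,
                                snapshot = utils::tail(
                                  names(ensemble$snapshots), 1L)) {
  stopifnot(inherits(ensemble, "simulation_ensemble"))
  lab <- ensemble$labels[[snapshot]]
  mean(lab == "rebellious")
}
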