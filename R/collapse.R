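# Plane-strain constitutive matrix for modulus E (or the dashpot viscosity
# substituted for E) and Poisson ratio nu.
plane_strain_C <- function(E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  f * matrix(c(1 - nu, nu, 0,
               nu, 1 - nu, 0,
               0, 0, (1 - 2 * nu) / 2), 3, 3)
}

# Assemble the global stiffness-like matrix for linear (constant-strain)
# triangles: sum over elements of A * t * B' C B, with C chosen per element.
assemble_matrix <- function(mesh, C_by_label) {
  p <- mesh$nodes
  tri <- mesh$triangles
  ne <- nrow(tri)
  areas <- triangle_areas(mesh)
  ii <- integer(36L * ne); jj <- integer(36L * ne); vv <- numeric(36L * ne)
  pos <- 0L
  for (e in seq_len(ne)) {
    nd <- tri[e, ]
    x <- p[nd, 1]; y <- p[nd, 2]
    A <- areas[e]
    b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2]) / (2 * A)
    c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / (2 * A)
    B <- matrix(0, 3, 6)
    B[1, c(1, 3, 5)] <- b
    B[2, c(2, 4, 6)] <- c_
    B[3, c(1, 3, 5)] <- c_
    B[3, c(2, 4, 6)] <- b
    Ce <- C_by_label[[as.integer(mesh$label[e])]]
    Ke <- (A * mesh$thickness) * crossprod(B, Ce %*% B)
    dof <- as.vector(rbind(2L * nd - 1L, 2L * nd))
    idx <- pos + seq_len(36L)
    ii[idx] <- rep(dof, times = 6L)
    jj[idx] <- rep(dof, each = 6L)
    vv[idx] <- as.vector(Ke)
    pos <- pos + 36L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(2L * nrow(p), 2L * nrow(p)), symmetric = FALSE)
}

# Consistent (lumped) nodal load vector for a body force rho * g downward plus
# an optional uniform downward traction on the top boundary edge.
assemble_load <- function(mesh, rho_by_label, gravity, top_traction) {
  p <- mesh$nodes
  tri <- mesh$triangles
  areas <- triangle_areas(mesh)
  f <- numeric(2L * nrow(p))
  if (gravity != 0) {
    rho <- rho_by_label[as.integer(mesh$label)]
    w_e <- rho * gravity * areas * mesh$thickness / 3  # N per node, downward
    for (e in seq_len(nrow(tri))) {
      dofz <- 2L * tri[e, ]
      f[dofz] <- f[dofz] - w_e[e]
    }
  }
  if (top_traction != 0) {
    top <- mesh$top[order(p[mesh$top, 1])]
    if (length(top) >= 2L) {
      seg_len <- diff(p[top, 1])
      # trapezoidal distribution of the line load onto the top edge nodes
      node_w <- c(seg_len / 2, 0) + c(0, seg_len / 2)
      f[2L * top] <- f[2L * top] - top_traction * node_w * mesh$thickness
    }
  }
  f
}

#' Transient Kelvin-Voigt collapse of a scaffold mesh under gravity
#'
#' Plane-strain linear-triangle finite elements with the Kelvin-Voigt
#' constitutive law: total stress = elastic stress (modulus E, Poisson ratio
#' nu) plus viscous stress (the same operator with the dashpot viscosity eta0
#' substituted for E). Gravity acts as a volumetric load; the quasi-static
#' system K u + D du/dt = f is stepped with implicit backward Euler from
#' u(0) = 0. The bottom edge is fixed (or vertically supported), the lateral
#' edges carry symmetry conditions (zero normal displacement) and the top is
#' free.
#'
#' @param mesh A [mesh2d][build_unit_cell_mesh()].
#' @param gel [kelvin_voigt] material for elements labelled `gel`.
#' @param support [kelvin_voigt] material for elements labelled `support`;
#'   required iff the mesh contains support elements.
#' @param gravity Gravitational acceleration, m/s^2. Default 9.81.
#' @param t_end End of the transient window, s. Default 200.
#' @param dt Backward-Euler step, s. Default 0.5.
#' @param top_traction Optional uniform downward traction on the top edge, Pa.
#' @param bottom `"fixed"` (both displacement components zero) or `"roller"`
#'   (zero vertical displacement only).
#' @param sides `"roller"` (symmetry: zero horizontal displacement) or
#'   `"free"`.
#' @param keep_history Keep the full nodal displacement field at every step?
#'   (Otherwise only the final field is stored.)
#' @return An object of class `collapse_solution`: `time` (s), `point_a`
#'   (downward displacement magnitude of the monitored node at each time, m),
#'   `final_strain` (point-A displacement / structure height), `displacement`
#'   (final n x 2 nodal field, m) and, if requested, `history` (list of
#'   fields).
#' @export
solve_collapse <- function(mesh, gel, support = NULL, gravity = 9.81,
                           t_end = 200, dt = 0.5, top_traction = 0,
                           bottom = c("fixed", "roller"),
                           sides = c("roller", "free"),
                           keep_history = FALSE) {
  stopifnot(inherits(mesh, "mesh2d"), inherits(gel, "kelvin_voigt"),
            t_end > 0, dt > 0)
  bottom <- match.arg(bottom)
  sides <- match.arg(sides)
  has_support <- any(mesh$label == "support")
  if (has_support && is.null(support)) {
    stop("mesh contains support elements: a support material is required")
  }
  if (has_support) stopifnot(inherits(support, "kelvin_voigt"))
  if (any(triangle_areas(mesh) <= 0)) stop("mesh contains inverted elements")

  mats <- list(gel, if (has_support) support else gel)
  C_el <- lapply(mats, function(m) plane_strain_C(m$E, m$nu))
  C_vi <- lapply(mats, function(m) plane_strain_C(m$eta0, m$nu))
  K <- assemble_matrix(mesh, C_el)
  D <- assemble_matrix(mesh, C_vi)
  f <- assemble_load(mesh, vapply(mats, `[[`, numeric(1), "rho"),
                     gravity, top_traction)

  ndof <- 2L * nrow(mesh$nodes)
  fixed <- logical(ndof)
  fixed[2L * mesh$bottom] <- TRUE
  if (bottom == "fixed") fixed[2L * mesh$bottom - 1L] <- TRUE
  if (sides == "roller") {
    fixed[2L * mesh$left - 1L] <- TRUE
    fixed[2L * mesh$right - 1L] <- TRUE
  }
  free <- which(!fixed)
  if (length(free) == 0L) stop("all degrees of freedom are constrained")

  Kf <- K[free, free, drop = FALSE]
  Df <- D[free, free, drop = FALSE]
  ff <- f[free]
  Asys <- Matrix::forceSymmetric(Kf + Df / dt)
  ch <- tryCatch(Matrix::Cholesky(Asys, LDL = FALSE),
                 error = function(e) stop("singular system: insufficient constraints or degenerate mesh"))

  times <- seq(0, t_end, by = dt)
  if (abs(times[length(times)] - t_end) > 1e-9) times <- c(times, t_end)
  nstep <- length(times) - 1L
  u <- numeric(length(free))
  ua <- numeric(length(times))
  dof_a <- 2L * mesh$point_a
  idx_a <- match(dof_a, free)
  history <- if (keep_history) vector("list", length(times)) else NULL
  expand <- function(u) {
    full <- numeric(ndof)
    full[free] <- u
    matrix(full, ncol = 2L, byrow = TRUE)
  }
  if (keep_history) history[[1L]] <- expand(u)
  for (s in seq_len(nstep)) {
    h <- times[s + 1L] - times[s]
    if (abs(h - dt) > 1e-12) {
      Asys_s <- Matrix::forceSymmetric(Kf + Df / h)
      u <- as.numeric(Matrix::solve(Asys_s, ff + (Df %*% u) / h))
    } else {
      u <- as.numeric(Matrix::solve(ch, ff + (Df %*% u) / dt))
    }
    ua[s + 1L] <- if (is.na(idx_a)) 0 else abs(u[idx_a])
    if (keep_history) history[[s + 1L]] <- expand(u)
  }
  structure(list(time = times, point_a = ua,
                 final_strain = ua[length(ua)] / mesh$height,
                 displacement = expand(u), mesh = mesh,
                 history = history),
            class = "collapse_solution")
}

#' @export
print.collapse_solution <- function(x, ...) {
  cat(sprintf("Collapse solution: %d steps to t = %g s\n",
              length(x$time) - 1L, x$time[length(x$time)]))
  cat(sprintf("  point A displacement: %.4g mm (strain %.2f%% of height)\n",
              1e3 * x$point_a[length(x$point_a)], 100 * x$final_strain))
  if (x$final_strain > 0.2) {
    cat("  note: strain exceeds 20%; beyond small-strain linear validity\n")
  }
  invisible(x)
}

#' Closed-form Kelvin-Voigt creep strain
#'
#' Strain of a spring-dashpot Kelvin-Voigt solid under constant stress:
#' (stress / E) * (1 - exp(-E t / eta)). With eta = 0 the response is
#' instantaneous, stress / E.
#'
#' @param E Spring constant, Pa, > 0.
#' @param eta Dashpot viscosity, Pa.s, >= 0.
#' @param stress Applied constant stress, Pa.
#' @param t Time(s), s (vectorized).
#' @return Strain (dimensionless), same length as `t`.
#' @export
analytic_kv_creep <- function(E, eta, stress, t) {
  stopifnot(E > 0, eta >= 0)
  eq <- stress / E
  if (eta == 0) return(rep(eq, length(t)))
  eq * (1 - exp(-E * t / eta))
}

#' Equilibrium self-weight compression of a uniform column
#'
#' Top displacement of a column of height H compressing under its own weight
#' between rigid lateral guides (the plane-strain symmetry conditions of the
#' collapse model): rho g H^2 / (2 M) with the constrained modulus
#' M = E (1 - nu) / ((1 + nu)(1 - 2 nu)). At nu = 0 this reduces to
#' rho g H^2 / (2 E).
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio in \[0, 0.5).
#' @param rho Density, kg/m^3.
#' @param H Column height, m.
#' @param gravity m/s^2.
#' @return Downward top displacement, m.
#' @export
analytic_column_compression <- function(E, nu = 0, rho = 1000, H,
                                        gravity = 9.81) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, H > 0)
  M <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  rho * gravity * H^2 / (2 * M)
}

#' Compare printing strategies: free-standing vs embedded (bioplotting)
#'
#' Runs the collapse model twice on matched gel geometry — once with empty
#' pores (printing directly on the plate) and once with the pores filled by a
#' sacrificial support bath — and summarizes the final point-A strains.
#'
#' @param cell A [scaffold_cell].
#' @param gel [kelvin_voigt] gel material.
#' @param support [kelvin_voigt] support-bath material.
#' @param gravity m/s^2.
#' @param t_end Transient window, s.
#' @param dt Time step, s.
#' @param target_element_size Mesh size, m.
#' @return List with `no_support` and `with_support` ([solve_collapse()]
#'   solutions) and `summary` (data frame: strategy, final displacement,
#'   final strain, plus the without/with strain ratio as attribute `ratio`).
#' @export
compare_strategies <- function(cell, gel, support, gravity = 9.81,
                               t_end = 200, dt = 0.5,
                               target_element_size = 1.4e-4) {
  mesh_free <- build_unit_cell_mesh(cell, with_support = FALSE,
                                    target_element_size = target_element_size)
  mesh_bath <- build_unit_cell_mesh(cell, with_support = TRUE,
                                    target_element_size = target_element_size)
  sol_free <- solve_collapse(mesh_free, gel, gravity = gravity,
                             t_end = t_end, dt = dt)
  sol_bath <- solve_collapse(mesh_bath, gel, support = support,
                             gravity = gravity, t_end = t_end, dt = dt)
  summ <- data.frame(
    strategy = c("no_support", "with_support"),
    final_displacement = c(sol_free$point_a[length(sol_free$point_a)],
                           sol_bath$point_a[length(sol_bath$point_a)]),
    final_strain = c(sol_free$final_strain, sol_bath$final_strain))
  attr(summ, "ratio") <- summ$final_strain[1] / summ$final_strain[2]
  list(no_support = sol_free, with_support = sol_bath, summary = summ)
}

#' Write a point-A displacement time series to CSV
#'
#' @param solution A [solve_collapse()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_collapse_csv <- function(solution, path) {
  stopifnot(inherits(solution, "collapse_solution"))
  utils::write.csv(data.frame(time = solution$time,
                              point_a_displacement = solution$point_a),
                   path, row.names = FALSE)
  invisible(path)
}
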