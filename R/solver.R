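#' Define a Pennes bioheat problem
#'
#' Bundles a domain with tissue properties and boundary conditions. The
#' steady-state Pennes balance solved is
#' `0 = div(k grad T) + w_b rho_b c_b (T_b - T) + Q_met + Q_e`,
#' with a fixed core temperature on the flat chord (Dirichlet), convective
#' exchange with ambient air on the skin arc (Robin) and an insulated
#' trachea boundary. The external source `Q_e` is zero in this work.
#'
#' @param geometry a [build_neck_section()] half-disc or a [slab_layers()]
#'   one-dimensional stack.
#' @param properties per-tissue table from [tissue_properties()].
#' @param h_conv skin convection coefficient, W/(m^2 degC); default 3.6.
#' @param T_air ambient air temperature, degC; default 20.
#' @param T_core Dirichlet temperature on the flat chord (deep-body side),
#'   degC; default 37.
#' @param Q_e external volumetric heat source, W/m^3; fixed 0 unless
#'   explicitly overridden.
#' @return object of class `pennes_problem`.
#' @export
pennes_problem <- function(geometry, properties = tissue_properties(),
                           h_conv = 3.6, T_air = 20, T_core = 37, Q_e = 0) {
  stopifnot(h_conv > 0)
  needed <- if (inherits(geometry, "slab_geometry")) unique(geometry$tissue)
            else c("skin", "fat", "muscle", "thyroid",
                   if (!is.null(geometry$nodule)) "nodule")
  missing <- setdiff(needed, properties$name)
  if (length(missing))
    stop("properties table lacks tissues: ", paste(missing, collapse = ", "))
  structure(list(geometry = geometry, properties = properties,
                 h_conv = h_conv, T_air = T_air, T_core = T_core, Q_e = Q_e),
            class = "pennes_problem")
}

#' One-dimensional layered-slab domain
#'
#' A stack of tissue layers from the core side (held at `T_core`) to the
#' surface (convective exchange). Used for verifying the finite-volume scheme
#' against the closed-form multilayer solution ([analytic_slab()]).
#'
#' @param tissues character vector of tissue names (inner to outer).
#' @param thicknesses layer thicknesses, cm.
#' @return object of class `slab_geometry` (a data frame).
#' @export
slab_layers <- function(tissues, thicknesses) {
  stopifnot(length(tissues) == length(thicknesses), all(thicknesses > 0))
  structure(data.frame(tissue = tissues, thickness = thicknesses,
                       stringsAsFactors = FALSE),
            class = c("slab_geometry", "data.frame"))
}

# --- shared finite-volume assembly -----------------------------------------
# faces: data frame (a, b, G) between unknowns  [W/K per unit depth]
# fixed: (a, G, Tval) conductance to a fixed temperature (Dirichlet or Robin)
# sink:  per-cell w_b rho_b c_b * V                 [W/K]
# src:   per-cell (Q_met + Q_e + w rho c T_b) * V   [W]
.fv_solve <- function(n, faces, fixed, sink, src) {
  ii <- c(faces$a, faces$b, faces$a, faces$b, fixed$a, seq_len(n))
  jj <- c(faces$b, faces$a, faces$a, faces$b, fixed$a, seq_len(n))
  xx <- c(-faces$G, -faces$G, faces$G, faces$G, fixed$G, sink)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # sparseMatrix() accumulates duplicate (a, a) Dirichlet/Robin entries
  b <- as.numeric(Matrix::sparseMatrix(i = fixed$a, j = rep(1, nrow(fixed)),
                                       x = fixed$G * fixed$Tval,
                                       dims = c(n, 1))) + src
  Ts <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                           super = TRUE)
    as.numeric(Matrix::solve(ch, b, system = "A"))
  }, error = function(e) as.numeric(Matrix::solve(A, b)))
  res <- sqrt(sum((as.numeric(A %*% Ts) - b)^2)) / sqrt(sum(b^2))
  if (!is.finite(res) || res > 1e-8)
    stop("linear solve failed: relative residual ", signif(res, 3))
  list(T = Ts, residual = res, A = A, b = b)
}

# half-cell series conductance across a face of area A (SI units)
.face_G <- function(A, d_a, k_a, d_b, k_b) A / (d_a / k_a + d_b / k_b)

# --- polar half-disc discretisation ----------------------------------------
.polar_domain <- function(geometry, resolution) {
  g <- geometry
  if (resolution > g$skin_thickness / 4 + 1e-12)
    stop("resolution too coarse: at least 4 cells must span the skin layer")
  R <- g$outer_radius
  nr <- max(8L, as.integer(round(R / resolution)))
  dr <- R / nr
  nt <- as.integer(round(pi * R / resolution))
  if (nt %% 2L == 1L) nt <- nt + 1L  # even count => exactly mirrored cells
  dth <- pi / nt
  r <- (seq_len(nr) - 0.5) * dr
  u <- (seq_len(nt) - 0.5) / nt             # theta / pi
  cth <- cospi(u); sth <- sinpi(u)
  half <- seq_len(nt %/% 2L)
  cth[nt + 1L - half] <- -cth[half]         # enforce exact mirror symmetry
  sth[nt + 1L - half] <- sth[half]
  X <- outer(r, cth); Y <- outer(r, sth)
  dtr2 <- (X - g$trachea_center[1])^2 + (Y - g$trachea_center[2])^2
  active <- dtr2 >= g$trachea_radius^2
  tis <- matrix(NA_character_, nr, nt)
  tis[active] <- tissue_at(g, X[active], Y[active], on_outside = "na")
  list(type = "polar", nr = nr, nt = nt, dr = dr, dth = dth, r = r, u = u,
       cth = cth, sth = sth, X = X, Y = Y, active = active, tissue = tis,
       outer_radius = R)
}

#' Solve the steady-state bioheat problem
#'
#' Finite-volume discretisation with conductivity harmonically averaged
#' across material interfaces and a direct sparse factorisation of the
#' (symmetric positive definite) system. For the neck half-disc the grid is
#' polar, so the skin arc, the flat chord and the concentric layer interfaces
#' are grid-aligned and a nodule-free problem is mirror-symmetric to solver
#' precision. For a [slab_layers()] domain the same assembly runs on a
#' one-dimensional stack.
#'
#' @param problem a [pennes_problem()].
#' @param resolution target grid spacing, cm; default 0.025. Must place at
#'   least 4 cells across the thinnest layer (skin, 0.2 cm).
#' @return object of class `temperature_field`: cell temperatures (`T`,
#'   degC, radial x angular, `NA` in the trachea hole), grid descriptors,
#'   skin-surface temperatures per angular cell (`T_surface`), tissue label
#'   map, solve metadata (`residual`), and the generating problem.
#' @examples
#' \donttest{
#' g <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
#' pr <- pennes_problem(g, tissue_properties("calibrated"))
#' fld <- solve_steady(pr, resolution = 0.05)
#' sample_field(fld, g$nodule$center[1], g$nodule$center[2])
#' }
#' @export
solve_steady <- function(problem, resolution = 0.025) {
  stopifnot(inherits(problem, "pennes_problem"))
  if (inherits(problem$geometry, "slab_geometry"))
    return(.solve_steady_slab(problem, resolution))
  dom <- .polar_domain(problem$geometry, resolution)
  co <- .cell_coefficients(dom$tissue, problem)
  asm <- .assemble_polar(dom, co, problem)
  sol <- .fv_solve(asm$n, asm$faces, asm$fixed, asm$sink, asm$src)
  Tm <- matrix(NA_real_, dom$nr, dom$nt)
  Tm[dom$active] <- sol$T
  # skin surface temperature from the Robin half-cell balance
  kc <- co$k[dom$nr, ] / (dom$dr / 2 * 0.01)
  T_surface <- (kc * Tm[dom$nr, ] + problem$h_conv * problem$T_air) /
    (kc + problem$h_conv)
  structure(list(T = Tm, T_surface = T_surface, domain = dom,
                 tissue = dom$tissue, problem = problem,
                 resolution = resolution, residual = sol$residual,
                 n_unknowns = asm$n),
            class = "temperature_field")
}

.cell_coefficients <- function(tissue, problem) {
  p <- problem$properties
  idx <- match(tissue, p$name)
  k <- matrix(p$k[idx], nrow(tissue), ncol(tissue))
  s <- matrix((p$w_b * p$rho_b * p$c_b)[idx], nrow(tissue), ncol(tissue))
  q <- matrix((p$Q_met + p$w_b * p$rho_b * p$c_b * p$T_b)[idx],
              nrow(tissue), ncol(tissue)) + problem$Q_e
  rc <- matrix((p$rho * p$c)[idx], nrow(tissue), ncol(tissue))
  list(k = k, s = s, q = q, rho_c = rc)
}

.assemble_polar <- function(dom, co, problem) {
  cm <- 0.01
  act <- dom$active
  id <- matrix(0L, dom$nr, dom$nt)
  id[act] <- seq_len(sum(act))
  n <- sum(act)
  dr_m <- dom$dr * cm

  # radial faces between (i, j) and (i+1, j)
  i1 <- which(act[-dom$nr, , drop = FALSE] & act[-1, , drop = FALSE],
              arr.ind = TRUE)
  rf <- dom$r[i1[, 1]] + dom$dr / 2           # face radius, cm
  ka <- co$k[cbind(i1[, 1], i1[, 2])]
  kb <- co$k[cbind(i1[, 1] + 1L, i1[, 2])]
  G_rad <- .face_G(rf * cm * dom$dth, dr_m / 2, ka, dr_m / 2, kb)
  faces <- data.frame(a = id[cbind(i1[, 1], i1[, 2])],
                      b = id[cbind(i1[, 1] + 1L, i1[, 2])], G = G_rad)

  # angular faces between (i, j) and (i, j+1)
  i2 <- which(act[, -dom$nt, drop = FALSE] & act[, -1, drop = FALSE],
              arr.ind = TRUE)
  ka <- co$k[cbind(i2[, 1], i2[, 2])]
  kb <- co$k[cbind(i2[, 1], i2[, 2] + 1L)]
  arc_half <- dom$r[i2[, 1]] * dom$dth / 2 * cm
  G_ang <- .face_G(dom$dr * cm, arc_half, ka, arc_half, kb)
  faces <- rbind(faces, data.frame(a = id[cbind(i2[, 1], i2[, 2])],
                                   b = id[cbind(i2[, 1], i2[, 2] + 1L)],
                                   G = G_ang))

  # Dirichlet chord at theta = 0 and theta = pi
  ic <- which(act[, 1]); G1 <- co$k[ic, 1] * dom$dr / (dom$r[ic] * dom$dth / 2)
  ic2 <- which(act[, dom$nt])
  G2 <- co$k[ic2, dom$nt] * dom$dr / (dom$r[ic2] * dom$dth / 2)
  fixed <- data.frame(a = c(id[ic, 1], id[ic2, dom$nt]), G = c(G1, G2),
                      Tval = problem$T_core)

  # Robin on the outer arc
  io <- which(act[dom$nr, ])
  A_arc <- dom$outer_radius * cm * dom$dth
  G_rob <- A_arc / (1 / problem$h_conv +
                      (dom$dr / 2 * cm) / co$k[dom$nr, io])
  fixed <- rbind(fixed, data.frame(a = id[dom$nr, io], G = G_rob,
                                   Tval = problem$T_air))

  V <- outer(dom$r, rep(1, dom$nt)) * dom$dr * dom$dth * cm^2  # m^2 per depth
  list(n = n, faces = faces, fixed = fixed,
       sink = (co$s * V)[act], src = (co$q * V)[act],
       cap = (co$rho_c * V)[act], id = id, V = V)
}

.solve_steady_slab <- function(problem, resolution) {
  g <- problem$geometry
  thin <- min(g$thickness)
  if (resolution > thin / 4 + 1e-12)
    stop("resolution too coarse: at least 4 cells must span the thinnest layer")
  nl <- pmax(4L, as.integer(round(g$thickness / resolution)))
  dx <- rep(g$thickness / nl, nl) * 0.01       # m
  tis <- rep(g$tissue, nl)
  n <- length(dx)
  x_face <- c(0, cumsum(dx))
  x_mid <- (x_face[-1] + x_face[-(n + 1)]) / 2
  p <- problem$properties
  idx <- match(tis, p$name)
  k <- p$k[idx]; s <- (p$w_b * p$rho_b * p$c_b)[idx]
  q <- (p$Q_met + p$w_b * p$rho_b * p$c_b * p$T_b)[idx] + problem$Q_e
  faces <- data.frame(a = seq_len(n - 1), b = seq_len(n - 1) + 1L,
                      G = .face_G(1, dx[-n] / 2, k[-n], dx[-1] / 2, k[-1]))
  fixed <- data.frame(
    a = c(1L, n),
    G = c(k[1] / (dx[1] / 2),
          1 / (1 / problem$h_conv + (dx[n] / 2) / k[n])),
    Tval = c(problem$T_core, problem$T_air))
  sol <- .fv_solve(n, faces, fixed, s * dx, q * dx)
  structure(list(x = x_mid / 0.01, T = sol$T, tissue = tis,
                 problem = problem, resolution = resolution,
                 residual = sol$residual, n_unknowns = n),
            class = c("slab_field", "temperature_field"))
}

#' Sample a solved temperature field at arbitrary points
#'
#' Bilinear interpolation on the solver grid (in polar coordinates for the
#' half-disc). Weights of missing neighbours (trachea hole) are renormalised;
#' radial positions beyond the outermost cell centre are clamped to it.
#'
#' @param field a [solve_steady()] result.
#' @param x,y point coordinates, cm.
#' @return temperatures, degC.
#' @export
sample_field <- function(field, x, y) {
  stopifnot(inherits(field, "temperature_field"),
            !inherits(field, "slab_field"), length(x) == length(y))
  dom <- field$domain
  r <- sqrt(x^2 + y^2)
  if (any(y < -1e-9 | r > dom$outer_radius + 1e-9))
    stop("sample point outside the half-disc domain")
  th <- atan2(pmax(y, 0), x)
  fi <- pmin(pmax(r / dom$dr + 0.5, 1), dom$nr)
  fj <- pmin(pmax(th / dom$dth + 0.5, 1), dom$nt)
  i0 <- pmin(floor(fi), dom$nr - 1L); j0 <- pmin(floor(fj), dom$nt - 1L)
  wi <- fi - i0; wj <- fj - j0
  Tm <- field$T
  g <- function(ii, jj) Tm[cbind(ii, jj)]
  v <- cbind(g(i0, j0), g(i0 + 1, j0), g(i0, j0 + 1), g(i0 + 1, j0 + 1))
  w <- cbind((1 - wi) * (1 - wj), wi * (1 - wj), (1 - wi) * wj, wi * wj)
  w[is.na(v)] <- 0
  v[is.na(v)] <- 0
  tot <- rowSums(w)
  if (any(tot <= 0)) stop("sample point has no solved neighbours (trachea?)")
  rowSums(v * w) / tot
}

#' Solve the transient bioheat problem
#'
#' Backward-Euler time stepping (unconditionally stable) with the steady
#' operator factorised once. The cold-start default initialises the whole
#' section at ambient air temperature; as `t_end` grows the field converges
#' to the [solve_steady()] solution.
#'
#' @param problem a [pennes_problem()] on a neck geometry.
#' @param resolution grid spacing, cm.
#' @param t_end final time, s.
#' @param dt time step, s (> 0).
#' @param init initial condition: `"ambient"` (T_air everywhere), a single
#'   number, or a `temperature_field` on the same grid.
#' @param snapshots number of intermediate fields to keep (final always kept).
#' @return list with `times` and `fields` (list of `temperature_field`s).
#' @export
solve_transient <- function(problem, resolution = 0.05, t_end, dt,
                            init = "ambient", snapshots = 5) {
  stopifnot(inherits(problem, "pennes_problem"))
  if (dt <= 0) stop("dt must be positive")
  if (t_end < 0) stop("t_end must be non-negative")
  dom <- .polar_domain(problem$geometry, resolution)
  co <- .cell_coefficients(dom$tissue, problem)
  asm <- .assemble_polar(dom, co, problem)

  T0 <- if (inherits(init, "temperature_field")) {
    stopifnot(identical(dim(init$T), c(dom$nr, dom$nt)))
    init$T[dom$active]
  } else if (identical(init, "ambient")) {
    rep(problem$T_air, asm$n)
  } else rep(as.numeric(init), length.out = asm$n)

  wrap <- function(vec) {
    Tm <- matrix(NA_real_, dom$nr, dom$nt); Tm[dom$active] <- vec
    kc <- co$k[dom$nr, ] / (dom$dr / 2 * 0.01)
    structure(list(T = Tm,
                   T_surface = (kc * Tm[dom$nr, ] +
                                  problem$h_conv * problem$T_air) /
                     (kc + problem$h_conv),
                   domain = dom, tissue = dom$tissue, problem = problem,
                   resolution = resolution, residual = NA_real_,
                   n_unknowns = asm$n),
              class = "temperature_field")
  }
  if (t_end == 0)
    return(list(times = 0, fields = list(wrap(T0))))

  nstep <- as.integer(ceiling(t_end / dt - 1e-9))
  sol0 <- .fv_solve(asm$n, asm$faces, asm$fixed, asm$sink, asm$src)
  A <- sol0$A; b <- sol0$b
  Mdt <- asm$cap / dt
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(
    A + Matrix::Diagonal(asm$n, Mdt)), LDL = FALSE, super = TRUE)
  keep <- unique(pmax(1L, round(seq_len(snapshots) / snapshots * nstep)))
  Tn <- T0; out <- list(); times <- numeric()
  for (s in seq_len(nstep)) {
    Tn <- as.numeric(Matrix::solve(ch, b + Mdt * Tn, system = "A"))
    if (s %in% keep) {
      out[[length(out) + 1L]] <- wrap(Tn)
      times <- c(times, s * dt)
    }
  }
  list(times = times, fields = out)
}

#' Export a solved field as CSV plus JSON metadata
#'
#' Writes `(x, y, T)` rows for every solved cell and a sidecar
#' `<path>.meta.json` with the geometry, resolution and residual.
#'
#' @param field a [solve_steady()] result on a neck geometry.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"),
            !inherits(field, "slab_field"))
  dom <- field$domain
  dt <- data.table::data.table(x = dom$X[dom$active], y = dom$Y[dom$active],
                               T = field$T[dom$active])
  data.table::fwrite(dt, path)
  g <- field$problem$geometry
  meta <- list(resolution = field$resolution, residual = field$residual,
               n_unknowns = field$n_unknowns,
               units = list(x = "cm", y = "cm", T = "degC"),
               geometry = unclass(g),
               perfusion_units =
                 as.list(attr(field$problem$properties, "perfusion_units")))
  if (!is.null(meta$geometry$nodule))
    meta$geometry$nodule <- unclass(meta$geometry$nodule)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
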