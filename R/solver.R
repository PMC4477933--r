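#' @useDynLib mvrepair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# per-element total-Lagrangian precomputation: reference edge matrix in
# the fiber frame, inverted; reference areas; material ids
fe_precompute <- function(mesh, materials) {
  tr <- mesh$triangles
  m <- nrow(tr)
  P <- mesh$nodes
  invR <- matrix(0, m, 4)
  areas <- triangle_areas(P, tr)
  if (any(areas <= 1e-12))
    stop("fe_precompute: zero-area element", call. = FALSE)
  for (e in seq_len(m)) {
    X0 <- P[tr[e, 1], ]; X1 <- P[tr[e, 2], ]; X2 <- P[tr[e, 3], ]
    e1 <- mesh$fiber_e1[e, ]; e2 <- mesh$fiber_e2[e, ]
    R <- matrix(c(sum((X1 - X0) * e1), sum((X2 - X0) * e1),
                  sum((X1 - X0) * e2), sum((X2 - X0) * e2)),
                2, 2, byrow = TRUE)
    detR <- R[1, 1] * R[2, 2] - R[1, 2] * R[2, 1]
    if (abs(detR) < 1e-12)
      stop("fe_precompute: degenerate reference element ", e, call. = FALSE)
    Ri <- solve(R)
    invR[e, ] <- c(Ri[1, 1], Ri[1, 2], Ri[2, 1], Ri[2, 2])
  }
  matid <- ifelse(mesh$leaflet == "anterior", 0L, 1L)
  fp <- materials$fung
  matpar <- rbind(
    c(fp$anterior$c, fp$anterior$a_cc, fp$anterior$a_rr, fp$anterior$a_cr,
      fp$anterior$a_ss),
    c(fp$posterior$c, fp$posterior$a_cc, fp$posterior$a_rr,
      fp$posterior$a_cr, fp$posterior$a_ss))
  list(invR = invR, areas = areas, matid = matid, matpar = matpar)
}

chordae_arrays <- function(chordae, materials) {
  d <- chordae$chordae
  if (nrow(d) == 0L)
    return(list(origin = integer(0), insertion = integer(0),
                area = numeric(0), rest = numeric(0), ogid = integer(0),
                ogpars = list(list(mu = 1, alpha = 1))))
  list(origin = ifelse(d$origin == "al", 0L, 1L),
       insertion = as.integer(d$insertion),
       area = d$area, rest = d$rest_length,
       ogid = ifelse(d$type == "marginal", 0L, 1L),
       ogpars = list(
         list(mu = materials$ogden$marginal$mu,
              alpha = materials$ogden$marginal$alpha),
         list(mu = materials$ogden$strut$mu,
              alpha = materials$ogden$strut$alpha)))
}

# contact exclusions: per node, the sorted 0-based triangle ids never
# tested against it -- the triangles incident to the node or its ring-1
# neighbors, plus every (node, triangle) pair already inside the
# detection shell in the REFERENCE configuration (initial overclosures,
# e.g. the coincident commissural columns of the two leaflets, are never
# treated as contact -- the standard general-contact convention)
contact_exclusions <- function(mesh, detection_thickness = 0) {
  n <- nrow(mesh$nodes)
  tr <- mesh$triangles
  e <- unique(mesh_edges(mesh))
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  tri_of <- vector("list", n)
  for (k in 1:3) for (i in seq_len(nrow(tr))) {
    v <- tr[i, k]
    tri_of[[v]] <- c(tri_of[[v]], i)
  }
  excl <- lapply(seq_len(n), function(i)
    unique(unlist(tri_of[c(i, adj[[i]])], use.names = FALSE)))
  if (detection_thickness > 0) {
    base <- list(ptr = c(0L, cumsum(vapply(excl, length, integer(1)))),
                 idx = unlist(lapply(excl, function(v) sort(v - 1L))))
    pairs <- cpp_contact_forces(mesh$nodes, matrix(0, n, 3), tr,
                                base$ptr, base$idx, 1.0, 0,
                                1.05 * detection_thickness, 0)$pairs
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs)))
        excl[[pairs$node[r]]] <- c(excl[[pairs$node[r]]], pairs$tri[r])
    }
  }
  excl <- lapply(excl, function(v) sort(unique(v)) - 1L)
  lens <- vapply(excl, length, integer(1))
  list(ptr = c(0L, cumsum(lens)), idx = unlist(excl))
}

lumped_masses <- function(mesh, tissue, mass_scaling = 1) {
  rho <- density_internal(tissue) * mass_scaling
  areas <- triangle_areas(mesh$nodes, mesh$triangles)
  m <- numeric(nrow(mesh$nodes))
  contrib <- rho * areas * mesh$thickness / 3
  for (k in 1:3) {
    tab <- tapply(contrib, mesh$triangles[, k], sum)
    idx <- as.integer(names(tab))
    m[idx] <- m[idx] + as.numeric(tab)
  }
  m[m <= 0] <- min(m[m > 0])  # isolated nodes keep a token mass
  m
}

#' Contact parameters
#'
#' @param penalty_stiffness normal penalty stiffness (mN/mm of
#'   penetration); `NULL` selects a mass- and timestep-scaled value at
#'   simulation time (stable by construction).
#' @param friction_mu Coulomb friction coefficient, default 0.05.
#' @param detection_thickness contact shell half-thickness (mm).
#' @param tangential_stiffness viscous regularization of the stick state
#'   (mN per mm/ms of slip); the tangential force is capped at
#'   `friction_mu * normal_force`.
#' @return object of class `contact_params`.
#' @export
contact_params <- function(penalty_stiffness = NULL, friction_mu = 0.05,
                           detection_thickness = 0.8,
                           tangential_stiffness = 50) {
  if (!is.null(penalty_stiffness) && penalty_stiffness <= 0)
    stop("contact_params: stiffness must be > 0", call. = FALSE)
  if (friction_mu < 0) stop("contact_params: mu must be >= 0", call. = FALSE)
  if (detection_thickness <= 0)
    stop("contact_params: detection thickness must be > 0", call. = FALSE)
  structure(list(penalty_stiffness = penalty_stiffness,
                 friction_mu = friction_mu,
                 detection_thickness = detection_thickness,
                 tangential_stiffness = tangential_stiffness),
            class = "contact_params")
}

#' Solver configuration
#'
#' @param dt timestep (ms) or `NULL` for `cfl_safety *`
#'   [stable_timestep()].
#' @param duration total simulated time (ms).
#' @param damping mass-proportional damping coefficient (1/ms).
#' @param mass_scaling density multiplier (explicit-dynamics mass
#'   scaling); results are flagged when the kinetic/strain energy ratio
#'   exceeds 5% at peak load.
#' @param output_stride store every k-th step.
#' @param cfl_safety safety factor on the zero-strain stable timestep;
#'   the small default leaves headroom for the exponential stiffening of
#'   the Fung law at working strains.
#' @param contact_every evaluate contact every k steps (1 = always).
#' @param seed recorded for provenance (the integrator itself is
#'   deterministic).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = NULL, duration = 250, damping = 0.25,
                          mass_scaling = 100, output_stride = 100,
                          cfl_safety = 0.12, contact_every = 1, seed = 1L) {
  stopifnot(duration > 0, damping >= 0, mass_scaling >= 1,
            output_stride >= 1)
  structure(list(dt = dt, duration = duration, damping = damping,
                 mass_scaling = mass_scaling,
                 output_stride = as.integer(output_stride),
                 cfl_safety = cfl_safety,
                 contact_every = as.integer(contact_every),
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Stable explicit timestep estimate
#'
#' CFL bound: `safety * min_e(L_e / c_e)` over membrane elements (and
#' chordae), with the dilatational wave speed from the zero-strain
#' tangent stiffness `c * max-eigenvalue([a_cc, a_cr; a_cr, a_rr])` and
#' the tissue density; element characteristic length = 2 area / longest
#' edge.
#'
#' @param mesh a [valve_mesh()].
#' @param materials an `mv_materials` list.
#' @param chordae optional [chordae_set()] included in the bound.
#' @param safety multiplier, default 0.8.
#' @param mass_scaling density multiplier (raises the bound by its
#'   square root).
#' @return timestep (ms).
#' @export
stable_timestep <- function(mesh, materials, chordae = NULL, safety = 0.8,
                            mass_scaling = 1) {
  rho <- density_internal(materials$tissue) * mass_scaling
  tr <- mesh$triangles
  P <- mesh$nodes
  areas <- triangle_areas(P, tr)
  if (any(areas <= 1e-12))
    stop("stable_timestep: zero-area element", call. = FALSE)
  el <- function(i, j) sqrt(rowSums((P[tr[, i], , drop = FALSE] -
                                       P[tr[, j], , drop = FALSE])^2))
  lmax <- pmax(el(1, 2), el(2, 3), el(3, 1))
  lchar <- 2 * areas / lmax
  kmax <- vapply(materials$fung, function(p) {
    p$c * max(eigen(matrix(c(p$a_cc, p$a_cr, p$a_cr, p$a_rr), 2, 2),
                    symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  kel <- ifelse(mesh$leaflet == "anterior", kmax[["anterior"]],
                kmax[["posterior"]])
  dt_mem <- min(lchar / sqrt(kel / rho))
  dt <- dt_mem
  if (!is.null(chordae) && nrow(chordae$chordae) > 0) {
    d <- chordae$chordae
    Emod <- vapply(d$type, function(ty) {
      p <- materials$ogden[[ty]]
      1.5 * sum(p$mu * p$alpha)
    }, numeric(1))
    dt <- min(dt, min(d$rest_length / sqrt(Emod / rho)))
  }
  safety * dt
}

#' One central-difference step
#'
#' Explicit update with mass-proportional damping:
#' `v_{n+1/2} = v_{n-1/2} + dt (f/m - damping v_{n-1/2})`,
#' `x_{n+1} = x_n + dt v_{n+1/2}`. Prescribed nodes follow their target
#' positions exactly, overriding the dynamics.
#'
#' @param positions,velocities `n x 3` matrices (mm, mm/ms).
#' @param forces `n x 3` assembled nodal forces (mN).
#' @param masses length-n nodal masses (mg).
#' @param dt timestep (ms).
#' @param damping mass-proportional damping (1/ms).
#' @param prescribed_ids optional node ids following `prescribed_targets`
#'   (matching rows, positions at `t + dt`).
#' @param prescribed_targets matrix of target positions.
#' @return list `positions`, `velocities`.
#' @export
solver_step <- function(positions, velocities, forces, masses, dt,
                        damping = 0, prescribed_ids = integer(0),
                        prescribed_targets = NULL) {
  a <- forces / masses - damping * velocities
  vnew <- velocities + dt * a
  xnew <- positions + dt * vnew
  if (length(prescribed_ids)) {
    vnew[prescribed_ids, ] <- (prescribed_targets -
                                 positions[prescribed_ids, , drop = FALSE]) / dt
    xnew[prescribed_ids, ] <- prescribed_targets
  }
  if (any(!is.finite(xnew)))
    stop("solver_step: non-finite coordinates (node ",
         which(!is.finite(rowSums(xnew)))[1], ")", call. = FALSE)
  list(positions = xnew, velocities = vnew)
}

#' Membrane internal forces
#'
#' Nodal forces `-d(total membrane energy)/d(positions)` of the Fung
#' membrane elements at the given configuration (total-Lagrangian,
#' constant-strain triangles evaluated in the per-element fiber frame).
#'
#' @param mesh reference [valve_mesh()].
#' @param positions current `n x 3` nodal coordinates; defaults to the
#'   reference (zero force).
#' @param materials `mv_materials`.
#' @return `n x 3` force matrix (mN) with attributes `energy` (kPa mm^3 =
#'   micro-J) and `strain` (per-element `E_cc, E_rr, E_cr`); inverted
#'   elements raise an error naming the element.
#' @export
internal_forces_membrane <- function(mesh, positions = mesh$nodes,
                                     materials = default_materials()) {
  pre <- fe_precompute(mesh, materials)
  out <- cpp_membrane_forces(positions, mesh$triangles, pre$invR,
                             pre$areas, mesh$thickness, pre$matid,
                             pre$matpar)
  if (out$inverted > 0)
    stop("internal_forces_membrane: collapsed/inverted element ",
         out$inverted, call. = FALSE)
  f <- out$force
  attr(f, "energy") <- out$energy
  attr(f, "strain") <- out$strain
  f
}

#' Chordal internal forces
#'
#' Tension-only Ogden cable forces along each chorda's current axis;
#' equal and opposite reactions are reported for the papillary tips.
#'
#' @inheritParams internal_forces_membrane
#' @param chordae a [chordae_set()].
#' @return `n x 3` nodal force matrix with attributes `tip_force`
#'   (2 x 3), `lambda`, `tension` (mN) and `energy`.
#' @export
internal_forces_chordae <- function(mesh, chordae, positions = mesh$nodes,
                                    materials = default_materials()) {
  ca <- chordae_arrays(chordae, materials)
  out <- cpp_chordae_forces(positions, mesh$papillary_tips, ca$origin,
                            ca$insertion, ca$area, ca$rest, ca$ogid,
                            ca$ogpars)
  f <- out$force
  attr(f, "tip_force") <- out$tip_force
  attr(f, "lambda") <- out$lambda
  attr(f, "tension") <- out$tension
  attr(f, "energy") <- out$energy
  f
}

#' Contact forces
#'
#' Node-to-triangle penalty contact over a two-sided detection shell with
#' Coulomb-capped tangential friction, plus node-to-chorda-segment
#' penalties (normal only). The reaction on each triangle is distributed
#' to its nodes by barycentric weights.
#'
#' @inheritParams internal_forces_chordae
#' @param velocities `n x 3` nodal velocities (for the slip direction).
#' @param params a [contact_params()] with explicit `penalty_stiffness`.
#' @return list `force` (n x 3), `pairs` (tibble: node, tri, depth,
#'   normal_force), `energy`.
#' @export
contact_forces <- function(mesh, chordae = NULL, positions = mesh$nodes,
                           velocities = NULL, params = contact_params(
                             penalty_stiffness = 10)) {
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  ex <- contact_exclusions(mesh, params$detection_thickness)
  out <- cpp_contact_forces(positions, velocities, mesh$triangles,
                            ex$ptr, ex$idx, params$penalty_stiffness,
                            params$friction_mu,
                            params$detection_thickness,
                            params$tangential_stiffness)
  list(force = out$force, pairs = tibble::as_tibble(out$pairs),
       energy = out$energy)
}

#' Dynamic closure simulation
#'
#' Explicit central-difference simulation of valve dynamics under the
#' transvalvular pressure program, with the annulus either following an
#' [annular_motion()] program or held at its current (mesh)
#' configuration, papillary tips fixed, leaflet-leaflet and
#' leaflet-chordae contact, and mass-proportional damping.
#'
#' @param mesh a [valve_mesh()] in its reference (t = 0) configuration.
#' @param chordae a [chordae_set()] (may be empty).
#' @param materials `mv_materials`, see [default_materials()].
#' @param pressure a [pressure_waveform()]; `NULL` means zero pressure.
#' @param motion an [annular_motion()] for the annulus nodes, or `NULL`
#'   to hold the annulus fixed.
#' @param contact a [contact_params()].
#' @param config a [solver_config()].
#' @return object of class `mv_sim`: `times` (ms), `positions`
#'   (n x 3 x frames array), `lambda` (frames x chordae stretch),
#'   `pairs` (list of per-frame contact tibbles), `energy` (tibble),
#'   `mesh`, `chordae`, plus solver metadata. Errors during time
#'   stepping abort with the last valid state attached.
#' @export
simulate_closure <- function(mesh, chordae, materials = default_materials(),
                             pressure = pressure_waveform(),
                             motion = NULL,
                             contact = contact_params(),
                             config = solver_config()) {
  stopifnot(inherits(mesh, "valve_mesh"), inherits(config, "solver_config"))
  pre <- fe_precompute(mesh, materials)
  ca <- chordae_arrays(chordae, materials)
  masses <- lumped_masses(mesh, materials$tissue, config$mass_scaling)
  dt <- config$dt
  if (is.null(dt))
    dt <- config$cfl_safety * stable_timestep(mesh, materials, chordae,
                                              safety = 1,
                                              mass_scaling =
                                                config$mass_scaling)
  kn <- contact$penalty_stiffness
  # soft penalty sized to the quasi-static contact force scale while
  # keeping the penalty oscillator far below the integration limit
  if (is.null(kn)) kn <- 0.0012 * min(masses) / dt^2

  if (is.null(pressure))
    press <- cbind(c(0, config$duration), c(0, 0))
  else press <- as.matrix(pressure$samples[, c("t", "dP")])

  ann <- mesh$annulus_ids
  if (is.null(motion)) {
    presc_base <- mesh$nodes[ann, , drop = FALSE]
    presc_dir <- matrix(0, length(ann), 3)
    gat <- cbind(c(0, config$duration), c(0, 0))
  } else {
    if (nrow(motion$config_systole) != length(ann))
      stop("simulate_closure: annular motion node count != annulus nodes",
           call. = FALSE)
    presc_base <- motion$config_systole
    presc_dir <- motion$direction
    gat <- as.matrix(motion$gating[, c("t", "g")])
  }
  ex <- contact_exclusions(mesh, contact$detection_thickness)

  out <- cpp_run_sim(mesh$nodes, mesh$triangles, pre$invR, pre$areas,
                     mesh$thickness, pre$matid, pre$matpar, masses,
                     mesh$papillary_tips, ca$origin, ca$insertion,
                     ca$area, ca$rest, ca$ogid, ca$ogpars,
                     press, 1.0,
                     as.integer(ann), presc_base, presc_dir, gat,
                     ex$ptr, ex$idx,
                     kn, contact$friction_mu, contact$detection_thickness,
                     contact$tangential_stiffness,
                     0.5 * kn, 0.5 * contact$detection_thickness,
                     dt, config$duration, config$damping,
                     config$output_stride, config$contact_every)
  nf <- out$n_frames
  if (out$status != 0)
    warning("simulate_closure: aborted at t = ",
            signif(out$times[nf], 4), " ms (", out$error,
            "); returning frames up to the last valid state")
  posarr <- array(unlist(out$positions[seq_len(nf)]),
                  dim = c(nrow(mesh$nodes), 3, nf))
  lam <- if (length(ca$insertion))
    t(vapply(out$lambda[seq_len(nf)], identity,
             numeric(length(ca$insertion))))
  else matrix(0, nf, 0)
  energy <- tibble::tibble(
    t = out$times[seq_len(nf)],
    kinetic = out$kinetic[seq_len(nf)],
    strain = out$strain[seq_len(nf)],
    contact = out$contact_energy[seq_len(nf)],
    external_work = out$wext[seq_len(nf)],
    dissipation = out$dissipation[seq_len(nf)],
    n_contact_pairs = out$n_pairs[seq_len(nf)])
  ptrace <- if (is.null(pressure)) rep(0, nf) else
    pressure_at(out$times[seq_len(nf)], pressure)
  structure(list(times = out$times[seq_len(nf)], positions = posarr,
                 lambda = lam, pressure_trace = ptrace,
                 pairs = lapply(out$pairs[seq_len(nf)], tibble::as_tibble),
                 energy = energy, mesh = mesh, chordae = chordae,
                 materials = materials, dt = dt,
                 penalty_stiffness = kn,
                 config = config, status = out$status),
            class = "mv_sim")
}

#' @export
print.mv_sim <- function(x, ...) {
  cat(sprintf("mv_sim: %d frames over %.0f ms (dt = %.4g ms, %d nodes)\n",
              length(x$times), max(x$times), x$dt, dim(x$positions)[1]))
  er <- energy_balance_residual(x)
  cat(sprintf("  energy balance residual: %.2f%% of peak external work\n",
              100 * er))
  invisible(x)
}

#' Energy balance residual of a simulation
#'
#' `|KE + strain + contact - W_ext + dissipation|` at the final frame,
#' normalized by the peak external work.
#'
#' @param sim an `mv_sim`.
#' @return dimensionless residual fraction.
#' @export
energy_balance_residual <- function(sim) {
  e <- sim$energy
  k <- nrow(e)
  res <- abs(e$kinetic[k] + e$strain[k] + e$contact[k] -
               e$external_work[k] + e$dissipation[k])
  peak <- max(abs(e$external_work), 1e-12)
  res / peak
}

#' Frame index at (or nearest to) a simulation time
#' @param sim an `mv_sim`.
#' @param t time (ms).
#' @return integer frame index.
#' @export
frame_at <- function(sim, t) which.min(abs(sim$times - t))

#' Tidy per-frame energy summary of a simulation
#' @param x an `mv_sim`.
#' @param ... unused.
#' @return the per-frame energy tibble.
#' @method tidy mv_sim
#' @export
tidy.mv_sim <- function(x, ...) x$energy

#' One-row summary of a simulation
#' @param x an `mv_sim`.
#' @param ... unused.
#' @return tibble with frames, duration, timestep, energy residual, peak
#'   contact pair count and status.
#' @method glance mv_sim
#' @export
glance.mv_sim <- function(x, ...) {
  tibble::tibble(
    n_frames = length(x$times),
    duration_ms = max(x$times),
    dt_ms = x$dt,
    energy_residual = energy_balance_residual(x),
    max_contact_pairs = max(x$energy$n_contact_pairs),
    kinetic_over_strain = {
      k <- nrow(x$energy)
      x$energy$kinetic[k] / max(x$energy$strain[k], 1e-12)
    },
    status = x$status)
}
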