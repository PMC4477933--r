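test_that("membrane forces vanish for undeformed and rigidly moved meshes", {
  mv <- small_valve()
  expect_lt(max(abs(internal_forces_membrane(mv))), 1e-9)
  th <- 0.4
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- sweep(mv$nodes %*% R, 2, c(3, -2, 7), "+")
  expect_lt(max(abs(internal_forces_membrane(mv, moved))), 1e-8)
})

test_that("membrane forces equal the numerical energy gradient", {
  mesh <- single_triangle_mesh()
  mats <- default_materials()
  pos <- mesh$nodes
  pos[, 1] <- pos[, 1] * 1.1          # 10% circumferential stretch
  f <- internal_forces_membrane(mesh, pos, mats)
  h <- 1e-6
  for (i in 1:3) for (c in 1:3) {
    pp <- pos; pp[i, c] <- pp[i, c] + h
    pm <- pos; pm[i, c] <- pm[i, c] - h
    fd <- -(attr(internal_forces_membrane(mesh, pp, mats), "energy") -
              attr(internal_forces_membrane(mesh, pm, mats), "energy")) /
      (2 * h)
    expect_equal(f[i, c], fd, tolerance = 1e-6)
  }
  # the recovered element strain matches the imposed stretch
  E <- attr(f, "strain")
  expect_equal(E[1, 1], (1.1^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(E[1, 2], 0, tolerance = 1e-12)
})

test_that("collapsed (inverted) elements are flagged with their id", {
  mesh <- single_triangle_mesh()
  pos <- mesh$nodes
  pos[3, ] <- c(4, 0, 0)      # all three nodes collinear: in-plane
  pos[2, ] <- c(2, 0, 0)      # Jacobian passes through zero
  expect_error(internal_forces_membrane(mesh, pos), "element 1")
})

test_that("chordal forces are tension-only, paired and composable", {
  mv <- small_valve()
  ch <- attach_chordae(mv, 4, 4, 2)
  expect_lt(max(abs(internal_forces_chordae(mv, ch))), 1e-9)

  # stretch one chorda to lambda = 1.1 by moving its insertion
  d <- ch$chordae
  j <- 1L
  tip <- mv$papillary_tips[ifelse(d$origin[j] == "al", 1, 2), ]
  pos <- mv$nodes
  dir <- pos[d$insertion[j], ] - tip
  pos[d$insertion[j], ] <- tip + 1.1 * dir
  f <- internal_forces_chordae(mv, ch, pos)
  mats <- default_materials()
  want_N <- chordal_force(1.1, mats$ogden$marginal, d$area[j])
  got_mN <- sqrt(sum(f[d$insertion[j], ]^2))
  expect_equal(got_mN / 1000, want_N, tolerance = 1e-9)
  # Newton's third law: tip reaction balances nodal forces exactly
  tipf <- attr(f, "tip_force")
  expect_equal(colSums(f) + colSums(tipf), c(0, 0, 0), tolerance = 1e-12)

  # compressed chord contributes nothing
  pos2 <- mv$nodes
  pos2[d$insertion[j], ] <- tip + 0.8 * dir
  f2 <- internal_forces_chordae(mv, ch, pos2)
  expect_lt(max(abs(f2[d$insertion[j], ])), 1e-12)
})

test_that("penalty contact produces the hand-computed normal force", {
  mesh <- single_triangle_mesh()
  # free-floating probe node: far away in the reference configuration,
  # moved above the triangle interior in the tested state
  mesh$nodes <- rbind(mesh$nodes, c(0.5, 0.5, 5))
  pos <- mesh$nodes
  pos[4, 3] <- 0.3
  k <- 10; h <- 0.8
  out <- contact_forces(mesh, positions = pos,
                        params = contact_params(penalty_stiffness = k,
                                                detection_thickness = h))
  expect_equal(nrow(out$pairs), 1L)
  depth <- h - 0.3
  expect_equal(out$pairs$normal_force, k * depth, tolerance = 1e-12)
  expect_equal(out$force[4, ], c(0, 0, k * depth), tolerance = 1e-12)
  # reaction distributed to the triangle sums to the opposite
  expect_equal(colSums(out$force), c(0, 0, 0), tolerance = 1e-12)
})

test_that("separated surfaces generate no contact", {
  mesh <- single_triangle_mesh()
  mesh$nodes <- rbind(mesh$nodes, c(0.5, 0.5, 5))
  out <- contact_forces(mesh, positions = mesh$nodes,
                        params = contact_params(penalty_stiffness = 10))
  expect_equal(nrow(out$pairs), 0L)
  expect_lt(max(abs(out$force)), 1e-15)
})

test_that("tangential contact force is capped at mu times normal force", {
  mesh <- single_triangle_mesh()
  mesh$nodes <- rbind(mesh$nodes, c(0.5, 0.5, 5))
  pos <- mesh$nodes
  pos[4, 3] <- 0.3
  vel <- matrix(0, 4, 3)
  vel[4, ] <- c(5, 0, 0)             # fast slip: demand >> mu N
  k <- 10; h <- 0.8; mu <- 0.05
  out <- contact_forces(mesh, positions = pos, velocities = vel,
                        params = contact_params(penalty_stiffness = k,
                                                detection_thickness = h,
                                                friction_mu = mu,
                                                tangential_stiffness = 50))
  fN <- k * (h - 0.3)
  ft <- out$force[4, 1:2]
  expect_equal(sqrt(sum(ft^2)), mu * fN, tolerance = 1e-12)  # exact cap
  expect_lt(ft[1], 0)                                        # opposes slip
  # slow slip below the cap follows the viscous regularization
  vel[4, 1] <- 1e-4
  out2 <- contact_forces(mesh, positions = pos, velocities = vel,
                         params = contact_params(penalty_stiffness = k,
                                                 detection_thickness = h,
                                                 friction_mu = mu,
                                                 tangential_stiffness = 50))
  expect_equal(out2$force[4, 1], -50 * 1e-4, tolerance = 1e-9)
})

test_that("stable timestep follows CFL scaling laws", {
  mats <- default_materials()
  mv1 <- small_valve()
  mv2 <- small_valve(n_circ = 33, n_rad_anterior = 9, n_rad_posterior = 7)
  dt1 <- stable_timestep(mv1, mats)
  dt2 <- stable_timestep(mv2, mats)
  expect_equal(dt2 / dt1, 0.5, tolerance = 0.07)   # half the edge length
  m4 <- mats
  m4$fung$anterior$c <- 4 * m4$fung$anterior$c
  m4$fung$posterior$c <- 4 * m4$fung$posterior$c
  expect_equal(stable_timestep(mv1, m4) / dt1, 0.5, tolerance = 0.05)

  # single element closed form
  mesh <- single_triangle_mesh()
  p <- mats$fung$anterior
  kmax <- p$c * max(eigen(matrix(c(p$a_cc, p$a_cr, p$a_cr, p$a_rr), 2, 2),
                          only.values = TRUE)$values)
  rho <- mats$tissue$density / 1000
  area <- 2; lmax <- sqrt(8)
  expect_equal(stable_timestep(mesh, mats),
               0.8 * (2 * area / lmax) / sqrt(kmax / rho),
               tolerance = 1e-12)
})

test_that("the central-difference step integrates canonical motions", {
  # zero force, zero damping: uniform motion
  x <- matrix(0, 1, 3); v <- matrix(c(1, 0, 0), 1, 3)
  st <- solver_step(x, v, matrix(0, 1, 3), 1, dt = 0.1)
  expect_equal(st$positions[1, 1], 0.1)
  expect_equal(st$velocities, v)

  # mass-spring oscillator: period within 1% at dt = period/100
  m <- 2; k <- 5
  period <- 2 * pi * sqrt(m / k)
  dt <- period / 100
  x <- matrix(c(1, 0, 0), 1, 3); v <- matrix(0, 1, 3)
  xs <- numeric(0)
  for (i in 1:400) {
    f <- matrix(c(-k * x[1, 1], 0, 0), 1, 3)
    st <- solver_step(x, v, f, m, dt)
    x <- st$positions; v <- st$velocities
    xs <- c(xs, x[1, 1])
  }
  crossings <- which(diff(sign(xs)) < 0)
  measured <- dt * mean(diff(crossings))
  expect_equal(measured, period, tolerance = 0.01)

  # prescribed node follows its program exactly
  x <- matrix(0, 2, 3); v <- matrix(0, 2, 3)
  tgt <- matrix(c(0.5, 1, 2), 1, 3)
  st <- solver_step(x, v, matrix(5, 2, 3), c(1, 1), 0.1,
                    prescribed_ids = 2L, prescribed_targets = tgt)
  expect_equal(st$positions[2, ], c(0.5, 1, 2))
})

test_that("unloaded valve stays at its reference configuration", {
  mv <- small_valve()
  ch <- attach_chordae(mv, 8, 8, 2)
  sim <- simulate_closure(mv, ch, pressure = NULL,
                          config = solver_config(duration = 40,
                                                 output_stride = 200))
  k <- length(sim$times)
  disp <- sqrt(rowSums((sim$positions[, , k] - mv$nodes)^2))
  ap <- measure_annulus(mv)[["ap_diameter_mm"]]
  expect_lt(max(disp), 0.01 * ap)
})

test_that("closure runs are deterministic and energy-consistent", {
  mv <- small_valve()
  ch <- attach_chordae(mv, 8, 8, 2)
  cfg <- solver_config(duration = 120, output_stride = 400)
  sim1 <- simulate_closure(mv, ch, config = cfg)
  sim2 <- simulate_closure(mv, ch, config = cfg)
  expect_identical(sim1$positions, sim2$positions)   # bit-reproducible
  expect_equal(sim1$status, 0)
  expect_lt(energy_balance_residual(sim1), 0.02)
  # quasi-static: kinetic energy negligible against strain energy
  expect_lt(glance(sim1)$kinetic_over_strain, 0.05)
  # contact complementarity: every recorded normal force repulsive
  k <- length(sim1$times)
  expect_true(all(sim1$pairs[[k]]$normal_force > 0))
  expect_true(all(sim1$pairs[[k]]$depth > 0))
})

test_that("symmetric valve under symmetric load closes symmetrically", {
  # margin undulation off: the generator is then exactly mirror-symmetric
  mv <- small_valve(posterior_margin_ripple = 0)
  ch <- attach_chordae(mv, 8, 8, 2)
  ap <- measure_annulus(mv)[["ap_diameter_mm"]]
  cfg <- solver_config(duration = 150, output_stride = 400)
  sim <- simulate_closure(mv, ch, config = cfg)
  k <- length(sim$times)
  pos <- sim$positions[, , k]
  # aggregate mirror symmetry of the closed state (the unsupported free
  # margin wrinkles through a symmetry-breaking buckling bifurcation, so
  # pointwise symmetry holds everywhere except isolated wrinkles)
  mir <- pos
  mir[, 1] <- -mir[, 1]
  dmin <- vapply(seq_len(nrow(pos)), function(i) {
    min(sqrt(rowSums(sweep(pos, 2, mir[i, ])^2)))
  }, numeric(1))
  expect_lt(median(dmin), 0.02 * ap)

  # solver mirror-equivariance: simulating the mirrored valve reproduces
  # the mirrored trajectory before the contact-slap regime
  mv2 <- mv
  mv2$nodes <- mv$nodes %*% diag(c(-1, 1, 1))
  mv2$triangles <- mv$triangles[, c(1, 3, 2)]
  mv2$fiber_e1 <- mv$fiber_e1 %*% diag(c(-1, 1, 1))
  mv2$papillary_tips <- mv$papillary_tips %*% diag(c(-1, 1, 1))
  mv2 <- mvrepair:::refresh_fiber_frames(mv2)
  cfg2 <- solver_config(duration = 100, output_stride = 400)
  s1 <- simulate_closure(mv, ch, config = cfg2)
  s2 <- simulate_closure(mv2, ch, config = cfg2)
  k2 <- length(s1$times)
  ref <- s1$positions[, , k2] %*% diag(c(-1, 1, 1))
  expect_lt(max(abs(s2$positions[, , k2] - ref)), 0.02 * ap)
})

test_that("slow-ramp loading matches a damped long-time settle", {
  mv <- small_valve()
  ch <- attach_chordae(mv, 8, 8, 2)
  press_step <- pressure_waveform(samples = data.frame(
    t = c(0, 10, 300), dP = c(0, 8, 8)))
  press_slow <- pressure_waveform(samples = data.frame(
    t = c(0, 250, 300), dP = c(0, 8, 8)))
  settle <- simulate_closure(mv, ch, pressure = press_step,
                             config = solver_config(duration = 300,
                                                    damping = 0.5,
                                                    output_stride = 500))
  ramp <- simulate_closure(mv, ch, pressure = press_slow,
                           config = solver_config(duration = 300,
                                                  output_stride = 500))
  ks <- length(settle$times); kr <- length(ramp$times)
  ap <- measure_annulus(mv)[["ap_diameter_mm"]]
  gap <- sqrt(rowSums((settle$positions[, , ks] -
                         ramp$positions[, , kr])^2))
  expect_lt(max(gap), 0.01 * ap)
})
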