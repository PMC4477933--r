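test_that("generator honors requested annular dimensions exactly", {
  mv <- patient_valve()
  d <- measure_annulus(mv)
  expect_equal(d[["ap_diameter_mm"]], 43, tolerance = 0.02)
  expect_equal(d[["alpm_diameter_mm"]], 37, tolerance = 0.02)
  d2 <- measure_annulus(build_synthetic_valve(ap_diameter = 30,
                                              alpm_diameter = 28,
                                              posterior_bulge = 4))
  expect_equal(unname(d2), c(30, 28), tolerance = 0.02 * 30)
})

test_that("zero saddle height gives a planar annulus", {
  mv <- small_valve(saddle_height = 0)
  z <- mv$nodes[mv$annulus_ids, 3]
  expect_lt(diff(range(z)), 1e-9)
})

test_that("generation is deterministic for identical params and seed", {
  a <- build_synthetic_valve(n_circ = 17, n_rad_anterior = 5,
                             n_rad_posterior = 4, jitter_sd = 0.2,
                             seed = 7)
  b <- build_synthetic_valve(n_circ = 17, n_rad_anterior = 5,
                             n_rad_posterior = 4, jitter_sd = 0.2,
                             seed = 7)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$triangles, b$triangles)
  c_ <- build_synthetic_valve(n_circ = 17, n_rad_anterior = 5,
                              n_rad_posterior = 4, jitter_sd = 0.2,
                              seed = 8)
  expect_false(identical(a$nodes, c_$nodes))
})

test_that("region labels partition each leaflet with enough elements", {
  mv <- patient_valve()
  areas <- mvrepair:::triangle_areas(mv$nodes, mv$triangles)
  for (lf in c("anterior", "posterior")) {
    sel <- mv$leaflet == lf
    regs <- if (lf == "anterior") c("A1", "A2", "A3") else
      c("P1", "P2", "P3")
    expect_setequal(unique(mv$region[sel]), regs)
    per <- vapply(regs, function(r) sum(areas[mv$region == r]), numeric(1))
    expect_equal(sum(per), sum(areas[sel]))          # exact partition
    expect_true(all(table(mv$region[sel]) >= 6))
  }
})

test_that("invalid generator inputs are rejected with messages", {
  expect_error(build_synthetic_valve(ap_diameter = -1), "positive")
  expect_error(build_synthetic_valve(n_circ = 4), "too coarse")
})

test_that("the generated mesh passes the full topology audit", {
  mv <- patient_valve()
  expect_true(validate_valve_mesh(mv, attach_chordae(mv)))
  expect_setequal(boundary_nodes_bruteforce(mv),
                  c(mv$annulus_ids,
                    unlist(mv$free_edge_ids, use.names = FALSE)))
})

test_that("chordae carry the documented default areas and origins", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)$chordae
  expect_equal(unique(ch$area[ch$type == "marginal" &
                                ch$leaflet == "anterior"]), 0.29)
  expect_equal(unique(ch$area[ch$type == "marginal" &
                                ch$leaflet == "posterior"]), 0.27)
  expect_equal(unique(ch$area[ch$type == "strut"]), 0.61)
  # each chorda originates on its own commissural side
  x <- mv$nodes[ch$insertion, 1]
  expect_true(all(ch$origin[x > 1e-9] == "al"))
  expect_true(all(ch$origin[x < -1e-9] == "pm"))
  # rest length = origin-insertion distance in the reference configuration
  tip <- mv$papillary_tips[ifelse(ch$origin == "al", 1, 2), , drop = FALSE]
  expect_equal(ch$rest_length,
               sqrt(rowSums((mv$nodes[ch$insertion, ] - tip)^2)),
               ignore_attr = TRUE)
})

test_that("marginal insertions are near-uniform along the free margin", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)$chordae
  for (lf in c("anterior", "posterior")) {
    edge <- mv$free_edge_ids[[lf]]
    pts <- mv$nodes[edge, ]
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    L <- max(s)
    ins <- ch$insertion[ch$type == "marginal" & ch$leaflet == lf]
    n <- length(ins)
    got <- sort(s[match(ins, edge)])
    want <- (seq_len(n) - 0.5) / n * L
    seg <- max(diff(s))
    expect_lt(max(abs(got - want)), seg + 1e-9)   # brute-force arc check
  }
})

test_that("chordae edge cases behave per contract", {
  mv <- small_valve()
  empty <- attach_chordae(mv, 0, 0, 0)
  expect_equal(nrow(empty$chordae), 0)
  expect_error(attach_chordae(mv, n_marginal_anterior = 1000),
               "exceeds")
  expect_error(attach_chordae(mv, n_marginal_anterior = -1), ">= 0")
})

test_that("prolapse induction removes floor(fraction * n) central chordae", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  reg <- node_region_lookup(mv)
  p2 <- ch$chordae$label[ch$chordae$type == "marginal" &
                           reg[ch$chordae$insertion] == "P2"]
  n <- length(p2)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  removed <- attr(pr, "removed")
  expect_length(removed, floor(0.7 * n))
  expect_true(all(removed %in% p2))
  # contiguous central block
  idx <- sort(match(removed, p2))
  expect_equal(idx, seq(idx[1], length.out = length(idx)))

  # fraction 0 is the identity; fraction 1 clears the scallop
  expect_identical(induce_prolapse(ch, mv, "P2", 0)$chordae, ch$chordae)
  full <- induce_prolapse(ch, mv, "P2", 1)
  expect_false(any(full$chordae$label %in% p2))
  expect_error(induce_prolapse(ch, mv, "Q9", 0.5), "unknown scallop")
  expect_error(induce_prolapse(ch, mv, "P2", 1.2), "fraction")
})

test_that("annulus measurement uses landmarks and is rigid-invariant", {
  # unit-circle annulus with landmarks at 0/180/90/270 degrees
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  nodes <- cbind(cos(th), sin(th), 0)
  nodes <- rbind(nodes, c(0, 0, 1))          # apex to form triangles
  tris <- cbind(seq_len(32), c(2:32, 1), 33L)
  mesh <- valve_mesh(nodes, tris, rep("anterior", 32), rep("A2", 32),
                     rep(0.5, 32), fiber_e1 = matrix(rep(c(1, 0, 0), 32),
                                                     ncol = 3, byrow = TRUE),
                     fiber_e2 = matrix(rep(c(0, 1, 0), 32), ncol = 3,
                                       byrow = TRUE),
                     annulus_ids = seq_len(32),
                     free_edge_ids = list(anterior = 33L,
                                          posterior = integer(0)),
                     landmarks = c(anterior_mid = which.min(abs(th - pi / 2)),
                                   posterior_mid = which.min(abs(th - 3 * pi / 2)),
                                   commissure_al = which.min(abs(th)),
                                   commissure_pm = which.min(abs(th - pi))),
                     papillary_tips = rbind(al = c(0, 0, -2),
                                            pm = c(0, 0, -2)))
  d <- measure_annulus(mesh)
  expect_equal(unname(d), c(2, 2), tolerance = 1e-12)

  mv <- small_valve()
  d0 <- measure_annulus(mv)
  th0 <- 0.7
  R <- matrix(c(cos(th0), -sin(th0), 0, sin(th0), cos(th0), 0, 0, 0, 1),
              3, 3)
  mv2 <- mv
  mv2$nodes <- sweep(mv$nodes %*% R, 2, c(5, -3, 2), "+")
  expect_equal(measure_annulus(mv2), d0, tolerance = 1e-9)

  mv3 <- mv
  mv3$landmarks <- mv$landmarks[1:3]
  expect_error(measure_annulus(mv3), "landmark")
})

test_that("mesh and chordae serialize losslessly to VTK + JSON", {
  mv <- small_valve()
  ch <- attach_chordae(mv, 6, 6, 2)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mv, path)
  mv2 <- read_mesh_vtk(path)
  expect_equal(mv2$nodes, mv$nodes, tolerance = 1e-12)
  expect_identical(mv2$triangles, mv$triangles)
  expect_identical(mv2$region, mv$region)
  expect_identical(mv2$annulus_ids, mv$annulus_ids)
  expect_equal(mv2$landmarks, mv$landmarks)
  expect_true(validate_valve_mesh(mv2))

  jpath <- withr::local_tempfile(fileext = ".json")
  write_chordae_json(ch, jpath)
  ch2 <- read_chordae_json(jpath)
  expect_equal(as.data.frame(ch2$chordae), as.data.frame(ch$chordae),
               tolerance = 1e-12, ignore_attr = TRUE)
})
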