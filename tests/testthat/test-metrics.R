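# minimal one-frame mv_sim wrapper for metric unit tests
fake_sim <- function(mesh, positions = mesh$nodes, chordae = NULL,
                     lambda = NULL, pairs = NULL) {
  n <- nrow(mesh$nodes)
  structure(list(
    times = 0,
    positions = array(positions, dim = c(n, 3, 1)),
    lambda = if (is.null(lambda)) matrix(0, 1, 0) else
      matrix(lambda, nrow = 1),
    pressure_trace = 0,
    pairs = list(if (is.null(pairs))
      tibble::tibble(node = integer(0), tri = integer(0),
                     depth = numeric(0), normal_force = numeric(0))
      else pairs),
    energy = tibble::tibble(t = 0, kinetic = 0, strain = 0, contact = 0,
                            external_work = 0, dissipation = 0,
                            n_contact_pairs = 0),
    mesh = mesh, chordae = chordae, materials = default_materials(),
    dt = 1, penalty_stiffness = 1, config = solver_config(duration = 1),
    status = 0), class = "mv_sim")
}

test_that("the stress field is zero at the reference configuration", {
  mv <- small_valve()
  sf <- stress_field(fake_sim(mv))
  expect_lt(max(sf$stress_mpa), 1e-9)
  expect_error(stress_field(fake_sim(mv), t = 99), "outside")
})

p_nu <- function(m) m$tissue$poisson

test_that("a prescribed uniaxial stretch reproduces the material law", {
  mesh <- single_triangle_mesh()
  lam <- 1.15
  pos <- mesh$nodes
  pos[, 1] <- pos[, 1] * lam
  sf <- stress_field(fake_sim(mesh, pos))
  # independent push-forward: E known analytically, S from fung_stress,
  # Cauchy = S C / (J lambda_t) for this shear-free uniaxial state
  mats <- default_materials()
  p <- mats$fung$anterior
  E <- c((lam^2 - 1) / 2, 0, 0)
  S <- fung_stress(E, p)
  J2 <- lam                      # det F2d = lam * 1
  lt <- J2^(-p_nu(mats) / (1 - p_nu(mats)))
  sig1 <- max(S[["S_cc"]] * lam^2, S[["S_rr"]]) / (J2 * lt)
  expect_equal(sf$stress_mpa[1], sig1 / 1000, tolerance = 1e-9)
})

test_that("regional averages are area-weighted and conservative", {
  mv <- small_valve()
  sf <- stress_field(fake_sim(mv))
  # uniform synthetic field
  sf$stress_mpa <- rep(0.7, nrow(sf))
  ra <- regional_average_stress(sf)
  expect_equal(ra$mean_stress_mpa, rep(0.7, 6))
  # indicator field concentrated on P2
  sf$stress_mpa <- ifelse(sf$region == "P2", 1.3, 0.2)
  ra <- regional_average_stress(sf)
  expect_equal(ra$mean_stress_mpa[ra$region == "P2"], 1.3)
  expect_equal(ra$mean_stress_mpa[ra$region == "A1"], 0.2)
  # conservation: area-weighted recombination equals the global mean
  glob <- sum(sf$stress_mpa * sf$area_mm2) / sum(sf$area_mm2)
  expect_equal(sum(ra$mean_stress_mpa * ra$area_mm2) / sum(ra$area_mm2),
               glob, tolerance = 1e-12)
  # a field restricted to a mesh without some region flags it missing
  sfa <- sf[sf$region != "P3", ]
  class(sfa) <- class(sf)
  ra2 <- regional_average_stress(sfa)
  expect_true(is.na(ra2$mean_stress_mpa[ra2$region == "P3"]))
})

test_that("threshold maps use a strict inequality and exact areas", {
  mv <- small_valve()
  sf <- stress_field(fake_sim(mv))
  sf$stress_mpa <- rep(0, nrow(sf))
  tm <- threshold_map(sf)
  expect_false(any(tm$mask))
  expect_equal(tm$exceed_fraction, 0)
  # exactly at the threshold: excluded
  sf$stress_mpa <- rep(0.4, nrow(sf))
  expect_false(any(threshold_map(sf, 0.4)$mask))
  # hand-built areas
  sf$stress_mpa <- ifelse(seq_len(nrow(sf)) <= 10, 1, 0)
  tm <- threshold_map(sf, 0.4)
  expect_equal(tm$exceed_fraction,
               sum(sf$area_mm2[1:10]) / sum(sf$area_mm2))
})

test_that("coaptation measures constructed parallel strips exactly", {
  # two flat strips along y, overlapping by 4 mm with a 0.4 mm gap
  strip <- function(y0, y1, z, nid0) {
    nodes <- rbind(c(-1, y0, z), c(1, y0, z), c(-1, y1, z), c(1, y1, z))
    tris <- rbind(c(1, 2, 3), c(2, 4, 3)) + nid0
    list(nodes = nodes, tris = tris)
  }
  a <- strip(-6, 4, 0, 0L)       # "anterior" strip
  b <- strip(0, 8, 0.4, 4L)      # "posterior" strip, overlap y in [0, 4]
  nodes <- rbind(a$nodes, b$nodes)
  mesh <- valve_mesh(nodes, rbind(a$tris, b$tris),
                     leaflet = c("anterior", "anterior", "posterior",
                                 "posterior"),
                     region = c("A2", "A2", "P2", "P2"),
                     thickness = rep(0.5, 4),
                     fiber_e1 = matrix(rep(c(1, 0, 0), 4), ncol = 3,
                                       byrow = TRUE),
                     fiber_e2 = matrix(rep(c(0, 1, 0), 4), ncol = 3,
                                       byrow = TRUE),
                     annulus_ids = c(3L, 4L, 7L, 8L),
                     free_edge_ids = list(anterior = 1:2,
                                          posterior = 5:6),
                     landmarks = c(anterior_mid = 7L, posterior_mid = 8L,
                                   commissure_al = 4L, commissure_pm = 3L),
                     papillary_tips = rbind(al = c(1, 0, -10),
                                            pm = c(-1, 0, -10)))
  co <- coaptation(fake_sim(mesh), planes = "A2P2", gap_tol = 0.41)
  expect_equal(co$coaptation_mm[1], 4, tolerance = 0.05)
  # fully separated strips coapt nowhere
  nodes2 <- nodes
  nodes2[5:8, 3] <- 5
  co0 <- coaptation(fake_sim(mesh, nodes2), planes = "A2P2",
                    gap_tol = 0.8)
  expect_equal(co0$coaptation_mm[1], 0)
  # longer detection thickness can only lengthen coaptation
  co2 <- coaptation(fake_sim(mesh), planes = "A2P2", gap_tol = 2)
  expect_gte(co2$coaptation_mm[1], co$coaptation_mm[1])
  co3 <- coaptation(fake_sim(mesh), planes = "A2P2", gap_tol = 0.8)
  expect_gte(co2$coaptation_mm[1], co3$coaptation_mm[1])
  expect_gte(co3$coaptation_mm[1], co$coaptation_mm[1])
})

test_that("percent change reproduces the published worked examples", {
  expect_equal(percent_change(2121, 799), -62L)
  expect_equal(percent_change(254, 208), -18L)
  expect_equal(percent_change(832, 371), -55L)
  expect_equal(percent_change(2953, 1315), -55L)
  expect_equal(percent_change(100, 100), 0L)
})

test_that("chordal stress tables pair labels and flag absent chordae", {
  mv <- small_valve()
  ch <- attach_chordae(mv, 4, 4, 0)
  lam <- rep(1.1, nrow(ch$chordae))
  sim1 <- fake_sim(mv, chordae = ch, lambda = lam)
  tab0 <- chordal_stress_table(sim1, sim1)
  expect_true(all(tab0$change_percent == 0))
  mats <- default_materials()
  expect_equal(tab0$pre_kpa[1],
               ogden_fiber_stress(1.1, mats$ogden$marginal))
  # a chorda missing post-repair comes back NA
  ch2 <- chordae_set(ch$chordae[-1, ])
  sim2 <- fake_sim(mv, chordae = ch2, lambda = lam[-1])
  tab <- chordal_stress_table(sim1, sim2)
  expect_true(is.na(tab$post_kpa[tab$label == ch$chordae$label[1]]))
  expect_true(is.na(tab$change_percent[tab$label == ch$chordae$label[1]]))
})

test_that("metrics are invariant under rigid motion of the trajectory", {
  mv <- small_valve()
  th <- 0.5
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(4, -1, 6)
  pos <- mv$nodes * 1.0
  pos[, 2] <- pos[, 2] * 1.08            # some deformation
  posR <- sweep(pos %*% R, 2, shift, "+")
  mvR <- mv
  mvR$nodes <- sweep(mv$nodes %*% R, 2, shift, "+")
  # rotate fiber frames consistently with the body
  mvR$fiber_e1 <- mv$fiber_e1 %*% R
  mvR$fiber_e2 <- mv$fiber_e2 %*% R
  sf <- stress_field(fake_sim(mv, pos))
  sfR <- stress_field(fake_sim(mvR, posR))
  expect_equal(sfR$stress_mpa, sf$stress_mpa, tolerance = 1e-9)
  co <- coaptation(fake_sim(mv, pos), planes = "A2P2")
  coR <- coaptation(fake_sim(mvR, posR), planes = "A2P2")
  expect_equal(coR$coaptation_mm, co$coaptation_mm, tolerance = 1e-6)
})
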