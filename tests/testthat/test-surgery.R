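test_that("resection plan respects the chordal margin and curve anatomy", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  plan <- plan_resection(mv, pr, "P2", chordal_margin = 5)

  # brute-force distance audit (dense curve sampling, independent of the
  # planner's own distance helper): every remaining marginal insertion is
  # at least 5 mm from both excision curves
  ins <- pr$chordae$insertion[pr$chordae$type == "marginal"]
  for (edge in list(plan$edge_A, plan$edge_B)) {
    poly <- mv$nodes[edge, ]
    tt <- seq(0, 1, length.out = 50)
    dense <- do.call(rbind, lapply(seq_len(nrow(poly) - 1), function(k)
      outer(1 - tt, poly[k, ]) + outer(tt, poly[k + 1, ])))
    dmin <- min(vapply(ins, function(i)
      min(sqrt(rowSums(sweep(dense, 2, mv$nodes[i, ])^2))), numeric(1)))
    expect_gte(dmin, 5 - 1e-6)
  }
  # curves run from the annulus to the free margin, ~15 mm long
  for (edge in list(plan$edge_A, plan$edge_B)) {
    expect_true(edge[1] %in% mv$annulus_ids)
    expect_true(edge[length(edge)] %in% mv$free_edge_ids$posterior)
  }
  expect_true(all(abs(plan$edge_lengths_mm - 15) < 5))
  # pairing is a bijection with monotone arc lengths
  expect_false(anyDuplicated(plan$node_pairing[, 1]) > 0)
  expect_false(anyDuplicated(plan$node_pairing[, 2]) > 0)
  expect_identical(plan$node_pairing[1, ],
                   c(edge_A = plan$edge_A[1], edge_B = plan$edge_B[1]))
  # removal region non-empty and inside P2
  expect_gt(length(plan$element_ids), 0)
  expect_true(all(mv$region[plan$element_ids] == "P2"))
})

test_that("a zero margin admits the widest quadrangle in the scallop", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  plan5 <- plan_resection(mv, pr, "P2", chordal_margin = 5)
  plan0 <- plan_resection(mv, pr, "P2", chordal_margin = 0)
  expect_gt(length(plan0$element_ids), length(plan5$element_ids))
  expect_gte(diff(plan0$theta_band), diff(plan5$theta_band))
})

test_that("an unsatisfiable margin is rejected with the achievable value", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  expect_error(plan_resection(mv, pr, "P2", chordal_margin = 50),
               "achievable")
})

test_that("excision removes exactly the planned elements and chordae", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  plan <- plan_resection(mv, pr, "P2", 5)
  ex <- excise(mv, pr, plan)
  expect_equal(nrow(ex$mesh$triangles),
               nrow(mv$triangles) - length(plan$element_ids))
  # boundary audit: annulus + free edges + the two excision curves
  got <- boundary_nodes_bruteforce(ex$mesh)
  want <- sort(unique(c(ex$mesh$annulus_ids,
                        unlist(ex$mesh$free_edge_ids, use.names = FALSE),
                        ex$plan$edge_A, ex$plan$edge_B)))
  expect_setequal(got, want)
  expect_true(validate_valve_mesh(
    ex$mesh, ex$chordae,
    extra_boundary_ids = c(ex$plan$edge_A, ex$plan$edge_B)))
  # no dangling insertions; chordae on removed tissue are gone
  expect_true(all(ex$chordae$chordae$insertion <= nrow(ex$mesh$nodes)))

  # empty plan is the identity
  plan0 <- plan
  plan0$element_ids <- integer(0)
  ex0 <- excise(mv, pr, plan0)
  expect_identical(ex0$mesh$nodes, mv$nodes)
  # stale plans are rejected
  planbad <- plan
  planbad$element_ids <- nrow(mv$triangles) + 5L
  expect_error(excise(mv, pr, planbad), "missing elements")
})

test_that("suture curve interpolates equidistant key points", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  ex <- excise(mv, pr, plan_resection(mv, pr, "P2", 5))
  sc <- suture_target_curve(ex$plan$edge_A, ex$plan$edge_B,
                            ex$plan$node_pairing, ex$mesh)
  P <- ex$mesh$nodes
  for (i in seq_len(nrow(sc$keypoints))) {
    da <- sqrt(sum((sc$keypoints[i, ] - P[ex$plan$node_pairing[i, 1], ])^2))
    db <- sqrt(sum((sc$keypoints[i, ] - P[ex$plan$node_pairing[i, 2], ])^2))
    expect_equal(da, db, tolerance = 1e-9)
  }
  # interpolating, not smoothing: the spline passes through every key point
  at <- cbind(sc$fx(sc$t), sc$fy(sc$t), sc$fz(sc$t))
  expect_lt(max(abs(at - sc$keypoints)), 1e-6)

  # degenerate zero-width resection: curve coincides with the shared edge
  edge <- ex$plan$edge_A
  pairing <- cbind(edge_A = edge, edge_B = edge)
  sc0 <- suture_target_curve(edge, edge, pairing, ex$mesh)
  expect_equal(sc0$keypoints, unname(ex$mesh$nodes[edge, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("plication fixes the anterior annulus and sutures watertight", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  ex <- excise(mv, pr, plan_resection(mv, pr, "P2", 5))
  sc <- suture_target_curve(ex$plan$edge_A, ex$plan$edge_B,
                            ex$plan$node_pairing, ex$mesh)
  ps <- plicate_and_suture(ex$mesh, sc, ex$plan, ex$chordae)

  # anterior annulus nodes never move: match program rows to the
  # pre-plication anterior annular coordinates
  ant_ann <- intersect(ex$mesh$annulus_ids,
                       unique(as.vector(
                         ex$mesh$triangles[ex$mesh$leaflet == "anterior", ])))
  prog <- ps$program
  d0 <- sqrt((prog$x1 - prog$x0)^2 + (prog$y1 - prog$y0)^2 +
               (prog$z1 - prog$z0)^2)
  key <- paste(signif(prog$x0, 12), signif(prog$y0, 12), signif(prog$z0, 12))
  antkey <- paste(signif(ex$mesh$nodes[ant_ann, 1], 12),
                  signif(ex$mesh$nodes[ant_ann, 2], 12),
                  signif(ex$mesh$nodes[ant_ann, 3], 12))
  rows <- key %in% antkey
  # commissural posterior end nodes share coordinates with the anterior
  # ends, so the match can pick up at most two extra (also fixed) nodes
  expect_gte(sum(rows), length(ant_ann))
  expect_lt(max(d0[rows]), 1e-9)

  # sutured mesh is a valid manifold, watertight along the suture
  expect_true(validate_valve_mesh(ps$mesh, ps$chordae))
  expect_equal(anyDuplicated(ps$mesh$annulus_ids), 0L)

  # annular outcome: A-P strictly decreases, Al-Pm preserved
  d_pre <- measure_annulus(mv)
  d_post <- measure_annulus(ps$mesh)
  expect_lt(d_post[["ap_diameter_mm"]], d_pre[["ap_diameter_mm"]])
  expect_lt(abs(d_post[["alpm_diameter_mm"]] -
                  d_pre[["alpm_diameter_mm"]]) /
              d_pre[["alpm_diameter_mm"]], 0.02)
  expect_lt(ps$gamma, 1)
})

test_that("ring sizing applies the largest-size-strictly-below rule", {
  expect_equal(as.numeric(size_ring(37, 35)), 34)
  expect_equal(as.numeric(size_ring(35, 37)), 34)   # argument symmetry
  expect_error(size_ring(24, 30), "no catalog size")
  expect_equal(as.numeric(size_ring(25, 40)), 24)
  # monotone non-decreasing in each measurement
  sizes <- vapply(seq(26, 44, by = 2),
                  function(m) as.numeric(size_ring(m, 39)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # anterior leaflet width can bind
  expect_equal(as.numeric(size_ring(39, 39, anterior_leaflet_width = 31)),
               30)
})

test_that("ring profiles scale exactly and close smoothly", {
  r34 <- ring_profile(34)
  expect_equal(r34$intercommissural_mm, 34, tolerance = 0.01 * 34)
  expect_equal(r34$septolateral_mm, 0.75 * 34, tolerance = 0.01 * 34)
  expect_gt(diff(range(r34$polyline[, 3])), 0)      # non-planar saddle
  # anterior peak higher than the posterior one
  ant <- r34$polyline[r34$polyline[, 2] > 0, 3]
  post <- r34$polyline[r34$polyline[, 2] < 0, 3]
  expect_gt(max(ant), max(post))
  # proportional scaling: profile(2s) = 2 profile(s)
  scaled <- ring_profile(28)$polyline * 34 / 28
  expect_equal(scaled, ring_profile(34, catalog = 34)$polyline,
               tolerance = 1e-9)
  # closure: endpoints coincide, C1 across the seam
  expect_equal(r34$polyline[1, ], r34$polyline[nrow(r34$polyline), ],
               tolerance = 1e-9)
  h <- 1e-6
  d0 <- (c(r34$fx(h), r34$fy(h), r34$fz(h)) -
           c(r34$fx(0), r34$fy(0), r34$fz(0))) / h
  d1 <- (c(r34$fx(1), r34$fy(1), r34$fz(1)) -
           c(r34$fx(1 - h), r34$fy(1 - h), r34$fz(1 - h))) / h
  expect_equal(d0, d1, tolerance = 1e-3)
  expect_error(ring_profile(33), "not in catalog")
})

test_that("ring implantation lands every annulus node on the ring", {
  mv <- patient_valve()
  ch <- attach_chordae(mv)
  pr <- induce_prolapse(ch, mv, "P2", 0.7)
  ex <- excise(mv, pr, plan_resection(mv, pr, "P2", 5))
  sc <- suture_target_curve(ex$plan$edge_A, ex$plan$edge_B,
                            ex$plan$node_pairing, ex$mesh)
  ps <- plicate_and_suture(ex$mesh, sc, ex$plan, ex$chordae)
  ring <- ring_profile(34)
  imp <- implant_ring(ps$mesh, ring)
  # point-to-curve distance oracle against a dense ring polyline
  tt <- seq(0, 1, length.out = 4000)
  lmk <- ps$mesh$landmarks
  P <- ps$mesh$nodes
  xhat <- P[lmk[["commissure_al"]], ] - P[lmk[["commissure_pm"]], ]
  xhat <- xhat / sqrt(sum(xhat^2))
  yraw <- P[lmk[["anterior_mid"]], ] - P[lmk[["posterior_mid"]], ]
  yhat <- yraw - sum(yraw * xhat) * xhat
  yhat <- yhat / sqrt(sum(yhat^2))
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  Rot <- cbind(xhat, yhat, zhat)
  ctr <- (P[lmk[["commissure_al"]], ] + P[lmk[["commissure_pm"]], ]) / 2
  dense <- sweep(cbind(ring$fx(tt), ring$fy(tt), ring$fz(tt)) %*% t(Rot),
                 2, ctr, "+")
  ann <- imp$mesh$nodes[imp$mesh$annulus_ids, ]
  d <- vapply(seq_len(nrow(ann)), function(i)
    min(sqrt(rowSums(sweep(dense, 2, ann[i, ])^2))), numeric(1))
  expect_lt(max(d), 0.1)
  # the P1-P2 side of a P2-resected annulus travels farthest
  ad <- imp$annulus_displacements
  expect_gt(mean(ad$displacement_mm[ad$region %in% c("P1", "P2")]),
            mean(ad$displacement_mm[!ad$region %in% c("P1", "P2")]))
})
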