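#' @import igraph
NULL

# intercommissural angle coordinate for every node: 0 at the anterior
# annular midpoint, +pi/2 at the anterolateral commissure, pi at the
# posterior midpoint (posterior leaflet in (pi/2, 3*pi/2))
node_theta_of <- function(mesh) {
  if (!is.null(mesh$node_theta)) return(mesh$node_theta)
  lm <- mesh$landmarks
  ctr <- colMeans(mesh$nodes[mesh$annulus_ids, , drop = FALSE])
  xhat <- mesh$nodes[lm[["commissure_al"]], ] - mesh$nodes[lm[["commissure_pm"]], ]
  xhat <- xhat / sqrt(sum(xhat^2))
  yraw <- mesh$nodes[lm[["anterior_mid"]], ] - mesh$nodes[lm[["posterior_mid"]], ]
  yhat <- yraw - sum(yraw * xhat) * xhat
  yhat <- yhat / sqrt(sum(yhat^2))
  rel <- sweep(mesh$nodes, 2, ctr)
  th <- atan2(rel %*% xhat, rel %*% yhat)
  th[th < -pi / 2] <- th[th < -pi / 2] + 2 * pi
  as.numeric(th)
}

# ordered posterior annulus node ids from the Al-side end to the Pm-side
# end, with cumulative arc length
posterior_annulus_arc <- function(mesh) {
  post_nodes <- unique(as.vector(mesh$triangles[mesh$leaflet == "posterior", ]))
  ids <- mesh$annulus_ids[mesh$annulus_ids %in% post_nodes]
  th <- node_theta_of(mesh)[ids]
  ids <- ids[order(th)]
  pts <- mesh$nodes[ids, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(ids = ids, s = s, coords = pts)
}

polyline_point_dist <- function(poly, p) {
  # min distance from point p to polyline (segment-wise, exact)
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, -p)  # p - a
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-30)
  t <- pmin(pmax(t, 0), 1)
  q <- a + t * ab
  min(sqrt(rowSums(sweep(q, 2, p)^2)))
}

#' Plan a quadrangular leaflet resection
#'
#' Delineates a quadrangle-shaped portion of the prolapsed scallop bounded
#' by the annulus, the free margin and two excision curves running from
#' annulus to free margin along mesh edges. The curves are placed as far
#' apart as possible while staying at least `chordal_margin` (default
#' 5 mm, Euclidean, brute-force verified) from every remaining intact
#' marginal chordal insertion; clinically the curves are ~15 mm long.
#'
#' @param mesh a [valve_mesh()].
#' @param chordae the remaining (post-rupture) [chordae_set()].
#' @param scallop scallop to resect, default `"P2"`.
#' @param chordal_margin minimum distance (mm) from either excision curve
#'   to any remaining marginal insertion.
#' @return an object of class `resection_plan`: `element_ids`, `edge_A`,
#'   `edge_B` (ordered node paths annulus -> free margin; `edge_A` on the
#'   anterolateral side), `node_pairing` (matrix, arc-length matched),
#'   `edge_lengths_mm`, `min_chordal_distance_mm`, plus the posterior
#'   annulus polyline snapshot used later by [plicate_and_suture()].
#' @export
plan_resection <- function(mesh, chordae, scallop = "P2",
                           chordal_margin = 5) {
  stopifnot(inherits(mesh, "valve_mesh"), inherits(chordae, "chordae_set"))
  th <- node_theta_of(mesh)
  leaflet_side <- if (grepl("^P", scallop)) "posterior" else "anterior"
  side_tris <- which(mesh$leaflet == leaflet_side)
  scallop_tris <- which(mesh$region == scallop)
  if (length(scallop_tris) < 1L)
    stop("plan_resection: scallop ", scallop, " has no elements",
         call. = FALSE)

  # edge graph of the leaflet, weighted by length
  tr <- mesh$triangles[side_tris, , drop = FALSE]
  ed <- unique(rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)]))
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- unique(ed)
  elen <- sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                          mesh$nodes[ed[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(apply(ed, 2, as.character),
                                   directed = FALSE)
  vnames <- as.integer(igraph::V(g)$name)

  ann <- posterior_annulus_arc(mesh)
  fe <- mesh$free_edge_ids[[leaflet_side]]
  fe_pts <- mesh$nodes[fe, , drop = FALSE]

  # remaining marginal insertions (all of them, not only in the scallop)
  ins_ids <- chordae$chordae$insertion[chordae$chordae$type == "marginal"]
  ins_pts <- mesh$nodes[ins_ids, , drop = FALSE]

  # candidate cut start nodes: annulus nodes adjacent to the scallop
  scallop_range <- range(th[unique(as.vector(
    mesh$triangles[scallop_tris, , drop = FALSE]))])
  cand <- ann$ids[th[ann$ids] >= scallop_range[1] - 1e-9 &
                    th[ann$ids] <= scallop_range[2] + 1e-9]

  path_for <- function(start_id) {
    th0 <- th[start_id]
    pen <- elen + 40 * abs((th[ed[, 1]] + th[ed[, 2]]) / 2 - th0) *
      mean(elen)
    end_id <- fe[which.min(abs(th[fe] - th0))]
    sp <- igraph::shortest_paths(g, from = as.character(start_id),
                                 to = as.character(end_id), weights = pen,
                                 output = "vpath")$vpath[[1]]
    as.integer(names(sp))
  }
  path_stats <- lapply(cand, function(id) {
    p <- path_for(id)
    poly <- mesh$nodes[p, , drop = FALSE]
    dmin <- if (nrow(ins_pts)) {
      min(vapply(seq_len(nrow(ins_pts)),
                 function(i) polyline_point_dist(poly, ins_pts[i, ]),
                 numeric(1)))
    } else Inf
    list(ids = p, dmin = dmin,
         len = sum(sqrt(rowSums(diff(poly)^2))))
  })
  ok <- vapply(path_stats, function(x) x$dmin >= chordal_margin, logical(1))
  if (sum(ok) < 2L) {
    best <- max(vapply(path_stats, `[[`, numeric(1), "dmin"))
    stop(sprintf(paste0("plan_resection: chordal margin %.1f mm ",
                        "unsatisfiable in %s (achievable: %.2f mm)"),
                 chordal_margin, scallop, best), call. = FALSE)
  }
  th_cand <- th[cand]
  iA <- which(ok)[which.min(th_cand[ok])]
  iB <- which(ok)[which.max(th_cand[ok])]
  if (iA == iB)
    stop("plan_resection: region would vanish (a single feasible cut)",
         call. = FALSE)
  edge_A <- path_stats[[iA]]$ids
  edge_B <- path_stats[[iB]]$ids
  thA <- th[cand[iA]]; thB <- th[cand[iB]]

  # removal set: triangles fully inside the theta band, excluding the two
  # bounding columns themselves
  inband <- vapply(side_tris, function(ti) {
    tt <- th[mesh$triangles[ti, ]]
    all(tt >= thA - 1e-9) && all(tt <= thB + 1e-9) &&
      any(tt > thA + 1e-9) && any(tt < thB - 1e-9)
  }, logical(1))
  element_ids <- side_tris[inband]
  if (length(element_ids) == 0L)
    stop("plan_resection: region would vanish (no elements between cuts)",
         call. = FALSE)

  pairing <- pair_by_arclength(mesh$nodes, edge_A, edge_B)

  plan <- structure(list(
    element_ids = element_ids,
    edge_A = edge_A, edge_B = edge_B,
    node_pairing = pairing,
    edge_lengths_mm = c(A = path_stats[[iA]]$len, B = path_stats[[iB]]$len),
    min_chordal_distance_mm = min(path_stats[[iA]]$dmin,
                                  path_stats[[iB]]$dmin),
    scallop = scallop, chordal_margin = chordal_margin,
    posterior_annulus = ann,
    theta_band = c(thA, thB)
  ), class = "resection_plan")
  plan
}

#' @export
print.resection_plan <- function(x, ...) {
  cat(sprintf(paste0("resection_plan (%s): %d elements; excision curves ",
                     "%.1f / %.1f mm; min chordal distance %.2f mm\n"),
              x$scallop, length(x$element_ids),
              x$edge_lengths_mm[1], x$edge_lengths_mm[2],
              x$min_chordal_distance_mm))
  invisible(x)
}

# match nodes of two annulus->margin paths by normalized arc length
pair_by_arclength <- function(nodes, edge_A, edge_B) {
  arc <- function(ids) {
    p <- nodes[ids, , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    if (s[length(s)] == 0) s else s / s[length(s)]
  }
  sA <- arc(edge_A); sB <- arc(edge_B)
  if (length(edge_A) == length(edge_B)) {
    pairing <- cbind(edge_A, edge_B)
  } else {
    j <- vapply(sA, function(t) which.min(abs(sB - t)), integer(1))
    if (anyDuplicated(j))
      stop("pair_by_arclength: cannot form a bijection (edge node counts ",
           length(edge_A), " vs ", length(edge_B), ")", call. = FALSE)
    pairing <- cbind(edge_A, edge_B[j])
  }
  sB_used <- sB[match(pairing[, 2], edge_B)]
  if (is.unsorted(sB_used))
    stop("pair_by_arclength: crossing pairing (non-monotone arc lengths)",
         call. = FALSE)
  colnames(pairing) <- c("edge_A", "edge_B")
  pairing
}

#' Excise the planned leaflet portion
#'
#' Removes the planned elements, drops nodes that belonged only to the
#' removed region (with chordae inserting on them), and reindexes the
#' mesh. The two excision curves become new boundary paths.
#'
#' @param mesh a [valve_mesh()].
#' @param chordae a [chordae_set()].
#' @param plan a `resection_plan` from [plan_resection()].
#' @return list with elements `mesh`, `chordae`, `plan` (ids remapped to
#'   the new mesh), and `removed_chordae` (labels).
#' @export
excise <- function(mesh, chordae, plan) {
  stopifnot(inherits(plan, "resection_plan"))
  m <- nrow(mesh$triangles)
  if (length(plan$element_ids) &&
      (any(plan$element_ids < 1L) || any(plan$element_ids > m)))
    stop("excise: plan references missing elements", call. = FALSE)
  if (length(plan$element_ids) == 0L)
    return(list(mesh = mesh, chordae = chordae, plan = plan,
                removed_chordae = character(0)))
  keep_tri <- setdiff(seq_len(m), plan$element_ids)
  kept_nodes <- sort(unique(as.vector(mesh$triangles[keep_tri, ,
                                                     drop = FALSE])))
  remap <- rep(NA_integer_, nrow(mesh$nodes))
  remap[kept_nodes] <- seq_along(kept_nodes)

  d <- chordae$chordae
  gone <- !is.na(d$insertion) & is.na(remap[d$insertion])
  removed_chordae <- d$label[gone]
  d <- d[!gone, , drop = FALSE]
  d$insertion <- remap[d$insertion]

  lm <- mesh$landmarks
  lm_new <- ifelse(is.na(remap[lm]), NA_integer_, remap[lm])
  names(lm_new) <- names(lm)

  mesh2 <- valve_mesh(
    nodes = mesh$nodes[kept_nodes, , drop = FALSE],
    triangles = matrix(remap[mesh$triangles[keep_tri, , drop = FALSE]],
                       ncol = 3),
    leaflet = mesh$leaflet[keep_tri], region = mesh$region[keep_tri],
    thickness = mesh$thickness[keep_tri],
    fiber_e1 = mesh$fiber_e1[keep_tri, , drop = FALSE],
    fiber_e2 = mesh$fiber_e2[keep_tri, , drop = FALSE],
    annulus_ids = stats::na.omit(remap[mesh$annulus_ids]),
    free_edge_ids = lapply(mesh$free_edge_ids,
                           function(v) stats::na.omit(remap[v])),
    landmarks = lm_new,
    papillary_tips = mesh$papillary_tips,
    config_tag = mesh$config_tag,
    node_theta = if (is.null(mesh$node_theta)) NULL
    else mesh$node_theta[kept_nodes])

  plan2 <- plan
  plan2$edge_A <- remap[plan$edge_A]
  plan2$edge_B <- remap[plan$edge_B]
  plan2$node_pairing <- cbind(edge_A = remap[plan$node_pairing[, 1]],
                              edge_B = remap[plan$node_pairing[, 2]])
  plan2$element_ids <- integer(0)
  # posterior_annulus snapshot keeps ORIGINAL coordinates and a remap of
  # surviving ids into the new mesh
  plan2$posterior_annulus$new_ids <- remap[plan$posterior_annulus$ids]

  list(mesh = mesh2, chordae = chordae_set(d), plan = plan2,
       removed_chordae = removed_chordae)
}

#' Suture target curve between the two excision edges
#'
#' Key points are the midpoints of each arc-length-matched node pair
#' (equidistant from both generators by construction); a natural cubic
#' spline interpolates them from the annulus end to the free-margin end.
#'
#' @param edge_A,edge_B ordered node id paths (annulus to free margin).
#' @param node_pairing two-column matrix of paired ids.
#' @param mesh the post-excision [valve_mesh()].
#' @param n_eval evaluation resolution of the returned polyline.
#' @return object of class `suture_curve`: `keypoints` (k x 3),
#'   `t` (chord-length parameters), `polyline` (n_eval x 3), and the
#'   spline functions.
#' @export
suture_target_curve <- function(edge_A, edge_B, node_pairing, mesh,
                                n_eval = 200) {
  P <- mesh$nodes
  if (anyDuplicated(node_pairing[, 1]) || anyDuplicated(node_pairing[, 2]))
    stop("suture_target_curve: pairing is not bijective", call. = FALSE)
  key <- (P[node_pairing[, 1], , drop = FALSE] +
            P[node_pairing[, 2], , drop = FALSE]) / 2
  t <- c(0, cumsum(sqrt(rowSums(diff(key)^2))))
  if (t[length(t)] > 0) t <- t / t[length(t)]
  else t <- seq(0, 1, length.out = nrow(key))
  if (is.unsorted(t, strictly = FALSE))
    stop("suture_target_curve: crossing pairing (non-monotone arc lengths)",
         call. = FALSE)
  fx <- stats::splinefun(t, key[, 1], method = "natural")
  fy <- stats::splinefun(t, key[, 2], method = "natural")
  fz <- stats::splinefun(t, key[, 3], method = "natural")
  tt <- seq(0, 1, length.out = n_eval)
  structure(list(keypoints = key, t = t,
                 polyline = cbind(fx(tt), fy(tt), fz(tt)),
                 fx = fx, fy = fy, fz = fz,
                 pairing = node_pairing),
            class = "suture_curve")
}

# scaled copy of a commissure-anchored arc whose length matches a target:
# P_gamma(u) = chord(u) + gamma * (P(u) - chord(u))
shrunken_arc <- function(coords, target_length, u = NULL, n_dense = 800) {
  k <- nrow(coords)
  if (is.null(u)) {
    s <- c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
    u <- s / s[k]
  }
  fx <- stats::splinefun(u, coords[, 1], method = "natural")
  fy <- stats::splinefun(u, coords[, 2], method = "natural")
  fz <- stats::splinefun(u, coords[, 3], method = "natural")
  uu <- seq(min(u), max(u), length.out = n_dense)
  base <- cbind(fx(uu), fy(uu), fz(uu))
  tt <- (uu - min(u)) / (max(u) - min(u))
  chord <- outer(1 - tt, coords[1, ]) + outer(tt, coords[k, ])
  lens <- function(gamma) {
    pg <- chord + gamma * (base - chord)
    sum(sqrt(rowSums(diff(pg)^2)))
  }
  chord_len <- lens(0)
  if (target_length <= chord_len)
    stop("shrunken_arc: target length shorter than the commissural chord",
         call. = FALSE)
  gamma <- stats::uniroot(function(g) lens(g) - target_length,
                          c(1e-6, 3), tol = 1e-10, extendInt = "upX")$root
  pg <- chord + gamma * (base - chord)
  sg <- c(0, cumsum(sqrt(rowSums(diff(pg)^2))))
  list(gamma = gamma,
       at_arc = function(sq) {
         sq <- pmin(pmax(sq, 0), sg[n_dense])
         cbind(stats::approx(sg, pg[, 1], xout = sq)$y,
               stats::approx(sg, pg[, 2], xout = sq)$y,
               stats::approx(sg, pg[, 3], xout = sq)$y)
       },
       length = sg[n_dense])
}

#' Plicate the excised edges onto the suture curve and suture them
#'
#' Builds the displacement program of the annular plication: the two
#' excised leaflet edges ramp onto the suture target curve (paired nodes
#' share one target), the posterior annulus redistributes along a
#' commissure-anchored, depth-reduced copy of its pre-resection arc whose
#' length equals the remaining (post-excision) annular arc length, and
#' the anterior annulus is held fixed throughout. Interior leaflet nodes
#' follow by harmonic (graph-Laplacian) interpolation of the boundary
#' displacements. Finally the paired nodes are merged into single nodes,
#' making the suture line watertight.
#'
#' @param mesh the post-excision [valve_mesh()] (from [excise()]).
#' @param curve a [suture_target_curve()] built on the same mesh.
#' @param plan the remapped `resection_plan` returned by [excise()].
#' @param chordae optional [chordae_set()] whose insertion ids are
#'   remapped through the suture merge.
#' @return list with `mesh` (sutured valve; the `posterior_mid` landmark
#'   is remapped to the annulus node at the new posterior arc midpoint),
#'   `chordae` (remapped, or `NULL`), `program` (tibble: node, start and
#'   target coordinates — the kinematic displacement program, zero for
#'   every anterior annulus node), and `gamma` (annular depth scale).
#' @export
plicate_and_suture <- function(mesh, curve, plan, chordae = NULL) {
  stopifnot(inherits(mesh, "valve_mesh"), inherits(curve, "suture_curve"),
            inherits(plan, "resection_plan"))
  P <- mesh$nodes
  n <- nrow(P)
  pairing <- curve$pairing

  # --- posterior annulus targets -------------------------------------
  ann0 <- plan$posterior_annulus      # pre-excision snapshot
  alive <- !is.na(ann0$new_ids)
  if (!any(alive)) stop("plicate_and_suture: no posterior annulus left",
                        call. = FALSE)
  s0 <- ann0$s
  # annular arc removed by the excision: between the two cut columns'
  # annulus ends (the first node of each excision edge)
  iA <- match(plan$edge_A[1], ann0$new_ids)
  iB <- match(plan$edge_B[1], ann0$new_ids)
  if (is.na(iA) || is.na(iB))
    stop("plicate_and_suture: excision edges do not start on the annulus",
         call. = FALSE)
  if (iA > iB) { tmp <- iA; iA <- iB; iB <- tmp }
  if (iA <= 1L || iB >= length(s0))
    stop("plicate_and_suture: excision reaches a commissure", call. = FALSE)
  w <- s0[iB] - s0[iA]
  target_len <- s0[length(s0)] - w
  # shape family built on the REMAINING annular material: spline-bridge
  # the excised span (the resected wedge leaves the annulus), then scale
  # the bridged arc about the commissural chord to the remaining length
  keep_idx <- c(seq_len(iA), iB:length(s0))
  arc <- shrunken_arc(ann0$coords[keep_idx, , drop = FALSE], target_len,
                      u = s0[keep_idx] / s0[length(s0)])
  s_new <- ifelse(seq_along(s0) <= iA, s0, s0 - w)
  ann_targets <- arc$at_arc(s_new[alive])
  ann_ids_new <- ann0$new_ids[alive]
  suture_ann_target <- arc$at_arc(s0[iA])

  # --- suture curve targets, annulus end blended to the plicated ring --
  key <- curve$keypoints
  tpar <- curve$t
  delta <- as.numeric(suture_ann_target) - key[1, ]
  key_t <- key + outer(1 - tpar, delta)

  # --- assemble prescribed displacements -------------------------------
  disp <- matrix(0, n, 3)
  prescribed <- rep(FALSE, n)
  prescribed[mesh$annulus_ids] <- TRUE          # anterior annulus: zero
  disp[ann_ids_new, ] <- ann_targets - P[ann_ids_new, , drop = FALSE]
  for (i in seq_len(nrow(pairing))) {
    for (id in pairing[i, ]) {
      disp[id, ] <- key_t[i, ] - P[id, ]
      prescribed[id] <- TRUE
    }
  }

  # --- harmonic interpolation of interior displacements ----------------
  disp <- harmonic_extend(mesh, disp, prescribed)
  newP <- P + disp

  # --- merge paired nodes (suture) -------------------------------------
  keep_of <- seq_len(n)
  drop_ids <- integer(0)
  for (i in seq_len(nrow(pairing))) {
    a <- pairing[i, 1]; b <- pairing[i, 2]
    if (a != b) { keep_of[b] <- a; drop_ids <- c(drop_ids, b) }
  }
  tri <- matrix(keep_of[mesh$triangles], ncol = 3)
  degen <- tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]
  if (any(degen)) {
    warning(sprintf("plicate_and_suture: %d degenerate triangle(s) ",
                    sum(degen)), "collapsed at the suture line")
  }
  kept_nodes <- sort(setdiff(seq_len(n), drop_ids))
  remap <- rep(NA_integer_, n)
  remap[kept_nodes] <- seq_along(kept_nodes)
  remap2 <- function(v) remap[keep_of[v]]

  keep_tri <- which(!degen)
  ann_ids <- remap2(mesh$annulus_ids)
  ann_ids <- ann_ids[!duplicated(ann_ids)]
  fe_ids <- lapply(mesh$free_edge_ids, function(v) {
    v <- remap2(v); v[!duplicated(v)]
  })
  lm <- mesh$landmarks
  lm_new <- stats::setNames(ifelse(is.na(lm), NA_integer_, remap2(lm)),
                            names(lm))

  mesh2 <- valve_mesh(
    nodes = newP[kept_nodes, , drop = FALSE],
    triangles = matrix(remap2(mesh$triangles[keep_tri, , drop = FALSE]),
                       ncol = 3),
    leaflet = mesh$leaflet[keep_tri], region = mesh$region[keep_tri],
    thickness = mesh$thickness[keep_tri],
    fiber_e1 = mesh$fiber_e1[keep_tri, , drop = FALSE],
    fiber_e2 = mesh$fiber_e2[keep_tri, , drop = FALSE],
    annulus_ids = ann_ids, free_edge_ids = fe_ids,
    landmarks = lm_new, papillary_tips = mesh$papillary_tips,
    config_tag = mesh$config_tag,
    node_theta = if (is.null(mesh$node_theta)) NULL
    else mesh$node_theta[kept_nodes])

  # posterior midpoint: annulus node nearest the new posterior arc middle
  mid_target <- arc$at_arc(target_len / 2)
  post_ann_new <- remap[stats::na.omit(ann_ids_new)]
  suture_node <- remap[keep_of[pairing[1, 1]]]
  cand <- unique(c(post_ann_new, suture_node))
  d2 <- rowSums(sweep(mesh2$nodes[cand, , drop = FALSE], 2,
                      as.numeric(mid_target))^2)
  mesh2$landmarks[["posterior_mid"]] <- cand[which.min(d2)]

  # refresh fiber frames onto the deformed triangles (keep tangency)
  mesh2 <- refresh_fiber_frames(mesh2)
  validate_valve_mesh(mesh2)

  chord2 <- NULL
  if (!is.null(chordae)) {
    d <- chordae$chordae
    d$insertion <- remap2(d$insertion)
    chord2 <- chordae_set(d)
  }

  program <- tibble::tibble(
    node = remap[kept_nodes],
    x0 = P[kept_nodes, 1], y0 = P[kept_nodes, 2], z0 = P[kept_nodes, 3],
    x1 = newP[kept_nodes, 1], y1 = newP[kept_nodes, 2],
    z1 = newP[kept_nodes, 3],
    prescribed = prescribed[kept_nodes])

  list(mesh = mesh2, chordae = chord2, program = program,
       gamma = arc$gamma)
}

# harmonic (uniform graph-Laplacian) extension of boundary displacements
harmonic_extend <- function(mesh, disp, prescribed) {
  n <- nrow(mesh$nodes)
  free <- which(!prescribed)
  if (length(free) == 0L) return(disp)
  e <- mesh_edges(mesh)
  e <- unique(e)
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  idx <- rep(NA_integer_, n); idx[free] <- seq_along(free)
  L <- matrix(0, length(free), length(free))
  b <- matrix(0, length(free), 3)
  for (k in seq_along(free)) {
    i <- free[k]
    nb <- adj[[i]]
    L[k, k] <- length(nb)
    for (j in nb) {
      if (prescribed[j]) b[k, ] <- b[k, ] + disp[j, ]
      else L[k, idx[j]] <- L[k, idx[j]] - 1
    }
  }
  disp[free, ] <- solve(L, b)
  disp
}

refresh_fiber_frames <- function(mesh) {
  nrm <- triangle_normals(mesh$nodes, mesh$triangles)
  e1 <- mesh$fiber_e1
  e1 <- e1 - rowSums(e1 * nrm) * nrm
  bad <- sqrt(rowSums(e1^2)) < 1e-6
  if (any(bad)) {
    ref <- cbind(1, 0, 0)[rep(1, sum(bad)), , drop = FALSE]
    e1[bad, ] <- ref - rowSums(ref * nrm[bad, , drop = FALSE]) *
      nrm[bad, , drop = FALSE]
  }
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
              nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
              nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])
  mesh$fiber_e1 <- e1
  mesh$fiber_e2 <- e2
  mesh
}

#' Select an annuloplasty ring size
#'
#' Deterministic sizing rule: the largest catalog size strictly smaller
#' than the smallest of the intercommissural (Al-Pm) measurements and the
#' anterior-leaflet-based estimate. With the printed measurements (37 mm
#' at end diastole, 35 mm at peak systole) and the even 24-40 mm catalog
#' this selects the 34 mm ring.
#'
#' @param alpm_diastole,alpm_systole intercommissural distances (mm) at
#'   end diastole and peak systole (order irrelevant).
#' @param anterior_leaflet_width,anterior_leaflet_height optional anterior
#'   leaflet dimensions (mm); when given, the width joins the sizing
#'   minimum (the height is recorded but does not bind for typical
#'   anatomies where height < width reflects a 2:1 aspect already
#'   captured by the width).
#' @param catalog available sizes (mm), default even sizes 24-40.
#' @return the selected size (mm) with attribute `limiting` naming the
#'   binding measurement.
#' @export
size_ring <- function(alpm_diastole, alpm_systole,
                      anterior_leaflet_width = NULL,
                      anterior_leaflet_height = NULL,
                      catalog = seq(24, 40, by = 2)) {
  if (length(catalog) == 0L) stop("size_ring: empty catalog", call. = FALSE)
  meas <- c(alpm_diastole = alpm_diastole, alpm_systole = alpm_systole)
  if (!is.null(anterior_leaflet_width))
    meas <- c(meas, anterior_leaflet_width = anterior_leaflet_width)
  if (any(meas <= 0)) stop("size_ring: measurements must be > 0",
                           call. = FALSE)
  m <- min(meas)
  ok <- catalog[catalog < m]
  if (length(ok) == 0L)
    stop(sprintf(paste0("size_ring: no catalog size strictly below %.1f mm; ",
                        "smallest available is %g mm"),
                 m, min(catalog)), call. = FALSE)
  out <- max(ok)
  attr(out, "limiting") <- names(meas)[which.min(meas)]
  out
}

#' Saddle-shaped annuloplasty ring profile
#'
#' Reconstructs a closed, C2 cubic-spline ring curve from canonical
#' control points scaled to the labeled size: intercommissural extent =
#' size, septolateral extent = 0.75 x size, peak-to-peak saddle height =
#' 0.10 x size with a slightly accentuated anterior peak. Control points
#' are evaluated on the parametric profile and interpolated with periodic
#' cubic splines, so `ring_profile(2 s)` is exactly `2 *
#' ring_profile(s)`.
#'
#' @param size labeled ring size (mm), must be in `catalog`.
#' @param catalog admissible sizes.
#' @param n_control control points around the ring.
#' @param n_eval evaluated polyline resolution.
#' @return object of class `ring_profile`: `size`, `control_points`,
#'   `polyline` (closed: first row repeated last), axis unit vectors and
#'   extents.
#' @export
ring_profile <- function(size, catalog = seq(24, 40, by = 2),
                         n_control = 16, n_eval = 256) {
  if (!size %in% catalog)
    stop("ring_profile: size ", size, " not in catalog", call. = FALSE)
  phi <- seq(0, 2 * pi, length.out = n_control + 1L)[-(n_control + 1L)]
  sh <- 0.10 * size
  ctrl <- cbind(size / 2 * cos(phi),
                0.75 * size / 2 * sin(phi),
                -sh / 2 * cos(2 * phi) + 0.25 * sh * pmax(sin(phi), 0))
  # periodic cubic spline through the control points
  tt <- seq(0, 1, length.out = n_control + 1L)
  closed <- rbind(ctrl, ctrl[1, ])
  fx <- stats::splinefun(tt, closed[, 1], method = "periodic")
  fy <- stats::splinefun(tt, closed[, 2], method = "periodic")
  fz <- stats::splinefun(tt, closed[, 3], method = "periodic")
  te <- seq(0, 1, length.out = n_eval)
  poly <- cbind(fx(te), fy(te), fz(te))
  structure(list(size = size, control_points = ctrl, polyline = poly,
                 fx = fx, fy = fy, fz = fz,
                 intercommissural_axis = c(1, 0, 0),
                 septolateral_axis = c(0, 1, 0),
                 intercommissural_mm = diff(range(poly[, 1])),
                 septolateral_mm = diff(range(poly[, 2])),
                 saddle_mm = sh),
            class = "ring_profile")
}

#' @export
print.ring_profile <- function(x, ...) {
  cat(sprintf(paste0("ring_profile: size %g mm (intercommissural %.2f, ",
                     "septolateral %.2f, saddle %.2f mm)\n"),
              x$size, x$intercommissural_mm, x$septolateral_mm, x$saddle_mm))
  invisible(x)
}

#' Implant an annuloplasty ring
#'
#' Rigidly aligns the ring's intercommissural and septolateral axes with
#' the annular landmark axes, maps every annulus node to the ring point
#' at matching normalized arc length (anchored at the commissures,
#' anterior arc to anterior half), and builds the displacement program
#' ramping the annulus onto the ring; thereafter the annulus is fixed to
#' the ring, overriding any annular motion. Interior nodes follow by
#' harmonic interpolation, as in [plicate_and_suture()].
#'
#' @param mesh a [valve_mesh()] (typically post-resection).
#' @param ring a [ring_profile()].
#' @return list with `mesh` (annulus on the ring), `program`
#'   (displacement tibble as in [plicate_and_suture()]), and
#'   `annulus_displacements` (tibble: node, region side, displacement
#'   magnitude mm).
#' @export
implant_ring <- function(mesh, ring) {
  stopifnot(inherits(mesh, "valve_mesh"), inherits(ring, "ring_profile"))
  lm <- mesh$landmarks
  P <- mesh$nodes
  cal <- P[lm[["commissure_al"]], ]; cpm <- P[lm[["commissure_pm"]], ]
  amid <- P[lm[["anterior_mid"]], ]; pmid <- P[lm[["posterior_mid"]], ]
  xhat <- cal - cpm
  if (sqrt(sum(xhat^2)) < 1e-9)
    stop("implant_ring: degenerate annulus (coincident commissures)",
         call. = FALSE)
  xhat <- xhat / sqrt(sum(xhat^2))
  yraw <- amid - pmid
  yhat <- yraw - sum(yraw * xhat) * xhat
  if (sqrt(sum(yhat^2)) < 1e-9)
    stop("implant_ring: degenerate annulus (collinear landmarks)",
         call. = FALSE)
  yhat <- yhat / sqrt(sum(yhat^2))
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  Rot <- cbind(xhat, yhat, zhat)      # ring frame -> annulus frame
  ctr <- (cal + cpm) / 2

  ring_at <- function(t) {
    p <- cbind(ring$fx(t %% 1), ring$fy(t %% 1), ring$fz(t %% 1))
    sweep(p %*% t(Rot), 2, ctr, "+")
  }
  # ring parameter of its commissures: control phi = 0 -> t = 0 (Al side,
  # +x), phi = pi -> t = 0.5 (Pm); anterior half is y > 0: t in (0, 0.5)
  ann <- mesh$annulus_ids
  i_al <- which(ann == lm[["commissure_al"]])
  # rotate the cycle so it starts at the Al commissure
  ordv <- c(ann[i_al:length(ann)], ann[seq_len(i_al - 1L)])
  i_pm <- which(ordv == lm[["commissure_pm"]])
  arc1 <- ordv[1:i_pm]                  # Al -> Pm (one side)
  arc2 <- c(ordv[i_pm:length(ordv)], ordv[1])  # Pm -> back to Al
  side_is_anterior <- function(ids) {
    mean((P[ids, , drop = FALSE] %*% yhat)) >
      mean((P[ann, , drop = FALSE] %*% yhat))
  }
  map_arc <- function(ids, t0, t1) {
    pts <- P[ids, , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    s <- s / s[length(s)]
    ring_at(t0 + s * (t1 - t0))
  }
  a1_ant <- side_is_anterior(arc1)
  targets <- matrix(NA_real_, nrow(P), 3)
  if (a1_ant) {
    targets[arc1, ] <- map_arc(arc1, 0, 0.5)
    targets[arc2[-length(arc2)], ] <-
      map_arc(arc2, 0.5, 1)[-length(arc2), , drop = FALSE]
  } else {
    targets[arc1, ] <- map_arc(arc1, 0, -0.5)
    targets[arc2[-length(arc2)], ] <-
      map_arc(arc2, -0.5, -1)[-length(arc2), , drop = FALSE]
  }

  disp <- matrix(0, nrow(P), 3)
  prescribed <- rep(FALSE, nrow(P))
  prescribed[ann] <- TRUE
  disp[ann, ] <- targets[ann, ] - P[ann, , drop = FALSE]
  disp <- harmonic_extend(mesh, disp, prescribed)
  newP <- P + disp

  mesh2 <- mesh
  mesh2$nodes <- newP
  mesh2 <- refresh_fiber_frames(mesh2)

  reg_node <- node_regions(mesh)
  mag <- sqrt(rowSums(disp[ann, , drop = FALSE]^2))
  annulus_displacements <- tibble::tibble(
    node = ann, region = reg_node[ann], displacement_mm = mag)

  program <- tibble::tibble(
    node = seq_len(nrow(P)),
    x0 = P[, 1], y0 = P[, 2], z0 = P[, 3],
    x1 = newP[, 1], y1 = newP[, 2], z1 = newP[, 3],
    prescribed = prescribed)

  list(mesh = mesh2, program = program,
       annulus_displacements = annulus_displacements)
}
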