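#' Build a synthetic labeled valve mesh
#'
#' Parametric generator standing in for patient-derived (3D TEE segmented)
#' valve geometry. Leaflet surfaces are smooth tensor-product patches
#' lofted from a saddle-shaped annulus to a parametric free-edge curve;
#' region labels partition each leaflet into thirds along the
#' intercommissural direction (Carpentier A1-A3 / P1-P3, anterolateral to
#' posteromedial).
#'
#' The annulus is a smooth closed curve with the requested
#' antero-posterior (A-P) and anterolateral-posteromedial (Al-Pm)
#' diameters: commissures at `(+/- alpm/2, 0, -saddle/2)`, anterior and
#' posterior midpoints on the y axis at heights `+saddle/2`. The anterior
#' annular arc carries `ap_fraction_anterior` of the A-P span. The
#' ventricle is at `z < 0`.
#'
#' @param ap_diameter A-P annular diameter (mm).
#' @param alpm_diameter Al-Pm (intercommissural) annular diameter (mm).
#' @param saddle_height peak-to-peak annular saddle height (mm).
#' @param leaflet_height_anterior,leaflet_height_posterior mid-leaflet
#'   heights (mm): the surface distance from annulus to free margin at the
#'   leaflet midline. Heights taper toward the commissures.
#' @param ap_fraction_anterior fraction of the A-P span on the anterior
#'   side of the commissural axis.
#' @param inplane_anterior,drop_anterior,inplane_posterior,drop_posterior
#'   leaflet shape fractions: in-plane travel and ventricular drop of the
#'   free margin, per unit leaflet height. The posterior defaults describe
#'   a steeply hanging, redundant posterior leaflet as seen with
#'   degenerative prolapse.
#' @param posterior_bulge local posterior annular bulge amplitude (mm) at
#'   the P2 midpoint — the asymmetric annular dilation that accompanies
#'   posterior prolapse; part of the requested A-P diameter (the total
#'   A-P span is preserved exactly).
#' @param bulge_sigma angular width (radians) of the posterior bulge.
#' @param posterior_margin_ripple amplitude (mm) of the scalloped
#'   undulation of the posterior free margin (three lobes), emulating the
#'   redundant billowing margin of a degenerative flail leaflet; adds
#'   free-margin arc length without changing leaflet height.
#' @param focus_y_anterior,focus_y_posterior y position (as a fraction of
#'   the A-P diameter) of the focal point each leaflet's free margin is
#'   drawn toward. A posterior focus well anterior of the annulus models
#'   the everted, flattened margin of a flail segment.
#' @param n_circ number of nodes along the annulus per leaflet (odd so the
#'   midline is sampled exactly).
#' @param n_rad_anterior,n_rad_posterior number of node rows from annulus
#'   (row 0) to free margin.
#' @param papillary_depth depth of the papillary tips below the annular
#'   plane (mm).
#' @param jitter_sd standard deviation of seeded surface jitter (mm);
#'   default 0 gives the deterministic nominal geometry.
#' @param seed integer seed for the jitter stream (recorded even when
#'   unused).
#' @param config_tag configuration label, default `"end_diastole"` (the
#'   open configuration virtual surgery operates on).
#' @return a [valve_mesh()] satisfying all mesh invariants; measured A-P
#'   and Al-Pm diameters match the request exactly by construction.
#' @export
#' @examples
#' mv <- build_synthetic_valve(ap_diameter = 43, alpm_diameter = 37)
#' measure_annulus(mv)
build_synthetic_valve <- function(ap_diameter = 43, alpm_diameter = 37,
                                  saddle_height = 5,
                                  leaflet_height_anterior = 26,
                                  leaflet_height_posterior = 16,
                                  ap_fraction_anterior = 0.4,
                                  n_circ = 33,
                                  n_rad_anterior = 9, n_rad_posterior = 7,
                                  inplane_anterior = 0.8,
                                  drop_anterior = 0.6,
                                  inplane_posterior = 0.30,
                                  drop_posterior = 0.85,
                                  posterior_bulge = 6.5, bulge_sigma = 0.30,
                                  posterior_margin_ripple = 3,
                                  focus_y_anterior = -0.12,
                                  focus_y_posterior = 0.3,
                                  papillary_depth = 22,
                                  jitter_sd = 0, seed = 1L,
                                  config_tag = "end_diastole") {
  if (ap_diameter <= 0 || alpm_diameter <= 0 || saddle_height < 0 ||
      leaflet_height_anterior <= 0 || leaflet_height_posterior <= 0)
    stop("build_synthetic_valve: dimensions must be positive", call. = FALSE)
  if (n_circ < 10 || n_rad_anterior < 3 || n_rad_posterior < 3)
    stop("build_synthetic_valve: resolution too coarse to honor the ",
         "region partition (need n_circ >= 10, n_rad >= 3)", call. = FALSE)
  if (n_circ %% 2 == 0) n_circ <- n_circ + 1L

  Rx <- alpm_diameter / 2
  b_ant <- ap_fraction_anterior * ap_diameter
  b_post <- (1 - ap_fraction_anterior) * ap_diameter - posterior_bulge
  if (b_post <= 0)
    stop("build_synthetic_valve: posterior_bulge too large for the A-P span",
         call. = FALSE)
  hs <- saddle_height

  annulus_pt <- function(theta) {
    w <- (1 + cos(theta)) / 2
    b <- b_ant * w + b_post * (1 - w)
    bulge <- posterior_bulge * exp(-0.5 * ((theta - pi) / bulge_sigma)^2)
    cbind(Rx * sin(theta), b * cos(theta) - bulge,
          hs / 2 * cos(2 * theta))
  }

  # free-edge target: in-plane travel toward a leaflet-specific focal
  # point plus a ventricular drop; fractions chosen so the chordwise
  # annulus-to-margin distance approximates the leaflet height
  build_leaflet <- function(theta, h_profile, n_rad, leaflet,
                            inplane_frac, drop_frac, focus_y, ripple = 0) {
    ann <- annulus_pt(theta)
    nv <- n_rad
    dirx <- -ann[, 1]
    diry <- focus_y - ann[, 2]
    dl <- sqrt(dirx^2 + diry^2)
    dl[dl < 1e-9] <- 1
    u <- (theta - theta[1]) / (theta[length(theta)] - theta[1])
    nodes <- vector("list", nv)
    for (r in seq_len(nv)) {
      v <- (r - 1) / (nv - 1)
      reach <- inplane_frac * h_profile * v
      sag <- 0.12 * h_profile * sin(pi * v)
      wave <- ripple * v^2 * sin(6 * pi * u)
      nodes[[r]] <- cbind(ann[, 1] + reach * dirx / dl,
                          ann[, 2] + reach * diry / dl,
                          ann[, 3] - drop_frac * h_profile * v - sag + wave)
    }
    do.call(rbind, nodes)
  }

  th_a <- seq(-pi / 2, pi / 2, length.out = n_circ)
  th_p <- seq(pi / 2, 3 * pi / 2, length.out = n_circ)
  taper <- function(theta, th0, th1, floor_frac = 0.35) {
    s <- (theta - th0) / (th1 - th0)
    floor_frac + (1 - floor_frac) * sin(pi * s)
  }
  h_a <- leaflet_height_anterior * taper(th_a, -pi / 2, pi / 2)
  h_p <- leaflet_height_posterior * taper(th_p, pi / 2, 3 * pi / 2)

  nodes_a <- build_leaflet(th_a, h_a, n_rad_anterior, "anterior",
                           inplane_frac = inplane_anterior,
                           drop_frac = drop_anterior,
                           focus_y = focus_y_anterior * ap_diameter)
  nodes_p <- build_leaflet(th_p, h_p, n_rad_posterior, "posterior",
                           inplane_frac = inplane_posterior,
                           drop_frac = drop_posterior,
                           focus_y = focus_y_posterior * ap_diameter,
                           ripple = posterior_margin_ripple)

  set.seed(as.integer(seed))
  if (jitter_sd > 0) {
    # jitter interior rows only; the annulus and landmarks stay exact
    jit <- function(nodes, n_circ, n_rad) {
      j <- matrix(stats::rnorm(length(nodes), sd = jitter_sd),
                  nrow = nrow(nodes))
      j[seq_len(n_circ), ] <- 0
      nodes + j
    }
    nodes_a <- jit(nodes_a, n_circ, n_rad_anterior)
    nodes_p <- jit(nodes_p, n_circ, n_rad_posterior)
  }

  grid_tris <- function(n_circ, n_rad, offset) {
    tris <- list()
    id <- function(r, c) offset + (r - 1L) * n_circ + c
    for (r in seq_len(n_rad - 1L)) for (c in seq_len(n_circ - 1L)) {
      tris[[length(tris) + 1L]] <- c(id(r, c), id(r, c + 1L), id(r + 1L, c))
      tris[[length(tris) + 1L]] <- c(id(r, c + 1L), id(r + 1L, c + 1L),
                                     id(r + 1L, c))
    }
    do.call(rbind, tris)
  }
  tris_a <- grid_tris(n_circ, n_rad_anterior, 0L)
  tris_p <- grid_tris(n_circ, n_rad_posterior, nrow(nodes_a))
  nodes <- rbind(nodes_a, nodes_p)
  triangles <- rbind(tris_a, tris_p)
  leaflet <- c(rep("anterior", nrow(tris_a)), rep("posterior", nrow(tris_p)))

  theta_of <- c(rep(th_a, n_rad_anterior), rep(th_p, n_rad_posterior))
  tri_theta <- rowMeans(matrix(theta_of[triangles], ncol = 3))
  region <- character(nrow(triangles))
  ia <- leaflet == "anterior"
  # anterolateral (Al) commissure at theta = +pi/2: A1/P1 on that side
  cuts_a <- c(pi / 2, pi / 6, -pi / 6, -pi / 2)
  region[ia] <- c("A1", "A2", "A3")[findInterval(-tri_theta[ia],
                                                 -cuts_a[c(2, 3)]) + 1L]
  cuts_p <- pi / 2 + c(1, 2) * pi / 3
  region[!ia] <- c("P1", "P2", "P3")[findInterval(tri_theta[!ia], cuts_p) + 1L]

  nrm <- triangle_normals(nodes, triangles)
  flip <- nrm[, 3] < 0
  triangles[flip, ] <- triangles[flip, c(1, 3, 2)]
  nrm <- triangle_normals(nodes, triangles)

  # fiber frame: circumferential along the theta direction projected into
  # the triangle plane; radial completes the right-handed tangent pair
  tri_mid <- tri_theta
  circ0 <- cbind(cos(tri_mid), -ifelse(ia, b_ant, b_post) / Rx * sin(tri_mid),
                 0)
  circ0 <- circ0 / sqrt(rowSums(circ0^2))
  e1 <- circ0 - rowSums(circ0 * nrm) * nrm
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
              nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
              nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])

  thickness <- ifelse(leaflet == "anterior", 0.69, 0.51)

  ann_a <- seq_len(n_circ)
  ann_p <- nrow(nodes_a) + seq_len(n_circ)
  # closed loop: Al commissure -> anterior arc -> Pm -> posterior arc -> Al
  annulus_ids <- c(rev(ann_a), rev(ann_p))
  # coapting free margin = last node row; the short commissural side
  # columns are boundary too but carry no marginal chordae
  margin_row <- function(n_rad, offset)
    offset + (n_rad - 1L) * n_circ + seq_len(n_circ)
  side_cols <- function(n_rad, offset) {
    idx <- function(r, c) offset + (r - 1L) * n_circ + c
    c(idx(2:(n_rad - 1L), 1L), idx(2:(n_rad - 1L), n_circ))
  }
  free_a <- margin_row(n_rad_anterior, 0L)
  free_p <- margin_row(n_rad_posterior, nrow(nodes_a))
  commissural <- c(side_cols(n_rad_anterior, 0L),
                   side_cols(n_rad_posterior, nrow(nodes_a)))

  mid <- (n_circ + 1L) %/% 2L
  landmarks <- c(anterior_mid = ann_a[mid],
                 posterior_mid = ann_p[mid],
                 commissure_al = ann_a[n_circ],   # theta = +pi/2
                 commissure_pm = ann_a[1L])       # theta = -pi/2
  papillary_tips <- rbind(
    al = c(0.55 * Rx, -0.18 * ap_diameter, -papillary_depth),
    pm = c(-0.55 * Rx, -0.18 * ap_diameter, -papillary_depth))

  mesh <- valve_mesh(nodes, triangles, leaflet, region, thickness,
                     e1, e2, annulus_ids,
                     list(anterior = free_a, posterior = free_p,
                          commissural = commissural),
                     landmarks, papillary_tips, config_tag,
                     node_theta = theta_of)
  validate_valve_mesh(mesh)
  mesh
}

#' Attach marginal and strut chordae to a valve mesh
#'
#' Marginal chordae insert on free-margin nodes, spaced approximately
#' uniformly along each margin's arc length; the two strut chordae insert
#' on belly (interior) nodes of the anterior leaflet. Each chorda
#' originates from the papillary tip on its own commissural side
#' (`x > 0` anterolateral, `x < 0` posteromedial) and its rest length is
#' the origin-insertion distance in the reference configuration.
#'
#' Default cross-sectional areas: 0.29 mm^2 anterior marginal, 0.27 mm^2
#' posterior marginal, 0.61 mm^2 strut.
#'
#' @param mesh a [valve_mesh()].
#' @param n_marginal_anterior,n_marginal_posterior marginal chordae counts
#'   per leaflet (default 16 each).
#' @param n_strut strut chordae count (default 2).
#' @param areas named numeric: `anterior_marginal`, `posterior_marginal`,
#'   `strut` (mm^2).
#' @param seed recorded; the default placement is deterministic.
#' @return a [chordae_set()]; posterior marginal chordae are labeled
#'   `C_1 ... C_n` from the anterolateral to the posteromedial commissure,
#'   anterior marginals `AC_i`, struts `S_i`.
#' @export
attach_chordae <- function(mesh, n_marginal_anterior = 16,
                           n_marginal_posterior = 16, n_strut = 2,
                           areas = c(anterior_marginal = 0.29,
                                     posterior_marginal = 0.27,
                                     strut = 0.61),
                           seed = 1L) {
  stopifnot(inherits(mesh, "valve_mesh"))
  if (n_marginal_anterior < 0 || n_marginal_posterior < 0 || n_strut < 0)
    stop("attach_chordae: counts must be >= 0", call. = FALSE)
  rows <- list()
  place_marginal <- function(edge_ids, n, leaflet, prefix, area) {
    if (n == 0L) return(NULL)
    if (n > length(edge_ids))
      stop("attach_chordae: marginal count exceeds free-edge node count",
           call. = FALSE)
    pts <- mesh$nodes[edge_ids, , drop = FALSE]
    seg <- sqrt(rowSums(diff(pts)^2))
    s <- c(0, cumsum(seg))
    L <- s[length(s)]
    target <- (seq_len(n) - 0.5) / n * L
    idx <- vapply(target, function(ti) which.min(abs(s - ti)), integer(1))
    ids <- edge_ids[idx]
    data.frame(label = paste0(prefix, seq_len(n)),
               origin = ifelse(mesh$nodes[ids, 1] >= 0, "al", "pm"),
               insertion = ids, type = "marginal", leaflet = leaflet,
               area = area,
               stringsAsFactors = FALSE)
  }
  # posterior marginals labeled C_1..C_n from the Al commissure (P1 side)
  # to the Pm commissure (P3 side); the stored posterior free edge already
  # runs in increasing theta (Al -> Pm)
  post_edge <- mesh$free_edge_ids$posterior
  rows$am <- place_marginal(mesh$free_edge_ids$anterior,
                            n_marginal_anterior, "anterior", "AC_",
                            areas[["anterior_marginal"]])
  rows$pm <- place_marginal(post_edge, n_marginal_posterior,
                            "posterior", "C_",
                            areas[["posterior_marginal"]])
  if (n_strut > 0) {
    # belly nodes: anterior leaflet interior, around 60% of the way to the
    # free margin, one per commissural side
    cand <- setdiff(seq_len(nrow(mesh$nodes)),
                    c(mesh$annulus_ids,
                      unlist(mesh$free_edge_ids, use.names = FALSE)))
    ant_nodes <- sort(unique(as.vector(
      mesh$triangles[mesh$leaflet == "anterior", ])))
    cand <- intersect(cand, ant_nodes)
    p <- mesh$nodes[cand, , drop = FALSE]
    zr <- range(mesh$nodes[ant_nodes, 3])
    score <- abs(p[, 3] - (zr[2] - 0.6 * (zr[2] - zr[1])))
    pick_side <- function(sgn) {
      side <- which(sgn * p[, 1] > 0.15 * max(abs(p[, 1])))
      side[which.min(score[side])]
    }
    picks <- c(pick_side(1), pick_side(-1))[seq_len(min(n_strut, 2L))]
    if (n_strut > 2L) {
      extra <- order(score)[seq_len(n_strut - 2L)]
      picks <- c(picks, extra)
    }
    ids <- cand[picks]
    rows$strut <- data.frame(label = paste0("S_", seq_along(ids)),
                             origin = ifelse(mesh$nodes[ids, 1] >= 0,
                                             "al", "pm"),
                             insertion = ids, type = "strut",
                             leaflet = "anterior",
                             area = areas[["strut"]],
                             stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  if (is.null(d)) {
    d <- data.frame(label = character(), origin = character(),
                    insertion = integer(), type = character(),
                    leaflet = character(), area = numeric(),
                    rest_length = numeric(), stringsAsFactors = FALSE)
    return(chordae_set(d))
  }
  tip <- mesh$papillary_tips[ifelse(d$origin == "al", 1L, 2L), , drop = FALSE]
  d$rest_length <- sqrt(rowSums((mesh$nodes[d$insertion, , drop = FALSE] -
                                   tip)^2))
  rownames(d) <- NULL
  out <- chordae_set(d)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Remove chordae in a scallop to induce prolapse
#'
#' Removes `floor(fraction * n)` of the `n` marginal chordae whose
#' insertions lie in the given scallop, emulating chordal rupture (e.g.
#' ~70% of the P2 chordae for a P2 flail). The default removes a
#' centrally contiguous block — mirroring the clinical picture of a
#' ruptured central segment flanked by intact chordae; `select =
#' "random"` draws a seeded random subset instead.
#'
#' @param chordae a [chordae_set()].
#' @param mesh the [valve_mesh()] the chordae attach to (for region
#'   lookup).
#' @param scallop region label, default `"P2"`.
#' @param fraction fraction in `[0, 1]` of the scallop's marginal
#'   chordae to remove.
#' @param select `"central"` (default) or `"random"`.
#' @param seed seed for `select = "random"`.
#' @return the pruned `chordae_set`, with attribute `removed` holding the
#'   removed labels.
#' @export
induce_prolapse <- function(chordae, mesh, scallop = "P2", fraction = 0.7,
                            select = c("central", "random"), seed = 1L) {
  select <- match.arg(select)
  stopifnot(inherits(chordae, "chordae_set"))
  if (fraction < 0 || fraction > 1)
    stop("induce_prolapse: fraction must be in [0, 1]", call. = FALSE)
  if (!scallop %in% c("A1", "A2", "A3", "P1", "P2", "P3"))
    stop("induce_prolapse: unknown scallop label ", scallop, call. = FALSE)
  d <- chordae$chordae
  reg <- node_regions(mesh)
  in_scallop <- which(d$type == "marginal" & reg[d$insertion] == scallop)
  n_rm <- floor(fraction * length(in_scallop))
  if (n_rm == 0L) {
    out <- chordae_set(d)
    attr(out, "removed") <- character(0)
    return(out)
  }
  ord <- in_scallop[order(match(d$label[in_scallop], d$label))]
  if (select == "central") {
    k <- length(ord)
    start <- (k - n_rm) %/% 2L + 1L
    rm_idx <- ord[start:(start + n_rm - 1L)]
  } else {
    set.seed(as.integer(seed))
    rm_idx <- sample(ord, n_rm)
  }
  out <- chordae_set(d[-rm_idx, , drop = FALSE])
  attr(out, "removed") <- d$label[rm_idx]
  out
}

# region label per node: majority label of incident triangles
node_regions <- function(mesh) {
  n <- nrow(mesh$nodes)
  reg <- character(n)
  for (lab in unique(mesh$region)) {
    ids <- unique(as.vector(mesh$triangles[mesh$region == lab, ]))
    reg[ids[reg[ids] == ""]] <- lab
  }
  # nodes on region boundaries: prefer the label of the triangle whose
  # centroid is nearest
  reg
}

#' Measure annular diameters
#'
#' A-P diameter = Euclidean distance between the anterior and posterior
#' annular midpoints; Al-Pm diameter = distance between the anterolateral
#' and posteromedial commissure landmarks.
#'
#' @param mesh a [valve_mesh()] with landmarks defined.
#' @return named numeric `c(ap_diameter_mm, alpm_diameter_mm)`.
#' @export
measure_annulus <- function(mesh) {
  stopifnot(inherits(mesh, "valve_mesh"))
  lm <- mesh$landmarks
  need <- c("anterior_mid", "posterior_mid", "commissure_al", "commissure_pm")
  if (!all(need %in% names(lm)) || any(is.na(lm[need])))
    stop("measure_annulus: missing landmark(s)", call. = FALSE)
  p <- mesh$nodes
  c(ap_diameter_mm = sqrt(sum((p[lm[["anterior_mid"]], ] -
                                 p[lm[["posterior_mid"]], ])^2)),
    alpm_diameter_mm = sqrt(sum((p[lm[["commissure_al"]], ] -
                                   p[lm[["commissure_pm"]], ])^2)))
}
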