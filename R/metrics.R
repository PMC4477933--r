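#' Element stress field at a simulation time
#'
#' Cauchy stress recovered from the deformation gradient and the Fung
#' membrane law at the frame nearest `t`. The reported scalar is the
#' maximum in-plane principal Cauchy stress (MPa); `measure = "von_mises"`
#' gives the planar von Mises equivalent instead. Thickness change
#' follows near-incompressibility,
#' `lambda_t = J_inplane^(-poisson/(1-poisson))`.
#'
#' @param sim an `mv_sim` from [simulate_closure()].
#' @param t time (ms); default the last frame (peak of the simulated
#'   loading window).
#' @param measure `"max_principal"` (default) or `"von_mises"`.
#' @return object of class `stress_field`: a tibble with `element`,
#'   `leaflet`, `region`, `area_mm2` (reference), `stress_mpa`, plus
#'   attributes `time_ms` and `measure`.
#' @export
stress_field <- function(sim, t = NULL, measure = c("max_principal",
                                                    "von_mises")) {
  measure <- match.arg(measure)
  stopifnot(inherits(sim, "mv_sim"))
  if (is.null(t)) t <- max(sim$times)
  if (t < min(sim$times) - 1e-9 || t > max(sim$times) + 1e-9)
    stop("stress_field: t outside the simulated range", call. = FALSE)
  k <- frame_at(sim, t)
  mesh <- sim$mesh
  mats <- sim$materials
  pre <- fe_precompute(mesh, mats)
  out <- cpp_membrane_forces(sim$positions[, , k], mesh$triangles,
                             pre$invR, pre$areas, mesh$thickness,
                             pre$matid, pre$matpar)
  E <- out$strain
  nu <- mats$tissue$poisson
  m <- nrow(E)
  stress <- numeric(m)
  for (e in seq_len(m)) {
    p <- if (mesh$leaflet[e] == "anterior") mats$fung$anterior
    else mats$fung$posterior
    E11 <- E[e, 1]; E22 <- E[e, 2]; E12 <- E[e, 3]
    C <- matrix(c(2 * E11 + 1, 2 * E12, 2 * E12, 2 * E22 + 1), 2, 2)
    Q <- p$a_cc * E11^2 + p$a_rr * E22^2 + 2 * p$a_cr * E11 * E22 +
      p$a_ss * E12^2
    eQ <- exp(min(Q, 250))
    S <- matrix(c(p$c * eQ * (p$a_cc * E11 + p$a_cr * E22),
                  0.5 * p$c * eQ * p$a_ss * E12,
                  0.5 * p$c * eQ * p$a_ss * E12,
                  p$c * eQ * (p$a_rr * E22 + p$a_cr * E11)), 2, 2)
    J2 <- sqrt(max(det(C), 1e-12))
    lt <- J2^(-nu / (1 - nu))
    sig_eigs <- Re(eigen(S %*% C, only.values = TRUE)$values) / (J2 * lt)
    stress[e] <- if (measure == "max_principal") max(sig_eigs, 0)
    else sqrt(max(sig_eigs)^2 - prod(range(sig_eigs)) + min(sig_eigs)^2)
  }
  d <- tibble::tibble(element = seq_len(m), leaflet = mesh$leaflet,
                      region = mesh$region, area_mm2 = pre$areas,
                      stress_mpa = stress / 1000)
  structure(d, class = c("stress_field", class(d)),
            time_ms = sim$times[k], measure = measure)
}

#' Area-weighted regional average stresses
#'
#' Mean stress in the six Carpentier sub-regions, weighted by reference
#' element area; the area-weighted mean of the six regional values equals
#' the global area-weighted mean exactly.
#'
#' @param field a [stress_field()].
#' @return tibble with `region`, `mean_stress_mpa`, `area_mm2`; regions
#'   with no elements are reported `NA` (flagged missing, not zero).
#' @export
regional_average_stress <- function(field) {
  stopifnot(inherits(field, "stress_field"))
  regions <- c("A1", "A2", "A3", "P1", "P2", "P3")
  out <- lapply(regions, function(r) {
    d <- field[field$region == r, ]
    if (nrow(d) == 0L)
      return(tibble::tibble(region = r, mean_stress_mpa = NA_real_,
                            area_mm2 = 0))
    tibble::tibble(region = r,
                   mean_stress_mpa = sum(d$stress_mpa * d$area_mm2) /
                     sum(d$area_mm2),
                   area_mm2 = sum(d$area_mm2))
  })
  dplyr::bind_rows(out)
}

#' Threshold map of a stress field
#'
#' Binary element mask `stress > threshold` (strictly greater) and the
#' exceeding area fraction, mirroring red-thresholded stress displays
#' (default threshold 0.4 MPa).
#'
#' @param field a [stress_field()].
#' @param threshold MPa, `> 0`.
#' @return list `mask` (logical per element), `exceed_fraction`
#'   (area above threshold / total area), `threshold`.
#' @export
threshold_map <- function(field, threshold = 0.4) {
  stopifnot(inherits(field, "stress_field"), threshold > 0)
  mask <- field$stress_mpa > threshold
  list(mask = mask,
       exceed_fraction = sum(field$area_mm2[mask]) / sum(field$area_mm2),
       threshold = threshold)
}

# plane-mesh intersection: segments of triangles crossing x . n = off
plane_cut_segments <- function(pos, tris, nvec, off) {
  s <- pos %*% nvec - off
  segs <- list()
  for (e in seq_len(nrow(tris))) {
    v <- tris[e, ]
    sv <- s[v]
    pos_side <- sv > 0
    if (all(pos_side) || all(!pos_side)) next
    pts <- matrix(NA_real_, 0, 3)
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- v[pair[1]]; b <- v[pair[2]]
      if ((s[a] > 0) != (s[b] > 0)) {
        tt <- s[a] / (s[a] - s[b])
        pts <- rbind(pts, pos[a, ] + tt * (pos[b, ] - pos[a, ]))
      }
    }
    if (nrow(pts) == 2L) segs[[length(segs) + 1L]] <- pts
  }
  segs
}

#' Coaptation lengths in the scallop-pair cut planes
#'
#' For each requested plane (A1-P1, A2-P2, A3-P3) the deformed leaflets
#' are cut with the antero-posteriorly oriented plane through the scallop
#' pair's midline; the coaptation length is the arc length of the
#' anterior intersection curve along which the anterior-posterior surface
#' gap is at most the contact detection thickness.
#'
#' @param sim an `mv_sim`.
#' @param t time (ms), default the last frame.
#' @param planes character subset of `c("A1P1", "A2P2", "A3P3")`.
#' @param gap_tol coaptation gap tolerance (mm); defaults to the contact
#'   detection thickness used by the simulation's contact model.
#' @return object of class `coaptation_result`: a tibble with `plane`,
#'   `coaptation_mm`; attribute `contact_nodes` flags nodes in active
#'   contact pairs at the frame. Planes missing a leaflet intersection
#'   report 0 with a warning.
#' @export
coaptation <- function(sim, t = NULL, planes = c("A1P1", "A2P2", "A3P3"),
                       gap_tol = 0.8) {
  stopifnot(inherits(sim, "mv_sim"))
  if (is.null(t)) t <- max(sim$times)
  k <- frame_at(sim, t)
  pos <- sim$positions[, , k]
  mesh <- sim$mesh
  lm <- mesh$landmarks
  xhat <- pos[lm[["commissure_al"]], ] - pos[lm[["commissure_pm"]], ]
  xhat <- xhat / sqrt(sum(xhat^2))
  ctr <- colMeans(pos[mesh$annulus_ids, , drop = FALSE])
  lens <- numeric(length(planes))
  for (pi in seq_along(planes)) {
    pl <- planes[pi]
    pair <- switch(pl, A1P1 = c("A1", "P1"), A2P2 = c("A2", "P2"),
                   A3P3 = c("A3", "P3"),
                   stop("coaptation: unknown plane ", pl, call. = FALSE))
    sel <- mesh$region %in% pair
    cent <- colMeans(pos[unique(as.vector(mesh$triangles[sel, ])), ,
                         drop = FALSE])
    off <- sum(cent * xhat)
    ant <- plane_cut_segments(pos,
                              mesh$triangles[mesh$leaflet == "anterior", ,
                                             drop = FALSE], xhat, off)
    post <- plane_cut_segments(pos,
                               mesh$triangles[mesh$leaflet == "posterior", ,
                                              drop = FALSE], xhat, off)
    if (length(ant) == 0L || length(post) == 0L) {
      warning("coaptation: plane ", pl, " misses a leaflet; length 0")
      lens[pi] <- 0
      next
    }
    pmat <- do.call(rbind, post)
    total <- 0
    for (sg in ant) {
      L <- sqrt(sum((sg[2, ] - sg[1, ])^2))
      ns <- max(2L, ceiling(L / 0.1))
      tt <- seq(0, 1, length.out = ns)
      pts <- outer(1 - tt, sg[1, ]) + outer(tt, sg[2, ])
      gap <- vapply(seq_len(ns), function(i) {
        min(segment_set_dist(pmat, pts[i, ]))
      }, numeric(1))
      total <- total + sum(gap <= gap_tol) / ns * L
    }
    lens[pi] <- total
  }
  flagged <- unique(sim$pairs[[k]]$node)
  d <- tibble::tibble(plane = planes, coaptation_mm = lens)
  structure(d, class = c("coaptation_result", class(d)),
            time_ms = sim$times[k], contact_nodes = flagged)
}

# distances from point p to each segment (rows 2i-1, 2i of segmat)
segment_set_dist <- function(segmat, p) {
  ns <- nrow(segmat) / 2
  a <- segmat[2 * seq_len(ns) - 1, , drop = FALSE]
  b <- segmat[2 * seq_len(ns), , drop = FALSE]
  ab <- b - a
  t <- rowSums(sweep(-a, 2, -p) * ab) / pmax(rowSums(ab^2), 1e-30)
  t <- pmin(pmax(t, 0), 1)
  q <- a + t * ab
  sqrt(rowSums(sweep(q, 2, p)^2))
}

#' Percent change between pre- and post-repair values
#'
#' `(post - pre)/pre * 100`, rounded to the nearest integer, the
#' convention used when reporting paired chordal stresses.
#'
#' @param pre,post numeric vectors.
#' @return integer percent changes.
#' @export
percent_change <- function(pre, post) {
  as.integer(round((post - pre) / pre * 100))
}

#' Paired chordal stress table
#'
#' Time-averaged axial Cauchy stress per chorda over the systolic
#' plateau (frames where the transvalvular pressure is at least 90% of
#' its peak; if the simulation carries no waveform, the last quarter of
#' the frames), before and after repair, with the integer percent
#' change. Chordae absent from the post-repair set (ruptured or resected)
#' are reported `NA`.
#'
#' @param sim_pre,sim_post `mv_sim` objects carrying their `chordae`.
#' @param labels chordal labels to report; default the union of both
#'   sets' labels.
#' @return tibble: `label`, `pre_kpa`, `post_kpa`, `change_percent`.
#' @export
chordal_stress_table <- function(sim_pre, sim_post, labels = NULL) {
  avg <- function(sim) {
    d <- sim$chordae$chordae
    if (nrow(d) == 0L) return(stats::setNames(numeric(0), character(0)))
    idx <- plateau_frames(sim)
    mats <- sim$materials
    sig <- vapply(seq_len(nrow(d)), function(j) {
      par <- mats$ogden[[d$type[j]]]
      mean(vapply(idx, function(k) ogden_fiber_stress(sim$lambda[k, j],
                                                      par), numeric(1)))
    }, numeric(1))
    stats::setNames(sig, d$label)
  }
  pre <- avg(sim_pre)
  post <- avg(sim_post)
  if (is.null(labels)) labels <- union(names(pre), names(post))
  pre_v <- pre[labels]; post_v <- post[labels]
  tibble::tibble(
    label = labels,
    pre_kpa = as.numeric(pre_v),
    post_kpa = as.numeric(post_v),
    change_percent = ifelse(is.na(pre_v) | is.na(post_v), NA_integer_,
                            percent_change(as.numeric(pre_v),
                                           as.numeric(post_v))))
}

plateau_frames <- function(sim, frac = 0.9) {
  p <- sim$pressure_trace
  if (is.null(p) || all(p <= 0)) {
    nf <- length(sim$times)
    return(seq.int(max(1L, nf - nf %/% 4L), nf))
  }
  which(p >= frac * max(p))
}

#' @export
print.coaptation_result <- function(x, ...) {
  cat("coaptation at t =", attr(x, "time_ms"), "ms\n")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Plot regional average stresses
#' @param object a [stress_field()].
#' @param ... unused.
#' @return a ggplot bar chart of the six regional mean stresses.
#' @method autoplot stress_field
#' @export
autoplot.stress_field <- function(object, ...) {
  d <- regional_average_stress(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region,
                                  y = .data$mean_stress_mpa)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "mean stress (MPa)",
                  title = sprintf("Regional leaflet stress at t = %.0f ms",
                                  attr(object, "time_ms"))) +
    ggplot2::theme_minimal()
}

#' Plot coaptation lengths per plane
#' @param object a [coaptation()] result.
#' @param ... unused.
#' @return a ggplot bar chart.
#' @method autoplot coaptation_result
#' @export
autoplot.coaptation_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$plane, y = .data$coaptation_mm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "coaptation length (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the energy history of a simulation
#' @param object an `mv_sim`.
#' @param ... unused.
#' @return a ggplot of kinetic/strain/external-work traces.
#' @method autoplot mv_sim
#' @export
autoplot.mv_sim <- function(object, ...) {
  e <- tidy(object)
  d <- tidyr::pivot_longer(
    e[, c("t", "kinetic", "strain", "external_work", "dissipation")],
    -"t", names_to = "component", values_to = "energy")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$energy,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "energy (µJ)") +
    ggplot2::theme_minimal()
}
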