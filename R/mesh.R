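#' Labeled triangulated valve mesh
#'
#' The single structure every stage of the toolkit transforms: triangulated
#' anterior/posterior leaflet surfaces with Carpentier region labels, an
#' ordered annulus polyline with anatomical landmarks, ordered free-edge
#' polylines, per-triangle thickness and fiber frames, and the two
#' papillary tip locations.
#'
#' @param nodes `n x 3` numeric matrix of coordinates (mm).
#' @param triangles `m x 3` integer matrix of 1-based node indices.
#' @param leaflet character/factor per triangle: `"anterior"`/`"posterior"`.
#' @param region character/factor per triangle: `A1,A2,A3,P1,P2,P3`.
#' @param thickness numeric per triangle (mm), `> 0`.
#' @param fiber_e1,fiber_e2 `m x 3` matrices: unit circumferential and
#'   radial directions, tangent to each triangle's plane.
#' @param annulus_ids ordered node ids tracing the closed annulus.
#' @param free_edge_ids named list (`anterior`, `posterior`) of ordered
#'   free-margin node ids (the coapting margin row).
#' @param landmarks named integer vector with entries `anterior_mid`,
#'   `posterior_mid`, `commissure_al`, `commissure_pm` (node ids on the
#'   annulus).
#' @param papillary_tips `2 x 3` matrix (rows `al`, `pm`) of papillary
#'   muscle tip coordinates (mm).
#' @param config_tag `"end_diastole"` or `"peak_systole"`.
#' @param node_theta optional per-node intercommissural angle (radians),
#'   kept by the generator and surgery ops as a convenience coordinate.
#' @return an object of class `valve_mesh`.
#' @seealso [build_synthetic_valve()], [validate_valve_mesh()]
#' @export
valve_mesh <- function(nodes, triangles, leaflet, region, thickness,
                       fiber_e1, fiber_e2, annulus_ids, free_edge_ids,
                       landmarks, papillary_tips,
                       config_tag = "end_diastole", node_theta = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  m <- nrow(triangles)
  stopifnot(ncol(nodes) == 3L, ncol(triangles) == 3L,
            length(leaflet) == m, length(region) == m,
            length(thickness) == m)
  if (any(thickness <= 0)) stop("valve_mesh: thickness must be > 0",
                                call. = FALSE)
  structure(list(
    nodes = nodes, triangles = triangles,
    leaflet = as.character(leaflet), region = as.character(region),
    thickness = as.numeric(thickness),
    fiber_e1 = as.matrix(fiber_e1), fiber_e2 = as.matrix(fiber_e2),
    annulus_ids = as.integer(annulus_ids),
    free_edge_ids = lapply(free_edge_ids, as.integer),
    landmarks = vapply(landmarks, as.integer, integer(1)),
    papillary_tips = as.matrix(papillary_tips),
    config_tag = config_tag,
    node_theta = if (is.null(node_theta)) NULL else as.numeric(node_theta)
  ), class = "valve_mesh")
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf("valve_mesh: %d nodes, %d triangles (%s)\n",
              nrow(x$nodes), nrow(x$triangles), x$config_tag))
  d <- tryCatch(measure_annulus(x), error = function(e) NULL)
  if (!is.null(d))
    cat(sprintf("  annulus: A-P %.1f mm, Al-Pm %.1f mm\n",
                d[["ap_diameter_mm"]], d[["alpm_diameter_mm"]]))
  tab <- table(x$region)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

# All edges of the triangulation as a 2-column matrix (each triangle
# contributes 3); `sorted` normalizes node order within the edge.
mesh_edges <- function(mesh, sorted = TRUE) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  if (sorted) e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e
}

# Boundary edges: edges used by exactly one triangle.
boundary_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

triangle_areas <- function(nodes, triangles) {
  a <- nodes[triangles[, 1], , drop = FALSE]
  b <- nodes[triangles[, 2], , drop = FALSE]
  c_ <- nodes[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

triangle_normals <- function(nodes, triangles) {
  a <- nodes[triangles[, 1], , drop = FALSE]
  b <- nodes[triangles[, 2], , drop = FALSE]
  c_ <- nodes[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cr / sqrt(rowSums(cr^2))
}

#' Topology and labeling audit of a valve mesh
#'
#' Checks the structural invariants every surgery stage must preserve:
#' orientable manifold-with-boundary (each edge shared by at most two
#' triangles), boundary equal to the union of annulus and free-edge node
#' sets, exactly one leaflet and one region label per triangle, unit
#' fiber-frame vectors tangent to their triangle, positive thickness and
#' no dangling chordal insertions.
#'
#' @param mesh a [valve_mesh()].
#' @param chordae optional [chordae_set()] checked for dangling insertions.
#' @param tol tolerance for unit-length / tangency checks.
#' @param extra_boundary_ids additional node ids allowed on the boundary
#'   (the excision curves of an intermediate post-excision mesh).
#' @return `TRUE` invisibly; otherwise stops with the failed invariant.
#' @export
validate_valve_mesh <- function(mesh, chordae = NULL, tol = 1e-6,
                                extra_boundary_ids = integer(0)) {
  stopifnot(inherits(mesh, "valve_mesh"))
  n <- nrow(mesh$nodes); tr <- mesh$triangles
  if (any(tr < 1L) || any(tr > n)) stop("triangle index out of range")
  if (!all(is.finite(mesh$nodes))) stop("non-finite node coordinates")
  e <- mesh_edges(mesh)
  cnt <- table(paste(e[, 1], e[, 2]))
  if (any(cnt > 2L)) stop("non-manifold edge (shared by > 2 triangles)")
  bnodes <- sort(unique(as.vector(boundary_edges(mesh))))
  expected <- sort(unique(c(mesh$annulus_ids,
                            unlist(mesh$free_edge_ids, use.names = FALSE),
                            extra_boundary_ids)))
  if (!identical(bnodes, expected))
    stop("boundary nodes != annulus + free-edge nodes (",
         length(setdiff(bnodes, expected)), " unlabeled, ",
         length(setdiff(expected, bnodes)), " not on boundary)")
  if (!all(mesh$leaflet %in% c("anterior", "posterior")))
    stop("invalid leaflet label")
  if (!all(mesh$region %in% c("A1", "A2", "A3", "P1", "P2", "P3")))
    stop("invalid region label")
  if (any(mesh$thickness <= 0)) stop("non-positive thickness")
  nrm <- triangle_normals(mesh$nodes, tr)
  for (f in c("fiber_e1", "fiber_e2")) {
    v <- mesh[[f]]
    if (max(abs(sqrt(rowSums(v^2)) - 1)) > tol)
      stop(f, " not unit length")
    if (max(abs(rowSums(v * nrm))) > 1e-3)
      stop(f, " not tangent to triangle plane")
  }
  lm <- mesh$landmarks
  need <- c("anterior_mid", "posterior_mid", "commissure_al", "commissure_pm")
  if (!all(need %in% names(lm))) stop("missing annulus landmark(s)")
  if (anyDuplicated(lm[need])) stop("landmark indices not distinct")
  if (!is.null(chordae)) {
    ins <- chordae$chordae$insertion
    if (length(ins) && (any(ins < 1L) || any(ins > n)))
      stop("dangling chordal insertion")
  }
  invisible(TRUE)
}

#' Write / read a valve mesh as legacy ASCII VTK
#'
#' Serializes the triangulation with cell-data fields `leaflet` (0 =
#' anterior, 1 = posterior), `region` (1..6 for A1..A3,P1..P3) and
#' `thickness`. Landmarks, annulus/free-edge orderings, fiber frames and
#' papillary tips travel in a JSON sidecar written next to the VTK file
#' (`<path>.meta.json`), so a round trip reproduces the full object.
#'
#' @param mesh a [valve_mesh()].
#' @param path output path (conventionally `.vtk`).
#' @return `write_mesh_vtk()` returns `path` invisibly; `read_mesh_vtk()`
#'   returns a `valve_mesh`.
#' @export
write_mesh_vtk <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mvrepair valve mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  regions <- c("A1", "A2", "A3", "P1", "P2", "P3")
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS leaflet int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(ifelse(mesh$leaflet == "anterior", 0L, 1L)), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, regions)), con)
  writeLines(c("SCALARS thickness double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh$thickness, digits = 17), con)
  meta <- list(annulus_ids = mesh$annulus_ids,
               free_edge_ids = mesh$free_edge_ids,
               landmarks = as.list(mesh$landmarks),
               papillary_tips = list(al = mesh$papillary_tips[1, ],
                                     pm = mesh$papillary_tips[2, ]),
               config_tag = mesh$config_tag,
               node_theta = mesh$node_theta,
               fiber_e1 = mesh$fiber_e1, fiber_e2 = mesh$fiber_e2)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  m <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  polys <- matrix(scan(text = lines[(it + 1):(it + m)], quiet = TRUE),
                  ncol = 4, byrow = TRUE)
  triangles <- polys[, 2:4, drop = FALSE] + 1L
  grab_scalar <- function(name, m) {
    i <- grep(paste0("^SCALARS ", name), lines)[1]
    scan(text = lines[(i + 2):(i + 1 + m)], quiet = TRUE)
  }
  leaflet_i <- grab_scalar("leaflet", m)
  region_i <- grab_scalar("region", m)
  thickness <- grab_scalar("thickness", m)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  regions <- c("A1", "A2", "A3", "P1", "P2", "P3")
  valve_mesh(
    nodes = nodes, triangles = triangles,
    leaflet = ifelse(leaflet_i == 0, "anterior", "posterior"),
    region = regions[region_i], thickness = thickness,
    fiber_e1 = matrix(unlist(meta$fiber_e1), ncol = 3),
    fiber_e2 = matrix(unlist(meta$fiber_e2), ncol = 3),
    annulus_ids = meta$annulus_ids,
    free_edge_ids = meta$free_edge_ids,
    landmarks = unlist(meta$landmarks),
    papillary_tips = rbind(al = unlist(meta$papillary_tips$al),
                           pm = unlist(meta$papillary_tips$pm)),
    config_tag = meta$config_tag,
    node_theta = meta$node_theta)
}

#' Chordae tendineae set
#'
#' A tibble-backed set of chordae: marginal chordae insert on free-edge
#' nodes, strut chordae on interior (belly) nodes of the anterior leaflet.
#'
#' @param chordae a data frame with columns `label`, `origin`
#'   (`"al"`/`"pm"` papillary tip), `insertion` (node id), `type`
#'   (`"marginal"`/`"strut"`), `leaflet`, `area` (mm^2), `rest_length`
#'   (mm).
#' @return object of class `chordae_set` wrapping the tibble.
#' @export
chordae_set <- function(chordae) {
  d <- tibble::as_tibble(chordae)
  need <- c("label", "origin", "insertion", "type", "leaflet", "area",
            "rest_length")
  stopifnot(all(need %in% names(d)))
  if (nrow(d)) {
    stopifnot(all(d$area > 0), all(d$rest_length > 0),
              all(d$type %in% c("marginal", "strut")),
              all(d$origin %in% c("al", "pm")))
  }
  structure(list(chordae = d), class = "chordae_set")
}

#' @export
print.chordae_set <- function(x, ...) {
  d <- x$chordae
  cat(sprintf("chordae_set: %d chordae (%d marginal, %d strut)\n",
              nrow(d), sum(d$type == "marginal"), sum(d$type == "strut")))
  invisible(x)
}

#' Write / read chordae as a JSON sidecar
#'
#' @param chordae a [chordae_set()].
#' @param path JSON file path.
#' @return the path / the `chordae_set`.
#' @export
write_chordae_json <- function(chordae, path) {
  jsonlite::write_json(chordae$chordae, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_chordae_json
#' @export
read_chordae_json <- function(path) {
  chordae_set(jsonlite::read_json(path, simplifyVector = TRUE))
}
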