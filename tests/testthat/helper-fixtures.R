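# shared fixtures, built in code at test time

# coarse synthetic valve for fast solver tests (224 elements)
small_valve <- function(...) {
  args <- utils::modifyList(
    list(ap_diameter = 32, alpm_diameter = 36, posterior_bulge = 0,
         posterior_margin_ripple = 1, n_circ = 17, n_rad_anterior = 5,
         n_rad_posterior = 4),
    list(...))
  do.call(build_synthetic_valve, args)
}

# the default patient twin (dilated, prolapse-prone) at full resolution
patient_valve <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_synthetic_valve()
    cache
  }
})

# one flat triangle in the x-y plane as a minimal membrane test body
single_triangle_mesh <- function(thickness = 0.5) {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  valve_mesh(nodes = nodes,
             triangles = matrix(c(1L, 2L, 3L), 1),
             leaflet = "anterior", region = "A2", thickness = thickness,
             fiber_e1 = matrix(c(1, 0, 0), 1),
             fiber_e2 = matrix(c(0, 1, 0), 1),
             annulus_ids = c(1L, 2L),
             free_edge_ids = list(anterior = 3L, posterior = integer(0)),
             landmarks = c(anterior_mid = 1L, posterior_mid = 2L,
                           commissure_al = 3L, commissure_pm = 1L),
             papillary_tips = rbind(al = c(1, 1, -10), pm = c(-1, 1, -10)))
}

# central-difference numerical gradient of the Fung energy
fung_stress_fd <- function(E, params, h = 1e-7) {
  vapply(1:3, function(i) {
    Ep <- E; Ep[i] <- Ep[i] + h
    Em <- E; Em[i] <- Em[i] - h
    (fung_energy(Ep, params) - fung_energy(Em, params)) / (2 * h)
  }, numeric(1))
}

# brute-force boundary walk: nodes on edges used by exactly one triangle
boundary_nodes_bruteforce <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1L))
  sort(unique(as.integer(unlist(strsplit(once, " ")))))
}

# region label per node (same rule the package applies)
node_region_lookup <- function(mesh) mvrepair:::node_regions(mesh)

run_prepost_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mv <- patient_valve()
    ch <- attach_chordae(mv)
    pr <- induce_prolapse(ch, mv, "P2", 0.7)
    plan <- plan_resection(mv, pr, "P2", 5)
    ex <- excise(mv, pr, plan)
    sc <- suture_target_curve(ex$plan$edge_A, ex$plan$edge_B,
                              ex$plan$node_pairing, ex$mesh)
    ps <- plicate_and_suture(ex$mesh, sc, ex$plan, ex$chordae)
    ring <- ring_profile(size_ring(37, 35))
    imp <- implant_ring(ps$mesh, ring)
    cfg <- solver_config(duration = 250)
    sim_pre <- simulate_closure(mv, pr,
                                motion = annular_motion_from_mesh(mv),
                                config = cfg)
    sim_post <- simulate_closure(imp$mesh, ps$chordae, config = cfg)
    cache <<- list(mesh = mv, chordae = ch, prolapsed = pr, plan = plan,
                   excised = ex, curve = sc, plicated = ps, ring = ring,
                   implanted = imp, sim_pre = sim_pre, sim_post = sim_post)
    cache
  }
})
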