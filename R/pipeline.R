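#' Default pipeline configuration
#'
#' The declarative configuration driving [run_pipeline()]: synthetic
#' geometry parameters, chordae counts, prolapse, surgery, solver and
#' output settings. Any element can be overridden; [validate_config()]
#' reports problems without throwing.
#'
#' @param seed integer seed recorded in all outputs and used for any
#'   seeded generator options.
#' @param out_dir output directory for [run_pipeline()].
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = "mvrepair_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    geometry = list(ap_diameter = 43, alpm_diameter = 37,
                    saddle_height = 5),
    chordae = list(n_marginal_anterior = 16, n_marginal_posterior = 16,
                   n_strut = 2),
    prolapse = list(scallop = "P2", fraction = 0.7),
    surgery = list(chordal_margin = 5,
                   ring_catalog = seq(24, 40, by = 2),
                   alpm_systole = 35),
    materials_file = NULL,       # NULL = default_materials()
    pressure_file = NULL,        # NULL = default waveform
    solver = list(duration = 250, mass_scaling = 100, damping = 0.25),
    skip_repair = FALSE,
    simulate = TRUE
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return `read_config()` returns a `run_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), x)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config` list.
#' @return character vector of issues, each naming the offending field;
#'   empty when the configuration is usable. Unreadable referenced files
#'   become issues, not errors.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(x) issues <<- c(issues, x)
  g <- config$geometry
  if (is.null(g$ap_diameter) || g$ap_diameter <= 0)
    add("geometry.ap_diameter: must be > 0")
  if (is.null(g$alpm_diameter) || g$alpm_diameter <= 0)
    add("geometry.alpm_diameter: must be > 0")
  ch <- config$chordae
  for (f in names(ch)) if (ch[[f]] < 0)
    add(paste0("chordae.", f, ": must be >= 0"))
  pr <- config$prolapse
  if (pr$fraction < 0 || pr$fraction > 1)
    add("prolapse.fraction: must be in [0, 1]")
  if (!pr$scallop %in% c("A1", "A2", "A3", "P1", "P2", "P3"))
    add("prolapse.scallop: unknown label")
  if (config$surgery$chordal_margin < 0)
    add("surgery.chordal_margin: must be >= 0")
  if (length(config$surgery$ring_catalog) == 0)
    add("surgery.ring_catalog: empty")
  if (!is.null(config$materials_file)) {
    m <- tryCatch(suppressWarnings(read_materials(config$materials_file)),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) add(paste0("materials_file: unreadable (", m, ")"))
    else {
      tis <- m$tissue
      if (tis$thickness_anterior <= 0 || tis$thickness_posterior <= 0)
        add("tissue.thickness: must be > 0")
    }
  }
  if (config$solver$duration <= 0) add("solver.duration: must be > 0")
  if (pr$fraction >= 1 && config$surgery$chordal_margin > 0)
    add(paste0("surgery: margin ", config$surgery$chordal_margin,
               " mm with no remaining scallop chordae cannot anchor the ",
               "excision curves (warning)"))
  issues
}

#' Run the virtual-repair pipeline
#'
#' The full protocol: generate the synthetic prolapsed valve, simulate
#' pre-repair closure, plan and perform quadrangular resection with
#' plication/suturing, size and implant the annuloplasty ring, simulate
#' post-repair closure, and write meshes (VTK), metrics (CSV + JSON) and
#' a provenance record into the run directory. Re-running with the same
#' configuration reproduces the metrics bit-identically.
#'
#' @param config a `run_config` from [default_config()] /
#'   [read_config()].
#' @return (invisibly) a list with the run directory, all intermediate
#'   objects and the metrics; written artifacts are the side effect.
#' @export
run_pipeline <- function(config = default_config()) {
  issues <- validate_config(config)
  hard <- issues[!grepl("\\(warning\\)$", issues)]
  if (length(hard))
    stop("run_pipeline: invalid config:\n  ",
         paste(hard, collapse = "\n  "), call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out_dir, "pipeline.log")
  logln <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- tryCatch(expr, error = function(e) {
      err <- list(stage = name, message = conditionMessage(e))
      jsonlite::write_json(err, file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("run_pipeline: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    logln("stage %-12s %.2f s", name,
          as.numeric(Sys.time() - t0, units = "secs"))
    v
  }
  cat("", file = log)
  mats <- if (is.null(config$materials_file)) default_materials()
  else read_materials(config$materials_file)
  press <- if (is.null(config$pressure_file)) pressure_waveform()
  else pressure_waveform(samples = stats::setNames(
    read_timeseries_csv(config$pressure_file), c("t", "dP")))

  g <- config$geometry
  mv <- stage("generate", do.call(build_synthetic_valve,
                                  c(g, list(seed = config$seed))))
  ch <- stage("chordae", do.call(attach_chordae,
                                 c(list(mesh = mv), config$chordae,
                                   list(seed = config$seed))))
  pr <- stage("prolapse", induce_prolapse(ch, mv, config$prolapse$scallop,
                                          config$prolapse$fraction,
                                          seed = config$seed))
  write_mesh_vtk(mv, file.path(config$out_dir, "valve_pre.vtk"))
  write_chordae_json(pr, file.path(config$out_dir, "chordae_pre.json"))

  scfg <- solver_config(duration = config$solver$duration,
                        mass_scaling = config$solver$mass_scaling,
                        damping = config$solver$damping,
                        seed = config$seed)
  motion <- annular_motion_from_mesh(mv, config$surgery$alpm_systole)
  sim_pre <- if (config$simulate)
    stage("simulate_pre", simulate_closure(mv, pr, mats, press,
                                           motion = motion, config = scfg))
  else NULL

  repair <- NULL
  sim_post <- NULL
  if (!isTRUE(config$skip_repair)) {
    plan <- stage("plan", plan_resection(mv, pr, config$prolapse$scallop,
                                         config$surgery$chordal_margin))
    exd <- stage("excise", excise(mv, pr, plan))
    curve <- stage("suture_curve",
                   suture_target_curve(exd$plan$edge_A, exd$plan$edge_B,
                                       exd$plan$node_pairing, exd$mesh))
    plic <- stage("plicate", plicate_and_suture(exd$mesh, curve, exd$plan,
                                                exd$chordae))
    dd <- measure_annulus(mv)
    size <- stage("size_ring",
                  size_ring(dd[["alpm_diameter_mm"]],
                            config$surgery$alpm_systole,
                            catalog = config$surgery$ring_catalog))
    ring <- ring_profile(size, catalog = config$surgery$ring_catalog)
    imp <- stage("implant", implant_ring(plic$mesh, ring))
    write_mesh_vtk(imp$mesh, file.path(config$out_dir, "valve_post.vtk"))
    write_chordae_json(plic$chordae,
                       file.path(config$out_dir, "chordae_post.json"))
    repair <- list(plan = plan, curve = curve, plication = plic,
                   ring_size = size, ring = ring, implant = imp)
    sim_post <- if (config$simulate)
      stage("simulate_post", simulate_closure(imp$mesh, plic$chordae,
                                              mats, press, motion = NULL,
                                              config = scfg))
    else NULL
  }

  metrics <- stage("metrics",
                   pipeline_metrics(mv, pr, repair, sim_pre, sim_post))
  utils::write.csv(metrics$regional,
                   file.path(config$out_dir, "regional_stress.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics$coaptation,
                   file.path(config$out_dir, "coaptation.csv"),
                   row.names = FALSE)
  if (!is.null(metrics$chordal))
    utils::write.csv(metrics$chordal,
                     file.path(config$out_dir, "chordal_stress.csv"),
                     row.names = FALSE)
  jsonlite::write_json(metrics$summary,
                       file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(seed = config$seed,
               config_hash = config_hash(config),
               r_version = as.character(getRversion()),
               package_version =
                 as.character(utils::packageVersion("mvrepair")))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(dir = config$out_dir, mesh = mv, chordae = pr,
                 repair = repair, sim_pre = sim_pre, sim_post = sim_post,
                 metrics = metrics))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_metrics <- function(mesh, chordae, repair, sim_pre, sim_post) {
  d_pre <- measure_annulus(mesh)
  summary <- list(ap_diameter_mm = unname(d_pre[["ap_diameter_mm"]]),
                  alpm_diameter_mm = unname(d_pre[["alpm_diameter_mm"]]))
  regional <- tibble::tibble()
  coap <- tibble::tibble()
  chordal <- NULL
  if (!is.null(repair)) {
    d_post <- measure_annulus(repair$plication$mesh)
    summary$ap_diameter_post_mm <- unname(d_post[["ap_diameter_mm"]])
    summary$alpm_diameter_post_mm <- unname(d_post[["alpm_diameter_mm"]])
    summary$ring_size_mm <- as.numeric(repair$ring_size)
  }
  if (!is.null(sim_pre)) {
    sf <- stress_field(sim_pre)
    ra <- regional_average_stress(sf)
    ra$phase <- "pre"
    regional <- dplyr::bind_rows(regional, ra)
    summary$max_stress_pre_mpa <- max(sf$stress_mpa)
    summary$exceed_fraction_pre <- threshold_map(sf)$exceed_fraction
    co <- coaptation(sim_pre)
    co$phase <- "pre"
    coap <- dplyr::bind_rows(coap, tibble::as_tibble(co))
    for (i in seq_len(nrow(co)))
      summary[[paste0("coaptation_",
                      tolower(co$plane[i]), "_pre_mm")]] <-
        co$coaptation_mm[i]
  }
  if (!is.null(sim_post)) {
    sf <- stress_field(sim_post)
    ra <- regional_average_stress(sf)
    ra$phase <- "post"
    regional <- dplyr::bind_rows(regional, ra)
    summary$max_stress_post_mpa <- max(sf$stress_mpa)
    summary$exceed_fraction_post <- threshold_map(sf)$exceed_fraction
    co <- coaptation(sim_post)
    co$phase <- "post"
    coap <- dplyr::bind_rows(coap, tibble::as_tibble(co))
    for (i in seq_len(nrow(co)))
      summary[[paste0("coaptation_",
                      tolower(co$plane[i]), "_post_mm")]] <-
        co$coaptation_mm[i]
  }
  if (!is.null(sim_pre) && !is.null(sim_post)) {
    chordal <- chordal_stress_table(sim_pre, sim_post)
    keep <- !is.na(chordal$change_percent)
    summary$max_chordal_reduction_percent <-
      -min(chordal$change_percent[keep])
  }
  list(summary = summary, regional = regional, coaptation = coap,
       chordal = chordal)
}
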