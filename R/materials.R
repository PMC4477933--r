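#' Fung-type anisotropic membrane material parameters
#'
#' Parameters of the Fung-type planar strain-energy function used for the
#' valve leaflets,
#' \deqn{W = \frac{c}{2}\left(e^{Q} - 1\right), \qquad
#'   Q = a_{cc} E_{cc}^2 + a_{rr} E_{rr}^2 + 2 a_{cr} E_{cc} E_{rr}
#'       + a_{ss} E_{cr}^2,}
#' where \eqn{E_{cc}}, \eqn{E_{rr}}, \eqn{E_{cr}} are in-plane Green strain
#' components in the local fiber frame (circumferential / radial). The
#' second Piola--Kirchhoff stress is \eqn{S = \partial W/\partial E}.
#'
#' @param c stress scale (kPa), `> 0`.
#' @param a_cc,a_rr,a_cr dimensionless exponents of the quadratic form `Q`.
#'   Positive semi-definiteness (`a_cc > 0`, `a_rr > 0`,
#'   `a_cc * a_rr >= a_cr^2`) is enforced: it guarantees a convex energy
#'   near the reference state.
#' @param a_ss dimensionless shear exponent; defaults to `(a_cc + a_rr)/2`.
#' @param leaflet which leaflet the set belongs to, `"anterior"` or
#'   `"posterior"` (bookkeeping only).
#'
#' @return An object of class `fung_params`.
#' @seealso [fung_stress()], [fit_fung_params()], [default_materials()]
#' @export
#' @examples
#' fp <- fung_params(c = 10, a_cc = 20, a_rr = 10, a_cr = 2)
#' fung_stress(c(0.1, 0, 0), fp)
fung_params <- function(c, a_cc, a_rr, a_cr, a_ss = (a_cc + a_rr) / 2,
                        leaflet = c("anterior", "posterior")) {
  leaflet <- match.arg(leaflet)
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  if (c <= 0) stop("fung_params: stress scale `c` must be > 0", call. = FALSE)
  if (a_cc <= 0 || a_rr <= 0)
    stop("fung_params: a_cc and a_rr must be > 0", call. = FALSE)
  if (a_cc * a_rr < a_cr^2)
    stop("fung_params: quadratic form not positive semi-definite ",
         "(need a_cc*a_rr >= a_cr^2)", call. = FALSE)
  if (a_ss < 0) stop("fung_params: a_ss must be >= 0", call. = FALSE)
  structure(list(c = c, a_cc = a_cc, a_rr = a_rr, a_cr = a_cr, a_ss = a_ss,
                 leaflet = leaflet),
            class = "fung_params")
}

#' @export
print.fung_params <- function(x, ...) {
  cat(sprintf("Fung membrane parameters (%s leaflet)\n", x$leaflet))
  cat(sprintf("  c = %.4g kPa; a_cc = %.4g, a_rr = %.4g, a_cr = %.4g, a_ss = %.4g\n",
              x$c, x$a_cc, x$a_rr, x$a_cr, x$a_ss))
  invisible(x)
}

#' Fung strain energy density
#'
#' Strain energy per unit reference volume (kPa) of the Fung membrane law
#' at the given in-plane Green strain.
#'
#' @param E numeric length-3 vector `c(E_cc, E_rr, E_cr)`.
#' @param params a [fung_params()] object.
#' @return energy density (kPa).
#' @export
fung_energy <- function(E, params) {
  stopifnot(inherits(params, "fung_params"), length(E) == 3L)
  Q <- fung_Q(E, params)
  if (Q > 250)
    stop(sprintf(
      "fung_energy: exponent Q = %.3g overflows at strain (%.3g, %.3g, %.3g)",
      Q, E[1], E[2], E[3]), call. = FALSE)
  params$c / 2 * (exp(Q) - 1)
}

fung_Q <- function(E, p) {
  p$a_cc * E[1]^2 + p$a_rr * E[2]^2 + 2 * p$a_cr * E[1] * E[2] + p$a_ss * E[3]^2
}

#' Second Piola-Kirchhoff stress of the Fung membrane law
#'
#' Closed-form stress `S = dW/dE` of the Fung-type energy. With
#' `W = (c/2)(exp(Q) - 1)` this is
#' `S_cc = c e^Q (a_cc E_cc + a_cr E_rr)`,
#' `S_rr = c e^Q (a_rr E_rr + a_cr E_cc)`,
#' `S_cr = c e^Q a_ss E_cr` (the gradient with respect to the single
#' shear coordinate `E_cr`; the corresponding symmetric-tensor component
#' is half this value).
#'
#' @inheritParams fung_energy
#' @return numeric length-3 `c(S_cc, S_rr, S_cr)` in kPa.
#' @details The tangent stiffness at zero strain is
#'   `c * matrix(c(a_cc, a_cr, a_cr, a_rr), 2, 2)` for the direct
#'   components, which the test-suite checks analytically.
#' @export
fung_stress <- function(E, params) {
  stopifnot(inherits(params, "fung_params"), length(E) == 3L)
  Q <- fung_Q(E, params)
  if (Q > 250)
    stop(sprintf(
      "fung_stress: exponent Q = %.3g overflows at strain (%.3g, %.3g, %.3g)",
      Q, E[1], E[2], E[3]), call. = FALSE)
  eQ <- exp(Q)
  c(S_cc = params$c * eQ * (params$a_cc * E[1] + params$a_cr * E[2]),
    S_rr = params$c * eQ * (params$a_rr * E[2] + params$a_cr * E[1]),
    S_cr = params$c * eQ * params$a_ss * E[3])
}

#' Fit Fung membrane parameters to biaxial stress-strain data
#'
#' Least-squares fit of `(c, a_cc, a_rr, a_cr)` (shear exponent `a_ss`
#' kept at its `(a_cc + a_rr)/2` default) to equibiaxial or proportional
#' samples of circumferential and radial stress at prescribed Green
#' strains. The
#' fit is performed in log-`c` / unconstrained coordinates and projected
#' onto the positive-semi-definite constraint set if the optimum violates
#' it (with a warning).
#'
#' @param biaxial_samples a data frame (or tibble) with columns
#'   `E_cc`, `E_rr`, `S_cc`, `S_rr` — Green strains and the corresponding
#'   measured second Piola-Kirchhoff stresses (kPa).
#' @param leaflet label stored on the result.
#' @param start optional numeric start `c(c, a_cc, a_rr, a_cr)`.
#' @return a [fung_params()] object with attributes `residual`
#'   (root-mean-square stress residual, kPa) and `n` (samples used).
#' @export
fit_fung_params <- function(biaxial_samples, leaflet = "anterior",
                            start = c(5, 20, 10, 2)) {
  d <- as.data.frame(biaxial_samples)
  need <- c("E_cc", "E_rr", "S_cc", "S_rr")
  if (!all(need %in% names(d)))
    stop("fit_fung_params: samples need columns E_cc, E_rr, S_cc, S_rr",
         call. = FALSE)
  if (nrow(d) < 4L)
    stop("fit_fung_params: need at least 4 biaxial samples (under-determined)",
         call. = FALSE)
  if (all(abs(d$S_cc) < 1e-12) && all(abs(d$S_rr) < 1e-12))
    stop("fit_fung_params: degenerate data (all stresses zero)", call. = FALSE)
  if (diff(range(d$E_cc)) <= 0 || diff(range(d$E_rr)) <= 0)
    stop("fit_fung_params: samples must span both strain axes", call. = FALSE)

  pred <- function(th) {
    cc <- exp(th[1]); a1 <- th[2]; a2 <- th[3]; a3 <- th[4]
    Q <- a1 * d$E_cc^2 + a2 * d$E_rr^2 + 2 * a3 * d$E_cc * d$E_rr
    eQ <- exp(pmin(Q, 250))
    cbind(cc * eQ * (a1 * d$E_cc + a3 * d$E_rr),
          cc * eQ * (a2 * d$E_rr + a3 * d$E_cc))
  }
  obj <- function(th) {
    p <- pred(th)
    sum((p[, 1] - d$S_cc)^2 + (p[, 2] - d$S_rr)^2)
  }
  th0 <- c(log(start[1]), start[2], start[3], start[4])
  fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  th <- fit$par
  c_hat <- exp(th[1]); a1 <- th[2]; a2 <- th[3]; a3 <- th[4]
  if (a1 <= 0 || a2 <= 0 || a1 * a2 < a3^2) {
    warning("fit_fung_params: unconstrained optimum violates positive ",
            "semi-definiteness; projecting onto the constraint boundary")
    a1 <- max(a1, 1e-6); a2 <- max(a2, 1e-6)
    amax <- sqrt(a1 * a2)
    a3 <- sign(a3) * min(abs(a3), amax * (1 - 1e-9))
  }
  out <- fung_params(c = c_hat, a_cc = a1, a_rr = a2, a_cr = a3,
                     leaflet = leaflet)
  attr(out, "residual") <- sqrt(obj(c(log(c_hat), a1, a2, a3)) / (2 * nrow(d)))
  attr(out, "n") <- nrow(d)
  out
}

#' Ogden chordae material parameters
#'
#' One or more Ogden terms for the tension-only chordae cable law. Under
#' incompressible uniaxial extension at stretch `lambda >= 1` the axial
#' Cauchy stress is
#' \deqn{\sigma(\lambda) = \sum_p \mu_p
#'   \left(\lambda^{\alpha_p} - \lambda^{-\alpha_p/2}\right),}
#' and zero for `lambda < 1` (a slack cable carries no compression).
#'
#' @param mu numeric vector of moduli (kPa).
#' @param alpha numeric vector of exponents (same length as `mu`).
#' @param chorda_type `"marginal"` or `"strut"` (bookkeeping).
#' @return an object of class `ogden_params`.
#' @export
ogden_params <- function(mu, alpha, chorda_type = c("marginal", "strut")) {
  chorda_type <- match.arg(chorda_type)
  stopifnot(length(mu) == length(alpha), length(mu) >= 1L)
  if (sum(mu * alpha) <= 0)
    stop("ogden_params: need positive initial stiffness (sum mu*alpha > 0)",
         call. = FALSE)
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                 chorda_type = chorda_type),
            class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("Ogden cable parameters (%s chordae): %d term(s)\n",
              x$chorda_type, length(x$mu)))
  for (i in seq_along(x$mu))
    cat(sprintf("  mu = %.4g kPa, alpha = %.4g\n", x$mu[i], x$alpha[i]))
  invisible(x)
}

#' Axial Cauchy stress of a tension-only Ogden cable
#'
#' @param lambda stretch ratio (current length / rest length), `> 0`.
#'   Vectorized.
#' @param params an [ogden_params()] object.
#' @return axial Cauchy stress (kPa); `0` whenever `lambda < 1`.
#' @export
ogden_fiber_stress <- function(lambda, params) {
  stopifnot(inherits(params, "ogden_params"))
  if (any(lambda <= 0)) stop("ogden_fiber_stress: lambda must be > 0",
                             call. = FALSE)
  s <- vapply(lambda, function(l) {
    if (l < 1) return(0)
    sum(params$mu * (l^params$alpha - l^(-params$alpha / 2)))
  }, numeric(1))
  unname(s)
}

#' Axial chordal force
#'
#' Force transmitted by a chorda at stretch `lambda`: the Ogden fiber
#' stress times the reference cross-sectional area, directed along the
#' current chord axis; zero in the slack state.
#'
#' @inheritParams ogden_fiber_stress
#' @param area reference cross-sectional area (mm^2), `> 0`.
#' @return axial force in N (kPa * mm^2 = mN, converted).
#' @export
chordal_force <- function(lambda, params, area) {
  if (any(area <= 0)) stop("chordal_force: area must be > 0", call. = FALSE)
  ogden_fiber_stress(lambda, params) * area / 1000
}

#' Tissue-level constants of the valve apparatus
#'
#' @param thickness_anterior,thickness_posterior leaflet thicknesses (mm);
#'   defaults 0.69 and 0.51 mm.
#' @param density tissue density (kg/m^3); default 1100.
#' @param poisson Poisson's ratio; default 0.48, must be `< 0.5`. Enters
#'   the membrane kinematics as near-incompressibility: the thickness
#'   stretch follows the in-plane area change as
#'   `J_thickness = J_inplane^(-poisson/(1 - poisson))`.
#' @return an object of class `tissue_props`.
#' @export
tissue_props <- function(thickness_anterior = 0.69,
                         thickness_posterior = 0.51,
                         density = 1100, poisson = 0.48) {
  stopifnot(thickness_anterior > 0, thickness_posterior > 0, density > 0,
            poisson > 0, poisson < 0.5)
  structure(list(thickness_anterior = thickness_anterior,
                 thickness_posterior = thickness_posterior,
                 density = density, poisson = poisson),
            class = "tissue_props")
}

# internal mg/mm^3 (1 mg/mm^3 = 1e3 kg/m^3)
density_internal <- function(tissue) tissue$density / 1000

#' Default material parameter set
#'
#' The constitutive defaults the package ships: Fung membrane parameters
#' per leaflet (anterior stiffer than posterior), single-term Ogden
#' parameters per chorda type, chordal cross-sectional areas
#' (anterior marginal 0.29, posterior marginal 0.27, strut 0.61 mm^2) and
#' tissue constants. The leaflet and chordae coefficients are editable
#' defaults (plausible valve-tissue stiffness), not measured ground truth;
#' replace them via [read_materials()].
#'
#' @return a named list of class `mv_materials` with elements
#'   `fung$anterior`, `fung$posterior`, `ogden$marginal`, `ogden$strut`,
#'   `areas` (named: anterior_marginal, posterior_marginal, strut, mm^2)
#'   and `tissue`.
#' @export
default_materials <- function() {
  structure(list(
    fung = list(
      anterior  = fung_params(c = 8, a_cc = 35, a_rr = 20, a_cr = 10,
                              leaflet = "anterior"),
      posterior = fung_params(c = 6, a_cc = 30, a_rr = 18, a_cr = 8,
                              leaflet = "posterior")
    ),
    ogden = list(
      marginal = ogden_params(mu = 600, alpha = 12, chorda_type = "marginal"),
      strut    = ogden_params(mu = 450, alpha = 10, chorda_type = "strut")
    ),
    areas = c(anterior_marginal = 0.29, posterior_marginal = 0.27,
              strut = 0.61),
    tissue = tissue_props()
  ), class = "mv_materials")
}

#' Read / write a material parameter file
#'
#' Materials serialize to a YAML (or JSON) file with named blocks
#' `fung.anterior`, `fung.posterior`, `ogden.marginal`, `ogden.strut`,
#' `areas`, `tissue`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_materials()` returns an `mv_materials` list;
#'   `write_materials()` returns `path` invisibly.
#' @export
read_materials <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  f <- function(b, leaflet) fung_params(b$c, b$a_cc, b$a_rr, b$a_cr,
                                        a_ss = b$a_ss %||% (b$a_cc + b$a_rr) / 2,
                                        leaflet = leaflet)
  o <- function(b, type) ogden_params(unlist(b$mu), unlist(b$alpha),
                                      chorda_type = type)
  t <- x$tissue
  structure(list(
    fung = list(anterior = f(x$fung$anterior, "anterior"),
                posterior = f(x$fung$posterior, "posterior")),
    ogden = list(marginal = o(x$ogden$marginal, "marginal"),
                 strut = o(x$ogden$strut, "strut")),
    areas = unlist(x$areas),
    tissue = tissue_props(t$thickness_anterior, t$thickness_posterior,
                          t$density, t$poisson)
  ), class = "mv_materials")
}

#' @rdname read_materials
#' @param materials an `mv_materials` list as from [default_materials()].
#' @export
write_materials <- function(materials, path) {
  stopifnot(inherits(materials, "mv_materials"))
  x <- list(
    fung = lapply(materials$fung, function(p)
      list(c = p$c, a_cc = p$a_cc, a_rr = p$a_rr, a_cr = p$a_cr,
           a_ss = p$a_ss)),
    ogden = lapply(materials$ogden, function(p)
      list(mu = p$mu, alpha = p$alpha)),
    areas = as.list(materials$areas),
    tissue = unclass(materials$tissue)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
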