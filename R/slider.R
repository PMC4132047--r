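# Explicit-dynamics slider: an elastoplastic crystalline block driven along
# a viscoelastic amorphous plate, coupled through a Newtonian lubrication
# film (tangential viscous traction + squeeze damping + normal penalty).
# Plane-strain Q4 elements, central differences, lumped mass.

#' Elastoplastic material card (crystalline phase)
#'
#' @param youngs Young's modulus, GPa.
#' @param poisson Poisson ratio, in (0, 0.5).
#' @param yield Initial yield stress, GPa.
#' @param tangent Tangent (hardening) modulus, GPa; must be < `youngs`.
#' @param hardening_mix 0 = fully isotropic, 1 = fully kinematic.
#' @param density Mass density, kg/m^3.
#' @return A `silk_mat_plastic` list.
#' @export
elastoplastic_card <- function(youngs = 20, poisson = 0.3, yield = 2,
                               tangent = 2, hardening_mix = 0.5,
                               density = 1300) {
  if (poisson <= 0 || poisson >= 0.5) stop("poisson must be in (0, 0.5)")
  if (tangent >= youngs) stop("tangent modulus must be < youngs")
  if (hardening_mix < 0 || hardening_mix > 1) stop("hardening_mix in [0, 1]")
  structure(list(youngs = youngs, poisson = poisson, yield = yield,
                 tangent = tangent, hardening_mix = hardening_mix,
                 density = density),
            class = "silk_mat_plastic")
}

#' Viscoelastic material card (amorphous phase)
#'
#' Deviatoric relaxation `G(t) = Ginf + (G0 - Ginf) exp(-beta t)` with an
#' elastic bulk response.
#'
#' @param bulk Bulk modulus, GPa.
#' @param G0 Short-time shear modulus, GPa.
#' @param Ginf Long-time shear modulus, GPa (0 < Ginf <= G0).
#' @param beta Relaxation decay constant, 1/s.
#' @param density Mass density, kg/m^3.
#' @return A `silk_mat_visco` list.
#' @export
viscoelastic_card <- function(bulk = 4, G0 = 1.2, Ginf = 0.4, beta = 1e8,
                              density = 1300) {
  if (!(G0 >= Ginf && Ginf > 0)) stop("need G0 >= Ginf > 0")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(bulk = bulk, G0 = G0, Ginf = Ginf, beta = beta,
                 density = density),
            class = "silk_mat_visco")
}

#' Newtonian lubrication-film card
#'
#' @param eta Dynamic viscosity, Ns/m^2 (default: the interface coefficient
#'   of viscosity extracted by the friction pipeline, order 2e2).
#' @param h Film thickness, nm.
#' @return A `silk_mat_film` list.
#' @export
film_card <- function(eta = 200, h = 500) {
  if (eta <= 0 || h <= 0) stop("eta and h must be > 0")
  structure(list(eta = eta, h = h), class = "silk_mat_film")
}

#' Film shear traction
#'
#' Newton's law of shear viscosity across the film: traction
#' `tau = eta * dv / h`, applied so as to oppose the relative motion.
#'
#' @param dv Relative tangential velocity, m/s.
#' @param card A [film_card()].
#' @return Traction on the faster body, Pa (sign opposite to `dv`).
#' @export
#' @examples
#' film_traction(1, film_card(eta = 200, h = 1)) # -2e11 Pa
film_traction <- function(dv, card) {
  -card$eta * dv / (card$h * 1e-9)
}

#' Slider load case
#'
#' Geometry in nm. The crystalline block sits centered above the plate,
#' separated by the film thickness; its top edge is driven at `velocity`
#' along `load_angle` below the horizontal (a positive angle presses the
#' block into the plate).
#'
#' @param velocity Driving speed, m/s.
#' @param load_angle Degrees in [0, 90).
#' @param block Block width and height, nm.
#' @param plate Plate width and thickness, nm.
#' @param el Element size, nm (block and plate meshes are aligned).
#' @param slide_distance Sliding distance budget, nm; with
#'   `duration = NULL` the run lasts `min(slide_distance / velocity, t_auto)`
#'   where `t_auto` covers the film/material relaxation transient.
#' @param duration Run duration, s (overrides the automatic choice).
#' @return A `silk_slider_case` list.
#' @export
slider_case <- function(velocity, load_angle = 0, block = c(400, 400),
                        plate = c(1600, 100), el = 50, slide_distance = 400,
                        duration = NULL) {
  if (load_angle < 0 || load_angle >= 90) stop("load_angle must be in [0, 90)")
  if (velocity < 0) stop("velocity must be >= 0")
  structure(list(velocity = velocity, load_angle = load_angle,
                 block = block, plate = plate, el = el,
                 slide_distance = slide_distance, duration = duration),
            class = "silk_slider_case")
}

#' Single-point elastoplastic stress update (radial return)
#'
#' Small-strain J2 plasticity with bilinear isotropic/kinematic hardening;
#' the same routine drives the slider kernel.
#'
#' @param strain_inc Strain increment, Voigt `[xx, yy, zz, gamma_xy]`.
#' @param state List with `stress` (Pa, Voigt), `backstress`, `ep`;
#'   `NULL` starts from virgin state.
#' @param card An [elastoplastic_card()].
#' @return Updated state list (plus `wp`, the plastic work increment).
#' @export
plastic_update <- function(strain_inc, state = NULL, card = elastoplastic_card()) {
  if (is.null(state)) state <- list(stress = rep(0, 4), backstress = rep(0, 4),
                                    ep = 0)
  out <- plastic_update_cpp(strain_inc, state$stress, state$backstress,
                            state$ep, card$youngs * 1e9, card$poisson,
                            card$yield * 1e9, card$tangent * 1e9,
                            card$hardening_mix)
  list(stress = out$stress, backstress = out$backstress, ep = out$ep,
       wp = out$wp)
}

#' Single-point viscoelastic stress update
#'
#' Recursive exponential integration of the single-branch relaxation
#' kernel; the same routine drives the slider kernel.
#'
#' @param strain_inc Strain increment, Voigt `[xx, yy, zz, gamma_xy]`.
#' @param state List with `q` (branch deviatoric stress, Pa), `e`
#'   (deviatoric strain), `evol` (volumetric strain); `NULL` = virgin.
#' @param card A [viscoelastic_card()].
#' @param dt Time increment, s.
#' @return Updated state list with `stress` (Pa) and `dissipation`.
#' @export
viscoelastic_update <- function(strain_inc, state = NULL,
                                card = viscoelastic_card(), dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(state)) state <- list(q = rep(0, 4), e = rep(0, 4), evol = 0)
  out <- visco_update_cpp(strain_inc, state$q, state$e, state$evol,
                          card$bulk * 1e9, card$G0 * 1e9, card$Ginf * 1e9,
                          card$beta, dt)
  list(stress = out$stress, q = out$q, e = out$e, evol = out$evol,
       dissipation = out$dissipation)
}

# structured mesh for block-on-plate; returns 0-based connectivity for C++
.slider_mesh <- function(case, standoff_nm) {
  el <- case$el
  wb <- case$block[1]; hb <- case$block[2]
  wp <- case$plate[1]; hp <- case$plate[2]
  nxb <- as.integer(round(wb / el)); nyb <- as.integer(round(hb / el))
  nxp <- as.integer(round(wp / el)); nyp <- max(as.integer(round(hp / el)), 1L)
  x0b <- round((wp - wb) / 2 / el) * el

  grid_nodes <- function(x0, y0, nx, ny, dx, dy) {
    g <- expand.grid(ix = 0:nx, iy = 0:ny)
    cbind(x0 + g$ix * dx, y0 + g$iy * dy)
  }
  plate_nodes <- grid_nodes(0, 0, nxp, nyp, el, hp / nyp)
  block_nodes <- grid_nodes(x0b, hp + standoff_nm, nxb, nyb, el, hb / nyb)
  nodes <- rbind(block_nodes, plate_nodes) * 1e-9
  nb <- nrow(block_nodes)

  elems_grid <- function(nx, ny, offset) {
    e <- list(); k <- 0
    for (iy in 0:(ny - 1)) for (ix in 0:(nx - 1)) {
      n1 <- iy * (nx + 1) + ix
      k <- k + 1
      e[[k]] <- offset + c(n1, n1 + 1, n1 + nx + 2, n1 + nx + 1)
    }
    do.call(rbind, e)
  }
  el_b <- elems_grid(nxb, nyb, 0L)
  el_p <- elems_grid(nxp, nyp, nb)
  elems <- rbind(el_b, el_p)
  matid <- c(rep(0L, nrow(el_b)), rep(1L, nrow(el_p)))

  driven <- (nyb * (nxb + 1)):(nyb * (nxb + 1) + nxb)        # block top row
  fixed <- nb + 0:nxp                                        # plate bottom row
  bot_block <- 0:nxb                                         # block bottom row
  top_plate <- nb + nyp * (nxp + 1) + 0:nxp                  # plate top row
  plate_top_x <- plate_nodes[nyp * (nxp + 1) + 0:nxp + 1, 1]
  pair_j <- vapply(block_nodes[bot_block + 1, 1], function(x) {
    top_plate[which.min(abs(plate_top_x - x))]
  }, numeric(1))
  area <- rep(el * 1e-9, length(bot_block))
  area[c(1, length(area))] <- area[c(1, length(area))] / 2
  list(nodes = nodes, elems = elems, matid = matid,
       driven = as.integer(driven), fixed = as.integer(fixed),
       film_pairs = cbind(as.integer(bot_block), as.integer(pair_j)),
       film_area = area, el_m = el * 1e-9)
}

#' Run one slider load case
#'
#' Explicit central-difference integration with lumped mass: the block's
#' top edge is driven at the prescribed velocity, the plate base is fixed,
#' and the facing surfaces are coupled by the viscous film (implicit
#' pairwise update, so the film does not restrict the stable time step)
#' plus a normal penalty preventing penetration. Reports stress histories,
#' steady-state values and a full energy audit.
#'
#' @param case A [slider_case()].
#' @param crystal An [elastoplastic_card()].
#' @param amorphous A [viscoelastic_card()].
#' @param film A [film_card()].
#' @param kpen Normal penalty stiffness per unit area, Pa/m.
#' @param dt Time step, s; `NULL` uses 0.8x the CFL bound (dilatational
#'   wave crossing of the smallest element); larger values error, naming
#'   the stable bound.
#' @param record_every Record interval in steps.
#' @return A `silk_slider_result`: `history` tibble (times, von Mises
#'   stresses per phase, interface shear traction, energy terms), `steady`
#'   one-row tibble, `energy_error` (relative), `steady_flag`.
#' @export
run_slider_case <- function(case, crystal = elastoplastic_card(),
                            amorphous = viscoelastic_card(),
                            film = film_card(), kpen = 5e16, dt = NULL,
                            record_every = NULL) {
  stopifnot(inherits(case, "silk_slider_case"))
  standoff_nm <- film$h
  mesh <- .slider_mesh(case, standoff_nm)
  Ep <- crystal$youngs * 1e9
  lam_p <- Ep * crystal$poisson / ((1 + crystal$poisson) * (1 - 2 * crystal$poisson))
  mu_p <- Ep / (2 * (1 + crystal$poisson))
  Mp <- lam_p + 2 * mu_p
  Mv <- (amorphous$bulk + 4 / 3 * amorphous$G0) * 1e9
  cd <- sqrt(max(Mp / crystal$density, Mv / amorphous$density))
  hmin <- mesh$el_m
  dt_cfl <- 0.8 * hmin / cd
  m_node_min <- min(crystal$density, amorphous$density) * hmin^2 / 4
  dt_pen <- 0.5 * sqrt(m_node_min / (kpen * max(mesh$film_area)))
  dt_stable <- min(dt_cfl, dt_pen)
  if (is.null(dt)) {
    dt <- dt_stable
  } else if (dt > dt_stable) {
    stop(sprintf("dt = %.3g s violates the stability bound %.3g s", dt,
                 dt_stable), call. = FALSE)
  }

  V <- case$velocity
  th <- case$load_angle * pi / 180
  vdrive <- c(V * cos(th), -V * sin(th))
  h_m <- film$h * 1e-9
  if (is.null(case$duration)) {
    Gc <- mu_p
    Gp <- amorphous$Ginf * 1e9
    t_relax <- (film$eta / h_m) *
      (case$block[2] * 1e-9 / Gc + case$plate[2] * 1e-9 / Gp)
    tau_target <- film$eta * max(V, 1e-12) / h_m
    Hh <- Ep * crystal$tangent * 1e9 / (Ep - crystal$tangent * 1e9)
    t_pl <- if (sqrt(3) * tau_target > crystal$yield * 1e9 && V > 0) {
      1.8 * (sqrt(3) * tau_target - crystal$yield * 1e9) / Hh *
        case$block[2] * 1e-9 / V
    } else 0
    duration <- 12 * t_relax + t_pl + 2000 * dt
    if (V > 0) duration <- min(duration, case$slide_distance * 1e-9 / V)
    if (case$load_angle > 0 && V > 0) {
      duration <- case$slide_distance * 1e-9 / V
    }
  } else {
    duration <- case$duration
  }
  n_steps <- max(as.integer(ceiling(duration / dt)), 200L)
  if (is.null(record_every)) {
    record_every <- max(1L, as.integer(floor(n_steps / 600)))
  }

  out <- slider_run_cpp(
    mesh$nodes, mesh$elems, mesh$matid,
    list(youngs = Ep, poisson = crystal$poisson, yield = crystal$yield * 1e9,
         tangent = crystal$tangent * 1e9, mix = crystal$hardening_mix),
    list(bulk = amorphous$bulk * 1e9, G0 = amorphous$G0 * 1e9,
         Ginf = amorphous$Ginf * 1e9, beta = amorphous$beta),
    c(crystal$density, amorphous$density),
    mesh$driven, vdrive, mesh$fixed,
    mesh$film_pairs, mesh$film_area,
    film$eta, h_m, kpen, standoff_nm * 1e-9,
    0.9 * standoff_nm * 1e-9, dt, n_steps, as.integer(record_every))
  if (isTRUE(out$penetration_fail)) {
    stop(sprintf("film collapsed: penetration beyond tolerance at step %d",
                 out$step_fail), call. = FALSE)
  }
  hist <- tibble::tibble(
    time = out$time,
    vm_crystal = out$vm_crystal, vm_crystal_max = out$vm_crystal_max,
    vm_amorphous = out$vm_amorphous, vm_amorphous_max = out$vm_amorphous_max,
    tau_interface = out$tau_interface,
    W_ext = out$W_ext, KE = out$KE, E_stored = out$E_stored,
    D_plastic = out$D_plastic, D_visco = out$D_visco, D_film = out$D_film,
    E_penalty = out$E_penalty, min_gap = out$min_gap
  )
  nw <- max(5L, as.integer(nrow(hist) * 0.15))
  tailw <- utils::tail(hist, nw)
  ref <- mean(abs(tailw$tau_interface)) + 1e-12
  steady_flag <- (max(tailw$tau_interface) - min(tailw$tau_interface)) / ref < 0.01
  last <- utils::tail(hist, 1)
  ebal <- last$W_ext -
    (last$KE + last$E_stored + last$D_plastic + last$D_visco + last$D_film +
       last$E_penalty)
  escale <- max(abs(last$W_ext), last$KE + last$E_stored + last$D_plastic +
                  last$D_visco + last$D_film, 1e-300)
  steady <- tibble::tibble(
    velocity = V, load_angle = case$load_angle,
    tau_interface = mean(tailw$tau_interface),
    vm_crystal = mean(tailw$vm_crystal),
    vm_crystal_max = mean(tailw$vm_crystal_max),
    vm_amorphous = mean(tailw$vm_amorphous),
    vm_amorphous_max = mean(tailw$vm_amorphous_max)
  )
  structure(list(history = hist, steady = steady,
                 energy_error = abs(ebal) / escale,
                 steady_flag = steady_flag, dt = dt, n_steps = n_steps,
                 case = case),
            class = "silk_slider_result")
}

#' Steady stresses over a velocity sweep
#'
#' Runs [run_slider_case()] per velocity and collects steady-state
#' interface shear and phase von Mises stresses.
#'
#' @param velocities Velocities, m/s.
#' @param case Template [slider_case()] (its velocity is overwritten).
#' @param ... Passed to [run_slider_case()].
#' @return A `silk_slider_sweep` tibble.
#' @export
velocity_sweep <- function(velocities, case = slider_case(1), ...) {
  rows <- lapply(velocities, function(v) {
    cs <- case
    cs$velocity <- v
    res <- run_slider_case(cs, ...)
    dplyr::mutate(res$steady, energy_error = res$energy_error,
                  steady = res$steady_flag)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("silk_slider_sweep", class(out))
  out
}

#' @export
print.silk_slider_result <- function(x, ...) {
  s <- x$steady
  cat(sprintf(
    "slider case: V = %g m/s at %g deg -> tau_int = %.3g Pa, vm(crystal) = %.3g Pa, vm(amorphous) = %.3g Pa\n",
    s$velocity, s$load_angle, s$tau_interface, s$vm_crystal, s$vm_amorphous))
  cat(sprintf("  %d steps, dt = %.3g s, energy closure error %.2g%%, steady: %s\n",
              x$n_steps, x$dt, 100 * x$energy_error, x$steady_flag))
  invisible(x)
}
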