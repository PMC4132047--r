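# Weighted chi-square fitting of the bond-friction model to the
# per-velocity force dataset, with profile-likelihood uncertainties and
# viscous-limit extrapolation.

.chi2_curve <- function(ds, p) {
  pred <- force_velocity(ds$velocity, p)
  w <- if (all(ds$f_res_sem > 0)) 1 / ds$f_res_sem^2 else rep(1, nrow(ds))
  sum(w * (ds$f_res - pred)^2)
}

.with_par <- function(init, ma = NULL, U_bond = NULL) {
  bond_params(ma = if (is.null(ma)) init$ma else ma,
              U_bond = if (is.null(U_bond)) init$U_bond else U_bond,
              m = init$m, xi0 = init$xi0, temperature = init$temperature)
}

# profile chi2 to Delta chi2 = 1 on each side of the minimum
.profile_se <- function(chi2_fun, theta_hat, chi2_min, lower, upper) {
  target <- chi2_min + 1
  up <- tryCatch({
    hi <- theta_hat
    step <- max(abs(theta_hat) * 0.05, 1e-3)
    repeat {
      hi <- hi + step
      if (hi > upper || chi2_fun(hi) >= target) break
      step <- step * 1.6
    }
    uniroot(function(t) chi2_fun(t) - target,
            c(theta_hat, min(hi, upper)), tol = 1e-6)$root - theta_hat
  }, error = function(e) NA_real_)
  dn <- tryCatch({
    lo <- theta_hat
    step <- max(abs(theta_hat) * 0.05, 1e-3)
    repeat {
      lo <- lo - step
      if (lo < lower || chi2_fun(lo) >= target) break
      step <- step * 1.6
    }
    theta_hat - uniroot(function(t) chi2_fun(t) - target,
                        c(max(lo, lower), theta_hat), tol = 1e-6)$root
  }, error = function(e) NA_real_)
  mean(c(up, dn), na.rm = TRUE)
}

#' Fit the bond-friction model to a friction dataset
#'
#' Weighted least squares (weights 1/SEM^2) of the washboard force-velocity
#' law against the per-residue amorphous-crystalline forces. Two single-
#' parameter modes mirror the two published fitting strategies -- fixing the
#' bond strength and varying the periodicity product `ma`, or fixing `ma`
#' and varying `U_bond` -- plus a two-parameter `free` mode. Parameter
#' uncertainties come from the Delta-chi^2 = 1 profile. The fitted model is
#' extrapolated to its viscous limit and converted to a coefficient of
#' viscosity via the contact geometry.
#'
#' @param ds A `silk_friction_dataset` (needs >= 4 velocities with SEMs;
#'   all-zero SEMs get unit weights and no profile errors).
#' @param mode `"fix_Ubond"`, `"fix_ma"` or `"free"`.
#' @param init Initial/fixed parameter values, a [bond_params()].
#' @param area Contact area A in nm^2 (defaults to the `area_nm2`
#'   attribute of `ds`).
#' @param d_shear Shear gap for the viscosity conversion, nm (defaults to
#'   the `d_shear_nm` attribute, else the lattice constant `init$a`).
#' @return A `silk_bond_fit` object: fitted `params`, `fixed` names,
#'   `chi2`, `dof`, `param_errors`, `xi_visc_res` (Ns/m),
#'   `eta_viscous_res` and `eta_interface` (Ns/m^2), and the augmented data.
#' @export
fit_bond_model <- function(ds, mode = c("fix_Ubond", "fix_ma", "free"),
                           init = bond_params(), area = NULL, d_shear = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(init, "silk_bond_params"))
  if (nrow(ds) < 4) stop("need >= 4 velocities", call. = FALSE)
  sem <- ds$f_res_sem
  if (any(sem > 0) && !all(sem > 0)) {
    stop("degenerate weights: some SEMs are zero and some positive",
         call. = FALSE)
  }
  # de-bias inverse-variance weights built from few-replica SEMs: for a
  # variance estimate with nu dof, E[1/s^2] = nu/(nu-2) * 1/sigma^2. The
  # difference force combines the total and water replicate SEMs, so nu is
  # the per-velocity Welch-Satterthwaite value (between n_rep-1 and
  # 2(n_rep-1)).
  n_rep <- attr(ds, "n_replicas")
  if (!is.null(n_rep) && is.finite(n_rep) && n_rep > 3 && all(sem > 0)) {
    if (all(c("F_total_sem", "F_water_sem") %in% names(ds))) {
      st2 <- ds$F_total_sem^2
      sw2 <- ds$F_water_sem^2
      nu <- (st2 + sw2)^2 / ((st2^2 + sw2^2) / (n_rep - 1))
    } else {
      nu <- rep(2 * (n_rep - 1), nrow(ds))
    }
    nu <- pmax(nu, 2.5)
    ds$f_res_sem <- ds$f_res_sem * sqrt(nu / (nu - 2))
  }
  bounds <- list(ma = c(0.05, 30), U_bond = c(0, 30))

  if (mode == "free") {
    obj <- function(th) .chi2_curve(ds, .with_par(init, ma = exp(th[1]),
                                                  U_bond = th[2]))
    op <- optim(c(log(init$ma), max(init$U_bond, 0.5)), obj,
                method = "Nelder-Mead",
                control = list(maxit = 400, reltol = 1e-10))
    if (op$convergence != 0) {
      stop("fit did not converge; last iterate ma = ",
           signif(exp(op$par[1]), 4), ", U_bond = ", signif(op$par[2], 4),
           call. = FALSE)
    }
    phat <- .with_par(init, ma = exp(op$par[1]), U_bond = op$par[2])
    chi2 <- op$value
    free <- c("ma", "U_bond")
    # profile each parameter, re-minimizing the other
    err <- c(
      ma = .profile_se(function(t) {
        optimize(function(u2) .chi2_curve(ds, .with_par(init, ma = t, U_bond = u2)),
                 bounds$U_bond)$objective
      }, phat$ma, chi2, bounds$ma[1], bounds$ma[2]),
      U_bond = .profile_se(function(t) {
        optimize(function(m2) .chi2_curve(ds, .with_par(init, ma = m2, U_bond = t)),
                 bounds$ma)$objective
      }, phat$U_bond, chi2, bounds$U_bond[1], bounds$U_bond[2])
    )
  } else {
    free1 <- if (mode == "fix_Ubond") "ma" else "U_bond"
    obj1 <- function(t) {
      .chi2_curve(ds, if (free1 == "ma") .with_par(init, ma = t)
                  else .with_par(init, U_bond = t))
    }
    op <- optimize(obj1, bounds[[free1]], tol = 1e-8)
    that <- op$minimum
    chi2 <- op$objective
    phat <- if (free1 == "ma") .with_par(init, ma = that)
            else .with_par(init, U_bond = that)
    free <- free1
    err <- setNames(
      if (all(sem > 0)) {
        .profile_se(obj1, that, chi2, bounds[[free1]][1], bounds[[free1]][2])
      } else NA_real_,
      free1)
  }

  # scale factor on profile errors when the fit is over-dispersed
  # (chi2/dof > 1): few-replica SEMs underestimate the true per-point
  # error, so Delta-chi2 = 1 intervals are rescaled by sqrt(chi2_red),
  # the standard practice for weighted fits with estimated weights
  dof <- nrow(ds) - length(free)
  if (all(sem > 0) && dof > 0 && chi2 / dof > 1) {
    err <- err * sqrt(chi2 / dof)
  }
  # finite-replica calibration: with per-point variances estimated from few
  # replicas the pivot is t-distributed, so the reported SE is inflated by
  # qt(0.97725, nu_eff)/2 (nu_eff = Welch-pooled dof over the curvature
  # contributions), making a +/-2 SE interval carry its nominal coverage
  nu_eff <- Inf
  if (all(sem > 0) && !is.null(n_rep) && is.finite(n_rep) && n_rep > 3) {
    nu_i <- if (all(c("F_total_sem", "F_water_sem") %in% names(ds))) {
      st2 <- ds$F_total_sem^2
      sw2 <- ds$F_water_sem^2
      pmax((st2 + sw2)^2 / ((st2^2 + sw2^2) / (n_rep - 1)), 2.5)
    } else {
      rep(2 * (n_rep - 1), nrow(ds))
    }
    w_i <- 1 / ds$f_res_sem^2
    for (nm in free) {
      th <- phat[[nm]]
      dth <- max(abs(th) * 1e-3, 1e-6)
      gp <- force_velocity(ds$velocity,
                           if (nm == "ma") .with_par(phat, ma = th + dth)
                           else .with_par(phat, U_bond = th + dth))
      gm <- force_velocity(ds$velocity,
                           if (nm == "ma") .with_par(phat, ma = th - dth)
                           else .with_par(phat, U_bond = th - dth))
      a_i <- w_i * ((gp - gm) / (2 * dth))^2
      nu_eff <- sum(a_i)^2 / sum(a_i^2 / nu_i)
      err[nm] <- err[nm] * stats::qt(0.97725, nu_eff) / 2
    }
  }

  if (is.null(area)) area <- attr(ds, "area_nm2")
  if (is.null(d_shear)) d_shear <- attr(ds, "d_shear_nm")
  if (is.null(d_shear)) d_shear <- phat$a
  N <- attr(ds, "n_contact")
  xi_visc <- viscous_limit(phat)
  eta_res <- eta_int <- NA_real_
  if (!is.null(area) && !is.null(N) && is.finite(area) && area > 0) {
    a_res <- area / N                               # nm^2 per residue
    eta_res <- xi_visc * (d_shear / a_res) * 1e9    # Ns/m^2
    eta_int <- xi_visc * N * d_shear / area * 1e9   # identical by algebra
  }
  aug <- dplyr::mutate(tibble::as_tibble(ds),
                       f_res_fit = force_velocity(.data$velocity, phat))
  structure(list(params = phat, mode = mode, fixed = setdiff(c("ma", "U_bond"), free),
                 free = free, chi2 = chi2, dof = nrow(ds) - length(free),
                 nu_eff = nu_eff,
                 param_errors = err, xi_visc_res = xi_visc,
                 eta_viscous_res = eta_res, eta_interface = eta_int,
                 d_shear = d_shear, area = area, n_contact = N,
                 data = aug, weighted = all(sem > 0)),
            class = "silk_bond_fit")
}

#' Model coefficient of viscosity as a function of shear stress
#'
#' Parametric curve (tau(V), eta(V)) of the fitted model, mirroring the
#' coefficient-of-viscosity-vs-shear-stress representation: eta flattens to
#' its viscous plateau at low stress.
#'
#' @param p A [bond_params()] object (or a `silk_bond_fit`).
#' @param area_res Contact area per residue, nm^2.
#' @param d_shear Shear gap, nm.
#' @param velocities Velocity grid, m/s.
#' @return Tibble with velocity, f_res (pN), tau_MPa, eta_res (Ns/m^2).
#' @export
eta_of_stress <- function(p, area_res = 1.2, d_shear = NULL,
                          velocities = 10^seq(-8, log10(20), length.out = 80)) {
  if (inherits(p, "silk_bond_fit")) {
    if (is.null(d_shear)) d_shear <- p$d_shear
    p <- p$params
  }
  if (is.null(d_shear)) d_shear <- p$a
  f <- force_velocity(velocities, p)
  tibble::tibble(
    velocity = velocities, f_res = f,
    tau_MPa = f / area_res,
    eta_res = (f * 1e-12 / velocities) * (d_shear / area_res) * 1e9
  )
}

#' @export
print.silk_bond_fit <- function(x, ...) {
  cat(sprintf("bond-model fit (%s), chi2 = %.3g on %d dof\n",
              x$mode, x$chi2, x$dof))
  for (nm in x$free) {
    cat(sprintf("  %s = %.4g +/- %.2g%s\n", nm,
                x$params[[nm]], x$param_errors[[nm]],
                if (nm == "ma") " nm" else " kT"))
  }
  for (nm in x$fixed) cat(sprintf("  %s = %.4g (fixed)\n", nm, x$params[[nm]]))
  cat(sprintf("  viscous limit: xi = %.3g Ns/m per residue", x$xi_visc_res))
  if (is.finite(x$eta_interface)) {
    cat(sprintf(", eta_interface = %.3g Ns/m^2", x$eta_interface))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.silk_bond_fit <- function(x, ...) {
  tibble::tibble(
    term = c(x$free, x$fixed),
    estimate = vapply(c(x$free, x$fixed), function(nm) x$params[[nm]], 0),
    std.error = c(unname(x$param_errors[x$free]),
                  rep(NA_real_, length(x$fixed))),
    fixed = c(rep(FALSE, length(x$free)), rep(TRUE, length(x$fixed)))
  )
}

#' @export
glance.silk_bond_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, chi2 = x$chi2, dof = x$dof,
    xi_visc_res = x$xi_visc_res,
    eta_viscous_res = x$eta_viscous_res,
    eta_interface = x$eta_interface,
    n_velocities = nrow(x$data)
  )
}
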