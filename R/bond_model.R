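# Stochastic bond-friction model: steady-state force-velocity relation of an
# overdamped contact in a tilted periodic (washboard) potential, its
# independent Fokker-Planck quadrature oracle, and the viscous-limit
# extrapolation.
#
# Parameterization: a group of m cooperatively rupturing bonds is one
# effective particle in a cosine washboard of period a and peak-to-trough
# depth m*U_bond*kT, with microscopic background friction m*xi0. Per-residue
# force is the group force divided by m, so the relation depends on the
# parameters only through the products ma (nm) and m*U_bond.

#' Parameters of the bond-friction model
#'
#' @param ma Product of bond cooperativity and lattice constant, nm. The
#'   force-velocity relation depends on `m` and `a` only through this
#'   product (and on `m * U_bond`), which is why it is fitted as one
#'   parameter.
#' @param U_bond Bond strength in units of kT.
#' @param m Bond cooperativity (number of bonds rupturing as one unit).
#' @param xi0 Background per-residue friction coefficient, Ns/m.
#' @param temperature Temperature, K.
#' @return A `silk_bond_params` list (also carries `a = ma / m` in nm).
#' @export
#' @examples
#' p <- bond_params()
#' p$a
bond_params <- function(ma = 1.32, U_bond = 8.4, m = 2, xi0 = 1e-12,
                        temperature = 300) {
  if (!all(is.finite(c(ma, U_bond, m, xi0, temperature)))) {
    stop("bond parameters must be finite", call. = FALSE)
  }
  if (ma <= 0 || m < 1 || U_bond < 0 || xi0 <= 0 || temperature <= 0) {
    stop("require ma > 0, m >= 1, U_bond >= 0, xi0 > 0, temperature > 0",
         call. = FALSE)
  }
  structure(list(ma = ma, U_bond = U_bond, m = m, a = ma / m, xi0 = xi0,
                 temperature = temperature),
            class = "silk_bond_params")
}

# cached Gauss-Legendre rule on [0, pi/2]
.gl_env <- new.env(parent = emptyenv())
.gl_quarter <- function() {
  if (is.null(.gl_env$gl)) .gl_env$gl <- pracma::gaussLegendre(240, 0, pi / 2)
  .gl_env$gl
}
# unit-interval rule, rescaled on demand (node generation is costly)
.gl_unit <- function() {
  if (is.null(.gl_env$gl01)) .gl_env$gl01 <- pracma::gaussLegendre(240, 0, 1)
  .gl_env$gl01
}

# log of B(f,u) = (2/pi) Int_0^{pi/2} I0(2u cos t) cosh(2 f t) dt,
# the squared modulus |I_{if}(u)|^2 of the modified Bessel function of
# imaginary order. Evaluated in log space; boundary-layer quadrature for
# large tilt f.
.log_B <- function(f, u) {
  f <- abs(f)
  if (u == 0) {
    if (f < 1e-8) return(0)
    return(pi * f + log1p(-exp(-2 * pi * f)) - log(2) - log(pi * f))
  }
  if (f <= 20) {
    gl <- .gl_quarter()
    th <- gl$x
    li <- log(besselI(2 * u * cos(th), 0, expon.scaled = TRUE)) +
      2 * u * cos(th) +
      abs(2 * f * th) + log1p(exp(-2 * abs(2 * f * th))) - log(2)
    mx <- max(li)
    mx + log(sum(gl$w * exp(li - mx))) + log(2 / pi)
  } else {
    hi <- min(pi / 2, 30 / (2 * f))
    gl <- .gl_unit()
    t <- gl$x * hi
    g <- besselI(2 * u * sin(t), 0, expon.scaled = TRUE) * exp(2 * u * sin(t)) *
      exp(-2 * f * t) * (1 + exp(-2 * f * (pi - 2 * t)))
    pi * f - log(pi) + log(sum(gl$w * hi * g))
  }
}

# log mobility ratio mu(F)/mu0 = sinh(pi f)/(pi f |I_{if}(u)|^2), f >= 0
.log_mobility <- function(f, u) {
  if (u == 0) return(0)
  if (f < 1e-10) {
    return(-2 * (log(besselI(u, 0, expon.scaled = TRUE)) + u))
  }
  (pi * f + log1p(-exp(-2 * pi * f)) - log(2)) - log(pi * f) - .log_B(f, u)
}

# cached spline of log-mobility vs log f for a given well depth u: the fit
# evaluates thousands of force-velocity inversions at fixed u, and the
# mobility curve is smooth and monotone in log f
.mob_cache <- new.env(parent = emptyenv())
.mob_fun <- function(u) {
  key <- sprintf("u%.10e", u)
  fn <- .mob_cache[[key]]
  if (is.null(fn)) {
    lf <- seq(log(1e-9), log(1e5), length.out = 200)
    lm <- vapply(exp(lf), .log_mobility, numeric(1), u = u)
    sp <- stats::splinefun(lf, lm, method = "monoH.FC")
    lo <- lm[1]
    fn <- function(lfq) {
      out <- sp(pmin(pmax(lfq, log(1e-9)), log(1e5)))
      out[lfq < log(1e-9)] <- lo
      out[lfq > log(1e5)] <- 0
      out
    }
    if (length(ls(.mob_cache)) > 300) rm(list = ls(.mob_cache), envir = .mob_cache)
    .mob_cache[[key]] <- fn
  }
  fn
}

# group force (N) at prescribed mean velocity V (m/s) for dimensionless well
# depth parameter u, period a (m), group friction xig (Ns/m), thermal kT (J)
.invert_mobility <- function(V, u, a, xig, kT, mob = NULL) {
  if (V == 0) return(0)
  sgn <- sign(V)
  V <- abs(V)
  logV <- log(V)
  lmob <- if (is.null(mob)) function(lf) .log_mobility(exp(lf), u) else mob
  gfun <- function(lF) {
    lF - log(xig) + lmob(lF + log(a / (kT * 2 * pi))) - logV
  }
  lo <- log(xig * V) - 1e-7
  hi <- log(xig * V) + 2 * (log(besselI(u, 0, expon.scaled = TRUE)) + u) + 1e-4
  if (hi <= lo) return(sgn * xig * V)
  sgn * exp(uniroot(gfun, c(lo, hi), tol = 1e-12)$root)
}

#' Per-residue friction force at a prescribed sliding velocity
#'
#' Closed-form solution of the overdamped washboard model: the mobility of a
#' particle in a tilted cosine potential, expressed through modified Bessel
#' functions of imaginary order, inverted to give the mean force that
#' sustains sliding at velocity `V`. Odd in `V`; tends to `xi0 * V` for
#' `U_bond = 0` and to the amplified viscous law `viscous_limit(p) * V` as
#' `V -> 0`.
#'
#' @param V Sliding velocity, m/s (vectorized).
#' @param p A [bond_params()] object.
#' @return Per-residue friction force in pN.
#' @export
#' @examples
#' force_velocity(c(0.02, 2, 20), bond_params())
force_velocity <- function(V, p) {
  stopifnot(inherits(p, "silk_bond_params"))
  kT <- .kB * p$temperature
  u <- p$m * p$U_bond / 2
  a <- p$a * 1e-9
  xig <- p$m * p$xi0
  mob <- .mob_fun(u)
  vapply(V, function(v) {
    if (!is.finite(v)) stop("velocity must be finite")
    .invert_mobility(v, u, a, xig, kT, mob = mob) / p$m * .pN_per_N
  }, numeric(1))
}

# Stratonovich mean velocity at fixed group force (independent oracle route):
# v = (kT / (xig a)) (1 - e^{-Fhat}) / Itilde,
# Itilde = (1/4pi^2) IntInt e^{u(cos(phi+psi)-cos phi) - Fhat psi/(2pi)}
.strat_velocity <- function(Fg, u, a, xig, kT, n = 160) {
  Fhat <- Fg * a / kT
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # split psi integration when the tilt factor decays fast
  brk <- 2 * pi * min(1, 40 / max(Fhat, 40))
  g1 <- pracma::gaussLegendre(n, 0, brk)
  ps <- g1$x
  w <- g1$w
  if (brk < 2 * pi) {
    g2 <- pracma::gaussLegendre(n, brk, 2 * pi)
    ps <- c(ps, g2$x)
    w <- c(w, g2$w)
  }
  M <- exp(u * (cos(outer(phi, ps, "+")) - cos(phi)) -
             rep(Fhat * ps / (2 * pi), each = n))
  Itilde <- sum((2 * pi / n) * (M %*% w)) / (4 * pi^2)
  kT / (xig * a) * (1 - exp(-Fhat)) / Itilde
}

#' Fokker-Planck oracle for the force-velocity relation
#'
#' Independent numerical route: the Stratonovich double-integral expression
#' for the stationary drift of an overdamped particle in a tilted cosine
#' washboard, evaluated by direct quadrature and inverted numerically for
#' the force at prescribed velocity. Shares no algebra with
#' [force_velocity()]; used to guard it.
#'
#' @param V Sliding velocity, m/s (vectorized).
#' @param p A [bond_params()] object.
#' @param rel_tol Relative tolerance on the mobility integrals; the
#'   quadrature order is doubled until two successive evaluations agree to
#'   this tolerance (error if not reached).
#' @return Per-residue friction force in pN.
#' @export
#' @examples
#' fp_oracle(2, bond_params())
fp_oracle <- function(V, p, rel_tol = 1e-6) {
  stopifnot(inherits(p, "silk_bond_params"))
  kT <- .kB * p$temperature
  u <- p$m * p$U_bond / 2
  a <- p$a * 1e-9
  xig <- p$m * p$xi0
  one <- function(v) {
    if (v == 0) return(0)
    sgn <- sign(v)
    v <- abs(v)
    vel <- function(Fg) {
      n <- 160
      last <- .strat_velocity(Fg, u, a, xig, kT, n)
      for (it in 1:4) {
        n <- n * 2
        cur <- .strat_velocity(Fg, u, a, xig, kT, n)
        if (abs(cur - last) <= rel_tol * abs(cur)) return(cur)
        last <- cur
      }
      stop("fp_oracle quadrature did not converge", call. = FALSE)
    }
    lo <- xig * v * (1 - 1e-7)
    hi <- xig * v * exp(2 * (log(besselI(u, 0, expon.scaled = TRUE)) + u)) *
      (1 + 1e-4)
    Fg <- uniroot(function(FF) log(vel(FF)) - log(v), c(lo, hi),
                  tol = max(lo * 1e-10, 1e-30))$root
    sgn * Fg / p$m * .pN_per_N
  }
  vapply(V, one, numeric(1))
}

#' Viscous-limit friction coefficient
#'
#' Closed-form low-velocity limit of the bond model: the background friction
#' amplified by the corrugation, `xi_visc = xi0 * I0(m U_bond / 2)^2`
#' (Zwanzig's result for a cosine potential). This is the per-residue
#' friction coefficient the model extrapolates to in the viscous regime.
#'
#' @param p A [bond_params()] object.
#' @return Per-residue viscous friction coefficient, Ns/m.
#' @export
#' @examples
#' viscous_limit(bond_params(U_bond = 0)) # = xi0
viscous_limit <- function(p) {
  stopifnot(inherits(p, "silk_bond_params"))
  u <- p$m * p$U_bond / 2
  p$xi0 * exp(2 * (log(besselI(u, 0, expon.scaled = TRUE)) + u))
}

#' Brownian-dynamics cross-check of the washboard mobility
#'
#' Simulates the overdamped particle in the tilted cosine potential at fixed
#' force and returns the empirical mean velocity; an independent stochastic
#' oracle for [force_velocity()] / [fp_oracle()].
#'
#' @param force_pN Applied group force, pN.
#' @param p A [bond_params()] object.
#' @param n_steps,n_burn Production / burn-in steps.
#' @param dt_frac Time step as a fraction of the corrugation relaxation time.
#' @param seed RNG seed.
#' @return List with `velocity` (m/s) and `se` (block standard error).
#' @export
washboard_bd <- function(force_pN, p, n_steps = 2e6, n_burn = 1e5,
                         dt_frac = 2e-3, seed = 1) {
  stopifnot(inherits(p, "silk_bond_params"))
  kT <- .kB * p$temperature
  u <- p$m * p$U_bond / 2
  a <- p$a * 1e-9
  xig <- p$m * p$xi0
  # relaxation time within one well: xi a^2 / (kT (2 pi)^2 max(u,1))
  dt <- dt_frac * xig * a^2 / (kT * (2 * pi)^2 * max(u, 1))
  set.seed(seed)
  nblock <- 10
  per <- as.integer(floor(n_steps / nblock))
  vs <- numeric(nblock)
  for (b in seq_len(nblock)) {
    noise <- rnorm(n_burn + per)
    vs[b] <- washboard_bd_cpp(force_pN * 1e-12, a, u * kT, xig, kT, dt,
                              as.integer(n_burn), per, noise)
  }
  list(velocity = mean(vs), se = sd(vs) / sqrt(nblock))
}

# per-residue bond-force lookup table for the pull emulator (N vs m/s)
.bond_force_table <- function(p, v_lo = 1e-8, v_hi = 1e3, n = 400) {
  vg <- 10^seq(log10(v_lo), log10(v_hi), length.out = n)
  fg <- force_velocity(vg, p) * 1e-12
  list(v = vg, f = fg)
}

#' @export
print.silk_bond_params <- function(x, ...) {
  cat(sprintf(
    "bond model: ma = %.3g nm (m = %g), U_bond = %.3g kT, xi0 = %.3g Ns/m, T = %g K\n",
    x$ma, x$m, x$U_bond, x$xi0, x$temperature))
  cat(sprintf("  viscous limit: %.3g Ns/m per residue\n", viscous_limit(x)))
  invisible(x)
}
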