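# Peak-force extraction, replica statistics, water subtraction and stress
# conversion: turns raw pulling traces into the per-velocity friction
# dataset the bond model is fitted to.

#' Peak force of a pulling trace
#'
#' Maximum of the running-mean-smoothed force signal.
#'
#' @param trace A trace tibble with a `force_pN` column.
#' @param smooth_window Running-mean window in samples (default 50).
#' @return Peak force, pN.
#' @export
#' @examples
#' tr <- tibble::tibble(force_pN = c(1:100, 99:1))
#' peak_force(tr, smooth_window = 5) # ~100
peak_force <- function(trace, smooth_window = 50) {
  f <- trace$force_pN
  if (length(f) == 0) stop("empty trace", call. = FALSE)
  w <- max(1L, min(as.integer(smooth_window), length(f)))
  if (w == 1L) return(max(f))
  sm <- stats::filter(f, rep(1 / w, w), sides = 2)
  max(sm, na.rm = TRUE)
}

#' Aggregate traces into a per-velocity friction dataset
#'
#' Per velocity: replica mean and SEM of the peak force for the crystal
#' pulls (total) and the water-only pulls; their difference is the
#' amorphous-crystalline friction force, with SEMs combined in quadrature.
#' The per-residue force divides by the number of contacting residues
#' (the force is taken as equally shared by all contacting residues).
#'
#' @param traces Tibble from [generate_dataset()] / [read_traces()].
#' @param n_contact Contacting residues N (defaults to the generator truth
#'   attached to `traces`, if any).
#' @param n_total Total pulled residues.
#' @param smooth_window Passed to [peak_force()].
#' @return A `silk_friction_dataset` tibble: velocity, F_total, F_total_sem,
#'   F_water, F_water_sem, F_ac, F_ac_sem, f_res, f_res_sem (pN), with
#'   `n_contact`, `n_total`, `n_replicas` attributes.
#' @export
aggregate_traces <- function(traces, n_contact = NULL, n_total = NULL,
                             smooth_window = 50) {
  truth <- attr(traces, "truth")
  if (is.null(n_contact)) {
    if (is.null(truth)) stop("n_contact not given and no truth attribute")
    n_contact <- truth$n_contact
  }
  if (is.null(n_total)) {
    n_total <- if (!is.null(truth)) truth$n_total else NA_real_
  }
  peaks <- traces |>
    dplyr::group_by(.data$velocity, .data$kind, .data$replica) |>
    dplyr::group_modify(~ tibble::tibble(peak = peak_force(.x, smooth_window))) |>
    dplyr::ungroup()
  n_rep <- peaks |>
    dplyr::count(.data$velocity, .data$kind) |>
    dplyr::pull(.data$n)
  if (any(n_rep < 2)) stop("need >= 2 replicas per velocity/kind", call. = FALSE)
  stats <- peaks |>
    dplyr::group_by(.data$velocity, .data$kind) |>
    dplyr::summarise(mean = mean(.data$peak),
                     sem = sd(.data$peak) / sqrt(dplyr::n()),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(stats, names_from = "kind",
                             values_from = c("mean", "sem"))
  if (!all(c("mean_total", "mean_water_only") %in% names(wide)) ||
      anyNA(wide$mean_total) || anyNA(wide$mean_water_only)) {
    stop("total and water-only traces must share the same velocity grid",
         call. = FALSE)
  }
  out <- tibble::tibble(
    velocity = wide$velocity,
    F_total = wide$mean_total, F_total_sem = wide$sem_total,
    F_water = wide$mean_water_only, F_water_sem = wide$sem_water_only
  ) |>
    dplyr::mutate(
      F_ac = .data$F_total - .data$F_water,
      F_ac_sem = sqrt(.data$F_total_sem^2 + .data$F_water_sem^2),
      f_res = .data$F_ac / n_contact,
      f_res_sem = .data$F_ac_sem / n_contact
    ) |>
    dplyr::arrange(.data$velocity)
  attr(out, "n_contact") <- n_contact
  attr(out, "n_total") <- n_total
  attr(out, "n_replicas") <- max(n_rep)
  class(out) <- c("silk_friction_dataset", class(out))
  out
}

#' Fit the linear water-friction law
#'
#' Zero-intercept weighted least squares of the water drag force against
#' `N_total * V` (`F_w = N xi_w V`): the straight-line viscous law the
#' water friction follows. Weights are 1/SEM^2 where SEMs are positive;
#' unit weights otherwise.
#'
#' @param ds A `silk_friction_dataset`.
#' @param n_total Pulled residues (defaults to the dataset attribute).
#' @return List with `xi_water` (Ns/m per residue), `se`, `n_velocities`.
#' @export
fit_water_law <- function(ds, n_total = NULL) {
  if (is.null(n_total)) n_total <- attr(ds, "n_total")
  if (is.null(n_total) || !is.finite(n_total)) stop("n_total required")
  if (nrow(ds) < 3) stop("need >= 3 velocities", call. = FALSE)
  x <- n_total * ds$velocity          # residues * m/s
  y <- ds$F_water * 1e-12             # N
  semN <- ds$F_water_sem * 1e-12
  w <- if (all(semN > 0)) 1 / semN^2 else rep(1, length(y))
  sxx <- sum(w * x^2)
  if (sxx <= 0) stop("singular design in water-law fit", call. = FALSE)
  slope <- sum(w * x * y) / sxx
  # standard WLS slope error: scaled by the weighted residual variance, as
  # lm() does, so misspecified per-point errors still give an honest SE
  res <- y - slope * x
  n <- length(y)
  se <- if (n > 1) sqrt(sum(w * res^2) / (n - 1) / sxx) else NA_real_
  list(xi_water = slope, se = se, n_velocities = nrow(ds))
}

#' Convert friction forces to shear stress and apparent viscosity
#'
#' Shear stress is the amorphous-crystalline force over the contact area
#' (pN/nm^2 = MPa). The apparent per-residue viscosity uses Newton's law
#' with a shear gap `d_shear`: `eta_res = (f_res / V) * d_shear / A_res`,
#' `A_res = A / N`.
#'
#' @param ds A `silk_friction_dataset`.
#' @param area Contact area A, nm^2.
#' @param d_shear Shear gap, nm (defaults to the washboard lattice
#'   constant 0.66 nm).
#' @return The dataset with `tau_MPa` and `eta_res` (Ns/m^2) columns and an
#'   `area_nm2` attribute.
#' @export
to_stress <- function(ds, area, d_shear = 0.66) {
  if (!is.numeric(area) || area <= 0) stop("contact area must be > 0",
                                           call. = FALSE)
  N <- attr(ds, "n_contact")
  a_res <- area / N
  out <- dplyr::mutate(
    ds,
    tau_MPa = .data$F_ac / area,
    eta_res = (.data$f_res * 1e-12 / .data$velocity) * (d_shear / a_res) * 1e9
  )
  attr(out, "area_nm2") <- area
  attr(out, "d_shear_nm") <- d_shear
  attr(out, "n_contact") <- N
  attr(out, "n_total") <- attr(ds, "n_total")
  attr(out, "n_replicas") <- attr(ds, "n_replicas")
  class(out) <- unique(c("silk_friction_dataset", class(out)))
  out
}
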