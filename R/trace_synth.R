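# Synthetic force-probe pulling: overdamped Langevin emulation of
# constant-velocity spring pulling of the amorphous bundles along the
# crystal interface (and through water alone).

#' Pulling protocol
#'
#' @param velocity Spring velocity, m/s.
#' @param spring_k Spring constant, pN/nm (830 pN/nm by default, the value
#'   used in the force-probe simulations this emulates). The seven bundle
#'   springs act on one effective coordinate, so the total stiffness is
#'   `n_springs * spring_k`.
#' @param n_springs Number of pulled bundles (one spring each).
#' @param n_replicas Independent replicas per condition.
#' @param temperature Temperature, K (0 switches thermal noise off).
#' @param dt Time step, s; `NULL` chooses `1e-4 * xi_total / k_spring`
#'   (a fraction of the relaxation time), capped at the stability bound.
#' @param seed Integer seed for this protocol's noise stream.
#' @param with_crystal If `FALSE`, the bundles are dragged through water
#'   only (no bond friction).
#' @return A `silk_pull_protocol` list.
#' @export
pull_protocol <- function(velocity, spring_k = 830, n_springs = 7,
                          n_replicas = 4, temperature = 300, dt = NULL,
                          seed = 1, with_crystal = TRUE) {
  if (velocity <= 0) stop("velocity must be > 0", call. = FALSE)
  if (spring_k <= 0) stop("spring_k must be > 0", call. = FALSE)
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(velocity = velocity, spring_k = spring_k,
                 n_springs = n_springs, n_replicas = n_replicas,
                 temperature = temperature, dt = dt, seed = seed,
                 with_crystal = with_crystal),
            class = "silk_pull_protocol")
}

#' Ground truth for the pull emulator
#'
#' The generator's defaults are the study conditions: bond model at
#' `U_bond = 8.4`, `ma = 1.32` nm, per-residue water friction 1e-12 Ns/m,
#' 1344 pulled residues (7 bundles x 8 chains x 24 residues), full-contact
#' hold of 5.6 nm (bundle length minus crystal length) followed by linear
#' contact decay over 2.8 nm (the crystal length along the pulling axis).
#'
#' @param bond A [bond_params()] object.
#' @param xi_water_res Per-residue water friction coefficient, Ns/m.
#' @param n_contact Number of residues in contact with the crystal.
#' @param n_total Total pulled residues (water drag acts on all of them).
#' @param hold_length Slide distance with full contact, nm.
#' @param detach_length Slide distance over which contact decays to zero, nm.
#' @return A `silk_ground_truth` list.
#' @export
ground_truth <- function(bond = bond_params(), xi_water_res = 1e-12,
                         n_contact = 200, n_total = 1344,
                         hold_length = 5.6, detach_length = 2.8) {
  stopifnot(inherits(bond, "silk_bond_params"))
  if (xi_water_res <= 0) stop("xi_water_res must be > 0", call. = FALSE)
  if (n_contact > n_total) stop("n_contact must be <= n_total", call. = FALSE)
  structure(list(bond = bond, xi_water_res = xi_water_res,
                 n_contact = n_contact, n_total = n_total,
                 hold_length = hold_length, detach_length = detach_length),
            class = "silk_ground_truth")
}

# shared scaffolding: one Langevin pull (SI in, tidy ps/nm/pN out)
.simulate_one <- function(protocol, truth, replica, kind, table, start_steady) {
  V <- protocol$velocity
  k <- protocol$spring_k * 1e-12 / 1e-9 * protocol$n_springs # N/m total
  kT <- .kB * max(protocol$temperature, 0)
  cw <- truth$n_total * truth$xi_water_res
  N0 <- if (kind == "total") truth$n_contact else 0
  hold <- truth$hold_length * 1e-9
  detach <- truth$detach_length * 1e-9

  # differential friction at the protocol velocity sets the relaxation time
  dGdv_num <- function(v) {
    eps <- v * 1e-3
    fb <- approx(table$v, table$f, xout = c(v - eps, v + eps), rule = 2)$y
    N0 * diff(fb) / (2 * eps) + cw
  }
  xi_diff <- dGdv_num(V)
  dt_stab <- 0.5 * cw / k
  dt <- protocol$dt
  slide <- hold + detach
  if (is.null(dt)) {
    # a small fraction of the relaxation time, floored so a trace stays
    # within ~4e5 steps, capped by the stability bound
    dt <- min(max(1e-4 * xi_diff / k, slide / V / 4e5), dt_stab)
  } else if (dt > 2 * cw / k) {
    stop(sprintf("dt = %.3g s unstable; stable bound is %.3g s (2 xi_min / k)",
                 dt, 2 * cw / k), call. = FALSE)
  }
  n_max <- as.integer(min(ceiling(slide / V / dt * 1.2) + 2000, 3e6))
  # ~200 recorded samples per trace: the default 50-sample smoothing window
  # of the peak extractor then averages about a quarter of the trace, which
  # suppresses the extreme-value bias of a maximum taken over correlated
  # thermal noise
  record_every <- max(1L, as.integer(floor(slide / V / dt / 200)))
  noise <- if (protocol$temperature > 0) rnorm(n_max) else numeric(0)
  out <- pull_langevin_cpp(V, k, dt, kT, N0, cw, hold, detach,
                           table$v, table$f, noise, start_steady,
                           record_every, n_max)
  tibble::tibble(
    time_ps = out$time * 1e12,
    spring_pos_nm = out$spring_pos * 1e9,
    bundle_pos_nm = out$x * 1e9,
    force_pN = out$force * 1e12,
    velocity = V, replica = replica, kind = kind
  )
}

#' Simulate one constant-velocity pull against the crystal interface
#'
#' Overdamped Langevin integration of one effective bundle coordinate: the
#' moving spring force balances bond friction on the contacting residues
#' (washboard model at the instantaneous sliding speed), linear water drag
#' on all pulled residues, and thermal noise obeying fluctuation-dissipation
#' with the local differential friction. The contact count stays full over
#' `hold_length` of slide, decays linearly to zero over `detach_length`,
#' and the trace ends at detachment. By default the replica starts in
#' developed steady sliding (spring pre-tensioned); `start = "rest"` keeps
#' the loading transient instead.
#'
#' @param protocol A [pull_protocol()].
#' @param truth A [ground_truth()].
#' @param replica Replica id (also offsets the noise stream).
#' @param start `"steady"` or `"rest"`.
#' @return A `PullTrace` tibble (time_ps, spring_pos_nm, bundle_pos_nm,
#'   force_pN, velocity, replica, kind).
#' @export
#' @examples
#' tr <- simulate_pull(pull_protocol(2, n_replicas = 1, seed = 7),
#'                     ground_truth(n_contact = 50, n_total = 200))
#' max(tr$force_pN) > 0
simulate_pull <- function(protocol, truth, replica = 1,
                          start = c("steady", "rest")) {
  stopifnot(inherits(protocol, "silk_pull_protocol"),
            inherits(truth, "silk_ground_truth"))
  start <- match.arg(start)
  set.seed(protocol$seed + 7919L * (replica - 1L))
  table <- .bond_force_table(truth$bond)
  kind <- if (protocol$with_crystal) "total" else "water_only"
  .simulate_one(protocol, truth, replica, kind, table, start == "steady")
}

#' Simulate a water-only drag pull (no crystalline units)
#'
#' Same protocol as [simulate_pull()] with the bond contribution switched
#' off; the trace covers the same slide distance.
#'
#' @inheritParams simulate_pull
#' @return A `PullTrace` tibble with `kind = "water_only"`.
#' @export
simulate_water_pull <- function(protocol, truth, replica = 1,
                                start = c("steady", "rest")) {
  protocol$with_crystal <- FALSE
  simulate_pull(protocol, truth, replica, start)
}

#' Generate a full synthetic pulling dataset
#'
#' For every velocity, `n_replicas` crystal pulls and `n_replicas`
#' water-only pulls; per-trace seeds are derived deterministically from the
#' master seed (seed + 1000*velocity index + replica-stream offset), so a
#' fixed master seed reproduces the dataset bit-exactly.
#'
#' @param velocities Velocity grid, m/s (default: the seven study
#'   velocities 0.02-20 m/s).
#' @param protocol Template [pull_protocol()] (its velocity/seed fields are
#'   overwritten per condition).
#' @param truth A [ground_truth()].
#' @param seed Master seed.
#' @param start Start condition passed to [simulate_pull()].
#' @return A tibble of all traces, with the generation settings in
#'   attributes `truth` and `velocities`.
#' @export
generate_dataset <- function(velocities = c(0.02, 0.05, 0.2, 0.5, 2, 5, 20),
                             protocol = pull_protocol(1), truth = ground_truth(),
                             seed = 1, start = c("steady", "rest")) {
  start <- match.arg(start)
  if (any(velocities <= 0) || any(velocities > 100)) {
    stop("velocities must lie in (0, 100] m/s", call. = FALSE)
  }
  table <- .bond_force_table(truth$bond)
  rows <- list()
  for (iv in seq_along(velocities)) {
    for (kind in c("total", "water_only")) {
      for (r in seq_len(protocol$n_replicas)) {
        pr <- protocol
        pr$velocity <- velocities[iv]
        pr$with_crystal <- kind == "total"
        set.seed(seed + 1000L * iv + 100000L * (kind == "water_only") +
                   7919L * (r - 1L))
        rows[[length(rows) + 1L]] <-
          .simulate_one(pr, truth, r, kind, table, start == "steady")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  attr(out, "velocities") <- velocities
  attr(out, "n_replicas") <- protocol$n_replicas
  out
}

#' Write a trace dataset as per-trace CSV files plus a JSON manifest
#'
#' @param traces Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- unique(traces[, c("velocity", "replica", "kind")])
  files <- character(nrow(key))
  for (i in seq_len(nrow(key))) {
    sub <- dplyr::semi_join(traces, key[i, ], by = c("velocity", "replica", "kind"))
    files[i] <- sprintf("trace_%s_V%g_r%d.csv", key$kind[i], key$velocity[i],
                        key$replica[i])
    write.csv(sub[, c("time_ps", "spring_pos_nm", "bundle_pos_nm", "force_pN")],
              file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- list(velocities = attr(traces, "velocities"),
                   n_replicas = attr(traces, "n_replicas"),
                   files = data.frame(key, file = files))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a trace dataset written by [write_traces()]
#'
#' @param dir Directory containing the CSVs and `manifest.json`.
#' @return A traces tibble as produced by [generate_dataset()].
#' @export
read_traces <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rows <- lapply(seq_len(nrow(man$files)), function(i) {
    df <- read.csv(file.path(dir, man$files$file[i]))
    df$velocity <- man$files$velocity[i]
    df$replica <- man$files$replica[i]
    df$kind <- man$files$kind[i]
    df
  })
  out <- tibble::as_tibble(dplyr::bind_rows(rows))
  attr(out, "velocities") <- man$velocities
  attr(out, "n_replicas") <- man$n_replicas
  out
}
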