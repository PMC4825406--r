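#' Molecular-dynamics configuration
#'
#' @param timestep integration step, fs (the droplet protocol uses 0.25
#'   fs).
#' @param n_steps number of velocity-Verlet steps.
#' @param initial_temperature Maxwell-Boltzmann draw temperature, K.
#' @param heating optional list \code{(t_start, t_end, duration_ps)}: the
#'   thermostat target is interpolated linearly from \code{t_start} to
#'   \code{t_end} over \code{duration_ps}, then held.
#' @param thermostat \code{"none"} (NVE) or \code{"rescale"} (velocity
#'   rescaling every \code{rescale_interval} steps).
#' @param rescale_interval steps between rescalings.
#' @param seed RNG seed for the initial velocities.
#' @param log_interval store every k-th frame (energies are logged for
#'   every step regardless).
#' @return list of class \code{qmmd_md_config}.
#' @export
md_config <- function(timestep = 0.25, n_steps = 100L,
                      initial_temperature = 0, heating = NULL,
                      thermostat = c("none", "rescale"),
                      rescale_interval = 10L, seed = 1L,
                      log_interval = 1L) {
  stopifnot(timestep > 0, n_steps >= 0, initial_temperature >= 0)
  thermostat <- match.arg(thermostat)
  if (!is.null(heating)) {
    stopifnot(all(c("t_start", "t_end", "duration_ps") %in% names(heating)),
              heating$t_start >= 0, heating$t_end >= 0,
              heating$duration_ps > 0)
  }
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 initial_temperature = initial_temperature,
                 heating = heating, thermostat = thermostat,
                 rescale_interval = as.integer(rescale_interval),
                 seed = as.integer(seed),
                 log_interval = as.integer(log_interval)),
            class = "qmmd_md_config")
}

#' Kinetic energy and instantaneous temperature
#'
#' @param velocities n x 3, Angstrom/fs.
#' @param masses amu.
#' @return list \code{kinetic} (kcal/mol) and \code{temperature} (K, with
#'   3N degrees of freedom).
#' @export
kinetic_temperature <- function(velocities, masses) {
  ke <- 0.5 * sum(masses * rowSums(velocities^2)) /
    qmmd_constants$akma_accel
  ndof <- 3 * length(masses)
  list(kinetic = ke,
       temperature = 2 * ke / (ndof * qmmd_constants$kB_kcalmol))
}

#' Maxwell-Boltzmann initial velocities
#'
#' Draws velocities at the requested temperature and removes the net linear
#' momentum. Deterministic given the seed.
#'
#' @param masses amu (non-empty).
#' @param temperature K.
#' @param seed RNG seed.
#' @return n x 3 matrix, Angstrom/fs.
#' @export
initialize_velocities <- function(masses, temperature, seed = 1L) {
  n <- length(masses)
  if (n == 0L) stop("no atoms")
  if (temperature == 0) return(matrix(0, n, 3))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sd <- sqrt(qmmd_constants$kB_kcalmol * temperature *
               qmmd_constants$akma_accel / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # remove centre-of-mass momentum
  p <- colSums(v * masses)
  sweep(v, 2, p / sum(masses))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' MM force backend for dynamics
#'
#' @param topology a \code{\link{topology_spec}}.
#' @param nb a \code{\link{nonbonded_config}}.
#' @param restraint optional \code{\link{spherical_restraint}}.
#' @return closure \code{f(positions)} returning \code{energy} (kcal/mol),
#'   \code{forces} and \code{extras}.
#' @export
mm_backend <- function(topology, nb = nonbonded_config(),
                       restraint = NULL) {
  force(topology); force(nb); force(restraint)
  function(x) {
    r <- mm_energy_forces(x, topology, nb, restraint)
    list(energy = r$energy, forces = r$forces, extras = list())
  }
}

#' QM/MM force backend for dynamics
#'
#' Ground- or excited-state on-the-fly QM/MM forces; per-frame ground and
#' followed-state energies are logged, and for excited-state runs the
#' vertical emission energy (excited minus ground) is recorded in eV and
#' nm.
#'
#' @param geom full-system \code{qmmd_geometry}.
#' @param partition a \code{\link{build_partition}} result.
#' @param qc a \code{\link{qm_config}}.
#' @param nb a \code{\link{nonbonded_config}}.
#' @param restraint optional restraint.
#' @return closure as for \code{\link{mm_backend}}; extras carry
#'   \code{e_ground}, \code{e_excited} (hartree) and \code{emission_ev},
#'   \code{emission_nm}.
#' @export
qmmm_backend <- function(geom, partition, qc, nb = nonbonded_config(),
                         restraint = NULL) {
  force(geom); force(partition); force(qc); force(nb); force(restraint)
  function(x) {
    r <- total_energy_forces(x, geom, partition, qc, nb, restraint)
    eg <- r$state_energies[1L]
    ee <- if (qc$state_index > 0L) {
      r$state_energies[qc$state_index + 1L]
    } else NA_real_
    em_ev <- if (is.na(ee)) NA_real_ else
      (ee - eg) * qmmd_constants$ev_per_hartree
    list(energy = r$report$E_tot, forces = r$forces,
         extras = list(e_ground = eg, e_excited = ee,
                       emission_ev = em_ev,
                       emission_nm = if (is.na(em_ev)) NA_real_ else
                         qmmd_constants$evnm / em_ev,
                       report = r$report))
  }
}

#' One velocity-Verlet step
#'
#' Standard half-kick / drift / half-kick update.
#'
#' @param state list with \code{positions}, \code{velocities},
#'   \code{forces}, \code{masses}, \code{time}.
#' @param backend force backend closure.
#' @param dt timestep, fs.
#' @return updated state (with the new backend evaluation in
#'   \code{energy}/\code{extras}).
#' @export
velocity_verlet_step <- function(state, backend, dt) {
  acc <- state$forces * qmmd_constants$akma_accel / state$masses
  v_half <- state$velocities + 0.5 * dt * acc
  x_new <- state$positions + dt * v_half
  ev <- backend(x_new)
  if (!is.finite(ev$energy)) {
    stop("non-finite energy in force backend at t = ", state$time + dt,
         " fs")
  }
  acc_new <- ev$forces * qmmd_constants$akma_accel / state$masses
  v_new <- v_half + 0.5 * dt * acc_new
  list(positions = x_new, velocities = v_new, forces = ev$forces,
       energy = ev$energy, extras = ev$extras, masses = state$masses,
       time = state$time + dt)
}

#' Run molecular dynamics
#'
#' Velocity-Verlet propagation over an arbitrary energy/force backend with
#' optional linear heating and velocity-rescaling temperature control. The
#' trajectory is deterministic given the seed. A non-finite energy aborts
#' the run with a warning; the frames up to the last good step are
#' returned with \code{aborted = TRUE}.
#'
#' @param positions initial coordinates, n x 3 Angstrom.
#' @param masses amu.
#' @param backend force backend closure
#'   (\code{\link{mm_backend}} / \code{\link{qmmm_backend}}).
#' @param config a \code{\link{md_config}}.
#' @param velocities optional initial velocities (drawn from
#'   Maxwell-Boltzmann at \code{initial_temperature} when absent).
#' @return object of class \code{qmmd_trajectory}: \code{frames} (list of
#'   positions/velocities snapshots every \code{log_interval} steps,
#'   always including step 0), \code{energies} (per-step data.frame:
#'   step, time_fs, potential, kinetic, total, temperature, e_ground,
#'   e_excited, emission_ev, emission_nm), \code{masses}, \code{config}.
#' @export
run_md <- function(positions, masses, backend, config = md_config(),
                   velocities = NULL) {
  x <- as.matrix(positions)
  if (is.null(velocities)) {
    velocities <- initialize_velocities(masses, config$initial_temperature,
                                        config$seed)
  }
  ev0 <- backend(x)
  state <- list(positions = x, velocities = velocities,
                forces = ev0$forces, energy = ev0$energy,
                extras = ev0$extras, masses = masses, time = 0)
  grab <- function(state, step) {
    kt <- kinetic_temperature(state$velocities, state$masses)
    ex <- state$extras
    data.frame(step = step, time_fs = state$time,
               potential = state$energy, kinetic = kt$kinetic,
               total = state$energy + kt$kinetic,
               temperature = kt$temperature,
               e_ground = ex$e_ground %||% NA_real_,
               e_excited = ex$e_excited %||% NA_real_,
               emission_ev = ex$emission_ev %||% NA_real_,
               emission_nm = ex$emission_nm %||% NA_real_)
  }
  energies <- grab(state, 0L)
  frames <- list(list(step = 0L, time_fs = 0,
                      positions = state$positions,
                      velocities = state$velocities))
  aborted <- FALSE
  if (config$n_steps > 0L) {
    target_T <- function(t_fs) {
      hh <- config$heating
      if (is.null(hh)) return(config$initial_temperature)
      frac <- min(1, t_fs / (hh$duration_ps * 1000))
      hh$t_start + frac * (hh$t_end - hh$t_start)
    }
    for (s in seq_len(config$n_steps)) {
      new_state <- tryCatch(
        velocity_verlet_step(state, backend, config$timestep),
        error = function(e) e)
      if (inherits(new_state, "error")) {
        warning("MD aborted at step ", s, ": ",
                conditionMessage(new_state),
                "; returning trajectory up to the last good frame")
        aborted <- TRUE
        break
      }
      state <- new_state
      state$masses <- masses
      if (config$thermostat == "rescale" &&
          s %% config$rescale_interval == 0L) {
        kt <- kinetic_temperature(state$velocities, masses)
        Tt <- target_T(state$time)
        if (kt$temperature > 0 && Tt >= 0) {
          state$velocities <- state$velocities *
            sqrt(Tt / kt$temperature)
        }
      }
      energies <- rbind(energies, grab(state, s))
      if (s %% config$log_interval == 0L || s == config$n_steps) {
        frames[[length(frames) + 1L]] <-
          list(step = s, time_fs = state$time,
               positions = state$positions,
               velocities = state$velocities)
      }
    }
  }
  structure(list(frames = frames, energies = energies, masses = masses,
                 config = config, aborted = aborted),
            class = "qmmd_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qmmd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<qmmd_trajectory: %d frames, %.3f fs%s>\n",
    nrow(x$energies), max(x$energies$time_fs),
    if (x$aborted) " (ABORTED)" else ""))
  invisible(x)
}

#' Emission-energy analysis
#'
#' Histograms the per-frame vertical emission energies of an excited-state
#' trajectory on a wavelength grid (default bin width 10 nm) and reports
#' the mean and standard deviation in both nm and eV, plus the minimum
#' emission energy.
#'
#' @param trajectory a \code{qmmd_trajectory} with emission energies, or a
#'   numeric vector of emission wavelengths (nm).
#' @param bin_width_nm histogram bin width, nm.
#' @return list of class \code{qmmd_emission}: \code{histogram}
#'   (data.frame: nm_lo, nm_hi, count), \code{mean_nm}, \code{sd_nm},
#'   \code{mean_ev}, \code{sd_ev}, \code{min_ev}, \code{min_nm} (longest
#'   wavelength), \code{n}.
#' @export
emission_analysis <- function(trajectory, bin_width_nm = 10) {
  nm <- if (inherits(trajectory, "qmmd_trajectory")) {
    trajectory$energies$emission_nm
  } else as.numeric(trajectory)
  nm <- nm[is.finite(nm)]
  if (length(nm) == 0L) {
    stop("trajectory carries no emission energies (ground-state run?)")
  }
  ev <- qmmd_constants$evnm / nm
  lo <- floor(min(nm) / bin_width_nm) * bin_width_nm
  hi <- ceiling(max(nm) / bin_width_nm) * bin_width_nm
  if (hi <= lo) hi <- lo + bin_width_nm
  breaks <- seq(lo, hi, by = bin_width_nm)
  cnt <- graphics::hist(nm, breaks = breaks, plot = FALSE)$counts
  structure(list(
    histogram = data.frame(nm_lo = breaks[-length(breaks)],
                           nm_hi = breaks[-1], count = cnt),
    mean_nm = mean(nm), sd_nm = stats::sd(nm),
    mean_ev = mean(ev), sd_ev = stats::sd(ev),
    min_ev = min(ev), min_nm = max(nm), n = length(nm)),
    class = "qmmd_emission")
}

#' @export
print.qmmd_emission <- function(x, ...) {
  cat(sprintf(
    "<qmmd_emission: %d frames, %.1f +- %.1f nm (%.2f +- %.2f eV), min %.2f eV>\n",
    x$n, x$mean_nm, x$sd_nm, x$mean_ev, x$sd_ev, x$min_ev))
  invisible(x)
}
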