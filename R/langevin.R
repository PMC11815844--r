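#' Configuration for the one-dimensional steered-pulling simulator
#'
#' Defines an overdamped Langevin particle dragged by a harmonic guide
#' along a scalar reaction coordinate (the membrane normal, in Angstrom).
#' The ground-truth free-energy landscape is a sum of Gaussian components
#' over a flat baseline, so every estimator downstream can be checked
#' against a known answer.
#'
#' The guide potential is `k/2 (x - lambda)^2` with `lambda` moving at the
#' configured velocity; external work is accumulated in the stiff-spring
#' convention `dW = k (lambda - x) dlambda`.
#'
#' @param potential Ground-truth potential: a data frame (or list of
#'   lists) with columns `height` (kcal/mol), `center` (Angstrom) and
#'   `width` (Angstrom, Gaussian sigma). `NULL` or zero rows means a flat
#'   landscape.
#' @param friction Friction coefficient gamma, kcal mol^-1 ns A^-2.
#'   Default 0.05, i.e. a diffusivity `kB*T/gamma` of about 12 A^2/ns at
#'   310.15 K, typical of a small solute in water.
#' @param temperature Bath temperature, Kelvin. `0` gives deterministic
#'   dynamics.
#' @param spring_constant Guide spring constant k, kcal mol^-1 A^-2
#'   (default 10).
#' @param velocity Pulling speed, Angstrom per ns (default 1).
#' @param timestep Integration step, ns (default 1e-3).
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   traces.
#' @return An object of class `langevin_config`.
#' @seealso [simulate_steered_pull()], [generate_work_ensemble()]
#' @export
#' @examples
#' cfg <- langevin_config(potential = data.frame(height = 5, center = 20,
#'                                               width = 3))
#' tr <- simulate_steered_pull(cfg, 0, 5)
#' tail(tr$work, 1)
langevin_config <- function(potential = NULL, friction = 0.05,
                            temperature = 310.15, spring_constant = 10,
                            velocity = 1, timestep = 1e-3, seed = 1L) {
  pot <- normalize_potential(potential)
  stopifnot_scalar(friction, "friction", positive = TRUE)
  stopifnot_scalar(spring_constant, "spring_constant", positive = TRUE)
  stopifnot_scalar(velocity, "velocity", positive = TRUE)
  stopifnot_scalar(timestep, "timestep", positive = TRUE)
  stopifnot_scalar(temperature, "temperature")
  if (temperature < 0) stop("`temperature` must be >= 0")
  if (timestep >= 2 * friction / spring_constant) {
    stop("timestep too large for stable integration: require ",
         "timestep < 2 * friction / spring_constant")
  }
  structure(
    list(potential = pot, friction = friction, temperature = temperature,
         spring_constant = spring_constant, velocity = velocity,
         timestep = timestep, seed = as.integer(seed)),
    class = "langevin_config"
  )
}

normalize_potential <- function(potential) {
  if (is.null(potential)) {
    return(data.frame(height = numeric(), center = numeric(),
                      width = numeric()))
  }
  if (is.list(potential) && !is.data.frame(potential)) {
    potential <- do.call(rbind, lapply(potential, function(p) {
      data.frame(height = p$height, center = p$center, width = p$width)
    }))
  }
  if (!is.data.frame(potential) ||
      !all(c("height", "center", "width") %in% names(potential))) {
    stop("`potential` needs columns height, center, width")
  }
  if (nrow(potential) && (!all(is.finite(as.matrix(potential))) ||
                          any(potential$width <= 0))) {
    stop("invalid configuration: non-finite potential parameters or ",
         "non-positive widths")
  }
  potential[c("height", "center", "width")]
}

#' Evaluate the ground-truth potential of a simulator configuration
#'
#' @param config A [langevin_config()] (or a bare potential data frame).
#' @param x Positions (Angstrom).
#' @return Potential energy U(x) in kcal/mol (flat baseline at 0).
#' @export
potential_energy <- function(config, x) {
  pot <- if (inherits(config, "langevin_config")) config$potential
         else normalize_potential(config)
  u <- numeric(length(x))
  for (j in seq_len(nrow(pot))) {
    u <- u + pot$height[j] * exp(-0.5 * ((x - pot$center[j]) / pot$width[j])^2)
  }
  u
}

#' Simulate one steered pull along the reaction coordinate
#'
#' Integrates the overdamped Langevin equation while the guide centre
#' moves from `start` to `end` at the configured velocity, and records the
#' accumulated external work. The pulled span must correspond to a whole
#' number of integration steps (`|end - start| / (velocity * timestep)`
#' integer), so the guide lands exactly on `end`.
#'
#' @param config A [langevin_config()].
#' @param start,end Guide start / end positions (Angstrom); `end != start`.
#' @param x0 Initial particle position (defaults to `start`; staged
#'   protocols hand over the previous stage's final position here).
#' @param seed RNG seed for this trace (defaults to `config$seed`).
#' @param stage_id,replica_id Integer labels stored on the trace.
#' @return A `work_trace`: list with `time` (ns), `lambda` (guide centre,
#'   A), `position` (A), `work` (kcal/mol, `work[1] == 0`), plus the
#'   labels and seed.
#' @export
simulate_steered_pull <- function(config, start, end, x0 = start,
                                  seed = config$seed, stage_id = 1L,
                                  replica_id = 1L) {
  if (!inherits(config, "langevin_config")) {
    stop("`config` must be a langevin_config")
  }
  stopifnot_scalar(start, "start")
  stopifnot_scalar(end, "end")
  stopifnot_scalar(x0, "x0")
  if (end == start) stop("zero-length pull: `end` must differ from `start`")
  span <- abs(end - start)
  n_exact <- span / (config$velocity * config$timestep)
  n_steps <- round(n_exact)
  if (n_steps < 1L || abs(n_exact - n_steps) > 1e-6 * max(1, n_exact)) {
    stop("pull span must be a whole number of integration steps; ",
         "got span/(velocity*timestep) = ", format(n_exact))
  }
  sgn <- sign(end - start)
  kT <- .kB * config$temperature
  set.seed(seed)
  noise <- if (config$temperature > 0) rnorm(n_steps) else numeric(n_steps)
  out <- sim_pull_impl(x0, start, sgn, config$velocity, config$timestep,
                       as.integer(n_steps), config$spring_constant,
                       config$friction, kT,
                       config$potential$height, config$potential$center,
                       config$potential$width, noise)
  structure(
    list(time = out$time, lambda = out$lambda, position = out$position,
         work = out$work, stage_id = as.integer(stage_id),
         replica_id = as.integer(replica_id), seed = as.integer(seed)),
    class = "work_trace"
  )
}

#' Generate an ensemble of independent pulling replicas
#'
#' Replica `i` is reproducible in isolation: its seed is derived
#' deterministically from `(seed, i)`, so re-running a single replica
#' gives the identical trace.
#'
#' @inheritParams simulate_steered_pull
#' @param n_replicas Number of replicas (>= 1); the staged protocol uses
#'   25 per stage.
#' @param seed Ensemble base seed.
#' @return List of `work_trace` objects with `replica_id` 1..n.
#' @export
generate_work_ensemble <- function(config, start, end, n_replicas,
                                   seed = config$seed, x0 = start,
                                   stage_id = 1L) {
  if (!is.numeric(n_replicas) || length(n_replicas) != 1L ||
      n_replicas < 1) {
    stop("`n_replicas` must be >= 1")
  }
  lapply(seq_len(n_replicas), function(i) {
    simulate_steered_pull(config, start, end, x0 = x0,
                          seed = derive_seed(seed, i),
                          stage_id = stage_id, replica_id = i)
  })
}

#' @export
print.work_trace <- function(x, ...) {
  cat(sprintf(
    "<work_trace> stage %d replica %d: lambda %.2f -> %.2f A, %d samples, final W = %.3f kcal/mol\n",
    x$stage_id, x$replica_id, x$lambda[1], tail(x$lambda, 1),
    length(x$work), tail(x$work, 1)))
  invisible(x)
}

final_work <- function(trace) tail(trace$work, 1L)
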