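#' Plan a staged pulling protocol
#'
#' Splits the reaction-coordinate span into contiguous stages of
#' `stage_width`; the last stage is truncated when the span is not an
#' integer multiple of the width. The canonical protocol divides a ~40 A
#' membrane span into 8 stages of 5 A with 25 replicas each at 1 A/ns.
#'
#' @param span_start,span_end Span of the reaction coordinate (Angstrom).
#' @param stage_width Width of each stage (Angstrom, > 0).
#' @param n_replicas Replicas per stage (>= 1).
#' @param velocity Pulling speed (Angstrom/ns, > 0).
#' @return A `stage_plan`: list with `stages` (data frame of start/end),
#'   `stage_width`, `n_replicas`, `velocity` and `direction`
#'   ("forward" if `span_end > span_start`, else "backward").
#' @export
#' @examples
#' plan_stages(0, 40, 5, 25, 1)$stages # 8 stages of 5 A
plan_stages <- function(span_start, span_end, stage_width, n_replicas,
                        velocity) {
  stopifnot_scalar(span_start, "span_start")
  stopifnot_scalar(span_end, "span_end")
  stopifnot_scalar(stage_width, "stage_width", positive = TRUE)
  stopifnot_scalar(velocity, "velocity", positive = TRUE)
  if (n_replicas < 1) stop("`n_replicas` must be >= 1")
  if (span_end == span_start) stop("zero-length span")
  sgn <- sign(span_end - span_start)
  span <- abs(span_end - span_start)
  n_full <- floor(span / stage_width + 1e-9)
  edges <- span_start + sgn * stage_width * seq(0, n_full)
  if (abs(edges[length(edges)] - span_end) > 1e-9) {
    edges <- c(edges, span_end)
  }
  structure(
    list(stages = data.frame(start = edges[-length(edges)],
                             end = edges[-1]),
         stage_width = stage_width, n_replicas = as.integer(n_replicas),
         velocity = velocity,
         direction = if (sgn > 0) "forward" else "backward"),
    class = "stage_plan"
  )
}

#' @export
print.stage_plan <- function(x, ...) {
  cat(sprintf("<stage_plan> %d %s stages of <= %g A, %d replicas, %g A/ns\n",
              nrow(x$stages), x$direction, x$stage_width, x$n_replicas,
              x$velocity))
  invisible(x)
}

#' Jarzynski free-energy estimate from final work values
#'
#' Estimates `dF = -(1/beta) * log( mean_i exp(-beta * W_i) )` with a
#' shifted-exponential (log-sum-exp) scheme, so large `beta * W` cannot
#' underflow. By Jensen's inequality the estimate never exceeds the
#' arithmetic mean of the works, and it is bounded above by
#' `min(W) + log(N)/beta`.
#'
#' @param works Finite nonequilibrium work values, kcal/mol (>= 1).
#' @param thermo A [thermo_params()].
#' @return Free-energy difference in kcal/mol.
#' @export
#' @examples
#' jarzynski_free_energy(c(0, 10), thermo_params())
jarzynski_free_energy <- function(works, thermo = thermo_params()) {
  if (length(works) == 0L) stop("empty work ensemble")
  if (!is.numeric(works) || !all(is.finite(works))) {
    stop("non-finite work values")
  }
  beta <- thermo$beta
  -logmeanexp(-beta * works) / beta
}

#' Pointwise Jarzynski free-energy profile for one stage
#'
#' Applies the Jarzynski estimator at every grid point, interpolating
#' each replica's accumulated work at that guide position (linear
#' interpolation; traces are densely sampled). The segment is anchored to
#' zero at its first grid point, i.e. at the stage start.
#'
#' @param traces List of `work_trace` objects from a single stage.
#' @param grid Reaction-coordinate values within the stage span.
#' @param thermo A [thermo_params()].
#' @return A `pmf_profile` segment (grid, free_energy, empty
#'   stage_boundaries).
#' @export
jarzynski_profile <- function(traces, grid, thermo = thermo_params()) {
  if (length(traces) == 0L) stop("empty trace list")
  sids <- vapply(traces, function(t) t$stage_id, integer(1))
  if (length(unique(sids)) != 1L) {
    stop("all traces must come from a single stage")
  }
  lo <- min(traces[[1]]$lambda)
  hi <- max(traces[[1]]$lambda)
  if (any(grid < lo - 1e-9) || any(grid > hi + 1e-9)) {
    stop("grid extends outside the stage span [", lo, ", ", hi, "]")
  }
  w <- vapply(traces, function(t) {
    approx(t$lambda, t$work, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  w <- matrix(w, nrow = length(grid))
  fe <- apply(w, 1L, jarzynski_free_energy, thermo = thermo)
  pmf_profile(grid, fe - fe[1L])
}

#' Select the replica closest to the Jarzynski average
#'
#' The staged protocol hands the final frame of the replica whose final
#' work is closest to the stage's Jarzynski estimate to the next stage.
#' Ties are broken deterministically by the lowest replica id.
#'
#' @param traces Non-empty list of `work_trace` objects.
#' @param thermo A [thermo_params()].
#' @return The selected trace's `replica_id`.
#' @export
select_representative_replica <- function(traces,
                                          thermo = thermo_params()) {
  if (length(traces) == 0L) stop("empty trace list")
  ids <- vapply(traces, function(t) t$replica_id, integer(1))
  ord <- order(ids)
  works <- vapply(traces[ord], final_work, numeric(1))
  dF <- jarzynski_free_energy(works, thermo)
  ids[ord][which.min(abs(works - dF))]
}

#' PMF profile container
#'
#' @param grid Reaction-coordinate values (Angstrom).
#' @param free_energy Free energy at each grid point (kcal/mol),
#'   `free_energy[1] == 0`.
#' @param stage_boundaries Grid indices where stages join.
#' @param replica_chain Selected representative replica per stage.
#' @return An object of class `pmf_profile`.
#' @export
pmf_profile <- function(grid, free_energy,
                        stage_boundaries = integer(0),
                        replica_chain = integer(0)) {
  if (length(grid) != length(free_energy)) {
    stop("grid and free_energy lengths differ")
  }
  if (length(free_energy) && abs(free_energy[1]) > 1e-12) {
    stop("free_energy must be anchored to 0 at the first grid point")
  }
  structure(list(grid = grid, free_energy = free_energy,
                 stage_boundaries = as.integer(stage_boundaries),
                 replica_chain = as.integer(replica_chain)),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "<pmf_profile> %d points over [%.2f, %.2f] A, %d stage boundaries, range [%.3f, %.3f] kcal/mol\n",
    length(x$grid), min(x$grid), max(x$grid),
    length(x$stage_boundaries), min(x$free_energy), max(x$free_energy)))
  invisible(x)
}

#' Run the full staged pulling protocol on the toy simulator
#'
#' For each stage: generate the replica ensemble (all replicas start from
#' the handed-over particle position), estimate the stage free-energy
#' segment pointwise, select the representative replica (closest final
#' work to the Jarzynski average) and hand its final position to the next
#' stage. Segments are concatenated with offset matching, so the profile
#' is continuous at stage boundaries by construction.
#'
#' @param plan A [plan_stages()] plan; its velocity overrides the
#'   simulator config's.
#' @param config A [langevin_config()] holding the ground-truth potential
#'   and bath parameters.
#' @param thermo A [thermo_params()].
#' @param seed Integer seed governing all stages (stage `s` uses a seed
#'   derived from `(seed, s)`).
#' @param grid_spacing Profile grid spacing within each stage (Angstrom).
#' @return A `pmf_profile` across the full span, with `stage_boundaries`
#'   and the selected `replica_chain`.
#' @export
run_asmd <- function(plan, config, thermo = thermo_params(), seed = 1L,
                     grid_spacing = 0.25) {
  if (!inherits(plan, "stage_plan")) stop("`plan` must be a stage_plan")
  if (!inherits(config, "langevin_config")) {
    stop("`config` must be a langevin_config")
  }
  if (plan$n_replicas < 1) stop("stage with zero replicas")
  cfg <- config
  cfg$velocity <- plan$velocity
  x0 <- plan$stages$start[1]
  grid_all <- numeric(0)
  fe_all <- numeric(0)
  bounds <- integer(0)
  chain <- integer(0)
  offset <- 0
  for (s in seq_len(nrow(plan$stages))) {
    st <- plan$stages$start[s]
    en <- plan$stages$end[s]
    sgn <- sign(en - st)
    traces <- generate_work_ensemble(cfg, st, en, plan$n_replicas,
                                     seed = derive_seed(seed, s),
                                     x0 = x0, stage_id = s)
    grid <- seq(st, en, by = sgn * grid_spacing)
    if (abs(grid[length(grid)] - en) > 1e-9) grid <- c(grid, en)
    seg <- jarzynski_profile(traces, grid, thermo)
    rid <- select_representative_replica(traces, thermo)
    chain <- c(chain, rid)
    x0 <- tail(traces[[rid]]$position, 1L)
    if (s == 1L) {
      grid_all <- seg$grid
      fe_all <- seg$free_energy
    } else {
      bounds <- c(bounds, length(grid_all))
      grid_all <- c(grid_all, seg$grid[-1L])
      fe_all <- c(fe_all, offset + seg$free_energy[-1L])
    }
    offset <- fe_all[length(fe_all)]
  }
  pmf_profile(grid_all, fe_all, bounds, chain)
}

#' Forward/backward hysteresis between two PMF profiles
#'
#' Interpolates both profiles on their common grid, anchors each to zero
#' at the common start, and reports the maximum and mean absolute
#' discrepancy. In the quasi-static limit a reversible landscape gives a
#' discrepancy bounded by estimator noise.
#'
#' @param forward,backward `pmf_profile` objects (the backward one as
#'   produced by a reversed-span plan).
#' @return List with `max` and `mean` absolute discrepancy (kcal/mol) and
#'   the comparison grid.
#' @export
hysteresis <- function(forward, backward) {
  gf <- sort(forward$grid)
  gb <- sort(backward$grid)
  lo <- max(min(gf), min(gb))
  hi <- min(max(gf), max(gb))
  if (lo >= hi) stop("profiles have disjoint grids")
  grid <- sort(unique(c(gf[gf >= lo & gf <= hi], gb[gb >= lo & gb <= hi])))
  ff <- approx(forward$grid, forward$free_energy, xout = grid)$y
  fb <- approx(backward$grid, backward$free_energy, xout = grid)$y
  ff <- ff - ff[1L]
  fb <- fb - fb[1L]
  d <- abs(ff - fb)
  list(max = max(d), mean = mean(d), grid = grid,
       forward = ff, backward = fb)
}

#' Simulated-time accounting for a staged protocol
#'
#' Reproduces the protocol arithmetic: each replica runs
#' `stage_width / velocity` ns per stage, a stage costs that times the
#' replica count, a simulation sums its stages, and a campaign multiplies
#' by the number of peptide and membrane systems. The canonical 8 x 5 A,
#' 25-replica, 1 A/ns design gives 125 ns per stage and 1000 ns per
#' simulation; 3 peptides x 3 membranes gives a 9 microsecond campaign.
#'
#' @param plan A [plan_stages()] plan.
#' @param n_peptides,n_membranes Campaign dimensions.
#' @return List with `per_replica_ns` (per stage), `per_stage_ns`,
#'   `per_simulation_ns` and `campaign_ns`.
#' @export
protocol_accounting <- function(plan, n_peptides = 1, n_membranes = 1) {
  if (!inherits(plan, "stage_plan")) stop("`plan` must be a stage_plan")
  widths <- abs(plan$stages$end - plan$stages$start)
  per_replica <- widths / plan$velocity
  per_stage <- per_replica * plan$n_replicas
  per_sim <- sum(per_stage)
  list(per_replica_ns = per_replica,
       per_stage_ns = per_stage,
       per_simulation_ns = per_sim,
       campaign_ns = per_sim * n_peptides * n_membranes)
}

#' Enumerate the peptide x membrane experiment matrix
#'
#' One system per (peptide, membrane) pair, plus one peptide-free control
#' per membrane when requested: 3 peptides x 3 membranes with controls is
#' the canonical 12-system design.
#'
#' @param peptides Character vector of peptide names (may be empty).
#' @param membranes Non-empty character vector of membrane labels.
#' @param include_controls Add a peptide-free control per membrane.
#' @return Data frame with columns `system`, `peptide` (`NA` for
#'   controls), `membrane`, `control`.
#' @export
plan_experiment_matrix <- function(peptides, membranes,
                                   include_controls = TRUE) {
  if (length(membranes) == 0L) stop("`membranes` must be non-empty")
  out <- expand.grid(peptide = as.character(peptides),
                     membrane = as.character(membranes),
                     stringsAsFactors = FALSE)
  if (include_controls) {
    out <- rbind(out,
                 data.frame(peptide = NA_character_,
                            membrane = as.character(membranes)))
  }
  out$control <- is.na(out$peptide)
  out <- out[order(out$control, out$membrane, out$peptide), ]
  out$system <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("system", "peptide", "membrane", "control")]
}
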