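#' Order parameter of explicit bond vectors
#'
#' For each vector computes `(3 cos^2(theta) - 1) / 2`, with `theta` the
#' angle against the z axis (the bilayer normal). 1 means aligned with
#' the normal, 0 isotropic, -0.5 perpendicular; values are bounded in
#' [-0.5, 1] for any input.
#'
#' @param vectors An `n x 3` matrix of bond vectors (or a length-3
#'   vector).
#' @return Numeric vector of per-bond order parameter values.
#' @export
bond_order_parameter <- function(vectors) {
  if (is.vector(vectors)) vectors <- matrix(vectors, ncol = 3)
  if (!is.matrix(vectors) || ncol(vectors) != 3L) {
    stop("`vectors` must be an n x 3 matrix")
  }
  len2 <- rowSums(vectors^2)
  if (any(len2 == 0) || any(!is.finite(len2))) {
    stop("zero-length or non-finite bond vector")
  }
  cos2 <- vectors[, 3]^2 / len2
  (3 * cos2 - 1) / 2
}

#' Acyl-chain order parameter profile
#'
#' Computes the order parameter per tail-carbon index, averaged over
#' lipids and frames. Pseudo C-H bond vectors default to the
#' consecutive-bead vectors along each chain (headgroup -> C1, C1 -> C2,
#' ...), the convention the synthetic generator emits; a perfectly
#' z-aligned chain therefore scores 1.
#'
#' @param traj A `cpp_trajectory` containing lipids with tail beads.
#' @param frames Frame indices to average over (default all).
#' @return Data frame with `carbon`, `mean_scd`, `sd_scd`, `n`.
#' @export
order_parameter <- function(traj, frames = seq_len(n_frames(traj))) {
  b <- traj$beads
  tails <- which(b$role == "tail")
  if (!length(tails)) stop("trajectory contains no tail beads")
  # bond index table, built once: previous bead along the chain
  from <- integer(length(tails))
  for (i in seq_along(tails)) {
    row <- tails[i]
    k <- b$carbon[row]
    prev <- if (k == 1L) {
      which(b$residue_id == b$residue_id[row] & b$role == "headgroup")
    } else {
      which(b$residue_id == b$residue_id[row] & b$role == "tail" &
              b$carbon == k - 1L)
    }
    if (length(prev) != 1L) {
      stop("broken chain in lipid residue ", b$residue_id[row])
    }
    from[i] <- prev
  }
  carbon <- b$carbon[tails]
  vals <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[fi])
    vals[[fi]] <- bond_order_parameter(xyz[tails, , drop = FALSE] -
                                         xyz[from, , drop = FALSE])
  }
  scd <- unlist(vals)
  kk <- rep(carbon, length(frames))
  out <- do.call(rbind, lapply(sort(unique(carbon)), function(k) {
    v <- scd[kk == k]
    data.frame(carbon = k, mean_scd = mean(v), sd_scd = sd(v),
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Water-defined pore radius profile of one frame
#'
#' Slices the membrane span into z slabs and measures, per slab, the
#' lateral extent of the water present: by default the maximum xy
#' distance of slab waters to the slab water centroid
#' (`method = "centroid"`), alternatively half the maximum pairwise xy
#' distance (`method = "pairwise"`). An empty slab scores 0 (no
#' continuous water pathway), and the frame value is the minimum over
#' slabs — the bottleneck of the water column.
#'
#' @param traj A `cpp_trajectory`.
#' @param frame Frame index.
#' @param slab_width Slab thickness (Angstrom, > 0; default 1).
#' @param z_bounds `c(lower, upper)` bounds of the scanned span; default
#'   the mean headgroup planes of the frame.
#' @param method Radius definition, `"centroid"` (default) or
#'   `"pairwise"`.
#' @return List with `slabs` (data frame `z_lo`, `z_hi`, `n_waters`,
#'   `radius`) and `min_radius`.
#' @export
pore_radius_profile <- function(traj, frame = 1L, slab_width = 1,
                                z_bounds = NULL,
                                method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  stopifnot_scalar(slab_width, "slab_width", positive = TRUE)
  xyz <- frame_coords(traj, frame)
  if (is.null(z_bounds)) {
    leaf <- assign_leaflets(traj, frame)
    hg <- which(traj$beads$role == "headgroup")
    if (!length(hg)) stop("no headgroup beads to set default z_bounds")
    zu <- mean(xyz[hg[leaf[as.character(traj$beads$residue_id[hg])] ==
                         "upper"], 3])
    zl <- mean(xyz[hg[leaf[as.character(traj$beads$residue_id[hg])] ==
                         "lower"], 3])
    z_bounds <- c(zl, zu)
  }
  z_bounds <- sort(z_bounds)
  lz <- traj$box[frame, 3]
  if (diff(z_bounds) <= 0) stop("z_bounds span zero slabs")
  if (diff(z_bounds) > lz) stop("z_bounds exceed the box")
  edges <- seq(z_bounds[1], z_bounds[2], by = slab_width)
  if (edges[length(edges)] < z_bounds[2] - 1e-9) {
    edges <- c(edges, z_bounds[2])
  }
  if (length(edges) < 2L) stop("z_bounds span zero slabs")
  wat <- xyz[traj$beads$role == "water", , drop = FALSE]
  slabs <- data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1])
  slabs$n_waters <- 0L
  slabs$radius <- 0
  for (j in seq_len(nrow(slabs))) {
    inside <- wat[, 3] >= slabs$z_lo[j] & wat[, 3] < slabs$z_hi[j]
    n <- sum(inside)
    slabs$n_waters[j] <- n
    if (n == 0L) next
    p <- wat[inside, 1:2, drop = FALSE]
    if (method == "centroid") {
      ctr <- colMeans(p)
      slabs$radius[j] <- sqrt(max((p[, 1] - ctr[1])^2 +
                                    (p[, 2] - ctr[2])^2))
    } else {
      slabs$radius[j] <- if (n == 1L) 0 else max(stats::dist(p)) / 2
    }
  }
  list(slabs = slabs, min_radius = min(slabs$radius))
}

#' Mean pore bottleneck radius over the trailing analysis window
#'
#' Per-frame bottleneck radii (see [pore_radius_profile()]) averaged over
#' the trailing fraction of frames — mirroring analyses restricted to the
#' last 80 of 100 ns of a relaxation run.
#'
#' @inheritParams pore_radius_profile
#' @param trailing_fraction Fraction of trailing frames analyzed,
#'   in (0, 1] (default 0.8).
#' @return List with `mean`, `sd` and the `per_frame` radii.
#' @export
mean_pore_radius <- function(traj, trailing_fraction = 0.8,
                             slab_width = 1, z_bounds = NULL,
                             method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  frames <- trailing_frames(traj, trailing_fraction)
  r <- vapply(frames, function(f) {
    pore_radius_profile(traj, f, slab_width, z_bounds,
                        method)$min_radius
  }, numeric(1))
  list(mean = mean(r), sd = if (length(r) > 1L) sd(r) else 0,
       per_frame = setNames(r, frames))
}

#' Membrane thickness time series
#'
#' Per frame: mean headgroup z of the upper leaflet minus mean headgroup
#' z of the lower leaflet.
#'
#' @param traj A `cpp_trajectory` with headgroup beads in both leaflets.
#' @return Numeric vector (Angstrom), one value per frame.
#' @export
thickness <- function(traj) {
  hg <- which(traj$beads$role == "headgroup")
  if (!length(hg)) stop("trajectory contains no headgroup beads")
  ids <- as.character(traj$beads$residue_id[hg])
  vapply(seq_len(n_frames(traj)), function(f) {
    leaf <- assign_leaflets(traj, f)[ids]
    if (!any(leaf == "upper") || !any(leaf == "lower")) {
      stop("empty leaflet in frame ", f)
    }
    z <- frame_coords(traj, f)[hg, 3]
    mean(z[leaf == "upper"]) - mean(z[leaf == "lower"])
  }, numeric(1))
}

#' Area per lipid time series, per leaflet
#'
#' Box-area method: per frame and leaflet, `Lx * Ly / n_lipids`, so that
#' area-per-lipid times the leaflet count equals the box area exactly.
#' Sterols count as lipids of their leaflet.
#'
#' @param traj A `cpp_trajectory`.
#' @return Data frame with `frame`, `upper`, `lower` (Angstrom^2).
#' @export
area_per_lipid <- function(traj) {
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    leaf <- assign_leaflets(traj, f)
    nu <- sum(leaf == "upper")
    nl <- sum(leaf == "lower")
    if (nu == 0L || nl == 0L) stop("zero lipids in a leaflet, frame ", f)
    area <- traj$box[f, 1] * traj$box[f, 2]
    data.frame(frame = f, upper = area / nu, lower = area / nl)
  })
  do.call(rbind, out)
}

#' Classify the fate of a peptide after release
#'
#' Maps the trailing-window behaviour of the peptide's centre of mass
#' (and the pore record) onto the four observed outcomes:
#' `lower_leaflet_equilibrium` (COM settled at/below the lower headgroup
#' region), `pore_formation` (COM inside the membrane with a sustained
#' water pore), `insertion` (inside without a sustained pore) and
#' `return` (back at/above the upper headgroup region). The three z
#' bands partition the axis, so every admissible input maps to exactly
#' one label.
#'
#' @param com_z Per-frame peptide centre-of-mass z (Angstrom).
#' @param pore_radius Per-frame pore bottleneck radii aligned with
#'   `com_z` (may be `NULL`: no pore record means no sustained pore).
#' @param planes `c(z_upper, z_lower)` (order-insensitive) headgroup
#'   planes.
#' @param margin Band margin (Angstrom, default 5): lower band is
#'   `z < z_lower + margin`, upper band `z > z_upper - margin`; requires
#'   `2 * margin` smaller than the plane separation.
#' @param pore_threshold Radius above which a frame counts as porous
#'   (Angstrom, default 1).
#' @param persistence Fraction of trailing frames that must be porous to
#'   call the pore sustained (default 0.5).
#' @param trailing_fraction Analysis window, fraction of trailing frames
#'   (default 0.8).
#' @return One of `"lower_leaflet_equilibrium"`, `"pore_formation"`,
#'   `"insertion"`, `"return"`.
#' @export
classify_outcome <- function(com_z, pore_radius = NULL, planes,
                             margin = 5, pore_threshold = 1,
                             persistence = 0.5,
                             trailing_fraction = 0.8) {
  if (length(com_z) == 0L) stop("empty centre-of-mass series")
  if (!is.null(pore_radius) && length(pore_radius) != length(com_z)) {
    stop("`pore_radius` must align with `com_z`")
  }
  z_lower <- min(planes)
  z_upper <- max(planes)
  if (z_lower + margin >= z_upper - margin) {
    stop("margins overlap: require 2 * margin < plane separation")
  }
  n <- length(com_z)
  keep <- seq.int(n - max(1L, ceiling(trailing_fraction * n)) + 1L, n)
  mz <- mean(com_z[keep])
  if (mz < z_lower + margin) return("lower_leaflet_equilibrium")
  if (mz > z_upper - margin) return("return")
  sustained <- !is.null(pore_radius) &&
    mean(pore_radius[keep] > pore_threshold) > persistence
  if (sustained) "pore_formation" else "insertion"
}
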