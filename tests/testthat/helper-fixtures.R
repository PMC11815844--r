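# Fixture builders and independent oracles shared across test files.

# Minimal membrane trajectory built from explicit geometry: lipids are a
# headgroup bead plus one vertical tail bead; waters and peptide beads
# are supplied as per-frame coordinate matrices (same counts per frame).
make_membrane_traj <- function(n_upper = 4, n_lower = n_upper,
                               planes = c(19.25, -19.25),
                               box = c(40, 40, 60), n_frames = 1,
                               waters = NULL, peptide = NULL,
                               species = "DPPC") {
  beads <- list()
  base <- list()
  rid <- 0L
  add <- function(resname, atom, role, xyz, carbon = NA_integer_,
                  residue_index = NA_integer_, same_res = FALSE) {
    if (!same_res) rid <<- rid + 1L
    beads[[length(beads) + 1L]] <<- data.frame(
      residue_id = rid, residue_name = resname, atom_name = atom,
      role = role, carbon = carbon, residue_index = residue_index)
    base[[length(base) + 1L]] <<- xyz
  }
  place <- function(n, plane, down) {
    if (n == 0) return()
    gx <- ceiling(sqrt(n))
    cell <- box[1] / gx
    for (i in seq_len(n) - 1L) {
      x <- -box[1] / 2 + (i %% gx + 0.5) * cell
      y <- -box[2] / 2 + (i %/% gx + 0.5) * cell
      sp <- if (length(species) > 1L) species[(i %% length(species)) + 1L]
            else species
      add(sp, "HD", "headgroup", c(x, y, plane))
      add(sp, "C1", "tail", c(x, y, plane + down * 1.8), carbon = 1L,
          same_res = TRUE)
    }
  }
  place(n_upper, planes[1], -1)
  place(n_lower, planes[2], +1)
  n_wat <- if (is.null(waters)) 0L else nrow(as_frame_list(waters, n_frames)[[1]])
  for (i in seq_len(n_wat)) add("SOL", "OW", "water", c(0, 0, 0))
  n_pep <- if (is.null(peptide)) 0L else nrow(as_frame_list(peptide, n_frames)[[1]])
  for (i in seq_len(n_pep)) {
    add("PEP", "CA", "peptide", c(0, 0, 0), residue_index = i)
  }
  beads <- do.call(rbind, beads)
  base <- do.call(rbind, base)
  wl <- as_frame_list(waters, n_frames)
  pl <- as_frame_list(peptide, n_frames)
  coords <- array(NA_real_, dim = c(nrow(beads), 3, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- base
    if (n_wat) fr[beads$role == "water", ] <- wl[[f]]
    if (n_pep) fr[beads$role == "peptide", ] <- pl[[f]]
    coords[, , f] <- fr
  }
  trajectory(beads, coords, box)
}

as_frame_list <- function(x, n_frames) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) x <- rep(list(x), n_frames)
  stopifnot(length(x) == n_frames)
  x
}

# waters uniform in a disk of the given radius (a scalar, or a function
# of slab-centre z), n per 1 A slab, covering the whole z range including
# a partial trailing slab
disk_channel_waters <- function(radius, z_range, n_per_slab,
                                seed = 42) {
  set.seed(seed)
  edges <- seq(z_range[1], z_range[2], by = 1)
  if (edges[length(edges)] < z_range[2]) edges <- c(edges, z_range[2])
  out <- lapply(seq_len(length(edges) - 1L), function(j) {
    dz <- edges[j + 1] - edges[j]
    n <- max(2L, round(n_per_slab * dz))
    rj <- if (is.function(radius)) radius((edges[j] + edges[j + 1]) / 2)
          else radius
    r <- rj * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th), runif(n, edges[j], edges[j + 1]))
  })
  do.call(rbind, out)
}

# naive Jarzynski evaluation (no log-sum-exp): the brute-force oracle
naive_jarzynski <- function(works, thermo) {
  -log(mean(exp(-thermo$beta * works))) / thermo$beta
}

# independent all-pairs occupancy oracle: plain double loop with
# minimum-image distances
oracle_occupancy <- function(traj, cutoff, group_role, leaflet = "both",
                             trailing_fraction = 1) {
  b <- traj$beads
  residues <- sort(unique(b$residue_index[b$role == "peptide"]))
  nf <- dim(traj$coords)[3]
  n_keep <- max(1, ceiling(trailing_fraction * nf))
  frames <- seq(nf - n_keep + 1, nf)
  occ <- numeric(length(residues))
  for (ri in seq_along(residues)) {
    hits <- logical(0)
    for (f in frames) {
      xyz <- frame_coords(traj, f)
      box <- traj$box[f, ]
      leafmap <- assign_leaflets(traj, f)
      grows <- which(b$role == group_role)
      if (leaflet != "both") {
        grows <- grows[leafmap[as.character(b$residue_id[grows])] ==
                         leaflet]
      }
      prows <- which(b$role == "peptide" &
                       b$residue_index == residues[ri])
      hit <- FALSE
      for (p in prows) {
        for (g in grows) {
          d2 <- 0
          for (dim in 1:3) {
            dd <- xyz[p, dim] - xyz[g, dim]
            dd <- dd - box[dim] * round(dd / box[dim])
            d2 <- d2 + dd^2
          }
          if (d2 <= cutoff^2) hit <- TRUE
        }
      }
      hits <- c(hits, hit)
    }
    occ[ri] <- 100 * mean(hits)
  }
  occ
}
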