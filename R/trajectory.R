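#' Labelled-bead trajectory container
#'
#' A coarse trajectory holds a fixed set of beads (constant across
#' frames), their per-frame coordinates and per-frame orthorhombic box
#' dimensions. Coordinates are in Angstrom, the z axis is the membrane
#' normal and fixtures are built with the bilayer midplane at z = 0.
#'
#' Bead roles form a closed set: `headgroup`, `tail` (with a carbon
#' index), `sterol`, `water`, `peptide` (with a residue index).
#'
#' @param beads Data frame with columns `residue_id` (integer),
#'   `residue_name`, `atom_name`, `role`, and optional `carbon`
#'   (tail-carbon index) and `residue_index` (peptide residue number).
#' @param coords Numeric array `n_beads x 3 x n_frames`, or a list of
#'   `n_beads x 3` matrices.
#' @param box Per-frame box dimensions: an `n_frames x 3` matrix or a
#'   length-3 vector recycled to every frame.
#' @return An object of class `cpp_trajectory`.
#' @export
trajectory <- function(beads, coords, box) {
  roles <- c("headgroup", "tail", "sterol", "water", "peptide")
  req <- c("residue_id", "residue_name", "atom_name", "role")
  if (!is.data.frame(beads) || !all(req %in% names(beads))) {
    stop("`beads` needs columns ", paste(req, collapse = ", "))
  }
  if (!all(beads$role %in% roles)) {
    bad <- unique(setdiff(beads$role, roles))
    stop("unknown bead role(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(beads$carbon)) beads$carbon <- NA_integer_
  if (is.null(beads$residue_index)) beads$residue_index <- NA_integer_
  if (is.list(coords) && !is.array(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L ||
      dim(coords)[1] != nrow(beads) || dim(coords)[2] != 3L) {
    stop("`coords` must be an n_beads x 3 x n_frames array")
  }
  n_frames <- dim(coords)[3]
  if (is.vector(box) && length(box) == 3L) {
    box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  }
  if (!is.matrix(box) || nrow(box) != n_frames || ncol(box) != 3L) {
    stop("`box` must be an n_frames x 3 matrix (or length-3 vector)")
  }
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("box dimensions must be finite and > 0")
  }
  rownames(beads) <- NULL
  structure(list(beads = beads, coords = coords, box = box),
            class = "cpp_trajectory")
}

#' @export
print.cpp_trajectory <- function(x, ...) {
  tab <- table(x$beads$role)
  cat(sprintf("<cpp_trajectory> %d beads x %d frames (%s)\n",
              nrow(x$beads), n_frames(x),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cpp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj A `cpp_trajectory`.
#' @param frame Frame index.
#' @return `n_beads x 3` matrix (columns x, y, z in Angstrom).
#' @export
frame_coords <- function(traj, frame = 1L) {
  if (frame < 1L || frame > n_frames(traj)) stop("frame out of range")
  m <- traj$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
}

# indices of the trailing analysis window (default 0.8 of frames,
# mirroring analysis restricted to the last 80 of 100 ns)
trailing_frames <- function(traj, trailing_fraction = 0.8) {
  if (!is.numeric(trailing_fraction) || trailing_fraction <= 0 ||
      trailing_fraction > 1) {
    stop("`trailing_fraction` must be in (0, 1]")
  }
  nf <- n_frames(traj)
  n_keep <- max(1L, ceiling(trailing_fraction * nf))
  seq.int(nf - n_keep + 1L, nf)
}

# per-lipid reference bead (headgroup, or the sterol bead itself);
# errors on lipids lacking both
lipid_reference_idx <- function(beads) {
  lip <- beads$role %in% c("headgroup", "tail", "sterol")
  ids <- unique(beads$residue_id[lip])
  ref <- vapply(ids, function(id) {
    rows <- which(beads$residue_id == id & beads$role == "headgroup")
    if (!length(rows)) {
      rows <- which(beads$residue_id == id & beads$role == "sterol")
    }
    if (!length(rows)) {
      stop("lipid residue ", id, " has no headgroup (or sterol) bead")
    }
    rows[1L]
  }, integer(1))
  data.frame(residue_id = ids, bead = ref)
}

#' Assign lipids to leaflets
#'
#' Lipids whose reference bead (headgroup, or the sterol bead for
#' sterols) sits at or above the median reference z are tagged `upper`,
#' the rest `lower`. The `z >= median` tie rule makes the split
#' deterministic for degenerate geometries (a single lipid is `upper`).
#'
#' @param traj A `cpp_trajectory`.
#' @param frame Frame index.
#' @return Named character vector (`upper`/`lower`) indexed by lipid
#'   `residue_id`.
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  ref <- lipid_reference_idx(traj$beads)
  if (!nrow(ref)) stop("trajectory contains no lipids")
  z <- frame_coords(traj, frame)[ref$bead, 3]
  med <- median(z)
  setNames(ifelse(z >= med, "upper", "lower"), ref$residue_id)
}
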