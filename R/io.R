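# Role encoding in PDB/GRO files (the package's format guide):
#   atom name HD  -> headgroup        (residue name = lipid species)
#   atom name Ck  -> tail carbon k    (same residue as its headgroup)
#   atom name ST  -> sterol bead      (residue name = sterol species)
#   atom name OW  -> water            (residue name SOL)
#   atom name CA  -> peptide residue  (residue name PEP, one residue per
#                                      amino acid; resno is the index)
# Coordinates are Angstrom in memory; GRO files are nm on disk.

role_from_atom <- function(atom_name, residue_name) {
  ifelse(atom_name == "HD", "headgroup",
  ifelse(grepl("^C[0-9]+$", atom_name), "tail",
  ifelse(atom_name == "ST", "sterol",
  ifelse(atom_name == "OW", "water",
  ifelse(atom_name == "CA", "peptide", NA_character_)))))
}

beads_from_atoms <- function(atom_name, residue_name, resno, where) {
  role <- role_from_atom(atom_name, residue_name)
  if (anyNA(role)) {
    bad <- unique(atom_name[is.na(role)])
    stop("unknown bead role for atom name(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  }
  carbon <- ifelse(role == "tail",
                   suppressWarnings(as.integer(sub("^C", "", atom_name))),
                   NA_integer_)
  pep_ids <- sort(unique(as.integer(resno)[role == "peptide"]))
  data.frame(residue_id = as.integer(resno), residue_name = residue_name,
             atom_name = atom_name, role = role, carbon = carbon,
             residue_index = ifelse(role == "peptide",
                                    match(as.integer(resno), pep_ids),
                                    NA_integer_))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; box dimensions go into a single
#' `CRYST1` record, so the PDB route requires a constant box (the GRO
#' route stores the box per frame). Roles are encoded in atom names as
#' documented in the package format guide.
#'
#' @param traj A `cpp_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  if (any(abs(sweep(traj$box, 2, traj$box[1, ])) > 1e-9)) {
    stop("PDB output requires a constant box; use GRO for varying boxes")
  }
  b <- traj$beads
  fmt <- "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    traj$box[1, 1], traj$box[1, 2], traj$box[1, 3]), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(fmt, seq_len(nrow(b)) %% 100000L, b$atom_name,
                       b$residue_name, "A", b$residue_id %% 10000L,
                       xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses ATOM records through [bio3d::read.pdb()] and the `CRYST1` box
#' record directly. Roles are inferred from the atom-name convention of
#' the format guide; unknown names are an error listing the offenders.
#'
#' @param path PDB file written by [write_trajectory_pdb()] (or any file
#'   following the naming convention).
#' @return A `cpp_trajectory`.
#' @export
read_trajectory_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cr)) stop("missing CRYST1 record in ", path)
  box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33)))
  if (anyNA(box)) stop("malformed CRYST1 record in ", path)
  beads <- beads_from_atoms(pdb$atom$elety, pdb$atom$resid,
                            pdb$atom$resno, path)
  nf <- nrow(pdb$xyz)
  nb <- nrow(beads)
  coords <- array(NA_real_, dim = c(nb, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (anyNA(coords)) stop("truncated frame in ", path)
  traj <- trajectory(beads, coords, box)
  wrap_check(traj)
  traj
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Frames are concatenated GRO blocks (title, atom count, atoms, box
#' line); lengths are converted to nm on disk, the GRO convention. The
#' box is stored per frame.
#'
#' @inheritParams write_trajectory_pdb
#' @return `path`, invisibly.
#' @export
write_trajectory_gro <- function(traj, path) {
  b <- traj$beads
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f) / 10 # nm
    writeLines(sprintf("cppkit frame %d", f), con)
    writeLines(sprintf("%5d", nrow(b)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$residue_id %% 100000L, b$residue_name,
                       b$atom_name, seq_len(nrow(b)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1] / 10,
                       traj$box[f, 2] / 10, traj$box[f, 3] / 10), con)
  }
  invisible(path)
}

#' Read a (multi-frame) GRO trajectory
#'
#' @param path One GRO file with concatenated frames, or a vector of
#'   single-frame GRO files (a frame series).
#' @return A `cpp_trajectory`.
#' @export
read_trajectory_gro <- function(path) {
  lines <- unlist(lapply(path, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    readLines(p)
  }))
  frames <- list()
  boxes <- list()
  beads <- NULL
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    frame_no <- frame_no + 1L
    if (i + 1L > length(lines)) {
      stop("truncated frame ", frame_no, ": missing atom count")
    }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) {
      stop("malformed atom count at line ", i + 1L, " (frame ",
           frame_no, ")")
    }
    if (i + 1L + n + 1L > length(lines)) {
      stop("truncated frame ", frame_no, ": expected ", n,
           " atom records plus a box line")
    }
    at <- lines[i + 1L + seq_len(n)]
    resno <- suppressWarnings(as.integer(substr(at, 1, 5)))
    resnm <- trimws(substr(at, 6, 10))
    atnm <- trimws(substr(at, 11, 15))
    x <- suppressWarnings(as.numeric(substr(at, 21, 28))) * 10
    y <- suppressWarnings(as.numeric(substr(at, 29, 36))) * 10
    z <- suppressWarnings(as.numeric(substr(at, 37, 44))) * 10
    if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))[1]
      stop("malformed atom record at line ", i + 1L + bad, " (frame ",
           frame_no, ")")
    }
    bx <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[i + 2L + n]), "\\s+")[[1]])) * 10
    if (length(bx) < 3L || anyNA(bx[1:3])) {
      stop("malformed box line at line ", i + 2L + n, " (frame ",
           frame_no, ")")
    }
    fb <- beads_from_atoms(atnm, resnm, resno, path[1])
    if (is.null(beads)) {
      beads <- fb
    } else if (!identical(fb$atom_name, beads$atom_name) ||
               !identical(fb$residue_id, beads$residue_id)) {
      stop("frame ", frame_no, " bead identity differs from frame 1")
    }
    frames[[frame_no]] <- cbind(x, y, z)
    boxes[[frame_no]] <- bx[1:3]
    i <- i + n + 3L
  }
  if (!length(frames)) stop("no frames found in ", path[1])
  traj <- trajectory(beads, frames, do.call(rbind, boxes))
  wrap_check(traj)
  traj
}

#' Read a trajectory, dispatching on file extension
#'
#' @param path A `.pdb` file (multi-model) or `.gro` file(s) (multi-frame
#'   or a series).
#' @return A `cpp_trajectory`.
#' @export
read_trajectory <- function(path) {
  ext <- tolower(tools::file_ext(path[1]))
  switch(ext,
         pdb = read_trajectory_pdb(path[1]),
         gro = read_trajectory_gro(path),
         stop("unsupported trajectory format: .", ext))
}

# molecules must be whole: no periodic-boundary unwrapping is performed,
# so a residue spread over more than half the box means a wrapped
# (broken) molecule
wrap_check <- function(traj) {
  b <- traj$beads
  multi <- b$residue_id[b$role %in% c("headgroup", "tail")]
  ids <- unique(multi[duplicated(multi)])
  if (!length(ids)) return(invisible(TRUE))
  xyz <- frame_coords(traj, 1L)
  half <- traj$box[1, ] / 2
  for (id in ids) {
    rows <- which(b$residue_id == id)
    spread <- apply(xyz[rows, , drop = FALSE], 2, function(v) {
      diff(range(v))
    })
    if (any(spread > half)) {
      stop("broken molecule across the periodic boundary: residue ", id)
    }
  }
  invisible(TRUE)
}

#' Write / read a steered-pull work log as CSV
#'
#' Column layout `time_ns, lambda_A, x_A, work_kcal_mol`, one file per
#' replica, so work logs exported from an MD engine can be analyzed with
#' the same estimators.
#'
#' @param trace A `work_trace`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `work_trace` (reader).
#' @export
write_work_trace <- function(trace, path) {
  df <- data.frame(time_ns = trace$time, lambda_A = trace$lambda,
                   x_A = trace$position, work_kcal_mol = trace$work)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_work_trace
#' @param stage_id,replica_id Labels attached to the read trace.
#' @export
read_work_trace <- function(path, stage_id = 1L, replica_id = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("time_ns", "lambda_A", "work_kcal_mol")
  if (!all(need %in% names(df))) {
    stop("work log must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) < 2L) stop("work log has fewer than 2 samples")
  if (abs(df$work_kcal_mol[1]) > 1e-9) {
    stop("work log must start at W = 0")
  }
  dl <- diff(df$lambda_A)
  if (!(all(dl >= 0) || all(dl <= 0))) {
    stop("lambda must be monotone in the pull direction")
  }
  structure(
    list(time = df$time_ns, lambda = df$lambda_A,
         position = df$x_A %||% rep(NA_real_, nrow(df)),
         work = df$work_kcal_mol, stage_id = as.integer(stage_id),
         replica_id = as.integer(replica_id), seed = NA_integer_),
    class = "work_trace"
  )
}

#' Export a PMF profile as CSV
#'
#' @param profile A `pmf_profile`.
#' @param path CSV path (columns `z_A`, `free_energy_kcal_mol`,
#'   `stage_boundary`).
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(profile, path) {
  df <- data.frame(z_A = profile$grid,
                   free_energy_kcal_mol = profile$free_energy,
                   stage_boundary = seq_along(profile$grid) %in%
                     profile$stage_boundaries)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame with `name` and `sequence`.
#' @export
read_fasta_peptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  data.frame(name = names(aa), sequence = as.character(aa),
             row.names = NULL)
}

#' Reaction coordinate: peptide vs lower-leaflet headgroup separation
#'
#' Per frame, the z distance between the centre of mass of the peptide
#' beads and the centre of mass of the lower-leaflet headgroup beads
#' (equal bead masses, matching the coarse model). Invariant under rigid
#' translation of all coordinates.
#'
#' @param traj A `cpp_trajectory` with peptide and headgroup beads.
#' @return Numeric vector (Angstrom), one value per frame.
#' @export
reaction_coordinate <- function(traj) {
  b <- traj$beads
  pep <- which(b$role == "peptide")
  hg <- which(b$role == "headgroup")
  if (!length(pep)) stop("empty peptide selection")
  if (!length(hg)) stop("empty headgroup selection")
  vapply(seq_len(n_frames(traj)), function(f) {
    leaf <- assign_leaflets(traj, f)
    low <- hg[leaf[as.character(b$residue_id[hg])] == "lower"]
    if (!length(low)) stop("no lower-leaflet headgroups in frame ", f)
    xyz <- frame_coords(traj, f)
    mean(xyz[pep, 3]) - mean(xyz[low, 3])
  }, numeric(1))
}
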