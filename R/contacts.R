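#' Per-residue peptide-lipid contact occupancy
#'
#' Occupancy of a peptide residue is the percentage of analyzed frames in
#' which any of its beads lies within `cutoff` of any bead of the
#' selected lipid group, under minimum-image distances in the
#' orthorhombic box. Analysis is restricted to the trailing window.
#'
#' Group selectors: `"headgroup"` (any species),
#' `"headgroup:<SPECIES>"`, `"tail"`, `"sterol"`; a `+` joins selectors
#' into a union (e.g. `"headgroup:DPPS+headgroup:DOPS"`). Several
#' selectors may be passed at once and yield one block of rows each.
#'
#' @param traj A `cpp_trajectory` containing peptide beads.
#' @param cutoff Contact distance cutoff (Angstrom, > 0; default 4).
#' @param groups Character vector of group selectors.
#' @param leaflet `"upper"`, `"lower"` or `"both"`.
#' @param trailing_fraction Analysis window (default 0.8).
#' @return Data frame with `residue`, `group`, `leaflet`,
#'   `occupancy_pct` (0-100); cutoff and window stored as attributes
#'   `cutoff` and `trailing_fraction`.
#' @export
residue_occupancy <- function(traj, cutoff = 4, groups = "headgroup",
                              leaflet = c("both", "upper", "lower"),
                              trailing_fraction = 0.8) {
  leaflet <- match.arg(leaflet)
  stopifnot_scalar(cutoff, "cutoff", positive = TRUE)
  b <- traj$beads
  pep <- which(b$role == "peptide")
  if (!length(pep)) stop("trajectory contains no peptide beads")
  residues <- sort(unique(b$residue_index[pep]))
  frames <- trailing_frames(traj, trailing_fraction)
  out <- list()
  for (g in groups) {
    sel_fun <- group_selector(g, b)
    hits <- matrix(FALSE, nrow = length(residues), ncol = length(frames))
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      leafmap <- assign_leaflets(traj, f)
      rows <- sel_fun(leafmap, leaflet)
      if (!length(rows)) next
      xyz <- frame_coords(traj, f)
      box <- traj$box[f, ]
      gxyz <- xyz[rows, , drop = FALSE]
      for (ri in seq_along(residues)) {
        prows <- pep[b$residue_index[pep] == residues[ri]]
        hits[ri, fi] <- any_contact(xyz[prows, , drop = FALSE], gxyz,
                                    box, cutoff)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      residue = residues, group = g, leaflet = leaflet,
      occupancy_pct = 100 * rowMeans(hits))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cutoff") <- cutoff
  attr(res, "trailing_fraction") <- trailing_fraction
  res
}

# parse one (possibly "+"-joined) selector into a function
# (leafmap, leaflet) -> bead row indices
group_selector <- function(selector, beads) {
  parts <- strsplit(selector, "+", fixed = TRUE)[[1]]
  masks <- lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    kind <- bits[1]
    if (!kind %in% c("headgroup", "tail", "sterol")) {
      stop("unknown lipid group: ", p)
    }
    m <- beads$role == kind
    if (length(bits) > 1L) m <- m & beads$residue_name == bits[2]
    m
  })
  mask <- Reduce(`|`, masks)
  function(leafmap, leaflet) {
    rows <- which(mask)
    if (leaflet != "both") {
      rows <- rows[leafmap[as.character(beads$residue_id[rows])] ==
                     leaflet]
    }
    rows
  }
}

# any minimum-image pair within cutoff between two coordinate sets
any_contact <- function(a, b, box, cutoff) {
  if (!nrow(a) || !nrow(b)) return(FALSE)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (dim in 1:3) {
    dd <- outer(a[, dim], b[, dim], "-")
    dd <- dd - box[dim] * round(dd / box[dim])
    d2 <- d2 + dd^2
  }
  any(d2 <= cutoff^2)
}

#' Occupancy contrast between two lipid groups
#'
#' Signed per-residue occupancy difference (group a minus group b), for
#' comparisons such as negatively charged versus neutral headgroups.
#'
#' @param table Output of [residue_occupancy()] containing both groups.
#' @param group_a,group_b Group selectors present in `table`.
#' @return Data frame with `residue`, `leaflet`, `delta_pct`.
#' @export
occupancy_contrast <- function(table, group_a, group_b) {
  a <- table[table$group == group_a, ]
  b <- table[table$group == group_b, ]
  if (!nrow(a)) stop("group not present in table: ", group_a)
  if (!nrow(b)) stop("group not present in table: ", group_b)
  m <- merge(a, b, by = c("residue", "leaflet"),
             suffixes = c("_a", "_b"))
  out <- data.frame(residue = m$residue, leaflet = m$leaflet,
                    delta_pct = m$occupancy_pct_a - m$occupancy_pct_b)
  out[order(out$residue), ]
}
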