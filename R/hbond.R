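# Geometric hydrogen-bond detection.
#
# Donors are N/O atoms carrying at least one hydrogen (covalent bond
# inferred from an H within 0.12 nm, appropriate for united-atom models
# that keep only polar hydrogens); acceptors are all N/O atoms.  A bond is
# counted when the donor-acceptor distance is within `d_cut` and the
# donor-hydrogen-acceptor geometry deviates from linearity by at most
# `angle_cut`.

.H_COVALENT_CUT <- 0.12  # nm, H attached to its donor heavy atom

#' Hydrogen-bond criteria
#'
#' @param d_cut donor-acceptor distance cutoff, nm (default 0.35)
#' @param angle_cut angular cutoff in degrees (default 60)
#' @param angle_convention `"deviation"` (default): `angle_cut` is the
#'   maximum deviation of the donor-hydrogen-acceptor angle from 180
#'   degrees (so D-H...A >= 120 degrees at the default); `"dha_min"`:
#'   `angle_cut` is itself the minimum D-H...A angle.
#' @export
hbond_criteria <- function(d_cut = 0.35, angle_cut = 60,
                           angle_convention = c("deviation", "dha_min")) {
  stopifnot(d_cut > 0, angle_cut > 0, angle_cut < 180)
  c <- list(d_cut = d_cut, angle_cut = angle_cut,
            angle_convention = match.arg(angle_convention))
  class(c) <- "HBondCriteria"
  c
}

# D-H...A angle at the hydrogen, degrees
.dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# donor table: heavy-atom index + attached hydrogen indices
.find_donors <- function(s, xyz, candidates) {
  hyd <- which(s$atoms$is_hydrogen)
  out <- list()
  for (d in candidates) {
    if (!length(hyd)) { h <- integer(0) } else {
      dd <- sqrt(rowSums(sweep(xyz[hyd, , drop = FALSE], 2, xyz[d, ])^2))
      h <- hyd[dd <= .H_COVALENT_CUT]
    }
    if (length(h)) out[[length(out) + 1]] <- list(donor = d, hydrogens = h)
  }
  out
}

#' Detect hydrogen bonds in one coordinate frame
#'
#' @param s a Structure (supplies elements and hydrogens)
#' @param criteria an [hbond_criteria()] object
#' @param donors,acceptors optional atom-index restrictions (e.g. the two
#'   sides of an interface); defaults: donors = all N/O with an attached
#'   hydrogen, acceptors = all N/O.
#' @param xyz optional n_atoms x 3 coordinates (nm) overriding the
#'   structure's own (for per-frame use)
#' @return list: `count` and `pairs` (data.frame `donor`, `hydrogen`,
#'   `acceptor`, `distance`, `angle` with the D-H...A angle in degrees)
#' @export
hydrogen_bonds <- function(s, criteria = hbond_criteria(), donors = NULL,
                           acceptors = NULL, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  polar <- which(s$atoms$element %in% c("N", "O"))
  don_cand <- if (is.null(donors)) polar else intersect(as.integer(donors), polar)
  acc <- if (is.null(acceptors)) polar else intersect(as.integer(acceptors), polar)
  no_h <- don_cand[!vapply(don_cand, function(d) {
    hyd <- which(s$atoms$is_hydrogen)
    length(hyd) && any(sqrt(rowSums(sweep(xyz[hyd, , drop = FALSE], 2, xyz[d, ])^2)) <= .H_COVALENT_CUT)
  }, logical(1))]
  if (!is.null(donors) && length(no_h))
    warning(length(no_h), " requested donor(s) have no attached hydrogen; skipped")
  dons <- .find_donors(s, xyz, don_cand)
  min_dha <- if (criteria$angle_convention == "deviation")
    180 - criteria$angle_cut else criteria$angle_cut
  pairs <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  for (dn in dons) {
    d <- dn$donor
    da <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ])^2))
    near <- acc[da <= criteria$d_cut & acc != d]
    for (a in near) {
      ang <- vapply(dn$hydrogens, function(h)
        .dha_angle(xyz[d, ], xyz[h, ], xyz[a, ]), numeric(1))
      best <- which.max(ang)
      if (ang[best] >= min_dha) {
        pairs <- rbind(pairs, data.frame(
          donor = d, hydrogen = dn$hydrogens[best], acceptor = a,
          distance = sqrt(sum((xyz[d, ] - xyz[a, ])^2)), angle = ang[best]))
      }
    }
  }
  list(count = nrow(pairs), pairs = pairs)
}

#' Occupancy of one hydrogen bond over a trajectory
#'
#' Fraction of frames in which the given donor-acceptor pair satisfies the
#' criteria (any attached hydrogen may provide the geometry).
#'
#' @param t a Trajectory
#' @param pair length-2 atom indices `c(donor, acceptor)`
#' @param criteria an [hbond_criteria()] object
#' @return fraction in `[0, 1]`
#' @export
hbond_occupancy <- function(t, pair, criteria = hbond_criteria()) {
  stopifnot(length(pair) == 2)
  hits <- vapply(seq_len(n_frames(t)), function(f) {
    hb <- hydrogen_bonds(t$topology, criteria, donors = pair[1],
                         acceptors = pair[2], xyz = frame_coords(t, f))
    hb$count > 0
  }, logical(1))
  mean(hits)
}

#' Count interface hydrogen bonds per frame
#'
#' Donors and acceptors are taken on opposite sides of the partition (both
#' directions), the typical per-interface count averaged over a
#' trajectory.
#'
#' @param t a Trajectory
#' @param groupA,groupB atom indices or selections for the two partners
#' @param criteria an [hbond_criteria()] object
#' @return data.frame `time`, `count`
#' @export
interface_hbonds <- function(t, groupA, groupB, criteria = hbond_criteria()) {
  resolve <- function(g) if (is.character(g)) atom_select(t$topology, g) else as.integer(g)
  ia <- resolve(groupA); ib <- resolve(groupB)
  counts <- vapply(seq_len(n_frames(t)), function(f) {
    xyz <- frame_coords(t, f)
    hydrogen_bonds(t$topology, criteria, donors = ia, acceptors = ib, xyz = xyz)$count +
      hydrogen_bonds(t$topology, criteria, donors = ib, acceptors = ia, xyz = xyz)$count
  }, numeric(1))
  data.frame(time = t$times, count = counts)
}
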