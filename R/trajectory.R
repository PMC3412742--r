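# Trajectory container and superposition-based observables.

#' Construct a Trajectory
#'
#' Ordered coordinate frames aligned to a Structure topology.  Frames are
#' stored as a matrix with one row per frame and 3 columns per atom
#' (x1 y1 z1 x2 ...), in nm.
#'
#' @param topology a Structure
#' @param xyz frame matrix (n_frames x 3*n_atoms, nm) or a list of
#'   n_atoms x 3 coordinate matrices
#' @param times optional frame times in ps (strictly increasing); defaults
#'   to the frame index
#' @export
trajectory <- function(topology, xyz, times = NULL) {
  if (is.list(xyz)) xyz <- do.call(rbind, lapply(xyz, function(f) as.numeric(t(f))))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  dimnames(xyz) <- NULL
  if (ncol(xyz) != 3 * nrow(topology$atoms))
    stop("frame width ", ncol(xyz), " does not match topology (",
         3 * nrow(topology$atoms), " coordinates)")
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz) || any(diff(times) <= 0))
    stop("times must be strictly increasing, one per frame")
  t <- list(topology = topology, xyz = xyz, times = as.numeric(times))
  class(t) <- "Trajectory"
  t
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              nrow(x$xyz), ncol(x$xyz) / 3))
  invisible(x)
}

#' Number of frames
#' @param t a Trajectory
#' @export
n_frames <- function(t) nrow(t$xyz)

# n_atoms x 3 coordinates of one frame
frame_coords <- function(t, i) matrix(t$xyz[i, ], ncol = 3, byrow = TRUE)

#' Read a multi-model PDB as a Trajectory
#' @param path multi-model PDB file
#' @param times optional frame times (ps)
#' @export
read_trajectory_pdb <- function(path, times = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_pdb(path)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  trajectory(topo, xyz / .ANG_PER_NM, times)
}

#' Read a plain whitespace XYZ-per-frame table as a Trajectory
#'
#' One row per frame, 3N whitespace-separated coordinates in nm.
#' @param path table file
#' @param topology Structure the frames belong to
#' @param times optional frame times (ps)
#' @export
read_trajectory_xyz <- function(path, topology, times = NULL) {
  xyz <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(xyz) <- NULL
  trajectory(topology, xyz, times)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits `mob` onto `ref` over `selection` (row indices) and
#' reports the post-fit RMSD over that selection, in the coordinate units
#' supplied.
#'
#' @param ref,mob n x 3 coordinate matrices
#' @param selection row indices used for the fit (default all rows);
#'   must contain at least 3 non-collinear points
#' @return list: `rotation` (3x3), `translation` (applied as
#'   `mob %*% t(rotation) + translation`), `rmsd`, and `fitted` (all of
#'   `mob` transformed)
#' @export
kabsch_superpose <- function(ref, mob, selection = NULL) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  if (!all(dim(ref) == dim(mob))) stop("coordinate sets differ in size")
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  if (length(selection) < 3) stop("need at least 3 points to superpose")
  rs <- ref[selection, , drop = FALSE]
  ms <- mob[selection, , drop = FALSE]
  rc <- colMeans(rs); mc <- colMeans(ms)
  A <- crossprod(sweep(ms, 2, mc), sweep(rs, 2, rc))
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rc - as.numeric(R %*% mc)
  fitted <- sweep(mob %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - rs)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, fitted = fitted)
}

# resolve selection + exclusions to C-alpha atom indices
.ca_selection <- function(s, selection = NULL, exclusions = NULL) {
  idx <- if (is.null(selection)) which(s$atoms$elety == "CA" & !s$atoms$is_hydrogen)
         else intersect(atom_select(s, selection, elety = "CA"),
                        which(!s$atoms$is_hydrogen))
  if (!is.null(exclusions) && length(exclusions))
    idx <- setdiff(idx, atom_select(s, exclusions))
  if (!length(idx)) stop("empty effective C-alpha selection")
  idx
}

#' Per-frame C-alpha RMSD to a reference structure
#'
#' Each frame is superposed on the reference over the selected C-alpha
#' atoms (minus exclusions) before the RMSD is taken.  Flexible tails --
#' such as the terminal receptor residues 134-153 that fluctuate freely in
#' simulation -- are the typical exclusions.
#'
#' @param t a Trajectory
#' @param ref reference Structure (default: the trajectory topology at its
#'   stored coordinates)
#' @param selection character selections (`"chain:start-end"`); default all
#'   C-alpha atoms
#' @param exclusions character selections removed from the fit/RMSD set
#' @return data.frame `time`, `rmsd` (nm)
#' @export
rmsd_series <- function(t, ref = NULL, selection = NULL, exclusions = NULL) {
  if (is.null(ref)) ref <- t$topology
  idx <- .ca_selection(t$topology, selection, exclusions)
  rxyz <- coords(ref)
  if (nrow(rxyz) != ncol(t$xyz) / 3)
    stop("reference and trajectory topology differ in atom count")
  vals <- vapply(seq_len(n_frames(t)), function(f)
    kabsch_superpose(rxyz, frame_coords(t, f), idx)$rmsd, numeric(1))
  data.frame(time = t$times, rmsd = vals)
}

# superpose all frames on the mean structure (one refit iteration); returns
# list(frames = list of fitted n_atoms x 3, mean = n_atoms x 3)
.superpose_to_mean <- function(t, idx) {
  frames <- lapply(seq_len(n_frames(t)), function(f) frame_coords(t, f))
  ref <- frames[[1]]
  fit1 <- lapply(frames, function(fc) kabsch_superpose(ref, fc, idx)$fitted)
  mean1 <- Reduce(`+`, fit1) / length(fit1)
  fit2 <- lapply(frames, function(fc) kabsch_superpose(mean1, fc, idx)$fitted)
  list(frames = fit2, mean = Reduce(`+`, fit2) / length(fit2))
}

#' Root-mean-square fluctuation of C-alpha atoms
#'
#' Frames are superposed on the average structure (computed once and
#' refitted once); `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`.
#'
#' @inheritParams rmsd_series
#' @return data.frame `chain`, `resno`, `rmsf` (nm), one row per selected
#'   C-alpha
#' @export
rmsf <- function(t, selection = NULL) {
  if (n_frames(t) < 2) stop("need at least 2 frames")
  idx <- .ca_selection(t$topology, selection)
  sp <- .superpose_to_mean(t, idx)
  dev2 <- Reduce(`+`, lapply(sp$frames, function(fc) rowSums((fc - sp$mean)^2))) /
    length(sp$frames)
  data.frame(chain = t$topology$atoms$chain[idx],
             resno = t$topology$atoms$resno[idx],
             rmsf = sqrt(dev2[idx]))
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Normalized covariance of C-alpha displacements after superposition on
#' the average structure:
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`.
#'
#' @inheritParams rmsd_series
#' @return symmetric matrix with unit diagonal, labelled by `chain:resno`
#' @export
dccm <- function(t, selection = NULL) {
  if (n_frames(t) < 2) stop("need at least 2 frames")
  idx <- .ca_selection(t$topology, selection)
  sp <- .superpose_to_mean(t, idx)
  n <- length(idx)
  cov <- matrix(0, n, n)
  for (fc in sp$frames) {
    d <- (fc - sp$mean)[idx, , drop = FALSE]
    cov <- cov + tcrossprod(d)
  }
  cov <- cov / length(sp$frames)
  v <- diag(cov)
  if (any(v <= 0)) {
    lab <- paste(t$topology$atoms$chain[idx], t$topology$atoms$resno[idx], sep = ":")
    stop("zero-variance residue(s): ", paste(lab[v <= 0], collapse = ", "))
  }
  C <- cov / sqrt(outer(v, v))
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  lab <- paste(t$topology$atoms$chain[idx], t$topology$atoms$resno[idx], sep = ":")
  dimnames(C) <- list(lab, lab)
  C
}

#' Distance between the geometric centers of two atom groups, per frame
#'
#' The typical use is a domain monitor, e.g. the distance between the
#' ligand's center and the center of a receptor CRD4 domain.
#'
#' @param t a Trajectory
#' @param groupA,groupB atom indices or character selections
#' @param weights `"geometric"` (unweighted, default) or `"mass"`
#' @return data.frame `time`, `distance` (nm)
#' @export
group_distance <- function(t, groupA, groupB,
                           weights = c("geometric", "mass")) {
  weights <- match.arg(weights)
  resolve <- function(g) if (is.character(g)) atom_select(t$topology, g) else as.integer(g)
  ia <- resolve(groupA); ib <- resolve(groupB)
  if (!length(ia) || !length(ib)) stop("empty atom group")
  w <- function(i) {
    if (weights == "geometric") rep(1, length(i))
    else { m <- .ATOMIC_MASS[t$topology$atoms$element[i]]; m[is.na(m)] <- 12; m }
  }
  wa <- w(ia); wb <- w(ib)
  d <- vapply(seq_len(n_frames(t)), function(f) {
    fc <- frame_coords(t, f)
    ca <- colSums(fc[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(fc[ib, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  data.frame(time = t$times, distance = d)
}

#' Distance between two single atoms, per frame
#' @param t a Trajectory
#' @param atomA,atomB single atom indices or selections resolving to one atom
#' @export
atom_pair_distance <- function(t, atomA, atomB) {
  group_distance(t, atomA, atomB)
}

#' RMSD between two receptor states read from PDB files
#'
#' Computes the C-alpha Kabsch RMSD over an author-numbered residue window
#' (default 15-150, the receptor core common to the bound and unbound
#' crystal forms) between every chain pairing of the two files and reports
#' the best-fitting pair, in Angstrom.
#'
#' @param path_a,path_b PDB files
#' @param range residue window, default `c(15, 150)`
#' @return list: `rmsd` (A), `chain_a`, `chain_b`, and the full `table` of
#'   all chain pairings
#' @export
receptor_state_rmsd <- function(path_a, path_b, range = c(15, 150)) {
  sa <- read_pdb(path_a); sb <- read_pdb(path_b)
  one_chain_ca <- function(s, ch) {
    sub <- try(select_residues(s, ch, range), silent = TRUE)
    if (inherits(sub, "try-error")) return(NULL)
    ca <- sub$atoms$elety == "CA" & !sub$atoms$is_hydrogen
    m <- coords(sub)[ca, , drop = FALSE]
    rownames(m) <- sub$atoms$resno[ca]
    m
  }
  res <- NULL
  for (ca_ch in unique(sa$atoms$chain)) for (cb_ch in unique(sb$atoms$chain)) {
    ma <- one_chain_ca(sa, ca_ch); mb <- one_chain_ca(sb, cb_ch)
    if (is.null(ma) || is.null(mb)) next
    common <- intersect(rownames(ma), rownames(mb))
    if (length(common) < 3) next
    r <- kabsch_superpose(ma[common, ], mb[common, ])$rmsd * .ANG_PER_NM
    res <- rbind(res, data.frame(chain_a = ca_ch, chain_b = cb_ch,
                                 n = length(common), rmsd = r))
  }
  if (is.null(res)) stop("no comparable chain pairing found")
  best <- res[which.min(res$rmsd), ]
  list(rmsd = best$rmsd, chain_a = best$chain_a, chain_b = best$chain_b,
       table = res)
}
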