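# Synthetic fixtures with known ground truth: toy structures, network-
# consistent Gaussian ensembles, planted hydrogen-bond interfaces, and
# energy tables.  Every generator is deterministic given its seed.

#' Generate a toy protein structure
#'
#' Builds a C-alpha trace following the requested secondary-structure
#' pattern (ideal helix geometry for `H`: 0.15 nm rise and 100 degrees
#' twist per residue on a 0.23 nm radius; extended zig-zag for `E`; a
#' gentle spiral for `C` -- consecutive C-alpha separations stay near
#' 0.38 nm throughout) and adds a pseudo side-chain heavy atom (CB) per
#' non-glycine residue.  Residues named in `disulfides` become cysteines
#' whose SG atoms are placed 0.203 nm apart between the two C-alphas.
#'
#' @param n_residues chain length
#' @param ss_pattern string over `H`/`E`/`C` of length `n_residues`
#'   (default all coil)
#' @param disulfides list of residue-index pairs to join by disulfides
#' @param chains number of identical chains (translated copies, ids A, B,
#'   C, ...), default 1
#' @param gly_at residue indices made glycine (no side chain)
#' @param seed integer seed controlling the small deterministic jitter
#' @return a Structure with secondary-structure labels attached
#' @export
make_toy_structure <- function(n_residues, ss_pattern = NULL,
                               disulfides = list(), chains = 1,
                               gly_at = integer(0), seed = 1) {
  if (is.null(ss_pattern)) ss_pattern <- strrep("C", n_residues)
  ss <- strsplit(ss_pattern, "")[[1]]
  if (length(ss) != n_residues) stop("ss_pattern length must equal n_residues")
  if (!all(ss %in% c("H", "E", "C"))) stop("ss_pattern must use H/E/C")
  set.seed(seed)
  jitter <- matrix(stats::runif(3 * n_residues, -0.005, 0.005), ncol = 3)

  ca <- matrix(0, n_residues, 3)
  for (i in seq_len(n_residues)) {
    if (ss[i] == "H") {
      ca[i, ] <- c(0.23 * cos(i * 100 * pi / 180),
                   0.23 * sin(i * 100 * pi / 180), 0.15 * i)
    } else if (ss[i] == "E") {
      ca[i, ] <- c(0.05 * (-1)^i, 0, 0.377 * i)
    } else {
      th <- i * 25 * pi / 180
      ca[i, ] <- c(0.6 * cos(th), 0.6 * sin(th), 0.30 * i) + jitter[i, ]
    }
  }
  # stitch mixed patterns into a continuous chain: rescale each step to
  # ~0.38 nm along the running direction
  for (i in 2:n_residues) {
    step <- ca[i, ] - ca[i - 1, ]
    len <- sqrt(sum(step^2))
    if (len < 1e-6) step <- c(0, 0, 0.38) else step <- step * (0.38 / len) *
        ifelse(ss[i] == "H" && ss[i - 1] == "H", len / 0.38, 1)
    ca[i, ] <- ca[i - 1, ] + step
  }

  is_cys <- rep(FALSE, n_residues)
  for (p in disulfides) {
    stopifnot(length(p) == 2, all(p >= 1), all(p <= n_residues))
    is_cys[p] <- TRUE
  }
  resid <- rep("ALA", n_residues)
  resid[gly_at] <- "GLY"
  resid[is_cys] <- "CYS"

  atoms <- list()
  for (i in seq_len(n_residues)) {
    atoms[[length(atoms) + 1]] <- data.frame(
      chain = "A", resno = i, resid = resid[i], elety = "CA", element = "C",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], stringsAsFactors = FALSE)
    if (resid[i] != "GLY") {
      # deterministic lateral offset, never coincident with the C-alpha
      cb <- ca[i, ] + 0.15 * c(cos(2.4 * i), sin(2.4 * i), 0)
      atoms[[length(atoms) + 1]] <- data.frame(
        chain = "A", resno = i, resid = resid[i], elety = "CB", element = "C",
        x = cb[1], y = cb[2], z = cb[3], stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, atoms)

  # SG atoms bracketing the midpoint between the paired C-alphas
  ds_tab <- NULL
  for (p in disulfides) {
    mid <- (ca[p[1], ] + ca[p[2], ]) / 2
    sep <- ca[p[2], ] - ca[p[1], ]
    len <- sqrt(sum(sep^2))
    if (len > 1.2) stop("infeasible disulfide: C-alphas ", p[1], " and ",
                        p[2], " are ", round(len, 2), " nm apart")
    u <- sep / len
    for (k in 1:2) {
      pos <- mid + (if (k == 1) -1 else 1) * 0.1015 * u
      at <- rbind(at, data.frame(
        chain = "A", resno = p[k], resid = "CYS", elety = "SG", element = "S",
        x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE))
    }
    ds_tab <- rbind(ds_tab, data.frame(chain1 = "A", resno1 = p[1],
                                       chain2 = "A", resno2 = p[2],
                                       stringsAsFactors = FALSE))
  }

  if (chains > 1) {
    base <- at
    for (c in 2:chains) {
      shifted <- base
      shifted$chain <- LETTERS[c]
      shifted$x <- shifted$x + 3 * (c - 1)
      at <- rbind(at, shifted)
    }
  }
  # restore residue-major atom order
  at <- at[order(match(at$chain, LETTERS), at$resno,
                 match(at$elety, c("CA", "CB", "SG"))), , drop = FALSE]
  rownames(at) <- NULL
  ss_tab <- do.call(rbind, lapply(unique(at$chain), function(ch)
    data.frame(chain = ch, resno = seq_len(n_residues), label = ss,
               stringsAsFactors = FALSE)))
  if (!is.null(ds_tab) && chains > 1) {
    extra <- do.call(rbind, lapply(2:chains, function(c) {
      d <- ds_tab; d$chain1 <- LETTERS[c]; d$chain2 <- LETTERS[c]; d
    }))
    ds_tab <- rbind(ds_tab, extra)
  }
  structure_new(at, ss = ss_tab, disulfides = ds_tab)
}

#' Sample a Gaussian ensemble from a spring network
#'
#' Frames are drawn from the network's own Boltzmann distribution:
#' `x = x0 + sum_modes (z_m sqrt(temperature / lambda_m)) v_m` with
#' independent standard-normal `z_m` over the non-rigid modes, so the
#' analytic fluctuations and correlations of the model are the exact
#' ground truth for the trajectory observables computed from the sample.
#' Projections onto rigid-body modes are identically zero.
#'
#' @param net a connected SpringNetwork
#' @param n_frames number of frames (>= 2)
#' @param temperature global variance scale (arbitrary units; all
#'   downstream comparisons are shape-based)
#' @param seed RNG seed
#' @param modes optional precomputed ModeSet for `net`
#' @return a Trajectory whose topology has one pseudo-atom per node
#'   (CA for backbone nodes, CB for side-chain nodes)
#' @export
sample_enm_ensemble <- function(net, n_frames, temperature = 1e-3, seed = 1,
                                modes = NULL) {
  stopifnot(n_frames >= 2)
  if (!net$connected) stop("network is disconnected; cannot sample")
  if (is.null(modes)) modes <- eigenmodes(build_hessian(net), net = net)
  idx <- nonrigid_idx(modes)
  x0 <- as.numeric(t(as.matrix(net$nodes[, c("x", "y", "z")])))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_frames * length(idx)), n_frames, length(idx))
  amp <- sqrt(temperature / modes$values[idx])
  disp <- z %*% (t(modes$vectors[, idx, drop = FALSE]) * amp)
  xyz <- sweep(disp, 2, x0, "+")
  topo_atoms <- data.frame(
    chain = net$nodes$chain, resno = net$nodes$resno, resid = net$nodes$resid,
    elety = ifelse(net$nodes$kind == "bb", "CA", "CB"),
    element = "C", x = net$nodes$x, y = net$nodes$y, z = net$nodes$z,
    stringsAsFactors = FALSE)
  trajectory(structure_new(topo_atoms), xyz)
}

#' Plant a hydrogen-bond interface with decoys
#'
#' Builds two chains (D: donor N atoms with attached H; A: acceptor O
#' atoms) containing exactly `n_bonds` donor-acceptor pairs satisfying the
#' criteria and `n_decoys` pairs violating exactly one criterion each
#' (alternating: distance too long with ideal angle / good distance with a
#' bent D-H...A geometry).  Pair sites sit on a 2 nm grid so no accidental
#' cross-pair bonds arise.
#'
#' @param n_bonds planted true bonds
#' @param n_decoys planted single-violation decoys
#' @param criteria an [hbond_criteria()] (geometry is planted relative to
#'   these cutoffs)
#' @param n_frames if > 1, also return a Trajectory; `break_schedule`
#'   lists, per planted bond, the frames in which it is broken (acceptor
#'   temporarily displaced)
#' @param break_schedule list (length `n_bonds`) of frame indices
#' @param seed RNG seed (decoy orientations)
#' @return list: `structure`, `donors`, `acceptors` (atom indices of
#'   donor/acceptor heavy atoms, true bonds first), and `trajectory` when
#'   `n_frames > 1`
#' @export
make_planted_interface <- function(n_bonds, n_decoys = 0,
                                   criteria = hbond_criteria(),
                                   n_frames = 1, break_schedule = NULL,
                                   seed = 1) {
  stopifnot(n_bonds >= 0, n_decoys >= 0)
  set.seed(seed)
  good_d <- 0.9 * criteria$d_cut          # comfortably inside
  bad_d <- 1.3 * criteria$d_cut           # distance violation
  bad_dev <- criteria$angle_cut + 30      # angle violation, degrees
  rows <- list(); don <- integer(0); acc <- integer(0)
  add <- function(rows, resno, chain, elety, element, pos) {
    rows[[length(rows) + 1]] <- data.frame(
      chain = chain, resno = resno, resid = "XXX", elety = elety,
      element = element, x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
    rows
  }
  total <- n_bonds + n_decoys
  for (p in seq_len(total)) {
    origin <- c(2 * p, 0, 0)
    is_decoy <- p > n_bonds
    decoy_type <- if (is_decoy) (p - n_bonds - 1) %% 2 else -1
    d_pos <- origin
    h_pos <- origin + c(0.1, 0, 0)
    da <- if (decoy_type == 0) bad_d else good_d
    if (decoy_type == 1) {
      dev <- bad_dev * pi / 180
      a_pos <- d_pos + da * c(cos(dev), sin(dev), 0)
    } else {
      a_pos <- d_pos + c(da, 0, 0)   # collinear D-H...A
    }
    rows <- add(rows, p, "D", "N", "N", d_pos)
    don <- c(don, length(rows))
    rows <- add(rows, p, "D", "H", "H", h_pos)
    rows <- add(rows, p, "A", "O", "O", a_pos)
    acc <- c(acc, length(rows))
  }
  at <- do.call(rbind, rows)
  s <- structure_new(at)
  out <- list(structure = s, donors = don, acceptors = acc,
              n_bonds = n_bonds, n_decoys = n_decoys)
  if (n_frames > 1) {
    base <- as.numeric(t(coords(s)))
    xyz <- matrix(rep(base, n_frames), nrow = n_frames, byrow = TRUE)
    if (!is.null(break_schedule)) {
      stopifnot(length(break_schedule) == n_bonds)
      for (b in seq_len(n_bonds)) for (f in break_schedule[[b]]) {
        ai <- acc[b]
        xyz[f, 3 * ai - 2] <- xyz[f, 3 * ai - 2] + 2 * criteria$d_cut
      }
    }
    out$trajectory <- trajectory(s, xyz)
  }
  out
}

#' Gaussian energy-component table with known truth
#'
#' Independent normal columns around `true_means`, one row per snapshot:
#' the recoverable ground truth for ledger aggregation.
#'
#' @param true_means named numeric over (a subset of) `H_int`, `H_vdW`,
#'   `H_elect`, `G_polar`, `G_apolar`; missing components default to 0
#' @param noise_sigma single value or named per-component noise SD
#' @param n snapshots (>= 2)
#' @param seed RNG seed
#' @param species species tag column value
#' @return data.frame `snapshot`, `species`, and the five components
#' @export
make_energy_table <- function(true_means, noise_sigma = 0, n = 100, seed = 1,
                              species = "complex") {
  stopifnot(n >= 2)
  mu <- stats::setNames(rep(0, 5), .ENERGY_COMPONENTS)
  mu[names(true_means)] <- true_means
  sig <- stats::setNames(rep_len(noise_sigma, 5), .ENERGY_COMPONENTS)
  if (!is.null(names(noise_sigma))) {
    sig[] <- 0; sig[names(noise_sigma)] <- noise_sigma
  }
  set.seed(seed)
  out <- data.frame(snapshot = seq_len(n), species = species)
  for (cc in .ENERGY_COMPONENTS)
    out[[cc]] <- stats::rnorm(n, mu[cc], sig[cc])
  out
}
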