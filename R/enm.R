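# Side-chain-augmented anisotropic network model.
#
# Each residue contributes a backbone node at its C-alpha and (except
# glycine) one side-chain node: the heavy-atom centre of mass, or a named
# terminal atom for the six residues whose interaction centre sits at the
# side-chain tip.  Springs carry force constants chosen by bonding
# criterion or distance shell.

.KCAL_A2_TO_KJ_NM2 <- 4.184 * 100   # kcal mol-1 A-2 -> kJ mol-1 nm-2
.B_FROM_MSF <- 8 * pi^2 / 3

# residues whose side-chain node is a named terminal atom, not the centre of mass
.TERMINAL_SC_ATOM <- c(ASP = "CG", ASN = "CG", ARG = "CZ",
                       LYS = "NZ", GLN = "CD", GLU = "CD")

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971)

#' Force-constant scheme for the extended anisotropic network model
#'
#' Constants are given in kcal mol-1 A-2 (the usual units for coarse-grained
#' network models) and converted to kJ mol-1 nm-2 internally.  Distance
#' shells assign `k_shells[1]` up to `shell_bounds[1]`, `k_shells[2]` up to
#' `shell_bounds[2]`, `k_shells[3]` up to the hard cutoff `shell_bounds[3]`;
#' node pairs farther apart are not connected.
#'
#' @param k_bonded C-alpha to side-chain tether within one residue.
#' @param k_bridge disulfide bridge between cysteine side-chain nodes.
#' @param k_ss_backbone sequential C-alpha pair inside one helix or strand.
#' @param k_shells three distance-shell constants (default 3, 2, 1).
#' @param shell_bounds shell upper bounds in nm (default 0.4, 0.8, 1.2);
#'   the last value is the interaction cutoff.
#' @param ss_mode `"sequential"` stiffens only (i, i+1) C-alpha pairs within
#'   one secondary-structure element; `"all_pairs"` stiffens every C-alpha
#'   pair inside the element that lies within the cutoff.
#' @return an object of class `ENMParams`.
#' @export
enm_params <- function(k_bonded = 10, k_bridge = 10, k_ss_backbone = 6,
                       k_shells = c(3, 2, 1),
                       shell_bounds = c(0.4, 0.8, 1.2),
                       ss_mode = c("sequential", "all_pairs")) {
  stopifnot(k_bonded > 0, k_bridge > 0, k_ss_backbone > 0,
            length(k_shells) == 3, all(k_shells > 0),
            length(shell_bounds) == 3, all(diff(shell_bounds) > 0),
            all(shell_bounds > 0))
  p <- list(k_bonded = k_bonded, k_bridge = k_bridge,
            k_ss_backbone = k_ss_backbone, k_shells = k_shells,
            shell_bounds = shell_bounds, ss_mode = match.arg(ss_mode))
  class(p) <- "ENMParams"
  p
}

#' Build coarse-grained nodes from a Structure
#'
#' One backbone node per residue at the C-alpha; one side-chain node at the
#' heavy-atom centre of mass of the side chain, except ASP/ASN/ARG/LYS/GLN/
#' GLU which use their CG/CG/CZ/NZ/CD/CD terminal atom (falling back to the
#' centre of mass with a warning if that atom is absent).  Glycine has no
#' side-chain node.
#'
#' @param s a Structure whose residues all carry a C-alpha.
#' @return data.frame of nodes: `chain`, `resno`, `resid`, `kind`
#'   (`"bb"`/`"sc"`), `x`, `y`, `z` (nm).
#' @export
build_nodes <- function(s) {
  at <- s$atoms
  key <- atom_res_key(s)
  backbone_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2", "O1", "O2")
  rows <- list()
  for (k in residue_keys(s)) {
    ri <- which(key == k)
    resid <- at$resid[ri[1]]
    ca <- ri[at$elety[ri] == "CA" & !at$is_hydrogen[ri]]
    if (!length(ca)) stop("residue ", k, " has no C-alpha; cannot build nodes")
    rows[[length(rows) + 1]] <- data.frame(
      chain = at$chain[ri[1]], resno = at$resno[ri[1]], resid = resid,
      kind = "bb", x = at$x[ca[1]], y = at$y[ca[1]], z = at$z[ca[1]],
      stringsAsFactors = FALSE)
    if (resid == "GLY") next
    sc <- ri[!(at$elety[ri] %in% backbone_names) & !at$is_hydrogen[ri]]
    if (!length(sc)) next
    pos <- NULL
    if (resid %in% names(.TERMINAL_SC_ATOM)) {
      term <- sc[at$elety[sc] == .TERMINAL_SC_ATOM[[resid]]]
      if (length(term)) {
        pos <- c(at$x[term[1]], at$y[term[1]], at$z[term[1]])
      } else {
        warning("residue ", k, " (", resid, "): terminal atom ",
                .TERMINAL_SC_ATOM[[resid]],
                " missing, using side-chain centre of mass")
      }
    }
    if (is.null(pos)) {
      m <- .ATOMIC_MASS[at$element[sc]]
      m[is.na(m)] <- 12
      pos <- c(sum(m * at$x[sc]), sum(m * at$y[sc]), sum(m * at$z[sc])) / sum(m)
    }
    rows[[length(rows) + 1]] <- data.frame(
      chain = at$chain[ri[1]], resno = at$resno[ri[1]], resid = resid,
      kind = "sc", x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# contiguous secondary-structure element id per residue (0 = coil)
.ss_elements <- function(rt) {
  elem <- integer(nrow(rt))
  cur <- 0L
  for (i in seq_len(nrow(rt))) {
    lab <- rt$ss[i]
    new_run <- i == 1 || rt$chain[i] != rt$chain[i - 1] ||
      rt$ss[i - 1] != lab || rt$resno[i] != rt$resno[i - 1] + 1L
    if (lab %in% c("H", "E")) {
      if (new_run) cur <- cur + 1L
      elem[i] <- cur
    }
  }
  elem
}

#' Assemble the spring network
#'
#' Every node pair within the cutoff receives exactly one spring whose
#' constant follows the precedence: (1) intra-residue C-alpha/side-chain
#' tether; (2) disulfide side-chain bridge; (3) sequential C-alpha pair
#' within one helix or strand; (4) distance-shell constant.  Rest lengths
#' are the build-time distances, so the network is at mechanical
#' equilibrium by construction.
#'
#' @param nodes node table from [build_nodes()].
#' @param params an [enm_params()] object.
#' @param disulfides optional disulfide pair table (as in a Structure).
#' @param ss optional residue table with columns `chain`, `resno`, `ss`
#'   (e.g. from [residue_table()]).
#' @return an object of class `SpringNetwork`: `nodes`, `springs`
#'   (data.frame `i`, `j`, `k` in kJ mol-1 nm-2, `rest` in nm, `rule`),
#'   and `connected` flag.
#' @export
build_springs <- function(nodes, params = enm_params(), disulfides = NULL,
                          ss = NULL) {
  n <- nrow(nodes)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  key <- paste(nodes$chain, nodes$resno)
  dm <- as.matrix(stats::dist(xyz))
  cutoff <- params$shell_bounds[3]

  # residue-level annotations mapped onto backbone nodes
  sslab <- rep("C", n)
  if (!is.null(ss) && nrow(ss)) {
    m <- match(key, paste(ss$chain, ss$resno))
    lab <- ifelse(is.na(m), "C", ss$ss[m])
    sslab <- lab
  }
  rt <- data.frame(chain = nodes$chain, resno = nodes$resno, ss = sslab,
                   stringsAsFactors = FALSE)
  bb <- which(nodes$kind == "bb")
  elem_bb <- .ss_elements(rt[bb, , drop = FALSE])
  elem <- integer(n); elem[bb] <- elem_bb

  bridge_key <- character(0)
  if (!is.null(disulfides) && nrow(disulfides)) {
    bridge_key <- c(paste(disulfides$chain1, disulfides$resno1,
                          disulfides$chain2, disulfides$resno2),
                    paste(disulfides$chain2, disulfides$resno2,
                          disulfides$chain1, disulfides$resno1))
  }

  pairs <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  ii <- pairs[, 1]; jj <- pairs[, 2]
  same_res <- key[ii] == key[jj]
  tether <- same_res & nodes$kind[ii] != nodes$kind[jj]
  is_cys_sc <- nodes$resid == "CYS" & nodes$kind == "sc"
  bridge <- is_cys_sc[ii] & is_cys_sc[jj] &
    paste(nodes$chain[ii], nodes$resno[ii], nodes$chain[jj], nodes$resno[jj]) %in% bridge_key
  both_bb <- nodes$kind[ii] == "bb" & nodes$kind[jj] == "bb"
  same_elem <- both_bb & elem[ii] > 0 & elem[ii] == elem[jj]
  sequential <- same_elem & nodes$chain[ii] == nodes$chain[jj] &
    abs(nodes$resno[ii] - nodes$resno[jj]) == 1
  ss_pair <- if (params$ss_mode == "sequential") sequential else same_elem

  d <- dm[pairs]
  shell <- findInterval(d, params$shell_bounds, left.open = FALSE) + 1L
  shell[d <= params$shell_bounds[1]] <- 1L
  shell[d > params$shell_bounds[1] & d <= params$shell_bounds[2]] <- 2L
  shell[d > params$shell_bounds[2]] <- 3L
  k <- params$k_shells[shell]
  rule <- rep("shell", length(d))
  k[ss_pair] <- params$k_ss_backbone; rule[ss_pair] <- "ss"
  k[bridge] <- params$k_bridge;       rule[bridge] <- "bridge"
  k[tether] <- params$k_bonded;       rule[tether] <- "tether"

  springs <- data.frame(i = ii, j = jj, k = k * .KCAL_A2_TO_KJ_NM2,
                        rest = d, rule = rule, stringsAsFactors = FALSE)
  net <- list(nodes = nodes, springs = springs,
              params = params, connected = TRUE)
  class(net) <- "SpringNetwork"
  comp <- .components(n, springs)
  if (max(comp) > 1 || any(tabulate(c(springs$i, springs$j), n) == 0)) {
    net$connected <- FALSE
    warning("spring network is not connected (",
            max(comp), " components)")
  }
  net$component <- comp
  net
}

#' @export
print.SpringNetwork <- function(x, ...) {
  cat(sprintf("SpringNetwork: %d nodes, %d springs (%sconnected)\n",
              nrow(x$nodes), nrow(x$springs),
              if (x$connected) "" else "NOT "))
  print(table(x$springs$rule))
  invisible(x)
}

# connected components of the spring graph (plain BFS)
.components <- function(n, springs) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n); cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Convenience: Structure to SpringNetwork in one step
#'
#' Uses the structure's attached disulfides and secondary-structure labels.
#' @param s a Structure
#' @param params an [enm_params()] object
#' @export
build_enm <- function(s, params = enm_params()) {
  build_springs(build_nodes(s), params, disulfides = s$disulfides,
                ss = residue_table(s))
}

#' Harmonic energy of a spring network at given coordinates
#'
#' `E = sum k/2 (|r_i - r_j| - rest)^2`, in kJ/mol.  Used both by the
#' ensemble sampler and as the function whose numerical second derivatives
#' cross-check the assembled Hessian.
#'
#' @param net a SpringNetwork
#' @param xyz coordinate matrix (n_nodes x 3, nm) or flat length-3N vector
#' @export
spring_energy <- function(net, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  dvec <- xyz[net$springs$i, , drop = FALSE] - xyz[net$springs$j, , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  sum(net$springs$k / 2 * (d - net$springs$rest)^2)
}

#' Assemble the anisotropic-network Hessian
#'
#' For spring (i, j) with constant k and bond vector r, the off-diagonal
#' 3x3 super-element is `-(k/d^2) r r^T`; diagonal super-elements are the
#' negative sums of their row's off-diagonal blocks, which makes every
#' uniform translation an exact null vector.
#'
#' @param net a SpringNetwork
#' @return symmetric 3N x 3N matrix (kJ mol-1 nm-2)
#' @export
build_hessian <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("need at least two nodes")
  xyz <- as.matrix(net$nodes[, c("x", "y", "z")])
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(net$springs))) {
    i <- net$springs$i[r]; j <- net$springs$j[r]
    k <- net$springs$k[r]
    rij <- xyz[j, ] - xyz[i, ]
    blk <- (k / sum(rij^2)) * tcrossprod(rij)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- H[ri, rj] - blk
    H[rj, ri] <- H[rj, ri] - blk
    H[ri, ri] <- H[ri, ri] + blk
    H[rj, rj] <- H[rj, rj] + blk
  }
  H
}

#' Diagonalize a network Hessian
#'
#' Eigenvalues are returned in ascending order; modes with
#' `|lambda| <= tol * lambda_max` are classified as rigid-body modes.  A
#' connected, externally unconstrained network has exactly six.  More than
#' six rigid modes means the network falls into pieces; the error names the
#' components when the network is supplied.
#'
#' @param H Hessian from [build_hessian()]
#' @param n_modes number of non-rigid modes to flag for analysis (default
#'   all)
#' @param net optional SpringNetwork, used to name disconnected components
#' @param rigid_tol relative tolerance for the rigid-mode classification
#' @return an object of class `ModeSet`: `values` (ascending), `vectors`
#'   (3N x 3N, columns orthonormal), `n_rigid`, `n_modes`, `coords`
#'   (equilibrium node coordinates if `net` given).
#' @export
eigenmodes <- function(H, n_modes = NULL, net = NULL, rigid_tol = 1e-8) {
  if (max(abs(H - t(H))) > 1e-9 * max(1, max(abs(H))))
    stop("Hessian is not symmetric")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lam_max <- max(abs(values))
  n_rigid <- sum(abs(values) <= rigid_tol * lam_max)
  if (n_rigid > 6) {
    msg <- sprintf("%d near-zero modes: network has multiple rigid bodies", n_rigid)
    if (!is.null(net) && !is.null(net$component)) {
      sizes <- table(net$component)
      msg <- paste0(msg, " (components of size ",
                    paste(sizes, collapse = ", "), ")")
    }
    stop(msg)
  }
  # deterministic sign: largest-magnitude component positive
  for (c in seq_len(ncol(vectors))) {
    mx <- which.max(abs(vectors[, c]))
    if (vectors[mx, c] < 0) vectors[, c] <- -vectors[, c]
  }
  n_avail <- length(values) - n_rigid
  if (is.null(n_modes)) n_modes <- n_avail
  if (n_modes > n_avail) stop("requested ", n_modes, " modes but only ",
                              n_avail, " non-rigid modes exist")
  m <- list(values = values, vectors = vectors, n_rigid = n_rigid,
            n_modes = n_modes,
            coords = if (!is.null(net)) as.matrix(net$nodes[, c("x", "y", "z")]) else NULL,
            nodes = if (!is.null(net)) net$nodes else NULL)
  class(m) <- "ModeSet"
  m
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet: %d modes (%d rigid), lowest non-rigid eigenvalue %.4g\n",
              length(x$values), x$n_rigid, x$values[x$n_rigid + 1]))
  invisible(x)
}

# indices (into columns of vectors) of the first n non-rigid modes
nonrigid_idx <- function(m, n = NULL) {
  avail <- (m$n_rigid + 1):length(m$values)
  if (is.null(n)) avail else {
    if (n > length(avail)) stop("only ", length(avail), " non-rigid modes available")
    avail[seq_len(n)]
  }
}

#' Predicted mean-square fluctuations and B-factors
#'
#' `MSF_i` is proportional to `sum_m |v_m,i|^2 / lambda_m` over the lowest
#' `n_modes` non-rigid modes (all by default); the B-factor column is
#' `(8 pi^2 / 3) MSF`, in arbitrary units up to the global kT scale.  Use
#' [scale_to_bfactors()] to least-squares match an experimental profile.
#'
#' @param m a ModeSet
#' @param n_modes number of non-rigid modes (default all)
#' @return data.frame with one row per node: `msf`, `bfactor`
#' @export
predicted_fluctuations <- function(m, n_modes = NULL) {
  idx <- nonrigid_idx(m, n_modes)
  if (!length(idx)) stop("no non-rigid modes")
  n <- length(m$values) / 3
  msf <- numeric(n)
  for (c in idx) {
    v2 <- matrix(m$vectors[, c]^2, ncol = 3, byrow = TRUE)
    msf <- msf + rowSums(v2) / m$values[c]
  }
  out <- data.frame(node = seq_len(n), msf = msf, bfactor = .B_FROM_MSF * msf)
  if (!is.null(m$nodes)) out <- cbind(m$nodes[, c("chain", "resno", "kind")], out)
  out
}

#' Least-squares scale of predicted onto observed B-factors
#' @param pred predicted B-factor vector
#' @param obs observed B-factor vector (same length)
#' @return scaled prediction, with the fitted factor as attribute `"scale"`
#' @export
scale_to_bfactors <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  a <- sum(pred * obs) / sum(pred^2)
  out <- a * pred
  attr(out, "scale") <- a
  out
}

#' Overlap matrix between the low-frequency modes of two models
#'
#' `O[i, j] = |v_i^a . v_j^b|` over a common node set: each eigenvector is
#' restricted to the mapped nodes, renormalized to unit length, and the
#' absolute dot product taken.  Values lie in `[0, 1]`; identical models
#' give the identity matrix.
#'
#' @param a,b ModeSet objects
#' @param node_map two-column integer matrix/data.frame pairing node indices
#'   of `a` with node indices of `b`; default pairs node k with node k.
#' @param n number of non-rigid modes to compare (default 10)
#' @export
mode_overlap <- function(a, b, node_map = NULL, n = 10) {
  na <- length(a$values) / 3; nb <- length(b$values) / 3
  if (is.null(node_map)) {
    if (na != nb) stop("models differ in size; supply a node_map")
    node_map <- cbind(seq_len(na), seq_len(na))
  }
  node_map <- as.matrix(node_map)
  if (!nrow(node_map)) stop("empty node map")
  ia <- as.vector(t(cbind(3 * node_map[, 1] - 2, 3 * node_map[, 1] - 1, 3 * node_map[, 1])))
  ib <- as.vector(t(cbind(3 * node_map[, 2] - 2, 3 * node_map[, 2] - 1, 3 * node_map[, 2])))
  ma <- nonrigid_idx(a, n); mb <- nonrigid_idx(b, n)
  va <- a$vectors[ia, ma, drop = FALSE]
  vb <- b$vectors[ib, mb, drop = FALSE]
  va <- sweep(va, 2, sqrt(colSums(va^2)), "/")
  vb <- sweep(vb, 2, sqrt(colSums(vb^2)), "/")
  O <- abs(crossprod(va, vb))
  dimnames(O) <- list(paste0("a", seq_len(n)), paste0("b", seq_len(n)))
  O
}

#' Cross-correlation matrix from normal modes
#'
#' Normalized covariance of node displacements from the n-mode
#' pseudo-inverse of the Hessian:
#' `C[i, j] = cov(i, j) / sqrt(cov(i, i) cov(j, j))` with
#' `cov(i, j) = sum_m (v_m,i . v_m,j) / lambda_m` (3x3-block trace).
#'
#' @param m a ModeSet
#' @param n_modes number of lowest-frequency non-rigid modes (default 25)
#' @return symmetric node x node matrix with unit diagonal, values in
#'   `[-1, 1]`
#' @export
nma_correlation <- function(m, n_modes = 25) {
  idx <- nonrigid_idx(m, n_modes)
  n <- length(m$values) / 3
  cov <- matrix(0, n, n)
  for (c in idx) {
    V <- matrix(m$vectors[, c], ncol = 3, byrow = TRUE)
    cov <- cov + tcrossprod(V) / m$values[c]
  }
  v <- diag(cov)
  if (any(v <= 0)) stop("node(s) with zero variance: ",
                        paste(which(v <= 0), collapse = ", "))
  C <- cov / sqrt(outer(v, v))
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  C
}

#' Displacement arrows for one mode, scaled to a target RMSD
#'
#' Returns per-node displacements `+s v` such that the RMSD between the
#' structures elongated by `+s v` and `-s v` equals `target_rmsd`
#' (default 0.2 nm, i.e. 2 A).
#'
#' @param m a ModeSet
#' @param mode_index non-rigid mode number (1 = lowest frequency)
#' @param target_rmsd RMSD between the two elongations, nm
#' @return data.frame `dx`, `dy`, `dz` (nm per node); elongated coordinate
#'   sets as attributes `"plus"` and `"minus"` when the ModeSet carries
#'   coordinates.
#' @export
mode_displacement_vectors <- function(m, mode_index = 1, target_rmsd = 0.2) {
  idx <- nonrigid_idx(m)[mode_index]
  v <- m$vectors[, idx]
  v <- v / sqrt(sum(v^2))
  n <- length(v) / 3
  s <- target_rmsd * sqrt(n) / 2
  V <- matrix(s * v, ncol = 3, byrow = TRUE)
  out <- data.frame(dx = V[, 1], dy = V[, 2], dz = V[, 3])
  if (!is.null(m$coords)) {
    attr(out, "plus") <- m$coords + V
    attr(out, "minus") <- m$coords - V
  }
  out
}

#' Write modes in NMD-style plain text
#'
#' Lines: `coordinates` (flat nm values), then per retained non-rigid mode
#' `mode <index> <eigenvalue> <3N vector components>`.
#'
#' @param m a ModeSet carrying coordinates (built with `net` supplied)
#' @param path output file
#' @param n number of non-rigid modes to write (default the ModeSet's
#'   `n_modes`)
#' @export
write_nmd <- function(m, path, n = NULL) {
  if (is.null(m$coords)) stop("ModeSet carries no coordinates")
  if (is.null(n)) n <- m$n_modes
  idx <- nonrigid_idx(m, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("nmd", "anmpbsa", "rigid_modes", m$n_rigid), con)
  writeLines(paste("coordinates",
                   paste(sprintf("%.6f", as.vector(t(m$coords))), collapse = " ")), con)
  for (k in seq_along(idx)) {
    writeLines(paste("mode", k, sprintf("%.8g", m$values[idx[k]]),
                     paste(sprintf("%.6f", m$vectors[, idx[k]]), collapse = " ")), con)
  }
  invisible(path)
}
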