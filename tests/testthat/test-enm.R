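KCAL <- 418.4   # kcal mol-1 A-2 in kJ mol-1 nm-2

test_that("node building follows the two-nodes-per-residue rule", {
  # poly-glycine: backbone nodes only
  gly <- make_toy_structure(10, gly_at = 1:10, seed = 1)
  nodes <- build_nodes(gly)
  expect_equal(nrow(nodes), 10)
  expect_true(all(nodes$kind == "bb"))

  # single alanine: side-chain node exactly at CB (centre of mass of one atom)
  ala <- structure_new(atoms_df(
    list("A", 1, "ALA", "CA", "C", 0, 0, 0),
    list("A", 1, "ALA", "CB", "C", 0.15, 0, 0)))
  n_ala <- build_nodes(ala)
  expect_equal(nrow(n_ala), 2)
  expect_equal(unlist(n_ala[n_ala$kind == "sc", c("x", "y", "z")]),
               c(x = 0.15, y = 0, z = 0))

  # lysine: side-chain node at the NZ terminal atom, not the centre of mass
  lys <- structure_new(atoms_df(
    list("A", 1, "LYS", "CA", "C", 0, 0, 0),
    list("A", 1, "LYS", "CB", "C", 0.15, 0, 0),
    list("A", 1, "LYS", "CG", "C", 0.30, 0, 0),
    list("A", 1, "LYS", "CD", "C", 0.45, 0, 0),
    list("A", 1, "LYS", "CE", "C", 0.60, 0, 0),
    list("A", 1, "LYS", "NZ", "N", 0.75, 0, 0)))
  n_lys <- build_nodes(lys)
  expect_equal(n_lys$x[n_lys$kind == "sc"], 0.75)

  # missing terminal atom falls back to the centre of mass with a warning
  glu <- structure_new(atoms_df(
    list("A", 1, "GLU", "CA", "C", 0, 0, 0),
    list("A", 1, "GLU", "CB", "C", 0.2, 0, 0),
    list("A", 1, "GLU", "CG", "C", 0.4, 0, 0)))
  expect_warning(n_glu <- build_nodes(glu), "terminal atom")
  expect_equal(n_glu$x[n_glu$kind == "sc"], 0.3)
})

test_that("spring constants follow the precedence and distance shells", {
  two_ca <- function(d, ss = c("C", "C")) {
    nodes <- data.frame(chain = "A", resno = 1:2, resid = "GLY", kind = "bb",
                        x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE)
    build_springs(nodes, ss = data.frame(chain = "A", resno = 1:2, ss = ss))
  }
  expect_warning(net <- two_ca(0.39), NA)   # connected, no warning
  expect_equal(net$springs$k, 3 * KCAL)
  expect_equal(two_ca(0.60)$springs$k, 2 * KCAL)
  expect_equal(two_ca(1.00)$springs$k, 1 * KCAL)
  expect_equal(suppressWarnings(nrow(two_ca(1.25)$springs)), 0)
  # shell boundaries are inclusive on the upper edge
  expect_equal(two_ca(0.40)$springs$k, 3 * KCAL)
  expect_equal(two_ca(0.80)$springs$k, 2 * KCAL)
  expect_equal(two_ca(1.20)$springs$k, 1 * KCAL)

  # sequential helix pair -> 6; same for sheets; coil stays on the shell
  expect_equal(two_ca(0.38, ss = c("H", "H"))$springs$k, 6 * KCAL)
  expect_equal(two_ca(0.38, ss = c("E", "E"))$springs$k, 6 * KCAL)
  expect_equal(two_ca(0.38, ss = c("H", "E"))$springs$k, 3 * KCAL)

  # disulfide side-chain pair -> 10 even though the shell would give 3
  nodes <- data.frame(chain = "A", resno = 1:2, resid = "CYS", kind = "sc",
                      x = c(0, 0.30), y = 0, z = 0, stringsAsFactors = FALSE)
  ds <- data.frame(chain1 = "A", resno1 = 1, chain2 = "A", resno2 = 2)
  net <- build_springs(nodes, disulfides = ds)
  expect_equal(net$springs$k, 10 * KCAL)
  expect_equal(net$springs$rule, "bridge")

  # intra-residue tether -> 10 regardless of distance shell
  nodes <- data.frame(chain = "A", resno = 1, resid = "ALA",
                      kind = c("bb", "sc"), x = c(0, 0.15), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  net <- build_springs(nodes)
  expect_equal(net$springs$k, 10 * KCAL)
  expect_equal(net$springs$rule, "tether")
})

test_that("ss stiffening is restricted to one element unless all_pairs is chosen", {
  # two separate helices: the (i, i+1) pair across the coil gap stays shell
  s <- make_toy_structure(9, ss_pattern = "HHHHCHHHH", seed = 4)
  net <- build_enm(s)
  sp <- net$springs
  bb <- which(net$nodes$kind == "bb")
  res_of <- net$nodes$resno
  seq_bb <- sp$rule == "ss"
  linked <- cbind(res_of[sp$i[seq_bb]], res_of[sp$j[seq_bb]])
  expect_true(all(abs(linked[, 1] - linked[, 2]) == 1))
  expect_false(any(apply(linked, 1, function(r) 5 %in% r)))
  # all_pairs mode adds non-sequential intra-element pairs
  net2 <- build_enm(s, enm_params(ss_mode = "all_pairs"))
  expect_gt(sum(net2$springs$rule == "ss"), sum(seq_bb))
})

test_that("two-body and three-body Hessians match closed forms", {
  # one spring k: single nonzero eigenvalue exactly 2k along the bond
  k <- 700
  net <- manual_network(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                        data.frame(i = 1, j = 2, k = k))
  m <- eigenmodes(build_hessian(net), net = net)
  expect_equal(m$n_rigid, 5 + 0)  # 2-body: 5 zero modes (3 trans + 2 rot)
  expect_equal(m$values[6], 2 * k, tolerance = 1e-12)
  # mode is antiparallel displacement along the bond
  v <- matrix(m$vectors[, 6], ncol = 3, byrow = TRUE)
  expect_equal(abs(v[, 1]), rep(sqrt(0.5), 2), tolerance = 1e-9)
  expect_equal(v[1, 1] * v[2, 1], -0.5, tolerance = 1e-9)

  # collinear 3-node chain: axial spectrum k and 3k (free-free chain)
  net3 <- manual_network(rbind(c(0, 0, 0), c(0.4, 0, 0), c(0.8, 0, 0)),
                         data.frame(i = c(1, 2), j = c(2, 3), k = k))
  H <- build_hessian(net3)
  ax <- seq(1, 9, by = 3)
  lam <- sort(eigen(H[ax, ax], symmetric = TRUE)$values)
  expect_equal(lam, c(0, k, 3 * k), tolerance = 1e-9)
})

test_that("the Hessian annihilates rigid-body motions and matches finite differences", {
  xyz <- irregular_cloud(14, seed = 11)
  net <- cloud_network(xyz)
  H <- build_hessian(net)
  expect_lt(max(abs(H - t(H))), 1e-9)
  n <- nrow(xyz)
  for (ax in 1:3) {
    tvec <- rep(0, 3 * n); tvec[seq(ax, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(H %*% tvec)), 1e-8 * max(abs(H)))
  }
  # infinitesimal rotations about the centroid are annihilated too
  cen <- colMeans(xyz)
  for (ax in 1:3) {
    w <- c(0, 0, 0); w[ax] <- 1
    rvec <- as.numeric(t(t(apply(sweep(xyz, 2, cen), 1, function(r)
      c(w[2] * r[3] - w[3] * r[2], w[3] * r[1] - w[1] * r[3],
        w[1] * r[2] - w[2] * r[1])))))
    expect_lt(max(abs(H %*% rvec)) / max(abs(H)), 1e-8)
  }
  # numerical second derivatives of the spring energy reproduce H
  skip_if_not_installed("pracma")
  x0 <- as.numeric(t(xyz))
  Hfd <- pracma::hessian(function(x) spring_energy(net, x), x0)
  expect_lt(max(abs(Hfd - H)) / max(abs(H)), 1e-6)
})

test_that("rigid-mode count diagnoses connectivity", {
  xyz <- irregular_cloud(20, seed = 3)
  net <- cloud_network(xyz)
  m <- eigenmodes(build_hessian(net), net = net)
  expect_equal(m$n_rigid, 6)
  expect_true(all(m$values[-(1:6)] > 0))
  # far-separated duplicate: two rigid bodies -> error naming components
  far <- rbind(xyz, sweep(xyz, 2, c(100, 0, 0), "+"))
  pr <- t(utils::combn(nrow(xyz), 2))
  springs <- data.frame(i = c(pr[, 1], pr[, 1] + 20),
                        j = c(pr[, 2], pr[, 2] + 20), k = 300)
  net2 <- manual_network(far, springs)
  net2$component <- rep(1:2, each = 20)
  expect_error(eigenmodes(build_hessian(net2), net = net2), "rigid bodies")
})

test_that("spectrum and fluctuations are invariant under rigid transforms", {
  s <- make_toy_structure(15, ss_pattern = strrep("H", 15), seed = 9)
  sR <- transform_structure(s, random_rotation(2), shift = c(0.5, -1, 2))
  m1 <- eigenmodes(build_hessian(build_enm(s)))
  m2 <- eigenmodes(build_hessian(build_enm(sR)))
  nr <- 7:30
  expect_equal(m1$values[nr], m2$values[nr], tolerance = 1e-8)
  f1 <- predicted_fluctuations(m1)$msf
  f2 <- predicted_fluctuations(m2)$msf
  expect_equal(f1, f2, tolerance = 1e-7)
})

test_that("uniform force-constant scaling scales eigenvalues and nothing else", {
  xyz <- irregular_cloud(10, seed = 8)
  net <- cloud_network(xyz)
  net2 <- net; net2$springs$k <- 3 * net$springs$k
  m1 <- eigenmodes(build_hessian(net), net = net)
  m2 <- eigenmodes(build_hessian(net2), net = net2)
  nr <- nonrigid <- 7:30
  expect_equal(3 * m1$values[nr], m2$values[nr], tolerance = 1e-9)
  expect_equal(nma_correlation(m1, 10), nma_correlation(m2, 10), tolerance = 1e-9)
  O <- mode_overlap(m1, m2, n = 8)
  expect_equal(diag(O), rep(1, 8), tolerance = 1e-7)
})

test_that("fluctuations match the pseudo-inverse computed by direct inversion", {
  xyz <- irregular_cloud(15, seed = 21)
  net <- cloud_network(xyz)
  H <- build_hessian(net)
  m <- eigenmodes(H, net = net)
  msf <- predicted_fluctuations(m)$msf
  # independent oracle: Moore-Penrose inverse by SVD (MASS)
  skip_if_not_installed("MASS")
  P <- MASS::ginv(H)
  msf_oracle <- vapply(seq_len(nrow(xyz)), function(i)
    sum(diag(P[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)])), numeric(1))
  expect_equal(msf, msf_oracle, tolerance = 1e-6)
  # symmetric dumbbell: equal fluctuation on both nodes
  nd <- manual_network(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                       data.frame(i = 1, j = 2, k = 400))
  fd <- predicted_fluctuations(eigenmodes(build_hessian(nd), net = nd))
  expect_equal(fd$msf[1], fd$msf[2], tolerance = 1e-12)
})

test_that("mode overlap is the absolute normalized dot product", {
  xyz <- irregular_cloud(12, seed = 13)
  net <- cloud_network(xyz)
  m <- eigenmodes(build_hessian(net), net = net)
  O <- mode_overlap(m, m, n = 8)
  expect_equal(unname(O), diag(8), tolerance = 1e-9)
  expect_true(all(O >= 0 & O <= 1 + 1e-12))
  # rotated twin: after rotating eigenvectors back, identity for
  # non-degenerate modes
  R <- random_rotation(7)
  xyzR <- xyz %*% t(R)
  netR <- cloud_network(xyzR)
  mR <- eigenmodes(build_hessian(netR), net = netR)
  back <- mR
  for (c in seq_len(ncol(back$vectors))) {
    V <- matrix(back$vectors[, c], ncol = 3, byrow = TRUE) %*% R
    back$vectors[, c] <- as.numeric(t(V))
  }
  lam <- m$values[7:14]
  gaps <- pmin(abs(c(Inf, diff(lam))), abs(c(diff(lam), Inf))) / lam
  O2 <- mode_overlap(m, back, n = 8)
  nondeg <- gaps > 1e-4
  expect_true(all(abs(diag(O2)[nondeg] - 1) < 1e-6))
  expect_error(mode_overlap(m, m, node_map = matrix(0, 0, 2)), "empty")
})

test_that("two coupled nodes are perfectly anti-correlated", {
  nd <- manual_network(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                       data.frame(i = 1, j = 2, k = 400))
  m <- eigenmodes(build_hessian(nd), net = nd)
  C <- nma_correlation(m, n_modes = 1)
  expect_equal(C[1, 2], -1, tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 2))
})

test_that("mode displacement arrows realize the requested RMSD exactly", {
  s <- make_toy_structure(12, seed = 5)
  net <- build_enm(s)
  m <- eigenmodes(build_hessian(net), net = net)
  arr <- mode_displacement_vectors(m, mode_index = 1, target_rmsd = 0.2)
  plus <- attr(arr, "plus"); minus <- attr(arr, "minus")
  rmsd <- sqrt(mean(rowSums((plus - minus)^2)))
  expect_equal(rmsd, 0.2, tolerance = 1e-10)
  # linear in the target
  arr2 <- mode_displacement_vectors(m, mode_index = 1, target_rmsd = 0.4)
  expect_equal(as.matrix(arr2), 2 * as.matrix(arr), tolerance = 1e-10)
  # 2-node toy: arrows antiparallel along the bond
  nd <- manual_network(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                       data.frame(i = 1, j = 2, k = 400))
  a2 <- mode_displacement_vectors(eigenmodes(build_hessian(nd), net = nd), 1)
  expect_equal(a2$dx[1], -a2$dx[2], tolerance = 1e-9)
  expect_equal(a2$dy, c(0, 0), tolerance = 1e-9)
})

test_that("NMD export round-trips eigenvalues and coordinates", {
  s <- make_toy_structure(8, seed = 6)
  net <- build_enm(s)
  m <- eigenmodes(build_hessian(net), net = net)
  f <- tempfile(fileext = ".nmd")
  write_nmd(m, f, n = 4)
  lines <- readLines(f)
  expect_match(lines[1], "rigid_modes 6")
  expect_equal(sum(grepl("^mode ", lines)), 4)
  lam1 <- as.numeric(strsplit(lines[grepl("^mode 1 ", lines)], " ")[[1]][3])
  expect_equal(lam1, m$values[7], tolerance = 1e-6)
})
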