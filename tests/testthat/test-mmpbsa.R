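# 4-atom fixture: two 2-atom partners with simple charges/LJ parameters
four_atom_system <- function() {
  at <- atoms_df(list("A", 1, "ALA", "CA", "C", 0, 0, 0),
                 list("A", 1, "ALA", "CB", "C", 0.3, 0, 0),
                 list("B", 1, "ALA", "CA", "C", 1.0, 0, 0),
                 list("B", 1, "ALA", "CB", "C", 1.0, 0.3, 0))
  s <- structure_new(at)
  ff <- ff_params(data.frame(chain = c("A", "A", "B", "B"), resno = 1,
                             elety = c("CA", "CB", "CA", "CB"),
                             charge = c(0.5, -0.2, -0.3, 0.4),
                             sigma = c(0.30, 0.32, 0.34, 0.30),
                             epsilon = c(0.4, 0.5, 0.6, 0.4)))
  list(s = s, ff = ff)
}

test_that("Coulomb sum reproduces the closed-form two-charge energy", {
  at <- atoms_df(list("A", 1, "ALA", "CA", "C", 0, 0, 0),
                 list("B", 1, "ALA", "CA", "C", 1.0, 0, 0))
  s <- structure_new(at)
  ff <- ff_params(data.frame(chain = c("A", "B"), resno = 1, elety = "CA",
                             charge = 1, sigma = 0.3, epsilon = 0.1))
  expect_equal(coulomb_energy(s, ff), 138.935458, tolerance = 1e-6)
  # zero-charge system
  ff0 <- ff_params(data.frame(chain = c("A", "B"), resno = 1, elety = "CA",
                              charge = 0, sigma = 0.3, epsilon = 0.1))
  expect_equal(coulomb_energy(s, ff0), 0)
  # dielectric scaling
  expect_equal(coulomb_energy(s, ff, dielectric = 2), 138.935458 / 2,
               tolerance = 1e-6)
  # coincident charges error
  s2 <- s; s2$atoms$x[2] <- 0
  expect_error(coulomb_energy(s2, ff), "coincident")
})

test_that("Lennard-Jones sum has its root at sigma and minimum at -epsilon", {
  mk <- function(r) {
    at <- atoms_df(list("A", 1, "ALA", "CA", "C", 0, 0, 0),
                   list("B", 1, "ALA", "CA", "C", r, 0, 0))
    structure_new(at)
  }
  ff <- ff_params(data.frame(chain = c("A", "B"), resno = 1, elety = "CA",
                             charge = 0, sigma = 0.34, epsilon = 0.8))
  expect_equal(lj_energy(mk(0.34), ff), 0, tolerance = 1e-12)
  expect_equal(lj_energy(mk(2^(1 / 6) * 0.34), ff), -0.8, tolerance = 1e-10)
  # missing parameters are reported
  bad <- mk(0.5); bad$atoms$elety[2] <- "ZZ"
  expect_error(lj_energy(bad, ff), "no force-field parameters")
})

test_that("gas-phase energies are bilinear: complex minus partners equals cross sum", {
  sys <- four_atom_system()
  idxA <- 1:2; idxB <- 3:4
  for (fun in list(coulomb_energy, lj_energy)) {
    full <- fun(sys$s, sys$ff)
    ea <- fun(sys$s, sys$ff, idxA = idxA)
    eb <- fun(sys$s, sys$ff, idxA = idxB)
    cross <- fun(sys$s, sys$ff, idxA = idxA, idxB = idxB, cross = TRUE)
    expect_equal(full - ea - eb, cross, tolerance = 1e-10)
  }
  # cross sums equal an explicit double loop
  xyz <- coords(sys$s)
  p <- sys$ff$params
  e_ref <- 0
  for (i in idxA) for (j in idxB) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e_ref <- e_ref + 138.935458 * p$charge[i] * p$charge[j] / r
  }
  expect_equal(coulomb_energy(sys$s, sys$ff, idxA, idxB, cross = TRUE), e_ref,
               tolerance = 1e-10)
})

test_that("bonded internal energy matches hand-computed terms", {
  at <- atoms_df(list("A", 1, "ALA", "N", "N", 0, 0, 0),
                 list("A", 1, "ALA", "CA", "C", 0.15, 0, 0),
                 list("A", 1, "ALA", "C", "C", 0.15, 0.14, 0),
                 list("A", 1, "ALA", "O", "O", 0.15, 0.14, 0.12))
  s <- structure_new(at)
  bonded <- list(
    bonds = data.frame(i = 1, j = 2, b0 = 0.14, kb = 1e4),
    angles = data.frame(i = 1, j = 2, k = 3, th0 = 100, ka = 500),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, phi0 = 0, kd = 5, mult = 2))
  ff <- ff_params(data.frame(chain = "A", resno = 1,
                             elety = c("N", "CA", "C", "O"), charge = 0,
                             sigma = 0.3, epsilon = 0.1), bonded = bonded)
  e_bond <- 1e4 / 2 * (0.15 - 0.14)^2
  e_angle <- 500 / 2 * ((90 - 100) * pi / 180)^2
  phi <- 90 * pi / 180   # planar zig-zag then out-of-plane O
  e_dih <- 5 * (1 + cos(2 * phi - 0))
  expect_equal(internal_energy(s, ff), e_bond + e_angle + e_dih,
               tolerance = 1e-9)
  ff_nb <- ff_params(ff$params)
  expect_error(internal_energy(s, ff_nb), "bonded")
})

test_that("apolar model is the printed linear SASA law", {
  expect_equal(apolar_solvation(0), 3.85112)
  expect_equal(apolar_solvation(100), 6.12112)
  g <- apolar_model()$gamma
  expect_equal(apolar_solvation(700) - apolar_solvation(350), g * 350,
               tolerance = 1e-12)
})

test_that("snapshot free energy sums the five components with TS = 0", {
  expect_equal(snapshot_free_energy(c(H_int = 0, H_vdW = 0, H_elect = 0,
                                      G_polar = 0, G_apolar = 0)), 0)
  comp <- c(H_int = 94.4, H_vdW = -202.2, H_elect = -434.2,
            G_polar = 461.6, G_apolar = -36.4)
  expect_equal(snapshot_free_energy(comp), -116.8, tolerance = 1e-10)
  expect_equal(snapshot_free_energy(sample(comp)), -116.8, tolerance = 1e-10)
  expect_error(snapshot_free_energy(comp[-2]), "missing")
})

test_that("binding energy applies fractional stoichiometric coefficients", {
  gC <- c(H_vdW = -10, H_elect = -20)
  gP <- c(H_vdW = -4, H_elect = -6)
  gL <- c(H_vdW = -2, H_elect = -8)
  expect_equal(binding_energy(gC, gP, gL),
               c(H_vdW = -4, H_elect = -6))
  # receptor supplied as half a dimer
  expect_equal(binding_energy(gC, gP, 2 * gL, coef = c(1, 0.5)),
               binding_energy(gC, gP, gL))
  expect_equal(unname(binding_energy(gC, (gC - gL), gL)), c(0, 0))
  expect_error(binding_energy(gC, gP[1], gL), "differ")
})

test_that("ledger identities hold for any component input", {
  set.seed(17)
  for (rep in 1:5) {
    m <- setNames(rnorm(5, 0, 300), c("H_int", "H_vdW", "H_elect",
                                      "G_polar", "G_apolar"))
    sem <- abs(rnorm(5, 0, 5))
    led <- ledger_from_components(m, setNames(sem, names(m)), mode = "SETA")
    df <- as.data.frame(led)
    g <- function(cc) df$mean[df$component == cc]
    expect_equal(g("G_solv"), g("G_polar") + g("G_apolar"), tolerance = 1e-12)
    expect_equal(g("G_total"),
                 g("H_int") + g("H_vdW") + g("H_elect") + g("G_polar") +
                   g("G_apolar"), tolerance = 1e-12)
    s_of <- function(cc) df$sem[df$component == cc]
    expect_equal(s_of("G_total"), sqrt(sum(sem^2)), tolerance = 1e-12)
  }
})

test_that("total electrostatics adds the polar solvation to the gas term", {
  led <- ledger_from_components(c(H_elect = -668.7, G_polar = 709.3))
  expect_equal(total_electrostatics(led), 40.6, tolerance = 1e-10)
  led2 <- ledger_from_components(c(H_elect = -183.0, G_polar = 143.3),
                                 mode = "SETA")
  expect_equal(total_electrostatics(led2), -39.7, tolerance = 1e-10)
  led3 <- ledger_from_components(c(H_elect = -12.5))
  expect_equal(total_electrostatics(led3), -12.5)
})

test_that("aggregate_stats is the mean and sigma/sqrt(n)", {
  expect_equal(aggregate_stats(c(5, 5, 5))[["sem"]], 0)
  out <- aggregate_stats(c(1, 2, 3))
  expect_equal(out[["mean"]], 2)
  expect_equal(out[["sem"]], sqrt(1 / 3))
  # SEM halves when n quadruples for i.i.d. noise
  set.seed(3)
  x <- rnorm(4000)
  s1 <- aggregate_stats(x[1:1000])[["sem"]]
  s2 <- aggregate_stats(x)[["sem"]]
  expect_equal(s2 / s1, 0.5, tolerance = 0.1)
})

test_that("SITA ledger equals hand-computed cross terms and zero internal energy", {
  sys <- four_atom_system()
  base <- as.numeric(t(coords(sys$s)))
  shift <- base; shift[7] <- shift[7] + 0.1   # move partner B in frame 2
  t <- trajectory(sys$s, rbind(base, shift))
  cfg <- sasa_config(n_points = 240)
  polar <- data.frame(snapshot = rep(1:2, 3),
                      species = rep(c("complex", "A", "B"), each = 2),
                      G_polar = c(100, 110, 30, 32, 40, 42))
  led <- sita_ledger(t, list(A = 1:2, B = 3:4), sys$ff, polar_table = polar,
                     sasa_cfg = cfg)
  snaps <- attr(led, "snapshots")
  expect_equal(snaps$H_int, c(0, 0))
  # hand-computed cross sums per frame
  for (f in 1:2) {
    xyz <- matrix(t$xyz[f, ], ncol = 3, byrow = TRUE)
    expect_equal(snaps$H_elect[f],
                 coulomb_energy(sys$s, sys$ff, 1:2, 3:4, cross = TRUE, xyz = xyz),
                 tolerance = 1e-10)
    expect_equal(snaps$H_vdW[f],
                 lj_energy(sys$s, sys$ff, 1:2, 3:4, cross = TRUE, xyz = xyz),
                 tolerance = 1e-10)
  }
  expect_equal(snaps$G_polar, c(30, 36))
  # apolar difference loses one intercept b: complex - A - B
  b <- apolar_model()$b
  g <- apolar_model()$gamma
  for (f in 1:2) {
    xyz <- matrix(t$xyz[f, ], ncol = 3, byrow = TRUE)
    sC <- sasa(sys$s, cfg, xyz = xyz)$total
    sA <- sasa(sys$s, cfg, xyz = xyz, atoms = 1:2)$total
    sB <- sasa(sys$s, cfg, xyz = xyz, atoms = 3:4)$total
    expect_equal(snaps$G_apolar[f], g * (sC - sA - sB) - b, tolerance = 1e-9)
  }
  # snapshot-count mismatch in the polar table errors
  expect_error(sita_ledger(t, list(A = 1:2, B = 3:4), sys$ff,
                           polar_table = polar[-1, ], sasa_cfg = cfg),
               "snapshots")
})

test_that("SITA is invariant to which partner is called the ligand", {
  sys <- four_atom_system()
  base <- as.numeric(t(coords(sys$s)))
  t <- trajectory(sys$s, rbind(base, base + 0.001))
  cfg <- sasa_config(n_points = 240)
  l1 <- sita_ledger(t, list(A = 1:2, B = 3:4), sys$ff, sasa_cfg = cfg)
  l2 <- sita_ledger(t, list(B = 3:4, A = 1:2), sys$ff, sasa_cfg = cfg)
  expect_equal(as.data.frame(l1), as.data.frame(l2), tolerance = 1e-12)
})

test_that("SETA with identical static species and unit coefficients gives zero", {
  tab <- make_energy_table(c(H_vdW = -50, H_elect = -120, G_polar = 90,
                             G_apolar = -7, H_int = 300), noise_sigma = 0, n = 5)
  st <- stoich_step(1); st$coef <- c(protein = 1, ligand = 0)
  led <- seta_ledger(tab, tab, tab, stoich = st)
  df <- as.data.frame(led)
  expect_equal(df$mean, rep(0, 7), tolerance = 1e-12)
})

test_that("SETA recovers planted differences within 2 SEM and books quadrature errors", {
  muC <- c(H_int = 500, H_vdW = -800, H_elect = -1500, G_polar = 1300, G_apolar = -80)
  muP <- c(H_int = 300, H_vdW = -500, H_elect = -900, G_polar = 700, G_apolar = -30)
  muL <- c(H_int = 211.2, H_vdW = -195.6, H_elect = -331.6, G_polar = 277.0,
           G_apolar = -27.2)
  tabC <- make_energy_table(muC, noise_sigma = 60, n = 1001, seed = 11)
  tabP <- make_energy_table(muP, noise_sigma = 60, n = 1001, seed = 12)
  tabL <- make_energy_table(muL, noise_sigma = 60, n = 1001, seed = 13)
  led <- seta_ledger(tabC, tabP, tabL, stoich = stoich_step(1))
  df <- as.data.frame(led)
  truth <- muC - muP - 0.5 * muL
  for (cc in names(truth)) {
    row <- df[df$component == cc, ]
    expect_lt(abs(row$mean - truth[[cc]]), 2 * row$sem + 1e-9)
  }
  # SEM combines in quadrature with the coefficients
  semC <- sd(tabC$H_vdW) / sqrt(1001)
  semP <- sd(tabP$H_vdW) / sqrt(1001)
  semL <- sd(tabL$H_vdW) / sqrt(1001)
  expect_equal(df$sem[df$component == "H_vdW"],
               sqrt(semC^2 + semP^2 + 0.25 * semL^2), tolerance = 1e-10)
  # Table-2-style step: printed column values sum to the printed total
  led2 <- ledger_from_components(c(H_int = -44.3, H_vdW = -21.4,
                                   H_elect = -183.0, G_polar = 143.3,
                                   G_apolar = -13.6), mode = "SETA")
  expect_equal(as.data.frame(led2)$mean[6:7], c(129.7, -119.0), tolerance = 1e-10)
})

test_that("energy tables round-trip through their text format", {
  tab <- make_energy_table(c(H_vdW = -5), noise_sigma = 1, n = 4, seed = 2)
  f <- tempfile()
  write_energy_table(tab, f)
  back <- read_energy_table(f)
  expect_equal(back$H_vdW, tab$H_vdW, tolerance = 1e-9)
  expect_equal(back$species, tab$species)
})
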