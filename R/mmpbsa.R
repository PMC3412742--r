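# MM/PBSA free-energy bookkeeping.
#
# Per snapshot:  H_gas  = H_int + H_vdW + H_elect
#                G_solv = G_polar + G_apolar
#                G      = H_gas + G_solv - TS,  with TS neglected throughout
# Binding:       dG = G(complex) - sum_partners coef * G(partner)
# The Poisson-Boltzmann polar term is always an imported per-snapshot
# column; gas-phase Coulomb/Lennard-Jones sums are computed here, in full
# (no cutoff, no periodicity).

.COULOMB_F <- 138.935458   # kJ mol-1 nm e-2

.ENERGY_COMPONENTS <- c("H_int", "H_vdW", "H_elect", "G_polar", "G_apolar")

#' Linear-SASA apolar solvation model
#'
#' `G_apolar = gamma * SASA + b` with the PARSE-style defaults
#' gamma = 0.0227 kJ mol-1 A-2 and b = 3.85112 kJ mol-1.
#'
#' @param gamma surface tension coefficient, kJ mol-1 A-2
#' @param b intercept, kJ mol-1
#' @export
apolar_model <- function(gamma = 0.0227, b = 3.85112) {
  stopifnot(is.finite(gamma), is.finite(b))
  m <- list(gamma = gamma, b = b)
  class(m) <- "ApolarModel"
  m
}

#' Apolar solvation free energy from a SASA value
#' @param sasa solvent-accessible surface area, A^2 (non-negative)
#' @param model an [apolar_model()]
#' @return kJ/mol
#' @export
apolar_solvation <- function(sasa, model = apolar_model()) {
  stopifnot(all(sasa >= 0))
  model$gamma * sasa + model$b
}

#' Metadata describing the provenance of imported polar-solvation columns
#'
#' Records, verbatim alongside every import, the Poisson-Boltzmann settings
#' the polar column was computed with.  Defaults mirror a typical APBS
#' protein setup: solute dielectric 2, solvent dielectric 78.54, 225 grid
#' points per direction at 0.5 A spacing, van der Waals dielectric
#' boundary, no counterions.
#' @param solute_dielectric,solvent_dielectric,grid_points,grid_spacing,
#'   boundary,counterions recorded settings
#' @export
polar_input_spec <- function(solute_dielectric = 2, solvent_dielectric = 78.54,
                             grid_points = 225, grid_spacing = 0.5,
                             boundary = "van der Waals", counterions = "none") {
  spec <- list(solute_dielectric = solute_dielectric,
               solvent_dielectric = solvent_dielectric,
               grid_points = grid_points, grid_spacing = grid_spacing,
               boundary = boundary, counterions = counterions)
  class(spec) <- "PolarInputSpec"
  spec
}

#' Per-atom force-field parameters
#'
#' @param params data.frame keyed by (`chain`, `resno`, `elety`) with
#'   columns `charge` (e), `sigma` (nm), `epsilon` (kJ/mol)
#' @param comb_rule Lennard-Jones combination rule: `"geometric"`
#'   (Gromos-style, default) or `"lorentz_berthelot"`
#' @param bonded optional list of bonded-term tables for the internal
#'   energy: `bonds` (`i`, `j`, `b0` nm, `kb` kJ mol-1 nm-2), `angles`
#'   (`i`, `j`, `k`, `th0` deg, `ka` kJ mol-1 rad-2), `dihedrals`
#'   (`i`, `j`, `k`, `l`, `phi0` deg, `kd` kJ/mol, `mult`)
#' @export
ff_params <- function(params, comb_rule = c("geometric", "lorentz_berthelot"),
                      bonded = NULL) {
  stopifnot(all(c("chain", "resno", "elety", "charge", "sigma", "epsilon") %in%
                  names(params)))
  ff <- list(params = params, comb_rule = match.arg(comb_rule), bonded = bonded)
  class(ff) <- "FFParams"
  ff
}

#' Read per-atom charges and Lennard-Jones parameters from a table file
#' @param path delimited file with header columns `chain`, `resno`,
#'   `elety`, `charge`, `sigma`, `epsilon`
#' @param ... passed to [ff_params()]
#' @export
read_ff_table <- function(path, ...) {
  ff_params(utils::read.table(path, header = TRUE, stringsAsFactors = FALSE), ...)
}

# match structure atoms (subset idx) to ff rows; error listing misses
.ff_rows <- function(s, ff, idx) {
  key <- paste(s$atoms$chain[idx], s$atoms$resno[idx], s$atoms$elety[idx])
  m <- match(key, paste(ff$params$chain, ff$params$resno, ff$params$elety))
  if (any(is.na(m)))
    stop("no force-field parameters for atom(s): ",
         paste(utils::head(key[is.na(m)], 5), collapse = "; "))
  ff$params[m, , drop = FALSE]
}

#' Gas-phase Coulomb energy (full pairwise sum)
#'
#' `E = f sum_{i<j} q_i q_j / r_ij` with `f = 138.935458` kJ mol-1 nm e-2
#' and relative dielectric `dielectric` (vacuum by default -- the reduced
#' solute dielectric belongs to the Poisson-Boltzmann stage, not here).
#' With `cross = TRUE`, only pairs with one atom in `idxA` and one in
#' `idxB` are summed (the interaction energy used by single-trajectory
#' ledgers).
#'
#' @param s a Structure
#' @param ff an [ff_params()] object
#' @param idxA,idxB atom index sets (default: all atoms as one set)
#' @param cross sum only A x B pairs?
#' @param dielectric relative dielectric constant (default 1)
#' @param xyz optional coordinate override (n_atoms x 3, nm)
#' @return kJ/mol
#' @export
coulomb_energy <- function(s, ff, idxA = NULL, idxB = NULL, cross = FALSE,
                           dielectric = 1, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  if (is.null(idxA)) idxA <- seq_len(nrow(s$atoms))
  qA <- .ff_rows(s, ff, idxA)$charge
  if (cross) {
    stopifnot(!is.null(idxB))
    qB <- .ff_rows(s, ff, idxB)$charge
    d <- .pair_dists(xyz[idxA, , drop = FALSE], xyz[idxB, , drop = FALSE])
    if (any(d < 1e-9)) stop("coincident charged atoms")
    .COULOMB_F / dielectric * sum(outer(qA, qB) / d)
  } else {
    d <- as.matrix(stats::dist(xyz[idxA, , drop = FALSE]))
    ut <- upper.tri(d)
    if (any(d[ut] < 1e-9)) stop("coincident charged atoms")
    .COULOMB_F / dielectric * sum((outer(qA, qA) / ifelse(d > 0, d, Inf))[ut])
  }
}

.pair_dists <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (c in 1:3) out <- out + outer(a[, c], b[, c], "-")^2
  sqrt(out)
}

#' Gas-phase Lennard-Jones energy (full pairwise 12-6 sum)
#'
#' `E = sum 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)` with the combination
#' rule recorded in the force-field object; no cutoff, no periodicity.
#' @inheritParams coulomb_energy
#' @export
lj_energy <- function(s, ff, idxA = NULL, idxB = NULL, cross = FALSE,
                      xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  if (is.null(idxA)) idxA <- seq_len(nrow(s$atoms))
  pA <- .ff_rows(s, ff, idxA)
  combine <- function(sA, sB, eA, eB) {
    if (ff$comb_rule == "geometric")
      list(sig = sqrt(outer(sA, sB)), eps = sqrt(outer(eA, eB)))
    else
      list(sig = outer(sA, sB, `+`) / 2, eps = sqrt(outer(eA, eB)))
  }
  lj <- function(sig, eps, d) {
    sr6 <- (sig / d)^6
    4 * eps * (sr6^2 - sr6)
  }
  if (cross) {
    stopifnot(!is.null(idxB))
    pB <- .ff_rows(s, ff, idxB)
    cc <- combine(pA$sigma, pB$sigma, pA$epsilon, pB$epsilon)
    d <- .pair_dists(xyz[idxA, , drop = FALSE], xyz[idxB, , drop = FALSE])
    sum(lj(cc$sig, cc$eps, d))
  } else {
    cc <- combine(pA$sigma, pA$sigma, pA$epsilon, pA$epsilon)
    d <- as.matrix(stats::dist(xyz[idxA, , drop = FALSE]))
    ut <- upper.tri(d)
    sum(lj(cc$sig[ut], cc$eps[ut], d[ut]))
  }
}

# bonded internal energy: harmonic bonds/angles + periodic dihedrals
.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Bonded internal energy H_int = H_bond + H_angle + H_dihedral
#'
#' Harmonic bonds `kb/2 (b - b0)^2`, harmonic angles `ka/2 (th - th0)^2`
#' (radians), periodic dihedrals `kd (1 + cos(mult phi - phi0))`.  Requires
#' the bonded tables in the force-field object.
#'
#' @inheritParams coulomb_energy
#' @export
internal_energy <- function(s, ff, xyz = NULL) {
  if (is.null(ff$bonded))
    stop("no bonded parameters supplied; H_int cannot be computed")
  if (is.null(xyz)) xyz <- coords(s)
  e <- 0
  b <- ff$bonded$bonds
  if (!is.null(b) && nrow(b)) {
    d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
    e <- e + sum(b$kb / 2 * (d - b$b0)^2)
  }
  a <- ff$bonded$angles
  if (!is.null(a) && nrow(a)) {
    for (r in seq_len(nrow(a))) {
      v1 <- xyz[a$i[r], ] - xyz[a$j[r], ]; v2 <- xyz[a$k[r], ] - xyz[a$j[r], ]
      th <- acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
      e <- e + a$ka[r] / 2 * (th - a$th0[r] * pi / 180)^2
    }
  }
  dh <- ff$bonded$dihedrals
  if (!is.null(dh) && nrow(dh)) {
    for (r in seq_len(nrow(dh))) {
      phi <- .dihedral_angle(xyz[dh$i[r], ], xyz[dh$j[r], ], xyz[dh$k[r], ],
                             xyz[dh$l[r], ])
      e <- e + dh$kd[r] * (1 + cos(dh$mult[r] * phi - dh$phi0[r] * pi / 180))
    }
  }
  e
}

#' Free energy of one snapshot from its components
#'
#' `G = H_int + H_vdW + H_elect + G_polar + G_apolar`; the entropy term
#' is identically zero (neglected).
#'
#' @param components named numeric vector (or 1-row data.frame) carrying
#'   all of `H_int`, `H_vdW`, `H_elect`, `G_polar`, `G_apolar` in kJ/mol
#' @return kJ/mol
#' @export
snapshot_free_energy <- function(components) {
  components <- unlist(components)
  miss <- setdiff(.ENERGY_COMPONENTS, names(components))
  if (length(miss)) stop("missing energy component(s): ",
                         paste(miss, collapse = ", "))
  vals <- components[.ENERGY_COMPONENTS]
  if (any(!is.finite(vals))) stop("non-finite energy component")
  sum(vals)
}

#' Mean and standard error over snapshots
#' @param series numeric vector (n >= 2)
#' @return named vector `mean`, `sem` (sd / sqrt(n))
#' @export
aggregate_stats <- function(series) {
  n <- length(series)
  stopifnot(n >= 2)
  c(mean = mean(series), sem = stats::sd(series) / sqrt(n))
}

#' Componentwise binding energy, Eq.-4 style
#'
#' `dG = G(complex) - coef_protein * G(protein) - coef_ligand * G(ligand)`,
#' applied componentwise.  Fractional coefficients implement reactions
#' whose reference species is an oligomer, e.g. a receptor supplied as
#' half a dimer.
#'
#' @param gC,gP,gL named component vectors (kJ/mol) for complex, protein
#'   and ligand; any common set of names is accepted
#' @param coef length-2 numeric `c(protein, ligand)` stoichiometric
#'   coefficients (default 1, 1)
#' @return named vector of component differences
#' @export
binding_energy <- function(gC, gP, gL, coef = c(1, 1)) {
  gC <- unlist(gC); gP <- unlist(gP); gL <- unlist(gL)
  comps <- names(gC)
  if (!setequal(comps, names(gP)) || !setequal(comps, names(gL)))
    stop("component names differ between species")
  gC[comps] - coef[1] * gP[comps] - coef[2] * gL[comps]
}

#' Total electrostatic interaction per ledger step
#'
#' `dH_elect + dG_polar`: positive values mean the desolvation penalty
#' outweighs the direct electrostatic attraction.
#'
#' @param ledger a `FreeEnergyLedger` (or any data.frame with `component`
#'   and `mean` columns containing `H_elect` and `G_polar` rows)
#' @return kJ/mol
#' @export
total_electrostatics <- function(ledger) {
  df <- as.data.frame(ledger)
  he <- df$mean[df$component == "H_elect"]
  gp <- df$mean[df$component == "G_polar"]
  if (!length(he)) stop("ledger has no H_elect row")
  if (!length(gp)) return(he)
  he + gp
}

#' Reaction stoichiometry for the sequential receptor-binding steps
#'
#' Step n forms the 3:n ligand-receptor complex from the 3:(n-1) species
#' plus half a receptor dimer (the dimer being the unbound reference
#' state), so the protein/ligand coefficients are 1 and 1/2.
#'
#' @param id step 1, 2 or 3
#' @return object of class `StoichStep`: `id`, species roles and
#'   `coef = c(protein, ligand)`
#' @export
stoich_step <- function(id) {
  stopifnot(id %in% 1:3)
  species <- switch(id,
    `1` = list(complex = "LT-(TNFR1)1", protein = "LT",          ligand = "(TNFR1)2"),
    `2` = list(complex = "LT-(TNFR1)2", protein = "LT-(TNFR1)1", ligand = "(TNFR1)2"),
    `3` = list(complex = "LT-(TNFR1)3", protein = "LT-(TNFR1)2", ligand = "(TNFR1)2"))
  st <- c(species, list(id = id, coef = c(protein = 1, ligand = 0.5)))
  class(st) <- "StoichStep"
  st
}

# assemble a FreeEnergyLedger data.frame from per-component mean/sem
.make_ledger <- function(means, sems, mode) {
  comp <- .ENERGY_COMPONENTS
  df <- data.frame(component = comp, mean = means[comp], sem = sems[comp],
                   stringsAsFactors = FALSE)
  gsolv <- c(mean = sum(df$mean[df$component %in% c("G_polar", "G_apolar")]),
             sem = sqrt(sum(df$sem[df$component %in% c("G_polar", "G_apolar")]^2)))
  total <- c(mean = sum(df$mean), sem = sqrt(sum(df$sem^2)))
  df <- rbind(df,
              data.frame(component = "G_solv", mean = gsolv["mean"], sem = gsolv["sem"]),
              data.frame(component = "G_total", mean = total["mean"], sem = total["sem"]))
  rownames(df) <- NULL
  attr(df, "mode") <- mode
  attr(df, "entropy") <- "neglected (TS = 0)"
  class(df) <- c("FreeEnergyLedger", "data.frame")
  df
}

#' @export
print.FreeEnergyLedger <- function(x, ...) {
  cat(sprintf("FreeEnergyLedger (%s), entropy %s\n",
              attr(x, "mode"), attr(x, "entropy")))
  y <- as.data.frame(x)
  y$mean <- round(y$mean, 1); y$sem <- round(y$sem, 1)
  print(y)
  invisible(x)
}

# fetch the per-snapshot polar column for one species from a polar table
.polar_column <- function(polar_table, species, n_expected) {
  col <- polar_table$G_polar[polar_table$species == species]
  if (length(col) != n_expected)
    stop("polar table supplies ", length(col), " snapshots for '", species,
         "' but ", n_expected, " coordinate snapshots are used")
  col
}

#' Single-trajectory (SITA) free-energy ledger
#'
#' Partner coordinates are taken from the complex trajectory itself, so
#' bonded terms cancel exactly (`dH_int = 0`), and the gas-phase
#' differences reduce to the explicit cross-partner Coulomb and
#' Lennard-Jones sums.  The apolar difference comes from the SASA of the
#' complex minus the partners on identical coordinates; the polar
#' difference is read from the imported per-snapshot table.
#'
#' @param t complex Trajectory
#' @param partition named list of two atom-index vectors (or selection
#'   strings) splitting the complex into its partners
#' @param ff an [ff_params()] object
#' @param polar_table data.frame (`snapshot`, `species`, `G_polar`) with
#'   species names `complex` plus the two partition names; pass `NULL` to
#'   book zero polar terms
#' @param apolar an [apolar_model()]
#' @param window snapshot (frame) indices to use; default all frames
#' @param sasa_cfg a [sasa_config()]
#' @param polar_spec a [polar_input_spec()] recorded as metadata
#' @return a `FreeEnergyLedger` with attribute `snapshots` (per-snapshot
#'   component table)
#' @export
sita_ledger <- function(t, partition, ff, polar_table = NULL,
                        apolar = apolar_model(), window = NULL,
                        sasa_cfg = sasa_config(),
                        polar_spec = polar_input_spec()) {
  s <- t$topology
  resolve <- function(g) if (is.character(g)) atom_select(s, g) else as.integer(g)
  parts <- lapply(partition, resolve)
  if (length(parts) != 2) stop("partition must name exactly two partners")
  if (is.null(window)) window <- seq_len(n_frames(t))
  nm <- names(parts)
  if (!is.null(polar_table)) {
    pc <- .polar_column(polar_table, "complex", length(window))
    p1 <- .polar_column(polar_table, nm[1], length(window))
    p2 <- .polar_column(polar_table, nm[2], length(window))
    dpol <- pc - p1 - p2
  } else dpol <- rep(0, length(window))
  rows <- matrix(0, length(window), 5,
                 dimnames = list(NULL, .ENERGY_COMPONENTS))
  for (w in seq_along(window)) {
    xyz <- frame_coords(t, window[w])
    dvdw <- lj_energy(s, ff, parts[[1]], parts[[2]], cross = TRUE, xyz = xyz)
    dele <- coulomb_energy(s, ff, parts[[1]], parts[[2]], cross = TRUE, xyz = xyz)
    sc <- sasa(s, sasa_cfg, xyz = xyz)$total
    s1 <- sasa(s, sasa_cfg, xyz = xyz, atoms = parts[[1]])$total
    s2 <- sasa(s, sasa_cfg, xyz = xyz, atoms = parts[[2]])$total
    dapo <- apolar_solvation(sc, apolar) - apolar_solvation(s1, apolar) -
      apolar_solvation(s2, apolar)
    rows[w, ] <- c(0, dvdw, dele, dpol[w], dapo)
  }
  means <- apply(rows, 2, mean)
  sems <- apply(rows, 2, function(x) stats::sd(x) / sqrt(length(x)))
  sems[!is.finite(sems)] <- 0
  led <- .make_ledger(means, sems, "SITA")
  attr(led, "snapshots") <- as.data.frame(rows)
  attr(led, "polar_spec") <- polar_spec
  led
}

#' Per-snapshot energy components for one species
#'
#' Computes the gas-phase and apolar columns of an energy-component table
#' from a trajectory and force-field parameters; the polar column is
#' supplied (per snapshot) since the Poisson-Boltzmann solve is external.
#' `H_int` is computed only when bonded parameters are present, else
#' booked as `NA`.
#'
#' @param t a Trajectory
#' @param ff an [ff_params()] object
#' @param polar per-snapshot polar solvation vector (kJ/mol), or a single
#'   value recycled, or `NULL` for zeros
#' @param apolar an [apolar_model()]
#' @param window frame indices (default all)
#' @param sasa_cfg a [sasa_config()]
#' @return data.frame `snapshot`, `H_int`, `H_vdW`, `H_elect`, `G_polar`,
#'   `G_apolar`
#' @export
energy_components <- function(t, ff, polar = NULL, apolar = apolar_model(),
                              window = NULL, sasa_cfg = sasa_config()) {
  if (is.null(window)) window <- seq_len(n_frames(t))
  if (is.null(polar)) polar <- 0
  polar <- rep_len(polar, length(window))
  s <- t$topology
  out <- data.frame(snapshot = window, H_int = NA_real_, H_vdW = NA_real_,
                    H_elect = NA_real_, G_polar = polar, G_apolar = NA_real_)
  for (w in seq_along(window)) {
    xyz <- frame_coords(t, window[w])
    out$H_vdW[w] <- lj_energy(s, ff, xyz = xyz)
    out$H_elect[w] <- coulomb_energy(s, ff, xyz = xyz)
    out$G_apolar[w] <- apolar_solvation(sasa(s, sasa_cfg, xyz = xyz)$total, apolar)
    if (!is.null(ff$bonded)) out$H_int[w] <- internal_energy(s, ff, xyz = xyz)
  }
  out
}

#' Separate-trajectory (SETA) free-energy ledger
#'
#' Complex, protein and ligand components are averaged independently over
#' their own snapshot sets and combined componentwise with the reaction's
#' stoichiometric coefficients; standard errors combine in quadrature.
#' `H_int` no longer cancels.  Each species argument may be a precomputed
#' energy-component table (data.frame as from [energy_components()] or
#' [make_energy_table()]) or a list `list(t =, ff =, polar =)` from which
#' the table is computed.
#'
#' @param complex,protein,ligand per-species component tables or input
#'   lists (see above)
#' @param stoich a [stoich_step()] (or any list with `coef = c(protein,
#'   ligand)`)
#' @param apolar an [apolar_model()] used when tables are computed here
#' @param window frame indices used when tables are computed here
#' @param polar_spec a [polar_input_spec()] recorded as metadata
#' @return a `FreeEnergyLedger`
#' @export
seta_ledger <- function(complex, protein, ligand, stoich = stoich_step(1),
                        apolar = apolar_model(), window = NULL,
                        polar_spec = polar_input_spec()) {
  as_table <- function(x) {
    if (is.data.frame(x)) return(x)
    energy_components(x$t, x$ff, polar = x$polar, apolar = apolar,
                      window = window)
  }
  tabs <- lapply(list(complex = complex, protein = protein, ligand = ligand),
                 as_table)
  has_hint <- all(vapply(tabs, function(tb) !anyNA(tb$H_int), logical(1)))
  stats_of <- function(tb) {
    sapply(.ENERGY_COMPONENTS, function(cc) {
      x <- tb[[cc]]
      if (anyNA(x)) c(mean = 0, sem = 0) else aggregate_stats(x)
    })
  }
  st <- lapply(tabs, stats_of)
  coef <- c(1, -stoich$coef[["protein"]], -stoich$coef[["ligand"]])
  means <- coef[1] * st$complex["mean", ] + coef[2] * st$protein["mean", ] +
    coef[3] * st$ligand["mean", ]
  sems <- sqrt((coef[1] * st$complex["sem", ])^2 +
                 (coef[2] * st$protein["sem", ])^2 +
                 (coef[3] * st$ligand["sem", ])^2)
  led <- .make_ledger(means, sems, "SETA")
  attr(led, "stoich") <- stoich
  attr(led, "polar_spec") <- polar_spec
  if (!has_hint) attr(led, "incomplete") <- "H_int unavailable (no bonded parameters); booked as 0"
  led
}

#' Assemble a ledger directly from printed component values
#'
#' Bookkeeping entry point for component differences that are already
#' known (e.g. typed from a published table): derives `G_solv` and the
#' grand total with their quadrature errors.
#'
#' @param means named numeric: some or all of `H_int`, `H_vdW`, `H_elect`,
#'   `G_polar`, `G_apolar` (missing components are booked as 0)
#' @param sems optional named numeric of matching standard errors
#' @param mode `"SITA"` or `"SETA"`
#' @return a `FreeEnergyLedger`
#' @export
ledger_from_components <- function(means, sems = NULL, mode = "SITA") {
  m <- stats::setNames(rep(0, 5), .ENERGY_COMPONENTS)
  m[names(means)] <- means
  s <- stats::setNames(rep(0, 5), .ENERGY_COMPONENTS)
  if (!is.null(sems)) s[names(sems)] <- sems
  .make_ledger(m, s, mode)
}

#' Read / write per-snapshot energy-component tables
#'
#' Delimited text with header `snapshot`, `species`, `H_int`, `H_vdW`,
#' `H_elect`, `G_polar`, `G_apolar`.
#' @param path file path
#' @export
read_energy_table <- function(path) {
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_energy_table
#' @param table the table to write
#' @export
write_energy_table <- function(table, path) {
  utils::write.table(table, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
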