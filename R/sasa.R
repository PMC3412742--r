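# Shrake-Rupley solvent-accessible surface area and buried interface area.

# Bondi-style van der Waals radii, nm
.VDW_RADII <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                S = 0.180, P = 0.180, SE = 0.190)

#' SASA configuration
#'
#' @param probe probe radius in nm (default 0.14, a water molecule)
#' @param n_points sphere sample points per atom (default 960); points are
#'   laid out on a deterministic golden-spiral lattice, so results are
#'   reproducible for a fixed count
#' @param radii named per-element van der Waals radii (nm)
#' @param default_radius radius for elements missing from `radii`; `NA`
#'   (default) makes an unknown element an error
#' @export
sasa_config <- function(probe = 0.14, n_points = 960, radii = .VDW_RADII,
                        default_radius = NA) {
  stopifnot(probe >= 0, n_points >= 32)
  cfg <- list(probe = probe, n_points = n_points, radii = radii,
              default_radius = default_radius)
  class(cfg) <- "SASAConfig"
  cfg
}

# deterministic golden-spiral points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(s, cfg) {
  r <- cfg$radii[s$atoms$element]
  if (any(is.na(r))) {
    if (is.na(cfg$default_radius))
      stop("no van der Waals radius for element(s): ",
           paste(unique(s$atoms$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- cfg$default_radius
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's accessible area is the fraction of points on its solvent-
#' expanded sphere (radius + probe) not occluded by any neighbour's
#' expanded sphere, times the sphere area.  Deterministic for a fixed
#' sphere-point count.
#'
#' @param s a Structure
#' @param cfg a [sasa_config()] object
#' @param xyz optional n_atoms x 3 coordinates (nm) overriding the
#'   structure's own
#' @param atoms optional atom indices to restrict the solute (others are
#'   removed entirely, not treated as occluders)
#' @return list: `total` (A^2), `per_atom` (A^2, length n_atoms of the
#'   solute), `per_residue` (data.frame `chain`, `resno`, `sasa`)
#' @export
sasa <- function(s, cfg = sasa_config(), xyz = NULL, atoms = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  if (is.null(atoms)) atoms <- seq_len(nrow(s$atoms))
  xyz <- xyz[atoms, , drop = FALSE]
  rad <- .atom_radii(s, cfg)[atoms] + cfg$probe
  n <- length(atoms)
  pts <- .sphere_points(cfg$n_points)
  area <- numeric(n)
  # neighbour lists via one distance matrix (structures here are modest)
  dm <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < rad[i] + rad & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rad[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(free)
  }
  area_A2 <- area * .ANG_PER_NM^2   # nm^2 -> A^2
  key <- paste(s$atoms$chain[atoms], s$atoms$resno[atoms], sep = ":")
  per_res <- tapply(area_A2, factor(key, levels = unique(key)), sum)
  pr <- data.frame(chain = sub(":.*", "", names(per_res)),
                   resno = as.integer(sub(".*:", "", names(per_res))),
                   sasa = as.numeric(per_res))
  list(total = sum(area_A2), per_atom = area_A2, per_residue = pr)
}

#' Per-residue buried surface area across an interface
#'
#' For each partner the buried area of residue i is its SASA computed with
#' the partner isolated minus its SASA in the complex; values are averaged
#' over frames when a Trajectory is given.  The partition must cover every
#' atom exactly once.
#'
#' @param x a Structure or Trajectory
#' @param partition named list of two atom-index vectors (or selection
#'   strings) covering all atoms exactly once
#' @param cfg a [sasa_config()] object
#' @return data.frame `partner`, `chain`, `resno`, `buried` (A^2)
#' @export
buried_area <- function(x, partition, cfg = sasa_config()) {
  s <- if (inherits(x, "Trajectory")) x$topology else x
  resolve <- function(g) if (is.character(g)) atom_select(s, g) else as.integer(g)
  parts <- lapply(partition, resolve)
  if (length(parts) != 2) stop("partition must name exactly two partners")
  all_idx <- sort(unname(unlist(parts)))
  if (any(duplicated(all_idx)) || !identical(all_idx, seq_len(nrow(s$atoms))))
    stop("partition must cover every atom exactly once")
  frames <- if (inherits(x, "Trajectory"))
    lapply(seq_len(n_frames(x)), function(f) frame_coords(x, f))
  else list(coords(s))
  acc <- NULL
  for (xyz in frames) {
    cplx <- sasa(s, cfg, xyz = xyz)
    rows <- list()
    for (p in names(parts)) {
      alone <- sasa(s, cfg, xyz = xyz, atoms = parts[[p]])
      key <- paste(alone$per_residue$chain, alone$per_residue$resno)
      m <- match(key, paste(cplx$per_residue$chain, cplx$per_residue$resno))
      rows[[p]] <- data.frame(partner = p,
                              chain = alone$per_residue$chain,
                              resno = alone$per_residue$resno,
                              buried = alone$per_residue$sasa - cplx$per_residue$sasa[m])
    }
    this <- do.call(rbind, rows)
    if (is.null(acc)) acc <- this else acc$buried <- acc$buried + this$buried
  }
  acc$buried <- acc$buried / length(frames)
  rownames(acc) <- NULL
  acc
}
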