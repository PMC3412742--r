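# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

`%||%` <- function(a, b) if (is.null(a)) b else a

# write raw PDB ATOM records (with altLoc/occupancy control)
write_pdb_fixture <- function(df, path) {
  lines <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    alt <- if (is.null(df$alt)) " " else r$alt
    occ <- if (is.null(df$occ)) 1.0 else r$occ
    name <- if (nchar(r$elety) < 4) sprintf(" %-3s", r$elety) else r$elety
    lines[i] <- sprintf(
      "ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name, alt, r$resid, r$chain, r$resno, r$x, r$y, r$z, occ, 0,
      r$element)
  }
  writeLines(c(lines, "END"), path)
  path
}

# minimal hand-built Structure from atom rows (coords in nm)
atoms_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], resno = as.integer(r[[2]]), resid = r[[3]],
               elety = r[[4]], element = r[[5]], x = r[[6]], y = r[[7]],
               z = r[[8]], stringsAsFactors = FALSE)))
}

# SpringNetwork assembled by hand: xyz is n x 3 (nm), springs a data.frame
# i, j, k (kJ mol-1 nm-2); rest lengths are the build distances
manual_network <- function(xyz, springs) {
  nodes <- data.frame(chain = "A", resno = seq_len(nrow(xyz)), resid = "ALA",
                      kind = "bb", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  d <- sqrt(rowSums((xyz[springs$i, , drop = FALSE] -
                       xyz[springs$j, , drop = FALSE])^2))
  net <- list(nodes = nodes,
              springs = data.frame(i = springs$i, j = springs$j, k = springs$k,
                                   rest = d, rule = "shell",
                                   stringsAsFactors = FALSE),
              params = enm_params(), connected = TRUE)
  class(net) <- "SpringNetwork"
  net
}

# deterministic irregular node cloud with all pairwise distances distinct
# (keeps eigenvalue degeneracies away from invariance tests)
irregular_cloud <- function(n, seed = 42, scale = 0.5) {
  set.seed(seed)
  matrix(stats::runif(3 * n, 0, scale * n^(1 / 3)), ncol = 3)
}

# fully connect a cloud with distance-dependent constants
cloud_network <- function(xyz, k0 = 500) {
  pr <- t(utils::combn(nrow(xyz), 2))
  d <- sqrt(rowSums((xyz[pr[, 1], ] - xyz[pr[, 2], ])^2))
  manual_network(xyz, data.frame(i = pr[, 1], j = pr[, 2], k = k0 / (1 + d)))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigid transform of a Structure
transform_structure <- function(s, R, shift = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}
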