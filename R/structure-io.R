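# Internal units: coordinates in nm (PDB Angstrom values are converted on
# read and write), energies in kJ/mol, force constants in kJ mol-1 nm-2.

.ANG_PER_NM <- 10

#' Construct a protein Structure
#'
#' A `Structure` is an atom-level table plus residue annotations: secondary
#' structure labels and disulfide pairs.  Coordinates are stored in nm.
#' Residue identity is the pair (chain, resno) with author numbering;
#' residue order follows first appearance in `atoms`.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer), `resid`
#'   (3-letter residue code), `elety` (atom name), `element` (chemical
#'   element symbol), `x`, `y`, `z` (nm).
#' @param ss optional data.frame (`chain`, `resno`, `label`) with labels in
#'   `H` (helix), `E` (strand), `C` (coil); residues not listed are coil.
#' @param disulfides optional data.frame (`chain1`, `resno1`, `chain2`,
#'   `resno2`) of cystine pairs.
#' @return an object of class `Structure`.
#' @export
structure_new <- function(atoms, ss = NULL, disulfides = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atoms")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols in atoms")
  atoms$resno <- as.integer(atoms$resno)
  atoms$is_hydrogen <- atoms$element == "H"
  s <- list(atoms = atoms, ss = NULL, disulfides = NULL)
  class(s) <- "Structure"
  if (!is.null(ss)) s <- load_ss_labels(s, ss)
  if (!is.null(disulfides)) s <- set_disulfides(s, disulfides)
  s
}

#' @export
print.Structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("Structure: %d residues, %d atoms, %d chains\n",
              length(rk), nrow(x$atoms), length(unique(x$atoms$chain))))
  if (!is.null(x$disulfides) && nrow(x$disulfides))
    cat(sprintf("  disulfides: %d\n", nrow(x$disulfides)))
  invisible(x)
}

# residue keys "chain:resno" in order of first appearance
residue_keys <- function(s) {
  unique(paste(s$atoms$chain, s$atoms$resno, sep = ":"))
}

#' Number of residues in a Structure
#' @param s a Structure
#' @export
n_residues <- function(s) length(residue_keys(s))

# per-atom residue key
atom_res_key <- function(s) paste(s$atoms$chain, s$atoms$resno, sep = ":")

#' Residue-level summary table
#'
#' One row per residue: chain, number, 3-letter code, secondary-structure
#' label (coil unless annotated) and whether a C-alpha atom is present.
#' @param s a Structure
#' @return data.frame with columns `chain`, `resno`, `resid`, `ss`, `has_ca`
#' @export
residue_table <- function(s) {
  key <- atom_res_key(s)
  idx <- !duplicated(key)
  tab <- data.frame(chain = s$atoms$chain[idx],
                    resno = s$atoms$resno[idx],
                    resid = s$atoms$resid[idx],
                    stringsAsFactors = FALSE)
  tab$ss <- "C"
  if (!is.null(s$ss) && nrow(s$ss)) {
    m <- match(paste(tab$chain, tab$resno), paste(s$ss$chain, s$ss$resno))
    tab$ss[!is.na(m)] <- s$ss$label[m[!is.na(m)]]
  }
  ca <- key[s$atoms$elety == "CA" & !s$atoms$is_hydrogen]
  tab$has_ca <- paste(tab$chain, tab$resno, sep = ":") %in% ca
  tab
}

#' Coordinate matrix of a Structure
#' @param s a Structure
#' @return numeric matrix, one row per atom, columns x/y/z in nm
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# derive element symbol from a PDB atom name when the element column is blank
.element_from_elety <- function(elety) {
  e <- sub("^[0-9']*", "", elety)
  first <- toupper(substr(e, 1, 1))
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"), two, first)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records via [bio3d::read.pdb()],
#' resolves alternate locations by keeping the highest-occupancy copy of
#' each (chain, resno, atom-name) triple, drops waters, and converts
#' coordinates to nm.  Residues lacking a C-alpha are kept but flagged with
#' a warning.
#'
#' @param path PDB file path.
#' @param keep_het keep non-water HETATM records? Default `FALSE`.
#' @return a [structure_new()] `Structure`.
#' @export
read_pdb <- function(path, keep_het = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!keep_het) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "SOL")), , drop = FALSE]
  if (!nrow(at)) stop("no atom records retained from ", path)
  at$chain[is.na(at$chain)] <- " "
  # alternate locations: keep the highest-occupancy copy (first on ties)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(match(key, unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- .element_from_elety(at$elety[bad])
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, element = trimws(elem),
                      x = at$x / .ANG_PER_NM, y = at$y / .ANG_PER_NM,
                      z = at$z / .ANG_PER_NM, stringsAsFactors = FALSE)
  s <- structure_new(atoms)
  rt <- residue_table(s)
  if (any(!rt$has_ca))
    warning(sum(!rt$has_ca), " residue(s) lack a C-alpha atom (flagged in residue_table)")
  s
}

#' Write a Structure (or coordinate frames) to a PDB file
#'
#' Coordinates are converted from nm to Angstrom.  When `xyz` is a matrix
#' with several rows, a multi-model PDB is written (one MODEL per row).
#'
#' @param s a Structure supplying the topology.
#' @param path output file.
#' @param xyz optional coordinate vector/matrix (nm, length 3 x n_atoms per
#'   frame); defaults to the structure's own coordinates.
#' @export
write_pdb <- function(s, path, xyz = NULL) {
  if (is.null(xyz)) xyz <- as.numeric(t(coords(s)))
  xyz <- if (is.matrix(xyz)) xyz * .ANG_PER_NM else matrix(xyz * .ANG_PER_NM, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = s$atoms$resno, chain = s$atoms$chain,
                   resid = s$atoms$resid, elety = s$atoms$elety)
  invisible(path)
}

#' Select a residue range from one chain
#'
#' Returns the sub-structure for `range[1]..range[2]` (author numbering,
#' inclusive) on `chain`, preserving atom order, secondary-structure labels
#' and disulfides internal to the selection.  Disulfides with one partner
#' outside the selection are dropped with a warning.
#'
#' @param s a Structure
#' @param chain chain identifier
#' @param range integer vector `c(start, end)`, inclusive
#' @export
select_residues <- function(s, chain, range) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  keep <- s$atoms$chain == chain & s$atoms$resno >= range[1] & s$atoms$resno <= range[2]
  if (!any(keep)) stop("empty selection: chain ", chain, " residues ",
                       range[1], "-", range[2])
  out <- structure_new(s$atoms[keep, , drop = FALSE])
  if (!is.null(s$ss) && nrow(s$ss)) {
    ssk <- s$ss$chain == chain & s$ss$resno >= range[1] & s$ss$resno <= range[2]
    if (any(ssk)) out$ss <- s$ss[ssk, , drop = FALSE]
  }
  if (!is.null(s$disulfides) && nrow(s$disulfides)) {
    d <- s$disulfides
    in1 <- d$chain1 == chain & d$resno1 >= range[1] & d$resno1 <= range[2]
    in2 <- d$chain2 == chain & d$resno2 >= range[1] & d$resno2 <= range[2]
    if (any(xor(in1, in2)))
      warning(sum(xor(in1, in2)), " disulfide(s) crossing the selection boundary dropped")
    if (any(in1 & in2)) out$disulfides <- d[in1 & in2, , drop = FALSE]
  }
  out
}

# validate and attach a disulfide table
set_disulfides <- function(s, pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("chain1", "resno1", "chain2", "resno2") %in% names(pairs)))
  rt <- residue_table(s)
  cys <- paste(rt$chain[rt$resid == "CYS"], rt$resno[rt$resid == "CYS"])
  k1 <- paste(pairs$chain1, pairs$resno1)
  k2 <- paste(pairs$chain2, pairs$resno2)
  if (any(k1 == k2)) stop("disulfide pairs a residue with itself")
  if (!all(c(k1, k2) %in% cys))
    stop("disulfide pair references a residue that is not a CYS in the structure")
  s$disulfides <- pairs
  s
}

#' Detect disulfide bridges geometrically
#'
#' All CYS pairs whose SG-SG distance is within `cutoff` are candidate
#' bridges; each cysteine joins at most one bridge, closest distance first.
#' The default cutoff of 0.25 nm comfortably covers the canonical ~0.205 nm
#' S-S bond.  Result is independent of residue order and of rigid motions.
#'
#' @param s a Structure
#' @param cutoff SG-SG distance cutoff in nm
#' @param attach attach the detected pairs to the returned Structure?
#' @return if `attach`, the Structure with `disulfides` set; otherwise the
#'   pair data.frame (`chain1`, `resno1`, `chain2`, `resno2`, `distance`).
#' @export
detect_disulfides <- function(s, cutoff = 0.25, attach = FALSE) {
  sg <- s$atoms$resid == "CYS" & s$atoms$elety == "SG"
  cys_all <- unique(atom_res_key(s)[s$atoms$resid == "CYS"])
  cys_sg <- atom_res_key(s)[sg]
  if (length(setdiff(cys_all, cys_sg)))
    warning("CYS residue(s) without an SG atom skipped: ",
            paste(setdiff(cys_all, cys_sg), collapse = ", "))
  pairs <- data.frame(chain1 = character(), resno1 = integer(),
                      chain2 = character(), resno2 = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (sum(sg) >= 2) {
    xyz <- coords(s)[sg, , drop = FALSE]
    ch <- s$atoms$chain[sg]; rn <- s$atoms$resno[sg]
    dm <- as.matrix(stats::dist(xyz))
    cand <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dm[cand]), , drop = FALSE]
      used <- logical(sum(sg))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          chain1 = ch[i], resno1 = rn[i], chain2 = ch[j], resno2 = rn[j],
          distance = dm[i, j], stringsAsFactors = FALSE))
      }
      in_cand <- unique(as.vector(cand))
      if (any(!used[in_cand]))
        warning("cysteine(s) within cutoff left unpaired (closest partner already bonded)")
    }
  }
  if (attach) {
    if (nrow(pairs)) s <- set_disulfides(s, pairs[, 1:4]) else s$disulfides <- NULL
    s
  } else pairs
}

#' Attach secondary-structure labels from a table
#'
#' Labels come from any assigner as a (chain, resnum, label) table; only
#' the `H`/`E`/`C` classes are consumed.  Residues absent from the table
#' stay coil; table rows naming residues absent from the structure raise a
#' warning.
#'
#' @param s a Structure
#' @param table data.frame (`chain`, `resno`, `label`) or path to a
#'   whitespace/comma-delimited 3-column file.
#' @export
load_ss_labels <- function(s, table) {
  if (is.character(table)) {
    table <- utils::read.table(table, header = FALSE, col.names = c("chain", "resno", "label"),
                               colClasses = c("character", "integer", "character"))
  }
  stopifnot(all(c("chain", "resno", "label") %in% names(table)))
  table$label <- toupper(table$label)
  if (!all(table$label %in% c("H", "E", "C")))
    stop("secondary-structure labels must be H, E or C")
  present <- paste(table$chain, table$resno) %in%
    sub(":", " ", residue_keys(s), fixed = TRUE)
  if (any(!present))
    warning(sum(!present), " secondary-structure label(s) for residues not in the structure")
  s$ss <- table[present, c("chain", "resno", "label"), drop = FALSE]
  s
}

#' Define named domain ranges
#'
#' A `DomainMap` names inclusive author-numbered ranges per chain, e.g. the
#' four cysteine-rich domains CRD1..CRD4 of a TNF-family receptor.  Ranges
#' must not overlap within a chain.
#'
#' @param ... named arguments, each `list(chain =, start =, end =)`.
#' @export
domain_map <- function(...) {
  doms <- list(...)
  if (!length(doms) || is.null(names(doms)) || any(!nzchar(names(doms))))
    stop("domains must be named")
  for (d in doms) {
    stopifnot(all(c("chain", "start", "end") %in% names(d)))
    if (d$start > d$end) stop("domain start exceeds end")
  }
  for (ch in unique(vapply(doms, `[[`, "", "chain"))) {
    in_ch <- Filter(function(d) d$chain == ch, doms)
    if (length(in_ch) > 1) {
      iv <- do.call(rbind, lapply(in_ch, function(d) c(d$start, d$end)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("overlapping domain ranges on chain ", ch)
    }
  }
  class(doms) <- "DomainMap"
  doms
}

#' Atom indices for a domain or selection string
#'
#' Selections are written `"chain:start-end"` (author numbering, inclusive)
#' or `"chain:*"` for a whole chain; several selections may be combined.
#'
#' @param s a Structure
#' @param sel character vector of selection strings
#' @param elety optional atom-name filter (e.g. `"CA"`)
#' @return integer atom indices into `s$atoms`
#' @export
atom_select <- function(s, sel, elety = NULL) {
  keep <- rep(FALSE, nrow(s$atoms))
  for (one in sel) {
    parts <- strsplit(one, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("bad selection string: ", one)
    ch <- parts[1]
    if (parts[2] == "*") {
      keep <- keep | s$atoms$chain == ch
    } else {
      rng <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      if (length(rng) == 1) rng <- c(rng, rng)
      keep <- keep | (s$atoms$chain == ch & s$atoms$resno >= rng[1] &
                        s$atoms$resno <= rng[2])
    }
  }
  if (!is.null(elety)) keep <- keep & s$atoms$elety %in% elety
  which(keep)
}
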