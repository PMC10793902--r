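#' Read a ligand structure
#'
#' Parses one small molecule from an SDF (V2000) or TRIPOS mol2 file into a
#' heavy-atom [Molecule]. Explicit hydrogens are stripped and folded into the
#' `num_h` annotation; formal charges come from `M  CHG` blocks (SDF) or the
#' old-style atom-line charge field.
#'
#' @param path file path
#' @param format `"sdf"` or `"mol2"`; guessed from the extension by default
#' @return a [Molecule] with `is_protein = FALSE` on every atom
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) lgn_stop("ligand file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  }
  parsed <- tryCatch(
    switch(format, sdf = parse_sdf(path), mol2 = parse_mol2(path)),
    error = function(e) {
      lgn_stop("cannot parse ligand file %s: %s", path, conditionMessage(e))
    }
  )
  hv <- strip_hydrogens(parsed$atoms, parsed$bonds)
  if (nrow(hv$atoms) == 0) lgn_stop("no heavy atoms in ligand file %s", path)
  hv$atoms$is_protein <- FALSE
  Molecule(hv$atoms, hv$bonds)
}

parse_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("file too short for an SDF record")
  sdfset <- ChemmineR::read.SDFset(path)
  if (length(sdfset) != 1) {
    stop(sprintf("expected exactly one molecule, found %d", length(sdfset)))
  }
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  # old-style charge field: 0 none, 1..7 -> +3..-3 (4 = doublet radical, kept 0)
  old_chg <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, nrow(ab))
  charge <- ifelse(old_chg %in% c(1, 2, 3, 5, 6, 7), 4 - old_chg, 0)
  # M  CHG lines override all old-style charges
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines) > 0) {
    charge[] <- 0
    for (ln in chg_lines) {
      f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      for (p in seq_len(k)) charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  atoms <- data.frame(
    element = element,
    x = ab[, "C1"], y = ab[, "C2"], z = ab[, "C3"],
    formal_charge = charge, stringsAsFactors = FALSE
  )
  order_map <- c("1" = "single", "2" = "double", "3" = "triple", "4" = "aromatic")
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  bonds <- data.frame(
    i = as.integer(bb[, "C1"]), j = as.integer(bb[, "C2"]),
    order = unname(order_map[as.character(bb[, "C3"])]),
    stringsAsFactors = FALSE
  )
  if (nrow(bonds) > 0 && anyNA(bonds$order)) stop("unsupported SDF bond type")
  list(atoms = atoms, bonds = bonds)
}

# Minimal TRIPOS mol2 reader (MOLECULE/ATOM/BOND records). SYBYL atom types
# provide element, aromaticity and hybridization; partial charges are not
# formal charges and are ignored.
parse_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sect <- grep("^@<TRIPOS>", lines)
  if (length(sect) == 0) stop("not a mol2 file (no @<TRIPOS> records)")
  get_section <- function(name) {
    start <- grep(paste0("^@<TRIPOS>", name, "\\s*$"), lines)
    if (length(start) == 0) return(character(0))
    start <- start[1]
    end <- sect[sect > start]
    end <- if (length(end)) min(end) - 1 else length(lines)
    block <- lines[(start + 1):end]
    block[nzchar(trimws(block))]
  }
  nmol <- length(grep("^@<TRIPOS>MOLECULE", lines))
  if (nmol != 1) stop(sprintf("expected exactly one molecule, found %d", nmol))
  atom_lines <- get_section("ATOM")
  bond_lines <- get_section("BOND")
  if (length(atom_lines) == 0) stop("mol2 file has no atoms")
  af <- do.call(rbind, lapply(strsplit(trimws(atom_lines), "\\s+"), function(f) {
    if (length(f) < 6) stop("malformed mol2 ATOM line")
    f[1:6]
  }))
  sybyl <- af[, 6]
  element <- sub("\\..*$", "", sybyl)
  element <- paste0(
    toupper(substring(element, 1, 1)),
    tolower(substring(element, 2))
  )
  hyb <- rep(NA_character_, length(sybyl))
  hyb[grepl("\\.1$", sybyl)] <- "sp"
  hyb[grepl("\\.(2|ar|am|pl3|co2|cat)$", sybyl)] <- "sp2"
  hyb[grepl("\\.(3|4)$", sybyl)] <- "sp3"
  atoms <- data.frame(
    element = element,
    x = as.numeric(af[, 3]), y = as.numeric(af[, 4]), z = as.numeric(af[, 5]),
    formal_charge = 0, hybridization = hyb, stringsAsFactors = FALSE
  )
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  if (length(bond_lines) > 0) {
    bf <- do.call(rbind, lapply(strsplit(trimws(bond_lines), "\\s+"), function(f) {
      if (length(f) < 4) stop("malformed mol2 BOND line")
      f[1:4]
    }))
    order_map <- c(
      "1" = "single", "2" = "double", "3" = "triple", "ar" = "aromatic",
      "am" = "single", "du" = "single", "un" = "single"
    )
    ord <- order_map[bf[, 4]]
    if (anyNA(ord)) stop("unsupported mol2 bond type")
    bonds <- data.frame(
      i = as.integer(bf[, 2]), j = as.integer(bf[, 3]), order = unname(ord),
      stringsAsFactors = FALSE
    )
  }
  list(atoms = atoms, bonds = bonds)
}

# Drop explicit hydrogens, counting them onto their heavy neighbor.
strip_hydrogens <- function(atoms, bonds) {
  is_h <- atoms$element %in% c("H", "D", "T")
  if (!any(is_h)) return(list(atoms = atoms, bonds = bonds))
  n <- nrow(atoms)
  explicit_h <- numeric(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (is_h[i] && !is_h[j]) explicit_h[j] <- explicit_h[j] + 1
      if (is_h[j] && !is_h[i]) explicit_h[i] <- explicit_h[i] + 1
    }
  }
  keep <- which(!is_h)
  remap <- match(seq_len(n), keep)
  atoms <- atoms[keep, , drop = FALSE]
  if (!is.null(atoms$num_h)) {
    atoms$num_h <- ifelse(explicit_h[keep] > 0, explicit_h[keep], atoms$num_h)
  } else {
    atoms$num_h <- ifelse(explicit_h[keep] > 0, explicit_h[keep], NA_real_)
  }
  if (nrow(bonds) > 0) {
    bonds <- bonds[!is_h[bonds$i] & !is_h[bonds$j], , drop = FALSE]
    bonds$i <- remap[bonds$i]
    bonds$j <- remap[bonds$j]
  }
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}

#' Read a protein pocket structure
#'
#' Reads a PDB-format pocket file into a heavy-atom [Molecule]. Water
#' molecules are removed; everything else the file contains (standard
#' residues, cofactors, metal ions) is kept. Covalent bonds are perceived
#' from interatomic distances with covalent radii; metal ions stay isolated
#' single-atom nodes. Residue names and per-atom protein annotations
#' (formal charge, implicit hydrogens, aromaticity of side-chain rings)
#' follow standard amino-acid chemistry.
#'
#' @param path PDB file path
#' @return a [Molecule] with `is_protein = TRUE` on every atom
#' @export
read_pocket <- function(path) {
  if (!file.exists(path)) lgn_stop("pocket file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) {
      lgn_stop("cannot parse pocket file %s: %s", path, conditionMessage(e))
    }
  )
  at <- pdb$atom
  elem <- normalize_element(at$elesy, at$elety)
  keep <- !(at$resid %in% WATER_RESNAMES) & !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) lgn_stop("no atoms left after filtering in %s", path)
  build_pocket_molecule(
    element = elem, x = at$x, y = at$y, z = at$z,
    residue_name = at$resid, residue_id = at$resno, atom_name = at$elety
  )
}

# Shared constructor for pockets read from PDB and generated synthetically.
build_pocket_molecule <- function(element, x, y, z, residue_name, residue_id,
                                  atom_name) {
  atoms <- data.frame(
    element = element, x = x, y = y, z = z,
    residue_name = residue_name, residue_id = residue_id,
    atom_name = atom_name, is_protein = TRUE, stringsAsFactors = FALSE
  )
  bonds <- perceive_bonds(atoms)
  ann <- protein_annotations(atoms, bonds)
  atoms$formal_charge <- ann$charge
  atoms$num_h <- ann$num_h
  atoms$hybridization <- ann$hybridization
  mol <- Molecule(atoms, bonds)
  # side-chain aromatic rings are flagged from residue templates (perceived
  # bonds carry no orders, so Kekule detection cannot apply)
  mol$atoms$aromatic <- ann$aromatic
  mol
}

# Distance-based covalent bond perception; metals form no covalent bonds.
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  rad <- COVALENT_RADIUS[atoms$element]
  bondable <- which(!is.na(rad))
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  if (length(bondable) >= 2) {
    xyz <- as.matrix(atoms[bondable, c("x", "y", "z")])
    d <- cross_dist(xyz, xyz)
    thr <- outer(rad[bondable], rad[bondable], "+") + 0.45
    hit <- which(d <= thr & d > 0.4 & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      bonds <- data.frame(
        i = bondable[hit[, 1]], j = bondable[hit[, 2]],
        order = "single", stringsAsFactors = FALSE
      )
    }
  }
  bonds
}

PROT_AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

PROT_CHARGED_ATOMS <- list(
  LYS = c(NZ = 1), ARG = c(NH1 = 1, NH2 = 1),
  ASP = c(OD1 = -1, OD2 = -1), GLU = c(OE1 = -1, OE2 = -1)
)

# Explicit hydrogen counts for atoms whose valence-model fallback is wrong
# without bond orders (carbonyl/carboxylate oxygens, amides, etc.)
PROT_NUMH_ATOMS <- list(
  ALL = c(O = 0, OXT = 0, C = 0),
  ASP = c(OD1 = 0, OD2 = 0), GLU = c(OE1 = 0, OE2 = 0),
  ASN = c(OD1 = 0, ND2 = 2), GLN = c(OE1 = 0, NE2 = 2),
  ARG = c(NE = 1, NH1 = 2, NH2 = 2, CZ = 0), LYS = c(NZ = 3),
  HIS = c(ND1 = 1, NE2 = 0), TRP = c(NE1 = 1), MET = c(SD = 0),
  SER = c(OG = 1), THR = c(OG1 = 1), TYR = c(OH = 1), CYS = c(SG = 1)
)

PROT_SP2_ATOMS <- list(
  ALL = c("C", "O", "OXT"),
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"),
  ASN = c("CG", "OD1", "ND2"), GLN = c("CD", "OE1", "NE2"),
  ARG = c("CZ", "NE", "NH1", "NH2")
)

protein_annotations <- function(atoms, bonds) {
  n <- nrow(atoms)
  deg <- integer(n)
  if (nrow(bonds) > 0) {
    deg <- as.integer(table(factor(c(bonds$i, bonds$j), levels = seq_len(n))))
  }
  res <- atoms$residue_name
  name <- atoms$atom_name
  elem <- atoms$element

  aromatic <- vapply(seq_len(n), function(k) {
    name[k] %in% (PROT_AROMATIC_ATOMS[[res[k]]] %||% character(0))
  }, logical(1))

  charge <- vapply(seq_len(n), function(k) {
    ch <- PROT_CHARGED_ATOMS[[res[k]]] %||% numeric(0)
    unname(ch[name[k]] %||% 0) %|NA|% 0
  }, numeric(1))
  is_metal <- elem %in% METAL_ELEMENTS
  charge[is_metal] <- ifelse(elem[is_metal] %in% c("Na", "K"), 1, 2)

  num_h <- vapply(seq_len(n), function(k) {
    tab <- c(PROT_NUMH_ATOMS[[res[k]]] %||% numeric(0), PROT_NUMH_ATOMS$ALL)
    v <- tab[name[k]]
    if (!is.na(v <- unname(v))) return(v)
    val <- DEFAULT_VALENCE[elem[k]]
    if (is.na(val)) return(0)
    max(0, val - deg[k] - as.integer(aromatic[k]))
  }, numeric(1))

  hyb <- vapply(seq_len(n), function(k) {
    if (is_metal[k]) return("other")
    if (aromatic[k]) return("sp2")
    sp2 <- c(PROT_SP2_ATOMS[[res[k]]] %||% character(0), PROT_SP2_ATOMS$ALL)
    if (name[k] %in% sp2) "sp2" else "sp3"
  }, character(1))

  list(aromatic = aromatic, charge = charge, num_h = num_h, hybridization = hyb)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

normalize_element <- function(elesy, elety) {
  e <- trimws(elesy)
  missing <- is.na(e) | e == ""
  # fall back to the leading letters of the atom name
  e[missing] <- sub("[^A-Za-z].*$", "", trimws(elety[missing]))
  e[missing] <- substr(e[missing], 1, 2)
  out <- paste0(toupper(substring(e, 1, 1)), tolower(substring(e, 2)))
  # single-letter organic elements mis-read as two letters (e.g. "CA" calcium
  # vs alpha carbon) are resolved by trusting the element column when present
  known <- c(names(COVALENT_RADIUS), METAL_ELEMENTS, "H", "D")
  fix <- !(out %in% known) & nchar(out) == 2
  out[fix] <- substr(out[fix], 1, 1)
  out
}

#' Convert a measured affinity to the pK scale
#'
#' Ki, Kd and IC50 measurements are treated interchangeably and mapped to
#' `-log10` of the molar value.
#'
#' @param value positive affinity value
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`
#' @param kind one of `"Ki"`, `"Kd"`, `"IC50"` (recorded, not transformed)
#' @return pK value (dimensionless)
#' @export
#' @examples
#' affinity_to_pk(1, "nM", "Ki") # 9
affinity_to_pk <- function(value, unit = c("M", "mM", "uM", "nM", "pM"),
                           kind = c("Ki", "Kd", "IC50")) {
  unit <- match.arg(unit)
  kind <- match.arg(kind)
  if (!is.finite(value) || value <= 0) {
    lgn_stop("affinity value must be positive and finite, got %s", value)
  }
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  -log10(value * scale)
}

#' Parse an affinity index file
#'
#' Reads a whitespace-delimited index in the PDBbind dialect: columns are
#' complex ID, resolution, deposit year and pK (`-logKd/Ki`), optionally
#' followed by a `Kd=...` / `Ki=...` / `IC50=...` annotation. Lines starting
#' with `#` are comments. When an ID occurs more than once the last
#' occurrence wins (with a warning).
#'
#' @param path index file path
#' @return data.frame with columns `complex_id`, `label_pk`, `measure_kind`,
#'   `deposit_year`
#' @export
parse_index <- function(path) {
  if (!file.exists(path)) lgn_stop("index file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  recs <- lapply(keep, function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 4) lgn_stop("malformed index line %d: %s", ln, lines[ln])
    year <- suppressWarnings(as.integer(f[3]))
    pk <- suppressWarnings(as.numeric(f[4]))
    if (is.na(pk)) lgn_stop("malformed index line %d: bad pK value", ln)
    kind <- NA_character_
    if (length(f) >= 5) {
      m <- regmatches(f[5], regexpr("^(Ki|Kd|IC50)", f[5]))
      if (length(m)) kind <- m
    }
    data.frame(
      complex_id = f[1], label_pk = pk, measure_kind = kind,
      deposit_year = year, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs) %||% data.frame(
    complex_id = character(), label_pk = numeric(),
    measure_kind = character(), deposit_year = integer()
  )
  if (nrow(out) > 0 && anyDuplicated(out$complex_id)) {
    dups <- unique(out$complex_id[duplicated(out$complex_id)])
    lgn_warn("duplicated complex IDs (%s); keeping last occurrence",
             paste(dups, collapse = ", "))
    out <- out[!duplicated(out$complex_id, fromLast = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a ligand Molecule as SDF
#'
#' V2000 connection table with aromatic bonds as type 4 and formal charges
#' in an `M  CHG` block. Round-trips through [read_ligand()].
#'
#' @param mol a ligand [Molecule]
#' @param path output file path
#' @param title molecule title line
#' @export
write_sdf <- function(mol, path, title = "ligand") {
  a <- mol$atoms
  b <- mol$bonds
  order_num <- c(single = 1, double = 2, triple = 3, aromatic = 4)
  lines <- c(
    title, "  lgn", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, a$element
    ),
    if (nrow(b) > 0) {
      sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, order_num[b$order])
    }
  )
  chg <- which(a$formal_charge != 0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste(sprintf("%4d%4d", grp, a$formal_charge[grp]), collapse = "")
      ))
    }
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}

#' Write a pocket Molecule as PDB
#'
#' @param mol a protein [Molecule]
#' @param path output file path
#' @export
write_pocket_pdb <- function(mol, path) {
  a <- mol$atoms
  std <- a$residue_name %in% names(AA3)
  rec <- ifelse(std, "ATOM  ", "HETATM")
  lines <- sprintf(
    "%s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    rec, seq_len(nrow(a)), substr(a$atom_name, 1, 4), a$residue_name,
    a$residue_id, a$x, a$y, a$z, toupper(a$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Amino-acid sequence of a pocket
#'
#' One-letter residue codes in residue-number order; non-standard residues
#' are skipped.
#'
#' @param pocket a protein [Molecule]
#' @return character scalar
#' @export
pocket_sequence <- function(pocket) {
  a <- pocket$atoms
  res <- unique(a[, c("residue_id", "residue_name")])
  res <- res[order(res$residue_id), ]
  paste(stats::na.omit(AA3[res$residue_name]), collapse = "")
}
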