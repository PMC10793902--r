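#' Synthetic protein-ligand complexes with a planted affinity signal
#'
#' The generator emulates, at desk scale, the inputs a structure-based
#' scoring function consumes: a drug-like heavy-atom ligand embedded in 3D
#' and a shell of amino-acid fragments forming a pocket around it, plus an
#' affinity label constructed from interpretable structural quantities
#' (protein-ligand contact count and ligand H-bond donor count) with
#' Gaussian noise. Both the complex-graph branch and the interaction
#' fingerprints carry the signal, while the ligand alone carries only part
#' of it, mirroring the ablation structure of fusion scoring models.
#'
#' @param n_complexes number of complexes
#' @param seed integer seed; the full dataset is a pure function of the spec
#' @param ligand_size_range heavy-atom count range for ligands
#' @param pocket_residues_range residue-count range for pockets
#' @param noise_sd label noise standard deviation, pK units
#' @param signal_coeffs numeric `c(a, b)`: pK per heavy-atom contact within
#'   5 Angstrom, and pK per ligand H-bond donor
#' @return an object of class `lgn_spec` to pass to [gen_dataset()]
#' @export
synthetic_spec <- function(n_complexes = 400, seed = 1,
                           ligand_size_range = c(10, 40),
                           pocket_residues_range = c(15, 40),
                           noise_sd = 0.3,
                           signal_coeffs = c(a = 0.025, b = 0.15)) {
  stopifnot(
    n_complexes >= 1, noise_sd >= 0,
    ligand_size_range[1] >= 1, pocket_residues_range[1] >= 1
  )
  structure(
    list(
      n_complexes = n_complexes, seed = seed,
      ligand_size_range = ligand_size_range,
      pocket_residues_range = pocket_residues_range,
      noise_sd = noise_sd, signal_coeffs = signal_coeffs
    ),
    class = "lgn_spec"
  )
}

LIGAND_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl")
LIGAND_ELEMENT_P <- c(0.70, 0.12, 0.12, 0.03, 0.02, 0.01)

#' Generate a random drug-like ligand
#'
#' Random tree-plus-rings molecular graph over C/N/O/S/F/Cl with valence
#' bookkeeping, occasional double bonds, an optional planar aromatic
#' six-ring, and sparse formal charges; embedded in 3D with ~1.5 Angstrom
#' bonds. Deterministic per seed.
#'
#' @param seed integer seed
#' @param size heavy-atom count (>= 1)
#' @return a ligand [Molecule]
#' @export
gen_ligand <- function(seed, size) {
  stopifnot(size >= 1)
  with_seed(seed, gen_ligand_impl(size))
}

gen_ligand_impl <- function(size) {
  elem <- character(size)
  xyz <- matrix(0, size, 3)
  charge <- numeric(size)
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      stringsAsFactors = FALSE)
  free <- numeric(size) # remaining valence

  place_near <- function(anchor) {
    for (try in 1:30) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      p <- xyz[anchor, ] + dir * 1.5
      placed <- xyz[seq_len(n_placed), , drop = FALSE]
      if (min(cross_dist(matrix(p, 1), placed)) > 1.2) return(p)
    }
    xyz[anchor, ] + stats::rnorm(3, sd = 0.1) + c(1.5, 0, 0)
  }

  # optional planted benzene ring for aromatic interactions
  use_ring <- size >= 8 && stats::runif(1) < 0.6
  n_placed <- 0
  if (use_ring) {
    basis <- pracma_orth(stats::rnorm(3))
    for (k in 1:6) {
      ang <- 2 * pi * (k - 1) / 6
      elem[k] <- "C"
      xyz[k, ] <- 1.39 * (cos(ang) * basis[, 1] + sin(ang) * basis[, 2])
      free[k] <- 1 # one substituent slot besides the two ring bonds and H
    }
    ring_bonds <- data.frame(
      i = 1:6, j = c(2:6, 1), order = "aromatic", stringsAsFactors = FALSE
    )
    bonds <- ring_bonds
    n_placed <- 6
  } else {
    elem[1] <- sample(LIGAND_ELEMENTS, 1, prob = LIGAND_ELEMENT_P)
    free[1] <- DEFAULT_VALENCE[elem[1]]
    n_placed <- 1
  }

  while (n_placed < size) {
    open <- which(free[seq_len(n_placed)] >= 1)
    if (length(open) == 0) { # everything saturated: grant one slot on a carbon
      fallback <- which(elem[seq_len(n_placed)] == "C")
      if (length(fallback) == 0) fallback <- 1L
      free[fallback[1]] <- free[fallback[1]] + 1
      open <- fallback[1]
    }
    anchor <- open[sample.int(length(open), 1)]
    k <- n_placed + 1
    elem[k] <- sample(LIGAND_ELEMENTS, 1, prob = LIGAND_ELEMENT_P)
    free[k] <- DEFAULT_VALENCE[elem[k]]
    xyz[k, ] <- place_near(anchor)
    ord <- "single"
    # occasional double bond where both sides can afford it
    if (free[anchor] >= 2 && free[k] >= 2 && elem[k] %in% c("C", "N", "O") &&
        stats::runif(1) < 0.12) {
      ord <- "double"
    }
    used <- BOND_ORDER_VALUE[ord]
    free[anchor] <- free[anchor] - used
    free[k] <- free[k] - used
    bonds <- rbind(bonds, data.frame(i = anchor, j = k, order = ord,
                                     stringsAsFactors = FALSE))
    n_placed <- k
  }

  # sparse formal charges: a terminal anionic oxygen, a cationic nitrogen
  term_o <- which(elem == "O" & tabulate(c(bonds$i, bonds$j), size) == 1)
  if (length(term_o) > 0 && stats::runif(1) < 0.35) {
    pick <- term_o[sample.int(length(term_o), 1)]
    if (bonds$order[bonds$i == pick | bonds$j == pick][1] == "single") {
      charge[pick] <- -1
    }
  }
  nit <- which(elem == "N" & free > 0)
  if (length(nit) > 0 && stats::runif(1) < 0.25) {
    charge[nit[sample.int(length(nit), 1)]] <- 1
  }

  Molecule(
    data.frame(
      element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      formal_charge = charge, is_protein = FALSE, stringsAsFactors = FALSE
    ),
    bonds
  )
}

# Orthonormal basis of the plane perpendicular to v (3 x 2 matrix).
pracma_orth <- function(v) {
  v <- v / sqrt(sum(v^2))
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- u - sum(u * v) * v
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(
    v[2] * b1[3] - v[3] * b1[2],
    v[3] * b1[1] - v[1] * b1[3],
    v[1] * b1[2] - v[2] * b1[1]
  )
  cbind(b1, b2)
}

# ---- residue templates ----------------------------------------------------

# Side chains as parent trees: "child>parent". A "ring6:"/"ring5:" item hangs
# a planar polygon off the named parent (first listed ring atom bonds the
# parent). Geometry is schematic but tetrahedral branching keeps every
# non-bonded intra-template pair above bond-perception range.
SIDE_CHAINS <- list(
  GLY = character(0),
  ALA = "CB>CA", SER = c("CB>CA", "OG>CB"), CYS = c("CB>CA", "SG>CB"),
  THR = c("CB>CA", "OG1>CB", "CG2>CB"), VAL = c("CB>CA", "CG1>CB", "CG2>CB"),
  LEU = c("CB>CA", "CG>CB", "CD1>CG", "CD2>CG"),
  ILE = c("CB>CA", "CG1>CB", "CG2>CB", "CD1>CG1"),
  MET = c("CB>CA", "CG>CB", "SD>CG", "CE>SD"),
  ASP = c("CB>CA", "CG>CB", "OD1>CG", "OD2>CG"),
  ASN = c("CB>CA", "CG>CB", "OD1>CG", "ND2>CG"),
  GLU = c("CB>CA", "CG>CB", "CD>CG", "OE1>CD", "OE2>CD"),
  GLN = c("CB>CA", "CG>CB", "CD>CG", "OE1>CD", "NE2>CD"),
  LYS = c("CB>CA", "CG>CB", "CD>CG", "CE>CD", "NZ>CE"),
  ARG = c("CB>CA", "CG>CB", "CD>CG", "NE>CD", "CZ>NE", "NH1>CZ", "NH2>CZ"),
  PRO = c("CB>CA", "CG>CB", "CD>CG"),
  PHE = c("CB>CA", "ring6:CB:CG,CD1,CE1,CZ,CE2,CD2"),
  TYR = c("CB>CA", "ring6:CB:CG,CD1,CE1,CZ,CE2,CD2", "OH>CZ"),
  TRP = c("CB>CA", "ring5:CB:CG,CD1,NE1,CE2,CD2"),
  HIS = c("CB>CA", "ring5:CB:CG,ND1,CE1,NE2,CD2")
)

# Build local template coordinates for one residue type. Each atom carries an
# outgoing direction; children leave at ~109.5 degrees from the incoming bond,
# successive siblings rotated 120 degrees about it.
residue_template <- function(res) {
  name <- "N"
  pos <- matrix(c(0, 0, 0), 1, 3)
  dir <- matrix(c(1, 0, 0), 1, 3)
  n_children <- 0L
  depth <- 0L      # generation, for alternating (trans) chain dihedrals
  on_ring <- FALSE # ring atoms emit substituents radially

  perp_basis <- function(d) {
    u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- u - sum(u * d) * d
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    cbind(e1, e2)
  }
  add_child <- function(child, parent) {
    p <- match(parent, name)
    d <- dir[p, ]
    if (on_ring[p]) {
      nd <- d # radial continuation off a ring atom
    } else {
      e <- perp_basis(d)
      # trans backbone: odd generations flip the in-plane component, so a
      # slot-0 chain zig-zags instead of curling into a polygon
      phi <- n_children[p] * 2 * pi / 3 + (depth[p] %% 2L) * pi
      alpha <- 70.5 * pi / 180 # keeps ~109.5 degree bond angles
      nd <- cos(alpha) * d + sin(alpha) * (cos(phi) * e[, 1] + sin(phi) * e[, 2])
      nd <- nd / sqrt(sum(nd^2))
    }
    name <<- c(name, child)
    pos <<- rbind(pos, pos[p, ] + 1.5 * nd)
    dir <<- rbind(dir, nd)
    n_children[p] <<- n_children[p] + 1L
    n_children <<- c(n_children, 0L)
    depth <<- c(depth, depth[p] + 1L)
    on_ring <<- c(on_ring, FALSE)
  }
  add_ring <- function(attach, atoms, sz) {
    p <- match(attach, name)
    d <- dir[p, ]
    e <- perp_basis(d)
    rad <- if (sz == 6) 1.39 else 1.19
    centre <- pos[p, ] + (1.5 + rad) * d
    for (q in seq_along(atoms)) {
      th <- 2 * pi * (q - 1) / sz
      v <- -cos(th) * d + sin(th) * e[, 1]
      name <<- c(name, atoms[q])
      pos <<- rbind(pos, centre + rad * v)
      dir <<- rbind(dir, v)
      n_children <<- c(n_children, 0L)
      depth <<- c(depth, depth[p] + 1L)
      on_ring <<- c(on_ring, TRUE)
    }
    n_children[p] <<- n_children[p] + 1L
  }

  add_child("CA", "N")
  add_child("C", "CA")
  add_child("O", "C")
  for (it in SIDE_CHAINS[[res]]) {
    if (grepl("^ring", it)) {
      f <- strsplit(it, ":")[[1]]
      add_ring(f[2], strsplit(f[3], ",")[[1]], as.integer(substr(f[1], 5, 5)))
    } else {
      f <- strsplit(it, ">")[[1]]
      add_child(f[1], f[2])
    }
  }
  list(name = name, xyz = pos)
}

.template_cache <- new.env(parent = emptyenv())
residue_template_cached <- function(res) {
  if (is.null(.template_cache[[res]])) {
    t <- residue_template(res)
    t$xyz <- t$xyz - matrix(t$xyz[2, ], nrow(t$xyz), 3, byrow = TRUE) # CA origin
    .template_cache[[res]] <- t
  }
  .template_cache[[res]]
}

#' Generate a pocket shell around a ligand
#'
#' Places `n_residues` random amino-acid fragments (correct residue names and
#' typical side-chain atoms) on a shell 3-8 Angstrom from the ligand, with no
#' steric clash below 2 Angstrom between the pocket and the ligand or between
#' fragments, and every pocket atom within 12 Angstrom of some ligand atom.
#'
#' @param ligand an embedded ligand [Molecule]
#' @param seed integer seed
#' @param n_residues number of residues to place
#' @return a protein [Molecule]
#' @export
gen_pocket <- function(ligand, seed, n_residues) {
  with_seed(seed, gen_pocket_impl(ligand, n_residues))
}

gen_pocket_impl <- function(ligand, n_residues) {
  lig_xyz <- coords(ligand)
  placed_xyz <- matrix(numeric(0), 0, 3)
  out_name <- character(0)
  out_elem <- character(0)
  out_res <- character(0)
  out_resid <- integer(0)
  out_xyz <- matrix(numeric(0), 0, 3)
  res_types <- names(SIDE_CHAINS)
  k <- 0
  tries <- 0
  while (k < n_residues) {
    tries <- tries + 1
    if (tries > n_residues * 400) {
      lgn_stop("pocket placement failed after %d attempts", tries)
    }
    res <- sample(res_types, 1)
    tmpl <- residue_template_cached(res)
    rot <- random_rotation()
    loc <- tmpl$xyz %*% rot # template is pre-centred on CA
    anchor_atom <- lig_xyz[sample.int(nrow(lig_xyz), 1), ]
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    d <- stats::runif(1, 3.0, 8.0)
    ctr <- anchor_atom + dir * d
    cand <- loc + matrix(ctr, nrow(loc), 3, byrow = TRUE)
    # clash / span checks; fragments may pack closer to each other than to
    # the ligand (real pockets are covalently chained and denser)
    dl <- cross_dist(cand, lig_xyz)
    if (min(dl) < 2.6) next
    row_min <- dl[cbind(seq_len(nrow(dl)), max.col(-dl))]
    if (max(row_min) > 12) next
    if (nrow(placed_xyz) > 0 && min(cross_dist(cand, placed_xyz)) < 2.2) next
    k <- k + 1
    elem <- substr(tmpl$name, 1, 1) # atom names start with the element letter
    out_name <- c(out_name, tmpl$name)
    out_elem <- c(out_elem, elem)
    out_res <- c(out_res, rep(res, length(tmpl$name)))
    out_resid <- c(out_resid, rep(k, length(tmpl$name)))
    out_xyz <- rbind(out_xyz, cand)
    placed_xyz <- rbind(placed_xyz, cand)
  }
  build_pocket_molecule(
    element = out_elem, x = out_xyz[, 1], y = out_xyz[, 2], z = out_xyz[, 3],
    residue_name = out_res, residue_id = out_resid, atom_name = out_name
  )
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Count protein-ligand heavy-atom contacts
#'
#' Brute-force count of (pocket atom, ligand atom) pairs within `cutoff`
#' Angstrom; the same rule the planted affinity signal and the complex-graph
#' intermolecular edges use.
#'
#' @param pocket,ligand [Molecule]s
#' @param cutoff distance cutoff in Angstrom
#' @return integer pair count
#' @export
count_contacts <- function(pocket, ligand, cutoff = 5.0) {
  sum(cross_dist(coords(pocket), coords(ligand)) <= cutoff)
}

# Ligand H-bond donor count: N/O/S heavy atoms with at least one implicit H.
count_donors <- function(ligand) {
  a <- ligand$atoms
  sum(a$element %in% c("N", "O", "S") & a$num_h >= 1)
}

#' Generate a synthetic dataset
#'
#' For each complex the affinity label is
#' `a * contacts(<=5 A) + b * donors + N(0, noise_sd)`, clipped to the
#' empirical pK range 0-16 of real affinity data. Measurement kinds, deposit
#' years and a refined-quality flag are drawn per complex so splitting
#' protocols are exercisable.
#'
#' @param spec an [synthetic_spec()] object
#' @return list with `complexes` (list of `list(pocket, ligand)`) and
#'   `records` (data.frame: `complex_id`, `label_pk`, `measure_kind`,
#'   `deposit_year`, `refined`, `contacts`, `donors`)
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "lgn_spec"))
  with_seed(spec$seed, {
    n <- spec$n_complexes
    sizes <- sample(spec$ligand_size_range[1]:spec$ligand_size_range[2], n,
                    replace = TRUE)
    nres <- sample(spec$pocket_residues_range[1]:spec$pocket_residues_range[2],
                   n, replace = TRUE)
    # a 3-8 A shell around a small ligand cannot hold arbitrarily many
    # fragments; cap occupancy with ligand size, as real pockets do
    nres <- pmin(nres, 12L + sizes)
    sub_seeds <- sample.int(2^31 - 1, 2 * n)
    noise <- stats::rnorm(n, 0, spec$noise_sd)
    kinds <- sample(c("Ki", "Kd", "IC50"), n, TRUE, prob = c(0.3, 0.3, 0.4))
    years <- sample(2008:2023, n, TRUE)
    refined <- stats::runif(n) < 0.4
    # the refined tier carries no IC50 measurements, as in curated corpora
    refined[kinds == "IC50"] <- FALSE
    complexes <- vector("list", n)
    lab <- numeric(n)
    contacts <- integer(n)
    donors <- integer(n)
    a <- spec$signal_coeffs[[1]]
    b <- spec$signal_coeffs[[2]]
    for (i in seq_len(n)) {
      lig <- gen_ligand(sub_seeds[2 * i - 1], sizes[i])
      # deterministic back-off: crowded draws retry with fewer residues
      poc <- NULL
      for (attempt in 0:3) {
        poc <- tryCatch(
          gen_pocket(lig, (sub_seeds[2 * i] + attempt * 7919) %% 2147483646 + 1,
                     max(spec$pocket_residues_range[1], nres[i] - 4 * attempt)),
          error = function(e) NULL
        )
        if (!is.null(poc)) break
      }
      if (is.null(poc)) {
        lgn_stop("pocket generation failed for complex %d after back-off", i)
      }
      complexes[[i]] <- list(pocket = poc, ligand = lig)
      contacts[i] <- count_contacts(poc, lig)
      donors[i] <- count_donors(lig)
      lab[i] <- min(16, max(0, a * contacts[i] + b * donors[i] + noise[i]))
    }
    records <- data.frame(
      complex_id = sprintf("syn%04d", seq_len(n)), label_pk = lab,
      measure_kind = kinds, deposit_year = years, refined = refined,
      contacts = contacts, donors = donors, stringsAsFactors = FALSE
    )
    list(complexes = complexes, records = records)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits `<id>_pocket.pdb`, `<id>_ligand.sdf` and an `INDEX` file in the
#' dialects [read_pocket()], [read_ligand()] and [parse_index()] consume.
#'
#' @param dataset result of [gen_dataset()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- dataset$records
  for (i in seq_len(nrow(r))) {
    id <- r$complex_id[i]
    write_pocket_pdb(dataset$complexes[[i]]$pocket,
                     file.path(dir, paste0(id, "_pocket.pdb")))
    write_sdf(dataset$complexes[[i]]$ligand,
              file.path(dir, paste0(id, "_ligand.sdf")), title = id)
  }
  lines <- c(
    "# synthetic affinity index: id resolution year pK kind",
    sprintf("%s  2.00  %d  %.2f  %s=%.3guM", r$complex_id, r$deposit_year,
            r$label_pk, r$measure_kind, 10^(-r$label_pk) * 1e6)
  )
  writeLines(lines, file.path(dir, "INDEX"))
  invisible(dir)
}
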