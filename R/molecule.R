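#' Molecule container
#'
#' A `Molecule` holds the heavy atoms and covalent bonds of one structure
#' (ligand or protein pocket). Hydrogens are never stored as atoms; they enter
#' only through the per-atom `num_h` count derived from a standard valence
#' model. Coordinates are in Angstrom.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `formal_charge`, `num_h`, `chirality` (`"R"`, `"S"` or `"other"`),
#'   `hybridization`, `residue_name`, `residue_id`, `atom_name`, `is_protein`.
#'   Derived columns (`degree`, `aromatic`, `in_ring`) are recomputed.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (`"single"`, `"double"`, `"triple"`, `"aromatic"`); `conjugated`
#'   and `in_ring` are recomputed unless supplied.
#' @return object of class `Molecule`
#' @export
Molecule <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  defaults <- list(
    formal_charge = 0, num_h = NA_real_, chirality = "other",
    hybridization = NA_character_, residue_name = NA_character_,
    residue_id = NA_integer_, atom_name = NA_character_, is_protein = FALSE
  )
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- rep(defaults[[nm]], nrow(atoms))
  }
  if (nrow(bonds) == 0) {
    bonds <- data.frame(
      i = integer(), j = integer(), order = character(),
      conjugated = logical(), in_ring = logical(), stringsAsFactors = FALSE
    )
  }
  mol <- structure(list(atoms = atoms, bonds = bonds), class = "Molecule")
  validate_molecule(mol)
  annotate_molecule(mol)
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf(
    "<Molecule: %d heavy atoms, %d bonds, %s>\n", n_atoms(x), nrow(x$bonds),
    if (any(x$atoms$is_protein)) "protein" else "ligand"
  ))
  invisible(x)
}

#' @rdname Molecule
#' @param mol a `Molecule`
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

validate_molecule <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  if (nrow(a) == 0) lgn_stop("Molecule has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) lgn_stop("non-finite atom coordinates")
  if (any(a$element == "H")) lgn_stop("hydrogens must not be stored as atoms")
  if (nrow(b) > 0) {
    if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a))) {
      lgn_stop("bond endpoint indexes an invalid atom")
    }
    if (any(b$i == b$j)) lgn_stop("self-bond found")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) lgn_stop("duplicate undirected bond found")
    if (!all(b$order %in% c("single", "double", "triple", "aromatic"))) {
      lgn_stop("unknown bond order")
    }
  }
  invisible(mol)
}

# Recompute derived annotations: degree, ring membership, aromaticity
# propagation, conjugation, implicit hydrogen counts and hybridization.
# Explicitly supplied num_h / hybridization values are kept.
annotate_molecule <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  deg <- integer(n)
  if (nrow(b) > 0) {
    t <- table(factor(c(b$i, b$j), levels = seq_len(n)))
    deg <- as.integer(t)
  }
  a$degree <- deg

  ring <- ring_membership(n, b)
  b$in_ring <- ring$edge
  a$in_ring <- ring$atom

  # aromatic: explicit aromatic bonds, plus Kekule 6-rings of alternating
  # single/double bonds (isolated rings only; fused aromatics need explicit
  # aromatic bond orders)
  arom_edge <- b$order == "aromatic"
  if (nrow(b) > 0) {
    kek <- kekule_aromatic_edges(n, b)
    arom_edge <- arom_edge | kek
    b$order[kek] <- "aromatic"
  }
  arom_atom <- logical(n)
  if (any(arom_edge)) arom_atom[unique(c(b$i[arom_edge], b$j[arom_edge]))] <- TRUE
  a$aromatic <- arom_atom

  # bond order sum per atom (aromatic counts 1.5)
  bos <- numeric(n)
  if (nrow(b) > 0) {
    v <- BOND_ORDER_VALUE[b$order]
    bos <- rowsum_vec(c(v, v), c(b$i, b$j), n)
  }

  need_h <- is.na(a$num_h)
  if (any(need_h)) {
    val <- DEFAULT_VALENCE[a$element]
    val[is.na(val)] <- 0 # metals / unknowns carry no implicit H
    chg <- a$formal_charge
    adj <- ifelse(a$element %in% c("N", "P"), chg,
      ifelse(a$element %in% c("O", "S"), chg, 0)
    )
    a$num_h[need_h] <- pmax(0, round(val + adj - bos))[need_h]
  }
  a$num_h <- as.integer(a$num_h)

  need_hyb <- is.na(a$hybridization)
  if (any(need_hyb)) {
    hyb <- rep("sp3", n)
    if (nrow(b) > 0) {
      has_triple <- rowsum_vec(
        c(b$order == "triple", b$order == "triple"), c(b$i, b$j), n
      ) > 0
      n_double <- rowsum_vec(
        c(b$order == "double", b$order == "double"), c(b$i, b$j), n
      )
      hyb[n_double > 0 | arom_atom] <- "sp2"
      hyb[has_triple | n_double >= 2] <- "sp"
    }
    hyb[a$element %in% METAL_ELEMENTS] <- "other"
    a$hybridization[need_hyb] <- hyb[need_hyb]
  }

  # conjugated: aromatic bonds, and multiple bonds / single bonds joining two
  # atoms that each carry a multiple bond
  if (nrow(b) > 0) {
    multi <- numeric(n)
    v <- b$order %in% c("double", "triple", "aromatic")
    multi <- rowsum_vec(c(v, v), c(b$i, b$j), n) > 0
    b$conjugated <- v | (multi[b$i] & multi[b$j])
  }

  mol$atoms <- a
  mol$bonds <- b
  mol
}

# Edge/atom ring membership: an edge is in a ring iff it is not a bridge.
ring_membership <- function(n, bonds) {
  if (nrow(bonds) == 0) {
    return(list(edge = logical(0), atom = logical(n)))
  }
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  edge_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  atom_ring <- logical(n)
  if (any(edge_ring)) {
    atom_ring[unique(c(bonds$i[edge_ring], bonds$j[edge_ring]))] <- TRUE
  }
  list(edge = edge_ring, atom = atom_ring)
}

# Mark edges of isolated six-membered carbon rings with alternating
# single/double Kekule bonds as aromatic.
kekule_aromatic_edges <- function(n, bonds) {
  out <- logical(nrow(bonds))
  ring_edges <- which(ring_membership(n, bonds)$edge)
  if (length(ring_edges) == 0) return(out)
  sub <- bonds[ring_edges, ]
  g <- igraph::graph_from_edgelist(cbind(sub$i, sub$j), directed = FALSE)
  comp <- igraph::components(g)
  for (k in seq_len(comp$no)) {
    vs <- as.integer(which(comp$membership == k))
    es <- which(sub$i %in% vs & sub$j %in% vs)
    if (length(vs) == 6 && length(es) == 6) {
      ord <- sort(sub$order[es])
      if (identical(ord, c(rep("double", 3), rep("single", 3)))) {
        out[ring_edges[es]] <- TRUE
      }
    }
  }
  out
}

# Undirected adjacency list of a Molecule (list of integer vectors).
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  adj
}
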