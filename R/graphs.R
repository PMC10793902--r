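#' Molecular graphs for the fusion model
#'
#' Two graph views of a protein-ligand complex feed the model: the
#' *complex graph* over all pocket and ligand heavy atoms (41-dimensional
#' node features, 21-dimensional edge features, covalent plus distance-based
#' intermolecular edges) and the *ligand graph* over ligand atoms only
#' (27-dimensional node features, no edge features). Every covalent bond
#' appears as two directed edges.
#'
#' @name molecular-graphs
NULL

COMPLEX_ELEMENTS <- c(
  "C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "B", "Si", "Fe", "Zn",
  "Cu", "Mn", "Mo", "Other"
)
LIGAND_ELEMENT_VOCAB <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "other")
HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
CHIRALITIES <- c("R", "S", "other")
RBF_CENTERS <- seq(1.0, 7.5, length.out = 14)
RBF_WIDTH <- RBF_CENTERS[2] - RBF_CENTERS[1]

COMPLEX_NODE_DIM <- 41L
COMPLEX_EDGE_DIM <- 21L
LIGAND_NODE_DIM <- 27L

# Version stamp coupling checkpoints to the featurization scheme.
FEATURIZATION_VERSION <- "complex41-edge21-ligand27-rbf14-v1"

#' Complex-graph node features (length 41)
#'
#' Fixed-order concatenation: element one-hot over the 17-symbol vocabulary
#' (17), degree one-hot 0-5 (6), formal charge as a real value (1),
#' chirality one-hot R/S/other (3), implicit-H count one-hot 0-4 (5),
#' hybridization one-hot sp/sp2/sp3/sp3d/sp3d2/other (6), aromatic flag (1),
#' in-ring flag (1), is-ligand-atom flag (1). Out-of-range degree and H
#' counts clamp; unknown elements map to "Other".
#'
#' @param atoms the `atoms` data.frame of a [Molecule] (one or more rows)
#' @return matrix `nrow(atoms)` x 41
#' @export
featurize_atom_complex <- function(atoms) {
  m <- cbind(
    one_hot(atoms$element, COMPLEX_ELEMENTS),
    one_hot(pmin(atoms$degree, 5), 0:5),
    atoms$formal_charge,
    one_hot(atoms$chirality, CHIRALITIES),
    one_hot(pmin(atoms$num_h, 4), 0:4),
    one_hot(atoms$hybridization, HYBRIDIZATIONS),
    as.numeric(atoms$aromatic),
    as.numeric(atoms$in_ring),
    as.numeric(!atoms$is_protein)
  )
  stopifnot(ncol(m) == COMPLEX_NODE_DIM)
  m
}

#' Complex-graph edge features (length 21)
#'
#' Concatenation: covalent flag (1), bond-order one-hot
#' single/double/triple/aromatic (4; all zero for intermolecular edges),
#' conjugated flag (1), in-ring flag (1), and a Gaussian radial basis of the
#' interatomic distance with 14 centers evenly spaced on 1.0-7.5 Angstrom,
#' width equal to the center spacing (14).
#'
#' @param covalent logical vector
#' @param order character vector of bond orders (`NA` for intermolecular)
#' @param conjugated,in_ring logical vectors (`FALSE` for intermolecular)
#' @param distance numeric vector, Angstrom
#' @return matrix `length(distance)` x 21
#' @export
featurize_edge_complex <- function(covalent, order, conjugated, in_ring,
                                   distance) {
  if (any(!is.finite(distance))) lgn_stop("non-finite edge distance")
  ord <- matrix(0, length(distance), 4)
  lv <- c("single", "double", "triple", "aromatic")
  hit <- !is.na(order)
  ord[cbind(which(hit), match(order[hit], lv))] <- 1
  rbf <- exp(-(outer(distance, RBF_CENTERS, "-"))^2 / (2 * RBF_WIDTH^2))
  m <- cbind(as.numeric(covalent), ord, as.numeric(conjugated),
             as.numeric(in_ring), rbf)
  stopifnot(ncol(m) == COMPLEX_EDGE_DIM)
  m
}

#' Ligand-graph node features (length 27)
#'
#' Concatenation: element one-hot C/N/O/S/F/P/Cl/Br/I/other (10), degree
#' one-hot 0-5 (6), formal charge (1), implicit-H one-hot 0-4 (5),
#' hybridization one-hot sp/sp2/sp3 (3), aromatic flag (1), in-ring flag (1).
#'
#' @param atoms the `atoms` data.frame of a ligand [Molecule]
#' @return matrix `nrow(atoms)` x 27
#' @export
featurize_atom_ligand <- function(atoms) {
  hyb <- matrix(0, nrow(atoms), 3)
  hit <- atoms$hybridization %in% c("sp", "sp2", "sp3")
  hyb[cbind(which(hit), match(atoms$hybridization[hit], c("sp", "sp2", "sp3")))] <- 1
  m <- cbind(
    one_hot(atoms$element, LIGAND_ELEMENT_VOCAB),
    one_hot(pmin(atoms$degree, 5), 0:5),
    atoms$formal_charge,
    one_hot(pmin(atoms$num_h, 4), 0:4),
    hyb,
    as.numeric(atoms$aromatic),
    as.numeric(atoms$in_ring)
  )
  stopifnot(ncol(m) == LIGAND_NODE_DIM)
  m
}

new_molecular_graph <- function(num_nodes, edges, node_features, edge_features,
                                tag) {
  structure(
    list(
      num_nodes = num_nodes, edges = edges, node_features = node_features,
      edge_features = edge_features, tag = tag,
      featurization = FEATURIZATION_VERSION
    ),
    class = "MolecularGraph"
  )
}

#' @export
print.MolecularGraph <- function(x, ...) {
  cat(sprintf(
    "<MolecularGraph[%s]: %d nodes, %d directed edges, node dim %d%s>\n",
    x$tag, x$num_nodes, nrow(x$edges), ncol(x$node_features),
    if (is.null(x$edge_features)) "" else sprintf(", edge dim %d", ncol(x$edge_features))
  ))
  invisible(x)
}

# Directed covalent edge list (both directions) with per-edge annotations.
covalent_edges <- function(mol, offset = 0L) {
  b <- mol$bonds
  if (nrow(b) == 0) {
    return(list(
      edges = matrix(integer(0), 0, 2), order = character(0),
      conjugated = logical(0), in_ring = logical(0), distance = numeric(0)
    ))
  }
  xyz <- coords(mol)
  d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
  list(
    edges = cbind(c(b$i, b$j), c(b$j, b$i)) + offset,
    order = rep(b$order, 2),
    conjugated = rep(b$conjugated, 2),
    in_ring = rep(b$in_ring, 2),
    distance = rep(d, 2)
  )
}

#' Build the complex graph
#'
#' Nodes are pocket atoms followed by ligand atoms. Edges are all covalent
#' bonds of both molecules (each as two directed edges) plus bidirectional
#' intermolecular edges between every protein-ligand heavy-atom pair within
#' `contact_cutoff`. A complex with zero intermolecular contacts is returned
#' with a warning.
#'
#' @param pocket,ligand [Molecule]s
#' @param contact_cutoff intermolecular distance cutoff, Angstrom
#' @return a `MolecularGraph` with tag `"complex"`
#' @export
build_complex_graph <- function(pocket, ligand, contact_cutoff = 5.0) {
  if (n_atoms(pocket) == 0 || n_atoms(ligand) == 0) {
    lgn_stop("empty pocket or ligand")
  }
  np <- n_atoms(pocket)
  nl <- n_atoms(ligand)
  pe <- covalent_edges(pocket)
  le <- covalent_edges(ligand, offset = np)
  d <- cross_dist(coords(pocket), coords(ligand))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    lgn_warn("no intermolecular contacts within %.1f Angstrom", contact_cutoff)
  }
  inter_src <- c(hit[, 1], np + hit[, 2])
  inter_dst <- c(np + hit[, 2], hit[, 1])
  inter_d <- rep(d[hit], 2)
  edges <- rbind(pe$edges, le$edges, cbind(inter_src, inter_dst))
  dimnames(edges) <- NULL
  n_inter <- length(inter_src)
  edge_features <- featurize_edge_complex(
    covalent = c(rep(TRUE, nrow(pe$edges) + nrow(le$edges)), rep(FALSE, n_inter)),
    order = c(pe$order, le$order, rep(NA_character_, n_inter)),
    conjugated = c(pe$conjugated, le$conjugated, rep(FALSE, n_inter)),
    in_ring = c(pe$in_ring, le$in_ring, rep(FALSE, n_inter)),
    distance = c(pe$distance, le$distance, inter_d)
  )
  node_features <- rbind(
    featurize_atom_complex(pocket$atoms),
    featurize_atom_complex(ligand$atoms)
  )
  new_molecular_graph(np + nl, edges, node_features, edge_features, "complex")
}

#' Build the ligand graph
#'
#' Ligand heavy atoms with bidirectional covalent edges and no edge
#' features; protein nodes are deliberately absent so the encoder sees the
#' small molecule alone.
#'
#' @param ligand a ligand [Molecule]
#' @return a `MolecularGraph` with tag `"ligand"`
#' @export
build_ligand_graph <- function(ligand) {
  if (n_atoms(ligand) == 0) lgn_stop("empty ligand")
  le <- covalent_edges(ligand)
  new_molecular_graph(
    n_atoms(ligand), le$edges, featurize_atom_ligand(ligand$atoms),
    NULL, "ligand"
  )
}

#' Save / load a molecular graph
#'
#' The graph (node features, directed edge index, edge features, tag) is
#' stored as an RDS container with a JSON sidecar (`<path>.json`) recording
#' the tag, sizes and featurization version for provenance. Loading refuses
#' a featurization-version mismatch.
#'
#' @param graph a `MolecularGraph`
#' @param path output path (conventionally `.rds`)
#' @return `path` (write) / the graph (read)
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "MolecularGraph"))
  saveRDS(graph, path)
  jsonlite::write_json(
    list(
      tag = graph$tag, num_nodes = graph$num_nodes,
      num_edges = nrow(graph$edges),
      node_dim = ncol(graph$node_features),
      edge_dim = if (is.null(graph$edge_features)) NULL else ncol(graph$edge_features),
      featurization = graph$featurization
    ),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "MolecularGraph")) lgn_stop("%s is not a MolecularGraph", path)
  if (!identical(g$featurization, FEATURIZATION_VERSION)) {
    lgn_stop("featurization version mismatch: file has %s, package uses %s",
             g$featurization, FEATURIZATION_VERSION)
  }
  g
}
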