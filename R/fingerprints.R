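#' Interaction and ligand fingerprints
#'
#' Three fingerprint families complement the graph encoders: SIFP, a
#' 168-slot count vector over 21 residue entries (20 amino acids + one
#' cofactor/other entry) times 8 interaction types; ECIF, counts of typed
#' protein-ligand atom pairs over a fixed 1746-pair vocabulary; and CFP, a
#' hashed circular (ECFP4-style) bit fingerprint of the ligand folded to
#' 2048 bits.
#'
#' @name fingerprints
NULL

SIFP_RESIDUES <- c(names(AA3), "OTH")
SIFP_TYPES <- c(
  "hydrophobic", "aromatic_f2f", "aromatic_e2f", "hbond_prot_donor",
  "hbond_lig_donor", "ionic_prot_cation", "ionic_prot_anion", "metal"
)
SIFP_LENGTH <- 168L
ECIF_LENGTH <- 1746L
CFP_BITS <- 2048L

# Geometric rule set (cutoffs in Angstrom). Hydrogens are implicit, so the
# H-bond angle criterion uses the donor's heavy-atom frame: the acceptor must
# not sit buried towards the donor's skeleton (max X-D-A angle >= 90 deg).
SIFP_RULES <- list(
  hydrophobic_cut = 4.5,
  aromatic_f2f_cut = 4.0, aromatic_f2f_angle = 30,
  aromatic_e2f_cut = 5.5,
  hbond_cut = 3.5, hbond_angle = 90,
  ionic_cut = 4.0,
  metal_cut = 2.8
)

# H-bond donors: N/O/S with at least one implicit H and zero formal charge
# (charged pairs are classified as ionic, not hydrogen bonds).
is_hb_donor <- function(atoms) {
  atoms$element %in% c("N", "O", "S") & atoms$num_h >= 1 &
    atoms$formal_charge == 0
}
# Acceptors: neutral N/O.
is_hb_acceptor <- function(atoms) {
  atoms$element %in% c("N", "O") & atoms$formal_charge == 0
}

# Aromatic ring systems of a molecule: connected components of aromatic
# atoms, returned as centroid + unit plane normal (SVD of centred coords).
aromatic_rings <- function(mol) {
  a <- mol$atoms
  idx <- which(a$aromatic)
  if (length(idx) < 3) return(list())
  b <- mol$bonds
  sub <- b[b$i %in% idx & b$j %in% idx, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(match(sub$i, idx), match(sub$j, idx)), directed = FALSE
  )
  if (igraph::vcount(g) < length(idx)) {
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    ring <- idx[comp$membership == k]
    if (length(ring) < 3) next
    xyz <- coords(mol)[ring, , drop = FALSE]
    ctr <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, ctr))
    out[[length(out) + 1]] <- list(
      atoms = ring, centroid = ctr, normal = sv$v[, 3]
    )
  }
  out
}

# Angle in degrees between two unit-ish vectors, folded to [0, 90].
plane_angle <- function(n1, n2) {
  ca <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, ca)) * 180 / pi
}

# Does any heavy neighbor X of donor d satisfy angle(X-d-acceptor) >= thr?
donor_angle_ok <- function(mol_adj, mol_xyz, d_idx, a_xyz, thr) {
  nb <- mol_adj[[d_idx]]
  if (length(nb) == 0) return(TRUE)
  v1 <- mol_xyz[nb, , drop = FALSE] -
    matrix(mol_xyz[d_idx, ], length(nb), 3, byrow = TRUE)
  v2 <- a_xyz - mol_xyz[d_idx, ]
  cosang <- (v1 %*% v2) / (sqrt(rowSums(v1^2)) * sqrt(sum(v2^2)))
  any(acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= thr)
}

#' Compute the SIFP interaction fingerprint
#'
#' Counts, for each of 21 residue entries (20 standard amino acids plus one
#' cofactor/other entry) and 8 interaction types (hydrophobic, aromatic
#' face-to-face, aromatic edge-to-face, H-bond donated by the protein,
#' H-bond donated by the ligand, ionic with protein cation, ionic with
#' protein anion, metal), the residues of that class engaging the ligand via
#' that type: one count per residue-type event. Slot order is residue-major.
#'
#' @param pocket protein [Molecule] with residue names
#' @param ligand ligand [Molecule]
#' @param rules geometric rule set (cutoffs/angles); the default follows the
#'   package's standard thresholds
#' @return integer vector of length 168
#' @export
compute_sifp <- function(pocket, ligand, rules = SIFP_RULES) {
  pa <- pocket$atoms
  if (anyNA(pa$residue_name)) lgn_stop("pocket atoms lack residue names")
  la <- ligand$atoms
  p_xyz <- coords(pocket)
  l_xyz <- coords(ligand)
  d <- cross_dist(p_xyz, l_xyz)
  r <- rules
  fp <- matrix(0L, length(SIFP_RESIDUES), length(SIFP_TYPES),
               dimnames = list(SIFP_RESIDUES, SIFP_TYPES))

  l_rings <- aromatic_rings(ligand)
  l_adj <- adjacency_list(ligand)
  p_adj <- adjacency_list(pocket)
  l_donor <- which(is_hb_donor(la))
  l_accept <- which(is_hb_acceptor(la))
  p_metal_lig <- which(la$element %in% c("N", "O", "S"))

  res_ids <- unique(pa$residue_id)
  for (rid in res_ids) {
    ratoms <- which(pa$residue_id == rid)
    rname <- pa$residue_name[ratoms[1]]
    entry <- if (rname %in% names(AA3)) rname else "OTH"
    dr <- d[ratoms, , drop = FALSE]

    # hydrophobic: C/S vs C/S contact
    ph <- pa$element[ratoms] %in% c("C", "S")
    lh <- la$element %in% c("C", "S")
    if (any(ph) && any(lh) &&
        min(dr[ph, lh, drop = FALSE]) <= r$hydrophobic_cut) {
      fp[entry, "hydrophobic"] <- fp[entry, "hydrophobic"] + 1L
    }

    # aromatic ring pairs
    r_arom <- ratoms[pa$aromatic[ratoms]]
    if (length(r_arom) >= 3 && length(l_rings) > 0) {
      xyz <- p_xyz[r_arom, , drop = FALSE]
      ctr <- colMeans(xyz)
      nrm <- svd(sweep(xyz, 2, ctr))$v[, 3]
      for (lr in l_rings) {
        cd <- sqrt(sum((ctr - lr$centroid)^2))
        ang <- plane_angle(nrm, lr$normal)
        if (cd <= r$aromatic_f2f_cut && ang < r$aromatic_f2f_angle) {
          fp[entry, "aromatic_f2f"] <- fp[entry, "aromatic_f2f"] + 1L
          break
        }
        if (cd <= r$aromatic_e2f_cut && ang >= r$aromatic_f2f_angle) {
          fp[entry, "aromatic_e2f"] <- fp[entry, "aromatic_e2f"] + 1L
          break
        }
      }
    }

    # H-bonds, protein donor -> ligand acceptor
    p_don <- ratoms[is_hb_donor(pa[ratoms, ])]
    hit <- FALSE
    for (dd in p_don) {
      if (hit) break
      for (aa in l_accept) {
        if (d[dd, aa] <= r$hbond_cut &&
            donor_angle_ok(p_adj, p_xyz, dd, l_xyz[aa, ], r$hbond_angle)) {
          fp[entry, "hbond_prot_donor"] <- fp[entry, "hbond_prot_donor"] + 1L
          hit <- TRUE
          break
        }
      }
    }
    # H-bonds, ligand donor -> protein acceptor
    p_acc <- ratoms[is_hb_acceptor(pa[ratoms, ])]
    hit <- FALSE
    for (dd in l_donor) {
      if (hit) break
      for (aa in p_acc) {
        if (d[aa, dd] <= r$hbond_cut &&
            donor_angle_ok(l_adj, l_xyz, dd, p_xyz[aa, ], r$hbond_angle)) {
          fp[entry, "hbond_lig_donor"] <- fp[entry, "hbond_lig_donor"] + 1L
          hit <- TRUE
          break
        }
      }
    }

    # ionic contacts
    p_chg <- pa$formal_charge[ratoms]
    if (any(p_chg > 0) && any(la$formal_charge < 0)) {
      dd <- dr[p_chg > 0, la$formal_charge < 0, drop = FALSE]
      if (min(dd) <= r$ionic_cut) {
        fp[entry, "ionic_prot_cation"] <- fp[entry, "ionic_prot_cation"] + 1L
      }
    }
    if (any(p_chg < 0) && any(la$formal_charge > 0)) {
      dd <- dr[p_chg < 0, la$formal_charge > 0, drop = FALSE]
      if (min(dd) <= r$ionic_cut) {
        fp[entry, "ionic_prot_anion"] <- fp[entry, "ionic_prot_anion"] + 1L
      }
    }

    # metal coordination
    pm <- pa$element[ratoms] %in% METAL_ELEMENTS
    if (any(pm) && length(p_metal_lig) > 0 &&
        min(dr[pm, p_metal_lig, drop = FALSE]) <= r$metal_cut) {
      fp[entry, "metal"] <- fp[entry, "metal"] + 1L
    }
  }
  out <- as.integer(t(fp))
  stopifnot(length(out) == SIFP_LENGTH)
  names(out) <- paste(rep(SIFP_RESIDUES, each = length(SIFP_TYPES)),
                      rep(SIFP_TYPES, length(SIFP_RESIDUES)), sep = ".")
  out
}

#' ECIF atom types
#'
#' The typed-atom string concatenates element, explicit valence (bond-order
#' sum plus implicit hydrogens), heavy-neighbor count, attached-H count,
#' aromaticity flag and ring flag, separated by semicolons.
#'
#' @param mol a [Molecule]
#' @return character vector, one type string per atom
#' @export
ecif_atom_type <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  bos <- numeric(n)
  if (nrow(b) > 0) {
    v <- BOND_ORDER_VALUE[b$order]
    bos <- rowsum_vec(c(v, v), c(b$i, b$j), n)
  }
  sprintf(
    "%s;%d;%d;%d;%d;%d", a$element, as.integer(round(bos + a$num_h)),
    a$degree, a$num_h, as.integer(a$aromatic), as.integer(a$in_ring)
  )
}

.ecif_vocab_cache <- new.env(parent = emptyenv())

#' ECIF pair vocabulary
#'
#' The ordered list of 1746 (protein type, ligand type) pairs shipped with
#' the package (`extdata/ecif_vocabulary.tsv`), generated once from a seed
#' corpus of synthetic complexes and frozen; it is canonical for this
#' implementation.
#'
#' @return data.frame with columns `protein` and `ligand`
#' @export
ecif_vocabulary <- function() {
  if (is.null(.ecif_vocab_cache$vocab)) {
    path <- system.file("extdata", "ecif_vocabulary.tsv", package = "lgn")
    if (!nzchar(path) || !file.exists(path)) {
      lgn_stop("ECIF vocabulary file not found in the installed package")
    }
    v <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(v) != ECIF_LENGTH) {
      lgn_stop("ECIF vocabulary must have %d pairs, found %d",
               ECIF_LENGTH, nrow(v))
    }
    .ecif_vocab_cache$vocab <- v
  }
  .ecif_vocab_cache$vocab
}

#' Compute the ECIF fingerprint
#'
#' Entry k counts (protein atom, ligand atom) pairs whose typed-atom strings
#' match vocabulary pair k and whose distance is at most `cutoff`. Pairs
#' outside the vocabulary are ignored (reported via `message()` when
#' `options(lgn.debug = TRUE)`).
#'
#' @param pocket,ligand [Molecule]s
#' @param cutoff distance cutoff, Angstrom
#' @return integer vector of length 1746
#' @export
compute_ecif <- function(pocket, ligand, cutoff = 6.0) {
  vocab <- ecif_vocabulary()
  pt <- ecif_atom_type(pocket)
  lt <- ecif_atom_type(ligand)
  d <- cross_dist(coords(pocket), coords(ligand))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  out <- integer(ECIF_LENGTH)
  if (nrow(hit) > 0) {
    key <- paste(pt[hit[, 1]], lt[hit[, 2]], sep = "-")
    vkey <- paste(vocab$protein, vocab$ligand, sep = "-")
    idx <- match(key, vkey)
    unknown <- sum(is.na(idx))
    if (unknown > 0 && isTRUE(getOption("lgn.debug", FALSE))) {
      message(sprintf("compute_ecif: %d pairs outside the vocabulary", unknown))
    }
    tab <- table(idx[!is.na(idx)])
    out[as.integer(names(tab))] <- as.integer(tab)
  }
  names(out) <- paste(vocab$protein, vocab$ligand, sep = "-")
  out
}

#' Compute the circular ligand fingerprint (CFP)
#'
#' Hashed circular fingerprint in the ECFP style: per-atom invariants
#' (element, degree, charge, implicit H, ring and aromatic flags) are
#' iteratively rehashed with sorted (bond order, neighbor invariant) pairs
#' for `radius` rounds; every intermediate invariant sets one bit modulo
#' `n_bits`.
#'
#' @param ligand a ligand [Molecule]
#' @param radius neighborhood radius (2 = ECFP4-like)
#' @param n_bits folded length
#' @return integer 0/1 vector of length `n_bits`
#' @export
compute_cfp <- function(ligand, radius = 2, n_bits = CFP_BITS) {
  a <- ligand$atoms
  n <- nrow(a)
  order_code <- c(single = 1, double = 2, triple = 3, aromatic = 4)
  inv <- vapply(seq_len(n), function(k) {
    hash_ints(c(
      match(a$element[k], c(LIGAND_ELEMENT_VOCAB, "Other")) %|NA|% 10,
      a$degree[k], a$formal_charge[k] + 10, a$num_h[k],
      as.integer(a$in_ring[k]), as.integer(a$aromatic[k])
    ))
  }, numeric(1))
  nb <- vector("list", n)
  for (k in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[k]; j <- ligand$bonds$j[k]
    o <- order_code[[ligand$bonds$order[k]]]
    nb[[i]] <- rbind(nb[[i]], c(o, j))
    nb[[j]] <- rbind(nb[[j]], c(o, i))
  }
  all_inv <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(k) {
      if (is.null(nb[[k]])) return(hash_ints(c(r, inv[k])))
      pairs <- cbind(nb[[k]][, 1], inv[nb[[k]][, 2]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_ints(c(r, inv[k], as.vector(t(pairs))))
    }, numeric(1))
    all_inv <- c(all_inv, inv)
  }
  bits <- integer(n_bits)
  bits[(all_inv %% n_bits) + 1] <- 1L
  bits
}

#' All three fingerprints of a complex
#'
#' @param pocket,ligand [Molecule]s
#' @return list with integer vectors `sifp` (168), `ecif` (1746), `cfp` (2048)
#' @export
compute_fingerprints <- function(pocket, ligand) {
  list(
    sifp = compute_sifp(pocket, ligand),
    ecif = compute_ecif(pocket, ligand),
    cfp = compute_cfp(ligand)
  )
}

#' Tanimoto similarity
#'
#' Generalized Tanimoto coefficient `sum(min) / sum(max)`, which reduces to
#' the usual `|intersection| / |union|` on bit vectors. Two all-zero vectors
#' compare as 0 with a warning.
#'
#' @param a,b equal-length non-negative numeric vectors
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) lgn_stop("fingerprint lengths differ")
  if (any(a < 0) || any(b < 0)) lgn_stop("fingerprints must be non-negative")
  den <- sum(pmax(a, b))
  if (den == 0) {
    lgn_warn("tanimoto of two all-zero vectors; returning 0")
    return(0)
  }
  sum(pmin(a, b)) / den
}
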