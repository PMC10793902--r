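#' Protein sequence similarity
#'
#' Global pairwise alignment identity: matches divided by alignment length,
#' with match score 1, mismatch 0 and gap penalty 0.5 per position.
#'
#' @param seq_a,seq_b amino-acid strings (one-letter codes)
#' @return similarity in `[0, 1]`
#' @export
protein_seq_similarity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) lgn_stop("empty protein sequence")
  alphabet <- c(unname(AA3), "X")
  mat <- matrix(0, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0.5
  )
  aligned_len <- nchar(as.character(Biostrings::pattern(aln)))
  Biostrings::nmatch(aln) / aligned_len
}

#' Similarity-controlled split specification
#'
#' Thresholds above which a training complex counts as *similar* to the test
#' set: 0.9 for protein sequence identity, 0.4 for ligand-fingerprint
#' Tanimoto, 0.65 for interaction-fingerprint Tanimoto. Mixtures always
#' total 3000 samples; the similar fraction runs over
#' 0, 0.2, 0.4, 0.6, 0.8, 1.
#'
#' @param mode one of `"similarity_mixture"`, `"size_variant"`, `"time"`,
#'   `"kfold"`
#' @param fraction_similar fraction of similar samples in the mixture
#' @param total mixture size
#' @param thresholds named vector `c(seq=, ligand=, ifp=)`
#' @param cutoff_year first test-set year for the time split
#' @param seed sampling seed
#' @return a `SplitSpec` object
#' @export
split_spec <- function(mode = c("similarity_mixture", "size_variant", "time",
                                "kfold"),
                       fraction_similar = 0, total = 3000L,
                       thresholds = c(seq = 0.9, ligand = 0.4, ifp = 0.65),
                       cutoff_year = 2019L, seed = 1L) {
  mode <- match.arg(mode)
  if (!isTRUE(any(abs(fraction_similar - c(0, .2, .4, .6, .8, 1)) < 1e-9))) {
    lgn_stop("fraction_similar must be one of 0, 0.2, 0.4, 0.6, 0.8, 1")
  }
  stopifnot(all(thresholds >= 0 & thresholds <= 1),
            all(c("seq", "ligand", "ifp") %in% names(thresholds)))
  structure(
    list(mode = mode, fraction_similar = fraction_similar,
         total = as.integer(total), thresholds = thresholds,
         cutoff_year = as.integer(cutoff_year), seed = as.integer(seed)),
    class = "SplitSpec"
  )
}

#' Per-complex descriptors for similarity profiling
#'
#' Pocket sequence, ligand circular fingerprint and interaction fingerprint
#' for every complex of a dataset.
#'
#' @param dataset result of [gen_dataset()] or equivalent
#' @return list of per-complex descriptor lists (`id`, `seq`, `cfp`, `sifp`)
#' @export
complex_descriptors <- function(dataset) {
  Map(function(cx, id) {
    list(
      id = id,
      seq = pocket_sequence(cx$pocket),
      cfp = compute_cfp(cx$ligand),
      sifp = compute_sifp(cx$pocket, cx$ligand)
    )
  }, dataset$complexes, dataset$records$complex_id)
}

#' Similarity profiles of a training pool against a test set
#'
#' Each training complex receives its *maximum* similarity to any test
#' complex on three axes: protein sequence identity, ligand circular
#' fingerprint Tanimoto, and interaction fingerprint Tanimoto.
#'
#' @param train_pool,test_set descriptor lists from [complex_descriptors()]
#' @return data.frame with `complex_id`, `seq_sim`, `lig_sim`, `ifp_sim`
#' @export
build_similarity_profiles <- function(train_pool, test_set) {
  if (length(test_set) == 0) lgn_stop("empty test set")
  for (d in c(train_pool, test_set)) {
    if (is.null(d$cfp) || is.null(d$sifp) || is.null(d$seq)) {
      lgn_stop("missing descriptor for complex %s", d$id %||% "<unnamed>")
    }
  }
  rows <- lapply(train_pool, function(tr) {
    seq_sim <- max(vapply(test_set, function(te) {
      protein_seq_similarity(tr$seq, te$seq)
    }, numeric(1)))
    lig_sim <- max(vapply(test_set, function(te) {
      suppressWarnings(tanimoto(tr$cfp, te$cfp))
    }, numeric(1)))
    ifp_sim <- max(vapply(test_set, function(te) {
      suppressWarnings(tanimoto(tr$sifp, te$sifp))
    }, numeric(1)))
    data.frame(complex_id = tr$id, seq_sim = seq_sim, lig_sim = lig_sim,
               ifp_sim = ifp_sim, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample a similarity-controlled training mixture
#'
#' Draws, without replacement, `round(fraction * total)` complexes from the
#' similar pool (axis similarity above the threshold) and the remainder from
#' the dissimilar pool.
#'
#' @param profiles data.frame from [build_similarity_profiles()]
#' @param axis `"seq"`, `"ligand"` or `"ifp"`
#' @param spec a [split_spec()]
#' @return list with `ids` (character) and `manifest` (composition counts)
#' @export
sample_mixture <- function(profiles, axis = c("seq", "ligand", "ifp"), spec) {
  axis <- match.arg(axis)
  col <- c(seq = "seq_sim", ligand = "lig_sim", ifp = "ifp_sim")[[axis]]
  thr <- spec$thresholds[[axis]]
  sim_pool <- profiles$complex_id[profiles[[col]] > thr]
  dis_pool <- profiles$complex_id[profiles[[col]] <= thr]
  n_sim <- round(spec$fraction_similar * spec$total)
  n_dis <- spec$total - n_sim
  if (length(sim_pool) < n_sim) {
    lgn_stop("similar pool too small: need %d, have %d (axis %s)",
             n_sim, length(sim_pool), axis)
  }
  if (length(dis_pool) < n_dis) {
    lgn_stop("dissimilar pool too small: need %d, have %d (axis %s)",
             n_dis, length(dis_pool), axis)
  }
  with_seed(spec$seed, {
    ids <- c(
      if (n_sim > 0) sample(sim_pool, n_sim) else character(0),
      if (n_dis > 0) sample(dis_pool, n_dis) else character(0)
    )
    list(
      ids = ids,
      manifest = list(
        axis = axis, threshold = thr, fraction_similar = spec$fraction_similar,
        n_similar = n_sim, n_dissimilar = n_dis, total = spec$total,
        seed = spec$seed
      )
    )
  })
}

#' Size-variant training sets
#'
#' Three nested views of an affinity table: `small` keeps refined-quality
#' entries only, `medium` drops IC50 measurements, `large` keeps everything.
#'
#' @param records data.frame with `complex_id`, `measure_kind` and a logical
#'   `refined` quality tier
#' @return list of character ID vectors `small`, `medium`, `large`
#' @export
size_variants <- function(records) {
  if (is.null(records$refined)) lgn_stop("records lack the refined quality tier")
  if (nrow(records) == 0) {
    return(list(small = character(0), medium = character(0),
                large = character(0)))
  }
  is_ic50 <- !is.na(records$measure_kind) & records$measure_kind == "IC50"
  list(
    small = records$complex_id[records$refined],
    medium = records$complex_id[!is_ic50],
    large = records$complex_id
  )
}

#' Time-based split
#'
#' Structures deposited before the cutoff year form the training/validation
#' pool; structures from the cutoff year onwards form the test set. Records
#' without a year are routed to the training pool with a warning.
#'
#' @param records data.frame with `complex_id` and `deposit_year`
#' @param cutoff_year first test year
#' @return list with `train_val` and `test` ID vectors
#' @export
time_split <- function(records, cutoff_year = 2019L) {
  yr <- records$deposit_year
  if (anyNA(yr)) {
    lgn_warn("%d records lack a deposit year; routed to train_val", sum(is.na(yr)))
  }
  test <- records$complex_id[!is.na(yr) & yr >= cutoff_year]
  train_val <- setdiff(records$complex_id, test)
  if (length(test) == 0) lgn_warn("time split produced an empty test set")
  list(train_val = train_val, test = test)
}
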