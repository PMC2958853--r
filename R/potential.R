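# Three-body log-likelihood potential over buriedness/connectivity
# strata, and mutation scoring.
#
# For a triplet type t = (i,j,k,c,b) the score is
#   Q_t = log( f_t / (C * a_i * a_j * a_k * p_cb) )
# with f_t the observed frequency of the composition within its (c,b)
# stratum, a_i background amino-acid frequencies, p_cb the fraction of
# all screened triplets falling in stratum (c,b), and C the multiset
# multiplicity factor. Natural logarithm throughout; types never
# observed in the estimation set score 0 (neutral) unless a pseudocount
# is requested.

#' Multiset multiplicity factor of a triplet composition
#'
#' `3! / prod(multiplicities!)`: 6 when all three amino acids differ, 3
#' when exactly two coincide, 1 when all three are equal. Accounts for
#' the duplicate ordered versions of an unordered composition in the
#' expected-frequency term.
#'
#' @param aa Character vector of three one-letter codes, or an m x 3
#'   matrix (row-wise).
#' @return Integer vector.
#' @export
combinatorial_factor <- function(aa) {
  if (!is.matrix(aa)) aa <- matrix(aa, ncol = 3)
  apply(aa, 1, function(a) {
    as.integer(factorial(3) / prod(factorial(table(a))))
  })
}

#' Count triplet types over a structure set
#'
#' Each structure is tessellated, buriedness-classified on the full
#' tessellation, screened at `cutoff`, and its faces tallied by
#' (composition, c, b). Background amino-acid frequencies are taken over
#' all residues of all structures; stratum fractions p_cb over all
#' screened triplets.
#'
#' @param structures A [residue_points] data frame or a list of them.
#' @param cutoff Contact screen in Angstroms (default 9).
#' @return A `triplet_potential` data frame (`aa1,aa2,aa3,c,b,count`)
#'   with attributes `aa_freq`, `p_cb`, `n_triplets`, `n_residues`.
#' @export
count_triplets <- function(structures, cutoff = 9) {
  if (inherits(structures, "residue_points")) structures <- list(structures)
  if (length(structures) == 0) stop("empty structure list")
  all_fc <- lapply(structures, function(s) {
    face_classes(delaunay_tessellation(s), cutoff = cutoff)
  })
  fc <- do.call(rbind, all_fc)
  aa_all <- unlist(lapply(structures, `[[`, "aa"))
  aa_freq <- table(factor(aa_all, levels = aa_alphabet()))
  aa_freq <- stats::setNames(as.numeric(aa_freq) / length(aa_all),
                             names(aa_freq))
  counts <- stats::aggregate(
    list(count = rep(1L, nrow(fc))),
    by = fc[c("aa1", "aa2", "aa3", "c", "b")], FUN = sum)
  counts <- counts[order(counts$aa1, counts$aa2, counts$aa3,
                         counts$c, counts$b), , drop = FALSE]
  rownames(counts) <- NULL
  strat <- stats::aggregate(list(n = counts$count),
                            by = counts[c("c", "b")], FUN = sum)
  strat$p <- strat$n / sum(strat$n)
  structure(counts,
            class = c("triplet_potential", "data.frame"),
            aa_freq = aa_freq,
            p_cb = strat,
            n_triplets = nrow(fc),
            n_residues = length(aa_all))
}

#' Compute log-likelihood scores from triplet counts
#'
#' Adds `f` and `Q` columns to a [count_triplets()] table. With
#' `pseudocount > 0` the table is first expanded to the full
#' 1540 x 3 x 9 key grid and the pseudocount added to every count;
#' the default (0) leaves unobserved types out of the table, and they
#' score 0 wherever looked up.
#'
#' @param counts A `triplet_potential` counts table.
#' @param pseudocount Additive count applied to all possible types.
#' @return The table with `f` and `Q` columns; same attributes.
#' @export
log_likelihood <- function(counts, pseudocount = 0) {
  stopifnot(inherits(counts, "triplet_potential"))
  aa_freq <- attr(counts, "aa_freq")
  strat <- attr(counts, "p_cb")
  if (is.null(aa_freq) || is.null(strat))
    stop("counts table lacks aa_freq/p_cb attributes; ",
         "recompute with count_triplets()")
  df <- as.data.frame(counts)
  if (pseudocount > 0) {
    grid <- full_key_grid()
    have <- triplet_key(df$aa1, df$aa2, df$aa3, df$c, df$b)
    miss <- grid[!triplet_key(grid$aa1, grid$aa2, grid$aa3, grid$c,
                              grid$b) %in% have, , drop = FALSE]
    miss$count <- 0L
    df <- rbind(df, miss)
    df$count <- df$count + pseudocount
    strat <- stats::aggregate(list(n = df$count), by = df[c("c", "b")],
                              FUN = sum)
    strat$p <- strat$n / sum(strat$n)
  }
  skey <- paste(df$c, df$b)
  stot <- stats::setNames(strat$n, paste(strat$c, strat$b))
  df$f <- df$count / as.numeric(stot[skey])
  p_cb <- stats::setNames(strat$p, paste(strat$c, strat$b))
  C <- combinatorial_factor(as.matrix(df[c("aa1", "aa2", "aa3")]))
  expected <- C * aa_freq[df$aa1] * aa_freq[df$aa2] * aa_freq[df$aa3] *
    as.numeric(p_cb[skey])
  df$Q <- ifelse(df$f > 0 & expected > 0, log(df$f / expected), 0)
  structure(df,
            class = c("triplet_potential", "data.frame"),
            aa_freq = aa_freq, p_cb = strat,
            n_triplets = attr(counts, "n_triplets"),
            n_residues = attr(counts, "n_residues"))
}

#' Estimate a scored potential from structures in one call
#'
#' @inheritParams count_triplets
#' @inheritParams log_likelihood
#' @return A scored `triplet_potential` (counts plus `f` and `Q`).
#' @export
train_potential <- function(structures, cutoff = 9, pseudocount = 0) {
  log_likelihood(count_triplets(structures, cutoff = cutoff),
                 pseudocount = pseudocount)
}

# all 1540 sorted compositions x 3 connectivity x 9 buriedness classes
full_key_grid <- function(b = 0:8) {
  aas <- aa_alphabet()
  comp <- expand.grid(aa1 = aas, aa2 = aas, aa3 = aas,
                      stringsAsFactors = FALSE)
  comp <- comp[comp$aa1 <= comp$aa2 & comp$aa2 <= comp$aa3, , drop = FALSE]
  out <- merge(merge(comp, data.frame(c = 0:2)), data.frame(b = b))
  out[c("aa1", "aa2", "aa3", "c", "b")]
}

# named Q vector keyed aa1:aa2:aa3:c:b, cached on the object
q_lookup <- function(potential) {
  cached <- attr(potential, "q_vector")
  if (!is.null(cached)) return(cached)
  if (is.null(potential$Q))
    stop("potential has no Q column; run log_likelihood()")
  stats::setNames(potential$Q,
                  triplet_key(potential$aa1, potential$aa2, potential$aa3,
                              potential$c, potential$b))
}

# Q values for a key vector; unobserved types score 0
q_of <- function(keys, qv) {
  out <- unname(qv[keys])
  out[is.na(out)] <- 0
  out
}

# weight values for a key vector; untabulated types default to `default`
w_of <- function(keys, weights, default = 1) {
  if (is.null(weights)) return(rep(default, length(keys)))
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$w,
                               triplet_key(weights$aa1, weights$aa2,
                                           weights$aa3, weights$c,
                                           weights$b))
  if (inherits(weights, "solubility_weights")) weights <- weights$w
  out <- unname(weights[keys])
  out[is.na(out)] <- default
  out
}

#' Total surface score of a structure
#'
#' Sum of weighted log-likelihood scores over the screened faces in the
#' five most non-buried triplet classes (b = 0..4); faces with b in 5..8
#' contribute nothing.
#'
#' @param structure A [residue_points] data frame (or a precomputed
#'   tessellation of one).
#' @param potential A scored `triplet_potential`.
#' @param weights Optional weight table / named vector /
#'   `solubility_weights`; absent types weigh 1.
#' @param cutoff Contact screen in Angstroms.
#' @param aa_override Optional character vector replacing the amino-acid
#'   labels (used for mutant rescoring on wild-type geometry).
#' @return Numeric score with attribute `n_faces` (number of
#'   contributing faces).
#' @export
total_surface_score <- function(structure, potential, weights = NULL,
                                cutoff = 9, aa_override = NULL) {
  tess <- if (inherits(structure, "tessellation")) structure
          else delaunay_tessellation(structure)
  if (!is.null(aa_override)) {
    stopifnot(length(aa_override) == nrow(tess$points))
    tess$points$aa <- aa_override
  }
  fc <- face_classes(tess, cutoff = cutoff)
  fc <- fc[fc$b <= 4, , drop = FALSE]
  qv <- q_lookup(potential)
  sc <- sum(w_of(fc$key, weights) * q_of(fc$key, qv))
  attr(sc, "n_faces") <- nrow(fc)
  sc
}

#' Triplet types changed by a mutation
#'
#' Mutant-side (`M`) and wild-type-side (`W`) key multisets over the
#' screened b = 0..4 faces whose amino-acid composition changes under
#' the substitutions. Wild-type geometry is kept for the mutant; only
#' residue identities change.
#'
#' @param structure The wild-type [residue_points].
#' @param mutation A `mutation_record` (sites are matched by
#'   `author_resnum` within the record's chain; the recorded wild-type
#'   amino acid must agree with the structure).
#' @param cutoff Contact screen in Angstroms.
#' @param tess,fc Optional precomputed tessellation and b<=4-filtered
#'   [face_classes()] table (for repeated calls on one structure).
#' @return List with character vectors `M` and `W` and the integer
#'   vector `sites` (0-based seq_index of substituted residues).
#' @export
mutation_triplets <- function(structure, mutation, cutoff = 9,
                              tess = NULL, fc = NULL) {
  stopifnot(inherits(mutation, "mutation_record"))
  if (!is.null(structure$chain_id) &&
      !mutation$chain_id %in% structure$chain_id)
    stop("mutation targets chain '", mutation$chain_id,
         "' but structure holds chain(s) ",
         paste(unique(structure$chain_id), collapse = ", "))
  if (is.null(tess)) tess <- delaunay_tessellation(structure)
  if (is.null(fc)) {
    fc <- face_classes(tess, cutoff = cutoff)
    fc <- fc[fc$b <= 4, , drop = FALSE]
  }
  subs <- mutation$substitutions
  idx <- match(subs$author_resnum, structure$author_resnum)
  if (anyNA(idx))
    stop("mutation site(s) not found in structure: ",
         paste(subs$author_resnum[is.na(idx)], collapse = ", "))
  mism <- structure$aa[idx] != subs$wt
  if (any(mism))
    stop("wild-type mismatch at site(s) ",
         paste0(subs$author_resnum[mism], " (structure has ",
                structure$aa[idx][mism], ", record says ",
                subs$wt[mism], ")", collapse = "; "))
  site_seq <- structure$seq_index[idx]
  aa_mut <- structure$aa
  aa_mut[idx] <- subs$mut
  touched <- fc$r1 %in% site_seq | fc$r2 %in% site_seq |
    fc$r3 %in% site_seq
  tf <- fc[touched, , drop = FALSE]
  if (nrow(tf) == 0)
    return(list(M = character(0), W = character(0), sites = site_seq))
  aam <- cbind(aa_mut[tf$r1 + 1L], aa_mut[tf$r2 + 1L], aa_mut[tf$r3 + 1L])
  aam <- t(apply(aam, 1, sort))
  mkeys <- triplet_key(aam[, 1], aam[, 2], aam[, 3], tf$c, tf$b)
  changed <- mkeys != tf$key
  list(M = mkeys[changed], W = tf$key[changed], sites = site_seq)
}

#' Score of a mutation
#'
#' Weighted total score of the mutant conformation minus that of the
#' wild type, computed over only the triangles whose composition
#' changes (equal to the full-rescoring difference). Positive scores
#' predict increased solubility.
#'
#' @inheritParams mutation_triplets
#' @param potential A scored `triplet_potential`.
#' @param weights Optional weights (absent types weigh 1).
#' @return Numeric score.
#' @export
mutation_score <- function(structure, mutation, potential, weights = NULL,
                           cutoff = 9, tess = NULL, fc = NULL) {
  mw <- mutation_triplets(structure, mutation, cutoff = cutoff,
                          tess = tess, fc = fc)
  qv <- q_lookup(potential)
  sum(w_of(mw$M, weights) * q_of(mw$M, qv)) -
    sum(w_of(mw$W, weights) * q_of(mw$W, qv))
}
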