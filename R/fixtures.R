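# Synthetic fixtures: random well-separated residue clouds with a
# backbone ordering, PDB emission, brute-force buriedness oracle, and
# mutant datasets with planted discriminative triplet signals.
#
# The generators are pure functions of their seeds: the global RNG
# stream is saved and restored around every draw.

#' Generate a synthetic structure
#'
#' Residue centers are laid down as a self-avoiding random walk in a
#' cubic box: consecutive residues are placed 3.5-4.5 Angstroms apart
#' (so sequence-adjacent pairs form Delaunay edges at realistic rates and
#' all connectivity classes occur), and every pair of residues is at
#' least `min_separation` apart. The default box volume allows roughly
#' 130 cubic Angstroms per residue, matching the packing density of
#' residue centers in globular proteins.
#'
#' @param n_residues Number of residues.
#' @param min_separation Minimum pairwise distance in Angstroms.
#' @param box_size Cube edge in Angstroms; default scales with
#'   `n_residues` to keep protein-like density.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param aa_freq Optional named probability vector over the 20 amino
#'   acids used to sample residue identities (default uniform).
#' @param max_step Maximum distance between consecutive residues.
#' @return A [residue_points] data frame (chain "A").
#' @export
generate_structure <- function(n_residues, min_separation = 3.5,
                               box_size = NULL, seed = 0L,
                               aa_freq = NULL, max_step = 4.5) {
  stopifnot(n_residues >= 4, min_separation > 0,
            max_step > min_separation)
  if (is.null(box_size))
    box_size <- max(12, ceiling((n_residues * 130)^(1 / 3)))
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / 20, 20), aa_alphabet())
  }
  stopifnot(all(names(aa_freq) %in% aa_alphabet()))
  with_local_seed(seed, {
    for (restart in 1:50) {
      P <- matrix(NA_real_, n_residues, 3)
      P[1, ] <- stats::runif(3, 0.1 * box_size, 0.9 * box_size)
      ok <- TRUE
      for (i in 2:n_residues) {
        placed <- FALSE
        for (try in 1:200) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          step <- stats::runif(1, min_separation, max_step)
          cand <- P[i - 1, ] + dir * step
          if (any(cand < 0) || any(cand > box_size)) next
          d2 <- rowSums(sweep(P[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2)
          if (min(d2) < min_separation^2) next
          P[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        aa <- sample(names(aa_freq), n_residues, replace = TRUE,
                     prob = aa_freq)
        return(residue_points("A", aa, P))
      }
    }
    stop("could not place ", n_residues, " residues at separation ",
         min_separation, " in a box of ", box_size,
         " Angstroms; increase box_size")
  })
}

#' Render residue points as PDB text
#'
#' Each residue is written with a CA record at its center and, for
#' non-glycine residues, a CB record at the same position, so that
#' [read_structure()]'s side-chain-centroid policy reproduces the input
#' points (to the 1e-3 Angstrom precision of the PDB fixed-width
#' format).
#'
#' @param points A [residue_points] data frame.
#' @return A single character scalar of PDB text.
#' @export
as_pdb_text <- function(points) {
  stopifnot(inherits(points, "residue_points"))
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(points))) {
    aa3 <- AA_THREE[[points$aa[i]]]
    resno <- suppressWarnings(as.integer(points$author_resnum[i]))
    if (is.na(resno)) resno <- i
    atoms <- if (points$aa[i] == "G") "CA" else c("CA", "CB")
    for (at in atoms) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, at, aa3, points$chain_id[i], resno,
        points$x[i], points$y[i], points$z[i],
        substr(at, 1, 1)))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Brute-force buriedness oracle
#'
#' Recomputes every buried/non-buried flag by naive membership counting:
#' a face's occurrence count is recounted over all tetrahedra by subset
#' testing, and each edge/vertex flag by scanning all faces that contain
#' it. Quadratic; used as the equivalence oracle for
#' [assign_buriedness()].
#'
#' @param tess A tessellation.
#' @return A `buriedness_map` (same layout as [assign_buriedness()]).
#' @export
brute_force_buriedness <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  n <- nrow(tess$coords)
  fm <- tess$faces
  tm <- tess$tetrahedra
  # vertex-in-tetrahedron incidence, recomputed from scratch
  inc <- matrix(FALSE, n, nrow(tm))
  for (j in seq_len(nrow(tm))) inc[tm[j, ] + 1L, j] <- TRUE
  # a face is in tetrahedron j iff all three vertices are
  cnt <- vapply(seq_len(nrow(fm)), function(i)
    sum(inc[fm[i, 1] + 1L, ] & inc[fm[i, 2] + 1L, ] &
          inc[fm[i, 3] + 1L, ]), integer(1))
  face_buried <- cnt == 2L
  # vertex (edge) is buried iff every face containing it is buried
  vertex_buried <- rep(FALSE, n)
  vin <- matrix(FALSE, n, nrow(fm))
  for (i in seq_len(nrow(fm))) vin[fm[i, ] + 1L, i] <- TRUE
  for (v in seq_len(n)) {
    if (any(vin[v, ])) vertex_buried[v] <- all(face_buried[vin[v, ]])
  }
  ekey <- paste(tess$edges[, 1], tess$edges[, 2], sep = ":")
  edge_buried <- structure(logical(nrow(tess$edges)), names = ekey)
  for (i in seq_len(nrow(tess$edges))) {
    inface <- vin[tess$edges[i, 1] + 1L, ] & vin[tess$edges[i, 2] + 1L, ]
    edge_buried[i] <- all(face_buried[inface])
  }
  structure(
    list(face_buried = face_buried, edge_buried = edge_buried,
         vertex_buried = vertex_buried,
         face_key = paste(fm[, 1], fm[, 2], fm[, 3])),
    class = "buriedness_map"
  )
}

#' Generate a mutant dataset with planted triplet signals
#'
#' Plants a recoverable composition signal into a fixture structure:
#' `n_planted_sites` residues of the base structure are substituted away
#' from the composition the potential was estimated on, and the
#' perturbed structure becomes the dataset's wild type. Mutants that
#' revert planted sites restore high-likelihood triplet types and score
#' strongly positive (label I); mutants of random other sites destroy
#' observed types and score negative (label D). Labels are the sign of
#' the unweighted mutation score plus optional Gaussian noise, and
#' candidates with |score| below `effect_size` are discarded, so at
#' `noise_sd = 0` the dataset is linearly separable by construction: the
#' default weight vector (1 everywhere) separates every instance with
#' margin at least `effect_size`, hence the max-margin LP attains
#' mu >= effect_size - 1.
#'
#' @param structure The base [residue_points] fixture structure (one of
#'   the structures the potential was estimated from).
#' @param potential A scored [triplet_potential].
#' @param n_mutants Number of mutants (labels balanced to within one).
#' @param n_planted_sites Number of pre-perturbed sites carrying the
#'   discriminative signal (at least 2).
#' @param effect_size Minimum absolute mutation score of an accepted
#'   candidate (score units; must be positive).
#' @param noise_sd Standard deviation of the label noise (score units);
#'   0 keeps the dataset separable.
#' @param seed Integer seed; the dataset is a pure function of it.
#' @param max_sites Maximum substitutions per class-D mutant.
#' @param cutoff Contact screen in Angstroms.
#' @return List with `structure` (the perturbed wild type to score
#'   mutants against), `mutants` (list of `mutation_record`, labelled),
#'   `labels`, `informative_keys` (triplet types changed by planted-site
#'   reversions; these fully determine the I class), `planted_sites`
#'   (0-based seq_index), and `separating_weights` (the unit certificate
#'   over all changed types).
#' @export
generate_planted_dataset <- function(structure, potential,
                                     n_mutants = 30, n_planted_sites = 6,
                                     effect_size = 2, noise_sd = 0,
                                     seed = 0L, max_sites = 3,
                                     cutoff = 9) {
  stopifnot(n_planted_sites >= 2, n_mutants >= 2, effect_size > 0)
  n <- nrow(structure)
  tess <- delaunay_tessellation(structure)
  qv <- q_lookup(potential)

  with_local_seed(seed, {
    # plant: perturb sites, spread over the chain, away from the
    # composition the potential saw
    planted_sites <- sort(sample.int(n, n_planted_sites))
    base_aa <- structure$aa
    wt <- structure
    for (s in planted_sites)
      wt$aa[s] <- sample(setdiff(aa_alphabet(), base_aa[s]), 1)
    fc <- face_classes(within_points(tess, wt), cutoff = cutoff)
    fc <- fc[fc$b <= 4, , drop = FALSE]

    make_rec <- function(sites, mut_aa, label) {
      mutation_record(
        "SYN1", "A",
        data.frame(author_resnum = wt$author_resnum[sites],
                   wt = wt$aa[sites], mut = mut_aa,
                   stringsAsFactors = FALSE),
        label = label)
    }
    score_of <- function(rec) {
      mutation_score(wt, rec, potential, cutoff = cutoff,
                     tess = within_points(tess, wt), fc = fc)
    }

    # designated discriminative types: everything a planted-site
    # reversion changes
    informative <- character(0)
    for (s in planted_sites) {
      mw <- mutation_triplets(
        wt, make_rec(s, base_aa[s], "I"),
        tess = within_points(tess, wt), fc = fc)
      informative <- union(informative, c(mw$M, mw$W))
    }

    want_I <- ceiling(n_mutants / 2)
    want_D <- n_mutants - want_I
    got <- list(); labels <- character(0)
    n_I <- 0; n_D <- 0
    seen <- character(0)
    for (attempt in seq_len(500 * n_mutants)) {
      if (n_I >= want_I && n_D >= want_D) break
      if (stats::runif(1) < 0.5) {
        # reversion candidate: restore 1..2 planted sites
        k <- sample.int(min(2, n_planted_sites), 1)
        sites <- sample(planted_sites, k)
        mut_aa <- base_aa[sites]
      } else {
        # random candidate on non-planted sites
        k <- sample.int(max_sites, 1)
        sites <- sample(setdiff(seq_len(n), planted_sites), k)
        mut_aa <- vapply(wt$aa[sites], function(a)
          sample(setdiff(aa_alphabet(), a), 1), "")
      }
      sig <- paste(sites, mut_aa, collapse = ";")
      if (sig %in% seen) next
      rec <- make_rec(sites, mut_aa, "I")
      s <- score_of(rec)
      if (abs(s) < effect_size) next
      lab <- if (s + stats::rnorm(1, 0, noise_sd) > 0) "I" else "D"
      if (lab == "I" && n_I >= want_I) next
      if (lab == "D" && n_D >= want_D) next
      rec$label <- lab
      seen <- c(seen, sig)
      got[[length(got) + 1]] <- rec
      labels <- c(labels, lab)
      if (lab == "I") n_I <- n_I + 1 else n_D <- n_D + 1
    }
    if (n_I < want_I || n_D < want_D)
      stop("could not assemble a balanced planted dataset (got ", n_I,
           " I / ", n_D, " D); lower effect_size or enlarge the ",
           "structure")
    all_keys <- sort(unique(unlist(lapply(got, function(r) {
      mw <- mutation_triplets(wt, r, tess = within_points(tess, wt),
                              fc = fc)
      c(mw$M, mw$W)
    }))))
    list(structure = wt,
         mutants = got,
         labels = labels,
         informative_keys = sort(informative),
         planted_sites = planted_sites - 1L,
         separating_weights = stats::setNames(rep(1, length(all_keys)),
                                              all_keys))
  })
}

# re-label a tessellation with the amino acids of `points` (geometry is
# shared; only residue identities differ)
within_points <- function(tess, points) {
  tess$points <- points
  tess
}

# net multiset count (M minus W) aligned over the union of keys
key_count_diff <- function(M, W) {
  keys <- sort(unique(c(M, W)))
  cm <- tabulate(factor(M, levels = keys), nbins = length(keys))
  cw <- tabulate(factor(W, levels = keys), nbins = length(keys))
  stats::setNames(as.numeric(cm - cw), keys)
}
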