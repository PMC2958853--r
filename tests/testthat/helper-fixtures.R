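# Shared fixtures, built once per test run.

fix_structures <- lapply(1:4, function(i) generate_structure(50, seed = i))
fix_str <- fix_structures[[1]]
fix_potential <- train_potential(fix_structures)
fix_tess <- delaunay_tessellation(fix_str)

# independent O(n^5) Delaunay oracle: a 4-subset is a Delaunay
# tetrahedron iff its circumsphere contains no other point
oracle_delaunay <- function(P) {
  n <- nrow(P)
  combs <- utils::combn(n, 4)
  keep <- NULL
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    q <- P[idx, , drop = FALSE]
    A <- 2 * sweep(q[2:4, , drop = FALSE], 2, q[1, ])
    bb <- rowSums(q[2:4, , drop = FALSE]^2) - sum(q[1, ]^2)
    cen <- tryCatch(solve(A, bb), error = function(e) NULL)
    if (is.null(cen)) next
    r2 <- sum((cen - q[1, ])^2)
    others <- setdiff(seq_len(n), idx)
    d2 <- rowSums(sweep(P[others, , drop = FALSE], 2, cen)^2)
    if (all(d2 > r2 * (1 + 1e-9))) keep <- rbind(keep, sort(idx))
  }
  keep
}

# two regular-ish tetrahedra glued on a common face
glued_tets_points <- function() {
  matrix(c(0, 0, 0,
           2, 0, 0,
           1, 2, 0,
           1, 0.7, 1.5,
           1, 0.7, -1.5), ncol = 3, byrow = TRUE)
}

# classify every face of a tessellation under a given buriedness map
classify_all <- function(tess, map) {
  vapply(seq_len(nrow(tess$faces)), function(i)
    three_body_class(tess$faces[i, ], map), integer(1))
}

# a random mutation record for `str` (1..max_sites substitutions)
random_mutation <- function(str, max_sites = 3) {
  k <- sample.int(max_sites, 1)
  sites <- sample.int(nrow(str), k)
  wt <- str$aa[sites]
  mut <- vapply(wt, function(a) sample(setdiff(aa_alphabet(), a), 1), "")
  mutation_record(
    "FIX", "A",
    data.frame(author_resnum = str$author_resnum[sites],
               wt = wt, mut = mut, stringsAsFactors = FALSE),
    label = "I")
}

# full-rescoring reference for a mutation: score the relabelled mutant
# over all faces and subtract the wild-type total
full_rescore <- function(str, rec, potential, tess, weights = NULL) {
  idx <- match(rec$substitutions$author_resnum, str$author_resnum)
  aa_mut <- str$aa
  aa_mut[idx] <- rec$substitutions$mut
  total_surface_score(tess, potential, weights = weights,
                      aa_override = aa_mut) -
    total_surface_score(tess, potential, weights = weights,
                        aa_override = str$aa)
}
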