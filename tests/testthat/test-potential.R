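test_that("combinatorial factor counts distinct orderings of the composition", {
  expect_equal(combinatorial_factor(c("A", "G", "V")), 6L)
  expect_equal(combinatorial_factor(c("A", "A", "G")), 3L)
  expect_equal(combinatorial_factor(c("A", "A", "A")), 1L)
  m <- rbind(c("C", "C", "W"), c("D", "E", "F"))
  expect_equal(combinatorial_factor(m), c(3L, 6L))
})

test_that("triplet counts are additive over structures and normalised per stratum", {
  c1 <- count_triplets(fix_structures[[1]])
  c2 <- count_triplets(fix_structures[[2]])
  c12 <- count_triplets(fix_structures[1:2])
  key <- function(df) triplet_key(df$aa1, df$aa2, df$aa3, df$c, df$b)
  merged <- merge(setNames(data.frame(key(c1), c1$count), c("k", "n1")),
                  setNames(data.frame(key(c2), c2$count), c("k", "n2")),
                  all = TRUE)
  merged[is.na(merged)] <- 0
  both <- setNames(data.frame(key(c12), c12$count), c("k", "n"))
  m <- merge(merged, both, all = TRUE)
  m[is.na(m)] <- 0
  expect_equal(m$n, m$n1 + m$n2)

  # p_cb sums to 1, background composition sums to 1
  expect_equal(sum(attr(c12, "p_cb")$p), 1)
  expect_equal(sum(attr(c12, "aa_freq")), 1)
  expect_error(count_triplets(list()), "empty")
})

test_that("log-likelihood matches the defining formula on every observed type", {
  pot <- fix_potential
  aa <- attr(pot, "aa_freq")
  strat <- attr(pot, "p_cb")
  p_cb <- setNames(strat$p, paste(strat$c, strat$b))
  n_cb <- setNames(strat$n, paste(strat$c, strat$b))
  for (i in sample(nrow(pot), 40)) {
    row <- pot[i, ]
    f <- row$count / n_cb[[paste(row$c, row$b)]]
    C <- combinatorial_factor(c(row$aa1, row$aa2, row$aa3))
    expected <- C * aa[[row$aa1]] * aa[[row$aa2]] * aa[[row$aa3]] *
      p_cb[[paste(row$c, row$b)]]
    expect_equal(row$Q, log(f / expected), tolerance = 1e-12)
    expect_equal(row$f, f, tolerance = 1e-12)
  }
  # stratum frequencies sum to one
  agg <- stats::aggregate(list(f = pot$f), by = pot[c("c", "b")], FUN = sum)
  expect_equal(agg$f, rep(1, nrow(agg)))
})

test_that("a type owning its whole stratum scores -log(expected); unobserved types score 0", {
  pot <- fix_potential
  strat <- attr(pot, "p_cb")
  own <- merge(pot, strat[strat$n == 1, c("c", "b")])
  if (nrow(own) > 0) {
    aa <- attr(pot, "aa_freq")
    p_cb <- setNames(strat$p, paste(strat$c, strat$b))
    for (i in seq_len(nrow(own))) {
      row <- own[i, ]
      C <- combinatorial_factor(c(row$aa1, row$aa2, row$aa3))
      expect_equal(row$Q,
                   -log(C * aa[[row$aa1]] * aa[[row$aa2]] * aa[[row$aa3]] *
                          p_cb[[paste(row$c, row$b)]]),
                   tolerance = 1e-12)
    }
  }
  # an unobserved key contributes zero to any score
  qv <- setNames(pot$Q, triplet_key(pot$aa1, pot$aa2, pot$aa3, pot$c, pot$b))
  fake <- "W:W:W:2:0"
  expect_false(fake %in% names(qv))
  inst <- structure(list(id = "x", label = "I", M = fake, W = character(0)),
                    class = "lp_instance")
  expect_equal(predict_solubility(list(inst), NULL, pot)$score, 0)
})

test_that("total surface score is the unweighted Q sum over b 0-4 faces", {
  fc <- face_classes(fix_tess, cutoff = 9)
  qv <- setNames(fix_potential$Q,
                 triplet_key(fix_potential$aa1, fix_potential$aa2,
                             fix_potential$aa3, fix_potential$c,
                             fix_potential$b))
  keep <- fc[fc$b <= 4, ]
  manual <- sum(vapply(keep$key, function(k)
    if (k %in% names(qv)) qv[[k]] else 0, numeric(1)))
  got <- total_surface_score(fix_str, fix_potential)
  expect_equal(as.numeric(got), manual, tolerance = 1e-12)
  expect_equal(attr(got, "n_faces"), nrow(keep))
})

test_that("identity substitutions score zero and order does not matter", {
  s <- fix_str
  rec0 <- mutation_record("FIX", "A",
    data.frame(author_resnum = s$author_resnum[c(5, 9)],
               wt = s$aa[c(5, 9)], mut = s$aa[c(5, 9)],
               stringsAsFactors = FALSE), "I")
  expect_equal(mutation_score(s, rec0, fix_potential, tess = fix_tess), 0)

  set.seed(5)
  rec <- random_mutation(s, max_sites = 3)
  while (nrow(rec$substitutions) < 2) rec <- random_mutation(s)
  rev_rec <- rec
  rev_rec$substitutions <- rec$substitutions[rev(seq_len(nrow(rec$substitutions))), ]
  expect_equal(mutation_score(s, rec, fix_potential, tess = fix_tess),
               mutation_score(s, rev_rec, fix_potential, tess = fix_tess))
})

test_that("delta scoring equals full mutant-vs-wild-type rescoring", {
  set.seed(31)
  for (trial in 1:25) {
    rec <- random_mutation(fix_str, max_sites = 3)
    delta <- mutation_score(fix_str, rec, fix_potential, tess = fix_tess)
    full <- full_rescore(fix_str, rec, fix_potential, fix_tess)
    expect_equal(delta, as.numeric(full), tolerance = 1e-9)
  }
})

test_that("two substitutions sharing a triangle are applied jointly", {
  # pick a screened face and mutate two of its residues at once
  fc <- face_classes(fix_tess, cutoff = 9)
  fc <- fc[fc$b <= 4, ]
  # first screened face whose residues can all be mutated to W
  ok <- fix_str$aa[fc$r1 + 1L] != "W" & fix_str$aa[fc$r2 + 1L] != "W"
  f <- fc[which(ok)[1], ]
  sites <- c(f$r1, f$r2) + 1L
  rec <- mutation_record("FIX", "A",
    data.frame(author_resnum = fix_str$author_resnum[sites],
               wt = fix_str$aa[sites],
               mut = c("W", "W"), stringsAsFactors = FALSE), "I")
  delta <- mutation_score(fix_str, rec, fix_potential, tess = fix_tess)
  full <- full_rescore(fix_str, rec, fix_potential, fix_tess)
  expect_equal(delta, as.numeric(full), tolerance = 1e-9)
  mw <- mutation_triplets(fix_str, rec, tess = fix_tess)
  # the shared triangle is listed once, carrying both substitutions
  shared_wt <- f$key
  shared_mut_aa <- sort(c("W", "W", fix_str$aa[f$r3 + 1L]))
  shared_mut <- triplet_key(shared_mut_aa[1], shared_mut_aa[2],
                            shared_mut_aa[3], f$c, f$b)
  expect_equal(sum(mw$W == shared_wt), 1)
  expect_equal(sum(mw$M == shared_mut), 1)
})

test_that("unknown sites and wild-type mismatches are errors", {
  rec <- mutation_record("FIX", "A",
    data.frame(author_resnum = "9999", wt = "A", mut = "G",
               stringsAsFactors = FALSE), "I")
  expect_error(mutation_score(fix_str, rec, fix_potential, tess = fix_tess),
               "not found")
  wrong_wt <- setdiff(aa_alphabet(), fix_str$aa[3])[1]
  rec2 <- mutation_record("FIX", "A",
    data.frame(author_resnum = fix_str$author_resnum[3],
               wt = wrong_wt, mut = "G", stringsAsFactors = FALSE), "I")
  expect_error(mutation_score(fix_str, rec2, fix_potential, tess = fix_tess),
               "mismatch")
})
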