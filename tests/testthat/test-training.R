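# a minimal potential whose single type has Q = 1
unit_potential <- function() {
  structure(data.frame(aa1 = "A", aa2 = "A", aa3 = "A", c = 0L, b = 0L,
                       count = 1L, f = 1, Q = 1),
            class = c("triplet_potential", "data.frame"))
}

lp_inst <- function(id, label, M = character(0), W = character(0)) {
  structure(list(id = id, label = label, M = M, W = W),
            class = "lp_instance")
}

test_that("the one-variable LP solves by hand: w = 2, mu = 1", {
  w <- train_weights(list(lp_inst("m1", "I", M = "A:A:A:0:0")),
                     unit_potential())
  expect_equal(unname(w$w[["A:A:A:0:0"]]), 2, tolerance = 1e-7)
  expect_equal(w$mu, 1, tolerance = 1e-7)
  expect_equal(unname(w$epsilon), 1, tolerance = 1e-7)
})

test_that("disjoint sign-consistent instances separate with non-negative margin", {
  pot <- structure(
    data.frame(aa1 = c("A", "C"), aa2 = c("A", "C"), aa3 = c("A", "C"),
               c = c(0L, 0L), b = c(0L, 0L), count = 1L, f = 1,
               Q = c(1.5, -2)),
    class = c("triplet_potential", "data.frame"))
  insts <- list(lp_inst("i1", "I", M = "A:A:A:0:0"),
                lp_inst("d1", "D", M = "C:C:C:0:0"))
  w <- train_weights(insts, pot)
  expect_gte(w$mu, 0)
  expect_true(all(w$w >= 0 & w$w <= 2))
  expect_equal(w$mu, min(w$epsilon), tolerance = 1e-7)
})

test_that("weights stay in [0,2] and mu equals the smallest margin on planted data", {
  pd <- generate_planted_dataset(fix_str, fix_potential, n_mutants = 16,
                                 seed = 5)
  inst <- build_lp_instances(pd$structure, pd$mutants, fix_potential)
  w <- train_weights(inst, fix_potential)
  expect_true(all(w$w >= 0 & w$w <= 2))
  expect_equal(w$mu, min(w$epsilon), tolerance = 1e-6)
  expect_gte(w$mu, 0)  # separable by construction
  # every satisfied training constraint implies a correct training sign
  p <- predict_solubility(inst, w, fix_potential)
  expect_equal(p$pred, pd$labels)
})

test_that("the printed class-D sign variant trains and ignores D in the objective", {
  pot <- unit_potential()
  insts <- list(lp_inst("i1", "I", M = "A:A:A:0:0"),
                lp_inst("d1", "D", W = "A:A:A:0:0"))
  w <- train_weights(insts, pot, d_sign = "printed")
  expect_true(all(w$w >= 0 & w$w <= 2))
  # with the printed sign, eps_D is only bounded below, so mu is set by
  # the I instance alone
  expect_equal(w$mu, 1, tolerance = 1e-6)
})

test_that("singleton triplet types predict with weight exactly 1", {
  pot <- structure(
    data.frame(aa1 = c("A", "C"), aa2 = c("A", "C"), aa3 = c("A", "C"),
               c = c(0L, 0L), b = c(0L, 0L), count = 1L, f = 1,
               Q = c(0.7, -1.1)),
    class = c("triplet_potential", "data.frame"))
  w <- train_weights(list(lp_inst("t", "I", M = "A:A:A:0:0")), pot)
  test_inst <- lp_inst("s", NA, M = "C:C:C:0:0")  # never seen in training
  p <- predict_solubility(list(test_inst), w, pot)
  expect_equal(p$score, -1.1)   # unweighted
  expect_equal(p$n_singleton, 1)
  expect_equal(p$pred, "D")
})

test_that("a zero score predicts D with the tie flag set", {
  pot <- unit_potential()
  p <- predict_solubility(list(lp_inst("z", NA)), NULL, pot)
  expect_equal(p$score, 0)
  expect_equal(p$pred, "D")
  expect_true(p$tie)
})

test_that("evaluation statistics match the standard formulas", {
  perfect <- evaluate_predictions(c("I", "D", "I"), c("I", "D", "I"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  # TP=3 TN=4 FP=1 FN=2 -> MCC = (12-2)/sqrt(4*5*6*5)
  pred <- c(rep("I", 3), rep("D", 2), "I", rep("D", 4))
  truth <- c(rep("I", 3), rep("I", 2), "D", rep("D", 4))
  ev <- evaluate_predictions(pred, truth)
  expect_equal(c(ev$tp, ev$tn, ev$fp, ev$fn), c(3, 4, 1, 2))
  expect_equal(ev$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(ev$accuracy, 0.7)
  expect_equal(ev$precision_I, 3 / 4)
  expect_equal(ev$precision_D, 4 / 6)
  # degenerate all-I predictions: MCC 0 by convention, precision(D) NA
  allI <- evaluate_predictions(rep("I", 4), c("I", "D", "I", "D"))
  expect_equal(allI$mcc, 0)
  expect_true(is.na(allI$precision_D))
  expect_error(evaluate_predictions(character(0), character(0)), "empty")
})

test_that("evaluation is symmetric under relabelling I and D", {
  set.seed(8)
  for (trial in 1:10) {
    n <- sample(5:20, 1)
    pred <- sample(c("I", "D"), n, replace = TRUE)
    truth <- sample(c("I", "D"), n, replace = TRUE)
    a <- evaluate_predictions(pred, truth)
    flip <- function(x) ifelse(x == "I", "D", "I")
    b <- evaluate_predictions(flip(pred), flip(truth))
    expect_equal(a$accuracy, b$accuracy)
    expect_equal(a$mcc, b$mcc)
    expect_equal(a$precision_I, b$precision_D)
    expect_equal(a$precision_D, b$precision_I)
  }
})

test_that("cross-validation schemes partition correctly and reproduce", {
  pd <- generate_planted_dataset(fix_str, fix_potential, n_mutants = 12,
                                 seed = 3)
  inst <- build_lp_instances(pd$structure, pd$mutants, fix_potential)
  loo <- cross_validate(inst, fix_potential, scheme = "loo")
  expect_length(loo$per_fold, length(inst))
  expect_equal(sort(names(loo$fold_assignment)),
               sort(vapply(inst, `[[`, "", "id")))

  cv1 <- cross_validate(inst, fix_potential, scheme = "kfold", k = 4,
                        seed = 11)
  cv2 <- cross_validate(inst, fix_potential, scheme = "kfold", k = 4,
                        seed = 11)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$report, cv2$report)

  expect_error(cross_validate(inst, fix_potential, scheme = "kfold",
                              k = 99, seed = 1), "k <= n")
  expect_error(cross_validate(inst, fix_potential, scheme = "kfold",
                              k = 1, seed = 1), "k <= n")
})

test_that("folds-from-file trains per fold and tests each mutant exactly once", {
  pd <- generate_planted_dataset(fix_str, fix_potential, n_mutants = 8,
                                 seed = 13)
  inst <- build_lp_instances(pd$structure, pd$mutants, fix_potential)
  ids <- vapply(inst, `[[`, "", "id")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutant_id\tfold_id",
               paste(ids, rep(1:2, length.out = length(ids)), sep = "\t")),
             path)
  cv <- cross_validate(inst, fix_potential, scheme = "folds", folds = path)
  expect_length(cv$per_fold, 2)
  expect_setequal(cv$predictions$id, ids)
  expect_equal(nrow(cv$predictions), length(ids))

  writeLines(c("mutant_id\tfold_id", "nonexistent\t1"), path)
  expect_error(cross_validate(inst, fix_potential, scheme = "folds",
                              folds = path), "unknown mutant")
})

test_that("hydrophobicity windows average over 7 residues, truncated at termini", {
  scale <- setNames(seq(-4.5, 4.5, length.out = 20), aa_alphabet())
  seqv <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # identical substitution -> 0
  expect_equal(
    hydrophobicity_change(seqv, data.frame(pos = 10, mut = seqv[10]), scale),
    0)
  # interior site: only the center residue changes within its window
  expect_equal(
    hydrophobicity_change(seqv, data.frame(pos = 10, mut = "A"), scale),
    (scale[["A"]] - scale[[seqv[10]]]) / 7)
  # site 1: the window truncates to 4 residues
  expect_equal(
    hydrophobicity_change(seqv, data.frame(pos = 1, mut = "W"), scale),
    (scale[["W"]] - scale[[seqv[1]]]) / 4)
  # multi-site averaging, verified by direct summation
  subs <- data.frame(pos = c(4, 12), mut = c("Y", "A"))
  mut_seq <- seqv; mut_seq[subs$pos] <- subs$mut
  manual <- mean(vapply(subs$pos, function(j) {
    win <- max(1, j - 3):min(length(seqv), j + 3)
    mean(scale[mut_seq[win]]) - mean(scale[seqv[win]])
  }, numeric(1)))
  expect_equal(hydrophobicity_change(seqv, subs, scale), manual)
  expect_error(
    hydrophobicity_change(seqv, data.frame(pos = 99, mut = "A"), scale),
    "outside")
})
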