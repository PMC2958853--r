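# Max-margin training of per-triplet-type weights by linear
# programming, prediction, evaluation, and cross-validation.
#
# The LP (one weight w_t in [0,2] per triplet type seen in training,
# one free margin variable eps_i per training mutant, and the minimum
# margin mu):
#
#   max mu
#   s.t.  sum_{t in M_i} w_t Q_t - sum_{t in W_i} w_t Q_t >=  1 + eps_i   (i in I)
#         sum_{t in M_i} w_t Q_t - sum_{t in W_i} w_t Q_t <= -1 - eps_i   (i in D)
#         mu <= eps_i  for all i;   0 <= w_t <= 2.
#
# The class-D constraint uses the symmetric "-1 - eps_i" margin so that
# eps_i measures separation beyond the unit band for both classes; the
# asymmetric variant "-1 + eps_i" (under which class D never restricts
# the max-min objective) is available via d_sign = "printed".
#
# boot::simplex() requires non-negative variables, so eps_i and mu are
# shifted by a data-derived constant L large enough that the optimum is
# interior to the shift.

#' Build LP instances from mutants
#'
#' @param structures A named list of wild-type [residue_points] (names
#'   are structure ids), or a single structure used for every mutant.
#' @param mutants List of `mutation_record`s (see [read_mutant_table()]).
#' @param potential A scored `triplet_potential`.
#' @param cutoff Contact screen in Angstroms.
#' @return List of `lp_instance` objects: `id`, `label` (I/D or NA),
#'   `M`, `W` (key multisets over changed b = 0..4 faces).
#' @export
build_lp_instances <- function(structures, mutants, potential, cutoff = 9) {
  single <- inherits(structures, "residue_points")
  if (!single && is.null(names(structures)))
    stop("structure list must be named by structure id")
  cache <- new.env(parent = emptyenv())
  get_ctx <- function(id) {
    key <- if (single) ".single" else id
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- if (single) structures else structures[[id]]
    if (is.null(s)) stop("no structure supplied for id '", id, "'")
    tess <- delaunay_tessellation(s)
    fc <- face_classes(tess, cutoff = cutoff)
    fc <- fc[fc$b <= 4, , drop = FALSE]
    cache[[key]] <- list(s = s, tess = tess, fc = fc)
    cache[[key]]
  }
  lapply(seq_along(mutants), function(i) {
    m <- mutants[[i]]
    ctx <- get_ctx(m$structure_id)
    mw <- mutation_triplets(ctx$s, m, tess = ctx$tess, fc = ctx$fc)
    structure(list(id = instance_id(m, i), label = m$label,
                   M = mw$M, W = mw$W),
              class = "lp_instance")
  })
}

instance_id <- function(m, i) {
  muts <- paste0(m$substitutions$wt, m$substitutions$author_resnum,
                 m$substitutions$mut, collapse = "/")
  paste0(m$structure_id, ":", m$chain_id, ":", muts)
}

#' Train triplet-type weights by the max-margin LP
#'
#' @param instances List of labelled `lp_instance`s.
#' @param potential A scored `triplet_potential` supplying Q values.
#' @param d_sign `"margin"` (default; symmetric `-1 - eps_i` class-D
#'   constraint) or `"printed"` (`-1 + eps_i` variant, under which class
#'   D does not constrain the max-min objective).
#' @param tie_break Weight of the secondary objective resolving
#'   degenerate max-margin optima toward the pre-training default
#'   weight 1 (types not needed for the margin keep their default
#'   instead of drifting to an arbitrary vertex). Small relative to the
#'   margin scale; 0 disables it.
#' @param n_iter Simplex iteration cap.
#' @return An object of class `solubility_weights`: `w` (named vector in
#'   \[0,2\] over trained types, clipped for solver round-off), `mu`
#'   (optimal minimum margin), `epsilon` (named per-instance margins
#'   recomputed from the returned weights), `keys` (trained types),
#'   `d_sign`, `value` (raw LP objective).
#' @export
train_weights <- function(instances, potential,
                          d_sign = c("margin", "printed"),
                          tie_break = 1e-6, n_iter = NULL) {
  d_sign <- match.arg(d_sign)
  if (length(instances) < 1) stop("need at least one training instance")
  labels <- vapply(instances, `[[`, "", "label")
  if (!all(labels %in% c("I", "D")))
    stop("all training instances must be labelled I or D")
  qv <- q_lookup(potential)
  keys <- sort(unique(unlist(lapply(instances, function(x) c(x$M, x$W)))))
  # coefficient matrix: a[i, t] = (count in M_i - count in W_i) * Q_t
  A <- matrix(0, length(instances), length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(instances)) {
    d <- key_count_diff(instances[[i]]$M, instances[[i]]$W)
    A[i, names(d)] <- d * q_of(names(d), qv)
  }
  informative <- colSums(A != 0) > 0
  # types whose Q is zero everywhere cannot affect any score; they keep
  # the default weight 1 and stay out of the LP
  Ai <- A[, informative, drop = FALSE]
  nt <- ncol(Ai); ni <- nrow(Ai)
  if (nt == 0) stop("no informative triplet types (all Q zero?)")

  L <- 2 + 2 * max(rowSums(abs(Ai)))
  is_I <- labels == "I"
  rA <- rowSums(Ai)
  # The max-margin optimum is typically degenerate (many more triplet
  # types than instances); among optimal weight vectors we prefer the
  # one closest to the pre-training default w = 1, via a tiny secondary
  # penalty. Substituting w = 1 + u - v with u, v in [0, 1] keeps the LP
  # linear; tie_break scales the penalty (small enough not to disturb
  # the margin).
  # variables x = (u [nt], v [nt], e [ni], m [1]) >= 0 with the shift
  # e_i = eps_i + L, m = mu + L; all constraints as rows over x
  nv <- 2 * nt + ni + 1
  u_col <- seq_len(nt); v_col <- nt + seq_len(nt)
  e_col <- function(i) 2 * nt + i
  rows <- list(); rhs <- numeric(0)
  add_row <- function(r, b) {
    rows[[length(rows) + 1]] <<- r
    rhs <<- c(rhs, b)
  }
  for (i in seq_len(ni)) {
    r <- numeric(nv)
    if (is_I[i]) {
      # A_i w >= 1 + eps_i  ->  -A_i u + A_i v + e_i <= L - 1 + A_i 1
      r[u_col] <- -Ai[i, ]; r[v_col] <- Ai[i, ]; r[e_col(i)] <- 1
      add_row(r, L - 1 + rA[i])
    } else if (d_sign == "margin") {
      # A_i w <= -1 - eps_i  ->  A_i u - A_i v + e_i <= L - 1 - A_i 1
      r[u_col] <- Ai[i, ]; r[v_col] <- -Ai[i, ]; r[e_col(i)] <- 1
      add_row(r, L - 1 - rA[i])
    } else {
      # printed variant: A_i w <= -1 + eps_i
      r[u_col] <- Ai[i, ]; r[v_col] <- -Ai[i, ]; r[e_col(i)] <- -1
      add_row(r, -1 - L - rA[i])
    }
  }
  for (i in seq_len(ni)) {   # mu <= eps_i  ->  m - e_i <= 0
    r <- numeric(nv); r[e_col(i)] <- -1; r[nv] <- 1
    add_row(r, 0)
  }
  for (t in seq_len(nt)) {   # u_t <= 1 and v_t <= 1 (so w_t in [0, 2])
    r <- numeric(nv); r[u_col[t]] <- 1
    add_row(r, 1)
    r <- numeric(nv); r[v_col[t]] <- 1
    add_row(r, 1)
  }
  A1 <- do.call(rbind, rows)
  # boot::simplex needs non-negative right-hand sides: flip any
  # negative-rhs row into a >= constraint
  neg <- rhs < 0
  A1le <- A1[!neg, , drop = FALSE]; b1 <- rhs[!neg]
  A2ge <- -A1[neg, , drop = FALSE]; b2 <- -rhs[neg]
  obj <- c(rep(-tie_break, 2 * nt), numeric(ni), 1)
  if (is.null(n_iter)) n_iter <- 200 * (2 * nt + 2 * ni + 20)
  sol <- boot::simplex(a = obj, A1 = A1le, b1 = b1,
                       A2 = if (nrow(A2ge)) A2ge else NULL,
                       b2 = if (nrow(A2ge)) b2 else NULL,
                       maxi = TRUE, n.iter = n_iter, eps = 1e-10)
  if (sol$solved != 1)
    stop("LP solver failed (status ", sol$solved,
         "): ", if (sol$solved == 0) "iteration limit reached"
         else "no feasible solution / unbounded")
  x <- sol$soln
  w <- pmin(pmax(1 + x[u_col] - x[v_col], 0), 2)  # absorb round-off
  names(w) <- keys[informative]
  w_full <- stats::setNames(rep(1, length(keys)), keys)
  w_full[names(w)] <- w
  mu <- unname(x[nv] - L)
  score <- as.numeric(Ai %*% w)
  eps <- if (d_sign == "printed") ifelse(is_I, score - 1, score + 1)
         else ifelse(is_I, score, -score) - 1
  names(eps) <- vapply(instances, `[[`, "", "id")
  structure(list(w = w_full, mu = mu, epsilon = eps,
                 keys = keys, d_sign = d_sign,
                 value = unname(sol$value)),
            class = "solubility_weights")
}

#' @export
print.solubility_weights <- function(x, ...) {
  cat("LP-trained triplet weights: ", length(x$w), " types, mu = ",
      format(x$mu, digits = 4), " (", x$d_sign, " class-D sign)\n",
      sep = "")
  invisible(x)
}

#' Predict solubility change for test mutants
#'
#' The test score is `s_j = sum_{t in M_j} w_t Q_t - sum_{t in W_j}
#' w_t Q_t`, with weight exactly 1 for any singleton triplet type
#' (absent from training). `s_j > 0` predicts increase (I), `s_j < 0`
#' decrease (D); an exact tie predicts D and is flagged.
#'
#' @param instances List of `lp_instance`s (labels, if present, are
#'   ignored).
#' @param weights A `solubility_weights` from [train_weights()], or NULL
#'   for the unweighted score.
#' @param potential A scored `triplet_potential`.
#' @return Data frame: `id`, `score`, `pred`, `tie`, `n_singleton`.
#' @export
predict_solubility <- function(instances, weights, potential) {
  qv <- q_lookup(potential)
  trained <- if (is.null(weights)) character(0) else names(weights$w)
  rows <- lapply(instances, function(x) {
    keys <- c(x$M, x$W)
    wM <- w_of(x$M, weights, default = 1)
    wW <- w_of(x$W, weights, default = 1)
    s <- sum(wM * q_of(x$M, qv)) - sum(wW * q_of(x$W, qv))
    data.frame(id = x$id, score = s,
               pred = if (s > 0) "I" else "D",
               tie = s == 0,
               n_singleton = sum(!unique(keys) %in% trained),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate predicted against observed labels
#'
#' Class I is the positive class. The Matthews correlation coefficient
#' is 0 by convention when its denominator vanishes; a per-class
#' precision with no predictions of that class is reported as NA.
#'
#' @param pred,truth Character vectors over \{I, D\} of equal length.
#' @return An object of class `solubility_eval`: `tp`, `tn`, `fp`,
#'   `fn`, `accuracy`, `mcc`, `precision_I`, `precision_D`, `n`.
#' @export
evaluate_predictions <- function(pred, truth) {
  if (length(pred) == 0) stop("empty prediction vector")
  if (length(pred) != length(truth))
    stop("pred and truth differ in length")
  stopifnot(all(pred %in% c("I", "D")), all(truth %in% c("I", "D")))
  tp <- sum(pred == "I" & truth == "I")
  tn <- sum(pred == "D" & truth == "D")
  fp <- sum(pred == "I" & truth == "D")
  fn <- sum(pred == "D" & truth == "I")
  den <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(pred),
    mcc = mcc,
    precision_I = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    precision_D = if (tn + fn == 0) NA_real_ else tn / (tn + fn),
    n = length(pred)), class = "solubility_eval")
}

#' @export
print.solubility_eval <- function(x, ...) {
  cat(sprintf(
    "n = %d  accuracy = %.3f  MCC = %.3f  precision(I) = %s  precision(D) = %s\n",
    x$n, x$accuracy, x$mcc,
    ifelse(is.na(x$precision_I), "NA", sprintf("%.3f", x$precision_I)),
    ifelse(is.na(x$precision_D), "NA", sprintf("%.3f", x$precision_D))))
  cat(sprintf("confusion (I positive): TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Cross-validate the LP-trained scoring function
#'
#' Folds partition the instances exactly; for each fold, weights are
#' trained on the complement and the fold is predicted. `"loo"` uses n
#' singleton folds; `"kfold"` assigns folds by a seeded shuffle
#' (deterministic given `seed`); `"folds"` consumes an explicit
#' assignment (e.g. sequence-similarity folds from a file).
#'
#' @param instances Labelled `lp_instance`s.
#' @param potential A scored `triplet_potential`.
#' @param scheme `"loo"`, `"kfold"`, or `"folds"`.
#' @param k Number of folds for `"kfold"` (2 <= k <= n).
#' @param seed Seed for the `"kfold"` shuffle.
#' @param folds For `"folds"`: a named vector / two-column data frame
#'   (`mutant_id`, `fold_id`), or a path to a TSV with that header.
#' @param d_sign Passed to [train_weights()].
#' @return An object of class `solubility_cv`: `report` (pooled
#'   [evaluate_predictions()]), `per_fold` (list of reports),
#'   `predictions` (data frame with fold ids), `fold_assignment`.
#' @export
cross_validate <- function(instances, potential,
                           scheme = c("loo", "kfold", "folds"),
                           k = NULL, seed = NULL, folds = NULL,
                           d_sign = "margin") {
  scheme <- match.arg(scheme)
  n <- length(instances)
  ids <- vapply(instances, `[[`, "", "id")
  truth <- vapply(instances, `[[`, "", "label")
  assign <- switch(scheme,
    loo = seq_len(n),
    kfold = {
      if (is.null(k) || k < 2 || k > n)
        stop("kfold needs 2 <= k <= n (n = ", n, ")")
      if (is.null(seed)) stop("kfold needs a seed for reproducibility")
      with_local_seed(seed, sample(rep_len(seq_len(k), n)))
    },
    folds = {
      fmap <- read_fold_assignment(folds)
      unknown <- setdiff(names(fmap), ids)
      if (length(unknown))
        stop("fold file references unknown mutant(s): ",
             paste(unknown, collapse = ", "))
      missing <- setdiff(ids, names(fmap))
      if (length(missing))
        stop("fold file does not cover mutant(s): ",
             paste(missing, collapse = ", "))
      as.integer(factor(fmap[ids]))
    })
  fold_ids <- sort(unique(assign))
  preds <- vector("list", length(fold_ids))
  per_fold <- vector("list", length(fold_ids))
  for (fi in seq_along(fold_ids)) {
    test <- assign == fold_ids[fi]
    if (all(test)) stop("a fold contains every instance; nothing to train on")
    w <- train_weights(instances[!test], potential, d_sign = d_sign)
    p <- predict_solubility(instances[test], w, potential)
    p$fold <- fold_ids[fi]
    p$truth <- truth[test]
    preds[[fi]] <- p
    per_fold[[fi]] <- evaluate_predictions(p$pred, p$truth)
  }
  pred_all <- do.call(rbind, preds)
  structure(list(
    report = evaluate_predictions(pred_all$pred, pred_all$truth),
    per_fold = per_fold,
    predictions = pred_all,
    fold_assignment = stats::setNames(assign, ids),
    scheme = scheme), class = "solubility_cv")
}

read_fold_assignment <- function(folds) {
  if (is.character(folds) && length(folds) == 1 && file.exists(folds)) {
    df <- utils::read.delim(folds, stringsAsFactors = FALSE)
    if (!all(c("mutant_id", "fold_id") %in% names(df)))
      stop("fold file must have columns mutant_id, fold_id")
    return(stats::setNames(df$fold_id, df$mutant_id))
  }
  if (is.data.frame(folds))
    return(stats::setNames(folds[[2]], folds[[1]]))
  if (!is.null(names(folds))) return(folds)
  stop("folds must be a TSV path, a data frame, or a named vector")
}

#' @export
print.solubility_cv <- function(x, ...) {
  cat("Cross-validation (", x$scheme, ", ",
      length(x$per_fold), " folds)\npooled: ", sep = "")
  print(x$report)
  invisible(x)
}

#' Windowed hydrophobicity change of a mutation
#'
#' Per-residue average hydrophobicity `H_av(j)` is the mean scale value
#' over a 7-residue window centered at site j, truncated at the chain
#' termini. The change is mutant minus wild type, averaged over all
#' mutation sites (all substitutions are applied to the mutant sequence
#' before windowing).
#'
#' @param sequence Character vector of one-letter codes (or a single
#'   string).
#' @param substitutions Data frame with columns `pos` (1-based), `mut`,
#'   and optionally `wt` (checked against the sequence when present).
#' @param scale Named numeric vector mapping the 20 amino acids to
#'   hydrophobicity values.
#' @return The averaged change in windowed hydrophobicity.
#' @export
hydrophobicity_change <- function(sequence, substitutions, scale) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  stopifnot(all(sequence %in% aa_alphabet()),
            all(aa_alphabet() %in% names(scale)))
  L <- length(sequence)
  pos <- as.integer(substitutions$pos)
  if (any(pos < 1 | pos > L))
    stop("mutation site(s) outside the sequence: ",
         paste(pos[pos < 1 | pos > L], collapse = ", "))
  if (!is.null(substitutions$wt)) {
    mism <- sequence[pos] != substitutions$wt
    if (any(mism))
      stop("wild-type mismatch at position(s) ",
           paste(pos[mism], collapse = ", "))
  }
  mut_seq <- sequence
  mut_seq[pos] <- substitutions$mut
  h_av <- function(s, j) {
    win <- max(1, j - 3):min(L, j + 3)
    mean(scale[s[win]])
  }
  mean(vapply(pos, function(j) h_av(mut_seq, j) - h_av(sequence, j),
              numeric(1)))
}
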