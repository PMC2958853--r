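# Delaunay tessellation of residue points.
#
# Incremental Bowyer-Watson insertion into a large enclosing
# super-tetrahedron. For every inserted point, all tetrahedra whose
# circumsphere contains the point are removed and the star of the point
# over the cavity boundary is re-created. Simplices touching the
# super-tetrahedron are discarded at the end, leaving the Delaunay
# tessellation of the convex hull of the input.
#
# All simplex tuples in the returned object are 0-based seq_index values
# (matching the residue_points convention), sorted ascending within each
# tuple.

#' Delaunay tessellation of residue points
#'
#' No distance cutoff is applied at this stage; the tessellation covers
#' the full convex hull. Use [screen_faces()] afterwards to restrict
#' three-body contacts to biochemically relevant distances.
#'
#' @param points A [residue_points] data frame, or a plain n x 3
#'   coordinate matrix.
#' @param jitter Magnitude (Angstroms) of a deterministic symmetry-breaking
#'   perturbation applied to the coordinates before tessellating; 0
#'   (default) disables it. Use a small value such as 1e-6 for exactly
#'   cospherical inputs (e.g. points on a lattice).
#' @param jitter_seed Seed for the jitter stream (default 0); the caller's
#'   RNG state is untouched.
#' @return An object of class `tessellation`: a list with `points`,
#'   `tetrahedra` (T x 4 integer matrix), `faces` (F x 3), `face_count`
#'   (occurrences of each face among tetrahedra, 1 or 2), `edges` (E x 2)
#'   and `T` (number of tetrahedra).
#' @export
delaunay_tessellation <- function(points, jitter = 0, jitter_seed = 0L) {
  pts_df <- if (inherits(points, "residue_points")) points else NULL
  P <- coord_matrix(points)
  n <- nrow(P)
  if (n < 4) stop("need at least 4 points to tessellate, got ", n)
  if (qr(sweep(P, 2, colMeans(P)))$rank < 3)
    stop("degenerate input: points are coplanar or collinear")
  if (jitter > 0) {
    P <- P + with_local_seed(jitter_seed,
      matrix(stats::runif(3 * n, -jitter, jitter), n, 3))
  }

  ctr <- colMeans(P)
  scale <- max(sqrt(max(rowSums(sweep(P, 2, ctr)^2))), 1)
  # slightly irregular enclosing tetrahedron: exact symmetry here makes
  # axis-aligned inputs coplanar with cavity faces during insertion
  sv <- rbind(c(1.000, 1.043, 0.957), c(1.029, -0.973, -1.013),
              c(-0.991, 1.017, -1.061), c(-1.051, -0.987, 1.023))
  sv <- sweep(sv * scale * 1e4, 2, ctr, "+")
  V <- rbind(P, sv)

  cap <- 24L * n + 64L
  tets <- matrix(0L, cap, 4)
  cc <- matrix(0, cap, 3)
  r2 <- numeric(cap)
  alive <- logical(cap)
  ntet <- 0L

  push_tet <- function(idx) {
    q <- V[idx, , drop = FALSE]
    A <- 2 * sweep(q[2:4, , drop = FALSE], 2, q[1, ])
    bb <- rowSums(q[2:4, , drop = FALSE]^2) - sum(q[1, ]^2)
    cen <- tryCatch(solve(A, bb), error = function(e) NULL)
    if (is.null(cen))
      stop("degenerate (coplanar) tetrahedron encountered; ",
           "retry with jitter = 1e-6")
    if (ntet == cap) {  # grow storage
      cap <<- cap * 2L
      tets2 <- matrix(0L, cap, 4); tets2[1:ntet, ] <- tets; tets <<- tets2
      cc2 <- matrix(0, cap, 3); cc2[1:ntet, ] <- cc; cc <<- cc2
      length(r2) <<- cap; length(alive) <<- cap
    }
    ntet <<- ntet + 1L
    tets[ntet, ] <<- idx
    cc[ntet, ] <<- cen
    r2[ntet] <<- sum((cen - q[1, ])^2)
    alive[ntet] <<- TRUE
  }

  push_tet(as.integer(n + 1:4))

  for (p in seq_len(n)) {
    ai <- which(alive[seq_len(ntet)])
    d2 <- (cc[ai, 1] - V[p, 1])^2 + (cc[ai, 2] - V[p, 2])^2 +
      (cc[ai, 3] - V[p, 3])^2
    bad <- ai[d2 < r2[ai]]
    if (length(bad) == 0)
      stop("point location failed at point ", p,
           "; input may be degenerate (retry with jitter = 1e-6)")
    ff <- tet_faces(tets[bad, , drop = FALSE])
    key <- paste(ff[, 1], ff[, 2], ff[, 3])
    dupe <- key %in% key[duplicated(key)]
    boundary <- ff[!dupe, , drop = FALSE]
    alive[bad] <- FALSE
    for (k in seq_len(nrow(boundary)))
      push_tet(c(boundary[k, ], p))
  }

  final <- tets[which(alive[seq_len(ntet)]), , drop = FALSE]
  final <- final[rowSums(final > n) == 0, , drop = FALSE]
  if (nrow(final) == 0)
    stop("tessellation produced no tetrahedra; input likely degenerate")

  final <- t(apply(final, 1, sort))
  ff <- tet_faces(final)
  fkey <- paste(ff[, 1], ff[, 2], ff[, 3])
  cnt <- table(fkey)
  ufaces <- ff[!duplicated(fkey), , drop = FALSE]
  face_count <- as.integer(cnt[paste(ufaces[, 1], ufaces[, 2], ufaces[, 3])])
  if (any(face_count > 2))
    stop("inconsistent tessellation (a triangle in >2 tetrahedra); ",
         "input likely near-degenerate, retry with jitter = 1e-6")
  ord <- order(ufaces[, 1], ufaces[, 2], ufaces[, 3])
  ufaces <- ufaces[ord, , drop = FALSE]
  face_count <- face_count[ord]

  ee <- tet_edges(final)
  ekey <- paste(ee[, 1], ee[, 2])
  uedges <- ee[!duplicated(ekey), , drop = FALSE]
  uedges <- uedges[order(uedges[, 1], uedges[, 2]), , drop = FALSE]

  structure(
    list(points = pts_df,
         coords = P,
         tetrahedra = final - 1L,  # 0-based seq_index
         faces = ufaces - 1L,
         face_count = face_count,
         edges = uedges - 1L,
         T = nrow(final)),
    class = "tessellation"
  )
}

# the four faces of each tetrahedron row, each face sorted ascending
tet_faces <- function(tm) {
  drop_col <- function(j) {
    m <- tm[, -j, drop = FALSE]
    sort3(m)
  }
  do.call(rbind, lapply(1:4, drop_col))
}

tet_edges <- function(tm) {
  pairs <- utils::combn(4, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- tm[, pairs[1, k]]; b <- tm[, pairs[2, k]]
    cbind(pmin(a, b), pmax(a, b))
  }))
  out
}

# row-wise sort of an m x 3 integer matrix
sort3 <- function(m) {
  lo <- pmin(m[, 1], m[, 2], m[, 3])
  hi <- pmax(m[, 1], m[, 2], m[, 3])
  cbind(lo, m[, 1] + m[, 2] + m[, 3] - lo - hi, hi, deparse.level = 0)
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Delaunay tessellation: ", nrow(x$coords), " points, ",
      x$T, " tetrahedra, ", nrow(x$faces), " faces, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Screen three-body contacts by edge length
#'
#' Keeps the faces whose three edges are all no longer than `cutoff`
#' (default 9 Angstroms), selecting biochemically relevant contacts.
#' Buriedness flags are assigned on the full tessellation and are not
#' affected by screening.
#'
#' @param tess A [delaunay_tessellation()] result.
#' @param cutoff Maximum edge length in Angstroms; `Inf` keeps everything.
#' @return Integer vector: row indices into `tess$faces` of the faces
#'   that pass the screen.
#' @export
screen_faces <- function(tess, cutoff = 9) {
  stopifnot(inherits(tess, "tessellation"), cutoff > 0)
  P <- tess$coords
  f <- tess$faces + 1L
  d <- function(a, b) sqrt(rowSums((P[a, , drop = FALSE] -
                                      P[b, , drop = FALSE])^2))
  keep <- d(f[, 1], f[, 2]) <= cutoff &
    d(f[, 1], f[, 3]) <= cutoff &
    d(f[, 2], f[, 3]) <= cutoff
  which(keep)
}

#' Edge lengths of screened faces (for reporting)
#'
#' @param tess A tessellation.
#' @param idx Face row indices (default all).
#' @return Matrix with columns `d12`, `d13`, `d23` in Angstroms.
#' @export
face_edge_lengths <- function(tess, idx = seq_len(nrow(tess$faces))) {
  P <- tess$coords
  f <- tess$faces[idx, , drop = FALSE] + 1L
  d <- function(a, b) sqrt(rowSums((P[a, , drop = FALSE] -
                                      P[b, , drop = FALSE])^2))
  cbind(d12 = d(f[, 1], f[, 2]), d13 = d(f[, 1], f[, 3]),
        d23 = d(f[, 2], f[, 3]))
}
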