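# Combinatorial buriedness of Delaunay simplices.
#
# A triangle is buried when it is shared by two tetrahedra; a triangle in
# one tetrahedron is on the surface. An edge or vertex is non-buried when
# it belongs to at least one non-buried triangle, and buried otherwise.
# These definitions induce 4 two-body classes (edges) and 9 three-body
# classes (triangles), counted over the buried component simplices.

# canonical three-body class index, keyed by "<buried vertices>.<buried edges>"
# among configurations with a buried face; the all-surface configuration is
# class 0. Ordering: total buried simplices ascending, ties broken by the
# number of buried edges ascending.
TRIANGLE_CLASS_TABLE <- c(
  "0.0" = 1L, "0.1" = 2L, "0.2" = 3L, "1.2" = 4L,
  "0.3" = 5L, "1.3" = 6L, "2.3" = 7L, "3.3" = 8L
)

#' Assign Delaunay buriedness flags
#'
#' Follows the three-pass list algorithm: the tetrahedron list is swept
#' once to split triangles into surface (seen once) and buried (seen
#' twice) lists; the buried list is swept marking subsimplices buried;
#' the surface list is swept marking subsimplices non-buried (a surface
#' membership always wins). Runs in O(T) time and space for T tetrahedra.
#'
#' @param tess A [delaunay_tessellation()] result.
#' @return An object of class `buriedness_map`: list with `face_buried`
#'   (logical, aligned with `tess$faces`), `edge_buried` (logical, named
#'   by `"i:j"` seq_index pairs), `vertex_buried` (logical, indexed by
#'   seq_index + 1).
#' @export
assign_buriedness <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  n <- nrow(tess$coords)

  # pass 1: split triangles into surface / buried lists from the
  # tetrahedron sweep (first sighting -> surface, second -> buried)
  ff <- tet_faces(tess$tetrahedra + 1L)
  fkey <- paste(ff[, 1], ff[, 2], ff[, 3])
  seen_twice <- fkey %in% fkey[duplicated(fkey)]
  uf <- ff[!duplicated(fkey), , drop = FALSE]
  uf_buried <- seen_twice[!duplicated(fkey)]

  # align with the face table of the tessellation
  tkey1 <- paste(tess$faces[, 1] + 1L, tess$faces[, 2] + 1L,
                 tess$faces[, 3] + 1L)
  face_buried <- uf_buried[match(tkey1, paste(uf[, 1], uf[, 2], uf[, 3]))]
  tkey <- paste(tess$faces[, 1], tess$faces[, 2], tess$faces[, 3])

  # pass 2a: buried faces mark subsimplices buried
  vertex_buried <- rep(FALSE, n)
  ekey_all <- paste(tess$edges[, 1], tess$edges[, 2], sep = ":")
  edge_buried <- structure(rep(FALSE, nrow(tess$edges)), names = ekey_all)
  bf <- tess$faces[face_buried, , drop = FALSE]
  vertex_buried[unique(as.vector(bf)) + 1L] <- TRUE
  edge_buried[face_edge_keys(bf)] <- TRUE
  # pass 2b: surface faces override to non-buried
  sf <- tess$faces[!face_buried, , drop = FALSE]
  vertex_buried[unique(as.vector(sf)) + 1L] <- FALSE
  edge_buried[face_edge_keys(sf)] <- FALSE

  structure(
    list(face_buried = face_buried, edge_buried = edge_buried,
         vertex_buried = vertex_buried, face_key = tkey),
    class = "buriedness_map"
  )
}

# the three edge keys ("i:j", i<j, seq_index) of each face row (0-based)
face_edge_keys <- function(fm) {
  c(paste(fm[, 1], fm[, 2], sep = ":"),
    paste(fm[, 1], fm[, 3], sep = ":"),
    paste(fm[, 2], fm[, 3], sep = ":"))
}

#' Two-body buriedness class of an edge
#'
#' The class (0-3) counts how many of the edge's component simplices
#' (two vertices and the edge itself) are buried.
#'
#' @param edge Integer pair of seq_index values.
#' @param map A [assign_buriedness()] result.
#' @return Integer in 0..3.
#' @export
two_body_class <- function(edge, map) {
  edge <- sort(as.integer(edge))
  key <- paste(edge[1], edge[2], sep = ":")
  if (!key %in% names(map$edge_buried))
    stop("edge (", key, ") not present in the tessellation")
  nv <- sum(map$vertex_buried[edge + 1L])
  cls <- nv + as.integer(map$edge_buried[[key]])
  validate_edge_config(nv, map$edge_buried[[key]])
  cls
}

#' Three-body buriedness class of a face
#'
#' The nine classes 0-8 run from completely non-buried (0) to completely
#' buried (8); see [enumerate_triangle_classes()] for the canonical
#' ordering.
#'
#' @param face Integer triple of seq_index values.
#' @param map A [assign_buriedness()] result.
#' @return Integer in 0..8.
#' @export
three_body_class <- function(face, map) {
  face <- sort(as.integer(face))
  classify_faces(matrix(face, 1), map)
}

# vectorised classification of 0-based face rows
classify_faces <- function(fm, map) {
  nv <- (map$vertex_buried[fm[, 1] + 1L] + map$vertex_buried[fm[, 2] + 1L] +
           map$vertex_buried[fm[, 3] + 1L])
  ek <- matrix(face_edge_keys(fm), ncol = 3)
  missing_e <- !(ek %in% names(map$edge_buried))
  if (any(missing_e))
    stop("face edge(s) not present in the tessellation: ",
         paste(unique(ek[missing_e]), collapse = ", "))
  ne <- (map$edge_buried[ek[, 1]] + map$edge_buried[ek[, 2]] +
           map$edge_buried[ek[, 3]])
  fb <- face_lookup(fm, map)
  cls <- ifelse(!fb, 0L,
                unname(TRIANGLE_CLASS_TABLE[paste(nv, ne, sep = ".")]))
  bad <- (!fb & (nv > 0 | ne > 0)) | (fb & is.na(cls))
  if (any(bad))
    stop("buriedness configuration outside the 9 valid classes; ",
         "corrupted buriedness map")
  as.integer(cls)
}

# face_buried flag looked up by face tuple; the map stores flags aligned
# with the tessellation face table, so carry the key alongside
face_lookup <- function(fm, map) {
  key <- paste(fm[, 1], fm[, 2], fm[, 3])
  i <- match(key, map$face_key)
  if (anyNA(i))
    stop("face (", key[which(is.na(i))[1]], ") not present in the tessellation")
  map$face_buried[i]
}

validate_edge_config <- function(nv, eb) {
  # a non-buried edge forces both endpoints non-buried
  if (!eb && nv > 0)
    stop("invalid two-body configuration (non-buried edge with buried ",
         "endpoint); corrupted buriedness map")
  invisible(TRUE)
}

#' Backbone connectivity class of a residue triple
#'
#' Counts sequence-adjacent pairs (seq_index differing by 1) among the
#' three residues: 0, 1 or 2 bonded edges.
#'
#' @param r Integer vector of three distinct seq_index values, or an
#'   m x 3 matrix of triples (classified row-wise).
#' @return Integer vector in 0..2.
#' @export
connectivity_class <- function(r) {
  if (!is.matrix(r)) r <- matrix(as.integer(r), ncol = 3)
  if (any(r[, 1] == r[, 2] | r[, 1] == r[, 3] | r[, 2] == r[, 3]))
    stop("duplicate residue indices in triple")
  s <- sort3(r)
  as.integer((s[, 2] - s[, 1] == 1L) + (s[, 3] - s[, 2] == 1L))
}

#' Enumerate the valid triangle buriedness configurations
#'
#' All assignments of buried/non-buried to the 3 vertices, 3 edges, and
#' face of a triangle that satisfy the defining constraints (a non-buried
#' face forces all subsimplices non-buried; a non-buried edge forces both
#' endpoints non-buried), reduced modulo triangle symmetry. Classes are
#' indexed by total number of buried simplices ascending, ties broken by
#' buried edge count ascending.
#'
#' @return Data frame with one row per class: `class`, `face_buried`,
#'   `n_buried_edges`, `n_buried_vertices`, `n_buried_total`.
#' @export
enumerate_triangle_classes <- function() {
  grid <- expand.grid(v1 = 0:1, v2 = 0:1, v3 = 0:1,
                      e12 = 0:1, e13 = 0:1, e23 = 0:1, f = 0:1)
  ok <- apply(grid, 1, function(g) {
    v <- g[1:3]; e <- g[4:6]; f <- g[7]
    if (f == 0 && (any(v == 1) || any(e == 1))) return(FALSE)
    # edge non-buried => both endpoints non-buried
    ends <- rbind(c(1, 2), c(1, 3), c(2, 3))
    for (k in 1:3) if (e[k] == 0 && any(v[ends[k, ]] == 1)) return(FALSE)
    TRUE
  })
  valid <- grid[ok, , drop = FALSE]
  # orbit representative under the 6 vertex permutations
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  edge_of <- function(i, j) c("12" = 1, "13" = 2, "23" = 3)[[
    paste0(min(i, j), max(i, j))]]
  canon <- apply(valid, 1, function(g) {
    reps <- apply(perms, 1, function(p) {
      v <- g[1:3][p]
      e <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr)
        g[3 + edge_of(p[pr[1]], p[pr[2]])])
      paste(c(v, e, g[7]), collapse = "")
    })
    min(reps)
  })
  uniq <- valid[!duplicated(canon), , drop = FALSE]
  out <- data.frame(
    face_buried = uniq$f == 1,
    n_buried_edges = uniq$e12 + uniq$e13 + uniq$e23,
    n_buried_vertices = uniq$v1 + uniq$v2 + uniq$v3
  )
  out$n_buried_total <- out$n_buried_vertices + out$n_buried_edges +
    as.integer(out$face_buried)
  out <- out[order(out$n_buried_total, out$n_buried_edges), , drop = FALSE]
  out <- cbind(class = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  out
}

#' Enumerate the valid edge buriedness configurations
#'
#' The two-body analogue of [enumerate_triangle_classes()]: assignments
#' of buried/non-buried to 2 vertices and the edge, constrained so a
#' non-buried edge has non-buried endpoints, modulo swapping endpoints.
#'
#' @return Data frame with one row per class: `class`, `edge_buried`,
#'   `n_buried_vertices`, `n_buried_total`.
#' @export
enumerate_edge_classes <- function() {
  grid <- expand.grid(v1 = 0:1, v2 = 0:1, e = 0:1)
  ok <- !(grid$e == 0 & (grid$v1 == 1 | grid$v2 == 1))
  valid <- grid[ok, , drop = FALSE]
  canon <- paste(pmin(valid$v1, valid$v2), pmax(valid$v1, valid$v2), valid$e)
  uniq <- valid[!duplicated(canon), , drop = FALSE]
  out <- data.frame(
    edge_buried = uniq$e == 1,
    n_buried_vertices = uniq$v1 + uniq$v2
  )
  out$n_buried_total <- out$n_buried_vertices + as.integer(out$edge_buried)
  out <- out[order(out$n_buried_total), , drop = FALSE]
  out <- cbind(class = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  out
}

#' Classify all faces of a tessellation
#'
#' One row per (optionally screened) face with residue indices, sorted
#' amino-acid composition, connectivity class `c` and buriedness class
#' `b`, plus the triplet-type key used by the potential and weight
#' tables.
#'
#' @param tess A tessellation built from a [residue_points] table (amino
#'   acids are needed for the composition).
#' @param map Optional precomputed [assign_buriedness()] map.
#' @param cutoff Edge-length screen in Angstroms applied after buriedness
#'   assignment; `Inf` disables it.
#' @return Data frame: `r1, r2, r3` (seq_index), `aa1, aa2, aa3`
#'   (alphabetical), `c`, `b`, `key`.
#' @export
face_classes <- function(tess, map = NULL, cutoff = 9) {
  stopifnot(inherits(tess, "tessellation"))
  if (is.null(tess$points))
    stop("tessellation was built from bare coordinates; amino-acid ",
         "composition unavailable")
  if (is.null(map)) map <- assign_buriedness(tess)
  idx <- screen_faces(tess, cutoff)
  fm <- tess$faces[idx, , drop = FALSE]
  b <- classify_faces(fm, map)
  cc <- connectivity_class(fm)
  aa <- matrix(tess$points$aa[fm + 1L], ncol = 3)
  aa <- t(apply(aa, 1, sort))
  out <- data.frame(
    r1 = fm[, 1], r2 = fm[, 2], r3 = fm[, 3],
    aa1 = aa[, 1], aa2 = aa[, 2], aa3 = aa[, 3],
    c = cc, b = b, stringsAsFactors = FALSE
  )
  out$key <- triplet_key(out$aa1, out$aa2, out$aa3, out$c, out$b)
  out
}
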