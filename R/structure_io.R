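# Structure and table input/output.
#
# A structure is reduced to one labelled 3D point per residue (the
# "unified residue" representation): the centroid of the side-chain heavy
# atoms, falling back to CA for glycine or residues with no resolved
# side-chain atoms.

#' Construct a residue-point table
#'
#' @param chain_id Chain identifier (single string).
#' @param aa Character vector of one-letter amino-acid codes.
#' @param coords Numeric matrix (n x 3) of residue centers in Angstroms.
#' @param author_resnum Character vector of author residue numbers
#'   (PDB numbering plus insertion code). Defaults to `1:n`.
#' @return A `data.frame` of class `residue_points` with columns
#'   `chain_id`, `seq_index` (0-based, consecutive in chain order),
#'   `author_resnum`, `aa`, `x`, `y`, `z`.
#' @export
residue_points <- function(chain_id, aa, coords, author_resnum = NULL) {
  coords <- as.matrix(coords)
  n <- length(aa)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  bad <- setdiff(unique(aa), aa_alphabet())
  if (length(bad) > 0)
    stop("non-standard amino-acid code(s): ", paste(bad, collapse = ", "))
  if (is.null(author_resnum)) author_resnum <- as.character(seq_len(n))
  out <- data.frame(
    chain_id = rep_len(as.character(chain_id), n),
    seq_index = seq_len(n) - 1L,
    author_resnum = as.character(author_resnum),
    aa = as.character(aa),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE
  )
  class(out) <- c("residue_points", "data.frame")
  out
}

coord_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    return(unname(points))
  }
  unname(as.matrix(points[, c("x", "y", "z")]))
}

#' Read a PDB chain as residue points
#'
#' Parses ATOM records of one chain and reduces each standard residue to a
#' single point: the centroid of its side-chain heavy atoms (all non-H
#' atoms except N, CA, C, O, OXT), or the CA position when no side-chain
#' atom is present (glycine, unresolved side chains). Only the first
#' alternate conformer is kept; HETATM records, waters and non-standard
#' residues are dropped (the latter with a warning). Multi-model files use
#' the first model.
#'
#' @param pdb Path to a PDB file, or a character scalar holding PDB text.
#' @param chain_id Chain identifier to extract.
#' @return A [residue_points] data frame ordered by file appearance.
#' @export
read_structure <- function(pdb, chain_id) {
  path <- pdb
  if (length(pdb) == 1 && (grepl("\n", pdb) || grepl("^(ATOM|HEADER|MODEL)", pdb))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    on.exit(unlink(path))
  }
  parsed <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain_id %in% chains)
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain_id, , drop = FALSE]
  # first conformer only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  # drop hydrogens (element symbol if present, else atom-name heuristic)
  if (!is.null(at$elesy) && any(!is.na(at$elesy))) {
    at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  } else {
    at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  }
  nonstd <- !(at$resid %in% names(AA_ONE))
  if (any(nonstd)) {
    warning("excluding ", length(unique(at$resno[nonstd])),
            " non-standard residue(s): ",
            paste(unique(at$resid[nonstd]), collapse = ", "))
    at <- at[!nonstd, , drop = FALSE]
  }
  if (nrow(at) == 0)
    stop("no standard-residue ATOM records for chain '", chain_id, "'")
  ins <- ifelse(is.na(at$insert), "", at$insert)
  rid <- paste0(at$resno, ins)
  rid_order <- unique(rid)  # file order
  aa <- character(0); ctr <- NULL; keep_rid <- character(0)
  for (r in rid_order) {
    sub <- at[rid == r, , drop = FALSE]
    side <- sub[!(sub$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(side) > 0) {
      p <- c(mean(side$x), mean(side$y), mean(side$z))
    } else {
      ca <- sub[sub$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0) {
        warning("residue ", r, " has neither side-chain atoms nor CA; skipped")
        next
      }
      p <- c(ca$x[1], ca$y[1], ca$z[1])
    }
    aa <- c(aa, AA_ONE[[sub$resid[1]]])
    ctr <- rbind(ctr, p)
    keep_rid <- c(keep_rid, r)
  }
  residue_points(chain_id, aa, ctr, keep_rid)
}

#' Parse a mutant table
#'
#' Expected CSV columns: `structure_id,chain,mutations,label`. The
#' mutations field uses compact notation (`K97R`), with multi-point
#' mutants joined by `/` and optionally parenthesised:
#' `(T17S/N68D/I77V)`. Labels are `I` (solubility increases) or `D`
#' (decreases).
#'
#' @param csv Path to a CSV file, or a character scalar of CSV text.
#' @return A list of `mutation_record` objects, each a list with elements
#'   `structure_id`, `chain_id`, `substitutions` (data frame with columns
#'   `author_resnum`, `wt`, `mut`) and `label`.
#' @export
read_mutant_table <- function(csv) {
  if (length(csv) == 1 && grepl("\n", csv)) {
    df <- utils::read.csv(text = csv, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    df <- utils::read.csv(csv, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  need <- c("structure_id", "chain", "mutations", "label")
  if (!all(need %in% names(df)))
    stop("mutant table must have columns: ", paste(need, collapse = ","))
  lapply(seq_len(nrow(df)), function(i) {
    subs <- parse_mutations(df$mutations[i], row = i)
    lab <- df$label[i]
    if (!lab %in% c("I", "D"))
      stop("row ", i, ": label must be I or D, got '", lab, "'")
    if (all(subs$wt == subs$mut))
      stop("row ", i, ": no substitution changes the amino acid")
    mutation_record(df$structure_id[i], df$chain[i], subs, lab)
  })
}

#' @rdname read_mutant_table
#' @param structure_id,chain_id,substitutions,label Record fields; see above.
#' @export
mutation_record <- function(structure_id, chain_id, substitutions, label) {
  stopifnot(nrow(substitutions) >= 1)
  structure(
    list(structure_id = structure_id, chain_id = chain_id,
         substitutions = substitutions, label = label),
    class = "mutation_record"
  )
}

parse_mutations <- function(s, row = NA) {
  s <- gsub("[()\\s]", "", s, perl = TRUE)
  toks <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(toks) == 0)
    stop("row ", row, ": empty mutation field")
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+[A-Za-z]?)([A-Z])$", toks))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("row ", row, ": malformed mutation token(s): ",
         paste(toks[bad], collapse = ", "))
  aa_ok <- function(x) x %in% aa_alphabet()
  wt <- vapply(m, `[`, "", 2); pos <- vapply(m, `[`, "", 3)
  mut <- vapply(m, `[`, "", 4)
  if (!all(aa_ok(wt)) || !all(aa_ok(mut)))
    stop("row ", row, ": unknown amino-acid code in mutation field")
  data.frame(author_resnum = pos, wt = wt, mut = mut,
             stringsAsFactors = FALSE)
}

#' Write a mutant table
#'
#' @param records List of `mutation_record` objects.
#' @param path Output CSV path.
#' @export
write_mutant_table <- function(records, path) {
  rows <- vapply(records, function(r) {
    muts <- paste0(r$substitutions$wt, r$substitutions$author_resnum,
                   r$substitutions$mut, collapse = "/")
    if (nrow(r$substitutions) > 1) muts <- paste0("(", muts, ")")
    paste(r$structure_id, r$chain_id, muts, r$label, sep = ",")
  }, "")
  writeLines(c("structure_id,chain,mutations,label", rows), path)
  invisible(path)
}

POTENTIAL_COLS <- c("aa1", "aa2", "aa3", "c", "b", "count", "Q")
WEIGHT_COLS <- c("aa1", "aa2", "aa3", "c", "b", "w")

#' Read and write potential tables
#'
#' Tab-separated with header `aa1 aa2 aa3 c b count Q`; amino acids are
#' sorted alphabetically within each row. Write-then-read is the identity
#' on keys and values to full stored precision.
#'
#' @param x Data frame with the potential columns.
#' @param path File path.
#' @return `read_potential_table` returns the data frame (with any
#'   `aa_freq`/`p_cb` metadata lost; scores `Q` are self-contained).
#' @export
write_potential_table <- function(x, path) {
  stopifnot(all(POTENTIAL_COLS %in% names(x)))
  utils::write.table(format_full(x[POTENTIAL_COLS]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_potential_table
#' @export
read_potential_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(POTENTIAL_COLS %in% names(df)))
    stop("potential table must have columns: ",
         paste(POTENTIAL_COLS, collapse = ", "))
  check_triplet_keys(df)
  class(df) <- c("triplet_potential", "data.frame")
  df
}

#' Read and write weight tables
#'
#' Tab-separated with header `aa1 aa2 aa3 c b w`; weights must lie in
#' \[0, 2\] (reading a violating row is an error).
#'
#' @param x Data frame with the weight columns, or a named weight vector
#'   as produced by [train_weights()] (keys `aa1:aa2:aa3:c:b`).
#' @param path File path.
#' @export
write_weight_table <- function(x, path) {
  if (is.numeric(x) && !is.null(names(x))) {
    parts <- do.call(rbind, strsplit(names(x), ":", fixed = TRUE))
    x <- data.frame(aa1 = parts[, 1], aa2 = parts[, 2], aa3 = parts[, 3],
                    c = as.integer(parts[, 4]), b = as.integer(parts[, 5]),
                    w = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(all(WEIGHT_COLS %in% names(x)))
  utils::write.table(format_full(x[WEIGHT_COLS]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(WEIGHT_COLS %in% names(df)))
    stop("weight table must have columns: ",
         paste(WEIGHT_COLS, collapse = ", "))
  check_triplet_keys(df)
  if (any(df$w < 0 | df$w > 2))
    stop("weight(s) outside [0, 2] in ", path)
  df
}

check_triplet_keys <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  ok_aa <- df$aa1 %in% aa_alphabet() & df$aa2 %in% aa_alphabet() &
    df$aa3 %in% aa_alphabet()
  if (!all(ok_aa)) stop("unknown amino-acid code in table")
  if (!all(df$aa1 <= df$aa2 & df$aa2 <= df$aa3))
    stop("amino acids must be sorted alphabetically within each row")
  if (!all(df$c %in% 0:2)) stop("connectivity class c out of range 0..2")
  if (!all(df$b %in% 0:8)) stop("buriedness class b out of range 0..8")
  invisible(df)
}

# full-precision numeric formatting for table round-trips
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

triplet_key <- function(aa1, aa2, aa3, c, b) {
  paste(aa1, aa2, aa3, c, b, sep = ":")
}
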