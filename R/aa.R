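# Amino-acid alphabets shared across modules.

#' The 20 standard one-letter amino-acid codes
#'
#' Alphabetically ordered; this is the alphabet over which triplet
#' compositions and background frequencies are defined.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# one-letter -> three-letter
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# three-letter -> one-letter
AA_ONE <- structure(names(AA_THREE), names = unname(AA_THREE))

# backbone atom names excluded from the side-chain centroid
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# run code with a private RNG stream, restoring the caller's stream after
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
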