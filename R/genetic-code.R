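#' The standard genetic code over the 61 sense codons
#'
#' The codon state space used throughout the package.  Codons are ordered
#' lexicographically by nucleotide (A < C < G < T), and the 61 sense codons
#' of the standard code (all 64 triplets minus TAA, TAG, TGA) define the
#' state indexing of every frequency vector, rate matrix and transition
#' matrix in the package.
#'
#' @return A list with components:
#'   \item{codons}{character(64), all triplets in lexicographic order.}
#'   \item{sense}{character(61), the sense codons in lexicographic order.}
#'   \item{stop}{character(3), the stop codons.}
#'   \item{aa}{named character(61), amino acid (one-letter) per sense codon.}
#' @examples
#' gc <- genetic_code()
#' gc$sense[1:4]
#' @export
genetic_code <- function() .hearsel_code

# built once at load; Biostrings supplies the standard code table
.build_code <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste0,
                  collapse = "")
  codons <- sort(codons)
  aa <- Biostrings::GENETIC_CODE[codons]
  stopifnot(sum(aa == "*") == 3L)
  sense <- codons[aa != "*"]
  list(codons = codons, sense = sense,
       stop = codons[aa == "*"], aa = aa[aa != "*"])
}

# Precomputed structural masks over sense-codon pairs, used to assemble
# Goldman-Yang rate matrices without re-deriving the code each call.
# one_diff: pair differs at exactly one nucleotide position
# transition: that differing pair is A<->G or C<->T
# nonsyn: the two codons encode different amino acids
.build_code_masks <- function(code) {
  n <- length(code$sense)
  mat <- do.call(rbind, strsplit(code$sense, ""))
  ndiff <- matrix(0L, n, n)
  trans <- matrix(FALSE, n, n)
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (k in 1:3) {
    d <- outer(mat[, k], mat[, k], "!=")
    ndiff <- ndiff + d
    trans <- trans | (d & outer(mat[, k], mat[, k], is_ts))
  }
  one <- ndiff == 1L
  nonsyn <- outer(code$aa, code$aa, "!=")
  # flat indices of the single-difference pairs, for fast Q assembly
  pos <- which(one)
  list(one_diff = one, transition = trans & one, nonsyn = nonsyn & one,
       pair_pos = pos,
       pair_col = ((pos - 1L) %/% n) + 1L,  # target codon j of each pair
       pair_ts = (trans & one)[pos],
       pair_ns = (nonsyn & one)[pos])
}

#' Map codon strings to sense-codon state indices
#'
#' @param x character vector of codon 3-mers (uppercase).
#' @return integer vector of indices into `genetic_code()$sense`; NA for
#'   strings that are not sense codons.
#' @keywords internal
codon_index <- function(x) match(x, .hearsel_code$sense)

# expand a codon possibly containing IUPAC ambiguity letters or gap
# characters into the set of compatible sense-codon indices.  Returns
# integer(0) when nothing is compatible (e.g. a forced stop).
.compatible_set <- function(codon) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
                "?" = c("A", "C", "G", "T"))
  ch <- strsplit(codon, "")[[1]]
  sets <- iupac[ch]
  if (any(vapply(sets, is.null, logical(1)))) {
    stop("unrecognised nucleotide character in codon '", codon, "'")
  }
  combos <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                        stringsAsFactors = FALSE)
  cods <- paste0(combos[[1]], combos[[2]], combos[[3]])
  sort(unique(stats::na.omit(codon_index(cods))))
}
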