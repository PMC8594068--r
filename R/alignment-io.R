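#' Construct a codon alignment
#'
#' Builds the package's codon-alignment container from aligned in-frame
#' nucleotide sequences.  Sequences must have equal length divisible by 3.
#' `---` triplets are gaps; codons containing IUPAC ambiguity letters (or a
#' mix of gaps and bases) become ambiguous states carrying their set of
#' compatible sense codons.  A stop codon in the final column is stripped
#' (replaced by a gap; the column is dropped if it becomes all-gap); a stop
#' anywhere else is an error, since the selection models have no stop state.
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @return object of class `codon_alignment`: list with `taxa`,
#'   `codons` (character matrix of 3-mers, `---` for gaps), `states`
#'   (integer matrix: 1..61 sense-codon index, 0 gap, negative k = entry k
#'   of `ambig`), and `ambig` (list of compatible sense-codon index sets).
#' @export
codon_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  taxa <- names(seqs)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths)")
  }
  if (lens[1] %% 3 != 0) {
    bad <- taxa[1]
    stop("sequence length ", lens[1], " is not divisible by 3 (taxon ",
         bad, ")")
  }
  nsite <- lens[1] %/% 3
  if (nsite < 1L) stop("alignment has no codon sites")
  cod <- matrix("", length(taxa), nsite, dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    cod[i, ] <- substring(seqs[i], 3 * seq_len(nsite) - 2, 3 * seq_len(nsite))
  }

  stop_codons <- .hearsel_code$stop
  # terminal stop codons: strip silently
  term <- cod[, nsite] %in% stop_codons
  if (any(term)) {
    cod[term, nsite] <- "---"
    if (all(cod[, nsite] == "---")) {
      cod <- cod[, -nsite, drop = FALSE]
      nsite <- nsite - 1L
      if (nsite < 1L) stop("alignment has no codon sites after stripping ",
                           "terminal stop codons")
    }
  }
  internal_stop <- which(matrix(cod %in% stop_codons, nrow(cod)),
                         arr.ind = TRUE)
  if (nrow(internal_stop) > 0) {
    stop("internal stop codon in taxon ", taxa[internal_stop[1, 1]],
         " at codon site ", internal_stop[1, 2])
  }

  states <- matrix(0L, length(taxa), nsite, dimnames = list(taxa, NULL))
  ambig <- list()
  plain <- codon_index(cod)
  dim(plain) <- dim(cod)
  states[!is.na(plain)] <- plain[!is.na(plain)]
  todo <- which(is.na(plain), arr.ind = TRUE)
  for (k in seq_len(nrow(todo))) {
    cd <- cod[todo[k, 1], todo[k, 2]]
    if (cd == "---") next  # gap, state 0
    set <- .compatible_set(cd)
    if (length(set) == 0) {
      stop("codon '", cd, "' in taxon ", taxa[todo[k, 1]], " at site ",
           todo[k, 2], " is compatible only with stop codons")
    }
    ambig[[length(ambig) + 1L]] <- set
    states[todo[k, 1], todo[k, 2]] <- -length(ambig)
  }
  structure(list(taxa = taxa, codons = cod, states = states, ambig = ambig),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa x", ncol(x$states),
      "codon sites\n")
  ngap <- sum(x$states == 0L)
  namb <- sum(x$states < 0L)
  cat("  gaps:", ngap, " ambiguous codons:", namb, "\n")
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$states)

#' Read a codon alignment from FASTA or sequential PHYLIP
#'
#' The format is auto-detected: files whose first non-blank character is
#' `>` are parsed as FASTA (via Biostrings), anything else as sequential
#' PHYLIP with whitespace-delimited taxon names.
#'
#' @param path file path.
#' @return a [codon_alignment].
#' @export
read_codon_alignment <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0) stop("empty alignment file: ", path)
  if (startsWith(trimws(first[1]), ">")) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), names(ss))
    # FASTA headers: taxon = first whitespace token
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  } else {
    seqs <- .read_phylip_sequential(path)
  }
  codon_alignment(seqs)
}

# sequential PHYLIP: header "ntaxa nchar"; each taxon = name token followed
# by sequence characters, possibly wrapped over lines.
.read_phylip_sequential <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2 || any(is.na(hdr[1:2]))) {
    stop("malformed PHYLIP header in ", path)
  }
  ntax <- hdr[1]; nchar_ <- hdr[2]
  toks <- strsplit(paste(lines[-1], collapse = " "), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  seqs <- character(0)
  i <- 1L
  for (k in seq_len(ntax)) {
    if (i > length(toks)) stop("truncated PHYLIP file: expected ", ntax,
                               " taxa, found ", k - 1L)
    name <- toks[i]; i <- i + 1L
    seq <- ""
    while (nchar(seq) < nchar_) {
      if (i > length(toks)) {
        stop("sequence for taxon ", name, " shorter than declared length")
      }
      seq <- paste0(seq, toks[i]); i <- i + 1L
    }
    if (nchar(seq) != nchar_) {
      stop("sequence for taxon ", name, " longer than declared length")
    }
    seqs[name] <- seq
  }
  seqs
}

#' Write a codon alignment
#'
#' @param alignment a [codon_alignment].
#' @param path output file.
#' @param format "fasta" or "phylip" (sequential).
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(alignment, path,
                                  format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(alignment$codons, 1, paste0, collapse = "")
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", alignment$taxa), seqs))
  } else {
    out <- c(paste(length(alignment$taxa), nchar(seqs[1])),
             paste(alignment$taxa, seqs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Tip partial-likelihood cube for a codon alignment
#'
#' One 61 x nsite matrix per taxon: a unit vector for an observed sense
#' codon, an indicator over the compatible set for an ambiguous codon, and
#' all ones for a gap (fully missing data).
#'
#' @param alignment a [codon_alignment].
#' @param taxa taxon order for the slices (default alignment order).
#' @return 61 x nsite x ntaxa numeric array.
#' @keywords internal
tip_partials <- function(alignment, taxa = alignment$taxa) {
  st <- alignment$states[taxa, , drop = FALSE]
  nsite <- ncol(st)
  out <- array(0, dim = c(.NSTATE, nsite, length(taxa)))
  for (i in seq_along(taxa)) {
    for (s in seq_len(nsite)) {
      v <- st[i, s]
      if (v > 0L) out[v, s, i] <- 1
      else if (v == 0L) out[, s, i] <- 1
      else out[alignment$ambig[[-v]], s, i] <- 1
    }
  }
  out
}
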