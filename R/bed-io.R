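#' Read a BED file (BED3/4/6)
#'
#' Intervals are kept in BED's native 0-based half-open convention, which is
#' the coordinate convention used everywhere inside the package.  Column 4
#' becomes `id`, column 6 `strand`; missing columns give `NA` ids and `.`
#' strands.
#'
#' @param path tab-separated BED file; `#` comment and `track` lines are
#'   skipped.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  recs <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  n <- length(recs)
  out <- data.frame(chrom = character(n), start = numeric(n),
                    end = numeric(n), id = NA_character_,
                    strand = rep(".", n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- recs[[i]]
    if (length(f) < 3) {
      stop("BED record with fewer than 3 fields at line ", lineno[i])
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop("non-numeric coordinates at line ", lineno[i])
    }
    if (s < 0 || s >= e) {
      stop("invalid interval (need 0 <= start < end) at line ", lineno[i])
    }
    out$chrom[i] <- f[1]; out$start[i] <- s; out$end[i] <- e
    if (length(f) >= 4) out$id[i] <- f[4]
    if (length(f) >= 6 && f[6] %in% c("+", "-")) out$strand[i] <- f[6]
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `id`, `strand` (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  has_id <- "id" %in% names(intervals) && any(!is.na(intervals$id))
  has_strand <- "strand" %in% names(intervals) &&
    any(intervals$strand %in% c("+", "-"))
  cols <- data.frame(intervals$chrom,
                     format(intervals$start, scientific = FALSE, trim = TRUE),
                     format(intervals$end, scientific = FALSE, trim = TRUE))
  if (has_id || has_strand) {
    cols$id <- ifelse(is.na(intervals$id), ".", intervals$id)
  }
  if (has_strand) {
    cols$score <- "0"
    cols$strand <- intervals$strand
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as a TSV report
#'
#' @param records a data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#'
#' @param path text file, one gene id per line; `#` comments allowed.
#' @return character vector of unique ids, in first-seen order.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
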