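# Gene assignment of accelerated noncoding regions.  All coordinates are
# 0-based half-open (BED convention); overlap of [s1,e1) and [s2,e2) is
# max(0, min(e1,e2) - max(s1,s2)) bases.

.ov_bases <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

.region_ids <- function(regions) {
  ids <- if ("id" %in% names(regions)) regions$id else rep(NA_character_, nrow(regions))
  fill <- is.na(ids) | !nzchar(ids)
  ids[fill] <- paste0("region_", which(fill))
  if (anyDuplicated(ids)) stop("region ids must be unique")
  ids
}

#' Transcription start sites of transcriptional units
#'
#' Strand-aware single-base TSS: `start` on the + strand, `end - 1` on the
#' - strand (0-based).  Unstranded units are treated as + strand.
#'
#' @param units data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return numeric vector of TSS positions, one per unit.
#' @export
tss_position <- function(units) {
  ifelse(units$strand == "-", units$end - 1, units$start)
}

#' Classify accelerated regions as coding or noncoding
#'
#' A region is CODING when it overlaps at least one exon by at least
#' `min_overlap` bases (half-open semantics: abutting intervals do not
#' overlap); otherwise NONCODING.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (and optional
#'   `id`).
#' @param exons data.frame of exon intervals (`chrom`, `start`, `end`).
#' @param min_overlap minimum overlapping bases to count (default 1).
#' @return `regions` with a `coding_class` column (`"CODING"` /
#'   `"NONCODING"`).
#' @export
classify_coding <- function(regions, exons, min_overlap = 1) {
  cls <- rep("NONCODING", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ex <- exons[exons$chrom == regions$chrom[i], ]
    if (nrow(ex) == 0) next
    ov <- .ov_bases(regions$start[i], regions$end[i], ex$start, ex$end)
    if (any(ov >= min_overlap)) cls[i] <- "CODING"
  }
  regions$coding_class <- cls
  regions
}

#' Assign regions to genes by transcriptional-unit overlap
#'
#' A region is assigned to every gene whose gene body (TSS to TES span) it
#' overlaps.  With `noncoding_only = TRUE` the region must additionally
#' overlap the body at one or more positions outside every exon of that
#' gene (the non-exonic portion of the transcriptional unit).
#'
#' @param regions data.frame of intervals (optional `id`).
#' @param units transcriptional units (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param exons exon intervals with a `gene_id` column, used when
#'   `noncoding_only` is set.
#' @param noncoding_only require overlap outside the gene's exons.
#' @return data.frame `region_id`, `gene_id`, `mode = "GENE_BODY"`.
#' @export
assign_gene_body <- function(regions, units, exons = NULL,
                             noncoding_only = FALSE) {
  if (noncoding_only && is.null(exons)) {
    stop("noncoding_only assignment needs the exon table")
  }
  ids <- .region_ids(regions)
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    u <- units[units$chrom == regions$chrom[i], ]
    if (nrow(u) == 0) next
    ov <- .ov_bases(regions$start[i], regions$end[i], u$start, u$end)
    for (j in which(ov > 0)) {
      if (noncoding_only) {
        # positions of the region inside the body but outside this gene's
        # exons must be non-empty
        s <- max(regions$start[i], u$start[j])
        e <- min(regions$end[i], u$end[j])
        ex <- exons[exons$gene_id == u$gene_id[j] &
                      exons$chrom == regions$chrom[i], ]
        covered <- 0
        if (nrow(ex) > 0) {
          ex <- ex[order(ex$start), ]
          # merge exons then count covered bases of [s, e)
          pos <- s
          for (k in seq_len(nrow(ex))) {
            a <- max(ex$start[k], pos); b <- min(ex$end[k], e)
            if (b > a) { covered <- covered + (b - a); pos <- max(pos, b) }
          }
        }
        if ((e - s) - covered <= 0) next
      }
      hits[[length(hits) + 1L]] <- data.frame(
        region_id = ids[i], gene_id = u$gene_id[j], mode = "GENE_BODY",
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(region_id = character(0), gene_id = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' GREAT-style gene regulatory domains
#'
#' Each gene receives a basal domain around its TSS (`basal_up` bases
#' upstream, `basal_down` downstream, strand-aware, regardless of
#' neighbours).  The domain is then extended on each side to the nearest
#' other gene's basal-domain boundary, but no further than `max_extension`
#' from the TSS, never shrinking below the basal domain, and clipped at
#' chromosome bounds.
#'
#' @param units transcriptional units (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param basal_up,basal_down basal extents from the TSS in bases
#'   (defaults 5000 / 1000, the GREAT defaults).
#' @param max_extension cap on the extension from the TSS (default 1e6,
#'   "up to 1000 kb").
#' @param chrom_sizes optional named numeric vector of chromosome lengths
#'   for right-clipping.
#' @return data.frame `gene_id`, `chrom`, `basal_start`, `basal_end`,
#'   `start`, `end` (the extended domain).
#' @export
build_regulatory_domains <- function(units, basal_up = 5000,
                                     basal_down = 1000,
                                     max_extension = 1e6,
                                     chrom_sizes = NULL) {
  stopifnot(basal_up >= 0, basal_down >= 0, max_extension >= 0)
  t <- tss_position(units)
  minus <- units$strand == "-"
  basal_start <- ifelse(minus, t - basal_down + 1, t - basal_up)
  basal_end <- ifelse(minus, t + basal_up + 1, t + basal_down)
  basal_start <- pmax(0, basal_start)
  n <- nrow(units)
  start <- end <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(units$chrom == units$chrom[i])
    others <- setdiff(same, i)
    lim_l <- suppressWarnings(
      max(basal_end[others][basal_end[others] <= basal_start[i]]))
    lim_r <- suppressWarnings(
      min(basal_start[others][basal_start[others] >= basal_end[i]]))
    start[i] <- min(basal_start[i], max(t[i] - max_extension, lim_l))
    end[i] <- max(basal_end[i], min(t[i] + max_extension, lim_r))
  }
  start <- pmax(0, start)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[units$chrom]
    end <- pmin(end, sz)
    basal_end <- pmin(basal_end, sz)
  }
  data.frame(gene_id = units$gene_id, chrom = units$chrom,
             basal_start = basal_start, basal_end = basal_end,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Assign regions to genes by regulatory-domain overlap
#'
#' @param regions data.frame of intervals (optional `id`).
#' @param domains output of [build_regulatory_domains()].
#' @return data.frame `region_id`, `gene_id`, `mode = "REG_DOMAIN"`.
#' @export
assign_reg_domain <- function(regions, domains) {
  ids <- .region_ids(regions)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    d <- domains[domains$chrom == regions$chrom[i], ]
    if (nrow(d) == 0) next
    ov <- .ov_bases(regions$start[i], regions$end[i], d$start, d$end)
    for (j in which(ov > 0)) {
      out[[length(out) + 1L]] <- data.frame(
        region_id = ids[i], gene_id = d$gene_id[j], mode = "REG_DOMAIN",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_id = character(0), gene_id = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assign regions to genes sharing a topologically associating domain
#'
#' A region is assigned to every gene whose TSS falls inside a TAD that
#' overlaps any base of the region (permissive any-base membership);
#' regions outside all TADs receive no assignments.
#'
#' @param regions data.frame of intervals (optional `id`).
#' @param units transcriptional units.
#' @param tads data.frame of TAD intervals (`chrom`, `start`, `end`),
#'   disjoint within a chromosome.
#' @return data.frame `region_id`, `gene_id`, `mode = "TAD"`.
#' @export
assign_tad <- function(regions, units, tads) {
  for (ch in unique(tads$chrom)) {
    tt <- tads[tads$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1 && any(tt$start[-1] < tt$end[-nrow(tt)])) {
      stop("TADs overlap within chromosome ", ch)
    }
  }
  ids <- .region_ids(regions)
  t <- tss_position(units)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    td <- tads[tads$chrom == regions$chrom[i], ]
    if (nrow(td) == 0) next
    ov <- .ov_bases(regions$start[i], regions$end[i], td$start, td$end)
    for (j in which(ov > 0)) {
      in_tad <- units$chrom == regions$chrom[i] &
        t >= td$start[j] & t < td$end[j]
      for (g in units$gene_id[in_tad]) {
        out[[length(out) + 1L]] <- data.frame(
          region_id = ids[i], gene_id = g, mode = "TAD",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_id = character(0), gene_id = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Summarise region-to-gene assignments
#'
#' @param regions data.frame with `coding_class` (from [classify_coding()])
#'   and optionally a `lineage` column.
#' @param assignments data.frame binding rows of the `assign_*` outputs.
#' @return list with `by_mode` (per lineage x mode: region and gene
#'   counts), `gene_ranking` (genes by number of assigned regions, per
#'   mode), and `coding_split` (per lineage coding/noncoding counts).
#' @export
summarize_assignments <- function(regions, assignments) {
  ids <- .region_ids(regions)
  lineage <- if ("lineage" %in% names(regions)) regions$lineage else
    rep("ALL", nrow(regions))
  names(lineage) <- ids
  cs <- as.data.frame(base::table(lineage = lineage,
                                  coding_class = regions$coding_class),
                      stringsAsFactors = FALSE)
  names(cs)[3] <- "n_regions"
  if (nrow(assignments) > 0) {
    assignments$lineage <- lineage[assignments$region_id]
    by_mode <- do.call(rbind, lapply(
      split(assignments, list(assignments$lineage, assignments$mode),
            drop = TRUE),
      function(d) data.frame(lineage = d$lineage[1], mode = d$mode[1],
                             n_regions = length(unique(d$region_id)),
                             n_genes = length(unique(d$gene_id)),
                             stringsAsFactors = FALSE)))
    rownames(by_mode) <- NULL
    rank_tab <- do.call(rbind, lapply(split(assignments, assignments$mode),
                                      function(d) {
      cnt <- sort(base::table(d$gene_id), decreasing = TRUE)
      data.frame(mode = d$mode[1], gene_id = names(cnt),
                 n_regions = as.integer(cnt), stringsAsFactors = FALSE)
    }))
    rownames(rank_tab) <- NULL
  } else {
    by_mode <- data.frame(lineage = character(0), mode = character(0),
                          n_regions = integer(0), n_genes = integer(0))
    rank_tab <- data.frame(mode = character(0), gene_id = character(0),
                           n_regions = integer(0))
  }
  list(by_mode = by_mode, gene_ranking = rank_tab, coding_split = cs)
}
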