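#' Merge gene lists into a non-redundant union
#'
#' Builds the non-redundant gene catalogue from several source lists (e.g.
#' a human non-syndromic deafness panel and a mouse-screen candidate list),
#' after canonicalising identifiers through an explicit synonym map.
#' Provenance (which source lists contain each gene) is retained, and the
#' pairwise overlap matrix is returned alongside the union.
#'
#' @param lists named list of character vectors of gene identifiers.
#' @param synonym_map named character vector mapping alias -> canonical id
#'   (may be empty).
#' @return list with `union` (data.frame `gene`, `sources`,
#'   comma-separated), `overlap` (k x k matrix of pairwise intersection
#'   sizes; diagonal = list sizes), and `sizes` (per-list sizes after
#'   canonicalisation).
#' @examples
#' merge_gene_lists(list(A = c("g1", "g2"), B = c("g2", "g3")))$overlap
#' @export
merge_gene_lists <- function(lists, synonym_map = character(0)) {
  stopifnot(is.list(lists))
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("every gene list must be named")
  }
  canon <- function(x) {
    hit <- x %in% names(synonym_map)
    x[hit] <- synonym_map[x[hit]]
    unique(x)
  }
  lists <- lapply(lists, canon)
  k <- length(lists)
  overlap <- matrix(0L, k, k, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      overlap[i, j] <- length(intersect(lists[[i]], lists[[j]]))
    }
  }
  genes <- unique(unlist(lists, use.names = FALSE))
  sources <- vapply(genes, function(g) {
    paste(names(lists)[vapply(lists, function(l) g %in% l, logical(1))],
          collapse = ",")
  }, character(1))
  list(union = data.frame(gene = genes, sources = unname(sources),
                          stringsAsFactors = FALSE),
       overlap = overlap,
       sizes = vapply(lists, length, integer(1)))
}

#' Substitute missing roster species from same-taxon relatives
#'
#' For each (gene, species) cell of the roster that is MISSING, searches the
#' non-roster rows of the ortholog table for a species of the same taxon
#' group with a one-to-one ortholog for that gene; the first such species
#' (alphabetically, for determinism) substitutes, and the provenance is
#' recorded.  Non-MISSING cells are never changed.
#'
#' @param table ortholog table: data.frame with columns `gene`, `species`,
#'   `status` (ONE2ONE / ONE2MANY / MANY2MANY / MISSING), `taxon_group`.
#' @param roster character vector of the target species.
#' @return the table with MISSING roster cells upgraded where possible and
#'   a `substituted_from` column recording the donor species (NA
#'   otherwise).
#' @export
substitute_species <- function(table, roster) {
  .check_ortholog_table(table)
  if (!"substituted_from" %in% names(table)) {
    table$substituted_from <- NA_character_
  }
  pool <- table[!(table$species %in% roster) & table$status == "ONE2ONE", ]
  miss <- which(table$species %in% roster & table$status == "MISSING")
  for (i in miss) {
    cand <- pool[pool$gene == table$gene[i] &
                   pool$taxon_group == table$taxon_group[i], ]
    if (nrow(cand) > 0) {
      donor <- sort(cand$species)[1]
      table$status[i] <- "ONE2ONE"
      table$substituted_from[i] <- donor
    }
  }
  table
}

#' Orthology filtering of a gene catalogue
#'
#' Applies the screening's gene-level filters and returns the bookkeeping
#' ledger.  A gene is excluded as `EXCLUDED_NO_REFERENCE` when flagged
#' absent from the reference genome; as `EXCLUDED_ORTHOLOGY` when, across
#' the roster species, it has more than `max_missing` MISSING orthologs or
#' any one-to-many / many-to-many relationship; otherwise it is `ANALYZED`.
#' Apply [substitute_species()] first if same-taxon rescue is wanted.
#'
#' @param table ortholog table (see [substitute_species()]).
#' @param genes character vector of gene ids to filter.
#' @param max_missing largest tolerated number of missing roster species
#'   (default 1: "more than one species missing" excludes).
#' @param no_reference character vector of gene ids absent from the
#'   reference genome.
#' @param roster character vector of roster species (default: all species
#'   in `table`).
#' @return data.frame `gene`, `disposition`, `reason` whose dispositions
#'   partition `genes`.
#' @export
filter_orthology <- function(table, genes, max_missing = 1,
                             no_reference = character(0), roster = NULL) {
  .check_ortholog_table(table)
  if (is.null(roster)) roster <- unique(table$species)
  tab <- table[table$species %in% roster, ]
  known <- unique(tab$gene)
  if (any(!genes %in% known)) {
    stop("gene(s) not present in ortholog table: ",
         paste(head(setdiff(genes, known), 5), collapse = ", "))
  }
  cells <- base::table(tab$gene[tab$gene %in% genes],
                       tab$species[tab$gene %in% genes])
  if (any(cells != 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)[1, ]
    stop("ortholog table must contain each (gene, species) cell exactly ",
         "once; offending gene: ", rownames(cells)[bad[1]])
  }
  out <- data.frame(gene = genes, disposition = "ANALYZED",
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (g %in% no_reference) {
      out$disposition[i] <- "EXCLUDED_NO_REFERENCE"
      out$reason[i] <- "no coordinates in reference genome"
      next
    }
    rows <- tab[tab$gene == g, ]
    n_miss <- sum(rows$status == "MISSING")
    multi <- rows$status %in% c("ONE2MANY", "MANY2MANY")
    if (n_miss > max_missing || any(multi)) {
      out$disposition[i] <- "EXCLUDED_ORTHOLOGY"
      out$reason[i] <- paste0(
        if (n_miss > max_missing) {
          paste0(n_miss, " missing orthologs")
        },
        if (n_miss > max_missing && any(multi)) "; ",
        if (any(multi)) {
          paste0("non-one-to-one orthology in ",
                 paste(rows$species[multi], collapse = ","))
        })
    }
  }
  out
}

.check_ortholog_table <- function(table) {
  need <- c("gene", "species", "status", "taxon_group")
  if (!all(need %in% names(table))) {
    stop("ortholog table needs columns ", paste(need, collapse = ", "))
  }
  ok <- c("ONE2ONE", "ONE2MANY", "MANY2MANY", "MISSING")
  if (any(!table$status %in% ok)) {
    stop("unknown orthology status: ",
         paste(unique(setdiff(table$status, ok)), collapse = ", "))
  }
  invisible(TRUE)
}
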