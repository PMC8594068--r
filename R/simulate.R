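#' Default 14-species study tree
#'
#' A 14-leaf caricature of the default screening roster (human, olive
#' baboon, mouse, guinea pig, dog, cow, pig, opossum, chicken, duck,
#' collared flycatcher, turtle, anole lizard, frog) with realistic branch
#' lengths in \[0.01, 0.5\] substitutions per codon and the basal mammalian
#' branch (the therian stem) flagged as foreground.
#'
#' @return a [labeled_tree] with 14 tips and one foreground edge.
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "((((((human:0.05,baboon:0.06):0.08,(mouse:0.25,guinea_pig:0.20):0.10)",
    ":0.03,(dog:0.12,(cow:0.12,pig:0.11):0.04):0.05):0.06,opossum:0.30)",
    "#1:0.15,((chicken:0.10,(duck:0.10,flycatcher:0.12):0.05):0.15,",
    "(turtle:0.15,lizard:0.35):0.08):0.10):0.10,frog:0.50);")
  read_labeled_tree(text = txt)
}

#' Default species roster with taxon groups
#'
#' The 14 screening species plus a pool of same-taxon substitutes used by
#' the ortholog-table simulator.
#'
#' @return list with `roster` and `pool`, both data.frames with `species`
#'   and `taxon_group`.
#' @export
default_species_roster <- function() {
  roster <- data.frame(
    species = c("human", "baboon", "mouse", "guinea_pig", "dog", "cow",
                "pig", "opossum", "chicken", "duck", "flycatcher",
                "turtle", "lizard", "frog"),
    taxon_group = c("primates", "primates", "rodents", "rodents",
                    "carnivora", "artiodactyla", "artiodactyla",
                    "marsupials", "birds", "birds", "birds", "reptiles",
                    "reptiles", "amphibians"),
    stringsAsFactors = FALSE)
  pool <- data.frame(
    species = c("macaque", "rat", "goat", "cat"),
    taxon_group = c("primates", "rodents", "artiodactyla", "carnivora"),
    stringsAsFactors = FALSE)
  list(roster = roster, pool = pool)
}

#' Simulate a codon alignment along a tree
#'
#' Evolves codon sequences site by site under the one-ratio (M0) model or
#' branch-site Model A.  Under Model A each site first draws its class from
#' `(p0, p1, p2a, p2b)`; the class fixes the dN/dS used on background and
#' foreground branches (class 0: omega0/omega0; class 1: 1/1; class 2a:
#' omega0/omega2; class 2b: 1/omega2).  The root codon is drawn from `pi`
#' and each branch applies its exact transition matrix `P(t)` (matrix
#' exponential, not an event-level simulation).  Output is deterministic
#' given `seed`.
#'
#' @param ltree a [labeled_tree]; Model A requires a non-empty foreground.
#' @param model "M0", "MODEL_A", or "MODEL_A_NULL" (Model A with
#'   `omega2 = 1`).
#' @param params list: for M0, `kappa`, `omega` (and optional `pi`); for
#'   Model A, `kappa`, `omega0`, `omega2`, `p0`, `p1` (optional `pi`).
#'   `pi` defaults to uniform over the 61 sense codons.
#' @param n_sites number of codon sites (>= 1).
#' @param seed integer seed.
#' @return list with `alignment` (a [codon_alignment]) and `truth` (model,
#'   parameters, per-site class labels for Model A, seed).
#' @export
simulate_alignment <- function(ltree, model = c("M0", "MODEL_A",
                                                "MODEL_A_NULL"),
                               params, n_sites, seed) {
  model <- match.arg(model)
  stopifnot(inherits(ltree, "labeled_tree"), n_sites >= 1)
  pi <- if (!is.null(params$pi)) validate_pi(params$pi) else rep(1 / .NSTATE,
                                                                 .NSTATE)
  if (model == "M0") {
    if (is.null(params$kappa) || is.null(params$omega)) {
      stop("M0 simulation needs kappa and omega")
    }
    bsp <- NULL
  } else {
    need <- c("kappa", "omega0", "p0", "p1")
    if (any(!need %in% names(params))) {
      stop("Model A simulation needs ", paste(need, collapse = ", "))
    }
    omega2 <- if (model == "MODEL_A_NULL") 1 else params$omega2
    if (is.null(omega2)) stop("MODEL_A simulation needs omega2")
    bsp <- branch_site_params(params$kappa, params$omega0, omega2,
                              params$p0, params$p1, pi)
    if (!length(ltree$foreground)) {
      stop("Model A simulation needs a foreground branch")
    }
  }

  set.seed(seed)
  tree <- ape::reorder.phylo(ltree$tree, "cladewise")
  ord <- ape::reorder.phylo(ltree$tree, "cladewise", index.only = TRUE)
  fg <- (seq_len(nrow(ltree$tree$edge)) %in% ltree$foreground)[ord]
  edge <- tree$edge
  len <- tree$edge.length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  if (model == "M0") {
    classes <- rep(1L, n_sites)
    # omega by (class, background/foreground): single ratio
    omega_tab <- matrix(params$omega, 1, 2)
    kappa <- params$kappa
  } else {
    classes <- sample.int(4L, n_sites, replace = TRUE,
                          prob = bsp$proportions)
    omega_tab <- rbind(c(bsp$omega0, bsp$omega0),
                       c(1, 1),
                       c(bsp$omega0, bsp$omega2),
                       c(1, bsp$omega2))
    kappa <- bsp$kappa
  }
  omegas <- sort(unique(as.vector(omega_tab)))
  Qs <- lapply(omegas, function(w) codon_rate_matrix(kappa, w, pi))
  decs <- lapply(Qs, decompose_rate_matrix)
  names(decs) <- as.character(omegas)
  # common-scale convention: site classes share one rate normalisation, so
  # branch lengths are substitutions per codon averaged over classes on the
  # background and class-2 sites genuinely evolve faster under omega2 > 1
  rates <- setNames(vapply(Qs, `[[`, 0, "scale"), as.character(omegas))
  rho <- if (model == "M0") {
    setNames(1, as.character(params$omega))
  } else {
    R <- (bsp$p0 + bsp$p2a) * rates[as.character(bsp$omega0)] +
      (bsp$p1 + bsp$p2b) * rates["1"]
    rates / R
  }

  states <- matrix(0L, nnode, n_sites)
  states[root, ] <- sample.int(.NSTATE, n_sites, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    wcol <- if (fg[e]) 2L else 1L
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      w <- omega_tab[cl, wcol]
      dec <- decs[[as.character(w)]]
      P <- cpp_transition_matrices(dec$V, dec$lambda, dec$sqrtpi,
                                   len[e] * rho[[as.character(w)]])[, , 1]
      ps <- states[parent, idx]
      for (v in unique(ps)) {
        sel <- idx[ps == v]
        states[child, sel] <- sample.int(.NSTATE, length(sel),
                                         replace = TRUE, prob = P[v, ])
      }
    }
  }

  sense <- .hearsel_code$sense
  seqs <- vapply(seq_len(ntip), function(i)
    paste0(sense[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  truth <- list(model = model,
                parameters = if (model == "M0") {
                  list(kappa = params$kappa, omega = params$omega, pi = pi)
                } else bsp,
                site_classes = if (model == "M0") NULL else
                  c("0", "1", "2a", "2b")[classes],
                seed = seed)
  list(alignment = codon_alignment(seqs), truth = truth)
}

#' Simulate an ortholog table with planted filtering defects
#'
#' Builds a gene-by-species orthology table in which exactly the planted
#' numbers of genes fail each screening filter: `planted_missing` genes
#' have unsalvageable missing orthologs in `max_missing + 1` roster species
#' (no same-taxon substitute exists), `planted_multi` genes carry a
#' one-to-many relationship, `planted_noref` genes are flagged absent from
#' the reference genome, and `planted_substitutable` genes have one missing
#' roster species that a same-taxon pool species can rescue.  All remaining
#' cells are one-to-one.
#'
#' @param n_genes total genes.
#' @param roster data.frame `species`, `taxon_group` (default
#'   [default_species_roster()]).
#' @param pool same-taxon substitute species (default roster's pool).
#' @param planted_missing,planted_multi,planted_noref,planted_substitutable
#'   planted counts (mutually exclusive gene sets).
#' @param max_missing tolerated missing count (default 1), controls how
#'   many missing species a planted-missing gene receives.
#' @param seed integer seed.
#' @return list with `table` (ortholog table including pool-species rows),
#'   `genes` (character vector), `no_reference` (character vector), and
#'   `truth` (data.frame `gene`, `category`).
#' @export
simulate_ortholog_table <- function(n_genes, roster = NULL, pool = NULL,
                                    planted_missing = 0, planted_multi = 0,
                                    planted_noref = 0,
                                    planted_substitutable = 0,
                                    max_missing = 1, seed = 1) {
  if (is.null(roster) || is.null(pool)) {
    d <- default_species_roster()
    if (is.null(roster)) roster <- d$roster
    if (is.null(pool)) pool <- d$pool
  }
  planted <- c(planted_missing, planted_multi, planted_noref,
               planted_substitutable)
  if (any(planted < 0) || sum(planted) > n_genes) {
    stop("planted counts must be non-negative and sum to at most n_genes")
  }
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  category <- rep("CLEAN", n_genes)
  idx <- seq_len(sum(planted))
  lab <- rep(c("MISSING", "MULTI", "NOREF", "SUBSTITUTABLE"), planted)
  # scatter planted genes over the catalogue deterministically
  where <- sample(n_genes, sum(planted))
  category[where[idx]] <- lab

  # species without a same-taxon pool substitute, used to plant
  # unsalvageable missing cells
  no_sub <- roster$species[!roster$taxon_group %in% pool$taxon_group]
  if (length(no_sub) < max_missing + 1) {
    stop("roster must contain at least max_missing + 1 species without ",
         "same-taxon substitutes")
  }
  sub_ok <- roster$species[roster$taxon_group %in% pool$taxon_group]

  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    status <- setNames(rep("ONE2ONE", nrow(roster)), roster$species)
    if (category[i] == "MISSING") {
      status[no_sub[seq_len(max_missing + 1)]] <- "MISSING"
    } else if (category[i] == "MULTI") {
      status[sample(roster$species, 1)] <- "ONE2MANY"
    } else if (category[i] == "SUBSTITUTABLE") {
      status[sample(sub_ok, 1)] <- "MISSING"
    }
    rows[[i]] <- data.frame(gene = genes[i],
                            species = c(roster$species, pool$species),
                            status = c(status,
                                       setNames(rep("ONE2ONE",
                                                    nrow(pool)),
                                                pool$species)),
                            taxon_group = c(roster$taxon_group,
                                            pool$taxon_group),
                            stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, genes = genes,
       no_reference = genes[category == "NOREF"],
       truth = data.frame(gene = genes, category = category,
                          stringsAsFactors = FALSE))
}

#' Simulate a genome annotation with planted region assignments
#'
#' Lays out `n_genes` transcriptional units (20 kb bodies, four exons, +
#' strand) every 3 Mb on one chromosome, one TAD of 3 Mb centred on each
#' TSS, and plants accelerated regions of known category: `coding`
#' (overlapping an exon), `intronic` (inside a gene body, outside all
#' exons), `domain_only` (inside the GREAT extended regulatory domain but
#' outside every gene body), `tad_only` (inside the gene's TAD but beyond
#' the regulatory-domain cap), and `outside` (beyond all TADs).  The truth
#' table lists each region's intended classification and gene.
#'
#' @param n_genes number of genes (>= 1 when any gene-linked count is
#'   positive).
#' @param planted named list/vector of counts: `coding`, `intronic`,
#'   `domain_only`, `tad_only`, `outside` (missing entries = 0).
#' @param seed integer seed (jitters region placement).
#' @param chrom chromosome name.
#' @return list with `units`, `exons`, `regions`, `tads` (data.frames in
#'   0-based half-open coordinates) and `truth` (data.frame `region_id`,
#'   `category`, `gene_id`).
#' @export
simulate_annotation <- function(n_genes, planted, seed = 1,
                                chrom = "chr1") {
  keys <- c("coding", "intronic", "domain_only", "tad_only", "outside")
  cnt <- setNames(rep(0L, length(keys)), keys)
  cnt[names(planted)] <- unlist(planted)
  if (any(!names(planted) %in% keys)) {
    stop("unknown planted categories: ",
         paste(setdiff(names(planted), keys), collapse = ", "))
  }
  if (any(cnt < 0)) stop("planted counts must be non-negative")
  gene_linked <- sum(cnt[c("coding", "intronic", "domain_only",
                           "tad_only")])
  if (gene_linked > 0 && n_genes < 1) {
    stop("planted spec needs at least one gene")
  }
  set.seed(seed)
  spacing <- 3e6
  tss <- 2e6 + spacing * (seq_len(n_genes) - 1)
  body_len <- 2e4
  units <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                      chrom = chrom, start = tss, end = tss + body_len,
                      strand = "+", stringsAsFactors = FALSE)
  exoff <- c(0, 5000, 10000, 19500)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(gene_id = units$gene_id[i], chrom = chrom,
               start = tss[i] + exoff, end = tss[i] + exoff + 500,
               stringsAsFactors = FALSE)
  }))
  tads <- data.frame(chrom = chrom, start = tss - 1.5e6,
                     end = tss + 1.5e6, stringsAsFactors = FALSE)

  regions <- list(); truth <- list()
  add <- function(start, end, category, gene) {
    k <- length(regions) + 1L
    id <- sprintf("R%03d", k)
    regions[[k]] <<- data.frame(chrom = chrom, start = start, end = end,
                                id = id, stringsAsFactors = FALSE)
    truth[[k]] <<- data.frame(region_id = id, category = category,
                              gene_id = gene, stringsAsFactors = FALSE)
  }
  pick_gene <- function(k) ((k - 1L) %% n_genes) + 1L
  for (k in seq_len(cnt["coding"])) {
    i <- pick_gene(k)
    s <- tss[i] + 5000 + sample(0:300, 1)  # inside exon 2
    add(s, s + 200, "coding", units$gene_id[i])
  }
  for (k in seq_len(cnt["intronic"])) {
    i <- pick_gene(k)
    s <- tss[i] + 1000 + sample(0:3000, 1)  # between exons 1 and 2
    add(s, s + 200, "intronic", units$gene_id[i])
  }
  for (k in seq_len(cnt["domain_only"])) {
    i <- pick_gene(k)
    s <- tss[i] - 6e4 - sample(0:2e4, 1)  # upstream, within 1 Mb cap
    add(s, s + 200, "domain_only", units$gene_id[i])
  }
  for (k in seq_len(cnt["tad_only"])) {
    i <- pick_gene(k)
    s <- tss[i] + 1.2e6 + sample(0:1e5, 1)  # in TAD, past the domain cap
    add(s, s + 200, "tad_only", units$gene_id[i])
  }
  base_out <- if (n_genes > 0) max(tads$end) + 1e6 else 1e6
  for (k in seq_len(cnt["outside"])) {
    s <- base_out + 1e4 * k + sample(0:5000, 1)
    add(s, s + 200, "outside", NA_character_)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               id = character(0), stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(region_id = character(0), category = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  list(units = units, exons = exons, regions = regions, tads = tads,
       truth = truth)
}
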