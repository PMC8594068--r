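# Independent oracles and shared fixtures.  Everything here is deliberately
# naive: enumeration over internal states instead of pruning, per-base
# membership instead of interval arithmetic, quadratic step-up instead of
# vectorised ranking.  They exist to check the fast implementations.

# --- trees -----------------------------------------------------------------

tree_2tx <- function() read_labeled_tree(text = "(A:0.15,B:0.25);")
tree_3tx <- function() read_labeled_tree(text = "((A:0.1,B:0.2):0.1,C:0.3);")
# unrooted-style (trifurcating root) topologies keep the internal-state
# enumeration small: ntip - 2 internal nodes
tree_4tx <- function() {
  read_labeled_tree(text = "(A:0.2,B:0.15,(C:0.1,D:0.3):0.2);")
}
tree_5tx <- function() {
  read_labeled_tree(text = "(A:0.2,B:0.15,(C:0.1,(D:0.3,E:0.25):0.1):0.2);")
}
tree_8tx <- function(fg_len = 0.5) {
  read_labeled_tree(text = sprintf(
    "(((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1)#1:%g,((E:0.2,F:0.2):0.1,(G:0.25,H:0.25):0.1):0.15);",
    fg_len))
}
tree_6tx_fg <- function() {
  read_labeled_tree(text =
    "(((A:0.2,B:0.2):0.1,C:0.3)#1:0.4,(D:0.25,(E:0.2,F:0.2):0.1):0.15);")
}

# random alignment with optional gaps/ambiguity, over sense codons
random_alignment <- function(taxa, n_sites, gap_frac = 0, amb_frac = 0) {
  sense <- genetic_code()$sense
  seqs <- vapply(taxa, function(t) {
    cod <- sample(sense, n_sites, replace = TRUE)
    if (gap_frac > 0) {
      cod[runif(n_sites) < gap_frac] <- "---"
    }
    if (amb_frac > 0) {
      hit <- which(runif(n_sites) < amb_frac & cod != "---")
      for (i in hit) substr(cod[i], 3, 3) <- "N"
    }
    paste0(cod, collapse = "")
  }, character(1))
  codon_alignment(seqs)
}

random_pi <- function() {
  x <- rgamma(61, shape = 2)
  x / sum(x)
}

# --- enumeration likelihood oracle ----------------------------------------

# Per-site log-likelihood by explicit summation over all internal-node
# state assignments; independent of the pruning code path.
enum_site_loglik <- function(alignment, ltree, P, pi) {
  tree <- ltree$tree
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nnode <- ntip + tree$Nnode
  internals <- (ntip + 1L):nnode
  root <- ntip + 1L
  # tip partial vectors (1 for compatible states)
  st <- alignment$states[tree$tip.label, , drop = FALSE]
  tipvec <- function(tip, site) {
    v <- st[tip, site]
    out <- numeric(61)
    if (v > 0) out[v] <- 1
    else if (v == 0) out[] <- 1
    else out[alignment$ambig[[-v]]] <- 1
    out
  }
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  colnames(grid) <- as.character(internals)
  n_sites <- ncol(st)
  out <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    term <- pi[grid[, as.character(root)]]
    for (e in seq_len(nrow(edge))) {
      parent <- edge[e, 1]; child <- edge[e, 2]
      ps <- grid[, as.character(parent)]
      if (child <= ntip) {
        tv <- tipvec(child, s)
        # sum over the child's compatible states for each parent state
        contrib <- as.vector(P[, , e] %*% tv)[ps]
      } else {
        contrib <- P[, , e][cbind(ps, grid[, as.character(child)])]
      }
      term <- term * contrib
    }
    out[s] <- log(sum(term))
  }
  out
}

# --- Benjamini-Hochberg brute force ---------------------------------------

bh_brute <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # q_i = min over j with p_j >= p_i of m * p_j / rank(p_j)
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        cand <- min(cand, m * p[j] / rank_j)
      }
    }
    q[i] <- min(1, cand)
  }
  q
}

# --- per-base interval oracles --------------------------------------------

# set of covered bases of [start, end), as integer positions
bases_of <- function(start, end) seq.int(start, end - 1L)

oracle_coding <- function(regions, exons) {
  vapply(seq_len(nrow(regions)), function(i) {
    rb <- bases_of(regions$start[i], regions$end[i])
    for (j in seq_len(nrow(exons))) {
      if (exons$chrom[j] != regions$chrom[i]) next
      if (any(rb %in% bases_of(exons$start[j], exons$end[j]))) {
        return("CODING")
      }
    }
    "NONCODING"
  }, character(1))
}

oracle_gene_body <- function(regions, units, exons = NULL,
                             noncoding_only = FALSE) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rb <- bases_of(regions$start[i], regions$end[i])
    for (j in seq_len(nrow(units))) {
      if (units$chrom[j] != regions$chrom[i]) next
      inside <- rb[rb %in% bases_of(units$start[j], units$end[j])]
      if (length(inside) == 0) next
      if (noncoding_only) {
        ex <- exons[exons$gene_id == units$gene_id[j], ]
        exb <- unlist(lapply(seq_len(nrow(ex)), function(k)
          bases_of(ex$start[k], ex$end[k])))
        if (all(inside %in% exb)) next
      }
      out[[length(out) + 1L]] <- c(regions$id[i], units$gene_id[j])
    }
  }
  if (!length(out)) return(data.frame(region_id = character(0),
                                      gene_id = character(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("region_id", "gene_id")
  df
}

oracle_tad <- function(regions, units, tads) {
  t <- tss_position(units)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rb <- bases_of(regions$start[i], regions$end[i])
    for (k in seq_len(nrow(tads))) {
      if (tads$chrom[k] != regions$chrom[i]) next
      tb <- bases_of(tads$start[k], tads$end[k])
      if (!any(rb %in% tb)) next
      for (j in seq_len(nrow(units))) {
        if (units$chrom[j] != regions$chrom[i]) next
        if (t[j] %in% tb) {
          out[[length(out) + 1L]] <- c(regions$id[i], units$gene_id[j])
        }
      }
    }
  }
  if (!length(out)) return(data.frame(region_id = character(0),
                                      gene_id = character(0)))
  df <- unique(as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE))
  names(df) <- c("region_id", "gene_id")
  df
}

# normalized assignment comparison
sorted_pairs <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$region_id, df$gene_id))
}

# --- BEB exhaustive oracle -------------------------------------------------

# Exhaustive-summation oracle for the BEB posterior: explicit loops over
# every grid cell and class, with likelihoods from the enumeration oracle
# rather than the pruning code.
beb_oracle <- function(alignment, ltree, mle, grid) {
  pi <- mle$pi
  rate_of <- function(w) codon_rate_matrix(mle$kappa, w, pi)$scale
  R <- (mle$p0 + mle$p2a) * rate_of(mle$omega0) +
    (mle$p1 + mle$p2b) * rate_of(1)
  len <- ltree$tree$edge.length
  fg <- seq_along(len) %in% ltree$foreground
  class_lik <- function(w0, w2, k) {
    # per-edge omega for class k
    wbg <- c(w0, 1, w0, 1)[k]
    wfg <- c(w0, 1, w2, w2)[k]
    P <- array(0, c(61, 61, length(len)))
    for (e in seq_along(len)) {
      w <- if (fg[e]) wfg else wbg
      Q <- codon_rate_matrix(mle$kappa, w, pi)
      P[, , e] <- transition_matrix(Q, len[e] * rate_of(w) / R)
    }
    exp(enum_site_loglik(alignment, ltree, P, pi))
  }
  cells_p <- expand.grid(p0 = grid$p0, p1 = grid$p1)
  cells_p <- cells_p[cells_p$p0 + cells_p$p1 <= 1 + 1e-12, ]
  cells_w <- expand.grid(w0 = grid$omega0, w2 = grid$omega2)
  n_sites <- ncol(alignment$states)
  num <- matrix(0, n_sites, 4)
  for (ip in seq_len(nrow(cells_p))) {
    p0 <- cells_p$p0[ip]; p1 <- cells_p$p1[ip]
    rest <- max(0, 1 - p0 - p1)
    pk <- c(p0, p1, rest * p0 / (p0 + p1), rest * p1 / (p0 + p1))
    for (iw in seq_len(nrow(cells_w))) {
      mass <- 1 / (nrow(cells_p) * nrow(cells_w))
      for (k in 1:4) {
        num[, k] <- num[, k] +
          mass * pk[k] * class_lik(cells_w$w0[iw], cells_w$w2[iw], k)
      }
    }
  }
  num / rowSums(num)
}

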