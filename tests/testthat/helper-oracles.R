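# Independent oracles the tests compare the package against. These are
# deliberately naive implementations (direct enumeration, brute force) that
# share no code with the package internals.

# --- six-frame ORF oracle -------------------------------------------------

oracle_codon <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, codons)
})

oracle_translate1 <- function(codon) {
  if (grepl("N", codon)) return("X")
  unname(oracle_codon[codon])
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# All ORFs in all 6 frames by direct walking, matching the package's stated
# convention: atg_to_stop = first ATG of every stop-free codon run to the
# stop (or sequence end); coordinates forward-strand, stop excluded.
oracle_orfs <- function(seq, min_aa = 1L, mode = "atg_to_stop") {
  seq <- toupper(seq)
  L <- nchar(seq)
  res <- list()
  for (strand in c(1L, -1L)) {
    nt <- if (strand == 1L) seq else oracle_revcomp(seq)
    for (off in 0:2) {
      pos <- seq(off + 1L, L - 2L, by = 3L)
      if (off + 3L > L) next
      codons <- substring(nt, pos, pos + 2L)
      aa <- vapply(codons, oracle_translate1, character(1))
      run_start <- 1L
      i <- 1L
      flush <- function(run) {
        if (length(run) == 0) return()
        if (mode == "atg_to_stop") {
          atg <- run[codons[run] == "ATG"]
          if (length(atg) == 0) return()
          run <- seq(atg[1], run[length(run)])
        }
        pep <- paste(aa[run], collapse = "")
        if (nchar(pep) < min_aa) return()
        s0 <- pos[run[1]]
        e0 <- pos[run[length(run)]] + 2L
        if (strand == -1L) {
          tmp <- L - e0 + 1L
          e0 <- L - s0 + 1L
          s0 <- tmp
        }
        res[[length(res) + 1L]] <<- data.frame(
          frame = strand * (off + 1L), start = s0, end = e0,
          peptide = pep, stringsAsFactors = FALSE)
      }
      run <- integer()
      for (i in seq_along(aa)) {
        if (aa[i] == "*") {
          flush(run)
          run <- integer()
        } else run <- c(run, i)
      }
      flush(run)
    }
  }
  if (length(res) == 0) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$frame), , drop = FALSE]
}

# --- Fisher 2x2 two-sided exact oracle ------------------------------------

# Enumerate every table with the observed margins; two-sided p = sum of the
# probabilities of tables no more probable than the observed one.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  prob <- function(a) {
    stats::dhyper(a, r1, r2, c1)
  }
  a_obs <- tab[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(support, prob, numeric(1))
  sum(ps[ps <= prob(a_obs) * (1 + 1e-7)])
}

# --- UPGMA agglomeration oracle -------------------------------------------

# Average-linkage clustering by direct recomputation of cluster-average
# distances from the original matrix; returns the merge heights and a nested
# set representation of the clusters for topology comparison.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric()
  merges <- list()
  avg_dist <- function(c1, c2) mean(d[c1, c2])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- avg_dist(clusters[[i]], clusters[[j]])
      if (dd < best[1]) best <- c(dd, j, i)
    }
    i <- best[3]; j <- best[2]
    heights <- c(heights, best[1])
    merged <- c(clusters[[j]], clusters[[i]])
    merges[[length(merges) + 1L]] <- sort(merged)
    clusters[[j]] <- merged
    clusters[[i]] <- NULL
  }
  list(heights = heights, clades = merges)
}

# Clades (as sorted leaf sets) of a phylo tree, for topology comparison.
tree_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  lapply(nodes, function(nd) {
    sort(ape::extract.clade(tree, nd)$tip.label)
  })
}

# Topology equality as zero Robinson-Foulds distance between the unrooted
# trees (bipartition sets coincide).
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Canonical ordering for interolog tables before comparison.
ord_interlogs <- function(x) {
  x <- as.data.frame(x)[, c("source_edge_id", "species_id", "protein_a",
                            "protein_b")]
  x <- x[order(x$source_edge_id, x$species_id, x$protein_a, x$protein_b), ]
  rownames(x) <- NULL
  x
}

# --- brute-force interolog oracle -----------------------------------------

# Exhaustive enumeration over a plain list representation of ortholog sets:
# orth[[species]][[protein]] = character vector of partners.
oracle_interlogs <- function(edges, orth, tfs, homodimer_mode = "full",
                             dbd_filter = "both") {
  rows <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges$protein_a[r]; b <- edges$protein_b[r]
    s <- edges$species_id[r]; eid <- edges$edge_id[r]
    for (i in names(orth)) {
      if (i == s) next
      oa <- orth[[i]][[a]]; ob <- orth[[i]][[b]]
      if (is.null(oa)) oa <- character()
      if (is.null(ob)) ob <- character()
      pairs <- list()
      if (a == b) {
        oa <- sort(unique(oa))
        if (homodimer_mode == "diagonal") {
          pairs <- lapply(oa, function(x) c(x, x))
        } else {
          for (x in oa) for (y in oa) {
            p <- sort(c(x, y))
            pairs[[paste(p, collapse = "\r")]] <- p
          }
        }
      } else {
        for (x in oa) for (y in ob) {
          p <- sort(c(x, y))
          pairs[[paste(p, collapse = "\r")]] <- p
        }
      }
      for (p in pairs) {
        ok <- if (dbd_filter == "both") {
          p[1] %in% tfs[[i]] && p[2] %in% tfs[[i]]
        } else {
          p[1] %in% tfs[[i]] || p[2] %in% tfs[[i]]
        }
        if (!ok) next
        rows[[length(rows) + 1L]] <- data.frame(
          source_edge_id = eid, species_id = i, protein_a = p[1],
          protein_b = p[2], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(source_edge_id = character(), species_id = character(),
                      protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$source_edge_id, out$species_id, out$protein_a, out$protein_b), ,
      drop = FALSE]
}

# Random small interolog instance: <= 4 species, <= n_edges source edges,
# <= 4 orthologs per protein; returns package-shaped and oracle-shaped views.
random_interlog_instance <- function(n_edges = 8) {
  species <- c("S1", "S2", "S3", "S4")
  src <- "S1"
  prots <- sprintf("%s_g%d", src, 1:8)
  # ortholog maps: for each target species, each source protein gets 0-4
  # orthologs; represented as pairwise maps with one group per source protein
  maps <- list()
  orth <- setNames(vector("list", length(species)), species)
  for (i in setdiff(species, src)) {
    rows <- list()
    olist <- list()
    g <- 0L
    for (p in prots) {
      k <- sample(0:4, 1)
      if (k == 0) { olist[[p]] <- character(); next }
      g <- g + 1L
      partners <- sprintf("%s_%s_o%d", i, p, seq_len(k))
      olist[[p]] <- partners
      rows[[p]] <- data.frame(
        group_id = g, bitscore = 100,
        species_id = c(src, rep(i, k)),
        confidence = c(1, rep(0.8, k)),
        protein_id = c(p, partners), stringsAsFactors = FALSE)
    }
    m <- dplyr::bind_rows(rows)
    if (nrow(m) == 0) {
      m <- data.frame(group_id = integer(), bitscore = numeric(),
                      species_id = character(), confidence = numeric(),
                      protein_id = character())
    }
    m <- tibble::as_tibble(m)
    attr(m, "species_pair") <- sort(c(src, i))
    maps[[paste(sort(c(src, i)), collapse = "|")]] <- m
    orth[[i]] <- olist
  }
  orth[[src]] <- setNames(as.list(prots), prots)
  # random edges (some homodimers)
  ea <- sample(prots, n_edges, replace = TRUE)
  eb <- ifelse(runif(n_edges) < 0.2, ea, sample(prots, n_edges, replace = TRUE))
  edges <- tibble::tibble(
    edge_id = sprintf("e%02d", seq_len(n_edges)),
    protein_a = pmin(ea, eb), protein_b = pmax(ea, eb),
    species_id = src, evidence = "x")
  edges <- dplyr::distinct(edges, protein_a, protein_b, .keep_all = TRUE)
  # TF membership: each candidate protein is a TF with prob 0.8
  all_targets <- unlist(lapply(setdiff(species, src),
                               function(i) unlist(orth[[i]])))
  is_tf <- runif(length(all_targets)) < 0.8
  tf_tbl <- tibble::tibble(
    protein_id = c(prots, all_targets[is_tf]),
    species_id = c(rep(src, length(prots)),
                   sub("^(S[0-9]+)_.*$", "\\1", all_targets[is_tf])))
  tfs <- split(tf_tbl$protein_id, tf_tbl$species_id)
  list(edges = edges, maps = maps, orth = orth, tf_tbl = tf_tbl, tfs = tfs,
       species = species, source = src)
}
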