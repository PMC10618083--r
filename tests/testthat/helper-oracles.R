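# Independent brute-force oracles. Deliberately naive (double loops,
# all-pairs graphs) and kept free of any package internals so they can
# arbitrate the optimized implementations.

# TRS by explicit double loop over samples and genes
bruteTrs <- function(stdExpr, geneIds, weights) {
  out <- numeric(nrow(stdExpr))
  for (i in seq_len(nrow(stdExpr))) {
    s <- 0
    for (g in seq_along(geneIds)) {
      s <- s + weights[g] * stdExpr[i, geneIds[g]]
    }
    out[i] <- s
  }
  out
}

# connected components of the graph with an edge between every same-
# chromosome pair at TSS distance <= gap (all pairs, breadth-first)
bruteComponents <- function(chrom, tss, gap) {
  n <- length(chrom)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- chrom[i] == chrom[j] && abs(tss[i] - tss[j]) <= gap
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# per-cluster argmin of p with the tie rules (smaller tss, then gene id)
bruteLead <- function(geneIds, pvals, tss, comp) {
  keep <- character()
  for (k in unique(comp)) {
    idx <- which(comp == k)
    o <- idx[order(pvals[idx], tss[idx], geneIds[idx])]
    keep <- c(keep, geneIds[o[1L]])
  }
  keep
}

# direct filter on p <= threshold
bruteSelect <- function(df, thr) sort(df$gene_id[df$pvalue <= thr])

# random TWAS panel as a plain data.frame
randomPanelDf <- function(n, seed) {
  set.seed(seed)
  z <- rnorm(n)
  data.frame(gene_id = sprintf("g%03d", sample(n)),
             zscore = z,
             pvalue = 2 * pnorm(-abs(z)),
             chrom = paste0("chr", sample(1:3, n, replace = TRUE)),
             tss = sample.int(5e6, n),
             stringsAsFactors = FALSE)
}
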