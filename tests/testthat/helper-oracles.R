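# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the BPP oracle sums over the enumerated ensemble,
# the parsimony oracle enumerates internal labelings, and the structure
# counter is a bare nesting recursion.

# Boltzmann BPP by direct summation over the enumerated ensemble
oracle_bpp <- function(seq, model = energy_model()) {
  en <- enumerate_ensemble(seq, model)
  n <- nchar(seq)
  p <- matrix(0, n, n)
  for (r in seq_len(nrow(en))) {
    pm <- en$pairs[[r]]
    if (nrow(pm) > 0) {
      for (k in seq_len(nrow(pm))) {
        p[pm[k, 1], pm[k, 2]] <- p[pm[k, 1], pm[k, 2]] + en$prob[r]
      }
    }
  }
  p <- p + t(p)
  list(p = p, q = 1 - rowSums(p))
}

# count nested canonical-pair structures by a plain interval recursion
count_structures <- function(seq, min_loop = 3) {
  bases <- strsplit(seq, "")[[1]]
  can <- function(a, b) paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (j - i < min_loop + 1) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (can(bases[i], bases[k])) total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
    }
    memo[[key]] <- total
    total
  }
  cnt(1, nchar(seq))
}

# minimal Wagner length by enumerating all internal-node labelings
brute_wagner <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  S <- states[tree$tip.label, , drop = FALSE]
  k <- max(S) + 1L
  internals <- unique(tree$edge[, 1])
  total <- 0
  for (ch in seq_len(ncol(S))) {
    grid <- expand.grid(rep(list(0:(k - 1)), length(internals)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- numeric(max(tree$edge))
      lab[seq_len(ntip)] <- S[, ch]
      lab[internals] <- as.numeric(grid[g, ])
      best <- min(best, sum(abs(lab[tree$edge[, 1]] - lab[tree$edge[, 2]])))
    }
    total <- total + best
  }
  total
}

# canonical string for the root bipartition of a rooted tree
root_bipartition <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == ntip + 1, 2]
  side <- sort(if (kids[1] <= ntip) tree$tip.label[kids[1]] else
                 ape::extract.clade(tree, kids[1])$tip.label)
  a <- paste(side, collapse = ",")
  b <- paste(sort(setdiff(tree$tip.label, side)), collapse = ",")
  paste(sort(c(a, b)), collapse = "|")
}

random_char_matrix <- function(ntax, nchar_, k) {
  st <- matrix(sample(0:(k - 1), ntax * nchar_, TRUE), ntax, nchar_,
               dimnames = list(paste0("t", seq_len(ntax)),
                               paste0("c", seq_len(nchar_))))
  char_matrix(st, k)
}

moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  mean((x - mean(x))^3) / m2^1.5
}
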