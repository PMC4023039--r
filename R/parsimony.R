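# Wagner (ordered-character) maximum parsimony: tree length, exact and
# heuristic searches with Lundberg rooting, homoplasy indices, g1 skewness,
# and node distances.
#
# Internal tree representation during search: a two-column integer edge
# matrix. Tip ids are row indices of the state matrix (1..ntax); internal
# ids are allocated contiguously from ntax+1. When a hypothetical ancestor
# row "ANC" is present it is kept as an ordinary leaf (Lundberg rooting) and
# the reported trees are rooted on its attachment edge.

.states_of <- function(m) m$states

.anc_row <- function(states) {
  w <- which(rownames(states) == "ANC")
  if (length(w) == 0) NA_integer_ else w
}

.eval_len <- function(edge, states) {
  sum(wagner_length_cpp(edge, nrow(states), states))
}

# Serialise an internal edge matrix to Newick, then parse with ape.
.itree_to_phylo <- function(edge, labels) {
  parent <- edge[, 1]
  child <- edge[, 2]
  kids <- split(child, parent)
  root <- setdiff(parent, child)[1]
  build <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(labels[v])
    paste0("(", paste(vapply(ch, build, character(1)), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(root), ";"))
}

.root_on_anc <- function(phy) {
  if (!"ANC" %in% phy$tip.label) return(phy)
  phy <- ape::root(phy, outgroup = "ANC", resolve.root = TRUE)
  phy
}

#' Wagner parsimony length of a tree
#'
#' Minimal total cost of a rooted binary tree under linearly ordered states
#' (a change from state i to j costs |i - j|), summed over characters, via
#' the Farris interval algorithm. The length is invariant to root placement.
#'
#' @param tree a rooted binary `phylo` whose tip labels equal the matrix taxa.
#' @param m a `char_matrix`.
#' @param by_char return the per-character length vector instead of the sum.
#' @return Total steps (or per-character steps).
#' @export
wagner_length <- function(tree, m, by_char = FALSE) {
  states <- .states_of(m)
  if (!setequal(tree$tip.label, rownames(states))) {
    stop("tree taxa and matrix taxa differ", call. = FALSE)
  }
  states <- states[tree$tip.label, , drop = FALSE]
  len <- wagner_length_cpp(tree$edge, length(tree$tip.label), states)
  if (by_char) setNames(len, colnames(states)) else sum(len)
}

# ---- search engine ---------------------------------------------------------

# DFS over unrooted topologies represented as rooted trees with the anchor
# taxon (ANC when present, else the first taxon) fixed as a root child.
# Insertion into every edge except the anchor pendant edge enumerates each
# unrooted topology exactly once.
.search_dfs <- function(states, taxa_order, anchor, upper = Inf,
                        prune = TRUE, max_trees = 1000L) {
  ntax <- nrow(states)
  range_all <- apply(states, 2, function(x) diff(range(x)))
  env <- new.env(parent = emptyenv())
  env$best <- upper
  env$trees <- list()
  env$examined <- 0L
  rest <- setdiff(taxa_order, anchor)
  t1 <- rest[1]
  rest <- rest[-1]

  rec <- function(edge, ntips_in, depth, minc, maxc) {
    if (depth > length(rest)) {
      env$examined <- env$examined + 1L
      L <- .eval_len(edge, states)
      if (L < env$best - 1e-9) {
        env$best <- L
        env$trees <- list(edge)
      } else if (abs(L - env$best) <= 1e-9 && length(env$trees) < max_trees) {
        env$trees <- c(env$trees, list(edge))
      }
      return(invisible(NULL))
    }
    t <- rest[depth]
    minc2 <- pmin(minc, states[t, ])
    maxc2 <- pmax(maxc, states[t, ])
    rem <- sum(pmax(0, range_all - (maxc2 - minc2)))
    x <- ntax + ntips_in  # next internal id (contiguous)
    slots <- which(edge[, 2] != anchor)
    for (r in slots) {
      e2 <- rbind(edge, c(x, edge[r, 2]), c(x, t))
      e2[r, 2] <- x
      if (prune) {
        Lp <- .eval_len(e2, states)
        if (Lp + rem > env$best + 1e-9) next
      }
      rec(e2, ntips_in + 1L, depth + 1L, minc2, maxc2)
    }
  }

  root <- ntax + 1L
  edge0 <- rbind(c(root, anchor), c(root, t1))
  rec(edge0, 2L, 1L,
      pmin(states[anchor, ], states[t1, ]),
      pmax(states[anchor, ], states[t1, ]))
  env
}

# decreasing distinctiveness: taxa far from the column means are added early
.addition_order <- function(states, anchor) {
  centre <- colMeans(states)
  score <- rowSums((sweep(states, 2, centre))^2)
  ids <- order(-score, rownames(states))
  setdiff(ids, anchor)
}

.finish_result <- function(env, states, m, method, seed = NA_integer_,
                           g1_samples = 10000L) {
  labels <- rownames(states)
  trees <- lapply(env$trees, function(e) .root_on_anc(.itree_to_phylo(e, labels)))
  keys <- vapply(trees, ape::write.tree, character(1))
  trees <- trees[!duplicated(keys)]
  class(trees) <- "multiPhylo"
  cons <- if (length(trees) > 1) {
    ape::consensus(trees, p = 1, rooted = TRUE)
  } else NULL
  res <- structure(list(trees = trees, length = env$best, matrix = m,
                        method = method, seed = seed,
                        trees_examined = env$examined,
                        consensus = cons, fit = NULL),
                   class = "parsimony_result")
  if (g1_samples > 0) {
    res$fit <- fit_stats(trees[[1]], m, g1_samples = g1_samples,
                         seed = if (is.na(seed)) 1L else seed)
  }
  res
}

#' Exhaustive parsimony search
#'
#' Evaluates every topology (each unrooted topology on the full taxon set,
#' rooted on the ancestor's edge when `ANC` is present) and retains all
#' optimal trees. Refused beyond 9 non-ancestor taxa; use
#' [branch_and_bound()] there.
#'
#' @param m a `char_matrix` (attach the ancestor first for rooted trees).
#' @param max_trees cap on retained equally parsimonious trees.
#' @param g1_samples topology sample size for the g1 statistic.
#' @return A `parsimony_result`.
#' @export
exhaustive_search <- function(m, max_trees = 1000L, g1_samples = 10000L) {
  states <- .states_of(m)
  anc <- .anc_row(states)
  n_free <- nrow(states) - ifelse(is.na(anc), 0L, 1L)
  if (n_free > 9) {
    stop("exhaustive search refused for ", n_free,
         " taxa; use branch_and_bound()", call. = FALSE)
  }
  if (nrow(states) < 2) stop("need at least 2 taxa", call. = FALSE)
  anchor <- if (is.na(anc)) 1L else anc
  order_t <- .addition_order(states, anchor)
  env <- .search_dfs(states, c(anchor, order_t), anchor,
                     prune = FALSE, max_trees = max_trees)
  .finish_result(env, states, m, "exhaustive", g1_samples = g1_samples)
}

#' Branch-and-bound parsimony search
#'
#' Provably minimal Wagner length. The initial upper bound comes from a short
#' heuristic search; taxa are added in decreasing order of distinctiveness
#' and partial trees are pruned with the bound (partial length + per-character
#' remaining state range not yet spanned). Above `taxa_cap` taxa the search
#' falls back to [heuristic_search()] with a warning.
#'
#' @inheritParams exhaustive_search
#' @param taxa_cap fall back to the heuristic above this many taxa.
#' @param seed seed for the internal heuristic that sets the upper bound (the
#'   optimum found is independent of it).
#' @return A `parsimony_result`.
#' @export
branch_and_bound <- function(m, taxa_cap = 25L, seed = 1L,
                             max_trees = 1000L, g1_samples = 10000L) {
  states <- .states_of(m)
  if (nrow(states) > taxa_cap) {
    warning("more than ", taxa_cap,
            " taxa: falling back to heuristic search", call. = FALSE)
    return(heuristic_search(m, seed = seed, g1_samples = g1_samples))
  }
  anc <- .anc_row(states)
  anchor <- if (is.na(anc)) 1L else anc
  up <- heuristic_search(m, seed = seed, restarts = 3L, g1_samples = 0L)
  order_t <- .addition_order(states, anchor)
  # lengths are integral, so +0.5 admits every tree tying the upper bound
  env <- .search_dfs(states, c(anchor, order_t), anchor,
                     upper = up$length + 0.5, prune = TRUE,
                     max_trees = max_trees)
  .finish_result(env, states, m, "branch-and-bound", seed, g1_samples)
}

#' Heuristic parsimony search
#'
#' Random-addition stepwise insertion followed by nearest-neighbour
#' interchange hill climbing, repeated over `restarts` addition orders.
#' Deterministic given the seed. Scales to hundreds of taxa.
#'
#' @inheritParams exhaustive_search
#' @param seed RNG seed (mandatory for reproducibility).
#' @param restarts number of random-addition replicates.
#' @param g1_samples topology sample size for g1 (0 skips fit statistics).
#' @return A `parsimony_result`.
#' @export
heuristic_search <- function(m, seed, restarts = 10L, max_trees = 1000L,
                             g1_samples = 10000L) {
  states <- .states_of(m)
  ntax <- nrow(states)
  if (ntax < 2) stop("need at least 2 taxa", call. = FALSE)
  anc <- .anc_row(states)
  anchor <- if (is.na(anc)) 1L else anc
  free <- setdiff(seq_len(ntax), anchor)
  set.seed(seed)
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$trees <- list()
  env$examined <- 0L

  record <- function(edge, L) {
    if (L < env$best - 1e-9) {
      env$best <- L
      env$trees <- list(edge)
    } else if (abs(L - env$best) <= 1e-9 && length(env$trees) < max_trees) {
      env$trees <- c(env$trees, list(edge))
    }
  }

  for (r in seq_len(restarts)) {
    ord <- if (length(free) > 1) sample(free) else free
    root <- ntax + 1L
    edge <- rbind(c(root, anchor), c(root, ord[1]))
    ntips_in <- 2L
    for (t in ord[-1]) {
      x <- ntax + ntips_in
      slots <- which(edge[, 2] != anchor)
      bestL <- Inf; bestE <- NULL
      for (s in slots) {
        e2 <- rbind(edge, c(x, edge[s, 2]), c(x, t))
        e2[s, 2] <- x
        L <- .eval_len(e2, states)
        env$examined <- env$examined + 1L
        if (L < bestL - 1e-9) { bestL <- L; bestE <- e2 }
      }
      edge <- bestE
      ntips_in <- ntips_in + 1L
    }
    # NNI hill climbing (best-improvement, first tie kept)
    curL <- .eval_len(edge, states)
    repeat {
      bestL <- curL; bestE <- NULL
      internal_rows <- which(edge[, 2] > ntax)
      for (ir in internal_rows) {
        p <- edge[ir, 1]; cc <- edge[ir, 2]
        sib_row <- which(edge[, 1] == p & edge[, 2] != cc)
        kid_rows <- which(edge[, 1] == cc)
        for (kr in kid_rows) {
          e2 <- edge
          e2[sib_row, 2] <- edge[kr, 2]
          e2[kr, 2] <- edge[sib_row, 2]
          L <- .eval_len(e2, states)
          env$examined <- env$examined + 1L
          if (L < bestL - 1e-9) { bestL <- L; bestE <- e2 }
        }
      }
      if (is.null(bestE)) break
      edge <- bestE
      curL <- bestL
    }
    record(edge, curL)
  }
  if (g1_samples <= 0) {
    labels <- rownames(states)
    trees <- lapply(env$trees, function(e) .root_on_anc(.itree_to_phylo(e, labels)))
    keys <- vapply(trees, ape::write.tree, character(1))
    trees <- trees[!duplicated(keys)]
    class(trees) <- "multiPhylo"
    return(structure(list(trees = trees, length = env$best, matrix = m,
                          method = "heuristic", seed = seed,
                          trees_examined = env$examined,
                          consensus = NULL, fit = NULL),
                     class = "parsimony_result"))
  }
  .finish_result(env, states, m, "heuristic", seed, g1_samples)
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> ", x$method, " search: length ", x$length,
      ", ", length(x$trees), " optimal tree(s), ",
      x$trees_examined, " trees examined\n", sep = "")
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' @export
glance.parsimony_result <- function(x, ...) {
  tibble::tibble(
    length = x$length,
    n_trees = length(x$trees),
    ci = if (is.null(x$fit)) NA_real_ else x$fit$ci,
    ri = if (is.null(x$fit)) NA_real_ else x$fit$ri,
    rc = if (is.null(x$fit)) NA_real_ else x$fit$rc,
    g1 = if (is.null(x$fit)) NA_real_ else x$fit$g1,
    method = x$method,
    trees_examined = x$trees_examined
  )
}

#' @export
tidy.parsimony_result <- function(x, ...) {
  node_distances(x$trees[[1]])
}

# ---- fit statistics --------------------------------------------------------

# maximum conceivable steps of one ordered character: star-tree length with
# the optimal (median) central state
.star_max_steps <- function(col) {
  cands <- sort(unique(col))
  min(vapply(cands, function(mm) sum(abs(col - mm)), numeric(1)))
}

# enumerate lengths of every rooted labelled topology (small n)
.all_rooted_lengths <- function(states) {
  ntax <- nrow(states)
  out <- numeric(0)
  rec <- function(edge, ntips_in, nexttip, root) {
    if (nexttip > ntax) {
      out[length(out) + 1L] <<- .eval_len(edge, states)
      return(invisible(NULL))
    }
    x <- ntax + ntips_in
    for (r in seq_len(nrow(edge) + 1L)) {
      if (r <= nrow(edge)) {
        e2 <- rbind(edge, c(x, edge[r, 2]), c(x, nexttip))
        e2[r, 2] <- x
        rec(e2, ntips_in + 1L, nexttip + 1L, root)
      } else {  # new root above
        e2 <- rbind(edge, c(x, root), c(x, nexttip))
        rec(e2, ntips_in + 1L, nexttip + 1L, x)
      }
    }
  }
  root <- ntax + 1L
  rec(rbind(c(root, 1L), c(root, 2L)), 2L, 3L, root)
  out
}

.skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

#' Homoplasy and signal statistics of a tree
#'
#' Computes the tree length s, the consistency index CI = M/s (M = minimum
#' conceivable steps, the sum of per-character state ranges), the retention
#' index RI = (G - s)/(G - M) (G = maximum conceivable steps, the sum of
#' star-tree lengths), the rescaled consistency index RC = CI * RI, and the
#' g1 skewness of the length distribution over uniformly sampled rooted
#' topologies (complete enumeration when the matrix has at most 7 taxa).
#' Strongly negative g1 indicates phylogenetic signal. A zero-variance length
#' distribution yields g1 = NA, not 0.
#'
#' @param tree a rooted binary `phylo` over the matrix taxa.
#' @param m a `char_matrix`.
#' @param g1_samples number of sampled topologies when enumeration is not
#'   feasible.
#' @param seed RNG seed for the topology sample.
#' @return An object of class `fit_stats`.
#' @export
fit_stats <- function(tree, m, g1_samples = 10000L, seed = 1L) {
  states <- .states_of(m)
  s_char <- wagner_length(tree, m, by_char = TRUE)
  s <- sum(s_char)
  M <- sum(apply(states, 2, function(x) diff(range(x))))
  G <- sum(apply(states, 2, .star_max_steps))
  ci <- if (s > 0) M / s else 1
  ri <- if (G > M) (G - s) / (G - M) else 1
  ntax <- nrow(states)
  if (ntax <= 7) {
    lens <- .all_rooted_lengths(states)
    g1_method <- "enumeration"
    g1_n <- length(lens)
  } else {
    set.seed(seed)
    lens <- sample_topology_lengths_cpp(states, as.integer(g1_samples))
    g1_method <- "sampling"
    g1_n <- g1_samples
  }
  structure(list(length = s, ci = ci, ri = ri, rc = ci * ri,
                 g1 = .skewness(lens), g1_method = g1_method,
                 g1_samples = g1_n, steps_min = M, steps_max = G),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("length %s; CI = %.3f, RI = %.3f, RC = %.3f, g1 = %s (%s, n = %d)\n",
              format(x$length), x$ci, x$ri, x$rc,
              if (is.na(x$g1)) "undefined" else sprintf("%.3f", x$g1),
              x$g1_method, x$g1_samples))
  invisible(x)
}

#' @export
glance.fit_stats <- function(x, ...) {
  tibble::tibble(length = x$length, ci = x$ci, ri = x$ri, rc = x$rc,
                 g1 = x$g1, g1_method = x$g1_method, g1_samples = x$g1_samples)
}

#' Node distances and relative ages
#'
#' For every leaf of a rooted tree, the node distance nd is the number of
#' internal nodes on the path from the root to the leaf, and the relative
#' age is 1 - nd/nd_max (1 = most ancient/basal, 0 = most derived). The
#' hypothetical ancestor `ANC`, when present, is excluded from both the
#' output and the nd_max normalisation.
#'
#' @param tree a rooted `phylo`.
#' @return A tibble with columns `taxon`, `nd`, `relative_age`.
#' @export
node_distances <- function(tree) {
  if (!ape::is.rooted(tree)) stop("node distances require a rooted tree", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  depth <- integer(max(edge))
  for (r in seq_len(nrow(edge))) {
    depth[edge[r, 2]] <- depth[edge[r, 1]] + 1L
  }
  nd <- depth[seq_len(ntip)]
  keep <- tree$tip.label != "ANC"
  nd <- nd[keep]
  nd_max <- max(nd)
  tibble::tibble(taxon = tree$tip.label[keep], nd = nd,
                 relative_age = 1 - nd / nd_max)
}

#' Write the trees of a search result as Newick
#'
#' @param x a `parsimony_result`.
#' @param path output path; the strict consensus, when present, is appended
#'   as the last tree.
#' @export
write_result_trees <- function(x, path) {
  trees <- unclass(x$trees)
  if (!is.null(x$consensus)) trees <- c(trees, list(x$consensus))
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}
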