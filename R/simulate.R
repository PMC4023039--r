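# Synthetic data with known ground truth: reference trees, cloverleaf tRNA
# families evolved along them, drifted character matrices, and
# domain-abundance censuses from an accretion process.

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package's tests:
#' a 76-nt consensus cloverleaf scaffold, per-site substitution probability
#' 0.05 per edge with compensatory (pairing-preserving) stem mutations at
#' probability 0.9, and an accretion census with 30 domains, per-node birth
#' probability 0.25, abundance growth factor 1.5 per edge with lognormal
#' noise (sigma 0.25) on an initial abundance of 1.
#'
#' @param p_sub per-site substitution probability per edge.
#' @param p_comp probability that a stem mutation is compensatory (the
#'   partner base switches to the Watson-Crick complement, keeping the pair).
#' @param scaffold an `rna_structure` cloverleaf; must decompose cleanly
#'   under `template`.
#' @param template the [cloverleaf_template()] the scaffold follows.
#' @param n_domains,p_birth,growth,sigma,a0 accretion parameters: number of
#'   domains, per-node birth probability, multiplicative abundance growth per
#'   edge (>= 1), lognormal noise sigma, initial abundance at birth.
#' @param age_origin age (Gy) assigned to the root in truth tables.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p_sub = 0.05, p_comp = 0.9,
                       scaffold = trna_scaffold(),
                       template = cloverleaf_template(),
                       n_domains = 30L, p_birth = 0.25, growth = 1.5,
                       sigma = 0.25, a0 = 1, age_origin = 3.8) {
  stopifnot(p_sub >= 0, p_sub <= 1, p_comp >= 0, p_comp <= 1,
            p_birth > 0, p_birth <= 1, growth >= 1, sigma >= 0, a0 > 0)
  dec <- decompose_cloverleaf(scaffold, template)
  arms <- dec[dec$region != "variable_loop", ]
  if (!all(arms$present)) {
    stop("scaffold does not decompose into a full cloverleaf", call. = FALSE)
  }
  structure(list(p_sub = p_sub, p_comp = p_comp, scaffold = scaffold,
                 template = template, n_domains = as.integer(n_domains),
                 p_birth = p_birth, growth = growth, sigma = sigma,
                 a0 = a0, age_origin = age_origin),
            class = "sim_config")
}

#' The packaged consensus cloverleaf scaffold
#'
#' A synthetic 76-nt consensus cloverleaf consistent with the default
#' template (it is not any organism's tRNA), shipped as a plain-text
#' dot-bracket fixture.
#'
#' @return An `rna_structure`.
#' @export
trna_scaffold <- function() {
  path <- system.file("extdata", "cloverleaf_scaffold.dbn",
                      package = "rnaphylo", mustWork = TRUE)
  read_dotbracket(path)[[1]]
}

#' Simulate a reference tree
#'
#' Uniformly distributed rooted binary labelled topology (sequential random
#' attachment), deterministic per seed. Tips are labelled `t1..tn`.
#'
#' @param n_taxa number of tips, >= 2.
#' @param seed RNG seed (mandatory).
#' @return A rooted `phylo`.
#' @export
simulate_reference_tree <- function(n_taxa, seed) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  ntax <- as.integer(n_taxa)
  root <- ntax + 1L
  edge <- rbind(c(root, 1L), c(root, 2L))
  nexti <- ntax + 2L
  for (tip in seq_len(ntax)[-(1:2)]) {
    nedge <- nrow(edge)
    choice <- sample.int(nedge + 1L, 1L)
    x <- nexti
    nexti <- nexti + 1L
    if (choice > nedge) {
      edge <- rbind(edge, c(x, root), c(x, tip))
      root <- x
    } else {
      edge <- rbind(edge, c(x, edge[choice, 2]), c(x, tip))
      edge[choice, 2] <- x
    }
  }
  .itree_to_phylo(edge, paste0("t", seq_len(ntax)))
}

.complement <- c(A = "U", U = "A", G = "C", C = "G")

#' Evolve a cloverleaf tRNA family along a tree
#'
#' The scaffold sequence is mutated independently along each edge: every site
#' substitutes with probability `p_sub` (uniform over the three alternative
#' bases; no indels, so the position template stays valid). A substitution
#' inside a stem is compensatory with probability `p_comp`: the partner base
#' is replaced by the Watson-Crick complement so the pair survives. Each leaf
#' is emitted with the scaffold pairs that remain canonical (including G-U
#' wobbles) in its sequence, so low compensation erodes arms and
#' `p_comp = 1` preserves the full cloverleaf by construction.
#'
#' @param tree a rooted `phylo` (e.g. [simulate_reference_tree()]).
#' @param config a [sim_config()].
#' @param seed RNG seed (mandatory).
#' @return A list: `seqs` (tibble `name`, `sequence`, `structure`), `tree`,
#'   `config`.
#' @export
evolve_trna_family <- function(tree, config = sim_config(), seed) {
  set.seed(seed)
  scaffold <- config$scaffold
  n <- nchar(scaffold$sequence)
  pairs <- scaffold$pairs
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]

  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs_at <- vector("list", max(tree$edge))
  seqs_at[[root]] <- strsplit(scaffold$sequence, "")[[1]]

  mutate_edge <- function(bases) {
    hit <- which(runif(n) < config$p_sub)
    for (i in hit) {
      old <- bases[i]
      bases[i] <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
      if (partner[i] > 0 && runif(1) < config$p_comp) {
        bases[partner[i]] <- .complement[[bases[i]]]
      }
    }
    bases
  }

  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
    seqs_at[[ch]] <- mutate_edge(seqs_at[[p]])
  }

  canonical <- c("GC", "CG", "AU", "UA", "GU", "UG")
  rows <- lapply(seq_len(ntip), function(tip) {
    bases <- seqs_at[[tip]]
    keep <- paste0(bases[pairs[, 1]], bases[pairs[, 2]]) %in% canonical
    s <- rna_structure(paste(bases, collapse = ""),
                       pairs[keep, , drop = FALSE],
                       name = tree$tip.label[tip])
    tibble::tibble(name = s$name, sequence = s$sequence,
                   structure = dotbracket_string(s))
  })
  list(seqs = dplyr::bind_rows(rows), tree = tree, config = config)
}

#' Simulate an ordered-character matrix drifting away from the ancestor
#'
#' Characters start at state 0 at the root (the polarised ancestral
#' condition) and drift toward higher states along every edge: the change
#' per edge is Poisson(`lambda_up`) upward minus Poisson(`lambda_down`)
#' downward (reversals = noise), clamped to `0..k-1`. Change is
#' punctuational — associated with cladogenetic events rather than with
#' elapsed time — which is the model of evolution implied by reading node
#' distances as relative ages: a lineage's accumulated conformational change
#' is proportional to the number of nodes behind it. Under this model the
#' least-derived extant taxa genuinely carry near-ancestral states.
#'
#' @param tree a rooted `phylo`.
#' @param n_char number of characters.
#' @param k number of states.
#' @param lambda_up,lambda_down Poisson means of the upward drift and of the
#'   reversal noise, per edge.
#' @param seed RNG seed (mandatory).
#' @return A `char_matrix` over the tree's tips (polarity "low"; attach the
#'   ancestor with [attach_ancestor()] before searching).
#' @export
simulate_drift_matrix <- function(tree, n_char = 40L, k = 24L,
                                  lambda_up = 1.0, lambda_down = 0.1, seed) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  st <- matrix(NA_integer_, nrow = max(tree$edge), ncol = n_char)
  st[root, ] <- 0L
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
    delta <- rpois(n_char, lambda_up) - rpois(n_char, lambda_down)
    st[ch, ] <- pmin(pmax(st[p, ] + delta, 0L), k - 1L)
  }
  states <- st[seq_len(ntip), , drop = FALSE]
  dimnames(states) <- list(tree$tip.label, paste0("c", seq_len(n_char)))
  char_matrix(states, k,
              polarity = setNames(rep("low", n_char), colnames(states)))
}

#' Simulate a domain-abundance census by accretion
#'
#' Every domain is born exactly once at an internal node (geometric trials
#' with probability `p_birth` along the preorder sequence of internal nodes;
#' birth order defines the true age rank). From its birth node downward the
#' domain's abundance multiplies by `growth` per edge with lognormal noise;
#' leaves are the proteomes of the census. Domains born at the root are
#' present in every proteome. True ages map node depth linearly onto
#' `[0, age_origin]` Gy. A faithful interaction map ties each of the five
#' cloverleaf substructures (ordered acceptor, T arm, D arm, anticodon arm,
#' variable loop, oldest first) to the domain defining its age, plus one
#' younger interacting domain when available, so anchored ages reproduce the
#' true substructure age order.
#'
#' @param tree a rooted `phylo`; tips become proteomes.
#' @param config a [sim_config()].
#' @param seed RNG seed (mandatory).
#' @return A list: `census` (domains x proteomes integer matrix),
#'   `domain_ages` (tibble `unit`, `birth_node`, `depth`, `age_gy`),
#'   `interaction_map` (tibble `domain_id`, `substructure`, `evidence`),
#'   `substructure_ages` (tibble `unit`, `age_gy`), `tree`.
#' @export
simulate_domain_census <- function(tree, config = sim_config(), seed) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nnode <- max(edge)
  root <- ntip + 1L
  depth <- integer(nnode)
  for (r in seq_len(nrow(edge))) depth[edge[r, 2]] <- depth[edge[r, 1]] + 1L
  internals <- c(root, sort(unique(edge[edge[, 2] > ntip, 2])))
  internals <- internals[order(depth[internals], internals)]  # preorder-ish

  n_dom <- config$n_domains
  birth <- integer(n_dom)
  for (d in seq_len(n_dom)) {
    b <- NA_integer_
    for (v in internals) {
      if (runif(1) < config$p_birth) { b <- v; break }
    }
    birth[d] <- if (is.na(b)) internals[length(internals)] else b
  }
  dom_names <- sprintf("dom%02d", seq_len(n_dom))

  # abundance accretion below each birth node
  children <- split(edge[, 2], edge[, 1])
  census <- matrix(0L, nrow = n_dom, ncol = ntip,
                   dimnames = list(dom_names, tree$tip.label))
  for (d in seq_len(n_dom)) {
    ab <- numeric(nnode)
    ab[birth[d]] <- config$a0
    walk <- function(v) {
      for (ch in children[[as.character(v)]] %||% integer(0)) {
        noise <- if (config$sigma > 0) exp(rnorm(1, 0, config$sigma)) else 1
        ab[ch] <<- ab[v] * config$growth * noise
        walk(ch)
      }
    }
    walk(birth[d])
    leaf_ab <- ab[seq_len(ntip)]
    census[d, leaf_ab > 0] <- pmax(1L, as.integer(round(leaf_ab[leaf_ab > 0])))
  }

  max_depth <- max(depth[internals])
  birth_depth <- depth[birth]
  domain_ages <- tibble::tibble(
    unit = dom_names, birth_node = birth, depth = birth_depth,
    age_gy = config$age_origin * (1 - birth_depth / (max_depth + 1))
  )

  subs <- c("acceptor", "t_arm", "d_arm", "anticodon_arm", "variable_loop")
  ord <- order(domain_ages$depth, seq_len(n_dom))
  defining <- ord[seq_len(min(5L, n_dom))]
  map_rows <- list()
  for (i in seq_along(defining)) {
    d <- defining[i]
    map_rows[[length(map_rows) + 1L]] <-
      tibble::tibble(domain_id = dom_names[d], substructure = subs[i],
                     evidence = "simulated-defining")
    younger <- ord[ord > 0 & domain_ages$age_gy[ord] < domain_ages$age_gy[d]]
    younger <- setdiff(younger, defining)
    if (length(younger) > 0) {
      map_rows[[length(map_rows) + 1L]] <-
        tibble::tibble(domain_id = dom_names[younger[1]],
                       substructure = subs[i],
                       evidence = "simulated-extra")
    }
  }
  interaction_map <- dplyr::bind_rows(map_rows)
  substructure_ages <- tibble::tibble(
    unit = subs[seq_along(defining)],
    age_gy = domain_ages$age_gy[defining]
  )
  list(census = census, domain_ages = domain_ages,
       interaction_map = interaction_map,
       substructure_ages = substructure_ages, tree = tree)
}

#' Write a census matrix as TSV
#'
#' Header row carries proteome labels; first column (`domain`) the domain
#' labels — the format [read_census()] reads back.
#'
#' @param census integer matrix with dimnames.
#' @param path output path.
#' @export
write_census <- function(census, path) {
  tbl <- tibble::as_tibble(census, rownames = "domain")
  readr::write_tsv(tbl, path)
  invisible(path)
}
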