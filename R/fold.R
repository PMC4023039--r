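# Ensemble folding under a transparent energy model, plus the three
# morphospace statistics used as phylogenetic characters.

#' Simplified RNA energy model
#'
#' Per-pair free energies in thermal units (kT) for the three canonical pair
#' types, a bonus for every stacked adjacency (pairs (i,j) and (i+1,j-1) both
#' formed), and a minimum hairpin-loop length. The model is deliberately
#' transparent so the partition function can be verified against exhaustive
#' enumeration; it is the default backend of an interface that a
#' nearest-neighbour engine could replace.
#'
#' @param e_gc,e_au,e_gu pair energies (kT), must be <= 0.
#' @param e_stack stacking bonus (kT) per stacked adjacency.
#' @param min_loop minimum number of unpaired nucleotides in a hairpin loop.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(e_gc = -3.0, e_au = -2.0, e_gu = -1.0,
                         e_stack = -1.0, min_loop = 3L) {
  if (any(c(e_gc, e_au, e_gu) > 0)) stop("pair energies must be <= 0", call. = FALSE)
  if (min_loop < 0) stop("min_loop must be >= 0", call. = FALSE)
  structure(list(e_gc = e_gc, e_au = e_au, e_gu = e_gu,
                 e_stack = e_stack, min_loop = as.integer(min_loop)),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> GC %.1f, AU %.1f, GU %.1f, stack %.1f kT; min_loop %d\n",
              x$e_gc, x$e_au, x$e_gu, x$e_stack, x$min_loop))
  invisible(x)
}

.check_rna <- function(sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGU]+$", sequence)) {
    stop("sequence must be a non-empty RNA string over {A,C,G,U}", call. = FALSE)
  }
  sequence
}

.pair_energy_lookup <- function(model) {
  c(GC = model$e_gc, CG = model$e_gc, AU = model$e_au, UA = model$e_au,
    GU = model$e_gu, UG = model$e_gu)
}

#' Structure energy under the model
#'
#' Sum of pair energies plus the stacking bonus for every adjacency
#' (i,j),(i+1,j-1) in the pair set.
#'
#' @param s an `rna_structure`.
#' @param model an [energy_model()].
#' @return Energy in kT.
#' @export
structure_energy <- function(s, model = energy_model()) {
  pairs <- s$pairs
  if (nrow(pairs) == 0) return(0)
  bases <- strsplit(s$sequence, "")[[1]]
  lut <- .pair_energy_lookup(model)
  types <- paste0(bases[pairs[, 1]], bases[pairs[, 2]])
  if (any(!types %in% names(lut))) stop("non-canonical pair in structure", call. = FALSE)
  key <- paste(pairs[, 1], pairs[, 2])
  stacks <- sum(paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% key)
  sum(lut[types]) + stacks * model$e_stack
}

#' Exhaustively enumerate the structure ensemble (oracle)
#'
#' Lists every pseudoknot-free structure over canonical pairs respecting the
#' minimum loop length, with its energy and Boltzmann weight exp(-E). This is
#' the brute-force reference the dynamic-programming engine is validated
#' against; it refuses sequences longer than `max_len`.
#'
#' @param sequence RNA string.
#' @param model an [energy_model()].
#' @param max_len refusal threshold (combinatorial explosion guard).
#' @return A tibble with list-column `pairs` (two-column matrices), `energy`,
#'   `weight`, and `prob` (normalised weights).
#' @export
enumerate_ensemble <- function(sequence, model = energy_model(), max_len = 25L) {
  sequence <- .check_rna(sequence)
  n <- nchar(sequence)
  if (n > max_len) {
    stop("enumeration refused for length ", n, " > ", max_len,
         " (oracle use only)", call. = FALSE)
  }
  bases <- strsplit(sequence, "")[[1]]
  lut <- .pair_energy_lookup(model)
  can_pair <- function(i, j) paste0(bases[i], bases[j]) %in% names(lut)
  memo <- new.env(parent = emptyenv())
  # all pair sets on [i, j], decomposing on the leftmost position
  enum <- function(i, j) {
    if (j - i < model$min_loop + 1L) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j)                      # i unpaired
    for (k in (i + model$min_loop + 1L):j) {
      if (!can_pair(i, k)) next
      for (inner in enum(i + 1L, k - 1L)) {
        for (outer in enum(k + 1L, j)) {
          out[[length(out) + 1L]] <- rbind(c(i, k), inner, outer)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  sets <- enum(1L, n)
  energies <- vapply(sets, function(p) {
    if (is.null(p)) return(0)
    s <- rna_structure(sequence, p)
    structure_energy(s, model)
  }, numeric(1))
  w <- exp(-energies)
  tibble::tibble(
    pairs = lapply(sets, function(p) {
      if (is.null(p)) matrix(integer(), ncol = 2) else {
        p <- p[order(p[, 1]), , drop = FALSE]
        storage.mode(p) <- "integer"
        p
      }
    }),
    energy = energies, weight = w, prob = w / sum(w)
  )
}

#' Base-pairing probability matrix
#'
#' Computes the Boltzmann-ensemble probability p_ij that positions i and j
#' pair, and the unpaired probabilities q_i, by an inside-outside partition
#' function over the energy model. Invariants: the matrix is symmetric,
#' p_ij is zero inside the minimum loop span, and q_i + sum_j p_ij = 1.
#'
#' @param sequence RNA string.
#' @param model an [energy_model()].
#' @return An object of class `bpp_matrix`: list with `n`, symmetric matrix
#'   `p`, vector `q`, and the total partition function `Z`.
#' @export
partition_bpp <- function(sequence, model = energy_model()) {
  sequence <- .check_rna(sequence)
  res <- fold_partition_cpp(sequence, model$e_gc, model$e_au, model$e_gu,
                            model$e_stack, model$min_loop)
  structure(list(n = nchar(sequence), p = res$p, q = as.numeric(res$q),
                 Z = res$Z, sequence = sequence),
            class = "bpp_matrix")
}

#' @export
print.bpp_matrix <- function(x, ...) {
  cat("<bpp_matrix> ", x$n, " nt, Z = ", format(x$Z, digits = 6),
      ", max p_ij = ", format(max(x$p), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Minimum free energy structure
#'
#' Ties are broken deterministically: minimum energy, then fewest pairs, then
#' the lexicographically smallest sorted pair set.
#'
#' @inheritParams partition_bpp
#' @param name label of the returned structure.
#' @return An `rna_structure` carrying an `energy` attribute.
#' @export
mfe_structure <- function(sequence, model = energy_model(), name = "seq") {
  sequence <- .check_rna(sequence)
  res <- fold_mfe_cpp(sequence, model$e_gc, model$e_au, model$e_gu,
                      model$e_stack, model$min_loop)
  s <- rna_structure(sequence, res$pairs, name = name)
  attr(s, "energy") <- res$energy
  s
}

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# region = NULL means the whole molecule; otherwise an index vector.
.stats_one <- function(bpp, mfe, region = NULL, weighted = FALSE) {
  n_all <- bpp$n
  idx <- if (is.null(region)) seq_len(n_all) else sort(region)
  nr <- length(idx)
  p <- bpp$p[idx, idx, drop = FALSE]
  q <- bpp$q[idx]
  up <- p[upper.tri(p)]
  Q <- (.entropy_bits(up) + .entropy_bits(q)) / nr

  pairs <- mfe$pairs
  inside <- if (nrow(pairs) > 0) {
    pairs[, 1] %in% idx & pairs[, 2] %in% idx
  } else logical(0)
  crossing <- if (nrow(pairs) > 0) xor(pairs[, 1] %in% idx, pairs[, 2] %in% idx) else logical(0)
  sub_pairs <- pairs[inside, , drop = FALSE]
  if (weighted) {
    P <- 1 - mean(q)
    S <- .weighted_stem_length(bpp, idx)
  } else {
    P <- length(unique(c(sub_pairs))) / nr
    S <- if (nrow(sub_pairs) == 0) 0 else {
      h <- find_helices(rna_structure(mfe$sequence, sub_pairs))
      mean(h$length)
    }
  }
  tibble::tibble(Q = Q, P = P, S = S, context = sum(crossing))
}

# Ensemble-averaged variant: expected paired fraction and expected pairs per
# expected helix start (a pair whose outer neighbour is not formed).
.weighted_stem_length <- function(bpp, idx) {
  p <- bpp$p
  n <- bpp$n
  tot <- 0; starts <- 0
  for (r in seq_along(idx)) {
    for (s2 in seq_along(idx)) {
      i <- idx[r]; j <- idx[s2]
      if (j <= i || p[i, j] <= 0) next
      tot <- tot + p[i, j]
      outer_p <- if (i > 1 && j < n) p[i - 1, j + 1] else 0
      starts <- starts + max(0, p[i, j] - outer_p)
    }
  }
  if (starts <= 0) 0 else tot / starts
}

#' Morphospace statistics of folded molecules
#'
#' For each molecule (and optionally each cloverleaf region) computes the
#' three statistics that span the molecular morphospace:
#' \describe{
#'   \item{Q}{Shannon entropy of the base-pairing probability matrix, in bits
#'     per nucleotide: \eqn{Q = -(1/n)[\sum_{i<j} p_{ij} \log_2 p_{ij} +
#'     \sum_i q_i \log_2 q_i]} with \eqn{0 \log 0 = 0}.}
#'   \item{P}{base-pairing propensity: fraction of positions paired in the
#'     MFE structure.}
#'   \item{S}{mean stem (helix) length of the MFE structure, in pairs; 0 when
#'     there are no helices.}
#' }
#' With `weighted = TRUE`, P and S are ensemble averages instead of MFE
#' values (P = 1 - mean unpaired probability; S = expected pairs per expected
#' helix start). When a template is given, statistics are additionally
#' restricted to each region's index range; MFE pairs crossing a region
#' boundary are excluded there and counted in the `context` column.
#'
#' @param seqs a data frame with columns `name` and `sequence`, or a named
#'   character vector of sequences.
#' @param model an [energy_model()].
#' @param template optional [cloverleaf_template()]; adds per-region rows.
#' @param weighted use ensemble-averaged P and S.
#' @return A tibble with columns `name`, `region` ("all" for whole-molecule
#'   rows), `Q`, `P`, `S`, `context`.
#' @export
morphospace_stats <- function(seqs, model = energy_model(), template = NULL,
                              weighted = FALSE) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(name = names(seqs) %||% paste0("seq", seq_along(seqs)),
                           sequence = unname(seqs))
  }
  stopifnot(all(c("name", "sequence") %in% names(seqs)))
  regions <- if (is.null(template)) NULL else template_regions(template)
  purrr::map2(seqs$name, seqs$sequence, function(nm, sq) {
    bpp <- partition_bpp(sq, model)
    mfe <- mfe_structure(sq, model, name = nm)
    rows <- dplyr::bind_cols(tibble::tibble(name = nm, region = "all"),
                             .stats_one(bpp, mfe, NULL, weighted))
    if (!is.null(regions)) {
      reg_rows <- purrr::imap(regions, function(idx, rname) {
        dplyr::bind_cols(tibble::tibble(name = nm, region = rname),
                         .stats_one(bpp, mfe, idx, weighted))
      })
      rows <- dplyr::bind_rows(rows, dplyr::bind_rows(reg_rows))
    }
    rows
  }) |> dplyr::bind_rows()
}

#' Write morphospace statistics as TSV
#'
#' One row per molecule (or molecule x region); LF line endings.
#'
#' @param stats tibble from [morphospace_stats()].
#' @param path output path.
#' @export
write_morphospace_tsv <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
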