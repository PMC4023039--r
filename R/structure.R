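# Secondary-structure representation and cloverleaf decomposition.
# All coordinates are 1-based, closed ranges, matching tRNA numbering habits.

#' RNA secondary structure
#'
#' A light container for one RNA sequence plus a set of nested base pairs.
#' Pairs are stored as a two-column integer matrix (columns `i`, `j` with
#' `i < j`, 1-based). Structures are validated on construction: every index
#' occurs in at most one pair and pairs must be properly nested
#' (pseudoknot-free). Pseudoknotted input is rejected rather than silently
#' pruned because every downstream statistic assumes nested structures.
#'
#' @param sequence RNA string over `A`, `C`, `G`, `U`.
#' @param pairs two-column integer matrix of base pairs (may have zero rows).
#' @param name molecule label.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(sequence, pairs = matrix(integer(), ncol = 2),
                          name = "seq") {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGU]*$", sequence)) {
    stop("sequence must be an RNA string over {A,C,G,U}", call. = FALSE)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  colnames(pairs) <- c("i", "j")
  n <- nchar(sequence)
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j", call. = FALSE)
    if (any(pairs < 1L) || any(pairs > n)) stop("pair index out of range", call. = FALSE)
    idx <- c(pairs)
    if (anyDuplicated(idx)) stop("an index appears in more than one pair", call. = FALSE)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    if (.has_pseudoknot(pairs)) stop("pseudoknotted pair set rejected", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, pairs = pairs),
            class = "rna_structure")
}

.has_pseudoknot <- function(pairs) {
  if (nrow(pairs) < 2) return(FALSE)
  for (r in seq_len(nrow(pairs) - 1)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    rest <- pairs[(r + 1):nrow(pairs), , drop = FALSE]
    if (any(rest[, 1] > i & rest[, 1] < j & rest[, 2] > j)) return(TRUE)
  }
  FALSE
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$name, ": ", nchar(x$sequence), " nt, ",
      nrow(x$pairs), " pairs\n", sep = "")
  cat(x$sequence, "\n", dotbracket_string(x), "\n", sep = "")
  invisible(x)
}

#' Parse a dot-bracket string
#'
#' Matched parentheses become base pairs; the result is pseudoknot-free by
#' construction. Unbalanced brackets or a sequence/structure length mismatch
#' raise an error.
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string over `.`, `(`, `)`.
#' @inheritParams rna_structure
#' @return An `rna_structure`.
#' @examples
#' parse_dotbracket("GGGAAACCC", "(((...)))")
#' @export
parse_dotbracket <- function(sequence, structure, name = "seq") {
  if (nchar(sequence) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("structure may contain only '.', '(' and ')'", call. = FALSE)
  }
  open <- integer(0)
  pairs <- matrix(integer(), ncol = 2)
  plist <- list()
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      open <- c(open, pos)
    } else if (chars[pos] == ")") {
      if (length(open) == 0) stop("unbalanced brackets", call. = FALSE)
      plist[[length(plist) + 1]] <- c(open[length(open)], pos)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0) stop("unbalanced brackets", call. = FALSE)
  if (length(plist) > 0) pairs <- do.call(rbind, plist)
  rna_structure(sequence, pairs, name = name)
}

#' Dot-bracket string of a structure
#' @param s an `rna_structure`.
#' @return A character scalar.
#' @export
dotbracket_string <- function(s) {
  chars <- rep(".", nchar(s$sequence))
  if (nrow(s$pairs) > 0) {
    chars[s$pairs[, 1]] <- "("
    chars[s$pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Read / write Vienna-style dot-bracket files
#'
#' Three-line records: `>name`, sequence, structure. Writers emit LF line
#' endings; coordinates in the parsed pair sets are 1-based.
#'
#' @param path file path.
#' @return `read_dotbracket()` returns a list of `rna_structure` objects.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0 || any(diff(heads) != 3)) {
    stop("expected three-line records: >name, sequence, structure", call. = FALSE)
  }
  lapply(heads, function(h) {
    parse_dotbracket(lines[h + 1], lines[h + 2], name = sub("^>\\s*", "", lines[h]))
  })
}

#' @rdname read_dotbracket
#' @param structures list of `rna_structure` objects (or a single one).
#' @export
write_dotbracket <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in structures) {
    writeLines(c(paste0(">", s$name), s$sequence, dotbracket_string(s)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Maximal helices of a structure
#'
#' A helix is a maximal run of stacked pairs (i,j), (i+1,j-1), ... Every pair
#' belongs to exactly one helix.
#'
#' @param s an `rna_structure`.
#' @return A tibble with one row per helix: `helix`, `start5`, `end5`,
#'   `start3`, `end3`, `length` (number of pairs).
#' @export
find_helices <- function(s) {
  pairs <- s$pairs
  if (nrow(pairs) == 0) {
    return(tibble::tibble(helix = integer(), start5 = integer(),
                          end5 = integer(), start3 = integer(),
                          end3 = integer(), length = integer()))
  }
  key <- paste(pairs[, 1], pairs[, 2])
  starts <- which(!paste(pairs[, 1] - 1L, pairs[, 2] + 1L) %in% key)
  out <- lapply(seq_along(starts), function(h) {
    i <- pairs[starts[h], 1]; j <- pairs[starts[h], 2]
    len <- 1L
    while (paste(i + len, j - len) %in% key) len <- len + 1L
    tibble::tibble(helix = h, start5 = i, end5 = i + len - 1L,
                   start3 = j - len + 1L, end3 = j, length = len)
  })
  dplyr::bind_rows(out)
}

#' Cloverleaf position template
#'
#' Index ranges of the five canonical tRNA regions on a fixed numbering,
#' plus the anticodon triplet. The default follows conventional tRNA
#' numbering (76 nt): acceptor 1-7 and 66-72, D arm 10-25, anticodon arm
#' 27-43 (anticodon 34-36), variable loop 44-48, T arm 49-65. These
#' coordinates are a configurable convention, not a fixed standard; supply
#' your own `regions` tibble to override.
#'
#' @param regions tibble with columns `region`, `start`, `end`; region names
#'   must be among the five canonical ones and ranges must be disjoint.
#' @param anticodon integer triplet of anticodon positions.
#' @return An object of class `cloverleaf_template`.
#' @export
cloverleaf_template <- function(regions = NULL, anticodon = 34:36) {
  if (is.null(regions)) {
    regions <- tibble::tribble(
      ~region,          ~start, ~end,
      "acceptor",           1L,   7L,
      "acceptor",          66L,  72L,
      "d_arm",             10L,  25L,
      "anticodon_arm",     27L,  43L,
      "variable_loop",     44L,  48L,
      "t_arm",             49L,  65L
    )
  }
  canonical <- c("acceptor", "d_arm", "anticodon_arm", "variable_loop", "t_arm")
  if (!all(regions$region %in% canonical)) {
    stop("region names must be among: ", paste(canonical, collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$end < regions$start)) stop("end < start in template", call. = FALSE)
  covered <- unlist(Map(seq, regions$start, regions$end))
  if (anyDuplicated(covered)) stop("template ranges overlap", call. = FALSE)
  structure(list(regions = regions, anticodon = as.integer(anticodon)),
            class = "cloverleaf_template")
}

#' @export
print.cloverleaf_template <- function(x, ...) {
  cat("<cloverleaf_template> anticodon at",
      paste(range(x$anticodon), collapse = "-"), "\n")
  print(x$regions)
  invisible(x)
}

#' Decompose a structure into cloverleaf substructures
#'
#' Assigns template regions to a folded molecule. A region is flagged present
#' when at least one base pair falls entirely inside its index range(s); the
#' variable loop is classified type I or type II by its range length
#' (type II when longer than `type2_threshold` nucleotides, a convention for
#' the long variable loops of serine/leucine-type tRNAs).
#'
#' @param s an `rna_structure`.
#' @param template a [cloverleaf_template()].
#' @param type2_threshold variable-loop length (nt) above which the loop is
#'   called type II.
#' @return A tibble with columns `region`, `start`, `end`, `present`,
#'   `variable_type` (NA outside the variable loop), `n_pairs`.
#' @export
decompose_cloverleaf <- function(s, template = cloverleaf_template(),
                                 type2_threshold = 10) {
  n <- nchar(s$sequence)
  if (max(template$regions$end) > n) {
    stop("template range exceeds sequence length (", n, " nt)", call. = FALSE)
  }
  pairs <- s$pairs
  reg <- template$regions
  per_region <- reg |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(idx = list(unlist(Map(seq, .data$start, .data$end))),
                     span = sum(.data$end - .data$start + 1L))
  info <- purrr::pmap(per_region, function(region, idx, span) {
    inside <- if (nrow(pairs) > 0) {
      pairs[, 1] %in% idx & pairs[, 2] %in% idx
    } else logical(0)
    tibble::tibble(
      region = region,
      present = if (region == "variable_loop") TRUE else any(inside),
      variable_type = if (region == "variable_loop") {
        if (span > type2_threshold) "II" else "I"
      } else NA_character_,
      n_pairs = sum(inside)
    )
  }) |> dplyr::bind_rows()
  dplyr::left_join(reg, info, by = "region")
}

#' Region index sets of a template
#'
#' @param template a [cloverleaf_template()].
#' @return Named list mapping each region to its (possibly split) index vector.
#' @export
template_regions <- function(template) {
  reg <- template$regions
  split(unlist(Map(seq, reg$start, reg$end)),
        rep(reg$region, reg$end - reg$start + 1L))
}

#' Read / write FASTA sequence files
#'
#' Wrappers around [Biostrings::readBStringSet()] /
#' [Biostrings::writeXStringSet()]; sequences are upper-cased on read.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  toupper(setNames(as.character(set), names(set)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
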