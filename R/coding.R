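# Coding continuous statistics and abundance counts as linearly ordered
# multistate phylogenetic characters.

#' Character matrix of ordered multistate characters
#'
#' Taxa x characters integer matrix with entries in `0..k-1`, interpreted as
#' linearly ordered states (a change from state i to j costs |i - j|).
#' Carries a per-character polarity convention ("low": state 0 ancestral;
#' "high": state k-1 ancestral) used to build the hypothetical ancestor, and
#' a per-character informativeness flag (zero-range characters are retained
#' but marked uninformative so matrix dimensions match the input).
#'
#' @param states integer matrix with dimnames (taxa, characters).
#' @param k number of states (at most 24, the size of the parsimony symbol
#'   alphabet `0-9A-N`).
#' @param polarity named character vector per character: "low", "high" or NA.
#' @param informative logical per character; computed from state ranges when
#'   omitted.
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(states, k, polarity = NULL, informative = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states)) || is.null(colnames(states))) {
    stop("states must carry taxon and character names", call. = FALSE)
  }
  if (k < 2 || k > 24) stop("k must be in 2..24", call. = FALSE)
  if (any(states < 0L | states > k - 1L)) {
    stop("states out of range 0..k-1", call. = FALSE)
  }
  if (is.null(polarity)) polarity <- setNames(rep(NA_character_, ncol(states)),
                                              colnames(states))
  if (is.null(informative)) {
    informative <- apply(states, 2, function(col) diff(range(col)) > 0)
  }
  structure(list(states = states, k = as.integer(k),
                 polarity = polarity, informative = informative,
                 ordered = TRUE),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", nrow(x$states), " taxa x ", ncol(x$states),
      " ordered characters, k = ", x$k,
      if (has_ancestor(x)) ", ANC attached" else "", "\n", sep = "")
  cat(sum(!x$informative), "uninformative character(s)\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' @rdname char_matrix
#' @param x a `char_matrix`.
#' @export
has_ancestor <- function(x) "ANC" %in% rownames(x$states)

#' @export
tidy.char_matrix <- function(x, ...) {
  tibble::as_tibble(x$states, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "character", values_to = "state")
}

#' Discretise a continuous character column
#'
#' Linear binning of `[min, max]` into `k` equal-width states. Values on a
#' bin boundary go to the lower state; constant columns map to state 0 and
#' are flagged uninformative via the `informative` attribute. Discretisation
#' is monotone: value order is preserved by state order.
#'
#' @param values finite numeric vector (one value per taxon).
#' @param k number of states, >= 2.
#' @return Integer vector of states in `0..k-1` with attribute `informative`.
#' @export
discretize <- function(values, k = 24L) {
  if (any(!is.finite(values))) stop("non-finite value in character column", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  rng <- range(values)
  if (diff(rng) == 0) {
    out <- rep(0L, length(values))
    attr(out, "informative") <- FALSE
    return(out)
  }
  u <- (values - rng[1]) / diff(rng)
  s <- as.integer(pmin(pmax(ceiling(u * k - 1e-9) - 1L, 0L), k - 1L))
  attr(s, "informative") <- TRUE
  s
}

#' Build a character matrix from morphospace statistics
#'
#' In `ToM` mode taxa are molecules and characters are statistic-by-region
#' combinations; `ToS` mode is the transposed arrangement, with substructures
#' as taxa and molecule-by-statistic combinations as characters (the matrix
#' whose parsimony tree is a tree of substructures). Each character column is
#' discretised independently with [discretize()]. Polarity follows the
#' statistic: entropy (`Q`) is polarised with maximal disorder ancestral
#' (state k-1), propensity and stem length (`P`, `S`) with minimal order
#' ancestral (state 0); additional statistic columns default to "low".
#'
#' @param stats tibble from [morphospace_stats()] (columns `name`, `region`,
#'   and the statistic columns).
#' @param mode `"ToM"` or `"ToS"`.
#' @param k number of states.
#' @param stat_cols which statistic columns to use.
#' @param polarity_map named vector giving the ancestral extreme per
#'   statistic ("low" or "high").
#' @return A `char_matrix`.
#' @export
build_character_matrix <- function(stats, mode = c("ToM", "ToS"), k = 24L,
                                   stat_cols = c("Q", "P", "S"),
                                   polarity_map = c(Q = "high", P = "low", S = "low")) {
  mode <- match.arg(mode)
  stopifnot(all(c("name", "region") %in% names(stats)))
  missing_cols <- setdiff(stat_cols, names(stats))
  if (length(missing_cols) > 0) {
    stop("missing statistic columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  long <- stats |>
    dplyr::select(dplyr::all_of(c("name", "region", stat_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(stat_cols),
                        names_to = "stat", values_to = "value")
  if (any(!is.finite(long$value))) {
    bad <- long[!is.finite(long$value), c("name", "region", "stat")]
    stop("missing/non-finite cells: ",
         paste(utils::capture.output(print(as.data.frame(bad))), collapse = "\n"),
         call. = FALSE)
  }
  if (mode == "ToM") {
    long$taxon <- long$name
    long$character <- paste(long$region, long$stat, sep = ".")
  } else {
    long$taxon <- long$region
    long$character <- paste(long$name, long$stat, sep = ".")
  }
  wide <- long |>
    dplyr::select("taxon", "character", "value", "stat") |>
    tidyr::pivot_wider(id_cols = "taxon", names_from = "character",
                       values_from = "value")
  vals <- as.matrix(wide[, -1])
  rownames(vals) <- wide$taxon
  if (anyNA(vals)) stop("incomplete stats table: some taxon/character cells missing",
                        call. = FALSE)
  cols <- lapply(seq_len(ncol(vals)), function(j) discretize(vals[, j], k))
  states <- do.call(cbind, lapply(cols, as.integer))
  dimnames(states) <- dimnames(vals)
  stat_of <- sub("^.*\\.", "", colnames(states))
  pol <- unname(polarity_map[stat_of])
  pol[is.na(pol) & stat_of %in% stat_cols] <- "low"
  char_matrix(states, k,
              polarity = setNames(pol, colnames(states)),
              informative = vapply(cols, attr, logical(1), "informative"))
}

#' Transpose a character matrix
#'
#' Swaps taxa and characters; an involution that preserves every cell.
#' Refused once an ancestor row is attached (the ancestor is a taxon, not a
#' character). Per-character polarity does not survive transposition and is
#' reset to the common polarity when all characters agree, otherwise NA.
#'
#' @param m a `char_matrix`.
#' @return The transposed `char_matrix`.
#' @export
transpose_matrix <- function(m) {
  if (has_ancestor(m)) stop("transpose before attaching the ancestor", call. = FALSE)
  pol <- unique(m$polarity)
  newpol <- if (length(pol) == 1) pol else NA_character_
  st <- t(m$states)
  char_matrix(st, m$k,
              polarity = setNames(rep(newpol, ncol(st)), colnames(st)))
}

#' Attach the polarising hypothetical ancestor
#'
#' Adds a taxon row named `ANC` carrying the ancestral extreme of every
#' character: state `k-1` for characters polarised "high" (maximal ensemble
#' disorder ancestral, the convention for entropy-derived characters) and
#' state 0 for characters polarised "low" (minimal conformational order or
#' minimal abundance ancestral). With the ancestor included as an ordinary
#' taxon, parsimony trees are rooted Lundberg-style on its attachment edge.
#'
#' @param m a `char_matrix`.
#' @param polarity optional override, recycled or per character.
#' @return A `char_matrix` with the `ANC` row appended; other rows unchanged.
#' @export
attach_ancestor <- function(m, polarity = NULL) {
  if (has_ancestor(m)) stop("matrix already contains a taxon named ANC", call. = FALSE)
  pol <- m$polarity
  if (!is.null(polarity)) {
    pol <- setNames(rep(polarity, length.out = ncol(m$states)), colnames(m$states))
  }
  if (any(is.na(pol))) {
    stop("polarity undefined for character(s): ",
         paste(colnames(m$states)[is.na(pol)], collapse = ", "), call. = FALSE)
  }
  if (!all(pol %in% c("low", "high"))) stop("polarity must be 'low' or 'high'", call. = FALSE)
  anc <- ifelse(pol == "high", m$k - 1L, 0L)
  states <- rbind(m$states, ANC = as.integer(anc))
  char_matrix(states, m$k, polarity = pol, informative = m$informative)
}

#' Code a domain-abundance census as ordered characters
#'
#' Taxa are domains, characters are proteomes. Genomic abundance g is mapped
#' to `round_half_up((k-1) * ln(g+1) / ln(g_max+1))` with `g_max` the
#' per-proteome maximum, a logarithmic rescaling that keeps coding monotone
#' in abundance and robust to overall scale. All-zero proteome columns code
#' to state 0 and are flagged uninformative. The default polarity treats
#' maximal abundance as ancestral ("high"), following the generality
#' criterion: under accretion the oldest domains are the most abundant and
#' ubiquitous, so the hypothetical ancestor carries state k-1 and the most
#' abundant domains attach basally. The opposite convention ("low") is
#' available; results record which was used.
#'
#' @param census non-negative integer matrix (domains x proteomes) with
#'   dimnames, or a data frame whose first column holds domain labels.
#' @param k number of states.
#' @param polarity "high" (default) or "low".
#' @return A `char_matrix`.
#' @export
code_abundance <- function(census, k = 24L, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  if (is.data.frame(census)) {
    labs <- census[[1]]
    census <- as.matrix(census[, -1])
    rownames(census) <- labs
  }
  if (any(census < 0)) stop("negative counts in census", call. = FALSE)
  if (any(census != round(census))) stop("census counts must be integers", call. = FALSE)
  states <- apply(census, 2, function(g) {
    gmax <- max(g)
    if (gmax == 0) return(rep(0L, length(g)))
    as.integer(floor((k - 1) * log1p(g) / log1p(gmax) + 0.5))
  })
  dimnames(states) <- dimnames(census)
  char_matrix(states, k,
              polarity = setNames(rep(polarity, ncol(states)), colnames(states)))
}

#' Read a domain-abundance census TSV
#'
#' Header row gives proteome labels; the first column gives domain labels.
#'
#' @param path file path.
#' @return Integer matrix domains x proteomes.
#' @export
read_census <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "integer"
  m
}

.nexus_symbols <- strsplit("0123456789ABCDEFGHIJKLMN", "")[[1]]

#' Write a character matrix as NEXUS
#'
#' Emits a DATA block using the symbol alphabet `0-9A-N` (up to 24 states)
#' with the ancestor, when present, written as an ordinary taxon, and an
#' ASSUMPTIONS block declaring every character ordered, for interoperability
#' with classic parsimony programs.
#'
#' @param m a `char_matrix`.
#' @param path output path.
#' @export
write_nexus <- function(m, path) {
  st <- m$states
  rows <- apply(st, 1, function(r) paste(.nexus_symbols[r + 1L], collapse = ""))
  pad <- max(nchar(rownames(st))) + 2L
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(.nexus_symbols[seq_len(m$k)], collapse = "")),
    "  MATRIX",
    paste0("    ", formatC(rownames(st), width = -pad), rows),
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    "  TYPESET * default = ord: ALL;",
    "END;"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a NEXUS character matrix
#'
#' Reads a DATA block (via [ape::read.nexus.data()]) written with the
#' `0-9A-N` ordered-state symbol convention.
#'
#' @param path file path.
#' @return A `char_matrix`.
#' @export
read_nexus_matrix <- function(path) {
  dat <- ape::read.nexus.data(path)
  txt <- readLines(path)
  sym_line <- grep("SYMBOLS", txt, value = TRUE, ignore.case = TRUE)[1]
  k <- if (!is.na(sym_line)) {
    nchar(sub('.*SYMBOLS="([^"]+)".*', "\\1", sym_line, ignore.case = TRUE))
  } else 24L
  states <- do.call(rbind, lapply(dat, function(chars) {
    match(toupper(chars), .nexus_symbols) - 1L
  }))
  colnames(states) <- paste0("c", seq_len(ncol(states)))
  char_matrix(states, k)
}
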