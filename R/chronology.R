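# Linear molecular clock on node distances and interaction-based anchoring
# of RNA substructure ages. Ages are in Gy (gigayears before present).

#' Calibrate a linear molecular clock
#'
#' Ordinary least squares of geological age (Gy) on a tree-derived distance
#' (relative age `1 - nd/nd_max` by default, or raw node distance), following
#' the practice of calibrating structural phylogenies against diagnostic
#' ages. Relative age is the recommended x-variable because it transfers
#' across trees of different depth.
#'
#' @param points data frame with columns `x` (node distance or relative age)
#'   and `age_gy`.
#' @param age_ceiling oldest admissible age (Gy); predictions are clamped to
#'   `[0, age_ceiling]` with a flag, never silently.
#' @return An object of class `clock_model`.
#' @export
calibrate_clock <- function(points, age_ceiling = 4.2) {
  stopifnot(all(c("x", "age_gy") %in% names(points)))
  if (length(unique(points$x)) < 2) {
    stop("clock calibration needs at least 2 distinct x-values", call. = FALSE)
  }
  fit <- lm(age_gy ~ x, data = points)
  # perfect (collinear) calibrations are legitimate here; silence lm's
  # "essentially perfect fit" note
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 points = tibble::as_tibble(points),
                 age_ceiling = age_ceiling),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> age = %.4g + %.4g * x (Gy), R^2 = %.4f, %d calibration points\n",
              x$intercept, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.clock_model <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.clock_model <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 slope = x$slope, intercept = x$intercept,
                 nobs = nrow(x$points))
}

#' Convert node distances to ages
#'
#' Applies the fitted clock to each unit. Predictions below 0 or above the
#' ceiling are clamped and flagged; x-values outside the calibration range
#' are flagged as extrapolations.
#'
#' @param clock a [calibrate_clock()] model.
#' @param units data frame with columns `unit` and `x` (and optionally
#'   `kind`, defaulting to "domain").
#' @return A timeline tibble: `unit`, `kind`, `age_gy`, `provenance`,
#'   `flags` (empty string when clean).
#' @export
apply_clock <- function(clock, units) {
  stopifnot(all(c("unit", "x") %in% names(units)))
  kind <- if ("kind" %in% names(units)) units$kind else rep("domain", nrow(units))
  raw <- clock$intercept + clock$slope * units$x
  rng <- range(clock$points$x)
  flags <- character(nrow(units))
  extra <- units$x < rng[1] | units$x > rng[2]
  flags[extra] <- paste0(flags[extra], "extrapolated;")
  clamped <- raw < -1e-9 | raw > clock$age_ceiling + 1e-9
  flags[clamped] <- paste0(flags[clamped], "clamped;")
  age <- pmin(pmax(raw, 0), clock$age_ceiling)
  tibble::tibble(unit = units$unit, kind = kind, age_gy = age,
                 provenance = "clock", flags = flags)
}

#' Anchor substructure ages through RNA-protein interactions
#'
#' Operationalises "the age of an interaction is the age of the interacting
#' components": each substructure inherits the maximum age over its
#' interacting protein domains (the oldest partner sets a lower bound on the
#' substructure's age). Anchoring is monotone: adding an older interacting
#' domain never decreases an anchored age.
#'
#' @param domain_ages timeline tibble with `unit` (domain ids) and `age_gy`.
#' @param interaction_map data frame with columns `domain_id`,
#'   `substructure`, and optionally `evidence`.
#' @return A timeline tibble for the substructures, provenance
#'   `"interaction-anchor"`.
#' @export
anchor_substructures <- function(domain_ages, interaction_map) {
  stopifnot(all(c("domain_id", "substructure") %in% names(interaction_map)))
  unknown <- setdiff(interaction_map$domain_id, domain_ages$unit)
  if (length(unknown) > 0) {
    stop("interaction map references unknown domain(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(interaction_map) == 0) {
    return(tibble::tibble(unit = character(), kind = character(),
                          age_gy = numeric(), provenance = character(),
                          flags = character()))
  }
  interaction_map |>
    dplyr::left_join(dplyr::select(domain_ages, "unit", "age_gy"),
                     by = c(domain_id = "unit")) |>
    dplyr::group_by(unit = .data$substructure) |>
    dplyr::summarise(age_gy = max(.data$age_gy), .groups = "drop") |>
    dplyr::mutate(kind = "substructure", provenance = "interaction-anchor",
                  flags = "") |>
    dplyr::select("unit", "kind", "age_gy", "provenance", "flags")
}

#' Age of each individual interaction
#'
#' The complementary aggregation rule: an interaction can be no older than
#' its youngest component, so its age is the minimum of the component ages.
#'
#' @inheritParams anchor_substructures
#' @param substructure_ages optional timeline for the substructures; when
#'   given, the interaction age is `min(domain age, substructure age)`,
#'   otherwise the domain age is reported.
#' @return A tibble `domain_id`, `substructure`, `age_gy`.
#' @export
interaction_ages <- function(domain_ages, interaction_map,
                             substructure_ages = NULL) {
  out <- interaction_map |>
    dplyr::left_join(dplyr::select(domain_ages, "unit", dom_age = "age_gy"),
                     by = c(domain_id = "unit"))
  if (!is.null(substructure_ages)) {
    out <- out |>
      dplyr::left_join(dplyr::select(substructure_ages, "unit", sub_age = "age_gy"),
                       by = c(substructure = "unit")) |>
      dplyr::mutate(age_gy = pmin(.data$dom_age, .data$sub_age, na.rm = TRUE))
  } else {
    out <- dplyr::mutate(out, age_gy = .data$dom_age)
  }
  dplyr::select(out, "domain_id", "substructure", "age_gy")
}

#' Check anchored ages against tree-derived relative ages
#'
#' Flags substructures whose anchored-age rank order contradicts the relative
#' ages read off a substructure tree. Both values are reported; a
#' contradiction raises a flag, never an error.
#'
#' @param anchored timeline tibble from [anchor_substructures()].
#' @param relative_ages tibble with columns `taxon` and `relative_age` (from
#'   [node_distances()] on a substructure tree).
#' @return The anchored timeline with `relative_age` and `consistent`
#'   columns; `consistent` is FALSE for any unit involved in an order
#'   inversion between the two age scales.
#' @export
check_timeline_consistency <- function(anchored, relative_ages) {
  merged <- dplyr::inner_join(anchored,
                              dplyr::select(relative_ages, unit = "taxon",
                                            "relative_age"),
                              by = "unit")
  n <- nrow(merged)
  bad <- rep(FALSE, n)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        d1 <- merged$age_gy[a] - merged$age_gy[b]
        d2 <- merged$relative_age[a] - merged$relative_age[b]
        if (d1 * d2 < 0) bad[c(a, b)] <- TRUE
      }
    }
  }
  merged$consistent <- !bad
  merged$flags <- ifelse(bad, paste0(merged$flags, "order-conflict;"), merged$flags)
  merged
}

#' Read / write chronology tables
#'
#' Calibration TSV has columns `x`, `age_gy`; interaction TSV has columns
#' `domain_id`, `substructure`, `evidence`. Timelines are written as TSV (and
#' optionally JSON) with provenance and flags on every row.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_calibration <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_calibration
#' @export
read_interaction_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_calibration
#' @param timeline a timeline tibble.
#' @param json also write a JSON rendering next to the TSV.
#' @export
write_timeline <- function(timeline, path, json = FALSE) {
  readr::write_tsv(timeline, path)
  if (json) {
    jsonlite::write_json(timeline, sub("\\.tsv$", ".json", path),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
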