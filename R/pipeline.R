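# End-to-end orchestration: simulate -> fold-stats -> code -> searches ->
# chronology, with a reproducible run manifest.

.pipeline_stages <- c("simulate", "fold_stats", "code", "tom", "tos", "tod",
                      "timeline")

#' Run the retrodiction pipeline end-to-end
#'
#' Executes the selected stages in their canonical order on synthetic input
#' with known ground truth, writing every artifact plus a JSON manifest
#' (package version, seed, parameters, MD5 checksum of each artifact) into
#' `out_dir`. Outputs are pure functions of (config, seed): reruns produce
#' identical checksums. Each stage requires its predecessors' outputs; a
#' missing prerequisite aborts with the stage and input named.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; per-stage substreams are derived from it.
#' @param n_taxa number of simulated tRNA molecules.
#' @param stages subset of `simulate`, `fold_stats`, `code`, `tom`, `tos`,
#'   `tod`, `timeline`.
#' @param config a [sim_config()].
#' @param model an [energy_model()].
#' @param k number of character states.
#' @param force_bnb force branch-and-bound regardless of taxon count.
#' @param restarts heuristic restarts for large searches.
#' @param g1_samples topology sample size for fit statistics.
#' @param calibration optional calibration table (columns `x`, `age_gy`) or
#'   TSV path; when NULL the timeline stage calibrates against the simulated
#'   true domain ages (the synthetic demonstration mode).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(out_dir, seed, n_taxa = 8L,
                         stages = .pipeline_stages,
                         config = sim_config(), model = energy_model(),
                         k = 24L, force_bnb = FALSE, restarts = 5L,
                         g1_samples = 2000L, calibration = NULL) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  artifacts <- character(0)
  need <- function(what, from) {
    if (is.null(res[[what]])) {
      stop("stage needs '", what, "' from stage '", from,
           "': include it in `stages`", call. = FALSE)
    }
  }
  emit <- function(name) artifacts <<- c(artifacts, file.path(out_dir, name))

  search_fun <- function(m, stage_seed) {
    n_free <- nrow(m$states) - as.integer(has_ancestor(m))
    if (force_bnb || n_free <= 12) {
      branch_and_bound(m, seed = stage_seed, g1_samples = g1_samples)
    } else {
      heuristic_search(m, seed = stage_seed, restarts = restarts,
                       g1_samples = g1_samples)
    }
  }

  if ("simulate" %in% stages) {
    tree <- simulate_reference_tree(n_taxa, seed)
    fam <- evolve_trna_family(tree, config, seed + 1L)
    cen <- simulate_domain_census(tree, config, seed + 2L)
    res$simulate <- list(tree = tree, family = fam, census = cen)
    ape::write.tree(tree, file.path(out_dir, "true_tree.nwk"))
    write_fasta(setNames(fam$seqs$sequence, fam$seqs$name),
                file.path(out_dir, "family.fasta"))
    structs <- purrr::pmap(fam$seqs, function(name, sequence, structure) {
      parse_dotbracket(sequence, structure, name = name)
    })
    write_dotbracket(structs, file.path(out_dir, "family.dbn"))
    write_census(cen$census, file.path(out_dir, "census.tsv"))
    readr::write_tsv(cen$domain_ages, file.path(out_dir, "true_domain_ages.tsv"))
    readr::write_tsv(cen$interaction_map, file.path(out_dir, "interaction_map.tsv"))
    readr::write_tsv(cen$substructure_ages,
                     file.path(out_dir, "true_substructure_ages.tsv"))
    for (f in c("true_tree.nwk", "family.fasta", "family.dbn", "census.tsv",
                "true_domain_ages.tsv", "interaction_map.tsv",
                "true_substructure_ages.tsv")) emit(f)
  }

  if ("fold_stats" %in% stages) {
    need("simulate", "simulate")
    stats <- morphospace_stats(res$simulate$family$seqs, model,
                               template = config$template)
    res$fold_stats <- stats
    write_morphospace_tsv(stats, file.path(out_dir, "morphospace.tsv"))
    emit("morphospace.tsv")
  }

  if ("code" %in% stages) {
    need("fold_stats", "fold_stats")
    tom <- attach_ancestor(build_character_matrix(res$fold_stats, "ToM", k = k))
    tos <- attach_ancestor(build_character_matrix(res$fold_stats, "ToS", k = k))
    res$code <- list(tom = tom, tos = tos)
    write_nexus(tom, file.path(out_dir, "tom_matrix.nex"))
    write_nexus(tos, file.path(out_dir, "tos_matrix.nex"))
    emit("tom_matrix.nex"); emit("tos_matrix.nex")
  }

  if ("tom" %in% stages) {
    need("code", "code")
    r <- search_fun(res$code$tom, seed + 10L)
    res$tom <- r
    write_result_trees(r, file.path(out_dir, "tom.nwk"))
    jsonlite::write_json(glance(r), file.path(out_dir, "tom_fit.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    emit("tom.nwk"); emit("tom_fit.json")
  }

  if ("tos" %in% stages) {
    need("code", "code")
    r <- search_fun(res$code$tos, seed + 11L)
    res$tos <- r
    write_result_trees(r, file.path(out_dir, "tos.nwk"))
    readr::write_tsv(node_distances(r$trees[[1]]),
                     file.path(out_dir, "tos_node_distances.tsv"))
    emit("tos.nwk"); emit("tos_node_distances.tsv")
  }

  if ("tod" %in% stages) {
    need("simulate", "simulate")
    tod_m <- attach_ancestor(code_abundance(res$simulate$census$census, k = k))
    r <- search_fun(tod_m, seed + 12L)
    res$tod <- r
    write_result_trees(r, file.path(out_dir, "tod.nwk"))
    readr::write_tsv(node_distances(r$trees[[1]]),
                     file.path(out_dir, "tod_node_distances.tsv"))
    emit("tod.nwk"); emit("tod_node_distances.tsv")
  }

  if ("timeline" %in% stages) {
    need("tod", "tod")
    nd <- node_distances(res$tod$trees[[1]])
    if (is.character(calibration)) {
      if (!file.exists(calibration)) {
        stop("timeline stage: calibration file not found: ", calibration,
             call. = FALSE)
      }
      calibration <- read_calibration(calibration)
    }
    if (is.null(calibration)) {
      truth <- res$simulate$census$domain_ages
      calibration <- dplyr::inner_join(nd, truth, by = c(taxon = "unit")) |>
        dplyr::transmute(x = .data$relative_age, age_gy = .data$age_gy)
    }
    clock <- calibrate_clock(calibration)
    dom_tl <- apply_clock(clock, tibble::tibble(unit = nd$taxon,
                                                x = nd$relative_age))
    anchored <- anchor_substructures(dom_tl,
                                     res$simulate$census$interaction_map)
    if (!is.null(res$tos)) {
      anchored <- check_timeline_consistency(
        anchored, node_distances(res$tos$trees[[1]]))
    }
    res$timeline <- list(clock = clock, domains = dom_tl, anchored = anchored)
    write_timeline(dom_tl, file.path(out_dir, "domain_timeline.tsv"))
    write_timeline(anchored, file.path(out_dir, "substructure_timeline.tsv"))
    emit("domain_timeline.tsv"); emit("substructure_timeline.tsv")
  }

  manifest <- list(
    package = "rnaphylo",
    version = as.character(utils::packageVersion("rnaphylo")),
    seed = seed, n_taxa = n_taxa, stages = stages, k = k,
    model = unclass(model),
    config = list(p_sub = config$p_sub, p_comp = config$p_comp,
                  n_domains = config$n_domains, p_birth = config$p_birth,
                  growth = config$growth, sigma = config$sigma,
                  a0 = config$a0, age_origin = config$age_origin),
    artifacts = lapply(setNames(nm = basename(artifacts)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}
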