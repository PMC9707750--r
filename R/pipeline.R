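# End-to-end orchestration: community in, simulated pool, observed pool,
# contributions, overlap and contrasts out, with deterministic per-stage
# seeds derived from one global seed.

#' Run the full predation analysis pipeline
#'
#' Executes the stages in sequence: obtain a community (given table, or
#' generated from a [community_config()]), simulate feasibility-filtered
#' predation events, summarise predator/prey sizes and prey-group
#' contributions; obtain gut-content records (given table, or generated from
#' a [gut_config()]), impute observed predator sizes, summarise observed
#' contributions; compute the simulated-vs-observed size overlap and the
#' per-bin contribution contrasts. All stage seeds are derived
#' deterministically from `seed`, so a rerun with identical inputs and seed
#' is identical.
#'
#' @param community A classified `reef_community` table, or a
#'   [community_config()] to generate one.
#' @param gut_records A gut-content record `data.frame`, or a [gut_config()]
#'   to generate one.
#' @param coeffs A [trait_coefficients()] object.
#' @param sim_config A [simulation_config()].
#' @param meta_reps Imputation replicates for the metanalysis stage.
#' @param seed Global integer seed.
#' @param output_dir Optional directory; when given, stage outputs are
#'   written as CSV/JSON and listed in the manifest.
#' @return A list of class `reefpred_run` with elements `community`,
#'   `composition`, `pool`, `predator_sizes`, `prey_sizes`,
#'   `simulated_contributions`, `observed_pool`, `observed_contributions`,
#'   `overlap`, `contrasts`, and `manifest` (seeds, row counts, headline
#'   numbers).
#' @examples
#' run <- run_pipeline(community_config(n_individuals = 400),
#'                     gut_config(n_records = 40),
#'                     sim_config = simulation_config(2000, 5),
#'                     meta_reps = 20, seed = 1)
#' run$manifest$acceptance
#' @export
run_pipeline <- function(community = community_config(),
                         gut_records = gut_config(),
                         coeffs = trait_coefficients(),
                         sim_config = simulation_config(),
                         meta_reps = 1000,
                         seed = 1,
                         output_dir = NULL) {
  seeds <- c(community = derive_seed(seed, "community"),
             gut = derive_seed(seed, "gut"),
             simulate = derive_seed(seed, "simulate"),
             metanalysis = derive_seed(seed, "metanalysis"))
  if (inherits(community, "community_config")) {
    community <- generate_community(community, seed = seeds[["community"]])
  }
  if (!inherits(community, "reef_community")) {
    community <- as_reef_community(community)
  }
  if (inherits(gut_records, "gut_config")) {
    gut_records <- generate_gut_records(gut_records, seed = seeds[["gut"]])
  }
  gut_records <- validate_gut_records(gut_records)

  pool <- simulate_events(community, coeffs, sim_config,
                          seed = seeds[["simulate"]])
  if (nrow(pool$events) == 0L) {
    stop("no feasible predation events; check community and coefficients",
         call. = FALSE)
  }
  predator_sizes <- summarize_sizes(pool, "predator")
  prey_sizes <- summarize_sizes(pool, "prey")
  sim_contrib <- prey_group_contributions(pool)

  obs_pool <- draw_observed_sizes(gut_records, n_reps = meta_reps,
                                  seed = seeds[["metanalysis"]])
  obs_contrib <- observed_contributions(obs_pool, edges = sim_config$bin_edges)
  overlap <- overlap_summary(pool$events$predator_tl,
                             observed_size_distribution(obs_pool))
  contrasts <- compare_contributions(sim_contrib, obs_contrib)

  comp <- community_composition(community)
  prey_share <- prop.table(table(factor(pool$events$prey_group,
                                        levels = prey_groups())))
  manifest <- list(seed = seed, stage_seeds = as.list(seeds),
                   n_individuals = nrow(community),
                   n_species = length(unique(community$species)),
                   n_predators = comp$n_predators,
                   attempted = pool$attempted,
                   feasible_events = nrow(pool$events),
                   acceptance = pool$acceptance,
                   median_predator_tl = predator_sizes$median,
                   median_prey_tl = prey_sizes$median,
                   prey_event_share = as.list(c(prey_share)),
                   observed_events_per_rep = obs_pool$n_events_per_rep,
                   overlap_mean = overlap$mean,
                   overlap_pooled = overlap$pooled,
                   n_flagged_bins = sum(contrasts$flagged))
  out <- structure(list(community = community, composition = comp,
                        pool = pool, predator_sizes = predator_sizes,
                        prey_sizes = prey_sizes,
                        simulated_contributions = sim_contrib,
                        observed_pool = obs_pool,
                        observed_contributions = obs_contrib,
                        overlap = overlap, contrasts = contrasts,
                        manifest = manifest),
                   class = "reefpred_run")
  if (!is.null(output_dir)) {
    out$manifest$files <- write_run_outputs(out, output_dir)
  }
  out
}

write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(community = file.path(output_dir, "community.csv"),
             simulated_contributions =
               file.path(output_dir, "simulated_contributions.csv"),
             observed_contributions =
               file.path(output_dir, "observed_contributions.csv"),
             contrasts = file.path(output_dir, "contrasts.csv"),
             manifest = file.path(output_dir, "manifest.json"))
  write_community_csv(run$community, paths[["community"]])
  utils::write.csv(as.data.frame(run$simulated_contributions),
                   paths[["simulated_contributions"]], row.names = FALSE)
  utils::write.csv(as.data.frame(run$observed_contributions),
                   paths[["observed_contributions"]], row.names = FALSE)
  utils::write.csv(run$contrasts, paths[["contrasts"]], row.names = FALSE)
  manifest <- run$manifest
  manifest$overlap_per_rep <- NULL
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  as.list(paths)
}

#' @export
print.reefpred_run <- function(x, ...) {
  m <- x$manifest
  cat("Community-level predation analysis run\n")
  cat(sprintf("  community: %d individuals, %d predators\n",
              m$n_individuals, m$n_predators))
  cat(sprintf("  simulated: %d feasible of %d attempted (%.1f%%)\n",
              m$feasible_events, m$attempted, 100 * m$acceptance))
  cat(sprintf("  median predator TL %.2f cm, median prey TL %.2f cm\n",
              m$median_predator_tl, m$median_prey_tl))
  cat(sprintf("  observed events/rep: %d; size overlap %.3f (pooled %.3f)\n",
              m$observed_events_per_rep, m$overlap_mean, m$overlap_pooled))
  cat(sprintf("  bins flagged (envelopes disjoint): %d\n", m$n_flagged_bins))
  invisible(x)
}

#' Validate pipeline input CSV files
#'
#' Schema-checks the survey, community trait and gut-content CSVs before any
#' computation: required columns present, lengths and areas positive, groups
#' drawn from the known label sets, size ranges ordered. Violations are
#' reported with row numbers rather than thrown, so a single pass surfaces
#' every problem.
#'
#' @param survey_csv,community_csv,gut_csv Optional file paths; `NULL` skips
#'   a file.
#' @return A `data.frame` with columns `file`, `row`, `problem`; zero rows
#'   when everything is valid. Missing files are an error.
#' @export
validate_inputs <- function(survey_csv = NULL, community_csv = NULL,
                            gut_csv = NULL) {
  out <- list()
  note <- function(file, row, problem) {
    out[[length(out) + 1L]] <<- data.frame(file = file, row = row,
                                           problem = problem,
                                           stringsAsFactors = FALSE)
  }
  check_file <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(survey_csv)) {
    df <- check_file(survey_csv)
    need <- c("method", "reef_zone", "area", "species", "total_length", "count")
    for (col in setdiff(need, names(df))) {
      note(survey_csv, NA_integer_, paste("missing column", col))
    }
    if (all(need %in% names(df))) {
      for (r in which(df$total_length <= 0)) {
        note(survey_csv, r, "non-positive total_length")
      }
      for (r in which(df$area <= 0)) note(survey_csv, r, "non-positive area")
      for (r in which(df$count < 0)) note(survey_csv, r, "negative count")
    }
  }
  if (!is.null(community_csv)) {
    df <- check_file(community_csv)
    need <- c("species", "total_length", "prey_group", "is_predator")
    for (col in setdiff(need, names(df))) {
      note(community_csv, NA_integer_, paste("missing column", col))
    }
    if (all(need %in% names(df))) {
      for (r in which(df$total_length <= 0)) {
        note(community_csv, r, "non-positive total_length")
      }
      for (r in which(!df$prey_group %in% prey_groups())) {
        note(community_csv, r, "unknown prey_group")
      }
    }
  }
  if (!is.null(gut_csv)) {
    df <- check_file(gut_csv)
    need <- c("size_min", "size_max", "prey_group", "occurrences")
    for (col in setdiff(need, names(df))) {
      note(gut_csv, NA_integer_, paste("missing column", col))
    }
    if (all(need %in% names(df))) {
      for (r in which(df$size_min > df$size_max)) {
        note(gut_csv, r, "size_min exceeds size_max")
      }
      for (r in which(df$size_min <= 0)) {
        note(gut_csv, r, "non-positive size_min")
      }
      for (r in which(df$occurrences < 1)) {
        note(gut_csv, r, "occurrences below 1")
      }
      for (r in which(!df$prey_group %in% prey_groups())) {
        note(gut_csv, r, "unknown prey_group")
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(file = character(), row = integer(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
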