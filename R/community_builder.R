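# Survey standardisation and functional-group classification: turn raw
# multi-method survey records into one fixed-area community table in which
# every individual carries a prey group and, for piscivores, a predator group.

# Survey methods and their footprints (m^2). Clove-oil stations enclose a
# small quadrat; the value here is the conventional per-station area.
survey_methods <- function() {
  c(transect_50x5 = 250, transect_30x5_mobile = 150,
    transect_30x5_benthic = 150, transect_30x1_cryptic = 30,
    clove_oil_station = 4)
}

as_reef_community <- function(df, standardized_area = NA_real_) {
  required <- c("species", "total_length", "prey_group", "is_predator",
                "predator_group")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("community table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0L) {
    check_prey_group(df$prey_group)
    if (any(df$is_predator & is.na(df$predator_group))) {
      stop("predators must carry a predator_group", call. = FALSE)
    }
    if (any(df$is_predator)) check_predator_group(df$predator_group[df$is_predator])
  }
  rownames(df) <- NULL
  structure(df, class = c("reef_community", "data.frame"),
            standardized_area = standardized_area)
}

#' @export
print.reef_community <- function(x, ...) {
  cat(sprintf("Reef fish community: %d individuals, %d species, %d predators\n",
              nrow(x), length(unique(x$species)), sum(x$is_predator)))
  area <- attr(x, "standardized_area")
  if (!is.na(area)) cat(sprintf("  standardized area: %.0f m^2\n", area))
  NextMethod()
}

#' Standardize survey records to a common area
#'
#' Different survey methods cover very different footprints (a 50 x 5 m
#' transect vs. a clove-oil station of a few m^2), so raw counts are not
#' comparable. This resampler rescales, per reef zone x method x species x
#' length, the observed count `n` over surveyed area `a` to a target area `A`
#' per zone, preserving the expectation `n * A / a`: when `A > a` counts are
#' drawn from a Poisson with that mean; when `A < a` each surveyed individual
#' is retained independently with probability `A / a` (subsampling); the
#' deterministic mode rounds the expectation instead. Zones are standardized
#' independently and concatenated, yielding one community spanning all zones
#' with equal area in each.
#'
#' @param records Survey records: a `data.frame` with columns `method`,
#'   `reef_zone`, `site`, `area` (m^2), `species`, `total_length` (cm),
#'   `count`.
#' @param target_area_per_zone Standard area per reef zone, m^2. The default
#'   300 gives a 1,200 m^2 community over the four conventional zones.
#' @param seed Integer seed for the stochastic draws.
#' @param mode `"stochastic"` (default) or `"deterministic"` (rounded
#'   expectations, reproducible without a seed).
#' @return A `reef_community` table of individual fishes (classification
#'   columns set to placeholders; see [classify_individuals()]).
#' @export
standardize_community <- function(records, target_area_per_zone = 300,
                                  seed = NULL,
                                  mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  required <- c("method", "reef_zone", "area", "species", "total_length",
                "count")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("survey table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) > 0L && any(records$area <= 0)) {
    stop("surveyed area must be positive", call. = FALSE)
  }
  if (nrow(records) > 0L && any(records$count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  maybe_seed(seed)
  empty <- data.frame(species = character(), total_length = numeric(),
                      prey_group = character(), is_predator = logical(),
                      predator_group = character(), reef_zone = character())
  if (nrow(records) == 0L) {
    return(as_reef_community(empty, 0))
  }
  # aggregate identical zone/method/species/length cells first so the draw is
  # one per cell, then expand standardized counts back to individuals
  key <- interaction(records$reef_zone, records$method, records$species,
                     records$total_length, drop = TRUE)
  agg <- data.frame(reef_zone = tapply(records$reef_zone, key, `[`, 1L),
                    method = tapply(records$method, key, `[`, 1L),
                    species = tapply(records$species, key, `[`, 1L),
                    total_length = as.numeric(
                      tapply(records$total_length, key, `[`, 1L)),
                    count = as.integer(tapply(records$count, key, sum)),
                    area = as.numeric(tapply(records$area, key, sum)),
                    stringsAsFactors = FALSE)
  scale <- target_area_per_zone / agg$area
  expected <- agg$count * scale
  std_count <- switch(mode,
    deterministic = as.integer(round(expected)),
    stochastic = {
      n <- nrow(agg)
      out <- integer(n)
      up <- scale >= 1
      out[up] <- stats::rpois(sum(up), expected[up])
      out[!up] <- stats::rbinom(sum(!up), agg$count[!up], scale[!up])
      out
    })
  keep <- std_count > 0L
  idx <- rep(which(keep), std_count[keep])
  out <- data.frame(species = agg$species[idx],
                    total_length = agg$total_length[idx],
                    prey_group = NA_character_,
                    is_predator = NA,
                    predator_group = NA_character_,
                    reef_zone = agg$reef_zone[idx],
                    stringsAsFactors = FALSE)
  n_zones <- length(unique(records$reef_zone))
  comm <- structure(out, class = c("reef_community", "data.frame"),
                    standardized_area = target_area_per_zone * n_zones)
  rownames(comm) <- NULL
  comm
}

#' Classify community individuals into functional groups
#'
#' Annotates every individual with its prey functional group, predator status
#' and (for predators) predator functional group from a species trait map.
#' Species absent from the map are an error, never silently dropped: a
#' misclassified community would bias every downstream contribution.
#'
#' @param table A `reef_community` table (e.g. from
#'   [standardize_community()]).
#' @param trait_db `data.frame` with columns `species`, `prey_group`,
#'   `is_predator`, `predator_group` (NA for non-predators).
#' @return The annotated `reef_community`.
#' @export
classify_individuals <- function(table, trait_db) {
  required <- c("species", "prey_group", "is_predator", "predator_group")
  missing <- setdiff(required, names(trait_db))
  if (length(missing) > 0L) {
    stop("trait_db missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(table$species), trait_db$species)
  if (length(unknown) > 0L) {
    stop("species missing from trait_db: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  i <- match(table$species, trait_db$species)
  table$prey_group <- as.character(trait_db$prey_group[i])
  table$is_predator <- as.logical(trait_db$is_predator[i])
  table$predator_group <- as.character(trait_db$predator_group[i])
  table$predator_group[!table$is_predator] <- NA_character_
  as_reef_community(as.data.frame(table),
                    standardized_area = attr(table, "standardized_area"))
}

#' Community composition summaries
#'
#' @param table A non-empty classified `reef_community`.
#' @return A list with `prey_group_proportions` (over all individuals),
#'   `predator_fraction`, `n_predators`, and `predator_group_proportions`
#'   (over predators; all-zero if there are none). Each proportion vector
#'   sums to 1.
#' @export
community_composition <- function(table) {
  if (nrow(table) == 0L) stop("empty community", call. = FALSE)
  prey <- prop.table(table(factor(table$prey_group, levels = prey_groups())))
  n_pred <- sum(table$is_predator)
  pg <- if (n_pred > 0L) {
    prop.table(table(factor(table$predator_group[table$is_predator],
                            levels = predator_groups())))
  } else {
    table(factor(character(), levels = predator_groups()))
  }
  list(prey_group_proportions = c(prey),
       predator_fraction = n_pred / nrow(table),
       n_predators = n_pred,
       predator_group_proportions = c(pg))
}

#' Read and write community tables as CSV
#'
#' @param path CSV file path.
#' @param table A `reef_community`.
#' @return `read_community_csv()` returns a `reef_community`;
#'   `write_community_csv()` returns `path` invisibly.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_predator <- as.logical(df$is_predator)
  if (!"predator_group" %in% names(df)) df$predator_group <- NA_character_
  df$predator_group[df$predator_group %in% c("", "NA")] <- NA_character_
  if (!"reef_zone" %in% names(df)) df$reef_zone <- NA_character_
  as_reef_community(df)
}

#' @rdname read_community_csv
#' @export
write_community_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
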