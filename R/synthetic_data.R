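# Synthetic community and gut-content generators. These emulate the
# statistical structure the analysis assumes so every downstream stage is
# testable without field data: per-group size distributions, group
# proportions, predator fraction and predator-group split, and literature
# diet records with predator size ranges.

#' Configuration for a synthetic reef fish community
#'
#' Defaults mirror the composition of a standardised multizone reef survey:
#' prey-group proportions of roughly 59/7/34% cryptobenthic/epibenthic/social,
#' a 5.4% predator fraction, and an 85/15 grabber/engulfer split among
#' predators. Per-group sizes are drawn from truncated lognormal distributions
#' whose medians reflect each group's typical adult size (cryptobenthic fishes
#' are tiny, epibenthic mid-sized, social small schooling fishes in between);
#' predators get their own, right-skewed size distribution because piscivores
#' span gobies to groupers.
#'
#' @param n_individuals Number of fish to generate.
#' @param prey_group_proportions Length-3 simplex over
#'   (cryptobenthic, epibenthic, social).
#' @param predator_fraction Probability that an individual is a piscivore.
#' @param predator_group_proportions Length-2 simplex over
#'   (grabber, engulfer).
#' @param size_meanlog,size_sdlog Named lognormal parameters (log-cm) per prey
#'   group.
#' @param predator_meanlog,predator_sdlog Lognormal parameters for predator
#'   total length.
#' @param size_range Truncation bounds in cm for every size draw.
#' @param n_species Number of synthetic species labels per prey group.
#' @return A list of class `community_config`.
#' @seealso [generate_community()]
#' @export
community_config <- function(n_individuals = 32218,
                             prey_group_proportions = c(cryptobenthic = 0.59,
                                                        epibenthic = 0.07,
                                                        social = 0.34),
                             predator_fraction = 0.054,
                             predator_group_proportions = c(grabber = 0.85,
                                                            engulfer = 0.15),
                             size_meanlog = c(cryptobenthic = log(2),
                                              epibenthic = log(6),
                                              social = log(4)),
                             size_sdlog = c(cryptobenthic = 0.5,
                                            epibenthic = 0.6,
                                            social = 0.6),
                             predator_meanlog = log(5),
                             predator_sdlog = 0.8,
                             size_range = c(0.5, 80),
                             n_species = c(cryptobenthic = 40,
                                           epibenthic = 15,
                                           social = 25)) {
  stopifnot(n_individuals >= 0,
            predator_fraction >= 0, predator_fraction <= 1,
            length(size_range) == 2L, size_range[1] > 0,
            size_range[1] < size_range[2])
  check_simplex(prey_group_proportions, "prey_group_proportions")
  check_simplex(predator_group_proportions, "predator_group_proportions")
  stopifnot(setequal(names(prey_group_proportions), prey_groups()),
            setequal(names(predator_group_proportions), predator_groups()),
            setequal(names(size_meanlog), prey_groups()),
            setequal(names(size_sdlog), prey_groups()))
  structure(list(n_individuals = as.integer(n_individuals),
                 prey_group_proportions = prey_group_proportions[prey_groups()],
                 predator_fraction = predator_fraction,
                 predator_group_proportions =
                   predator_group_proportions[predator_groups()],
                 size_meanlog = size_meanlog[prey_groups()],
                 size_sdlog = size_sdlog[prey_groups()],
                 predator_meanlog = predator_meanlog,
                 predator_sdlog = predator_sdlog,
                 size_range = size_range,
                 n_species = n_species[prey_groups()]),
            class = "community_config")
}

# Truncated lognormal draws by rejection; truncation mass is modest for all
# default parameterisations so this terminates quickly.
rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic fish community
#'
#' Draws `n_individuals` fishes: a prey functional group (multinomial), a
#' total length from that group's truncated lognormal, a Bernoulli predator
#' flag, and for predators a predator functional group plus a length redrawn
#' from the predator size distribution. Every predator also carries a prey
#' group, because every fish in the community is potential prey.
#'
#' @param config A [community_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `data.frame` of class `reef_community` with columns `species`,
#'   `total_length`, `prey_group`, `is_predator`, `predator_group`,
#'   `reef_zone`.
#' @examples
#' comm <- generate_community(community_config(n_individuals = 500), seed = 1)
#' community_composition(comm)
#' @export
generate_community <- function(config = community_config(), seed = NULL) {
  stopifnot(inherits(config, "community_config"))
  maybe_seed(seed)
  n <- config$n_individuals
  if (n == 0L) {
    return(as_reef_community(data.frame(species = character(),
                                        total_length = numeric(),
                                        prey_group = character(),
                                        is_predator = logical(),
                                        predator_group = character(),
                                        reef_zone = character())))
  }
  grp <- sample(prey_groups(), n, replace = TRUE,
                prob = config$prey_group_proportions)
  tl <- numeric(n)
  for (g in prey_groups()) {
    idx <- which(grp == g)
    tl[idx] <- rlnorm_trunc(length(idx), config$size_meanlog[[g]],
                            config$size_sdlog[[g]],
                            config$size_range[1], config$size_range[2])
  }
  is_pred <- stats::runif(n) < config$predator_fraction
  pred_grp <- rep(NA_character_, n)
  npred <- sum(is_pred)
  if (npred > 0L) {
    pred_grp[is_pred] <- sample(predator_groups(), npred, replace = TRUE,
                                prob = config$predator_group_proportions)
    tl[is_pred] <- rlnorm_trunc(npred, config$predator_meanlog,
                                config$predator_sdlog,
                                config$size_range[1], config$size_range[2])
  }
  # species labels are plumbing: per group, sizes cluster by species index
  sp_id <- integer(n)
  for (g in prey_groups()) {
    idx <- which(grp == g)
    sp_id[idx] <- sample.int(config$n_species[[g]], length(idx), replace = TRUE)
  }
  species <- sprintf("%s_sp%02d", substr(grp, 1, 5), sp_id)
  zones <- c("back", "flat", "crest", "slope")
  as_reef_community(data.frame(species = species,
                               total_length = tl,
                               prey_group = grp,
                               is_predator = is_pred,
                               predator_group = pred_grp,
                               reef_zone = sample(zones, n, replace = TRUE),
                               stringsAsFactors = FALSE))
}

#' Configuration for synthetic gut-content records
#'
#' Emulates the schema of a diet metanalysis: per record, a study label, a
#' predator species and functional group, a predator size range (or an exact
#' size), a prey functional group, and an occurrence count. Size-range
#' midpoints are lognormal (diet studies target large piscivores, so the
#' default median is 25 cm) and range half-widths uniform.
#'
#' @param n_records Number of records.
#' @param n_studies Number of synthetic study labels.
#' @param exact_size_probability Probability a record reports an exact size
#'   (`size_min == size_max`).
#' @param midpoint_meanlog,midpoint_sdlog Lognormal parameters for the range
#'   midpoint (log-cm).
#' @param max_halfwidth Maximum half-width of a size range, cm.
#' @param prey_group_mix Length-3 simplex over prey groups for recorded prey.
#' @param occurrence_lambda Occurrence counts are `1 + Poisson(lambda)`.
#' @param pelagic_probability Probability a record is flagged pelagic (such
#'   records are excluded from analysis).
#' @return A list of class `gut_config`.
#' @seealso [generate_gut_records()]
#' @export
gut_config <- function(n_records = 150,
                       n_studies = 12,
                       exact_size_probability = 0.2,
                       midpoint_meanlog = log(25),
                       midpoint_sdlog = 0.5,
                       max_halfwidth = 10,
                       prey_group_mix = c(cryptobenthic = 0.35,
                                          epibenthic = 0.15,
                                          social = 0.5),
                       occurrence_lambda = 7,
                       pelagic_probability = 0) {
  stopifnot(n_records >= 0, n_studies >= 1,
            exact_size_probability >= 0, exact_size_probability <= 1,
            max_halfwidth >= 0, occurrence_lambda >= 0,
            pelagic_probability >= 0, pelagic_probability <= 1)
  check_simplex(prey_group_mix, "prey_group_mix")
  stopifnot(setequal(names(prey_group_mix), prey_groups()))
  structure(list(n_records = as.integer(n_records),
                 n_studies = as.integer(n_studies),
                 exact_size_probability = exact_size_probability,
                 midpoint_meanlog = midpoint_meanlog,
                 midpoint_sdlog = midpoint_sdlog,
                 max_halfwidth = max_halfwidth,
                 prey_group_mix = prey_group_mix[prey_groups()],
                 occurrence_lambda = occurrence_lambda,
                 pelagic_probability = pelagic_probability),
            class = "gut_config")
}

#' Generate synthetic gut-content records
#'
#' @param config A [gut_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `study`, `predator_species`,
#'   `predator_group`, `size_min`, `size_max`, `prey_group`, `occurrences`,
#'   `pelagic_flag`. Exact-size records have `size_min == size_max`.
#' @export
generate_gut_records <- function(config = gut_config(), seed = NULL) {
  stopifnot(inherits(config, "gut_config"))
  maybe_seed(seed)
  n <- config$n_records
  if (n == 0L) {
    return(data.frame(study = character(), predator_species = character(),
                      predator_group = character(), size_min = numeric(),
                      size_max = numeric(), prey_group = character(),
                      occurrences = integer(), pelagic_flag = logical()))
  }
  mid <- stats::rlnorm(n, config$midpoint_meanlog, config$midpoint_sdlog)
  exact <- stats::runif(n) < config$exact_size_probability
  halfw <- ifelse(exact, 0, stats::runif(n, 0, config$max_halfwidth))
  size_min <- pmax(mid - halfw, 0.5)
  size_max <- mid + halfw
  data.frame(study = sprintf("study_%02d",
                             sample.int(config$n_studies, n, replace = TRUE)),
             predator_species = sprintf("pred_sp%02d",
                                        sample.int(30, n, replace = TRUE)),
             predator_group = sample(predator_groups(), n, replace = TRUE,
                                     prob = c(0.85, 0.15)),
             size_min = size_min,
             size_max = size_max,
             prey_group = sample(prey_groups(), n, replace = TRUE,
                                 prob = config$prey_group_mix),
             occurrences = 1L + stats::rpois(n, config$occurrence_lambda),
             pelagic_flag = stats::runif(n) < config$pelagic_probability,
             stringsAsFactors = FALSE)
}
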