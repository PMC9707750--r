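# Monte-Carlo simulation of potential predation events: random
# predator-prey pairings filtered through the depth:gape feasibility window,
# then binned and summarised by predator size and prey functional group.

#' Simulation configuration
#'
#' @param events_per_rep Pairings attempted per replicate (default 10,000).
#' @param n_reps Number of replicates (default 100; with the default
#'   `events_per_rep` this gives 1,000,000 attempted pairings).
#' @param bin_edges Predator size-bin edges in cm, strictly increasing
#'   (default 5 to 50 cm at 5 cm intervals). Binning adds explicit underflow
#'   and overflow bins, see [bin_events()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(events_per_rep = 10000, n_reps = 100,
                              bin_edges = seq(5, 50, by = 5)) {
  stopifnot(events_per_rep >= 1, n_reps >= 1, length(bin_edges) >= 2)
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  structure(list(events_per_rep = as.integer(events_per_rep),
                 n_reps = as.integer(n_reps),
                 bin_edges = as.numeric(bin_edges)),
            class = "simulation_config")
}

#' Simulate potential predation events within a community
#'
#' Each attempt samples one predator uniformly from the predator individuals
#' and one prey uniformly from all individuals (every fish is potential
#' prey), with replacement across attempts. The prey's body depth and the
#' predator's gape are computed from their lengths and functional groups, and
#' the attempt is kept only when the depth:gape ratio falls inside the
#' feasible window — pairings outside it are forbidden links. Self-pairings
#' (one individual as both predator and prey) are redrawn. Replicates are
#' independent seeded batches, retained so per-bin envelopes can be reported.
#'
#' @param community A classified `reef_community` with at least one predator
#'   and at least two individuals.
#' @param coeffs A [trait_coefficients()] object.
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical inputs and seed give an identical
#'   pool.
#' @return An object of class `event_pool`: a list with `events` (a
#'   `data.frame` of feasible events: `rep`, `predator_id`, `prey_id`,
#'   `predator_tl`, `prey_tl`, `gape`, `depth`, `ratio`, `prey_group`,
#'   `predator_group`), `attempted`, `acceptance` (fraction of attempts that
#'   were feasible) and `bin_edges`.
#' @examples
#' comm <- generate_community(community_config(n_individuals = 300), seed = 1)
#' pool <- simulate_events(comm, config = simulation_config(1000, 5), seed = 2)
#' pool$acceptance
#' @export
simulate_events <- function(community, coeffs = trait_coefficients(),
                            config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(community) < 2L) {
    stop("community must contain at least two individuals", call. = FALSE)
  }
  pred_idx <- which(community$is_predator)
  attempted <- config$events_per_rep * config$n_reps
  if (length(pred_idx) == 0L) {
    warning("community contains no predators; returning an empty pool")
    return(empty_pool(attempted, config$bin_edges))
  }
  maybe_seed(seed)
  # precompute per-individual traits once; sampling then indexes into them
  depth_all <- prey_body_depth(community$total_length, community$prey_group,
                               coeffs)
  gape_pred <- predator_gape(community$total_length[pred_idx],
                             community$predator_group[pred_idx], coeffs)
  n <- nrow(community)
  reps <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    m <- config$events_per_rep
    pi <- sample.int(length(pred_idx), m, replace = TRUE)
    prey <- sample.int(n, m, replace = TRUE)
    # redraw self-pairings: a fish cannot eat itself
    self <- which(pred_idx[pi] == prey)
    while (length(self) > 0L) {
      prey[self] <- sample.int(n, length(self), replace = TRUE)
      self <- self[pred_idx[pi[self]] == prey[self]]
    }
    ratio <- depth_all[prey] / gape_pred[pi]
    keep <- ratio >= coeffs$ratio_min & ratio <= coeffs$ratio_max
    reps[[r]] <- data.frame(rep = rep.int(r, sum(keep)),
                            predator_id = pred_idx[pi[keep]],
                            prey_id = prey[keep],
                            predator_tl = community$total_length[pred_idx[pi[keep]]],
                            prey_tl = community$total_length[prey[keep]],
                            gape = gape_pred[pi[keep]],
                            depth = depth_all[prey[keep]],
                            ratio = ratio[keep],
                            prey_group = community$prey_group[prey[keep]],
                            predator_group =
                              community$predator_group[pred_idx[pi[keep]]],
                            stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, reps)
  rownames(events) <- NULL
  structure(list(events = events, attempted = attempted,
                 acceptance = nrow(events) / attempted,
                 bin_edges = config$bin_edges),
            class = "event_pool")
}

empty_pool <- function(attempted, bin_edges) {
  structure(list(events = data.frame(rep = integer(), predator_id = integer(),
                                     prey_id = integer(),
                                     predator_tl = numeric(),
                                     prey_tl = numeric(), gape = numeric(),
                                     depth = numeric(), ratio = numeric(),
                                     prey_group = character(),
                                     predator_group = character()),
                 attempted = attempted, acceptance = 0,
                 bin_edges = bin_edges),
            class = "event_pool")
}

#' @export
print.event_pool <- function(x, ...) {
  cat(sprintf(paste0("Potential predation event pool: %d feasible of %d",
                     " attempted (acceptance %.3f)\n"),
              nrow(x$events), x$attempted, x$acceptance))
  invisible(x)
}

#' Summarise predator or prey sizes over feasible events
#'
#' @param pool An `event_pool` with at least one feasible event.
#' @param role `"predator"` or `"prey"`.
#' @return A list with `median`, `mean`, `interval_low` and `interval_high`
#'   (equal-tailed central 95%, i.e. the 2.5th and 97.5th percentiles), all
#'   in cm TL.
#' @export
summarize_sizes <- function(pool, role = c("predator", "prey")) {
  role <- match.arg(role)
  if (nrow(pool$events) == 0L) stop("empty event pool", call. = FALSE)
  tl <- switch(role, predator = pool$events$predator_tl,
               prey = pool$events$prey_tl)
  q <- unname(stats::quantile(tl, c(0.025, 0.975)))
  list(median = stats::median(tl), mean = mean(tl),
       interval_low = q[1], interval_high = q[2])
}

# Shared binning: left-open/right-closed intervals with explicit underflow
# (0, first edge] and overflow (last edge, Inf) bins, so every event is
# counted. Returns a factor over all bins.
bin_factor <- function(tl, edges) {
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  breaks <- c(0, edges, Inf)
  cut(tl, breaks = breaks, right = TRUE, include.lowest = FALSE)
}

#' Bin events by predator size
#'
#' Bins are left-open/right-closed; an implicit `(0, first-edge]` underflow
#' bin and an `(last-edge, Inf)` overflow bin keep events outside the printed
#' range (simulated predators can be smaller than the first edge).
#'
#' @param pool An `event_pool`.
#' @param edges Bin edges in cm (defaults to the pool's configured edges).
#' @return Named integer vector of per-bin event counts.
#' @export
bin_events <- function(pool, edges = pool$bin_edges) {
  counts <- table(bin_factor(pool$events$predator_tl, edges))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# Core contribution arithmetic: for one set of events, the share C_{f,b} of
# each prey group f within each predator size bin b.
contribution_matrix <- function(predator_tl, prey_group, edges) {
  b <- bin_factor(predator_tl, edges)
  g <- factor(prey_group, levels = prey_groups())
  counts <- table(b, g)
  totals <- rowSums(counts)
  frac <- sweep(counts, 1, pmax(totals, 1), "/")
  frac[totals == 0, ] <- NA_real_
  list(fraction = unclass(frac), totals = as.integer(totals),
       bins = rownames(counts))
}

#' Relative prey-group contributions by predator size bin
#'
#' For each predator size bin `b`, the relative contribution of prey group
#' `f` is `C[f,b] = A[f,b] / sum_f A[f,b]`, where `A[f,b]` is the number of
#' feasible events in the bin whose prey belongs to group `f`. Computed per
#' replicate, then summarised as the across-replicate mean with a (min, max)
#' envelope. Bins with no events in a replicate contribute nothing to that
#' replicate's envelope; bins empty in every replicate are flagged
#' (`has_events = FALSE`) with NA contributions rather than NaN.
#'
#' @param pool An `event_pool` with at least one feasible event.
#' @param edges Predator size-bin edges in cm.
#' @return A `data.frame` of class `bin_contribution` with columns `bin`,
#'   `prey_group`, `mean`, `min`, `max`, `n_events` (pooled across reps) and
#'   `has_events`. Within every bin that has events, means sum to 1.
#' @export
prey_group_contributions <- function(pool, edges = pool$bin_edges) {
  if (nrow(pool$events) == 0L) stop("empty event pool", call. = FALSE)
  per_rep <- lapply(split(pool$events, pool$events$rep), function(ev) {
    contribution_matrix(ev$predator_tl, ev$prey_group, edges)
  })
  pooled <- contribution_matrix(pool$events$predator_tl,
                                pool$events$prey_group, edges)
  summarize_rep_contributions(per_rep, pooled)
}

# Assemble the long-format mean/min/max table from per-rep contribution
# matrices. Shared with the metanalysis module.
summarize_rep_contributions <- function(per_rep, pooled) {
  bins <- pooled$bins
  arr <- vapply(per_rep, function(x) x$fraction,
                matrix(0, length(bins), length(prey_groups())))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  mean_m <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  min_m <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else min(v)
  })
  max_m <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else max(v)
  })
  out <- data.frame(bin = factor(rep(bins, times = length(prey_groups())),
                                 levels = bins),
                    prey_group = rep(prey_groups(), each = length(bins)),
                    mean = as.vector(mean_m),
                    min = as.vector(min_m),
                    max = as.vector(max_m),
                    n_events = rep(pooled$totals, times = length(prey_groups())),
                    has_events = rep(pooled$totals > 0,
                                     times = length(prey_groups())),
                    stringsAsFactors = FALSE)
  class(out) <- c("bin_contribution", "data.frame")
  out
}
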