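# Internal helpers shared across modules.

#' Prey functional group labels
#'
#' The three prey functional groups, in canonical order. Cryptobenthic fishes
#' sit on or in the substratum, epibenthic fishes are solitary fishes just
#' above the benthos, and social fishes school in the water column.
#'
#' @return Character vector of length 3.
#' @export
prey_groups <- function() c("cryptobenthic", "epibenthic", "social")

#' Predator functional group labels
#'
#' The two piscivore functional groups, which differ in strike and
#' prey-processing mode: grabbers seize prey with oral jaws, engulfers draw
#' prey in whole.
#'
#' @return Character vector of length 2.
#' @export
predator_groups <- function() c("grabber", "engulfer")

# Validate a vector of prey-group labels; returns it (as character) or stops.
check_prey_group <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), prey_groups())
  if (length(bad) > 0L) {
    stop("unknown prey functional group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  group
}

check_predator_group <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), predator_groups())
  if (length(bad) > 0L) {
    stop("unknown predator functional group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  group
}

# Check that a probability vector is a simplex (sums to 1, all >= 0).
check_simplex <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop(what, " must be non-negative and sum to 1 (got sum = ", sum(p), ")",
         call. = FALSE)
  }
  invisible(p)
}

# Derive a stage seed from a global seed. Keeps results < 2^31 and distinct
# across stages; deterministic in (seed, stage).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(community = 11L, gut = 23L, standardize = 37L,
               simulate = 53L, metanalysis = 71L, compare = 89L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 101L
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

# set.seed only when a seed is supplied.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
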