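# Independent oracles for the simulation and trait maths. These deliberately
# re-derive everything from the printed coefficient values with plain loops
# and scalar arithmetic, not via the package's own code paths.

oracle_depth <- function(L, group) {
  a <- c(cryptobenthic = -1.58, epibenthic = -0.78, social = -0.9)[[group]]
  b <- c(cryptobenthic = 1.04, epibenthic = 0.74, social = 0.95)[[group]]
  exp(a + b * log(L))
}

oracle_gape <- function(L, group) {
  a <- c(grabber = 0.04, engulfer = 0.93)[[group]]
  a + 0.17 * L
}

# Exact enumeration of all predator x prey ordered pairs (self-pairs
# excluded), each pair equally likely under uniform predator and prey
# sampling with self-pair redraw. Returns one row per pair with feasibility.
oracle_enumerate <- function(community, rmin = 0.14, rmax = 0.7) {
  preds <- which(community$is_predator)
  rows <- list()
  for (i in preds) {
    g <- oracle_gape(community$total_length[i], community$predator_group[i])
    for (j in seq_len(nrow(community))) {
      if (j == i) next
      d <- oracle_depth(community$total_length[j], community$prey_group[j])
      r <- d / g
      rows[[length(rows) + 1L]] <- data.frame(
        predator_id = i, prey_id = j,
        predator_tl = community$total_length[i],
        prey_tl = community$total_length[j],
        ratio = r, feasible = (r >= rmin && r <= rmax),
        prey_group = community$prey_group[j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Weighted (uniform over feasible pairs) exact median of a column.
oracle_median <- function(x) stats::median(x)

# Exact per-bin prey-group contributions from an enumeration table,
# using the same (0, e1], (e1, e2], ... binning convention.
oracle_contributions <- function(enum, edges = seq(5, 50, by = 5)) {
  feas <- enum[enum$feasible, , drop = FALSE]
  breaks <- c(0, edges, Inf)
  b <- cut(feas$predator_tl, breaks = breaks, right = TRUE)
  groups <- c("cryptobenthic", "epibenthic", "social")
  out <- list()
  for (bin in levels(b)) {
    sub <- feas[b == bin, , drop = FALSE]
    if (nrow(sub) == 0L) next
    shares <- vapply(groups, function(g) mean(sub$prey_group == g), numeric(1))
    out[[bin]] <- shares
  }
  out
}

# A small fully-specified community for enumeration checks: mixed sizes and
# groups, several predators of both functional groups.
toy_community <- function(seed = 42, n = 40) {
  set.seed(seed)
  grp <- sample(c("cryptobenthic", "epibenthic", "social"), n, replace = TRUE,
                prob = c(0.5, 0.2, 0.3))
  tl <- round(exp(runif(n, log(1), log(30))), 2)
  is_pred <- rep(FALSE, n)
  is_pred[sample.int(n, 6)] <- TRUE
  pgrp <- rep(NA_character_, n)
  pgrp[is_pred] <- sample(c("grabber", "engulfer"), 6, replace = TRUE,
                          prob = c(0.7, 0.3))
  df <- data.frame(species = sprintf("sp%02d", seq_len(n)),
                   total_length = tl, prey_group = grp,
                   is_predator = is_pred, predator_group = pgrp,
                   reef_zone = "flat", stringsAsFactors = FALSE)
  reefpred:::as_reef_community(df)
}

# One-predator-one-prey community with chosen lengths/groups.
pair_community <- function(pred_tl, pred_group, prey_tl, prey_group) {
  reefpred:::as_reef_community(data.frame(
    species = c("pred", "prey"),
    total_length = c(pred_tl, prey_tl),
    prey_group = c("social", prey_group),
    is_predator = c(TRUE, FALSE),
    predator_group = c(pred_group, NA_character_),
    reef_zone = "flat", stringsAsFactors = FALSE))
}
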