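# Length-to-trait conversion: prey body depth, predator gape, and the
# feasibility window on the depth:gape ratio that defines forbidden links.

#' Trait conversion coefficients
#'
#' Bundles the allometric coefficients that convert total length (TL, cm) to
#' the two functional traits governing whether a predation event is
#' morphologically possible: prey body depth and predator gape. Also carries
#' the bounds of the feasible depth:gape window.
#'
#' Body depth follows a power law, fitted on log-log axes per prey functional
#' group: `ln(D) = depth_a[group] + depth_b[group] * ln(L)` (natural log).
#' Gape is linear in length per predator functional group:
#' `G = gape_a[group] + gape_b[group] * L`. A pairing is feasible when
#' `ratio_min <= D/G <= ratio_max`; defaults 0.14 and 0.7 bracket the relative
#' prey sizes within which ~95% of piscivory occurs.
#'
#' @param depth_a Named numeric intercepts (log-cm) for the three prey groups
#'   (`cryptobenthic`, `epibenthic`, `social`).
#' @param depth_b Named numeric slopes (dimensionless, all > 0) for the same
#'   groups.
#' @param gape_a Named numeric gape intercepts (cm) for `grabber` and
#'   `engulfer`.
#' @param gape_b Named numeric gape slopes (dimensionless, all > 0).
#' @param ratio_min,ratio_max Bounds of the feasible depth:gape window
#'   (dimensionless, `0 < ratio_min < ratio_max`).
#'
#' @return An object of class `trait_coefficients` (a named list).
#' @examples
#' cf <- trait_coefficients()
#' prey_body_depth(10, "cryptobenthic", cf)
#' predator_gape(10, "grabber", cf)
#' @export
trait_coefficients <- function(depth_a = c(cryptobenthic = -1.58,
                                           epibenthic = -0.78,
                                           social = -0.9),
                               depth_b = c(cryptobenthic = 1.04,
                                           epibenthic = 0.74,
                                           social = 0.95),
                               gape_a = c(grabber = 0.04, engulfer = 0.93),
                               gape_b = c(grabber = 0.17, engulfer = 0.17),
                               ratio_min = 0.14,
                               ratio_max = 0.7) {
  stopifnot(setequal(names(depth_a), prey_groups()),
            setequal(names(depth_b), prey_groups()),
            setequal(names(gape_a), predator_groups()),
            setequal(names(gape_b), predator_groups()))
  if (any(depth_b <= 0) || any(gape_b <= 0)) {
    stop("all slopes must be positive", call. = FALSE)
  }
  if (!(ratio_min > 0 && ratio_min < ratio_max)) {
    stop("need 0 < ratio_min < ratio_max", call. = FALSE)
  }
  structure(list(depth_a = depth_a[prey_groups()],
                 depth_b = depth_b[prey_groups()],
                 gape_a = gape_a[predator_groups()],
                 gape_b = gape_b[predator_groups()],
                 ratio_min = ratio_min,
                 ratio_max = ratio_max),
            class = "trait_coefficients")
}

#' @export
print.trait_coefficients <- function(x, ...) {
  cat("Trait conversion coefficients\n")
  cat("  body depth  ln(D) = a + b ln(L):\n")
  for (g in prey_groups()) {
    cat(sprintf("    %-13s a = %6.2f  b = %5.2f\n", g,
                x$depth_a[[g]], x$depth_b[[g]]))
  }
  cat("  gape        G = a + b L:\n")
  for (g in predator_groups()) {
    cat(sprintf("    %-13s a = %6.2f  b = %5.2f\n", g,
                x$gape_a[[g]], x$gape_b[[g]]))
  }
  cat(sprintf("  feasible depth:gape window: [%.2f, %.2f]\n",
              x$ratio_min, x$ratio_max))
  invisible(x)
}

#' Read or write trait coefficients as JSON
#'
#' Coefficients ship as a plain config so alternative morphometric fits can be
#' swapped in without touching code.
#'
#' @param path File path.
#' @param coeffs A [trait_coefficients()] object (for writing).
#' @return `read_trait_coefficients()` returns a `trait_coefficients` object;
#'   `write_trait_coefficients()` returns `path` invisibly.
#' @export
read_trait_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trait_coefficients(depth_a = unlist(x$depth_a), depth_b = unlist(x$depth_b),
                     gape_a = unlist(x$gape_a), gape_b = unlist(x$gape_b),
                     ratio_min = x$ratio_min, ratio_max = x$ratio_max)
}

#' @rdname read_trait_coefficients
#' @export
write_trait_coefficients <- function(coeffs, path) {
  # named vectors must become JSON objects, not bare arrays
  x <- lapply(unclass(coeffs), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Prey body depth from total length
#'
#' Converts total length to maximum body depth via the per-group power law
#' `D = exp(a + b * ln(L))`. Body depth, not length, is what must fit through
#' a predator's gape.
#'
#' @param L Total length in cm (vector, all > 0).
#' @param group Prey functional group label(s); recycled against `L`.
#' @param coeffs A [trait_coefficients()] object.
#' @return Body depth in cm (always positive, strictly increasing in `L`).
#' @examples
#' prey_body_depth(c(5, 10), "cryptobenthic")
#' @export
prey_body_depth <- function(L, group, coeffs = trait_coefficients()) {
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("total length must be positive and finite", call. = FALSE)
  }
  group <- check_prey_group(group)
  exp(coeffs$depth_a[group] + coeffs$depth_b[group] * log(L))
}

#' Total length from prey body depth (inverse conversion)
#'
#' @param depth Body depth in cm (all > 0).
#' @inheritParams prey_body_depth
#' @return Total length in cm.
#' @export
prey_length_from_depth <- function(depth, group, coeffs = trait_coefficients()) {
  if (any(!is.finite(depth)) || any(depth <= 0)) {
    stop("body depth must be positive and finite", call. = FALSE)
  }
  group <- check_prey_group(group)
  exp((log(depth) - coeffs$depth_a[group]) / coeffs$depth_b[group])
}

#' Predator gape from total length
#'
#' Gape scales linearly (untransformed) with length within each predator
#' functional group: `G = a + b * L`. Engulfers have a larger intercept than
#' grabbers at equal slope, so their gape exceeds a grabber's at every length.
#'
#' @param L Total length in cm (vector, all > 0).
#' @param group Predator functional group label(s); recycled against `L`.
#' @param coeffs A [trait_coefficients()] object.
#' @return Gape in cm (strictly increasing in `L`).
#' @examples
#' predator_gape(10, "engulfer") - predator_gape(10, "grabber")
#' @export
predator_gape <- function(L, group, coeffs = trait_coefficients()) {
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("total length must be positive and finite", call. = FALSE)
  }
  group <- check_predator_group(group)
  coeffs$gape_a[group] + coeffs$gape_b[group] * L
}

#' Relative prey size (depth:gape ratio)
#'
#' @param depth Prey body depth in cm (> 0).
#' @param gape Predator gape in cm (> 0).
#' @return Dimensionless ratio `depth / gape`.
#' @export
relative_prey_size <- function(depth, gape) {
  if (any(!is.finite(gape)) || any(gape <= 0)) {
    stop("gape must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(depth)) || any(depth <= 0)) {
    stop("body depth must be positive and finite", call. = FALSE)
  }
  depth / gape
}

#' Feasibility of a predation event
#'
#' A pairing is morphologically feasible when the prey depth to predator gape
#' ratio lies in the closed window `[ratio_min, ratio_max]`; anything outside
#' is a forbidden link.
#'
#' @param ratio Depth:gape ratio(s), > 0.
#' @param coeffs A [trait_coefficients()] object.
#' @return Logical vector.
#' @export
is_feasible <- function(ratio, coeffs = trait_coefficients()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive and finite", call. = FALSE)
  }
  ratio >= coeffs$ratio_min & ratio <= coeffs$ratio_max
}

#' Feasible prey-length window for a predator
#'
#' Solves the feasibility condition in closed form: for a predator of length
#' `L` and group `pred_group`, the prey lengths of group `prey_group` whose
#' body depth falls inside the feasible window form a contiguous interval
#' `[exp((ln(r_min G) - a)/b), exp((ln(r_max G) - a)/b)]`.
#'
#' @param L Predator total length in cm (scalar, > 0).
#' @param pred_group Predator functional group.
#' @param prey_group Prey functional group.
#' @param coeffs A [trait_coefficients()] object.
#' @return Named numeric `c(min, max)` of prey total lengths in cm.
#' @export
feasible_prey_lengths <- function(L, pred_group, prey_group,
                                  coeffs = trait_coefficients()) {
  stopifnot(length(L) == 1L)
  gape <- predator_gape(L, pred_group, coeffs)
  c(min = unname(prey_length_from_depth(coeffs$ratio_min * gape, prey_group, coeffs)),
    max = unname(prey_length_from_depth(coeffs$ratio_max * gape, prey_group, coeffs)))
}
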