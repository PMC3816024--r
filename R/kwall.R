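#' Wall correction factors from a tally
#'
#' Turns tagged cavity deposits into the chamber wall correction factors:
#' the attenuation component `k_att = <e^{+mu t} eps_P> / <eps_P>`, the
#' scatter component `k_sc = <eps_P> / <eps_P + eps_S>`, and their product
#' `k_wall = k_att * k_sc`, where `eps_P`/`eps_S` are the cavity energy
#' deposits of primary/scattered photons and `t` the wall path each primary
#' crossed before entering the cavity. Relative uncertainties come from the
#' history-by-history second moments; ratios are propagated in quadrature
#' ignoring correlations (both ratios share the primary deposit), a
#' documented approximation.
#'
#' @param acc an `irk_tally` from [simulate_chamber()] (needs at least two
#'   histories and a positive primary deposit).
#' @return A list of class `irk_wall_factors` with elements `k_att`, `k_sc`,
#'   `k_wall`, `rel_unc_att`, `rel_unc_sc`, `rel_unc_wall`, `n_histories`.
#' @export
wall_factors <- function(acc) {
  stopifnot(inherits(acc, "irk_tally"))
  if (acc$n_histories < 2) abort("need at least 2 histories")
  s <- acc$sums
  if (s[["primary"]] <= 0) {
    abort("zero primary cavity deposit: wall factors are undefined")
  }
  n <- acc$n_histories
  relvar_mean <- function(sum1, sum2) {
    m <- sum1 / n
    v <- pmax(0, sum2 / n - m^2) / n  # variance of the mean
    v / m^2
  }
  rv_p <- relvar_mean(s[["primary"]], acc$sumsq[["primary"]])
  rv_u <- relvar_mean(s[["primary_unatt"]], acc$sumsq[["primary_unatt"]])
  rv_t <- relvar_mean(s[["primary"]] + s[["scatter"]], acc$sumsq[["total"]])
  k_att <- s[["primary_unatt"]] / s[["primary"]]
  k_sc <- s[["primary"]] / (s[["primary"]] + s[["scatter"]])
  ru_att <- sqrt(rv_u + rv_p)
  ru_sc <- sqrt(rv_p + rv_t)
  structure(
    list(k_att = k_att, k_sc = k_sc, k_wall = k_att * k_sc,
         rel_unc_att = ru_att, rel_unc_sc = ru_sc,
         rel_unc_wall = sqrt(ru_att^2 + ru_sc^2),
         n_histories = n, chamber = acc$chamber %||% NA_character_,
         source = acc$source %||% NA_character_),
    class = "irk_wall_factors")
}

#' @export
print.irk_wall_factors <- function(x, ...) {
  cat(sprintf(
    "<irk_wall_factors> %s (%s)\n  k_sc   %.4f (%.3g%%)\n  k_att  %.4f (%.3g%%)\n  k_wall %.4f (%.3g%%)\n  %s histories\n",
    x$chamber, x$source, x$k_sc, 100 * x$rel_unc_sc, x$k_att,
    100 * x$rel_unc_att, x$k_wall, 100 * x$rel_unc_wall,
    format(x$n_histories, big.mark = ",")))
  invisible(x)
}

#' @method tidy irk_wall_factors
#' @export
tidy.irk_wall_factors <- function(x, ...) {
  tibble(term = c("k_sc", "k_att", "k_wall"),
         estimate = c(x$k_sc, x$k_att, x$k_wall),
         rel_uncertainty = c(x$rel_unc_sc, x$rel_unc_att, x$rel_unc_wall))
}

#' @method glance irk_wall_factors
#' @export
glance.irk_wall_factors <- function(x, ...) {
  tibble(chamber = x$chamber, source = x$source, k_sc = x$k_sc,
         k_att = x$k_att, k_wall = x$k_wall,
         rel_unc_sc = x$rel_unc_sc, rel_unc_att = x$rel_unc_att,
         rel_unc_wall = x$rel_unc_wall, n_histories = x$n_histories)
}

#' Wall factors as a function of incident photon energy
#'
#' Runs one monoenergetic chamber simulation per energy (same configuration
#' and seed for every energy: common random numbers sharpen the energy
#' dependence) and tabulates the wall correction factors.
#'
#' @param chamber an [chamber_spec()].
#' @param energies monoenergetic photon energies, MeV.
#' @param config an [run_config()].
#' @return A tibble of class `irk_kwall_scan` with one row per energy.
#' @export
energy_scan <- function(chamber, energies, config = run_config()) {
  stopifnot(length(energies) >= 1)
  rows <- lapply(energies, function(e) {
    glance(wall_factors(simulate_chamber(chamber, e, config)))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, energy = as.numeric(energies), .before = 1)
  class(out) <- c("irk_kwall_scan", class(out))
  out
}

#' Compare wall factors across chamber geometries
#'
#' Runs the same source through each chamber and tabulates the factors; when
#' reference `k_wall` values from the owning laboratories are supplied the
#' percent difference is reported relative to the external value,
#' `100 * (ours - reference) / reference`.
#'
#' @param chambers a list of [chamber_spec()] objects (named or using the
#'   specs' own names).
#' @param source an `irk_spectrum` or monoenergetic energy (MeV).
#' @param config an [run_config()].
#' @param reference optional named numeric vector of external `k_wall`
#'   values, named like the chambers.
#' @return A tibble with one row per chamber.
#' @export
chamber_comparison <- function(chambers, source, config = run_config(),
                               reference = NULL) {
  if (inherits(chambers, "irk_chamber")) chambers <- list(chambers)
  stopifnot(length(chambers) >= 1)
  nms <- names(chambers) %||% vapply(chambers, `[[`, "", "name")
  if (is.null(names(chambers))) names(chambers) <- nms
  rows <- lapply(names(chambers), function(nm) {
    g <- glance(wall_factors(simulate_chamber(chambers[[nm]], source, config)))
    g$chamber <- nm
    g
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(reference)) {
    ref <- unname(reference[out$chamber])
    out$reference_k_wall <- ref
    out$percent_difference <- 100 * (out$k_wall - ref) / ref
  }
  out
}
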