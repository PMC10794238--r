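## Decoy-ensemble selection-fitness measures: thermodynamic stability,
## kinetic accessibility (funnel Z-score), ground-state check, rank sums.

#' Construct a decoy ensemble
#'
#' Native energy of one conformation plus the energies of its folding or
#' binding decoys under an energy model.
#'
#' @param native_energy Energy of the native conformation (MJ units).
#' @param decoy_energies Numeric vector of decoy energies (finite, native
#'   not included; at least 2 for the variance-based measures).
#' @param kind `"folding"` or `"binding"`.
#' @param kT Temperature factor \eqn{K_B T} in MJ units (default 1).
#' @param entropy Conformational entropy S; default \eqn{\ln} (number of
#'   decoys).
#' @return Object of class `decoy_ensemble`.
#' @export
decoy_ensemble <- function(native_energy, decoy_energies,
                           kind = c("folding", "binding"), kT = 1,
                           entropy = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(decoy_energies) >= 1L,
            all(is.finite(decoy_energies)), is.finite(native_energy),
            kT > 0)
  structure(list(native = native_energy,
                 decoys = as.numeric(decoy_energies),
                 kind = kind, kT = kT,
                 S = entropy %||% log(length(decoy_energies))),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat(sprintf("<decoy_ensemble> %s: native %.3f, %d decoys in [%.3f, %.3f]\n",
              x$kind, x$native, length(x$decoys), min(x$decoys),
              max(x$decoys)))
  invisible(x)
}

#' Thermodynamic stability of a decoy ensemble
#'
#' \deqn{\Delta G = -K_B T \ln(P_N / P_D)} with
#' \eqn{P_N = e^{-E_N/K_BT}} and \eqn{P_D = \sum_d e^{-E_d/K_BT}}
#' (native excluded from the denominator). Evaluated via log-sum-exp, so
#' the result is finite whenever the energies are. More negative is more
#' stable.
#'
#' @param ens A `decoy_ensemble`.
#' @return \eqn{\Delta G} in MJ units.
#' @export
stability <- function(ens) {
  stopifnot(inherits(ens, "decoy_ensemble"))
  kT <- ens$kT
  ens$native + kT * logsumexp(-ens$decoys / kT)
}

#' Kinetic accessibility (funnel Z-score)
#'
#' \deqn{\Lambda = \sqrt{\frac{K_B}{2S}} \frac{\delta E}{\Delta E}} with
#' energy gap \eqn{\delta E = \langle E_d \rangle - E_N}, decoy-energy
#' spread \eqn{\Delta E} (population standard deviation), conformational
#' entropy \eqn{S = \ln}(number of decoys) and \eqn{K_B = 1} in MJ units.
#' Larger \eqn{\Lambda} means a more funneled landscape.
#'
#' @param ens A `decoy_ensemble`.
#' @return \eqn{\Lambda} (dimensionless).
#' @export
accessibility <- function(ens) {
  stopifnot(inherits(ens, "decoy_ensemble"))
  if (length(ens$decoys) < 2L)
    stop("degenerate-ensemble error: need at least 2 decoys")
  dE <- sd_pop(ens$decoys)
  if (dE == 0) stop("degenerate-ensemble error: zero decoy-energy variance")
  if (ens$S <= 0) stop("conformational entropy must be positive")
  sqrt(1 / (2 * ens$S)) * (mean(ens$decoys) - ens$native) / dE
}

#' Unique-ground-state check
#'
#' `TRUE` iff the native energy is strictly below every decoy energy.
#'
#' @param ens A `decoy_ensemble`.
#' @return Logical.
#' @export
ground_state_check <- function(ens) {
  stopifnot(inherits(ens, "decoy_ensemble"))
  ens$native < min(ens$decoys)
}

#' Combined fitness ranks of a population
#'
#' Per component, rank 1 is best (most negative \eqn{\Delta G}; largest
#' \eqn{\Lambda}); the combined score is the sum of the component ranks
#' (folding only, or folding plus binding). Ties break by input order.
#'
#' @param reports Data frame with columns `dG_f`, `L_f` and (for
#'   `"folding+binding"`) `dG_b`, `L_b`; one row per sequence.
#' @param mode `"folding"` or `"folding+binding"`.
#' @return List with `component_ranks` (matrix), `combined` (rank-sum per
#'   sequence) and `order` (sequence indices from best to worst combined
#'   rank, ties by input order).
#' @export
fitness_ranks <- function(reports, mode = c("folding", "folding+binding")) {
  mode <- match.arg(mode)
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0L) stop("empty population")
  comp <- c("dG_f", "L_f")
  if (mode == "folding+binding") comp <- c(comp, "dG_b", "L_b")
  if (!all(comp %in% names(reports)))
    stop("missing fitness components: ",
         paste(setdiff(comp, names(reports)), collapse = ", "))
  rk <- sapply(comp, function(cn) {
    x <- reports[[cn]]
    if (startsWith(cn, "L")) x <- -x      # larger Lambda is better
    rank(x, ties.method = "first")
  })
  rk <- matrix(rk, nrow = nrow(reports),
               dimnames = list(NULL, comp))
  combined <- rowSums(rk)
  list(component_ranks = rk, combined = combined,
       order = order(combined))
}
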