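# Post-survey weighting: poststratification, nonresponse and multi-phone
# adjustments, and the Kish design-effect diagnostics they feed.

#' Assemble a per-respondent weight set
#'
#' A weight set carries each respondent's weight factors — base,
#' poststratification, nonresponse factor R and multi-phone factor A — and
#' their product `w`, normalised to mean 1 (a cosmetic convention: every
#' reported diagnostic is invariant to rescaling all weights by a positive
#' constant).
#'
#' @param stratum Character stratum key per respondent.
#' @param respondent_id Optional integer ids.
#' @param base,poststrat,R,A Weight factors (recycled; default 1).
#' @param normalize Rescale the final weights to mean 1?
#' @return A `data.frame` of class `mps_weights` with columns
#'   `respondent_id`, `stratum`, `base`, `poststrat`, `R`, `A`, `w`.
#' @seealso [cv_weights()], [kish_deff()], [effective_n()],
#'   [summary.mps_weights()]
#' @export
weight_set <- function(stratum, respondent_id = seq_along(stratum),
                       base = 1, poststrat = 1, R = 1, A = 1,
                       normalize = TRUE) {
  n <- length(stratum)
  if (n == 0) stop("empty sample")
  out <- data.frame(respondent_id = respondent_id,
                    stratum = as.character(stratum),
                    base = rep_len(base, n), poststrat = rep_len(poststrat, n),
                    R = rep_len(R, n), A = rep_len(A, n),
                    stringsAsFactors = FALSE)
  out$w <- out$base * out$poststrat * out$R * out$A
  if (any(!is.finite(out$w)) || any(out$w <= 0))
    stop("all weights must be positive and finite")
  if (normalize) out$w <- out$w / mean(out$w)
  class(out) <- c("mps_weights", "data.frame")
  out
}

get_w <- function(weights) {
  w <- if (inherits(weights, "mps_weights") || is.data.frame(weights))
    weights$w else weights
  if (length(w) == 0) stop("empty weight vector")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all weights must be positive and finite")
  w
}

#' Poststratification weights against a reference distribution
#'
#' Assigns each respondent in stratum h the weight
#' `w_h = reference proportion_h / sample proportion_h`, so that the
#' weighted strata shares reproduce the census/DHS reference exactly. When
#' the sample already matches the reference — the AASM quota engine's whole
#' purpose — all weights are 1 (up to quota rounding) and poststratification
#' costs nothing in precision.
#'
#' @param stratum Character stratum key per respondent.
#' @param reference A [reference_distribution()] or data.frame with
#'   `stratum` and `proportion` columns.
#' @return Numeric weight per respondent.
#' @examples
#' ref <- data.frame(stratum = c("A", "B"), proportion = c(0.6, 0.4))
#' poststrat_weights(rep(c("A", "B"), each = 50), ref) # 1.2 then 0.8
#' @export
poststrat_weights <- function(stratum, reference) {
  if (length(stratum) == 0) stop("empty sample")
  stopifnot(all(c("stratum", "proportion") %in% names(reference)))
  pos <- match(stratum, reference$stratum)
  if (anyNA(pos))
    stop("sampled stratum absent from reference: ",
         paste(unique(stratum[is.na(pos)]), collapse = ", "))
  if (any(reference$proportion[unique(pos)] <= 0))
    stop("sampled stratum has zero reference proportion")
  samp_prop <- as.numeric(table(factor(stratum,
                                       levels = reference$stratum))) /
    length(stratum)
  reference$proportion[pos] / samp_prop[pos]
}

#' Nonresponse weighting factor R = 1 / (1 - f)
#'
#' Respondents in a group with nonresponse rate f stand in for the group's
#' nonrespondents as well, so their weight is multiplied by the inverse of
#' the group's response rate.
#'
#' @param f Nonresponse rate(s) in `[0, 1)`.
#' @return `1 / (1 - f)`.
#' @examples
#' nonresponse_factor(c(0, 0.5, 0.9)) # 1 2 10
#' @export
nonresponse_factor <- function(f) {
  if (any(f < 0) || any(f >= 1))
    stop("nonresponse rate f must be in [0, 1); f = 1 means no respondents")
  1 / (1 - f)
}

#' Apply the nonresponse adjustment to a weight set
#'
#' @param weights An [weight_set()].
#' @param table A nonresponse table: data.frame with `group` (stratum key)
#'   and `f` columns, e.g. from [nonresponse_table()].
#' @return The weight set with `R` replaced and `w` recomputed.
#' @export
adjust_nonresponse <- function(weights, table) {
  stopifnot(inherits(weights, "mps_weights"),
            all(c("group", "f") %in% names(table)))
  pos <- match(weights$stratum, table$group)
  if (anyNA(pos))
    stop("respondent group missing from nonresponse table: ",
         paste(unique(weights$stratum[is.na(pos)]), collapse = ", "))
  weight_set(weights$stratum, weights$respondent_id, base = weights$base,
             poststrat = weights$poststrat,
             R = nonresponse_factor(table$f[pos]), A = weights$A)
}

#' Apply the multiple-phone adjustment A = 1 / T
#'
#' A person owning T phones is T times as likely to be reached by random
#' digit dialling; multiplying their weight by `A = 1/T` restores equal
#' effective contribution per person.
#'
#' @param weights An [weight_set()].
#' @param T Integer phone counts per respondent (all `>= 1`).
#' @return The weight set with `A` replaced and `w` recomputed.
#' @export
adjust_multiphone <- function(weights, T) {
  stopifnot(inherits(weights, "mps_weights"))
  T <- rep_len(T, nrow(weights))
  if (any(T < 1)) stop("phone counts T must be >= 1 for every respondent")
  weight_set(weights$stratum, weights$respondent_id, base = weights$base,
             poststrat = weights$poststrat, R = weights$R, A = 1 / T)
}

#' Coefficient of variation of the weights
#'
#' `CV = sd(w) / mean(w)` using the divide-by-n (population) standard
#' deviation, the convention under which the Kish identity
#' `1 + CV^2 = n * sum(w^2) / sum(w)^2` is exact. Scale-invariant.
#'
#' @param weights A positive numeric vector or [weight_set()].
#' @return The CV.
#' @examples
#' cv_weights(c(1, 3)) # 0.5
#' @export
cv_weights <- function(weights) {
  w <- get_w(weights)
  m <- mean(w)
  sqrt(mean((w - m)^2)) / m
}

#' Kish design effect of weighting
#'
#' The variance of a weighted estimate is inflated relative to simple
#' random sampling by `deff = 1 + CV^2` of the weights, equivalently
#' `n * sum(w^2) / sum(w)^2`. Always `>= 1`.
#'
#' @inheritParams cv_weights
#' @return The design effect.
#' @examples
#' kish_deff(c(1, 1, 1, 3)) # 4/3
#' @export
kish_deff <- function(weights) {
  1 + cv_weights(weights)^2
}

#' Effective sample size under weighting
#'
#' `n / deff`: the simple-random-sample size with the same precision as the
#' weighted sample of nominal size n.
#'
#' @inheritParams cv_weights
#' @return Effective sample size (`<= n`).
#' @export
effective_n <- function(weights) {
  w <- get_w(weights)
  length(w) / kish_deff(w)
}

#' Individual selection probability in an RDD survey
#'
#' The probability that a given person is selected when `n` numbers are
#' sampled from `total_phones` phones and the person owns
#' `phones_per_person` of them: `n * phones_per_person / total_phones`.
#' Owning more phones raises selection probability proportionally, though
#' in a national number space the absolute probability stays minute.
#'
#' @param n Targeted sample size.
#' @param phones_per_person Phones owned by the person (`>= 1`).
#' @param total_phones Total phones in the population (`> 0`).
#' @return The selection probability.
#' @examples
#' selection_probability(1, 3, 120e6) # 2.5e-08
#' @export
selection_probability <- function(n, phones_per_person, total_phones) {
  if (any(total_phones <= 0)) stop("total_phones must be positive")
  if (any(phones_per_person < 1)) stop("phones_per_person must be >= 1")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(phones_per_person > total_phones))
    stop("a person cannot own more phones than exist")
  n * phones_per_person / total_phones
}

#' Relative probability of inclusion between two owners
#'
#' For two people in the same number space, the ratio of selection
#' probabilities reduces to the ratio of their phone counts.
#'
#' @param phones_1,phones_2 Phone counts of the two people.
#' @return `phones_1 / phones_2`.
#' @examples
#' relative_probability(3, 1) # 3
#' @export
relative_probability <- function(phones_1, phones_2) {
  if (any(phones_1 < 1) || any(phones_2 < 1))
    stop("phone counts must be >= 1")
  phones_1 / phones_2
}

#' Trim extreme weights
#'
#' Clips weights to `[lower, upper]` and rescales the clipped vector to
#' preserve the original weight total. Trimming reduces the CV of the
#' weights (and hence the design effect) at the price of a possible bias in
#' the weighted estimate — a trade, not a free lunch.
#'
#' @param weights A positive numeric vector or [weight_set()].
#' @param lower,upper Clipping bounds, `0 < lower <= upper`.
#' @return A numeric vector of trimmed, rescaled weights.
#' @examples
#' trim_weights(c(1, 1, 10), upper = 2) # 3 3 6
#' @export
trim_weights <- function(weights, lower = 0, upper = Inf) {
  w <- get_w(weights)
  if (lower < 0 || lower > upper) stop("need 0 <= lower <= upper")
  clipped <- pmin(pmax(w, lower), upper)
  clipped * sum(w) / sum(clipped)
}

#' Weighted estimate with Kish variance inflation
#'
#' The weighted mean `sum(w * y) / sum(w)` with its variance approximated
#' as the unweighted sampling variance inflated by the Kish design effect:
#' `var = (var(y) / n) * deff`. This is Kish's approximation, reported as
#' such; it is exact only under the haphazard-weights model.
#'
#' @param y Numeric outcomes, one per respondent.
#' @param weights A positive numeric vector or [weight_set()] of matching
#'   length.
#' @return A list with `estimate`, `variance`, `se`, `deff`, `n`,
#'   `effective_n`.
#' @export
weighted_estimate <- function(y, weights) {
  w <- get_w(weights)
  if (length(y) != length(w)) stop("y and weights differ in length")
  n <- length(y)
  est <- sum(w * y) / sum(w)
  deff <- kish_deff(w)
  v <- if (n > 1) stats::var(y) / n * deff else NA_real_
  list(estimate = est, variance = v, se = sqrt(v), deff = deff,
       n = n, effective_n = n / deff)
}

#' Summarise a weight set
#'
#' @param object An [weight_set()].
#' @param ... Unused.
#' @return A list of class `summary.mps_weights`: n, CV/deff/effective n of
#'   the final weights and of the poststratification factor alone, and the
#'   weight range.
#' @export
summary.mps_weights <- function(object, ...) {
  w <- object$w
  out <- list(
    n = nrow(object),
    cv = cv_weights(w), deff = kish_deff(w), effective_n = effective_n(w),
    cv_poststrat = cv_weights(object$poststrat),
    deff_poststrat = kish_deff(object$poststrat),
    min_w = min(w), max_w = max(w))
  class(out) <- "summary.mps_weights"
  out
}

#' @export
print.summary.mps_weights <- function(x, ...) {
  cat(sprintf("Weights: n = %d, CV = %.4f, deff = %.4f, effective n = %.1f\n",
              x$n, x$cv, x$deff, x$effective_n))
  cat(sprintf("  poststratification factor alone: CV = %.4f, deff = %.4f\n",
              x$cv_poststrat, x$deff_poststrat))
  cat(sprintf("  weight range: [%.4f, %.4f]\n", x$min_w, x$max_w))
  invisible(x)
}

#' Full weighting stack for a finished survey run
#'
#' Composes the three adjustments multiplicatively for each completed
#' interview of a run: poststratification against `reference`, the
#' nonresponse factor `R = 1/(1-f)` from the run's own per-stratum
#' nonresponse rates, and the multi-phone factor `A = 1/T`.
#'
#' @param run An `mps_run`.
#' @param reference Reference distribution to calibrate to; defaults to the
#'   one the run's quota was built from.
#' @return An [weight_set()].
#' @export
run_weights <- function(run, reference = run$reference) {
  rs <- run$respondents
  if (nrow(rs) == 0) stop("run has no completed interviews")
  ps <- poststrat_weights(rs$stratum, reference)
  nr <- nonresponse_table(run)
  pos <- match(rs$stratum, nr$group)
  R <- nonresponse_factor(nr$f[pos])
  weight_set(rs$stratum, rs$respondent_id, poststrat = ps, R = R,
             A = 1 / rs$n_phones)
}

#' Export a weight set as CSV / diagnostics as JSON
#'
#' @param weights An [weight_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(as.data.frame(weights), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
write_weight_diagnostics <- function(weights, path) {
  s <- summary(weights)
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
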