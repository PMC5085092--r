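# Tunable parameter sets for alignment, filtering and pairing.

#' Scoring parameters for read-to-graph alignment and genotype likelihoods
#'
#' The match/mismatch model is base-quality aware: a read base with error
#' probability `eps` (from its Phred quality, floored at `eps_floor` and
#' capped at `eps_ceiling`) scores `log(1 - eps)` on a match and
#' `log(eps / 3)` on a mismatch. 'N' graph edges match any base with the
#' match score; '-' graph edges are traversed for free (they encode known
#' deletion alleles, not alignment errors). All penalties are natural-log
#' units.
#'
#' @param gap_open log-penalty for opening a read gap (insertion or deletion).
#' @param gap_extend log-penalty for extending a read gap.
#' @param clip per-base log-penalty for soft-clipped read bases; set to `-Inf`
#'   semantics via any value below `-1e8` to disable clipping.
#' @param improper_pair log-penalty replacing the insert-size term for pairs
#'   on the same strand or with non-positive implied insert size.
#' @param score_drop extension termination: DP cells more than this far below
#'   the running per-boundary maximum are pruned (`Inf` disables, as required
#'   when comparing against the brute-force oracle).
#' @param eps_floor,eps_ceiling bounds on Phred-derived error probabilities.
#' @param min_seed minimum seed length in bases; `NULL` means the index k.
#' @param max_windows maximum number of candidate extension windows per read
#'   and strand.
#' @param window_margin extra levels added on both sides of the seed-implied
#'   window.
#' @return a list of class `prg_scoring_params`.
#' @export
scoring_params <- function(gap_open = -4.605, gap_extend = -2.303,
                           clip = -1.386, improper_pair = -13.8,
                           score_drop = 25, eps_floor = 1e-4,
                           eps_ceiling = 0.75, min_seed = NULL,
                           max_windows = 8L, window_margin = 24L) {
  stopifnot(gap_open <= 0, gap_extend <= 0, clip <= 0, improper_pair <= 0,
            score_drop >= 0, eps_floor > 0, eps_ceiling < 1)
  structure(list(gap_open = gap_open, gap_extend = gap_extend, clip = clip,
                 improper_pair = improper_pair, score_drop = score_drop,
                 eps_floor = eps_floor, eps_ceiling = eps_ceiling,
                 min_seed = min_seed, max_windows = as.integer(max_windows),
                 window_margin = as.integer(window_margin)),
            class = "prg_scoring_params")
}

#' Read-pair filter thresholds
#'
#' A pair is kept iff (a) the fraction of its pooled k-mers present in the
#' graph index strictly exceeds `positive_fraction`, and (b) at least one mate
#' has a k-mer unique to the PRG (present in the graph, absent from the
#' background), or at least one mate has a background k-mer fraction strictly
#' below `background_fraction`.
#'
#' @param positive_fraction positive-selection threshold (default 0.30).
#' @param background_fraction negative-selection threshold (default 0.45).
#' @param require_unique if `FALSE`, clause (b) is skipped entirely and pairs
#'   are kept on positive selection alone.
#' @param mask_below_q optional Phred floor: read bases below this quality are
#'   masked to 'N' before k-mer extraction (default off).
#' @return a list of class `prg_filter_thresholds`.
#' @export
filter_thresholds <- function(positive_fraction = 0.30,
                              background_fraction = 0.45,
                              require_unique = TRUE,
                              mask_below_q = NULL) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1,
            background_fraction >= 0, background_fraction <= 1)
  structure(list(positive_fraction = positive_fraction,
                 background_fraction = background_fraction,
                 require_unique = isTRUE(require_unique),
                 mask_below_q = mask_below_q),
            class = "prg_filter_thresholds")
}

#' Normal insert-size model (in graph levels)
#'
#' The implied insert size of a proper pair is the number of levels between
#' the outermost aligned levels of the two mates; its log-density under a
#' normal model enters the paired-alignment likelihood.
#'
#' @param mean,sd normal parameters in levels (`sd > 0`).
#' @return a list of class `prg_insert_model` with a `log_density` function.
#' @export
insert_size_model <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(list(mean = mean, sd = sd,
                 log_density = function(x) dnorm(x, mean, sd, log = TRUE)),
            class = "prg_insert_model")
}

#' Estimate an insert-size model from proper pairs by median/MAD
#' @param inserts numeric vector of observed implied insert sizes.
#' @return a `prg_insert_model`.
#' @export
estimate_insert_model <- function(inserts) {
  inserts <- inserts[is.finite(inserts) & inserts > 0]
  if (length(inserts) < 10L)
    stop("too few proper pairs (", length(inserts),
         ") to estimate an insert-size model")
  insert_size_model(median(inserts), max(mad(inserts), 1))
}
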