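# Detection power for a variant at true plasma VAF f sequenced to depth D
# under the plasma filter rules. Alt reads (true variant molecules plus
# sequencing errors toward the alt allele, which are indistinguishable) are
# Binomial(D, p) with p = f + (1 - f) * e; a draw of k alt reads is called
# when k >= max(min_alt_reads, ceil(min_vaf_plasma * D)) and, when the
# strand rule is on, both strands carry >= 1 read (strands are independent
# fair coin flips per alt read, so that survives with prob 1 - 2 * 0.5^k).

.kmin_for <- function(depth, cfg) {
  # inclusive >= semantics: when min_vaf_plasma * depth is an exact integer
  # that count passes; guard the ceiling against floating-point fuzz
  k_vaf <- as.integer(ceiling(cfg$min_vaf_plasma * depth - 1e-9))
  max(cfg$min_alt_reads, k_vaf, 0L)
}

#' Analytic probability of detecting a variant in plasma
#'
#' Closed-form detection probability under the plasma filter rules for a
#' variant at true allele fraction `true_vaf` sequenced to fixed depth
#' `depth`, with per-read substitution errors toward the alt allele at rate
#' `error_rate`. The depth rule (`min_depth_case`), the alt-read support
#' rule, the plasma VAF threshold and (optionally) the both-strands rule
#' are all accounted for; the matched normal is assumed clean.
#'
#' The tail sums are evaluated exactly via binomial CDFs: with
#' `p = f + (1 - f) e` and threshold `k_min`,
#' `power = P(K >= k_min) - 2 (1 - p/2)^D P(K' >= k_min)` when the strand
#' rule is on, where `K' ~ Binomial(D, (p/2) / (1 - p/2))` absorbs the
#' `0.5^k` strand-survival deficit.
#'
#' @param depth sequencing depth (reads) at the site.
#' @param true_vaf true tumor-derived allele fraction in \[0, 1\].
#' @param error_rate per-read substitution probability toward the alt
#'   allele.
#' @param cfg a [filter_config()].
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_probability(561, 0.037)
#' detection_probability(309, 0.0002)   # the deep-remission regime
#' @export
detection_probability <- function(depth, true_vaf, error_rate = 0,
                                  cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (anyNA(c(depth, true_vaf, error_rate)) || depth < 0 ||
      true_vaf < 0 || true_vaf > 1 || error_rate < 0 || error_rate >= 1)
    stop("detection_probability: invalid query", call. = FALSE)
  depth <- as.integer(depth)
  if (depth < cfg$min_depth_case) return(0)   # depth rule can never pass
  p <- true_vaf + (1 - true_vaf) * error_rate
  kmin <- .kmin_for(depth, cfg)
  if (kmin > depth) return(0)
  if (!cfg$require_both_strands_plasma) {
    if (kmin == 0L) return(1)
    return(pbinom(kmin - 1L, depth, p, lower.tail = FALSE))
  }
  kmin <- max(kmin, 1L)     # zero alt reads can never satisfy both strands
  tail_p <- pbinom(kmin - 1L, depth, p, lower.tail = FALSE)
  # sum_{k >= kmin} C(D,k) p^k q^(D-k) 0.5^k, via a tilted binomial
  p2 <- (p / 2) / (1 - p / 2)
  tilt <- (1 - p / 2)^depth *
    pbinom(kmin - 1L, depth, p2, lower.tail = FALSE)
  max(0, tail_p - 2 * tilt)
}

#' Monte-Carlo probability of detecting a variant in plasma
#'
#' Simulates read draws (alt count binomial in depth, strand split binomial
#' fair) and pushes every replicate through the same plasma rule engine
#' used by [classify_variant()], with a clean high-depth matched normal.
#' Serves as the simulation cross-check of [detection_probability()].
#'
#' @inheritParams detection_probability
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return List with `estimate`, binomial `se` and `n_reps`.
#' @export
detection_probability_mc <- function(depth, true_vaf, error_rate = 0,
                                     cfg = filter_config(),
                                     n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(cfg, "filter_config"), n_reps >= 1L)
  if (anyNA(c(depth, true_vaf, error_rate)) || depth < 0 ||
      true_vaf < 0 || true_vaf > 1 || error_rate < 0 || error_rate >= 1)
    stop("detection_probability_mc: invalid query", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  depth <- as.integer(depth)
  p <- true_vaf + (1 - true_vaf) * error_rate
  alt <- rbinom(n_reps, depth, p)
  fwd <- rbinom(n_reps, alt, 0.5)
  normal_depth <- max(cfg$min_depth_normal, 100L)
  called <- .eval_rules("plasma",
                        depth = rep(depth, n_reps), alt = alt,
                        alt_fwd = fwd, alt_rev = alt - fwd,
                        normal_depth = rep(normal_depth, n_reps),
                        normal_alt = rep(0L, n_reps),
                        in_dbsnp = rep(FALSE, n_reps),
                        in_cosmic = rep(FALSE, n_reps),
                        cfg = cfg)$called
  est <- mean(called)
  list(estimate = est, se = sqrt(est * (1 - est) / n_reps), n_reps = n_reps)
}

#' Smallest depth achieving a target detection power
#'
#' Finds, by doubling then bisection (power is monotone nondecreasing in
#' depth up to threshold-granularity effects, which a final local scan
#' absorbs), the smallest sequencing depth at which
#' [detection_probability()] reaches `target_power`.
#'
#' @param true_vaf true allele fraction (> `error_rate`).
#' @param target_power required detection probability in (0, 1).
#' @param cfg a [filter_config()].
#' @param error_rate per-read substitution rate toward the alt allele.
#' @param depth_cap give up beyond this depth (default 1e7) with an error:
#'   at very low allele fractions the thresholds make the target
#'   unreachable at any practical depth.
#' @return Integer depth.
#' @examples
#' min_depth_for_power(0.037, 0.95)
#' @export
min_depth_for_power <- function(true_vaf, target_power, cfg = filter_config(),
                                error_rate = 0, depth_cap = 1e7) {
  if (!(target_power > 0 && target_power < 1))
    stop("min_depth_for_power: target_power must lie in (0, 1)", call. = FALSE)
  if (!(true_vaf > error_rate))
    stop("min_depth_for_power: true_vaf must exceed error_rate", call. = FALSE)
  pow <- function(d) detection_probability(d, true_vaf, error_rate, cfg)
  lo <- max(1L, cfg$min_depth_case)
  hi <- lo
  last <- -1
  while (pow(hi) < target_power) {
    cur <- pow(hi)
    if (cur < last - 1e-12)
      warning("min_depth_for_power: power not monotone along search path",
              call. = FALSE)
    last <- cur
    hi <- hi * 2L
    if (hi > depth_cap)
      stop("min_depth_for_power: target power unreachable below depth ",
           format(depth_cap, scientific = FALSE),
           " at this allele fraction and threshold setting", call. = FALSE)
  }
  lo <- max(lo, hi %/% 2L)
  while (lo < hi) {                # first depth with power >= target
    mid <- (lo + hi) %/% 2L
    if (pow(mid) >= target_power) hi <- mid else lo <- mid + 1L
  }
  # absorb local non-monotonicity from the ceil(vaf * depth) threshold
  while (hi > 1L && pow(hi - 1L) >= target_power) hi <- hi - 1L
  as.integer(hi)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
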