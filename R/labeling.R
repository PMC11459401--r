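#' Three-level boundaries of the five-pattern inventory scores
#'
#' Closed integer intervals mapping each trait's inventory score to a
#' low/medium/high level. The printed source table for TYi overlaps at score
#' 7 (low ends and medium begins there); this package resolves the overlap
#' as medium = \[8, 13\], i.e. score 7 is low, keeping the intervals
#' disjoint by analogy with the other four traits.
#'
#' @return Named list (one entry per trait) of 3 x 2 matrices with columns
#'   `lo`, `hi` and rows `low`, `medium`, `high`.
#' @export
trait_level_bounds <- function() {
  mk <- function(l1, l2, m1, m2, h1, h2) {
    matrix(c(l1, l2, m1, m2, h1, h2), ncol = 2, byrow = TRUE,
           dimnames = list(c("low", "medium", "high"), c("lo", "hi")))
  }
  list(
    TYa = mk(0, 10, 11, 15, 16, 20),
    SYa = mk(0, 9, 10, 15, 16, 22),
    Yy  = mk(0, 4, 5, 7, 8, 10),
    SYi = mk(0, 11, 12, 16, 17, 21),
    TYi = mk(0, 7, 8, 13, 14, 22)
  )
}

#' Discretize an inventory score into a level
#'
#' @param trait one of `"TYa"`, `"SYa"`, `"Yy"`, `"SYi"`, `"TYi"`.
#' @param score integer score(s) within the trait's admissible range.
#' @return factor with levels `low`, `medium`, `high`.
#' @examples
#' discretize_score("TYa", 16) # high
#' discretize_score("Yy", 5)   # medium
#' @export
discretize_score <- function(trait, score) {
  trait <- match.arg(trait, trait_names())
  b <- trait_level_bounds()[[trait]]
  if (any(score < b["low", "lo"] | score > b["high", "hi"] |
          score != round(score))) {
    stop(sprintf("score out of admissible range [%d, %d] for %s",
                 b["low", "lo"], b["high", "hi"], trait))
  }
  lev <- ifelse(score <= b["low", "hi"], "low",
                ifelse(score <= b["medium", "hi"], "medium", "high"))
  factor(lev, levels = c("low", "medium", "high"))
}

#' Label table for a cohort inventory
#'
#' Discretizes every trait score of every participant.
#'
#' @param inventory data frame with `participant_id` and the five trait
#'   score columns (as produced by [generate_cohort()]).
#' @return Data frame `participant_id`, `trait`, `score`, `level` (long
#'   format, one row per participant x trait).
#' @export
label_table <- function(inventory) {
  out <- lapply(trait_names(), function(tr) {
    data.frame(participant_id = inventory$participant_id,
               trait = tr,
               score = inventory[[tr]],
               level = discretize_score(tr, inventory[[tr]]))
  })
  do.call(rbind, out)
}

#' Masking-scale exclusion filter
#'
#' Removes participants whose masking (validity) score falls below the
#' threshold, mirroring the study's exclusion of respondents scoring less
#' than 5 on the masking scale.
#'
#' @param inventory data frame with `participant_id` and `masking` columns.
#' @param threshold minimum retained masking score (default 5; scores
#'   strictly below are excluded).
#' @return List with `retained` (filtered inventory) and `excluded`
#'   (data frame `participant_id`, `masking`, `reason`).
#' @export
apply_masking_filter <- function(inventory, threshold = 5L) {
  drop <- inventory$masking < threshold
  excluded <- data.frame(
    participant_id = inventory$participant_id[drop],
    masking = inventory$masking[drop],
    reason = if (any(drop)) {
      sprintf("masking score %d below threshold %d",
              inventory$masking[drop], threshold)
    } else character(0)
  )
  list(retained = inventory[!drop, , drop = FALSE], excluded = excluded)
}
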