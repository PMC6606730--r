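# Stimulus selection: normalized rating scores and anchor-nearest
# training-clip selection on each emotion dimension.

#' Normalized rating score of one clip
#'
#' The mean rating divided by its population standard deviation
#' (`sd_type = "sample"` switches to the n-1 convention). Undefined for
#' dispersion zero.
#'
#' @param ratings Numeric vector of at least 2 ratings.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param clip Optional clip id used in the error message.
#' @return Scalar score.
#' @export
normalized_score <- function(ratings, sd_type = c("population", "sample"),
                             clip = NULL) {
  sd_type <- match.arg(sd_type)
  abort_if(length(ratings) < 2, "need at least 2 ratings")
  s <- if (sd_type == "population") pop_sd(ratings) else stats::sd(ratings)
  abort_if(s == 0, "zero rating dispersion",
           if (!is.null(clip)) paste0(" for clip ", clip) else "",
           "; the score is undefined")
  mean(ratings) / s
}

#' Per-clip normalized scores of a rating table
#'
#' @param table A [simulate_rating_table()] result (or a compatible list
#'   with `clip_id` and `arousal`/`valence` rating matrices).
#' @param sd_type Passed to [normalized_score()].
#' @return Data frame with columns `clip_id`, `score_a`, `score_v`.
#' @export
score_table <- function(table, sd_type = "population") {
  stopifnot(!is.null(table$clip_id))
  sc <- function(r) vapply(seq_len(nrow(r)), function(i)
    normalized_score(r[i, ], sd_type, clip = table$clip_id[i]), numeric(1))
  data.frame(clip_id = table$clip_id,
             score_a = sc(table$arousal),
             score_v = sc(table$valence),
             stringsAsFactors = FALSE)
}

#' Anchor values per level for a dimension
#'
#' Arousal anchors: -2.5, -0.7, 0, 0.7, 2.5 (levels 1-5); valence anchors:
#' -1.5, -0.4, 0, 1, 3 (deliberately asymmetric, matching the skewed
#' distribution of induced valence).
#'
#' @param dimension `"arousal"` or `"valence"`.
#' @return Numeric vector of 5 anchors, one per level.
#' @export
level_anchors <- function(dimension = c("arousal", "valence")) {
  dimension <- match.arg(dimension)
  if (dimension == "arousal") c(-2.5, -0.7, 0, 0.7, 2.5)
  else c(-1.5, -0.4, 0, 1, 3)
}

#' Select the 40 training stimuli nearest the level anchors
#'
#' For each of the 5 anchors of the chosen dimension (processed in level
#' order 1 to 5), selects the 8 clips with the smallest absolute score
#' distance, without replacement, yielding 40 unique clips tagged with
#' their level. Distance ties resolve to the lower clip id.
#'
#' @param scores Data frame from [score_table()] (columns `clip_id`,
#'   `score_a`, `score_v`), or any data frame with `clip_id` and a
#'   `score_a`/`score_v` column for the requested dimension.
#' @param dimension `"arousal"` or `"valence"`.
#' @param per_level Clips per level (default 8).
#' @return Data frame with columns `clip_id`, `dimension`, `level`,
#'   `score`, 5 x `per_level` rows.
#' @export
select_training_stimuli <- function(scores,
                                    dimension = c("arousal", "valence"),
                                    per_level = 8) {
  dimension <- match.arg(dimension)
  col <- if (dimension == "arousal") "score_a" else "score_v"
  abort_if(!all(c("clip_id", col) %in% names(scores)),
           "`scores` must have columns clip_id and ", col)
  need <- 5L * per_level
  abort_if(nrow(scores) < need, "need at least ", need,
           " clips with defined scores, got ", nrow(scores))
  anchors <- level_anchors(dimension)
  pool <- scores[, c("clip_id", col)]
  names(pool)[2] <- "score"
  out <- NULL
  for (lev in 1:5) {
    d <- abs(pool$score - anchors[lev])
    pick <- order(d, pool$clip_id)[seq_len(per_level)]
    out <- rbind(out, data.frame(clip_id = pool$clip_id[pick],
                                 dimension = dimension, level = lev,
                                 score = pool$score[pick],
                                 stringsAsFactors = FALSE))
    pool <- pool[-pick, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
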