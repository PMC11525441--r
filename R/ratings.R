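# Observer-experiment computations: forced-choice emotion judgments.

.emotion_levels <- function() {
  c("anger", "contentment", "fear", "joy", "neutrality", "sadness")
}

.check_ratings <- function(ratings) {
  need <- c("participant", "stimulus", "sequence", "presentation",
            "intended", "decoded", "beauty")
  miss <- setdiff(need, names(ratings))
  if (length(miss))
    stop(sprintf("ratings table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- unique(c(setdiff(ratings$intended, .emotion_levels()),
                  setdiff(ratings$decoded, .emotion_levels())))
  if (length(bad))
    stop(sprintf("unknown emotion label(s): %s", paste(bad, collapse = ", ")))
  if (any(ratings$beauty < 0 | ratings$beauty > 100, na.rm = TRUE))
    stop("beauty scores must lie in [0, 100]")
  invisible(ratings)
}

#' Confusion matrix of intended versus decoded emotion
#'
#' Row-normalized percentages of forced-choice responses: rows are groups
#' (intended emotion by default, or visual presentation, or stimulus),
#' columns are the six decoded emotions, each row summing to 100. When
#' grouping by emotion the diagonal is the correct-recognition rate.
#' Responses are pooled across participants before normalization.
#'
#' @param ratings data.frame with columns participant, stimulus, sequence,
#'   presentation, intended, decoded, beauty.
#' @param group_by `"emotion"` (default), `"presentation"` or `"stimulus"`.
#' @return A list with `percent` (matrix of row percentages), `counts`
#'   (response counts), and `correct` (per-row percent of responses where
#'   decoded matched intended).
#' @export
confusion_matrix <- function(ratings,
                             group_by = c("emotion", "presentation",
                                          "stimulus")) {
  group_by <- match.arg(group_by)
  .check_ratings(ratings)
  key <- switch(group_by, emotion = ratings$intended,
                presentation = ratings$presentation,
                stimulus = ratings$stimulus)
  decoded <- factor(ratings$decoded, levels = .emotion_levels())
  counts <- table(key, decoded)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning(sprintf("omitting empty group(s): %s",
                    paste(rownames(counts)[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  percent <- sweep(counts, 1, rowSums(counts), "/") * 100
  correct <- vapply(rownames(counts), function(g) {
    sel <- key == g
    100 * mean(ratings$decoded[sel] == ratings$intended[sel])
  }, numeric(1))
  list(percent = unclass(percent), counts = unclass(counts),
       correct = correct)
}

#' Chi-square test of recognition against chance
#'
#' Two-cell goodness-of-fit test of observed correct/incorrect counts
#' against the forced-choice chance proportion `1/categories` (16.67% for
#' six emotion options): `X^2 = sum (O - E)^2 / E` with 1 degree of
#' freedom. Symmetric in the correct/incorrect labelling.
#'
#' @param correct_count number of correct responses.
#' @param total total responses, > 0.
#' @param categories number of forced-choice options (default 6). Any value
#'   `> 1` is accepted so the complementary formulation (expected proportion
#'   `1 - 1/k`, i.e. `categories = k/(k-1)`) can express the same test with
#'   the correct/incorrect labels swapped.
#' @return A list with statistic, df, p_value, observed_rate and
#'   chance_rate (percent).
#' @export
chance_test <- function(correct_count, total, categories = 6L) {
  stopifnot(total > 0, categories > 1)
  if (correct_count > total)
    stop("correct_count cannot exceed total")
  p0 <- 1 / categories
  expected <- c(total * p0, total * (1 - p0))
  observed <- c(correct_count, total - correct_count)
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed_rate = 100 * correct_count / total,
       chance_rate = 100 * p0)
}

#' Recognition-rate summary
#'
#' Percent of correct responses per participant, then group means and
#' standard errors by visual presentation and by intended emotion.
#'
#' @param ratings data.frame as in [confusion_matrix()].
#' @return A list with `by_presentation` and `by_emotion` data.frames
#'   (group, mean_percent, se, n_participants).
#' @export
recognition_summary <- function(ratings) {
  .check_ratings(ratings)
  summarize <- function(key) {
    groups <- sort(unique(key))
    out <- lapply(groups, function(g) {
      sel <- key == g
      per <- tapply(ratings$decoded[sel] == ratings$intended[sel],
                    ratings$participant[sel], function(v) 100 * mean(v))
      per <- per[!is.na(per)]
      data.frame(group = g, mean_percent = mean(per),
                 se = stats::sd(per) / sqrt(length(per)),
                 n_participants = length(per), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  list(by_presentation = summarize(ratings$presentation),
       by_emotion = summarize(ratings$intended))
}

#' Simulate a forced-choice ratings table
#'
#' Generates observer responses with a specified per-emotion accuracy:
#' each response is correct with the emotion's accuracy, otherwise a
#' uniformly random other emotion. Beauty scores are drawn around a
#' per-emotion mean. Deterministic given the seed.
#'
#' @param n_participants observers per presentation.
#' @param n_sequences stimuli sequences (each crossed with all six
#'   emotions).
#' @param presentations character vector of visual presentation labels.
#' @param accuracy named numeric vector of per-emotion probabilities of a
#'   correct response (default 0.4 for all six emotions).
#' @param seed integer seed.
#' @return A ratings data.frame.
#' @export
simulate_ratings <- function(n_participants = 30L, n_sequences = 9L,
                             presentations = c("avatar", "FLD", "PLD",
                                               "silhouette"),
                             accuracy = NULL, seed = 1L) {
  emotions <- .emotion_levels()
  if (is.null(accuracy))
    accuracy <- stats::setNames(rep(0.4, 6), emotions)
  if (!all(emotions %in% names(accuracy)))
    stop("accuracy must be named with all six emotions")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% 2147483629L)
  grid <- expand.grid(participant = seq_len(n_participants),
                      sequence = seq_len(n_sequences),
                      intended = emotions,
                      presentation = presentations,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  is_correct <- stats::runif(n) < accuracy[grid$intended]
  wrong <- vapply(grid$intended, function(e)
    sample(setdiff(emotions, e), 1L), character(1))
  grid$decoded <- ifelse(is_correct, grid$intended, wrong)
  grid$stimulus <- sprintf("seq%d_%s_%s", grid$sequence,
                           substr(grid$intended, 1, 4), grid$presentation)
  grid$beauty <- pmin(100, pmax(0, stats::rnorm(n, mean = 50, sd = 15)))
  grid[, c("participant", "stimulus", "sequence", "presentation",
           "intended", "decoded", "beauty")]
}
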