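## The EXACT / E-RS:COPD instrument: structure, scoring, and diary file IO.

#' EXACT instrument item definitions
#'
#' The 14-item daily diary for COPD exacerbation symptoms.  Nine items have
#' five ordered response categories (scored 0-4) and five items have four
#' (scored 0-3).  Items 1-11 form the E-RS:COPD respiratory-symptom scale
#' (RS-Total, 0-40) with three subscales: breathlessness (items 7-11, 0-17),
#' cough and sputum (items 2-4, 0-11) and chest symptoms (items 1, 5, 6,
#' 0-12).  Items 12-14 contribute only to the 14-item EXACT total.
#'
#' @return a data.frame with one row per item: `item_id`, `construct`,
#'   `max_score`, `in_ers`, `subscale`.
#' @export
exact_items <- function() {
  df <- data.frame(
    item_id = 1:14,
    construct = c(
      "Congestion", "Cough frequency", "Mucus quantity",
      "Difficulty with mucus", "Discomfort", "Tightness",
      "Breathless today", "Breathless with activity",
      "Short of breath - personal care",
      "Short of breath - indoor activities",
      "Short of breath - outdoor activities",
      "Tired or weak", "Sleep disturbance", "Scared or worried"),
    max_score = c(4L, 4L, 3L, 4L, 4L, 4L, 4L, 3L, 4L, 3L, 3L, 4L, 4L, 3L),
    in_ers = c(rep(TRUE, 11), rep(FALSE, 3)),
    subscale = c("chest_symptoms", "cough_sputum", "cough_sputum",
                 "cough_sputum", "chest_symptoms", "chest_symptoms",
                 rep("breathlessness", 5), rep("none", 3)),
    stringsAsFactors = FALSE)
  df
}

## subscale membership lookups used by the scoring functions
.ers_items <- 1:11
.subscale_members <- list(
  breathlessness = c(7L, 8L, 9L, 10L, 11L),
  cough_sputum   = c(2L, 3L, 4L),
  chest_symptoms = c(1L, 5L, 6L))

.check_responses <- function(responses) {
  if (is.matrix(responses) || is.data.frame(responses)) {
    responses <- as.matrix(responses)
    if (ncol(responses) != 14L)
      stop("responses must have 14 columns (one per item)", call. = FALSE)
  } else {
    if (length(responses) != 14L)
      stop("responses must have length 14 (one per item)", call. = FALSE)
    responses <- matrix(as.numeric(responses), nrow = 1L)
  }
  if (anyNA(responses))
    stop("cannot score missing day", call. = FALSE)
  items <- exact_items()
  bad <- which(responses < 0 | responses > rep(items$max_score,
                                               each = nrow(responses)))
  if (length(bad))
    stop("item response out of range for its maximum score", call. = FALSE)
  responses
}

#' RS-Total: the E-RS:COPD summed score
#'
#' Sum of the 11 respiratory-symptom items (items 1-11); range 0-40.
#'
#' @param responses a complete day's responses: numeric vector of length 14
#'   in item order, or a matrix/data.frame with 14 columns (one row per day).
#' @return integer score(s) in `[0, 40]`.
#' @export
rs_total <- function(responses) {
  r <- .check_responses(responses)
  out <- rowSums(r[, .ers_items, drop = FALSE])
  if (length(out) == 1L) unname(out) else out
}

#' E-RS:COPD subscale scores
#'
#' @inheritParams rs_total
#' @return a named vector (or matrix, one row per day) with
#'   `breathlessness` (0-17), `cough_sputum` (0-11), `chest_symptoms` (0-12).
#' @export
subscale_totals <- function(responses) {
  r <- .check_responses(responses)
  out <- vapply(.subscale_members,
                function(m) rowSums(r[, m, drop = FALSE]),
                numeric(nrow(r)))
  if (nrow(r) == 1L) {
    v <- as.numeric(out)
    names(v) <- names(.subscale_members)
    v
  } else out
}

#' EXACT-Total score on the 0-100 interval scale
#'
#' The instrument's total score is a logit-type transform of the 14-item
#' raw sum (0-54) onto a 0-100 interval scale.  The official score-to-measure
#' table is proprietary; [default_score_map()] builds a structurally
#' equivalent map from a set of item characteristic functions, and any
#' user-supplied two-column table can be passed instead.
#'
#' @inheritParams rs_total
#' @param score_map data.frame with columns `raw_sum` (0-51, complete) and
#'   `measure` (0-100, monotone non-decreasing), e.g. from
#'   [default_score_map()].
#' @return numeric score(s) in `[0, 100]`.
#' @export
exact_total <- function(responses, score_map) {
  r <- .check_responses(responses)
  map <- .check_score_map(score_map)
  s <- rowSums(r)
  out <- map$measure[match(s, map$raw_sum)]
  if (length(out) == 1L) unname(out) else out
}

.check_score_map <- function(score_map) {
  if (!is.data.frame(score_map) ||
      !all(c("raw_sum", "measure") %in% names(score_map)))
    stop("score_map must be a data.frame with columns raw_sum and measure",
         call. = FALSE)
  score_map <- score_map[order(score_map$raw_sum), ]
  ## nine 0-4 items and five 0-3 items: raw sums span 0..51
  if (!identical(as.integer(score_map$raw_sum), 0:51))
    stop("score_map must cover raw sums 0..51 exactly once", call. = FALSE)
  if (is.unsorted(score_map$measure))
    stop("score_map measures must be monotone non-decreasing", call. = FALSE)
  score_map
}

#' Default EXACT score-to-measure map from item characteristic functions
#'
#' For each raw 14-item sum `s` (0-51) the expected-a-posteriori latent
#' disease status `E[psi | sum = s]` is computed under the given item bank
#' and a standard-normal latent distribution, then rescaled linearly so the
#' minimum sum maps to 0 and the maximum to 100.  Sum distributions given
#' psi are obtained by exact convolution of the per-item category
#' distributions, so the map is deterministic.
#'
#' @param bank an [item_bank] (defaults to [default_item_bank()]).
#' @param nodes number of Gauss-Hermite nodes for the latent integral.
#' @return data.frame with columns `raw_sum` (0-51) and `measure` (0-100).
#' @export
default_score_map <- function(bank = default_item_bank(), nodes = 61) {
  bank <- .check_bank(bank)
  gh <- gauss_hermite_normal(nodes)
  smax <- sum(bank$K)
  ## P(sum = s | psi_q): convolve item category distributions per node
  psum <- matrix(0, nodes, smax + 1)
  for (q in seq_len(nodes)) {
    conv <- 1
    for (j in seq_len(nrow(bank))) {
      pj <- category_probabilities(bank_item(bank, j), gh$nodes[q])
      conv <- convolve_pmf(conv, as.numeric(pj))
    }
    psum[q, ] <- conv
  }
  marg <- colSums(gh$weights * psum)
  eap <- colSums(gh$weights * gh$nodes * psum) / marg
  measure <- 100 * (eap - eap[1]) / (eap[smax + 1] - eap[1])
  data.frame(raw_sum = 0:smax, measure = measure)
}

## exact convolution of two probability mass functions on 0..n
convolve_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

#' Read / write a score-to-measure table
#'
#' Plain two-column CSV (`raw_sum`, `measure`) so a user-supplied official
#' table can be dropped in.
#'
#' @param path file path.
#' @param score_map table as returned by [default_score_map()].
#' @return `read_score_map` returns the validated table.
#' @export
read_score_map <- function(path) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "measure_0_100"] <- "measure"
  .check_score_map(df)
}

#' @rdname read_score_map
#' @export
write_score_map <- function(score_map, path) {
  utils::write.csv(.check_score_map(score_map), path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## DiaryDataset: wide in memory (one row per present subject-day), long on
## disk.  Whole-day missingness is represented by absent rows; the schedule
## runs from day 0 to each subject's last observed day.

#' Construct a diary dataset
#'
#' @param wide data.frame with columns `subject_id`, `arm` (`"drug"` or
#'   `"placebo"`), `day` (non-negative integer) and `i1` ... `i14` (ordinal
#'   responses).  Each row is a complete observed day; days a subject skipped
#'   are simply absent.
#' @return an object of class `diary_dataset`.
#' @export
diary_dataset <- function(wide) {
  need <- c("subject_id", "arm", "day", paste0("i", 1:14))
  if (!all(need %in% names(wide)))
    stop("wide diary needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  wide <- as.data.frame(wide)[, need]
  wide$subject_id <- as.character(wide$subject_id)
  wide$arm <- as.character(wide$arm)
  wide$day <- as.integer(wide$day)
  if (nrow(wide)) {
    if (!all(wide$arm %in% c("drug", "placebo")))
      stop("arm must be 'drug' or 'placebo'", call. = FALSE)
    if (any(wide$day < 0)) stop("day must be >= 0", call. = FALSE)
    if (anyDuplicated(wide[, c("subject_id", "day")]))
      stop("duplicate (subject_id, day) pair", call. = FALSE)
    arms <- tapply(wide$arm, wide$subject_id, function(a) length(unique(a)))
    if (any(arms > 1))
      stop("arm must be constant within subject", call. = FALSE)
    items <- exact_items()
    for (j in 1:14) {
      y <- wide[[paste0("i", j)]]
      if (anyNA(y) || any(y < 0 | y > items$max_score[j]))
        stop(sprintf("item %d responses out of range 0..%d",
                     j, items$max_score[j]), call. = FALSE)
      wide[[paste0("i", j)]] <- as.integer(y)
    }
    wide <- wide[order(wide$subject_id, wide$day), ]
    rownames(wide) <- NULL
  }
  subj <- if (nrow(wide)) {
    agg <- aggregate(day ~ subject_id + arm, data = wide, FUN = max)
    names(agg)[3] <- "last_day"
    agg[order(agg$subject_id), ]
  } else {
    data.frame(subject_id = character(), arm = character(),
               last_day = integer())
  }
  structure(list(data = wide, subjects = subj), class = "diary_dataset")
}

#' @export
print.diary_dataset <- function(x, ...) {
  cat(sprintf("diary_dataset: %d subjects (%d drug / %d placebo), %d present days\n",
              nrow(x$subjects), sum(x$subjects$arm == "drug"),
              sum(x$subjects$arm == "placebo"), nrow(x$data)))
  invisible(x)
}

#' @export
as.data.frame.diary_dataset <- function(x, ...) x$data

## number of scheduled-but-missing days (schedule = 0..last_day per subject)
n_missing_days <- function(dataset) {
  sched <- sum(dataset$subjects$last_day + 1L)
  sched - nrow(dataset$data)
}

#' Read a long-format diary CSV
#'
#' Expected columns: `subject_id`, `arm`, `day`, `item_id`, `score`; one row
#' per subject-day-item.  A present day must carry all 14 items (the
#' electronic diary does not allow partial entries); days with fewer rows
#' raise a validation error, and out-of-range scores are reported with the
#' offending subject/day/item.
#'
#' @param path CSV file path.
#' @return a [diary_dataset].
#' @export
read_diary_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "day", "item_id", "score")
  if (!all(need %in% names(long)))
    stop("diary CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  items <- exact_items()
  bad <- which(!long$item_id %in% 1:14)
  if (length(bad))
    stop("invalid item_id at row ", bad[1], call. = FALSE)
  maxs <- items$max_score[long$item_id]
  bad <- which(long$score < 0 | long$score > maxs | is.na(long$score))
  if (length(bad))
    stop(sprintf("score out of range at row %d (subject %s, day %s, item %s: score %s, max %d)",
                 bad[1], long$subject_id[bad[1]], long$day[bad[1]],
                 long$item_id[bad[1]], long$score[bad[1]], maxs[bad[1]]),
         call. = FALSE)
  key <- interaction(long$subject_id, long$day, drop = TRUE)
  counts <- table(key)
  if (any(counts != 14L)) {
    k <- names(counts)[counts != 14L][1]
    stop(sprintf("partial day: (subject, day) = %s has %d of 14 items",
                 k, counts[[k]]), call. = FALSE)
  }
  if (anyDuplicated(long[, c("subject_id", "day", "item_id")]))
    stop("duplicate (subject, day, item) row", call. = FALSE)
  wide <- stats::reshape(long, idvar = c("subject_id", "arm", "day"),
                         timevar = "item_id", direction = "wide")
  names(wide) <- sub("^score\\.", "i", names(wide))
  diary_dataset(wide)
}

#' Write a diary dataset as long-format CSV
#'
#' @param dataset a [diary_dataset].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_diary_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "diary_dataset"))
  w <- dataset$data
  long <- do.call(rbind, lapply(1:14, function(j) {
    data.frame(subject_id = w$subject_id, arm = w$arm, day = w$day,
               item_id = j, score = w[[paste0("i", j)]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$subject_id, long$day, long$item_id), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Score every present day of a diary dataset
#'
#' @param dataset a [diary_dataset].
#' @param score_map optional score-to-measure table; when supplied an
#'   `exact_total` column is added.
#' @return data.frame with one row per present subject-day and columns
#'   `subject_id`, `arm`, `day`, `rs_total`, the three subscale scores and
#'   optionally `exact_total`.
#' @export
score_diary <- function(dataset, score_map = NULL) {
  stopifnot(inherits(dataset, "diary_dataset"))
  w <- dataset$data
  resp <- as.matrix(w[, paste0("i", 1:14)])
  out <- data.frame(subject_id = w$subject_id, arm = w$arm, day = w$day,
                    stringsAsFactors = FALSE)
  if (nrow(w) == 0L) {
    out$rs_total <- numeric(0)
    return(out)
  }
  out$rs_total <- rs_total(resp)
  sub <- subscale_totals(resp)
  if (is.null(dim(sub))) sub <- matrix(sub, nrow = 1,
                                       dimnames = list(NULL, names(sub)))
  out <- cbind(out, as.data.frame(sub))
  if (!is.null(score_map)) out$exact_total <- exact_total(resp, score_map)
  out
}
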