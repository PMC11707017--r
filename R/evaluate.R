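#' The clinician grading rubric
#'
#' Five binary questions per case x task, with the scoring direction of
#' each category.  For accuracy, patient suitability and clinician
#' suitability a "yes" earns the point; for completeness ("is anything
#' crucial missing?") and safety ("does this statement put the patient
#' at risk?") a "yes" marks a flaw, so the score is inverted: yes -> 0,
#' no -> 1.
#'
#' @format data.frame with columns `category` and `yes_scores`
#'   (the points a "yes" answer earns).
#' @export
grading_rubric <- data.frame(
  category = c("accuracy", "completeness", "safety",
               "patient_suitability", "clinician_suitability"),
  yes_scores = c(1L, 0L, 0L, 1L, 1L)
)

#' Score one rating record
#'
#' Maps the five yes/no rubric answers of one rater on one case x task
#' to points per [grading_rubric].
#'
#' @param answers named logical vector (or list) with elements
#'   `accuracy`, `completeness`, `safety`, `patient_suitability`,
#'   `clinician_suitability`; `TRUE` means "yes".
#' @return named integer vector of five points in `{0, 1}`.
#' @export
score_record <- function(answers) {
  answers <- unlist(answers)
  if (!all(grading_rubric$category %in% names(answers))) {
    stop("answers must be named for all five rubric categories")
  }
  a <- as.logical(answers[grading_rubric$category])
  if (anyNA(a)) stop("all five answers must be TRUE/FALSE")
  pts <- ifelse(a, grading_rubric$yes_scores, 1L - grading_rubric$yes_scores)
  stats::setNames(as.integer(pts), grading_rubric$category)
}

#' Read a ratings CSV
#'
#' Flat schema: columns `case_id`, `task`, `rater_id`, then the five
#' rubric categories with values `yes`/`no` (case-insensitive; `1`/`0`
#' and `TRUE`/`FALSE` also accepted).
#'
#' @param path path to the CSV.
#' @return data.frame with logical answer columns.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("case_id", "task", "rater_id", grading_rubric$category)
  if (!all(need %in% names(df))) {
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "))
  }
  for (cat in grading_rubric$category) {
    v <- tolower(trimws(df[[cat]]))
    ans <- ifelse(v %in% c("yes", "1", "true"), TRUE,
                  ifelse(v %in% c("no", "0", "false"), FALSE, NA))
    if (anyNA(ans)) stop("unparsable yes/no value in column ", cat)
    df[[cat]] <- ans
  }
  df
}

#' Aggregate rubric scores the way the study design totals them
#'
#' For each task and category, each rater's points are summed over
#' cases (maximum = number of cases), and the headline figure is the
#' mean of the raters' totals.  The grid must be complete — every case
#' x task x rater combination present exactly once — unless
#' `allow_incomplete` is set.
#'
#' @param records data.frame as returned by [read_ratings_csv()].
#' @param allow_incomplete tolerate missing cells (default FALSE).
#' @return list with `by_rater` (task, category, rater_id, total,
#'   n_cases) and `summary` (task, category, mean_total, max_total).
#' @export
aggregate_scores <- function(records, allow_incomplete = FALSE) {
  key <- paste(records$case_id, records$task, records$rater_id)
  if (anyDuplicated(key)) {
    stop("duplicate rating record(s): ", key[duplicated(key)][1])
  }
  cases <- sort(unique(records$case_id))
  tasks <- sort(unique(records$task))
  raters <- sort(unique(records$rater_id))
  full <- expand.grid(case_id = cases, task = tasks, rater_id = raters,
                      stringsAsFactors = FALSE)
  missing <- !(paste(full$case_id, full$task, full$rater_id) %in% key)
  if (any(missing) && !allow_incomplete) {
    m <- full[missing, ][1, ]
    stop(sprintf(
      "incomplete rating grid (e.g. case %s, task %s, rater %s missing); set allow_incomplete = TRUE to override",
      m$case_id, m$task, m$rater_id))
  }
  pts <- t(apply(records[grading_rubric$category], 1, score_record))
  by_rater <- do.call(rbind, lapply(tasks, function(tk) {
    do.call(rbind, lapply(grading_rubric$category, function(cat) {
      do.call(rbind, lapply(raters, function(r) {
        sel <- records$task == tk & records$rater_id == r
        data.frame(task = tk, category = cat, rater_id = r,
                   total = sum(pts[sel, cat]), n_cases = sum(sel))
      }))
    }))
  }))
  summary <- do.call(rbind, lapply(tasks, function(tk) {
    do.call(rbind, lapply(grading_rubric$category, function(cat) {
      sel <- by_rater$task == tk & by_rater$category == cat
      data.frame(task = tk, category = cat,
                 mean_total = mean(by_rater$total[sel]),
                 max_total = length(cases))
    }))
  }))
  rownames(by_rater) <- rownames(summary) <- NULL
  list(by_rater = by_rater, summary = summary)
}

#' Gwet's AC1 chance-corrected agreement for two raters
#'
#' For binary ratings, with observed agreement \eqn{p_a} (fraction of
#' items the raters answer identically) and mean prevalence
#' \eqn{\pi = (\pi_A + \pi_B)/2} of the "yes" category, the chance
#' agreement is \eqn{p_e = 2\pi(1 - \pi)} and
#' \eqn{AC_1 = (p_a - p_e)/(1 - p_e)}.  Since \eqn{p_e \le 1/2} for
#' binary ratings the denominator is always at least 1/2, and
#' \eqn{AC_1 = 1} exactly when agreement is perfect.  AC1 is preferred
#' over kappa when prevalence is extreme (e.g. nearly all "yes"),
#' which binary rubric data routinely is.
#'
#' @param answers_a,answers_b logical vectors of equal length (>= 1),
#'   one element per rated item.
#' @return object of class `agreement_result`: list with `pa`, `pe`,
#'   `ac1`, `n_items`.
#' @export
gwet_ac1 <- function(answers_a, answers_b) {
  a <- as.logical(answers_a)
  b <- as.logical(answers_b)
  if (length(a) != length(b)) stop("rating vectors differ in length")
  if (length(a) == 0) stop("no items to compare")
  if (anyNA(a) || anyNA(b)) stop("ratings must be TRUE/FALSE")
  pa <- mean(a == b)
  pi_hat <- (mean(a) + mean(b)) / 2
  pe <- 2 * pi_hat * (1 - pi_hat)
  res <- list(pa = pa, pe = pe, ac1 = (pa - pe) / (1 - pe),
              n_items = length(a))
  class(res) <- "agreement_result"
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n = %d, pa = %.3f, pe = %.3f, AC1 = %.3f\n",
    x$n_items, x$pa, x$pe, x$ac1))
  invisible(x)
}

#' Per-category AC1 across a two-rater rating set
#'
#' Pairs the two raters' answers item-by-item (case x task) and
#' computes [gwet_ac1()] for each rubric category.
#'
#' @param records data.frame as returned by [read_ratings_csv()]; must
#'   contain exactly two raters and a complete grid.
#' @return data.frame with columns `category`, `pa`, `pe`, `ac1`,
#'   `n_items`.
#' @export
agreement_by_category <- function(records) {
  raters <- sort(unique(records$rater_id))
  if (length(raters) != 2) stop("exactly two raters required")
  a <- records[records$rater_id == raters[1], ]
  b <- records[records$rater_id == raters[2], ]
  a <- a[order(a$case_id, a$task), ]
  b <- b[order(b$case_id, b$task), ]
  if (!identical(paste(a$case_id, a$task), paste(b$case_id, b$task))) {
    stop("raters did not rate the same case x task items")
  }
  do.call(rbind, lapply(grading_rubric$category, function(cat) {
    r <- gwet_ac1(a[[cat]], b[[cat]])
    data.frame(category = cat, pa = r$pa, pe = r$pe, ac1 = r$ac1,
               n_items = r$n_items)
  }))
}
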