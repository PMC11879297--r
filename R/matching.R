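# Construction of the standard-care comparator: logistic propensity scores and
# greedy 1:1 nearest-neighbour matching without replacement on age, gender and
# ICD-10 primary diagnosis.

covariate_frame <- function(treated, controls, truncate_icd10 = FALSE) {
  need <- c("id", "age", "gender", "icd10")
  for (nm in c("treated", "controls")) {
    df <- get(nm)
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop(nm, " table is missing column(s): ", paste(missing, collapse = ", "))
    }
  }
  pooled <- rbind(
    data.frame(id = treated$id, group = 1L, age = as.numeric(treated$age),
               gender = as.character(treated$gender),
               icd10 = as.character(treated$icd10), stringsAsFactors = FALSE),
    data.frame(id = controls$id, group = 0L, age = as.numeric(controls$age),
               gender = as.character(controls$gender),
               icd10 = as.character(controls$icd10), stringsAsFactors = FALSE)
  )
  if (truncate_icd10) pooled$icd10 <- substr(pooled$icd10, 1L, 3L)
  pooled
}

#' Estimate propensity scores
#'
#' Logistic regression of group membership (treated vs control) on age,
#' gender and ICD-10 primary diagnosis (entered as categorical indicators).
#' Covariates that are constant in the pooled sample are dropped from the
#' design. Perfect or quasi-perfect separation is rejected with an error
#' advising exact matching, since the scores are then degenerate.
#'
#' @param treated,controls Data frames with columns `id`, `age`, `gender`,
#'   `icd10`.
#' @param truncate_icd10 Match diagnoses at 3-character granularity instead
#'   of the full code. Default `FALSE`.
#' @return List with `treated_scores` and `control_scores` (named by id,
#'   all in (0, 1)) and the fitted coefficients.
#' @export
estimate_propensity <- function(treated, controls, truncate_icd10 = FALSE) {
  pooled <- covariate_frame(treated, controls, truncate_icd10)
  pooled$gender <- factor(pooled$gender)
  pooled$icd10 <- factor(pooled$icd10)
  terms <- c("age"[stats::var(pooled$age) > 0],
             "gender"[nlevels(pooled$gender) > 1],
             "icd10"[nlevels(pooled$icd10) > 1])
  if (!length(terms)) stop("degenerate design: no covariate varies in the pool")
  fml <- stats::as.formula(paste("group ~", paste(terms, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = pooled, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  scores <- stats::fitted(fit)
  if (separated || any(scores <= 1e-12) || any(scores >= 1 - 1e-12)) {
    stop("propensity model is (quasi-)separated: scores are degenerate; ",
         "consider exact matching on the offending covariate instead")
  }
  names(scores) <- pooled$id
  list(treated_scores = scores[pooled$group == 1L],
       control_scores = scores[pooled$group == 0L],
       coefficients = stats::coef(fit))
}

smd_one <- function(x_t, x_c) {
  pooled_sd <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
  if (!is.finite(pooled_sd) || pooled_sd == 0) return(0)
  (mean(x_t) - mean(x_c)) / pooled_sd
}

#' Standardized mean differences before and after matching
#'
#' Age, a female indicator, and one indicator per diagnosis code; "before"
#' compares all treated against the full control pool, "after" compares
#' matched treated against their matched controls.
#'
#' @param treated,controls Covariate tables (`id`, `age`, `gender`, `icd10`).
#' @param pairs Data frame with columns `treated_id`, `control_id`.
#' @return Data frame with columns `covariate`, `smd_before`, `smd_after`.
#' @export
balance_table <- function(treated, controls, pairs) {
  codes <- sort(unique(c(treated$icd10, controls$icd10)))
  design <- function(df) {
    cbind(age = as.numeric(df$age),
          female = as.numeric(df$gender == "F"),
          sapply(codes, function(cd) as.numeric(df$icd10 == cd)))
  }
  x_t <- design(treated)
  x_c <- design(controls)
  x_tm <- design(treated[match(pairs$treated_id, treated$id), , drop = FALSE])
  x_cm <- design(controls[match(pairs$control_id, controls$id), , drop = FALSE])
  data.frame(
    covariate = colnames(x_t),
    smd_before = vapply(seq_len(ncol(x_t)),
                        function(j) smd_one(x_t[, j], x_c[, j]), numeric(1)),
    smd_after = vapply(seq_len(ncol(x_t)),
                       function(j) smd_one(x_tm[, j], x_cm[, j]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' 1:1 greedy nearest-neighbour matching without replacement
#'
#' Treated subjects are processed in descending propensity-score order (ties
#' by input order); each takes the unused control with the smallest absolute
#' score distance (ties by control input order). With a caliper set, a
#' treated subject whose nearest available control is farther than the
#' caliper stays unmatched. No control is used twice.
#'
#' @param treated_scores,control_scores Propensity scores named by id (from
#'   [estimate_propensity()]).
#' @param caliper Optional maximum |score distance| for an admissible pair.
#' @param treated,controls Optional covariate tables; when both are given a
#'   before/after balance table is computed.
#' @return An object of class `match_result`: `pairs` (data frame
#'   `treated_id`, `control_id`, `distance`), `unmatched_treated`, `balance`
#'   (or `NULL`).
#' @export
match_1to1 <- function(treated_scores, control_scores, caliper = NULL,
                       treated = NULL, controls = NULL) {
  if (!length(control_scores)) stop("control pool is empty")
  if (!length(treated_scores)) stop("no treated subjects to match")
  t_ids <- names(treated_scores)
  c_ids <- names(control_scores)
  ord <- order(-treated_scores)   # descending score, stable for ties
  available <- rep(TRUE, length(control_scores))
  pairs <- vector("list", length(t_ids))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (!any(available)) break
    d <- abs(control_scores - treated_scores[i])
    d[!available] <- Inf
    j <- which.min(d)   # first minimum: ties by control input order
    if (!is.null(caliper) && d[j] > caliper) next
    available[j] <- FALSE
    pairs[[k]] <- data.frame(treated_id = t_ids[i], control_id = c_ids[j],
                             distance = unname(d[j]), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(treated_id = character(), control_id = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
  }
  balance <- NULL
  if (!is.null(treated) && !is.null(controls) && nrow(pairs)) {
    balance <- balance_table(treated, controls, pairs)
  }
  structure(
    list(pairs = pairs,
         unmatched_treated = setdiff(t_ids, pairs$treated_id),
         balance = balance),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " pairs, ",
      length(x$unmatched_treated), " unmatched treated\n", sep = "")
  if (!is.null(x$balance)) {
    cat("  max |SMD| before ", round(max(abs(x$balance$smd_before)), 3),
        " -> after ", round(max(abs(x$balance$smd_after)), 3), "\n", sep = "")
  }
  invisible(x)
}
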