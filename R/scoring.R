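#' Quadrant score for one phase-plane step
#'
#' Scores the day-to-day displacement of an animal in the (v0, A) phase
#' plane. Decreases in the acid-status descriptors indicate adaptation,
#' increases the opposite:
#' both decrease -> +2; both increase -> -2; v0 up but A down -> +1 (the
#' animal's effort limited the post-prandial deviation despite a higher
#' baseline); v0 down but A up -> -1.
#'
#' A zero change is classified as a decrease by default (non-deterioration
#' is credited); set `zero_as = "increase"` for the opposite convention.
#' When both deltas are zero the step weight is zero, so the choice does
#' not affect any index.
#'
#' The rule generalises to n descriptors (see [daily_scores()]): +2 / -2
#' when all coordinates decrease / increase, otherwise +/-1 by majority,
#' with ties among the remaining coordinates decided after dropping the
#' baseline-like first coordinate.
#'
#' @param delta_v0,delta_A Numeric vectors of signed day-to-day changes
#'   (recycled to a common length).
#' @param zero_as `"decrease"` (default) or `"increase"`.
#' @return Integer vector of scores in \{-2, -1, 1, 2\}.
#' @examples
#' score_step(-1, -1)  #  2
#' score_step( 1, -1)  #  1
#' score_step(-1,  1)  # -1
#' @export
score_step <- function(delta_v0, delta_A, zero_as = c("decrease", "increase")) {
  zero_as <- match.arg(zero_as)
  n <- max(length(delta_v0), length(delta_A))
  delta_v0 <- rep_len(delta_v0, n)
  delta_A <- rep_len(delta_A, n)
  vapply(seq_len(n), function(i) {
    score_step_nd(c(delta_v0[i], delta_A[i]), zero_as)
  }, integer(1))
}

# n-dimensional quadrant rule; deltas[1] is the baseline-like coordinate.
score_step_nd <- function(deltas, zero_as = "decrease") {
  dec <- if (zero_as == "decrease") deltas <= 0 else deltas < 0
  k <- sum(dec); n <- length(dec)
  if (k == n) return(2L)
  if (k == 0L) return(-2L)
  if (k * 2L > n) return(1L)
  if (k * 2L < n) return(-1L)
  # even split: decide on the non-baseline coordinates
  if (n > 1L) {
    rest <- dec[-1L]
    if (sum(rest) * 2L >= length(rest)) 1L else -1L
  } else if (dec[1L]) 1L else -1L
}

#' Step weight: relative Euclidean distance per calendar day
#'
#' The Euclidean distance between two consecutive phase-plane points
#' divided by the number of calendar days separating the sampling days, so
#' that steps spanning long gaps are not over-weighted relative to
#' consecutive-day steps.
#'
#' @param p_i,p_j Numeric coordinate vectors of the two points (same
#'   length).
#' @param gap_days Positive number of calendar days between them.
#' @return Non-negative numeric weight (coordinate units per day).
#' @examples
#' step_weight(c(0, 0), c(3, 4), 1)  # 5
#' step_weight(c(0, 0), c(3, 4), 5)  # 1
#' @export
step_weight <- function(p_i, p_j, gap_days) {
  if (length(p_i) != length(p_j)) {
    stop("points must have the same dimension", call. = FALSE)
  }
  if (!is.finite(gap_days) || gap_days <= 0) {
    stop("gap_days must be a positive number of calendar days",
         call. = FALSE)
  }
  sqrt(sum((p_j - p_i)^2)) / gap_days
}

#' Daily step scores along one animal's phase trajectory
#'
#' For each pair of consecutive sampling days of one animal, computes the
#' quadrant score `s`, the calendar-gap-weighted Euclidean step weight
#' `omega`, and the daily index `d = s * omega`.
#'
#' @param traj Data frame for one animal with columns `day_label`,
#'   `day_offset` and the coordinate columns (one row per sampling day,
#'   sorted by `day_offset`).
#' @param coords Coordinate columns of the phase space, default
#'   `c("v0", "A")` (first is the baseline-like coordinate used for
#'   tie-breaking).
#' @param zero_as Zero-delta convention, see [score_step()].
#' @return Data frame with one row per step: `from_day`, `to_day`,
#'   `gap_days`, `s`, `omega`, `d`.
#' @export
daily_scores <- function(traj, coords = c("v0", "A"),
                         zero_as = c("decrease", "increase")) {
  zero_as <- match.arg(zero_as)
  stopifnot(is.data.frame(traj),
            all(c("day_label", "day_offset", coords) %in% names(traj)))
  if (nrow(traj) < 2L) stop("need at least 2 trajectory points", call. = FALSE)
  if (anyDuplicated(traj$day_label)) {
    stop("duplicate day_label in trajectory", call. = FALSE)
  }
  if (is.unsorted(traj$day_offset, strictly = TRUE)) {
    stop("trajectory must be strictly sorted by day_offset", call. = FALSE)
  }
  P <- as.matrix(traj[coords])
  n <- nrow(traj)
  out <- data.frame(
    from_day = traj$day_label[-n],
    to_day = traj$day_label[-1],
    gap_days = diff(traj$day_offset)
  )
  out$s <- vapply(seq_len(n - 1L), function(i) {
    score_step_nd(P[i + 1L, ] - P[i, ], zero_as)
  }, integer(1))
  out$omega <- vapply(seq_len(n - 1L), function(i) {
    step_weight(P[i, ], P[i + 1L, ], out$gap_days[i])
  }, numeric(1))
  out$d <- out$s * out$omega
  out
}

#' Global adaptive-capacity index
#'
#' Sums the daily indices `d = s * omega` of a trajectory into a single
#' per-animal index: the higher (less negative) the index, the better the
#' animal buffered the diet challenge. By default the first step (between
#' the two pre-change sampling days) is excluded, so the index covers the
#' steps from the last standard-diet day through the end of the challenge;
#' `include_first_step = TRUE` restores the all-steps sum.
#'
#' @param steps Either a step table from [daily_scores()] or a numeric
#'   vector of daily indices ordered by step (first element = first step).
#' @param include_first_step Include the pre-change step? Default `FALSE`.
#' @return List of class `global_index`: `gi` (sum of included daily
#'   indices, on the scale of the input), `steps`, `include_first_step`.
#' @examples
#' global_index(c(0.89, -5.64, -17.74, -2.22, -0.64, 1.1, 2.9, -4.19))
#' @export
global_index <- function(steps, include_first_step = FALSE) {
  if (is.numeric(steps)) {
    d <- as.numeric(steps)
    included <- if (include_first_step) seq_along(d) else seq_along(d)[-1L]
  } else {
    stopifnot(is.data.frame(steps), "d" %in% names(steps))
    d <- steps$d
    included <- if (include_first_step) seq_along(d) else seq_along(d)[-1L]
  }
  structure(
    list(gi = sum(d[included]),
         steps = steps,
         include_first_step = include_first_step),
    class = "global_index"
  )
}

#' @export
print.global_index <- function(x, ...) {
  cat(sprintf("Global index: %.4g (%s first step)\n", x$gi,
              if (x$include_first_step) "including" else "excluding"))
  invisible(x)
}

#' Unweighted global index
#'
#' Variant of [global_index()] with all step weights set to 1: the raw
#' quadrant scores are summed. Comparing the weighted and unweighted
#' indices shows how much of an animal's rank is driven by the magnitude of
#' its phase-plane displacements rather than their direction.
#'
#' @inheritParams daily_scores
#' @param include_first_step As in [global_index()].
#' @return A `global_index` object whose steps carry `omega = 1`.
#' @export
unweighted_global_index <- function(traj, coords = c("v0", "A"),
                                    zero_as = c("decrease", "increase"),
                                    include_first_step = FALSE) {
  steps <- daily_scores(traj, coords, zero_as)
  steps$omega <- 1
  steps$d <- as.numeric(steps$s)
  global_index(steps, include_first_step)
}

#' Rank animals by global index
#'
#' Orders animals by decreasing global index (higher = better adaptive
#' capacity). Ties are broken by animal identifier and flagged.
#'
#' @param indices Data frame with columns `animal_id` and `gi`, or a named
#'   numeric vector of indices.
#' @return Data frame sorted by rank with columns `rank`, `animal_id`,
#'   `gi`, `tied`.
#' @export
rank_animals <- function(indices) {
  if (is.numeric(indices) && !is.null(names(indices))) {
    indices <- data.frame(animal_id = names(indices), gi = unname(indices),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(indices),
            all(c("animal_id", "gi") %in% names(indices)),
            nrow(indices) >= 1)
  ord <- order(-indices$gi, indices$animal_id)
  out <- indices[ord, c("animal_id", "gi")]
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$gi) | duplicated(out$gi, fromLast = TRUE)
  rownames(out) <- NULL
  out[, c("rank", "animal_id", "gi", "tied")]
}

#' Score a whole cohort from its descriptor table
#'
#' Convenience wrapper running [daily_scores()] and [global_index()] for
#' every animal of a descriptor table (one row per animal-day, as produced
#' by [fit_all()]), and ranking the animals.
#'
#' @param var_table Descriptor table with `animal_id`, `day_label`,
#'   `day_offset` and the coordinate columns.
#' @inheritParams daily_scores
#' @param include_first_step As in [global_index()].
#' @param weighted Use Euclidean step weights (default) or raw quadrant
#'   scores (`FALSE`).
#' @return List of class `cohort_scores`: `steps` (all animals' step
#'   tables, stacked, with `animal_id`), `indices` (per-animal `gi`),
#'   `ranking` (from [rank_animals()]).
#' @export
score_cohort <- function(var_table, coords = c("v0", "A"),
                         zero_as = c("decrease", "increase"),
                         include_first_step = FALSE, weighted = TRUE) {
  zero_as <- match.arg(zero_as)
  trajs <- split(var_table, var_table$animal_id)
  steps_list <- lapply(names(trajs), function(id) {
    tr <- trajs[[id]]
    tr <- tr[order(tr$day_offset), ]
    st <- daily_scores(tr, coords, zero_as)
    if (!weighted) {
      st$omega <- 1
      st$d <- as.numeric(st$s)
    }
    cbind(animal_id = id, st, stringsAsFactors = FALSE)
  })
  steps <- do.call(rbind, steps_list)
  gi <- vapply(steps_list, function(st) {
    global_index(st, include_first_step)$gi
  }, numeric(1))
  indices <- data.frame(animal_id = names(trajs), gi = gi,
                        stringsAsFactors = FALSE)
  structure(
    list(steps = steps, indices = indices, ranking = rank_animals(indices),
         include_first_step = include_first_step, weighted = weighted),
    class = "cohort_scores"
  )
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat(sprintf("Cohort scoring (%s, %s first step):\n",
              if (x$weighted) "weighted" else "unweighted",
              if (x$include_first_step) "including" else "excluding"))
  print(x$ranking)
  invisible(x)
}
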