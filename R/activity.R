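#' Allocate a cage-day's spin total to its three mice
#'
#' Each mouse's observed running seconds are summed over the day's sampled
#' 3-minute windows; each mouse's proportion of activity is its seconds over
#' the total time at least one mouse ran. Because mice can run
#' simultaneously these proportions can sum above one, so they are
#' renormalized before allocating the digitally recorded spins — which makes
#' the allocation conserve the cage-day total exactly.
#'
#' @param log_day data.frame of one cage-day: columns \code{animal_id},
#'   \code{run_seconds} (one row per mouse per window) and
#'   \code{total_spins} (constant within the cage-day).
#' @param union_seconds optional total seconds in which at least one mouse
#'   ran; only used for the unattributable-activity check (it cancels from
#'   the renormalized allocation).
#' @param split_equally_if_unobserved if TRUE, a day with spins but no
#'   observed running splits the total equally instead of erroring.
#' @return named numeric of per-mouse spin shares (fractional; sums to
#'   \code{total_spins}).
#' @examples
#' d <- data.frame(animal_id = rep(c("a", "b", "c"), each = 2),
#'                 run_seconds = c(30, 30, 15, 15, 15, 15),
#'                 total_spins = 900)
#' allocate_spins(d)  # 450, 225, 225
#' @export
allocate_spins <- function(log_day, union_seconds = NULL,
                           split_equally_if_unobserved = FALSE) {
  mice <- unique(log_day$animal_id)
  if (length(mice) != 3L)
    stop("expected 3 mice per cage")
  total_spins <- unique(log_day$total_spins)
  if (length(total_spins) != 1L)
    stop("total_spins must be constant within a cage-day")
  t_i <- vapply(mice, function(m)
    sum(log_day$run_seconds[log_day$animal_id == m]), numeric(1))
  if (any(t_i < 0)) stop("negative running seconds")
  T_union <- if (!is.null(union_seconds)) union_seconds else max(t_i)
  if (sum(t_i) == 0) {
    if (total_spins == 0) return(stats::setNames(rep(0, 3), mice))
    if (!split_equally_if_unobserved)
      stop("unattributable activity: spins recorded but no mouse observed running")
    return(stats::setNames(rep(total_spins / 3, 3), mice))
  }
  p <- t_i / max(T_union, max(t_i))   # proportions of observed running time
  stats::setNames(total_spins * p / sum(p), mice)
}

#' Total running distance per mouse
#'
#' Allocates every cage-day's spins with [allocate_spins()] and converts the
#' per-mouse totals to kilometres with the wheel circumference.
#'
#' @param activity long activity table (\code{cage_id}, \code{day},
#'   \code{animal_id}, \code{run_seconds}, \code{total_spins}).
#' @param circumference_m wheel circumference in metres.
#' @param split_equally_if_unobserved passed to [allocate_spins()].
#' @return a data.frame \code{animal_id}, \code{distance_km}, plus a
#'   \code{per_day} attribute with the cage-day breakdown.
#' @export
total_distance <- function(activity, circumference_m = 0.38,
                           split_equally_if_unobserved = FALSE) {
  if (circumference_m <= 0) stop("circumference must be positive")
  per_day <- list()
  key <- interaction(activity$cage_id, activity$day, drop = TRUE)
  for (d in split(activity, key)) {
    spins <- allocate_spins(d, split_equally_if_unobserved =
                              split_equally_if_unobserved)
    per_day[[length(per_day) + 1L]] <- data.frame(
      cage_id = d$cage_id[1], day = d$day[1], animal_id = names(spins),
      spins = unname(spins), stringsAsFactors = FALSE)
  }
  per_day <- do.call(rbind, per_day)
  tot <- stats::aggregate(list(spins = per_day$spins),
                          by = per_day["animal_id"], FUN = sum)
  res <- data.frame(animal_id = tot$animal_id,
                    distance_km = tot$spins * circumference_m / 1000,
                    stringsAsFactors = FALSE)
  attr(res, "per_day") <- per_day
  res
}
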