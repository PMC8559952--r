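#' Polar angle of an allocation relative to the default-centred origin
#'
#' Allocations live on the plane of (points to self, points to other). The
#' task's geometry is a circle band centred at (50, 50); the angle of an
#' allocation is measured from the positive self axis (the direction of the
#' default allocation (100, 50) sits at 0 degrees) counter-clockwise towards
#' the other axis, in (-180, 180].
#'
#' @param pi_self integer points for the decision maker.
#' @param pi_other integer points for the recipient.
#' @return angle in degrees. Vectorised.
#' @examples
#' allocation_angle(100, 50)  # 0
#' allocation_angle(50, 100)  # 90
#' @export
allocation_angle <- function(pi_self, pi_other) {
  if (any(pi_self == 50 & pi_other == 50))
    stop("allocation (50, 50) is the band centre; its angle is undefined")
  atan2(pi_other - 50, pi_self - 50) * 180 / pi
}

#' Generate the circle-band allocation set
#'
#' Enumerates every integer allocation within `tolerance` points of the
#' circumference of radius `radius` centred at (50, 50), then applies the
#' task's exclusion rules in order: polar angle within `angle_limit` of the
#' self axis (drops extreme allocations such as (15, 15)); no more points to
#' self than the default's 100; points to other different from the default's
#' 50 (drops e.g. (0, 50)); points to other within [0, 100]. Band and angle
#' boundaries are inclusive. With the default parameters the procedure yields
#' 406 allocations, half prosocial (other gets more than 50) and half
#' antisocial.
#'
#' @param radius band centre radius in points (default 50).
#' @param tolerance half-width of the band in points (default 1).
#' @param angle_limit inclusion limit on |angle| in degrees (default 112.5).
#' @return data frame of class `allocation_set` with columns `pi_self`,
#'   `pi_other`, `role` (`"prosocial_alt"` or `"antisocial_alt"`) and `angle`
#'   (degrees), sorted by angle.
#' @export
generate_allocation_set <- function(radius = 50, tolerance = 1,
                                    angle_limit = 112.5) {
  stopifnot(radius > tolerance, tolerance > 0)
  span <- ceiling(radius + tolerance)
  grid <- expand.grid(pi_self = (50 - span):(50 + span),
                      pi_other = (50 - span):(50 + span))
  d <- sqrt((grid$pi_self - 50)^2 + (grid$pi_other - 50)^2)
  keep <- d >= radius - tolerance & d <= radius + tolerance
  grid <- grid[keep, , drop = FALSE]
  ang <- allocation_angle(grid$pi_self, grid$pi_other)
  keep <- abs(ang) <= angle_limit &
    grid$pi_self <= 100 &
    grid$pi_other != 50 &
    grid$pi_other >= 0 & grid$pi_other <= 100
  out <- grid[keep, , drop = FALSE]
  out$role <- ifelse(out$pi_other > 50, "prosocial_alt", "antisocial_alt")
  out$angle <- allocation_angle(out$pi_self, out$pi_other)
  out <- out[order(out$angle, out$pi_self), ]
  rownames(out) <- NULL
  class(out) <- c("allocation_set", "data.frame")
  out
}

#' Partition the allocation set into four angle-balanced subsets
#'
#' Sorts allocations by angle and deals them round-robin into four subsets,
#' which keeps the subsets evenly distributed around the arc. The 406
#' allocations split into two subsets of 102 and two of 101 trials (the final
#' two allocations of the deal land in subsets 1 and 2).
#'
#' @param allocations the 406-row set from [generate_allocation_set()].
#' @return the input with an added integer `subset_id` column (1-4).
#' @export
partition_subsets <- function(allocations) {
  if (nrow(allocations) != 406)
    stop("expected the 406-allocation generated set, got ",
         nrow(allocations), " rows (partition mismatch)")
  ord <- order(allocations$angle, allocations$pi_self)
  out <- allocations[ord, , drop = FALSE]
  out$subset_id <- rep_len(1:4, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("allocation_set", "data.frame")
  out
}

#' Self-advantageous catch trials
#'
#' The task mixes in a handful of alternatives that pay the decision maker
#' more than the default's 100 points while leaving the recipient at 50.
#' Because the recipient's payoff matches the default, these trials carry no
#' information about social attitude; they help identify the default-penalty
#' bias. The original point values are not in the deposited text, so this
#' generates synthetic stand-ins: distinct integers uniformly drawn from
#' (100, 110] for the self payoff.
#'
#' @param n number of trials (default 9).
#' @param seed integer seed for reproducibility.
#' @return data frame with `pi_self`, `pi_other` (= 50), `role`
#'   (`"selfish_alt"`).
#' @export
make_selfish_trials <- function(n = 9, seed = 1L) {
  stopifnot(n >= 0, n <= 10)
  if (n == 0)
    return(data.frame(pi_self = integer(0), pi_other = integer(0),
                      role = character(0)))
  self <- withr_seed(seed, sample(101:110, n))
  data.frame(pi_self = sort(self), pi_other = 50L, role = "selfish_alt")
}

# run expr under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read or write allocation lists
#'
#' CSV dialect: header `pi_self,pi_other,role,subset_id`, UTF-8, comma
#' separated, no row-name column. `subset_id` is written as NA when absent.
#'
#' @param allocations allocation data frame.
#' @param path file path.
#' @return `read_allocations` returns an `allocation_set` data frame.
#' @export
write_allocations <- function(allocations, path) {
  df <- data.frame(pi_self = allocations$pi_self,
                   pi_other = allocations$pi_other,
                   role = allocations$role,
                   subset_id = if (is.null(allocations$subset_id)) NA_integer_
                               else allocations$subset_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_allocations
#' @export
read_allocations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pi_self", "pi_other", "role", "subset_id")
  if (!all(need %in% names(df)))
    stop("allocation CSV must have columns ", paste(need, collapse = ","))
  ok <- df$role == "selfish_alt"
  df$angle <- NA_real_
  df$angle[!ok] <- allocation_angle(df$pi_self[!ok], df$pi_other[!ok])
  class(df) <- c("allocation_set", "data.frame")
  df
}

#' @export
print.allocation_set <- function(x, ...) {
  cat("Allocation set:", nrow(x), "allocations\n")
  tab <- table(x$role)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  if (!is.null(x$subset_id))
    cat("  subset sizes:",
        paste(table(x$subset_id), collapse = "/"), "\n")
  invisible(x)
}
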