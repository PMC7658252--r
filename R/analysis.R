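# Library-level bookkeeping and the closed-form estimates: class
# distributions, success rates, theoretical maximum, overall success ratio,
# SAR-neighbor estimate, ring-system census and database overlap.

#' Per-transform and global statistics of a library run
#'
#' @param records Saved-reaction tibble from [run_library()].
#' @param audit Audit tibble (killed and failed reactions).
#' @param tested Named integer vector: tested pair count per transform id.
#' @return Object of class `library_stats` with `per_transform` (tested,
#'   saved, killed, success_rate, one column per score class) and `totals`
#'   (saved, per-class saved/unique, unique_combined).
#' @export
library_stats <- function(records, audit, tested) {
  ids <- names(tested)
  per <- tibble::tibble(
    transform_id = as.integer(ids),
    tested = as.integer(tested),
    saved = vapply(ids, function(i)
      sum(records$transform_id == as.integer(i)), integer(1), USE.NAMES = FALSE),
    killed = vapply(ids, function(i)
      sum(audit$transform_id == as.integer(i) & audit$reason == "killed"),
      integer(1), USE.NAMES = FALSE)
  )
  per$success_rate <- ifelse(per$tested > 0, per$saved / per$tested, NA_real_)
  for (cl in .CLASS_LEVELS) {
    per[[cl]] <- vapply(ids, function(i)
      sum(records$transform_id == as.integer(i) & records$class_label == cl),
      integer(1), USE.NAMES = FALSE)
  }
  class_saved <- vapply(.CLASS_LEVELS, function(cl)
    sum(records$class_label == cl), integer(1))
  class_unique <- vapply(.CLASS_LEVELS, function(cl)
    length(unique(records$product_key[records$class_label == cl])), integer(1))
  totals <- list(
    saved = nrow(records),
    class_saved = class_saved,
    class_unique = class_unique,
    unique_combined = length(unique(records$product_key))
  )
  structure(list(per_transform = per, totals = totals),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("per-transform:\n")
  print(as.data.frame(x$per_transform), row.names = FALSE)
  cat(sprintf("total saved: %d   unique products: %d\n",
              x$totals$saved, x$totals$unique_combined))
  invisible(x)
}

#' Score-class distribution table
#'
#' Formats per-class saved counts (and, when available, unique-product
#' counts) with the share of total saved reactions, rounded to two
#' decimals.  Accepts either a record tibble or externally supplied counts,
#' so the formatter can also be used for published bookkeeping tables.
#'
#' @param records Saved-reaction tibble (used when `counts` is NULL).
#' @param counts Named numeric vector of per-class saved counts.
#' @param unique_counts Optional named numeric vector of per-class unique
#'   product counts.
#' @return Tibble with columns class, saved, unique, percent.  Empty when
#'   the total is zero.
#' @export
class_distribution <- function(records = NULL, counts = NULL,
                               unique_counts = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(records))
    counts <- vapply(.CLASS_LEVELS, function(cl)
      as.numeric(sum(records$class_label == cl)), numeric(1))
    unique_counts <- vapply(.CLASS_LEVELS, function(cl)
      as.numeric(length(unique(records$product_key[records$class_label == cl]))),
      numeric(1))
  }
  classes <- intersect(.CLASS_LEVELS, names(counts))
  counts <- counts[classes]
  total <- sum(counts)
  if (total == 0) {
    return(tibble::tibble(class = character(0), saved = numeric(0),
                          unique = numeric(0), percent = numeric(0)))
  }
  uq <- if (is.null(unique_counts)) rep(NA_real_, length(classes)) else
    as.numeric(unique_counts[classes])
  tibble::tibble(
    class = classes,
    saved = as.numeric(counts),
    unique = uq,
    percent = round(as.numeric(counts) / total * 100, 2)
  )
}

#' Theoretical maximum number of products
#'
#' Upper bound on the library size from `n_bb` building blocks and
#' `n_transforms` two-reactant transforms: every unordered pair under every
#' transform, i.e. n_bb^2 / 2 * n_transforms.
#'
#' @param n_bb Number of accepted building blocks.
#' @param n_transforms Number of transforms.
#' @return The bound (numeric; may exceed integer range).
#' @export
theoretical_max <- function(n_bb, n_transforms) {
  stopifnot(n_bb >= 0, n_transforms >= 0)
  0.5 * as.numeric(n_bb)^2 * as.numeric(n_transforms)
}

#' Overall success ratio of an enumeration
#'
#' Ratio of the theoretical maximum to the actually saved product count
#' ("one saved product per `ratio` conceivable ones").
#'
#' @param theoretical_max The bound from [theoretical_max()].
#' @param total_saved Number of saved reactions.
#' @param digits Significant digits for display rounding (default 2).
#' @return List with `ratio` (exact) and `ratio_display` (rounded to
#'   `digits` significant figures); both NA with a message when
#'   `total_saved` is 0.
#' @export
success_ratio <- function(theoretical_max, total_saved, digits = 2) {
  if (total_saved == 0) {
    return(list(ratio = NA_real_, ratio_display = NA_real_,
                note = "undefined: no saved reactions"))
  }
  r <- theoretical_max / total_saved
  list(ratio = r, ratio_display = signif(r, digits))
}

#' Loss rate caused by KILL statements
#'
#' Fraction of tested reactant pairs not saved: 1 - saved / tested.
#'
#' @param tested_pairs Number of tested reactant pairs.
#' @param total_saved Number of saved reactions.
#' @return Proportion in 0..1.
#' @export
kill_loss_rate <- function(tested_pairs, total_saved) {
  stopifnot(tested_pairs > 0)
  1 - total_saved / tested_pairs
}

#' Mean SAR-neighbor estimate
#'
#' Projects the saved products onto the flattened triangular N x N
#' enumeration matrix: fill = total_saved / (N^2 / 2); a product's SAR
#' neighbors (same building block A, varying B, and vice versa) then
#' average to fill * N.
#'
#' @param n_bb Number of building blocks spanning the matrix.
#' @param total_saved Number of saved products.
#' @return List with `fill` (occupied fraction of the triangular matrix)
#'   and `mean_neighbors`.
#' @export
sar_neighbors <- function(n_bb, total_saved) {
  stopifnot(n_bb > 0, total_saved >= 0)
  fill <- total_saved / (0.5 * as.numeric(n_bb)^2)
  list(fill = fill, mean_neighbors = fill * as.numeric(n_bb))
}

#' Ring-system census
#'
#' A ring system is a connected component of ring atoms and ring bonds:
#' fused (and spiro) rings count as one unit, and exocyclic atoms - e.g. a
#' carbonyl oxygen on a ring - are excluded.  Systems are identified by the
#' canonical SMILES of the ring-system substructure.
#'
#' @param smiles Character vector of product SMILES.
#' @return Object of class `ring_census`: tibble (system, count) sorted by
#'   decreasing count, with attribute `n_unique`.
#' @export
ring_system_census <- function(smiles) {
  empty <- structure(tibble::tibble(system = character(0), count = integer(0)),
                     n_unique = 0L, class = c("ring_census", "tbl_df", "tbl", "data.frame"))
  if (length(smiles) == 0) return(empty)
  res <- chem_call("ring_systems", list(smiles = smiles))$records
  systems <- unlist(lapply(res, function(x) unlist(x)))
  if (length(systems) == 0) return(empty)
  tab <- sort(table(systems), decreasing = TRUE)
  out <- tibble::tibble(system = names(tab), count = as.integer(tab))
  structure(out, n_unique = nrow(out),
            class = c("ring_census", class(out)))
}

#' Exact overlap of two key sets
#'
#' @param a,b Character vectors of unique structure keys (same
#'   canonicalization scheme on both sides).
#' @return List with n_intersection, n_a_only, n_b_only and the
#'   intersection keys.
#' @export
overlap_keys <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  inter <- intersect(a, b)
  list(n_intersection = length(inter),
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)),
       intersection = inter)
}

#' Bookkeeping counts of the original billion-scale production run
#'
#' The per-class saved and unique-product counts, tested-pair total and
#' building-block counts reported for the publicly released billion-member
#' library that this package's method re-implements at desk scale.  They
#' serve as reference inputs for the bookkeeping formulas
#' ([class_distribution()], [theoretical_max()], [success_ratio()],
#' [kill_loss_rate()], [sar_neighbors()]).
#'
#' @format A list: `class_saved` and `class_unique` (named numeric, classes
#'   Plus/Neg0/Neg10/Neg20/Neg30), `total_saved`, `unique_combined`,
#'   `tested_pairs`, `n_bb_accepted`, `n_bb_matched`, `n_transforms`.
#' @export
production_run_counts <- list(
  class_saved = c(Plus = 1094782440, Neg0 = 609262, Neg10 = 54775204,
                  Neg20 = 82180372, Neg30 = 516116725),
  class_unique = c(Plus = 976051945, Neg0 = 579532, Neg10 = 48036148,
                   Neg20 = 80366188, Neg30 = 457508945),
  total_saved = 1748464003,
  unique_combined = 1526316392,
  tested_pairs = 3.59e9,
  n_bb_accepted = 152532,
  n_bb_matched = 143365,
  n_transforms = 53
)
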