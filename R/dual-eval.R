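#' Pairing of units to their two platform samples
#'
#' A paired design measures the same unit (e.g. a single cell) twice on
#' independent platforms, giving two samples per unit. Because the two runs
#' interrogate the same DNA, any mutation's status should match between them;
#' disagreements expose miscalled negatives. Only within-unit comparisons are
#' meaningful — cross-unit comparisons are confounded by real heterogeneity.
#'
#' @param unit unit (e.g. cell) names, unique.
#' @param sample_a,sample_b the two sample names of each unit; all
#'   `2 * length(unit)` names must be distinct.
#' @return Object of class `pair_map`: a data frame with columns `unit`,
#'   `sample_a`, `sample_b`.
#' @export
pair_map <- function(unit, sample_a, sample_b) {
  unit <- as.character(unit)
  sample_a <- as.character(sample_a)
  sample_b <- as.character(sample_b)
  stopifnot(length(unit) == length(sample_a),
            length(unit) == length(sample_b))
  if (anyDuplicated(unit)) stop("unit names must be unique", call. = FALSE)
  if (anyDuplicated(c(sample_a, sample_b))) {
    stop("each sample may belong to only one unit/platform slot", call. = FALSE)
  }
  structure(data.frame(unit = unit, sample_a = sample_a, sample_b = sample_b),
            class = c("pair_map", "data.frame"))
}

#' Concordance and informative data points of a paired design
#'
#' A unit x mutation "data point" is *informative* when neither platform's
#' status is unknown, and *concordant* when the two statuses agree (both
#' positive or both negative). Concordance is reported as a percentage of
#' informative points; when a rule leaves no informative point at all it is
#' `NA` — there is no basis to call agreement either perfect or absent.
#'
#' @param statuses a [status_matrix()] with final labels.
#' @param pairs a [pair_map()]; every referenced sample must exist in
#'   `statuses`.
#' @param method,threshold optional labels copied into the result row.
#' @return One-row data frame with columns `method`, `threshold`,
#'   `informative_points`, `concordant_points`, `concordance_pct`.
#' @export
evaluate_pairs <- function(statuses, pairs, method = NA_character_,
                           threshold = NA_real_) {
  stopifnot(inherits(statuses, "status_matrix"), inherits(pairs, "pair_map"))
  missing_s <- setdiff(c(pairs$sample_a, pairs$sample_b), statuses$samples)
  if (length(missing_s) > 0) {
    stop("pair sample(s) not in the status matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  a <- statuses$status[, pairs$sample_a, drop = FALSE]
  b <- statuses$status[, pairs$sample_b, drop = FALSE]
  informative <- a != "unknown" & b != "unknown"
  concordant <- informative & a == b
  ni <- sum(informative)
  nc <- sum(concordant)
  data.frame(
    method = method,
    threshold = threshold,
    informative_points = ni,
    concordant_points = nc,
    concordance_pct = if (ni > 0) 100 * nc / ni else NA_real_
  )
}

#' Sweep negative-defining methods over a threshold grid on a paired design
#'
#' Calls positives once with `rule`, then classifies every non-positive cell
#' under each method/threshold of the grid and evaluates platform concordance
#' against informative data points — the trade-off curve of the paired-design
#' benchmark. For the MSN rows, positives from *all* samples of the matrix
#' are eligible comparison anchors (all samples are related); set
#' `per_pair_only = TRUE` to restrict each unit's tests to its own two
#' samples.
#'
#' @param counts a [count_matrix()] holding every platform sample.
#' @param pairs a [pair_map()].
#' @param rule [positive_rule()]; the paired single-cell benchmark uses a
#'   minimum of two mutant reads.
#' @param methods data frame with columns `method` and `threshold`; defaults
#'   to six UMC coverages (10, 20, 50, 100, 300, 1000) and two MSN cutoffs
#'   (0.05, 0.01).
#' @param sidedness Fisher-test sidedness for the MSN rows.
#' @param per_pair_only restrict MSN comparison anchors to each unit's own
#'   pair of samples.
#' @return Data frame with one [evaluate_pairs()] row per grid entry.
#' @export
sweep_thresholds <- function(counts, pairs, rule = positive_rule(2),
                             methods = default_pair_grid(),
                             sidedness = "two-sided",
                             per_pair_only = FALSE) {
  stopifnot(inherits(counts, "count_matrix"), inherits(pairs, "pair_map"),
            nrow(methods) > 0,
            all(c("method", "threshold") %in% names(methods)),
            all(methods$method %in% c("msn", "umc")))
  positives <- define_positive(counts, rule)
  rows <- vector("list", nrow(methods))
  for (g in seq_len(nrow(methods))) {
    st <- if (methods$method[g] == "msn") {
      if (per_pair_only) {
        classify_msn_per_pair(counts, positives, pairs,
                              msn_config(methods$threshold[g],
                                         sidedness = sidedness))
      } else {
        classify_msn(counts, positives,
                     msn_config(methods$threshold[g], sidedness = sidedness))
      }
    } else {
      classify_umc(counts, positives, umc_config(methods$threshold[g]))
    }
    rows[[g]] <- evaluate_pairs(st, pairs, methods$method[g],
                                methods$threshold[g])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# per-unit variant: classify each pair's two samples in isolation
classify_msn_per_pair <- function(counts, positives, pairs, cfg) {
  status <- positives$status
  for (u in seq_len(nrow(pairs))) {
    cols <- c(pairs$sample_a[u], pairs$sample_b[u])
    sub_counts <- count_matrix(counts$keys,
                               counts$mutant[, cols, drop = FALSE],
                               counts$total[, cols, drop = FALSE], cols)
    sub_pos <- status_matrix(positives$keys,
                             positives$status[, cols, drop = FALSE], cols)
    sub <- suppressWarnings(classify_msn(sub_counts, sub_pos, cfg))
    status[, cols] <- sub$status
  }
  status_matrix(counts$keys, status, counts$samples)
}

# default paired-design grid: six UMC coverages, two MSN p-cutoffs
default_pair_grid <- function() {
  data.frame(
    method = c(rep("umc", 6), "msn", "msn"),
    threshold = c(10, 20, 50, 100, 300, 1000, 0.05, 0.01)
  )
}
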