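#' Simulation scenario for benchmarking negative-defining rules
#'
#' Describes one tumor-cell-fraction condition of the count-level simulation:
#' a set of clonal mutations present in every measurement and subclonal
#' mutations present in a random subset, measured several times (mimicking
#' multi-site or longitudinal sampling) at a common coverage. Assuming diploid
#' sites, a mutation's expected VAF is half the tumor cell fraction, and the
#' mutant read count of a present cell is Poisson with mean
#' `coverage x fraction / 2`.
#'
#' @param tumor_fraction fraction of tumor cells in (0, 1]; the benchmark
#'   conditions are 0.90, 0.20, 0.05 and 0.01.
#' @param mean_coverage expected total reads per site (default 200).
#' @param n_clonal,n_subclonal numbers of clonal and subclonal mutations
#'   (defaults 100 and 100).
#' @param n_measurements independent measurements per scenario (default 3;
#'   2 is the minimum the multi-sample rule supports).
#' @param subclonal_presence_prob probability a subclonal mutation is present
#'   in any one measurement (default 0.5), drawn independently per
#'   measurement under `presence_model = "bernoulli"`;
#'   `"exact-half"` instead assigns each subclonal mutation to a random
#'   exactly-half subset of measurements (rounded down).
#' @param coverage_model `"fixed"` (default): every cell's total is
#'   `mean_coverage`, raised to the mutant count in the rare event the Poisson
#'   draw exceeds it; `"poisson"`: per-cell totals are Poisson(mean_coverage).
#' @param seed optional RNG seed for [simulate_counts()].
#' @return Object of class `scenario`.
#' @export
scenario <- function(tumor_fraction, mean_coverage = 200L,
                     n_clonal = 100L, n_subclonal = 100L,
                     n_measurements = 3L, subclonal_presence_prob = 0.5,
                     presence_model = c("bernoulli", "exact-half"),
                     coverage_model = c("fixed", "poisson"),
                     seed = NULL) {
  stopifnot(is.numeric(tumor_fraction), length(tumor_fraction) == 1L,
            tumor_fraction > 0, tumor_fraction <= 1,
            mean_coverage >= 1, n_clonal >= 1, n_subclonal >= 0,
            n_measurements >= 1,
            subclonal_presence_prob >= 0, subclonal_presence_prob <= 1)
  structure(list(tumor_fraction = tumor_fraction,
                 mean_coverage = as.integer(mean_coverage),
                 n_clonal = as.integer(n_clonal),
                 n_subclonal = as.integer(n_subclonal),
                 n_measurements = as.integer(n_measurements),
                 subclonal_presence_prob = subclonal_presence_prob,
                 presence_model = match.arg(presence_model),
                 coverage_model = match.arg(coverage_model),
                 seed = seed),
            class = "scenario")
}

#' Ground-truth presence matrix accompanying a simulated count matrix
#'
#' @param keys mutation key data frame.
#' @param present logical matrix, mutations x measurements.
#' @param clonal logical vector flagging the clonal mutations.
#' @param samples measurement names.
#' @return Object of class `truth_matrix`.
#' @export
truth_matrix <- function(keys, present, clonal, samples = colnames(present)) {
  present <- as.matrix(present)
  stopifnot(is.logical(present), length(clonal) == nrow(present),
            nrow(keys) == nrow(present), ncol(present) == length(samples))
  if (any(clonal & !apply(present, 1, all)[seq_along(clonal)])) {
    stop("clonal mutations must be present in every measurement", call. = FALSE)
  }
  dimnames(present) <- list(mutation_id(keys), samples)
  rownames(keys) <- NULL
  structure(list(keys = keys, samples = as.character(samples),
                 present = present, clonal = as.logical(clonal)),
            class = "truth_matrix")
}

#' Simulate read counts for one scenario
#'
#' Draws presence of every mutation in every measurement (clonal: always;
#' subclonal: per `presence_model`), then mutant reads for present cells from
#' Poisson(`mean_coverage x tumor_fraction / 2`); absent cells have zero
#' mutant reads. Totals follow `coverage_model`. Reproducible for a fixed
#' `scenario$seed`.
#'
#' @param sc a [scenario()].
#' @return List with elements `counts` (a [count_matrix()]) and `truth`
#'   (a [truth_matrix()]); measurement names are `"meas1"`, `"meas2"`, ...
#' @export
#' @examples
#' sim <- simulate_counts(scenario(0.90, seed = 1))
#' mean(sim$counts$mutant[sim$truth$present])  # ~ 200 * 0.45
simulate_counts <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (!is.null(sc$seed)) set.seed(sc$seed)
  n_mut <- sc$n_clonal + sc$n_subclonal
  m <- sc$n_measurements
  clonal <- rep(c(TRUE, FALSE), c(sc$n_clonal, sc$n_subclonal))

  present <- matrix(TRUE, n_mut, m)
  if (sc$n_subclonal > 0) {
    sub <- which(!clonal)
    if (sc$presence_model == "bernoulli") {
      present[sub, ] <- matrix(
        stats::runif(length(sub) * m) < sc$subclonal_presence_prob,
        length(sub), m)
    } else {
      k <- m %/% 2L
      for (i in sub) {
        present[i, ] <- FALSE
        present[i, sample.int(m, k)] <- TRUE
      }
    }
  }

  lambda <- sc$mean_coverage * sc$tumor_fraction / 2
  mutant <- matrix(0L, n_mut, m)
  mutant[present] <- stats::rpois(sum(present), lambda)
  total <- if (sc$coverage_model == "fixed") {
    matrix(sc$mean_coverage, n_mut, m)
  } else {
    matrix(stats::rpois(n_mut * m, sc$mean_coverage), n_mut, m)
  }
  total <- pmax(total, mutant)

  keys <- data.frame(
    chrom = "sim",
    pos = seq_len(n_mut),
    ref = "A",
    alt = "T"
  )
  samples <- paste0("meas", seq_len(m))
  colnames(mutant) <- colnames(total) <- samples
  list(counts = count_matrix(keys, mutant, total, samples),
       truth = truth_matrix(keys, present, clonal, samples))
}

#' Drop mutations never detected in any measurement
#'
#' A mutation with zero mutant reads across all measurements would not have
#' been captured by any somatic variant caller, so it is excluded before
#' scoring the negative-defining rules. Counts and truth are filtered
#' identically.
#'
#' @param counts a [count_matrix()].
#' @param truth the matching [truth_matrix()].
#' @return List with filtered `counts` and `truth`.
#' @export
exclude_undetected <- function(counts, truth) {
  stopifnot(inherits(counts, "count_matrix"), inherits(truth, "truth_matrix"))
  if (!identical(rownames(counts$mutant), rownames(truth$present))) {
    stop("counts and truth describe different mutations", call. = FALSE)
  }
  keep <- rowSums(counts$mutant) > 0
  list(
    counts = count_matrix(counts$keys[keep, , drop = FALSE],
                          counts$mutant[keep, , drop = FALSE],
                          counts$total[keep, , drop = FALSE],
                          counts$samples),
    truth = truth_matrix(truth$keys[keep, , drop = FALSE],
                         truth$present[keep, , drop = FALSE],
                         truth$clonal[keep],
                         truth$samples)
  )
}

#' Score status calls against simulation ground truth
#'
#' Each mutation x measurement cell is categorised by its call and the true
#' presence: positive+present = TP, positive+absent = FP, negative+present =
#' FN (the error the methods try to avoid), negative+absent = TN, and any
#' unknown call stays unknown. Fractions are over all retained cells and sum
#' to one. With no sequencing-error model, absent cells can never show mutant
#' reads, so FP is structurally zero.
#'
#' @param statuses a [status_matrix()] from [classify_msn()]/[classify_umc()].
#' @param truth the matching [truth_matrix()].
#' @return Object of class `sim_score`: named numeric vector with components
#'   `unknown`, `fn`, `tn`, `fp`, `tp` and an `n_cells` attribute.
#' @export
score_statuses <- function(statuses, truth) {
  stopifnot(inherits(statuses, "status_matrix"), inherits(truth, "truth_matrix"))
  if (!identical(rownames(statuses$status), rownames(truth$present)) ||
      !identical(statuses$samples, truth$samples)) {
    stop("statuses and truth describe different axes", call. = FALSE)
  }
  s <- statuses$status
  pr <- truth$present
  n <- length(s)
  out <- c(
    unknown = sum(s == "unknown"),
    fn = sum(s == "negative" & pr),
    tn = sum(s == "negative" & !pr),
    fp = sum(s == "positive" & !pr),
    tp = sum(s == "positive" & pr)
  ) / n
  structure(out, n_cells = n, class = "sim_score")
}

#' @export
print.sim_score <- function(x, ...) {
  cat(sprintf("<sim_score> over %d cells\n", attr(x, "n_cells")))
  print(round(unclass(x), 4))
  invisible(x)
}

# default benchmark grid: two MSN p-cutoffs, four UMC coverage cutoffs
default_method_grid <- function() {
  data.frame(
    method = c("msn", "msn", "umc", "umc", "umc", "umc"),
    threshold = c(0.01, 0.05, 20, 50, 200, 300)
  )
}

#' Run the simulation benchmark over scenarios and methods
#'
#' For each scenario and replicate: simulate counts, call positives (any
#' mutant read, the simulation convention), drop never-detected mutations,
#' classify the remaining non-positive cells with each method/threshold, and
#' score against the truth. The result is the long-format table behind the
#' stacked-fraction benchmark figure.
#'
#' @param scenarios list of [scenario()] objects (a bare `scenario` is
#'   accepted).
#' @param methods data frame with columns `method` (`"msn"`/`"umc"`) and
#'   `threshold` (alpha for msn, min coverage for umc); defaults to the
#'   six-setting benchmark grid.
#' @param replicates independent replicate datasets per scenario (default 1).
#' @param seed base RNG seed; replicate r of scenario s uses a distinct seed
#'   derived from it, so the whole table is reproducible.
#' @param rule [positive_rule()] applied inside the simulation (default: one
#'   mutant read).
#' @param sidedness Fisher-test sidedness for the msn rows.
#' @return Data frame with columns `scenario` (tumor fraction), `replicate`,
#'   `method`, `threshold`, `category`, `fraction`.
#' @export
#' @examples
#' run_scenarios(scenario(0.9), replicates = 2, seed = 1)
run_scenarios <- function(scenarios, methods = default_method_grid(),
                          replicates = 1L, seed = NULL,
                          rule = positive_rule(min_mutant_reads = 1),
                          sidedness = "two-sided") {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) > 0, nrow(methods) > 0,
            all(c("method", "threshold") %in% names(methods)),
            all(methods$method %in% c("msn", "umc")))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(replicates)) {
      sc_r <- sc
      # distinct reproducible sub-seed per (scenario, replicate)
      sc_r$seed <- if (is.null(seed)) NULL else
        (seed + 7919L * si + 104729L * r) %% .Machine$integer.max
      sim <- simulate_counts(sc_r)
      kept <- exclude_undetected(sim$counts, sim$truth)
      if (nrow(kept$counts$mutant) == 0L) next
      positives <- define_positive(kept$counts, rule)
      for (g in seq_len(nrow(methods))) {
        st <- if (methods$method[g] == "msn") {
          classify_msn(kept$counts, positives,
                       msn_config(alpha = methods$threshold[g],
                                  sidedness = sidedness))
        } else {
          classify_umc(kept$counts, positives,
                       umc_config(min_coverage = methods$threshold[g]))
        }
        sc_score <- score_statuses(st, kept$truth)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc$tumor_fraction,
          replicate = r,
          method = methods$method[g],
          threshold = methods$threshold[g],
          category = names(sc_score),
          fraction = as.numeric(sc_score)
        )
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Expected unknown fraction under UMC when the threshold exceeds coverage
#'
#' Closed-form check for the fixed-coverage model at a high tumor fraction
#' (where present cells are detected essentially always): every absent
#' subclonal cell is unknown, and a subclonal mutation absent from all `m`
#' measurements (probability `q = (1 - p)^m`) is excluded beforehand. The
#' expected unknown fraction among retained statuses is then the ratio of
#' expected retained absent cells, `n_sub * (m * (1 - p) - m * q)`, to
#' expected retained cells, `m * (n_clonal + n_sub * (1 - q))`. At the
#' default design (100 + 100 mutations, 3 measurements, p = 0.5) this is
#' exactly 0.20.
#'
#' @param n_clonal,n_subclonal,n_measurements scenario dimensions.
#' @param presence_prob subclonal per-measurement presence probability.
#' @return Expected unknown fraction in `[0, 1]`.
#' @export
expected_unknown_umc_high_fraction <- function(n_clonal = 100,
                                               n_subclonal = 100,
                                               n_measurements = 3,
                                               presence_prob = 0.5) {
  m <- n_measurements
  p <- presence_prob
  q <- (1 - p)^m                       # subclonal never present -> excluded
  absent_retained <- n_subclonal * (m * (1 - p) - m * q)
  retained_cells <- m * (n_clonal + n_subclonal * (1 - q))
  absent_retained / retained_cells
}
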