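#' Read-count matrix for a set of mutations across related samples
#'
#' The universal input of the package: for every unique somatic mutation
#' (identified by chromosome, 1-based position, reference allele and mutant
#' allele) and every related sample, the number of reads supporting the mutant
#' allele and the total number of reads covering the site (the coverage).
#' Wildtype read counts are derived as `total - mutant`; variant allele
#' frequency (VAF) as `mutant / total` where `total > 0`.
#'
#' A mutation that was not measured in some sample is encoded as
#' `mutant = 0, total = 0`; such cells deterministically come out `"unknown"`
#' under every classification rule, so no special missing-value path exists.
#'
#' @param keys data frame with columns `chrom` (character), `pos` (positive
#'   integer), `ref`, `alt` (character, `ref != alt`); rows must be unique.
#' @param mutant,total integer matrices, one row per mutation and one column
#'   per sample, with `0 <= mutant <= total` cell-wise.
#' @param samples character vector of unique sample names; defaults to the
#'   column names of `mutant`.
#'
#' @return An object of class `count_matrix`: a list with elements `keys`,
#'   `samples`, `mutant` and `total`. Row names of the matrices are the
#'   `chrom:pos:ref:alt` identifiers, column names the sample names.
#' @seealso [read_count_matrix()], [define_positive()], [classify_msn()]
#' @export
#' @examples
#' cm <- count_matrix(
#'   keys = data.frame(chrom = "7", pos = 55249071L, ref = "C", alt = "T"),
#'   mutant = matrix(c(40L, 0L), 1), total = matrix(c(72L, 15L), 1),
#'   samples = c("biopsy1", "biopsy2")
#' )
#' vaf(cm)
count_matrix <- function(keys, mutant, total, samples = colnames(mutant)) {
  keys <- as.data.frame(keys)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(keys))) {
    stop("`keys` must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  keys <- keys[need]
  keys$chrom <- as.character(keys$chrom)
  keys$ref <- as.character(keys$ref)
  keys$alt <- as.character(keys$alt)
  pos <- keys$pos
  if (any(is.na(pos)) || any(pos < 1) || any(pos != as.integer(pos))) {
    stop("`pos` must be a 1-based integer position", call. = FALSE)
  }
  keys$pos <- as.integer(pos)
  if (any(keys$ref == keys$alt)) {
    stop("reference and mutant allele must differ", call. = FALSE)
  }
  ids <- mutation_id(keys)
  if (anyDuplicated(ids)) {
    stop("duplicate mutation key(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  mutant <- as.matrix(mutant)
  total <- as.matrix(total)
  storage.mode(mutant) <- "integer"
  storage.mode(total) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(ncol(mutant)))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample names must be unique", call. = FALSE)
  if (nrow(mutant) != nrow(keys) || !all(dim(mutant) == dim(total)) ||
      ncol(mutant) != length(samples)) {
    stop("dimensions of `keys`, `mutant`, `total` and `samples` disagree",
         call. = FALSE)
  }
  if (anyNA(mutant) || anyNA(total)) stop("counts must not be NA", call. = FALSE)
  if (any(mutant < 0) || any(total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(mutant > total)) {
    stop("mutant reads exceed total reads in ", sum(mutant > total), " cell(s)",
         call. = FALSE)
  }
  dimnames(mutant) <- dimnames(total) <- list(ids, samples)
  rownames(keys) <- NULL
  structure(list(keys = keys, samples = samples, mutant = mutant, total = total),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d mutation(s) x %d sample(s)\n",
              nrow(x$mutant), length(x$samples)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  n <- min(5L, nrow(x$mutant))
  if (n > 0) {
    shown <- matrix(paste0(x$mutant[seq_len(n), , drop = FALSE], "/",
                           x$total[seq_len(n), , drop = FALSE]),
                    nrow = n, dimnames = list(rownames(x$mutant)[seq_len(n)],
                                              x$samples))
    print(shown, quote = FALSE)
    if (nrow(x$mutant) > n) cat("... and", nrow(x$mutant) - n, "more\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$mutant)

#' Variant allele frequencies of a count matrix
#'
#' @param x a [count_matrix()].
#' @return Numeric matrix of `mutant / total`; `NA` where `total == 0`
#'   (no measurement, VAF undefined).
#' @export
vaf <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  out <- x$mutant / x$total
  out[x$total == 0] <- NA_real_
  out
}

# canonical "chrom:pos:ref:alt" identifier used as matrix row names
mutation_id <- function(keys) {
  paste(keys$chrom, keys$pos, keys$ref, keys$alt, sep = ":")
}

#' Per-cell mutation status labels
#'
#' The universal output: one label per mutation x sample cell. Intermediate
#' objects produced by [define_positive()] use `"positive"`/`"TBD"`
#' (to-be-determined); final objects from [classify_msn()] or [classify_umc()]
#' use `"positive"`/`"negative"`/`"unknown"`.
#'
#' @param keys mutation key data frame (see [count_matrix()]).
#' @param status character matrix of labels, same shape as the count matrices.
#' @param samples character vector of sample names.
#' @return An object of class `status_matrix`: list with `keys`, `samples`,
#'   `status`.
#' @export
status_matrix <- function(keys, status, samples = colnames(status)) {
  status <- as.matrix(status)
  ok <- c("positive", "negative", "unknown", "TBD")
  if (!all(status %in% ok)) {
    bad <- setdiff(unique(as.vector(status)), ok)
    stop("invalid status label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(status) != nrow(keys) || ncol(status) != length(samples)) {
    stop("status dimensions disagree with keys/samples", call. = FALSE)
  }
  dimnames(status) <- list(mutation_id(keys), samples)
  rownames(keys) <- NULL
  structure(list(keys = keys, samples = as.character(samples), status = status),
            class = "status_matrix")
}

#' @export
print.status_matrix <- function(x, ...) {
  cat(sprintf("<status_matrix> %d mutation(s) x %d sample(s)\n",
              nrow(x$status), length(x$samples)))
  print(table(factor(x$status, c("positive", "negative", "unknown", "TBD"))))
  invisible(x)
}

#' @export
dim.status_matrix <- function(x) dim(x$status)

# shared guard: counts and statuses must describe the same axes
check_same_axes <- function(counts, statuses) {
  if (!identical(rownames(counts$mutant), rownames(statuses$status)) ||
      !identical(counts$samples, statuses$samples)) {
    stop("count matrix and status matrix have different mutations or samples",
         call. = FALSE)
  }
  invisible(TRUE)
}
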