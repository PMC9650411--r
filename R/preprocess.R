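#' Remove genes expressed in too few samples
#'
#' Keeps a gene iff the fraction of samples in which its value exceeds
#' `expression_floor` is at least `min_fraction`.  Applied per RNA class;
#' row order is preserved.  With the defaults this is the usual rule that
#' drops genes not expressed in more than 50% of samples.
#'
#' @param bundle An [expression_bundle()].
#' @param min_fraction Minimum fraction of expressing samples, in (0, 1].
#' @param expression_floor A value must exceed this to count as expressed;
#'   0 is appropriate for log-scale matrices.
#' @return A filtered `expression_bundle`.
#' @export
filter_low_expression <- function(bundle, min_fraction = 0.5,
                                  expression_floor = 0) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  out <- bundle
  for (cls in c("mrna", "lncrna", "mirna")) {
    m <- bundle[[cls]]
    frac <- rowMeans(m > expression_floor)
    keep <- frac >= min_fraction
    if (!any(keep))
      stop("expression filter removed every ", cls, " gene", call. = FALSE)
    out[[cls]] <- m[keep, , drop = FALSE]
  }
  validate_bundle(out)
  out
}

#' Standardized sample-network connectivity scores
#'
#' Builds the sample-sample Pearson correlation matrix over the combined
#' mRNA + lncRNA rows (miRNAs excluded: few genes, noisy), sums each
#' sample's correlations to the others (connectivity k), and standardizes:
#' Z = (k - mean(k)) / sd(k).  Samples with strongly negative Z are
#' outliers weakly connected to the rest of the cohort.
#'
#' @param bundle An [expression_bundle()].
#' @return Named numeric vector of Z scores, one per sample (they sum to 0).
#' @export
sample_outlier_z <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  x <- rbind(bundle$mrna, bundle$lncrna)
  if (ncol(x) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  cc <- stats::cor(x)
  k <- colSums(cc) - 1  # exclude self-correlation
  (k - mean(k)) / stats::sd(k)
}

#' Drop outlier samples by connectivity Z score
#'
#' Single pass: computes [sample_outlier_z()] once and removes samples with
#' Z below the cutoff from all three matrices and the trait table.
#'
#' @param bundle An [expression_bundle()].
#' @param z_cutoff Samples with Z < `z_cutoff` are removed (default -2).
#' @return The cleaned `expression_bundle`.
#' @export
remove_outliers <- function(bundle, z_cutoff = -2) {
  z <- sample_outlier_z(bundle)
  keep <- z >= z_cutoff
  if (all(keep)) return(bundle)
  if (sum(keep) < 3)
    stop("fewer than 3 samples would remain after outlier removal",
         call. = FALSE)
  out <- bundle
  for (cls in c("mrna", "lncrna", "mirna"))
    out[[cls]] <- bundle[[cls]][, keep, drop = FALSE]
  out$traits <- bundle$traits[keep, , drop = FALSE]
  rownames(out$traits) <- NULL
  validate_bundle(out)
  out
}
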