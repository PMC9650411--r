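#' Expression bundle: matched mRNA, lncRNA and miRNA expression
#'
#' An expression bundle holds three genes x samples matrices (one per RNA
#' class) aligned on a shared, identically ordered sample axis, plus a trait
#' table keyed by sample id.  All downstream stages (filtering, network
#' construction, sponge identification, preservation, ROC screening) operate
#' on this container.
#'
#' @param mrna,lncrna,mirna Numeric matrices, genes x samples, with unique
#'   rownames (gene ids) and identical colnames (sample ids) in identical
#'   order.
#' @param traits A data.frame with one row per sample: columns `sample_id`,
#'   `diagnosis` (integer code, e.g. ASD-1, SCZ-2, BD-3) and `case`
#'   (0/1 case-control flag).  Row order must match the sample order of the
#'   expression matrices.
#' @return An object of class `"expression_bundle"`.
#' @export
expression_bundle <- function(mrna, lncrna, mirna, traits) {
  bundle <- structure(
    list(mrna = mrna, lncrna = lncrna, mirna = mirna, traits = traits),
    class = "expression_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Validate an expression bundle
#'
#' Checks the container invariants: numeric matrices, unique gene ids within
#' and across classes, identical sample id sequences in the three matrices
#' and the trait table, and finite values.
#'
#' @param bundle An `expression_bundle`.
#' @return The bundle, invisibly, if valid; otherwise an error is raised.
#' @export
validate_bundle <- function(bundle) {
  for (cls in c("mrna", "lncrna", "mirna")) {
    m <- bundle[[cls]]
    if (!is.matrix(m) || !is.numeric(m))
      stop(cls, " must be a numeric matrix", call. = FALSE)
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      stop("duplicate or missing gene ids in ", cls, call. = FALSE)
    if (is.null(colnames(m)))
      stop("missing sample ids in ", cls, call. = FALSE)
    if (any(!is.finite(m)))
      stop("non-finite values in ", cls, call. = FALSE)
  }
  ids <- c(rownames(bundle$mrna), rownames(bundle$lncrna),
           rownames(bundle$mirna))
  if (anyDuplicated(ids))
    stop("gene ids duplicated across RNA classes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  samples <- colnames(bundle$mrna)
  for (cls in c("lncrna", "mirna")) {
    if (!identical(colnames(bundle[[cls]]), samples))
      stop("sample ids of ", cls, " do not match mrna", call. = FALSE)
  }
  tr <- bundle$traits
  if (!is.data.frame(tr) || !all(c("sample_id", "diagnosis", "case") %in%
                                 names(tr)))
    stop("traits must be a data.frame with sample_id, diagnosis, case",
         call. = FALSE)
  if (!identical(as.character(tr$sample_id), samples))
    stop("trait table sample order does not match expression matrices",
         call. = FALSE)
  invisible(bundle)
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("expression_bundle:",
      nrow(x$mrna), "mRNAs,",
      nrow(x$lncrna), "lncRNAs,",
      nrow(x$mirna), "miRNAs x",
      ncol(x$mrna), "samples\n")
  cat("  cases:", sum(x$traits$case), " controls:",
      sum(x$traits$case == 0), "\n")
  invisible(x)
}

#' Look up the RNA class of gene ids in a bundle
#'
#' @param bundle An `expression_bundle`.
#' @param ids Character vector of gene ids.
#' @return Character vector of classes (`"mrna"`, `"lncrna"`, `"mirna"`),
#'   `NA` for ids absent from the bundle.
#' @export
gene_class <- function(bundle, ids) {
  cls <- rep(NA_character_, length(ids))
  cls[ids %in% rownames(bundle$mrna)] <- "mrna"
  cls[ids %in% rownames(bundle$lncrna)] <- "lncrna"
  cls[ids %in% rownames(bundle$mirna)] <- "mirna"
  names(cls) <- ids
  cls
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a reproducible per-stage seed from a global seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, test_data = 23L, null = 37L,
               preserve = 53L, pipeline = 71L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
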