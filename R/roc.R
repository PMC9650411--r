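#' Single-gene ROC analysis
#'
#' AUC by the rank (Mann-Whitney) identity with ties counted 0.5: the
#' probability that a random case sample expresses the gene higher than a
#' random control.  The direction is chosen automatically so AUC >= 0.5 and
#' recorded (`"case_high"` or `"control_high"`).  The ROC curve is traced
#' over every distinct expression threshold.
#'
#' @param values Per-sample expression of one gene.
#' @param labels Binary labels (1/TRUE = case), same length; both classes
#'   must be non-empty.
#' @return A `roc_result` list: `auc` in `[0.5, 1]`, `direction`, `curve`
#'   (data.frame of fpr, tpr from (0,0) to (1,1)), `n_case`, `n_control`.
#' @export
auc_single <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be non-empty", call. = FALSE)
  r <- rank(values)  # midranks: ties count 0.5 in the U statistic
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  auc_raw <- u / (n1 * n0)
  direction <- if (auc_raw >= 0.5) "case_high" else "control_high"
  score <- if (direction == "case_high") values else -values

  ord <- order(score, decreasing = TRUE)
  lab <- labels[ord]
  sc <- score[ord]
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # end of each tie block
  tpr <- c(0, cumsum(lab)[last] / n1)
  fpr <- c(0, cumsum(1 - lab)[last] / n0)
  structure(
    list(auc = max(auc_raw, 1 - auc_raw), direction = direction,
         curve = data.frame(fpr = fpr, tpr = tpr),
         n_case = n1, n_control = n0),
    class = "roc_result"
  )
}

#' Screen candidate lncRNAs as diagnostic biomarkers
#'
#' Computes the single-gene AUC of each candidate lncRNA against the
#' case/control labels of one or more datasets and flags candidates whose
#' AUC exceeds `auc_cutoff` in every supplied dataset (mirroring the
#' requirement that a biomarker validates across independent cohorts).
#'
#' @param bundles An [expression_bundle()] or a named list of them; labels
#'   are taken from each bundle's trait table `case` column.
#' @param candidates Character vector of lncRNA ids (must be present in
#'   every bundle).
#' @param auc_cutoff Flagging threshold (strict inequality).
#' @return data.frame with one row per candidate: per-dataset AUC and
#'   direction columns, and `flagged` (TRUE iff AUC > cutoff in all
#'   datasets).
#' @export
screen_lncrnas <- function(bundles, candidates, auc_cutoff = 0.7) {
  if (inherits(bundles, "expression_bundle")) bundles <- list(bundles)
  if (is.null(names(bundles)))
    names(bundles) <- paste0("dataset", seq_along(bundles))
  out <- data.frame(lncrna = candidates, stringsAsFactors = FALSE)
  pass <- matrix(FALSE, length(candidates), length(bundles))
  for (j in seq_along(bundles)) {
    b <- bundles[[j]]
    missing <- setdiff(candidates, rownames(b$lncrna))
    if (length(missing))
      stop("candidate(s) absent from ", names(bundles)[j], ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    res <- lapply(candidates, function(g)
      auc_single(b$lncrna[g, ], b$traits$case))
    auc <- vapply(res, `[[`, numeric(1), "auc")
    out[[paste0("auc_", names(bundles)[j])]] <- auc
    out[[paste0("direction_", names(bundles)[j])]] <-
      vapply(res, `[[`, character(1), "direction")
    pass[, j] <- auc > auc_cutoff
  }
  out$flagged <- apply(pass, 1, all)
  out[order(-out[[paste0("auc_", names(bundles)[1])]], out$lncrna), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
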