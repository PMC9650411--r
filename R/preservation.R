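#' Permutation Z-summary module preservation
#'
#' Quantifies whether modules defined in a reference dataset keep their
#' density and connectivity structure in a test dataset.  Signed
#' soft-threshold adjacencies are built in both datasets on the common
#' genes (same transform, same power as the reference run).  Per module:
#' density = mean off-diagonal intramodular adjacency in the test network;
#' connectivity = mean of (a) the correlation between reference and test
#' intramodular connectivity vectors and (b) the correlation between the
#' vectorized reference and test intramodular adjacency upper triangles.
#' Each observed statistic is standardized against `n_perm` random
#' reassignments of module labels over the common genes (sizes preserved):
#' `Z = (obs - mean_perm) / sd_perm`, and
#' `Z_summary = (Z_density + Z_connectivity) / 2`.
#'
#' @param ref_expr,test_expr Genes x samples matrices (gene ids must
#'   overlap; statistics are computed on the intersection).
#' @param modules A `module_assignment` (or named label vector) on the
#'   reference genes.
#' @param power Soft-threshold power; use the reference run's power.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return data.frame with one row per module: observed density and
#'   connectivity, `z_density`, `z_connectivity`, `z_summary`, and the
#'   evidence class from [classify_evidence()].  Modules with fewer than 3
#'   common genes are skipped with a warning.
#' @export
preservation_zsummary <- function(ref_expr, test_expr, modules, power,
                                  n_perm = 200, seed = 1L) {
  labels <- if (inherits(modules, "module_assignment")) modules$labels else
    modules
  common <- intersect(intersect(names(labels)[labels > 0],
                                rownames(ref_expr)), rownames(test_expr))
  # permutation universe: all common genes, assigned or not
  universe <- intersect(rownames(ref_expr), rownames(test_expr))
  if (length(universe) < 3)
    stop("fewer than 3 genes shared between reference and test",
         call. = FALSE)
  a_ref <- soft_adjacency(signed_similarity(
    ref_expr[universe, , drop = FALSE]), power)
  a_test <- soft_adjacency(signed_similarity(
    test_expr[universe, , drop = FALSE]), power)

  mod_stats <- function(genes) {
    r <- a_ref[genes, genes]
    t <- a_test[genes, genes]
    ut <- upper.tri(r)
    k_ref <- rowSums(r) - 1
    k_test <- rowSums(t) - 1
    dens <- mean(t[ut])
    conn <- mean(c(stats::cor(k_ref, k_test), stats::cor(r[ut], t[ut])))
    c(dens, conn)
  }

  mods <- sort(unique(labels[labels > 0]))
  keep <- vapply(mods, function(k)
    sum(names(labels)[labels == k] %in% universe) >= 3, logical(1))
  if (any(!keep))
    warning("skipping module(s) with < 3 common genes: ",
            paste(mods[!keep], collapse = ", "), call. = FALSE)
  mods <- mods[keep]
  if (!length(mods)) stop("no module with >= 3 common genes", call. = FALSE)
  sizes <- vapply(mods, function(k)
    sum(names(labels)[labels == k] %in% common), integer(1))
  obs <- vapply(mods, function(k)
    mod_stats(intersect(names(labels)[labels == k], common)), numeric(2))

  perm <- with_seed(stage_seed(seed, "preserve"), {
    array(vapply(seq_len(n_perm), function(p) {
      pool <- sample(universe)
      off <- 0L
      vapply(seq_along(mods), function(j) {
        genes <- pool[seq(off + 1L, off + sizes[j])]
        off <<- off + sizes[j]
        mod_stats(genes)
      }, numeric(2))
    }, matrix(0, 2, length(mods))), dim = c(2, length(mods), n_perm))
  })

  z <- matrix(NA_real_, 2, length(mods))
  for (s in 1:2) {
    mu <- apply(perm[s, , , drop = FALSE], 2, mean)
    sd_p <- apply(perm[s, , , drop = FALSE], 2, stats::sd)
    # degenerate permutation spread: sign convention, 0 when obs == mean
    zero <- sd_p < 1e-12
    if (any(zero))
      warning("zero permutation spread for module(s) ",
              paste(mods[zero], collapse = ", "),
              "; Z set by sign convention", call. = FALSE)
    d <- obs[s, ] - mu
    z[s, ] <- ifelse(zero, ifelse(abs(d) < 1e-12, 0, sign(d) * Inf),
                     d / sd_p)
  }
  z_summary <- colMeans(z)
  data.frame(
    module = mods, n_genes = sizes,
    density = obs[1, ], connectivity = obs[2, ],
    z_density = z[1, ], z_connectivity = z[2, ],
    z_summary = z_summary,
    evidence = vapply(z_summary, classify_evidence, character(1)),
    row.names = NULL
  )
}

#' Classify preservation evidence from a Z-summary value
#'
#' `> 10` is strong evidence of preservation, `(2, 10]` weak to moderate,
#' `<= 2` no evidence (the boundary 10 is assigned to moderate; infinite
#' values from degenerate permutation spreads classify by sign).
#'
#' @param z_summary A Z-summary value (must not be NA).
#' @return `"strong"`, `"moderate"` or `"none"`.
#' @export
classify_evidence <- function(z_summary) {
  if (is.na(z_summary)) stop("z_summary must not be NA", call. = FALSE)
  if (z_summary > 10) "strong" else if (z_summary > 2) "moderate" else
    "none"
}

#' Re-test a sponge module's canonical correlation in a test dataset
#'
#' Recomputes the sensitivity canonical correlation and its null-model
#' p-value for a previously identified module on an independent test
#' bundle, on the intersection of the module genes with the test bundle.
#'
#' @param test_bundle An [expression_bundle()].
#' @param lncrna_ids,mrna_ids,mirna_ids The module's members and shared
#'   miRNAs from the reference analysis.
#' @param n_null,seed,dim_cap,cache Passed to [null_model_pvalue()].
#' @param min_lncrna Minimum lncRNAs that must remain after intersection.
#' @return List with the canonical correlations, `scc` and `p`.
#' @export
test_set_canonical_correlation <- function(test_bundle, lncrna_ids,
                                           mrna_ids, mirna_ids,
                                           n_null = 1e4, seed = 1L,
                                           dim_cap = NULL, min_lncrna = 3,
                                           cache = .null_cache) {
  lnc <- intersect(lncrna_ids, rownames(test_bundle$lncrna))
  mr <- intersect(mrna_ids, rownames(test_bundle$mrna))
  mir <- intersect(mirna_ids, rownames(test_bundle$mirna))
  if (length(lnc) < min_lncrna)
    stop("fewer than ", min_lncrna,
         " module lncRNAs present in the test bundle", call. = FALSE)
  if (!length(mr) || !length(mir))
    stop("module mRNAs or shared miRNAs missing from the test bundle",
         call. = FALSE)
  sc <- sensitivity_cc(test_bundle, lnc, mr, mir, dim_cap)
  p <- null_model_pvalue(sc$scc, m = length(lnc), n = length(mr),
                         q = length(mir),
                         n_samples = ncol(test_bundle$mrna),
                         cc_lnc_mr = sc$cc_lnc_mr, n_null = n_null,
                         seed = seed, dim_cap = dim_cap, cache = cache)
  c(sc, list(p = as.numeric(p)))
}
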