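#' Count miRNA sharing between a module's lncRNAs and mRNAs
#'
#' Against the universe of the N1 miRNAs present in the expression data,
#' counts M1 = miRNAs targeting at least one module lncRNA, K1 = miRNAs
#' targeting at least one module mRNA, and L1 = miRNAs doing both (the
#' shared miRNAs that could be sponged).
#'
#' @param lncrna_ids,mrna_ids Module member ids.
#' @param targets A [target_matrix()].
#' @param mirna_universe Character vector of miRNA ids in the expression
#'   data.
#' @return A `sharing_counts` list: `N1`, `M1`, `K1`, `L1`, and the id sets
#'   `mirnas_lncrna`, `mirnas_mrna`, `shared`.
#' @export
sharing_counts <- function(lncrna_ids, mrna_ids, targets, mirna_universe) {
  stopifnot(inherits(targets, "target_matrix"))
  if (!length(mirna_universe)) stop("empty miRNA universe", call. = FALSE)
  if (!length(lncrna_ids) || !length(mrna_ids))
    stop("module needs at least one lncRNA and one mRNA", call. = FALSE)
  mirs <- intersect(rownames(targets$mirna_lncrna), mirna_universe)
  lnc <- intersect(lncrna_ids, colnames(targets$mirna_lncrna))
  mr <- intersect(mrna_ids, colnames(targets$mirna_mrna))
  hit_lnc <- if (length(lnc))
    mirs[rowSums(targets$mirna_lncrna[mirs, lnc, drop = FALSE]) > 0]
  else character()
  hit_mr <- if (length(mr))
    mirs[rowSums(targets$mirna_mrna[mirs, mr, drop = FALSE]) > 0]
  else character()
  shared <- intersect(hit_lnc, hit_mr)
  structure(
    list(N1 = length(mirna_universe), M1 = length(hit_lnc),
         K1 = length(hit_mr), L1 = length(shared),
         mirnas_lncrna = hit_lnc, mirnas_mrna = hit_mr, shared = shared),
    class = "sharing_counts"
  )
}

#' Hypergeometric p-value for miRNA sharing
#'
#' Probability of observing at least L1 shared miRNAs when K1 miRNAs are
#' drawn without replacement from a universe of N1 containing M1
#' lncRNA-targeting miRNAs:
#' `p = 1 - sum_{i=0}^{L1-1} C(M1,i) C(N1-M1, K1-i) / C(N1,K1)`.
#' Computed via the log-gamma-stable hypergeometric tail.
#'
#' @param counts A [sharing_counts()] object.
#' @return Upper-tail p-value (1 when L1 = 0: the sum is empty).
#' @export
hypergeom_sharing_pvalue <- function(counts) {
  stopifnot(inherits(counts, "sharing_counts"))
  with(counts, {
    if (M1 > N1 || K1 > N1)
      stop("M1 and K1 cannot exceed N1", call. = FALSE)
    if (L1 > min(M1, K1))
      stop("L1 exceeds min(M1, K1): sharing counts inconsistent",
           call. = FALSE)
    if (L1 == 0) return(1)
    stats::phyper(L1 - 1, M1, N1 - M1, K1, lower.tail = FALSE)
  })
}

# centre/scale columns and drop-in covariance whitener used by the CCA core
.whiten <- function(s, tol = 1e-10) {
  e <- eigen(s, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, tol)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

# first canonical correlation of two samples x vars matrices (no guard)
.cca_core <- function(x, y) {
  xs <- scale(x)
  ys <- scale(y)
  n <- nrow(xs)
  sxx <- crossprod(xs) / (n - 1)
  syy <- crossprod(ys) / (n - 1)
  sxy <- crossprod(xs, ys) / (n - 1)
  wx <- .whiten(sxx)
  wy <- .whiten(syy)
  m <- crossprod(wx, sxy %*% wy)
  sv <- svd(m, nu = 1, nv = 1)
  cc <- min(max(sv$d[1], 0), 1)
  list(cc = cc, a = as.numeric(wx %*% sv$u), b = as.numeric(wy %*% sv$v))
}

# project a samples x vars matrix onto its top `cap` principal components
.pca_cap <- function(x, cap) {
  xc <- scale(x, scale = FALSE)
  sv <- svd(xc, nu = cap, nv = 0)
  sv$u[, seq_len(cap), drop = FALSE] %*% diag(sv$d[seq_len(cap)], cap)
}

#' First canonical correlation between two variable groups
#'
#' Maximal Pearson correlation `cor(X a, Y b)` over canonical vectors a, b,
#' computed by whitening the within-group covariances and taking the top
#' singular value of the whitened cross-covariance.  When a group has more
#' variables than `dim_cap` (default `floor(n_samples / 3)`), it is first
#' projected onto its top `dim_cap` principal components; without this
#' guard, modules with more genes than samples would trivially reach a
#' canonical correlation of 1.
#'
#' @param x,y Numeric samples x variables matrices on the same samples.
#' @param dim_cap Maximum columns per group before PCA projection; `NULL`
#'   for `floor(n_samples / 3)`.
#' @return A `cc_result` list: `cc` in `[0, 1]`, canonical vectors `a`, `b`
#'   (in the projected coordinates when the guard fired), and `dims`
#'   (effective dimensions used).
#' @export
canonical_correlation <- function(x, y, dim_cap = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (n != nrow(y)) stop("x and y need the same samples", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  for (nm in c("x", "y")) {
    m <- get(nm)
    v <- apply(m, 2, stats::var)
    if (any(v == 0))
      stop("constant column(s) in ", nm, ": ",
           paste(utils::head(which(v == 0), 5), collapse = ", "),
           call. = FALSE)
  }
  if (is.null(dim_cap)) dim_cap <- max(1L, floor(n / 3))
  if (ncol(x) > dim_cap) x <- .pca_cap(x, dim_cap)
  if (ncol(y) > dim_cap) y <- .pca_cap(y, dim_cap)
  res <- .cca_core(x, y)
  structure(list(cc = res$cc, a = res$a, b = res$b,
                 dims = c(ncol(x), ncol(y))),
            class = "cc_result")
}

#' Partial canonical correlation given a conditioning group
#'
#' Removes the (canonical-correlation level) linear influence of the
#' conditioning miRNA group from the lncRNA-mRNA canonical correlation:
#' `pcc = (cc_lnc_mr - cc_mir_mr * cc_mir_lnc) /
#'        sqrt((1 - cc_mir_mr^2) (1 - cc_mir_lnc^2))`.
#'
#' @param cc_lnc_mr Canonical correlation of the lncRNA and mRNA groups.
#' @param cc_mir_mr,cc_mir_lnc Canonical correlations of the shared-miRNA
#'   group with the mRNA and lncRNA groups (must be < 1 in magnitude).
#' @return The partial canonical correlation.
#' @export
partial_cc <- function(cc_lnc_mr, cc_mir_mr, cc_mir_lnc) {
  if (abs(cc_mir_mr) >= 1 || abs(cc_mir_lnc) >= 1)
    stop("partial canonical correlation undefined when a conditioning ",
         "canonical correlation is 1", call. = FALSE)
  (cc_lnc_mr - cc_mir_mr * cc_mir_lnc) /
    sqrt((1 - cc_mir_mr^2) * (1 - cc_mir_lnc^2))
}

# CC/PCC/SCC triple from raw samples x vars matrices (shared by the data
# path and the null-model sampler, so both go through the same estimator)
.scc_from_matrices <- function(x_lnc, y_mr, z_mir, dim_cap = NULL) {
  cc1 <- canonical_correlation(x_lnc, y_mr, dim_cap)$cc
  cc2 <- canonical_correlation(z_mir, y_mr, dim_cap)$cc
  cc3 <- canonical_correlation(z_mir, x_lnc, dim_cap)$cc
  pcc <- partial_cc(cc1, cc2, cc3)
  list(cc_lnc_mr = cc1, cc_mir_mr = cc2, cc_mir_lnc = cc3,
       pcc = pcc, scc = cc1 - pcc)
}

#' Sensitivity canonical correlation of a module
#'
#' Computes the three canonical correlations (lncRNA group vs mRNA group,
#' shared-miRNA group vs mRNA group, shared-miRNA group vs lncRNA group) on
#' the expression data, the partial canonical correlation, and the
#' sensitivity canonical correlation `scc = cc_lnc_mr - pcc`: the part of
#' the lncRNA-mRNA association attributable to the shared miRNAs.  A
#' positive SCC is the signature of miRNA-mediated (sponge) coupling.
#'
#' @param bundle An [expression_bundle()].
#' @param lncrna_ids,mrna_ids Module members.
#' @param mirna_ids The module's shared miRNAs (non-empty).
#' @param dim_cap Passed to [canonical_correlation()].
#' @return List with `cc_lnc_mr`, `cc_mir_mr`, `cc_mir_lnc`, `pcc`, `scc`.
#' @export
sensitivity_cc <- function(bundle, lncrna_ids, mrna_ids, mirna_ids,
                           dim_cap = NULL) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!length(mirna_ids))
    stop("shared miRNA set is empty", call. = FALSE)
  x <- t(bundle$lncrna[lncrna_ids, , drop = FALSE])
  y <- t(bundle$mrna[mrna_ids, , drop = FALSE])
  z <- t(bundle$mirna[mirna_ids, , drop = FALSE])
  .scc_from_matrices(x, y, z, dim_cap)
}

# package-level cache of sorted null SCC samples
.null_cache <- new.env(parent = emptyenv())

# single-factor loading giving a target population canonical correlation
# between groups of m and n equicorrelated unit-variance variables
.loading_for_cc <- function(target_cc, m, n) {
  cc_of <- function(l2)
    l2 / sqrt((l2 + (1 - l2) / m) * (l2 + (1 - l2) / n))
  if (target_cc <= cc_of(1e-8)) return(sqrt(1e-8))
  if (target_cc >= cc_of(1 - 1e-8)) return(sqrt(1 - 1e-8))
  sqrt(stats::uniroot(function(l2) cc_of(l2) - target_cc,
                      c(1e-8, 1 - 1e-8), tol = 1e-10)$root)
}

#' Empirical null-model p-value for an observed SCC
#'
#' Null hypothesis: the miRNAs do not influence the lncRNA-mRNA canonical
#' correlation (true SCC = 0).  Null datasets of the observed shape are
#' sampled: m lncRNAs and n mRNAs loading on one shared latent factor whose
#' loading is tuned so the population canonical correlation matches the
#' observed `cc_lnc_mr` (binned to 0.05), plus q miRNAs as independent
#' standard normals.  The SCC is recomputed on each sampled dataset through
#' the same estimator as the data, and
#' `p = (1 + #\{SCC_null >= observed\}) / (1 + n_null)`.
#' Null distributions are cached per (m, n, q, samples, cc-bin, n_null,
#' seed) so the draws are amortized across modules of the same shape.
#'
#' @param observed_scc The module's SCC.
#' @param m,n,q Numbers of lncRNAs, mRNAs and shared miRNAs.
#' @param n_samples Sample count of the data.
#' @param cc_lnc_mr Observed lncRNA-mRNA canonical correlation (matched by
#'   the null, binned to 0.05).
#' @param n_null Number of sampled null datasets (>= 100).
#' @param seed Integer seed for the null sampler.
#' @param dim_cap Passed to [canonical_correlation()].
#' @param cache Environment used as the null cache; defaults to a
#'   package-level cache.
#' @return Empirical p-value with attribute `"n_null"`.
#' @export
null_model_pvalue <- function(observed_scc, m, n, q, n_samples, cc_lnc_mr,
                              n_null = 1e6, seed = 1L, dim_cap = NULL,
                              cache = .null_cache) {
  if (n_null < 100) stop("n_null must be >= 100", call. = FALSE)
  bin <- min(max(round(cc_lnc_mr * 20) / 20, 0.05), 0.95)
  key <- paste(m, n, q, n_samples, format(bin, nsmall = 2), n_null, seed,
               if (is.null(dim_cap)) "auto" else dim_cap, sep = "_")
  if (is.null(cache[[key]])) {
    nulls <- with_seed(seed, {
      # the observed cc is a sample estimate and biased upward; tune the
      # loading so the null's EXPECTED SAMPLE cc (pilot estimate) matches
      # the bin, else the null sits at a higher effective cc than the data
      lam <- .loading_for_cc(bin, m, n)
      res <- sqrt(1 - lam^2)
      pilot <- vapply(seq_len(200), function(b) {
        f <- stats::rnorm(n_samples)
        x <- lam * f + res * matrix(stats::rnorm(n_samples * m), n_samples)
        y <- lam * f + res * matrix(stats::rnorm(n_samples * n), n_samples)
        canonical_correlation(x, y, dim_cap)$cc
      }, numeric(1))
      target <- min(max(bin - (mean(pilot) - bin), 0.01), 0.99)
      lam <- .loading_for_cc(target, m, n)
      res <- sqrt(1 - lam^2)
      vapply(seq_len(n_null), function(b) {
        f <- stats::rnorm(n_samples)
        x <- lam * f + res * matrix(stats::rnorm(n_samples * m), n_samples)
        y <- lam * f + res * matrix(stats::rnorm(n_samples * n), n_samples)
        z <- matrix(stats::rnorm(n_samples * q), n_samples)
        .scc_from_matrices(x, y, z, dim_cap)$scc
      }, numeric(1))
    })
    cache[[key]] <- sort(nulls)
  }
  nulls <- cache[[key]]
  p <- (1 + sum(nulls >= observed_scc)) / (1 + length(nulls))
  attr(p, "n_null") <- length(nulls)
  p
}

#' Identify lncRNA-related miRNA sponge modules
#'
#' The three-condition screen: a co-expression module is a miRNA sponge
#' module if (1) its lncRNAs and mRNAs share significantly more miRNAs than
#' expected (hypergeometric p < `sharing_alpha`), (2) the lncRNA and mRNA
#' groups are canonically correlated, and (3) the sensitivity canonical
#' correlation is significant against the sampled null model after
#' Benjamini-Hochberg adjustment across tested modules
#' (adj p < `adj_alpha`).  Modules with fewer than `min_lncrna` lncRNAs are
#' dropped before testing.  Results are returned for every candidate
#' module, flagged, not only the passers.
#'
#' @param bundle A preprocessed [expression_bundle()].
#' @param modules A `module_assignment` from [cut_modules()] (or a named
#'   integer label vector over mRNA + lncRNA ids).
#' @param targets A [target_matrix()].
#' @param min_lncrna Minimum lncRNAs per candidate module.
#' @param sharing_alpha Threshold on the raw hypergeometric sharing p.
#' @param adj_alpha Threshold on the BH-adjusted null-model p.
#' @param n_null,seed,dim_cap Passed to [null_model_pvalue()] /
#'   [canonical_correlation()].
#' @param cache Null-distribution cache environment (fresh by default).
#' @return A `sponge_result` list: `summary` (one row per candidate module
#'   with counts, canonical correlations, p-values and the `is_sponge`
#'   flag), `interactions` (extracted ceRNA pairs of flagged modules),
#'   `members` (per-module lncRNA/mRNA/shared-miRNA id sets).
#' @export
identify_sponge_modules <- function(bundle, modules, targets,
                                    min_lncrna = 3, sharing_alpha = 0.05,
                                    adj_alpha = 0.05, n_null = 1e6,
                                    seed = 1L, dim_cap = NULL,
                                    cache = new.env(parent = emptyenv())) {
  labels <- if (inherits(modules, "module_assignment")) modules$labels else
    modules
  universe <- rownames(bundle$mirna)
  mods <- sort(unique(labels[labels > 0]))
  members <- list()
  rows <- list()
  for (k in mods) {
    genes <- names(labels)[labels == k]
    cls <- gene_class(bundle, genes)
    lnc <- genes[cls == "lncrna" & !is.na(cls)]
    mr <- genes[cls == "mrna" & !is.na(cls)]
    if (length(lnc) < min_lncrna || length(mr) < 1) next
    cnt <- sharing_counts(lnc, mr, targets, universe)
    sharing_p <- hypergeom_sharing_pvalue(cnt)
    row <- data.frame(module = k, n_lncrna = length(lnc),
                      n_mrna = length(mr), N1 = cnt$N1, M1 = cnt$M1,
                      K1 = cnt$K1, L1 = cnt$L1, sharing_p = sharing_p,
                      cc_lnc_mr = NA_real_, cc_mir_mr = NA_real_,
                      cc_mir_lnc = NA_real_, pcc = NA_real_,
                      scc = NA_real_, null_p = NA_real_,
                      adj_p = NA_real_, is_sponge = FALSE)
    if (sharing_p < sharing_alpha && cnt$L1 >= 1) {
      sc <- sensitivity_cc(bundle, lnc, mr, cnt$shared, dim_cap)
      row[c("cc_lnc_mr", "cc_mir_mr", "cc_mir_lnc", "pcc", "scc")] <-
        sc[c("cc_lnc_mr", "cc_mir_mr", "cc_mir_lnc", "pcc", "scc")]
      row$null_p <- as.numeric(null_model_pvalue(
        sc$scc, m = length(lnc), n = length(mr), q = cnt$L1,
        n_samples = ncol(bundle$mrna), cc_lnc_mr = sc$cc_lnc_mr,
        n_null = n_null, seed = seed, dim_cap = dim_cap, cache = cache))
    }
    members[[as.character(k)]] <- list(lncrna = lnc, mrna = mr,
                                       shared_mirna = cnt$shared)
    rows[[as.character(k)]] <- row
  }
  if (!length(rows)) {
    warning("no module with >= ", min_lncrna, " lncRNAs", call. = FALSE)
    return(structure(list(summary = data.frame(),
                          interactions = data.frame(), members = list()),
                     class = "sponge_result"))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  tested <- !is.na(summary$null_p)
  summary$adj_p[tested] <- stats::p.adjust(summary$null_p[tested],
                                           method = "BH")
  summary$is_sponge <- summary$n_lncrna >= min_lncrna &
    summary$sharing_p < sharing_alpha &
    !is.na(summary$adj_p) & summary$adj_p < adj_alpha

  inter <- lapply(which(summary$is_sponge), function(i) {
    k <- as.character(summary$module[i])
    ints <- extract_interactions(members[[k]]$lncrna, members[[k]]$mrna,
                                 members[[k]]$shared_mirna, targets)
    if (nrow(ints)) cbind(module = summary$module[i], ints) else NULL
  })
  inter <- do.call(rbind, inter)
  if (is.null(inter))
    inter <- data.frame(module = integer(), lncrna = character(),
                        mrna = character(), mirnas = character())
  structure(list(summary = summary, interactions = inter,
                 members = members),
            class = "sponge_result")
}

#' Extract ceRNA interaction pairs within a sponge module
#'
#' Emits each (lncRNA, mRNA) pair in the module whose members are both
#' targeted by at least one of the module's shared miRNAs, each pair once
#' with the full set of miRNAs it shares.
#'
#' @param lncrna_ids,mrna_ids Module members.
#' @param shared_mirnas The module's shared miRNA ids.
#' @param targets A [target_matrix()].
#' @return data.frame with columns lncrna, mrna, mirnas
#'   (semicolon-joined ids).
#' @export
extract_interactions <- function(lncrna_ids, mrna_ids, shared_mirnas,
                                 targets) {
  stopifnot(inherits(targets, "target_matrix"))
  empty <- data.frame(lncrna = character(), mrna = character(),
                      mirnas = character())
  if (!length(shared_mirnas)) return(empty)
  tl <- targets$mirna_lncrna[shared_mirnas,
                             intersect(lncrna_ids,
                                       colnames(targets$mirna_lncrna)),
                             drop = FALSE]
  tm <- targets$mirna_mrna[shared_mirnas,
                           intersect(mrna_ids,
                                     colnames(targets$mirna_mrna)),
                           drop = FALSE]
  if (!ncol(tl) || !ncol(tm)) return(empty)
  counts <- crossprod(tl, tm)  # lnc x mr: number of shared miRNAs per pair
  hits <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  out <- data.frame(
    lncrna = rownames(counts)[hits[, 1]],
    mrna = colnames(counts)[hits[, 2]],
    mirnas = apply(hits, 1, function(ij)
      paste(shared_mirnas[tl[, ij[1]] == 1 & tm[, ij[2]] == 1],
            collapse = ";")),
    stringsAsFactors = FALSE
  )
  out[order(out$lncrna, out$mrna), , drop = FALSE]
}

#' Rank lncRNAs by ceRNA out-degree
#'
#' Descending count of distinct mRNA partners per lncRNA in an interaction
#' table; ties broken by id.
#'
#' @param interactions data.frame with columns `lncrna`, `mrna` (e.g. from
#'   [extract_interactions()] or a `sponge_result`).
#' @return data.frame with columns lncrna, out_degree.
#' @export
lncrna_outdegree <- function(interactions) {
  if (!nrow(interactions))
    return(data.frame(lncrna = character(), out_degree = integer()))
  deg <- tapply(interactions$mrna, interactions$lncrna,
                function(x) length(unique(x)))
  out <- data.frame(lncrna = names(deg), out_degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$out_degree, out$lncrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
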