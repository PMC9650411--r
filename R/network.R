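#' Signed co-expression similarity
#'
#' Maps the Pearson correlation of every gene pair to `[0, 1]` by the signed
#' linear transformation `s_ij = (1 + r_ij) / 2`, so anti-correlated genes
#' get low similarity instead of high (as they would in an unsigned
#' network).
#'
#' @param expr Numeric genes x samples matrix with unique rownames.
#' @return Symmetric gene x gene similarity matrix with unit diagonal.
#' @export
signed_similarity <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "),
         call. = FALSE)
  s <- (1 + stats::cor(t(expr))) / 2
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Soft-threshold adjacency
#'
#' Raises the signed similarity elementwise to the power beta:
#' `a_ij = s_ij^beta`.  Larger beta suppresses weak similarities and pushes
#' the connectivity distribution towards scale-free topology.
#'
#' @param similarity Output of [signed_similarity()].
#' @param power Soft-threshold exponent beta.
#' @return Adjacency matrix with attribute `"power"`.
#' @export
soft_adjacency <- function(similarity, power) {
  stopifnot(power > 0)
  a <- similarity^power
  diag(a) <- 1
  attr(a, "power") <- power
  a
}

#' Scale-free topology fit index
#'
#' Computes total connectivity `k_i = sum_{j != i} a_ij`, bins k into
#' `n_bins` equal-width bins, and regresses `log10(relative frequency)` on
#' `log10(mean k)` over non-empty bins.  Returns the signed fit index
#' `-sign(slope) * R^2`: close to 1 when frequency decays as a power of k
#' (scale-free), negative when frequency increases with k.
#'
#' @param adjacency Output of [soft_adjacency()].
#' @param n_bins Number of connectivity bins.
#' @return Signed R-squared in `[-1, 1]`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- rowSums(adjacency) - diag(adjacency)
  if (max(k) - min(k) < .Machine$double.eps^0.5)
    stop("all connectivities identical; scale-free fit undefined",
         call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(ok) < 2)
    stop("fewer than 2 non-empty connectivity bins", call. = FALSE)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  unname(-sign(slope) * r2)
}

#' Choose the soft-threshold power by scale-free criterion
#'
#' Returns the smallest candidate power whose signed scale-free fit reaches
#' `r2_cutoff`; if none does, the power with the maximal fit is returned and
#' flagged.
#'
#' @param similarity Output of [signed_similarity()].
#' @param powers Ascending candidate powers.
#' @param r2_cutoff Saturation threshold on the signed R-squared.
#' @param n_bins Bins passed to [scale_free_fit()].
#' @return List with `power`, `saturated` (logical), and `fits`
#'   (data.frame of power and signed R-squared).
#' @export
pick_soft_threshold <- function(similarity, powers = 1:20, r2_cutoff = 0.8,
                                n_bins = 10) {
  stopifnot(length(powers) >= 1, !is.unsorted(powers))
  r2 <- vapply(powers, function(p)
    scale_free_fit(soft_adjacency(similarity, p), n_bins), numeric(1))
  fits <- data.frame(power = powers, r2 = r2)
  hit <- which(r2 >= r2_cutoff)
  if (length(hit)) {
    list(power = powers[hit[1]], saturated = TRUE, fits = fits)
  } else {
    warning("no candidate power reached R^2 >= ", r2_cutoff,
            "; using argmax", call. = FALSE)
    list(power = powers[which.max(r2)], saturated = FALSE, fits = fits)
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, where the sum runs over u != i, j and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1.  Two genes have high overlap when they share network
#' neighbours, which makes 1 - TOM a noise-robust clustering distance.
#'
#' @param adjacency Output of [soft_adjacency()].
#' @return Symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a          # (l)_ij = sum_{u != i,j} a_iu a_uj, diag(a) = 0
  k <- rowSums(a)
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by tree cut on the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the distance 1 - TOM; the
#' dendrogram is cut at `cut_fraction` times its top merge height (the
#' static tree-cut convention), subtrees below the cut are candidate
#' modules, and those smaller than `min_module_size` are assigned the
#' unassigned label 0.  Modules are renumbered 1..K by decreasing size.
#' Unclustered background genes merge in a narrow band just under the top
#' height, so a cut slightly below it isolates them as small subtrees while
#' leaving coherent modules intact.
#'
#' @param tom Output of [topological_overlap()].
#' @param min_module_size Minimum genes per module.
#' @param cut_fraction Fraction of the top merge height at which to cut.
#' @return A `module_assignment`: list with `labels` (named integer vector,
#'   0 = unassigned), `sizes` (table of module sizes) and `cut_height`.
#' @export
cut_modules <- function(tom, min_module_size = 50, cut_fraction = 0.99) {
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    labels <- stats::setNames(integer(nrow(tom)), genes)
    return(structure(list(labels = labels, sizes = integer(),
                          cut_height = NA_real_),
                     class = "module_assignment"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- cut_fraction * max(hc$height)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- stats::setNames(integer(length(raw)), genes)
  if (length(big)) {
    ord <- big[order(-sizes[as.character(big)], big)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  structure(
    list(labels = labels,
         sizes = if (any(labels > 0)) table(labels[labels > 0]) else
           integer(),
         cut_height = h),
    class = "module_assignment"
  )
}

#' Module eigengenes by singular value decomposition
#'
#' For each module, member genes are standardized across samples and the
#' first right-singular vector of the standardized submatrix is taken as
#' the module eigengene (ME), scaled to unit variance and sign-aligned so
#' it correlates positively with the module's mean standardized profile.
#'
#' @param expr Genes x samples matrix covering all assigned genes.
#' @param modules A `module_assignment` (or named integer label vector).
#' @return List with `eigengenes` (modules x samples matrix, rows
#'   `"ME1"`, ...) and `var_explained` (first singular value^2 / total).
#' @export
module_eigengene <- function(expr, modules) {
  labels <- if (inherits(modules, "module_assignment")) modules$labels else
    modules
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  n <- ncol(expr)
  me <- matrix(NA_real_, nrow = length(mods), ncol = n,
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (j in seq_along(mods)) {
    genes <- intersect(names(labels)[labels == mods[j]], rownames(expr))
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))                 # standardize each gene
    if (nrow(xs) == 1) {
      v1 <- as.numeric(xs)
      ve[j] <- 1
    } else {
      sv <- svd(xs, nu = 0, nv = 1)
      v1 <- sv$v[, 1]
      ve[j] <- sv$d[1]^2 / sum(sv$d^2)
    }
    mean_profile <- colMeans(xs)
    if (stats::sd(mean_profile) > 0 &&
        stats::cor(v1, mean_profile) < 0) v1 <- -v1
    me[j, ] <- v1 / stats::sd(v1)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Correlate module eigengenes with numeric traits
#'
#' Pearson correlation of each eigengene with each numeric trait column,
#' with the two-sided p-value from the t distribution on n - 2 degrees of
#' freedom (unadjusted).
#'
#' @param eigengenes Modules x samples ME matrix (from
#'   [module_eigengene()]).
#' @param traits Data.frame of numeric trait columns, one row per sample in
#'   the eigengene column order (non-numeric columns such as `sample_id`
#'   are ignored).
#' @return data.frame with columns module, trait, r, p.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (is.list(eigengenes) && !is.null(eigengenes$eigengenes))
    eigengenes <- eigengenes$eigengenes
  num <- traits[vapply(traits, is.numeric, logical(1))]
  if (!ncol(num)) stop("no numeric trait columns", call. = FALSE)
  const <- vapply(num, function(x) stats::var(x) == 0, logical(1))
  if (any(const))
    stop("constant trait(s): ", paste(names(num)[const], collapse = ", "),
         call. = FALSE)
  n <- ncol(eigengenes)
  out <- expand.grid(module = rownames(eigengenes), trait = names(num),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(m, tr)
    stats::cor(eigengenes[m, ], num[[tr]]), out$module, out$trait)
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out
}
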